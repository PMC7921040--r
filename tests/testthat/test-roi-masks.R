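test_that("pixel-centre containment matches simple geometry", {
  g <- pixel_grid(c(0.25, 0.75, 0.25, 0.75), c(0.25, 0.25, 0.75, 0.75),
                  data.frame(E = 1:4))
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(rasterize_feature(square, g), rep(TRUE, 4))

  expect_error_class(rasterize_feature(rbind(c(0, 0), c(1, 1)), g),
                     "elemap_validation_error")
  expect_warning(m <- rasterize_feature(rbind(c(0, 0), c(1, 1), c(2, 2)), g),
                 class = "elemap_empty_mask_warning")
  expect_false(any(m))
})

test_that("half-open boundary rule: shared edges claim a pixel exactly once", {
  # pixel centres sitting exactly on the shared edge x = 1 and on
  # horizontal edges y = 0 / y = 1
  g <- pixel_grid(c(1, 1, 0.5, 0.5), c(0.5, 0.25, 0, 1),
                  data.frame(E = 1:4))
  left <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  right <- rbind(c(1, 0), c(2, 0), c(2, 1), c(1, 1))
  in_left <- rasterize_feature(left, g)
  in_right <- rasterize_feature(right, g)
  # centres on x = 1 belong to the right square (their left edge) only
  expect_equal(in_left[1:2], c(FALSE, FALSE))
  expect_equal(in_right[1:2], c(TRUE, TRUE))
  # lower edge inside, upper edge outside
  expect_true(in_left[3])
  expect_false(in_left[4])
  expect_true(xor(in_left[1], in_right[1]) || (!in_left[1] && in_right[1]))
})

test_that("rasterization agrees with an independent ray-casting oracle", {
  for (seed in 1:30) {
    with_seed_local(seed, {
      poly <- random_simple_polygon(sample(3:12, 1), centre = runif(2, 1, 4),
                                    r_min = 0.5, r_max = 4)
      gx <- expand.grid(x = seq(-1, 6, by = 0.35), y = seq(-1, 6, by = 0.35))
      g <- pixel_grid(gx$x, gx$y, data.frame(E = seq_len(nrow(gx))))
      impl <- rasterize_feature(poly, g)
      oracle <- ray_cast_oracle(g$coords$x, g$coords$y, poly)
      expect_identical(impl, oracle)
    })
  }
})

test_that("rasterization agrees with mgcv::in.out away from boundaries", {
  skip_if_not_installed("mgcv")
  with_seed_local(5, {
    poly <- random_simple_polygon(10, centre = c(2, 2), r_min = 1, r_max = 3)
    gx <- expand.grid(x = seq(-1, 5, by = 0.17), y = seq(-1, 5, by = 0.17))
    g <- pixel_grid(gx$x, gx$y, data.frame(E = seq_len(nrow(gx))))
    impl <- rasterize_feature(poly, g)
    ref <- mgcv::in.out(rbind(poly, poly[1, ]), cbind(g$coords$x, g$coords$y))
    agree <- mean(impl == ref)
    expect_gte(agree, 0.999)
  })
})

test_that("polyline buffering reproduces the stadium area", {
  L <- 200
  w <- 17.5
  poly <- buffer_polyline(rbind(c(0, 0), c(L, 0)), halfwidth = w)
  area <- abs(sum(poly[, 1] * c(poly[-1, 2], poly[1, 2]) -
                  c(poly[-1, 1], poly[1, 1]) * poly[, 2])) / 2
  expect_equal(area, 2 * w * L + pi * w^2, tolerance = 0.02)

  expect_error_class(buffer_polyline(rbind(c(0, 0), c(1, 0)), 0),
                     "elemap_validation_error")
  expect_error_class(buffer_polyline(rbind(c(1, 1), c(1, 1)), 5),
                     "elemap_validation_error")
})

test_that("derived difference masks obey set identities", {
  n <- 50
  with_seed_local(3, {
    contour <- runif(n) < 0.7
    yolk <- runif(n) < 0.4
  })
  body <- derive_roi_difference(contour, yolk)
  expect_equal(sum(body) + sum(yolk & contour), sum(contour))
  expect_false(any(derive_roi_difference(contour, contour)))
  expect_equal(derive_roi_difference(contour, rep(FALSE, n)), contour)
  expect_error_class(derive_roi_difference(contour, yolk[1:10]),
                     "elemap_shape_error")
})

test_that("build_roi_set assembles contours, derived rules and total", {
  ds <- render_scene(synth_scene(seed = 2))
  ann <- transform_annotations(ds$annotations, ds$scene$annotation_affine)
  rois <- build_roi_set(ann, ds$grid,
                        derived = list(fish_body = list(op = "difference",
                                                        a = "body", b = "yolk"),
                                       eyes = list(op = "union",
                                                   of = c("eye_left", "eye_right"))))
  expect_setequal(rois$order,
                  c("body", "yolk", "eye_left", "eye_right", "notochord",
                    "bladder", "fish_body", "eyes", "total"))
  expect_equal(sum(rois$masks$total), n_pixels(ds$grid))
  expect_equal(sum(rois$masks$fish_body) + sum(rois$masks$yolk & rois$masks$body),
               sum(rois$masks$body))
  # masks recover the planted truth regions exactly
  truth_body <- ds$truth >= 2
  expect_equal(rois$masks$body, truth_body)
  expect_equal(rois$masks$yolk & rois$masks$body, ds$truth == 3)
  expect_equal(rois$masks$eyes & rois$masks$body, ds$truth == 4)

  expect_error_class(
    build_roi_set(ann, ds$grid,
                  derived = list(bad = list(op = "difference",
                                            a = "body", b = "nope"))),
    "elemap_config_error")

  # feature entirely outside the grid: empty mask with a warning, not an error
  far <- annotation_set(list(list(name = "far", kind = "contour",
                                  vertices = rbind(c(9e5, 9e5), c(9.1e5, 9e5),
                                                   c(9e5, 9.1e5)))),
                        1000, 300)
  expect_warning(r2 <- build_roi_set(far, ds$grid),
                 class = "elemap_empty_mask_warning")
  expect_false(any(r2$masks$far))
})

test_that("ROI CSV export and pixel counts are consistent", {
  inst <- random_crosstab_instance(11)
  path <- withr_tempfile(".csv")
  write_roi_csv(inst$rois, path)
  df <- utils::read.csv(path)
  expect_equal(nrow(df), inst$rois$n_pixels * length(inst$rois$order))
  counts <- tapply(df$member, df$roi, sum)
  expect_equal(as.vector(counts[inst$rois$order]),
               as.vector(roi_pixel_counts(inst$rois)))
})
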