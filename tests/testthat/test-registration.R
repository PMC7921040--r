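test_that("landmark fits recover exact affines and flag degenerate input", {
  # identity landmarks
  id <- estimate_affine(data.frame(u = c(0, 1, 0), v = c(0, 0, 1),
                                   x = c(0, 1, 0), y = c(0, 0, 1)))
  expect_equal(unlist(id[c("a11", "a12", "a21", "a22", "tx", "ty")]),
               c(a11 = 1, a12 = 0, a21 = 0, a22 = 1, tx = 0, ty = 0),
               tolerance = 1e-12)
  expect_equal(attr(id, "rms_residual"), 0, tolerance = 1e-12)

  # planted transform (x, y) = (2u + 10, -2v + 500), exactly 3 points
  uv <- data.frame(u = c(0, 7, 3), v = c(0, 2, 9))
  pairs <- transform(uv, x = 2 * u + 10, y = -2 * v + 500)
  T <- estimate_affine(pairs)
  expect_equal(c(T$a11, T$a12, T$a21, T$a22, T$tx, T$ty),
               c(2, 0, 0, -2, 10, 500), tolerance = 1e-9)
  expect_lt(attr(T, "rms_residual"), 1e-9)

  expect_error_class(estimate_affine(pairs[1:2, ]),
                     "elemap_underdetermined_error")
  collinear <- data.frame(u = c(0, 1, 2), v = c(0, 1, 2),
                          x = c(0, 1, 2), y = c(0, 1, 2))
  expect_error_class(estimate_affine(collinear),
                     "elemap_underdetermined_error")
})

test_that("random well-conditioned affines are recovered from noisy-free landmarks", {
  for (seed in 1:25) {
    with_seed_local(seed, {
      T0 <- affine_transform(runif(1, 0.5, 4), runif(1, -1, 1),
                             runif(1, -1, 1), runif(1, 0.5, 4) *
                               sample(c(-1, 1), 1),
                             runif(1, -500, 500), runif(1, -500, 500))
      uv <- matrix(runif(12, 0, 100), ncol = 2)
      xy <- apply_affine(T0, uv)
      T <- estimate_affine(data.frame(u = uv[, 1], v = uv[, 2],
                                      x = xy[, 1], y = xy[, 2]))
      expect_equal(unlist(T[1:6]), unlist(T0[1:6]), tolerance = 1e-9)
    })
  }
})

test_that("extent-based default maps the image rectangle onto the grid box", {
  ann <- annotation_set(list(list(name = "c", kind = "contour",
                                  vertices = rbind(c(0, 0), c(100, 0), c(100, 100)))),
                        image_width = 100, image_height = 100)
  g <- pixel_grid(c(0, 3500, 0, 3500), c(0, 0, 1000, 1000),
                  data.frame(E = 1:4))
  T <- default_transform_from_extents(ann, g, flip_y = FALSE)
  expect_equal(c(T$a11, T$a22, T$a12, T$a21), c(35, 10, 0, 0))
  # flip_y: corners still map to corners, v axis inverted
  Tf <- default_transform_from_extents(ann, g, flip_y = TRUE)
  expect_equal(Tf$a22, -10)
  expect_equal(apply_affine(Tf, rbind(c(0, 0), c(100, 100))),
               rbind(c(0, 1000), c(3500, 0)))

  g_line <- pixel_grid(c(10, 10, 10), c(0, 35, 70), data.frame(E = 1:3))
  expect_error_class(default_transform_from_extents(ann, g_line),
                     "elemap_degeneracy_error")
})

test_that("transform, inversion and composition behave as a group", {
  ann <- annotation_set(list(list(name = "sq", kind = "contour",
                                  vertices = rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))),
                        10, 10)
  # identity leaves vertices unchanged; 2x scale doubles the square side
  ident <- affine_transform()
  expect_equal(transform_annotations(ann, ident)$features$sq$vertices,
               ann$features$sq$vertices)
  sc <- transform_annotations(ann, affine_transform(2, 0, 0, 2, 0, 0))
  expect_equal(max(sc$features$sq$vertices), 2)

  expect_equal(unlist(affine_invert(affine_transform(tx = 5, ty = -3))[1:6]),
               unlist(affine_transform(tx = -5, ty = 3)[1:6]))

  for (seed in 1:20) {
    with_seed_local(seed, {
      T <- affine_transform(runif(1, 0.5, 3), runif(1, -0.5, 0.5),
                            runif(1, -0.5, 0.5), runif(1, 0.5, 3),
                            runif(1, -100, 100), runif(1, -100, 100))
      comp <- affine_compose(T, affine_invert(T))
      expect_equal(unlist(comp[1:6]),
                   c(a11 = 1, a12 = 0, a21 = 0, a22 = 1, tx = 0, ty = 0),
                   tolerance = 1e-9)
      # round trip on annotations
      back <- transform_annotations(transform_annotations(ann, T),
                                    affine_invert(T))
      expect_equal(back$features$sq$vertices, ann$features$sq$vertices,
                   tolerance = 1e-9)
      # double inversion returns the original
      expect_equal(unlist(affine_invert(affine_invert(T))[1:6]),
                   unlist(T[1:6]), tolerance = 1e-9)
    })
  }
})

test_that("affinity is preserved: collinear points stay collinear", {
  for (seed in 1:10) {
    with_seed_local(seed, {
      T <- affine_transform(runif(1, 0.5, 3), runif(1, -1, 1),
                            runif(1, -1, 1), runif(1, 0.5, 3),
                            runif(1, -10, 10), runif(1, -10, 10))
      p <- runif(2)
      q <- runif(2)
      lambda <- runif(1)
      mid <- p + lambda * (q - p)
      img <- apply_affine(T, rbind(p, q, mid))
      cross <- (img[2, 1] - img[1, 1]) * (img[3, 2] - img[1, 2]) -
        (img[2, 2] - img[1, 2]) * (img[3, 1] - img[1, 1])
      expect_equal(cross, 0, tolerance = 1e-9)
    })
  }
})

test_that("singular transforms are rejected and big residuals warn", {
  expect_error_class(affine_transform(1, 1, 1, 1), "elemap_degeneracy_error")
  near <- affine_transform(1, 0, 0, 1e-13)
  expect_error_class(affine_invert(near), "elemap_degeneracy_error")

  pairs <- data.frame(u = c(0, 10, 0, 10), v = c(0, 0, 10, 10),
                      x = c(0, 10, 0, 10), y = c(0, 0, 10, 15))
  expect_warning(estimate_affine(pairs, warn_rms = 0.1),
                 class = "elemap_registration_warning")
})

test_that("transform JSON and landmark CSV readers round trip", {
  T <- affine_transform(3.5, 0, 0, -3.5, 0, 1050)
  path <- withr_tempfile(".json")
  write_transform_json(T, path)
  expect_equal(unlist(read_transform_json(path)[1:6]), unlist(T[1:6]))

  lm_path <- withr_tempfile(".csv")
  utils::write.csv(data.frame(u = 1:3, v = 4:6, x = 7:9, y = 10:12),
                   lm_path, row.names = FALSE)
  lm <- read_landmarks_csv(lm_path)
  expect_equal(names(lm), c("u", "v", "x", "y"))
  expect_equal(lm$x, 7:9)
})
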