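test_that("count_pct matches manual enumeration and the ablation-area semantics", {
  # 10 pixels: 6 in cluster 0, 4 in cluster 1; ROI covers 5 label-0 pixels
  labs <- cluster_labels(c(rep(0L, 6), rep(1L, 4)), "fixture")
  masks <- list(roi = c(rep(TRUE, 5), rep(FALSE, 5)),
                total = rep(TRUE, 10))
  rois <- roi_mask_set(masks, 10)
  m <- count_pct(labs, rois)
  expect_equal(m["0", "roi"], 50)
  expect_equal(m["1", "roi"], 0)
  expect_equal(m[, "total"], c(`0` = 60, `1` = 40))

  one <- cluster_labels(rep(0L, 7), "fixture")
  expect_equal(count_pct(one, roi_mask_set(list(total = rep(TRUE, 7)), 7))[1, 1],
               100)
})

test_that("mean intensity cells equal brute-force means; empty cells are NA", {
  g <- pixel_grid((0:5) * 35, rep(0, 6),
                  data.frame(E = c(10, 20, 30, 40, 50, 60)))
  labs <- cluster_labels(c(0L, 0L, 0L, 1L, 1L, 1L), "fixture")
  rois <- roi_mask_set(list(a = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE),
                            b = rep(FALSE, 6) | c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
                            total = rep(TRUE, 6)), 6)
  m <- mean_intensity(labs, rois, g, "E")
  expect_equal(m["0", "a"], mean(c(10, 20)), tolerance = 1e-12)
  expect_equal(m["1", "a"], 60, tolerance = 1e-12)
  expect_true(is.na(m["0", "b"]))
  expect_equal(m["1", "b"], 50, tolerance = 1e-12)

  # constant map: every nonempty cell equals the constant
  gc <- pixel_grid((0:5) * 35, rep(0, 6), data.frame(E = rep(7, 6)))
  mc <- mean_intensity(labs, rois, gc, "E")
  expect_true(all(mc[!is.na(mc)] == 7))
})

test_that("all layers agree with the per-pixel enumeration oracle on random instances", {
  for (seed in 1:12) {
    inst <- random_crosstab_instance(seed)
    masks <- inst$rois$masks
    lab_vec <- inst$labels$labels
    expect_equal(unname(count_pct(inst$labels, inst$rois)),
                 unname(brute_crosstab(lab_vec, masks, stat = "count_pct")),
                 tolerance = 1e-9)
    expect_equal(unname(mean_intensity(inst$labels, inst$rois, inst$grid, "E")),
                 unname(brute_crosstab(lab_vec, masks, inst$grid$intensity$E,
                                       stat = "mean")),
                 tolerance = 1e-12)
    expect_equal(unname(sum_amount(inst$labels, inst$rois, inst$amounts)),
                 unname(brute_crosstab(lab_vec, masks, inst$amounts,
                                       stat = "sum")),
                 tolerance = 1e-9)
  }
})

test_that("column identity and amount conservation hold", {
  for (seed in 13:20) {
    inst <- random_crosstab_instance(seed)
    n_total <- sum(!is.na(inst$labels$labels))
    cp <- count_pct(inst$labels, inst$rois)
    for (r in inst$rois$order) {
      expect_equal(sum(cp[, r]),
                   100 * sum(inst$rois$masks[[r]]) / n_total,
                   tolerance = 1e-9)
    }
    sa <- sum_amount(inst$labels, inst$rois, inst$amounts)
    expect_equal(sum(sa[, "total"], na.rm = TRUE), sum(inst$amounts),
                 tolerance = 1e-9 * sum(inst$amounts))
    # mean x count = sum cross-check identity
    mi <- mean_intensity(inst$labels, inst$rois, inst$grid, "E")
    ids <- rownames(mi)
    for (i in seq_along(ids)) {
      in_c <- !is.na(inst$labels$labels) &
        inst$labels$labels == as.integer(ids[i])
      for (r in inst$rois$order) {
        cnt <- sum(in_c & inst$rois$masks[[r]])
        if (cnt > 0) {
          expect_equal(mi[i, r] * cnt,
                       sum(inst$grid$intensity$E[in_c & inst$rois$masks[[r]]]),
                       tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("cluster area shares include noise, sort -1 first, and sum to 100", {
  labs <- cluster_labels(c(0L, 0L, 1L, 1L, 1L, -1L), "fixture")
  v <- cluster_area_pct(labs)
  expect_equal(names(v), c("-1", "0", "1"))
  expect_equal(unname(v), c(100 / 6, 200 / 6, 300 / 6), tolerance = 1e-9)

  expect_equal(unname(cluster_area_pct(cluster_labels(rep(0L, 9), "f"))), 100)

  for (seed in 1:10) {
    labs <- with_seed_local(seed, {
      cluster_labels(sample(c(-1L, 0L, 1L, 2L), 37, replace = TRUE), "f")
    })
    expect_equal(sum(cluster_area_pct(labs)), 100, tolerance = 1e-9)
  }
})

test_that("build_heatmap composes the individually computed layers", {
  inst <- random_crosstab_instance(21)
  hm <- build_heatmap(inst$labels, inst$rois, inst$grid,
                      elements = "E", amounts = list(E = inst$amounts))
  expect_s3_class(hm, "elemap_heatmap")
  expect_equal(names(hm$layers),
               c("count_pct", "mean_intensity:E", "sum_amount:E"))
  expect_equal(hm$layers$count_pct, count_pct(inst$labels, inst$rois))
  expect_equal(hm$layers[["mean_intensity:E"]],
               mean_intensity(inst$labels, inst$rois, inst$grid, "E"))
  expect_equal(hm$layers[["sum_amount:E"]],
               sum_amount(inst$labels, inst$rois, inst$amounts))
  expect_equal(dim(hm$layers$count_pct),
               c(length(hm$clusters), length(hm$rois)))
})

test_that("shape mismatches across labels and masks are rejected", {
  labs <- cluster_labels(c(0L, 1L), "fixture")
  rois <- roi_mask_set(list(total = rep(TRUE, 3)), 3)
  expect_error_class(count_pct(labs, rois), "elemap_shape_error")
  expect_error_class(sum_amount(labs, roi_mask_set(list(t = rep(TRUE, 2)), 2),
                                c(1, 2, 3)), "elemap_shape_error")
})
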