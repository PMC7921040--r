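# Shared fixtures and independent oracles, built in code at test time.

# Small deterministic grid: n pixels on an approximate raster, two elements.
tiny_grid <- function(n = 12, seed = 99, elements = c("A", "B")) {
  with_seed_local(seed, {
    nx <- ceiling(sqrt(n))
    xy <- expand.grid(x = (0:(nx - 1)) * 35, y = (0:(nx - 1)) * 35)[1:n, ]
    intensity <- as.data.frame(lapply(elements, function(e) runif(n, 0, 1e5)))
    names(intensity) <- elements
    pixel_grid(xy$x, xy$y, intensity)
  })
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Random simple (star-shaped) polygon around a centre.
random_simple_polygon <- function(n_vertices, centre = c(0, 0),
                                  r_min = 1, r_max = 5) {
  ang <- sort(runif(n_vertices, 0, 2 * pi))
  r <- runif(n_vertices, r_min, r_max)
  cbind(centre[1] + r * cos(ang), centre[2] + r * sin(ang))
}

# Independent per-point ray-casting oracle for the half-open even-odd rule.
# Scalar loop, edges parametrized from their lower endpoint (a different
# arithmetic path than the vectorized implementation).
ray_cast_oracle <- function(px, py, poly) {
  n <- nrow(poly)
  out <- logical(length(px))
  for (p in seq_along(px)) {
    crossings <- 0L
    for (e in seq_len(n)) {
      a <- poly[e, ]
      b <- poly[if (e == n) 1L else e + 1L, ]
      if (a[2] == b[2]) next
      lo <- if (a[2] < b[2]) a else b
      hi <- if (a[2] < b[2]) b else a
      if (py[p] >= lo[2] && py[p] < hi[2]) {
        xc <- lo[1] + (py[p] - lo[2]) * (hi[1] - lo[1]) / (hi[2] - lo[2])
        if (px[p] < xc) crossings <- crossings + 1L
      }
    }
    out[p] <- crossings %% 2L == 1L
  }
  out
}

# Brute-force per-pixel enumeration of the cross-tab layers.
brute_crosstab <- function(labels_vec, masks, values = NULL,
                           stat = c("count_pct", "mean", "sum")) {
  stat <- match.arg(stat)
  ids <- sort(unique(labels_vec[!is.na(labels_vec)]))
  n_total <- sum(!is.na(labels_vec))
  out <- matrix(NA_real_, length(ids), length(masks),
                dimnames = list(ids, names(masks)))
  for (i in seq_along(ids)) {
    for (j in seq_along(masks)) {
      acc <- c()
      for (p in seq_along(labels_vec)) {
        if (!is.na(labels_vec[p]) && labels_vec[p] == ids[i] && masks[[j]][p]) {
          acc <- c(acc, if (is.null(values)) 1 else values[p])
        }
      }
      out[i, j] <- switch(stat,
        count_pct = 100 * length(acc) / n_total,
        mean = if (length(acc)) mean(acc[!is.na(acc)]) else NA_real_,
        sum = if (length(acc)) sum(acc, na.rm = TRUE) else NA_real_)
    }
  }
  if (stat == "count_pct") out[is.na(out)] <- 0
  out
}

# Random labelled instance for cross-tab tests: <= 500 pixels, <= 6 clusters
# (possibly with noise -1), <= 5 overlapping ROIs, plus amounts.
random_crosstab_instance <- function(seed) {
  with_seed_local(seed, {
    n <- sample(20:500, 1)
    k <- sample(1:6, 1)
    labs <- sample(c(-1L, seq_len(k) - 1L), n, replace = TRUE)
    n_roi <- sample(1:5, 1)
    masks <- lapply(seq_len(n_roi), function(i) runif(n) < runif(1, 0.2, 0.9))
    names(masks) <- paste0("roi", seq_len(n_roi))
    masks$total <- rep(TRUE, n)
    vals <- rlnorm(n, log(1e4), 1)
    amts <- runif(n, 0, 2)
    nx <- ceiling(sqrt(n))
    xy <- expand.grid(x = (0:(nx - 1)) * 35, y = (0:(nx - 1)) * 35)[1:n, ]
    grid <- pixel_grid(xy$x, xy$y, data.frame(E = vals))
    list(
      labels = cluster_labels(labs, "fixture"),
      rois = roi_mask_set(masks, n),
      grid = grid,
      amounts = amts
    )
  })
}

# Mid-rank Spearman oracle: ranks by counting, Pearson by the textbook sums.
spearman_oracle <- function(a, b) {
  midrank <- function(v) {
    sapply(seq_along(v), function(i) {
      sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    })
  }
  ra <- midrank(a)
  rb <- midrank(b)
  n <- length(a)
  num <- sum((ra - mean(ra)) * (rb - mean(rb)))
  den <- sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  num / den
}

# Equilateral three-blob feature matrix for elbow tests.
three_blobs <- function(seed, n_per = 100, sep = 10, sd = 1) {
  with_seed_local(seed, {
    ctr <- rbind(c(0, 0), c(sep, 0), c(sep / 2, sep * sqrt(3) / 2))
    do.call(rbind, lapply(1:3, function(i) {
      sweep(matrix(rnorm(2 * n_per, 0, sd), ncol = 2), 2, ctr[i, ], "+")
    }))
  })
}

expect_error_class <- function(expr, class) {
  testthat::expect_error(expr, class = class)
}

withr_tempfile <- function(ext = ".txt") {
  tempfile("elemap-test-", fileext = ext)
}
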