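#' Feature specification for segmentation
#'
#' Which channels feed the clustering: a set of element intensity maps,
#' optionally the stage coordinates, and the per-column scaling.  The
#' default scaling is a z-score (population convention): intensities are in
#' units of 1e4-1e6 cps while coordinates are in 1e2-1e3 um, so unscaled
#' mixing is dominated by whichever unit happens to be larger.  `"none"`
#' reproduces workflows that cluster raw cps plus coordinates, where the
#' intensity channel effectively dominates.
#'
#' @param elements Character vector of element labels to include.
#' @param include_xy Include the stage coordinates as two features.
#' @param scaling `"zscore"` (default) or `"none"`.
#' @export
feature_spec <- function(elements = character(), include_xy = FALSE,
                         scaling = c("zscore", "none")) {
  scaling <- match.arg(scaling)
  if (length(elements) == 0L && !include_xy) {
    stop_elemap("feature spec needs at least one element or include_xy",
                "elemap_config_error")
  }
  structure(list(elements = as.character(elements),
                 include_xy = isTRUE(include_xy), scaling = scaling),
            class = "feature_spec")
}

#' Build the pixels-by-features matrix
#'
#' Pixels with a missing value in any selected element are excluded from the
#' matrix and their indices recorded — they are reported as "excluded"
#' downstream, never silently dropped, and no `NA` ever reaches an
#' algorithm.  Z-scoring uses the population convention (divisor n);
#' constant columns map to all-zeros with a warning.
#'
#' @param grid A [pixel_grid()].
#' @param spec A [feature_spec()].
#' @return List of class `feature_matrix`: `features` (matrix over retained
#'   pixels), `excluded` (integer pixel indices), `columns`, `n_pixels`,
#'   `spec`.
#' @export
build_features <- function(grid, spec) {
  unknown <- setdiff(spec$elements, grid$elements)
  if (length(unknown)) {
    stop_elemap(sprintf("unknown element label(s): %s",
                        paste(unknown, collapse = ", ")),
                "elemap_config_error")
  }
  cols <- lapply(spec$elements, function(el) grid$intensity[[el]])
  names(cols) <- spec$elements
  if (spec$include_xy) {
    cols$x <- grid$coords$x
    cols$y <- grid$coords$y
  }
  X <- do.call(cbind, cols)
  excluded <- which(rowSums(is.na(X)) > 0)
  keep <- setdiff(seq_len(nrow(X)), excluded)
  if (length(keep) == 0L) {
    stop_elemap("all pixels have missing values in the selected elements",
                "elemap_empty_input")
  }
  X <- X[keep, , drop = FALSE]
  if (spec$scaling == "zscore") {
    for (j in seq_len(ncol(X))) {
      mu <- mean(X[, j])
      sdev <- sqrt(mean((X[, j] - mu)^2))
      if (sdev == 0) {
        warn_elemap(sprintf("feature column '%s' is constant; z-score maps it to zeros",
                            colnames(X)[j]), "elemap_constant_feature_warning")
        X[, j] <- 0
      } else {
        X[, j] <- (X[, j] - mu) / sdev
      }
    }
  }
  structure(list(features = X, excluded = excluded,
                 columns = colnames(X), n_pixels = n_pixels(grid),
                 spec = spec),
            class = "feature_matrix")
}

#' Per-pixel segmentation labels
#'
#' Integer label per pixel: `0 .. K-1` for clusters, `-1` for noise/outlier
#' pixels (density-based algorithms), `NA` for pixels excluded because of
#' missing values.  Carries full provenance (algorithm, parameters, seed,
#' feature spec).
#'
#' @param labels Integer vector over all grid pixels.
#' @param algorithm,params,seed,featurespec Provenance.
#' @param converged Did the algorithm converge.
#' @export
cluster_labels <- function(labels, algorithm, params = list(), seed = NULL,
                           featurespec = NULL, converged = TRUE) {
  labels <- as.integer(labels)
  if (any(labels < -1L, na.rm = TRUE)) {
    stop_elemap("labels must be >= -1 (or NA for excluded pixels)",
                "elemap_validation_error")
  }
  if (all(is.na(labels))) {
    stop_elemap("no pixel received a label", "elemap_validation_error")
  }
  if (!any(labels >= 0L, na.rm = TRUE)) {
    warn_elemap("algorithm returned all-noise labels", "elemap_all_noise_warning")
  }
  structure(list(labels = labels, algorithm = algorithm, params = params,
                 seed = seed, featurespec = featurespec,
                 converged = converged),
            class = "cluster_labels")
}

#' @export
print.cluster_labels <- function(x, ...) {
  tab <- table(x$labels, useNA = "ifany")
  cat(sprintf("<cluster_labels> %s, %d pixels (%d excluded)\n",
              x$algorithm, length(x$labels), sum(is.na(x$labels))))
  print(tab)
  invisible(x)
}

cluster_algorithms <- c("kmeans", "meanshift", "affinity_propagation",
                        "spectral", "dbscan", "hdbscan")

require_params <- function(algorithm, params, needed) {
  missing <- setdiff(needed, names(params))
  if (length(missing)) {
    stop_elemap(sprintf("%s requires parameter(s): %s",
                        algorithm, paste(missing, collapse = ", ")),
                "elemap_config_error")
  }
}

#' Segment the map with one of six clustering algorithms
#'
#' Partitioning algorithms: `kmeans` (k-means++ seeding, best of 10
#' restarts), `affinity_propagation`, `spectral` (via \pkg{kernlab}).
#' Density/mode algorithms: `meanshift`, `dbscan`, `hdbscan`; the latter two
#' may emit the noise label `-1`, which is treated as a first-class cluster
#' in all downstream tables.  Identical features, parameters and seed give
#' bit-identical labels.
#'
#' @param features A [build_features()] result (or a bare numeric matrix).
#' @param algorithm One of `"kmeans"`, `"meanshift"`,
#'   `"affinity_propagation"`, `"spectral"`, `"dbscan"`, `"hdbscan"`.
#' @param params Named list of algorithm parameters. Mandatory:
#'   `n_clusters` (kmeans, spectral); `eps`, `min_samples` (dbscan);
#'   `min_cluster_size` (hdbscan). Optional: `bandwidth` (meanshift),
#'   `damping`, `preference` (affinity_propagation), `min_samples`
#'   (hdbscan), `restarts`, `iter_max` (kmeans).
#' @param seed Integer seed for stochastic algorithms.
#' @return A [cluster_labels()].
#' @export
cluster_pixels <- function(features, algorithm, params = list(), seed = NULL) {
  if (!algorithm %in% cluster_algorithms) {
    stop_elemap(sprintf("unknown algorithm '%s'; available: %s", algorithm,
                        paste(cluster_algorithms, collapse = ", ")),
                "elemap_config_error")
  }
  if (is.matrix(features)) {
    features <- structure(list(features = features, excluded = integer(0),
                               columns = colnames(features),
                               n_pixels = nrow(features), spec = NULL),
                          class = "feature_matrix")
  }
  X <- features$features
  fit <- switch(
    algorithm,
    kmeans = {
      require_params("kmeans", params, "n_clusters")
      f <- kmeans_best(X, params$n_clusters, seed = seed,
                       restarts = params$restarts %||% 10L,
                       iter_max = params$iter_max %||% 100L)
      list(labels = f$cluster - 1L, converged = f$converged)
    },
    spectral = {
      require_params("spectral", params, "n_clusters")
      k <- params$n_clusters
      if (k == 1L) {
        list(labels = rep(0L, nrow(X)), converged = TRUE)
      } else {
        sp <- with_seed(seed %||% 0L,
                        kernlab::specc(as.matrix(X), centers = k))
        list(labels = as.integer(sp) - 1L, converged = TRUE)
      }
    },
    dbscan = {
      require_params("dbscan", params, c("eps", "min_samples"))
      dbscan_fit(X, eps = params$eps, min_samples = params$min_samples)
    },
    hdbscan = {
      require_params("hdbscan", params, "min_cluster_size")
      hdbscan_fit(X, min_cluster_size = params$min_cluster_size,
                  min_samples = params$min_samples)
    },
    meanshift = {
      meanshift_fit(X, bandwidth = params$bandwidth)
    },
    affinity_propagation = {
      with_seed(seed %||% 0L,
                affinity_propagation_fit(X,
                                         damping = params$damping %||% 0.5,
                                         preference = params$preference))
    }
  )
  if (!isTRUE(fit$converged)) {
    warn_elemap(sprintf("%s did not converge; labels are the last iterate",
                        algorithm), "elemap_convergence_warning")
  }
  full <- rep(NA_integer_, features$n_pixels)
  full[setdiff(seq_len(features$n_pixels), features$excluded)] <- fit$labels
  cluster_labels(full, algorithm = algorithm, params = params, seed = seed,
                 featurespec = features$spec, converged = isTRUE(fit$converged))
}

#' Choose k for k-means with the elbow rule
#'
#' Runs k-means for each k in `k_min..k_max`, records the within-cluster sum
#' of squares (inertia), and picks the k of maximum curvature: the argmax of
#' the discrete second difference of the inertia curve over interior k.  The
#' full curve is returned so the analyst can override the choice.
#'
#' @param features A [build_features()] result or numeric matrix.
#' @param k_min,k_max Range of cluster counts.
#' @param seed Integer seed.
#' @return List with `chosen_k`, `k`, `inertia`.
#' @export
elbow_k <- function(features, k_min, k_max, seed = NULL) {
  X <- if (inherits(features, "feature_matrix")) features$features else as.matrix(features)
  if (k_min < 1L || k_min > k_max || k_max > nrow(X) - 1L) {
    stop_elemap("need 1 <= k_min <= k_max <= pixels - 1", "elemap_config_error")
  }
  ks <- seq.int(k_min, k_max)
  inertia <- vapply(ks, function(k) {
    kmeans_best(X, k, seed = seed)$tot.withinss
  }, numeric(1))
  chosen <- if (length(ks) < 3L) {
    ks[1]  # no interior point: the elbow is undefined, report k_min
  } else {
    d2 <- inertia[-c(length(ks), length(ks) - 1L)] -
      2 * inertia[-c(1L, length(ks))] + inertia[-c(1L, 2L)]
    ks[which.max(d2) + 1L]
  }
  list(chosen_k = as.integer(chosen), k = ks, inertia = inertia)
}

#' Canonicalize cluster numbering by a reference element
#'
#' Cluster indices from any algorithm are arbitrary; for replicate
#' comparison they are renumbered `0..K-1` in ascending order of the
#' cluster's mean reference-element intensity.  Noise (`-1`) and excluded
#' (`NA`) pixels are preserved.  Ties break by cluster size (descending),
#' then by the original label.
#'
#' @param labels A [cluster_labels()].
#' @param grid The [pixel_grid()] the labels live on.
#' @param ref_element Element label used for ordering.
#' @return A [cluster_labels()] with renumbered labels.
#' @export
canonical_relabel <- function(labels, grid, ref_element) {
  if (!ref_element %in% grid$elements) {
    stop_elemap(sprintf("unknown element '%s'", ref_element),
                "elemap_config_error")
  }
  lab <- labels$labels
  ids <- sort(unique(lab[!is.na(lab) & lab >= 0L]))
  if (length(ids) == 0L) return(labels)
  v <- grid$intensity[[ref_element]]
  means <- vapply(ids, function(c) mean(v[!is.na(lab) & lab == c], na.rm = TRUE),
                  numeric(1))
  sizes <- vapply(ids, function(c) sum(lab == c, na.rm = TRUE), numeric(1))
  ord <- order(means, -sizes, ids)
  new <- lab
  for (j in seq_along(ord)) {
    new[!is.na(lab) & lab == ids[ord[j]]] <- j - 1L
  }
  labels$labels <- new
  labels$params$canonical_ref <- ref_element
  labels
}

#' Export labels as CSV (pixel, x, y, label)
#'
#' Excluded pixels are written with the sentinel label `"excluded"`.
#'
#' @param labels A [cluster_labels()].
#' @param grid The matching [pixel_grid()].
#' @param path Output path.
#' @export
write_labels_csv <- function(labels, grid, path) {
  lab <- as.character(labels$labels)
  lab[is.na(lab)] <- "excluded"
  df <- data.frame(pixel = seq_along(lab),
                   x = grid$coords$x, y = grid$coords$y, label = lab)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
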