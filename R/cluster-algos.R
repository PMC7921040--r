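# Internal clustering algorithm implementations.
#
# k-means delegates its Lloyd iterations to stats::kmeans behind a
# kmeans++-style, best-of-n-restarts wrapper; spectral clustering delegates
# to kernlab::specc.  Mean shift, affinity propagation, DBSCAN and HDBSCAN
# are implemented here directly on dense distance matrices — adequate for
# ablation images of a few thousand pixels.

# kmeans++ initial centres (D^2 sampling).
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centres <- integer(k)
  centres[1] <- sample.int(n, 1L)
  d2 <- rowSums((X - matrix(X[centres[1], ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1L)) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centres[j + 1L] <- sample.int(n, 1L, prob = probs)
    nd <- rowSums((X - matrix(X[centres[j + 1L], ], n, ncol(X), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  X[centres, , drop = FALSE]
}

# Best-of-`restarts` k-means with kmeans++ seeding; returns a stats::kmeans
# fit augmented with $converged.  Seed-derived substreams keep runs
# bit-reproducible.
kmeans_best <- function(X, k, seed = NULL, restarts = 10L, iter_max = 100L) {
  X <- as.matrix(X)
  if (k == 1L) {
    # closed form: one cluster, inertia = total sum of squares about the mean
    ctr <- matrix(colMeans(X), 1L, ncol(X))
    tss <- sum(sweep(X, 2, ctr[1, ])^2)
    return(list(cluster = rep(1L, nrow(X)), centers = ctr,
                tot.withinss = tss, iter = 1L, converged = TRUE))
  }
  if (k >= nrow(X)) restarts <- 1L
  seeds <- derive_seeds(seed %||% 0L, restarts)
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- with_seed(seeds[r], {
      init <- kmeanspp_init(X, k)
      # jitter exact duplicates so stats::kmeans accepts the centres
      if (anyDuplicated(round(init, 12))) {
        init <- init + matrix(stats::rnorm(length(init), 0, 1e-9), nrow(init))
      }
      suppressWarnings(stats::kmeans(X, centers = init, iter.max = iter_max,
                                     algorithm = "Lloyd"))
    })
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best$converged <- best$iter < iter_max
  best
}

# Flat-kernel mean shift.  Bandwidth defaults to the scikit-learn style
# estimate: the mean over points of the distance to their ceil(q * n)-th
# nearest neighbour (q = 0.3).
estimate_bandwidth <- function(D, quantile = 0.3) {
  n <- nrow(D)
  k <- max(1L, ceiling(quantile * n))
  mean(apply(D, 1, function(row) sort(row)[k + 1L]))
}

meanshift_fit <- function(X, bandwidth = NULL, max_iter = 300L, tol = 1e-3) {
  X <- as.matrix(X)
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  bw <- bandwidth %||% estimate_bandwidth(D)
  if (bw <= 0) bw <- mean(D[D > 0]) %||% 1
  modes <- X
  converged <- TRUE
  for (it in seq_len(max_iter)) {
    newm <- modes
    for (i in seq_len(n)) {
      within <- rowSums((X - matrix(modes[i, ], n, ncol(X), byrow = TRUE))^2) <= bw^2
      newm[i, ] <- colMeans(X[within, , drop = FALSE])
    }
    shift <- sqrt(max(rowSums((newm - modes)^2)))
    modes <- newm
    if (shift < tol * bw) break
    if (it == max_iter) converged <- FALSE
  }
  # merge modes closer than the bandwidth, largest basin first
  labels <- rep(NA_integer_, n)
  order_idx <- order(-vapply(seq_len(n), function(i) {
    sum(rowSums((modes - matrix(modes[i, ], n, ncol(X), byrow = TRUE))^2) <= (bw / 2)^2)
  }, numeric(1)))
  centres <- NULL
  for (i in order_idx) {
    if (!is.na(labels[i])) next
    close <- which(rowSums((modes - matrix(modes[i, ], n, ncol(X),
                                           byrow = TRUE))^2) <= bw^2 & is.na(labels))
    lab <- if (is.null(centres)) 0L else nrow(centres)
    labels[close] <- lab
    centres <- rbind(centres, modes[i, ])
  }
  list(labels = labels, converged = converged, bandwidth = bw)
}

# Affinity propagation (Frey & Dueck message passing) on negative squared
# Euclidean similarities; preference defaults to the median similarity.
affinity_propagation_fit <- function(X, damping = 0.5, max_iter = 200L,
                                     convergence_iter = 15L, preference = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n == 1L) return(list(labels = 0L, converged = TRUE))
  S <- -as.matrix(stats::dist(X))^2
  pref <- preference %||% stats::median(S[upper.tri(S)])
  diag(S) <- pref
  # tiny deterministic tie-break noise, as in the reference implementation
  S <- S + 1e-12 * S * matrix(stats::runif(n * n), n, n)
  R <- A <- matrix(0, n, n)
  last_ex <- NULL
  stable <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    AS <- A + S
    max1 <- apply(AS, 1, max)
    which1 <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(n), which1)] <- -Inf
    max2 <- apply(AS2, 1, max)
    Rnew <- S - max1
    Rnew[cbind(seq_len(n), which1)] <- S[cbind(seq_len(n), which1)] - max2
    R <- damping * R + (1 - damping) * Rnew
    # A[i, k] = min(0, R[k, k] + sum_{i' != i, k} max(0, R[i', k]))
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    Anew <- t(pmin(matrix(colSums(Rp), n, n, byrow = FALSE) - t(Rp), 0))
    diag(Anew) <- colSums(pmax(R, 0)) - pmax(diag(R), 0)
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(A + R) > 0)
    if (identical(ex, last_ex)) stable <- stable + 1L else stable <- 0L
    last_ex <- ex
    if (stable >= convergence_iter && length(ex) > 0) {
      converged <- TRUE
      break
    }
  }
  ex <- which(diag(A + R) > 0)
  if (length(ex) == 0L) ex <- which.max(diag(A + R))
  assign_to <- apply(S[, ex, drop = FALSE], 1, which.max)
  assign_to[ex] <- seq_along(ex)
  list(labels = as.integer(assign_to) - 1L, converged = converged,
       exemplars = ex)
}

# Classic DBSCAN; min_samples counts the point itself (scikit-learn
# convention).  Border points join the first core point that reaches them.
dbscan_fit <- function(X, eps, min_samples) {
  X <- as.matrix(X)
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  neighbours <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- lengths(neighbours) >= min_samples
  labels <- rep(-2L, n)  # -2 = unvisited
  cl <- -1L
  for (i in seq_len(n)) {
    if (labels[i] != -2L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- neighbours[[i]]
    while (length(queue)) {
      j <- queue[1]
      queue <- queue[-1]
      if (labels[j] == -2L || labels[j] == -1L) {
        newly <- labels[j] == -2L
        labels[j] <- cl
        if (core[j] && newly) queue <- c(queue, neighbours[[j]])
      }
    }
  }
  labels[labels == -2L] <- -1L
  list(labels = labels, converged = TRUE, core = core)
}

# ---- HDBSCAN ---------------------------------------------------------------
# Campello/Moulavi/Sander hierarchy: mutual-reachability MST, single-linkage
# dendrogram, condensation at min_cluster_size, excess-of-mass selection.
# Points in no selected cluster get label -1.

hdbscan_fit <- function(X, min_cluster_size, min_samples = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  mcs <- as.integer(min_cluster_size)
  ms <- as.integer(min_samples %||% mcs)
  if (mcs < 2L) {
    stop_elemap("min_cluster_size must be >= 2", "elemap_config_error")
  }
  if (n <= mcs) return(list(labels = rep(-1L, n), converged = TRUE))
  D <- as.matrix(stats::dist(X))
  # core distance: distance to the ms-th neighbour, the point counting as
  # its own first neighbour
  core <- apply(D, 1, function(row) sort(row)[min(ms, n)])
  M <- pmax(D, outer(core, rep(1, n)), outer(rep(1, n), core))

  # Prim MST on the dense mutual-reachability graph
  in_tree <- logical(n)
  in_tree[1] <- TRUE
  best_d <- M[1, ]
  best_from <- rep(1L, n)
  edges <- matrix(0, n - 1L, 3L)  # from, to, dist
  for (e in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best_d[cand])]
    edges[e, ] <- c(best_from[j], j, best_d[j])
    in_tree[j] <- TRUE
    upd <- !in_tree & M[j, ] < best_d
    best_from[upd] <- j
    best_d[upd] <- M[j, upd]
  }
  edges <- edges[order(edges[, 3]), , drop = FALSE]

  # single-linkage dendrogram via union-find; node ids: 1..n points,
  # n+1..2n-1 merge nodes
  parent <- seq_len(2L * n - 1L)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  comp_node <- seq_len(n)          # representative dendrogram node per root
  merge_left <- integer(n - 1L)
  merge_right <- integer(n - 1L)
  merge_dist <- numeric(n - 1L)
  merge_size <- integer(n - 1L)
  sizes <- c(rep(1L, n), integer(n - 1L))
  for (e in seq_len(n - 1L)) {
    ra <- find(edges[e, 1]); rb <- find(edges[e, 2])
    node <- n + e
    merge_left[e] <- comp_node[ra]
    merge_right[e] <- comp_node[rb]
    merge_dist[e] <- edges[e, 3]
    sizes[node] <- sizes[comp_node[ra]] + sizes[comp_node[rb]]
    merge_size[e] <- sizes[node]
    parent[ra] <- node
    parent[rb] <- node
    parent[node] <- node
    comp_node[find(node)] <- node
  }

  # condense: walk from the root; spawn a new condensed cluster only when a
  # split leaves two children of size >= mcs
  children_of <- function(node) c(merge_left[node - n], merge_right[node - n])
  dist_of <- function(node) merge_dist[node - n]
  size_of <- function(node) sizes[node]
  leaves_of <- function(node) {
    stack <- node
    out <- integer(0)
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (v <= n) out <- c(out, v) else stack <- c(stack, children_of(v))
    }
    out
  }

  root <- 2L * n - 1L
  cl_parent <- integer(0)    # condensed-tree parent cluster (0 = none)
  cl_birth <- numeric(0)     # lambda at which the cluster appears
  split_mass <- numeric(0)   # stability mass from points passing into children
  pt_cluster <- integer(n)   # condensed cluster each point departs from
  pt_lambda <- numeric(n)    # lambda at which it departs

  new_cluster <- function(parent_id, birth_lambda) {
    cl_parent[length(cl_parent) + 1L] <<- parent_id
    cl_birth[length(cl_birth) + 1L] <<- birth_lambda
    split_mass[length(split_mass) + 1L] <<- 0
    length(cl_parent)
  }
  root_cl <- new_cluster(0L, 0)

  # iterative traversal: stack of (node, cluster id)
  stack_node <- root
  stack_cl <- root_cl
  while (length(stack_node)) {
    node <- stack_node[length(stack_node)]
    cl <- stack_cl[length(stack_cl)]
    stack_node <- stack_node[-length(stack_node)]
    stack_cl <- stack_cl[-length(stack_cl)]
    repeat {
      if (node <= n) {                       # singleton: departs at +Inf
        pt_cluster[node] <- cl
        pt_lambda[node] <- Inf
        break
      }
      lam <- if (dist_of(node) > 0) 1 / dist_of(node) else Inf
      ch <- children_of(node)
      big <- size_of(ch[1]) >= mcs
      big2 <- size_of(ch[2]) >= mcs
      if (big && big2) {                     # true split: two new clusters
        # every point still present departs the parent here, towards a child
        split_mass[cl] <- split_mass[cl] +
          size_of(node) * (min(lam, 1e300) - cl_birth[cl])
        c1 <- new_cluster(cl, lam)
        c2 <- new_cluster(cl, lam)
        stack_node <- c(stack_node, ch[1], ch[2])
        stack_cl <- c(stack_cl, c1, c2)
        break
      } else if (big || big2) {              # small side falls out as noise
        small <- if (big) ch[2] else ch[1]
        lv <- leaves_of(small)
        pt_cluster[lv] <- cl
        pt_lambda[lv] <- lam
        node <- if (big) ch[1] else ch[2]    # continue down the big side
      } else {                               # cluster dissolves entirely
        lv <- leaves_of(node)
        pt_cluster[lv] <- cl
        pt_lambda[lv] <- lam
        break
      }
    }
  }

  n_cl <- length(cl_parent)
  # stability = split mass + sum over noise departures of (lambda_p - birth)
  stability <- split_mass
  for (i in seq_len(n)) {
    c0 <- pt_cluster[i]
    lam <- pt_lambda[i]
    if (!is.finite(lam)) {
      # departures at zero distance (duplicate points): cap at the largest
      # finite departure lambda seen within the cluster
      lam <- max(c(pt_lambda[is.finite(pt_lambda) & pt_cluster == c0],
                   cl_birth[c0]))
    }
    stability[c0] <- stability[c0] + (lam - cl_birth[c0])
  }

  kids <- lapply(seq_len(n_cl), function(i) which(cl_parent == i))
  selected <- logical(n_cl)
  subtree_val <- numeric(n_cl)
  # bottom-up excess-of-mass; root (the all-data cluster) is not selectable
  for (i in rev(seq_len(n_cl))) {
    if (length(kids[[i]]) == 0L) {
      selected[i] <- i != root_cl
      subtree_val[i] <- stability[i]
    } else {
      child_sum <- sum(subtree_val[kids[[i]]])
      if (i == root_cl || child_sum > stability[i]) {
        subtree_val[i] <- child_sum
      } else {
        selected[i] <- TRUE
        subtree_val[i] <- stability[i]
        # deselect all descendants
        stack <- kids[[i]]
        while (length(stack)) {
          v <- stack[length(stack)]
          stack <- stack[-length(stack)]
          selected[v] <- FALSE
          stack <- c(stack, kids[[v]])
        }
      }
    }
  }

  # label: the selected ancestor-or-self of the departure cluster, if any
  sel_of <- integer(n_cl)
  for (i in seq_len(n_cl)) {
    v <- i
    sel_of[i] <- 0L
    while (v != 0L) {
      if (selected[v]) {
        sel_of[i] <- v
        break
      }
      v <- cl_parent[v]
    }
  }
  raw <- sel_of[pt_cluster]
  labels <- rep(-1L, n)
  live <- sort(unique(raw[raw > 0L]))
  for (k in seq_along(live)) labels[raw == live[k]] <- k - 1L
  list(labels = labels, converged = TRUE, n_clusters = length(live))
}
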