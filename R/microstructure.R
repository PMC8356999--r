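# Microstructure-based parcellation: DN voxels described by a 7-metric
# diffusion profile (FA, MD, AD, RD, MK, AK, RK), preprocessed by
# per-feature max normalization and IQR outlier replacement, soft-clustered
# by fuzzy c-means, hardened by maximum membership, and reduced to a
# two-cluster medial/lateral atlas.

#' Assemble the DN voxel-by-metric feature matrix
#'
#' Masks the seven diffusion-metric volumes with the DN and stacks one row
#' per DN voxel, in [mask_indices()] order.
#'
#' @param metrics Named list of seven `ScalarVolume`s; names must include
#'   FA, MD, AD, RD, MK, AK, RK (any order; stored in this canonical
#'   order).
#' @param dn_mask A `LabelVolume`.
#' @param mask_label DN label in `dn_mask` (default 1).
#' @return Object of class `FeatureMatrix`: `values` (n x 7), `voxel_ijk`,
#'   `feature_names`, `grid`.
#' @export
build_feature_matrix <- function(metrics, dn_mask, mask_label = 1L) {
  stopifnot(inherits(dn_mask, "LabelVolume"))
  missing <- setdiff(.METRIC_NAMES, names(metrics))
  if (length(missing))
    stop("missing metric volume(s): ", paste(missing, collapse = ", "))
  metrics <- metrics[.METRIC_NAMES]
  if (!check_same_grid(c(metrics, list(dn_mask)))) stop("grid mismatch")
  mi <- mask_indices(dn_mask, mask_label)
  lin <- attr(mi, "linear")
  vals <- vapply(metrics, function(v) v$values[lin], numeric(length(lin)))
  vals <- matrix(vals, nrow = length(lin),
                 dimnames = list(NULL, .METRIC_NAMES))
  if (any(!is.finite(vals))) stop("non-finite metric values inside the DN mask")
  structure(list(values = vals, voxel_ijk = mi,
                 feature_names = .METRIC_NAMES, grid = dn_mask$grid),
            class = "FeatureMatrix")
}

#' Normalize each feature to its maximum
#'
#' Divides every column by its own maximum over this subject's DN voxels,
#' so each normalized feature has maximum exactly 1 and metrics on very
#' different physical scales become commensurable.
#'
#' @param fm A `FeatureMatrix`.
#' @return The normalized `FeatureMatrix`.
#' @export
normalize_max <- function(fm) {
  mx <- apply(fm$values, 2L, max)
  if (any(mx <= 0))
    stop("cannot normalize all-zero feature column(s): ",
         paste(fm$feature_names[mx <= 0], collapse = ", "))
  fm$values <- sweep(fm$values, 2L, mx, "/")
  fm
}

#' Replace per-feature outliers by the column median (IQR method)
#'
#' Per column, values outside the Tukey fences `[Q1 - k*IQR, Q3 + k*IQR]`
#' are replaced by that column's median; quartiles and the median are
#' computed on the column before any replacement, with linear-interpolation
#' quantiles (R type 7).
#'
#' @param fm A `FeatureMatrix` with at least 4 rows.
#' @param k Fence multiplier (default 1.5).
#' @return The cleaned `FeatureMatrix`.
#' @export
replace_outliers_iqr <- function(fm, k = 1.5) {
  stopifnot(nrow(fm$values) >= 4L)
  fm$values <- apply(fm$values, 2L, function(x) {
    q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2L] - q[1L]
    lo <- q[1L] - k * iqr
    hi <- q[2L] + k * iqr
    x[x < lo | x > hi] <- stats::median(x)
    x
  })
  colnames(fm$values) <- fm$feature_names
  fm
}

#' Fuzzy c-means clustering
#'
#' Minimizes the fuzzy within-cluster objective
#' \deqn{J = \sum_i \sum_j u_{ij}^m \lVert x_i - c_j \rVert^2}
#' by alternating the standard membership and centroid updates
#' \deqn{u_{ij} = 1 / \sum_k (d_{ij}/d_{ik})^{2/(m-1)}, \quad
#'       c_j = \sum_i u_{ij}^m x_i / \sum_i u_{ij}^m}
#' until the objective changes by less than `tol` or `max_iter` is
#' reached. Memberships are initialized as random row-stochastic vectors;
#' `n_restarts` independent starts are run and the solution with the
#' lowest final objective kept. The objective is non-increasing within
#' each run. A point coinciding with one or more centroids receives all
#' its membership on the coincident centroid(s), split equally.
#'
#' @param x A `FeatureMatrix` or plain numeric matrix (rows = points).
#' @param c Number of clusters (>= 2; default 3).
#' @param m Fuzziness exponent (> 1; default 2).
#' @param tol Convergence tolerance on the objective change (default 1e-6).
#' @param max_iter Maximum iterations per restart (default 300).
#' @param seed Integer seed for the random initializations; the global RNG
#'   state is restored on exit.
#' @param n_restarts Number of random restarts (default 5).
#' @return Object of class `FuzzyPartition`: `memberships` (n x c,
#'   row-stochastic), `centroids` (c x p), `objective` (final J),
#'   `objective_trace` (J per iteration of the winning run), `n_iter`.
#' @export
fuzzy_cmeans <- function(x, c = 3L, m = 2, tol = 1e-6, max_iter = 300L,
                         seed = 1L, n_restarts = 5L) {
  X <- if (inherits(x, "FeatureMatrix")) x$values else as.matrix(x)
  n <- nrow(X)
  stopifnot(c >= 2L, m > 1, n >= c, max_iter >= 1L, n_restarts >= 1L)
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(seed)
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    u <- matrix(stats::runif(n * c), n, c)
    u <- u / rowSums(u)
    fit <- fcm_run(X, u, m, tol, max_iter)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  structure(best, class = "FuzzyPartition")
}

fcm_run <- function(X, u, m, tol, max_iter) {
  n <- nrow(X)
  c <- ncol(u)
  trace <- numeric(0L)
  j_prev <- Inf
  d2 <- NULL
  for (it in seq_len(max_iter)) {
    um <- u^m
    ctr <- crossprod(um, X) / colSums(um)      # c x p centroid update
    # squared Euclidean distances point-to-centroid
    d2 <- outer(rowSums(X^2), rep(1, c)) - 2 * X %*% t(ctr) +
      outer(rep(1, n), rowSums(ctr^2))
    d2[d2 < 0] <- 0
    j_now <- sum(um * d2)
    trace <- c(trace, j_now)
    if (is.finite(j_prev) && abs(j_prev - j_now) < tol) {
      u <- fcm_memberships(d2, m)
      j_prev <- j_now
      break
    }
    j_prev <- j_now
    u <- fcm_memberships(d2, m)
  }
  list(memberships = u, centroids = ctr, objective = j_prev,
       objective_trace = trace, n_iter = length(trace))
}

fcm_memberships <- function(d2, m) {
  pow <- 1 / (m - 1)
  inv <- d2^(-pow)                       # Inf where a distance is (near) zero
  s <- rowSums(inv)
  u <- inv / s
  bad <- !is.finite(s)
  if (any(bad)) {
    # degenerate rows: all membership on the coincident centroid(s)
    zb <- !is.finite(inv[bad, , drop = FALSE])
    u[bad, ] <- zb / rowSums(zb)
  }
  u
}

#' Harden a fuzzy partition by maximum membership
#'
#' @param fp A `FuzzyPartition`.
#' @return Integer vector of 1-based cluster labels (argmax membership;
#'   ties go to the lowest cluster index).
#' @export
assign_max_membership <- function(fp) {
  max.col(fp$memberships, ties.method = "first")
}

#' Reduce a 2- or 3-cluster labeling to a named medial/lateral atlas
#'
#' With three nonempty clusters, the pair whose mean feature vectors are
#' closest (single agglomerative step, Euclidean distance) is merged.
#' The two surviving clusters are then named by geometry: the cluster
#' whose voxel centroid lies nearer the mid-sagittal plane (smaller
#' absolute world x) becomes "medial" (label 2), the other "lateral"
#' (label 1). The input affine must place the mid-sagittal plane at world
#' x = 0.
#'
#' @param labels Integer per-voxel cluster labels aligned with `fm` rows.
#' @param fm The `FeatureMatrix` the clustering ran on (supplies both the
#'   feature space for the merge and the voxel geometry for the naming).
#' @param dn_mask Optional `LabelVolume` supplying the output grid
#'   (defaults to the grid carried by `fm`).
#' @return A `LabelVolume` with labels 1 = lateral, 2 = medial.
#' @export
reduce_to_two <- function(labels, fm, dn_mask = NULL) {
  stopifnot(length(labels) == nrow(fm$values))
  grid <- if (is.null(dn_mask)) fm$grid else dn_mask$grid
  present <- sort(unique(labels))
  if (length(present) < 2L) stop("fewer than 2 nonempty clusters")
  if (length(present) > 3L) stop("more than 3 input clusters")
  if (length(present) == 3L) {
    ctr <- t(vapply(present, function(l)
      colMeans(fm$values[labels == l, , drop = FALSE]),
      numeric(ncol(fm$values))))
    d <- as.matrix(stats::dist(ctr))
    diag(d) <- Inf
    pair <- which(d == min(d), arr.ind = TRUE)[1L, ]
    labels[labels == present[pair[2L]]] <- present[pair[1L]]
    present <- sort(unique(labels))
  }
  # name by |world x| of each cluster's voxel centroid
  xs <- world_coords(grid, fm$voxel_ijk)[, 1L]
  cx <- vapply(present, function(l) abs(mean(xs[labels == l])), numeric(1L))
  medial_cluster <- present[which.min(cx)]
  out <- ifelse(labels == medial_cluster, 2L, 1L)
  arr <- array(0L, grid$shape)
  arr[attr(fm$voxel_ijk, "linear")] <- out
  label_volume(arr, grid, c("1" = "lateral", "2" = "medial"))
}

#' Full microstructure parcellation chain for one subject
#'
#' normalize-to-max, IQR outlier replacement, fuzzy c-means (c = 3 by
#' default), maximum-membership assignment, and reduction to the named
#' two-cluster medial/lateral atlas. The preprocessing order
#' (normalize then IQR) can be flipped with `order`.
#'
#' @param metrics Named list of seven `ScalarVolume`s.
#' @param dn_mask DN `LabelVolume`.
#' @param c,m,seed,n_restarts Passed to [fuzzy_cmeans()].
#' @param order `"normalize_first"` (default) or `"iqr_first"`.
#' @return List with `atlas` (two-label `LabelVolume`), `partition`
#'   (`FuzzyPartition`), `labels3` (hardened labels before reduction) and
#'   `features` (the preprocessed `FeatureMatrix`).
#' @export
microstructure_parcellation <- function(metrics, dn_mask, c = 3L, m = 2,
                                        seed = 1L, n_restarts = 5L,
                                        order = c("normalize_first", "iqr_first")) {
  order <- match.arg(order)
  fm <- build_feature_matrix(metrics, dn_mask)
  fm <- if (order == "normalize_first")
    replace_outliers_iqr(normalize_max(fm))
  else normalize_max(replace_outliers_iqr(fm))
  fp <- fuzzy_cmeans(fm, c = c, m = m, seed = seed, n_restarts = n_restarts)
  labels3 <- assign_max_membership(fp)
  atlas <- reduce_to_two(labels3, fm, dn_mask)
  list(atlas = atlas, partition = fp, labels3 = labels3, features = fm)
}
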