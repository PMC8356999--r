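metric_list <- function(vals, grid, lin) {
  # vals: n x 7, rows aligned with sorted linear indices lin
  out <- lapply(1:7, function(m) {
    arr <- array(0, grid$shape)
    arr[lin] <- vals[, m]
    scalar_volume(arr, grid)
  })
  names(out) <- c("FA", "MD", "AD", "RD", "MK", "AK", "RK")
  out
}

test_that("feature matrix carries masked metric values row per voxel", {
  lin <- c(2L, 7L, 20L)
  grid <- tiny_grid()
  vals <- matrix(seq_len(21) / 10, 3, 7)
  vals[1, 1] <- 0.28; vals[1, 5] <- 1.2
  fm <- build_feature_matrix(metric_list(vals, grid, lin), tiny_mask(lin))
  expect_equal(dim(fm$values), c(3L, 7L))
  expect_equal(unname(fm$values[1, "FA"]), 0.28)
  expect_equal(unname(fm$values[1, "MK"]), 1.2)
  expect_equal(nrow(fm$values), nrow(mask_indices(tiny_mask(lin), 1L)))

  expect_error(build_feature_matrix(metric_list(vals, grid, lin)[1:6],
                                    tiny_mask(lin)), "missing metric")
})

test_that("max normalization makes every column peak at exactly 1", {
  lin <- c(1L, 2L)
  fm <- build_feature_matrix(
    metric_list(matrix(c(0.2, 0.4), 2, 7), tiny_grid(), lin), tiny_mask(lin))
  out <- normalize_max(fm)
  expect_equal(out$values[, 1], c(0.5, 1.0))
  expect_true(all(apply(out$values, 2, max) == 1))

  const <- build_feature_matrix(
    metric_list(matrix(3, 2, 7), tiny_grid(), lin), tiny_mask(lin))
  expect_equal(unname(normalize_max(const)$values), matrix(1, 2, 7))

  zero <- build_feature_matrix(
    metric_list(matrix(0, 2, 7), tiny_grid(), lin), tiny_mask(lin))
  expect_error(normalize_max(zero), "all-zero")
})

test_that("IQR outlier replacement uses pre-replacement median and is idempotent", {
  # hand-computed with linear-interpolation quantiles:
  # column (1,2,3,4,100): Q1=2, Q3=4, IQR=2, fences (-1, 7); 100 -> median 3
  lin <- 1:5
  vals <- matrix(c(1, 2, 3, 4, 100), 5, 7)
  grid <- small_grid(c(6L, 4L, 4L))
  mask <- label_volume({a <- array(0L, c(6, 4, 4)); a[lin] <- 1L; a}, grid)
  fm <- build_feature_matrix(metric_list(vals, grid, lin), mask)
  q <- quantile(c(1, 2, 3, 4, 100), c(0.25, 0.75), type = 7)
  expect_equal(unname(q), c(2, 4))
  out <- replace_outliers_iqr(fm)
  expect_equal(out$values[, 1], c(1, 2, 3, 4, 3))
  # idempotent on its own output
  expect_equal(replace_outliers_iqr(out)$values, out$values)

  ok <- fm
  ok$values <- matrix(c(1, 2, 3, 4, 5), 5, 7,
                      dimnames = dimnames(fm$values))
  expect_equal(replace_outliers_iqr(ok)$values, ok$values)
})

test_that("FCM separates well-separated clouds with confident memberships", {
  set.seed(21)
  n <- 60
  mu1 <- rep(0, 7); mu2 <- rep(1, 7) # inter-mean distance sqrt(7) >= 10 sd
  X <- rbind(matrix(rnorm(n * 7, mu1, 0.05), n, 7, byrow = FALSE),
             matrix(rnorm(n * 7, rep(mu2, each = n), 0.05), n, 7))
  fp <- fuzzy_cmeans(X, c = 2, seed = 5)
  expect_true(all(apply(fp$memberships, 1, max) > 0.95))
  ctr <- fp$centroids[order(fp$centroids[, 1]), ]
  expect_true(max(abs(ctr[1, ] - mu1)) < 0.05)
  expect_true(max(abs(ctr[2, ] - mu2)) < 0.05)
  expect_true(max(abs(rowSums(fp$memberships) - 1)) < 1e-9)
})

test_that("a point equidistant from both centroids gets memberships (0.5, 0.5)", {
  # two symmetric clusters around the midpoint; the midpoint itself is
  # equidistant by symmetry of the membership update
  X <- rbind(matrix(rep(c(0, 1), each = 10), ncol = 1), 0.5)
  fp <- fuzzy_cmeans(X, c = 2, m = 2, seed = 3)
  expect_equal(unname(fp$memberships[21, ]), c(0.5, 0.5), tolerance = 1e-6)
})

test_that("the FCM objective is non-increasing on random data", {
  for (rep in 1:20) {
    set.seed(rep)
    X <- matrix(rnorm(40 * 5), 40, 5)
    fp <- fuzzy_cmeans(X, c = 3, seed = rep, n_restarts = 1)
    expect_true(all(diff(fp$objective_trace) <= 1e-9))
  }
})

test_that("FCM agrees with an independent implementation on separated data", {
  skip_if_not_installed("e1071")
  set.seed(8)
  X <- rbind(matrix(rnorm(50 * 3, 0, 0.1), 50, 3),
             matrix(rnorm(50 * 3, 2, 0.1), 50, 3))
  ours <- fuzzy_cmeans(X, c = 2, seed = 1)
  ref <- e1071::cmeans(X, centers = 2, m = 2, iter.max = 300)
  ours_ctr <- ours$centroids[order(ours$centroids[, 1]), ]
  ref_ctr <- ref$centers[order(ref$centers[, 1]), ]
  expect_equal(ours_ctr, ref_ctr, tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("degenerate coincident points concentrate membership on their centroid", {
  X <- rbind(matrix(0, 20, 2), matrix(5, 20, 2))
  fp <- fuzzy_cmeans(X, c = 2, seed = 2)
  # every point coincides with a centroid -> memberships effectively hard
  expect_true(all(apply(fp$memberships, 1, max) > 0.999))
})

test_that("maximum-membership hardening follows argmax with lowest-index ties", {
  fp <- structure(list(memberships = rbind(c(0.7, 0.2, 0.1),
                                           c(0.5, 0.5, 0),
                                           c(0, 0, 1))),
                  class = "FuzzyPartition")
  expect_equal(assign_max_membership(fp), c(1L, 1L, 3L))
  onehot <- structure(list(memberships = diag(3)), class = "FuzzyPartition")
  expect_equal(assign_max_membership(onehot), 1:3)
})

test_that("three clusters reduce by merging the closest centroid pair", {
  grid <- small_grid(c(10L, 4L, 4L))
  n <- 30
  lin <- 1:n
  mask <- label_volume({a <- array(0L, c(10, 4, 4)); a[lin] <- 1L; a}, grid)
  # clusters A and B nearly coincide in feature space; C is far away
  vals <- rbind(matrix(0.00, 10, 7), matrix(0.08, 10, 7), matrix(1, 10, 7))
  fm <- build_feature_matrix(metric_list(vals, grid, lin), mask)
  # derive labels from the features themselves so they align with fm rows
  labels <- ifelse(fm$values[, 1] > 0.5, 3L, ifelse(fm$values[, 1] > 0.04, 2L, 1L))
  out <- reduce_to_two(labels, fm, mask)
  merged <- out$labels[attr(fm$voxel_ijk, "linear")]
  expect_equal(length(unique(merged[labels != 3L])), 1L) # A,B merged
  expect_true(all(merged[labels == 3L] != merged[labels == 1L][1]))

  # two-cluster input: only medial/lateral renaming applies
  two <- reduce_to_two(rep(1:2, 15), fm, mask)
  expect_setequal(unique(two$labels[lin]), 1:2)
  expect_error(reduce_to_two(rep(1L, n), fm, mask), "fewer than 2")
})

test_that("the full chain recovers a planted medial/lateral truth", {
  spec <- small_spec()
  ph <- make_dn_phantom(spec, "right")
  set.seed(4)
  mets <- simulate_metrics(ph$truth_micro, spec)
  res <- microstructure_parcellation(mets, ph$dn_mask, seed = 9)
  sel <- ph$dn_mask$labels == 1L
  acc <- mean(res$atlas$labels[sel] == ph$truth_micro$labels[sel])
  expect_gte(acc, 0.95)
})

test_that("voxel-order permutation leaves the named parcellation unchanged", {
  spec <- small_spec()
  ph <- make_dn_phantom(spec, "right")
  set.seed(6)
  mets <- simulate_metrics(ph$truth_micro, spec)
  fm <- replace_outliers_iqr(normalize_max(build_feature_matrix(mets, ph$dn_mask)))
  perm <- sample(nrow(fm$values))
  fmp <- fm
  fmp$values <- fm$values[perm, ]
  fmp$voxel_ijk <- structure(fm$voxel_ijk[perm, ],
                             linear = attr(fm$voxel_ijk, "linear")[perm])
  a1 <- reduce_to_two(assign_max_membership(fuzzy_cmeans(fm, seed = 2)), fm)
  a2 <- reduce_to_two(assign_max_membership(fuzzy_cmeans(fmp, seed = 2)), fmp)
  expect_identical(a1$labels, a2$labels)
})
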