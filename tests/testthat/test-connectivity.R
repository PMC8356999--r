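test_that("membership vectors copy masked counts voxel for voxel", {
  lin <- 5L
  f <- build_membership_field(tiny_counts(lin, list(5L, 0L, 2L)), tiny_mask(lin))
  expect_equal(dim(f$counts), c(1L, 3L))
  expect_equal(as.vector(f$counts), c(5L, 0L, 2L))

  lin <- c(1L, 6L, 11L, 16L)
  cms <- tiny_counts(lin, list(rep(0L, 4), rep(0L, 4)))
  f0 <- build_membership_field(cms, tiny_mask(lin))
  expect_true(all(f0$counts == 0L))

  # sum over the field equals a brute-force sum of masked raw counts
  set.seed(3)
  lin <- sort(sample(24L, 9L))
  per <- lapply(1:3, function(t) sample(0:9, 9, replace = TRUE))
  cms <- tiny_counts(lin, per)
  f <- build_membership_field(cms, tiny_mask(lin))
  expect_equal(nrow(f$counts), 9L)
  brute <- sum(vapply(cms$counts, function(a) sum(a[lin]), numeric(1)))
  expect_equal(sum(f$counts), brute)

  other <- tiny_counts(lin, per, shape = c(5L, 3L, 2L))
  expect_error(build_membership_field(other, tiny_mask(lin)), "grid mismatch")
})

test_that("winner-takes-all follows the argmax, unassigned and tie rules", {
  lin <- c(2L, 3L, 4L)
  cms <- tiny_counts(lin, list(c(5L, 0L, 3L), c(1L, 0L, 3L), c(0L, 0L, 0L)))
  f <- build_membership_field(cms, tiny_mask(lin))
  low <- winner_takes_all(f, "lowest_index")
  expect_equal(low$labels[lin], c(1L, 0L, 1L)) # (5,1,0)->1; zeros->0; tie->1
  una <- winner_takes_all(f, "unassigned")
  expect_equal(una$labels[lin], c(1L, 0L, 0L)) # tie -> unassigned
  expect_true(all(low$labels[-lin] == 0L))
})

test_that("winner-takes-all matches a per-voxel argmax oracle and scales freely", {
  for (rep in 1:20) {
    set.seed(rep)
    n_t <- sample(3:6, 1)
    lin <- sort(sample(24L, 20L))
    per <- lapply(seq_len(n_t), function(t) sample(0:20, 20, replace = TRUE))
    f <- build_membership_field(tiny_counts(lin, per), tiny_mask(lin))
    wta <- winner_takes_all(f)
    oracle <- apply(f$counts, 1L, function(v) {
      if (all(v == 0)) 0L else which.max(v)
    })
    expect_equal(wta$labels[attr(f$voxel_ijk, "linear")], as.integer(oracle))
    # invariance to multiplying all counts by a positive constant
    f3 <- f
    f3$counts <- f$counts * 7L
    expect_identical(winner_takes_all(f3)$labels, wta$labels)
  }
})

test_that("distribution maps are per-voxel count fractions summing to 0 or 1", {
  lin <- c(2L, 3L)
  cms <- tiny_counts(lin, list(c(5L, 0L), c(0L, 0L), c(5L, 0L)))
  dm <- distribution_maps(build_membership_field(cms, tiny_mask(lin)))
  expect_equal(vapply(dm, function(v) v$values[2L], numeric(1)),
               c(T1 = 0.5, T2 = 0, T3 = 0.5))
  expect_equal(vapply(dm, function(v) v$values[3L], numeric(1)),
               c(T1 = 0, T2 = 0, T3 = 0)) # no counts at all -> all zero

  # single-target counts give a map of ones on connected voxels;
  # per-voxel sums over targets are exhaustively in {0, 1}
  set.seed(11)
  lin <- sort(sample(24L, 15L))
  per <- lapply(1:4, function(t) sample(0:5, 15, replace = TRUE))
  f <- build_membership_field(tiny_counts(lin, per), tiny_mask(lin))
  dm <- distribution_maps(f)
  sums <- Reduce(`+`, lapply(dm, function(v) v$values))
  expect_true(all(abs(sums[lin][rowSums(f$counts) > 0] - 1) < 1e-12))
  expect_true(all(sums[rowSums(f$counts) == 0] == 0 | abs(sums - 1) < 1e-12))

  one <- build_membership_field(tiny_counts(lin, per[1]), tiny_mask(lin))
  m1 <- distribution_maps(one)[[1]]$values[lin]
  expect_true(all(m1[per[[1]] > 0] == 1))
})

test_that("parcel summaries add to 100% and match brute-force totals", {
  lin <- c(1L, 2L, 3L, 4L)
  cms <- tiny_counts(lin, list(c(0L, 1L, 0L, 2L), c(9L, 8L, 7L, 6L), c(0L, 0L, 0L, 0L)))
  f <- build_membership_field(cms, tiny_mask(lin))
  s <- summarize_parcellation(f, winner_takes_all(f))
  expect_equal(s$volume_pct, c(0, 100, 0)) # all four voxels won by target 2
  expect_equal(s$total_streamlines, c(3, 30, 0))

  for (rep in 1:20) {
    set.seed(100 + rep)
    lin <- sort(sample(24L, 12L))
    per <- lapply(1:4, function(t) sample(0:8, 12, replace = TRUE))
    cms <- tiny_counts(lin, per)
    f <- build_membership_field(cms, tiny_mask(lin))
    atlas <- winner_takes_all(f)
    s <- summarize_parcellation(f, atlas)
    expect_equal(s$total_streamlines,
                 vapply(cms$counts, function(a) sum(a[lin]), numeric(1)),
                 ignore_attr = TRUE)
    brute_pct <- vapply(1:4, function(t)
      100 * sum(atlas$labels[lin] == t) / 12, numeric(1))
    expect_equal(s$volume_pct, brute_pct)
    expect_equal(sum(s$volume_pct) + attr(s, "unassigned_pct"), 100)
  }
})

test_that("fractions in a four-voxel field are multiples of 25 percent", {
  lin <- c(1L, 2L, 3L, 4L)
  cms <- tiny_counts(lin, list(c(4L, 1L, 0L, 0L), c(1L, 5L, 3L, 0L), c(0L, 0L, 1L, 9L)))
  f <- build_membership_field(cms, tiny_mask(lin))
  s <- summarize_parcellation(f, winner_takes_all(f))
  expect_equal(s$volume_pct, c(25, 50, 25))
  expect_true(all(s$volume_pct %% 25 == 0))
})

test_that("retention reproduces the published cerebellar and thalamic filters", {
  cere <- data.frame(
    target = c("I-VI", "CrusI-II", "VIIb", "VIIIa", "VIIIb", "IX-X"),
    total_streamlines = c(18.9, 38.0, 9.2, 2.7, 2.0, 11.8) * 1000,
    volume_pct = c(28.9, 39.5, 8.0, 3.0, 4.2, 16.4))
  kept <- apply_retention(cere, retention_thresholds(10000, 15))
  expect_setequal(kept$target[kept$retained], c("I-VI", "CrusI-II", "IX-X"))

  thal <- data.frame(
    target = c("motor", "prefrontal", "sensory", "posterior-parietal",
               "occipital", "temporal"),
    total_streamlines = c(330, 390, 50, 60, 1, 30),
    volume_pct = c(45.9, 44.8, 3.8, 4.7, 0.1, 0.7))
  kept <- apply_retention(thal, retention_thresholds(300, 40))
  expect_setequal(kept$target[kept$retained], c("motor", "prefrontal"))

  all_in <- apply_retention(thal, retention_thresholds(0, 0))
  expect_true(all(all_in$retained == (thal$total_streamlines > 0 & thal$volume_pct > 0)))
})
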