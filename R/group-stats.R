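# Cohort summaries and nonparametric tests: per-parcel metric means,
# paired left/right Wilcoxon signed-rank, across-parcel Friedman, and
# two-group Mann-Whitney comparisons. All tests are two-sided at the
# conventional alpha = 0.05; no multiple-testing correction is applied (a
# deliberate caveat, see the methods vignette).

#' Mean of a metric within each parcel of an atlas
#'
#' @param atlas A `LabelVolume`.
#' @param metric A `ScalarVolume` on the same grid.
#' @return Named numeric vector of per-parcel means over every nonzero
#'   dictionary label (names = parcel names); `NA` for empty parcels.
#' @export
parcel_metric_means <- function(atlas, metric) {
  stopifnot(inherits(atlas, "LabelVolume"), inherits(metric, "ScalarVolume"))
  if (!check_same_grid(list(atlas, metric))) stop("grid mismatch")
  labs <- as.integer(names(atlas$label_names))
  out <- vapply(labs, function(l) {
    sel <- atlas$labels == l
    if (!any(sel)) return(NA_real_)
    mean(metric$values[sel])
  }, numeric(1L))
  stats::setNames(out, unname(atlas$label_names))
}

# Exact permutation distributions over (doubled) midranks by convolution.
# Base R's wilcox.test cannot compute exact p values in the presence of
# ties; these small dynamic programs can, at negligible cost for the
# cohort sizes involved (n <= 25).
signrank_pmf <- function(r2) {
  tot <- sum(r2)
  f <- numeric(tot + 1L)
  f[1L] <- 1
  for (r in r2) {
    g <- f
    g[(r + 1L):(tot + 1L)] <- g[(r + 1L):(tot + 1L)] + f[1L:(tot - r + 1L)]
    f <- g
  }
  f / 2^length(r2)
}

ranksum_pmf <- function(r2, na) {
  tot <- sum(r2)
  dp <- matrix(0, na + 1L, tot + 1L)
  dp[1L, 1L] <- 1
  for (r in r2) {
    for (k in seq(min(na, nrow(dp) - 1L), 1L)) {
      dp[k + 1L, (r + 1L):(tot + 1L)] <-
        dp[k + 1L, (r + 1L):(tot + 1L)] + dp[k, 1L:(tot - r + 1L)]
    }
  }
  dp[na + 1L, ] / choose(length(r2), na)
}

two_sided_p <- function(pmf, obs2) {
  p_le <- sum(pmf[seq_len(obs2 + 1L)])
  p_ge <- sum(pmf[(obs2 + 1L):length(pmf)])
  min(1, 2 * min(p_le, p_ge))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test for paired samples (e.g. left vs right DN
#' features across subjects). Zero differences are dropped; the p value is
#' exact (full sign-flip permutation distribution, ties handled by
#' midranks) for up to 25 informative pairs, and a tie-corrected normal
#' approximation beyond that. All pairs equal yields p = 1 with a warning.
#'
#' @param x,y Equal-length numeric vectors (>= 5 pairs).
#' @return List with `statistic` (V, the positive-rank sum) and `p.value`.
#' @export
wilcoxon_paired <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 5L)
  d <- x - y
  d <- d[d != 0]
  if (!length(d)) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = 0, p.value = 1))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (length(d) <= 25L) {
    r2 <- as.integer(round(2 * r))
    p <- two_sided_p(signrank_pmf(r2), as.integer(round(2 * v)))
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE,
                         alternative = "two.sided"))
    p <- ht$p.value
  }
  list(statistic = v, p.value = p)
}

#' Friedman test across parcels
#'
#' Tests whether a feature differs across parcels, subjects acting as
#' blocks: chi-square statistic on tie-corrected within-subject ranks with
#' k - 1 degrees of freedom. Data with no within-subject variation at all
#' (every row constant) carry no rank information and return statistic 0,
#' p = 1 with a warning.
#'
#' @param tab Numeric matrix or data frame, subjects x parcels, complete.
#' @return List with `statistic`, `df` and `p.value`.
#' @export
friedman_parcels <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(ncol(tab) >= 2L, nrow(tab) >= 5L, all(is.finite(tab)))
  if (all(apply(tab, 1L, function(r) max(r) == min(r)))) {
    warning("no within-subject variation; p = 1")
    return(list(statistic = 0, df = ncol(tab) - 1L, p.value = 1))
  }
  ht <- stats::friedman.test(tab)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value)
}

#' Mann-Whitney U test between two groups
#'
#' Two-sided rank-sum comparison (e.g. females vs males). The p value is
#' exact (full labeling permutation distribution, ties handled by
#' midranks) when the combined sample size is at most 25, and a
#' tie-corrected normal approximation otherwise.
#'
#' @param a,b Numeric vectors, each of length >= 3.
#' @return List with `statistic` (U for the first group) and `p.value`.
#' @export
mann_whitney_groups <- function(a, b) {
  stopifnot(length(a) >= 3L, length(b) >= 3L)
  na <- length(a)
  pool <- c(a, b)
  r <- rank(pool)
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (length(pool) <= 25L) {
    r2 <- as.integer(round(2 * r))
    pmf <- ranksum_pmf(r2, na)
    w2 <- as.integer(round(2 * sum(r[seq_len(na)])))
    p <- two_sided_p(pmf, w2)
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE,
                         alternative = "two.sided"))
    p <- ht$p.value
  }
  list(statistic = u, p.value = p)
}

#' Per-subject feature table for a cohort of parcellations
#'
#' Convenience builder for cohort-level testing: one row per subject, one
#' column per target for streamline totals (`streamlines_<target>`) and
#' volume percentages (`volume_pct_<target>`), plus an optional `sex`
#' column.
#'
#' @param summaries List of `ParcelSummary` data frames, one per subject.
#' @param sex Optional per-subject character/factor vector.
#' @return Data frame with `subject` as first column.
#' @export
subject_feature_table <- function(summaries, sex = NULL) {
  stopifnot(length(summaries) >= 1L)
  targets <- summaries[[1L]]$target
  rows <- lapply(seq_along(summaries), function(i) {
    s <- summaries[[i]]
    stopifnot(identical(s$target, targets))
    vals <- c(stats::setNames(s$total_streamlines, paste0("streamlines_", s$target)),
              stats::setNames(s$volume_pct, paste0("volume_pct_", s$target)))
    as.data.frame(as.list(vals), check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(subject = seq_along(summaries), out)
  if (!is.null(sex)) out$sex <- as.character(sex)
  out
}
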