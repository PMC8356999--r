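# Connectivity-based parcellation: per-voxel membership vectors from
# track-density maps, winner-takes-all assignment, distribution
# connectivity maps, retention filtering and streamline/volume summaries.

#' Build the per-voxel membership field
#'
#' Masks a set of track-density maps with the DN and collects, for every
#' DN voxel, the membership vector: one streamline count per connectivity
#' target. Rows follow [mask_indices()] order.
#'
#' @param tdi A `CountMapSet`.
#' @param dn_mask A `LabelVolume`; voxels with `mask_label` form the DN.
#' @param mask_label Label selecting DN voxels in `dn_mask` (default 1).
#' @return Object of class `MembershipField`: `counts` (n_voxels x
#'   n_targets integer matrix), `voxel_ijk`, `target_names`, `grid`.
#' @export
build_membership_field <- function(tdi, dn_mask, mask_label = 1L) {
  stopifnot(inherits(tdi, "CountMapSet"), inherits(dn_mask, "LabelVolume"))
  if (!check_same_grid(list(tdi, dn_mask))) stop("grid mismatch")
  mi <- mask_indices(dn_mask, mask_label)
  if (nrow(mi) == 0L) stop("DN mask is empty")
  lin <- attr(mi, "linear")
  counts <- vapply(tdi$counts, function(a) a[lin], integer(length(lin)))
  counts <- matrix(as.integer(counts), nrow = length(lin),
                   dimnames = list(NULL, tdi$target_names))
  structure(list(counts = counts, voxel_ijk = mi,
                 target_names = tdi$target_names, grid = tdi$grid),
            class = "MembershipField")
}

#' Winner-takes-all parcellation of the DN
#'
#' Assigns each DN voxel the 1-based index of its maximal membership
#' component. Voxels with an all-zero membership vector are unassigned
#' (label 0), as are voxels outside the DN. Ties are resolved by
#' `tie_policy`: `"lowest_index"` (default, deterministic) keeps the first
#' maximal target; `"unassigned"` labels tied voxels 0.
#'
#' @param field A `MembershipField`.
#' @param tie_policy `"lowest_index"` or `"unassigned"`.
#' @return A `LabelVolume` whose label dictionary maps indices to target
#'   names.
#' @export
winner_takes_all <- function(field, tie_policy = c("lowest_index", "unassigned")) {
  tie_policy <- match.arg(tie_policy)
  cnt <- field$counts
  best <- max.col(cnt, ties.method = "first")
  mx <- cnt[cbind(seq_len(nrow(cnt)), best)]
  lab <- best
  lab[mx == 0L] <- 0L
  if (tie_policy == "unassigned") {
    n_max <- rowSums(cnt == mx)
    lab[n_max > 1L & mx > 0L] <- 0L
  }
  arr <- array(0L, field$grid$shape)
  arr[attr(field$voxel_ijk, "linear")] <- lab
  label_volume(arr, field$grid,
               stats::setNames(field$target_names,
                               as.character(seq_along(field$target_names))))
}

#' Distribution connectivity maps
#'
#' For each target, the per-voxel fraction of that voxel's total count
#' carried by the target: `counts[v, t] / sum_t counts[v, t]`, 0 where the
#' voxel has no counts at all. Per-voxel sums over targets are exactly 1
#' wherever any count is positive.
#'
#' @param field A `MembershipField`.
#' @return Named list of `ScalarVolume`s, one per target.
#' @export
distribution_maps <- function(field) {
  cnt <- field$counts
  tot <- rowSums(cnt)
  frac <- cnt / ifelse(tot > 0, tot, 1)
  lin <- attr(field$voxel_ijk, "linear")
  out <- lapply(seq_along(field$target_names), function(t) {
    arr <- array(0, field$grid$shape)
    arr[lin] <- frac[, t]
    scalar_volume(arr, field$grid)
  })
  names(out) <- field$target_names
  out
}

#' Per-target streamline totals and won-volume fractions
#'
#' Totals are DN-masked sums of the raw counts; volume fractions are the
#' percentage of DN voxels won by each target in `atlas`. Unassigned
#' voxels count in the denominator but in no target's numerator, so target
#' fractions plus the unassigned fraction sum to exactly 100.
#'
#' @param field A `MembershipField`.
#' @param atlas `LabelVolume` produced from `field` by
#'   [winner_takes_all()].
#' @return Data frame (class `ParcelSummary`) with columns `target`,
#'   `total_streamlines`, `volume_pct`, `retained` (NA until
#'   [apply_retention()]), plus attribute `unassigned_pct`.
#' @export
summarize_parcellation <- function(field, atlas) {
  stopifnot(inherits(field, "MembershipField"), inherits(atlas, "LabelVolume"))
  lin <- attr(field$voxel_ijk, "linear")
  lab <- atlas$labels[lin]
  n_t <- length(field$target_names)
  won <- tabulate(lab, nbins = n_t)
  out <- data.frame(
    target = field$target_names,
    total_streamlines = colSums(field$counts),
    volume_pct = 100 * won / nrow(field$counts),
    retained = NA,
    row.names = NULL)
  attr(out, "unassigned_pct") <- 100 * sum(lab == 0L) / nrow(field$counts)
  class(out) <- c("ParcelSummary", "data.frame")
  out
}

#' Retention thresholds for parcellations
#'
#' @param min_streamlines Minimum total streamline count (strict).
#' @param min_volume_pct Minimum volume percentage of the DN (strict), on
#'   the same 0-100 scale as `ParcelSummary$volume_pct`.
#' @return Object of class `RetentionThresholds`.
#' @export
retention_thresholds <- function(min_streamlines, min_volume_pct) {
  stopifnot(min_streamlines >= 0, min_volume_pct >= 0)
  structure(list(min_streamlines = min_streamlines,
                 min_volume_pct = min_volume_pct),
            class = "RetentionThresholds")
}

#' Apply retention thresholds to a parcel summary
#'
#' A target is retained iff its total streamline count strictly exceeds
#' `min_streamlines` AND its volume percentage strictly exceeds
#' `min_volume_pct` (the filter is a conjunction with strict inequalities,
#' matching "more than N streamlines ... and volume > x%").
#'
#' @param summary A `ParcelSummary` (or data frame with
#'   `total_streamlines` and `volume_pct` columns).
#' @param thr A `RetentionThresholds`.
#' @return The summary with its logical `retained` column filled; the
#'   retained target set is `summary$target[summary$retained]`.
#' @export
apply_retention <- function(summary, thr) {
  stopifnot(inherits(thr, "RetentionThresholds"))
  summary$retained <- summary$total_streamlines > thr$min_streamlines &
    summary$volume_pct > thr$min_volume_pct
  summary
}
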