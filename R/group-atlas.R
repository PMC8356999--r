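# Inter-subject group atlases: voxel-wise mode of categorical labels
# across subjects, plus per-label probability maps.

check_cohort <- function(atlases) {
  stopifnot(length(atlases) >= 2L)
  if (!check_same_grid(atlases)) stop("grid mismatch across subjects")
  ref <- atlases[[1L]]$label_names
  for (a in atlases[-1L])
    if (!identical(a$label_names, ref))
      stop("label dictionary mismatch across subjects")
  ref
}

#' Modal (majority-vote) group atlas
#'
#' Assigns each voxel the most frequent nonzero label across subjects —
#' the standard way of averaging categorical values. A subject's
#' unassigned voxel (label 0) casts no vote. Voxels where no subject votes,
#' or where the winning label's frequency over all subjects falls below
#' `min_support`, are unassigned. Ties go to the lowest label.
#'
#' @param atlases List of >= 2 `LabelVolume`s on one grid sharing one
#'   label dictionary.
#' @param min_support Minimum frequency (winning votes / n_subjects, in
#'   `[0, 1]`) required to keep a voxel (default 0).
#' @return A `LabelVolume`.
#' @export
modal_atlas <- function(atlases, min_support = 0) {
  label_names <- check_cohort(atlases)
  n_sub <- length(atlases)
  max_lab <- max(1L, as.integer(names(label_names)))
  shape <- atlases[[1L]]$grid$shape
  nvox <- prod(shape)
  votes <- matrix(0L, nvox, max_lab)
  for (a in atlases) {
    lv <- as.vector(a$labels)
    nz <- which(lv > 0L)
    idx <- cbind(nz, lv[nz])
    votes[idx] <- votes[idx] + 1L
  }
  win <- max.col(votes, ties.method = "first")
  top <- votes[cbind(seq_len(nvox), win)]
  win[top == 0L | top / n_sub < min_support] <- 0L
  label_volume(array(win, shape), atlases[[1L]]$grid, label_names)
}

#' Per-label probability maps across subjects
#'
#' `map_k(v)` is the fraction of subjects labeling voxel `v` with `k`.
#' Sums over labels are at most 1 per voxel, with equality exactly where
#' every subject assigns the voxel some nonzero label.
#'
#' @inheritParams modal_atlas
#' @return Named list of `ScalarVolume`s, one per dictionary label, named
#'   by parcel name.
#' @export
label_probability_maps <- function(atlases) {
  label_names <- check_cohort(atlases)
  n_sub <- length(atlases)
  grid <- atlases[[1L]]$grid
  out <- lapply(as.integer(names(label_names)), function(k) {
    acc <- array(0, grid$shape)
    for (a in atlases) acc <- acc + (a$labels == k)
    scalar_volume(acc / n_sub, grid)
  })
  names(out) <- unname(label_names)
  out
}
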