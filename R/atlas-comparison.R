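# Atlas comparison via the Dice similarity coefficient.

#' Dice similarity coefficient of two voxel sets
#'
#' `DSC = 2 |A intersect B| / (|A| + |B|)`: twice the intersection volume
#' over the sum of the two volumes. Symmetric, in `[0, 1]`; two empty sets
#' give 0 by convention (absence of both parcels is not evidence of
#' agreement).
#'
#' @param a,b Logical 3-D arrays of identical shape (voxel membership
#'   indicators).
#' @return The DSC, a number in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("grid mismatch")
  na <- sum(a)
  nb <- sum(b)
  if (na + nb == 0L) return(0)
  2 * sum(a & b) / (na + nb)
}

#' Pairwise DSC matrix between two parcellation atlases
#'
#' Entry `(i, j)` is the Dice coefficient between the voxels labeled `i`
#' in atlas A and those labeled `j` in atlas B, over all nonzero
#' dictionary labels.
#'
#' @param atlasA,atlasB `LabelVolume`s on the same grid.
#' @return Numeric matrix with parcel names of A as row names and of B as
#'   column names (class `DSCMatrix`).
#' @export
dsc_matrix <- function(atlasA, atlasB) {
  stopifnot(inherits(atlasA, "LabelVolume"), inherits(atlasB, "LabelVolume"))
  if (!check_same_grid(list(atlasA, atlasB))) stop("grid mismatch")
  la <- as.integer(names(atlasA$label_names))
  lb <- as.integer(names(atlasB$label_names))
  out <- matrix(NA_real_, length(la), length(lb),
                dimnames = list(unname(atlasA$label_names),
                                unname(atlasB$label_names)))
  for (i in seq_along(la)) {
    ai <- atlasA$labels == la[i]
    for (j in seq_along(lb))
      out[i, j] <- dice(ai, atlasB$labels == lb[j])
  }
  class(out) <- c("DSCMatrix", class(out))
  out
}
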