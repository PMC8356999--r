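# Volume data model shared by every pipeline stage: a common voxel grid,
# scalar maps (diffusion metrics, probability maps), integer label volumes
# (DN masks, parcellation atlases) and per-target streamline-count sets.
# All stages require inputs already on one grid; no resampling is done here.

#' Voxel grid: shape, voxel-to-world affine and voxel size
#'
#' A `VoxelGrid` ties a 3-D array shape to world (scanner) coordinates via a
#' 4x4 affine. World coordinates of the voxel with 1-based index
#' `(i, j, k)` are `affine %*% c(i - 1, j - 1, k - 1, 1)`. The voxel size is
#' derived from the affine (Euclidean norms of its 3x3 block's columns).
#'
#' @param shape Integer vector of length 3, all positive.
#' @param affine 4x4 numeric voxel-to-world matrix in mm; must be invertible
#'   with last row `(0, 0, 0, 1)`.
#' @return An object of class `VoxelGrid` with fields `shape`, `affine`,
#'   `voxel_size`.
#' @examples
#' g <- voxel_grid(c(10, 10, 10), diag(c(1.25, 1.25, 1.25, 1)))
#' g$voxel_size
#' @export
voxel_grid <- function(shape, affine) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape > 0L))
  affine <- as.matrix(affine)
  stopifnot(identical(dim(affine), c(4L, 4L)))
  if (abs(det(affine)) < .Machine$double.eps * 100)
    stop("affine is not invertible")
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  structure(list(shape = shape, affine = affine, voxel_size = vs),
            class = "VoxelGrid")
}

#' @export
print.VoxelGrid <- function(x, ...) {
  cat("VoxelGrid ", paste(x$shape, collapse = " x "),
      " voxels, ", paste(signif(x$voxel_size, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' World coordinates of voxel indices
#'
#' @param grid A `VoxelGrid`.
#' @param ijk n x 3 matrix of 1-based voxel indices.
#' @return n x 3 matrix of world coordinates (mm).
#' @export
world_coords <- function(grid, ijk) {
  ijk <- rbind2cols(ijk)
  xyz0 <- sweep(ijk, 2L, c(1, 1, 1)) # 0-based offsets into the affine
  out <- xyz0 %*% t(grid$affine[1:3, 1:3])
  sweep(out, 2L, grid$affine[1:3, 4], "+")
}

rbind2cols <- function(ijk) {
  if (is.null(dim(ijk))) ijk <- matrix(ijk, ncol = 3L)
  ijk
}

#' Scalar volume on a voxel grid
#'
#' @param values 3-D numeric array matching `grid$shape`. Values may be NaN
#'   outside any mask the volume is later used with; they must be finite
#'   inside it.
#' @param grid A `VoxelGrid`.
#' @param units Unit string for documentation (e.g. `"1e-3 mm^2/s"` for MD).
#' @return Object of class `ScalarVolume`.
#' @export
scalar_volume <- function(values, grid, units = "") {
  stopifnot(inherits(grid, "VoxelGrid"))
  values <- as.array(values)
  if (!identical(dim(values), as.integer(grid$shape)))
    stop("values shape does not match grid")
  structure(list(values = values, grid = grid, units = units),
            class = "ScalarVolume")
}

#' Integer label volume on a voxel grid
#'
#' Label 0 is reserved for background/unassigned voxels everywhere in the
#' package and never appears in the label dictionary.
#'
#' @param labels 3-D array of nonnegative integers matching `grid$shape`.
#' @param grid A `VoxelGrid`.
#' @param label_names Named character vector mapping label value (as name)
#'   to parcel name, e.g. `c("1" = "I-VI", "2" = "CrusI-II")`. Every nonzero
#'   label present in `labels` must be covered.
#' @return Object of class `LabelVolume`.
#' @export
label_volume <- function(labels, grid, label_names = NULL) {
  stopifnot(inherits(grid, "VoxelGrid"))
  labels <- as.array(labels)
  if (!identical(dim(labels), as.integer(grid$shape)))
    stop("labels shape does not match grid")
  if (is.double(labels)) {
    if (max(abs(labels - round(labels)), na.rm = TRUE) > 1e-6)
      stop("labels are not integer-valued")
    labels <- round(labels)
  }
  storage.mode(labels) <- "integer"
  if (any(labels < 0L)) stop("labels must be nonnegative")
  present <- setdiff(sort(unique(as.vector(labels))), 0L)
  if (is.null(label_names)) {
    label_names <- stats::setNames(as.character(present), as.character(present))
  }
  missing <- setdiff(as.character(present), names(label_names))
  if (length(missing))
    stop("labels present in volume but absent from label_names: ",
         paste(missing, collapse = ", "))
  structure(list(labels = labels, grid = grid, label_names = label_names),
            class = "LabelVolume")
}

#' Set of per-target streamline-count volumes on one grid
#'
#' Houses track-density images (TDI): one nonnegative-integer count volume
#' per connectivity target, in a fixed, recorded target order.
#'
#' @param counts Named list of 3-D arrays (one per target), or unnamed list
#'   paired with `target_names`.
#' @param grid A `VoxelGrid` shared by all volumes.
#' @param target_names Ordered character vector of target names.
#' @return Object of class `CountMapSet`.
#' @export
count_map_set <- function(counts, grid, target_names = names(counts)) {
  stopifnot(inherits(grid, "VoxelGrid"), length(counts) >= 1L)
  if (is.null(target_names) || any(!nzchar(target_names)))
    stop("target_names required")
  stopifnot(length(target_names) == length(counts))
  counts <- lapply(counts, function(a) {
    a <- as.array(a)
    if (!identical(dim(a), as.integer(grid$shape)))
      stop("count volume shape does not match grid")
    if (any(a < 0)) stop("counts must be nonnegative")
    storage.mode(a) <- "integer"
    a
  })
  names(counts) <- target_names
  structure(list(counts = counts, grid = grid, target_names = target_names),
            class = "CountMapSet")
}

grid_from_nifti <- function(img) {
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  voxel_grid(dim(img), matrix(as.numeric(aff), 4L, 4L))
}

#' Read a 3-D NIfTI volume
#'
#' Reads a single 3-D volume from a `.nii` or `.nii.gz` file. For
#' `expected = "label"` the data must be integer-valued (tolerance 1e-6
#' before rounding); a sidecar JSON `<path>.labels.json` written by
#' [write_volume()] supplies the label dictionary when present.
#'
#' @param path Path to a NIfTI file.
#' @param expected Either `"scalar"` or `"label"`.
#' @return A `ScalarVolume` or `LabelVolume`.
#' @export
read_volume <- function(path, expected = c("scalar", "label")) {
  expected <- match.arg(expected)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected 3-D volume, got ", length(dim(img)), "-D")
  grid <- grid_from_nifti(img)
  vals <- array(as.numeric(img), dim = dim(img))
  if (expected == "scalar") return(scalar_volume(vals, grid))
  label_names <- NULL
  sidecar <- paste0(path, ".labels.json")
  if (file.exists(sidecar)) {
    ln <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    label_names <- stats::setNames(as.character(unlist(ln)), names(ln))
  }
  label_volume(vals, grid, label_names = label_names)
}

#' Write a volume as NIfTI
#'
#' Label volumes are written as integer data and their label dictionary as
#' a sidecar JSON `<path>.labels.json`; round-trip through
#' [read_volume()] is label-exact.
#'
#' @param vol A `ScalarVolume` or `LabelVolume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  is_label <- inherits(vol, "LabelVolume")
  arr <- if (is_label) vol$labels else vol$values
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vol$grid$voxel_size
  aff <- structure(vol$grid$affine, code = 2L)
  RNifti::`sform<-`(img, aff) -> img
  RNifti::`qform<-`(img, aff) -> img
  RNifti::writeNifti(img, path)
  if (is_label)
    jsonlite::write_json(as.list(vol$label_names),
                         paste0(path, ".labels.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Do volumes share one grid?
#'
#' @param volumes List of two or more volumes (`ScalarVolume`,
#'   `LabelVolume` or `CountMapSet`).
#' @param tol Tolerance on affine entries in mm (default 1e-4).
#' @return `TRUE` iff all shapes are equal and all affines agree within
#'   `tol`; `FALSE` otherwise (never an error).
#' @export
check_same_grid <- function(volumes, tol = 1e-4) {
  stopifnot(length(volumes) >= 2L)
  grids <- lapply(volumes, function(v) if (inherits(v, "VoxelGrid")) v else v$grid)
  ref <- grids[[1L]]
  for (g in grids[-1L]) {
    if (!identical(as.integer(g$shape), as.integer(ref$shape))) return(FALSE)
    if (max(abs(g$affine - ref$affine)) > tol) return(FALSE)
  }
  TRUE
}

#' Ordered voxel indices of one label
#'
#' Returns the 1-based voxel indices carrying `label`, in lexicographic
#' order by `(i, j, k)` — a deterministic ordering that is stable across
#' calls and platforms and shared by every stage that flattens DN voxels
#' into rows (membership fields, feature matrices).
#'
#' @param mask A `LabelVolume`.
#' @param label Integer label; must be 0 or present in `label_names`.
#' @return n x 3 integer matrix of voxel indices, with attribute `linear`
#'   holding the matching R linear (column-major) indices.
#' @export
mask_indices <- function(mask, label) {
  stopifnot(inherits(mask, "LabelVolume"))
  label <- as.integer(label)
  if (label != 0L && !(as.character(label) %in% names(mask$label_names)))
    stop("unknown label: ", label)
  lin <- which(mask$labels == label)
  ijk <- arrayInd(lin, dim(mask$labels))
  o <- order(ijk[, 1L], ijk[, 2L], ijk[, 3L])
  structure(ijk[o, , drop = FALSE], linear = lin[o])
}
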