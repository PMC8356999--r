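# Small fixtures shared across test files. Everything is generated in code;
# the "small" spec shrinks the grid and cohort so unit tests stay fast while
# keeping the default study-scale conditions for the acceptance checks.

small_grid <- function(shape = c(24L, 16L, 16L), vox = 1.25) {
  aff <- diag(c(vox, vox, vox, 1))
  aff[1:3, 4] <- -vox * (shape - 1) / 2
  voxel_grid(shape, aff)
}

small_spec <- function(...) {
  args <- utils::modifyList(
    list(grid = small_grid(), dn_semi_axes = c(4, 6, 5), dn_center_x = 7),
    list(...))
  do.call(phantom_spec, args)
}

# tiny grid + hand-placed volumes for arithmetic-level tests
tiny_grid <- function(shape = c(4L, 3L, 2L)) {
  voxel_grid(shape, diag(c(1, 1, 1, 1)))
}

tiny_mask <- function(lin, shape = c(4L, 3L, 2L), label = 1L) {
  arr <- array(0L, shape)
  arr[lin] <- label
  label_volume(arr, tiny_grid(shape))
}

# CountMapSet from a list of per-target vectors over given linear indices
tiny_counts <- function(lin, per_target, shape = c(4L, 3L, 2L),
                        targets = paste0("T", seq_along(per_target))) {
  maps <- lapply(per_target, function(v) {
    arr <- array(0L, shape)
    arr[lin] <- v
    arr
  })
  names(maps) <- targets
  count_map_set(maps, tiny_grid(shape), targets)
}
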