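#' Reference cohort means for the DN connectivity targets
#'
#' Across-subject mean total streamline counts and DN volume percentages
#' for the six cerebellar-lobule and six thalamic connectivity targets of
#' the left dentate nucleus, as reported for a 25-subject in-vivo cohort.
#' These serve as worked-example inputs for the retention filter and as
#' the calibration point for the synthetic cohort's default parameters:
#' applying [apply_retention()] with thresholds (10000 streamlines, 15%)
#' to the cerebellar rows retains lobules I–VI, Crus I–II and lobules
#' IX–X; thresholds (300, 40%) on the thalamic rows retain the motor and
#' prefrontal targets.
#'
#' @param system `"cerebellar"` or `"thalamic"`.
#' @return Data frame with columns `target`, `total_streamlines`,
#'   `volume_pct`, `retained` (NA; fill with [apply_retention()]).
#' @export
reference_parcel_means <- function(system = c("cerebellar", "thalamic")) {
  system <- match.arg(system)
  out <- if (system == "cerebellar") {
    data.frame(
      target = c("I-VI", "CrusI-II", "VIIb", "VIIIa", "VIIIb", "IX-X"),
      total_streamlines = c(18.9, 38.0, 9.2, 2.7, 2.0, 11.8) * 1000,
      volume_pct = c(28.9, 39.5, 8.0, 3.0, 4.2, 16.4))
  } else {
    data.frame(
      target = c("motor", "prefrontal", "sensory", "posterior-parietal",
                 "occipital", "temporal"),
      total_streamlines = c(330, 390, 50, 60, 1, 30),
      volume_pct = c(45.9, 44.8, 3.8, 4.7, 0.1, 0.7))
  }
  out$retained <- NA
  class(out) <- c("ParcelSummary", "data.frame")
  out
}
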