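# Synthetic multi-subject cohort with planted ground truth. The phantom
# emulates the statistical structure of the real inputs: ellipsoidal DN
# masks of realistic voxel counts on a 1.25 mm isotropic grid, per-target
# streamline-count maps concentrated on planted medio-lateral bands with
# count leakage and Poisson noise, and seven diffusion-metric maps with two
# planted microstructural clusters. Subject variability enters as i.i.d.
# per-voxel label noise; spatial warps are deliberately out of scope.

.CEREBELLAR_TARGETS <- c("I-VI", "CrusI-II", "VIIb", "VIIIa", "VIIIb", "IX-X")
.THALAMIC_TARGETS <- c("motor", "prefrontal", "sensory",
                       "posterior-parietal", "occipital", "temporal")
.METRIC_NAMES <- c("FA", "MD", "AD", "RD", "MK", "AK", "RK")

#' Specification of the synthetic DN phantom and cohort
#'
#' Defaults encode the study conditions the pipeline is meant to emulate:
#' a 25-subject cohort on a 1.25 mm isotropic grid; six cerebellar
#' connectivity targets whose volume fractions and total streamline counts
#' follow the left-DN cohort means of the source data (fractions 28.9,
#' 39.5, 8.0, 3.0, 4.2, 16.4 percent; counts 18900, 38000, 9200, 2700,
#' 2000, 11800 streamlines); six thalamic targets likewise (fractions 45.9,
#' 44.8, 3.8, 4.7, 0.1, 0.7 percent; counts 330, 390, 50, 60, 1, 30 — note
#' the thalamic system genuinely carries two orders of magnitude fewer
#' streamlines); and two microstructural clusters (lateral ~55% / medial
#' ~45% of DN volume) whose per-metric means differ between clusters with
#' a 3-standard-deviation separation.
#'
#' @param grid `VoxelGrid` for the phantom; the default 48 x 24 x 24 grid
#'   at 1.25 mm is symmetric about the mid-sagittal plane (world x = 0), as
#'   the medial/lateral naming convention requires.
#' @param dn_semi_axes Ellipsoid semi-axes in mm (x, y, z); the default
#'   gives ~870 voxels per DN.
#' @param dn_center_x Distance of each DN center from the mid-sagittal
#'   plane in mm (left at −x, right at +x).
#' @param conn_targets,conn_fractions,parcel_counts Cerebellar target
#'   names, per-parcel volume fractions (sum 1) and per-parcel expected
#'   total streamline counts.
#' @param parcel_order Permutation of `seq_along(conn_targets)` giving the
#'   band layout from medial to lateral; the default places lobules IX–X
#'   most medially and Crus I–II most laterally.
#' @param thalamic_targets,thalamic_fractions,thalamic_counts Same three
#'   settings for the thalamic connectivity system.
#' @param thalamic_order Medial-to-lateral layout of the thalamic bands
#'   (default: prefrontal medial, motor lateral).
#' @param leakage Fraction of a voxel's expected counts spilled uniformly
#'   onto the other targets; in `[0, 0.5)`.
#' @param micro_fraction_lateral Fraction of DN voxels in the lateral
#'   microstructural cluster (label 1); the medial cluster (label 2) takes
#'   the rest.
#' @param micro_cluster_means 2 x 7 matrix of per-cluster metric means
#'   (rows: lateral, medial; columns FA, MD, AD, RD, MK, AK, RK; MD/AD/RD
#'   in 1e-3 mm^2/s).
#' @param micro_cluster_sd Per-metric noise SD (length 7, >= 0); the
#'   default is one third of the between-cluster mean separation.
#' @param n_subjects Cohort size.
#' @param sex Per-subject factor with levels `F`/`M` (default 16 F, 9 M).
#' @param label_noise Per-voxel probability that a subject's true label is
#'   replaced by a random other label; in `[0, 0.5)`.
#' @param seed Integer seed from which all cohort randomness flows.
#' @return Object of class `PhantomSpec`.
#' @export
phantom_spec <- function(grid = NULL,
                         dn_semi_axes = c(6, 9, 7.5),
                         dn_center_x = 15,
                         conn_targets = .CEREBELLAR_TARGETS,
                         conn_fractions = c(28.9, 39.5, 8.0, 3.0, 4.2, 16.4) / 100,
                         parcel_counts = c(18900, 38000, 9200, 2700, 2000, 11800),
                         parcel_order = c(6L, 5L, 4L, 3L, 1L, 2L),
                         thalamic_targets = .THALAMIC_TARGETS,
                         thalamic_fractions = c(45.9, 44.8, 3.8, 4.7, 0.1, 0.7) / 100,
                         thalamic_counts = c(330, 390, 50, 60, 1, 30),
                         thalamic_order = c(2L, 5L, 6L, 3L, 4L, 1L),
                         leakage = 0.1,
                         micro_fraction_lateral = 0.55,
                         micro_cluster_means = NULL,
                         micro_cluster_sd = NULL,
                         n_subjects = 25L,
                         sex = NULL,
                         label_noise = 0.2,
                         seed = 1L) {
  if (is.null(grid)) {
    shape <- c(48L, 24L, 24L)
    aff <- diag(c(1.25, 1.25, 1.25, 1))
    # center the grid so world x = 0 lies mid-grid (mid-sagittal plane)
    aff[1:3, 4] <- -1.25 * (shape - 1) / 2
    grid <- voxel_grid(shape, aff)
  }
  if (is.null(micro_cluster_means)) {
    micro_cluster_means <- rbind(
      lateral = c(FA = 0.292, MD = 0.753, AD = 1.05, RD = 0.62,
                  MK = 1.213, AK = 0.95, RK = 1.40),
      medial  = c(FA = 0.276, MD = 0.820, AD = 1.12, RD = 0.68,
                  MK = 1.165, AK = 0.90, RK = 1.30))
    colnames(micro_cluster_means) <- .METRIC_NAMES
  }
  micro_cluster_means <- as.matrix(micro_cluster_means)
  stopifnot(identical(dim(micro_cluster_means), c(2L, 7L)))
  if (is.null(micro_cluster_sd))
    micro_cluster_sd <- abs(micro_cluster_means[1L, ] - micro_cluster_means[2L, ]) / 3
  stopifnot(length(micro_cluster_sd) == 7L, all(micro_cluster_sd >= 0))
  n_par <- length(conn_targets)
  stopifnot(length(conn_fractions) == n_par, length(parcel_counts) == n_par,
            abs(sum(conn_fractions) - 1) < 1e-9,
            identical(sort(as.integer(parcel_order)), seq_len(n_par)),
            length(thalamic_fractions) == length(thalamic_targets),
            abs(sum(thalamic_fractions) - 1) < 1e-9,
            leakage >= 0, leakage < 0.5,
            label_noise >= 0, label_noise < 0.5,
            micro_fraction_lateral > 0, micro_fraction_lateral < 1,
            n_subjects >= 1L)
  if (is.null(sex))
    sex <- factor(rep(c("F", "M"), times = pmax(c(0L, 0L),
            c(ceiling(n_subjects * 16 / 25), n_subjects - ceiling(n_subjects * 16 / 25)))),
            levels = c("F", "M"))
  structure(list(
    grid = grid, dn_semi_axes = dn_semi_axes, dn_center_x = dn_center_x,
    conn_targets = conn_targets, conn_fractions = conn_fractions,
    parcel_counts = parcel_counts, parcel_order = as.integer(parcel_order),
    thalamic_targets = thalamic_targets,
    thalamic_fractions = thalamic_fractions,
    thalamic_counts = thalamic_counts,
    thalamic_order = as.integer(thalamic_order),
    leakage = leakage,
    micro_fraction_lateral = micro_fraction_lateral,
    micro_cluster_means = micro_cluster_means,
    micro_cluster_sd = micro_cluster_sd,
    n_subjects = as.integer(n_subjects), sex = sex,
    label_noise = label_noise, seed = as.integer(seed)),
    class = "PhantomSpec")
}

# Split ordered voxels into bands whose sizes hit cumulative targets,
# guaranteeing each boundary is within one voxel of fraction * n.
band_split <- function(n, fractions) {
  cuts <- round(cumsum(fractions) * n)
  cuts[length(cuts)] <- n
  sizes <- diff(c(0L, cuts))
  rep(seq_along(fractions), times = sizes)
}

#' Build one DN phantom hemisphere
#'
#' Constructs the ellipsoidal DN mask and the planted ground truths: a
#' cerebellar connectivity parcellation of contiguous medio-lateral bands
#' matching `conn_fractions`, a thalamic parcellation likewise, and a
#' two-band microstructural truth (1 = lateral, 2 = medial). Left and right
#' masks are mirror images in world x.
#'
#' @param spec A `PhantomSpec`.
#' @param side `"left"` or `"right"`.
#' @return List with `LabelVolume` members `dn_mask`, `truth_conn`,
#'   `truth_conn_thal`, `truth_micro`.
#' @export
make_dn_phantom <- function(spec, side = c("left", "right")) {
  side <- match.arg(side)
  grid <- spec$grid
  if (any(spec$dn_semi_axes < 2 * grid$voxel_size))
    stop("degenerate ellipsoid: semi-axis under 2 voxels")
  shape <- grid$shape
  ijk <- as.matrix(expand.grid(i = seq_len(shape[1L]), j = seq_len(shape[2L]),
                               k = seq_len(shape[3L])))
  xyz <- world_coords(grid, ijk)
  cx <- if (side == "left") -spec$dn_center_x else spec$dn_center_x
  center <- c(cx, mean(range(xyz[, 2L])), mean(range(xyz[, 3L])))
  d2 <- ((xyz[, 1L] - center[1L]) / spec$dn_semi_axes[1L])^2 +
        ((xyz[, 2L] - center[2L]) / spec$dn_semi_axes[2L])^2 +
        ((xyz[, 3L] - center[3L]) / spec$dn_semi_axes[3L])^2
  inside <- d2 <= 1
  if (!any(inside)) stop("ellipsoid does not intersect the grid")
  if (max(abs(xyz[inside, 1L])) > max(abs(xyz[, 1L])) - 1e-9)
    stop("ellipsoid does not fit inside grid in x")

  mask_arr <- array(0L, shape)
  mask_arr[ijk[inside, , drop = FALSE]] <- 1L
  dn_mask <- label_volume(mask_arr, grid, c("1" = paste0("DN-", side)))

  # Order DN voxels medial -> lateral (by |world x|), ties broken
  # lexicographically so both hemispheres split identically.
  mi <- mask_indices(dn_mask, 1L)
  mx <- world_coords(grid, mi)[, 1L]
  med_first <- order(abs(mx), mi[, 1L], mi[, 2L], mi[, 3L])
  n <- nrow(mi)

  assign_bands <- function(fractions, order_med2lat, names_vec) {
    bands <- band_split(n, fractions[order_med2lat])
    lab <- integer(n)
    lab[med_first] <- order_med2lat[bands]
    arr <- array(0L, shape)
    arr[attr(mi, "linear")] <- lab
    label_volume(arr, grid,
                 stats::setNames(names_vec, as.character(seq_along(names_vec))))
  }
  truth_conn <- assign_bands(spec$conn_fractions, spec$parcel_order,
                             spec$conn_targets)
  truth_thal <- assign_bands(spec$thalamic_fractions, spec$thalamic_order,
                             spec$thalamic_targets)
  # micro: medial cluster = 2, lateral cluster = 1
  fl <- spec$micro_fraction_lateral
  truth_micro <- assign_bands(c(fl, 1 - fl), c(2L, 1L),
                              c("lateral", "medial"))
  list(dn_mask = dn_mask, truth_conn = truth_conn,
       truth_conn_thal = truth_thal, truth_micro = truth_micro)
}

#' Simulate per-target streamline-count maps from a planted parcellation
#'
#' For each DN voxel with true parcel p, the count toward target p is
#' Poisson with mean `lambda_p * (1 - leakage)` and the count toward each
#' other target q is Poisson with mean `lambda_p * leakage / (n_targets -
#' 1)`, where `lambda_p = parcel_counts[p] / n_voxels(p)`. Counts outside
#' the DN are zero. Uses the current RNG state; seed upstream (see
#' [simulate_cohort()]).
#'
#' @param truth_conn `LabelVolume` of true parcel labels (0 outside DN).
#' @param spec A `PhantomSpec`.
#' @param system `"cerebellar"` or `"thalamic"`: which target set and
#'   count scale to use.
#' @return A `CountMapSet`.
#' @export
simulate_tdi <- function(truth_conn, spec, system = c("cerebellar", "thalamic")) {
  system <- match.arg(system)
  targets <- if (system == "cerebellar") spec$conn_targets else spec$thalamic_targets
  totals <- if (system == "cerebellar") spec$parcel_counts else spec$thalamic_counts
  n_t <- length(targets)
  lin <- which(truth_conn$labels > 0L)
  if (!length(lin)) stop("truth_conn has no nonzero voxels")
  lab <- truth_conn$labels[lin]
  vox_per <- tabulate(lab, nbins = n_t)
  lambda <- ifelse(vox_per > 0L, totals / pmax(vox_per, 1L), 0)
  lam_v <- lambda[lab]
  maps <- vector("list", n_t)
  for (t in seq_len(n_t)) {
    mu <- ifelse(lab == t, lam_v * (1 - spec$leakage),
                 lam_v * spec$leakage / (n_t - 1L))
    arr <- array(0L, spec$grid$shape)
    arr[lin] <- stats::rpois(length(lin), mu)
    maps[[t]] <- arr
  }
  names(maps) <- targets
  count_map_set(maps, spec$grid, targets)
}

#' Simulate the seven diffusion-metric maps from a planted cluster truth
#'
#' Metric m at a voxel of true cluster k is Normal with mean
#' `micro_cluster_means[k, m]` and SD `micro_cluster_sd[m]`, truncated at 0
#' (all seven metrics are nonnegative). Voxels outside the DN are 0. Uses
#' the current RNG state.
#'
#' @param truth_micro `LabelVolume` with labels 1 (lateral) / 2 (medial).
#' @param spec A `PhantomSpec`; its `micro_cluster_means` rows must differ.
#' @return Named list of seven `ScalarVolume`s (FA, MD, AD, RD, MK, AK, RK).
#' @export
simulate_metrics <- function(truth_micro, spec) {
  mu <- spec$micro_cluster_means
  if (max(abs(mu[1L, ] - mu[2L, ])) == 0)
    stop("micro_cluster_means rows are identical")
  lin <- which(truth_micro$labels > 0L)
  lab <- truth_micro$labels[lin]
  out <- vector("list", 7L)
  for (m in seq_len(7L)) {
    v <- stats::rnorm(length(lin), mean = mu[lab, m], sd = spec$micro_cluster_sd[m])
    v <- pmax(v, 0)
    arr <- array(0, spec$grid$shape)
    arr[lin] <- v
    units <- if (.METRIC_NAMES[m] %in% c("MD", "AD", "RD")) "1e-3 mm^2/s" else ""
    out[[m]] <- scalar_volume(arr, spec$grid, units = units)
  }
  names(out) <- .METRIC_NAMES
  out
}

perturb_labels <- function(truth, p_noise) {
  if (p_noise <= 0) return(truth)
  labs <- truth$labels
  lin <- which(labs > 0L)
  present <- sort(unique(labs[lin]))
  if (length(present) < 2L) return(truth)
  flip <- lin[stats::runif(length(lin)) < p_noise]
  if (length(flip)) {
    cur <- labs[flip]
    # draw uniformly from the other labels
    new <- vapply(cur, function(l) {
      others <- present[present != l]
      others[sample.int(length(others), 1L)]
    }, integer(1L))
    labs[flip] <- new
  }
  label_volume(labs, truth$grid, truth$label_names)
}

#' Simulate a multi-subject synthetic cohort
#'
#' Builds the two phantom hemispheres once, then per subject perturbs the
#' true labels i.i.d. with probability `label_noise` and simulates count
#' maps (both connectivity systems) and metric maps from the perturbed
#' truths. All randomness flows from `spec$seed`; the same spec yields a
#' bit-identical cohort.
#'
#' @param spec A `PhantomSpec`.
#' @param sides Hemispheres to simulate (default both).
#' @return List with `phantom` (per-side ground truths) and `subjects`, a
#'   list of per-subject bundles each holding `subject_id`, `sex` and, per
#'   side, `dn_mask`, `tdi_cerebellar`, `tdi_thalamic`, `metrics`,
#'   `truth_conn`, `truth_conn_thal`, `truth_micro` (the perturbed truths).
#' @export
simulate_cohort <- function(spec, sides = c("left", "right")) {
  sides <- match.arg(sides, several.ok = TRUE)
  phantom <- lapply(stats::setNames(sides, sides),
                    function(s) make_dn_phantom(spec, s))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  subjects <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    per_side <- lapply(phantom, function(ph) {
      tc <- perturb_labels(ph$truth_conn, spec$label_noise)
      tt <- perturb_labels(ph$truth_conn_thal, spec$label_noise)
      tm <- perturb_labels(ph$truth_micro, spec$label_noise)
      list(dn_mask = ph$dn_mask,
           truth_conn = tc, truth_conn_thal = tt, truth_micro = tm,
           tdi_cerebellar = simulate_tdi(tc, spec, "cerebellar"),
           tdi_thalamic = simulate_tdi(tt, spec, "thalamic"),
           metrics = simulate_metrics(tm, spec))
    })
    subjects[[s]] <- c(list(subject_id = sprintf("sub-%02d", s),
                            sex = as.character(spec$sex[s])), per_side)
  }
  list(phantom = phantom, subjects = subjects)
}
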