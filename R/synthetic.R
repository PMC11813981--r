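# Synthetic study generator: phantom anatomy, per-subject 4D BOLD with
# planted thalamocortical connectivity, motion files, and a clinical
# manifest, with ground truth stored for every downstream check.
#
# Signal model: each cortical ROI r has a latent band-limited (0.01-0.08
# Hz) unit-variance source s_r(t); cortical voxels carry s_r + noise, and
# each thalamic voxel with true assignment a carries w * s_a + noise,
# where the mixing weight w is chosen per (subject, side, ROI) so that
# the ROI-pair Fisher z between the cortical mean and the subregion mean
# equals the subject's planted z target in expectation AFTER the
# band-pass stage (which removes the out-of-band fraction of the white
# noise but passes the in-band sources untouched), at the REFERENCE
# noise level noise_sd = 1:
#     r_pair = w / sqrt(w^2 + f_pass / n_subregion),
#     f_pass = 2 * (high - low) * tr  (in-band white-noise fraction)
# noise_sd != 1 moves the realized SNR away from the calibrated targets
# (0 gives the noise-free limit with voxelwise r = 1), so planted-effect
# recovery statements hold at the default noise level.
# Group effects are planted additively on the z scale (where inference
# operates); patients' targets are control baseline + group_effect on the
# lesion-referenced side, plus a per-subject N(0, subject_sd^2) deviation
# shared with the behavioral model.

#' Default planted group effects (patients minus controls, Fisher z)
#'
#' Somatosensory-thalamic connectivity decreased bilaterally; occipital
#' increased bilaterally; temporal increased ipsilesionally only.
#' @return 2 x 6 matrix (ipsilesional/contralesional x [ROI_NAMES]).
#' @export
default_group_effect <- function() {
  ge <- matrix(0, 2, 6,
               dimnames = list(c("ipsilesional", "contralesional"),
                               ROI_NAMES))
  ge["ipsilesional", c("temporal", "somatosensory", "occipital")] <-
    c(0.3, -0.3, 0.3)
  ge["contralesional", c("somatosensory", "occipital")] <- c(-0.3, 0.3)
  ge
}

#' Build a phantom anatomy with stored ground truth
#'
#' Lays out six bilateral cortical blocks and two thalamus blobs on a
#' left/right symmetric grid (mid-sagittal flips are exact), assigns every
#' thalamic voxel to one cortical ROI in six contiguous mirror-symmetric
#' sectors, and fixes all generator parameters.
#'
#' @param grid_shape Integer length-3, each >= 16; the x extent must be
#'   even so the mid-sagittal plane falls between voxels.
#' @param voxel_mm Isotropic voxel size.
#' @param noise_sd Per-voxel noise SD (sources have unit SD). Mixing
#'   weights are calibrated at the reference level 1, so the planted z
#'   targets are realized exactly at the default; other values move the
#'   SNR (0 = noise-free limit).
#' @param control_z Baseline (control) ROI-pair Fisher z, recycled to 6.
#' @param subject_sd Between-subject SD of the per-(side, ROI) z target.
#' @param group_effect 2 x 6 planted z delta, see [default_group_effect()].
#' @param behavior List: `beta` (FMA-UE points per z unit), `resid_sd`,
#'   plus the recovery model for 1-year scores; defaults are calibrated so
#'   the observed connectivity-FMA correlation sits near the reported
#'   effect size (~0.36) at default scan length.
#' @param sensory List: planted deficits of the impaired-sensory subgroup
#'   (`z_delta` on ipsilesional somatosensory z; `fma_ue`/`fma_le` direct
#'   score penalties).
#' @param seed Stored with the truth; phantom geometry is deterministic.
#' @return A `phantom_truth` object.
#' @export
make_phantom <- function(grid_shape = c(24L, 24L, 24L), voxel_mm = 2,
                         noise_sd = 1, control_z = atanh(0.85),
                         subject_sd = 0.2,
                         group_effect = default_group_effect(),
                         behavior = list(beta = 30, resid_sd = 11,
                                         recovery_mean = 30.1,
                                         recovery_slope = 20,
                                         recovery_sd = 8),
                         sensory = list(z_delta = 0.25, fma_ue = 10,
                                        fma_le = 5),
                         seed = 1L) {
  gs <- as.integer(grid_shape)
  if (length(gs) != 3L || any(gs < 16L))
    stop("grid too small: need at least 16x16x16 to host 8 disjoint regions")
  if (gs[1] %% 2L != 0L)
    stop("x extent must be even for an exact mid-sagittal plane")
  nx <- gs[1]; ny <- gs[2]; nz <- gs[3]
  affine <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
  affine[1:3, 4] <- -voxel_mm * (gs - 1) / 2

  mirror_x <- function(ix) nx + 1L - ix
  cort_x_l <- seq(2L, max(3L, floor(nx * 0.3)))
  thal_x_l <- seq(floor(nx * 0.3) + 2L, nx %/% 2L)
  if (length(thal_x_l) < 2L) stop("grid too small for thalamus blobs")
  cort_y <- 3:(ny - 2L)
  slab_h <- (nz - 6L) %/% 6L
  cort_z <- lapply(1:6, function(r) 3L + (r - 1L) * slab_h + 0:(slab_h - 1L))
  thal_y <- max(2L, ny %/% 2L - 3L):min(ny - 1L, ny %/% 2L + 4L)
  thal_z0 <- nz %/% 2L - 2L
  if (max(unlist(cort_z)) >= nz) stop("grid too small for cortical slabs")

  atlas <- array(0L, gs)
  for (r in 1:6) {
    atlas[cort_x_l, cort_y, cort_z[[r]]] <- r
    atlas[mirror_x(cort_x_l), cort_y, cort_z[[r]]] <- 10L + r
  }
  assignment <- array(0L, gs)
  for (r in 1:6) {
    z <- thal_z0 + r - 1L
    assignment[thal_x_l, thal_y, z] <- r
    assignment[mirror_x(thal_x_l), thal_y, z] <- r
  }
  atlas[thal_x_l, thal_y, thal_z0 + 0:5] <- 7L
  atlas[mirror_x(thal_x_l), thal_y, thal_z0 + 0:5] <- 17L

  grouping <- c(lapply(1:6, function(r) c(r, 10L + r)),
                list(7L, 17L))
  names(grouping) <- c(ROI_NAMES, "thalamus_left", "thalamus_right")
  atlas_vol <- label_volume(atlas, affine)
  rois <- resolve_rois(atlas_vol, grouping)

  control_z <- rep_len(control_z, 6L)
  names(control_z) <- ROI_NAMES
  stopifnot(identical(dim(group_effect), c(2L, 6L)))

  structure(list(
    grid_shape = gs, affine = affine, voxel_mm = voxel_mm,
    atlas = atlas_vol, grouping = grouping,
    cortex = rois$cortex, thalamus = rois$thalamus,
    assignment = assignment,
    noise_sd = noise_sd, control_z = control_z, subject_sd = subject_sd,
    group_effect = group_effect, behavior = behavior, sensory = sensory,
    seed = as.integer(seed)),
    class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf(
    "<phantom_truth %s grid, %d thalamic voxels/side, noise_sd=%g>\n",
    paste(x$grid_shape, collapse = "x"),
    sum(x$thalamus$left$data), x$noise_sd))
  invisible(x)
}

# z targets (2 x 6, left/right) for one subject. For patients the planted
# group effect is applied with ipsilesional = the lesion side (volumes are
# generated pre-harmonization).
subject_z_targets <- function(truth, group, lesion_side, delta,
                              sensory_impaired = FALSE) {
  zt <- rbind(left = truth$control_z, right = truth$control_z)
  if (group == "patient") {
    ge <- truth$group_effect
    ipsi <- lesion_side
    contra <- setdiff(c("left", "right"), ipsi)
    zt[ipsi, ] <- zt[ipsi, ] + ge["ipsilesional", ]
    zt[contra, ] <- zt[contra, ] + ge["contralesional", ]
    if (sensory_impaired)
      zt[ipsi, "somatosensory"] <-
        zt[ipsi, "somatosensory"] - truth$sensory$z_delta
  }
  zt + delta
}

# Unit-variance band-limited source signals (columns).
band_limited_sources <- function(n, T_, tr, low = 0.01, high = 0.08) {
  s <- bandpass(matrix(stats::rnorm(T_ * n), T_, n), tr, low, high)
  sweep(s, 2, apply(s, 2, stats::sd), `/`)
}

#' Simulate one subject's 4D BOLD and motion parameters
#'
#' @param truth A `phantom_truth`.
#' @param group `"patient"` or `"control"`.
#' @param lesion_side `"left"`, `"right"`, or `"none"` (controls).
#' @param n_timepoints Acquired frames (>= 60); the first `discard` have
#'   no motion rows (motion files cover retained frames only).
#' @param tr Repetition time, seconds.
#' @param seed Integer seed; identical seeds give identical subjects.
#' @param z_targets Optional 2 x 6 (left/right x ROI) planted pair-level z
#'   matrix; when `NULL` it is drawn here from the truth's subject model.
#' @param discard Frames the cleaning stage will drop (motion row count).
#' @param motion_spike Inject one >3 mm translation spike (for QC tests).
#' @param noise_mask Optional [label_volume] (or 3D array): voxel noise is
#'   generated inside it only and out-of-mask voxels are exactly zero.
#'   Any analysis restricted to the mask is unaffected by this shortcut
#'   (out-of-mask voxels are pure noise by construction), but the RNG
#'   stream differs from the full simulation, so use one convention
#'   consistently within a study.
#' @return List: `vol` ([volume4d]), `motion` (T' x 6), `wm`, `csf`
#'   (length T'), `z_targets`.
#' @export
simulate_subject <- function(truth, group = "control",
                             lesion_side = "none",
                             n_timepoints = 150L, tr = 2,
                             seed = 1L, z_targets = NULL,
                             discard = 5L, motion_spike = FALSE,
                             noise_mask = NULL) {
  if (n_timepoints < 60L) stop("n_timepoints must be >= 60")
  set.seed(as.integer(seed))
  T_ <- as.integer(n_timepoints)
  if (is.null(z_targets)) {
    delta <- matrix(stats::rnorm(12, 0, truth$subject_sd), 2, 6,
                    dimnames = list(c("left", "right"), ROI_NAMES))
    z_targets <- subject_z_targets(truth, group, lesion_side, delta)
  }
  src <- band_limited_sources(6L, T_, tr)

  gs <- truth$grid_shape
  nvox <- prod(gs)
  # standard normals scaled afterwards: the RNG stream advances the same
  # way at every noise level (including the noise-free limit), so
  # subjects with equal seeds share sources/motion/confounds across SNRs
  if (is.null(noise_mask)) {
    data <- matrix(stats::rnorm(nvox * T_) * truth$noise_sd, nvox, T_)
  } else {
    nm <- if (inherits(noise_mask, "label_volume")) noise_mask$data
    else noise_mask
    nidx <- which(nm > 0L)
    data <- matrix(0, nvox, T_)
    data[nidx, ] <- stats::rnorm(length(nidx) * T_) * truth$noise_sd
  }

  for (r in 1:6) {
    idx <- which(truth$cortex[[r]]$data > 0L)
    data[idx, ] <- data[idx, ] + matrix(src[, r], length(idx), T_,
                                        byrow = TRUE)
  }
  for (side in c("left", "right")) {
    thal <- truth$thalamus[[side]]$data > 0L
    for (r in 1:6) {
      idx <- which(thal & truth$assignment == r)
      if (length(idx) == 0L) next
      # weight calibrated at the REFERENCE noise level (sd 1, the
      # default): the planted pair-level z is realized exactly there,
      # while truth$noise_sd genuinely moves the SNR away from it
      # (noise_sd -> 0 gives voxelwise r -> 1)
      r_pair <- tanh(z_targets[side, r])
      r_pair <- min(max(r_pair, -0.999), 0.999)
      f_pass <- 2 * (0.08 - 0.01) * tr     # in-band white-noise fraction
      sig_bar <- sqrt(f_pass / length(idx))
      w <- r_pair * sig_bar / sqrt(1 - r_pair^2)
      data[idx, ] <- data[idx, ] + w * matrix(src[, r], length(idx), T_,
                                              byrow = TRUE)
    }
  }
  dim(data) <- c(gs, T_)
  vol <- new_volume4d(data, truth$affine, tr)

  Tret <- T_ - as.integer(discard)
  motion <- cbind(matrix(stats::rnorm(Tret * 3, 0, 0.05), Tret, 3),
                  matrix(stats::rnorm(Tret * 3, 0, 0.001), Tret, 3))
  if (motion_spike) motion[max(1L, Tret %/% 2L), 1] <- 3.5
  list(vol = vol,
       motion = motion,
       wm = stats::rnorm(Tret),
       csf = stats::rnorm(Tret),
       z_targets = z_targets)
}

#' Simulate a complete study cohort
#'
#' Draws the clinical manifest (demographics matched to a two-group
#' stroke-rehabilitation cohort: 39 patients with 17 left / 22 right
#' lesions, 32 controls by default), per-subject planted connectivity
#' targets, and the behavioral model linking ipsilesional
#' somatosensory-thalamic z to FMA-UE baseline (positive slope) and to
#' its 1-year change rate (negative), with the impaired-sensory subgroup
#' (19/39 by default) planted lower on both.
#'
#' Volumes are not materialized here: the returned plan carries one seed
#' and z-target matrix per subject, and [realize_subject()] generates any
#' subject's BOLD deterministically on demand. Use [write_cohort()] to put
#' the whole dataset on disk.
#'
#' @param truth A `phantom_truth`.
#' @param n_patients,n_controls Group sizes (default 39 / 32).
#' @param n_timepoints,tr Acquisition parameters (default 150 frames, 2s).
#' @param seed Master seed; the full dataset is a pure function of it.
#' @return A `cohort_plan`: `manifest` (data frame), `subjects` (named
#'   list with per-subject `seed` and `z_targets`), `truth`,
#'   `n_timepoints`, `tr`.
#' @export
simulate_cohort <- function(truth, n_patients = 39L, n_controls = 32L,
                            n_timepoints = 150L, tr = 2, seed = 1L) {
  set.seed(as.integer(seed))
  n <- n_patients + n_controls
  ids <- c(sprintf("pat%02d", seq_len(n_patients)),
           sprintf("con%02d", seq_len(n_controls)))
  group <- rep(c("patient", "control"), c(n_patients, n_controls))

  n_left <- round(n_patients * 17 / 39)
  lesion <- rep("none", n)
  lesion[seq_len(n_patients)] <-
    sample(rep(c("left", "right"), c(n_left, n_patients - n_left)))

  n_imp <- round(n_patients * 19 / 39)
  impaired <- rep(FALSE, n)
  impaired[seq_len(n_patients)] <-
    sample(rep(c(TRUE, FALSE), c(n_imp, n_patients - n_imp)))

  subj_seeds <- (as.integer(seed) %% 100000L) * 20011L +
    17L * seq_len(n)              # < 2^31, deterministic, collision-free
  deltas <- lapply(seq_len(n), function(i)
    matrix(stats::rnorm(12, 0, truth$subject_sd), 2, 6,
           dimnames = list(c("left", "right"), ROI_NAMES)))
  # mean-preserving sensory split: impaired patients sit z_delta below the
  # nonimpaired on ipsilesional somatosensory z, but the patient group
  # mean stays exactly control + group_effect
  f_imp <- n_imp / n_patients
  for (i in seq_len(n_patients)) {
    shift <- if (impaired[i]) -truth$sensory$z_delta * (1 - f_imp)
    else truth$sensory$z_delta * f_imp
    deltas[[i]][lesion[i], "somatosensory"] <-
      deltas[[i]][lesion[i], "somatosensory"] + shift
  }
  zt <- lapply(seq_len(n), function(i)
    subject_z_targets(truth, group[i], lesion[i], deltas[[i]]))

  bh <- truth$behavior
  # planted ipsilesional somatosensory z per patient drives the scores
  z_ss <- vapply(seq_len(n), function(i) {
    if (group[i] == "patient") zt[[i]][lesion[i], "somatosensory"]
    else NA_real_
  }, 0)
  mean_zp <- mean(truth$control_z["somatosensory"] +
                    truth$group_effect["ipsilesional", "somatosensory"])
  alpha_ue <- 22.6 - bh$beta * mean_zp
  clampi <- function(x, lo, hi) as.integer(pmin(pmax(round(x), lo), hi))

  fma_ue_t1 <- fma_ue_t2 <- fma_le_t1 <- fma_le_t2 <- rep(NA_integer_, n)
  nihss_t1 <- nihss_t2 <- sens <- rep(NA_integer_, n)
  pat_i <- which(group == "patient")
  zdev <- z_ss[pat_i] - mean_zp
  fma_ue_t1[pat_i] <- clampi(alpha_ue + bh$beta * z_ss[pat_i] +
                               stats::rnorm(n_patients, 0, bh$resid_sd) -
                               truth$sensory$fma_ue * impaired[pat_i],
                             0, 66)
  fma_le_t1[pat_i] <- clampi(21.9 + 10 * zdev +
                               stats::rnorm(n_patients, 0, 6) -
                               truth$sensory$fma_le * impaired[pat_i],
                             0, 34)
  rec_ue <- bh$recovery_mean - bh$recovery_slope * zdev +
    stats::rnorm(n_patients, 0, bh$recovery_sd)
  fma_ue_t2[pat_i] <- clampi(fma_ue_t1[pat_i] + pmax(rec_ue, 0), 0, 66)
  rec_le <- 10 - 5 * zdev + stats::rnorm(n_patients, 0, 4)
  fma_le_t2[pat_i] <- clampi(fma_le_t1[pat_i] + pmax(rec_le, 0), 0, 34)
  nihss_t1[pat_i] <- clampi(stats::rnorm(n_patients, 6.4, 3.6) +
                              2 * impaired[pat_i], 0, 42)
  nihss_t2[pat_i] <- clampi(0.2 * nihss_t1[pat_i] +
                              stats::rnorm(n_patients, 0, 1), 0, 42)
  sens[pat_i] <- ifelse(impaired[pat_i],
                        sample(1:2, n_patients, replace = TRUE), 0L)

  is_pat <- group == "patient"
  manifest <- data.frame(
    subject_id = ids, group = group, lesion_side = lesion,
    bold_path = paste0(ids, "_bold.nii"),
    motion_path = paste0(ids, "_motion.txt"),
    fma_ue_t1 = fma_ue_t1, fma_ue_t2 = fma_ue_t2,
    fma_le_t1 = fma_le_t1, fma_le_t2 = fma_le_t2,
    nihss_t1 = nihss_t1, nihss_t2 = nihss_t2, nihss_sensory_t1 = sens,
    age = round(ifelse(is_pat, stats::rnorm(n, 57.7, 11.5),
                       stats::rnorm(n, 52.5, 12))),
    male = as.integer(stats::runif(n) < ifelse(is_pat, 29/39, 24/32)),
    bmi = round(ifelse(is_pat, stats::rnorm(n, 26.1, 3.2),
                       stats::rnorm(n, 25.2, 3.5)), 1),
    smoke = as.integer(stats::runif(n) < ifelse(is_pat, 17/39, 9/32)),
    hypertension = as.integer(stats::runif(n) <
                                ifelse(is_pat, 27/39, 19/32)),
    diabetes = as.integer(stats::runif(n) < ifelse(is_pat, 13/39, 6/32)),
    dyslipidemia = as.integer(stats::runif(n) <
                                ifelse(is_pat, 22/39, 14/32)),
    mmse = round(ifelse(is_pat, stats::rnorm(n, 29.4, 1.1),
                        stats::rnorm(n, 29.6, 0.7))),
    days_poststroke = ifelse(is_pat,
                             round(stats::rnorm(n, 20.1, 6.6)), NA),
    stringsAsFactors = FALSE)
  manifest$mmse <- pmin(manifest$mmse, 30)

  subjects <- lapply(seq_len(n), function(i)
    list(subject_id = ids[i], seed = subj_seeds[i],
         z_targets = zt[[i]], sensory_impaired = impaired[i]))
  names(subjects) <- ids
  structure(list(manifest = validate_manifest(manifest),
                 subjects = subjects, truth = truth,
                 n_timepoints = as.integer(n_timepoints), tr = tr,
                 seed = as.integer(seed)),
            class = "cohort_plan")
}

#' Materialize one subject of a cohort plan
#'
#' @param cohort A `cohort_plan` from [simulate_cohort()].
#' @param subject_id Subject identifier (or integer index).
#' @param noise_mask Passed to [simulate_subject()].
#' @return The [simulate_subject()] output for that subject.
#' @export
realize_subject <- function(cohort, subject_id, noise_mask = NULL) {
  s <- if (is.numeric(subject_id)) cohort$subjects[[subject_id]]
  else cohort$subjects[[as.character(subject_id)]]
  if (is.null(s)) stop("unknown subject: ", subject_id)
  rec <- cohort$manifest[cohort$manifest$subject_id == s$subject_id, ]
  simulate_subject(cohort$truth, rec$group, rec$lesion_side,
                   cohort$n_timepoints, cohort$tr, seed = s$seed,
                   z_targets = s$z_targets, noise_mask = noise_mask)
}

#' Write a cohort plan to disk
#'
#' Writes per-subject BOLD NIfTI and motion text files, the TSV manifest,
#' and a JSON ground-truth file (seeds, planted targets, thalamic voxel
#' assignment) sufficient to score every downstream stage.
#'
#' @param cohort A `cohort_plan`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$subjects)) {
    s <- realize_subject(cohort, id)
    write_volume(s$vol, file.path(dir, paste0(id, "_bold.nii")))
    utils::write.table(s$motion,
                       file.path(dir, paste0(id, "_motion.txt")),
                       row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(cohort$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_volume(cohort$truth$atlas, file.path(dir, "atlas.nii"))
  jsonlite::write_json(
    list(seed = cohort$seed, n_timepoints = cohort$n_timepoints,
         tr = cohort$tr, grid_shape = cohort$truth$grid_shape,
         noise_sd = cohort$truth$noise_sd,
         control_z = as.list(cohort$truth$control_z),
         group_effect = cohort$truth$group_effect,
         grouping = cohort$truth$grouping,
         assignment_index = which(cohort$truth$assignment > 0L),
         assignment_label =
           cohort$truth$assignment[cohort$truth$assignment > 0L],
         subjects = lapply(cohort$subjects, function(s)
           list(seed = s$seed, z_targets = s$z_targets,
                sensory_impaired = s$sensory_impaired))),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(cohort$truth$grouping,
                       file.path(dir, "grouping.json"))
  invisible(dir)
}

#' Fast connectivity-level simulation of a cohort's ROI-pair z table
#'
#' Draws the measured per-entry ROI-pair Fisher z values directly from
#' the subject model the BOLD generator realizes: measured z = planted
#' target + N(0, m^2), with measurement SD `m = 1 / sqrt(df_eff - 3)` and
#' `df_eff = 2 * (high - low) * T_retained * tr` the effective temporal
#' degrees of freedom after band-pass filtering. Used where many replicate
#' cohorts are needed (e.g. null calibration); the full BOLD path is
#' validated against the same model elsewhere.
#'
#' @param cohort A `cohort_plan`.
#' @param low,high Band limits assumed for the effective df.
#' @param discard Frames dropped before analysis.
#' @return A cohort connectivity table as from [cohort_connectivity()].
#' @export
simulate_pair_z <- function(cohort, low = 0.01, high = 0.08,
                            discard = 5L) {
  Tret <- cohort$n_timepoints - discard
  df_eff <- max(8, 2 * (high - low) * Tret * cohort$tr)
  m_sd <- 1 / sqrt(df_eff - 3)
  plan <- harmonize_plan(cohort$manifest)
  rows <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    s <- cohort$subjects[[plan$subject_id[i]]]
    zt <- s$z_targets                 # rows: left, right (anatomical)
    if (plan$flip[i]) zt <- zt[c("right", "left"), ]
    rownames(zt) <- c("contralesional", "ipsilesional")
    zhat <- zt + matrix(stats::rnorm(12, 0, m_sd), 2, 6)
    rows[[i]] <- data.frame(
      entry_id = plan$entry_id[i], subject_id = plan$subject_id[i],
      group = plan$group[i], provenance = plan$provenance[i],
      side = rep(rownames(zhat), 6),
      roi = rep(ROI_NAMES, each = 2),
      r = tanh(as.vector(zhat)), z = as.vector(zhat),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
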