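# Validation criteria computed end-to-end on the synthetic study. These
# functions are the single implementation behind both the acceptance test
# suite and scripts/acceptance.R: each one regenerates its inputs from a
# seed, runs the analysis stack, and measures the recovery/calibration
# quantity. Replicate counts are the stated validation design; grid sizes
# are scaled (24^3 / 16^3) to keep runtimes inside test budgets.

.sub_seed <- function(seed, k) (abs(as.integer(seed)) %% 1000000L) *
  1009L + 7L * k

#' Published demographics chi-squares
#'
#' Pearson chi-squares (no continuity correction) for the five binary
#' demographic traits of the study cohort, from the reference cohort's 2x2 counts
#' (39 patients vs 32 controls): male 29/24, smoker 17/9, hypertension
#' 27/19, diabetes 13/6, dyslipidemia 22/14.
#'
#' @return Named numeric vector of five chi-square statistics.
#' @export
criterion_table1_chisq <- function() {
  counts <- list(male = c(29, 10, 24, 8),
                 smoke = c(17, 22, 9, 23),
                 hypertension = c(27, 12, 19, 13),
                 diabetes = c(13, 26, 6, 26),
                 dyslipidemia = c(22, 17, 14, 18))
  vapply(counts, function(ct) do.call(chi_square_2x2,
                                      as.list(ct))$chisq, 0)
}

#' Harmonized cohort structure
#'
#' Builds the default cohort (39 patients, 17 left / 22 right lesions, 32
#' controls) and counts the harmonized entries.
#'
#' @param seed Master seed.
#' @return List: `n_patients_right` (patients, all right-lesion after
#'   harmonization), `n_control_entries` (flip-augmented set).
#' @export
criterion_cohort_structure <- function(seed = 1L) {
  truth <- make_phantom(c(16L, 16L, 16L))
  cohort <- simulate_cohort(truth, seed = .sub_seed(seed, 1L))
  plan <- harmonize_plan(cohort$manifest)
  list(n_patients_right = sum(plan$group == "patient"),
       n_flipped_patients = sum(plan$group == "patient" & plan$flip),
       n_control_entries = sum(plan$group == "control"))
}

#' Group winner-take-all recovery of the planted parcellation
#'
#' Runs the full stack (simulate, clean, correlate, group WTA) on a
#' 20-subject cohort at default SNR (24^3 grid) and scores the group
#' labels against the planted assignment over both thalami; also checks
#' a single noise-free subject.
#'
#' @param seed Master seed.
#' @param n_subjects Cohort size (controls).
#' @return List: `group_accuracy`, `noisefree_accuracy` (fractions).
#' @export
criterion_parcellation_recovery <- function(seed = 1L, n_subjects = 20L) {
  truth <- make_phantom()
  cohort <- simulate_cohort(truth, n_patients = 0L,
                            n_controls = n_subjects,
                            seed = .sub_seed(seed, 2L))
  res <- analyze_cohort(cohort)
  acc <- mean(c(res$wta$left$label == true_assignment(truth, "left"),
                res$wta$right$label == true_assignment(truth, "right")))

  t0 <- make_phantom(noise_sd = 0)
  s <- simulate_subject(t0, n_timepoints = 150L,
                        seed = .sub_seed(seed, 3L))
  v <- clean_pipeline(s$vol, confound_set(s$motion, s$wm, s$csf))
  cts <- do.call(cbind, lapply(t0$cortex, function(m)
    roi_mean_timeseries(v, m)))
  nf <- mean(vapply(c("left", "right"), function(side) {
    w <- winner_take_all(voxel_cortex_correlations(
      v, t0$thalamus[[side]], cts))
    mean(w$label == true_assignment(t0, side))
  }, 0))
  list(group_accuracy = acc, noisefree_accuracy = nf)
}

#' Planted labels of one thalamus, in correlation-map voxel order
#' @param truth A `phantom_truth`.
#' @param side `"left"` or `"right"`.
#' @return Integer vector of planted ROI indices.
#' @export
true_assignment <- function(truth, side) {
  truth$assignment[which(truth$thalamus[[side]]$data > 0L)]
}

#' Recovery of the planted somatosensory group effect
#'
#' Simulates replicate default cohorts (39 patients / 32 controls, 24^3,
#' 150 frames), runs the full pipeline (clean, harmonize, pooled group
#' WTA, ROI-pair connectivity) and measures the patient-minus-control
#' ipsilesional somatosensory Fisher-z difference; repeats with the
#' planted effect doubled.
#'
#' @param seed Master seed.
#' @param n_reps Replicate cohorts at the default effect.
#' @param n_reps_doubled Replicate cohorts at the doubled effect.
#' @return List: `mean_dz`, `planted_dz`, `mean_dz_doubled`,
#'   `planted_dz_doubled`, `ratio`, and the per-replicate values.
#' @export
criterion_effect_recovery <- function(seed = 1L, n_reps = 20L,
                                      n_reps_doubled = 10L) {
  dz_of <- function(truth, s) {
    cohort <- simulate_cohort(truth, seed = s)
    ct <- roi_pair_contrasts(analyze_cohort(cohort)$conn)
    ct$mean_diff[ct$side == "ipsilesional" & ct$roi == "somatosensory"]
  }
  t1 <- make_phantom()
  dz <- vapply(seq_len(n_reps), function(r)
    dz_of(t1, .sub_seed(seed, 10L + r)), 0)
  t2 <- make_phantom(group_effect = 2 * default_group_effect())
  dz2 <- vapply(seq_len(n_reps_doubled), function(r)
    dz_of(t2, .sub_seed(seed, 50L + r)), 0)
  list(mean_dz = mean(dz),
       planted_dz = unname(t1$group_effect["ipsilesional",
                                           "somatosensory"]),
       mean_dz_doubled = mean(dz2),
       planted_dz_doubled = unname(t2$group_effect["ipsilesional",
                                                   "somatosensory"]),
       ratio = mean(dz2) / mean(dz), dz = dz, dz_doubled = dz2)
}

#' Familywise type-I calibration of permutation cluster inference
#'
#' Replicate null datasets of smoothed Gaussian maps (two groups from the
#' same distribution, 16^3 grid, spatial autocorrelation sigma = 1 voxel)
#' are fed to [perm_cluster_fwe()]; the rejection rate of the
#' patient-greater contrast at corrected p <= 0.05 estimates the
#' familywise type-I rate at nominal 0.05.
#'
#' @param seed Master seed.
#' @param n_reps Null replicates (200).
#' @param n_per_group Maps per group (10).
#' @param n_perm Permutations per replicate (500).
#' @return List: `rate`, `n_reps`.
#' @export
criterion_cluster_calibration <- function(seed = 1L, n_reps = 200L,
                                          n_per_group = 10L,
                                          n_perm = 500L) {
  dims <- c(16L, 16L, 16L)
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- -15
  mask <- label_volume(array(1L, dims), aff)
  mk <- function() {
    a <- gaussian_smooth3d(array(stats::rnorm(prod(dims)), dims), 1)
    a / stats::sd(a)
  }
  rej <- vapply(seq_len(n_reps), function(r) {
    set.seed(.sub_seed(seed, 100L + r))
    A <- lapply(seq_len(n_per_group), function(i) mk())
    B <- lapply(seq_len(n_per_group), function(i) mk())
    cl <- perm_cluster_fwe(A, B, mask, n_perm = n_perm,
                           seed = .sub_seed(seed, 5000L + r))$clusters
    any(cl$p_fwe[cl$contrast == "a>b"] <= 0.05)
  }, NA)
  list(rate = mean(rej), n_reps = n_reps)
}

#' Type-I calibration of the ROI-pair contrast
#'
#' Replicate cohorts with the default planted world (prefrontal carries a
#' planted zero effect) are drawn through the connectivity-level
#' generator; the ipsilesional prefrontal contrast is tested at alpha =
#' 0.05 in the independence-safe control mode (the 32 original subjects;
#' the flip-augmented 64-entry mode double-counts subjects and is not a
#' calibration target). The Welch variant is used because averaging each
#' control's two hemispheres makes the group variances unequal by
#' construction, which the pooled test is not calibrated for.
#'
#' @param seed Master seed.
#' @param n_reps Replicates (500).
#' @return List: `rate`, `n_reps`.
#' @export
criterion_roipair_null <- function(seed = 1L, n_reps = 500L) {
  truth <- make_phantom(c(16L, 16L, 16L))
  rej <- vapply(seq_len(n_reps), function(r) {
    cohort <- simulate_cohort(truth, seed = .sub_seed(seed, 2000L + r))
    conn <- simulate_pair_z(cohort)
    roi_pair_contrast(conn, "ipsilesional", "prefrontal",
                      control_mode = "independent",
                      variant = "welch")$p < 0.05
  }, NA)
  list(rate = mean(rej), n_reps = n_reps)
}

#' Behavioral direction: connectivity-FMA correlation sign
#'
#' Replicate patient cohorts (39 patients, 16^3 grid) are simulated and
#' measured through the imaging stack (clean, connectivity on the planted
#' thalamic sectors); the criterion is the fraction of replicates in
#' which [behavior_correlation()] between ipsilesional somatosensory z
#' and the FMA-UE baseline score is positive.
#'
#' @param seed Master seed.
#' @param n_reps Replicates (100).
#' @return List: `frac_positive`, `mean_r`, `n_reps`.
#' @export
criterion_behavior_direction <- function(seed = 1L, n_reps = 100L) {
  truth <- make_phantom(c(16L, 16L, 16L))
  rs <- vapply(seq_len(n_reps), function(r) {
    cohort <- simulate_cohort(truth, n_controls = 2L,
                              seed = .sub_seed(seed, 3000L + r))
    res <- analyze_cohort(cohort, use_truth_labels = TRUE)
    conn <- res$conn
    pat <- cohort$manifest[cohort$manifest$group == "patient", ]
    zz <- conn[conn$group == "patient" & conn$side == "ipsilesional" &
                 conn$roi == "somatosensory", ]
    z <- zz$z[match(pat$subject_id, zz$subject_id)]
    behavior_correlation(z, pat$fma_ue_t1)$r
  }, 0)
  list(frac_positive = mean(rs > 0), mean_r = mean(rs), n_reps = n_reps)
}
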