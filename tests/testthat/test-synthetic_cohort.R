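# synthetic_cohort: phantom geometry, subject/cohort determinism, planted
# structure, on-disk dataset

test_that("phantom masks partition and thalamic sectors cover the thalamus", {
  truth <- make_phantom()
  all_masks <- c(truth$cortex, truth$thalamus)
  total <- Reduce(`+`, lapply(all_masks, function(m) m$data))
  expect_true(all(total <= 1L))
  thal <- truth$thalamus$left$data + truth$thalamus$right$data
  expect_identical(truth$assignment > 0L, thal > 0L)
  for (side in c("left", "right"))
    expect_setequal(unique(true_labels(truth, side)), 1:6)
})

test_that("phantom construction is deterministic and validates grids", {
  expect_identical(make_phantom(seed = 4L)[names(make_phantom())],
                   make_phantom(seed = 4L)[names(make_phantom())])
  expect_error(make_phantom(c(8L, 8L, 8L)), "grid too small")
  expect_error(make_phantom(c(17L, 16L, 16L)), "even")
})

test_that("same seed gives bit-identical subjects; different seeds differ", {
  truth <- small_phantom()
  a <- simulate_subject(truth, n_timepoints = 70, seed = 5L)
  b <- simulate_subject(truth, n_timepoints = 70, seed = 5L)
  expect_identical(a$vol$data, b$vol$data)
  expect_identical(a$motion, b$motion)
  c_ <- simulate_subject(truth, n_timepoints = 70, seed = 6L)
  expect_false(identical(a$vol$data, c_$vol$data))
  expect_error(simulate_subject(truth, n_timepoints = 50), ">= 60")
})

test_that("noise-free limit: each thalamic voxel correlates 1 with its ROI", {
  truth <- small_phantom(noise_sd = 0)
  cm <- subject_cm(truth, "left", seed = 7L)
  lab <- true_labels(truth, "left")
  r_true <- cm$r[cbind(seq_along(lab), lab)]
  expect_true(all(r_true > 0.999))
  r_other <- cm$r; r_other[cbind(seq_along(lab), lab)] <- -Inf
  expect_true(all(apply(r_other, 1, max) < r_true))
})

test_that("noise mask shortcut leaves masked analyses untouched in law", {
  truth <- small_phantom()
  s <- simulate_subject(truth, n_timepoints = 70, seed = 9L,
                        noise_mask = truth$atlas)
  flat <- s$vol$data
  dim(flat) <- c(prod(truth$grid_shape), 70L)
  expect_true(all(flat[truth$atlas$data == 0L, ] == 0))
  expect_true(stats::sd(flat[truth$atlas$data > 0L, ]) > 0)
})

test_that("motion spike is injected for QC tests", {
  truth <- small_phantom()
  s <- simulate_subject(truth, n_timepoints = 70, seed = 2L,
                        motion_spike = TRUE)
  expect_false(motion_qc(s$motion)$pass)
})

test_that("default cohort matches the study composition", {
  truth <- small_phantom()
  cohort <- simulate_cohort(truth, seed = 3L)
  m <- cohort$manifest
  expect_equal(nrow(m), 71L)
  expect_equal(sum(m$group == "patient"), 39L)
  expect_equal(sum(m$group == "control"), 32L)
  expect_equal(sum(m$lesion_side == "left"), 17L)
  expect_equal(sum(m$lesion_side == "right"), 22L)
  pat <- m[m$group == "patient", ]
  expect_equal(sum(pat$nihss_sensory_t1 > 0), 19L)
  expect_equal(sum(pat$nihss_sensory_t1 == 0), 20L)
  expect_true(all(pat$fma_ue_t1 >= 0 & pat$fma_ue_t1 <= 66))
  expect_true(all(pat$fma_le_t1 >= 0 & pat$fma_le_t1 <= 34))
  # full determinism of the plan under a fixed master seed
  cohort2 <- simulate_cohort(truth, seed = 3L)
  expect_identical(cohort$manifest, cohort2$manifest)
  expect_identical(cohort$subjects, cohort2$subjects)
})

test_that("planted behavioral slope is positive; zero-noise limit exact", {
  # degenerate world: no behavioral residual, no sensory penalties, no
  # between-subject noise beyond the z deviations themselves
  truth <- small_phantom(
    behavior = list(beta = 30, resid_sd = 0, recovery_mean = 30.1,
                    recovery_slope = 20, recovery_sd = 0),
    sensory = list(z_delta = 0, fma_ue = 0, fma_le = 0))
  cohort <- simulate_cohort(truth, seed = 21L)
  pat <- cohort$manifest[cohort$manifest$group == "patient", ]
  z <- vapply(pat$subject_id, function(id) {
    s <- cohort$subjects[[id]]
    rec <- pat[pat$subject_id == id, ]
    s$z_targets[rec$lesion_side, "somatosensory"]
  }, 0)
  # scores are integer-rounded and clamped to the scale bounds, so the
  # zero-noise limit is exact up to that discretization
  expect_gt(cor(z, pat$fma_ue_t1), 0.99)
})

test_that("planted pair z table has the planted group structure", {
  truth <- small_phantom()
  cohort <- simulate_cohort(truth, seed = 31L)
  tab <- simulate_pair_z(cohort)
  expect_equal(nrow(tab), 103L * 12L)
  agg <- function(g, side, roi)
    mean(tab$z[tab$group == g & tab$side == side & tab$roi == roi])
  expect_lt(agg("patient", "ipsilesional", "somatosensory"),
            agg("control", "ipsilesional", "somatosensory"))
  expect_gt(agg("patient", "ipsilesional", "occipital"),
            agg("control", "ipsilesional", "occipital"))
})

test_that("BOLD path and connectivity-level fast path agree in law", {
  # same cohort plan, measured through the imaging stack vs drawn from the
  # connectivity-level model: group means of ipsilesional somatosensory z
  # must agree within Monte-Carlo error
  truth <- small_phantom()
  cohort <- simulate_cohort(truth, seed = 41L)
  full <- analyze_cohort(cohort)$conn
  fast <- simulate_pair_z(cohort)
  for (g in c("patient", "control")) {
    a <- full$z[full$group == g & full$side == "ipsilesional" &
                  full$roi == "somatosensory"]
    b <- fast$z[fast$group == g & fast$side == "ipsilesional" &
                  fast$roi == "somatosensory"]
    expect_lt(abs(mean(a) - mean(b)), 0.12)
    expect_lt(abs(sd(a) - sd(b)), 0.12)
  }
})

test_that("write_cohort produces a loadable on-disk dataset", {
  truth <- small_phantom()
  cohort <- simulate_cohort(truth, n_patients = 2, n_controls = 2,
                            n_timepoints = 70, seed = 51L)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  expect_length(list.files(dir, pattern = "_bold\\.nii$"), 4L)
  m <- read_manifest(file.path(dir, "manifest.tsv"))
  expect_equal(nrow(m), 4L)
  v <- load_volume4d(file.path(dir, m$bold_path[1]))
  s <- realize_subject(cohort, m$subject_id[1])
  expect_identical(v$data, s$vol$data)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$seed, 51L)
  expect_equal(length(gt$assignment_index),
               sum(truth$assignment > 0L))
})
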