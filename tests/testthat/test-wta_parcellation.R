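# wta_parcellation: ROI series, voxelwise correlations, winner-take-all,
# group maps, confidence rendering

test_that("roi_mean_timeseries is the unweighted mask mean", {
  vol <- toy_volume(6L, 20L)
  arr <- array(0L, c(6, 6, 6)); arr[2, 3, 4] <- 1L
  one <- label_volume(arr, toy_affine(6))
  expect_equal(roi_mean_timeseries(vol, one)[, 1], vol$data[2, 3, 4, ])

  # two voxels with series s and -s average to zero
  d <- array(0, c(6, 6, 6, 20))
  d[1, 1, 1, ] <- sin(1:20); d[2, 1, 1, ] <- -sin(1:20)
  v2 <- volume4d(d, toy_affine(6), 2)
  arr2 <- array(0L, c(6, 6, 6)); arr2[1:2, 1, 1] <- 1L
  expect_equal(roi_mean_timeseries(v2, label_volume(arr2, toy_affine(6))),
               matrix(0, 20, 1), tolerance = 1e-14)

  empty <- label_volume(array(0L, c(6, 6, 6)), toy_affine(6))
  expect_error(roi_mean_timeseries(vol, empty), "empty mask")
})

test_that("phantom ROI mean recovers the latent source at high SNR", {
  truth <- small_phantom(noise_sd = 0.2)
  s <- simulate_subject(truth, n_timepoints = 100, seed = 3L)
  v <- clean_pipeline(s$vol, confound_set(s$motion, s$wm, s$csf))
  # source proxy: noise-free sibling subject shares the seed, so its ROI
  # mean is the band-passed source itself
  s0 <- simulate_subject(small_phantom(noise_sd = 0), n_timepoints = 100,
                         seed = 3L)
  v0 <- clean_pipeline(s0$vol, confound_set(s0$motion, s0$wm, s0$csf))
  for (k in c(1L, 4L)) {
    m <- truth$cortex[[k]]
    expect_gt(cor(roi_mean_timeseries(v, m), roi_mean_timeseries(v0, m)),
              0.95)
  }
})

test_that("voxel_cortex_correlations matches a per-voxel loop oracle", {
  truth <- small_phantom()
  s <- simulate_subject(truth, n_timepoints = 80, seed = 17L)
  v <- clean_pipeline(s$vol, confound_set(s$motion, s$wm, s$csf))
  cts <- do.call(cbind, lapply(truth$cortex, function(m)
    roi_mean_timeseries(v, m)))
  cm <- voxel_cortex_correlations(v, truth$thalamus$left, cts)
  ts <- mask_timeseries(v, truth$thalamus$left)
  oracle <- matrix(0, ncol(ts), 6)
  for (i in seq_len(ncol(ts)))
    for (j in 1:6) oracle[i, j] <- cor(ts[, i], cts[, j])
  expect_equal(unname(cm$r), oracle, tolerance = 1e-12)
  expect_true(all(abs(cm$r) <= 1))
})

test_that("zero-variance voxels get r = 0 with a warning", {
  d <- array(rnorm(6^3 * 30), c(6, 6, 6, 30))
  d[3, 3, 3, ] <- 7            # constant voxel
  v <- volume4d(d, toy_affine(6), 2)
  arr <- array(0L, c(6, 6, 6)); arr[3, 3, 3:4] <- 1L
  th <- label_volume(arr, toy_affine(6))
  cts <- matrix(rnorm(180), 30, 6)
  expect_warning(cm <- voxel_cortex_correlations(v, th, cts),
                 "zero-variance")
  flat_row <- which(cm$voxel_index == which(arr > 0)[1])
  expect_equal(unname(cm$r[flat_row, ]), rep(0, 6))
})

test_that("winner_take_all follows argmax, tie-break and unassigned rules", {
  mk <- function(rows) structure(
    list(r = rows, voxel_index = seq_len(nrow(rows)), dim = c(4, 4, 4),
         affine = toy_affine(4), side = NA), class = "correlation_maps")
  w <- winner_take_all(mk(rbind(
    c(0.1, 0.5, 0.2, 0.0, -0.1, 0.3),
    c(0.4, 0.4, 0, 0, 0, 0),
    c(-0.2, -0.1, -0.3, -0.4, -0.5, -0.6))))
  expect_equal(w$label, c(2L, 1L, 0L))
  expect_equal(w$winning_r[1], 0.5)
  expect_equal(w$winning_r[2], 0.4)
})

test_that("noise-free subject recovers the planted assignment exactly", {
  truth <- small_phantom(noise_sd = 0)
  for (side in c("left", "right")) {
    w <- winner_take_all(subject_cm(truth, side, seed = 2L))
    expect_equal(w$label, true_labels(truth, side))
    expect_true(all(w$winning_r > 0.99))
  }
})

test_that("group_wta of one subject equals its individual map", {
  truth <- small_phantom()
  cm <- subject_cm(truth, "left", seed = 8L)
  g1 <- group_wta(list(cm))
  expect_equal(g1$label, winner_take_all(cm)$label)
  expect_equal(g1$agreement, rep(1, length(g1$label)))
  g3 <- group_wta(list(cm, cm, cm))
  expect_equal(g3$label, g1$label)
  expect_equal(g3$agreement, rep(1, length(g3$label)))
  expect_error(group_wta(list()), "empty")
})

test_that("ROI permutation equivariance", {
  truth <- small_phantom()
  cm <- subject_cm(truth, "left", seed = 12L)
  perm <- c(3L, 1L, 2L, 6L, 4L, 5L)
  cmp <- cm; cmp$r <- cm$r[, perm]
  w <- winner_take_all(cm); wp <- winner_take_all(cmp)
  relabel <- match(seq_len(6), perm)   # old label -> new label
  expect_equal(wp$label[w$label > 0],
               relabel[w$label[w$label > 0]])
  expect_equal(wp$winning_r, w$winning_r)
})

test_that("group recovery is monotone nonincreasing in noise", {
  acc <- vapply(c(0.5, 1.5, 4), function(ns) {
    truth <- small_phantom(noise_sd = ns)
    cms <- lapply(1:5, function(i)
      subject_cm(truth, "left", seed = 100L + i, tframes = 80L))
    mean(group_wta(cms)$label == true_labels(truth, "left"))
  }, 0)
  expect_true(all(diff(acc) <= 0))
  expect_gt(acc[1], 0.95)
})

test_that("zmean and vote group rules agree away from boundaries", {
  truth <- small_phantom()
  cms <- lapply(1:6, function(i) subject_cm(truth, "right",
                                            seed = 300L + i))
  gz <- group_wta(cms, "zmean"); gv <- group_wta(cms, "vote")
  expect_gt(mean(gz$label == gv$label), 0.85)
})

test_that("pure-noise voxels stay inside the null band of Pearson r", {
  # null distribution of Pearson r at T = 200 (sd ~ 1/sqrt(T)):
  # |r| < 0.25 with probability > 0.99 per (voxel, ROI)
  set.seed(77)
  d <- array(rnorm(6^3 * 200), c(6, 6, 6, 200))
  v <- volume4d(d, toy_affine(6), 2)
  arr <- array(0L, c(6, 6, 6)); arr[2:5, 2:5, 3] <- 1L   # 16 noise voxels
  th <- label_volume(arr, toy_affine(6))
  cts <- matrix(rnorm(200 * 6), 200, 6)       # independent null series
  cm <- voxel_cortex_correlations(v, th, cts)
  expect_gte(mean(abs(cm$r) < 0.25), 0.99)
})

test_that("group subregion maps are mirror-symmetric on the phantom", {
  truth <- small_phantom()
  cohort <- simulate_cohort(truth, n_patients = 0L, n_controls = 8L,
                            seed = 19L)
  res <- analyze_cohort(cohort)
  # mirror the left-thalamus voxel order onto the right mask
  gs <- truth$grid_shape
  idxL <- which(truth$thalamus$left$data > 0L)
  idxR <- which(truth$thalamus$right$data > 0L)
  co <- arrayInd(idxL, gs); co[, 1] <- gs[1] + 1L - co[, 1]
  mirrored <- match(
    (co[, 1] - 1) + gs[1] * ((co[, 2] - 1) + gs[2] * (co[, 3] - 1)),
    (arrayInd(idxR, gs)[, 1] - 1) +
      gs[1] * ((arrayInd(idxR, gs)[, 2] - 1) +
                 gs[2] * (arrayInd(idxR, gs)[, 3] - 1)))
  agree <- mean(res$wta$left$label == res$wta$right$label[mirrored])
  expect_gte(agree, 0.9)
})

test_that("render_confidence maps the ROI max to 100 with a 50 floor", {
  truth <- small_phantom()
  g <- group_wta(lapply(1:3, function(i)
    subject_cm(truth, "left", seed = 40L + i)))
  rc <- render_confidence(g)
  for (k in 1:6) {
    sel <- g$label == k
    if (!any(sel)) next
    expect_equal(max(rc$value[sel]), 100)
    expect_gte(min(rc$value[sel]), 50)
    # monotone: higher winning r never displays lower
    o <- order(g$winning_r[sel])
    expect_true(all(diff(rc$value[sel][o]) >= -1e-12))
  }
  expect_equal(sum(wta_summary(g)$n_voxels), length(g$label))
})
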