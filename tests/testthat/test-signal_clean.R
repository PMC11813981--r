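# signal_clean: discard, motion QC, detrend, band-pass, nuisance
# regression, full pipeline properties

test_that("discard_initial drops exactly the leading frames", {
  vol <- toy_volume(6L, 40L)
  out <- discard_initial(vol, 5L)
  expect_equal(dim(out$data)[4], 35L)
  expect_identical(out$data[, , , 1], vol$data[, , , 6])
  expect_identical(discard_initial(vol, 0L), vol)
  short <- toy_volume(6L, 5L)
  expect_error(discard_initial(short, 5L), "cannot discard")
})

test_that("motion_qc thresholds translation strictly above 3 mm", {
  zeros <- matrix(0, 20, 6)
  q <- motion_qc(zeros)
  expect_true(q$pass)
  expect_equal(q$max_translation_mm, 0)

  spike <- zeros; spike[7, 1] <- 3.5
  expect_false(motion_qc(spike)$pass)

  edge <- zeros; edge[3, 2] <- 3.0        # exactly 3 mm passes (> 3 rule)
  expect_true(motion_qc(edge)$pass)

  rot <- zeros; rot[5, 5] <- 10           # rotations reported, not gated
  expect_true(motion_qc(rot)$pass)
  expect_equal(motion_qc(rot)$max_rotation, 10)

  expect_error(motion_qc(zeros[, 1:5]), "6 columns")
})

test_that("detrend_linear matches a normal-equations oracle", {
  expect_equal(detrend_linear(matrix(5, 10, 1)), matrix(0, 10, 1))
  expect_equal(detrend_linear(matrix(2 * (1:10), ncol = 1)),
               matrix(0, 10, 1))
  set.seed(4)
  y <- matrix(rnorm(50), 25, 2)
  X <- cbind(1, 1:25)
  oracle <- y - X %*% solve(t(X) %*% X, t(X) %*% y)  # direct solve
  expect_equal(detrend_linear(y), oracle, tolerance = 1e-12)
  expect_error(detrend_linear(matrix(1, 2, 1)), "at least 3")
})

test_that("bandpass meets the pass/stop amplitude contracts (FFT oracle)", {
  tr <- 0.5; T_ <- 512
  tt <- (0:(T_ - 1)) * tr
  amp <- function(x, f) {       # FFT amplitude at frequency f
    sp <- abs(fft(x)) / (T_ / 2)
    sp[round(f * T_ * tr) + 1]
  }
  pass <- matrix(sin(2 * pi * 0.04 * tt), ncol = 1)
  out <- bandpass(pass, tr)
  expect_gt(amp(out[, 1], 0.04) / amp(pass[, 1], 0.04), 0.9)

  stopb <- matrix(sin(2 * pi * 0.2 * tt), ncol = 1)
  outs <- bandpass(stopb, tr)
  expect_lt(max(abs(outs)) / max(abs(stopb)), 0.1)

  expect_equal(bandpass(matrix(0, 64, 2), tr), matrix(0, 64, 2))
  expect_error(bandpass(pass, tr, high = 1.1), "Nyquist")
  expect_error(bandpass(pass, tr, low = 0.09, high = 0.08), "below")
})

test_that("regress_nuisance projects out confounds exactly", {
  set.seed(5)
  conf <- matrix(rnorm(60), 20, 3)
  expect_lt(max(abs(regress_nuisance(conf[, 1, drop = FALSE], conf))),
            1e-10)

  y <- matrix(rnorm(40), 20, 2)
  centered <- regress_nuisance(y, matrix(0, 20, 2)[, 0])  # intercept only
  expect_equal(colMeans(centered), c(0, 0), tolerance = 1e-12)

  res <- regress_nuisance(y, conf)
  X <- cbind(1, conf)
  oracle <- y - X %*% solve(t(X) %*% X, t(X) %*% y)
  expect_equal(res, oracle, tolerance = 1e-10)
  expect_lt(max(abs(t(conf) %*% res)) / max(abs(y)), 1e-8)

  dup <- cbind(a = conf[, 1], b = conf[, 1])
  expect_error(regress_nuisance(y, dup), "collinear")
  expect_error(regress_nuisance(y, conf[1:10, ]), "!= timepoints")
})

test_that("clean_pipeline is deterministic, zero-mean, and ordered", {
  truth <- small_phantom()
  s <- simulate_subject(truth, n_timepoints = 80, seed = 9L)
  conf <- confound_set(s$motion, s$wm, s$csf)
  v1 <- clean_pipeline(s$vol, conf)
  v2 <- clean_pipeline(s$vol, conf)
  expect_identical(v1$data, v2$data)
  expect_true(all(is.finite(v1$data)))
  ts <- mask_timeseries(v1, truth$thalamus$left)
  expect_lt(max(abs(colMeans(ts))), 1e-8)
  log <- attr(v1, "clean_log")
  expect_equal(log$order, c("discard", "detrend", "bandpass", "regress"))
  expect_false(log$global_signal_regression)
  expect_false(log$spatial_smoothing)
})

test_that("clean_pipeline is a linear operator (superposition)", {
  truth <- small_phantom()
  a <- simulate_subject(truth, n_timepoints = 70, seed = 21L)
  b <- simulate_subject(truth, n_timepoints = 70, seed = 22L)
  conf <- confound_set(a$motion, a$wm, a$csf)
  vsum <- volume4d(a$vol$data + b$vol$data, a$vol$affine, a$vol$tr)
  lhs <- clean_pipeline(vsum, conf)$data
  rhs <- clean_pipeline(a$vol, conf)$data + clean_pipeline(b$vol, conf)$data
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("cleaning preserves in-band planted correlation structure", {
  # noise-free-limit subject: the planted thalamus-to-ROI correlations
  # are in-band, so the cleaning chain must leave them (near) unchanged
  truth <- small_phantom(noise_sd = 0)
  s <- simulate_subject(truth, n_timepoints = 120, seed = 31L)
  raw <- discard_initial(s$vol, 5L)
  v <- clean_pipeline(s$vol, confound_set(s$motion, s$wm, s$csf))
  lab <- true_labels(truth, "left")
  cor_with_true <- function(vol) {
    cts <- do.call(cbind, lapply(truth$cortex, function(m)
      roi_mean_timeseries(vol, m)))
    cm <- voxel_cortex_correlations(vol, truth$thalamus$left, cts)
    cm$r[cbind(seq_along(lab), lab)]
  }
  expect_lt(mean(abs(cor_with_true(v) - cor_with_true(raw))), 0.05)
})

test_that("clean_timeseries equals the masked volume pipeline", {
  truth <- small_phantom()
  s <- simulate_subject(truth, n_timepoints = 70, seed = 41L)
  conf <- confound_set(s$motion, s$wm, s$csf)
  mask <- truth$thalamus$right
  v <- clean_pipeline(s$vol, conf, mask = mask)
  direct <- clean_timeseries(
    mask_timeseries(discard_initial(s$vol, 5L), mask), s$vol$tr, conf)
  expect_equal(mask_timeseries(v, mask), direct, tolerance = 1e-12)
})
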