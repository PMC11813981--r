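# group_inference: t tests, ROI-pair contrasts, permutation cluster FWE,
# CR-MF, behavioral correlations, sensory subgroups, chi-square,
# demographics

test_that("two_sample_t reproduces the pooled formula and symmetries", {
  r <- two_sample_t(1:3, 4:6)
  expect_equal(r$t, -3.674235, tolerance = 1e-6)
  expect_equal(r$df, 4)

  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  flat <- two_sample_t(c(2, 2), c(2, 2))
  expect_equal(flat$t, 0); expect_equal(flat$p, 1)
  expect_error(two_sample_t(c(2, 2), c(3, 3)), "zero variance")
  expect_error(two_sample_t(1, 1:4), "at least 2")

  set.seed(8)
  a <- rnorm(6); b <- rnorm(7, 0.5)
  fw <- two_sample_t(a, b); bw <- two_sample_t(b, a)
  expect_equal(fw$t, -bw$t)
  expect_equal(fw$p, bw$p)
  # agrees with stats::t.test in both variants
  expect_equal(fw$p, t.test(a, b, var.equal = TRUE)$p.value)
  w <- two_sample_t(a, b, "welch")
  expect_equal(w$p, t.test(a, b)$p.value)
})

test_that("pooled t p-value matches an exact permutation oracle", {
  set.seed(9)
  a <- rnorm(4); b <- rnorm(4, 1)
  t_obs <- two_sample_t(a, b)$t
  pool <- c(a, b)
  combos <- combn(8, 4)
  t_perm <- apply(combos, 2, function(ix)
    two_sample_t(pool[ix], pool[-ix])$t)
  p_perm <- mean(abs(t_perm) >= abs(t_obs) - 1e-12)
  expect_lt(abs(two_sample_t(a, b)$p - p_perm), 0.06)
})

test_that("roi_pair_contrasts runs 12 deterministic tests with planted signs", {
  truth <- small_phantom()
  cohort <- simulate_cohort(truth, seed = 61L)
  conn <- simulate_pair_z(cohort)
  ct <- roi_pair_contrasts(conn)
  expect_equal(nrow(ct), 12L)
  expect_equal(ct$n_patient, rep(39L, 12))
  expect_equal(ct$n_control, rep(64L, 12))
  expect_lt(ct$t[ct$side == "ipsilesional" & ct$roi == "somatosensory"],
            0)
  expect_gt(ct$t[ct$side == "ipsilesional" & ct$roi == "occipital"], 0)
  ct2 <- roi_pair_contrasts(simulate_pair_z(cohort))
  # the z table is stochastic but the contrast of a fixed table is not
  expect_identical(roi_pair_contrasts(conn), ct)
  expect_false(identical(ct2$t, ct$t))

  ind <- roi_pair_contrasts(conn, control_mode = "independent")
  expect_equal(ind$n_control, rep(32L, 12))
  fdr <- roi_pair_contrasts(conn, fdr = TRUE)
  expect_true(all(fdr$p_fdr >= fdr$p - 1e-12))
})

test_that("planted somatosensory effect is detected with the right sign", {
  truth <- small_phantom()
  hits <- vapply(1:10, function(r) {
    cohort <- simulate_cohort(truth, seed = 700L + r)
    ct <- roi_pair_contrasts(simulate_pair_z(cohort))
    row <- ct[ct$side == "ipsilesional" & ct$roi == "somatosensory", ]
    row$p < 0.05 && row$t < 0
  }, NA)
  expect_gte(mean(hits), 0.9)
})

test_that("perm_cluster_fwe obeys its formula bounds and monotonicity", {
  set.seed(12)
  dims <- c(12L, 12L, 12L)
  aff <- toy_affine(12)
  mask <- label_volume(array(1L, dims), aff)
  mk <- function(eff = 0) {
    a <- gaussian_smooth3d(array(rnorm(prod(dims)), dims), 1)
    a <- a / sd(a)
    a[5:8, 5:8, 5:8] <- a[5:8, 5:8, 5:8] + eff
    a
  }
  A <- lapply(1:8, function(i) mk(1.5))
  B <- lapply(1:8, function(i) mk(0))
  cr <- perm_cluster_fwe(A, B, mask, n_perm = 400, seed = 3L)
  cl <- cr$clusters
  expect_true(all(cl$p_fwe > 0 & cl$p_fwe <= 1))
  expect_gte(min(cl$p_fwe), 1 / (1 + cr$n_perm))
  # the planted block is the top cluster and significant
  top <- cl[1, ]
  expect_equal(top$contrast, "a>b")
  expect_lte(top$p_fwe, 0.05)
  expect_true(all(abs(c(top$peak_x, top$peak_y, top$peak_z)) <= 5))
  # corrected p monotone nonincreasing in extent within a contrast
  ab <- cl[cl$contrast == "a>b", ]
  o <- order(ab$extent)
  expect_true(all(diff(ab$p_fwe[o]) <= 1e-12))
  # determinism under the seed
  cr2 <- perm_cluster_fwe(A, B, mask, n_perm = 400, seed = 3L)
  expect_identical(cr$clusters, cr2$clusters)
})

test_that("perm_cluster_fwe enumerates exactly when permutations are few", {
  set.seed(13)
  dims <- c(8L, 8L, 8L)
  mask <- label_volume(array(1L, dims), toy_affine(8))
  A <- lapply(1:5, function(i) array(rnorm(512), dims))
  B <- lapply(1:5, function(i) array(rnorm(512), dims))
  cr <- perm_cluster_fwe(A, B, mask, n_perm = 1000, seed = 1L)
  expect_true(cr$exact)
  expect_equal(cr$n_perm, choose(10, 5))
  suppressWarnings(          # n_perm < 100 also warns before erroring
    expect_error(perm_cluster_fwe(A[1:4], B, mask, n_perm = 10,
                                  seed = 1L), "at least 5"))
})

test_that("label_components identifies 26- and 6-connected clusters", {
  dims <- c(6L, 6L, 6L)
  # two voxels touching only diagonally: one 26-cluster, two 6-clusters
  co <- rbind(c(2, 2, 2), c(3, 3, 3), c(6, 6, 6))
  c26 <- label_components(co, dims, 26L)
  expect_equal(length(unique(c26)), 2L)
  expect_equal(c26[1], c26[2])
  c6 <- label_components(co, dims, 6L)
  expect_equal(length(unique(c6)), 3L)
})

test_that("cr_mf matches its closed form and is antisymmetric", {
  expect_lt(abs(cr_mf(52.7, 22.6) - 0.39973), 5e-6)  # printed precision
  expect_equal(cr_mf(10, 10), 0)
  expect_equal(cr_mf(66, 0), 1)
  expect_true(is.na(cr_mf(0, 0)))
  expect_error(cr_mf(-1, 5), ">= 0")
  for (p in list(c(30, 12), c(5, 60), c(1, 1)))
    expect_equal(cr_mf(p[1], p[2]), -cr_mf(p[2], p[1]))
  expect_true(all(abs(cr_mf(0:66, rep(33, 67))) <= 1, na.rm = TRUE))
})

test_that("behavior_correlation gates on normality and matches oracles", {
  set.seed(14)
  x <- rnorm(30); y <- 0.8 * x + rnorm(30, 0, 0.5)
  res <- behavior_correlation(x, y)
  expect_equal(res$method, "pearson")
  expect_equal(res$r, cor(x, y))
  expect_equal(res$n, 30L)

  lin <- behavior_correlation(1:10 / 10 - 0.5, 3 + 2 * (1:10))
  expect_equal(lin$r, 1, tolerance = 1e-12)

  # heavy-tailed input -> spearman; equals rank-then-pearson oracle
  xe <- exp(rnorm(40, 0, 2)); ye <- xe + exp(rnorm(40, 0, 2))
  rs <- behavior_correlation(xe, ye)
  expect_equal(rs$method, "spearman")
  expect_equal(rs$r, cor(rank(xe), rank(ye)), tolerance = 1e-12)

  expect_error(behavior_correlation(rep(1, 10), rnorm(10)), "constant")
  expect_error(behavior_correlation(1:2, 2:3), "at least 3")
})

test_that("sensory subgrouping splits 19/20 and detects planted deficits", {
  truth <- small_phantom()
  cohort <- simulate_cohort(truth, seed = 71L)
  conn <- simulate_pair_z(cohort)
  res <- sensory_subgroup_compare(cohort$manifest, conn)
  expect_equal(res$n_impaired, 19L)
  expect_equal(res$n_nonimpaired, 20L)
  # impaired group planted lower on both measures
  expect_lt(res$connectivity_test$mean_diff, 0)
  expect_lt(res$fma_test$mean_diff, 0)

  m_all0 <- cohort$manifest
  m_all0$nihss_sensory_t1[m_all0$group == "patient"] <- 0L
  expect_error(sensory_subgroup_compare(m_all0, conn), "size < 2")
})

test_that("chi_square_2x2 reproduces the reference demographics statistics", {
  # 2x2 counts are inputs (patients yes/no, controls yes/no); reference
  # statistics are printed to 3 decimals
  expect_equal(round(chi_square_2x2(29, 10, 24, 8)$chisq, 3), 0.004)
  expect_equal(round(chi_square_2x2(17, 22, 9, 23)$chisq, 3), 1.811)
  expect_equal(chi_square_2x2(5, 5, 3, 3)$chisq, 0)   # ad = bc
  # invariance under simultaneous row and column swap
  expect_equal(chi_square_2x2(17, 22, 9, 23)$chisq,
               chi_square_2x2(23, 9, 22, 17)$chisq)
  # matches stats::chisq.test without continuity correction
  tab <- matrix(c(13, 26, 6, 26), 2, byrow = TRUE)
  expect_equal(chi_square_2x2(13, 26, 6, 26)$chisq,
               unname(chisq.test(tab, correct = FALSE)$statistic))
  expect_error(chi_square_2x2(0, 0, 3, 4), "zero margin")
})

test_that("demographics_table summarizes the synthetic manifest", {
  m <- toy_manifest()
  tab <- demographics_table(m)
  expect_true(all(c("age", "male", "smoke") %in% tab$variable))
  expect_true(all(is.finite(tab$statistic)))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  # identical binary trait -> chi-square 0
  m2 <- m; m2$smoke <- 1L; m2$smoke[1] <- 0L
  m2$smoke <- rep(c(0L, 1L), length.out = nrow(m2))
  m3 <- m; m3$diabetes <- rep(1L, nrow(m))
  tab3 <- demographics_table(m3)
  expect_equal(tab3$statistic[tab3$variable == "diabetes"], 0)
})
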