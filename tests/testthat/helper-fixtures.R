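# Shared fixtures, built in code. All tests use small grids (16^3 unless a
# criterion states otherwise) and fixed seeds.

toy_affine <- function(n = 8L, vx = 2) {
  a <- diag(c(vx, vx, vx, 1))
  a[1:3, 4] <- -vx * (n - 1) / 2
  a
}

toy_volume <- function(n = 8L, tframes = 40L, seed = 1L, vx = 2) {
  set.seed(seed)
  volume4d(array(stats::rnorm(n^3 * tframes), c(n, n, n, tframes)),
           toy_affine(n, vx), tr = 2)
}

small_phantom <- function(...) make_phantom(c(16L, 16L, 16L), ...)

# phantom voxel-assignment labels restricted to one thalamus mask, in the
# voxel order used by correlation maps (column-major which())
true_labels <- function(truth, side) {
  truth$assignment[which(truth$thalamus[[side]]$data > 0L)]
}

# one cleaned subject with its correlation maps for one thalamus
subject_cm <- function(truth, side = "left", seed = 1L, tframes = 100L,
                       group = "control", lesion = "none") {
  s <- simulate_subject(truth, group, lesion, tframes, 2, seed = seed)
  v <- clean_pipeline(s$vol, confound_set(s$motion, s$wm, s$csf))
  cts <- do.call(cbind, lapply(truth$cortex, function(m)
    roi_mean_timeseries(v, m)))
  voxel_cortex_correlations(v, truth$thalamus[[side]], cts, side = side)
}

# manifest with the reference cohort composition (39 patients, 32 controls)
toy_manifest <- function(n_pat = 39L, n_con = 32L, n_left = 17L) {
  simulate_cohort(small_phantom(), n_pat, n_con, seed = 11L)$manifest
}
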