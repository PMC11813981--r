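# Group statistics: two-sample t tests on ROI-pair z values, permutation
# cluster-level FWE on voxelwise contrasts, behavioral correlations, the
# motor-function change rate, sensory subgrouping, and demographics-table
# tests.

#' Two-sample t test
#'
#' Student (pooled variance) by default, Welch selectable; two-tailed p.
#'
#' @param a,b Numeric vectors (each n >= 2).
#' @param variant `"student"` (pooled) or `"welch"`.
#' @return List: `t`, `p` (two-tailed), `df`, `mean_diff` (`mean(a) -
#'   mean(b)`).
#' @export
two_sample_t <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 values")
  va <- stats::var(a); vb <- stats::var(b)
  md <- mean(a) - mean(b)
  if (variant == "student") {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    df <- na + nb - 2
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  if (se == 0) {
    if (md == 0) return(list(t = 0, p = 1, df = df, mean_diff = 0))
    stop("zero variance in both groups with unequal means")
  }
  tt <- md / se
  list(t = tt, p = 2 * stats::pt(-abs(tt), df), df = df, mean_diff = md)
}

#' Assemble a cohort connectivity table
#'
#' Stacks per-entry [roi_pair_connectivity()] outputs and maps hemispheres
#' to analysis sides. After harmonization the right hemisphere is
#' ipsilesional and the left contralesional, for patients and
#' flip-augmented control entries alike.
#'
#' @param entry_tables Named list (by entry id) of per-entry data frames
#'   from [roi_pair_connectivity()].
#' @param plan Harmonization plan ([harmonize_plan()]) with one row per
#'   entry, in the same order.
#' @return Long data frame with columns `entry_id`, `subject_id`, `group`,
#'   `provenance`, `side` (`ipsilesional`/`contralesional`), `roi`, `r`,
#'   `z`.
#' @export
cohort_connectivity <- function(entry_tables, plan) {
  stopifnot(length(entry_tables) == nrow(plan))
  out <- vector("list", length(entry_tables))
  for (i in seq_along(entry_tables)) {
    tab <- entry_tables[[i]]
    tab$side <- ifelse(tab$side == "right", "ipsilesional", "contralesional")
    tab$entry_id <- plan$entry_id[i]
    tab$subject_id <- plan$subject_id[i]
    tab$group <- plan$group[i]
    tab$provenance <- plan$provenance[i]
    out[[i]] <- tab
  }
  do.call(rbind, out)
}

#' Patient-versus-control contrast for one ROI pair
#'
#' Two-sample t test on Fisher-z connectivity, patients minus controls.
#' In the default `"augmented"` mode the control sample is the 64
#' flip-augmented entries (each original subject counted with both
#' hemispheres, mirroring the reference study design); `"independent"` uses
#' the 32 original subjects only, averaging each subject's two
#' hemispheres on the z scale, and is the calibrated choice.
#'
#' @param conn Cohort connectivity table ([cohort_connectivity()]).
#' @param side `"ipsilesional"` or `"contralesional"` (patient side).
#' @param roi One of [ROI_NAMES].
#' @param control_mode `"augmented"` (default) or `"independent"`.
#' @param variant Passed to [two_sample_t()].
#' @return List from [two_sample_t()] plus `side`, `roi`, `n_patient`,
#'   `n_control`.
#' @export
roi_pair_contrast <- function(conn, side, roi,
                              control_mode = c("augmented", "independent"),
                              variant = "student") {
  control_mode <- match.arg(control_mode)
  side <- match.arg(side, c("ipsilesional", "contralesional"))
  roi <- match.arg(roi, ROI_NAMES)
  pat <- conn$z[conn$group == "patient" & conn$side == side &
                  conn$roi == roi]
  if (control_mode == "augmented") {
    con <- conn$z[conn$group == "control" & conn$side == side &
                    conn$roi == roi]
  } else {
    cc <- conn[conn$group == "control" & conn$provenance == "original" &
                 conn$roi == roi, , drop = FALSE]
    con <- tapply(cc$z, cc$subject_id, mean)
  }
  pat <- pat[!is.na(pat)]; con <- con[!is.na(con)]
  if (length(pat) == 0L || length(con) == 0L) stop("empty group")
  res <- two_sample_t(pat, con, variant)
  c(res, list(side = side, roi = roi,
              n_patient = length(pat), n_control = length(con)))
}

#' All 12 ROI-pair contrasts
#'
#' @inheritParams roi_pair_contrast
#' @param fdr Add Benjamini-Hochberg adjusted p values (off by default;
#'   the reference design uses uncorrected alpha = 0.05).
#' @return Data frame, one row per (side, ROI).
#' @export
roi_pair_contrasts <- function(conn, control_mode = "augmented",
                               variant = "student", fdr = FALSE) {
  grid <- expand.grid(side = c("ipsilesional", "contralesional"),
                      roi = ROI_NAMES, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    r <- roi_pair_contrast(conn, grid$side[i], grid$roi[i],
                           control_mode, variant)
    data.frame(side = r$side, roi = r$roi, t = r$t, df = r$df, p = r$p,
               mean_diff = r$mean_diff, n_patient = r$n_patient,
               n_control = r$n_control, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (fdr) out$p_fdr <- stats::p.adjust(out$p, "BH")
  out
}

# ---- connected components ------------------------------------------------

neighbor_offsets <- function(connectivity = 26L) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6L) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  off
}

# Label connected components among `coords` (k x 3 integer voxel indices,
# 1-based) under 26- or 6-connectivity. Returns an integer component id
# per row. Union-find; intended for sparse suprathreshold sets.
label_components <- function(coords, dims, connectivity = 26L,
                             offsets = neighbor_offsets(connectivity)) {
  k <- nrow(coords)
  if (k == 0L) return(integer(0))
  if (k == 1L) return(1L)
  # adjacency via hashed voxel keys: one match per neighbor offset
  keys <- (coords[, 1] - 1) + dims[1] * ((coords[, 2] - 1) +
                                           dims[2] * (coords[, 3] - 1))
  dkey <- offsets[, 1] + dims[1] * (offsets[, 2] + dims[2] * offsets[, 3])
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (o in seq_len(nrow(offsets))) {
    # key arithmetic would wrap across the x/y faces; filter real coords
    nb1 <- coords[, 1] + offsets[o, 1]
    nb2 <- coords[, 2] + offsets[o, 2]
    nb3 <- coords[, 3] + offsets[o, 3]
    ok <- nb1 >= 1L & nb1 <= dims[1] & nb2 >= 1L & nb2 <= dims[2] &
      nb3 >= 1L & nb3 <= dims[3]
    m <- match(keys[ok] + dkey[o], keys)
    here <- which(ok)[!is.na(m)]
    there <- m[!is.na(m)]
    for (j in seq_along(here)) {
      a <- find(here[j]); b <- find(there[j])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(k), find, 0L)
  match(roots, unique(roots))
}

# Vectorized pooled-variance two-sample t maps for a set of group-label
# assignments. X is V x N; G is N x P 0/1 membership of group A.
perm_t_maps <- function(X, G, na, nb) {
  tot <- rowSums(X); tot2 <- rowSums(X^2)
  SA <- X %*% G
  QA <- (X^2) %*% G
  mA <- SA / na
  mB <- (tot - SA) / nb
  vA <- (QA - na * mA^2) / (na - 1)
  vB <- ((tot2 - QA) - nb * mB^2) / (nb - 1)
  sp2 <- ((na - 1) * vA + (nb - 1) * vB) / (na + nb - 2)
  sp2[sp2 < .Machine$double.eps] <- .Machine$double.eps
  (mA - mB) / sqrt(sp2 * (1 / na + 1 / nb))
}

#' Permutation cluster-level FWE inference on z maps
#'
#' Voxelwise pooled two-sample t map, thresholded at the cluster-forming p
#' (one-sided per contrast, both contrasts assessed separately), connected
#' clusters (26-connectivity by default), and a max-cluster-extent null
#' distribution over group-label permutations. Corrected
#' `p = (1 + #\{perm max >= observed extent\}) / (1 + n_perm)`; the
#' attainable lower bound is `1 / (1 + n_perm)`.
#'
#' When fewer distinct group assignments exist than `n_perm`, all distinct
#' assignments are enumerated exactly (up to 100000), else an error is
#' raised.
#'
#' @param maps_a,maps_b Lists of 3D arrays (e.g. `stat_map$data`), one per
#'   subject entry; group A is the "patient" side of the contrast.
#' @param mask Binary [label_volume] restricting the analysis.
#' @param cluster_forming_p One-sided voxelwise p threshold (default
#'   0.001).
#' @param n_perm Number of permutations (default 1000; < 100 warns).
#' @param seed Integer seed for the permutation draw (required).
#' @param connectivity 26 (default) or 6.
#' @return A `cluster_result`: data frame `clusters` (contrast, extent,
#'   peak world x/y/z mm, peak t, p_fwe; sorted by p then extent) plus
#'   metadata (`n_perm`, `seed`, `df`, `t_threshold`, `n_distinct`).
#' @export
perm_cluster_fwe <- function(maps_a, maps_b, mask,
                             cluster_forming_p = 0.001,
                             n_perm = 1000L, seed, connectivity = 26L) {
  if (missing(seed)) stop("a permutation seed is required")
  n_perm <- as.integer(n_perm)
  if (n_perm < 100L) warning("n_perm < 100 gives a very coarse null")
  na <- length(maps_a); nb <- length(maps_b)
  if (na < 5L || nb < 5L) stop("need at least 5 maps per group")
  idx <- which(mask$data > 0L)
  dims <- dim(mask$data)
  X <- vapply(c(maps_a, maps_b), function(m) {
    stopifnot(identical(dim(m), dims))
    m[idx]
  }, numeric(length(idx)))
  bad <- !is.finite(X)
  if (any(bad)) {
    drop <- rowSums(bad) > 0              # voxels NA in any map leave the mask
    X <- X[!drop, , drop = FALSE]
    idx <- idx[!drop]
  }
  N <- na + nb
  df <- N - 2
  t_thr <- stats::qt(1 - cluster_forming_p, df)

  n_distinct <- choose(N, na)
  exact <- n_distinct <= n_perm
  if (exact && n_distinct > 1e5)
    stop("exact enumeration infeasible (", n_distinct, " assignments)")
  if (exact) {
    combos <- utils::combn(N, na)
    G <- matrix(0, N, ncol(combos))
    G[cbind(as.vector(combos),
            rep(seq_len(ncol(combos)), each = na))] <- 1
    n_perm_used <- ncol(combos)
  } else {
    set.seed(as.integer(seed))
    G <- vapply(seq_len(n_perm), function(i) {
      g <- numeric(N); g[sample.int(N, na)] <- 1; g
    }, numeric(N))
    n_perm_used <- n_perm
  }
  Tm <- perm_t_maps(X, G, na, nb)

  t_obs <- perm_t_maps(X, matrix(c(rep(1, na), rep(0, nb)), ncol = 1),
                       na, nb)[, 1]
  coords_all <- arrayInd(idx, dims)
  offs <- neighbor_offsets(connectivity)
  max_extent <- function(tv, sign) {
    sel <- if (sign > 0) tv > t_thr else tv < -t_thr
    k <- sum(sel)
    if (k <= 1L) return(k)
    comp <- label_components(coords_all[sel, , drop = FALSE], dims,
                             connectivity, offs)
    max(tabulate(comp))
  }
  observed_clusters <- function(sign) {
    sel <- if (sign > 0) t_obs > t_thr else t_obs < -t_thr
    if (!any(sel)) return(NULL)
    co <- coords_all[sel, , drop = FALSE]
    comp <- label_components(co, dims, connectivity, offs)
    tv <- t_obs[sel]
    lapply(seq_len(max(comp)), function(cid) {
      rows <- comp == cid
      pk <- which(rows)[which.max(abs(tv[rows]))]
      world <- (co[pk, ] - 1)              # 0-based voxel
      world <- (mask$affine %*% c(world, 1))[1:3]
      list(extent = sum(rows), peak = world,
           peak_t = tv[pk])
    })
  }
  out <- list()
  for (sgn in c(1, -1)) {
    contrast <- if (sgn > 0) "a>b" else "b>a"
    null_max <- vapply(seq_len(ncol(Tm)), function(p)
      max_extent(Tm[, p], sgn), 0L)
    for (cl in observed_clusters(sgn)) {
      p_fwe <- (1 + sum(null_max >= cl$extent)) / (1 + n_perm_used)
      out[[length(out) + 1L]] <- data.frame(
        contrast = contrast, extent = cl$extent,
        peak_x = cl$peak[1], peak_y = cl$peak[2], peak_z = cl$peak[3],
        peak_t = cl$peak_t, p_fwe = p_fwe, stringsAsFactors = FALSE)
    }
  }
  clusters <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(contrast = character(), extent = integer(),
               peak_x = numeric(), peak_y = numeric(), peak_z = numeric(),
               peak_t = numeric(), p_fwe = numeric())
  clusters <- clusters[order(clusters$p_fwe, -clusters$extent), ,
                       drop = FALSE]
  rownames(clusters) <- NULL
  structure(list(clusters = clusters, n_perm = n_perm_used,
                 seed = if (exact) NA_integer_ else as.integer(seed),
                 exact = exact, df = df, t_threshold = t_thr,
                 cluster_forming_p = cluster_forming_p,
                 connectivity = connectivity, n_distinct = n_distinct),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "<cluster_result: %d cluster(s), %d permutation(s)%s, p<%g forming, %d-conn>\n",
    nrow(x$clusters), x$n_perm, if (x$exact) " (exact)" else "",
    x$cluster_forming_p, x$connectivity))
  if (nrow(x$clusters) > 0) print(x$clusters, ...)
  invisible(x)
}

# ---- behavioral / clinical statistics ------------------------------------

#' Change rate of motor function
#'
#' `(FMA_1yr - FMA_baseline) / (FMA_1yr + FMA_baseline)`, bounded in
#' [-1, 1]; controls for the ceiling effect of the FMA scale. Undefined
#' (NA) when both scores are zero.
#'
#' @param fma_t2 Score at 1 year.
#' @param fma_t1 Score at baseline.
#' @return Change rate(s); `NA` where both scores are zero.
#' @export
cr_mf <- function(fma_t2, fma_t1) {
  if (any(fma_t1 < 0 | fma_t2 < 0, na.rm = TRUE))
    stop("FMA scores must be >= 0")
  out <- (fma_t2 - fma_t1) / (fma_t2 + fma_t1)
  out[!is.na(fma_t1) & !is.na(fma_t2) & fma_t1 + fma_t2 == 0] <- NA_real_
  out
}

#' Connectivity-behavior correlation
#'
#' Pearson when both variables pass Shapiro-Wilk normality at alpha =
#' 0.05, Spearman otherwise; two-tailed p.
#'
#' @param z Connectivity values (Fisher z), one per subject.
#' @param scores Paired behavioral scores.
#' @return List: `method` (`"pearson"`/`"spearman"`), `r`, `p`, `n`.
#' @export
behavior_correlation <- function(z, scores) {
  keep <- !is.na(z) & !is.na(scores)
  z <- z[keep]; scores <- scores[keep]
  n <- length(z)
  if (n < 3L) stop("need at least 3 paired observations")
  if (stats::sd(z) == 0 || stats::sd(scores) == 0)
    stop("constant input: correlation undefined")
  normal <- stats::shapiro.test(z)$p.value >= 0.05 &&
    stats::shapiro.test(scores)$p.value >= 0.05
  method <- if (normal) "pearson" else "spearman"
  ct <- suppressWarnings(
    stats::cor.test(z, scores, method = method, exact = FALSE))
  list(method = method, r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Sensory subgroup comparison
#'
#' Splits patients on the NIHSS sensory item (impaired: item > 0) and runs
#' two independent t tests: ipsilesional somatosensory-thalamic z, and
#' whole-extremity baseline FMA (upper + lower summed, since the sensory
#' item does not distinguish extremities).
#'
#' @param manifest Validated manifest data frame.
#' @param conn Cohort connectivity table ([cohort_connectivity()]).
#' @return List: `n_impaired`, `n_nonimpaired`, `connectivity_test` and
#'   `fma_test` (each a [two_sample_t()] result; mean_diff is impaired
#'   minus nonimpaired).
#' @export
sensory_subgroup_compare <- function(manifest, conn) {
  pat <- manifest[manifest$group == "patient", , drop = FALSE]
  impaired <- pat$subject_id[pat$nihss_sensory_t1 > 0]
  nonimp <- pat$subject_id[pat$nihss_sensory_t1 == 0]
  if (length(impaired) < 2L || length(nonimp) < 2L)
    stop("sensory subgroup of size < 2 (", length(impaired), " impaired, ",
         length(nonimp), " nonimpaired)")
  zz <- conn[conn$group == "patient" & conn$side == "ipsilesional" &
               conn$roi == "somatosensory", , drop = FALSE]
  z_of <- function(ids) zz$z[match(ids, zz$subject_id)]
  fma <- pat$fma_ue_t1 + pat$fma_le_t1
  fma_of <- function(ids) fma[match(ids, pat$subject_id)]
  list(n_impaired = length(impaired), n_nonimpaired = length(nonimp),
       connectivity_test = two_sample_t(z_of(impaired), z_of(nonimp)),
       fma_test = two_sample_t(fma_of(impaired), fma_of(nonimp)))
}

#' Pearson chi-square for a 2x2 table
#'
#' No continuity correction:
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, df = 1.
#'
#' @param a,b,c,d Cell counts (row-wise: a,b top row, c,d bottom row).
#' @return List: `chisq`, `p`, `df = 1`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be >= 0")
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    stop("zero margin in 2x2 table")
  N <- sum(counts)
  chisq <- N * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE),
       df = 1L)
}

#' Demographics summary table
#'
#' Per-group means (SD) with pooled t tests for continuous traits and
#' counts (%) with 2x2 chi-squares for binary traits, for whichever of
#' the conventional demographic columns the manifest carries.
#'
#' @param manifest Manifest data frame.
#' @param continuous,binary Column names to summarize (defaults cover the
#'   generator's manifest).
#' @return Data frame: variable, patient/control summaries, statistic
#'   (`t` or `chisq`), `p`, `test`.
#' @export
demographics_table <- function(manifest,
                               continuous = c("age", "bmi", "mmse"),
                               binary = c("male", "smoke", "hypertension",
                                          "diabetes", "dyslipidemia")) {
  pat <- manifest[manifest$group == "patient", , drop = FALSE]
  con <- manifest[manifest$group == "control", , drop = FALSE]
  rows <- list()
  for (v in intersect(continuous, names(manifest))) {
    tt <- two_sample_t(pat[[v]], con[[v]])
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v,
      patients = sprintf("%.1f (±%.1f)", mean(pat[[v]]),
                         stats::sd(pat[[v]])),
      controls = sprintf("%.1f (±%.1f)", mean(con[[v]]),
                         stats::sd(con[[v]])),
      statistic = tt$t, p = tt$p, test = "t", stringsAsFactors = FALSE)
  }
  for (v in intersect(binary, names(manifest))) {
    a <- sum(pat[[v]] == 1); b <- sum(pat[[v]] == 0)
    c_ <- sum(con[[v]] == 1); d <- sum(con[[v]] == 0)
    cs <- if (a + c_ == 0 || b + d == 0)
      list(chisq = 0, p = 1) else chi_square_2x2(a, b, c_, d)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v,
      patients = sprintf("%d (%.1f%%)", a, 100 * a / nrow(pat)),
      controls = sprintf("%d (%.1f%%)", c_, 100 * c_ / nrow(con)),
      statistic = cs$chisq, p = cs$p, test = "chisq",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Separable 3D Gaussian smoothing (reflective edges); used for building
# spatially autocorrelated null maps, not for data (the pipeline applies
# no spatial smoothing).
gaussian_smooth3d <- function(arr, sigma = 1) {
  if (sigma <= 0) return(arr)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  smooth_axis <- function(a, axis) {
    d <- dim(a)
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    m <- matrix(ap, nrow = d[axis])
    n <- nrow(m)
    pad <- rbind(m[rev(seq_len(half)), , drop = FALSE], m,
                 m[n - seq_len(half) + 1L, , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * pad[(j - 1) + seq_len(n), , drop = FALSE]
    aperm(array(out, d[perm]), order(perm))
  }
  for (ax in 1:3) arr <- smooth_axis(arr, ax)
  arr
}
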