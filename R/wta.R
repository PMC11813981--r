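# Winner-take-all parcellation of the thalamus: each thalamic voxel is
# assigned to the cortical ROI whose mean BOLD time series it correlates
# with most strongly. Individual maps are computed per subject; the group
# map averages the per-ROI correlation maps on the Fisher-z scale across
# subjects before taking the argmax.

#' Mean time series over a mask
#'
#' @param vol A [volume4d] (typically cleaned).
#' @param roi Nonempty binary [label_volume] on the same grid.
#' @return T x 1 matrix: the unweighted mean over mask voxels per frame.
#' @export
roi_mean_timeseries <- function(vol, roi) {
  ts <- mask_timeseries(vol, roi)   # errors on empty mask
  matrix(rowMeans(ts), ncol = 1L)
}

#' Voxelwise thalamocortical correlations
#'
#' Pearson correlation of every thalamus-mask voxel with each of the six
#' cortical ROI mean series. Zero-variance voxels get r = 0 with a warning.
#'
#' @param vol Cleaned [volume4d].
#' @param thalamus Binary [label_volume] (one thalamus).
#' @param cortex_ts T x 6 matrix of cortical ROI mean series (columns in
#'   [ROI_NAMES] order), e.g. from [roi_mean_timeseries()].
#' @param side Optional side tag carried through to results.
#' @return A `correlation_maps` object: `r` (V x 6), `voxel_index` (linear
#'   indices into the grid), `dim`, `affine`, `side`.
#' @export
voxel_cortex_correlations <- function(vol, thalamus, cortex_ts,
                                      side = NA_character_) {
  cortex_ts <- as.matrix(cortex_ts)
  if (ncol(cortex_ts) != 6L) stop("cortex_ts must have 6 columns")
  if (nrow(cortex_ts) < 3L) stop("need at least 3 timepoints")
  ts <- mask_timeseries(vol, thalamus)
  if (nrow(ts) != nrow(cortex_ts))
    stop("timepoint mismatch between volume and cortical series")
  T_ <- nrow(ts)
  tc <- scale(ts, scale = FALSE)
  cc <- scale(cortex_ts, scale = FALSE)
  sd_t <- sqrt(colSums(tc^2) / (T_ - 1))
  sd_c <- sqrt(colSums(cc^2) / (T_ - 1))
  flat <- sd_t == 0
  if (any(flat))
    warning(sum(flat), " zero-variance thalamic voxel(s); r set to 0")
  if (any(sd_c == 0)) stop("zero-variance cortical ROI series")
  denom <- outer(pmax(sd_t, .Machine$double.xmin), sd_c) * (T_ - 1)
  r <- crossprod(tc, cc) / denom
  r[flat, ] <- 0
  r <- pmin(pmax(r, -1), 1)
  colnames(r) <- ROI_NAMES
  structure(list(r = r, voxel_index = which(thalamus$data > 0L),
                 dim = dim(thalamus$data), affine = thalamus$affine,
                 side = side),
            class = "correlation_maps")
}

#' Winner-take-all labelling
#'
#' Assigns each voxel the index (1..6) of the ROI with the largest
#' correlation. Ties break toward the lowest ROI index; voxels whose
#' maximum correlation is <= 0 are left unassigned (label 0).
#'
#' @param cm A `correlation_maps` object.
#' @return A `wta_map`: `label` (V integers in 0..6), `winning_r`,
#'   `voxel_index`, `dim`, `affine`, and `agreement` (NULL for individual
#'   maps).
#' @export
winner_take_all <- function(cm) {
  stopifnot(inherits(cm, "correlation_maps"))
  lab <- max.col(cm$r, ties.method = "first")
  win <- cm$r[cbind(seq_len(nrow(cm$r)), lab)]
  lab[win <= 0] <- 0L
  structure(list(label = as.integer(lab), winning_r = win,
                 voxel_index = cm$voxel_index, dim = cm$dim,
                 affine = cm$affine, side = cm$side, agreement = NULL),
            class = "wta_map")
}

#' Group-level winner-take-all parcellation
#'
#' Per-ROI correlation maps are Fisher-z transformed, averaged across
#' subjects, back-transformed, and the winner-take-all rule is applied to
#' the averaged maps (`method = "zmean"`, the default). The alternative
#' `method = "vote"` takes the majority of individual winners. `agreement`
#' is the fraction of subjects whose individual winner equals the group
#' winner.
#'
#' @param cms List of `correlation_maps`, one per subject entry, on a
#'   shared thalamus grid.
#' @param method `"zmean"` or `"vote"`.
#' @return A `wta_map` with `agreement` populated.
#' @export
group_wta <- function(cms, method = c("zmean", "vote")) {
  method <- match.arg(method)
  if (length(cms) == 0L) stop("empty subject list")
  vi <- cms[[1]]$voxel_index
  for (cm in cms)
    if (!identical(cm$voxel_index, vi))
      stop("subjects do not share a thalamus grid")
  zs <- lapply(cms, function(cm) atanh(pmin(pmax(cm$r, -1 + 1e-7), 1 - 1e-7)))
  zbar <- Reduce(`+`, zs) / length(zs)
  indiv <- vapply(cms, function(cm)
    winner_take_all(cm)$label, integer(length(vi)))
  indiv <- matrix(indiv, nrow = length(vi))
  if (method == "zmean") {
    gm <- winner_take_all(structure(
      list(r = tanh(zbar), voxel_index = vi, dim = cms[[1]]$dim,
           affine = cms[[1]]$affine, side = cms[[1]]$side),
      class = "correlation_maps"))
  } else {
    lab <- apply(indiv, 1, function(v) {
      v <- v[v > 0L]
      if (length(v) == 0L) return(0L)
      tab <- tabulate(v, 6L)
      which.max(tab)            # ties break to lowest index
    })
    win <- tanh(zbar)[cbind(seq_along(lab), pmax(lab, 1L))]
    win[lab == 0L] <- 0
    gm <- structure(list(label = as.integer(lab), winning_r = win,
                         voxel_index = vi, dim = cms[[1]]$dim,
                         affine = cms[[1]]$affine, side = cms[[1]]$side,
                         agreement = NULL),
                    class = "wta_map")
  }
  gm$agreement <- rowMeans(indiv == matrix(gm$label, nrow = length(vi),
                                           ncol = ncol(indiv)))
  gm
}

#' Materialize a WTA map as a label volume
#'
#' @param map A `wta_map`.
#' @return A [label_volume] with labels 0..6 on the full grid.
#' @export
wta_label_volume <- function(map) {
  arr <- array(0L, map$dim)
  arr[map$voxel_index] <- map$label
  label_volume(arr, map$affine)
}

#' Display-scaled confidence map
#'
#' Rescales each voxel's winning averaged correlation to the 50%-100%
#' range of its ROI's maximum (the conventional display for group WTA
#' parcellations): a voxel at the ROI maximum maps to 100, a voxel at or
#' below half the maximum maps to the 50 floor. Visualization output only.
#'
#' @param map A group-level `wta_map`.
#' @return List: `value` (per-voxel display percentage, 0 for unassigned),
#'   plus the map's geometry fields.
#' @export
render_confidence <- function(map) {
  stopifnot(inherits(map, "wta_map"))
  val <- numeric(length(map$label))
  for (k in 1:6) {
    sel <- map$label == k
    if (!any(sel)) next
    mx <- max(map$winning_r[sel])
    val[sel] <- if (mx > 0) pmax(50, 100 * map$winning_r[sel] / mx) else 0
  }
  list(value = val, voxel_index = map$voxel_index, dim = map$dim,
       affine = map$affine)
}

#' Voxel-count summary of a parcellation
#'
#' @param map A `wta_map`.
#' @return Data frame: one row per label 0..6 with voxel counts.
#' @export
wta_summary <- function(map) {
  data.frame(label = 0:6,
             roi = c("unassigned", ROI_NAMES),
             n_voxels = vapply(0:6, function(k) sum(map$label == k), 0L))
}
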