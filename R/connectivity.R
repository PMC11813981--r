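# ROI-to-ROI thalamocortical connectivity and seed-to-voxel whole-brain
# maps, on the Fisher-z scale.

#' Fisher r-to-z transform
#'
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`: odd, strictly
#' increasing, variance-stabilizing for Pearson correlations.
#'
#' @param r Correlation value(s), all strictly inside (-1, 1).
#' @return Transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(!is.na(r) & abs(r) >= 1))
    stop("fisher_z requires |r| < 1")
  atanh(r)
}

#' ROI-pair thalamocortical connectivity for one subject entry
#'
#' For each thalamus side and each of the six cortical ROIs, the Pearson
#' correlation between the cortical ROI mean series and the mean series
#' over the thalamic voxels carrying that ROI's winner-take-all label,
#' plus its Fisher z. An absent label yields an `NA` row with a warning.
#'
#' @param vol Cleaned [volume4d].
#' @param cortex Named list of six cortical masks ([resolve_rois()] order).
#' @param wta Named list with thalamic parcellations for `left` and
#'   `right`: `wta_map`s or label [label_volume]s with labels 1..6.
#' @return Data frame: `side` (`left`/`right`), `roi`, `n_voxels`, `r`, `z`.
#' @export
roi_pair_connectivity <- function(vol, cortex, wta) {
  stopifnot(all(c("left", "right") %in% names(wta)))
  cortex_ts <- do.call(cbind, lapply(cortex[ROI_NAMES], function(m)
    roi_mean_timeseries(vol, m)))
  rows <- list()
  for (side in c("left", "right")) {
    labvol <- if (inherits(wta[[side]], "wta_map"))
      wta_label_volume(wta[[side]]) else wta[[side]]
    assert_same_grid(vol, labvol)
    for (k in 1:6) {
      idx <- which(labvol$data == k)
      if (length(idx) == 0L) {
        warning("no thalamic voxels labelled ", ROI_NAMES[k],
                " on side ", side)
        rows[[length(rows) + 1L]] <- data.frame(
          side = side, roi = ROI_NAMES[k], n_voxels = 0L,
          r = NA_real_, z = NA_real_, stringsAsFactors = FALSE)
        next
      }
      d <- dim(vol$data)
      sub_ts <- colMeans(matrix(
        matrix(vol$data, nrow = prod(d[1:3]))[idx, , drop = FALSE],
        nrow = length(idx)))
      r <- stats::cor(sub_ts, cortex_ts[, k])
      rows[[length(rows) + 1L]] <- data.frame(
        side = side, roi = ROI_NAMES[k], n_voxels = length(idx),
        r = r, z = fisher_z(min(max(r, -1 + 1e-12), 1 - 1e-12)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Seed-to-voxel whole-brain connectivity map
#'
#' Pearson correlation of the seed-mask mean series with every brain-mask
#' voxel, Fisher-z transformed. Voxels with r numerically at 1 (e.g. the
#' self-correlation of a one-voxel seed) are masked out (`NA`) rather than
#' carrying an infinite z.
#'
#' @param vol Cleaned [volume4d].
#' @param seed_mask Nonempty binary [label_volume].
#' @param brain_mask Binary [label_volume] defining the analysis domain.
#' @return A `stat_map`: list with `data` (3D array of z, `NA` outside the
#'   brain mask and at capped voxels), `affine`, `statistic = "fisher_z"`.
#' @export
seed_to_voxel <- function(vol, seed_mask, brain_mask) {
  seed_ts <- roi_mean_timeseries(vol, seed_mask)
  ts <- mask_timeseries(vol, brain_mask)
  r <- as.vector(stats::cor(ts, seed_ts))
  r[!is.finite(r)] <- 0                      # zero-variance voxels
  capped <- abs(r) >= 1 - 1e-12
  z <- rep(NA_real_, length(r))
  z[!capped] <- atanh(r[!capped])
  arr <- array(NA_real_, dim(brain_mask$data))
  arr[which(brain_mask$data > 0L)] <- z
  structure(list(data = arr, affine = brain_mask$affine,
                 statistic = "fisher_z", n_capped = sum(capped)),
            class = "stat_map")
}
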