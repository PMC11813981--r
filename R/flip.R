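# Mid-sagittal flipping and lesion-side harmonization. Left-lesion
# patients are mirrored so every lesion sits in the right hemisphere
# (ipsilesional = right, contralesional = left), and each control is
# duplicated with a mirrored copy, turning 32 controls into the
# 64-entry flip-augmented control set.

#' Flip a volume about the mid-sagittal plane
#'
#' Reverses the voxel axis aligned with the world left-right direction.
#' Requires the grid to be symmetric about the world `x = 0` plane (checked
#' from the affine) so the flip is exact and needs no interpolation; an
#' asymmetric grid is an error, never a silent approximate flip. The
#' affine is unchanged: world-space content is mirrored about `x = 0`.
#'
#' @param vol A [volume4d] or [label_volume].
#' @return The flipped volume, same class.
#' @export
flip_lr <- function(vol) {
  ax <- lr_axis(vol)
  d <- dim(vol$data)
  idx <- rep(list(quote(expr = )), length(d))
  idx[[ax]] <- d[ax]:1
  flipped <- do.call(`[`, c(list(vol$data), idx, list(drop = FALSE)))
  if (inherits(vol, "volume4d")) {
    new_volume4d(flipped, vol$affine, vol$tr)
  } else {
    label_volume(flipped, vol$affine)
  }
}

#' Harmonization plan for a cohort
#'
#' Computes, without touching any image, which entries the harmonized
#' cohort contains: one entry per patient (flipped when the lesion is on
#' the left) and two entries per control (original and flipped). This is
#' the bookkeeping behind [harmonize()]; pipelines that stream subjects
#' can apply the `flip` flag lazily (flipping the analysis masks instead
#' of the data, which is exactly equivalent on a symmetric grid since all
#' cleaning stages are per-voxel temporal operators).
#'
#' @param records Manifest data frame ([read_manifest()]).
#' @return Data frame with columns `entry_id`, `subject_id`, `group`,
#'   `flip` (logical), `provenance` (`original`/`flipped`).
#' @export
harmonize_plan <- function(records) {
  records <- validate_manifest(records)
  pat <- records[records$group == "patient", , drop = FALSE]
  con <- records[records$group == "control", , drop = FALSE]
  block <- function(ids, group, flip) {
    if (length(ids) == 0L) return(NULL)
    data.frame(subject_id = ids, group = group, flip = flip,
               stringsAsFactors = FALSE)
  }
  plan <- rbind(
    block(pat$subject_id, "patient", pat$lesion_side == "left"),
    block(con$subject_id, "control", FALSE),
    block(con$subject_id, "control", TRUE))
  if (is.null(plan)) stop("empty manifest")
  plan$provenance <- ifelse(plan$flip, "flipped", "original")
  plan$entry_id <- paste0(plan$subject_id,
                          ifelse(plan$flip, "_flip", ""))
  plan[, c("entry_id", "subject_id", "group", "flip", "provenance")]
}

#' Harmonize a cohort to a common lesion side
#'
#' Materializes the [harmonize_plan()]: flips the volumes of left-lesion
#' patients (their `lesion_side` becomes `right`), leaves right-lesion
#' patients untouched, and appends a flipped duplicate of every control,
#' yielding `2 * n_controls` control entries. Note the flip-augmented
#' control entries are not statistically independent (each subject appears
#' twice); downstream inference exposes an independence-safe mode.
#'
#' @param entries List of subject entries, each a list with `record` (a
#'   one-row slice of the manifest, as a list or data frame) and `vol`
#'   (a [volume4d]).
#' @return List with `patients` and `controls`: lists of entries, each
#'   carrying `record`, `vol` and `provenance`.
#' @export
harmonize <- function(entries) {
  groups <- vapply(entries, function(e) as.character(e$record$group), "")
  sides  <- vapply(entries, function(e) as.character(e$record$lesion_side), "")
  if (any(groups == "patient" & sides == "none"))
    stop("patient with lesion_side 'none' cannot be harmonized")
  patients <- list(); controls <- list()
  for (e in entries) {
    if (e$record$group == "patient") {
      if (e$record$lesion_side == "left") {
        e$vol <- flip_lr(e$vol)
        e$record$lesion_side <- "right"
        e$provenance <- "flipped"
      } else e$provenance <- "original"
      patients[[length(patients) + 1L]] <- e
    } else {
      e$provenance <- "original"
      controls[[length(controls) + 1L]] <- e
      f <- e
      f$vol <- flip_lr(e$vol)
      f$provenance <- "flipped"
      controls[[length(controls) + 1L]] <- f
    }
  }
  list(patients = patients, controls = controls)
}
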