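# Cortical ROI definition by atlas grouping, and the subject manifest.
#
# The six cortical ROIs follow the standard thalamus-parcellation scheme:
# prefrontal, motor, temporal, posterior parietal, somatosensory and
# occipital cortex, each defined as a union of atlas labels (both
# hemispheres). Two reserved names select the thalamus masks.

#' Canonical cortical ROI names, in label order 1..6
#' @export
ROI_NAMES <- c("prefrontal", "motor", "temporal",
               "posterior_parietal", "somatosensory", "occipital")

.THAL_NAMES <- c("thalamus_left", "thalamus_right")

#' Read an atlas-grouping config
#'
#' The config is a JSON object mapping each of the six cortical ROI names
#' (plus `thalamus_left` and `thalamus_right`) to an array of atlas label
#' integers, e.g. `{"prefrontal": [1, 11], ..., "thalamus_left": [7]}`.
#' Any atlas can be plugged in by supplying its own grouping.
#'
#' @param path Path to a JSON grouping file.
#' @return Named list of integer label vectors.
#' @export
read_roi_grouping <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_roi_grouping(g)
}

#' Validate an atlas grouping
#'
#' @param g Named list mapping ROI names to integer label vectors.
#' @return The validated grouping (labels as integers).
#' @export
validate_roi_grouping <- function(g) {
  need <- c(ROI_NAMES, .THAL_NAMES)
  missing <- setdiff(need, names(g))
  if (length(missing) > 0L)
    stop("grouping is missing ROI(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(g), need)
  if (length(extra) > 0L)
    stop("grouping has unknown ROI name(s): ", paste(extra, collapse = ", "))
  g <- lapply(g[need], function(v) as.integer(v))
  all_labels <- unlist(g, use.names = FALSE)
  dup <- unique(all_labels[duplicated(all_labels)])
  if (length(dup) > 0L)
    stop("non-disjoint grouping: label(s) ", paste(dup, collapse = ", "),
         " assigned to more than one ROI")
  g
}

#' Resolve cortical ROI and thalamus masks from an atlas
#'
#' Builds six binary cortical masks (pairwise disjoint by construction,
#' since the grouping is label-disjoint) and the left/right thalamus masks
#' from an integer atlas volume.
#'
#' @param atlas A [label_volume] with integer atlas labels.
#' @param grouping A grouping as returned by [read_roi_grouping()].
#' @return List with `cortex` (named list of six binary [label_volume]s in
#'   [ROI_NAMES] order) and `thalamus` (list `left`, `right`).
#' @export
resolve_rois <- function(atlas, grouping) {
  grouping <- validate_roi_grouping(grouping)
  present <- unique(as.vector(atlas$data))
  wanted <- unlist(grouping, use.names = FALSE)
  absent <- setdiff(wanted, present)
  if (length(absent) > 0L)
    stop("label(s) absent from atlas: ", paste(absent, collapse = ", "))
  mask_of <- function(labels) {
    m <- array(0L, dim(atlas$data))
    m[atlas$data %in% labels] <- 1L
    label_volume(m, atlas$affine)
  }
  cortex <- lapply(grouping[ROI_NAMES], mask_of)
  thalamus <- list(left = mask_of(grouping$thalamus_left),
                   right = mask_of(grouping$thalamus_right))
  list(cortex = cortex, thalamus = thalamus)
}

.MANIFEST_REQUIRED <- c("subject_id", "group", "lesion_side",
                        "bold_path", "motion_path")
.SCORE_BOUNDS <- list(
  fma_ue_t1 = c(0, 66), fma_ue_t2 = c(0, 66),
  fma_le_t1 = c(0, 34), fma_le_t2 = c(0, 34),
  nihss_t1 = c(0, 42), nihss_t2 = c(0, 42),
  nihss_sensory_t1 = c(0, 2))

#' Read and validate a subject manifest
#'
#' Tab- or comma-separated table with one row per subject. Required
#' columns: `subject_id`, `group` (`patient`/`control`), `lesion_side`
#' (`left`/`right`/`none`), `bold_path`, `motion_path`. Clinical score
#' columns (`fma_ue_t1/t2` 0-66, `fma_le_t1/t2` 0-34, `nihss_t1/t2` 0-42,
#' `nihss_sensory_t1` 0-2) are required for patients and may be missing or
#' `NA` for controls; any present value is bound-checked. Additional
#' demographic columns pass through untouched.
#'
#' @param path Path to a `.tsv` or `.csv` manifest.
#' @return A `data.frame` of validated subject records.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  m <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = TRUE)
  validate_manifest(m)
}

#' Validate a subject-manifest data frame
#' @param m A data frame shaped like [read_manifest()] output.
#' @return The validated data frame.
#' @export
validate_manifest <- function(m) {
  missing <- setdiff(.MANIFEST_REQUIRED, names(m))
  if (length(missing) > 0L)
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(m$subject_id))
    stop("duplicate subject_id in manifest")
  bad_grp <- setdiff(unique(m$group), c("patient", "control"))
  if (length(bad_grp) > 0L)
    stop("unknown group value(s): ", paste(bad_grp, collapse = ", "))
  bad_side <- setdiff(unique(m$lesion_side), c("left", "right", "none"))
  if (length(bad_side) > 0L)
    stop("unknown lesion_side value(s): ", paste(bad_side, collapse = ", "))
  if (any(m$group == "control" & m$lesion_side != "none"))
    stop("controls must have lesion_side 'none'")
  if (any(m$group == "patient" & m$lesion_side == "none"))
    stop("patients must have lesion_side 'left' or 'right'")
  for (col in names(.SCORE_BOUNDS)) {
    if (col %in% names(m)) {
      v <- m[[col]]
      b <- .SCORE_BOUNDS[[col]]
      bad <- which(!is.na(v) & (v < b[1] | v > b[2]))
      if (length(bad) > 0L)
        stop(col, " out of bounds [", b[1], ", ", b[2], "] for subject(s): ",
             paste(m$subject_id[bad], collapse = ", "))
    } else if (any(m$group == "patient")) {
      stop("manifest has patients but is missing score column ", col)
    }
  }
  pat <- m$group == "patient"
  for (col in names(.SCORE_BOUNDS)) {
    if (any(is.na(m[[col]][pat])))
      stop("missing ", col, " for one or more patients")
  }
  m
}
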