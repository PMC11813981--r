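# End-to-end orchestration: clean -> harmonize -> parcellate -> ROI-pair
# connectivity -> inference (ROI contrasts, seed-to-voxel with permutation
# cluster FWE, behavioral correlations), from a single JSON config, plus a
# small subcommand CLI.

#' Default run configuration
#'
#' @param dataset_dir Directory holding `manifest.tsv`, `atlas.nii`,
#'   `grouping.json` and the per-subject files the manifest points at.
#' @param out_dir Output directory for tables, maps and the summary JSON.
#' @param tr Repetition time override (`NULL`: take from headers).
#' @param discard,low,high,motion_threshold_mm Cleaning parameters.
#' @param wta_method Group parcellation rule (`"zmean"` or `"vote"`).
#' @param control_mode Control sample for contrasts (`"augmented"`: the
#'   64 flip-augmented entries, mirroring the reference study design;
#'   `"independent"`: the 32 original subjects).
#' @param cluster_forming_p,n_perm,connectivity Cluster inference options.
#' @param seed Permutation seed (required for inference).
#' @param max_seeds Cap on seed-to-voxel analyses (most significant ROI
#'   pairs first).
#' @return Named list of settings.
#' @export
run_config <- function(dataset_dir, out_dir,
                       tr = NULL, discard = 5L, low = 0.01, high = 0.08,
                       motion_threshold_mm = 3.0,
                       wta_method = "zmean", control_mode = "augmented",
                       cluster_forming_p = 0.001, n_perm = 1000L,
                       connectivity = 26L, seed = 1L, max_seeds = 5L) {
  as.list(environment())
}

#' Read a run configuration from JSON
#' @param path JSON file whose keys match [run_config()] arguments.
#' @return A config list.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, cfg)
}

#' Run the full analysis pipeline
#'
#' Streams subjects one at a time: load, QC, clean, flip into harmonized
#' orientation (ipsilesional = right), correlate; then builds the pooled
#' group winner-take-all parcellation for each thalamus, the ROI-pair
#' connectivity table and its 12 contrasts, seed-to-voxel maps with
#' permutation cluster-level FWE for the significant pairs, behavioral
#' correlations with FMA-UE baseline and its 1-year change rate, the
#' sensory subgroup comparison, and a demographics table. All outputs are
#' written under `cfg$out_dir` and returned invisibly.
#'
#' @param cfg A [run_config()] list.
#' @return Invisibly, the results list (also serialized to
#'   `summary.json` and TSV files in `out_dir`).
#' @export
run_pipeline <- function(cfg) {
  dd <- cfg$dataset_dir
  manifest <- read_manifest(file.path(dd, "manifest.tsv"))
  atlas <- load_label_volume(file.path(dd, "atlas.nii"))
  grouping <- read_roi_grouping(file.path(dd, "grouping.json"))
  rois <- resolve_rois(atlas, grouping)
  brain <- label_volume(array(as.integer(atlas$data > 0L),
                              dim(atlas$data)), atlas$affine)
  ccfg <- clean_config(cfg$discard, cfg$low, cfg$high,
                       cfg$motion_threshold_mm)

  plan <- harmonize_plan(manifest)
  qc <- list(); cms <- list(left = list(), right = list())
  cortex_ts <- list(); thal_ts <- list(left = list(), right = list())
  brain_ts <- list()
  for (i in seq_len(nrow(plan))) {
    sid <- plan$subject_id[i]
    rec <- manifest[manifest$subject_id == sid, ]
    vol <- load_volume4d(file.path(dd, rec$bold_path), tr = cfg$tr)
    motion <- read_motion(file.path(dd, rec$motion_path))
    q <- motion_qc(motion, cfg$motion_threshold_mm)
    qc[[sid]] <- q
    if (!q$pass)
      stop("subject ", sid, " fails motion QC (max translation ",
           round(q$max_translation_mm, 2), " mm)")
    wm <- roi_or_zero(dd, sid, "wm", nrow(motion))
    csf <- roi_or_zero(dd, sid, "csf", nrow(motion))
    conf <- confound_set(motion, wm, csf)
    vol <- clean_pipeline(vol, conf, ccfg)
    if (plan$flip[i]) vol <- flip_lr(vol)
    cts <- do.call(cbind, lapply(rois$cortex, function(m)
      roi_mean_timeseries(vol, m)))
    cortex_ts[[i]] <- cts
    for (side in c("left", "right")) {
      cms[[side]][[i]] <- voxel_cortex_correlations(
        vol, rois$thalamus[[side]], cts, side = side)
      thal_ts[[side]][[i]] <- mask_timeseries(vol, rois$thalamus[[side]])
    }
    brain_ts[[i]] <- mask_timeseries(vol, brain)
  }

  wta <- list(left = group_wta(cms$left, cfg$wta_method),
              right = group_wta(cms$right, cfg$wta_method))

  conn_rows <- lapply(seq_len(nrow(plan)), function(i) {
    tabs <- lapply(c("left", "right"), function(side) {
      lab <- wta[[side]]$label
      vapply(1:6, function(k) {
        sel <- lab == k
        if (!any(sel)) return(NA_real_)
        stats::cor(rowMeans(thal_ts[[side]][[i]][, sel, drop = FALSE]),
                   cortex_ts[[i]][, k])
      }, 0)
    })
    data.frame(side = rep(c("left", "right"), each = 6),
               roi = rep(ROI_NAMES, 2),
               n_voxels = c(vapply(1:6, function(k)
                 sum(wta$left$label == k), 0L),
                 vapply(1:6, function(k) sum(wta$right$label == k), 0L)),
               r = c(tabs[[1]], tabs[[2]]),
               z = fisher_z(pmin(pmax(c(tabs[[1]], tabs[[2]]),
                                      -1 + 1e-12), 1 - 1e-12)),
               stringsAsFactors = FALSE)
  })
  conn <- cohort_connectivity(conn_rows, plan)
  contrasts <- roi_pair_contrasts(conn, cfg$control_mode)

  sig <- contrasts[contrasts$p < 0.05, , drop = FALSE]
  sig <- utils::head(sig[order(sig$p), , drop = FALSE], cfg$max_seeds)
  cluster_results <- list()
  if (sum(plan$group == "patient") < 5L ||
      sum(plan$group == "control") < 5L) {
    if (nrow(sig) > 0)
      warning("fewer than 5 maps per group: seed-to-voxel cluster ",
              "inference skipped")
    sig <- sig[0, , drop = FALSE]
  }
  side_of <- c(ipsilesional = "right", contralesional = "left")
  for (j in seq_len(nrow(sig))) {
    side <- side_of[[sig$side[j]]]
    k <- match(sig$roi[j], ROI_NAMES)
    sel <- wta[[side]]$label == k
    if (!any(sel)) next
    bidx <- which(brain$data > 0L)
    seed_maps <- lapply(seq_len(nrow(plan)), function(i) {
      seed_ts <- rowMeans(thal_ts[[side]][[i]][, sel, drop = FALSE])
      r <- as.vector(stats::cor(brain_ts[[i]], seed_ts))
      r[!is.finite(r)] <- 0
      z <- rep(NA_real_, length(r))
      ok <- abs(r) < 1 - 1e-12
      z[ok] <- atanh(r[ok])
      arr <- array(NA_real_, dim(brain$data))
      arr[bidx] <- z
      arr
    })
    is_pat <- plan$group == "patient"
    cluster_results[[paste(sig$side[j], sig$roi[j], sep = "_")]] <-
      perm_cluster_fwe(seed_maps[is_pat], seed_maps[!is_pat], brain,
                       cfg$cluster_forming_p, cfg$n_perm, cfg$seed,
                       cfg$connectivity)
  }

  pat <- manifest[manifest$group == "patient", ]
  zz <- conn[conn$group == "patient" & conn$side == "ipsilesional" &
               conn$roi == "somatosensory", ]
  z_ss <- zz$z[match(pat$subject_id, zz$subject_id)]
  try_stat <- function(expr)
    tryCatch(expr, error = function(e)
      list(skipped = conditionMessage(e)))
  behav <- list(
    fma_ue_baseline = try_stat(behavior_correlation(z_ss, pat$fma_ue_t1)),
    cr_mf_ue = try_stat(behavior_correlation(z_ss, cr_mf(pat$fma_ue_t2,
                                                         pat$fma_ue_t1))))
  sensory <- try_stat(sensory_subgroup_compare(manifest, conn))
  if (!is.null(sensory$skipped))
    sensory <- c(sensory, list(n_impaired = NA, n_nonimpaired = NA,
                               connectivity_test = NULL, fma_test = NULL))
  demo <- demographics_table(manifest)

  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(contrasts, file.path(out, "roi_pair_contrasts.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(conn, file.path(out, "connectivity.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(demo, file.path(out, "demographics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (side in c("left", "right")) {
    write_volume(wta_label_volume(wta[[side]]),
                 file.path(out, paste0("wta_", side, ".nii")))
    utils::write.table(wta_summary(wta[[side]]),
                       file.path(out, paste0("wta_", side, "_summary.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (length(cluster_results) > 0) {
    ctab <- do.call(rbind, lapply(names(cluster_results), function(nm) {
      cl <- cluster_results[[nm]]$clusters
      if (nrow(cl) == 0) return(NULL)
      cbind(seed = nm, cl)
    }))
    if (!is.null(ctab))
      utils::write.table(ctab, file.path(out, "clusters.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  }
  summary <- list(
    settings = cfg[setdiff(names(cfg), c("dataset_dir", "out_dir"))],
    n_entries = nrow(plan),
    n_patients = sum(plan$group == "patient"),
    n_control_entries = sum(plan$group == "control"),
    qc = lapply(qc, function(q) q[c("pass", "max_translation_mm")]),
    contrasts = contrasts,
    clusters = lapply(cluster_results, function(x)
      c(list(clusters = x$clusters), x[c("n_perm", "seed",
                                         "t_threshold")])),
    behavioral = behav,
    sensory = sensory[c("n_impaired", "n_nonimpaired")],
    sensory_tests = list(connectivity = sensory$connectivity_test,
                         fma = sensory$fma_test))
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(plan = plan, wta = wta, connectivity = conn,
                 contrasts = contrasts, clusters = cluster_results,
                 behavioral = behav, sensory = sensory,
                 demographics = demo, qc = qc))
}

#' In-memory end-to-end analysis of a simulated cohort
#'
#' The fast counterpart of [run_pipeline()] for `cohort_plan` objects:
#' streams subjects (simulated with noise restricted to the analysis
#' mask), cleans them, builds the pooled group winner-take-all
#' parcellation per thalamus and the harmonized ROI-pair connectivity
#' table. Flip-augmented entries reuse the original subject's series with
#' hemispheres swapped, which on the phantom's mirror-symmetric masks is
#' exactly equivalent to flipping the volume (all cleaning stages are
#' per-voxel temporal operators); the equivalence is asserted once.
#'
#' @param cohort A `cohort_plan`.
#' @param cfg A [clean_config()].
#' @param wta_method Group parcellation rule, see [group_wta()].
#' @param use_truth_labels Use the phantom's planted thalamic sectors as
#'   the parcellation instead of the estimated group map.
#' @param use_noise_mask Simulate voxel noise only inside the analysis
#'   mask (faster, default). Disable to reproduce the exact RNG stream of
#'   full-volume simulation, e.g. for equivalence checks against the
#'   on-disk pipeline.
#' @return List: `conn` (cohort connectivity table), `wta` (left/right
#'   group `wta_map`s, `NULL` when `use_truth_labels`), `plan`, `cms`
#'   (per-entry correlation maps by harmonized side).
#' @export
analyze_cohort <- function(cohort, cfg = clean_config(),
                           wta_method = "zmean",
                           use_truth_labels = FALSE,
                           use_noise_mask = TRUE) {
  truth <- cohort$truth
  analysis_mask <- label_volume(
    array(as.integer(truth$atlas$data > 0L), dim(truth$atlas$data)),
    truth$affine)
  # mirror correspondence between the two thalamus masks
  if (!identical(flip_lr(truth$thalamus$left)$data,
                 truth$thalamus$right$data))
    stop("phantom thalamus masks are not mirror-symmetric")
  for (m in truth$cortex)
    if (!identical(flip_lr(m)$data, m$data))
      stop("phantom cortical masks are not mirror-symmetric")
  gs <- truth$grid_shape
  idxL <- which(truth$thalamus$left$data > 0L)
  idxR <- which(truth$thalamus$right$data > 0L)
  co <- arrayInd(idxL, gs)
  co[, 1] <- gs[1] + 1L - co[, 1]
  perm_l2r <- match((co[, 1] - 1) + gs[1] * ((co[, 2] - 1) +
                                               gs[2] * (co[, 3] - 1)),
                    (arrayInd(idxR, gs)[, 1] - 1) +
                      gs[1] * ((arrayInd(idxR, gs)[, 2] - 1) +
                                 gs[2] * (arrayInd(idxR, gs)[, 3] - 1)))
  stopifnot(!anyNA(perm_l2r))

  ids <- names(cohort$subjects)
  per_subject <- vector("list", length(ids)); names(per_subject) <- ids
  cort_idx <- lapply(truth$cortex, function(m) which(m$data > 0L))
  nthal <- length(idxL) + length(idxR)
  keepT <- (cfg$discard + 1L):cohort$n_timepoints
  for (sid in ids) {
    s <- realize_subject(cohort, sid,
                         noise_mask = if (use_noise_mask) analysis_mask)
    flat <- s$vol$data
    dim(flat) <- c(prod(dim(s$vol$data)[1:3]), dim(s$vol$data)[4])
    # cleaning is linear and identical per column, so cleaning the six
    # cortical ROI mean series equals averaging cleaned voxel series;
    # only thalamic voxels need voxel-level cleaning
    raw <- cbind(t(flat[c(idxL, idxR), keepT, drop = FALSE]),
                 vapply(cort_idx, function(p)
                   colMeans(flat[p, keepT, drop = FALSE]),
                   numeric(length(keepT))))
    ts <- clean_timeseries(raw, s$vol$tr,
                           confound_set(s$motion, s$wm, s$csf), cfg)
    per_subject[[sid]] <- list(
      cortex_ts = ts[, nthal + (1:6), drop = FALSE],
      thal = list(left = ts[, seq_along(idxL), drop = FALSE],
                  right = ts[, length(idxL) + seq_along(idxR),
                             drop = FALSE]))
  }

  plan <- harmonize_plan(cohort$manifest)
  # per-entry series in harmonized orientation (right = ipsilesional)
  entry_series <- lapply(seq_len(nrow(plan)), function(i) {
    ps <- per_subject[[plan$subject_id[i]]]
    if (!plan$flip[i]) return(ps)
    # flipped entry: right thal <- left-thal rows reordered to the right
    # mask's voxel order, and vice versa
    # left-mask col j mirrors right-mask col perm_l2r[j] and vice versa
    list(cortex_ts = ps$cortex_ts,
         thal = list(left = ps$thal$right[, perm_l2r, drop = FALSE],
                     right = ps$thal$left[, order(perm_l2r),
                                          drop = FALSE]))
  })

  mk_cm <- function(ts, cts, vidx) {
    structure(list(
      r = {
        T_ <- nrow(ts)
        tc <- scale(ts, scale = FALSE); cc <- scale(cts, scale = FALSE)
        den <- outer(pmax(sqrt(colSums(tc^2)), .Machine$double.xmin),
                     sqrt(colSums(cc^2)))
        r <- crossprod(tc, cc) / den
        colnames(r) <- ROI_NAMES
        pmin(pmax(r, -1), 1)
      },
      voxel_index = vidx, dim = gs, affine = truth$affine,
      side = NA_character_), class = "correlation_maps")
  }
  cms <- list(
    left = lapply(entry_series, function(e)
      mk_cm(e$thal$left, e$cortex_ts, idxL)),
    right = lapply(entry_series, function(e)
      mk_cm(e$thal$right, e$cortex_ts, idxR)))

  if (use_truth_labels) {
    wta <- NULL
    labels <- list(left = truth$assignment[idxL],
                   right = truth$assignment[idxR])
  } else {
    wta <- list(left = group_wta(cms$left, wta_method),
                right = group_wta(cms$right, wta_method))
    labels <- list(left = wta$left$label, right = wta$right$label)
  }

  entry_tables <- lapply(entry_series, function(e) {
    rows <- lapply(c("left", "right"), function(side) {
      vapply(1:6, function(k) {
        sel <- labels[[side]] == k
        if (!any(sel)) return(NA_real_)
        stats::cor(rowMeans(e$thal[[side]][, sel, drop = FALSE]),
                   e$cortex_ts[, k])
      }, 0)
    })
    r <- c(rows[[1]], rows[[2]])
    data.frame(side = rep(c("left", "right"), each = 6),
               roi = rep(ROI_NAMES, 2),
               n_voxels = c(vapply(1:6, function(k)
                 sum(labels$left == k), 0L),
                 vapply(1:6, function(k) sum(labels$right == k), 0L)),
               r = r,
               z = fisher_z(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)),
               stringsAsFactors = FALSE)
  })
  conn <- cohort_connectivity(entry_tables, plan)
  list(conn = conn, wta = wta, plan = plan, cms = cms)
}

# Optional per-subject wm/csf signal files; zero signals when absent
# (they then drop out of the nuisance design).
roi_or_zero <- function(dd, sid, what, n) {
  p <- file.path(dd, paste0(sid, "_", what, ".txt"))
  if (file.exists(p)) as.numeric(readLines(p)) else numeric(n)
}

#' Simulate a dataset to disk (CLI backend)
#'
#' @param dir Output dataset directory.
#' @param n_patients,n_controls,grid,n_timepoints,tr,seed Generator
#'   settings (defaults are the full default cohort).
#' @return The dataset directory, invisibly.
#' @export
simulate_dataset <- function(dir, n_patients = 39L, n_controls = 32L,
                             grid = c(24L, 24L, 24L),
                             n_timepoints = 150L, tr = 2, seed = 1L) {
  truth <- make_phantom(grid)
  cohort <- simulate_cohort(truth, n_patients, n_controls,
                            n_timepoints, tr, seed)
  write_cohort(cohort, dir)
}

#' Command-line entry point
#'
#' Subcommands: `simulate --out DIR [--n-patients N] [--n-controls N]
#' [--seed S] [--grid N] [--timepoints T]`; `run --dataset DIR --out DIR
#' [--seed S] [--n-perm P] [--control-mode MODE]` (executes clean ->
#' harmonize -> parcellate -> connect -> infer); and `report --out DIR`,
#' which prints a digest of an existing run directory. A JSON config can
#' replace flags via `--config FILE`.
#'
#' @param args Character vector of CLI arguments (defaults to the
#'   process's trailing arguments).
#' @return Exit status 0 on success (invisibly); errors propagate.
#' @export
thalparc_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L)
    stop("usage: thalparc <simulate|run> [--options]")
  cmd <- args[1]
  opts <- list()
  rest <- args[-1]
  while (length(rest) > 0L) {
    key <- sub("^--", "", rest[1])
    opts[[gsub("-", "_", key)]] <- rest[2]
    rest <- rest[-(1:2)]
  }
  if (!is.null(opts$config))
    opts <- utils::modifyList(
      jsonlite::read_json(opts$config, simplifyVector = TRUE), opts)
  num <- function(x, d) if (is.null(x)) d else as.numeric(x)
  if (cmd == "simulate") {
    if (is.null(opts$out)) stop("simulate needs --out DIR")
    g <- as.integer(num(opts$grid, 24))
    simulate_dataset(opts$out,
                     n_patients = as.integer(num(opts$n_patients, 39)),
                     n_controls = as.integer(num(opts$n_controls, 32)),
                     grid = rep(g, 3),
                     n_timepoints = as.integer(num(opts$timepoints, 150)),
                     seed = as.integer(num(opts$seed, 1)))
    message("dataset written to ", opts$out)
  } else if (cmd == "run") {
    if (is.null(opts$dataset) || is.null(opts$out))
      stop("run needs --dataset DIR and --out DIR")
    cfg <- run_config(opts$dataset, opts$out,
                      n_perm = as.integer(num(opts$n_perm, 1000)),
                      seed = as.integer(num(opts$seed, 1)),
                      control_mode =
                        if (is.null(opts$control_mode)) "augmented"
                      else opts$control_mode)
    run_pipeline(cfg)
    message("results written to ", opts$out)
  } else if (cmd == "report") {
    if (is.null(opts$out)) stop("report needs --out DIR (a run directory)")
    sm <- jsonlite::read_json(file.path(opts$out, "summary.json"),
                              simplifyVector = TRUE)
    cat(sprintf("entries: %d (%d patients, %d control entries)\n",
                sm$n_entries, sm$n_patients, sm$n_control_entries))
    cat("ROI-pair contrasts (p < 0.05):\n")
    ct <- as.data.frame(sm$contrasts)
    print(ct[ct$p < 0.05, c("side", "roi", "t", "p")], row.names = FALSE)
    if (length(sm$clusters) > 0)
      for (nm in names(sm$clusters))
        cat(sprintf("seed %s: %d cluster(s), %d permutations\n", nm,
                    NROW(sm$clusters[[nm]]$clusters),
                    sm$clusters[[nm]]$n_perm))
  } else stop("unknown subcommand: ", cmd)
  invisible(0L)
}
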