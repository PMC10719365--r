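# End-to-end orchestration: a YAML-configurable extraction stage
# (segmentation -> features -> foci -> gating inputs) and an analysis
# stage (pruning -> balancing -> LOPO CV -> majority vote -> permutation
# baseline -> importance ranking -> Welch/BH screen -> QC embedding),
# with per-nucleus fail-soft error handling and resumable outputs.

#' Default pipeline configuration
#'
#' Defaults match the pipeline's reference settings: voxel geometry
#' 0.09/0.09/0.5 um, the segmentation constants of
#' [segmentation_params()], the focus constants of [foci_params()],
#' gating floor of 20 cells, pruning threshold |r| > 0.8, 10 label
#' permutations.
#'
#' @param manifest Path to the sample manifest CSV.
#' @param out_dir Output directory.
#' @return Nested list of class `pipeline_config`.
#' @export
default_config <- function(manifest = NULL, out_dir = "chromscope_out") {
  structure(list(
    paths = list(manifest = manifest, out_dir = out_dir),
    acquisition = list(dx_um = 0.09, dy_um = 0.09, dz_um = 0.5),
    segmentation = unclass(segmentation_params()),
    foci = unclass(foci_params()),
    gating = list(min_cells = 20L, min_separation = 0.5),
    analysis = list(label_col = "condition", cells_per_unit = NULL,
                    r_thresh = 0.8, n_perm = 10L, ntree = 500L,
                    top_n = 15L, seed = 1L,
                    embedding = "lda")),
    class = "pipeline_config")
}

#' Read and validate a pipeline configuration
#'
#' Reads a YAML file and merges it over [default_config()]; unknown
#' top-level sections are rejected.
#'
#' @param path YAML file path.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  .assert(file.exists(path), sprintf("config not found: %s", path))
  user <- yaml::read_yaml(path)
  base <- default_config()
  bad <- setdiff(names(user), names(base))
  .assert(length(bad) == 0,
          paste("unknown config sections:", paste(bad, collapse = ", ")))
  for (sec in names(user)) {
    for (k in names(user[[sec]])) base[[sec]][[k]] <- user[[sec]][[k]]
  }
  .assert(base$segmentation$area_min_px < base$segmentation$area_max_px,
          "area_min_px must be < area_max_px")
  .assert(base$analysis$n_perm >= 1, "n_perm must be >= 1")
  base
}

.config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass(config), f, auto_unbox = TRUE, digits = 12)
  unname(tools::md5sum(f))
}

#' Run the extraction stage
#'
#' For every sample in the manifest: read the stack, range-normalize the
#' DAPI channel, segment nuclei in 2D and 3D, extract chrometric
#' profiles, marker quantifications and focus counts for QC-passing
#' nuclei, and write per-sample CSV outputs. Samples whose output already
#' exists are skipped (resumable re-runs); a failing sample or nucleus is
#' logged and skipped without aborting the batch.
#'
#' @param config A `pipeline_config` with `paths$manifest` set, or the
#'   manifest path itself.
#' @param out_dir Output directory override.
#' @return List: `features` (combined feature table), `qc` (per-nucleus
#'   QC table with rejection reasons), `failed_samples`.
#' @export
run_extraction <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- default_config(manifest = config)
  .assert(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  if (!is.null(out_dir)) config$paths$out_dir <- out_dir
  .assert(!is.null(config$paths$manifest), "config$paths$manifest is required")
  mf <- read_manifest(config$paths$manifest)
  od <- config$paths$out_dir
  if (!dir.exists(od)) dir.create(od, recursive = TRUE)
  sp <- do.call(segmentation_params, config$segmentation)
  fp <- do.call(foci_params, config$foci)
  acq <- config$acquisition
  hash <- .config_hash(config)
  feats <- list(); qc <- list(); failed <- character(0)
  for (i in seq_len(nrow(mf))) {
    sid <- mf$sample_id[i]
    f_feat <- file.path(od, paste0(sid, "_features.csv"))
    f_qc <- file.path(od, paste0(sid, "_qc.csv"))
    if (file.exists(f_feat) && file.exists(f_qc)) {
      feats[[sid]] <- utils::read.csv(f_feat, stringsAsFactors = FALSE)
      qc[[sid]] <- utils::read.csv(f_qc, stringsAsFactors = FALSE)
      next
    }
    res <- tryCatch({
      stack <- read_stack(mf$path[i], mf[i, ], dx_um = acq$dx_um,
                          dy_um = acq$dy_um, dz_um = acq$dz_um)
      dch <- .dapi_channel(stack$spec)
      d <- dim(stack$voxels)
      stack$voxels[dch, , , ] <- range_normalize(
        array(stack$voxels[dch, , , ], d[2:4]))
      recs <- segment_stack(stack, sp)
      qrows <- lapply(recs, function(r) {
        data.frame(nucleus_id = r$nucleus_id, sample_id = sid,
                   qc_pass = isTRUE(r$qc_pass),
                   reason = ifelse(is.na(r$qc_reason), "", r$qc_reason),
                   border_clipped = r$border_clipped,
                   stringsAsFactors = FALSE)
      })
      frows <- lapply(Filter(function(r) isTRUE(r$qc_pass), recs),
                      function(r) {
                        tryCatch(assemble_profile(r, fp),
                                 error = function(e) {
                                   message(sprintf("nucleus %s failed: %s",
                                                   r$nucleus_id,
                                                   conditionMessage(e)))
                                   NULL
                                 })
                      })
      list(q = do.call(rbind, qrows),
           f = if (length(frows)) do.call(rbind, Filter(Negate(is.null),
                                                        frows)) else NULL)
    }, error = function(e) {
      message(sprintf("sample %s failed: %s", sid, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) {
      failed <- c(failed, sid)
      next
    }
    if (!is.null(res$f)) {
      res$f$config_hash <- hash
      utils::write.csv(res$f, f_feat, row.names = FALSE)
      feats[[sid]] <- res$f
    } else {
      utils::write.csv(data.frame(), f_feat, row.names = FALSE)
    }
    if (!is.null(res$q)) {
      utils::write.csv(res$q, f_qc, row.names = FALSE)
      qc[[sid]] <- res$q
    }
  }
  features <- if (length(feats)) do.call(rbind, Filter(
    function(x) is.data.frame(x) && nrow(x) > 0, feats)) else NULL
  if (!is.null(features)) rownames(features) <- NULL
  list(features = features,
       qc = if (length(qc)) do.call(rbind, qc) else NULL,
       failed_samples = failed)
}

#' Run the analysis stage
#'
#' Correlation pruning, patient-balanced sampling, leave-one-patient-out
#' random-forest cross-validation, patient-level majority voting, the
#' label-permutation baseline with a Wilcoxon comparison, Gini importance
#' ranking, the Welch/BH biomarker screen and a QC embedding. All
#' randomness is driven by the config seed; the bundle is written as JSON
#' and CSVs stamped with the config hash.
#'
#' @param features Feature data.frame from [run_extraction()] (or any
#'   feature table with metadata columns).
#' @param config A `pipeline_config`.
#' @param out_dir Output directory override; `NULL` skips writing.
#' @return List of class `chromscope_bundle`: `cv`, `majority`, `null`,
#'   `importance`, `screen`, `embedding`, `pruned_features`,
#'   `config_hash`.
#' @export
run_analysis <- function(features, config = default_config(),
                         out_dir = NULL) {
  an <- config$analysis
  seed <- as.integer(an$seed)
  hash <- .config_hash(config)
  drop <- c("config_hash")
  features <- features[setdiff(names(features), drop)]
  pruned <- prune_correlated(features, r_thresh = an$r_thresh)
  balanced <- balance_sample(pruned, cells_per_unit = an$cells_per_unit,
                             seed = seed)
  cfg <- rf_config(ntree = an$ntree)
  cv <- lopo_cv_rfc(balanced, an$label_col, config = cfg, seed = seed)
  maj <- patient_majority_vote(cv)
  null <- permutation_baseline(balanced, an$label_col, n_perm = an$n_perm,
                               config = cfg, seed = seed, observed = cv)
  imp <- gini_ranking(cv, top_n = an$top_n)
  screen <- welch_screen_bh(balanced, an$label_col)
  emb <- tryCatch(
    qc_embedding(balanced, method = an$embedding, seed = seed,
                 color_col = an$label_col),
    error = function(e) NULL)
  bundle <- structure(list(cv = cv, majority = maj, null = null,
                           importance = imp, screen = screen,
                           embedding = emb, pruned_features = balanced,
                           config_hash = hash),
                      class = "chromscope_bundle")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    jsonlite::write_json(list(
      config_hash = hash,
      mean_balanced_accuracy = cv$mean_accuracy,
      sd_balanced_accuracy = cv$sd_accuracy,
      fold_accuracy = as.list(stats::setNames(cv$fold_accuracy, cv$patients)),
      confusion = cv$confusion,
      patient_accuracy = maj$patient_accuracy,
      null_mean_accuracy = null$null_mean_accuracy,
      wilcoxon_p = null$wilcoxon_p),
      file.path(out_dir, "analysis.json"), auto_unbox = TRUE, digits = 12)
    utils::write.csv(imp, file.path(out_dir, "importance.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(screen),
                     file.path(out_dir, "screen.csv"), row.names = FALSE)
    if (!is.null(emb)) {
      utils::write.csv(emb, file.path(out_dir, "embedding.csv"),
                       row.names = FALSE)
    }
  }
  bundle
}

#' @export
print.chromscope_bundle <- function(x, ...) {
  cat("chromscope analysis bundle (config", substr(x$config_hash, 1, 8),
      ")\n\n")
  print(x$cv)
  cat(sprintf("patient-level majority-vote accuracy: %.3f\n",
              x$majority$patient_accuracy))
  print(x$null)
  cat("\nTop features by Gini importance:\n")
  print(utils::head(x$importance, 5))
  invisible(x)
}
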