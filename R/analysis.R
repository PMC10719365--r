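# Analysis layer: feature-table preprocessing (correlation pruning,
# patient-balanced sampling), leave-one-patient-out random-forest
# cross-validation with patient-level majority voting, permutation-null
# baselines, ablation curves, Gini importance ranking, Welch/BH biomarker
# screens and control-normalized comparisons.

.META_COLS <- c("nucleus_id", "sample_id", "patient_id", "condition",
                "timepoint", "cell_type", "subset", "cd3_status")

#' Feature columns of a feature table
#'
#' Every numeric column that is not one of the reserved metadata columns
#' (`nucleus_id`, `sample_id`, `patient_id`, `condition`, `timepoint`,
#' `cell_type`, `subset`, `cd3_status`).
#'
#' @param table Feature data.frame (rows = cells).
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(table) {
  cand <- setdiff(names(table), .META_COLS)
  cand[vapply(table[cand], is.numeric, logical(1))]
}

#' Patient-balanced subsampling
#'
#' Randomly selects an equal number of cells from every patient sample
#' (patient x timepoint unit by default) so that no patient's cells can
#' dominate downstream analyses. Units with fewer than `cells_per_unit`
#' cells are excluded ("with sufficient cells"); reproducible under
#' `seed`.
#'
#' @param table Feature data.frame.
#' @param cells_per_unit Cells to draw per unit. `NULL` uses the minimum
#'   unit size (largest balanced subset).
#' @param unit_cols Columns defining the balancing unit (default
#'   `patient_id` + `timepoint` when present).
#' @param seed Integer seed.
#' @return Subsampled data.frame (row order: unit blocks).
#' @export
balance_sample <- function(table, cells_per_unit = NULL,
                           unit_cols = NULL, seed = 1L) {
  if (is.null(unit_cols)) {
    unit_cols <- intersect(c("patient_id", "timepoint"), names(table))
    unit_cols <- unit_cols[vapply(unit_cols,
                                  function(cc) !all(is.na(table[[cc]])),
                                  logical(1))]
  }
  .assert(length(unit_cols) >= 1, "no balancing unit columns present")
  unit <- interaction(table[unit_cols], drop = TRUE, sep = "|")
  sizes <- table(unit)
  if (is.null(cells_per_unit)) cells_per_unit <- min(sizes)
  keep_units <- names(sizes)[sizes >= cells_per_unit]
  .assert(length(keep_units) > 0, "no unit meets the requested cell count")
  set.seed(seed)
  rows <- unlist(lapply(keep_units, function(u) {
    idx <- which(unit == u)
    sort(sample(idx, cells_per_unit))
  }), use.names = FALSE)
  table[rows, , drop = FALSE]
}

#' Remove highly correlated features
#'
#' Greedy pruning in fixed column order: a feature is dropped if its
#' absolute Pearson correlation with any earlier kept feature is strictly
#' greater than `r_thresh` (pairs at exactly the threshold are both
#' kept). Constant columns, whose correlation is undefined, are removed
#' first with a warning.
#'
#' @param table Feature data.frame.
#' @param r_thresh Correlation threshold (default 0.8).
#' @return The pruned data.frame, with attribute `removed` listing the
#'   dropped feature names.
#' @export
prune_correlated <- function(table, r_thresh = 0.8) {
  feats <- feature_columns(table)
  .assert(length(feats) >= 2, "need at least two features")
  .assert(nrow(table) >= 3, "need at least three rows")
  x <- as.matrix(table[feats])
  const <- feats[apply(x, 2, function(v) stats::var(v) == 0 || !all(is.finite(v)))]
  if (length(const)) {
    warning("removing constant/non-finite feature columns: ",
            paste(const, collapse = ", "))
    feats <- setdiff(feats, const)
    x <- x[, feats, drop = FALSE]
  }
  cm <- abs(stats::cor(x))
  kept <- character(0)
  removed <- const
  for (f in feats) {
    # strict "> r_thresh" rule, robust to floating-point representation
    if (length(kept) == 0L || all(cm[f, kept] <= r_thresh + 1e-10)) {
      kept <- c(kept, f)
    } else {
      removed <- c(removed, f)
    }
  }
  out <- table[c(intersect(.META_COLS, names(table)), kept)]
  attr(out, "removed") <- removed
  out
}

#' Balanced classification accuracy
#'
#' Mean over the classes present in `truth` of the per-class recall.
#'
#' @param truth,pred Vectors of true and predicted labels.
#' @return Scalar in \[0, 1\].
#' @export
balanced_accuracy <- function(truth, pred) {
  .assert(length(truth) == length(pred) && length(truth) > 0,
          "truth and pred must be equal-length, non-empty")
  classes <- unique(as.character(truth))
  mean(vapply(classes, function(cl) {
    idx <- truth == cl
    mean(pred[idx] == cl)
  }, numeric(1)))
}

#' Random-forest configuration
#'
#' @param ntree Number of trees (default 500).
#' @param mtry Candidate features per split; `NULL` = `floor(sqrt(p))`.
#' @return List of class `rf_config`.
#' @export
rf_config <- function(ntree = 500L, mtry = NULL) {
  structure(list(ntree = as.integer(ntree), mtry = mtry),
            class = "rf_config")
}

.row_normalize <- function(cm) {
  rs <- rowSums(cm)
  sweep(cm, 1, ifelse(rs > 0, rs, 1), "/")
}

.fit_rf <- function(x, y, config) {
  mtry <- if (is.null(config$mtry)) max(1L, floor(sqrt(ncol(x)))) else config$mtry
  randomForest::randomForest(x = x, y = y, ntree = config$ntree,
                             mtry = mtry, importance = FALSE)
}

#' Leave-one-patient-out random-forest cross-validation
#'
#' One fold per patient: the forest is trained on the cells of all other
#' patients and evaluated on the held-out patient's cells, so the
#' classifier never sees any cell of the patient it is tested on.
#' Reports per-fold balanced accuracy (plus sensitivity/specificity for
#' binary tasks), the average of the row-normalized per-fold confusion
#' matrices, per-cell predictions and per-fold Gini importances
#' (normalized to sum to one).
#'
#' By default every patient must hold cells of a single class (violations
#' are a sign of label leakage for condition-type tasks). Tasks in which
#' classes genuinely vary within a patient -- e.g. classifying treatment
#' time points, where each patient contributes cells at every time point
#' -- require `allow_multiclass_patients = TRUE`.
#'
#' @param table Feature data.frame with `patient_id` and the label column.
#' @param label_col Name of the label column.
#' @param config [rf_config()].
#' @param seed Integer seed (per-fold seeds are derived from it).
#' @param allow_multiclass_patients Allow patients holding >1 class.
#' @return Object of class `chrome_cv`.
#' @export
lopo_cv_rfc <- function(table, label_col, config = rf_config(), seed = 1L,
                        allow_multiclass_patients = FALSE) {
  .assert(label_col %in% names(table), sprintf("no column '%s'", label_col))
  .assert("patient_id" %in% names(table), "table needs a patient_id column")
  feats <- feature_columns(table)
  feats <- setdiff(feats, label_col)
  .assert(length(feats) >= 1, "no feature columns")
  y <- factor(as.character(table[[label_col]]))
  classes <- levels(y)
  .assert(length(classes) >= 2, "need at least two classes")
  pat <- as.character(table$patient_id)
  per_pat_classes <- tapply(as.character(y), pat,
                            function(v) length(unique(v)))
  if (!allow_multiclass_patients && any(per_pat_classes > 1)) {
    stop("label leakage: patient(s) hold cells of more than one class (",
         paste(names(per_pat_classes)[per_pat_classes > 1], collapse = ", "),
         "); set allow_multiclass_patients = TRUE for within-patient tasks",
         call. = FALSE)
  }
  if (!allow_multiclass_patients) {
    cls_pat <- tapply(pat, as.character(y), function(v) length(unique(v)))
    .assert(all(cls_pat >= 2), "need >= 2 patients per class")
  }
  patients <- sort(unique(pat))
  x <- as.matrix(table[feats])
  folds <- vector("list", length(patients))
  names(folds) <- patients
  cm_sum <- matrix(0, length(classes), length(classes),
                   dimnames = list(classes, classes))
  cm_rows <- stats::setNames(numeric(length(classes)), classes)
  imp <- matrix(NA_real_, length(patients), length(feats),
                dimnames = list(patients, feats))
  pred_all <- character(nrow(table))
  for (i in seq_along(patients)) {
    p <- patients[i]
    test <- pat == p
    set.seed(seed + i)
    fit <- .fit_rf(x[!test, , drop = FALSE], droplevels(y[!test]), config)
    pr <- as.character(stats::predict(fit, x[test, , drop = FALSE]))
    pred_all[test] <- pr
    truth <- as.character(y[test])
    cm <- table(factor(truth, levels = classes),
                factor(pr, levels = classes))
    cm <- matrix(as.numeric(cm), length(classes), length(classes),
                 dimnames = list(classes, classes))
    cm_sum <- cm_sum + .row_normalize(cm)
    cm_rows <- cm_rows + (rowSums(cm) > 0)
    gi <- fit$importance[, "MeanDecreaseGini"]
    imp[i, names(gi)] <- gi / sum(gi)
    fold <- list(patient = p, n_test = sum(test),
                 balanced_accuracy = balanced_accuracy(truth, pr))
    if (length(classes) == 2) {
      pos <- classes[2]; neg <- classes[1]
      fold$sensitivity <- if (any(truth == pos)) mean(pr[truth == pos] == pos) else NA_real_
      fold$specificity <- if (any(truth == neg)) mean(pr[truth == neg] == neg) else NA_real_
    }
    folds[[i]] <- fold
  }
  acc <- vapply(folds, `[[`, numeric(1), "balanced_accuracy")
  res <- list(label_col = label_col, classes = classes,
              patients = patients,
              fold_accuracy = acc,
              mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc),
              # each row averaged over the folds whose test set held that class
              confusion = sweep(cm_sum, 1, pmax(cm_rows, 1), "/"),
              importance = imp,
              predictions = data.frame(patient_id = pat,
                                       truth = as.character(y),
                                       pred = pred_all,
                                       stringsAsFactors = FALSE),
              folds = folds, config = config, seed = seed)
  if (length(classes) == 2) {
    sens <- vapply(folds, `[[`, numeric(1), "sensitivity")
    spec <- vapply(folds, `[[`, numeric(1), "specificity")
    res$mean_sensitivity <- mean(sens, na.rm = TRUE)
    res$mean_specificity <- mean(spec, na.rm = TRUE)
  }
  structure(res, class = "chrome_cv")
}

#' @export
print.chrome_cv <- function(x, ...) {
  cat(sprintf("Leave-one-patient-out RF cross-validation ('%s', %d classes, %d folds)\n",
              x$label_col, length(x$classes), length(x$patients)))
  cat(sprintf("balanced accuracy: %.3f (+/- %.3f)\n",
              x$mean_accuracy, x$sd_accuracy))
  if (!is.null(x$mean_sensitivity)) {
    cat(sprintf("sensitivity %.3f | specificity %.3f (positive = '%s')\n",
                x$mean_sensitivity, x$mean_specificity, x$classes[2]))
  }
  invisible(x)
}

#' @export
summary.chrome_cv <- function(object, ...) {
  print(object)
  cat("\nAverage row-normalized confusion matrix:\n")
  print(round(object$confusion, 3))
  cat("\nPer-fold balanced accuracy:\n")
  print(round(object$fold_accuracy, 3))
  invisible(object)
}

#' Patient-level majority vote
#'
#' Assigns each patient its modal predicted class and compares with the
#' patient's true class (its modal true label). Exact ties are broken
#' deterministically by class order and flagged ambiguous.
#'
#' @param cv A `chrome_cv` from [lopo_cv_rfc()].
#' @return List: `per_patient` data.frame (`patient_id`, `truth`, `call`,
#'   `ambiguous`, `correct`) and `patient_accuracy`.
#' @export
patient_majority_vote <- function(cv) {
  pr <- cv$predictions
  patients <- cv$patients
  rows <- lapply(patients, function(p) {
    sub <- pr[pr$patient_id == p, ]
    votes <- table(factor(sub$pred, levels = cv$classes))
    top <- which(votes == max(votes))
    truth_tab <- table(factor(sub$truth, levels = cv$classes))
    data.frame(patient_id = p,
               truth = names(truth_tab)[which.max(truth_tab)],
               call = names(votes)[top[1]],
               ambiguous = length(top) > 1,
               stringsAsFactors = FALSE)
  })
  per_patient <- do.call(rbind, rows)
  per_patient$correct <- per_patient$call == per_patient$truth
  list(per_patient = per_patient,
       patient_accuracy = mean(per_patient$correct))
}

#' Permutation-null baseline for the LOPO classifier
#'
#' Re-runs the full leave-one-patient-out cross-validation `n_perm` times
#' on copies of the table whose condition labels have been randomly
#' permuted across the whole table, destroying any feature-label
#' association while preserving class frequencies and fold structure.
#' When the observed run is supplied, the real per-fold accuracies are
#' compared with the pooled null per-fold accuracies by a two-sided
#' Wilcoxon rank-sum test.
#'
#' @param table,label_col,config As in [lopo_cv_rfc()].
#' @param n_perm Number of permutations (default 10).
#' @param seed Integer seed.
#' @param observed Optional `chrome_cv` of the unpermuted run.
#' @return List of class `chrome_null`: `null_mean_accuracy` (one per
#'   permutation), `null_fold_accuracy` (pooled), `mean`, and when
#'   `observed` is given, `wilcoxon_p` and `observed_mean`.
#' @export
permutation_baseline <- function(table, label_col, n_perm = 10L,
                                 config = rf_config(), seed = 1L,
                                 observed = NULL) {
  .assert(n_perm >= 1, "n_perm must be >= 1")
  null_means <- numeric(n_perm)
  null_folds <- list()
  for (b in seq_len(n_perm)) {
    set.seed(seed * 1000L + b)
    perm <- table
    perm[[label_col]] <- sample(perm[[label_col]])
    cv <- lopo_cv_rfc(perm, label_col, config = config, seed = seed + b,
                      allow_multiclass_patients = TRUE)
    null_means[b] <- cv$mean_accuracy
    null_folds[[b]] <- cv$fold_accuracy
  }
  res <- list(n_perm = n_perm,
              null_mean_accuracy = null_means,
              null_fold_accuracy = unlist(null_folds, use.names = FALSE),
              mean = mean(null_means))
  if (!is.null(observed)) {
    wt <- suppressWarnings(
      stats::wilcox.test(observed$fold_accuracy, res$null_fold_accuracy,
                         alternative = "two.sided"))
    res$observed_mean <- observed$mean_accuracy
    res$wilcoxon_p <- wt$p.value
  }
  structure(res, class = "chrome_null")
}

#' @export
print.chrome_null <- function(x, ...) {
  cat(sprintf("Permutation baseline: %d permutations, mean balanced accuracy %.3f\n",
              x$n_perm, x$mean))
  if (!is.null(x$wilcoxon_p)) {
    cat(sprintf("observed %.3f vs null, two-sided Wilcoxon rank-sum p = %.3g\n",
                x$observed_mean, x$wilcoxon_p))
  }
  invisible(x)
}

# shared machinery for both ablation protocols: per repetition and LOPO
# fold, subsample the training set by `subsample(train_table, rep_seed)`
.ablation_run <- function(table, label_col, grid, reps, config, seed,
                          subsample, allow_multiclass_patients = FALSE) {
  feats <- setdiff(feature_columns(table), label_col)
  y <- factor(as.character(table[[label_col]]))
  classes <- levels(y)
  pat <- as.character(table$patient_id)
  patients <- sort(unique(pat))
  x <- as.matrix(table[feats])
  acc <- array(NA_real_, c(reps, length(grid)),
               dimnames = list(NULL, as.character(grid)))
  for (gi in seq_along(grid)) {
    for (r in seq_len(reps)) {
      fold_acc <- numeric(length(patients))
      for (i in seq_along(patients)) {
        p <- patients[i]
        test <- pat == p
        tr_idx <- which(!test)
        rep_seed <- seed + 7919L * gi + 131L * r + i
        keep <- subsample(tr_idx, grid[gi], rep_seed)
        set.seed(rep_seed)
        fit <- .fit_rf(x[keep, , drop = FALSE], droplevels(y[keep]), config)
        pr <- as.character(stats::predict(fit, x[test, , drop = FALSE]))
        fold_acc[i] <- balanced_accuracy(as.character(y[test]), pr)
      }
      acc[r, gi] <- mean(fold_acc)
    }
  }
  structure(list(grid = grid, reps = reps, accuracy = acc,
                 mean = colMeans(acc), sd = apply(acc, 2, stats::sd),
                 label_col = label_col),
            class = "chrome_ablation")
}

#' @export
print.chrome_ablation <- function(x, ...) {
  cat(sprintf("Ablation ('%s'): %d repetitions\n", x$label_col, x$reps))
  print(data.frame(grid = x$grid, mean = round(x$mean, 3),
                   sd = round(x$sd, 3)))
  invisible(x)
}

#' Ablation over the number of training patients
#'
#' For each `k` in the grid and each leave-one-patient-out fold, the
#' forest is trained on a random subset of `k` patients per class drawn
#' from the training patients, and evaluated on the held-out patient; the
#' whole procedure is repeated `reps` times with fresh random draws.
#'
#' @param table,label_col,config,seed As in [lopo_cv_rfc()].
#' @param k_grid Patients per class used for training (default 1:9).
#' @param reps Repetitions (default 10).
#' @return `chrome_ablation`: accuracy matrix (reps x grid), means, SDs.
#' @export
ablation_patients <- function(table, label_col, k_grid = 1:9, reps = 10L,
                              config = rf_config(), seed = 1L) {
  pat <- as.character(table$patient_id)
  y <- as.character(table[[label_col]])
  pat_class <- tapply(y, pat, function(v) v[1])
  max_k <- min(table(pat_class)) - 1L   # one patient per class may be held out
  .assert(max(k_grid) <= max_k,
          sprintf("k_grid exceeds available patients per class (max %d)", max_k))
  subsample <- function(tr_idx, k, rep_seed) {
    set.seed(rep_seed)
    tr_pat <- unique(pat[tr_idx])
    chosen <- unlist(lapply(split(tr_pat, pat_class[tr_pat]),
                            function(ps) sample(ps, min(k, length(ps)))),
                     use.names = FALSE)
    tr_idx[pat[tr_idx] %in% chosen]
  }
  .ablation_run(table, label_col, k_grid, reps, config, seed, subsample)
}

#' Ablation over the fraction of training cells
#'
#' For each fraction `p` in the grid, each patient in the training set is
#' represented by `max(1, floor(p * n))` randomly drawn cells.
#'
#' @param table,label_col,config,seed As in [lopo_cv_rfc()].
#' @param p_grid Fractions (default 0.1 ... 1.0).
#' @param reps Repetitions (default 10).
#' @return `chrome_ablation`.
#' @export
ablation_cells <- function(table, label_col, p_grid = seq(0.1, 1, by = 0.1),
                           reps = 10L, config = rf_config(), seed = 1L) {
  pat <- as.character(table$patient_id)
  subsample <- function(tr_idx, p, rep_seed) {
    set.seed(rep_seed)
    unlist(lapply(split(tr_idx, pat[tr_idx]), function(idx) {
      n <- max(1L, floor(p * length(idx)))
      sample(idx, n)
    }), use.names = FALSE)
  }
  .ablation_run(table, label_col, p_grid, reps, config, seed, subsample)
}

#' Gini importance ranking
#'
#' Mean decrease-in-impurity importance averaged over the cross-validation
#' folds (each fold's importances are normalized to sum to one), in
#' descending order, with feature categories from [feature_dictionary()].
#'
#' @param cv A `chrome_cv`.
#' @param top_n Number of features to report (default 15).
#' @return data.frame `feature`, `importance`, `category`.
#' @export
gini_ranking <- function(cv, top_n = 15L) {
  imp <- colMeans(cv$importance, na.rm = TRUE)
  ord <- order(imp, decreasing = TRUE)
  top <- utils::head(ord, top_n)
  dict <- feature_dictionary()
  data.frame(feature = names(imp)[top],
             importance = as.numeric(imp[top]),
             category = dict$category[match(names(imp)[top], dict$name)],
             stringsAsFactors = FALSE)
}

#' Significance star coding
#'
#' `ns` for p > 0.05, then `*`, `**`, `***`, `****` at 0.05, 0.01, 0.001
#' and 0.0001.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

#' Welch/Benjamini-Hochberg biomarker screen
#'
#' Two-sided Welch t-tests of every feature between the groups (pairwise
#' for more than two groups), with Benjamini-Hochberg adjustment across
#' the whole screen and significance at adjusted p < `alpha`. Features
#' with zero variance in both groups of a comparison get `NA` p-values.
#'
#' @param table Feature data.frame.
#' @param group_col Grouping column name.
#' @param alpha FDR level (default 0.05).
#' @return data.frame of class `chrome_screen`: `feature`, `group1`,
#'   `group2`, `statistic`, `mean1`, `mean2`, `direction`, `p`, `p_adj`,
#'   `significant`, `stars`.
#' @export
welch_screen_bh <- function(table, group_col, alpha = 0.05) {
  .assert(group_col %in% names(table), sprintf("no column '%s'", group_col))
  g <- factor(as.character(table[[group_col]]))
  .assert(nlevels(g) >= 2, "need at least two groups")
  .assert(all(table(g) >= 2), "need >= 2 cells per group")
  feats <- feature_columns(table)
  pairs <- utils::combn(levels(g), 2)
  rows <- list()
  for (f in feats) {
    for (j in seq_len(ncol(pairs))) {
      a <- table[[f]][g == pairs[1, j]]
      b <- table[[f]][g == pairs[2, j]]
      if (stats::var(a) == 0 && stats::var(b) == 0) {
        stat <- NA_real_; p <- NA_real_
      } else {
        tt <- stats::t.test(a, b, var.equal = FALSE)
        stat <- unname(tt$statistic); p <- tt$p.value
      }
      rows[[length(rows) + 1L]] <-
        data.frame(feature = f, group1 = pairs[1, j], group2 = pairs[2, j],
                   statistic = stat, mean1 = mean(a), mean2 = mean(b),
                   direction = ifelse(mean(a) > mean(b), "up", "down"),
                   p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  out$stars <- significance_stars(out$p_adj)
  class(out) <- c("chrome_screen", "data.frame")
  out
}

#' @export
print.chrome_screen <- function(x, ...) {
  cat(sprintf("Welch/BH screen: %d tests, %d significant (adjusted p < 0.05)\n",
              nrow(x), sum(x$significant, na.rm = TRUE)))
  sig <- x[order(x$p_adj), ]
  print.data.frame(utils::head(sig, 10), row.names = FALSE)
  invisible(x)
}

#' Control-normalized group comparison
#'
#' Divides every value by the mean of the control group, then reports each
#' group's normalized mean and SD together with a two-sided Welch t-test
#' against the control and significance stars. The control group's
#' normalized mean is exactly 1.
#'
#' @param values Numeric vector (e.g. a marker's area-normalized levels).
#' @param groups Group label vector of the same length.
#' @param control_label The control group's label.
#' @return data.frame `group`, `mean`, `sd`, `n`, `p`, `stars` (p is `NA`
#'   for the control row).
#' @export
compare_to_control <- function(values, groups, control_label) {
  groups <- as.character(groups)
  .assert(control_label %in% groups, "control group not present")
  ctrl <- values[groups == control_label]
  .assert(mean(ctrl) != 0, "zero control mean")
  norm <- values / mean(ctrl)
  out <- do.call(rbind, lapply(unique(groups), function(gr) {
    v <- norm[groups == gr]
    p <- if (gr == control_label) NA_real_ else
      stats::t.test(v, norm[groups == control_label], var.equal = FALSE)$p.value
    data.frame(group = gr, mean = mean(v), sd = stats::sd(v), n = length(v),
               p = p, stringsAsFactors = FALSE)
  }))
  out$stars <- ifelse(is.na(out$p), "", significance_stars(out$p))
  out
}
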