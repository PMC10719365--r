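# Marker gating: per-sample two-component Gaussian mixture models on the
# area-normalized marker intensities, positive/negative calls and PBMC
# subset labels.

#' Fit a marker gate for one sample
#'
#' Fits a two-component univariate Gaussian mixture (unequal variances) to
#' the area-normalized marker intensities of one patient blood sample and
#' derives the positivity threshold as the point between the two component
#' means where the posterior responsibilities are equal (which honors
#' unequal weights and variances, unlike the midpoint). The higher-mean
#' component is the positive one. Gates are flagged unreliable when the
#' fit does not converge or the component separation
#' `|mu2 - mu1| / max(sigma)` falls below `min_separation`.
#'
#' @param values Numeric vector of area-normalized intensities for one
#'   sample and marker.
#' @param sample_id,marker Identifiers attached to the gate.
#' @param min_cells Minimum number of cells required to fit (default 20).
#' @param min_separation Minimum component separation for a reliable gate
#'   (default 0.5).
#' @return Object of class `marker_gate`: component `means`, `sds`,
#'   `weights`, `threshold`, `separation`, `reliable` and `n`.
#' @export
fit_marker_gate <- function(values, sample_id = NA_character_,
                            marker = NA_character_, min_cells = 20L,
                            min_separation = 0.5) {
  values <- values[is.finite(values)]
  .assert(length(values) >= min_cells,
          sprintf("need >= %d cells to fit a gate (got %d)",
                  min_cells, length(values)))
  gate <- list(sample_id = sample_id, marker = marker, n = length(values))
  if (length(unique(values)) < 2L) {
    gate <- c(gate, list(means = rep(mean(values), 2), sds = c(0, 0),
                         weights = c(0.5, 0.5), threshold = NA_real_,
                         separation = 0, reliable = FALSE,
                         reason = "degenerate values"))
    class(gate) <- "marker_gate"
    return(gate)
  }
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(values, G = 2, modelNames = "V",
                                    verbose = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    gate <- c(gate, list(means = c(NA, NA), sds = c(NA, NA),
                         weights = c(NA, NA), threshold = NA_real_,
                         separation = 0, reliable = FALSE,
                         reason = "fit failed"))
    class(gate) <- "marker_gate"
    return(gate)
  }
  mu <- as.numeric(fit$parameters$mean)
  sig <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  if (length(sig) == 1L) sig <- rep(sig, 2)
  w <- as.numeric(fit$parameters$pro)
  ord <- order(mu)                 # component 1 = negative (lower mean)
  mu <- mu[ord]; sig <- sig[ord]; w <- w[ord]
  sep <- abs(mu[2] - mu[1]) / max(sig)
  # equal-posterior crossing between the means
  logratio <- function(x) {
    log(w[1]) + stats::dnorm(x, mu[1], sig[1], log = TRUE) -
      log(w[2]) - stats::dnorm(x, mu[2], sig[2], log = TRUE)
  }
  thr <- tryCatch({
    eps <- (mu[2] - mu[1]) * 1e-6
    stats::uniroot(logratio, lower = mu[1] + eps, upper = mu[2] - eps)$root
  }, error = function(e) (mu[1] + mu[2]) / 2)   # no crossing: midpoint
  reliable <- sep >= min_separation
  gate <- c(gate, list(means = mu, sds = sig, weights = w, threshold = thr,
                       separation = sep, reliable = reliable,
                       reason = if (reliable) NA_character_ else "low separation"))
  class(gate) <- "marker_gate"
  gate
}

#' @export
print.marker_gate <- function(x, ...) {
  cat(sprintf("marker_gate %s / %s (n = %d)\n", x$sample_id, x$marker, x$n))
  cat(sprintf("components: N(%.4g, %.4g^2) w=%.2f | N(%.4g, %.4g^2) w=%.2f\n",
              x$means[1], x$sds[1], x$weights[1],
              x$means[2], x$sds[2], x$weights[2]))
  cat(sprintf("threshold %.4g | separation %.2f | %s\n", x$threshold,
              x$separation,
              if (isTRUE(x$reliable)) "reliable" else
                paste0("UNRELIABLE (", x$reason, ")")))
  invisible(x)
}

#' Apply a gate to intensity values
#'
#' Positive means strictly greater than the threshold (values exactly at
#' the threshold are negative -- deterministic tie rule).
#'
#' @param gate A [fit_marker_gate()] result.
#' @param values Numeric vector.
#' @return Logical vector.
#' @export
apply_gate <- function(gate, values) {
  .assert(isTRUE(gate$reliable), "cannot apply an unreliable gate")
  values > gate$threshold
}

#' Call cell types from marker gates
#'
#' Thresholds the per-cell area-normalized intensities of CD3/CD4/CD8
#' against their sample gates and assigns the CD4/CD8 subset label
#' (`CD4+CD8-`, `CD4-CD8+`, `CD4+CD8+`, `CD4-CD8-`) plus the separate CD3
#' status. Cells from samples whose gate is unreliable, or with missing
#' markers, are flagged partial (subset `NA`).
#'
#' @param gates Named list of `marker_gate`s for one sample; names are
#'   marker names (must include "CD4" and "CD8" for subset labels; "CD3"
#'   optional).
#' @param quants data.frame with one row per nucleus and one column per
#'   marker holding the area-normalized intensities, plus a `nucleus_id`
#'   column.
#' @return data.frame: `nucleus_id`, one logical column per gated marker
#'   (`<marker>_pos`), `subset`, `cd3_status`, `partial`.
#' @export
call_cell_types <- function(gates, quants) {
  .assert(is.data.frame(quants) && "nucleus_id" %in% names(quants),
          "quants must contain a nucleus_id column")
  out <- data.frame(nucleus_id = quants$nucleus_id, stringsAsFactors = FALSE)
  ok <- TRUE
  for (m in names(gates)) {
    g <- gates[[m]]
    if (!m %in% names(quants) || !isTRUE(g$reliable)) {
      out[[paste0(m, "_pos")]] <- NA
      ok <- FALSE
      next
    }
    out[[paste0(m, "_pos")]] <- apply_gate(g, quants[[m]])
  }
  has4 <- "CD4_pos" %in% names(out) && !all(is.na(out$CD4_pos))
  has8 <- "CD8_pos" %in% names(out) && !all(is.na(out$CD8_pos))
  if (has4 && has8) {
    out$subset <- paste0(ifelse(out$CD4_pos, "CD4+", "CD4-"),
                         ifelse(out$CD8_pos, "CD8+", "CD8-"))
  } else {
    out$subset <- NA_character_
    ok <- FALSE
  }
  if ("CD3_pos" %in% names(out) && !all(is.na(out$CD3_pos))) {
    out$cd3_status <- ifelse(out$CD3_pos, "CD3+", "CD3-")
  } else {
    out$cd3_status <- NA_character_
  }
  out$partial <- !ok
  out
}

#' Relative abundance of PBMC subsets
#'
#' Per-sample fractions of the four CD4/CD8 subsets (summing to 1 within
#' each sample), and group-level means and SDs across samples. Samples
#' with fewer than `min_cells` typed cells are excluded.
#'
#' @param calls data.frame of [call_cell_types()] results with `sample_id`
#'   and `group` columns appended (group = the condition to aggregate by).
#' @param min_cells Minimum typed cells per sample (default 6).
#' @return List: `per_sample` (sample x subset fractions) and `by_group`
#'   (group x subset mean and sd).
#' @export
subset_abundance <- function(calls, min_cells = 6L) {
  .assert(all(c("sample_id", "group", "subset") %in% names(calls)),
          "calls must have sample_id, group and subset columns")
  calls <- calls[!is.na(calls$subset), , drop = FALSE]
  .assert(nrow(calls) > 0, "no typed cells")
  subsets <- c("CD4+CD8-", "CD4-CD8+", "CD4+CD8+", "CD4-CD8-")
  keep <- names(which(table(calls$sample_id) >= min_cells))
  calls <- calls[calls$sample_id %in% keep, , drop = FALSE]
  .assert(nrow(calls) > 0, "no sample meets the cell floor")
  samples <- unique(calls[, c("sample_id", "group")])
  frac <- matrix(0, nrow(samples), length(subsets),
                 dimnames = list(samples$sample_id, subsets))
  for (i in seq_len(nrow(samples))) {
    sub <- calls$subset[calls$sample_id == samples$sample_id[i]]
    tab <- table(factor(sub, levels = subsets))
    frac[i, ] <- as.numeric(tab) / length(sub)
  }
  per_sample <- data.frame(sample_id = samples$sample_id,
                           group = samples$group, frac,
                           check.names = FALSE)
  groups <- unique(samples$group)
  by_group <- do.call(rbind, lapply(groups, function(g) {
    fr <- frac[samples$group == g, , drop = FALSE]
    data.frame(group = g, subset = subsets,
               mean = colMeans(fr),
               sd = apply(fr, 2, stats::sd),
               n_samples = nrow(fr), row.names = NULL)
  }))
  list(per_sample = per_sample, by_group = by_group)
}
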