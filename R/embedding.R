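# 2-D embeddings for visual batch-effect QC: cells should cluster by
# condition, not by patient sample.

# exact O(n^2) t-SNE: per-point bandwidths by bisection to the target
# perplexity, then momentum gradient descent on the Kullback-Leibler
# divergence with early exaggeration. Deterministic under the caller's seed.
.tsne_exact <- function(x, perplexity = 30, n_iter = 400L, eta = 100,
                        exaggeration = 4, exag_iter = 100L) {
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  logu <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (it in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { beta <- beta / 2; next }
      h <- log(sw) + beta * sum(di * w) / sw
      if (abs(h - logu) < 1e-5) break
      if (h > logu) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    p <- exp(-di * beta); p <- p / sum(p)
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  inc <- matrix(0, n, 2)
  for (it in seq_len(n_iter)) {
    Pe <- if (it <= exag_iter) P * exaggeration else P
    num <- 1 / (1 + as.matrix(stats::dist(y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% y
    mom <- if (it < 250) 0.5 else 0.8
    inc <- mom * inc - eta * grad
    y <- y + inc
    y <- sweep(y, 2, colMeans(y))
  }
  y
}

#' 2-D QC embedding of a feature table
#'
#' Projects cells to two dimensions for visual batch-effect control:
#' `"tsne"` (exact t-distributed stochastic neighbor embedding, suitable
#' up to a few thousand cells), `"lda"` (linear discriminant axes of
#' `color_col`) or `"pca"` (first two principal components of the scaled
#' features). Deterministic under `seed`; coordinates are returned with
#' the metadata columns so plots can be colored by patient or condition.
#'
#' @param table Pruned feature data.frame.
#' @param method One of `"tsne"`, `"lda"`, `"pca"`.
#' @param seed Integer seed.
#' @param color_col Label column for LDA (default `condition`).
#' @param perplexity t-SNE perplexity (default 30; must be < n/3).
#' @return data.frame: metadata columns plus `dim1`, `dim2`.
#' @export
qc_embedding <- function(table, method = c("tsne", "lda", "pca"), seed = 1L,
                         color_col = "condition", perplexity = 30) {
  method <- match.arg(method)
  feats <- feature_columns(table)
  x <- scale(as.matrix(table[feats]))
  x <- x[, apply(x, 2, function(v) all(is.finite(v))), drop = FALSE]
  set.seed(seed)
  if (method == "tsne") {
    .assert(nrow(x) >= 3 * perplexity + 2,
            "too few cells for the requested perplexity")
    # PCA pre-reduction, standard before t-SNE
    if (ncol(x) > 30) x <- stats::prcomp(x)$x[, 1:30, drop = FALSE]
    y <- .tsne_exact(x, perplexity = perplexity)
  } else if (method == "lda") {
    g <- factor(as.character(table[[color_col]]))
    fit <- MASS::lda(x, grouping = g)
    pr <- stats::predict(fit, x)$x
    y <- if (ncol(pr) >= 2) pr[, 1:2] else cbind(pr[, 1], stats::rnorm(nrow(pr), sd = 1e-6))
  } else {
    pr <- stats::prcomp(x)$x
    y <- pr[, 1:2]
  }
  meta <- intersect(.META_COLS, names(table))
  out <- table[meta]
  out$dim1 <- y[, 1]
  out$dim2 <- y[, 2]
  out
}
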