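#' Otsu threshold
#'
#' Returns the intensity threshold maximizing the between-class variance of
#' the two classes it induces. The search is exhaustive over cuts between
#' consecutive distinct values (exact for discrete data such as 8-bit
#' images); for images with more than `max_levels` distinct values the
#' histogram is first quantized to `max_levels` bins. Foreground is defined
#' as intensity strictly greater than the returned threshold.
#'
#' @param x Numeric vector, matrix or array of intensities with at least
#'   two distinct values.
#' @param max_levels Maximum number of distinct candidate levels before
#'   binning kicks in (default 256).
#' @return Scalar threshold, the midpoint of the optimal cut pair.
#' @export
otsu_threshold <- function(x, max_levels = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  u <- sort(unique(v))
  if (length(u) < 2L) stop("degenerate histogram", call. = FALSE)
  if (length(u) > max_levels) {
    # quantize to max_levels equal-width bins over the observed range
    br <- seq(min(v), max(v), length.out = max_levels + 1L)
    mid <- (br[-1] + br[-length(br)]) / 2
    v <- mid[pmin(pmax(findInterval(v, br, rightmost.closed = TRUE), 1L),
                  max_levels)]
    u <- sort(unique(v))
  }
  cnt <- tabulate(match(v, u), nbins = length(u))
  n <- length(v)
  w <- cumsum(cnt)                    # class-1 counts up to each level
  s <- cumsum(cnt * u)                # class-1 intensity sums
  tot <- s[length(s)]
  k <- seq_len(length(u) - 1L)        # cut after level k
  w1 <- w[k]; w2 <- n - w1
  m1 <- s[k] / w1
  m2 <- (tot - s[k]) / w2
  between <- (w1 / n) * (w2 / n) * (m1 - m2)^2
  kbest <- which.max(between)
  (u[kbest] + u[kbest + 1L]) / 2
}
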