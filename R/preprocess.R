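#' Range-normalize an image to \[0, 1\]
#'
#' Min-max normalization per image: `(I - min) / (max - min)`. Applied to
#' DAPI stacks to absorb the acquisition-to-acquisition variability of the
#' explored intensity range. A constant image maps to all zeros (the
#' degenerate case has no range to normalize).
#'
#' @param x Numeric array of any dimensionality, finite values.
#' @return Array of the same shape with values in \[0, 1\].
#' @examples
#' range_normalize(c(0, 5, 10))  # 0.0 0.5 1.0
#' @export
range_normalize <- function(x) {
  .assert(all(is.finite(x)), "image must be finite")
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(x * 0)
  (x - lo) / (hi - lo)
}

#' Gamma adjustment
#'
#' Pointwise power transform `I^gamma` for contrast enhancement of images
#' in \[0, 1\]. The pipeline's nuclear segmentation uses `gamma = 0.7`,
#' which brightens dim nuclear interiors while fixing 0 and 1.
#'
#' @param x Numeric array with values in \[0, 1\].
#' @param gamma Positive exponent.
#' @return Array of the same shape.
#' @export
gamma_adjust <- function(x, gamma = 0.7) {
  .assert(is.numeric(gamma) && length(gamma) == 1 && gamma > 0,
          "gamma must be a positive scalar")
  .assert(min(x) >= -1e-12 && max(x) <= 1 + 1e-12,
          "gamma_adjust expects values in [0, 1]")
  pmin(pmax(x, 0), 1)^gamma
}

#' Median denoising with a cross-shaped footprint
#'
#' Replaces each pixel by the median of its plus-shaped (cross)
#' neighborhood of the given radius (radius 1 = the pixel and its 4 edge
#' neighbors). Edges are handled by reflective padding. Used on max-z
#' projections before thresholding.
#'
#' @param x 2-D numeric matrix.
#' @param footprint_radius Cross arm length in pixels (default 1).
#' @return Matrix of the same shape.
#' @export
median_denoise <- function(x, footprint_radius = 1L) {
  .assert(is.matrix(x), "median_denoise expects a 2-D matrix")
  r <- as.integer(footprint_radius)
  .assert(r >= 1L, "footprint_radius must be >= 1")
  xp <- .pad_reflect(x, r)
  n <- nrow(x); m <- ncol(x)
  core <- function(dy, dx) xp[(1 + r + dy):(n + r + dy),
                              (1 + r + dx):(m + r + dx), drop = FALSE]
  cols <- list(core(0L, 0L))
  for (s in seq_len(r)) {
    cols <- c(cols, list(core(s, 0L), core(-s, 0L), core(0L, s), core(0L, -s)))
  }
  .vec_median(cols)
}

#' Maximum-intensity projection along z
#'
#' @param volume 3-D numeric array (z, y, x) with at least one plane.
#' @return 2-D matrix (y, x): the per-pixel maximum over z.
#' @export
max_z_project <- function(volume) {
  .assert(is.array(volume) && length(dim(volume)) == 3,
          "max_z_project expects a 3-D (z, y, x) array")
  d <- dim(volume)
  out <- matrix(volume[1, , ], d[2], d[3])
  if (d[1] > 1) {
    for (z in 2:d[1]) out <- pmax(out, matrix(volume[z, , ], d[2], d[3]))
  }
  out
}
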