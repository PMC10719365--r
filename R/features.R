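# Chrometric feature extraction: nuclear morphology, boundary shape,
# DNA-intensity distribution, image moments and HC/EC content, plus
# per-marker protein quantification. Features carry physical units where
# applicable (um, um^2, um^3, 1/um); everything else is dimensionless.

#' Morphology features of a nucleus
#'
#' Volume, projected area, height, 2D concavity (one minus the ratio of
#' the projected area to its convex-hull area), a slice-wise 3D
#' solidity-type concavity (one minus the voxel count over the voxel count
#' of the per-slice convex hulls), and principal-axis shape descriptors
#' computed on physically scaled coordinates (z multiplied by dz/dx, so
#' anisotropy does not distort the axes).
#'
#' @param mask3d Logical 3-D array (z, y, x), QC-passing nuclear mask.
#' @param mask2d Logical matrix, the 2D nuclear mask.
#' @param spec [acquisition_spec()] providing the voxel geometry.
#' @return Named numeric vector. `concavity_3d` is `NA` for single-plane
#'   masks (degenerate for a 3D hull).
#' @export
morphology_features <- function(mask3d, mask2d, spec) {
  vx <- spec$dx_um * spec$dy_um * spec$dz_um
  px <- spec$dx_um * spec$dy_um
  vol <- sum(mask3d) * vx
  area <- sum(mask2d) * px
  z_occ <- sum(apply(mask3d, 1, any))
  height <- z_occ * spec$dz_um
  hull2d <- .convex_hull_mask(mask2d)
  conc2d <- 1 - sum(mask2d) / sum(hull2d)
  if (z_occ <= 1L) {
    conc3d <- NA_real_
  } else {
    hull_vox <- 0L
    for (z in seq_len(dim(mask3d)[1])) {
      sl <- matrix(mask3d[z, , ], dim(mask3d)[2], dim(mask3d)[3])
      if (any(sl)) hull_vox <- hull_vox + sum(.convex_hull_mask(sl))
    }
    conc3d <- 1 - sum(mask3d) / hull_vox
  }
  idx <- which(mask3d, arr.ind = TRUE)
  coords <- cbind(idx[, 1] * spec$dz_um,
                  idx[, 2] * spec$dy_um,
                  idx[, 3] * spec$dx_um)
  ev <- sort(eigen(stats::cov(coords), symmetric = TRUE,
                   only.values = TRUE)$values, decreasing = TRUE)
  ev <- pmax(ev, 1e-12)
  c(volume_um3 = vol,
    projected_area_um2 = area,
    height_um = height,
    concavity_2d = conc2d,
    concavity_3d = conc3d,
    aspect_ratio = sqrt(ev[1] / ev[3]),
    elongation = sqrt(ev[1] / ev[2]))
}

# closed boundary contour of a 2D mask, resampled to n_points of equal
# arc length; returns an n x 2 matrix of (y, x) coordinates in pixels
.boundary_contour <- function(mask, n_points = 128L) {
  oc <- EBImage::ocontour(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  .assert(length(oc) >= 1, "mask has no boundary contour")
  ctr <- oc[[which.max(vapply(oc, nrow, integer(1)))]]
  # EBImage indexes (x=row, y=col) on our (y, x) matrix; col1 = our y index
  pts <- cbind(ctr[, 1] + 1, ctr[, 2] + 1)   # 0-based -> 1-based
  closed <- rbind(pts, pts[1, , drop = FALSE])
  seg <- sqrt(diff(closed[, 1])^2 + diff(closed[, 2])^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  target <- seq(0, total, length.out = n_points + 1L)[-(n_points + 1L)]
  y <- stats::approx(s, closed[, 1], xout = target)$y
  x <- stats::approx(s, closed[, 2], xout = target)$y
  cbind(y, x)
}

#' Boundary-shape features of a nucleus
#'
#' Extracts the closed 2D boundary contour, resamples it to `n_points`
#' equally spaced arc-length points, low-passes the contour by truncating
#' its Fourier series to `n_harmonics` harmonics (suppressing the
#' pixel-staircase noise of a rasterized boundary), and computes the local
#' curvature from the analytic derivatives of the truncated series.
#' Reported in physical units (1/um): the mean absolute curvature, its
#' standard deviation (the boundary "variability") and the maximum
#' absolute curvature.
#'
#' @param mask2d Logical matrix, single connected 2D mask.
#' @param spec [acquisition_spec()].
#' @param n_points Number of resampled contour points (default 128).
#' @param n_harmonics Fourier harmonics kept for the smooth contour
#'   (default 8: ample for nuclear shapes, which are low-order, and well
#'   below the staircase frequencies of 20-40 px radius masks).
#' @return Named numeric vector `curvature_mean`, `curvature_sd`,
#'   `curvature_max` (1/um).
#' @export
boundary_features <- function(mask2d, spec, n_points = 128L,
                              n_harmonics = 8L) {
  pts <- .boundary_contour(mask2d, n_points)
  pts <- pts * spec$dx_um                      # physical coordinates
  n <- nrow(pts)
  kk <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))  # signed harmonic numbers
  lowpass <- abs(kk) <= n_harmonics
  deriv <- function(v, order) {
    f <- stats::fft(v)
    f[!lowpass] <- 0
    f <- f * (1i * kk)^order
    Re(stats::fft(f, inverse = TRUE)) / n
  }
  d1y <- deriv(pts[, 1], 1); d1x <- deriv(pts[, 2], 1)
  d2y <- deriv(pts[, 1], 2); d2x <- deriv(pts[, 2], 2)
  denom <- (d1x^2 + d1y^2)^1.5
  kappa <- ifelse(denom > 1e-12, (d1x * d2y - d1y * d2x) / denom, 0)
  c(curvature_mean = mean(abs(kappa)),
    curvature_sd = stats::sd(kappa),
    curvature_max = max(abs(kappa)))
}

#' DNA-intensity distribution features
#'
#' Descriptive statistics of the in-mask DAPI voxel intensities: mean, SD,
#' skewness, excess kurtosis, the nine deciles, and the Shannon entropy
#' (bits) of a 64-bin histogram over the in-mask intensity range.
#'
#' @param dapi_crop 3-D array (z, y, x), background-cleared DAPI crop.
#' @param mask3d Logical 3-D array, the nuclear mask.
#' @param n_bins Histogram bins for the entropy (default 64).
#' @return Named numeric vector.
#' @export
intensity_features <- function(dapi_crop, mask3d, n_bins = 64L) {
  v <- dapi_crop[mask3d]
  .assert(length(v) > 0, "empty mask")
  m <- mean(v); s <- stats::sd(v)
  if (s > 0) {
    skew <- mean((v - m)^3) / (mean((v - m)^2))^1.5
    kurt <- mean((v - m)^4) / (mean((v - m)^2))^2 - 3
  } else {
    skew <- 0; kurt <- 0
  }
  dec <- stats::quantile(v, probs = seq(0.1, 0.9, by = 0.1), names = FALSE)
  rng <- range(v)
  if (rng[1] == rng[2]) {
    ent <- 0
  } else {
    br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
    cnt <- tabulate(pmin(pmax(findInterval(v, br, rightmost.closed = TRUE),
                              1L), n_bins), nbins = n_bins)
    p <- cnt[cnt > 0] / length(v)
    ent <- -sum(p * log2(p))
  }
  out <- c(intensity_mean = m, intensity_sd = ifelse(is.na(s), 0, s),
           intensity_skewness = skew, intensity_kurtosis = kurt,
           stats::setNames(dec, paste0("intensity_d", seq(10, 90, by = 10))),
           intensity_entropy = ent)
  out
}

#' Image-moment features of the projected nucleus
#'
#' Normalized central moments of the masked projected DAPI intensity up to
#' order 3 and the seven rotation-invariant Hu combinations. Central
#' moments are translation invariant by construction; the Hu invariants
#' are additionally invariant under rotation and scale.
#'
#' @param proj 2-D matrix, max-z projected DAPI.
#' @param mask2d Logical matrix.
#' @return Named numeric vector: `eta11`, `eta20`, `eta02`, `eta21`,
#'   `eta12`, `eta30`, `eta03`, `hu1` ... `hu7`.
#' @export
moment_features <- function(proj, mask2d) {
  .assert(any(mask2d), "empty mask")
  img <- proj * mask2d
  m00 <- sum(img)
  .assert(m00 > 0, "zero-mass image")
  n <- nrow(img); mcol <- ncol(img)
  yy <- matrix(rep(seq_len(n), mcol), n, mcol)
  xx <- matrix(rep(seq_len(mcol), each = n), n, mcol)
  cy <- sum(yy * img) / m00
  cx <- sum(xx * img) / m00
  mu <- function(p, q) sum((xx - cx)^p * (yy - cy)^q * img)
  eta <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  e20 <- eta(2, 0); e02 <- eta(0, 2); e11 <- eta(1, 1)
  e30 <- eta(3, 0); e03 <- eta(0, 3); e21 <- eta(2, 1); e12 <- eta(1, 2)
  hu1 <- e20 + e02
  hu2 <- (e20 - e02)^2 + 4 * e11^2
  hu3 <- (e30 - 3 * e12)^2 + (3 * e21 - e03)^2
  hu4 <- (e30 + e12)^2 + (e21 + e03)^2
  hu5 <- (e30 - 3 * e12) * (e30 + e12) *
    ((e30 + e12)^2 - 3 * (e21 + e03)^2) +
    (3 * e21 - e03) * (e21 + e03) *
    (3 * (e30 + e12)^2 - (e21 + e03)^2)
  hu6 <- (e20 - e02) * ((e30 + e12)^2 - (e21 + e03)^2) +
    4 * e11 * (e30 + e12) * (e21 + e03)
  hu7 <- (3 * e21 - e03) * (e30 + e12) *
    ((e30 + e12)^2 - 3 * (e21 + e03)^2) -
    (e30 - 3 * e12) * (e21 + e03) *
    (3 * (e30 + e12)^2 - (e21 + e03)^2)
  c(eta11 = e11, eta20 = e20, eta02 = e02, eta21 = e21, eta12 = e12,
    eta30 = e30, eta03 = e03,
    hu1 = hu1, hu2 = hu2, hu3 = hu3, hu4 = hu4, hu5 = hu5, hu6 = hu6,
    hu7 = hu7)
}

#' Heterochromatin / euchromatin features
#'
#' Partitions the in-mask DAPI voxels into heterochromatin (high intensity)
#' and euchromatin by a two-class Otsu threshold computed within the mask.
#' Reports the HC volume, the HC/EC volume ratio, the HC volume fraction
#' and the HC intensity fraction. The partition conserves the nuclear
#' volume exactly. A uniform (degenerate) nucleus yields `NA`s.
#'
#' @param dapi_crop 3-D array (z, y, x).
#' @param mask3d Logical 3-D array.
#' @param spec [acquisition_spec()].
#' @return Named numeric vector `hc_volume_um3`, `ec_volume_um3`,
#'   `hc_ec_ratio`, `hc_volume_fraction`, `hc_intensity_fraction`.
#' @export
hc_ec_features <- function(dapi_crop, mask3d, spec) {
  v <- dapi_crop[mask3d]
  .assert(length(v) > 0, "empty mask")
  vx <- spec$dx_um * spec$dy_um * spec$dz_um
  thr <- tryCatch(otsu_threshold(v), error = function(e) NULL)
  if (is.null(thr)) {
    return(c(hc_volume_um3 = NA_real_, ec_volume_um3 = NA_real_,
             hc_ec_ratio = NA_real_, hc_volume_fraction = NA_real_,
             hc_intensity_fraction = NA_real_))
  }
  hc <- v > thr
  n_hc <- sum(hc); n_ec <- sum(!hc)
  c(hc_volume_um3 = n_hc * vx,
    ec_volume_um3 = n_ec * vx,
    hc_ec_ratio = n_hc / max(n_ec, 1L),
    hc_volume_fraction = n_hc / length(v),
    hc_intensity_fraction = sum(v[hc]) / sum(v))
}

#' Quantify a marker within the nuclear mask
#'
#' Total in-mask intensity of the max-z projected marker image and the
#' area-normalized total (total divided by the projected mask area in
#' pixels), the statistic used for mixture-model gating.
#'
#' @param marker_proj 2-D matrix, max-z projected marker image.
#' @param mask2d Logical matrix, projected nuclear mask.
#' @return Named vector `total_intensity`, `area_norm_intensity`.
#' @export
quantify_marker <- function(marker_proj, mask2d) {
  area <- sum(mask2d)
  .assert(area > 0, "empty mask")
  total <- sum(marker_proj[mask2d])
  c(total_intensity = total, area_norm_intensity = total / area)
}

#' Assemble the full chrometric profile of one nucleus
#'
#' Runs every feature family on a QC-passing record and flattens the
#' result into a one-row data.frame: metadata, chrometric features,
#' per-marker quantifications (`<marker>_total`, `<marker>_areanorm`) and
#' the gamma-H2AX focus count when that channel is present. Feature order
#' is deterministic.
#'
#' @param record A QC-passing `nucleus_record` (see [segment_nucleus_3d()]).
#' @param fparams [foci_params()] for the focus counter.
#' @param gh2ax_marker Name of the gamma-H2AX channel in the channel map
#'   (matched case-insensitively against "gh2ax"/"gammah2ax" by default).
#' @return One-row data.frame.
#' @export
assemble_profile <- function(record, fparams = NULL, gh2ax_marker = NULL) {
  if (is.null(fparams)) fparams <- foci_params()
  .assert(isTRUE(record$qc_pass), "assemble_profile requires a QC-passing record")
  d <- dim(record$crop)
  spec <- record$spec
  dch <- .dapi_channel(spec)
  dapi <- array(record$crop[dch, , , ], d[2:4])
  mask3d <- record$mask3d
  mask2d_proj <- max_z_project(array(as.numeric(mask3d), dim(mask3d))) > 0.5
  proj <- max_z_project(dapi)
  feats <- c(morphology_features(mask3d, mask2d_proj, spec),
             boundary_features(mask2d_proj, spec),
             intensity_features(dapi, mask3d),
             moment_features(proj, mask2d_proj),
             hc_ec_features(dapi, mask3d, spec))
  markers <- names(spec$channels)[-dch]
  mk <- numeric(0)
  if (is.null(gh2ax_marker)) {
    hit <- markers[grepl("h2ax", markers, ignore.case = TRUE)]
    gh2ax_marker <- if (length(hit)) hit[1] else NA_character_
  }
  for (m in markers) {
    mp <- max_z_project(array(record$crop[spec$channels[[m]], , , ], d[2:4]))
    q <- quantify_marker(mp, mask2d_proj)
    mk <- c(mk, stats::setNames(q, paste0(m, c("_total", "_areanorm"))))
  }
  if (!is.na(gh2ax_marker) && gh2ax_marker %in% markers) {
    g <- array(record$crop[spec$channels[[gh2ax_marker]], , , ], d[2:4])
    fs <- detect_foci(g, mask3d, fparams)
    mk <- c(mk, foci_count = fs$count)
  }
  out <- data.frame(nucleus_id = record$nucleus_id,
                    sample_id = record$sample_id,
                    patient_id = record$patient_id,
                    condition = record$condition,
                    timepoint = record$timepoint,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(as.list(c(feats, mk)), check.names = TRUE))
}

#' Feature dictionary
#'
#' Name, category and units for every chrometric feature the pipeline
#' emits. Categories follow the four chromatin-feature families (intensity
#' distribution, image moments, HC/EC, boundary shape) plus morphology.
#'
#' @return data.frame with columns `name`, `category`, `units`.
#' @export
feature_dictionary <- function() {
  rbind(
    data.frame(name = c("volume_um3", "projected_area_um2", "height_um",
                        "concavity_2d", "concavity_3d", "aspect_ratio",
                        "elongation"),
               category = "morphology",
               units = c("um^3", "um^2", "um", "1", "1", "1", "1")),
    data.frame(name = c("curvature_mean", "curvature_sd", "curvature_max"),
               category = "boundary",
               units = "1/um"),
    data.frame(name = c("intensity_mean", "intensity_sd",
                        "intensity_skewness", "intensity_kurtosis",
                        paste0("intensity_d", seq(10, 90, by = 10)),
                        "intensity_entropy"),
               category = "intensity",
               units = c(rep("1", 13), "bits")),
    data.frame(name = c("eta11", "eta20", "eta02", "eta21", "eta12",
                        "eta30", "eta03", paste0("hu", 1:7)),
               category = "moments",
               units = "1"),
    data.frame(name = c("hc_volume_um3", "ec_volume_um3", "hc_ec_ratio",
                        "hc_volume_fraction", "hc_intensity_fraction"),
               category = "hc_ec",
               units = c("um^3", "um^3", "1", "1", "1")),
    data.frame(name = "foci_count", category = "dna_damage", units = "count")
  )
}
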