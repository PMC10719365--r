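#' Focus-detection parameters
#'
#' @param sd_multiplier Intensity threshold in SD units above the in-mask
#'   mean (default 2.5).
#' @param min_size_px Minimum focus area in pixels (default 4, i.e.
#'   0.032 um^2 at 0.09 um pixels).
#' @param ws_tolerance Watershed tolerance on the \[0, 1\] normalized
#'   intensity: local maxima closer in height than this are merged to one
#'   seed (plateau handling).
#' @param ws_ext Watershed neighborhood radius in pixels; sets the minimum
#'   separation of seed maxima.
#' @return List of class `foci_params`.
#' @export
foci_params <- function(sd_multiplier = 2.5, min_size_px = 4L,
                        ws_tolerance = 0.05, ws_ext = 2L) {
  .assert(sd_multiplier > 0, "sd_multiplier must be > 0")
  .assert(min_size_px >= 1, "min_size_px must be >= 1")
  structure(list(sd_multiplier = sd_multiplier,
                 min_size_px = as.integer(min_size_px),
                 ws_tolerance = ws_tolerance, ws_ext = as.integer(ws_ext)),
            class = "foci_params")
}

#' Detect and count gamma-H2AX foci in one nucleus
#'
#' Pipeline: max-z project the marker crop and the 3D nuclear mask,
#' range-normalize the projection, threshold at the in-mask mean plus
#' `sd_multiplier` standard deviations (statistics over pixels inside the
#' projected mask, so the zeroed background does not bias them), remove
#' components smaller than `min_size_px`, split touching foci with a
#' watershed seeded at the local intensity maxima of the projected image,
#' and remove sub-minimum fragments again. Because normalization precedes
#' thresholding, the count is invariant under affine rescaling of the crop
#' intensities. A flat in-mask signal (SD = 0) yields zero foci.
#'
#' @param gh2ax_crop 3-D array (z, y, x): the marker channel crop.
#' @param mask3d Logical 3-D array: the nuclear mask (same geometry).
#' @param params [foci_params()].
#' @return List of class `foci_set`: `count` and `foci`, a data.frame with
#'   one row per focus (`label`, `area_px`, `centroid_y`, `centroid_x`).
#' @export
detect_foci <- function(gh2ax_crop, mask3d, params = foci_params()) {
  .assert(identical(dim(gh2ax_crop), dim(mask3d)),
          "crop and mask must share dimensions")
  mask2d <- max_z_project(array(as.numeric(mask3d), dim(mask3d))) > 0.5
  .assert(any(mask2d), "empty mask")
  proj <- range_normalize(max_z_project(gh2ax_crop))
  v <- proj[mask2d]
  s <- stats::sd(v)
  empty <- structure(list(count = 0L,
                          foci = data.frame(label = integer(0),
                                            area_px = integer(0),
                                            centroid_y = numeric(0),
                                            centroid_x = numeric(0))),
                     class = "foci_set")
  if (is.na(s) || s == 0) return(empty)
  thr <- mean(v) + params$sd_multiplier * s
  bin <- mask2d & (proj >= thr)
  if (!any(bin)) return(empty)
  lab <- matrix(as.integer(EBImage::bwlabel(matrix(as.numeric(bin),
                                                   nrow(bin), ncol(bin)))),
                nrow(bin), ncol(bin))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= params$min_size_px)
  if (length(keep) == 0L) return(empty)
  bin2 <- matrix(lab %in% keep, nrow(bin), ncol(bin))
  # watershed on the intensity landscape restricted to the retained mask
  ws <- EBImage::watershed(EBImage::Image(proj * bin2),
                           tolerance = params$ws_tolerance,
                           ext = params$ws_ext)
  wl <- matrix(as.integer(EBImage::imageData(ws)), nrow(bin), ncol(bin))
  wl[!bin2] <- 0L
  sizes2 <- tabulate(wl[wl > 0L])
  keep2 <- which(sizes2 >= params$min_size_px)
  if (length(keep2) == 0L) return(empty)
  foci <- data.frame(label = seq_along(keep2),
                     area_px = sizes2[keep2],
                     centroid_y = NA_real_, centroid_x = NA_real_)
  for (i in seq_along(keep2)) {
    idx <- which(wl == keep2[i], arr.ind = TRUE)
    foci$centroid_y[i] <- mean(idx[, 1])
    foci$centroid_x[i] <- mean(idx[, 2])
  }
  structure(list(count = nrow(foci), foci = foci), class = "foci_set")
}

#' @export
print.foci_set <- function(x, ...) {
  cat(sprintf("foci_set: %d foci\n", x$count))
  if (x$count > 0) print(x$foci)
  invisible(x)
}
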