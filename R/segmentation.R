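#' Segmentation parameters
#'
#' Bundles the tunable constants of the nuclear/cell segmentation stage.
#' Defaults are the pipeline's reference settings: gamma 0.7 contrast
#' adjustment; 2D candidates kept between 800 and 5000 px (6.48-40.5 um^2
#' at 0.09 um pixels) -- the upper cap is also what removes merged/touching
#' nuclei; 12 px bounding-box pad; background cleared outside the convex
#' hull of the mask dilated 12 times with a 3x3 cross; Chan-Vese with
#' (lambda1, lambda2) = (1, 2) for at most 300 iterations; 3D masks kept at
#' >= 400 voxels (1.62 um^3) and height 2.5-10 um; cell masks expanded
#' 12 px laterally and 2 planes axially.
#'
#' @param gamma Gamma-adjustment exponent for the 2D stage.
#' @param area_min_px,area_max_px 2D candidate area bounds in pixels.
#' @param bbox_pad_px Bounding-box pad for 3D crops, pixels.
#' @param clear_dilations Iterations of 3x3-cross dilation before the
#'   convex-hull background clearing.
#' @param chanvese_lambda1,chanvese_lambda2,chanvese_max_iter Chan-Vese
#'   weights and iteration cap.
#' @param min_voxels Minimum 3D mask size in voxels.
#' @param height_min_um,height_max_um Acceptable nuclear height along z, um.
#' @param cell_pad_xy_px,cell_pad_z_px Cell-mask expansion in pixels/planes.
#' @return List of class `segmentation_params`.
#' @export
segmentation_params <- function(gamma = 0.7, area_min_px = 800L,
                                area_max_px = 5000L, bbox_pad_px = 12L,
                                clear_dilations = 12L,
                                chanvese_lambda1 = 1, chanvese_lambda2 = 2,
                                chanvese_max_iter = 300L,
                                min_voxels = 400L,
                                height_min_um = 2.5, height_max_um = 10,
                                cell_pad_xy_px = 12L, cell_pad_z_px = 2L) {
  .assert(area_min_px < area_max_px, "area_min_px must be < area_max_px")
  .assert(height_min_um < height_max_um, "height_min_um must be < height_max_um")
  .assert(bbox_pad_px >= 0 && cell_pad_xy_px >= 0 && cell_pad_z_px >= 0,
          "pads must be >= 0")
  structure(list(gamma = gamma, area_min_px = as.integer(area_min_px),
                 area_max_px = as.integer(area_max_px),
                 bbox_pad_px = as.integer(bbox_pad_px),
                 clear_dilations = as.integer(clear_dilations),
                 chanvese_lambda1 = chanvese_lambda1,
                 chanvese_lambda2 = chanvese_lambda2,
                 chanvese_max_iter = as.integer(chanvese_max_iter),
                 min_voxels = as.integer(min_voxels),
                 height_min_um = height_min_um, height_max_um = height_max_um,
                 cell_pad_xy_px = as.integer(cell_pad_xy_px),
                 cell_pad_z_px = as.integer(cell_pad_z_px)),
            class = "segmentation_params")
}

#' 2D nucleus candidates from a DAPI stack
#'
#' Candidate pipeline: max-z projection, cross-footprint median denoising,
#' gamma adjustment, Otsu thresholding, connected components; components
#' are then kept only if their area lies in
#' `[area_min_px, area_max_px]` and they do not touch the image border.
#' The area cap is what removes merged nuclei touching in 2D.
#'
#' @param dapi Range-normalized single-channel 3-D array (z, y, x).
#' @param params [segmentation_params()].
#' @return List of candidates; each has `label`, `mask` (logical matrix
#'   cropped to the bounding box), `bbox` (1-based inclusive
#'   `c(y0, y1, x0, x1)` in the full image) and `area_px`. Empty list if no
#'   nuclei are found (including the degenerate constant-image case).
#' @export
segment_nuclei_2d <- function(dapi, params = segmentation_params()) {
  proj <- max_z_project(dapi)
  den <- median_denoise(proj)
  den <- pmin(pmax(den, 0), 1)
  adj <- gamma_adjust(den, params$gamma)
  thr <- tryCatch(otsu_threshold(adj), error = function(e) NULL)
  if (is.null(thr)) return(list())   # degenerate histogram -> no nuclei found
  bin <- adj > thr
  lab <- EBImage::bwlabel(matrix(as.numeric(bin), nrow(bin), ncol(bin)))
  lab <- matrix(as.integer(lab), nrow(bin), ncol(bin))
  nlab <- max(lab)
  if (nlab == 0L) return(list())
  n <- nrow(lab); m <- ncol(lab)
  out <- list()
  for (l in seq_len(nlab)) {
    comp <- lab == l
    area <- sum(comp)
    if (area < params$area_min_px || area > params$area_max_px) next
    bb <- .bbox2d(comp)
    if (bb[1] == 1L || bb[2] == n || bb[3] == 1L || bb[4] == m) next  # border
    out[[length(out) + 1L]] <- list(
      label = l,
      mask = comp[bb[1]:bb[2], bb[3]:bb[4], drop = FALSE],
      bbox = bb,
      area_px = area)
  }
  out
}

#' Extract a background-cleared multi-channel 3D crop for one candidate
#'
#' The candidate's bounding box is padded by `bbox_pad_px` (clipped at the
#' image border, flagged when clipped) and cropped across all z and
#' channels. Voxels outside the convex hull of the candidate mask dilated
#' `clear_dilations` times with a 3x3 cross -- an approximate whole-cell
#' region -- are zeroed in every channel. The DAPI channel is additionally
#' re-cleared: median filter on its max-z projection, Otsu, hole filling,
#' then zeroing DAPI outside that 2D mask at every z.
#'
#' @param stack An [image_stack()] (DAPI range-normalized upstream).
#' @param candidate One element of [segment_nuclei_2d()]'s output.
#' @param params [segmentation_params()].
#' @param nucleus_id Identifier attached to the record.
#' @return A `nucleus_record` list: `nucleus_id`, sample metadata, `mask2d`
#'   (candidate mask in crop coordinates), `dapi_mask2d` (the re-clearing
#'   mask), `crop` (4-D channel, z, y, x), `bbox_crop`, `border_clipped`,
#'   and placeholders for the 3D stage (`mask3d`, `qc_pass`, `qc_reason`).
#' @export
extract_nucleus_crop <- function(stack, candidate,
                                 params = segmentation_params(),
                                 nucleus_id = NA_character_) {
  d <- dim(stack$voxels)
  ny <- d[3]; nx <- d[4]
  bb <- candidate$bbox
  pad <- params$bbox_pad_px
  y0 <- max(1L, bb[1] - pad); y1 <- min(ny, bb[2] + pad)
  x0 <- max(1L, bb[3] - pad); x1 <- min(nx, bb[4] + pad)
  clipped <- (bb[1] - pad < 1L) || (bb[2] + pad > ny) ||
    (bb[3] - pad < 1L) || (bb[4] + pad > nx)
  crop <- stack$voxels[, , y0:y1, x0:x1, drop = FALSE]
  .assert(length(crop) > 0, "empty crop")
  cy <- y1 - y0 + 1L; cx <- x1 - x0 + 1L
  # candidate mask placed in crop coordinates
  mask2d <- matrix(FALSE, cy, cx)
  mask2d[(bb[1] - y0 + 1L):(bb[2] - y0 + 1L),
         (bb[3] - x0 + 1L):(bb[4] - x0 + 1L)] <- candidate$mask
  # whole-cell clearing region: convex hull of the 12x cross-dilated mask
  cell_region <- .convex_hull_mask(.dilate_cross2d(mask2d, params$clear_dilations))
  keep <- array(rep(cell_region, each = d[1] * d[2]), c(d[1], d[2], cy, cx))
  crop <- crop * keep
  # DAPI-specific re-clearing
  dch <- .dapi_channel(stack$spec)
  dapi <- array(crop[dch, , , ], c(d[2], cy, cx))
  proj <- median_denoise(max_z_project(dapi))
  thr <- tryCatch(otsu_threshold(proj), error = function(e) NULL)
  if (is.null(thr)) {
    dmask <- mask2d
  } else {
    bin <- proj > thr
    filled <- EBImage::fillHull(matrix(as.numeric(bin), cy, cx))
    dmask <- matrix(filled > 0.5, cy, cx)
  }
  for (z in seq_len(d[2])) {
    pl <- matrix(crop[dch, z, , ], cy, cx)
    pl[!dmask] <- 0
    crop[dch, z, , ] <- pl
  }
  structure(list(nucleus_id = as.character(nucleus_id),
                 sample_id = stack$sample_id, patient_id = stack$patient_id,
                 condition = stack$condition, timepoint = stack$timepoint,
                 spec = stack$spec,
                 mask2d = mask2d, dapi_mask2d = dmask,
                 crop = crop,
                 bbox_crop = c(y0, y1, x0, x1),
                 border_clipped = clipped,
                 mask3d = NULL, qc_pass = NA, qc_reason = NA_character_),
            class = "nucleus_record")
}

#' @export
print.nucleus_record <- function(x, ...) {
  d <- dim(x$crop)
  cat(sprintf("nucleus_record %s (%s): crop %d ch x %d z x %d x %d px\n",
              x$nucleus_id, x$sample_id, d[1], d[2], d[3], d[4]))
  if (!is.null(x$mask3d)) {
    cat(sprintf("mask3d: %d voxels; qc_pass: %s%s\n", sum(x$mask3d),
                x$qc_pass,
                if (!is.na(x$qc_reason)) paste0(" (", x$qc_reason, ")") else ""))
  }
  invisible(x)
}

#' Refine a nucleus crop into a QC'd 3D mask
#'
#' Runs Chan-Vese on the (range-normalized) background-cleared DAPI crop,
#' keeps the largest connected component, and applies the quality filters:
#' at least `min_voxels` voxels and a z-height (occupied planes times the
#' axial step) within `[height_min_um, height_max_um]`. Failing records get
#' `qc_pass = FALSE` and a rejection reason (`"no object"`, `"size"` or
#' `"height"`).
#'
#' @param record A `nucleus_record` from [extract_nucleus_crop()].
#' @param params [segmentation_params()].
#' @return The record with `mask3d`, `volume_voxels`, `height_um`,
#'   `qc_pass` and `qc_reason` filled in.
#' @export
segment_nucleus_3d <- function(record, params = segmentation_params()) {
  d <- dim(record$crop)
  dch <- .dapi_channel(record$spec)
  dapi <- range_normalize(array(record$crop[dch, , , ], d[2:4]))
  cv <- chan_vese_3d(dapi, lambda1 = params$chanvese_lambda1,
                     lambda2 = params$chanvese_lambda2,
                     max_iter = params$chanvese_max_iter)
  # orient: the nucleus is the brighter phase
  if (sum(cv) > 0 && sum(cv) < length(cv) &&
      mean(dapi[cv]) < mean(dapi[!cv])) cv <- !cv
  lab <- .label3d(cv)
  if (max(lab) == 0L) {
    record$mask3d <- cv & FALSE
    record$qc_pass <- FALSE
    record$qc_reason <- "no object"
    return(record)
  }
  sizes <- tabulate(lab[lab > 0L])
  mask <- lab == which.max(sizes)
  record$mask3d <- mask
  record$volume_voxels <- sum(mask)
  z_occ <- sum(apply(mask, 1, any))
  record$height_um <- z_occ * record$spec$dz_um
  if (record$volume_voxels < params$min_voxels) {
    record$qc_pass <- FALSE; record$qc_reason <- "size"
  } else if (record$height_um < params$height_min_um ||
             record$height_um > params$height_max_um) {
    record$qc_pass <- FALSE; record$qc_reason <- "height"
  } else {
    record$qc_pass <- TRUE; record$qc_reason <- NA_character_
  }
  record
}

#' Expand a nuclear mask into an approximate cell mask
#'
#' Anisotropic box dilation: `cell_pad_xy_px` pixels laterally and
#' `cell_pad_z_px` planes axially, clipped to the crop bounds. Exploits the
#' approximately ball-like shape of PBMCs; the nuclear mask is always
#' contained in the result.
#'
#' @param mask3d Logical 3-D array (z, y, x).
#' @param params [segmentation_params()].
#' @return Logical 3-D array of the same shape.
#' @export
expand_cell_mask <- function(mask3d, params = segmentation_params()) {
  .assert(is.array(mask3d) && length(dim(mask3d)) == 3 && is.logical(mask3d),
          "mask3d must be a logical 3-D array")
  .dilate_box3d(mask3d, params$cell_pad_xy_px, params$cell_pad_z_px)
}

#' Run the full segmentation stage on one stack
#'
#' Convenience wrapper: 2D candidates, crop extraction and 3D refinement
#' for every candidate in a stack.
#'
#' @param stack An [image_stack()] with the DAPI channel range-normalized.
#' @param params [segmentation_params()].
#' @return List of `nucleus_record`s (QC-passing and failing alike).
#' @export
segment_stack <- function(stack, params = segmentation_params()) {
  dch <- .dapi_channel(stack$spec)
  d <- dim(stack$voxels)
  dapi <- array(stack$voxels[dch, , , ], d[2:4])
  cands <- segment_nuclei_2d(dapi, params)
  out <- vector("list", length(cands))
  for (i in seq_along(cands)) {
    rec <- extract_nucleus_crop(stack, cands[[i]], params,
                                nucleus_id = sprintf("%s_n%02d",
                                                     stack$sample_id, i))
    out[[i]] <- segment_nucleus_3d(rec, params)
  }
  out
}
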