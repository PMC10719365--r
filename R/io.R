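#' Acquisition geometry and channel map
#'
#' Describes the voxel geometry of a confocal acquisition and the mapping
#' from marker names to channel indices. The defaults correspond to the
#' acquisition settings the pipeline was designed for: 0.09 um lateral
#' pixel size and 0.5 um axial step.
#'
#' @param dx_um,dy_um Lateral pixel size in micrometres.
#' @param dz_um Axial (z) step in micrometres.
#' @param channels Named integer vector mapping marker names to channel
#'   indices (1-based). A DAPI channel (name matching "dapi", case
#'   insensitive) must be present.
#' @return An object of class `acquisition_spec`.
#' @examples
#' spec <- acquisition_spec(channels = c(DAPI = 1, gH2AX = 2, LaminAC = 3))
#' @export
acquisition_spec <- function(dx_um = 0.09, dy_um = 0.09, dz_um = 0.5,
                             channels = c(DAPI = 1)) {
  .assert(is.numeric(dx_um) && dx_um > 0, "dx_um must be > 0")
  .assert(is.numeric(dy_um) && dy_um > 0, "dy_um must be > 0")
  .assert(is.numeric(dz_um) && dz_um > 0, "dz_um must be > 0")
  .assert(length(channels) >= 1 && !is.null(names(channels)) &&
            all(nzchar(names(channels))), "channels must be a named vector")
  .assert(!anyDuplicated(names(channels)), "channel names must be unique")
  .assert(any(grepl("^dapi$", names(channels), ignore.case = TRUE)),
          "a DAPI channel must be present")
  channels <- stats::setNames(as.integer(channels), names(channels))
  structure(list(dx_um = dx_um, dy_um = dy_um, dz_um = dz_um,
                 channels = channels),
            class = "acquisition_spec")
}

#' @export
print.acquisition_spec <- function(x, ...) {
  cat(sprintf("acquisition_spec: %g x %g um (xy), %g um (z)\n",
              x$dx_um, x$dy_um, x$dz_um))
  cat("channels:", paste(sprintf("%s=%d", names(x$channels), x$channels),
                         collapse = ", "), "\n")
  invisible(x)
}

.dapi_channel <- function(spec) {
  which(grepl("^dapi$", names(spec$channels), ignore.case = TRUE))[1]
}

#' Multi-channel 3D image stack
#'
#' Container for one acquisition: a 4-D intensity array indexed
#' (channel, z, y, x), the acquisition geometry, and sample metadata.
#'
#' @param voxels 4-D numeric array, dimensions (channel, z, y, x), finite
#'   and non-negative.
#' @param spec An [acquisition_spec()]; channel count must match.
#' @param sample_id,patient_id,condition,timepoint Sample metadata strings.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, spec, sample_id = NA_character_,
                        patient_id = NA_character_,
                        condition = NA_character_,
                        timepoint = NA_character_) {
  .assert(is.array(voxels) && length(dim(voxels)) == 4,
          "voxels must be a 4-D array (channel, z, y, x)")
  .assert(all(is.finite(voxels)), "voxel intensities must be finite")
  .assert(all(voxels >= 0), "voxel intensities must be non-negative")
  .assert(inherits(spec, "acquisition_spec"), "spec must be an acquisition_spec")
  .assert(dim(voxels)[1] == length(spec$channels),
          sprintf("channel mismatch: %d channels in array, %d in spec",
                  dim(voxels)[1], length(spec$channels)))
  structure(list(voxels = voxels, spec = spec,
                 sample_id = as.character(sample_id),
                 patient_id = as.character(patient_id),
                 condition = as.character(condition),
                 timepoint = as.character(timepoint)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_stack '%s': %d channels, %d z-planes, %d x %d px\n",
              x$sample_id, d[1], d[2], d[3], d[4]))
  cat(sprintf("patient %s | condition %s | timepoint %s\n",
              x$patient_id, x$condition, x$timepoint))
  invisible(x)
}

#' Extract one channel of a stack by marker name
#'
#' @param stack An [image_stack()].
#' @param marker Marker name as listed in the stack's channel map.
#' @return 3-D array (z, y, x).
#' @export
get_channel <- function(stack, marker) {
  ch <- stack$spec$channels[[marker]]
  .assert(!is.null(ch), sprintf("unknown marker '%s'", marker))
  d <- dim(stack$voxels)
  array(stack$voxels[ch, , , ], d[2:4])
}

#' Read a sample manifest
#'
#' The manifest is a CSV with columns `sample_id`, `patient_id`,
#' `condition`, `timepoint`, `path`, plus one column per marker giving its
#' channel index within the TIFF stack.
#'
#' @param path Path to the manifest CSV.
#' @return data.frame with one row per sample; marker columns are integer.
#' @export
read_manifest <- function(path) {
  .assert(file.exists(path), sprintf("manifest not found: %s", path))
  mf <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("sample_id", "patient_id", "condition", "timepoint", "path")
  missing <- setdiff(req, names(mf))
  .assert(length(missing) == 0,
          paste("manifest missing columns:", paste(missing, collapse = ", ")))
  markers <- setdiff(names(mf), req)
  .assert(length(markers) >= 1, "manifest must name at least one marker channel")
  .assert(any(grepl("^dapi$", markers, ignore.case = TRUE)),
          "manifest must include a DAPI channel column")
  mf
}

.spec_from_manifest_row <- function(row, dx_um = 0.09, dy_um = 0.09,
                                    dz_um = 0.5) {
  meta <- c("sample_id", "patient_id", "condition", "timepoint", "path")
  markers <- setdiff(names(row), meta)
  ch <- vapply(markers, function(m) as.integer(row[[m]]), integer(1))
  acquisition_spec(dx_um, dy_um, dz_um, channels = stats::setNames(ch, markers))
}

#' Read a multi-channel z-stack from TIFF
#'
#' Pages are interpreted channel-major: all z-planes of channel 1, then all
#' z-planes of channel 2, and so on; the number of channels is taken from
#' the manifest row. Intensities are returned as doubles in \[0, 1\]
#' (integer TIFFs are scaled by the `tiff` package on read).
#'
#' @param path Path to a multi-page TIFF.
#' @param manifest_row One row of a [read_manifest()] data.frame (list or
#'   single-row data.frame).
#' @param dx_um,dy_um,dz_um Voxel geometry, defaulting to the pipeline's
#'   acquisition settings.
#' @return An [image_stack()] with channels ordered per the manifest's
#'   channel map and metadata attached.
#' @export
read_stack <- function(path, manifest_row, dx_um = 0.09, dy_um = 0.09,
                       dz_um = 0.5) {
  if (is.data.frame(manifest_row)) manifest_row <- as.list(manifest_row[1, ])
  .assert(file.exists(path), sprintf("stack file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  .assert(all(dims[1, ] == dims[1, 1]) && all(dims[2, ] == dims[2, 1]),
          "non-uniform plane shapes in stack")
  spec <- .spec_from_manifest_row(manifest_row, dx_um, dy_um, dz_um)
  nc <- length(spec$channels)
  .assert(length(pages) %% nc == 0,
          sprintf("channel mismatch: %d pages not divisible by %d channels",
                  length(pages), nc))
  nz <- length(pages) %/% nc
  ny <- dims[1, 1]; nx <- dims[2, 1]
  vox <- array(0, c(nc, nz, ny, nx))
  # pages are stored channel-major in on-disk channel order; re-order the
  # output channels to the manifest's marker order
  .assert(all(sort(spec$channels) == seq_len(nc)),
          "manifest channel indices must be a permutation of 1..n_channels")
  for (ci in seq_len(nc)) {
    disk_block <- spec$channels[[ci]]  # on-disk channel block for marker ci
    for (z in seq_len(nz)) {
      pg <- pages[[(disk_block - 1L) * nz + z]]
      if (length(dim(pg)) == 3) pg <- pg[, , 1]
      vox[ci, z, , ] <- pg
    }
  }
  spec$channels <- stats::setNames(seq_len(nc), names(spec$channels))
  image_stack(vox, spec,
              sample_id = manifest_row$sample_id,
              patient_id = manifest_row$patient_id,
              condition = manifest_row$condition,
              timepoint = manifest_row$timepoint)
}

#' Write an image stack to a multi-page TIFF
#'
#' Pages are written channel-major (all z of channel 1, then channel 2, ...),
#' 16-bit. Intensities must lie in \[0, 1\]; values on the 16-bit grid
#' (k / 65535) round-trip exactly.
#'
#' @param stack An [image_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  v <- stack$voxels
  .assert(max(v) <= 1 + 1e-12, "write_stack expects intensities in [0, 1]")
  d <- dim(v)
  pages <- vector("list", d[1] * d[2])
  k <- 0L
  for (ci in seq_len(d[1])) {
    for (z in seq_len(d[2])) {
      k <- k + 1L
      pages[[k]] <- matrix(pmin(pmax(v[ci, z, , ], 0), 1), d[3], d[4])
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}
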