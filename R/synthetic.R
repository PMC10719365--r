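# Synthetic 3D multi-channel nucleus images and whole cohorts with known
# ground truth. The generator emulates what the analysis stages assume:
# ellipsoidal textured nuclei on a dark background, condition-dependent
# shifts of volume / heterochromatin / boundary irregularity / focus rate,
# punctate gamma-H2AX foci, a rim-weighted Lamin channel, bimodal
# per-sample CD-marker intensities, and patient-level random effects.

#' Synthetic-image specification
#'
#' Defaults describe a resting PBMC nucleus imaged at 0.09 um lateral /
#' 0.5 um axial voxels in a 150 x 150 px x 21 plane field (13.5 um
#' square): lateral semi-axes around 2.2 um, axial semi-axis around
#' 1.8 um (height about 3.6 um, inside the 2.5-10 um QC window),
#' heterochromatin blobs occupying about 25% of the nucleus, around two
#' foci per nucleus at baseline, and multiplicative patient random
#' effects of a few percent.
#'
#' @param ny,nx,nz Field size in pixels / planes.
#' @param dx_um,dz_um Voxel geometry (um).
#' @param semi_xy_um,semi_xy_sd Mean/SD of the lateral ellipsoid semi-axes.
#' @param semi_z_um,semi_z_sd Mean/SD of the axial semi-axis.
#' @param boundary_irregularity Amplitude of the angular radius modulation
#'   (dimensionless; 0 = perfect ellipse).
#' @param dapi_base In-nucleus baseline DAPI level (0-1 scale).
#' @param texture_amp,texture_sigma_px Gaussian-random-field texture
#'   amplitude and smoothing length.
#' @param hc_fraction Target heterochromatin volume fraction.
#' @param hc_amp Intensity boost of heterochromatin blobs.
#' @param foci_rate Poisson mean of the per-nucleus focus count.
#' @param foci_amp,foci_sigma_px Focus amplitude and Gaussian radius.
#' @param lamin_level,cd_neg_level,cd_pos_level Marker intensity levels.
#' @param background,noise_sd Additive background level and Gaussian noise
#'   SD.
#' @param patient_sd SD of the per-patient multiplicative log-normal
#'   random effect on geometry/HC/foci dials.
#' @param volume_effect,hc_effect,foci_effect,boundary_effect Named
#'   multiplicative condition effects (scalars applied to a "case"
#'   condition; 1 = no effect).
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(ny = 150L, nx = 150L, nz = 21L,
                           dx_um = 0.09, dz_um = 0.5,
                           semi_xy_um = 2.2, semi_xy_sd = 0.2,
                           semi_z_um = 1.8, semi_z_sd = 0.15,
                           boundary_irregularity = 0.04,
                           dapi_base = 0.45,
                           texture_amp = 0.1, texture_sigma_px = 2,
                           hc_fraction = 0.25, hc_amp = 0.3,
                           foci_rate = 2,
                           foci_amp = 0.75, foci_sigma_px = 1.3,
                           lamin_level = 0.5,
                           cd_neg_level = 0.05, cd_pos_level = 0.3,
                           background = 0.04, noise_sd = 0.02,
                           patient_sd = 0.05,
                           volume_effect = 1, hc_effect = 1,
                           foci_effect = 1, boundary_effect = 1) {
  .assert(all(c(semi_xy_sd, semi_z_sd, noise_sd, patient_sd) >= 0),
          "SDs must be >= 0")
  .assert(hc_fraction >= 0 && hc_fraction <= 1, "hc_fraction must be in [0,1]")
  .assert(all(c(volume_effect, hc_effect, foci_effect, boundary_effect) > 0),
          "effect sizes must be > 0")
  structure(as.list(environment()), class = "synthetic_spec")
}

# separable 3D Gaussian smoothing (small kernel), used for the texture field
.smooth3d <- function(x, sigma) {
  r <- max(1L, ceiling(2 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  d <- dim(x)
  conv_along <- function(a, dim_idx) {
    out <- array(0, dim(a))
    for (s in -r:r) {
      sh <- c(0L, 0L, 0L)
      sh[dim_idx] <- s
      w <- k[s + r + 1L]
      src <- a
      # shift with edge replication
      idx <- lapply(seq_len(3), function(j) {
        i <- seq_len(d[j]) - sh[j]
        pmin(pmax(i, 1L), d[j])
      })
      out <- out + w * src[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    }
    out
  }
  conv_along(conv_along(conv_along(x, 1L), 2L), 3L)
}

#' Render one synthetic nucleus image
#'
#' Voxelizes an anisotropic ellipsoid with an angularly modulated lateral
#' radius, fills it with a smooth random DAPI texture plus discrete
#' heterochromatin blobs, plants Poisson-many Gaussian foci in the
#' gamma-H2AX channel, renders a rim-weighted Lamin channel and uniform
#' CD3/CD4/CD8 levels set by the cell's subset, then adds background and
#' Gaussian noise. Ground truth (mask, volume, HC fraction, focus count
#' and positions, subset) is recorded before noise.
#'
#' @param spec [synthetic_spec()].
#' @param seed Integer seed; same seed, same image.
#' @param condition Condition label; `apply_effects = TRUE` applies the
#'   spec's multiplicative effects to this nucleus.
#' @param apply_effects Whether the spec's condition effects apply.
#' @param subset Cell subset for the CD channels (one of `"CD4+CD8-"`,
#'   `"CD4-CD8+"`, `"CD4+CD8+"`, `"CD4-CD8-"`).
#' @param cd3_positive Logical, CD3 status.
#' @param patient_factor Multiplicative patient random effect (default 1).
#' @param sample_id,patient_id,timepoint Metadata attached to the stack.
#' @return List: `stack` (an [image_stack()] with channels DAPI, gH2AX,
#'   LaminAC, CD3, CD4, CD8) and `truth` (mask, volume_um3, hc_fraction,
#'   foci_count, foci_centers, subset, cd3_positive).
#' @export
generate_nucleus_image <- function(spec = synthetic_spec(), seed = 1L,
                                   condition = "control",
                                   apply_effects = FALSE,
                                   subset = "CD4+CD8-", cd3_positive = TRUE,
                                   patient_factor = 1,
                                   sample_id = "synthetic",
                                   patient_id = "p1",
                                   timepoint = NA_character_) {
  set.seed(seed)
  ny <- spec$ny; nx <- spec$nx; nz <- spec$nz
  dx <- spec$dx_um; dz <- spec$dz_um
  vol_f <- if (apply_effects) spec$volume_effect else 1
  hc_f <- if (apply_effects) spec$hc_effect else 1
  foci_f <- if (apply_effects) spec$foci_effect else 1
  bnd_f <- if (apply_effects) spec$boundary_effect else 1
  ax <- max(0.8, stats::rnorm(1, spec$semi_xy_um, spec$semi_xy_sd)) *
    patient_factor * vol_f^(1 / 3)
  ay <- max(0.8, stats::rnorm(1, spec$semi_xy_um, spec$semi_xy_sd)) *
    patient_factor * vol_f^(1 / 3)
  az <- max(1.3, stats::rnorm(1, spec$semi_z_um, spec$semi_z_sd)) *
    patient_factor * vol_f^(1 / 3)
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2; cz <- (nz + 1) / 2
  # physical coordinates of every voxel relative to the center
  zz <- (seq_len(nz) - cz) * dz
  yy <- (seq_len(ny) - cy) * dx
  xx <- (seq_len(nx) - cx) * dx
  Z <- array(rep(zz, ny * nx), c(nz, ny, nx))
  Y <- array(rep(rep(yy, each = nz), nx), c(nz, ny, nx))
  X <- array(rep(xx, each = nz * ny), c(nz, ny, nx))
  # angular modulation of the lateral radius (boundary irregularity)
  irr <- spec$boundary_irregularity * bnd_f
  nmodes <- 3L
  amps <- stats::rnorm(nmodes, 0, irr)
  phis <- stats::runif(nmodes, 0, 2 * pi)
  theta <- atan2(Y, X)
  mod <- 1
  for (k in seq_len(nmodes)) mod <- mod + amps[k] * cos((k + 1) * theta + phis[k])
  r2 <- (X / (ax * mod))^2 + (Y / (ay * mod))^2 + (Z / az)^2
  mask <- r2 <= 1
  .assert(any(mask), "geometry produced an empty mask")
  .assert(!any(mask[1, , ]) && !any(mask[nz, , ]) &&
            !any(mask[, 1, ]) && !any(mask[, ny, ]) &&
            !any(mask[, , 1]) && !any(mask[, , nx]),
          "geometry exceeds the field of view")
  # DAPI: base + smooth texture + HC blobs
  dapi <- array(0, c(nz, ny, nx))
  if (spec$texture_amp > 0) {
    grf <- .smooth3d(array(stats::rnorm(nz * ny * nx), c(nz, ny, nx)),
                     spec$texture_sigma_px)
    grf <- grf / max(stats::sd(grf), 1e-9) * spec$texture_amp
  } else grf <- 0
  dapi[mask] <- spec$dapi_base
  dapi <- dapi + mask * grf
  hc_target <- min(0.9, spec$hc_fraction * hc_f * patient_factor^0)
  hc_mask <- array(FALSE, dim(mask))
  if (hc_target > 0) {
    n_in <- sum(mask)
    n_seeds <- max(3L, round(n_in * hc_target / 60))
    in_idx <- which(mask)
    seeds <- sample(in_idx, n_seeds)
    hc_mask[seeds] <- TRUE
    while (sum(hc_mask & mask) < hc_target * n_in) {
      hc_mask <- .dilate_box3d(hc_mask, 1L, 0L) |
        (.dilate_box3d(hc_mask, 0L, 1L) & stats::runif(length(hc_mask)) < 0.3)
      hc_mask <- hc_mask & mask
      if (all(hc_mask == mask)) break
    }
    dapi[hc_mask] <- dapi[hc_mask] + spec$hc_amp
  }
  # gamma-H2AX: dim nucleoplasmic signal + planted foci
  gh2ax <- array(0, c(nz, ny, nx))
  gh2ax[mask] <- 0.1
  n_foci <- stats::rpois(1, spec$foci_rate * foci_f)
  foci_centers <- NULL
  if (n_foci > 0) {
    # centers in the mid-plane region of the mask, min separation 6 px
    mid <- which(mask[round(cz), , ], arr.ind = TRUE)
    placed <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(placed) < n_foci && tries < 500L) {
      tries <- tries + 1L
      cand <- mid[sample(nrow(mid), 1), ]
      if (nrow(placed) == 0 ||
          min(sqrt((placed[, 1] - cand[1])^2 + (placed[, 2] - cand[2])^2)) >= 6) {
        placed <- rbind(placed, cand)
      }
    }
    n_foci <- nrow(placed)
    foci_centers <- placed
    for (i in seq_len(n_foci)) {
      fy <- placed[i, 1]; fx <- placed[i, 2]
      dy2 <- outer((seq_len(ny) - fy)^2, (seq_len(nx) - fx)^2, `+`)
      bump <- spec$foci_amp * exp(-dy2 / (2 * spec$foci_sigma_px^2))
      zrange <- max(1, round(cz) - 1):min(nz, round(cz) + 1)
      for (z in zrange) gh2ax[z, , ] <- gh2ax[z, , ] + bump
    }
    gh2ax <- gh2ax * mask
  }
  # Lamin A/C: rim-weighted (mask minus its lateral erosion)
  eroded <- !.dilate_box3d(!mask, 2L, 0L)
  rim <- mask & !eroded
  lamin <- array(0, c(nz, ny, nx))
  lamin[rim] <- spec$lamin_level
  lamin[eroded] <- spec$lamin_level * 0.15
  # CD channels: uniform within the cell region at subset-specific levels
  cell <- .dilate_box3d(mask, 6L, 1L)
  lv <- function(pos) if (pos) spec$cd_pos_level else spec$cd_neg_level
  cd4_pos <- grepl("CD4\\+", subset)
  cd8_pos <- grepl("CD8\\+", subset)
  cd3 <- array(0, c(nz, ny, nx)); cd3[cell] <- lv(cd3_positive)
  cd4 <- array(0, c(nz, ny, nx)); cd4[cell] <- lv(cd4_pos)
  cd8 <- array(0, c(nz, ny, nx)); cd8[cell] <- lv(cd8_pos)
  truth <- list(mask = mask,
                volume_um3 = sum(mask) * dx * dx * dz,
                hc_fraction = sum(hc_mask & mask) / sum(mask),
                foci_count = n_foci,
                foci_centers = foci_centers,
                subset = subset, cd3_positive = cd3_positive,
                semi_axes_um = c(ax, ay, az))
  add_noise <- function(ch) {
    ch <- ch + spec$background
    if (spec$noise_sd > 0) ch <- ch + stats::rnorm(length(ch), 0, spec$noise_sd)
    array(pmin(pmax(ch, 0), 1), dim(ch))
  }
  vox <- array(0, c(6, nz, ny, nx))
  vox[1, , , ] <- add_noise(dapi)
  vox[2, , , ] <- add_noise(gh2ax)
  vox[3, , , ] <- add_noise(lamin)
  vox[4, , , ] <- add_noise(cd3)
  vox[5, , , ] <- add_noise(cd4)
  vox[6, , , ] <- add_noise(cd8)
  aspec <- acquisition_spec(dx, dx, dz,
                            channels = c(DAPI = 1, gH2AX = 2, LaminAC = 3,
                                         CD3 = 4, CD4 = 5, CD8 = 6))
  stack <- image_stack(vox, aspec, sample_id = sample_id,
                       patient_id = patient_id, condition = condition,
                       timepoint = timepoint)
  list(stack = stack, truth = truth)
}

#' Generate a synthetic imaging cohort
#'
#' Hierarchical sampling: per-patient multiplicative random effects, then
#' per-cell geometry/texture; condition effects are applied to every
#' non-first condition (the first condition listed is the reference).
#' Subset labels are drawn from `subset_probs`. When `dir` is given, each
#' cell's stack is written as a 16-bit multi-page TIFF and a manifest CSV
#' is emitted alongside the ground-truth table.
#'
#' @param spec [synthetic_spec()].
#' @param n_patients_per_condition,cells_per_patient Cohort design.
#' @param conditions Condition labels (first = reference, no effects).
#' @param timepoints Optional time point labels; each patient then gets
#'   `cells_per_patient` cells per time point.
#' @param subset_probs Probabilities of the four CD4/CD8 subsets.
#' @param p_cd3 Probability of CD3 positivity.
#' @param seed Integer seed.
#' @param dir Optional output directory for TIFFs + manifest.
#' @return List: `stacks` (list of per-cell results, `NULL` when `dir` is
#'   used), `truth` (data.frame), `manifest` (data.frame; paths filled
#'   when written).
#' @export
generate_cohort <- function(spec = synthetic_spec(),
                            n_patients_per_condition = 2L,
                            cells_per_patient = 3L,
                            conditions = c("control", "tumor"),
                            timepoints = NULL,
                            subset_probs = c(0.45, 0.25, 0.05, 0.25),
                            p_cd3 = 0.7, seed = 1L, dir = NULL) {
  .assert(n_patients_per_condition >= 1 && cells_per_patient >= 1,
          "need at least one patient and one cell")
  subsets <- c("CD4+CD8-", "CD4-CD8+", "CD4+CD8+", "CD4-CD8-")
  tps <- if (is.null(timepoints)) NA_character_ else timepoints
  stacks <- list()
  truth_rows <- list()
  manifest_rows <- list()
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cell_seed <- seed * 10000L
  pnum <- 0L
  for (cond_i in seq_along(conditions)) {
    cond <- conditions[cond_i]
    for (p in seq_len(n_patients_per_condition)) {
      pnum <- pnum + 1L
      pid <- sprintf("P%02d", pnum)
      set.seed(seed * 100L + pnum)
      pf <- exp(stats::rnorm(1, 0, spec$patient_sd))
      for (tp in tps) {
        sid <- if (is.na(tp)) pid else paste0(pid, "_", tp)
        for (ci in seq_len(cells_per_patient)) {
          cell_seed <- cell_seed + 1L
          set.seed(cell_seed)
          subset <- sample(subsets, 1, prob = subset_probs)
          cd3p <- stats::runif(1) < p_cd3
          res <- generate_nucleus_image(
            spec, seed = cell_seed, condition = cond,
            apply_effects = cond_i > 1, subset = subset,
            cd3_positive = cd3p, patient_factor = pf,
            sample_id = sprintf("%s_c%03d", sid, ci), patient_id = pid,
            timepoint = tp)
          path <- NA_character_
          if (!is.null(dir)) {
            path <- file.path(dir, paste0(res$stack$sample_id, ".tif"))
            write_stack(res$stack, path)
          } else {
            stacks[[length(stacks) + 1L]] <- res
          }
          truth_rows[[length(truth_rows) + 1L]] <- data.frame(
            sample_id = res$stack$sample_id, patient_id = pid,
            condition = cond, timepoint = tp,
            volume_um3 = res$truth$volume_um3,
            hc_fraction = res$truth$hc_fraction,
            foci_count = res$truth$foci_count,
            subset = subset, cd3_positive = cd3p,
            stringsAsFactors = FALSE)
          manifest_rows[[length(manifest_rows) + 1L]] <- data.frame(
            sample_id = res$stack$sample_id, patient_id = pid,
            condition = cond, timepoint = tp, path = path,
            DAPI = 1L, gH2AX = 2L, LaminAC = 3L, CD3 = 4L, CD4 = 5L,
            CD8 = 6L, stringsAsFactors = FALSE)
        }
      }
    }
  }
  truth <- do.call(rbind, truth_rows)
  manifest <- do.call(rbind, manifest_rows)
  if (!is.null(dir)) {
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  list(stacks = if (is.null(dir)) stacks else NULL,
       truth = truth, manifest = manifest)
}

#' Simulate a chrometric feature cohort directly
#'
#' Draws a cell-by-feature table from the hierarchical statistical model
#' the imaging cohort induces -- multiplicative patient random effects,
#' multiplicative condition effects on named features, log-normal
#' cell-level variation, plus uninformative noise features -- without
#' rendering images. This is the workhorse for calibrating and testing
#' the analysis layer at cohort sizes where rendering every nucleus would
#' be disproportionate; the image generator above remains the ground
#' truth for the extraction stages.
#'
#' @param n_patients_per_condition,cells_per_patient Cohort design.
#' @param conditions Condition labels (first = reference).
#' @param effects Named list per non-reference condition: named numeric
#'   vectors of multiplicative feature effects, e.g.
#'   `list(tumor = c(volume_um3 = 1.3, hc_volume_fraction = 1.2))`.
#' @param base_features Named vector of reference-level feature means.
#' @param cell_cv Cell-level coefficient of variation (default 0.15).
#' @param patient_sd Patient random-effect SD on the log scale (default
#'   0.05).
#' @param n_noise_features Additional pure-noise features (default 20).
#' @param timepoints Optional time point labels; condition effects are
#'   then interpreted per time point via `timepoint_effects`.
#' @param seed Integer seed.
#' @return Feature data.frame with metadata columns `sample_id`,
#'   `patient_id`, `condition`, `timepoint`.
#' @export
simulate_feature_cohort <- function(n_patients_per_condition = 5L,
                                    cells_per_patient = 60L,
                                    conditions = c("control", "tumor"),
                                    effects = list(
                                      tumor = c(volume_um3 = 1.3,
                                                hc_volume_fraction = 1.25,
                                                foci_count = 1.6)),
                                    base_features = c(volume_um3 = 90,
                                                      projected_area_um2 = 25,
                                                      hc_volume_fraction = 0.25,
                                                      foci_count = 2,
                                                      curvature_sd = 0.08,
                                                      concavity_2d = 0.03),
                                    cell_cv = 0.15, patient_sd = 0.05,
                                    n_noise_features = 20L,
                                    timepoints = NULL, seed = 1L) {
  set.seed(seed)
  rows <- list()
  pnum <- 0L
  tps <- if (is.null(timepoints)) NA_character_ else timepoints
  for (cond_i in seq_along(conditions)) {
    cond <- conditions[cond_i]
    eff <- rep(1, length(base_features))
    names(eff) <- names(base_features)
    if (cond_i > 1 && cond %in% names(effects)) {
      e <- effects[[cond]]
      eff[names(e)] <- e
    }
    for (p in seq_len(n_patients_per_condition)) {
      pnum <- pnum + 1L
      pid <- sprintf("P%02d", pnum)
      pf <- exp(stats::rnorm(length(base_features), 0, patient_sd))
      for (tp in tps) {
        n <- cells_per_patient
        feat_mat <- sapply(seq_along(base_features), function(j) {
          mu <- base_features[j] * eff[j] * pf[j]
          mu * exp(stats::rnorm(n, 0, cell_cv))
        })
        colnames(feat_mat) <- names(base_features)
        noise <- matrix(stats::rnorm(n * n_noise_features), n,
                        n_noise_features,
                        dimnames = list(NULL, sprintf("feat_noise_%02d",
                                                      seq_len(n_noise_features))))
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = if (is.na(tp)) pid else paste0(pid, "_", tp),
          patient_id = pid, condition = cond, timepoint = tp,
          feat_mat, noise, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
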