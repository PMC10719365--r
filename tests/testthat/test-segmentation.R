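# 2D candidate image builder: discs of chosen radii on a dark background,
# rendered into a 3-plane stack so the 2D pipeline has something to project
disc_stack <- function(ny, nx, centers, radii, level = 0.9) {
  img <- matrix(0.05, ny, nx)
  for (i in seq_along(radii)) {
    img[disc_mask(ny, nx, centers[[i]][1], centers[[i]][2], radii[i])] <- level
  }
  array(rep(img, each = 3), c(3, ny, nx))
}

test_that("2D candidates honor the area band and border exclusion", {
  p <- segmentation_params()
  # blank image: no nuclei
  expect_length(segment_nuclei_2d(array(0.2, c(3, 120, 120)), p), 0)
  # 500 px disc (r~12.6) rejected, 1000 px disc (r~17.8) kept
  dapi <- disc_stack(200, 200, list(c(50, 50), c(140, 140)), c(12.6, 17.8))
  cands <- segment_nuclei_2d(dapi, p)
  expect_length(cands, 1)
  expect_gte(cands[[1]]$area_px, 800)
  expect_lte(cands[[1]]$area_px, 5000)
  # a 6000-px blob (r~43.7) exceeds the cap (the touching-nuclei filter)
  dapi <- disc_stack(200, 200, list(c(100, 100)), 43.7)
  expect_length(segment_nuclei_2d(dapi, p), 0)
  # a disc overlapping the image edge is excluded
  dapi <- disc_stack(200, 200, list(c(10, 100)), 17.8)
  expect_length(segment_nuclei_2d(dapi, p), 0)
  # candidates are pairwise disjoint
  dapi <- disc_stack(200, 200, list(c(60, 60), c(140, 140)), c(17.8, 20))
  cands <- segment_nuclei_2d(dapi, p)
  expect_length(cands, 2)
  full <- matrix(0L, 200, 200)
  for (cc in cands) {
    sub <- full[cc$bbox[1]:cc$bbox[2], cc$bbox[3]:cc$bbox[4]]
    expect_true(all(sub[cc$mask] == 0L))   # no overlap with earlier masks
    sub[cc$mask] <- 1L
    full[cc$bbox[1]:cc$bbox[2], cc$bbox[3]:cc$bbox[4]] <- sub
  }
})

test_that("crop extraction pads the bbox, clears outside the hull, erases neighbors", {
  p <- segmentation_params()
  sp <- acquisition_spec(channels = c(DAPI = 1, CD3 = 2))
  # main nucleus at (100,100) r=17; faint neighbor toward the padded-bbox
  # corner: inside the crop but beyond the dilated hull's diagonal reach
  ny <- 200; nx <- 200
  img <- matrix(0.05, ny, nx)
  img[disc_mask(ny, nx, 100, 100, 17)] <- 0.9
  neighbor <- disc_mask(ny, nx, 76, 124, 5)
  img2 <- img; img2[neighbor] <- 0.8
  vox <- array(0, c(2, 3, ny, nx))
  for (z in 1:3) { vox[1, z, , ] <- img2; vox[2, z, , ] <- img2 }
  stack <- image_stack(vox, sp, sample_id = "s")
  cands <- segment_nuclei_2d(array(vox[1, , , ], c(3, ny, nx)), p)
  expect_length(cands, 1)   # neighbor itself is below the area floor
  rec <- extract_nucleus_crop(stack, cands[[1]], p)
  # crop width = bbox width + 2 * pad (away from borders)
  bb <- cands[[1]]$bbox
  expect_equal(dim(rec$crop)[3], (bb[2] - bb[1] + 1) + 2 * p$bbox_pad_px)
  expect_equal(dim(rec$crop)[4], (bb[4] - bb[3] + 1) + 2 * p$bbox_pad_px)
  expect_false(rec$border_clipped)
  # all voxels outside the cleared cell region are exactly 0 in all channels
  cell <- chromscope:::.convex_hull_mask(
    chromscope:::.dilate_cross2d(rec$mask2d, p$clear_dilations))
  for (ch in 1:2) {
    for (z in 1:3) {
      pl <- matrix(rec$crop[ch, z, , ], dim(rec$crop)[3], dim(rec$crop)[4])
      expect_true(all(pl[!cell] == 0))
    }
  }
  # the neighbor disc fell inside the padded bbox: verify it was erased
  # from the non-DAPI channel wherever it lies outside the hull
  y0 <- rec$bbox_crop[1]; x0 <- rec$bbox_crop[3]
  nb_crop <- neighbor[y0:rec$bbox_crop[2], x0:rec$bbox_crop[4]]
  expect_true(any(nb_crop))                     # it is inside the crop
  outside <- nb_crop & !cell
  expect_true(any(outside))
  pl <- matrix(rec$crop[2, 1, , ], nrow(nb_crop), ncol(nb_crop))
  expect_true(all(pl[outside] == 0))
})

test_that("Chan-Vese recovers a planted ellipsoid and QC filters fire", {
  # planted solid ellipsoid, semi-axes 22 x 22 x 4 voxels
  truth <- ellipsoid_mask(15, 80, 80, 4, 22, 22)
  set.seed(41)
  vol <- array(0.1, dim(truth)) + truth * 0.7 +
    array(rnorm(length(truth), 0, 0.03), dim(truth))
  vol <- pmin(pmax(vol, 0), 1)
  cv <- chan_vese_3d(vol)
  lab <- chromscope:::.label3d(cv)
  mask <- lab == which.max(tabulate(lab[lab > 0]))
  jac <- sum(mask & truth) / sum(mask | truth)
  expect_gt(jac, 0.8)
})

test_that("3D QC rejects small and flat objects with the stated reasons", {
  p <- segmentation_params()
  sp <- acquisition_spec(channels = c(DAPI = 1))
  make_rec <- function(mask) {
    crop <- array(0, c(1, dim(mask)))
    crop[1, , , ] <- 0.05 + 0.85 * mask
    structure(list(nucleus_id = "n", sample_id = "s", patient_id = "p",
                   condition = "c", timepoint = NA, spec = sp,
                   mask2d = max_z_project(array(as.numeric(mask),
                                                dim(mask))) > 0.5,
                   dapi_mask2d = NULL, crop = crop,
                   bbox_crop = c(1, dim(mask)[2], 1, dim(mask)[3]),
                   border_clipped = FALSE, mask3d = NULL, qc_pass = NA,
                   qc_reason = NA_character_),
              class = "nucleus_record")
  }
  # 4 occupied z-slices -> height 4 * 0.5 = 2.0 um < 2.5 um: reject "height"
  flat <- cylinder_mask(12, 60, 60, 5, 8, 20)
  rec <- segment_nucleus_3d(make_rec(flat), p)
  expect_false(rec$qc_pass)
  expect_equal(rec$qc_reason, "height")
  # ~300-voxel object: reject "size" (checked before height)
  small <- cylinder_mask(12, 40, 40, 4, 9, 4)   # 6 slices x ~49 px = 294 vox
  expect_lt(sum(small), 400)
  rec <- segment_nucleus_3d(make_rec(small), p)
  expect_false(rec$qc_pass)
  expect_equal(rec$qc_reason, "size")
  # a healthy cylinder passes and satisfies the bounds by construction
  good <- cylinder_mask(14, 70, 70, 4, 10, 22)  # 7 slices -> 3.5 um
  rec <- segment_nucleus_3d(make_rec(good), p)
  expect_true(rec$qc_pass)
  expect_gte(rec$volume_voxels, 400)
  expect_gte(rec$height_um, 2.5)
  expect_lte(rec$height_um, 10)
})

test_that("cell-mask expansion matches its stated extent and a brute-force oracle", {
  p <- segmentation_params()
  # single voxel grows to a 25 x 25 x 5 box
  m <- array(FALSE, c(9, 31, 31)); m[5, 16, 16] <- TRUE
  cell <- expand_cell_mask(m, p)
  expect_equal(sum(cell), 25 * 25 * 5)
  idx <- which(cell, arr.ind = TRUE)
  expect_equal(range(idx[, 1]), c(3, 7))
  expect_equal(range(idx[, 2]), c(4, 28))
  expect_equal(range(idx[, 3]), c(4, 28))
  # nuclear mask always contained
  set.seed(42)
  m <- array(runif(20^3) < 0.05, c(20, 20, 20))
  cell <- expand_cell_mask(m, p)
  expect_true(all(cell[m]))
  # brute-force dilation oracle with small pads
  small_p <- segmentation_params(cell_pad_xy_px = 2, cell_pad_z_px = 1)
  cell <- expand_cell_mask(m, small_p)
  brute <- array(FALSE, dim(m))
  idx <- which(m, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    z <- idx[k, 1]; y <- idx[k, 2]; x <- idx[k, 3]
    brute[max(1, z - 1):min(20, z + 1),
          max(1, y - 2):min(20, y + 2),
          max(1, x - 2):min(20, x + 2)] <- TRUE
  }
  expect_equal(cell, brute)
})
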