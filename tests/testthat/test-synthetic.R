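test_that("the noise-free generator renders the analytic ellipsoid exactly", {
  spec <- synthetic_spec(noise_sd = 0, texture_amp = 0, hc_fraction = 0,
                         boundary_irregularity = 0, foci_rate = 0,
                         background = 0, semi_xy_sd = 0, semi_z_sd = 0)
  res <- generate_nucleus_image(spec, seed = 1)
  # rendered DAPI support equals the recorded truth mask exactly
  dapi <- get_channel(res$stack, "DAPI")
  expect_identical(dapi > 0, res$truth$mask)
  # and the truth mask is the analytic voxelization of the ellipsoid
  ax <- res$truth$semi_axes_um
  analytic <- ellipsoid_mask(21, 150, 150,
                             ax[3] / 0.5, ax[2] / 0.09, ax[1] / 0.09)
  expect_identical(res$truth$mask, analytic)
})

test_that("generation is reproducible under seed", {
  a <- generate_nucleus_image(seed = 33)
  b <- generate_nucleus_image(seed = 33)
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$truth$foci_count, b$truth$foci_count)
  c <- generate_nucleus_image(seed = 34)
  expect_false(identical(a$stack$voxels, c$stack$voxels))
})

test_that("planted foci are recovered end-to-end by the focus counter", {
  # well-separated planted foci (generator enforces 6 px separation; use a
  # low rate so crowding is unlikely), recovered through segmentation
  hits <- 0; total <- 0
  for (s in 1:4) {
    res <- generate_nucleus_image(synthetic_spec(foci_rate = 3), seed = 100 + s)
    stack <- res$stack
    d <- dim(stack$voxels)
    stack$voxels[1, , , ] <- range_normalize(array(stack$voxels[1, , , ],
                                                   d[2:4]))
    recs <- segment_stack(stack)
    expect_length(recs, 1)
    g <- array(recs[[1]]$crop[2, , , ], dim(recs[[1]]$mask3d))
    fs <- detect_foci(g, recs[[1]]$mask3d)
    total <- total + 1
    if (fs$count == res$truth$foci_count) hits <- hits + 1
  }
  expect_gte(hits, 3)   # allow one crowding/edge miss in four nuclei
})

test_that("cohort generation emits consistent truth, manifest and images", {
  td <- tempfile("cohort")
  on.exit(unlink(td, recursive = TRUE))
  res <- generate_cohort(n_patients_per_condition = 1, cells_per_patient = 2,
                         timepoints = c("prior", "end"), seed = 9, dir = td)
  # truth rows = conditions x patients x timepoints x cells
  expect_equal(nrow(res$truth), 2 * 1 * 2 * 2)
  expect_equal(nrow(res$manifest), nrow(res$truth))
  expect_true(all(file.exists(res$manifest$path)))
  mf <- read_manifest(file.path(td, "manifest.csv"))
  st <- read_stack(mf$path[1], mf[1, ])
  expect_equal(dim(st$voxels), c(6, 21, 150, 150))
  # same seed regenerates identical truth
  td2 <- tempfile("cohort2")
  on.exit(unlink(td2, recursive = TRUE), add = TRUE)
  res2 <- generate_cohort(n_patients_per_condition = 1, cells_per_patient = 2,
                          timepoints = c("prior", "end"), seed = 9, dir = td2)
  expect_equal(res$truth$volume_um3, res2$truth$volume_um3)
})

test_that("condition effect dials shift the measured features monotonically", {
  # volume effect 1.3x: generated tumor truth volumes scale accordingly
  spec <- synthetic_spec(volume_effect = 1.3, semi_xy_sd = 0.05,
                         semi_z_sd = 0.05)
  v_ctrl <- v_tum <- numeric(6)
  for (s in 1:6) {
    v_ctrl[s] <- generate_nucleus_image(spec, seed = 200 + s,
                                        apply_effects = FALSE)$truth$volume_um3
    v_tum[s] <- generate_nucleus_image(spec, seed = 200 + s,
                                       apply_effects = TRUE)$truth$volume_um3
  }
  # same seeds, so the ratio isolates the planted multiplicative effect
  expect_equal(mean(v_tum / v_ctrl), 1.3, tolerance = 0.05)
})

test_that("the feature-cohort simulator reproduces its design and dials", {
  tab <- simulate_feature_cohort(n_patients_per_condition = 4,
                                 cells_per_patient = 50, seed = 5)
  expect_equal(nrow(tab), 2 * 4 * 50)
  expect_equal(length(unique(tab$patient_id)), 8)
  # planted volume ratio ~ 1.3 between conditions
  r <- mean(tab$volume_um3[tab$condition == "tumor"]) /
    mean(tab$volume_um3[tab$condition == "control"])
  expect_equal(r, 1.3, tolerance = 0.08)
  # zero-effect cohort: ratio ~ 1
  tab0 <- simulate_feature_cohort(n_patients_per_condition = 4,
                                  cells_per_patient = 50,
                                  effects = list(), seed = 6)
  r0 <- mean(tab0$volume_um3[tab0$condition == "tumor"]) /
    mean(tab0$volume_um3[tab0$condition == "control"])
  expect_equal(r0, 1, tolerance = 0.1)
  expect_identical(tab, simulate_feature_cohort(n_patients_per_condition = 4,
                                                cells_per_patient = 50,
                                                seed = 5))
})
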