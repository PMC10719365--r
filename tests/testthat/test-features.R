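test_that("morphology features reproduce voxel arithmetic and convexity", {
  sp <- test_spec()
  # 1000 voxels -> 1000 * 0.09 * 0.09 * 0.5 = 4.05 um^3
  m <- cylinder_mask(10, 40, 40, 3, 7, 8)
  mask2d <- max_z_project(array(as.numeric(m), dim(m))) > 0.5
  f <- morphology_features(m, mask2d, sp)
  expect_equal(unname(f["volume_um3"]), sum(m) * 0.09 * 0.09 * 0.5)
  expect_equal(unname(f["projected_area_um2"]), sum(mask2d) * 0.09 * 0.09)
  expect_equal(unname(f["height_um"]), 5 * 0.5)
  # a filled disc is convex: concavity 0
  expect_equal(unname(f["concavity_2d"]), 0)
  # crescent concavity equals a brute-force hull-ratio oracle
  cres <- disc_mask(60, 60, 30, 30, 20) & !disc_mask(60, 60, 30, 42, 14)
  m3 <- array(FALSE, c(3, 60, 60)); for (z in 1:3) m3[z, , ] <- cres
  f2 <- morphology_features(m3, cres, sp)
  # oracle: per-pixel point-in-convex-polygon test against chull vertices
  idx <- which(cres, arr.ind = TRUE)
  hull <- idx[grDevices::chull(idx[, 2], idx[, 1]), , drop = FALSE]
  in_hull <- function(py, px) {
    k <- nrow(hull); sgn <- 0
    for (i in seq_len(k)) {
      j <- if (i == k) 1 else i + 1
      cr <- (hull[j, 2] - hull[i, 2]) * (py - hull[i, 1]) -
        (hull[j, 1] - hull[i, 1]) * (px - hull[i, 2])
      if (abs(cr) < 1e-9) next
      if (sgn == 0) sgn <- sign(cr)
      else if (sign(cr) != sgn) return(FALSE)
    }
    TRUE
  }
  hull_n <- 0
  for (py in 1:60) for (px in 1:60) if (in_hull(py, px)) hull_n <- hull_n + 1
  expect_equal(unname(f2["concavity_2d"]), 1 - sum(cres) / hull_n,
               tolerance = 1e-6)
  expect_gt(unname(f2["concavity_2d"]), 0.1)
  # translation invariance of every morphology feature
  m_shift <- array(FALSE, dim(m))
  m_shift[, c(6:40, 1:5), ] <- m[, , ]   # circular shift is safe: mask interior
  f3 <- morphology_features(chromscope:::.shift3d(m, 0L, 4L, 5L),
                            chromscope:::.shift2d(mask2d, 4, 5, FALSE) > 0,
                            sp)
  expect_equal(f3, f, tolerance = 1e-10)
})

test_that("synthetic ellipsoid volume is close to the analytic value", {
  sp <- test_spec()
  # semi-axes in voxels: a = b = 2.0 um / 0.09, c = 1.5 um / 0.5
  m <- ellipsoid_mask(15, 60, 60, 1.5 / 0.5, 2 / 0.09, 2 / 0.09)
  mask2d <- max_z_project(array(as.numeric(m), dim(m))) > 0.5
  f <- morphology_features(m, mask2d, sp)
  expect_equal(unname(f["volume_um3"]), 4 / 3 * pi * 2 * 2 * 1.5,
               tolerance = 0.1)
})

test_that("boundary curvature matches circle/ellipse analytics", {
  sp <- test_spec()
  circ <- disc_mask(80, 80, 40, 40, 25)
  f <- boundary_features(circ, sp)
  # circle of radius r px: mean |kappa| = 1 / (r * dx) in 1/um
  expect_equal(unname(f["curvature_mean"]), 1 / (25 * 0.09), tolerance = 0.05)
  expect_lt(unname(f["curvature_sd"]), 0.1 * unname(f["curvature_mean"]))
  # 2:1 ellipse has strictly larger curvature spread than the circle
  ell <- outer(((1:80) - 40)^2 / 30^2, ((1:80) - 40)^2 / 15^2, `+`) <= 1
  f2 <- boundary_features(ell, sp)
  expect_gt(unname(f2["curvature_sd"]), 5 * unname(f["curvature_sd"]))
})

test_that("intensity features match direct-formula oracles", {
  m <- array(TRUE, c(4, 5, 5))
  # constant: mean c, sd 0, entropy 0
  f <- intensity_features(array(0.37, dim(m)), m)
  expect_equal(unname(f["intensity_mean"]), 0.37)
  expect_equal(unname(f["intensity_sd"]), 0)
  expect_equal(unname(f["intensity_entropy"]), 0)
  # two equiprobable values: entropy exactly 1 bit
  v <- array(rep(c(0.2, 0.8), 50), c(4, 5, 5))
  f <- intensity_features(v, m)
  expect_equal(unname(f["intensity_entropy"]), 1)
  # moments vs direct formulas on random voxels
  set.seed(51)
  x <- runif(1000)
  crop <- array(x, c(10, 10, 10)); mm <- array(TRUE, dim(crop))
  f <- intensity_features(crop, mm)
  expect_equal(unname(f["intensity_mean"]), mean(x))
  expect_equal(unname(f["intensity_sd"]), sd(x))
  expect_equal(unname(f["intensity_skewness"]),
               mean((x - mean(x))^3) / mean((x - mean(x))^2)^1.5)
  expect_equal(unname(f["intensity_kurtosis"]),
               mean((x - mean(x))^4) / mean((x - mean(x))^2)^2 - 3)
  expect_equal(unname(f["intensity_d50"]), quantile(x, 0.5, names = FALSE))
})

test_that("moment invariants survive translation and 90-degree rotation", {
  set.seed(52)
  base <- matrix(0, 64, 64)
  blob <- disc_mask(64, 64, 30, 28, 12)
  base[blob] <- 0.5 + 0.4 * runif(sum(blob))
  f <- moment_features(base, blob)
  # translation: central moments unchanged
  tr <- chromscope:::.shift2d(base, 6, -4)
  trm <- chromscope:::.shift2d(blob, 6, -4, FALSE) > 0
  expect_equal(moment_features(tr, trm), f, tolerance = 1e-9)
  # 90-degree rotation: Hu invariants unchanged
  rot <- t(base)[, nrow(base):1]
  rotm <- t(blob)[, nrow(blob):1] > 0
  fr <- moment_features(rot, rotm)
  for (h in paste0("hu", 1:7)) {
    expect_equal(unname(fr[h]), unname(f[h]), tolerance = 1e-9)
  }
  # symmetric blob: third-order central moments vanish
  sym <- matrix(0, 41, 41); d <- disc_mask(41, 41, 21, 21, 10)
  sym[d] <- 1
  fs <- moment_features(sym, d)
  expect_lt(abs(unname(fs["eta30"])), 1e-12)
  expect_lt(abs(unname(fs["eta03"])), 1e-12)
})

test_that("HC/EC partition recovers planted fractions and conserves volume", {
  sp <- test_spec()
  m <- array(TRUE, c(10, 10, 10))
  set.seed(53)
  v <- array(0.3, dim(m))
  hc_idx <- sample(1000, 300)
  v[hc_idx] <- 0.9
  f <- hc_ec_features(v, m, sp)
  expect_equal(unname(f["hc_volume_fraction"]), 0.3)
  # partition conserves volume exactly
  expect_equal(unname(f["hc_volume_um3"] + f["ec_volume_um3"]),
               sum(m) * 0.09 * 0.09 * 0.5)
  expect_equal(unname(f["hc_intensity_fraction"]),
               300 * 0.9 / (300 * 0.9 + 700 * 0.3))
  # degenerate uniform nucleus: flagged missing
  f2 <- hc_ec_features(array(0.5, dim(m)), m, sp)
  expect_true(all(is.na(f2)))
})

test_that("marker quantification is exact and linear", {
  mask <- disc_mask(30, 30, 15, 15, 5.5)
  img <- matrix(0, 30, 30)
  img[mask] <- 5
  img[!mask] <- 100     # must not contribute
  q <- quantify_marker(img, mask)
  expect_equal(unname(q["total_intensity"]), 5 * sum(mask))
  expect_equal(unname(q["area_norm_intensity"]), 5)
  q2 <- quantify_marker(img * 2, mask)
  expect_equal(unname(q2["total_intensity"]), 2 * unname(q["total_intensity"]))
  expect_error(quantify_marker(img, mask & FALSE), "empty mask")
})

test_that("assembled profiles are deterministic, complete and stable in layout", {
  res <- generate_nucleus_image(synthetic_spec(foci_rate = 3), seed = 9)
  stack <- res$stack
  d <- dim(stack$voxels)
  stack$voxels[1, , , ] <- range_normalize(array(stack$voxels[1, , , ], d[2:4]))
  recs <- segment_stack(stack)
  expect_length(recs, 1)
  p1 <- assemble_profile(recs[[1]])
  p2 <- assemble_profile(recs[[1]])
  expect_identical(p1, p2)
  # no missing values for a QC-passing nucleus
  expect_false(anyNA(p1[feature_columns(p1)]))
  # feature names covered by the dictionary (markers aside)
  dict <- feature_dictionary()
  core <- intersect(names(p1), dict$name)
  expect_gte(length(core), 40)
})
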