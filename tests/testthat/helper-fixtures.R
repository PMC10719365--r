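# Shared fixture builders: small geometric masks and images built in code.

# filled disc mask in an ny x nx matrix
disc_mask <- function(ny, nx, cy, cx, r) {
  outer((seq_len(ny) - cy)^2, (seq_len(nx) - cx)^2, `+`) <= r^2
}

# solid ellipsoid mask in a (nz, ny, nx) array, semi-axes in voxels
ellipsoid_mask <- function(nz, ny, nx, az, ay, ax,
                           cz = (nz + 1) / 2, cy = (ny + 1) / 2,
                           cx = (nx + 1) / 2) {
  zz <- (seq_len(nz) - cz) / az
  yy <- (seq_len(ny) - cy) / ay
  xx <- (seq_len(nx) - cx) / ax
  Z <- array(rep(zz, ny * nx), c(nz, ny, nx))
  Y <- array(rep(rep(yy, each = nz), nx), c(nz, ny, nx))
  X <- array(rep(xx, each = nz * ny), c(nz, ny, nx))
  Z^2 + Y^2 + X^2 <= 1
}

# a cylindrical 3D nucleus mask spanning z-slices z0:z1
cylinder_mask <- function(nz, ny, nx, z0, z1, r) {
  m <- array(FALSE, c(nz, ny, nx))
  d <- disc_mask(ny, nx, (ny + 1) / 2, (nx + 1) / 2, r)
  for (z in z0:z1) m[z, , ] <- d
  m
}

# a default acquisition spec used across tests
test_spec <- function() {
  acquisition_spec(channels = c(DAPI = 1, gH2AX = 2, LaminAC = 3,
                                CD3 = 4, CD4 = 5, CD8 = 6))
}

# a tiny feature table with planted 2-condition effects, no patient noise
tiny_cohort <- function(seed = 1, patients = 4, cells = 40, effect = 1.4) {
  simulate_feature_cohort(
    n_patients_per_condition = patients, cells_per_patient = cells,
    effects = list(tumor = c(volume_um3 = effect,
                             hc_volume_fraction = effect,
                             foci_count = effect)),
    n_noise_features = 10, seed = seed)
}
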