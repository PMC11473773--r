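# Fixtures and independent brute-force oracles used across the test files.

# voxel_ts whose series is a shared sinusoid plus optional voxel noise
sinusoid_ts <- function(freq, n_voxels = 8, n_time = 160, tr = 2,
                        amplitude = 1, noise_sd = 0, seed = 1) {
  set.seed(seed)
  t_sec <- (seq_len(n_time) - 1) * tr
  base <- amplitude * sin(2 * pi * freq * t_sec)
  vals <- matrix(rep(base, each = n_voxels), n_voxels, n_time)
  if (noise_sd > 0) vals <- vals + matrix(rnorm(length(vals), 0, noise_sd),
                                          n_voxels, n_time)
  voxel_timeseries(vals, tr = tr)
}

# direct O(V^2) pairwise mean correlation (GCOR oracle)
gcor_bruteforce <- function(values) {
  V <- nrow(values)
  R <- cor(t(values))
  sapply(seq_len(V), function(i) mean(R[i, -i]))
}

# direct weighted mean correlation (LCOR oracle)
lcor_bruteforce <- function(values, coords, fwhm) {
  V <- nrow(values)
  R <- cor(t(values))
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  out <- numeric(V)
  for (i in seq_len(V)) {
    w <- exp(-colSums((t(coords) - coords[i, ])^2) / (2 * sigma^2))
    w[i] <- 0
    out[i] <- sum(w * R[i, ]) / sum(w)
  }
  out
}

# two-sample t through the closed form (voxel GLM oracle, no covariates)
two_sample_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# enumeration oracle for the colocalization group permutation test:
# recompute the mean Fisher-Z Spearman statistic for every PP/NP split
# using only the public one-subject functions
coloc_exhaustive_oracle <- function(pp_maps, np_maps, receptor) {
  maps <- rbind(pp_maps, np_maps)
  n <- nrow(maps)
  n_np <- nrow(np_maps)
  splits <- combn(n, n_np)
  stat <- function(np_idx) {
    z <- reference_z_maps(maps[-np_idx, , drop = FALSE],
                          maps[np_idx, , drop = FALSE])
    mean(apply(z, 1, function(zi) spatial_spearman(zi, receptor)$z_rho))
  }
  null <- apply(splits, 2, stat)
  obs <- stat(nrow(pp_maps) + seq_len(n_np))
  dev <- abs(null - mean(null))
  mean(dev >= abs(obs - mean(null)) - 1e-12)
}

# small two-group parcel dataset with an optional mean shift on some parcels
toy_parcel_maps <- function(n_pp, n_np, P, shift = 0, parcels = integer(0),
                            seed = 1) {
  set.seed(seed)
  pp <- matrix(rnorm(n_pp * P), n_pp, P,
               dimnames = list(sprintf("PP%02d_T0", seq_len(n_pp)), NULL))
  np <- matrix(rnorm(n_np * P), n_np, P,
               dimnames = list(sprintf("NP%02d_T0", seq_len(n_np)), NULL))
  pp[, parcels] <- pp[, parcels] + shift
  list(pp = pp, np = np)
}
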