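# Voxel-level metric computations against closed-form and brute-force
# oracles.

test_that("nuisance regression orthogonalizes against all confounds", {
  v <- generate_voxel_timeseries(3, 120, 2, list(noise_sd = 1), seed = 10)
  ts <- voxel_timeseries(v$bold, v$tr)
  out <- nuisance_regress(ts, v$confounds)
  X <- cbind(1, as.matrix(v$confounds))
  dots <- abs(out$values %*% X)
  scale_ref <- sqrt(rowSums(out$values^2)) %o% sqrt(colSums(X^2))
  expect_lt(max(dots / scale_ref), 1e-8)

  # a series equal to a confound column is annihilated
  ts2 <- voxel_timeseries(matrix(v$confounds$wm_signal, 2, 120, byrow = TRUE),
                          tr = 2)
  out2 <- nuisance_regress(ts2, v$confounds)
  expect_lt(max(abs(out2$values)), 1e-10 * max(abs(v$confounds$wm_signal)))

  # idempotence
  out3 <- nuisance_regress(out, v$confounds)
  expect_equal(out3$values, out$values, tolerance = 1e-10)

  # rank-deficient confounds: warning, then pseudo-inverse fit still
  # orthogonalizes
  conf_dup <- cbind(v$confounds, dup = v$confounds$wm_signal)
  expect_warning(out4 <- nuisance_regress(ts, conf_dup), "rank-deficient")
  expect_lt(max(abs(out4$values %*% as.matrix(v$confounds)) /
                  (sqrt(rowSums(out4$values^2)) %o%
                     sqrt(colSums(as.matrix(v$confounds)^2)))), 1e-8)
})

test_that("bandpass filter attenuates and passes the right frequencies", {
  # 0.2 Hz is outside the 0.01-0.08 Hz band at TR = 2 s
  hi <- sinusoid_ts(0.2, n_voxels = 2)
  out <- detrend_bandpass(hi)
  expect_lt(var(out$values[1, ]), 0.01 * var(hi$values[1, ]))

  lo <- sinusoid_ts(0.04, n_voxels = 2)
  lo_detr <- detrend_bandpass(lo, detrend_only = TRUE)
  out_lo <- detrend_bandpass(lo)
  expect_gte(var(out_lo$values[1, ]), 0.95 * var(lo_detr$values[1, ]))

  ramp <- voxel_timeseries(matrix(seq_len(160), 2, 160, byrow = TRUE), tr = 2)
  out_r <- detrend_bandpass(ramp)
  expect_lt(max(abs(out_r$values)), 1e-8 * max(ramp$values))

  expect_error(detrend_bandpass(sinusoid_ts(0.04, n_time = 100, tr = 8)),
               "Nyquist")
})

test_that("fALFF matches periodogram oracles and is scale invariant", {
  in_band <- compute_falff(detrend_bandpass(sinusoid_ts(0.04),
                                            detrend_only = TRUE))
  expect_true(all(in_band$values >= 0.95))
  out_band <- compute_falff(detrend_bandpass(sinusoid_ts(0.2),
                                             detrend_only = TRUE))
  expect_true(all(out_band$values <= 0.05))
  expect_true(all(in_band$values >= 0 & in_band$values <= 1))

  # white noise: expected fALFF ~ fraction of frequency bins in band
  set.seed(21)
  wn <- voxel_timeseries(matrix(rnorm(100 * 160), 100, 160), tr = 2)
  f <- compute_falff(detrend_bandpass(wn, detrend_only = TRUE))
  expect_equal(mean(f$values), (0.08 - 0.01) / 0.25, tolerance = 0.05)

  # positive rescaling leaves fALFF unchanged
  ts <- voxel_timeseries(matrix(rnorm(5 * 160), 5, 160), tr = 2)
  f1 <- compute_falff(ts)
  ts$values <- ts$values * 3.7
  f2 <- compute_falff(ts)
  expect_equal(f1$values, f2$values, tolerance = 1e-12)

  zero <- voxel_timeseries(matrix(0, 2, 160), tr = 2)
  expect_warning(fz <- compute_falff(zero), "all-zero")
  expect_equal(fz$values, c(0, 0))
})

test_that("GCOR equals the brute-force pairwise mean", {
  set.seed(31)
  ts <- voxel_timeseries(matrix(rnorm(40 * 120), 40, 120), tr = 2)
  g <- compute_gcor(ts)
  expect_equal(g$values, gcor_bruteforce(ts$values), tolerance = 1e-10)

  # hand-computed case: v1 = v2 = s, v3 = v4 = -s  ->  (1 - 1 - 1)/3 = -1/3
  s <- sin(2 * pi * 0.04 * seq(0, 318, by = 2))
  ts4 <- voxel_timeseries(rbind(s, s, -s, -s), tr = 2)
  g4 <- compute_gcor(ts4)
  expect_equal(unname(g4$values), rep(-1 / 3, 4), tolerance = 1e-10)

  # identical series everywhere -> GCOR 1
  tsi <- voxel_timeseries(matrix(rep(s, 5), 5, byrow = TRUE), tr = 2)
  expect_equal(unname(compute_gcor(tsi)$values), rep(1, 5), tolerance = 1e-10)

  # zero-variance voxel dropped from the mask with a warning
  vals <- rbind(matrix(rnorm(3 * 120), 3, 120), 0)
  expect_warning(gz <- compute_gcor(voxel_timeseries(vals, tr = 2)),
                 "zero-variance")
  expect_true(is.na(gz$values[4]))
  expect_equal(gz$values[1:3], gcor_bruteforce(vals[1:3, ]), tolerance = 1e-10)
})

test_that("LCOR equals the direct weighted-average oracle", {
  set.seed(32)
  bold <- array(rnorm(3 * 3 * 3 * 100), dim = c(3, 3, 3, 100))
  ts <- voxel_timeseries(bold, tr = 2)
  l <- compute_lcor(ts, fwhm_mm = 10)
  expect_equal(l$values, lcor_bruteforce(ts$values, ts$coords, 10),
               tolerance = 1e-10)

  # identical series everywhere -> LCOR 1
  s <- sin(2 * pi * 0.03 * seq(0, 198, by = 2))
  tsi <- voxel_timeseries(matrix(rep(s, 27), 27, byrow = TRUE),
                          coords = ts$coords, tr = 2)
  expect_equal(unname(compute_lcor(tsi, 10)$values), rep(1, 27),
               tolerance = 1e-10)

  # independent white noise: mean LCOR near 0
  set.seed(33)
  wn <- voxel_timeseries(array(rnorm(4^3 * 160), dim = c(4, 4, 4, 160)), tr = 2)
  lw <- compute_lcor(wn, fwhm_mm = 12)
  expect_lt(abs(mean(lw$values)), 3 / sqrt(160))

  # two anti-correlated blocks far apart, narrow kernel: LCOR ~ +1 inside
  blockA <- matrix(rep(s, 4), 4, byrow = TRUE)
  coords <- rbind(cbind(0:3, 0, 0), cbind(0:3 + 500, 0, 0))
  tsb <- voxel_timeseries(rbind(blockA, -blockA), coords = coords, tr = 2)
  lb <- compute_lcor(tsb, fwhm_mm = 5)
  expect_equal(unname(lb$values), rep(1, 8), tolerance = 1e-6)

  expect_error(compute_lcor(voxel_timeseries(matrix(rnorm(100), 1, 100), tr = 2)),
               "2 in-mask")
})

test_that("metrics are invariant to voxel reordering", {
  set.seed(34)
  bold <- array(rnorm(2 * 2 * 2 * 120), dim = c(2, 2, 2, 120))
  ts <- voxel_timeseries(bold, tr = 2)
  perm <- sample(8)
  tsp <- voxel_timeseries(ts$values[perm, ], coords = ts$coords[perm, ], tr = 2)
  expect_equal(compute_gcor(tsp)$values, compute_gcor(ts)$values[perm],
               tolerance = 1e-12)
  expect_equal(compute_lcor(tsp, 8)$values, compute_lcor(ts, 8)$values[perm],
               tolerance = 1e-12)
  expect_equal(compute_falff(tsp)$values, compute_falff(ts)$values[perm],
               tolerance = 1e-12)
})

test_that("parcellation averages voxels by label and flags empty parcels", {
  vals <- c(1, 2, 3, 10, 5, 6)
  labels <- c(1, 1, 1, 2, 0, 3)
  p <- parcellate(vals, labels, n_parcels = 4)
  expect_equal(unname(p[1:3]), c(2, 10, 6))
  expect_true(is.na(p[4]))
  expect_true(attr(p, "missing")[4])
  expect_false(any(attr(p, "missing")[1:3]))

  pc <- parcellate(rep(7, 6), labels, n_parcels = 3)
  expect_equal(unname(pc), rep(7, 3), ignore_attr = TRUE)

  expect_error(parcellate(vals, rep(0, 6)), "no overlap")
  expect_error(parcellate(vals, c(1, 1)), "voxels")
})
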