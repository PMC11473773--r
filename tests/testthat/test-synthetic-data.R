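# Synthetic study generator: design structure, determinism, generative
# moments, receptor atlas construction, voxel fixture spectra.

small_cfg <- function(...) {
  synth_config(n_np = 8, n_pp_cross = 10, n_pp_long = 6, n_parcels = 30,
               effect_specs = list(
                 effect_spec("GCOR", 25:30, sign = -1, magnitude = 0.8,
                             trajectory = trajectory_quadratic())),
               receptor_specs = list(), dropout_p = 0, ...)
}

test_that("study structure follows the two-group longitudinal design", {
  s <- generate_study(small_cfg(seed = 11))
  tb <- s$study_table
  np <- tb[tb$group == "NP", ]
  expect_equal(nrow(np), 8)
  expect_true(all(np$session == "T0"))
  expect_true(all(is.na(np$week)))
  cross <- tb[grepl("^PPC", tb$subject_id), ]
  expect_true(all(cross$session == "T0"))
  long <- tb[grepl("^PPL", tb$subject_id), ]
  expect_equal(nrow(long), 6 * 6)  # no dropout: all six sessions
  for (m in names(s$parcel_maps)) {
    expect_identical(rownames(s$parcel_maps[[m]]), tb$scan_id)
  }
  # truth round-trips the configuration
  expect_identical(s$truth$effect_specs, s$config$effect_specs)
  expect_identical(s$truth$noise_sd, s$config$noise_sd)
})

test_that("same seed and config give bit-identical studies", {
  cfg <- small_cfg(seed = 42)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$study_table, s2$study_table)
  expect_identical(s1$parcel_maps, s2$parcel_maps)
  expect_identical(s1$receptor_atlas, s2$receptor_atlas)
  s3 <- generate_study(small_cfg(seed = 43))
  expect_false(identical(s1$parcel_maps$GCOR, s3$parcel_maps$GCOR))
})

test_that("group mean differences match the generating equation over replicates", {
  # quadratically normalizing GCOR effect, magnitude 0.8 (in noise-SD units),
  # zero-crossing at week 7: the PP-NP difference at the first session should
  # equal 0.8 * noise_sd * m(week), and be ~0 at week 12
  diffs_t0 <- numeric(200)
  diffs_t4 <- numeric(200)
  for (r in seq_len(200)) {
    s <- generate_study(small_cfg(seed = 1000 + r))
    tb <- s$study_table
    g <- s$parcel_maps$GCOR[, 25:30]
    pp0 <- tb$group == "PP" & tb$session == "T0"
    np <- tb$group == "NP"
    diffs_t0[r] <- mean(g[pp0, ]) - mean(g[np, ])
    t4 <- tb$session == "T4"
    diffs_t4[r] <- mean(g[t4, ]) - mean(g[np, ])
  }
  cfg <- small_cfg()
  m_t0 <- trajectory_multiplier(trajectory_quadratic(), cfg$session_weeks[1])
  expected_t0 <- -0.8 * cfg$noise_sd * m_t0
  se <- sd(diffs_t0) / sqrt(200)
  expect_lt(abs(mean(diffs_t0) - expected_t0), 4 * se)
  expect_lt(abs(mean(diffs_t4)), 4 * sd(diffs_t4) / sqrt(200))
})

test_that("configuration errors are caught", {
  expect_error(effect_spec("BOLD", 1:3), "unknown metric")
  expect_error(synth_config(effect_specs = list(effect_spec("GCOR", 200:205))),
               "outside")
  expect_error(synth_config(session_weeks = c(3, 1)), "increasing")
  expect_error(synth_config(noise_sd = 0), "SDs")
  expect_error(synth_config(n_parcels = 1), "n_parcels")
})

test_that("quadratic trajectory normalizes and stays at zero", {
  tr <- trajectory_quadratic()  # zero at week 7
  expect_equal(trajectory_multiplier(tr, 0), 1)
  expect_equal(trajectory_multiplier(tr, 7), 0, tolerance = 1e-12)
  expect_equal(trajectory_multiplier(tr, c(9, 12, 25)), c(0, 0, 0))
  expect_equal(trajectory_multiplier(trajectory_persistent(), c(0, 10, 24)),
               c(1, 1, 1))
})

test_that("receptor atlas reaches target Spearman correlations", {
  pattern <- rnorm(116)
  at <- make_receptor_atlas(116, target_correlations = c(PGR = 0.95),
                            pattern = pattern, seed = 3)
  expect_gte(cor(at[, "PGR"], pattern, method = "spearman"), 0.9)
  at0 <- make_receptor_atlas(116,
                             target_correlations = c(PGR = 0, ESR1 = 0,
                                                     OXTR = 0),
                             pattern = pattern, seed = 4)
  for (r in c("PGR", "ESR1", "OXTR")) {
    expect_lt(abs(cor(at0[, r], pattern, method = "spearman")), 0.2)
  }
  at_neg <- make_receptor_atlas(60, target_correlations = c(mGluR5 = -0.6),
                                pattern = rnorm(60), seed = 5)
  expect_equal(dim(at_neg), c(60, 8))
  expect_error(make_receptor_atlas(50, target_correlations = c(PGR = 1.2),
                                   pattern = rnorm(50)), "\\(-1, 1\\)")
})

test_that("voxel fixture has the requested spectral and correlation structure", {
  # pure sinusoid: every voxel identical
  v <- generate_voxel_timeseries(4, 96, 2,
                                 list(sinusoids = data.frame(freq = 0.04,
                                                             amplitude = 1),
                                      noise_sd = 0, global_fraction = 0),
                                 seed = 1)
  m <- matrix(v$bold, 64, 96)
  expect_lt(max(abs(sweep(m, 2, m[1, ]))), 1e-12)
  expect_equal(ncol(v$confounds), 26)

  # independent white noise: mean pairwise correlation near 0
  v2 <- generate_voxel_timeseries(4, 300, 2,
                                  list(sinusoids = NULL, noise_sd = 1,
                                       global_fraction = 0), seed = 2)
  m2 <- matrix(v2$bold, 64, 300)
  R <- cor(t(m2))
  expect_lt(abs(mean(R[upper.tri(R)])), 3 / sqrt(300))

  # shared global signal with variance fraction f: mean pairwise cor ~ f
  f <- 0.4
  v3 <- generate_voxel_timeseries(5, 300, 2,
                                  list(sinusoids = NULL, noise_sd = 1,
                                       global_fraction = f), seed = 3)
  m3 <- matrix(v3$bold, 125, 300)
  R3 <- cor(t(m3))
  expect_equal(mean(R3[upper.tri(R3)]), f, tolerance = 0.06)

  expect_error(generate_voxel_timeseries(4, 96, 8,
                                         list(sinusoids = data.frame(freq = 0.08,
                                                                     amplitude = 1))),
               "Nyquist")
  expect_error(generate_voxel_timeseries(4, 32, 2, list()), "n_timepoints")
})

test_that("dropout removes only follow-up sessions at the configured rate", {
  cfg <- synth_config(n_np = 3, n_pp_cross = 0, n_pp_long = 60, n_parcels = 5,
                      effect_specs = list(), receptor_specs = list(),
                      dropout_p = 0.2, seed = 9)
  s <- generate_study(cfg)
  tb <- s$study_table[s$study_table$group == "PP", ]
  expect_equal(sum(tb$session == "T0"), 60)  # baseline never dropped
  follow <- table(factor(tb$session, levels = paste0("T", 0:5)))[-1]
  expect_lt(abs(mean(1 - follow / 60) - 0.2), 0.06)  # binomial noise, n = 300
})
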