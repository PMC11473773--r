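# Mixed models, ANCOVAs, paired tests, effect sizes, standardization, FDR
# and the regression-toward-the-mean diagnostic.

make_panel <- function(n_subj = 19, weeks = c(0.5, 3.2, 6.2, 9.2, 12.1, 24.8),
                       b0 = 0, b_lin = 0, b_quad = 0, subject_sd = 0.3,
                       noise_sd = 0.3, seed = 1) {
  set.seed(seed)
  u <- rnorm(n_subj, 0, subject_sd)
  d <- expand.grid(subject_id = sprintf("S%02d", seq_len(n_subj)),
                   week = weeks, stringsAsFactors = FALSE)
  d$session <- paste0("T", match(d$week, weeks) - 1)
  d$group <- "PP"
  d$y <- b0 + b_lin * d$week + b_quad * d$week^2 +
    u[match(d$subject_id, sprintf("S%02d", seq_len(n_subj)))] +
    rnorm(nrow(d), 0, noise_sd)
  d
}

test_that("Hedges' g matches hand computations and guards degenerate input", {
  expect_equal(hedges_g(c(1, 2, 3), c(3, 4, 5)), -1.6)
  expect_equal(hedges_g(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(hedges_g(c(0, 0), c(1, 1)), "zero variance")
  # paired variant: g = mean(d)/sd(d) * J with df = n - 1
  x <- c(2, 4, 6, 9)
  y <- c(1, 2, 3, 4)
  d <- x - y
  expect_equal(hedges_g(x, y, paired = TRUE),
               mean(d) / sd(d) * (1 - 3 / (4 * 3 - 1)))
})

test_that("Benjamini-Hochberg q values match hand computation and BH properties", {
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_correct(0.037), 0.037)
  set.seed(61)
  p <- runif(50)
  q <- fdr_correct(p)
  expect_true(all(q >= p))
  expect_equal(q, p.adjust(p, method = "BH"))
  # family-wise application corrects within each family separately
  fam <- rep(c("a", "b"), each = 25)
  qf <- fdr_correct(p, fam)
  expect_equal(qf[fam == "a"], p.adjust(p[fam == "a"], "BH"))
  expect_error(fdr_correct(c(0, 0.5)), "\\(0, 1\\]")
  expect_identical(fdr_correct(numeric(0)), numeric(0))
})

test_that("within-subject standardization centers and scales each subject", {
  d <- data.frame(subject_id = c("a", "a", "b", "b", "b", "c"),
                  x = c(2, 4, 1, 2, 3, 5))
  out <- suppressWarnings(zstandardize_within_subject(d, "x"))
  expect_equal(out$x[1:2], c(-sqrt(0.5), sqrt(0.5)), tolerance = 1e-6)
  expect_equal(mean(out$x[3:5]), 0)
  expect_equal(sd(out$x[3:5]), 1)
  expect_true(is.na(out$x[6]))  # single observation
  dc <- data.frame(subject_id = c("a", "a"), x = c(3, 3))
  expect_warning(outc <- zstandardize_within_subject(dc, "x"), "zero variance")
  expect_true(all(is.na(outc$x)))
})

test_that("the mixed model reduces to OLS when subject variance is zero", {
  d <- make_panel(n_subj = 30, subject_sd = 1e-8, noise_sd = 0.5,
                  b_lin = 0.05, b_quad = -0.002, seed = 62)
  fit <- fit_lmm(d, "y", quadratic = TRUE)
  ols <- lm(y ~ week + I(week^2), data = d)
  expect_equal(fit$terms$beta, unname(coef(ols)), tolerance = 1e-5)
  expect_true(fit$converged)
  expect_equal(fit$n_obs, nrow(d))
  expect_error(fit_lmm(d[1:2, ], "y"), ">= 2")
  expect_error(fit_lmm(d[, c("subject_id", "y")], "y"), "week")
})

test_that("mixed models recover injected linear and quadratic week effects", {
  d <- make_panel(b_lin = 0.022, b_quad = -0.0016, subject_sd = 0.1,
                  noise_sd = 0.05, seed = 63)
  fit <- fit_lmm(d, "y", quadratic = TRUE)
  betas <- fit$terms[match(c("week", "week2"), fit$terms$term), ]
  expect_lt(abs(betas$beta[1] - 0.022), 3 * betas$se[1])
  expect_lt(abs(betas$beta[2] + 0.0016), 3 * betas$se[2])
  expect_lt(betas$p[1], 0.05)
})

test_that("per-timepoint ANCOVAs adjust for covariates and skip empty sessions", {
  set.seed(64)
  pp <- make_panel(n_subj = 15, seed = 64)
  pp$age <- rnorm(nrow(pp), 31, 3)
  np <- data.frame(subject_id = sprintf("N%02d", 1:20), week = NA,
                   session = "T0", group = "NP",
                   y = rnorm(20), age = rnorm(20, 29, 4))
  d <- rbind(pp, np)
  # inject a baseline-only group difference
  d$y[d$group == "PP" & d$session == "T0"] <-
    d$y[d$group == "PP" & d$session == "T0"] + 2
  res <- ancova_group_by_timepoint(d, "y")
  expect_equal(nrow(res), 6)
  t0 <- res[res$session == "T0", ]
  expect_lt(t0$p, 0.001)
  expect_gt(t0$hedges_g, 1)
  expect_true(all(res$q >= res$p))
  # identical groups (PP baseline rows duplicate the NP rows exactly):
  # the adjusted group difference is exactly zero
  np2 <- np
  np2$y <- 0.3 * np2$age + rnorm(20)
  pp2 <- np2
  pp2$group <- "PP"
  pp2$subject_id <- sprintf("P%02d", 1:20)
  pp2$week <- 0.5
  d2 <- rbind(pp2, np2)
  res2 <- ancova_group_by_timepoint(d2, "y")
  expect_equal(res2$hedges_g, 0, tolerance = 1e-8)
  expect_equal(res2$p, 1, tolerance = 1e-8)
})

test_that("paired tests detect within-subject shifts and respect pairing", {
  d <- make_panel(n_subj = 12, weeks = c(0.5, 3.2), noise_sd = 0.01,
                  subject_sd = 1, seed = 65)
  d$y[d$session == "T1"] <- d$y[d$session == "T1"] + 1
  res <- paired_timepoint_tests(d, "y")
  expect_equal(nrow(res), 1)
  expect_lt(res$p, 1e-6)
  m <- merge(d[d$session == "T0", c("subject_id", "y")],
             d[d$session == "T1", c("subject_id", "y")], by = "subject_id")
  expect_equal(res$hedges_g,
               mean(m$y.x - m$y.y) / sd(m$y.x - m$y.y) * (1 - 3 / (4 * 11 - 1)),
               tolerance = 1e-9)
  # identical sessions: t = 0, p = 1
  d0 <- d
  d0$y <- rep(d0$y[d0$session == "T0"], 2)
  res0 <- paired_timepoint_tests(d0, "y")
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
})

test_that("interaction models recover decaying predictor-response coupling", {
  set.seed(66)
  weeks <- c(0.5, 3.2, 6.2, 9.2, 12.1, 24.8)
  n <- 19
  d <- expand.grid(subject_id = sprintf("S%02d", 1:n), week = weeks,
                   stringsAsFactors = FALSE)
  x_raw <- rnorm(nrow(d))
  # association strength decays linearly with week
  d$x <- x_raw
  d$y <- (1 - d$week / 25) * x_raw + rnorm(nrow(d), 0, 0.3)
  fit <- interaction_lmm(d, "y", "x", standardize_predictor = FALSE)
  inter <- fit$terms[fit$terms$term == "interaction", ]
  expect_lt(inter$beta, 0)
  expect_lt(inter$p, 0.05)

  # null: independent predictor keeps the interaction type-I error nominal
  reject <- logical(120)
  for (r in seq_len(120)) {
    set.seed(500 + r)
    dn <- d
    dn$x <- rnorm(nrow(dn))
    dn$y <- rnorm(nrow(dn))
    fr <- interaction_lmm(dn, "y", "x", standardize_predictor = FALSE)
    reject[r] <- fr$terms$p[fr$terms$term == "interaction"] < 0.05
  }
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 120)
  expect_gte(mean(reject), max(0, ci[1] - 1e-9))
  expect_lte(mean(reject), ci[2] + 0.02)
})

test_that("the RTM diagnostic separates pure regression-to-mean from true change", {
  # no true change: observed slope must fall inside the null band
  d_null <- make_panel(n_subj = 19, subject_sd = 0.5, noise_sd = 0.5, seed = 67)
  r_null <- rtm_check(d_null, "y", n_sim = 300, seed = 1)
  expect_true(r_null$consistent_with_rtm)
  # strong true normalization: slope outside the null band
  d_true <- make_panel(n_subj = 19, subject_sd = 0.2, noise_sd = 0.2, seed = 68)
  mult <- trajectory_multiplier(trajectory_quadratic(), d_true$week)
  d_true$y <- d_true$y - 1.5 * mult
  r_true <- rtm_check(d_true, "y", n_sim = 300, seed = 1)
  expect_false(r_true$consistent_with_rtm)
  # zero measurement noise and no true change: every follow-up equals the
  # baseline, so the baseline-change correlation is 0 by convention
  d0 <- make_panel(n_subj = 15, subject_sd = 1, noise_sd = 0, seed = 69)
  r0 <- rtm_check(d0, "y", n_sim = 50, seed = 2)
  expect_identical(r0$baseline_change_cor, 0)
})
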