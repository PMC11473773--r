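# Longitudinal and cross-sectional statistics on cluster-average metrics,
# colocalization scores, hormones and behavior: random-intercept mixed models
# with linear and quadratic postpartum week, per-timepoint ANCOVAs against
# the once-measured nulliparous controls, paired within-subject tests,
# Hedges' g, within-subject standardization, interaction models, per-family
# FDR correction and a regression-toward-the-mean diagnostic.

#' Random-intercept linear mixed model of a longitudinal response
#'
#' Fits `response ~ week (+ week^2) + (1 | subject)` by maximum likelihood
#' (so nested model comparisons remain valid; set `reml = TRUE` for REML).
#' Fixed-effect p values use the Wald normal approximation. Rows with missing
#' response or week (e.g. nulliparous controls, which have no postpartum
#' week) are dropped. Singular or non-converged fits are flagged, not hidden.
#'
#' @param data data.frame with columns `subject_id`, `week`, and the response.
#' @param response response column name.
#' @param quadratic include a quadratic week term.
#' @param covariates optional additional fixed-effect column names.
#' @param reml use REML instead of ML.
#' @return A `mixed_fit` list: `terms` data.frame (term, beta, se, z, p),
#'   `varcomp` (subject-intercept and residual SD), `n_obs`, `n_subjects`,
#'   `converged`, `singular`, and the underlying `lme4` fit.
#' @export
fit_lmm <- function(data, response, quadratic = FALSE, covariates = NULL,
                    reml = FALSE) {
  assert_columns(data, c("subject_id", "week", response), "long table")
  d <- data[!is.na(data[[response]]) & !is.na(data$week), , drop = FALSE]
  d$.y <- d[[response]]
  d$week2 <- d$week^2
  if (length(unique(d$subject_id)) < 2L || nrow(d) < 4L) {
    stop_input("need >= 2 observations for >= 2 subjects")
  }
  rhs <- c("week", if (quadratic) "week2", covariates)
  form <- stats::as.formula(paste(".y ~", paste(rhs, collapse = " + "),
                                  "+ (1 | subject_id)"))
  fit <- tryCatch(
    lme4::lmer(form, data = d, REML = reml,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(response = response, terms = NULL, varcomp = NULL,
                          n_obs = nrow(d), converged = FALSE, singular = NA,
                          message = conditionMessage(fit), fit = NULL),
                     class = "mixed_fit"))
  }
  sm <- summary(fit)$coefficients
  terms <- data.frame(term = rownames(sm), beta = sm[, "Estimate"],
                      se = sm[, "Std. Error"],
                      z = sm[, "Estimate"] / sm[, "Std. Error"],
                      row.names = NULL)
  terms$p <- 2 * stats::pnorm(-abs(terms$z))
  vc <- as.data.frame(lme4::VarCorr(fit))
  conv <- length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0L
  structure(list(response = response, terms = terms,
                 varcomp = c(subject_sd = vc$sdcor[1], residual_sd = vc$sdcor[2]),
                 n_obs = nrow(d),
                 n_subjects = length(unique(d$subject_id)),
                 converged = conv, singular = lme4::isSingular(fit),
                 fit = fit),
            class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf("Mixed model for %s (n_obs %d, converged %s, singular %s)\n",
              x$response, x$n_obs, x$converged, x$singular))
  if (!is.null(x$terms)) print(x$terms, digits = 4)
  invisible(x)
}

#' Hedges' g standardized mean difference
#'
#' Cohen's d with the pooled SD (or the SD of paired differences) multiplied
#' by the small-sample correction `J = 1 - 3 / (4 df - 1)`. The sign follows
#' `mean(x) - mean(y)`.
#'
#' @param x,y numeric samples (paired: equal length, pairs aligned).
#' @param paired treat `x`, `y` as paired.
#' @return Hedges' g.
#' @export
hedges_g <- function(x, y, paired = FALSE) {
  if (length(x) < 2L || length(y) < 2L) stop_input("need >= 2 values per sample")
  if (paired) {
    if (length(x) != length(y)) stop_input("paired samples must have equal length")
    d <- x - y
    s <- stats::sd(d)
    if (s == 0) stop_input("zero variance: effect size undefined")
    df <- length(d) - 1L
    g <- mean(d) / s
  } else {
    n1 <- length(x); n2 <- length(y)
    df <- n1 + n2 - 2L
    sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
    if (sp2 == 0) stop_input("zero variance: effect size undefined")
    g <- (mean(x) - mean(y)) / sqrt(sp2)
  }
  g * (1 - 3 / (4 * df - 1))
}

#' Per-timepoint group ANCOVAs against the control group
#'
#' At each postpartum session, compares the postpartum scans at that session
#' with all (once-measured) nulliparous scans in
#' `response ~ group + covariates`. Hedges' g is computed from the
#' covariate-adjusted group difference over the model residual SD, with the
#' same small-sample correction as [hedges_g()]. q values are BH-FDR within
#' the returned table; combine several responses with [fdr_correct()] for a
#' wider family.
#'
#' @param data data.frame with `group`, `session`, `week`, covariates and the
#'   response (one row per scan).
#' @param response response column name.
#' @param covariates covariate column names (default `"age"`).
#' @return data.frame: session, week, n_pp, n_np, t, p, hedges_g, q.
#' @export
ancova_group_by_timepoint <- function(data, response, covariates = "age") {
  assert_columns(data, c("group", "session", "week", response, covariates),
                 "session table")
  np <- data[data$group == "NP" & !is.na(data[[response]]), , drop = FALSE]
  sessions <- sort(unique(data$session[data$group == "PP"]))
  rows <- list()
  for (s in sessions) {
    pp <- data[data$group == "PP" & data$session == s &
                 !is.na(data[[response]]), , drop = FALSE]
    if (nrow(pp) < 2L || nrow(np) < 2L) {
      message(sprintf("session %s skipped: a group is empty or too small", s))
      next
    }
    d <- rbind(pp, np)
    form <- stats::as.formula(paste(response, "~ group_pp +",
                                    paste(covariates, collapse = " + ")))
    d$group_pp <- as.numeric(d$group == "PP")
    fit <- stats::lm(form, data = d)
    sm <- summary(fit)$coefficients
    tval <- sm["group_pp", "t value"]
    pval <- sm["group_pp", "Pr(>|t|)"]
    df <- nrow(pp) + nrow(np) - 2L
    g <- unname(stats::coef(fit)["group_pp"] / summary(fit)$sigma *
                  (1 - 3 / (4 * df - 1)))
    rows[[length(rows) + 1L]] <- data.frame(
      session = s, week = pp$week[1], n_pp = nrow(pp), n_np = nrow(np),
      t = tval, p = pval, hedges_g = g)
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Paired within-group tests between all session pairs
#'
#' Paired t tests on postpartum subjects measured at both sessions of each
#' pair, with the paired-variant Hedges' g; BH-FDR within the table.
#'
#' @param data data.frame with `subject_id`, `group`, `session` and the
#'   response.
#' @param response response column name.
#' @return data.frame: session_a, session_b, n_pairs, t, p, hedges_g, q.
#' @export
paired_timepoint_tests <- function(data, response) {
  assert_columns(data, c("subject_id", "group", "session", response),
                 "long table")
  pp <- data[data$group == "PP" & !is.na(data[[response]]), , drop = FALSE]
  sessions <- sort(unique(pp$session))
  rows <- list()
  for (i in seq_along(sessions)) {
    for (j in seq_along(sessions)) {
      if (j <= i) next
      a <- pp[pp$session == sessions[i], c("subject_id", response)]
      b <- pp[pp$session == sessions[j], c("subject_id", response)]
      m <- merge(a, b, by = "subject_id", suffixes = c("_a", "_b"))
      if (nrow(m) < 3L) next
      xa <- m[[paste0(response, "_a")]]
      xb <- m[[paste0(response, "_b")]]
      if (stats::sd(xa - xb) == 0) {
        tval <- if (all(xa == xb)) 0 else Inf
        pval <- if (all(xa == xb)) 1 else 0
        g <- 0
      } else {
        tt <- stats::t.test(xa, xb, paired = TRUE)
        tval <- unname(tt$statistic)
        pval <- tt$p.value
        g <- hedges_g(xa, xb, paired = TRUE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        session_a = sessions[i], session_b = sessions[j], n_pairs = nrow(m),
        t = tval, p = pval, hedges_g = g)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Z-standardize columns within each subject
#'
#' Per subject and column: `(x - subject mean) / subject SD` (denominator
#' n-1). Subjects with fewer than 2 non-missing values or zero variance get
#' `NA` with a warning.
#'
#' @param data data.frame with `subject_id`.
#' @param columns column names to standardize.
#' @return The data.frame with standardized columns.
#' @export
zstandardize_within_subject <- function(data, columns) {
  assert_columns(data, c("subject_id", columns), "long table")
  dropped <- FALSE
  for (cl in columns) {
    out <- rep(NA_real_, nrow(data))
    for (s in unique(data$subject_id)) {
      ii <- which(data$subject_id == s & !is.na(data[[cl]]))
      if (length(ii) < 2L) { dropped <- dropped || length(ii) == 1L; next }
      sdv <- stats::sd(data[[cl]][ii])
      if (is.na(sdv) || sdv == 0) { dropped <- TRUE; next }
      out[ii] <- (data[[cl]][ii] - mean(data[[cl]][ii])) / sdv
    }
    data[[cl]] <- out
  }
  if (dropped) warning("subjects with zero variance or a single value set to NA")
  data
}

#' Interaction mixed model between a predictor and postpartum week
#'
#' Fits `response ~ predictor * week + (1 | subject)` with random intercepts,
#' after z-standardizing the predictor within subjects (which removes
#' between-subject level differences and emphasizes temporal covariation)
#' and scaling the response to unit SD so the interaction coefficient is a
#' standardized effect size.
#'
#' @param data data.frame with `subject_id`, `week`, predictor and response.
#' @param response response column name.
#' @param predictor predictor column name (e.g. a log-hormone or MRI column).
#' @param moderator moderator column; default `"week"`.
#' @param standardize_predictor z-standardize the predictor within subjects
#'   first (set `FALSE` if already standardized).
#' @return A `mixed_fit`; the interaction row is tagged in `terms$term`.
#' @export
interaction_lmm <- function(data, response, predictor, moderator = "week",
                            standardize_predictor = TRUE) {
  assert_columns(data, c("subject_id", moderator, response, predictor),
                 "long table")
  d <- data
  if (standardize_predictor) {
    d <- suppressWarnings(zstandardize_within_subject(d, predictor))
  }
  d <- d[!is.na(d[[response]]) & !is.na(d[[predictor]]) &
           !is.na(d[[moderator]]), , drop = FALSE]
  sd_y <- stats::sd(d[[response]], na.rm = TRUE)
  if (is.na(sd_y) || sd_y == 0) stop_input("response has zero variance")
  d$.y <- d[[response]] / sd_y
  d$.x <- d[[predictor]]
  d$.w <- d[[moderator]]
  if (length(unique(d$subject_id)) < 2L || nrow(d) < 6L) {
    stop_input("need >= 2 observations for >= 2 subjects")
  }
  fit <- tryCatch(
    lme4::lmer(.y ~ .x * .w + (1 | subject_id), data = d, REML = FALSE,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(response = response, predictor = predictor,
                          terms = NULL, converged = FALSE,
                          message = conditionMessage(fit), fit = NULL),
                     class = "mixed_fit"))
  }
  sm <- summary(fit)$coefficients
  terms <- data.frame(term = rownames(sm), beta = sm[, "Estimate"],
                      se = sm[, "Std. Error"],
                      z = sm[, "Estimate"] / sm[, "Std. Error"],
                      row.names = NULL)
  terms$p <- 2 * stats::pnorm(-abs(terms$z))
  terms$term[terms$term == ".x:.w"] <- "interaction"
  terms$term[terms$term == ".x"] <- predictor
  terms$term[terms$term == ".w"] <- moderator
  conv <- length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0L
  structure(list(response = response, predictor = predictor, terms = terms,
                 n_obs = nrow(d),
                 n_subjects = length(unique(d$subject_id)),
                 converged = conv, singular = lme4::isSingular(fit), fit = fit),
            class = "mixed_fit")
}

#' Benjamini-Hochberg FDR correction within families
#'
#' @param p_values numeric p values in (0, 1].
#' @param family_id optional family labels; correction is applied separately
#'   within each family.
#' @return q values in the original order.
#' @export
fdr_correct <- function(p_values, family_id = NULL) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(p_values <= 0 | p_values > 1, na.rm = TRUE)) {
    stop_input("p values must lie in (0, 1]")
  }
  if (is.null(family_id)) return(stats::p.adjust(p_values, method = "BH"))
  q <- rep(NA_real_, length(p_values))
  for (f in unique(family_id)) {
    ii <- which(family_id == f)
    q[ii] <- stats::p.adjust(p_values[ii], method = "BH")
  }
  q
}

#' Regression-toward-the-mean diagnostic for longitudinal normalization
#'
#' Evaluates whether an apparent normalization of a baseline deviation could
#' be produced by regression toward the mean alone. Two parts: (a) the
#' correlation between baseline value and baseline-to-follow-up change,
#' compared with its simulation distribution under no true change; (b) a
#' parametric-bootstrap null in which data are regenerated with the observed
#' baseline distribution, the observed within/between-subject variance split,
#' and zero true trajectory; the observed week slope is compared against this
#' null band.
#'
#' @param data data.frame with `subject_id`, `week`, `session` and response;
#'   postpartum rows only are used.
#' @param response response column name.
#' @param n_sim number of null simulations.
#' @param seed integer seed.
#' @param level coverage of the null band.
#' @return An `rtm_report` list: `observed_slope`, `slope_null_band`,
#'   `baseline_change_cor`, `cor_null_band`, `consistent_with_rtm`, `n_sim`.
#' @export
rtm_check <- function(data, response, n_sim = 500, seed = 1L, level = 0.95) {
  assert_columns(data, c("subject_id", "week", response), "long table")
  d <- data[!is.na(data[[response]]) & !is.na(data$week), , drop = FALSE]
  base_week <- min(d$week)
  subj <- unique(d$subject_id)
  has_fu <- vapply(subj, function(s) {
    any(d$subject_id == s & d$week == base_week) &&
      any(d$subject_id == s & d$week > base_week)
  }, logical(1))
  if (sum(has_fu) < 3L) {
    message("rtm_check skipped: fewer than 3 subjects with baseline + follow-up")
    return(NULL)
  }
  d <- d[d$subject_id %in% subj[has_fu], , drop = FALSE]

  # observed quantities
  obs_slope <- unname(stats::coef(stats::lm(d[[response]] ~ d$week))[2])
  bl <- d[d$week == base_week, c("subject_id", response)]
  first_fu <- do.call(rbind, lapply(split(d[d$week > base_week, ],
                                          d$subject_id[d$week > base_week]),
                                    function(x) x[which.min(x$week), ]))
  m <- merge(bl, first_fu[, c("subject_id", response)], by = "subject_id",
             suffixes = c("_bl", "_fu"))
  chg <- m[[paste0(response, "_fu")]] - m[[paste0(response, "_bl")]]
  obs_cor <- if (stats::sd(chg) == 0) 0 else
    stats::cor(m[[paste0(response, "_bl")]], chg)

  # moment-based variance split under no true change: within-subject
  # (residual) variance pooled over subjects, between-subject variance from
  # the spread of subject means (method-of-moments, robust to degenerate fits)
  y_by_s <- split(d[[response]], d$subject_id)
  n_i <- lengths(y_by_s)
  sig2 <- stats::weighted.mean(vapply(y_by_s, stats::var, numeric(1)),
                               n_i - 1L, na.rm = TRUE)
  tau2 <- max(stats::var(vapply(y_by_s, mean, numeric(1))) -
                sig2 * mean(1 / n_i), 0)
  tau <- sqrt(tau2)
  sig <- sqrt(sig2)
  mu <- mean(d[[response]])

  set.seed(as.integer(seed))
  sim_slope <- sim_cor <- numeric(n_sim)
  layout <- d[, c("subject_id", "week")]
  for (k in seq_len(n_sim)) {
    u <- stats::rnorm(length(unique(layout$subject_id)), 0, tau)
    names(u) <- unique(layout$subject_id)
    y <- mu + u[layout$subject_id] + stats::rnorm(nrow(layout), 0, sig)
    sim_slope[k] <- unname(stats::coef(stats::lm(y ~ layout$week))[2])
    ybl <- y[layout$week == base_week]
    names(ybl) <- layout$subject_id[layout$week == base_week]
    sim_cor[k] <- local({
      fu_rows <- vapply(split(seq_len(nrow(layout))[layout$week > base_week],
                              layout$subject_id[layout$week > base_week]),
                        function(ii) ii[which.min(layout$week[ii])], integer(1))
      yfu <- y[fu_rows]
      sids <- layout$subject_id[fu_rows]
      ch <- yfu - ybl[sids]
      if (stats::sd(ch) == 0) 0 else stats::cor(ybl[sids], ch)
    })
  }
  alpha <- (1 - level) / 2
  slope_band <- stats::quantile(sim_slope, c(alpha, 1 - alpha), names = FALSE)
  cor_band <- stats::quantile(sim_cor, c(alpha, 1 - alpha), names = FALSE)
  structure(list(observed_slope = obs_slope, slope_null_band = slope_band,
                 baseline_change_cor = obs_cor, cor_null_band = cor_band,
                 consistent_with_rtm = obs_slope >= slope_band[1] &&
                   obs_slope <= slope_band[2],
                 n_sim = n_sim),
            class = "rtm_report")
}

#' @export
print.rtm_report <- function(x, ...) {
  cat(sprintf("RTM diagnostic: observed week slope %.4f, null band [%.4f, %.4f]\n",
              x$observed_slope, x$slope_null_band[1], x$slope_null_band[2]))
  cat(sprintf("baseline-change correlation %.3f (null band [%.3f, %.3f])\n",
              x$baseline_change_cor, x$cor_null_band[1], x$cor_null_band[2]))
  cat(if (x$consistent_with_rtm) "consistent with regression toward the mean\n"
      else "NOT consistent with regression toward the mean alone\n")
  invisible(x)
}
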