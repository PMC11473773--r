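# Synthetic longitudinal parcel-level study generator.
#
# The generator emulates the statistical structure of a two-group postpartum
# rsfMRI study: a large cross-sectional postpartum group scanned once in the
# first week, a longitudinal postpartum subgroup followed over six sessions
# spanning roughly half a year, and a once-scanned nulliparous control group.
# Group effects live on parcel-wise metric maps (fALFF, LCOR, GCOR) and can
# either persist or normalize quadratically with postpartum week; effects can
# additionally be spatially coupled to receptor distribution maps so that the
# colocalization statistics downstream have a known ground truth.

RECEPTOR_NAMES <- c("PGR", "ESR1", "ESR2", "NR3C1", "NR3C2", "OXTR",
                    "GABA_A", "mGluR5")
METRIC_NAMES <- c("fALFF", "LCOR", "GCOR")

#' Persistent group-effect trajectory
#'
#' Multiplier 1 at every postpartum week: the group effect does not change
#' over the observation period.
#' @return A trajectory object.
#' @export
trajectory_persistent <- function() {
  structure(list(type = "persistent"), class = "mfc_trajectory")
}

#' Quadratically normalizing group-effect trajectory
#'
#' Multiplier `1 + beta_lin * week + beta_quad * week^2`, floored at zero and
#' held at zero once the curve first reaches it, so that an initially strong
#' group effect shrinks and stays at control level. The default coefficients
#' place the zero-crossing at postpartum week 7, the middle of the 6-9 week
#' window in which global connectivity differences are expected to resolve.
#'
#' @param beta_lin linear coefficient of the multiplier.
#' @param beta_quad quadratic coefficient of the multiplier.
#' @return A trajectory object.
#' @export
trajectory_quadratic <- function(beta_lin = -2 / 7, beta_quad = 1 / 49) {
  structure(list(type = "quadratic_normalizing", beta_lin = beta_lin,
                 beta_quad = beta_quad), class = "mfc_trajectory")
}

#' Evaluate a trajectory multiplier at given postpartum weeks
#' @param traj trajectory from [trajectory_persistent()] or
#'   [trajectory_quadratic()].
#' @param week numeric vector of postpartum weeks.
#' @return Numeric multiplier vector in `[0, 1]` (persistent: all 1).
#' @export
trajectory_multiplier <- function(traj, week) {
  stopifnot(inherits(traj, "mfc_trajectory"))
  if (traj$type == "persistent") return(rep(1, length(week)))
  m <- 1 + traj$beta_lin * week + traj$beta_quad * week^2
  # hold at zero from the first root onward (normalized effects do not rebound)
  disc <- traj$beta_lin^2 - 4 * traj$beta_quad
  if (traj$beta_quad != 0 && disc >= 0) {
    r <- (-traj$beta_lin + c(-1, 1) * sqrt(disc)) / (2 * traj$beta_quad)
    r <- r[r > 0]
    if (length(r) > 0L) m[week >= min(r)] <- 0
  }
  pmax(m, 0)
}

#' Specify one group effect on a parcel-level metric
#'
#' @param metric one of `"fALFF"`, `"LCOR"`, `"GCOR"`.
#' @param parcels integer indices of affected parcels.
#' @param sign `+1` (postpartum > nulliparous) or `-1`.
#' @param magnitude effect at week 0 in units of the residual SD
#'   (a Cohen's-d-like scale).
#' @param trajectory a trajectory object; defaults to persistent.
#' @return An `effect_spec` object.
#' @export
effect_spec <- function(metric, parcels, sign = 1, magnitude = 1,
                        trajectory = trajectory_persistent()) {
  if (!metric %in% METRIC_NAMES) {
    stop_input("configuration error: unknown metric '%s' (expected one of %s)",
               metric, paste(METRIC_NAMES, collapse = ", "))
  }
  if (length(parcels) == 0L) stop_input("configuration error: empty parcel set")
  if (!sign %in% c(-1, 1)) stop_input("configuration error: sign must be +1 or -1")
  if (magnitude < 0) stop_input("configuration error: magnitude must be >= 0")
  structure(list(metric = metric, parcels = as.integer(parcels), sign = sign,
                 magnitude = magnitude, trajectory = trajectory),
            class = "effect_spec")
}

default_effect_specs <- function() {
  list(
    # persistent neocortical local-activity increases and decreases
    effect_spec("fALFF", 1:5, sign = +1, magnitude = 2.5),
    effect_spec("fALFF", 10:14, sign = -1, magnitude = 2.5),
    # persistent bilateral local-connectivity decrease
    effect_spec("LCOR", 21:28, sign = -1, magnitude = 2.5),
    # subcortical global-connectivity decrease normalizing by ~week 7
    effect_spec("GCOR", 101:108, sign = -1, magnitude = 2.5,
                trajectory = trajectory_quadratic())
  )
}

default_receptor_specs <- function() {
  list(
    fALFF = list(coupling = c(PGR = 0.35, mGluR5 = -0.35),
                 trajectory = trajectory_persistent()),
    LCOR = list(coupling = c(mGluR5 = -0.30),
                trajectory = trajectory_persistent()),
    GCOR = list(coupling = c(PGR = -0.35, OXTR = -0.35, NR3C1 = 0.30,
                             NR3C2 = 0.30, GABA_A = 0.30),
                trajectory = trajectory_quadratic())
  )
}

default_hormone_spec <- function() {
  list(
    # natural-log scale; postpartum progesterone falls steeply after delivery
    # and recovers with the return of ovarian cycling (quadratic in week)
    progesterone = list(beta = c(3.0, -0.35, 0.012), sd = 0.35, subject_sd = 0.25),
    estradiol = list(beta = c(5.0, -0.10, 0.001), sd = 0.35, subject_sd = 0.25)
  )
}

default_behavior_spec <- function() {
  list(
    epds = list(beta = c(5.5, -0.30, 0.008), sd = 2.0, subject_sd = 2.0,
                range = c(0, 30), sessions = paste0("T", 0:5)),
    mpas_quality = list(beta = c(36, 0.25, -0.006), sd = 2.0, subject_sd = 2.5,
                        range = c(9, 45), sessions = paste0("T", 1:5)),
    mpas_hostility = list(beta = c(20, 0.12, -0.003), sd = 1.5, subject_sd = 2.0,
                          range = c(5, 25), sessions = paste0("T", 1:5)),
    mpas_pleasure = list(beta = c(19, 0.15, -0.004), sd = 1.5, subject_sd = 2.0,
                         range = c(5, 25), sessions = paste0("T", 1:5))
  )
}

#' Configuration of a synthetic postpartum study
#'
#' Defaults mirror the design of the emulated study: 23 nulliparous controls
#' scanned once, 56 cross-sectional postpartum women scanned in the first
#' postpartum week, 19 longitudinal postpartum women scanned at all six
#' sessions (~0.5, 3.2, 6.2, 9.2, 12.1 and 24.8 weeks postpartum), and
#' 116 parcels (100 cortical + 16 subcortical, the subcortical ones last).
#'
#' @param n_np number of nulliparous controls.
#' @param n_pp_cross number of cross-sectional postpartum subjects
#'   (first session only).
#' @param n_pp_long number of longitudinal postpartum subjects (all sessions).
#' @param session_weeks strictly increasing postpartum weeks of sessions
#'   T0, T1, ...
#' @param n_parcels number of parcels (>= 2).
#' @param effect_specs list of [effect_spec()] objects.
#' @param receptor_specs per-metric receptor coupling: named list with
#'   elements `coupling` (named numeric, receptor -> coefficient in residual-SD
#'   units per standardized receptor value) and `trajectory`.
#' @param noise_sd residual SD of parcel values.
#' @param subject_sd SD of per-subject random intercepts (shared across the
#'   parcels of one metric).
#' @param hormone_spec,behavior_spec generating coefficients
#'   `(intercept, week, week^2)` plus noise/intercept SDs for hormones
#'   (natural-log scale) and behavioral scores (raw scale).
#' @param dropout_p probability that a longitudinal follow-up session
#'   (T1 onward) is missing.
#' @param seed root seed; all randomness flows from it via named substreams.
#' @return A `synth_config` object.
#' @export
synth_config <- function(n_np = 23, n_pp_cross = 56, n_pp_long = 19,
                         session_weeks = c(0.5, 3.2, 6.2, 9.2, 12.1, 24.8),
                         n_parcels = 116,
                         effect_specs = default_effect_specs(),
                         receptor_specs = default_receptor_specs(),
                         noise_sd = 0.5, subject_sd = 0.35,
                         hormone_spec = default_hormone_spec(),
                         behavior_spec = default_behavior_spec(),
                         dropout_p = 0.03, seed = 1L) {
  if (n_parcels < 2) stop_input("configuration error: n_parcels must be >= 2")
  if (is.unsorted(session_weeks, strictly = TRUE)) {
    stop_input("configuration error: session_weeks must be strictly increasing")
  }
  if (noise_sd <= 0 || subject_sd <= 0) {
    stop_input("configuration error: all SDs must be > 0")
  }
  if (dropout_p < 0 || dropout_p >= 1) {
    stop_input("configuration error: dropout_p must be in [0, 1)")
  }
  for (es in effect_specs) {
    if (!inherits(es, "effect_spec")) {
      stop_input("configuration error: effect_specs must be effect_spec objects")
    }
    if (any(es$parcels < 1L | es$parcels > n_parcels)) {
      stop_input("configuration error: effect on metric %s references parcels outside 1..%d",
                 es$metric, n_parcels)
    }
  }
  for (mn in names(receptor_specs)) {
    if (!mn %in% METRIC_NAMES) {
      stop_input("configuration error: receptor_specs names unknown metric '%s'", mn)
    }
    bad <- setdiff(names(receptor_specs[[mn]]$coupling), RECEPTOR_NAMES)
    if (length(bad) > 0L) {
      stop_input("configuration error: unknown receptor(s) %s",
                 paste(bad, collapse = ", "))
    }
  }
  structure(list(n_np = n_np, n_pp_cross = n_pp_cross, n_pp_long = n_pp_long,
                 session_weeks = session_weeks, n_parcels = n_parcels,
                 effect_specs = effect_specs, receptor_specs = receptor_specs,
                 noise_sd = noise_sd, subject_sd = subject_sd,
                 hormone_spec = hormone_spec, behavior_spec = behavior_spec,
                 dropout_p = dropout_p, seed = as.integer(seed)),
            class = "synth_config")
}

# draw from b0 + b1 w + b2 w^2 + subject intercept + noise for PP rows
sim_quadratic_outcome <- function(tab, spec, log_scale = FALSE) {
  subj <- unique(tab$subject_id[tab$group == "PP"])
  u <- stats::rnorm(length(subj), 0, spec$subject_sd)
  names(u) <- subj
  out <- rep(NA_real_, nrow(tab))
  pp <- tab$group == "PP"
  w <- tab$week[pp]
  mu <- spec$beta[1] + spec$beta[2] * w + spec$beta[3] * w^2
  val <- mu + u[tab$subject_id[pp]] + stats::rnorm(sum(pp), 0, spec$sd)
  if (log_scale) val <- exp(val)
  if (!is.null(spec$range)) val <- pmin(pmax(val, spec$range[1]), spec$range[2])
  out[pp] <- val
  if (!is.null(spec$sessions)) out[!(tab$session %in% spec$sessions)] <- NA_real_
  out
}

#' Generate a synthetic longitudinal postpartum study
#'
#' Parcel values are built as
#' `subject intercept + group effect (trajectory at the scan's week)
#'  + receptor-coupled spatial component + Gaussian noise`,
#' on a pseudo-standardized metric scale (grand mean 0). Group effects and
#' receptor couplings are expressed in units of `noise_sd`. Log-progesterone,
#' log-estradiol and the behavioral scores are generated with linear +
#' quadratic week effects. Deterministic given `config$seed`.
#'
#' @param config a [synth_config()] object.
#' @return A `synthetic_study` list with elements `study_table` (one row per
#'   scan), `parcel_maps` (named list of scans x parcels matrices, one per
#'   metric), `receptor_atlas` (parcels x receptors matrix) and `truth`
#'   (the generating parameters).
#' @export
generate_study <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  P <- config$n_parcels

  # --- subjects and sessions -------------------------------------------------
  np_ids <- sprintf("NP%03d", seq_len(config$n_np))
  ppc_ids <- sprintf("PPC%03d", seq_len(config$n_pp_cross))
  ppl_ids <- sprintf("PPL%03d", seq_len(config$n_pp_long))
  sessions <- paste0("T", seq_along(config$session_weeks) - 1L)

  set.seed(substream_seed(config$seed, "dropout"))
  rows <- list()
  for (s in np_ids) {
    rows[[length(rows) + 1L]] <- data.frame(subject_id = s, group = "NP",
                                            session = "T0", week = NA_real_)
  }
  for (s in ppc_ids) {
    rows[[length(rows) + 1L]] <- data.frame(subject_id = s, group = "PP",
                                            session = "T0",
                                            week = config$session_weeks[1])
  }
  for (s in ppl_ids) {
    keep <- c(TRUE, stats::runif(length(sessions) - 1L) >= config$dropout_p)
    rows[[length(rows) + 1L]] <- data.frame(subject_id = s, group = "PP",
                                            session = sessions[keep],
                                            week = config$session_weeks[keep])
  }
  tab <- do.call(rbind, rows)
  tab$longitudinal <- tab$subject_id %in% ppl_ids
  tab$scan_id <- paste(tab$subject_id, tab$session, sep = "_")

  # --- demographics / motion -------------------------------------------------
  set.seed(substream_seed(config$seed, "demographics"))
  subjects <- unique(tab$subject_id)
  age <- stats::setNames(numeric(length(subjects)), subjects)
  age[np_ids] <- stats::rnorm(length(np_ids), 28.0, 4.9)
  age[ppc_ids] <- stats::rnorm(length(ppc_ids), 29.8, 3.4)
  age[ppl_ids] <- stats::rnorm(length(ppl_ids), 32.7, 3.3)
  age <- pmax(age, 18)
  motion_mean <- stats::setNames(numeric(length(subjects)), subjects)
  motion_mean[c(np_ids, ppc_ids)] <- log(0.15)
  motion_mean[ppl_ids] <- log(0.12)
  tab$age <- round(age[tab$subject_id], 1)
  tab$max_motion <- round(stats::rlnorm(nrow(tab),
                                        motion_mean[tab$subject_id], 0.4), 3)

  # --- receptor atlas --------------------------------------------------------
  atlas <- make_receptor_atlas(P, seed = substream_seed(config$seed, "atlas"))
  atlas_z <- scale(atlas)

  # --- parcel maps -----------------------------------------------------------
  parcel_maps <- list()
  for (metric in METRIC_NAMES) {
    set.seed(substream_seed(config$seed, paste0("parcel_maps_", metric)))
    u <- stats::setNames(stats::rnorm(length(subjects), 0, config$subject_sd),
                         subjects)
    m <- matrix(stats::rnorm(nrow(tab) * P, 0, config$noise_sd),
                nrow = nrow(tab), ncol = P,
                dimnames = list(tab$scan_id, sprintf("parcel_%03d", seq_len(P))))
    m <- m + u[tab$subject_id]
    pp <- which(tab$group == "PP")
    for (es in config$effect_specs) {
      if (es$metric != metric) next
      mult <- trajectory_multiplier(es$trajectory, tab$week[pp])
      m[pp, es$parcels] <- m[pp, es$parcels] +
        es$sign * es$magnitude * config$noise_sd * mult
    }
    rs <- config$receptor_specs[[metric]]
    if (!is.null(rs) && length(rs$coupling) > 0L) {
      spatial <- as.vector(atlas_z[, names(rs$coupling), drop = FALSE] %*%
                             rs$coupling) * config$noise_sd
      mult <- trajectory_multiplier(rs$trajectory, tab$week[pp])
      m[pp, ] <- m[pp, ] + outer(mult, spatial)
    }
    parcel_maps[[metric]] <- m
  }

  # --- hormones and behavior -------------------------------------------------
  set.seed(substream_seed(config$seed, "hormones"))
  tab$progesterone <- sim_quadratic_outcome(tab, config$hormone_spec$progesterone,
                                            log_scale = TRUE)
  tab$estradiol <- sim_quadratic_outcome(tab, config$hormone_spec$estradiol,
                                         log_scale = TRUE)
  set.seed(substream_seed(config$seed, "behavior"))
  for (nm in names(config$behavior_spec)) {
    tab[[nm]] <- sim_quadratic_outcome(tab, config$behavior_spec[[nm]])
  }
  tab$mpas_total <- tab$mpas_quality + tab$mpas_hostility + tab$mpas_pleasure

  rownames(tab) <- NULL
  structure(list(study_table = tab, parcel_maps = parcel_maps,
                 receptor_atlas = atlas,
                 truth = list(effect_specs = config$effect_specs,
                              receptor_specs = config$receptor_specs,
                              hormone_spec = config$hormone_spec,
                              behavior_spec = config$behavior_spec,
                              noise_sd = config$noise_sd,
                              subject_sd = config$subject_sd),
                 config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  tb <- x$study_table
  cat(sprintf("Synthetic postpartum study: %d scans, %d subjects (%d PP / %d NP), %d parcels\n",
              nrow(tb), length(unique(tb$subject_id)),
              length(unique(tb$subject_id[tb$group == "PP"])),
              length(unique(tb$subject_id[tb$group == "NP"])),
              ncol(x$parcel_maps[[1]])))
  invisible(x)
}

#' Build a synthetic receptor atlas
#'
#' Without targets, returns spatially structured receptor maps: each column
#' loads on a shared latent gradient (receptor maps are known to be mutually
#' correlated) and the PGR/OXTR columns additionally load on the subcortical
#' parcels (the last 16 when `n_parcels >= 32`). With `target_correlations`,
#' each named column is constructed by rank-mixing so that its realized
#' Spearman correlation with `pattern` lies within `tol` of the target.
#' This is a synthetic stand-in for parcel-level receptor maps derived from
#' postmortem gene expression or nuclear imaging.
#'
#' @param n_parcels number of parcels.
#' @param target_correlations optional named numeric vector (names from
#'   `PGR, ESR1, ESR2, NR3C1, NR3C2, OXTR, GABA_A, mGluR5`) of target Spearman
#'   correlations in (-1, 1) with `pattern`; unnamed receptors get
#'   unconstrained noise columns.
#' @param pattern numeric vector of length `n_parcels`; required when targets
#'   are given.
#' @param seed integer seed.
#' @param tol tolerance on realized Spearman correlations.
#' @param max_attempts fresh-noise retries per receptor before giving up.
#' @return A `n_parcels` x 8 matrix with receptor column names.
#' @export
make_receptor_atlas <- function(n_parcels, target_correlations = NULL,
                                pattern = NULL, seed = 1L, tol = 0.1,
                                max_attempts = 25L) {
  set.seed(as.integer(seed))
  P <- n_parcels
  atlas <- matrix(NA_real_, P, length(RECEPTOR_NAMES),
                  dimnames = list(sprintf("parcel_%03d", seq_len(P)),
                                  RECEPTOR_NAMES))
  if (is.null(target_correlations)) {
    latent <- stats::rnorm(P)
    subcort <- rep(0, P)
    if (P >= 32) subcort[(P - 15):P] <- 1.5
    for (r in RECEPTOR_NAMES) {
      load_sub <- if (r %in% c("PGR", "OXTR")) subcort else 0
      atlas[, r] <- 0.3 * latent + load_sub + stats::rnorm(P)
    }
    return(atlas)
  }
  if (is.null(pattern) || length(pattern) != P) {
    stop_input("pattern of length n_parcels is required with target_correlations")
  }
  if (any(abs(target_correlations) >= 1)) {
    stop_input("target correlations must lie in (-1, 1)")
  }
  zp <- as.vector(scale(rank(pattern)))
  for (r in RECEPTOR_NAMES) {
    tgt <- target_correlations[r]
    if (is.na(tgt) || is.null(tgt) || !r %in% names(target_correlations)) {
      atlas[, r] <- stats::rnorm(P)
      next
    }
    base <- sign(tgt) * zp
    if (tgt == 0) base <- zp
    ok <- FALSE
    for (attempt in seq_len(max_attempts)) {
      noise <- as.vector(scale(stats::rnorm(P)))
      # realized Spearman is continuous and monotone in the mixing weight
      # for fixed noise, so bisection over the weight converges
      g <- function(lam) stats::cor(lam * base + (1 - lam) * noise, pattern,
                                    method = "spearman")
      lo <- 0; hi <- 1
      if ((g(lo) - tgt) * (g(hi) - tgt) > 0) {
        cand <- if (abs(g(lo) - tgt) < abs(g(hi) - tgt)) lo else hi
        if (abs(g(cand) - tgt) <= tol) {
          atlas[, r] <- cand * base + (1 - cand) * noise; ok <- TRUE; break
        }
        next
      }
      for (it in 1:40) {
        mid <- (lo + hi) / 2
        if ((g(lo) - tgt) * (g(mid) - tgt) <= 0) hi <- mid else lo <- mid
      }
      lam <- (lo + hi) / 2
      if (abs(g(lam) - tgt) <= tol) {
        atlas[, r] <- lam * base + (1 - lam) * noise; ok <- TRUE; break
      }
    }
    if (!ok) {
      stop_input("could not reach target Spearman correlation %.2f for %s within %d attempts",
                 tgt, r, max_attempts)
    }
  }
  atlas
}

#' Simulate a small 4D BOLD volume with a confound table
#'
#' Generates a cubic voxel grid whose time series are a mixture of shared
#' sinusoids, a shared global noise signal and voxel-specific white noise,
#' plus a 26-column confound table (24 motion-derived regressors and two
#' tissue signals). Intended as a ground-truth fixture for the voxel-level
#' metric computations.
#'
#' @param n_voxels_per_axis edge length of the cubic grid.
#' @param n_timepoints number of volumes (>= 64).
#' @param tr_seconds repetition time in seconds.
#' @param signal_spec list with elements `sinusoids` (data.frame with columns
#'   `freq` in Hz and `amplitude`; shared across voxels), `noise_sd` and
#'   `global_fraction` (fraction of noise variance shared by all voxels).
#' @param seed integer seed.
#' @return List with `bold` (4D array), `confounds` (data.frame, 26 columns)
#'   and `tr` (seconds).
#' @export
generate_voxel_timeseries <- function(n_voxels_per_axis = 12,
                                      n_timepoints = 160, tr_seconds = 2,
                                      signal_spec = list(sinusoids = NULL,
                                                         noise_sd = 1,
                                                         global_fraction = 0),
                                      seed = 1L) {
  if (n_timepoints < 64) stop_input("configuration error: n_timepoints must be >= 64")
  if (tr_seconds <= 0) stop_input("configuration error: tr_seconds must be > 0")
  nyq <- 1 / (2 * tr_seconds)
  sin_df <- signal_spec$sinusoids
  if (!is.null(sin_df) && any(sin_df$freq >= nyq)) {
    stop_input("configuration error: sinusoid frequency >= Nyquist (%.3f Hz)", nyq)
  }
  f <- signal_spec$global_fraction %||% 0
  if (f < 0 || f > 1) stop_input("configuration error: global_fraction must be in [0, 1]")
  noise_sd <- signal_spec$noise_sd %||% 1

  set.seed(as.integer(seed))
  V <- n_voxels_per_axis^3
  t_sec <- (seq_len(n_timepoints) - 1L) * tr_seconds
  shared <- rep(0, n_timepoints)
  if (!is.null(sin_df)) {
    for (i in seq_len(nrow(sin_df))) {
      shared <- shared + sin_df$amplitude[i] * sin(2 * pi * sin_df$freq[i] * t_sec)
    }
  }
  glob <- stats::rnorm(n_timepoints)
  eps <- matrix(stats::rnorm(V * n_timepoints), V, n_timepoints)
  ts <- matrix(shared, V, n_timepoints, byrow = TRUE) +
    noise_sd * (sqrt(f) * matrix(glob, V, n_timepoints, byrow = TRUE) +
                  sqrt(1 - f) * eps)
  bold <- array(t(ts), dim = c(n_timepoints, rep(n_voxels_per_axis, 3)))
  bold <- aperm(bold, c(2, 3, 4, 1))

  # Friston-24 expansion: 6 motion parameters, their one-volume lags, squares
  mot <- sapply(1:6, function(i) cumsum(stats::rnorm(n_timepoints, 0, 0.02)))
  colnames(mot) <- c(paste0("trans_", c("x", "y", "z")),
                     paste0("rot_", c("x", "y", "z")))
  lag1 <- rbind(0, mot[-n_timepoints, , drop = FALSE])
  colnames(lag1) <- paste0(colnames(mot), "_lag")
  conf <- data.frame(mot, lag1, mot^2, lag1^2, check.names = FALSE)
  names(conf)[13:18] <- paste0(colnames(mot), "_sq")
  names(conf)[19:24] <- paste0(colnames(mot), "_lag_sq")
  conf$wm_signal <- as.vector(stats::filter(stats::rnorm(n_timepoints), 0.6,
                                            method = "recursive"))
  conf$csf_signal <- as.vector(stats::filter(stats::rnorm(n_timepoints), 0.6,
                                             method = "recursive"))
  list(bold = bold, confounds = conf, tr = tr_seconds)
}
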