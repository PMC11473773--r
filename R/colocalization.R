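# Subject-level spatial colocalization between parcel-wise rsfMRI deviation
# maps and receptor distribution maps.
#
# Each postpartum subject's map is expressed as parcel-wise Z scores against
# the nulliparous reference, (PP - mean(NP)) / sd(NP), and correlated across
# parcels with each receptor map (Spearman). Group inference permutes the
# PP/NP labels and recomputes the Z maps against each permuted reference --
# required for exchangeability, because the Z transform itself depends on
# group membership. Exact p values come from the permutation rank; normal-
# approximation p values from a Gaussian fitted to the null, which supports
# rank-based FDR at resolution finer than 1/(B+1).

#' Parcel-wise Z maps of postpartum subjects against the nulliparous reference
#'
#' Per parcel `p` and postpartum scan: `z_p = (x_p - mean_NP,p) / sd_NP,p`
#' with the sample SD (denominator n-1) over nulliparous scans. Parcels with
#' zero reference SD are flagged missing (NA) and excluded pairwise
#' downstream.
#'
#' @param pp_maps postpartum scans x parcels matrix.
#' @param np_maps nulliparous scans x parcels matrix (>= 3 scans).
#' @return Matrix of Z scores (same shape as `pp_maps`) with attribute
#'   `missing_parcels`.
#' @export
reference_z_maps <- function(pp_maps, np_maps) {
  if (ncol(pp_maps) != ncol(np_maps)) {
    stop_input("PP and NP maps must share the parcel set")
  }
  if (nrow(np_maps) < 3L) stop_input("need >= 3 reference (NP) scans")
  mu <- colMeans(np_maps)
  sdv <- apply(np_maps, 2L, stats::sd)
  bad <- sdv == 0 | is.na(sdv)
  sdv[bad] <- NA_real_
  z <- sweep(sweep(pp_maps, 2L, mu, "-"), 2L, sdv, "/")
  attr(z, "missing_parcels") <- which(bad)
  z
}

#' Spearman correlation between a subject Z map and a receptor map
#'
#' Average-rank ties; pairwise-complete parcels; requires at least 8 shared
#' non-missing parcels. Returns the correlation and its Fisher
#' transform `atanh(rho)` (rho clipped away from +-1).
#'
#' @param zmap numeric parcel vector.
#' @param receptor numeric parcel vector.
#' @return List with `rho` and `z_rho`, or both `NA` (with a warning) when
#'   either input is constant.
#' @export
spatial_spearman <- function(zmap, receptor) {
  ok <- !is.na(zmap) & !is.na(receptor)
  if (sum(ok) < 8L) stop_input("need >= 8 shared non-missing parcels")
  if (stats::sd(zmap[ok]) == 0 || stats::sd(receptor[ok]) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(list(rho = NA_real_, z_rho = NA_real_))
  }
  rho <- stats::cor(zmap[ok], receptor[ok], method = "spearman")
  list(rho = rho, z_rho = atanh(clip_rho(rho)))
}

# mean Fisher-Z Spearman per receptor for a PP/NP split (fast matrix path);
# rows of `maps` indexed by pp_idx / np_idx. `atlas_ranked` is the
# rank-standardized atlas over the full parcel set; it is re-ranked when
# zero-SD parcels are dropped so that ranks refer to the parcels in use.
coloc_stat <- function(maps, pp_idx, np_idx, atlas, atlas_ranked) {
  mu <- colMeans(maps[np_idx, , drop = FALSE])
  sdv <- sqrt(colSums(sweep(maps[np_idx, , drop = FALSE], 2L, mu)^2) /
                (length(np_idx) - 1L))
  keep <- sdv > 0
  z <- sweep(sweep(maps[pp_idx, keep, drop = FALSE], 2L, mu[keep], "-"),
             2L, sdv[keep], "/")
  ar <- if (all(keep)) atlas_ranked else
    rank_standardize_cols(atlas[keep, , drop = FALSE])
  zr <- standardize_rows(rank_rows(z))
  rho <- zr %*% ar / (sum(keep) - 1L)
  z_rho <- atanh(clip_rho(rho))
  list(mean_z_rho = colMeans(z_rho), scores = z_rho)
}

# column-wise rank transform, then center/scale (sd with denominator n-1)
rank_standardize_cols <- function(m) {
  rk <- apply(m, 2L, rank, ties.method = "average")
  sc <- scale(rk)
  attr(sc, "scaled:center") <- attr(sc, "scaled:scale") <- NULL
  sc
}

#' Fit a Gaussian to a permutation null and return a two-sided p value
#'
#' @param null_values numeric permutation null (>= 100 values).
#' @param observed observed statistic.
#' @return `p_norm = 2 * (1 - pnorm(|observed - mean| / sd))`, floored away
#'   from exactly zero.
#' @export
fit_null_gaussian <- function(null_values, observed) {
  if (length(null_values) < 100L) stop_input("need >= 100 null values")
  s <- stats::sd(null_values)
  if (s == 0) stop_input("null distribution has zero SD")
  p <- 2 * stats::pnorm(-abs(observed - mean(null_values)) / s)
  max(p, .Machine$double.xmin)
}

#' Group-level colocalization test with permutation nulls
#'
#' The observed statistic per receptor is the mean over postpartum subjects
#' of Fisher-transformed Spearman correlations between subject Z maps and the
#' receptor map. The null shuffles the PP/NP labels and recomputes Z maps
#' against each permuted reference. Two-sided `p_exact` by rank of
#' `|statistic - null mean|` with the +1 correction (exact enumeration when
#' the number of distinct label splits does not exceed `n_perm`); `p_norm`
#' from a Gaussian fit to the null; `q` by Benjamini-Hochberg over the
#' receptors tested here.
#'
#' @param pp_maps,np_maps scans x parcels matrices (>= 3 scans each).
#' @param atlas parcels x receptors matrix with receptor column names.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return A data.frame with one row per receptor: `receptor`, `mean_z_rho`,
#'   `null_mean`, `null_sd`, `n_perm`, `p_exact`, `p_norm`, `q`; per-subject
#'   Fisher-Z scores in attribute `scores`; `exhaustive` flag in attribute.
#' @export
coloc_group_test <- function(pp_maps, np_maps, atlas, n_perm = 10000,
                             seed = 1L) {
  if (nrow(pp_maps) < 3L || nrow(np_maps) < 3L) {
    stop_input("need >= 3 scans per group")
  }
  if (ncol(pp_maps) != nrow(atlas)) {
    stop_input("atlas has %d parcels but maps have %d", nrow(atlas),
               ncol(pp_maps))
  }
  atlas <- as.matrix(atlas)
  maps <- rbind(pp_maps, np_maps)
  n <- nrow(maps)
  n_pp <- nrow(pp_maps)
  n_np <- nrow(np_maps)
  atlas_ranked <- rank_standardize_cols(atlas)
  obs <- coloc_stat(maps, seq_len(n_pp), n_pp + seq_len(n_np), atlas, atlas_ranked)

  exhaustive <- choose(n, n_np) <= n_perm
  if (exhaustive) {
    splits <- utils::combn(n, n_np)
    B <- ncol(splits)
  } else {
    B <- n_perm
  }
  set.seed(as.integer(seed))
  null_stats <- matrix(NA_real_, B, ncol(atlas),
                       dimnames = list(NULL, colnames(atlas)))
  for (b in seq_len(B)) {
    np_b <- if (exhaustive) splits[, b] else sample.int(n, n_np)
    null_stats[b, ] <- coloc_stat(maps, setdiff(seq_len(n), np_b), np_b,
                                  atlas, atlas_ranked)$mean_z_rho
  }
  null_mu <- colMeans(null_stats)
  null_sd <- apply(null_stats, 2L, stats::sd)
  p_exact <- p_norm <- numeric(ncol(atlas))
  for (r in seq_len(ncol(atlas))) {
    dev_obs <- abs(obs$mean_z_rho[r] - null_mu[r])
    dev_null <- abs(null_stats[, r] - null_mu[r])
    p_exact[r] <- if (exhaustive) {
      mean(dev_null >= dev_obs - 1e-12)
    } else {
      (1 + sum(dev_null >= dev_obs)) / (1 + B)
    }
    # the Gaussian approximation needs a reasonably sized null
    p_norm[r] <- if (B >= 100L) {
      fit_null_gaussian(null_stats[, r], obs$mean_z_rho[r])
    } else NA_real_
  }
  out <- data.frame(receptor = colnames(atlas), mean_z_rho = obs$mean_z_rho,
                    null_mean = null_mu, null_sd = null_sd, n_perm = B,
                    p_exact = p_exact, p_norm = p_norm,
                    q = stats::p.adjust(p_norm, method = "BH"),
                    row.names = NULL)
  attr(out, "scores") <- obs$scores
  attr(out, "exhaustive") <- exhaustive
  out
}

#' Multivariate variance explained by a receptor set
#'
#' Per postpartum subject, OLS of the rank-transformed Z map on the
#' rank-transformed receptor subset (consistent with the Spearman univariate
#' analyses; set `rank_transform = FALSE` for the raw scale). The group
#' statistic is the mean R-squared; `p_exact` comes from PP/NP label
#' permutation with Z maps recomputed per shuffle.
#'
#' @param pp_maps,np_maps scans x parcels matrices.
#' @param atlas parcels x receptors matrix.
#' @param receptors receptor names to use (default all columns).
#' @param n_perm permutations for `p_exact` (0 skips inference).
#' @param seed integer seed.
#' @param rank_transform rank-transform predictors and response first.
#' @return List with `r2` (per subject), `mean_r2`, `p_exact`, `receptors`.
#' @export
multivar_coloc_r2 <- function(pp_maps, np_maps, atlas, receptors = colnames(atlas),
                              n_perm = 1000, seed = 1L, rank_transform = TRUE) {
  atlas <- as.matrix(atlas)
  sub <- atlas[, receptors, drop = FALSE]
  if (nrow(sub) <= ncol(sub) + 1L) stop_input("need parcels > receptors + 1")
  kappa_x <- kappa(scale(sub))
  if (kappa_x > 1e8) {
    stop_input("collinear receptor subset (condition number %.3g)", kappa_x)
  }
  maps <- rbind(pp_maps, np_maps)
  n_pp <- nrow(pp_maps)
  n_np <- nrow(np_maps)
  n <- n_pp + n_np

  r2_stat <- function(pp_idx, np_idx) {
    mu <- colMeans(maps[np_idx, , drop = FALSE])
    sdv <- sqrt(colSums(sweep(maps[np_idx, , drop = FALSE], 2L, mu)^2) /
                  (length(np_idx) - 1L))
    keep <- sdv > 0
    z <- sweep(sweep(maps[pp_idx, keep, drop = FALSE], 2L, mu[keep], "-"),
               2L, sdv[keep], "/")
    Xr <- if (rank_transform) apply(sub[keep, , drop = FALSE], 2L, rank) else
      sub[keep, , drop = FALSE]
    Q <- qr.Q(qr(cbind(1, scale(Xr))))
    Y <- if (rank_transform) rank_rows(z) else z
    Yc <- Y - rowMeans(Y)
    fitted <- tcrossprod(Yc %*% Q[, -1L, drop = FALSE], Q[, -1L, drop = FALSE])
    r2 <- rowSums(fitted^2) / rowSums(Yc^2)
    pmax(r2, 0)
  }

  r2_obs <- r2_stat(seq_len(n_pp), n_pp + seq_len(n_np))
  p_exact <- NA_real_
  if (n_perm > 0) {
    exhaustive <- choose(n, n_np) <= n_perm
    set.seed(as.integer(seed))
    B <- if (exhaustive) choose(n, n_np) else n_perm
    splits <- if (exhaustive) utils::combn(n, n_np) else NULL
    null_mean <- numeric(B)
    for (b in seq_len(B)) {
      np_b <- if (exhaustive) splits[, b] else sample.int(n, n_np)
      null_mean[b] <- mean(r2_stat(setdiff(seq_len(n), np_b), np_b))
    }
    p_exact <- if (exhaustive) mean(null_mean >= mean(r2_obs) - 1e-12) else
      (1 + sum(null_mean >= mean(r2_obs))) / (1 + B)
  }
  list(r2 = as.numeric(r2_obs), mean_r2 = mean(r2_obs), p_exact = p_exact,
       receptors = receptors)
}

#' Spearman cross-correlation matrix between receptor maps
#'
#' @param atlas parcels x receptors matrix.
#' @return Symmetric receptors x receptors Spearman matrix with unit diagonal.
#' @export
receptor_cross_correlation <- function(atlas) {
  if (ncol(atlas) < 2L) stop_input("need >= 2 receptors")
  stats::cor(atlas, method = "spearman")
}

#' Spatial comparison of two parcel-level statistic maps
#'
#' Spearman correlation across parcels with a parcel-label permutation null.
#' The null permutes parcel identities without preserving spatial
#' autocorrelation, a documented simplification at parcel resolution.
#'
#' @param map_a,map_b numeric parcel vectors over the same parcel set.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return List with `rho`, `p_exact`, `n_perm`.
#' @export
compare_stat_maps <- function(map_a, map_b, n_perm = 10000, seed = 1L) {
  ok <- !is.na(map_a) & !is.na(map_b)
  if (sum(ok) < 8L) stop_input("need >= 8 shared parcels")
  a <- rank(map_a[ok])
  b <- rank(map_b[ok])
  rho <- stats::cor(a, b)
  set.seed(as.integer(seed))
  null_rho <- vapply(seq_len(n_perm),
                     function(b_) stats::cor(a, b[sample.int(length(b))]),
                     numeric(1))
  p_exact <- (1 + sum(abs(null_rho) >= abs(rho) - 1e-12)) / (1 + n_perm)
  list(rho = rho, p_exact = p_exact, n_perm = n_perm)
}
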