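# Voxel-wise group GLM and non-parametric cluster-mass inference.
#
# The group contrast (postpartum vs nulliparous) is tested per voxel in an
# OLS model with covariates; suprathreshold voxels are grouped into connected
# components and each component's mass (sum of |t| over member voxels) is
# compared against a permutation null of maximum cluster masses. With
# covariates, permutation follows the Freedman-Lane scheme: residuals from
# the covariates-only model are permuted and the full model is refit, which
# preserves the covariate structure under the null.

#' Group design for voxel-wise GLMs
#'
#' @param group character/factor per scan, `"PP"` or `"NP"`. The tested
#'   coefficient codes PP = 1, so the positive contrast is PP > NP.
#' @param covariates optional data.frame of numeric covariates (e.g. age).
#' @return A `group_design` object.
#' @export
group_design <- function(group, covariates = NULL) {
  group <- as.character(group)
  if (!all(group %in% c("PP", "NP"))) {
    stop_input("group must contain only 'PP' and 'NP'")
  }
  if (!any(group == "PP") || !any(group == "NP")) {
    stop_input("both groups must be non-empty")
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (anyNA(covariates)) stop_input("covariates contain missing values")
    if (nrow(covariates) != length(group)) {
      stop_input("covariates have %d rows for %d scans", nrow(covariates),
                 length(group))
    }
  }
  structure(list(group = group, covariates = covariates),
            class = "group_design")
}

design_matrix <- function(design) {
  X <- cbind(intercept = 1, group_pp = as.numeric(design$group == "PP"))
  if (!is.null(design$covariates)) X <- cbind(X, as.matrix(design$covariates))
  X
}

check_full_rank <- function(X) {
  if (qr(X)$rank < ncol(X)) {
    bad <- character(0)
    r_prev <- 0L
    for (j in seq_len(ncol(X))) {
      r <- qr(X[, seq_len(j), drop = FALSE])$rank
      if (r == r_prev) bad <- c(bad, colnames(X)[j] %||% paste0("col", j))
      r_prev <- r
    }
    stop_input("collinear design; offending column(s): %s",
               paste(bad, collapse = ", "))
  }
  invisible(X)
}

# t statistics for the group coefficient, all voxels at once
glm_group_t <- function(Y, X, qrX = qr(X), gcol = 2L) {
  n <- nrow(X); p <- ncol(X)
  B <- qr.coef(qrX, Y)
  resid <- Y - X %*% B
  sigma2 <- colSums(resid^2) / (n - p)
  xtxinv_gg <- chol2inv(qr.R(qrX))[gcol, gcol]
  tval <- B[gcol, ] / sqrt(sigma2 * xtxinv_gg)
  tval[!is.finite(tval)] <- 0
  tval
}

#' Voxel-wise GLM group t map
#'
#' Per voxel, OLS fit of `value ~ intercept + group + covariates`; returns the
#' t statistic for the group (PP vs NP) coefficient.
#'
#' @param maps scans x voxels matrix.
#' @param design a [group_design()] object.
#' @return List with `t` (numeric per voxel) and `dof` (`n - p`).
#' @export
fit_voxel_glm <- function(maps, design) {
  stopifnot(inherits(design, "group_design"))
  X <- design_matrix(design)
  if (nrow(maps) != nrow(X)) {
    stop_input("maps have %d scans but design has %d", nrow(maps), nrow(X))
  }
  if (nrow(X) < ncol(X) + 2L) stop_input("too few scans for the design")
  check_full_rank(X)
  list(t = glm_group_t(maps, X), dof = nrow(X) - ncol(X))
}

neighbor_offsets <- function(connectivity) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[rowSums(abs(g)) > 0, ]
  keep <- switch(as.character(connectivity),
                 "6" = rowSums(abs(g)) == 1,
                 "18" = rowSums(abs(g)) <= 2,
                 "26" = rep(TRUE, nrow(g)),
                 stop_input("connectivity must be 6, 18 or 26"))
  as.matrix(g[keep, ])
}

# connected components among voxel linear indices `idx` on a grid `dims`
find_components <- function(idx, dims, connectivity = 26) {
  if (length(idx) == 0L) return(list())
  off <- neighbor_offsets(connectivity)
  coords <- arrayInd(idx, dims)
  pos <- integer(prod(dims))
  pos[idx] <- seq_along(idx)
  comp <- integer(length(idx))
  ncomp <- 0L
  for (s in seq_along(idx)) {
    if (comp[s] != 0L) next
    ncomp <- ncomp + 1L
    stack <- s
    comp[s] <- ncomp
    while (length(stack) > 0L) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      nb <- off + matrix(coords[v, ], nrow(off), 3, byrow = TRUE)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      if (!any(ok)) next
      lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * dims[1] +
        (nb[ok, 3] - 1L) * dims[1] * dims[2]
      j <- pos[lin]
      j <- j[j > 0L]
      j <- j[comp[j] == 0L]
      if (length(j) > 0L) {
        comp[j] <- ncomp
        stack <- c(stack, j)
      }
    }
  }
  split(idx, comp)
}

# maximum cluster mass in one direction for a t map (internal, fast path)
max_cluster_mass <- function(tval, thr, dims, connectivity, direction) {
  idx <- if (direction == "positive") which(tval > thr) else which(tval < -thr)
  if (length(idx) == 0L) return(0)
  comps <- find_components(idx, dims, connectivity)
  max(vapply(comps, function(ii) sum(abs(tval[ii])), numeric(1)))
}

#' Extract suprathreshold clusters from a t map
#'
#' Voxels exceeding the one-sided threshold implied by `voxel_p` in the
#' requested direction are grouped into connected components. Cluster mass is
#' the sum of `|t|` over member voxels.
#'
#' @param tmap numeric t values, one per voxel (vector or 3D array).
#' @param dof GLM degrees of freedom.
#' @param voxel_p one-sided voxel-level p threshold.
#' @param direction `"positive"` (PP > NP) or `"negative"`.
#' @param connectivity 6, 18 or 26 (3D neighborhood).
#' @param dims grid dimensions; taken from `tmap` when it is an array.
#' @param voxel_size voxel edge lengths in mm.
#' @return List of clusters, sorted by mass descending; each has `voxels`
#'   (linear indices), `mass`, `extent_mm3`, `peak` (grid coordinates of the
#'   peak |t| voxel) and `peak_t`.
#' @export
extract_clusters <- function(tmap, dof, voxel_p = 0.01,
                             direction = c("positive", "negative"),
                             connectivity = 26, dims = NULL,
                             voxel_size = c(3, 3, 3)) {
  direction <- match.arg(direction)
  if (is.array(tmap) && length(dim(tmap)) == 3L) {
    dims <- dim(tmap)
    tval <- as.vector(tmap)
  } else {
    tval <- as.numeric(tmap)
    if (is.null(dims)) dims <- c(length(tval), 1L, 1L)
  }
  thr <- stats::qt(1 - voxel_p, dof)
  idx <- if (direction == "positive") which(tval > thr) else which(tval < -thr)
  comps <- find_components(idx, dims, connectivity)
  clusters <- lapply(comps, function(ii) {
    peak <- ii[which.max(abs(tval[ii]))]
    list(voxels = ii, mass = sum(abs(tval[ii])),
         extent_mm3 = length(ii) * prod(voxel_size),
         peak = arrayInd(peak, dims)[1, ], peak_t = tval[peak])
  })
  clusters <- clusters[order(-vapply(clusters, `[[`, numeric(1), "mass"))]
  unname(clusters)
}

#' Cluster-mass permutation test for a group contrast
#'
#' Builds the null distribution of the maximum cluster mass under group-label
#' permutation (Freedman-Lane residual permutation when covariates are
#' present) and assigns each observed cluster a family-wise-error corrected
#' p value, separately for the positive (PP > NP) and negative contrasts.
#' With a covariate-free design and fewer distinct group assignments than
#' `n_perm`, all assignments are enumerated exhaustively (with a message) and
#' p values are exact proportions; otherwise p = (1 + #{null >= mass}) /
#' (1 + n_perm).
#'
#' @param maps scans x voxels matrix.
#' @param design a [group_design()] object.
#' @param dims 3D grid dimensions with `prod(dims) == ncol(maps)`.
#' @param voxel_p one-sided voxel-level threshold.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param connectivity 6, 18 or 26.
#' @param voxel_size voxel edge lengths in mm.
#' @return A `cluster_result` list: per direction a list of clusters (each
#'   with `p_fwe`), plus the null maxima, `dof`, and run metadata.
#' @export
cluster_mass_permutation <- function(maps, design, dims, voxel_p = 0.01,
                                     n_perm = 10000, seed = 1L,
                                     connectivity = 26,
                                     voxel_size = c(3, 3, 3)) {
  stopifnot(inherits(design, "group_design"))
  if (n_perm < 100) stop_input("n_perm must be >= 100")
  if (prod(dims) != ncol(maps)) {
    stop_input("prod(dims) = %d does not match %d voxels", prod(dims), ncol(maps))
  }
  X <- design_matrix(design)
  check_full_rank(X)
  qrX <- qr(X)
  n <- nrow(X)
  dof <- n - ncol(X)
  thr <- stats::qt(1 - voxel_p, dof)
  t_obs <- glm_group_t(maps, X, qrX)
  observed <- list(
    positive = extract_clusters(t_obs, dof, voxel_p, "positive", connectivity,
                                dims, voxel_size),
    negative = extract_clusters(t_obs, dof, voxel_p, "negative", connectivity,
                                dims, voxel_size))

  has_cov <- !is.null(design$covariates)
  n_pp <- sum(design$group == "PP")
  exhaustive <- !has_cov && choose(n, n_pp) <= n_perm
  if (exhaustive) {
    message(sprintf("enumerating all %d distinct group assignments exhaustively",
                    choose(n, n_pp)))
    splits <- utils::combn(n, n_pp)
    B <- ncol(splits)
  } else {
    B <- n_perm
  }

  if (has_cov) {
    # Freedman-Lane: permute residuals of the covariates-only model
    Z <- X[, -2L, drop = FALSE]
    qrZ <- qr(Z)
    E <- qr.resid(qrZ, maps)
    Fz <- maps - E
  }

  set.seed(as.integer(seed))
  null_max <- matrix(0, B, 2L, dimnames = list(NULL, c("positive", "negative")))
  g_num <- as.numeric(design$group == "PP")
  for (b in seq_len(B)) {
    if (exhaustive) {
      gb <- numeric(n)
      gb[splits[, b]] <- 1
      Xb <- X
      Xb[, 2L] <- gb
      tb <- glm_group_t(maps, Xb)
    } else if (has_cov) {
      Yb <- Fz + E[sample.int(n), , drop = FALSE]
      tb <- glm_group_t(Yb, X, qrX)
    } else {
      Xb <- X
      Xb[, 2L] <- g_num[sample.int(n)]
      tb <- glm_group_t(maps, Xb)
    }
    null_max[b, 1L] <- max_cluster_mass(tb, thr, dims, connectivity, "positive")
    null_max[b, 2L] <- max_cluster_mass(tb, thr, dims, connectivity, "negative")
  }

  for (dir in c("positive", "negative")) {
    for (i in seq_along(observed[[dir]])) {
      m <- observed[[dir]][[i]]$mass
      if (exhaustive) {
        observed[[dir]][[i]]$p_fwe <- mean(null_max[, dir] >= m)
      } else {
        observed[[dir]][[i]]$p_fwe <- (1 + sum(null_max[, dir] >= m)) / (1 + B)
      }
    }
  }
  structure(list(clusters = observed, null_max = null_max, dof = dof,
                 n_perm = B, voxel_p = voxel_p, seed = seed,
                 connectivity = connectivity, exhaustive = exhaustive),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  for (dir in c("positive", "negative")) {
    cl <- x$clusters[[dir]]
    cat(sprintf("%s contrast: %d cluster(s)\n", dir, length(cl)))
    for (i in seq_along(cl)) {
      cat(sprintf("  #%d mass %.1f, %d voxels, p_fwe %.4g\n", i, cl[[i]]$mass,
                  length(cl[[i]]$voxels), cl[[i]]$p_fwe))
    }
  }
  invisible(x)
}

#' Average map values within clusters, per scan
#'
#' @param maps scans x voxels matrix (any sessions).
#' @param clusters list of clusters (from [extract_clusters()] or a
#'   `cluster_result` direction) or a list of voxel-index vectors.
#' @param names optional cluster column names.
#' @return scans x clusters matrix of within-cluster means.
#' @export
extract_cluster_means <- function(maps, clusters, names = NULL) {
  masks <- lapply(clusters, function(cl) if (is.list(cl)) cl$voxels else cl)
  if (any(vapply(masks, max, numeric(1)) > ncol(maps))) {
    stop_input("cluster voxel indices exceed the map grid (%d voxels)", ncol(maps))
  }
  out <- vapply(masks, function(ii) rowMeans(maps[, ii, drop = FALSE]),
                numeric(nrow(maps)))
  out <- matrix(out, nrow = nrow(maps),
                dimnames = list(rownames(maps),
                                names %||% paste0("cluster", seq_along(masks))))
  out
}
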