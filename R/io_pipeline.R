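# Readers/writers for the interchange formats (TSV tables, NIfTI volumes)
# and the pipeline orchestrator tying the stages together:
# simulate -> (voxel expansion) -> cluster inference -> cluster extraction ->
# colocalization -> longitudinal statistics. All tabular interchange uses
# tab-separated UTF-8 with a header row; volumes use NIfTI-1.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  utils::read.delim(path, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Read a session/study table
#'
#' @param path TSV with one row per scan; must contain `subject_id`, `group`,
#'   `session`, `week`.
#' @return data.frame.
#' @export
read_study_table <- function(path) {
  tab <- read_tsv(path)
  assert_columns(tab, c("subject_id", "group", "session", "week"),
                 sprintf("study table '%s'", path))
  tab
}

#' Write a study table to TSV
#' @param tab data.frame.
#' @param path output path.
#' @export
write_study_table <- function(tab, path) write_tsv(tab, path)

#' Write a parcel-map matrix (scans x parcels) to TSV
#' @param maps matrix with scan ids as rownames.
#' @param path output path.
#' @export
write_parcel_maps <- function(maps, path) {
  df <- data.frame(scan_id = rownames(maps), maps, check.names = FALSE)
  write_tsv(df, path)
}

#' Read a parcel-map matrix from TSV
#' @param path TSV written by [write_parcel_maps()].
#' @return Numeric matrix with scan ids as rownames.
#' @export
read_parcel_maps <- function(path) {
  df <- read_tsv(path)
  assert_columns(df, "scan_id", sprintf("parcel map table '%s'", path))
  m <- as.matrix(df[, setdiff(names(df), "scan_id"), drop = FALSE])
  rownames(m) <- df$scan_id
  m
}

#' Write / read a receptor atlas (parcels x receptors) as TSV
#' @param atlas matrix with parcel rownames and receptor colnames.
#' @param path file path.
#' @export
write_receptor_atlas <- function(atlas, path) {
  df <- data.frame(parcel = rownames(atlas), atlas, check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_receptor_atlas
#' @export
read_receptor_atlas <- function(path) {
  df <- read_tsv(path)
  assert_columns(df, "parcel", sprintf("receptor atlas '%s'", path))
  m <- as.matrix(df[, setdiff(names(df), "parcel"), drop = FALSE])
  rownames(m) <- df$parcel
  m
}

#' Read a 4D BOLD NIfTI into a voxel time-series object
#'
#' @param path NIfTI-1 file (.nii or .nii.gz).
#' @param tr repetition time in seconds; taken from the header when `NULL`.
#' @param mask optional logical voxel mask.
#' @return A `voxel_ts` object.
#' @export
read_bold <- function(path, tr = NULL, mask = NULL) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L) stop_input("%s is not a 4D volume", path)
  pix <- RNifti::pixdim(img)
  voxel_timeseries(unclass(img)[, , , , drop = FALSE],
                   tr = tr %||% pix[4], voxel_size = pix[1:3], mask = mask)
}

#' Read a parcellation label volume with its lookup table
#'
#' @param path NIfTI label volume (integer parcel ids, 0 outside).
#' @param lut_path TSV with columns `id`, `name` (optionally `subcortical`).
#' @return List with `labels` (integer vector), `dims`, `lut`.
#' @export
read_atlas_volume <- function(path, lut_path) {
  img <- RNifti::readNifti(path)
  if (!length(dim(img)) %in% c(3L, 4L)) stop_input("%s is not a 3D volume", path)
  lut <- read_tsv(lut_path)
  assert_columns(lut, c("id", "name"), sprintf("parcel lookup '%s'", lut_path))
  list(labels = as.integer(round(as.vector(img))), dims = dim(img)[1:3],
       lut = lut)
}

#' Write a voxel map as a NIfTI volume
#' @param vmap a `voxel_map` (from the metric functions).
#' @param path output path (.nii or .nii.gz).
#' @export
write_voxel_map <- function(vmap, path) {
  stopifnot(inherits(vmap, "voxel_map"))
  arr <- array(vmap$values, dim = vmap$dims)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vmap$voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Arrange parcels as cubic blocks on a 3D grid
#'
#' Gives parcel-level synthetic data a spatial embedding so that the
#' voxel-level cluster inference can operate on contiguous parcel blocks.
#' Parcels are laid out in raster order as `block^3`-voxel cubes on the
#' smallest near-cubic lattice that holds them; unused blocks get label 0.
#'
#' @param n_parcels number of parcels.
#' @param block block edge length in voxels.
#' @return List with `labels` (integer vector), `dims`.
#' @export
parcel_layout_volume <- function(n_parcels, block = 2L) {
  nb <- ceiling(n_parcels^(1 / 3))
  bx <- nb
  by <- ceiling(sqrt(n_parcels / nb))
  bz <- ceiling(n_parcels / (bx * by))
  dims <- c(bx, by, bz) * block
  labels <- integer(prod(dims))
  coords <- arrayInd(seq_len(prod(dims)), dims)
  bcoord <- (coords - 1L) %/% block
  bid <- bcoord[, 1] + bcoord[, 2] * bx + bcoord[, 3] * bx * by + 1L
  labels[bid <= n_parcels] <- bid[bid <= n_parcels]
  list(labels = labels, dims = dims)
}

# expand parcel maps (scans x parcels) to voxel maps on a block layout,
# adding voxel-level noise
expand_parcels_to_voxels <- function(parcel_maps, layout, voxel_noise_sd = 0.1,
                                     seed = 1L) {
  set.seed(as.integer(seed))
  V <- length(layout$labels)
  out <- matrix(0, nrow(parcel_maps), V,
                dimnames = list(rownames(parcel_maps), NULL))
  inside <- layout$labels > 0L
  out[, inside] <- parcel_maps[, layout$labels[inside], drop = FALSE]
  out <- out + matrix(stats::rnorm(length(out), 0, voxel_noise_sd), nrow(out))
  out
}

#' Pipeline configuration
#'
#' @param out_dir output directory.
#' @param seed root seed; per-stage seeds are derived as named substreams.
#' @param synth a [synth_config()] (its seed is overridden by the root seed's
#'   "simulate" substream).
#' @param stages named logical vector toggling `simulate`, `clusters`,
#'   `coloc`, `longitudinal`.
#' @param n_perm_cluster,n_perm_coloc permutation counts.
#' @param voxel_p voxel-level threshold for cluster inference.
#' @param connectivity cluster connectivity (6/18/26).
#' @param block parcel block edge for the voxel embedding.
#' @param voxel_noise_sd within-parcel voxel noise for the embedding.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, synth = synth_config(),
                            stages = c(simulate = TRUE, clusters = TRUE,
                                       coloc = TRUE, longitudinal = TRUE),
                            n_perm_cluster = 500, n_perm_coloc = 1000,
                            voxel_p = 0.01, connectivity = 26, block = 2L,
                            voxel_noise_sd = 0.1) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), synth = synth,
                 stages = stages, n_perm_cluster = n_perm_cluster,
                 n_perm_coloc = n_perm_coloc, voxel_p = voxel_p,
                 connectivity = connectivity, block = block,
                 voxel_noise_sd = voxel_noise_sd),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(config, force = TRUE,
                                           auto_unbox = TRUE, digits = NA)),
             tmp)
  unname(tools::md5sum(tmp))
}

#' Run the synthetic end-to-end analysis pipeline
#'
#' Executes the toggled stages in order and writes all stage outputs plus a
#' run manifest (config hash, per-stage seeds, output checksums) to
#' `config$out_dir`. Re-running with the same configuration reproduces the
#' deterministic outputs bit for bit.
#'
#' @param config a [pipeline_config()].
#' @return The manifest (invisibly), with stage results attached as
#'   attribute `results`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- config$stages
  seeds <- list(simulate = substream_seed(config$seed, "simulate"),
                clusters = substream_seed(config$seed, "clusters"),
                voxels = substream_seed(config$seed, "voxels"),
                coloc = substream_seed(config$seed, "coloc"),
                longitudinal = substream_seed(config$seed, "longitudinal"))
  results <- list()

  synth <- config$synth
  synth$seed <- seeds$simulate
  study <- generate_study(synth)
  tab <- study$study_table
  if (isTRUE(st[["simulate"]])) {
    write_study_table(tab, file.path(config$out_dir, "study_table.tsv"))
    for (m in names(study$parcel_maps)) {
      write_parcel_maps(study$parcel_maps[[m]],
                        file.path(config$out_dir, paste0("parcel_maps_", m, ".tsv")))
    }
    write_receptor_atlas(study$receptor_atlas,
                         file.path(config$out_dir, "receptor_atlas.tsv"))
    jsonlite::write_json(study$truth, file.path(config$out_dir, "truth.json"),
                         force = TRUE, auto_unbox = TRUE, digits = NA)
  }
  results$study <- study

  long_tab <- tab
  cluster_cols <- character(0)
  if (isTRUE(st[["clusters"]])) {
    layout <- parcel_layout_volume(ncol(study$parcel_maps[[1]]), config$block)
    baseline <- tab$session == "T0"
    cluster_rows <- list()
    for (m in names(study$parcel_maps)) {
      vox <- expand_parcels_to_voxels(study$parcel_maps[[m]], layout,
                                      config$voxel_noise_sd,
                                      substream_seed(seeds$voxels, m))
      design <- group_design(tab$group[baseline],
                             covariates = data.frame(age = tab$age[baseline]))
      res <- cluster_mass_permutation(vox[baseline, , drop = FALSE], design,
                                      dims = layout$dims,
                                      voxel_p = config$voxel_p,
                                      n_perm = config$n_perm_cluster,
                                      seed = substream_seed(seeds$clusters, m),
                                      connectivity = config$connectivity)
      for (dir in c("positive", "negative")) {
        sig <- Filter(function(cl) cl$p_fwe < 0.05, res$clusters[[dir]])
        if (length(sig) == 0L) next
        nms <- sprintf("%s_%s%d", m, substr(dir, 1, 3), seq_along(sig))
        cm <- extract_cluster_means(vox, sig, names = nms)
        long_tab <- cbind(long_tab, cm[match(long_tab$scan_id, rownames(cm)), ,
                                       drop = FALSE])
        cluster_cols <- c(cluster_cols, nms)
        for (i in seq_along(sig)) {
          cluster_rows[[length(cluster_rows) + 1L]] <- data.frame(
            metric = m, contrast = dir, name = nms[i], mass = sig[[i]]$mass,
            n_voxels = length(sig[[i]]$voxels),
            extent_mm3 = sig[[i]]$extent_mm3,
            neg_log10_p_fwe = -log10(sig[[i]]$p_fwe))
        }
      }
      results$cluster_tests[[m]] <- res
    }
    if (length(cluster_rows) > 0L) {
      write_tsv(do.call(rbind, cluster_rows),
                file.path(config$out_dir, "clusters.tsv"))
    }
    write_tsv(long_tab, file.path(config$out_dir, "long_table.tsv"))
  }
  results$cluster_cols <- cluster_cols
  results$long_table <- long_tab

  if (isTRUE(st[["coloc"]])) {
    pp0 <- tab$group == "PP" & tab$session == "T0"
    np0 <- tab$group == "NP"
    coloc_rows <- list()
    r2_rows <- list()
    for (m in names(study$parcel_maps)) {
      res <- coloc_group_test(study$parcel_maps[[m]][pp0, , drop = FALSE],
                              study$parcel_maps[[m]][np0, , drop = FALSE],
                              study$receptor_atlas,
                              n_perm = config$n_perm_coloc,
                              seed = substream_seed(seeds$coloc, m))
      res$metric <- m
      coloc_rows[[m]] <- res
      sig_rec <- res$receptor[res$q < 0.05]
      use_rec <- if (length(sig_rec) >= 2L) sig_rec else colnames(study$receptor_atlas)
      r2 <- multivar_coloc_r2(study$parcel_maps[[m]][pp0, , drop = FALSE],
                              study$parcel_maps[[m]][np0, , drop = FALSE],
                              study$receptor_atlas, receptors = use_rec,
                              n_perm = min(config$n_perm_coloc, 500),
                              seed = substream_seed(seeds$coloc, paste0(m, "_r2")))
      r2_rows[[m]] <- data.frame(metric = m, mean_r2 = r2$mean_r2,
                                 min_r2 = min(r2$r2), max_r2 = max(r2$r2),
                                 p_exact = r2$p_exact,
                                 receptors = paste(use_rec, collapse = ","))
    }
    coloc_tab <- do.call(rbind, coloc_rows)
    # one FDR family across all metric x receptor baseline tests
    coloc_tab$q <- fdr_correct(coloc_tab$p_norm)
    write_tsv(coloc_tab, file.path(config$out_dir, "coloc_baseline.tsv"))
    write_tsv(do.call(rbind, r2_rows),
              file.path(config$out_dir, "coloc_multivariate_r2.tsv"))
    utils::write.table(
      round(receptor_cross_correlation(study$receptor_atlas), 4),
      file.path(config$out_dir, "receptor_cross_correlation.tsv"),
      sep = "\t", quote = FALSE, col.names = NA)
    results$coloc <- coloc_tab
    results$r2 <- do.call(rbind, r2_rows)
  }

  if (isTRUE(st[["longitudinal"]]) && length(cluster_cols) > 0L) {
    anc <- list(); lmm_rows <- list(); inter_rows <- list()
    for (cc in cluster_cols) {
      a <- ancova_group_by_timepoint(long_tab, cc)
      if (!is.null(a)) { a$response <- cc; anc[[cc]] <- a }
      for (quad in c(FALSE, TRUE)) {
        f <- fit_lmm(long_tab[long_tab$group == "PP" & long_tab$longitudinal, ],
                     cc, quadratic = quad)
        if (!is.null(f$terms)) {
          tt <- f$terms[f$terms$term != "(Intercept)", ]
          tt$response <- cc
          tt$model <- if (quad) "linear+quadratic" else "linear"
          lmm_rows[[paste(cc, quad)]] <- tt
        }
      }
      # hormone x week interactions on the MRI measure
      ppl <- long_tab[long_tab$group == "PP" & long_tab$longitudinal, ]
      ppl$log_progesterone <- log(ppl$progesterone)
      ppl$log_estradiol <- log(ppl$estradiol)
      ppl$log_ratio <- ppl$log_progesterone - ppl$log_estradiol
      for (h in c("log_progesterone", "log_estradiol", "log_ratio")) {
        fi <- interaction_lmm(ppl, cc, h)
        if (!is.null(fi$terms)) {
          ir <- fi$terms[fi$terms$term == "interaction", ]
          ir$response <- cc; ir$predictor <- h
          inter_rows[[paste(cc, h)]] <- ir
        }
      }
      # MRI x week interactions on behavior
      for (bh in c("epds", "mpas_total")) {
        fi <- tryCatch(interaction_lmm(ppl, bh, cc), error = function(e) NULL)
        if (!is.null(fi) && !is.null(fi$terms)) {
          ir <- fi$terms[fi$terms$term == "interaction", ]
          ir$response <- bh; ir$predictor <- cc
          inter_rows[[paste(bh, cc)]] <- ir
        }
      }
    }
    if (length(anc) > 0L) {
      anc_tab <- do.call(rbind, anc)
      anc_tab$q <- fdr_correct(anc_tab$p)      # family: sessions x responses
      write_tsv(anc_tab, file.path(config$out_dir, "ancova_by_timepoint.tsv"))
      results$ancova <- anc_tab
    }
    if (length(lmm_rows) > 0L) {
      lmm_tab <- do.call(rbind, lmm_rows)
      lmm_tab$q <- fdr_correct(lmm_tab$p)      # family: LMM week terms
      write_tsv(lmm_tab, file.path(config$out_dir, "lmm_trajectories.tsv"))
      results$lmm <- lmm_tab
    }
    if (length(inter_rows) > 0L) {
      int_tab <- do.call(rbind, inter_rows)
      int_tab$q <- fdr_correct(int_tab$p)      # family: interaction LMMs
      write_tsv(int_tab, file.path(config$out_dir, "interaction_lmms.tsv"))
      results$interactions <- int_tab
    }
    gcor_cols <- grep("^GCOR_", cluster_cols, value = TRUE)
    if (length(gcor_cols) > 0L) {
      results$rtm <- rtm_check(
        long_tab[long_tab$group == "PP" & long_tab$longitudinal, ],
        gcor_cols[1], n_sim = 200,
        seed = substream_seed(seeds$longitudinal, "rtm"))
    }
  }

  out_files <- list.files(config$out_dir, full.names = TRUE)
  out_files <- out_files[!grepl("manifest\\.json$", out_files)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("maternalfc")),
    config_hash = config_hash(config),
    seeds = seeds,
    outputs = as.list(stats::setNames(unname(tools::md5sum(out_files)),
                                      basename(out_files))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       force = TRUE, auto_unbox = TRUE)
  attr(manifest, "results") <- results
  invisible(manifest)
}
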