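#' Pipeline configuration
#'
#' Assembles and validates the configuration of the end-to-end analysis:
#' either a synthetic-data generator parameter set or paths to existing
#' `fixations.tsv`/`aois.tsv`, plus the analysis window, grid, kernel
#' width, contrast list, permutation settings and thresholds. May be read
#' from a YAML file with the same field names.
#'
#' @param generator List of [generator_params()] arguments (used when
#'   `fixations_path` is `NULL`).
#' @param fixations_path,aois_path Input files for pre-existing data.
#' @param window Study-phase window rule.
#' @param grid_px,pixel_size Analysis grid (square), see [grid_spec()].
#' @param sigma Gaussian kernel SD in degrees.
#' @param map_contrasts List of `c(cond_a, cond_b)` race pairs for the
#'   density-map permutation tests.
#' @param aoi_contrasts Planned AOI contrast declarations, see
#'   [planned_contrasts()].
#' @param n_iter,alpha,q Permutation iterations, per-tail pixel threshold,
#'   FDR threshold.
#' @param seed Master seed (mandatory; all stages derive from it).
#' @param out_dir Output directory.
#' @return A validated `gc_config` list.
#' @export
pipeline_config <- function(generator = list(), fixations_path = NULL,
                            aois_path = NULL, window = "study_2_5",
                            grid_px = 64, pixel_size = 0.25, sigma = 0.3,
                            map_contrasts = list(c("caucasian", "african"),
                                                 c("caucasian", "chinese"),
                                                 c("african", "chinese")),
                            aoi_contrasts = default_contrasts(),
                            n_iter = 2000, alpha = 0.01, q = 0.05,
                            seed = NULL, out_dir = NULL) {
  if (is.null(seed)) stop("`seed` is mandatory")
  if (is.null(out_dir)) stop("`out_dir` is required")
  cfg <- list(generator = generator, fixations_path = fixations_path,
              aois_path = aois_path, window = window,
              grid_px = as.integer(grid_px), pixel_size = pixel_size,
              sigma = sigma, map_contrasts = map_contrasts,
              aoi_contrasts = aoi_contrasts, n_iter = as.integer(n_iter),
              alpha = alpha, q = q, seed = as.integer(seed),
              out_dir = out_dir)
  races <- if (is.null(cfg$fixations_path)) {
    gp <- utils::modifyList(list(seed = cfg$seed), cfg$generator)
    do.call(generator_params, gp)$races
  } else RACES
  for (ct in cfg$map_contrasts) {
    bad <- setdiff(ct, races)
    if (length(bad))
      stop("map contrast references undefined condition label(s): ",
           paste(bad, collapse = ", "))
  }
  structure(cfg, class = "gc_config")
}

#' @rdname pipeline_config
#' @param path YAML file with configuration fields.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/load, behavioural summary, AOI relative
#' frequencies and planned contrasts, and — per declared contrast — the
#' density-map permutation test with uncorrected and FDR-corrected
#' significance maps and profile p-values. All outputs are plain
#' tab-separated or JSON files under `config$out_dir`, and `manifest.json`
#' records every output file with its MD5 hash, the full configuration
#' echo and the package version, so re-running an identical configuration
#' is byte-identical. On failure the partial outputs are moved to a
#' `quarantine` subdirectory together with the error log.
#'
#' @param config A [pipeline_config()] (or YAML path).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  result <- tryCatch({
    # stage 1: data
    if (is.null(config$fixations_path)) {
      gp <- do.call(generator_params,
                    utils::modifyList(list(seed = config$seed), config$generator))
      ds <- generate_dataset(gp)
    } else {
      ds <- read_fixations(config$fixations_path, read_aois(config$aois_path))
    }
    write_fixations(ds, file.path(out, "fixations.tsv"))
    write_aois(ds$layouts, file.path(out, "aois.tsv"))
    files <- c(files, "fixations.tsv", "aois.tsv")

    # stage 2: behaviour (test phase, if present)
    if (any(ds$trials$phase == "test")) {
      beh <- behavior_summary(ds, by_start = TRUE)
      pooled <- behavior_summary(ds, by_start = FALSE)
      pooled$start_position <- "pooled"
      beh <- rbind(beh[names(pooled)], pooled)
      write_tsv(beh, file.path(out, "behavior_summary.tsv"))
      files <- c(files, "behavior_summary.tsv")
    }

    # stage 3: AOI analyses (long table keeps start position for external
    # ANOVA tools; contrasts run on the start-pooled table)
    rf_cells <- relative_frequencies(ds, "study", pool_start = FALSE,
                                     window = config$window)
    rf_pooled <- relative_frequencies(ds, "study", pool_start = TRUE,
                                      window = config$window)
    rf_cells$pooling <- "by_start"
    rf_pooled$start_position <- "pooled"
    rf_pooled$pooling <- "pooled"
    write_tsv(rbind(rf_cells[names(rf_pooled)], rf_pooled),
              file.path(out, "relfreq.tsv"))
    contr <- planned_contrasts(rf_pooled, config$aoi_contrasts)
    write_tsv(contr, file.path(out, "contrasts.tsv"))
    files <- c(files, "relfreq.tsv", "contrasts.tsv")

    # stage 4: density maps, statistical maps, profiles
    grid <- grid_spec(config$grid_px, config$grid_px, config$pixel_size)
    offs <- alignment_offsets(ds$layouts)
    msk <- face_mask(ds$layouts, offs, grid)
    sig_summary <- list()
    for (ct in config$map_contrasts) {
      tag <- paste0(ct[1], "_vs_", ct[2])
      pt <- permutation_test(ds, ct[1], ct[2], grid, config$sigma,
                             perm_config(config$n_iter,
                                         derive_seed(config$seed, 100),
                                         500),
                             window = config$window)
      unc <- threshold_pmap(pt$pmap, config$alpha)
      fdr <- fdr_correct(pt$pmap, msk, config$q)
      prof_y <- profile_pvalues(pt, "y")
      unc_y <- threshold_pmap(prof_y, 0.025)
      fdr_y <- fdr_correct(prof_y, NULL, config$q)
      fs <- c(write_map(pt$observed$values, grid, out, paste0("diff_", tag)),
              write_map(pt$pmap$p, grid, out, paste0("pvalues_", tag)),
              write_map(unc$mask * unc$tail_sign, grid, out,
                        paste0("sig_uncorrected_", tag)),
              write_map(fdr$mask * fdr$tail_sign, grid, out,
                        paste0("sig_fdr_", tag)),
              write_profile(prof_y, unc_y, fdr_y, out, paste0("profile_y_", tag)))
      files <- c(files, fs)
      sig_summary[[tag]] <- data.frame(
        contrast = tag, n_sig_uncorrected = sum(unc$mask),
        n_sig_fdr = sum(fdr$mask),
        n_sig_profile_y_uncorrected = sum(unc_y$mask),
        n_sig_profile_y_fdr = sum(fdr_y$mask))
    }
    write_tsv(do.call(rbind, sig_summary), file.path(out, "map_summary.tsv"))
    files <- c(files, "map_summary.tsv")

    manifest <- list(
      package = "gazecontrast",
      version = as.character(utils::packageVersion("gazecontrast")),
      seed = config$seed,
      config = config[setdiff(names(config), "out_dir")],
      files = lapply(stats::setNames(files, files), function(f)
        list(md5 = unname(tools::md5sum(file.path(out, f)))))
    )
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    manifest
  }, error = function(e) {
    qdir <- file.path(out, "quarantine")
    dir.create(qdir, showWarnings = FALSE)
    for (f in list.files(out, full.names = FALSE)) {
      if (f != "quarantine")
        file.rename(file.path(out, f), file.path(qdir, f))
    }
    writeLines(conditionMessage(e), file.path(qdir, "error.log"))
    stop(e)
  })
  invisible(result)
}

write_tsv <- function(d, path) {
  write.table(format_num_df(d), path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# matrix as TSV plus a JSON sidecar with the grid metadata
write_map <- function(values, grid, out, name) {
  f1 <- paste0(name, ".tsv")
  utils::write.table(format(values, digits = 17, trim = TRUE, scientific = TRUE),
                     file.path(out, f1), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  f2 <- paste0(name, ".json")
  jsonlite::write_json(list(width = grid$width, height = grid$height,
                            pixel_size = grid$pixel_size,
                            origin = unname(grid$origin)),
                       file.path(out, f2), auto_unbox = TRUE, digits = NA)
  c(f1, f2)
}

write_profile <- function(pm, unc, fdr, out, name) {
  f <- paste0(name, ".tsv")
  d <- data.frame(bin = seq_along(pm$p), p = pm$p, tail_sign = pm$tail_sign,
                  sig_uncorrected = as.vector(unc$mask),
                  sig_fdr = as.vector(fdr$mask))
  write_tsv(d, file.path(out, f))
  f
}

#' Render heatmap and profile figures from pipeline outputs
#'
#' Builds ggplot figures for the density difference maps and significance
#' masks written by [run_pipeline()]. All maps shown within one figure
#' share a single colour scale from zero (deep blue, transparent-like) to
#' the maximum absolute density observed across the figure's panels, so
#' panels are directly comparable; the normalization bounds are returned
#' in the metadata. Writing PNG files is optional.
#'
#' @param out_dir Directory with pipeline outputs (`manifest.json`).
#' @param write Write `figure_<contrast>.png` files into `out_dir`.
#' @return List with `plots` (ggplot objects per contrast) and
#'   `normalization` (shared scale limits per figure), invisibly.
#' @export
render_figures <- function(out_dir, write = FALSE) {
  man <- jsonlite::read_json(file.path(out_dir, "manifest.json"))
  tags <- vapply(man$config$map_contrasts,
                 function(ct) paste0(ct[[1]], "_vs_", ct[[2]]), "")
  plots <- list(); norm <- list()
  vals <- lapply(tags, function(tag)
    as.matrix(utils::read.table(file.path(out_dir, paste0("diff_", tag, ".tsv")))))
  lim <- max(abs(unlist(vals)), 0)
  for (i in seq_along(tags)) {
    d <- vals[[i]]
    df <- data.frame(x = rep(seq_len(ncol(d)), each = nrow(d)),
                     y = rep(seq_len(nrow(d)), ncol(d)),
                     v = as.vector(d))
    p <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, fill = v)) +
      ggplot2::geom_raster() +
      ggplot2::scale_y_reverse() +
      ggplot2::scale_fill_gradient2(low = "darkblue", mid = "white",
                                    high = "darkred", limits = c(-lim, lim)) +
      ggplot2::coord_fixed() +
      ggplot2::labs(title = gsub("_", " ", tags[i]), fill = "density diff")
    plots[[tags[i]]] <- p
    norm[[tags[i]]] <- c(-lim, lim)
    if (write && capabilities("png")) {
      ggplot2::ggsave(file.path(out_dir, paste0("figure_", tags[i], ".png")),
                      p, width = 5, height = 5, dpi = 120)
    }
  }
  invisible(list(plots = plots, normalization = norm))
}
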