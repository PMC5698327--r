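#' Default run configuration
#'
#' All tunable parameters of the analysis in one serialisable list: the
#' window registry, tangent-point anchor registry, HWN baseline anchors and
#' knot, both deconvolution models, PCA settings (fingerprint only; the HWN
#' region is processed without PCA), the water calibration constant, the
#' thickness criterion, and the deconvolution seed/multi-start settings.
#'
#' @param seed integer seed used for deconvolution start jitter
#' @return named list (class `run_config`)
#' @export
default_config <- function(seed = 1) {
  structure(list(
    windows = window_registry(),
    anchors = default_anchor_registry(),
    hwn_anchors = list(c(2776, 2810), c(3800, 3900)),
    hwn_knot = 3800,
    amide1_model = amide1_model(),
    hwn_model = hwn_model(),
    n_starts = 8,
    pca = TRUE,
    pca_k = 4,
    water_calibration = 1.0,
    thickness_threshold = 0.5,
    thickness_convention = "per_um",
    thickness_smooth = 3,
    grid_pct = seq(0, 100, 10),
    seed = seed
  ), class = "run_config")
}

.stage <- function(expr, volunteer, position, depth, stage) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[volunteer %s | position %s | depth %s | stage %s] %s",
                 volunteer, position, depth, stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full depth-profiling analysis on a cohort
#'
#' End-to-end pipeline: per-volunteer-per-depth PCA denoising of the
#' fingerprint spectra across lateral positions, per-spectrum baseline
#' correction and metric computation (including both constrained
#' deconvolutions), per-position surface detection from the 1655 cm^-1
#' keratin profile, per-volunteer averaging over positions on the
#' surface-aligned depth grid, SC thickness estimation from the water
#' profile, normalisation to percent SC depth with resampling to 10 percent
#' increments, and paired adjacent-depth statistics over volunteers.
#' Deterministic for a fixed configuration seed.
#'
#' @param ch a `raman_cohort` (e.g. from [synth_cohort()] or [read_cohort()])
#' @param config run configuration from [default_config()]
#' @param out_dir optional output directory; when given, all result tables,
#'   the configuration and a run log are written there as TSV/YAML
#' @param progress print one line per volunteer
#' @return list with `spectrum_metrics` (per volunteer/position/depth),
#'   `surfaces`, `thickness`, `profiles` (long metric x volunteer x
#'   depth_pct table), `cohort_mean` (mean +/- sd over volunteers), `stats`
#'   (paired adjacent-depth tests)
#' @export
run_analysis <- function(ch, config = default_config(), out_dir = NULL,
                         progress = FALSE) {
  validate_cohort(ch)
  met_rows <- list(); surf_rows <- list(); thick_rows <- list()
  prof_rows <- list(); log_rows <- character()

  for (vid in names(ch$volunteers)) {
    series <- ch$volunteers[[vid]]
    npos <- length(series)
    depths <- series[[1]]$depths_um
    ndep <- length(depths)

    # PCA denoising: group = all positions of this volunteer at one depth
    fp_use <- lapply(series, function(ds) ds$spectra_fp)
    if (isTRUE(config$pca) && npos >= config$pca_k) {
      for (di in seq_len(ndep)) {
        grp <- lapply(series, function(ds) ds$spectra_fp[[di]])
        rec <- .stage(pca_reconstruct(grp, k = config$pca_k),
                      vid, "all", depths[di], "pca")
        for (p in seq_len(npos)) fp_use[[p]][[di]] <- rec[[p]]
      }
    }

    per_pos <- vector("list", npos)
    vols_i1655 <- matrix(NA_real_, nrow = ndep, ncol = npos)
    for (p in seq_len(npos)) {
      ds <- series[[p]]
      vals <- matrix(NA_real_, nrow = ndep, ncol = length(metric_names()),
                     dimnames = list(NULL, metric_names()))
      conv <- logical(ndep)
      for (di in seq_len(ndep)) {
        m <- .stage(spectrum_metrics(fp_use[[p]][[di]], ds$spectra_hwn[[di]],
                                     config,
                                     seed = .sub_seed(config$seed, vid, p, di)),
                    vid, ds$position_id, depths[di], "metrics")
        vals[di, ] <- unlist(m[metric_names()], use.names = FALSE)
        vols_i1655[di, p] <- m$i1655
        conv[di] <- isTRUE(m$converged)
        log_rows <- c(log_rows,
                      sprintf("%s\t%s\t%g\tmetrics\tconverged=%s",
                              vid, ds$position_id, depths[di], conv[di]))
      }
      per_pos[[p]] <- vals
      met_rows[[length(met_rows) + 1L]] <- data.frame(
        volunteer = vid, position = ds$position_id, depth_um = depths,
        as.data.frame(vals), converged = conv, stringsAsFactors = FALSE)
    }

    # per-position surface, then align and average across positions
    surfaces <- vapply(seq_len(npos), function(p)
      .stage(find_surface(depths, vols_i1655[, p])$surface_um,
             vid, series[[p]]$position_id, NA, "surface"), numeric(1))
    for (p in seq_len(npos))
      surf_rows[[length(surf_rows) + 1L]] <- data.frame(
        volunteer = vid, position = series[[p]]$position_id,
        surface_um = surfaces[p], stringsAsFactors = FALSE)

    zal <- seq(0, max(depths) - max(surfaces), by = ch$step_um)
    vol_mat <- matrix(NA_real_, nrow = length(zal),
                      ncol = length(metric_names()),
                      dimnames = list(NULL, metric_names()))
    for (mi in seq_along(metric_names())) {
      acc <- matrix(NA_real_, nrow = length(zal), ncol = npos)
      for (p in seq_len(npos)) {
        v <- per_pos[[p]][, mi]
        ok <- is.finite(v)
        if (sum(ok) >= 2L)
          acc[, p] <- .interp_mono(depths[ok] - surfaces[p], v[ok], zal)
      }
      vol_mat[, mi] <- rowMeans(acc, na.rm = TRUE)
    }

    Tum <- .stage(sc_thickness(zal, vol_mat[, "water_mass_pct"],
                               threshold = config$thickness_threshold,
                               convention = config$thickness_convention,
                               smooth = config$thickness_smooth)$thickness_um,
                  vid, "all", NA, "thickness")
    thick_rows[[length(thick_rows) + 1L]] <- data.frame(
      volunteer = vid, thickness_um = Tum, stringsAsFactors = FALSE)

    for (m in metric_names()) {
      rs <- normalize_and_resample(zal, vol_mat[, m], 0, Tum,
                                   grid_pct = config$grid_pct)
      prof_rows[[length(prof_rows) + 1L]] <- data.frame(
        metric = m, volunteer = vid, depth_pct = rs$depth_pct,
        value = rs$value, stringsAsFactors = FALSE)
    }
    if (progress)
      message(sprintf("volunteer %s done (T = %.1f um)", vid, Tum))
  }

  profiles <- do.call(rbind, prof_rows)
  cohort_mean <- do.call(rbind, lapply(split(
    profiles, list(profiles$metric, profiles$depth_pct), drop = TRUE),
    function(d) data.frame(metric = d$metric[1], depth_pct = d$depth_pct[1],
                           mean = mean(d$value, na.rm = TRUE),
                           sd = stats::sd(d$value, na.rm = TRUE),
                           n = sum(is.finite(d$value)),
                           stringsAsFactors = FALSE)))
  cohort_mean <- cohort_mean[order(cohort_mean$metric, cohort_mean$depth_pct), ]
  rownames(cohort_mean) <- NULL

  res <- list(spectrum_metrics = do.call(rbind, met_rows),
              surfaces = do.call(rbind, surf_rows),
              thickness = do.call(rbind, thick_rows),
              profiles = profiles,
              cohort_mean = cohort_mean,
              stats = adjacent_depth_stats(profiles))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_profiles(res$profiles, file.path(out_dir, "profiles.tsv"))
    for (nm in c("spectrum_metrics", "surfaces", "thickness", "cohort_mean",
                 "stats"))
      utils::write.table(res[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    cfg <- config
    cfg$windows <- lapply(cfg$windows, function(w) c(w$lo, w$hi))
    cfg$amide1_model <- unclass(cfg$amide1_model)
    cfg$hwn_model <- unclass(cfg$hwn_model)
    yaml::write_yaml(lapply(unclass(cfg), function(x)
      if (is.numeric(x) || is.character(x) || is.logical(x) || is.list(x)) x
      else as.character(x)), file.path(out_dir, "config.yaml"))
    writeLines(log_rows, file.path(out_dir, "run.log"))
  }
  res
}
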