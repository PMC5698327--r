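#' @title On-disk layout for depth series and cohorts
#' @description
#' One subdirectory per lateral position holding one TSV per region
#' (`fingerprint.tsv`, `hwn.tsv`). Each TSV has a `wavenumber` column plus one
#' intensity column per depth, named `d<depth>um`; lines starting with `#` are
#' comments. A cohort directory holds `manifest.yaml` plus one subdirectory per
#' volunteer, each with one subdirectory per position.
#' @name raman_io
NULL

.depth_col <- function(z) sprintf("d%gum", z)

.parse_depth_cols <- function(nms) {
  m <- regmatches(nms, regexec("^d([0-9.]+)um$", nms))
  vapply(m, function(g) if (length(g) == 2L) as.numeric(g[2]) else NA_real_,
         numeric(1))
}

.write_region_tsv <- function(wn, mat, depths, path) {
  df <- data.frame(wavenumber = signif(wn, 12))
  for (i in seq_along(depths)) df[[.depth_col(depths[i])]] <- signif(mat[, i], 12)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# ramanSC spectra file", "# columns: wavenumber then one intensity column per depth (um)"), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
}

.read_region_tsv <- function(path, region) {
  if (!file.exists(path))
    stop("missing region file for region '", region, "': ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE)
  depths <- .parse_depth_cols(names(df)[-1])
  if (anyNA(depths))
    stop("unparseable depth columns in ", path, call. = FALSE)
  list(wavenumbers = df[[1]], mat = as.matrix(df[-1]), depths = depths)
}

#' Write a depth series to its directory layout
#'
#' @param ds a `depth_series`
#' @param dir target directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_depth_series <- function(ds, dir) {
  validate_depth_series(ds)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (reg in c("fingerprint", "hwn")) {
    specs <- if (reg == "fingerprint") ds$spectra_fp else ds$spectra_hwn
    wn <- specs[[1]]$wavenumbers
    mat <- vapply(specs, function(s) s$intensities, numeric(length(wn)))
    .write_region_tsv(wn, mat, ds$depths_um, file.path(dir, paste0(reg, ".tsv")))
  }
  invisible(dir)
}

#' Read a depth series from its directory layout
#'
#' @param path directory holding `fingerprint.tsv` and `hwn.tsv`
#' @param position_id,volunteer_id labels (default: basename of `path` and its
#'   parent)
#' @param step_um expected depth increment (um)
#' @return a validated `depth_series`
#' @export
read_depth_series <- function(path, position_id = basename(path),
                              volunteer_id = basename(dirname(path)),
                              step_um = 2) {
  if (!dir.exists(path)) stop("no such directory: ", path, call. = FALSE)
  if (length(list.files(path, pattern = "\\.tsv$")) == 0L)
    stop("no depth files found in ", path, call. = FALSE)
  fp <- .read_region_tsv(file.path(path, "fingerprint.tsv"), "fingerprint")
  hw <- .read_region_tsv(file.path(path, "hwn.tsv"), "hwn")
  if (!isTRUE(all.equal(fp$depths, hw$depths)))
    stop("fingerprint and hwn files disagree on depths in ", path, call. = FALSE)
  mk <- function(src, region) lapply(seq_along(src$depths), function(i)
    spectrum(src$wavenumbers, src$mat[, i], region))
  depth_series(fp$depths,
               mk(fp, "fingerprint"), mk(hw, "hwn"),
               position_id = position_id, volunteer_id = volunteer_id,
               step_um = step_um)
}

#' Write a cohort (all volunteers/positions) plus a YAML manifest
#'
#' @param ch a `raman_cohort`
#' @param dir target directory
#' @return `dir`, invisibly
#' @export
write_cohort <- function(ch, dir) {
  validate_cohort(ch)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(step_um = ch$step_um, volunteers = list())
  for (vid in names(ch$volunteers)) {
    pos_ids <- vapply(ch$volunteers[[vid]], function(d) d$position_id, character(1))
    manifest$volunteers[[vid]] <- as.list(pos_ids)
    for (ds in ch$volunteers[[vid]])
      write_depth_series(ds, file.path(dir, vid, ds$position_id))
  }
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#' @param dir cohort directory containing `manifest.yaml`
#' @return a validated `raman_cohort`
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "manifest.yaml")
  if (!file.exists(mf)) stop("no manifest.yaml in ", dir, call. = FALSE)
  manifest <- yaml::read_yaml(mf)
  vols <- lapply(names(manifest$volunteers), function(vid) {
    lapply(unlist(manifest$volunteers[[vid]]), function(pid)
      read_depth_series(file.path(dir, vid, pid), position_id = pid,
                        volunteer_id = vid, step_um = manifest$step_um))
  })
  names(vols) <- names(manifest$volunteers)
  cohort(vols, step_um = manifest$step_um)
}

#' Write a metric profile table to TSV
#'
#' Long table with columns (metric, volunteer, depth_pct, value); values are
#' written with 12 significant digits so that read/write round-trips are
#' lossless at that precision.
#'
#' @param table data.frame with columns metric, volunteer, depth_pct, value
#' @param path output file
#' @return `path`, invisibly
#' @export
write_profiles <- function(table, path) {
  need <- c("metric", "volunteer", "depth_pct", "value")
  if (!all(need %in% names(table)))
    stop("profile table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- table[, need]
  out$value <- signif(out$value, 12)
  out$depth_pct <- signif(out$depth_pct, 12)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a metric profile table written by [write_profiles()]
#' @param path TSV file
#' @return data.frame with columns metric, volunteer, depth_pct, value
#' @export
read_profiles <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
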