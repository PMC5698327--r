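#' Raman spectrum
#'
#' One wavenumber-indexed intensity trace with a region tag. The fingerprint
#' region covers 400-2000 cm^-1 and the high-wavenumber (HWN) region
#' 2000-4000 cm^-1, matching the two excitation/detection configurations of
#' in vivo confocal Raman instruments for skin.
#'
#' @param wavenumbers strictly increasing numeric vector of cm^-1 values
#' @param intensities numeric vector of detector counts, same length
#' @param region `"fingerprint"` or `"hwn"`
#' @return an object of class `raman_spectrum`
#' @export
spectrum <- function(wavenumbers, intensities, region = c("fingerprint", "hwn")) {
  region <- match.arg(region)
  obj <- structure(list(wavenumbers = as.numeric(wavenumbers),
                        intensities = as.numeric(intensities),
                        region = region),
                   class = "raman_spectrum")
  validate_spectrum(obj)
}

#' Validate a `raman_spectrum`
#'
#' Checks the type invariants: equal vector lengths, at least 16 samples,
#' strictly increasing wavenumbers, finite intensities, and a region tag
#' consistent with the acquired wavenumber span.
#'
#' @param x object to validate
#' @return `x`, invisibly valid (errors otherwise)
#' @export
validate_spectrum <- function(x) {
  if (!inherits(x, "raman_spectrum")) stop("not a raman_spectrum", call. = FALSE)
  wn <- x$wavenumbers
  if (length(wn) != length(x$intensities))
    stop("wavenumbers and intensities differ in length (",
         length(wn), " vs ", length(x$intensities), ")", call. = FALSE)
  if (length(wn) < 16L)
    stop("spectrum has fewer than 16 samples", call. = FALSE)
  d <- diff(wn)
  if (any(d <= 0)) {
    bad <- wn[which(d <= 0)[1] + 1L]
    stop("wavenumbers not strictly increasing (offending value ", bad, ")",
         call. = FALSE)
  }
  if (!all(is.finite(x$intensities)))
    stop("non-finite intensities", call. = FALSE)
  if (!x$region %in% c("fingerprint", "hwn"))
    stop("unknown region tag: ", x$region, call. = FALSE)
  lims <- if (x$region == "fingerprint") c(400, 2000) else c(2000, 4000)
  if (wn[1] > lims[2] || wn[length(wn)] < lims[1])
    stop("spectrum span [", wn[1], ", ", wn[length(wn)],
         "] does not intersect the ", x$region, " region", call. = FALSE)
  invisible(x)
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %s, %d points, %.1f-%.1f cm-1\n",
              x$region, length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

#' Linearly interpolated intensity at arbitrary wavenumbers
#' @param spec a `raman_spectrum`
#' @param at wavenumbers at which to interpolate (must lie inside the span)
#' @return intensities at `at`
#' @export
spectrum_at <- function(spec, at) {
  wn <- spec$wavenumbers
  if (any(at < wn[1] | at > wn[length(wn)]))
    stop("interpolation point outside spectrum span", call. = FALSE)
  stats::approx(wn, spec$intensities, xout = at, method = "linear")$y
}

#' Depth series of paired spectra
#'
#' Ordered stack of fingerprint + HWN spectra acquired at constant depth
#' increments (default 2 um) for one lateral measurement position.
#'
#' @param depths_um non-negative, strictly increasing, constant-increment depths
#' @param spectra_fp list of fingerprint `raman_spectrum`, one per depth
#' @param spectra_hwn list of hwn `raman_spectrum`, one per depth
#' @param position_id,volunteer_id labels
#' @param step_um expected increment (default 2)
#' @return an object of class `depth_series`
#' @export
depth_series <- function(depths_um, spectra_fp, spectra_hwn,
                         position_id = "p1", volunteer_id = "v1",
                         step_um = 2) {
  obj <- structure(list(depths_um = as.numeric(depths_um),
                        spectra_fp = spectra_fp, spectra_hwn = spectra_hwn,
                        position_id = position_id, volunteer_id = volunteer_id,
                        step_um = step_um),
                   class = "depth_series")
  validate_depth_series(obj)
}

#' Validate a `depth_series`
#' @param x object to validate
#' @return `x` invisibly (errors on violation)
#' @export
validate_depth_series <- function(x) {
  if (!inherits(x, "depth_series")) stop("not a depth_series", call. = FALSE)
  z <- x$depths_um
  n <- length(z)
  if (n < 2L) stop("depth series needs at least 2 depths", call. = FALSE)
  if (any(z < 0)) stop("negative depths", call. = FALSE)
  d <- diff(z)
  if (any(d <= 0)) stop("depths not strictly increasing", call. = FALSE)
  if (max(abs(d - x$step_um)) > 1e-9)
    stop("depth increment differs from configured step (", x$step_um, " um)",
         call. = FALSE)
  if (length(x$spectra_fp) != n)
    stop("need one fingerprint spectrum per depth (", length(x$spectra_fp),
         " vs ", n, ")", call. = FALSE)
  if (length(x$spectra_hwn) != n)
    stop("need one hwn spectrum per depth (", length(x$spectra_hwn),
         " vs ", n, ")", call. = FALSE)
  for (s in x$spectra_fp) {
    validate_spectrum(s)
    if (s$region != "fingerprint") stop("fingerprint slot holds a ", s$region,
                                        " spectrum", call. = FALSE)
  }
  for (s in x$spectra_hwn) {
    validate_spectrum(s)
    if (s$region != "hwn") stop("hwn slot holds a ", s$region, " spectrum",
                                call. = FALSE)
  }
  invisible(x)
}

#' @export
print.depth_series <- function(x, ...) {
  cat(sprintf("<depth_series> volunteer %s position %s: %d depths (%g-%g um, step %g)\n",
              x$volunteer_id, x$position_id, length(x$depths_um),
              min(x$depths_um), max(x$depths_um), x$step_um))
  invisible(x)
}

#' Integration window
#'
#' A named wavenumber window `[lo, hi]` for area-under-the-curve integration.
#'
#' @param name label
#' @param lo,hi bounds in cm^-1, `lo < hi`
#' @return an object of class `band_window`
#' @export
band_window <- function(name, lo, hi) {
  if (!(is.numeric(lo) && is.numeric(hi) && lo < hi))
    stop("band window requires numeric lo < hi", call. = FALSE)
  structure(list(name = name, lo = lo, hi = hi), class = "band_window")
}

#' Cohort of depth series
#'
#' A list of volunteer records, each holding one or more `depth_series`
#' (one per lateral position). All series must share the depth increment.
#'
#' @param volunteers named list; each element a list of `depth_series`
#' @param step_um common acquisition increment (um)
#' @return an object of class `raman_cohort`
#' @export
cohort <- function(volunteers, step_um = 2) {
  obj <- structure(list(volunteers = volunteers, step_um = step_um),
                   class = "raman_cohort")
  validate_cohort(obj)
}

#' Validate a `raman_cohort`
#' @param x object to validate
#' @return `x` invisibly
#' @export
validate_cohort <- function(x) {
  if (!inherits(x, "raman_cohort")) stop("not a raman_cohort", call. = FALSE)
  if (length(x$volunteers) < 1L) stop("empty cohort", call. = FALSE)
  for (vol in x$volunteers) {
    for (ds in vol) {
      validate_depth_series(ds)
      if (abs(ds$step_um - x$step_um) > 1e-9)
        stop("depth series step differs from cohort step", call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.raman_cohort <- function(x, ...) {
  np <- vapply(x$volunteers, length, integer(1))
  cat(sprintf("<raman_cohort> %d volunteers, %d depth series, step %g um\n",
              length(x$volunteers), sum(np), x$step_um))
  invisible(x)
}
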