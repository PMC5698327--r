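#' Default integration-window registry
#'
#' The fixed wavenumber windows used by the conformational and hydration
#' metrics:
#' \describe{
#'   \item{ss_ggg}{474-508, gauche-gauche-gauche S-S stretch}
#'   \item{ss_total}{474-578, total disulphide S-S stretch}
#'   \item{cs_cys}{690-712, cysteine C-S stretch}
#'   \item{tyr_buried}{816-838, buried tyrosine (830 doublet component)}
#'   \item{tyr_exposed}{838-874, exposed tyrosine (850 doublet component)}
#'   \item{alpha_cc}{924-946, C-C skeletal, alpha-helix (938)}
#'   \item{beta_cc}{952-966, C-C skeletal, beta-sheet (960)}
#'   \item{keratin_ch}{2910-2965, keratin CH3 stretch}
#'   \item{water_oh}{3350-3550, water OH stretch}
#' }
#'
#' @return named list of [band_window()] objects
#' @export
window_registry <- function() {
  w <- list(
    ss_ggg      = c(474, 508),
    ss_total    = c(474, 578),
    cs_cys      = c(690, 712),
    tyr_buried  = c(816, 838),
    tyr_exposed = c(838, 874),
    alpha_cc    = c(924, 946),
    beta_cc     = c(952, 966),
    keratin_ch  = c(2910, 2965),
    water_oh    = c(3350, 3550)
  )
  mapply(function(nm, b) band_window(nm, b[1], b[2]), names(w), w,
         SIMPLIFY = FALSE)
}

#' Area under the curve over a wavenumber window
#'
#' Trapezoidal integral of a (baseline-corrected) spectrum over `[lo, hi]`.
#' When the bounds fall between grid points the boundary intensities are
#' obtained by linear interpolation, which makes the integral exactly
#' additive over abutting windows and exact for the piecewise-linear data
#' model. Negative intensities are integrated as-is; a warning is emitted
#' when the resulting area is negative, since clipping would bias ratios.
#'
#' @param spec a `raman_spectrum` (baseline already removed)
#' @param window a [band_window()], or a numeric `c(lo, hi)`
#' @return area in counts * cm^-1
#' @export
auc <- function(spec, window) {
  if (inherits(window, "band_window")) {
    lo <- window$lo; hi <- window$hi; nm <- window$name
  } else {
    lo <- window[1]; hi <- window[2]; nm <- "window"
  }
  if (!(is.finite(lo) && is.finite(hi))) stop("non-finite window", call. = FALSE)
  if (lo >= hi) stop("reversed or empty window [", lo, ", ", hi, "]",
                     call. = FALSE)
  wn <- spec$wavenumbers
  if (lo < wn[1] || hi > wn[length(wn)])
    stop("window [", lo, ", ", hi, "] outside spectrum span [", wn[1], ", ",
         wn[length(wn)], "]", call. = FALSE)
  inside <- which(wn > lo & wn < hi)
  x <- c(lo, wn[inside], hi)
  y <- c(spectrum_at(spec, lo), spec$intensities[inside], spectrum_at(spec, hi))
  area <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  if (area < 0)
    warning("negative AUC (", signif(area, 4), ") in window '", nm, "'",
            call. = FALSE)
  area
}
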