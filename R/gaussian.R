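#' Gaussian spectral band
#'
#' A Raman band modelled as a Gaussian in wavenumber,
#' \deqn{g(\tilde\nu) = A \exp\left(-4\ln 2\,(\tilde\nu-\mu)^2/w^2\right),}
#' parameterised by its centre \eqn{\mu} (cm\eqn{^{-1}}), full width at half
#' maximum \eqn{w} (cm\eqn{^{-1}}) and peak amplitude \eqn{A} (detector
#' counts).
#'
#' @param center band centre in cm^-1
#' @param fwhm full width at half maximum in cm^-1, > 0
#' @param amplitude peak amplitude in counts, >= 0
#' @return an object of class `gaussian_band`
#' @examples
#' b <- gaussian_band(1655, 30, 1)
#' gauss_area(b)            # closed form A * w * sqrt(pi / (4 ln 2))
#' @export
gaussian_band <- function(center, fwhm, amplitude) {
  stopifnot(is.numeric(center), length(center) == 1L, is.finite(center))
  if (!is.numeric(fwhm) || length(fwhm) != 1L || !is.finite(fwhm) || fwhm <= 0)
    stop("`fwhm` must be a single positive number", call. = FALSE)
  if (!is.numeric(amplitude) || length(amplitude) != 1L || amplitude < 0)
    stop("`amplitude` must be a single non-negative number", call. = FALSE)
  structure(list(center = center, fwhm = fwhm, amplitude = amplitude),
            class = "gaussian_band")
}

#' @export
print.gaussian_band <- function(x, ...) {
  cat(sprintf("<gaussian_band> center %.2f cm-1, FWHM %.2f cm-1, amplitude %.4g\n",
              x$center, x$fwhm, x$amplitude))
  invisible(x)
}

#' Evaluate a sum of Gaussian bands on a wavenumber grid
#'
#' @param x wavenumber grid (cm^-1)
#' @param center,fwhm,amplitude numeric vectors of band parameters (recycled
#'   checks are not performed; all three must have equal length)
#' @return intensities on `x`
#' @export
gauss_sum <- function(x, center, fwhm, amplitude) {
  .gauss_sum_cpp(as.numeric(x), as.numeric(center), as.numeric(fwhm),
                 as.numeric(amplitude))
}

#' Closed-form area of a Gaussian band
#'
#' The full area under a Gaussian of amplitude \eqn{A} and FWHM \eqn{w} is
#' \eqn{A\,w\sqrt{\pi/(4\ln 2)}}. This is the area-under-the-Gaussian-curve
#' (AUGC) used for deconvolution-based band ratios.
#'
#' @param band a `gaussian_band`, or a numeric FWHM when `amplitude` is given
#' @param amplitude optional amplitude when `band` is the FWHM
#' @return area in counts * cm^-1
#' @export
gauss_area <- function(band, amplitude = NULL) {
  if (inherits(band, "gaussian_band"))
    return(band$amplitude * band$fwhm * sqrt(pi / (4 * log(2))))
  band * amplitude * sqrt(pi / (4 * log(2)))
}

#' Exact integral of a Gaussian band over a wavenumber window
#'
#' Uses the Gaussian CDF: with \eqn{\sigma = w / (2\sqrt{2\ln 2})} the
#' integral over \eqn{[lo, hi]} is
#' \eqn{A\sigma\sqrt{2\pi}\,[\Phi((hi-\mu)/\sigma) - \Phi((lo-\mu)/\sigma)]}.
#' Serves as the closed-form oracle for windowed trapezoidal integration.
#'
#' @param center,fwhm,amplitude band parameters (vectorised over bands)
#' @param lo,hi window bounds in cm^-1
#' @return total windowed area of all bands
#' @export
gauss_area_window <- function(center, fwhm, amplitude, lo, hi) {
  stopifnot(lo < hi)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  sum(amplitude * sigma * sqrt(2 * pi) *
        (stats::pnorm((hi - center) / sigma) - stats::pnorm((lo - center) / sigma)))
}
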