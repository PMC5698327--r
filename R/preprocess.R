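#' Default tangent-point anchor registry
#'
#' For each fingerprint analysis region, two flanking anchor windows from
#' which the local linear baseline is estimated. The published procedure
#' selects 5-10 tangent points on each side of a band by hand; for
#' reproducibility this package ships fixed anchor windows chosen to sit in
#' band-free parts of the skin Raman spectrum. Each window contains at least
#' 5 grid points at 1 cm^-1 sampling. All values are configurable per run.
#'
#' @return named list; each entry has `band` (the cm^-1 span the corrected
#'   segment must cover), `left` and `right` anchor windows
#' @export
default_anchor_registry <- function() {
  list(
    ss     = list(band = c(474, 578),  left = c(440, 468),  right = c(584, 612)),
    cs     = list(band = c(690, 712),  left = c(662, 686),  right = c(714, 730)),
    tyr    = list(band = c(816, 874),  left = c(790, 812),  right = c(906, 922)),
    cc     = list(band = c(924, 966),  left = c(906, 922),  right = c(970, 990)),
    amide1 = list(band = c(1580, 1720), left = c(1540, 1566), right = c(1730, 1756))
  )
}

.anchor_idx <- function(wn, win) which(wn >= win[1] & wn <= win[2])

#' Remove a local linear baseline anchored in flanking windows
#'
#' Pools the samples inside the two anchor windows, fits a straight line by
#' least squares, and returns the spectrum segment spanning
#' `[left lo, right hi]` with that line subtracted. After correction the mean
#' of the residual over the anchor samples is ~0 by construction.
#'
#' @param spec a `raman_spectrum`
#' @param anchor list with elements `left`, `right` (each `c(lo, hi)` in
#'   cm^-1) and optionally `band`; see [default_anchor_registry()]
#' @return a `raman_spectrum` holding the corrected segment
#' @export
remove_linear_baseline <- function(spec, anchor) {
  wn <- spec$wavenumbers
  for (side in c("left", "right")) {
    win <- anchor[[side]]
    if (win[1] < wn[1] || win[2] > wn[length(wn)])
      stop(side, " anchor window [", win[1], ", ", win[2],
           "] outside spectrum span", call. = FALSE)
  }
  il <- .anchor_idx(wn, anchor$left)
  ir <- .anchor_idx(wn, anchor$right)
  if (length(il) < 5L || length(ir) < 5L)
    stop("need at least 5 anchor samples per side (got ", length(il), " / ",
         length(ir), ")", call. = FALSE)
  ia <- c(il, ir)
  fit <- stats::lm.fit(cbind(1, wn[ia]), spec$intensities[ia])
  seg <- which(wn >= anchor$left[1] & wn <= anchor$right[2])
  base <- fit$coefficients[1] + fit$coefficients[2] * wn[seg]
  spectrum(wn[seg], spec$intensities[seg] - base, spec$region)
}

#' PCA reconstruction of a group of spectra
#'
#' Denoises a group of spectra (all lateral positions of one volunteer at one
#' nominal depth) by projecting the mean-centred intensity matrix onto its
#' first `k` principal components (default 4) and reconstructing. Components
#' are obtained by singular value decomposition with a deterministic sign
#' convention (the largest-magnitude loading of each component is positive).
#' The group mean spectrum is preserved exactly.
#'
#' @param spectra list of `raman_spectrum` on a common wavenumber grid
#' @param k number of retained components (default 4)
#' @return list of reconstructed `raman_spectrum`
#' @export
pca_reconstruct <- function(spectra, k = 4) {
  n <- length(spectra)
  if (n < k)
    stop("group size (", n, ") smaller than k (", k,
         "); lower k or enlarge the group", call. = FALSE)
  wn <- spectra[[1]]$wavenumbers
  X <- t(vapply(spectra, function(s) {
    if (!isTRUE(all.equal(s$wavenumbers, wn)))
      stop("spectra in a PCA group must share the wavenumber grid", call. = FALSE)
    s$intensities
  }, numeric(length(wn))))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  if (k == 0 || max(abs(Xc)) == 0) {
    R <- matrix(rep(mu, each = n), nrow = n)
  } else {
    sv <- svd(Xc)
    kk <- min(k, sum(sv$d > sv$d[1] * 1e-12), length(sv$d))
    V <- sv$v[, seq_len(kk), drop = FALSE]
    # deterministic sign: largest-|loading| entry of each component positive
    for (j in seq_len(kk)) {
      i <- which.max(abs(V[, j]))
      if (V[i, j] < 0) V[, j] <- -V[, j]
    }
    R <- Xc %*% V %*% t(V) + matrix(rep(mu, each = n), nrow = n)
  }
  lapply(seq_len(n), function(i) spectrum(wn, R[i, ], spectra[[i]]$region))
}

#' Piecewise-linear baseline for the high-wavenumber region
#'
#' Fits a continuous two-segment linear baseline to an HWN spectrum by
#' weighted least squares: weight 1 inside the two anchor regions
#' (2776-2810 and 3800-3900 cm^-1 by default), weight 0 elsewhere, with the
#' two segments joined at a configurable knot. The fitted baseline is
#' subtracted from the whole spectrum, preserving linearity with different
#' gradients in the two anchor regions. The default knot sits at the lower
#' edge of the upper anchor region (3800 cm^-1): the baseline under the
#' CH/OH band complex is then the chord through both anchor clusters, which
#' keeps the gradient-break coefficient from being extrapolated across the
#' analysis windows — a knot in the middle of the band complex makes the
#' integrated areas extremely sensitive to anchor noise (see the vignette).
#'
#' @param spec an hwn `raman_spectrum` spanning both anchor regions
#' @param anchors list of two `c(lo, hi)` anchor windows
#' @param knot join wavenumber of the two segments (cm^-1)
#' @return baseline-corrected `raman_spectrum` (full input span)
#' @export
hwn_baseline <- function(spec,
                         anchors = list(c(2776, 2810), c(3800, 3900)),
                         knot = 3800) {
  wn <- spec$wavenumbers
  for (win in anchors)
    if (win[1] < wn[1] || win[2] > wn[length(wn)])
      stop("hwn anchor region [", win[1], ", ", win[2],
           "] absent from spectrum span", call. = FALSE)
  ia <- sort(unique(unlist(lapply(anchors, function(w) .anchor_idx(wn, w)))))
  if (length(ia) < 4L) stop("too few anchor samples", call. = FALSE)
  basis <- function(x) cbind(1, pmin(x - knot, 0), pmax(x - knot, 0))
  fit <- stats::lm.fit(basis(wn[ia]), spec$intensities[ia])
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  base <- drop(basis(wn) %*% beta)
  spectrum(wn, spec$intensities - base, spec$region)
}
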