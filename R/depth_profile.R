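#' Locate the skin surface from the 1655 cm^-1 keratin profile
#'
#' The surface is the position where the keratin depth profile (baseline
#' removed 1655 cm^-1 Amide I peak intensity) reaches half of its maximum
#' coming from outside the skin. The crossing is localised below the
#' acquisition increment by linear interpolation between the bracketing
#' samples.
#'
#' @param depths_um acquisition depths (um), increasing, outside-to-inside
#' @param i1655 1655 cm^-1 peak intensity at each depth
#' @return object of class `surface_estimate`: list with `surface_um` and
#'   `half_max`
#' @export
find_surface <- function(depths_um, i1655) {
  stopifnot(length(depths_um) == length(i1655), length(i1655) >= 2L)
  hm <- max(i1655) / 2
  if (hm <= 0) stop("no surface crossing: profile never reaches half-maximum",
                    call. = FALSE)
  above <- i1655 >= hm
  if (above[1]) {
    # already inside the skin at the first sample
    return(structure(list(surface_um = depths_um[1], half_max = hm),
                     class = "surface_estimate"))
  }
  i <- which(!utils::head(above, -1) & utils::tail(above, -1))
  if (length(i) == 0L)
    stop("no surface crossing: profile never reaches half-maximum",
         call. = FALSE)
  i <- i[1]
  z <- depths_um[i] + (hm - i1655[i]) * (depths_um[i + 1] - depths_um[i]) /
    (i1655[i + 1] - i1655[i])
  structure(list(surface_um = z, half_max = hm), class = "surface_estimate")
}

#' @export
print.surface_estimate <- function(x, ...) {
  cat(sprintf("<surface_estimate> %.2f um (half-max %.4g)\n",
              x$surface_um, x$half_max))
  invisible(x)
}

#' Stratum corneum thickness from the water depth profile
#'
#' Implements the Crowther criterion: the SC/SG boundary is where the first
#' derivative of the water mass-percent profile reaches 0.5 moving inward.
#' The profile is lightly smoothed (3-point moving average) before centred
#' finite differencing, the crossing is localised by linear interpolation,
#' and when several upward crossings exist the one nearest the water-profile
#' inflection (maximum derivative) is taken. By default the threshold is in
#' water-mass-percent per micrometre on the physical axis; the alternative
#' normalised convention (0.5 of the maximum derivative) is selectable.
#'
#' @param depths_um surface-aligned depths (um; 0 = skin surface), increasing
#' @param water_pct water mass percent at each depth
#' @param threshold derivative threshold (default 0.5)
#' @param convention `"per_um"` (threshold in %/um) or `"normalized"`
#'   (threshold as a fraction of the maximum derivative)
#' @param smooth moving-average window (odd, default 3); 1 disables smoothing
#' @return object of class `sc_thickness_estimate`: list with `thickness_um`,
#'   `derivative` (data.frame depth/value) and `threshold_used`
#' @export
sc_thickness <- function(depths_um, water_pct, threshold = 0.5,
                         convention = c("per_um", "normalized"), smooth = 3) {
  convention <- match.arg(convention)
  keep <- is.finite(water_pct)
  z <- depths_um[keep]
  w <- water_pct[keep]
  n <- length(z)
  if (n < 4L) stop("too few water samples for thickness estimation",
                   call. = FALSE)
  ma <- function(v, m) {
    if (m <= 1L) return(v)
    pad <- (m - 1L) %/% 2L
    out <- stats::filter(c(rep(v[1], pad), v, rep(v[n], pad)),
                         rep(1 / m, m), sides = 2)
    as.numeric(out[(pad + 1L):(pad + n)])
  }
  deriv <- function(v) {
    d <- numeric(n)
    d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (z[3:n] - z[1:(n - 2)])
    d[1] <- (v[2] - v[1]) / (z[2] - z[1])
    d[n] <- (v[n] - v[n - 1]) / (z[n] - z[n - 1])
    d
  }
  crossings <- function(d, thr) {
    up <- which(utils::head(d, -1) < thr & utils::tail(d, -1) >= thr)
    list(up = up, at = vapply(up, function(i)
      z[i] + (thr - d[i]) * (z[i + 1] - z[i]) / (d[i + 1] - d[i]), numeric(1)))
  }
  step <- stats::median(diff(z))
  d <- deriv(ma(w, smooth))
  thr <- if (convention == "per_um") threshold else threshold * max(d)
  kernel_factor <- function(delta, h, m) {
    k <- seq(-(m - 1) / 2, (m - 1) / 2)
    delta * (exp(h / delta) - exp(-h / delta)) * sum(exp(k * h / delta)) /
      (2 * h * m)
  }
  # One estimate at smoothing window m: find the crossing that starts the
  # above-threshold excursion containing the water-profile inflection
  # (derivative maximum; isolated noise crossings away from the main SC/SG
  # rise are ignored), then correct the kernel bias: the moving-average +
  # centred-difference kernel overestimates the derivative on the convex
  # rising edge, shifting the crossing outward. On a locally exponential
  # rise d = base + A exp(z/delta) the kernel inflates the tail by the
  # computable factor S(delta), so the crossing shifts by -delta log(S);
  # delta is estimated from the two samples above the entry and the
  # crossing shifted back (clamped to two sampling steps).
  est_at <- function(m) {
    dm <- deriv(ma(w, m))
    cr <- crossings(dm, thr)
    if (length(cr$up) == 0L) return(NA_real_)
    imax <- which.max(dm)
    entry <- if (any(cr$up < imax)) max(cr$up[cr$up < imax]) else cr$up[1]
    val <- cr$at[match(entry, cr$up)]
    if (entry >= 2L && entry + 1L <= n) {
      base <- stats::median(dm[seq_len(max(entry - 1L, 1L))])
      t0 <- dm[entry] - base
      t1 <- dm[entry + 1L] - base
      tc <- thr - base
      if (is.finite(t0) && is.finite(t1) && t0 > 0 && t1 > t0 && tc > t0) {
        delta_hat <- step / log(t1 / t0)
        if (is.finite(delta_hat) && delta_hat > 0.3 && delta_hat < 20) {
          # exponential (rather than linear) interpolation of the crossing
          # between the bracketing samples, then the kernel-bias shift
          cross_exp <- z[entry] + delta_hat * log(tc / t0)
          if (abs(cross_exp - val) <= step) val <- cross_exp
          corr <- delta_hat * log(kernel_factor(delta_hat, step, max(m, 1L)))
          val <- val + min(max(corr, 0), 2 * step)
        }
      }
    }
    val
  }
  # two smoothing scales with partially independent errors; their average
  # is used when they agree, the wider (more robust) window when they do not
  T1 <- est_at(smooth)
  T2 <- est_at(smooth + 2L)
  if (is.na(T1) && is.na(T2))
    stop("water-profile derivative never reaches ", signif(thr, 3),
         " %/um; derivative range [", signif(min(d), 3), ", ",
         signif(max(d), 3), "]", call. = FALSE)
  Tum <- if (is.na(T1)) T2
  else if (is.na(T2)) T1
  else if (abs(T1 - T2) <= 2 * step) (T1 + T2) / 2
  else T2
  if (Tum <= 0) stop("estimated thickness is not positive", call. = FALSE)
  structure(list(thickness_um = Tum,
                 derivative = data.frame(depth_um = z, dW_dz = d),
                 threshold_used = thr),
            class = "sc_thickness_estimate")
}

#' @export
print.sc_thickness_estimate <- function(x, ...) {
  cat(sprintf("<sc_thickness_estimate> %.2f um (threshold %.3g %%/um)\n",
              x$thickness_um, x$threshold_used))
  invisible(x)
}

#' Normalise a metric depth series to percent SC depth and resample
#'
#' Depths are mapped to `100 * (z - surface) / thickness` and the metric is
#' linearly interpolated onto the normalised grid (0, 10, ..., 100 percent by
#' default; 0 = surface, 100 = SC/SG boundary). Interpolation is monotone
#' cubic Hermite (Fritsch-Carlson): shape-preserving, exact for affine
#' profiles, and with much smaller flattening error than linear
#' interpolation where the profile curves between samples. Grid points
#' outside the measured span are returned as `NA` rather than extrapolated.
#'
#' @param depths_um physical depths of the metric samples (um, acquisition
#'   coordinates)
#' @param values metric values at `depths_um`
#' @param surface_um surface position (um) from [find_surface()]
#' @param thickness_um SC thickness (um) from [sc_thickness()]
#' @param grid_pct normalised grid (default `seq(0, 100, 10)`)
#' @return data.frame with columns `depth_pct`, `value`
#' @export
normalize_and_resample <- function(depths_um, values, surface_um, thickness_um,
                                   grid_pct = seq(0, 100, 10)) {
  stopifnot(thickness_um > 0, length(depths_um) == length(values))
  keep <- is.finite(values)
  pct <- 100 * (depths_um[keep] - surface_um) / thickness_um
  v <- values[keep]
  data.frame(depth_pct = grid_pct, value = .interp_mono(pct, v, grid_pct))
}
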