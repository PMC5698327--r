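#' @title Conformational and hydration metrics
#' @description
#' Eight per-spectrum metrics summarising keratin secondary structure,
#' tertiary structure and SC hydration:
#' \describe{
#'   \item{beta_alpha_cc}{beta-sheet/alpha-helix from the C-C skeletal bands,
#'     AUC(952-966)/AUC(924-946)}
#'   \item{beta_alpha_amide1}{(beta-sheet + turns and random coils)/alpha-helix
#'     from the Amide I deconvolution, (AUGC_1670 + AUGC_1685)/AUGC_1655}
#'   \item{ss_stability}{gauche-gauche-gauche fraction of total disulphide
#'     bonds, AUC(474-508)/AUC(474-578)}
#'   \item{cs_ss}{cysteine C-S over disulphide S-S, AUC(690-712)/AUC(474-578)}
#'   \item{tyr_ratio}{buried/exposed tyrosine, AUC(816-838)/AUC(838-874)}
#'   \item{ch3_position}{fitted 2930 cm^-1 Gaussian peak position (cm^-1)}
#'   \item{water_mass_pct}{water mass percent from the OH/keratin AUC ratio}
#'   \item{bound_water_ratio}{weakly/strongly bound water AUGC ratio}
#' }
#' All ratio metrics are invariant under positive scaling of the spectrum.
#' @name conformation_metrics
NULL

.ratio_or_na <- function(num, den, what) {
  if (den <= 0) {
    warning(what, ": denominator AUC <= 0; ratio undefined", call. = FALSE)
    return(NA_real_)
  }
  num / den
}

#' beta-sheet/alpha-helix ratio from the C-C skeletal bands
#' @param segment baseline-removed fingerprint segment covering 924-966 cm^-1
#' @param windows window registry (default [window_registry()])
#' @return AUC(952-966)/AUC(924-946)
#' @export
beta_alpha_cc <- function(segment, windows = window_registry()) {
  .ratio_or_na(auc(segment, windows$beta_cc), auc(segment, windows$alpha_cc),
               "beta_alpha_cc")
}

#' Disulphide-bond stability (gauche-gauche-gauche fraction)
#'
#' Fraction of the total disulphide S-S stretch intensity contributed by the
#' most stable gauche-gauche-gauche conformer. Because the numerator window
#' (474-508) is a sub-window of the denominator (474-578), the value lies in
#' `[0, 1]` for non-negative spectra.
#'
#' @inheritParams beta_alpha_cc
#' @return AUC(474-508)/AUC(474-578)
#' @export
ss_stability <- function(segment, windows = window_registry()) {
  .ratio_or_na(auc(segment, windows$ss_ggg), auc(segment, windows$ss_total),
               "ss_stability")
}

#' Cysteine C-S to disulphide S-S ratio
#'
#' A larger value means less cysteine participates in disulphide bonds,
#' hence less folded keratin. The two windows live in different
#' locally-corrected segments, so both are passed explicitly.
#'
#' @param segment_cs baseline-removed segment covering 690-712 cm^-1
#' @param segment_ss baseline-removed segment covering 474-578 cm^-1
#' @param windows window registry
#' @return AUC(690-712)/AUC(474-578)
#' @export
cs_ss <- function(segment_cs, segment_ss, windows = window_registry()) {
  .ratio_or_na(auc(segment_cs, windows$cs_cys), auc(segment_ss, windows$ss_total),
               "cs_ss")
}

#' Buried/exposed tyrosine ratio (830/850 Fermi doublet)
#' @inheritParams beta_alpha_cc
#' @return AUC(816-838)/AUC(838-874)
#' @export
tyr_ratio <- function(segment, windows = window_registry()) {
  .ratio_or_na(auc(segment, windows$tyr_buried), auc(segment, windows$tyr_exposed),
               "tyr_ratio")
}

#' Water mass percentage from the OH/keratin AUC ratio
#'
#' Computes `R = AUC(3350-3550) / AUC(2910-2965)` on a baseline-corrected
#' HWN spectrum and maps it to water mass percent with the saturating form
#' `100 R / (R + c)`. The form follows from water/(water + protein) mass
#' bookkeeping when both AUCs are proportional to the respective mass
#' fractions; `c` is the instrument calibration constant (default 1 in
#' arbitrary units), so absolute values are calibration-dependent. The map
#' is strictly increasing in `R`, 0 at `R = 0` and approaches 100 as
#' `R` grows.
#'
#' @param spec_hwn baseline-corrected hwn `raman_spectrum`
#' @param calibration calibration constant `c > 0`
#' @param windows window registry
#' @return water mass percent in `[0, 100)`
#' @export
water_mass_pct <- function(spec_hwn, calibration = 1.0,
                           windows = window_registry()) {
  if (!is.numeric(calibration) || calibration <= 0)
    stop("calibration constant must be > 0", call. = FALSE)
  den <- auc(spec_hwn, windows$keratin_ch)
  if (den <= 0) {
    warning("keratin CH AUC <= 0; water mass undefined", call. = FALSE)
    return(NA_real_)
  }
  R <- auc(spec_hwn, windows$water_oh) / den
  100 * R / (R + calibration)
}

#' All eight metrics for one fingerprint + HWN spectrum pair
#'
#' Applies the local tangent-point baselines, the HWN piecewise baseline and
#' both constrained deconvolutions, then evaluates every metric. This is the
#' per-spectrum unit of work of the pipeline.
#'
#' @param spec_fp fingerprint `raman_spectrum` (raw or PCA-denoised)
#' @param spec_hwn hwn `raman_spectrum` (raw)
#' @param config run configuration, see [default_config()]
#' @param seed integer seed for the deconvolution multi-start jitter
#' @return named list with the eight metric values plus `i1655` (baseline
#'   removed 1655 cm^-1 peak height, used for surface detection) and
#'   `converged` (logical, both deconvolutions converged)
#' @export
spectrum_metrics <- function(spec_fp, spec_hwn, config = default_config(),
                             seed = 1) {
  anchors <- config$anchors
  windows <- config$windows
  seg_ss  <- remove_linear_baseline(spec_fp, anchors$ss)
  seg_cs  <- remove_linear_baseline(spec_fp, anchors$cs)
  seg_tyr <- remove_linear_baseline(spec_fp, anchors$tyr)
  seg_cc  <- remove_linear_baseline(spec_fp, anchors$cc)
  seg_am  <- remove_linear_baseline(spec_fp, anchors$amide1)

  fit_am <- fit_bands(seg_am, config$amide1_model, seed = seed,
                      n_starts = config$n_starts)

  hwn_corr <- hwn_baseline(spec_hwn, anchors = config$hwn_anchors,
                           knot = config$hwn_knot)
  fit_hwn <- fit_bands(hwn_corr, config$hwn_model, seed = seed + 1L,
                       n_starts = config$n_starts)

  list(
    beta_alpha_cc     = beta_alpha_cc(seg_cc, windows),
    beta_alpha_amide1 = amide1_ratio(fit_am),
    ss_stability      = ss_stability(seg_ss, windows),
    cs_ss             = cs_ss(seg_cs, seg_ss, windows),
    tyr_ratio         = tyr_ratio(seg_tyr, windows),
    ch3_position      = ch3_peak_position(fit_hwn),
    water_mass_pct    = water_mass_pct(hwn_corr, config$water_calibration,
                                       windows),
    bound_water_ratio = bound_water_ratio(fit_hwn),
    i1655             = spectrum_at(seg_am, 1655),
    converged         = fit_am$converged && fit_hwn$converged
  )
}

#' Names of the eight depth-profiled metrics
#' @return character vector
#' @export
metric_names <- function() {
  c("beta_alpha_cc", "beta_alpha_amide1", "ss_stability", "cs_ss",
    "tyr_ratio", "ch3_position", "water_mass_pct", "bound_water_ratio")
}
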