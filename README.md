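# ramanSC

Depth-resolved analysis of human stratum corneum (SC) by in vivo confocal
Raman microspectroscopy: keratin secondary and tertiary structure, water
content and water hydrogen-bonding state, as functions of normalized SC
depth, with cohort statistics.

## The problem

The outermost skin layer regulates water through the interplay of keratin
conformation, natural moisturizing factor and the hydrogen-bonding state of
water. Confocal Raman microscopes measure this non-invasively as stacks of
spectra acquired every 2 µm from above the skin surface down to ~40 µm, in
two regions: fingerprint (400–2000 cm⁻¹) and high-wavenumber (2000–4000
cm⁻¹). Turning those stacks into interpretable depth profiles requires a
chain of numerical steps — local tangent-point baselines, PCA denoising,
constrained multi-Gaussian band deconvolution, fixed-window band
integration, surface and SC-thickness estimation, depth normalization, and
paired statistics — each with pitfalls that this package implements,
documents and tests.

## What it computes

Per spectrum pair, eight metrics (windows in cm⁻¹):

* β-sheet/α-helix from the C–C skeleton: AUC(952–966)/AUC(924–946)
* (β-sheet + turns/random coil)/α-helix from a 4-Gaussian Amide I
  deconvolution over 1580–1720: (AUGC₁₆₇₀ + AUGC₁₆₈₅)/AUGC₁₆₅₅
* disulphide stability: gauche-gauche-gauche fraction,
  AUC(474–508)/AUC(474–578)
* free cysteine: C–S/S–S, AUC(690–712)/AUC(474–578)
* buried/exposed tyrosine: AUC(816–838)/AUC(838–874)
* keratin folding state: fitted 2930 cm⁻¹ Gaussian position from a
  10-band CH/OH deconvolution over 2800–3700
* water mass %: 100·R/(R + c) with R = AUC(3350–3550)/AUC(2910–2965)
* weakly/strongly bound water: AUGC₃₄₅₈/AUGC₃₂₇₇

Profiles are normalized per volunteer: surface (0%) at the half-maximum of
the 1655 cm⁻¹ keratin profile, SC/SG boundary (100%) where the water
profile's derivative reaches 0.5 %/µm (Crowther criterion), then
interpolation to 10% increments and paired t-tests between adjacent depths
across volunteers.

Because in vivo cohorts of this kind are ethically restricted, the package
ships a synthetic-cohort generator (`synth_cohort()`) that produces
depth series with full ground truth (band parameters, metric trajectories,
surface and thickness per volunteer), so the entire chain is testable.

## Worked example

```r
library(ramanSC)

sim <- synth_cohort(n_volunteers = 3, n_positions = 4, seed = 42)
res <- run_analysis(sim$cohort, default_config(seed = 42))

subset(res$cohort_mean, metric == "ss_stability")
#>        metric depth_pct  mean       sd n
#>  ss_stability         0 0.756 0.034679 3
#>  ss_stability        10 0.711 0.025963 3
#>  ss_stability        30 0.611 0.013932 3
#>  ss_stability        50 0.441 0.005998 3
#>  ss_stability        70 0.330 0.006179 3
#>  ss_stability       100 0.294 0.020109 3
```

The gauche-gauche-gauche fraction of disulphide bonds rises from ~0.3 at
the SC/SG boundary to ~0.76 at the surface: keratin is progressively more
cross-linked (folded) towards the surface. Thickness estimates track the
generator's imposed values within a fraction of the 2 µm sampling step:

```r
merge(res$thickness, sim$truth$volunteers[, c("volunteer", "thickness_um")],
      by = "volunteer", suffixes = c("_estimated", "_true"))
#>  volunteer thickness_um_estimated thickness_um_true
#>        v01                  23.65             24.94
#>        v02                  13.26             13.23
#>        v03                  19.95             19.57
```

And the statistical layer grades adjacent-depth changes (deepest first):

```r
head(subset(res$stats, metric == "ss_stability"), 4)
#>        metric depth_a_pct depth_b_pct      t      p           grade n
#>  ss_stability         100          90 -0.888 0.4681 not significant 3
#>  ss_stability          90          80 -1.748 0.2225 not significant 3
#>  ss_stability          80          70 -5.573 0.0307     significant 3
#>  ss_stability          70          60 -8.048 0.0151     significant 3
```

A thin command-line wrapper with `simulate` and `analyze` subcommands is
installed at `inst/scripts/ramansc.R`. See the vignette
(`vignettes/depth-profiling.Rmd`) for the model, parameter and design
documentation.

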