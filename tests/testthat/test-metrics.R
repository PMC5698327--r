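test_that("disulphide stability follows windowed area fractions", {
  x <- seq(430, 620, 1)
  # single band at 491, negligible intensity above 508
  one <- spectrum(x, gauss_sum(x, 491, 6, 1), "fingerprint")
  expect_equal(ss_stability(one), 1, tolerance = 0.02)

  # three equal-area narrow bands, one per conformer window third
  three <- spectrum(x, gauss_sum(x, c(491, 525, 546), c(6, 6, 6), c(1, 1, 1)),
                    "fingerprint")
  expect_equal(ss_stability(three), 1 / 3, tolerance = 0.02)

  flat <- spectrum(x, rep(1, length(x)), "fingerprint")
  expect_equal(ss_stability(flat), 34 / 104, tolerance = 1e-10)
})

test_that("beta/alpha C-C ratio matches the trapezoid oracle", {
  x <- seq(880, 1010, 1)
  eq <- spectrum(x, gauss_sum(x, c(938, 960), c(8, 8), c(1, 1)), "fingerprint")
  expect_equal(beta_alpha_cc(eq), 1, tolerance = 0.05)

  no960 <- spectrum(x, gauss_sum(x, 938, 8, 1), "fingerprint")
  expect_lt(beta_alpha_cc(no960), 0.02)

  tenx <- spectrum(x, 10 * eq$intensities, "fingerprint")
  expect_equal(beta_alpha_cc(tenx), beta_alpha_cc(eq), tolerance = 1e-12)
})

test_that("C-S/S-S ratio reproduces constructed area ratios", {
  xs <- seq(430, 620, 1)
  xc <- seq(650, 740, 1)
  # S-S system with total windowed area 1.0, C-S band with area 0.12
  a_ss <- 1 / gauss_area_window(525, 20, 1, 474, 578)
  seg_ss <- spectrum(xs, gauss_sum(xs, 525, 20, a_ss), "fingerprint")
  a_cs <- 0.12 / gauss_area_window(700, 8, 1, 690, 712)
  seg_cs <- spectrum(xc, gauss_sum(xc, 700, 8, a_cs), "fingerprint")
  expect_equal(cs_ss(seg_cs, seg_ss), 0.12, tolerance = 5e-3)

  zero_cs <- spectrum(xc, numeric(length(xc)), "fingerprint")
  expect_equal(cs_ss(zero_cs, seg_ss), 0)

  seg_cs2 <- spectrum(xc, 3 * seg_cs$intensities, "fingerprint")
  seg_ss2 <- spectrum(xs, 3 * seg_ss$intensities, "fingerprint")
  expect_equal(cs_ss(seg_cs2, seg_ss2), cs_ss(seg_cs, seg_ss),
               tolerance = 1e-12)
})

test_that("tyrosine doublet ratio behaves linearly", {
  x <- seq(790, 910, 1)
  eq <- spectrum(x, gauss_sum(x, c(830, 850), c(9, 9), c(1, 1)), "fingerprint")
  expect_equal(tyr_ratio(eq), 1, tolerance = 0.05)

  no830 <- spectrum(x, gauss_sum(x, 850, 9, 1), "fingerprint")
  expect_lt(tyr_ratio(no830), 0.03)

  dbl850 <- spectrum(x, gauss_sum(x, c(830, 850), c(9, 9), c(1, 2)),
                     "fingerprint")
  expect_equal(tyr_ratio(dbl850), tyr_ratio(eq) / 2, tolerance = 0.02)
})

test_that("water mass percent has the saturating calibration form", {
  x <- seq(2000, 4000, 2)
  mk <- function(oh_amp) spectrum(
    x, gauss_sum(x, c(2930, 3450), c(34, 110), c(1, oh_amp)), "hwn")
  # R = c forces 50%
  ker <- gauss_area_window(2930, 34, 1, 2910, 2965)
  probe <- gauss_area_window(3450, 110, 1, 3350, 3550)
  amp50 <- ker / probe  # makes R = 1 = default calibration
  expect_equal(water_mass_pct(mk(amp50)), 50, tolerance = 0.2)
  expect_equal(water_mass_pct(mk(0)), 0, tolerance = 1e-8)
  # monotone in R and bounded
  w <- sapply(c(0.05, 0.2, 0.5, 1, 3, 10) * amp50, function(a)
    water_mass_pct(mk(a)))
  expect_true(all(diff(w) > 0))
  expect_true(all(w >= 0 & w < 100))
  expect_error(water_mass_pct(mk(1), calibration = 0), "> 0")
})

test_that("generator inverse water mapping round-trips within 1 mass %", {
  sim <- small_cohort(sigma = 0)
  ds <- sim$cohort$volunteers[[1]][[1]]
  st <- sim$truth$spectrum_truth
  for (di in c(8, 12, 16)) {
    w_est <- water_mass_pct(hwn_baseline(ds$spectra_hwn[[di]]))
    w_true <- st$value[st$volunteer == ds$volunteer_id &
                         st$position == ds$position_id &
                         st$depth_um == ds$depths_um[di] &
                         st$metric == "water_mass_pct"]
    expect_equal(w_est, w_true, tolerance = 1)
  }
})

test_that("every ratio metric is invariant under global intensity scaling", {
  sim <- small_cohort(sigma = 0)
  ds <- sim$cohort$volunteers[[1]][[1]]
  cfg <- default_config()
  m1 <- suppressWarnings(spectrum_metrics(ds$spectra_fp[[10]],
                                          ds$spectra_hwn[[10]], cfg, seed = 1))
  fp_s <- spectrum(ds$spectra_fp[[10]]$wavenumbers,
                   7 * ds$spectra_fp[[10]]$intensities, "fingerprint")
  hw_s <- spectrum(ds$spectra_hwn[[10]]$wavenumbers,
                   7 * ds$spectra_hwn[[10]]$intensities, "hwn")
  m2 <- suppressWarnings(spectrum_metrics(fp_s, hw_s, cfg, seed = 1))
  for (m in setdiff(metric_names(), "ch3_position"))
    expect_equal(m2[[m]], m1[[m]], tolerance = 1e-6, label = m)
  expect_equal(m2$ch3_position, m1$ch3_position, tolerance = 0.05)
})

test_that("ss_stability stays within [0, 1] on random non-negative spectra", {
  x <- seq(430, 620, 1)
  set.seed(31)
  for (i in 1:25) {
    nb <- sample(1:4, 1)
    y <- gauss_sum(x, runif(nb, 470, 580), runif(nb, 5, 30), runif(nb, 0, 2)) +
      runif(1, 0, 0.5)
    v <- ss_stability(spectrum(x, y, "fingerprint"))
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
})
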