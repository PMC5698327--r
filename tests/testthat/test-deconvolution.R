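amide_true <- list(center = c(1617, 1655, 1670, 1685),
                   fwhm = c(23, 30, 15, 37),
                   amp = c(0.2, 1.0, 0.3, 0.25))

amide_segment <- function(amp = amide_true$amp, noise_sd = 0, seed = NULL) {
  x <- seq(1540, 1760, 1)
  y <- gauss_sum(x, amide_true$center, amide_true$fwhm, amp)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + rnorm(length(x), 0, noise_sd)
  }
  spectrum(x, y, "fingerprint")
}

test_that("noiseless four-band Amide I construction is recovered exactly", {
  res <- fit_bands(amide_segment(), amide1_model(), seed = 1)
  expect_true(res$converged)
  expect_equal(res$bands$center, amide_true$center, tolerance = 0.01)
  expect_equal(res$bands$fwhm, amide_true$fwhm, tolerance = 0.01)
  expect_equal(res$bands$amplitude, amide_true$amp, tolerance = 0.01)
  energy <- sum(amide_segment()$intensities[
    amide_segment()$wavenumbers >= 1580 & amide_segment()$wavenumbers <= 1720]^2)
  expect_lt(res$rss, 1e-10 * energy)
})

test_that("zero segment yields zero amplitudes and zero residual", {
  x <- seq(1540, 1760, 1)
  res <- fit_bands(spectrum(x, numeric(length(x)), "fingerprint"),
                   amide1_model(), seed = 1)
  expect_equal(res$bands$amplitude, rep(0, 4), tolerance = 1e-8)
  expect_lt(res$rss, 1e-12)
})

test_that("a single in-box Gaussian is matched by the right band only", {
  seg <- amide_segment(amp = c(0, 1, 0, 0))
  res <- fit_bands(seg, amide1_model(), seed = 2)
  expect_equal(res$bands$center[2], 1655, tolerance = 0.1)
  expect_equal(res$bands$amplitude[2], 1, tolerance = 0.01)
  expect_lt(max(res$bands$amplitude[-2]), 0.01)

  # grid-search oracle over (center, fwhm, amplitude) for the single band
  x <- seg$wavenumbers; y <- seg$intensities
  grid <- expand.grid(c = seq(1650, 1660, 0.5), w = seq(24, 36, 0.5),
                      a = seq(0.8, 1.2, 0.02))
  sse <- mapply(function(c, w, a) sum((y - gauss_sum(x, c, w, a))^2),
                grid$c, grid$w, grid$a)
  best <- grid[which.min(sse), ]
  expect_equal(res$bands$center[2], best$c, tolerance = 0.5)
  expect_equal(res$bands$fwhm[2], best$w, tolerance = 0.5)
  expect_equal(res$bands$amplitude[2], best$a, tolerance = 0.02)
})

test_that("fit scales linearly with intensity and beats the null model", {
  seg <- amide_segment()
  res1 <- fit_bands(seg, amide1_model(), seed = 3)
  seg10 <- spectrum(seg$wavenumbers, 10 * seg$intensities, "fingerprint")
  res10 <- fit_bands(seg10, amide1_model(), seed = 3)
  expect_equal(res10$bands$amplitude, 10 * res1$bands$amplitude,
               tolerance = 1e-3)
  expect_equal(res10$bands$center, res1$bands$center, tolerance = 0.05)
  expect_equal(res10$bands$fwhm, res1$bands$fwhm, tolerance = 0.05)

  nseg <- amide_segment(noise_sd = 0.05, seed = 99)
  resn <- fit_bands(nseg, amide1_model(), seed = 3)
  x <- nseg$wavenumbers
  energy <- sum(nseg$intensities[x >= 1580 & x <= 1720]^2)
  expect_lt(resn$rss, energy)  # never worse than the all-zero model
})

test_that("amide ratio follows the closed-form AUGC arithmetic", {
  res <- fit_bands(amide_segment(), amide1_model(), seed = 1)
  expect_equal(amide1_ratio(res), (0.3 * 15 + 0.25 * 37) / (1.0 * 30),
               tolerance = 1e-3)

  res0 <- fit_bands(amide_segment(amp = c(0.2, 1, 0, 0)), amide1_model(),
                    seed = 1)
  expect_equal(amide1_ratio(res0), 0, tolerance = 1e-3)

  # all four bands with equal amplitude and equal FWHM -> ratio 2 by symmetry
  fake <- res
  fake$bands$fwhm <- rep(20, 4)
  fake$bands$amplitude <- rep(1, 4)
  fake$bands$augc <- gauss_area(fake$bands$fwhm, fake$bands$amplitude)
  expect_equal(amide1_ratio(fake), 2, tolerance = 1e-12)

  fake$bands$augc[2] <- 0
  expect_warning(r <- amide1_ratio(fake), "undefined")
  expect_true(is.na(r))
})

hwn_segment <- function(ch3_center = 2930, oh_amp = c(0.45, 1, 0.6, 0.35, 0.12),
                        noise_sd = 0, seed = NULL) {
  x <- seq(2000, 4000, 2)
  centers <- c(2850, 2880, ch3_center, 2980, 3063, 3180, 3277, 3458, 3550, 3630)
  fwhms <- c(22, 28, 34, 30, 40, 120, 100, 100, 80, 55)
  amps <- c(0.55, 0.72, 1.0, 0.4, 0.22, oh_amp)
  y <- gauss_sum(x, centers, fwhms, amps)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + rnorm(length(x), 0, noise_sd)
  }
  spectrum(x, y, "hwn")
}

test_that("the 2930 band position tracks the generated CH3 centre", {
  for (true_c in c(2928, 2930)) {
    res <- fit_bands(hwn_segment(ch3_center = true_c), hwn_model(), seed = 4)
    expect_equal(ch3_peak_position(res), true_c, tolerance = 0.2)
  }
  r1 <- fit_bands(hwn_segment(ch3_center = 2927), hwn_model(), seed = 5)
  r2 <- fit_bands(hwn_segment(ch3_center = 2931), hwn_model(), seed = 5)
  expect_equal(ch3_peak_position(r2) - ch3_peak_position(r1), 4,
               tolerance = 0.5)
})

test_that("bound water ratio is recovered from the OH sub-band system", {
  # equal amplitudes and FWHMs at 3277 and 3458 -> exactly 1
  res <- fit_bands(hwn_segment(oh_amp = c(0.45, 0.8, 0.8, 0.35, 0.12)),
                   hwn_model(), seed = 6)
  expect_equal(bound_water_ratio(res), 1, tolerance = 0.02)

  # generated AUGC ratio 0.6 at roughly SNR 50 (peak ~2, sd 0.04);
  # median over seeded noise replicates isolates estimator accuracy from
  # single-draw scatter
  r6 <- sapply(1:9, function(k) bound_water_ratio(
    fit_bands(hwn_segment(oh_amp = c(0.45, 1, 0.6, 0.35, 0.12),
                          noise_sd = 0.04, seed = 100 + k),
              hwn_model(), seed = 7)))
  expect_equal(median(r6), 0.6, tolerance = 0.05)

  res0 <- fit_bands(hwn_segment(oh_amp = c(0.45, 1, 0, 0.35, 0.12)),
                    hwn_model(), seed = 8)
  expect_equal(bound_water_ratio(res0), 0, tolerance = 0.01)
})

test_that("constraint sets validate their boxes", {
  expect_error(constraint_set("a", 100, -1, 10, 1, c(50, 150)), "non-negative")
  expect_error(constraint_set(c("a", "b"), c(100, 100), c(1, 1), c(10, 10),
                              c(1, 1), c(50, 150)), "distinct")
  expect_error(constraint_set("a", 100, 1, 5, 6, c(50, 150)), "positive")
  m <- amide1_model()
  expect_equal(m$center, c(1617, 1655, 1670, 1685))
  expect_equal(m$center_slack, c(7, 5, 5, 5))
  expect_equal(m$fwhm, c(23, 30, 15, 37))
  expect_equal(m$fwhm_slack, c(10, 6, 7, 7))
  expect_equal(m$fit_range, c(1580, 1720))
})
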