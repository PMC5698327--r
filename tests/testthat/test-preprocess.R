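anch <- list(band = c(600, 700), left = c(560, 590), right = c(710, 740))

test_that("linear baseline removal is exact on lines and preserves bands", {
  x <- seq(400, 1000, 1)
  line <- spectrum(x, 3 * x + 7, "fingerprint")
  seg <- remove_linear_baseline(line, anch)
  expect_lt(max(abs(seg$intensities)), 1e-9 * max(line$intensities))

  withband <- spectrum(x, 3 * x + 7 + gauss_sum(x, 650, 18, 2), "fingerprint")
  seg2 <- remove_linear_baseline(withband, anch)
  expect_equal(auc(seg2, c(600, 700)),
               gauss_area_window(650, 18, 2, 600, 700), tolerance = 5e-3)

  zero <- spectrum(x, numeric(length(x)), "fingerprint")
  expect_lt(max(abs(remove_linear_baseline(zero, anch)$intensities)), 1e-12)
})

test_that("baseline removal errors on bad anchors", {
  x <- seq(400, 1000, 1)
  sp <- spectrum(x, rnorm(length(x)), "fingerprint")
  expect_error(remove_linear_baseline(
    sp, list(band = c(600, 700), left = c(300, 390), right = c(710, 740))),
    "outside")
  sparse <- spectrum(seq(400, 1000, 10), rnorm(61), "fingerprint")
  expect_error(remove_linear_baseline(sparse, anch), "5 anchor samples")
})

test_that("baseline removal is idempotent and commutes with scaling", {
  x <- seq(400, 1000, 1)
  sp <- spectrum(x, 0.5 * x + gauss_sum(x, 650, 20, 3) + 10, "fingerprint")
  once <- remove_linear_baseline(sp, anch)
  twice <- remove_linear_baseline(once,
    list(band = anch$band, left = anch$left, right = anch$right))
  expect_equal(twice$intensities,
               once$intensities[once$wavenumbers >= anch$left[1] &
                                  once$wavenumbers <= anch$right[2]],
               tolerance = 1e-10)

  scaled <- spectrum(x, 4 * sp$intensities, "fingerprint")
  expect_equal(remove_linear_baseline(scaled, anch)$intensities,
               4 * once$intensities, tolerance = 1e-10)
})

test_that("PCA reconstruction: full rank is identity, mean is preserved", {
  x <- seq(400, 800, 2)
  set.seed(7)
  grp <- lapply(1:6, function(i)
    spectrum(x, gauss_sum(x, 600, 30, runif(1, 0.5, 2)) + rnorm(length(x), 0, 0.01),
             "fingerprint"))
  full <- pca_reconstruct(grp, k = 6)
  for (i in 1:6)
    expect_equal(full[[i]]$intensities, grp[[i]]$intensities, tolerance = 1e-8)

  rec <- pca_reconstruct(grp, k = 2)
  mean_in <- rowMeans(sapply(grp, function(s) s$intensities))
  mean_out <- rowMeans(sapply(rec, function(s) s$intensities))
  expect_equal(mean_out, mean_in, tolerance = 1e-10)

  expect_error(pca_reconstruct(grp[1:3], k = 4), "lower k")
})

test_that("PCA with k=1 denoises a rank-1 signal family below sigma", {
  x <- seq(400, 800, 2)
  clean <- gauss_sum(x, 600, 40, 1)
  sigma <- 0.05
  set.seed(11)
  scales <- seq(0.5, 5, length.out = 10)
  grp <- lapply(scales, function(s)
    spectrum(x, s * clean + rnorm(length(x), 0, sigma), "fingerprint"))
  rec <- pca_reconstruct(grp, k = 1)
  rmse <- sapply(seq_along(scales), function(i)
    sqrt(mean((rec[[i]]$intensities - scales[i] * clean)^2)))
  expect_lt(max(rmse), sigma)
})

test_that("PCA on an identical group returns the input for any k", {
  x <- seq(400, 800, 2)
  one <- spectrum(x, gauss_sum(x, 600, 30, 1), "fingerprint")
  grp <- replicate(5, one, simplify = FALSE)
  for (k in c(0, 2, 5)) {
    rec <- pca_reconstruct(grp, k = k)
    expect_equal(rec[[3]]$intensities, one$intensities, tolerance = 1e-10)
  }
})

test_that("HWN baseline removes its own model exactly", {
  x <- seq(2000, 4000, 2)
  knot <- 3800
  pw <- 5 + 0.002 * pmin(x - knot, 0) - 0.004 * pmax(x - knot, 0)
  sp <- spectrum(x, pw, "hwn")
  out <- hwn_baseline(sp)
  expect_lt(max(abs(out$intensities)), 1e-9 * max(abs(pw)))

  const <- spectrum(x, rep(2, length(x)), "hwn")
  expect_lt(max(abs(hwn_baseline(const)$intensities)), 1e-10)

  short <- spectrum(seq(2900, 3700, 2), rep(1, 401), "hwn")
  expect_error(hwn_baseline(short), "anchor region")
})

test_that("HWN baseline preserves OH band areas on top of the model", {
  x <- seq(2000, 4000, 2)
  knot <- 3800
  pw <- 1 + 0.001 * pmin(x - knot, 0) + 0.003 * pmax(x - knot, 0)
  bands <- gauss_sum(x, c(3277, 3458), c(100, 100), c(0.8, 0.5))
  sp <- spectrum(x, pw + bands, "hwn")
  out <- hwn_baseline(sp)
  expect_equal(auc(out, c(3350, 3550)),
               gauss_area_window(c(3277, 3458), c(100, 100), c(0.8, 0.5),
                                 3350, 3550),
               tolerance = 1e-2)
})
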