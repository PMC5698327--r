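test_that("spectrum validation rejects constructed violations", {
  wn <- seq(400, 2000, 1)
  ok <- spectrum(wn, rep(1, length(wn)), "fingerprint")
  expect_s3_class(ok, "raman_spectrum")

  expect_error(spectrum(wn, rep(1, 10), "fingerprint"), "length")
  expect_error(spectrum(wn[1:10], rep(1, 10), "fingerprint"), "fewer than 16")
  wn_bad <- wn; wn_bad[500] <- wn_bad[499]  # duplicated wavenumber
  expect_error(spectrum(wn_bad, rep(1, length(wn)), "fingerprint"),
               as.character(wn_bad[500]))
  wn_shuf <- sample(wn)
  expect_error(spectrum(wn_shuf, rep(1, length(wn)), "fingerprint"),
               "increasing")
  # region span mismatch
  expect_error(spectrum(seq(2500, 3000, 2), rep(1, 251), "fingerprint"),
               "region")
})

test_that("gaussian band area matches numerical integration", {
  b <- gaussian_band(1655, 30, 1.7)
  num <- integrate(function(x) gauss_sum(x, 1655, 30, 1.7),
                   1655 - 400, 1655 + 400, rel.tol = 1e-12)$value
  expect_equal(gauss_area(b), num, tolerance = 1e-9)
  # windowed closed form against integrate on a finite window
  numw <- integrate(function(x) gauss_sum(x, 960, 10, 0.8), 952, 966,
                    rel.tol = 1e-12)$value
  expect_equal(gauss_area_window(960, 10, 0.8, 952, 966), numw,
               tolerance = 1e-9)
})

test_that("depth series validation enforces pairing and increments", {
  wn_fp <- seq(400, 2000, 10)
  wn_hw <- seq(2000, 4000, 10)
  mkf <- function() spectrum(wn_fp, runif(length(wn_fp)), "fingerprint")
  mkh <- function() spectrum(wn_hw, runif(length(wn_hw)), "hwn")
  z <- seq(0, 8, 2)
  ds <- depth_series(z, replicate(5, mkf(), simplify = FALSE),
                     replicate(5, mkh(), simplify = FALSE))
  expect_s3_class(ds, "depth_series")
  expect_error(depth_series(z, replicate(4, mkf(), simplify = FALSE),
                            replicate(5, mkh(), simplify = FALSE)),
               "one fingerprint spectrum per depth")
  expect_error(depth_series(c(0, 2, 4, 6, 9),
                            replicate(5, mkf(), simplify = FALSE),
                            replicate(5, mkh(), simplify = FALSE)),
               "increment")
  expect_error(depth_series(z, replicate(5, mkh(), simplify = FALSE),
                            replicate(5, mkf(), simplify = FALSE)),
               "spectrum")
})

test_that("depth series round-trips losslessly through the TSV layout", {
  sim <- small_cohort()
  ds <- sim$cohort$volunteers[[1]][[1]]
  dir <- file.path(tempdir(), "rt", ds$volunteer_id, ds$position_id)
  write_depth_series(ds, dir)
  back <- read_depth_series(dir)
  expect_equal(back$depths_um, ds$depths_um)
  for (i in seq_along(ds$depths_um)) {
    expect_equal(back$spectra_fp[[i]]$intensities,
                 signif(ds$spectra_fp[[i]]$intensities, 12))
    expect_equal(back$spectra_hwn[[i]]$intensities,
                 signif(ds$spectra_hwn[[i]]$intensities, 12))
  }
})

test_that("read_depth_series reports structured errors", {
  empty <- file.path(tempdir(), "empty_dir")
  dir.create(empty, showWarnings = FALSE)
  expect_error(read_depth_series(empty), "no depth files found")

  sim <- small_cohort()
  ds <- sim$cohort$volunteers[[1]][[1]]
  dir <- file.path(tempdir(), "broken", "v01", "p01")
  write_depth_series(ds, dir)
  file.remove(file.path(dir, "hwn.tsv"))
  expect_error(read_depth_series(dir), "missing region file.*hwn")

  dir2 <- file.path(tempdir(), "dup", "v01", "p01")
  write_depth_series(ds, dir2)
  tsv <- readLines(file.path(dir2, "fingerprint.tsv"))
  i <- grep("^500\t", tsv)[1]
  tsv[i] <- sub("^500\t", "499\t", tsv[i])  # duplicate of previous grid point
  writeLines(tsv, file.path(dir2, "fingerprint.tsv"))
  expect_error(read_depth_series(dir2), "499")
})

test_that("cohort round-trips through manifest + directories", {
  sim <- small_cohort()
  dir <- file.path(tempdir(), "cohort_rt")
  write_cohort(sim$cohort, dir)
  back <- read_cohort(dir)
  expect_equal(names(back$volunteers), names(sim$cohort$volunteers))
  expect_equal(back$volunteers[[2]][[3]]$spectra_fp[[4]]$intensities,
               signif(sim$cohort$volunteers[[2]][[3]]$spectra_fp[[4]]$intensities, 12))
})

test_that("profile tables have the documented shape and round-trip", {
  one <- data.frame(metric = "water_mass_pct", volunteer = "v01",
                    depth_pct = seq(0, 100, 10), value = rnorm(11))
  f <- tempfile(fileext = ".tsv")
  write_profiles(one, f)
  expect_equal(nrow(read_profiles(f)), 11)
  expect_equal(read_profiles(f)$value, signif(one$value, 12))

  grid <- expand.grid(metric = metric_names(),
                      volunteer = sprintf("v%02d", 1:11),
                      depth_pct = seq(0, 100, 10),
                      stringsAsFactors = FALSE)
  grid$value <- seq_len(nrow(grid)) * 0.1
  write_profiles(grid, f)
  expect_equal(nrow(read_profiles(f)), 8 * 11 * 11)  # 968 data rows
})
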