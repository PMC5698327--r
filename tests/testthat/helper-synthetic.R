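# Shared fixtures, built in code at test time.

# Single-Gaussian spectrum on a regular grid.
gauss_spectrum <- function(center, fwhm, amplitude, from, to, by = 1,
                           region = "fingerprint", baseline = 0, slope = 0) {
  x <- seq(from, to, by = by)
  y <- gauss_sum(x, center, fwhm, amplitude) + baseline + slope * (x - from)
  spectrum(x, y, region)
}

# Multi-band fingerprint segment already baseline-free.
bands_spectrum <- function(centers, fwhms, amps, from, to, by = 1,
                           region = "fingerprint") {
  x <- seq(from, to, by = by)
  spectrum(x, gauss_sum(x, centers, fwhms, amps), region)
}

# Small synthetic cohort cached across test files (generation is the
# expensive part); built once per test run.
small_cohort <- local({
  cache <- NULL
  function(sigma = 0.02) {
    key <- paste0("s", sigma)
    if (is.null(cache[[key]])) {
      ns <- default_noise_spec()
      ns$sigma <- sigma
      cache[[key]] <<- synth_cohort(n_volunteers = 3, n_positions = 4,
                                    noise = ns, seed = 42)
    }
    cache[[key]]
  }
})

# Independent closed-form paired t (oracle for cohort_stats).
manual_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  p <- 2 * pt(-abs(t), df = n - 1)
  list(t = t, p = p)
}

# Independent Jarque-Bera (oracle).
manual_jb <- function(x) {
  n <- length(x)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  S <- mean((x - m)^3) / s2^1.5
  K <- mean((x - m)^4) / s2^2 - 3
  jb <- n / 6 * (S^2 + K^2 / 4)
  list(jb = jb, p = pchisq(jb, 2, lower.tail = FALSE))
}
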