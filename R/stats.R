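#' Significance grading of p-values
#'
#' `p <= 0.01` is graded "highly significant", `p <= 0.05` "significant",
#' `p <= 0.1` "trend" and anything larger "not significant". Boundary values
#' land in the stricter class.
#'
#' @param p p-value in `[0, 1]`
#' @return one of `"highly significant"`, `"significant"`, `"trend"`,
#'   `"not significant"`
#' @export
grade_p <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("p must be a single value in [0, 1]", call. = FALSE)
  if (p <= 0.01) "highly significant"
  else if (p <= 0.05) "significant"
  else if (p <= 0.1) "trend"
  else "not significant"
}

.stat_result <- function(statistic, p, n, method, warn = NULL) {
  structure(list(statistic = statistic, p = p, n = n, method = method,
                 grade = grade_p(min(max(p, 0), 1)), warning = warn),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: statistic %.4g, p %.4g (n=%d) -> %s\n",
              x$method, x$statistic, x$p, x$n, x$grade))
  if (!is.null(x$warning)) cat("  note:", x$warning, "\n")
  invisible(x)
}

#' Paired Student's t-test between two depths
#'
#' Classical paired two-sided t-test on the per-volunteer differences,
#' delegating to [stats::t.test()]. Zero-variance differences with nonzero
#' mean are reported as `p = 0` with a degeneracy note rather than an error.
#'
#' @param a,b equal-length per-volunteer value vectors (one pair per
#'   volunteer), `n >= 3`, no missing pairs
#' @return a `stat_result` with fields `statistic` (t), `p`, `n`, `grade`
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors differ in length",
                                   call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("missing pairs not allowed", call. = FALSE)
  n <- length(a)
  if (n < 3L) stop("paired t-test needs n >= 3", call. = FALSE)
  d <- a - b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(.stat_result(0, 1, n, "paired t",
                          warn = "all differences zero"))
    warning("zero variance of differences with nonzero mean; p reported as 0",
            call. = FALSE)
    return(.stat_result(sign(mean(d)) * Inf, 0, n, "paired t",
                        warn = "degenerate: constant nonzero differences"))
  }
  tt <- stats::t.test(a, b, paired = TRUE, alternative = "two.sided")
  .stat_result(unname(tt$statistic), tt$p.value, n, "paired t")
}

#' Jarque-Bera normality test
#'
#' `JB = n/6 (S^2 + K^2/4)` with `S` the sample skewness and `K` the excess
#' kurtosis (both with 1/n moments), referred to the chi-squared distribution
#' with 2 degrees of freedom. The chi-squared reference is asymptotic; for
#' small n the p-values are approximate, which is noted on the result.
#'
#' @param x numeric sample, `n >= 8`, non-constant
#' @return a `stat_result` with fields `statistic` (JB), `p`, `n`, `grade`
#' @export
jarque_bera <- function(x) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("missing values not allowed", call. = FALSE)
  n <- length(x)
  if (n < 8L) stop("Jarque-Bera needs n >= 8", call. = FALSE)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) stop("constant input: skewness undefined", call. = FALSE)
  S <- mean((x - m)^3) / s2^1.5
  K <- mean((x - m)^4) / s2^2 - 3
  jb <- n / 6 * (S^2 + K^2 / 4)
  p <- stats::pchisq(jb, df = 2, lower.tail = FALSE)
  .stat_result(jb, p, n, "Jarque-Bera",
               warn = if (n < 50) "chi-squared reference is asymptotic; small-n p approximate")
}

#' Paired comparisons between adjacent normalised depths
#'
#' For each metric, traverses the normalised profile from the deepest layers
#' towards the surface (matching the direction of corneocyte transformation)
#' and applies the paired t-test between each pair of adjacent depth grid
#' points across volunteers, together with a Jarque-Bera normality check of
#' the differences when enough volunteers are available. No multiple-testing
#' correction is applied: adjacent-depth comparisons are reported raw.
#'
#' @param profiles data.frame with columns metric, volunteer, depth_pct,
#'   value (one row per metric x volunteer x grid point)
#' @return data.frame: metric, depth_a_pct, depth_b_pct, t, p, grade, n,
#'   jb_p (NA when not computable)
#' @export
adjacent_depth_stats <- function(profiles) {
  out <- list()
  for (mname in unique(profiles$metric)) {
    sub <- profiles[profiles$metric == mname, ]
    grid <- sort(unique(sub$depth_pct), decreasing = TRUE)  # deepest first
    for (i in seq_len(length(grid) - 1L)) {
      da <- grid[i]; db <- grid[i + 1L]
      va <- sub[sub$depth_pct == da, ]
      vb <- sub[sub$depth_pct == db, ]
      vols <- intersect(va$volunteer, vb$volunteer)
      a <- va$value[match(vols, va$volunteer)]
      b <- vb$value[match(vols, vb$volunteer)]
      ok <- is.finite(a) & is.finite(b)
      a <- a[ok]; b <- b[ok]
      if (length(a) < 3L) next
      st <- paired_t(a, b)
      jb_p <- if (length(a) >= 8L && stats::sd(a - b) > 0)
        jarque_bera(a - b)$p else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        metric = mname, depth_a_pct = da, depth_b_pct = db,
        t = st$statistic, p = st$p, grade = st$grade, n = st$n, jb_p = jb_p,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
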