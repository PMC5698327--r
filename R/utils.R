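# Run code with a temporary RNG state; restores the caller's state afterwards.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Monotone cubic Hermite (Fritsch-Carlson) interpolation with NA outside
# the data range: shape-preserving, exact for affine data, and with far
# smaller corner-cutting error than linear interpolation on smooth curves.
.interp_mono <- function(x, y, xout) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) return(rep(NA_real_, length(xout)))
  f <- stats::splinefun(x, y, method = "monoH.FC")
  out <- f(xout)
  out[xout < min(x) | xout > max(x)] <- NA_real_
  out
}

# Deterministic sub-seed derivation, kept inside 32-bit integer range.
# Character parts are hashed by their byte values.
.sub_seed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  s <- 0
  for (p in parts) {
    v <- if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p)))
         else as.numeric(p)
    s <- (s * 1000003 + (v %% 2147483647)) %% 2147483629
  }
  as.integer(s %% 2147483629) + 1L
}
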