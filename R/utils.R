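# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

## wrap displacement components into the minimum image for an orthorhombic box
min_image <- function(d, L) d - L * round(d / L)

## linear interpolation with linear (first/last segment slope) extrapolation;
## exact for affine inputs, unlike approx(rule = 2)
lin_interp_extrap <- function(x, y, xout) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  if (length(x) == 1L) return(rep(y, length(xout)))
  o <- order(x)
  x <- x[o]; y <- y[o]
  out <- approx(x, y, xout = xout, rule = 2, ties = "ordered")$y
  lo <- xout < x[1L]
  if (any(lo)) {
    s <- (y[2L] - y[1L]) / (x[2L] - x[1L])
    out[lo] <- y[1L] + s * (xout[lo] - x[1L])
  }
  n <- length(x)
  hi <- xout > x[n]
  if (any(hi)) {
    s <- (y[n] - y[n - 1L]) / (x[n] - x[n - 1L])
    out[hi] <- y[n] + s * (xout[hi] - x[n])
  }
  out
}

## draw independent sub-seeds (< 2^31) from a master seed without
## disturbing the caller's RNG state
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max, n))
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)
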