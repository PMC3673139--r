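# Periodized discrete wavelet transform (Mallat filter bank).
#
# One analysis stage circularly convolves the signal with the decomposition
# low/high-pass filters and keeps every second output:
#
#   a[k] = sum_m lo[m] x[(2k + L/2 - m) mod N],   k = 0..N/2-1
#
# with L the (even) filter length. The synthesis stage upsamples by two and
# circularly convolves with the reconstruction filters at phase L/2 - 1. With
# the filter alignment used by the registry this pair is perfect-reconstructing
# with zero delay for every supported wavelet and any even N, and for
# orthogonal wavelets it is energy-preserving (Parseval). Non-dyadic windows
# are symmetrically reflection-padded up to the next multiple of 2^level
# before analysis, which is what keeps the textbook N/2^j coefficient-length
# arithmetic exact.

.dwt_max_level <- 7L

.dwt_step <- function(x, lo, hi) {
  n <- length(x)
  half <- n %/% 2L
  taps <- length(lo)
  pos <- 2L * (0:(half - 1L)) + taps %/% 2L
  a <- numeric(half)
  d <- numeric(half)
  for (m in seq_len(taps)) {
    xi <- x[((pos - (m - 1L)) %% n) + 1L]
    a <- a + lo[m] * xi
    d <- d + hi[m] * xi
  }
  list(a = a, d = d)
}

.idwt_step <- function(a, d, lo, hi) {
  half <- length(a)
  n <- 2L * half
  taps <- length(lo)
  up_a <- numeric(n)
  up_d <- numeric(n)
  odd <- seq(1L, n, by = 2L)
  up_a[odd] <- a
  up_d[odd] <- d
  x <- numeric(n)
  pos <- 0:(n - 1L) + taps %/% 2L - 1L
  for (m in seq_len(taps)) {
    idx <- ((pos - (m - 1L)) %% n) + 1L
    x <- x + lo[m] * up_a[idx] + hi[m] * up_d[idx]
  }
  x
}

# Reflection (half-sample symmetric) index into 1..n, valid for any distance.
.reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * n
  j <- ((i - 1L) %% period)
  j <- ifelse(j < 0L, j + period, j)
  ifelse(j < n, j + 1L, period - j)
}

.pad_dyadic <- function(x, level) {
  n <- length(x)
  block <- 2L^level
  target <- as.integer(block * ceiling(n / block))
  extra <- target - n
  left <- extra %/% 2L
  right <- extra - left
  if (extra == 0L) {
    return(list(x = x, left = 0L))
  }
  idx <- .reflect_index(seq.int(1L - left, n + right), n)
  list(x = x[idx], left = left)
}

#' Multilevel periodized discrete wavelet transform
#'
#' Iterates the two-channel analysis filter bank `level` times: each stage
#' splits the current approximation into new approximation and detail
#' coefficients and downsamples both by two. Signals whose length is not a
#' multiple of `2^level` are first reflection-padded symmetrically up to the
#' next multiple, so that the level-`j` coefficient vectors have exactly
#' `N/2^j` elements (`N` the padded length).
#'
#' @param signal numeric vector, at least 2 finite samples.
#' @param wavelet a wavelet name or `wavelet_spec` (see [get_wavelet()]).
#' @param level decomposition depth, an integer in 1..7. Deeper decompositions
#'   buy little for 9-second activity windows and are refused.
#' @return a `dwt_coefficients` object: `approximation` (the level-`level`
#'   approximation vector), `details` (list, element `j` is the level-`j`
#'   detail vector `D_j`), the padded length `n`, the unpadded input length
#'   `n_input`, and the left padding offset used.
#' @seealso [idwt_reconstruct()] for the inverse transform.
#' @export
dwt_decompose <- function(signal, wavelet, level) {
  w <- get_wavelet(wavelet)
  if (!is.numeric(signal) || length(signal) < 2L) {
    stop("`signal` must be a numeric vector with at least 2 samples",
         call. = FALSE)
  }
  if (anyNA(signal) || any(!is.finite(signal))) {
    stop("`signal` contains non-finite values", call. = FALSE)
  }
  if (length(level) != 1L || is.na(level) || level != as.integer(level) ||
      level < 1L) {
    stop("`level` must be a positive integer", call. = FALSE)
  }
  level <- as.integer(level)
  if (level > .dwt_max_level) {
    stop(sprintf("`level` must be at most %d", .dwt_max_level), call. = FALSE)
  }
  padded <- .pad_dyadic(as.numeric(signal), level)
  if (length(padded$x) < length(w$dec_lo)) {
    stop(sprintf(
      "signal too short: padded length %d is below the %d-tap filter of '%s'",
      length(padded$x), length(w$dec_lo), w$name), call. = FALSE)
  }
  a <- padded$x
  details <- vector("list", level)
  for (j in seq_len(level)) {
    st <- .dwt_step(a, w$dec_lo, w$dec_hi)
    details[[j]] <- st$d
    a <- st$a
  }
  structure(
    list(wavelet = w$name, level = level, approximation = a,
         details = details, n = length(padded$x),
         n_input = length(signal), pad_left = padded$left),
    class = "dwt_coefficients")
}

.validate_coefficients <- function(coeffs) {
  if (!inherits(coeffs, "dwt_coefficients")) {
    stop("`coeffs` must be a dwt_coefficients object", call. = FALSE)
  }
  lev <- coeffs$level
  n <- coeffs$n
  if (length(coeffs$details) != lev) {
    stop(sprintf("expected %d detail vectors, found %d",
                 lev, length(coeffs$details)), call. = FALSE)
  }
  if (length(coeffs$approximation) != n / 2^lev) {
    stop("approximation length inconsistent with level and padded length",
         call. = FALSE)
  }
  for (j in seq_len(lev)) {
    if (length(coeffs$details[[j]]) != n / 2^j) {
      stop(sprintf("detail vector D_%d has inconsistent length", j),
           call. = FALSE)
    }
  }
  invisible(coeffs)
}

#' Inverse periodized discrete wavelet transform
#'
#' Exact inverse of [dwt_decompose()]: runs the synthesis filter bank from the
#' deepest level upwards and strips the reflection padding, returning a vector
#' of the original input length. Reconstruction is exact to floating-point
#' rounding for every wavelet in the registry.
#'
#' @param coeffs a `dwt_coefficients` object.
#' @param wavelet wavelet name or spec; defaults to the one recorded in
#'   `coeffs`.
#' @return numeric vector of length `coeffs$n_input`.
#' @export
idwt_reconstruct <- function(coeffs, wavelet = coeffs$wavelet) {
  .validate_coefficients(coeffs)
  w <- get_wavelet(wavelet)
  a <- coeffs$approximation
  for (j in rev(seq_len(coeffs$level))) {
    a <- .idwt_step(a, coeffs$details[[j]], w$rec_lo, w$rec_hi)
  }
  a[seq.int(coeffs$pad_left + 1L, coeffs$pad_left + coeffs$n_input)]
}

#' @export
print.dwt_coefficients <- function(x, ...) {
  cat(sprintf(
    "<dwt_coefficients> wavelet %s, level %d, input %d samples (padded to %d)\n",
    x$wavelet, x$level, x$n_input, x$n))
  cat(sprintf("  |A_%d| = %d; %s\n", x$level, length(x$approximation),
              paste(sprintf("|D_%d| = %d", seq_len(x$level),
                            lengths(x$details)), collapse = ", ")))
  invisible(x)
}
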