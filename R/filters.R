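# Minimal IIR design and zero-phase filtering.
#
# Only what the pipeline needs: Butterworth low-pass/high-pass/band-pass via
# the analog prototype + bilinear transform, a generic analog biquad (for the
# flowmeter's Q = 0.5 low-pass), direct-form filtering vectorized across the
# columns of a matrix, and scipy-style filtfilt with odd reflection padding.

# analog Butterworth prototype poles (left half-plane), cutoff 1 rad/s
butter_prototype <- function(n) {
  k <- seq_len(n)
  exp(1i * pi * (2 * k + n - 1) / (2 * n))
}

# zeros/poles/gain -> b, a polynomial coefficients (decreasing powers of z)
zpk_to_ba <- function(z, p, k) {
  poly_from_roots <- function(r) {
    c0 <- 1 + 0i
    for (ri in r) c0 <- c(c0, 0) - c(0, c0 * ri)
    c0
  }
  list(b = Re(poly_from_roots(z) * k), a = Re(poly_from_roots(p)))
}

# bilinear transform of analog zpk at sample rate fs
bilinear_zpk <- function(z, p, k, fs) {
  fs2 <- 2 * fs
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  # zeros at analog infinity map to z = -1
  deg <- length(p) - length(z)
  zd <- c(zd, rep(-1 + 0i, deg))
  kd <- k * Re(prod(fs2 - z) / prod(fs2 - p))
  list(z = zd, p = pd, k = kd)
}

#' Butterworth digital filter design
#'
#' Designs a Butterworth filter by bilinear transform with frequency
#' pre-warping, matching the conventional (scipy/Matlab `butter`) result.
#' For `type = "band"` the returned filter has order `2 * n`.
#'
#' @param n Prototype order.
#' @param fc Cutoff frequency in Hz (length 2 for `"band"`).
#' @param fs Sample rate in Hz.
#' @param type `"low"`, `"high"` or `"band"`.
#' @return List with numerator `b` and denominator `a` coefficients.
#' @export
butter_design <- function(n, fc, fs, type = c("low", "high", "band")) {
  type <- match.arg(type)
  stopifnot(n >= 1, all(fc > 0), all(fc < fs / 2))
  warp <- function(f) 2 * fs * tan(pi * f / fs)
  p <- butter_prototype(n)
  if (type == "low") {
    w <- warp(fc)
    zpk <- list(z = complex(0), p = p * w, k = w^n)
  } else if (type == "high") {
    w <- warp(fc)
    zpk <- list(z = rep(0 + 0i, n), p = w / p, k = 1)
  } else {
    stopifnot(length(fc) == 2, fc[1] < fc[2])
    w1 <- warp(fc[1]); w2 <- warp(fc[2])
    bw <- w2 - w1; w0 <- sqrt(w1 * w2)
    pb <- p * bw / 2
    disc <- sqrt(pb^2 - w0^2)
    zpk <- list(z = rep(0 + 0i, n), p = c(pb + disc, pb - disc), k = bw^n)
  }
  d <- bilinear_zpk(zpk$z, zpk$p, zpk$k, fs)
  zpk_to_ba(d$z, d$p, d$k)
}

# second-order analog low-pass w0, quality factor Q, discretized at fs
# (the flowmeter hardware filter: f0 = 66.5 Hz, Q = 0.5)
biquad_lowpass <- function(f0, Q, fs) {
  w0 <- 2 * fs * tan(pi * f0 / fs)
  num <- c(w0^2)
  den <- c(1, w0 / Q, w0^2)
  # bilinear on polynomial form: substitute s = 2 fs (z-1)/(z+1)
  bilinear_poly(num, den, fs)
}

bilinear_poly <- function(num, den, fs) {
  n <- length(den) - 1
  num <- c(rep(0, n + 1 - length(num)), num)
  fs2 <- 2 * fs
  # expand num(s), den(s) with s = fs2 (1 - z^-1)/(1 + z^-1), multiply by (1+z^-1)^n
  pow <- function(coefs, k) {  # (a + b z^-1)^k convolution power
    out <- 1
    for (i in seq_len(k)) out <- convolve_poly(out, coefs)
    out
  }
  b <- rep(0, n + 1); a <- rep(0, n + 1)
  for (i in 0:n) {
    term <- convolve_poly(pow(c(fs2, -fs2), n - i), pow(c(1, 1), i))
    b <- b + num[i + 1] * term
    a <- a + den[i + 1] * term
  }
  list(b = b / a[1], a = a / a[1])
}

convolve_poly <- function(x, y) {
  out <- rep(0, length(x) + length(y) - 1)
  for (i in seq_along(x)) out[i + seq_along(y) - 1] <- out[i + seq_along(y) - 1] + x[i] * y
  out
}

# direct-form II transposed IIR, columns of a matrix filtered independently.
# init = "steady" seeds the state with the constant-input steady state scaled
# to each column's first sample, suppressing the start-up transient a zero
# state would produce (essential: bursts ride on a 2.5 V offset and a DC step
# into a narrow band-pass rings for tens of samples).
iir_filter <- function(b, a, x, init = c("zero", "steady")) {
  init <- match.arg(init)
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1) else x
  nb <- length(b); na <- length(a)
  m <- max(nb, na)
  b <- c(b, rep(0, m - nb)); a <- c(a, rep(0, m - na))
  b <- b / a[1]; a <- a / a[1]
  n <- nrow(X); nc <- ncol(X)
  Y <- matrix(0, n, nc)
  z <- matrix(0, m - 1, nc)
  if (init == "steady" && m > 1) {
    # per-unit steady state: constant input 1 gives constant output H(1)
    yss <- sum(b) / sum(a)
    zu <- numeric(m - 1)
    zu[m - 1] <- b[m] - a[m] * yss
    if (m > 2) for (j in (m - 2):1) zu[j] <- b[j + 1] - a[j + 1] * yss + zu[j + 1]
    z <- outer(zu, X[1, ])
  }
  for (t in seq_len(n)) {
    xt <- X[t, ]
    yt <- b[1] * xt + z[1, ]
    if (m > 2) {
      for (j in seq_len(m - 2)) z[j, ] <- b[j + 1] * xt + z[j + 1, ] - a[j + 1] * yt
    }
    z[m - 1, ] <- b[m] * xt - a[m] * yt
    Y[t, ] <- yt
  }
  if (vec) drop(Y) else Y
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies the filter forward and backward so the net response has zero phase
#' and squared magnitude. Edges are handled with odd-reflection padding of
#' length `3 * (max(length(a), length(b)) - 1)`.
#'
#' @param b,a Filter coefficients.
#' @param x Numeric vector, or matrix whose columns are filtered independently.
#' @return Filtered data, same shape as `x`.
#' @export
filtfilt2 <- function(b, a, x) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1) else x
  npad <- 3L * (max(length(a), length(b)) - 1L)
  n <- nrow(X)
  if (n <= npad) stop("signal too short for zero-phase filtering (need > ", npad, " samples)")
  top <- 2 * X[rep(1L, npad), , drop = FALSE] - X[(npad + 1L):2L, , drop = FALSE]
  bot <- 2 * X[rep(n, npad), , drop = FALSE] - X[(n - 1L):(n - npad), , drop = FALSE]
  Xp <- rbind(top, X, bot)
  Y <- iir_filter(b, a, Xp, init = "steady")
  Y <- iir_filter(b, a, Y[nrow(Y):1L, , drop = FALSE], init = "steady")
  Y <- Y[nrow(Y):1L, , drop = FALSE]
  Y <- Y[(npad + 1L):(npad + n), , drop = FALSE]
  if (vec) drop(Y) else Y
}

# |H(e^{i 2 pi f / fs})| for a digital b,a filter; used in tests
filter_gain <- function(b, a, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  zb <- outer(z, 0:(length(b) - 1), `^`)
  za <- outer(z, 0:(length(a) - 1), `^`)
  abs(as.vector(zb %*% b) / as.vector(za %*% a))
}
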