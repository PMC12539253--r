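# Butterworth band-pass design and zero-phase filtering.
#
# No signal-processing package ships with this toolchain, so the design is
# done from first principles: analog Butterworth prototype -> low-pass to
# band-pass transform in zero-pole-gain form -> bilinear transform. The
# forward-backward filter uses odd-symmetric edge extension with
# steady-state initial conditions, so steps and DC produce no transient.

# polynomial coefficients (monic, descending powers) from complex roots
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0i) - c(0i, p * rt)
  p
}

#' Butterworth band-pass coefficients
#'
#' Designs a digital Butterworth band-pass of the given analog prototype
#' order via the bilinear transform (the resulting digital filter has
#' `2 * order` poles). Matches the standard scipy/MATLAB `butter` design.
#'
#' @param low_hz,high_hz Band edges in Hz, `0 < low < high < rate/2`.
#' @param rate_hz Sampling rate in Hz.
#' @param order Prototype order (default 2).
#' @return A list with numerator `b` and denominator `a` coefficients.
#' @export
butter_bandpass <- function(low_hz, high_hz, rate_hz, order = 2) {
  if (!(low_hz > 0 && high_hz > low_hz && high_hz < rate_hz / 2)) {
    stop(sprintf(
      "band edges must satisfy 0 < low (%g) < high (%g) < Nyquist (%g)",
      low_hz, high_hz, rate_hz / 2), call. = FALSE)
  }
  n <- as.integer(order)
  stopifnot(n >= 1)
  # analog prototype: n poles on the unit circle, left half plane
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  gain <- 1
  # prewarped band edges (internal sampling rate 2, as in scipy)
  w1 <- 4 * tan(pi * low_hz / rate_hz)
  w2 <- 4 * tan(pi * high_hz / rate_hz)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  # low-pass -> band-pass on poles; n zeros appear at s = 0
  plp <- p * bw / 2
  pbp <- c(plp + sqrt(plp^2 - w0^2), plp - sqrt(plp^2 - w0^2))
  zbp <- rep(0 + 0i, n)
  gain <- gain * bw^n
  # bilinear transform at fs = 2 (factor 2*fs = 4)
  fs2 <- 4
  pd <- (fs2 + pbp) / (fs2 - pbp)
  zd <- (fs2 + zbp) / (fs2 - zbp)
  gain <- gain * Re(prod(fs2 - zbp) / prod(fs2 - pbp))
  zd <- c(zd, rep(-1 + 0i, length(pbp) - length(zbp)))
  list(b = Re(gain * poly_from_roots(zd)),
       a = Re(poly_from_roots(pd)))
}

# steady-state initial filter state for a unit step (direct form II
# transposed), solved from (I - A) zi = B
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, numeric(n - length(b)))
  a <- c(a, numeric(n - length(a)))
  b <- b / a[1]
  a <- a / a[1]
  if (n == 1) return(numeric(0))
  im_a <- diag(n - 1)
  im_a[, 1] <- im_a[, 1] + a[-1]
  if (n > 2) im_a[seq_len(n - 2), 2:(n - 1)] <-
      im_a[seq_len(n - 2), 2:(n - 1)] - diag(n - 2)
  solve(im_a, b[-1] - a[-1] * b[1])
}

# IIR filter with initial state; zero-state part runs through the
# C-level stats::filter, the zero-input part is the recursion driven by zi
lfilter <- function(b, a, x, zi = NULL) {
  n <- max(length(a), length(b))
  b <- c(b, numeric(n - length(b)))
  a <- c(a, numeric(n - length(a)))
  b <- b / a[1]
  a <- a / a[1]
  xp <- c(numeric(n - 1), x)
  w <- stats::filter(xp, b, method = "convolution", sides = 1)
  w <- as.numeric(w)[n:length(xp)]
  y <- if (n > 1) {
    as.numeric(stats::filter(w, -a[-1], method = "recursive"))
  } else w
  if (!is.null(zi) && length(zi)) {
    e <- c(zi, numeric(length(x) - length(zi)))
    y <- y + as.numeric(stats::filter(e, -a[-1], method = "recursive"))
  }
  y
}

# zero-phase forward-backward filtering with odd extension (scipy filtfilt
# default padding)
filtfilt_fb <- function(b, a, x) {
  n <- max(length(a), length(b))
  padlen <- 3 * n
  nx <- length(x)
  if (nx <= padlen) {
    stop(sprintf("signal length (%d) must exceed the filter pad length (%d)",
                 nx, padlen), call. = FALSE)
  }
  ext <- c(2 * x[1] - x[(padlen + 1):2],
           x,
           2 * x[nx] - x[(nx - 1):(nx - padlen)])
  zi <- lfilter_zi(b, a)
  y <- lfilter(b, a, ext, zi * ext[1])
  y <- rev(lfilter(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1):(padlen + nx)]
}
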