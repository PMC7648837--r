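# Minimal IIR design + zero-phase filtering + Welch spectral estimation.
# Only what the pipeline needs: Butterworth low-pass and band-pass designed
# by bilinear transform of the analog prototype, applied forward-backward.

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (x in r) p <- c(p, 0) - c(0, p * x)
  p
}

#' Butterworth filter coefficients
#'
#' Digital Butterworth design via analog prototype, frequency pre-warping
#' and bilinear transform.  `order` is the analog prototype order, so a
#' band-pass of order 4 has 8 poles (the usual convention).
#'
#' @param order Prototype order (4 for the pipeline's filters).
#' @param f_lo,f_hi Corner frequencies in Hz. Low-pass: give only `f_lo`.
#' @param fs Sampling rate in Hz.
#' @param type "low" or "band".
#' @return list(b, a) transfer-function coefficients, `a[1] == 1`.
#' @export
butter_coeffs <- function(order, f_lo, f_hi = NULL, fs,
                          type = c("band", "low")) {
  type <- match.arg(type)
  n <- as.integer(order)
  stopifnot(n >= 1, fs > 0, f_lo > 0)
  # analog prototype poles on the unit circle, left half-plane
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  fs2 <- 2 * fs
  warp <- function(f) fs2 * tan(pi * f / fs)
  if (type == "low") {
    wc <- warp(f_lo)
    pa <- p * wc
    za <- complex(0)
    ka <- wc^n
  } else {
    if (is.null(f_hi) || f_hi <= f_lo || f_hi >= fs / 2)
      stop("band-pass needs f_lo < f_hi < fs/2")
    w1 <- warp(f_lo); w2 <- warp(f_hi)
    w0 <- sqrt(w1 * w2); bw <- w2 - w1
    ph <- p * bw / 2
    pa <- c(ph + sqrt(ph^2 - w0^2), ph - sqrt(ph^2 - w0^2))
    za <- rep(0 + 0i, n)
    ka <- bw^n
  }
  # bilinear transform of the zpk form
  zd <- (fs2 + za) / (fs2 - za)
  pd <- (fs2 + pa) / (fs2 - pa)
  kd <- ka * Re(prod(fs2 - za) / prod(fs2 - pa))
  zd <- c(zd, rep(-1 + 0i, length(pa) - length(za)))
  b <- Re(poly_from_roots(zd)) * kd
  a <- Re(poly_from_roots(pd))
  list(b = b / a[1], a = a / a[1])
}

# steady-state filter state for a unit step, so filtfilt starts each pass
# without a start-up transient (same construction as scipy's lfilter_zi)
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b)) - 1L
  bb <- c(b, numeric(n + 1L - length(b)))
  aa <- c(a, numeric(n + 1L - length(a)))
  A <- rbind(-aa[-1], cbind(diag(1, n - 1L), 0))
  B <- bb[-1] - aa[-1] * bb[1]
  solve(diag(1, n) - t(A), B)
}

#' Zero-phase IIR filtering (forward-backward)
#'
#' Applies the filter twice, once in each direction, after odd-reflection
#' padding of `3 * (ncoef - 1)` samples at both ends and with steady-state
#' initial conditions, so the result has zero phase distortion, squared
#' magnitude response, and no start-up transient.
#'
#' @param ba list(b, a) as from [butter_coeffs()].
#' @param x Numeric signal.
#' @return Filtered signal, same length as `x`.
#' @export
filtfilt_ba <- function(ba, x) {
  b <- ba$b; a <- ba$a
  npad <- 3L * (max(length(a), length(b)) - 1L)
  n <- length(x)
  if (n <= npad) stop("signal too short for zero-phase filtering")
  zi <- lfilter_zi(b, a)
  pre <- 2 * x[1] - x[(npad + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - npad)]
  xe <- c(pre, x, post)
  y <- iir_filter_cpp(b, a, xe, zi * xe[1])
  y <- rev(iir_filter_cpp(b, a, rev(y), zi * y[length(y)]))
  y[(npad + 1):(npad + n)]
}

#' Welch power spectral density
#'
#' Hamming-tapered, mean-removed segments with 50% overlap; one-sided
#' density in (input unit)^2 per Hz.  With the default 1 s window the
#' frequency resolution is 1 Hz, the minimum that resolves the 2-7 Hz band.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param window_s Segment length in seconds (default 1).
#' @param overlap Fractional overlap (default 0.5).
#' @return list(freq, psd).
#' @export
welch_psd <- function(x, fs, window_s = 1, overlap = 0.5) {
  nper <- round(window_s * fs)
  n <- length(x)
  if (n < nper) stop("signal shorter than one Welch window")
  step <- max(1L, round(nper * (1 - overlap)))
  starts <- seq(1L, n - nper + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nper - 1)) / (nper - 1))
  u <- sum(w^2)
  nfreq <- nper %/% 2L + 1L
  segs <- vapply(starts, function(s) {
    seg <- x[s:(s + nper - 1L)]
    (seg - mean(seg)) * w
  }, numeric(nper))
  X <- stats::mvfft(segs)[seq_len(nfreq), , drop = FALSE]
  psd <- rowSums(Re(X)^2 + Im(X)^2) / (length(starts) * fs * u)
  scale2 <- rep(2, nfreq); scale2[1] <- 1
  if (nper %% 2L == 0L) scale2[nfreq] <- 1
  list(freq = (seq_len(nfreq) - 1) * fs / nper, psd = psd * scale2)
}
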