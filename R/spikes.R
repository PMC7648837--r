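# Spike detection on the 500-5000 Hz band-passed trace, 64-sample waveform
# extraction, 4-level Haar wavelet features, and Lilliefors-based selection
# of the most multimodal coefficients.

#' Band-pass filter a trace for spike visualisation/detection
#'
#' Zero-phase 4th-order Butterworth band-pass, corners 500 and 5000 Hz,
#' removing the high-power low-frequency background so spikes stand out.
#'
#' @param rec A [mer_recording] or numeric vector.
#' @param fs Sampling rate (taken from `rec` when it is a recording).
#' @param f_lo,f_hi Corner frequencies in Hz.
#' @param order Butterworth prototype order.
#' @return Filtered numeric vector, same length as the input.
#' @export
bandpass_spike_filter <- function(rec, fs = NULL, f_lo = 500, f_hi = 5000,
                                  order = 4) {
  if (inherits(rec, "mer_recording")) { x <- rec$samples; fs <- rec$fs }
  else { x <- as.numeric(rec); if (is.null(fs)) stop("fs required") }
  if (fs <= 2 * f_hi)
    stop("sampling rate ", fs, " Hz too low for a ", f_hi, " Hz corner")
  filtfilt_ba(butter_coeffs(order, f_lo, f_hi, fs = fs, type = "band"), x)
}

#' Robust noise level of a filtered trace
#'
#' `median(|x|) / 0.6745`, the usual spike-detection estimate of the noise
#' standard deviation, insensitive to the spikes themselves.
#' @param x Filtered trace.
#' @return Scalar sigma estimate.
#' @export
robust_sigma <- function(x) median(abs(x)) / 0.6745

#' Detect spikes by automatic amplitude threshold
#'
#' Threshold `k_thresh * robust_sigma(x)`; one spike per contiguous
#' supra-threshold excursion (either polarity), registered at the
#' largest-magnitude sample of the excursion; excursions starting within
#' the lockout of an accepted spike are suppressed.
#'
#' @param filtered Band-passed trace (see [bandpass_spike_filter()]).
#' @param fs Sampling rate in Hz.
#' @param k_thresh Threshold multiplier (default 4).
#' @param lockout_ms Dead time after an accepted spike (default 1.5 ms).
#' @return Numeric vector of spike times in seconds (sample (i-1)/fs);
#'   empty for an all-zero input.
#' @export
detect_spikes <- function(filtered, fs, k_thresh = 4, lockout_ms = 1.5) {
  x <- as.numeric(filtered)
  if (!length(x)) stop("empty input")
  theta <- k_thresh * robust_sigma(x)
  if (theta <= 0) return(numeric(0))
  above <- abs(x) > theta
  if (!any(above)) return(numeric(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  peaks <- integer(length(starts))
  mags <- numeric(length(starts))
  for (i in seq_along(starts)) {
    seg <- abs(x[starts[i]:ends[i]])
    peaks[i] <- starts[i] + which.max(seg) - 1L
    mags[i] <- max(seg)
  }
  # excursions closer than the lockout belong to one event (a multiphasic
  # spike crosses the threshold more than once); the event is registered
  # at its largest-magnitude extremum
  lock <- round(lockout_ms / 1000 * fs)
  acc <- integer(0)
  cur_p <- peaks[1]; cur_m <- mags[1]
  for (i in seq_along(peaks)[-1]) {
    if (peaks[i] - cur_p < lock) {
      if (mags[i] > cur_m) { cur_p <- peaks[i]; cur_m <- mags[i] }
    } else {
      acc <- c(acc, cur_p)
      cur_p <- peaks[i]; cur_m <- mags[i]
    }
  }
  acc <- c(acc, cur_p)
  (acc - 1) / fs
}

#' Extract aligned spike waveforms
#'
#' 64-sample windows with the detection extremum at sample `peak_sample`
#' (20, i.e. about 0.8 ms pre / 1.8 ms post at 24 kHz).  Spikes too close
#' to an edge for a full window are dropped together with their timestamps.
#'
#' @param filtered Band-passed trace.
#' @param timestamps Spike times in seconds.
#' @param fs Sampling rate in Hz.
#' @param n_samples Window length (default 64, so a 4-level Haar transform
#'   yields exactly 64 coefficients).
#' @param peak_sample Index of the extremum within the window (default 20).
#' @return list(waveforms = n x 64 matrix, timestamps = retained times).
#' @export
extract_waveforms <- function(filtered, timestamps, fs, n_samples = 64,
                              peak_sample = 20) {
  idx <- round(timestamps * fs) + 1L
  lo <- idx - (peak_sample - 1L)
  hi <- lo + n_samples - 1L
  ok <- lo >= 1L & hi <= length(filtered)
  idx <- idx[ok]
  w <- matrix(0, nrow = length(idx), ncol = n_samples)
  for (i in seq_along(idx))
    w[i, ] <- filtered[(idx[i] - peak_sample + 1L):(idx[i] - peak_sample + n_samples)]
  list(waveforms = w, timestamps = timestamps[ok])
}

#' Orthonormal Haar discrete wavelet transform features
#'
#' Four-level multiresolution decomposition of each 64-sample waveform,
#' giving 64 coefficients per spike, ordered as level-4 approximation (4),
#' then details level 4 (4), 3 (8), 2 (16), 1 (32).  The orthonormal
#' convention is used, so coefficient energy equals waveform energy
#' (Parseval).
#'
#' @param waveforms n x 64 numeric matrix.
#' @param levels Decomposition depth (default 4).
#' @return n x 64 matrix of wavelet coefficients.
#' @export
haar_features <- function(waveforms, levels = 4) {
  if (is.null(dim(waveforms))) waveforms <- matrix(waveforms, nrow = 1)
  nc <- ncol(waveforms)
  if (nc %% 2^levels != 0)
    stop("waveform width ", nc, " not divisible by 2^", levels)
  n <- nrow(waveforms)
  out <- matrix(0, n, nc)
  s2 <- sqrt(2)
  for (i in seq_len(n)) {
    a <- waveforms[i, ]
    details <- list()
    for (lev in seq_len(levels)) {
      ev <- a[seq(2, length(a), by = 2)]
      od <- a[seq(1, length(a), by = 2)]
      details[[lev]] <- (od - ev) / s2
      a <- (od + ev) / s2
    }
    out[i, ] <- c(a, unlist(rev(details), use.names = FALSE))
  }
  out
}

#' Lilliefors test statistic for normality
#'
#' Maximum deviation between the empirical CDF of `x` and the normal CDF
#' with mean/sd estimated from the sample (the Kolmogorov-Smirnov statistic
#' with fitted parameters).  Large values indicate non-normality, i.e.
#' multimodality for spike-shape coefficients.
#'
#' @param x Numeric sample.
#' @return The statistic (0 for constant input).
#' @export
lilliefors_stat <- function(x) {
  n <- length(x)
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(0)
  z <- sort((x - mean(x)) / s)
  p <- pnorm(z)
  i <- seq_len(n)
  max(pmax(i / n - p, p - (i - 1) / n))
}

#' Select the most discriminative wavelet coefficients
#'
#' Ranks the 64 coefficients by the Lilliefors statistic of their
#' distribution across spikes and returns the indices of the `n_select`
#' most non-normal (hence most multimodal) ones.  Zero-variance
#' coefficients are excluded.  With fewer than 10 spikes all nonconstant
#' coefficients are returned with a warning.
#'
#' @param features n x 64 coefficient matrix from [haar_features()].
#' @param n_select Number of coefficients to keep (default 10).
#' @return Integer vector of column indices (possibly empty when every
#'   coefficient is constant).
#' @export
select_coefficients <- function(features, n_select = 10) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  sds <- apply(features, 2, sd)
  nonconst <- which(is.finite(sds) & sds > 0)
  if (!length(nonconst)) {
    warning("all wavelet coefficients constant; no features selected")
    return(integer(0))
  }
  if (nrow(features) < 10) {
    warning("fewer than 10 spikes; returning all nonconstant coefficients")
    return(nonconst)
  }
  stat <- vapply(nonconst, function(j) lilliefors_stat(features[, j]),
                 numeric(1))
  nonconst[order(stat, decreasing = TRUE)][seq_len(min(n_select, length(nonconst)))]
}
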