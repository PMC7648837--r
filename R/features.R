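# The per-site parameter battery: spike-train statistics (mean/max spiking
# rate, modal interspike interval, burst index, LvR) and Welch band
# features of the reconstructed background activity.

#' Canonical frequency bands
#'
#' Low 2-7 Hz, alpha 8-12 Hz, low beta 13-20 Hz, high beta 21-30 Hz, beta
#' (the union band) 13-30 Hz, gamma 31-49 Hz.  `disjoint = TRUE` drops the
#' union beta band, leaving the five bands used for the RMS summaries.
#'
#' @param disjoint Drop the overlapping 13-30 Hz beta band.
#' @return data.frame with `name`, `f_lo`, `f_hi`.
#' @export
mer_bands <- function(disjoint = FALSE) {
  b <- data.frame(
    name = c("low", "alpha", "low_beta", "high_beta", "beta", "gamma"),
    f_lo = c(2, 8, 13, 21, 13, 31),
    f_hi = c(7, 12, 20, 30, 30, 49),
    stringsAsFactors = FALSE)
  if (disjoint) b[b$name != "beta", ] else b
}

#' Mean and maximum spiking rate over an epoch grid
#'
#' Firing rate is computed per non-overlapping epoch (spike count divided
#' by epoch length, default 0.5 s, the artifact-removal grid); the mean and
#' the maximum over epochs are returned.  Remainder samples beyond the last
#' full epoch are ignored.
#'
#' @param timestamps Spike times in seconds.
#' @param duration_s Recording duration in seconds.
#' @param epoch_len_s Epoch length in seconds (default 0.5).
#' @return Named numeric: `Mean_SR`, `Max_SR` (spikes/s; 0 and 0 for an
#'   empty train).
#' @export
spike_rates <- function(timestamps, duration_s, epoch_len_s = 0.5) {
  if (duration_s <= 0) stop("duration_s must be positive")
  l <- floor(duration_s / epoch_len_s)
  if (l < 1) stop("duration shorter than one epoch")
  counts <- tabulate(findInterval(timestamps, seq(0, by = epoch_len_s,
                                                  length.out = l + 1),
                                  rightmost.closed = FALSE), nbins = l + 1)[seq_len(l)]
  rates <- counts / epoch_len_s
  c(Mean_SR = mean(rates), Max_SR = max(rates))
}

#' Modal interspike interval
#'
#' Histogram of the intervals at `bin_ms` bins starting from 0; returns the
#' centre of the most populated bin, ties broken toward the smaller
#' interval.
#'
#' @param isis_ms Interspike intervals in ms.
#' @param bin_ms Bin width (default 1 ms).
#' @return Bin centre in ms, or NA when fewer than 2 intervals exist.
#' @export
modal_isi <- function(isis_ms, bin_ms = 1) {
  if (length(isis_ms) < 2) return(NA_real_)
  bins <- floor(isis_ms / bin_ms)
  tab <- table(bins)
  top <- as.integer(names(tab)[tab == max(tab)])
  (min(top) + 0.5) * bin_ms
}

#' Burst index
#'
#' The reciprocal of the modal interspike interval divided by the mean
#' firing rate; 1 for a perfectly regular train, above 1 when short
#' intervals (bursts) dominate the mode.
#'
#' @param modal_isi_ms Modal interval in ms.
#' @param mean_rate_hz Mean firing rate in spikes/s.
#' @return Dimensionless burst index, NA when either input is unusable.
#' @export
burst_index <- function(modal_isi_ms, mean_rate_hz) {
  if (is.na(modal_isi_ms) || is.na(mean_rate_hz) ||
      modal_isi_ms <= 0 || mean_rate_hz <= 0) return(NA_real_)
  (1000 / modal_isi_ms) / mean_rate_hz
}

#' Local variation of interspike intervals with refractoriness compensation
#'
#' `LvR = 3/(n-1) * sum_{i=1}^{n-1} (1 - 4 I_i I_{i+1} / (I_i + I_{i+1})^2)
#' * (1 + 4R / (I_i + I_{i+1}))` with `I_i` the i-th interval and `R` the
#' refractoriness constant, both in ms.  Near 0 for regular trains, near 1
#' for Poisson-like firing, invariant to rate fluctuations.
#'
#' @param isis_ms Interspike intervals in ms.
#' @param R_ms Refractoriness constant in ms (default 5).
#' @return LvR, or NA with fewer than 2 intervals (3 spikes).
#' @export
lvr <- function(isis_ms, R_ms = 5) {
  n <- length(isis_ms)
  if (n < 2) return(NA_real_)
  I1 <- isis_ms[-n]; I2 <- isis_ms[-1]
  s <- I1 + I2
  (3 / (n - 1)) * sum((1 - 4 * I1 * I2 / s^2) * (1 + 4 * R_ms / s))
}

#' Welch band features of a background trace
#'
#' Welch PSD (1 s Hamming windows, 50% overlap, 1 Hz resolution); the
#' amplitude spectrum is `A(f) = sqrt(PSD(f))`.  Per band: `mean_amplitude`
#' = mean of A over in-band bins, `max_peak` = max of A in-band, `rms` =
#' sqrt(sum of in-band PSD x bin width), i.e. the RMS amplitude of the
#' band-limited signal.
#'
#' @param background A `background_trace` (or numeric vector with `fs`).
#' @param bands data.frame as from [mer_bands()].
#' @param fs Sampling rate when `background` is a plain vector.
#' @param window_s Welch window length in seconds.
#' @return data.frame: `name`, `mean_amplitude`, `max_peak`, `rms`.
#' @export
band_features <- function(background, bands = mer_bands(), fs = NULL,
                          window_s = 1) {
  if (inherits(background, "background_trace")) {
    x <- background$samples; fs <- background$fs
  } else { x <- as.numeric(background); if (is.null(fs)) stop("fs required") }
  if (length(x) < 2 * window_s * fs)
    stop("background shorter than 2 s; cannot estimate band features")
  w <- welch_psd(x, fs, window_s = window_s)
  df <- w$freq[2] - w$freq[1]
  amp <- sqrt(w$psd)
  out <- lapply(seq_len(nrow(bands)), function(i) {
    inb <- w$freq >= bands$f_lo[i] & w$freq <= bands$f_hi[i]
    data.frame(name = bands$name[i],
               mean_amplitude = mean(amp[inb]),
               max_peak = max(amp[inb]),
               rms = sqrt(sum(w$psd[inb]) * df),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Assemble the 19-parameter battery for one site
#'
#' Spike-train statistics are computed on all sorted spikes pooled across
#' clusters (the feature table reports one value per site); spectral
#' features come from the reconstructed background.  Sites without spikes
#' get zero rates and missing ISI/BI/LvR, band features are still computed.
#'
#' @param rec The (cleaned) [mer_recording] the spikes were detected on.
#' @param sort_result A `spike_sort_result` (or any list with a
#'   `timestamps` field) for the site.
#' @param background A `background_trace` for the site.
#' @param epoch_len_s Epoch grid for the spiking rates.
#' @param R_ms Refractoriness constant for LvR.
#' @return Named numeric vector over [site_feature_names()].
#' @export
site_features <- function(rec, sort_result, background, epoch_len_s = 0.5,
                          R_ms = 5) {
  missing_in <- c(rec = is.null(rec), sort_result = is.null(sort_result),
                  background = is.null(background))
  if (any(missing_in))
    stop("missing stage outputs: ",
         paste(names(missing_in)[missing_in], collapse = ", "))
  ts <- sort_result$timestamps
  duration_s <- rec$duration_s
  sr <- spike_rates(ts, duration_s, epoch_len_s = epoch_len_s)
  isis <- diff(ts) * 1000
  mi <- modal_isi(isis)
  mean_rate <- length(ts) / duration_s
  bi <- burst_index(mi, mean_rate)
  lv <- lvr(isis, R_ms = R_ms)
  bf <- band_features(background)
  g <- function(band, col) bf[[col]][bf$name == band]
  rms5 <- bf$rms[bf$name != "beta"]
  out <- c(
    Mean_low_freq = g("low", "mean_amplitude"),
    Max_low_freq = g("low", "max_peak"),
    Mean_Alpha = g("alpha", "mean_amplitude"),
    Max_Alpha = g("alpha", "max_peak"),
    Mean_low_Beta = g("low_beta", "mean_amplitude"),
    Max_low_Beta = g("low_beta", "max_peak"),
    Mean_high_Beta = g("high_beta", "mean_amplitude"),
    Max_high_Beta = g("high_beta", "max_peak"),
    Mean_Beta = g("beta", "mean_amplitude"),
    Max_Beta = g("beta", "max_peak"),
    Mean_Gamma = g("gamma", "mean_amplitude"),
    Max_Gamma = g("gamma", "max_peak"),
    Mean_RMS = mean(rms5),
    Max_RMS = max(rms5),
    ISI = mi,
    BI = bi,
    LvR = lv,
    Mean_SR = unname(sr["Mean_SR"]),
    Max_SR = unname(sr["Max_SR"]))
  out[site_feature_names()]
}
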