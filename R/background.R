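# Background-activity reconstruction: every detected spike is excised
# (0.5 ms before to 2.5 ms after its timestamp) and replaced with 3 ms of
# spike-free signal drawn from a random location of the same trace, then
# the whole trace is low-passed at 500 Hz.  What remains is the aggregate
# field activity of distant and subthreshold sources.

#' Reconstruct the background activity of a recording
#'
#' @param raw Numeric trace in microvolts (typically the cleaned trace,
#'   before spike band-passing).
#' @param timestamps Spike times in seconds (from [detect_spikes()] /
#'   [sort_spikes()], all clusters pooled).
#' @param fs Sampling rate in Hz.
#' @param seed Seed for the donor-segment draws.
#' @param pre_ms,post_ms Excision window around each timestamp (defaults
#'   0.5 and 2.5 ms, i.e. 3 ms total).
#' @param fade_ms Cross-fade length at both patch edges (default 0.25 ms);
#'   avoids step discontinuities that would leak broadband power.
#' @param lp_hz Low-pass corner (default 500 Hz, 4th-order Butterworth,
#'   zero-phase), applied after patching.
#' @param donor_margin_ms Donor segments must lie at least this far from
#'   every spike window (default 3 ms).
#' @return Object of class `background_trace`: `samples` (same length as
#'   `raw`), `fs`, `n_patches`, `patch_source_offsets`, `seed`.
#' @export
reconstruct_background <- function(raw, timestamps, fs, seed = 1,
                                   pre_ms = 0.5, post_ms = 2.5,
                                   fade_ms = 0.25, lp_hz = 500,
                                   donor_margin_ms = 3) {
  x <- as.numeric(raw)
  n <- length(x)
  if (!n) stop("empty trace")
  lp <- butter_coeffs(4, lp_hz, fs = fs, type = "low")
  if (!length(timestamps)) {
    out <- filtfilt_ba(lp, x)
    return(structure(list(samples = out, fs = fs, n_patches = 0L,
                          patch_source_offsets = integer(0), seed = seed),
                     class = "background_trace"))
  }
  idx <- round(timestamps * fs) + 1L
  if (any(idx < 1L | idx > n)) stop("timestamps outside the trace")
  npre <- round(pre_ms / 1000 * fs)
  npost <- round(post_ms / 1000 * fs)
  L <- npre + npost + 1L        # patch length, ~3 ms
  lo <- pmax(1L, idx - npre)
  hi <- pmin(n, idx + npost)
  # eligible donor starts: [p, p + L - 1] at least donor_margin from all
  # spike windows
  marg <- round(donor_margin_ms / 1000 * fs)
  blocked <- logical(n)
  for (k in seq_along(lo))
    blocked[max(1L, lo[k] - marg):min(n, hi[k] + marg)] <- TRUE
  # a start is valid when the whole donor window is unblocked
  csum <- cumsum(blocked)
  valid <- which(seq_len(n) <= n - L + 1L)
  valid <- valid[(csum[valid + L - 1L] - csum[valid] + blocked[valid]) == 0]
  if (!length(valid))
    stop("no spike-free donor segment of ", pre_ms + post_ms,
         " ms exists; spiking too dense for background reconstruction")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  donors <- valid[ceiling(runif(length(lo)) * length(valid))]
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  nf <- max(1L, round(fade_ms / 1000 * fs))
  y <- x
  for (k in seq_along(lo)) {
    w <- lo[k]:hi[k]
    seg <- x[donors[k]:(donors[k] + length(w) - 1L)]
    m <- length(w)
    alpha <- rep(1, m)
    nf_k <- min(nf, m %/% 2L)
    if (nf_k > 0) {
      ramp <- seq_len(nf_k) / (nf_k + 1)
      alpha[seq_len(nf_k)] <- ramp
      alpha[(m - nf_k + 1L):m] <- rev(ramp)
    }
    y[w] <- (1 - alpha) * y[w] + alpha * seg
  }
  out <- filtfilt_ba(lp, y)
  structure(list(samples = out, fs = fs, n_patches = length(lo),
                 patch_source_offsets = donors, seed = seed),
            class = "background_trace")
}

#' @export
print.background_trace <- function(x, ...) {
  cat(sprintf("<background_trace> %d samples at %g Hz, %d patches\n",
              length(x$samples), x$fs, x$n_patches))
  invisible(x)
}
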