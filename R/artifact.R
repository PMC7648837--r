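# Exogenous-artifact rejection: 0.5 s epoch segmentation, variance-
# coefficient screening against a critical threshold of 1.8, and monotone
# piecewise-cubic bridging of the excised gaps.

#' Segment a recording into non-overlapping epochs
#'
#' The trace is first trimmed to `max_duration_s` (30 s) when longer, then
#' cut into `floor(duration / epoch_len_s)` equal epochs; trailing remainder
#' samples are dropped.
#'
#' @param rec A [mer_recording] (or plain numeric vector with `fs` given).
#' @param epoch_len_s Epoch length in seconds (default 0.5).
#' @param fs Sampling rate; taken from `rec` when it is a recording.
#' @param max_duration_s Trim limit in seconds (default 30).
#' @return Object of class `epoch_array`: list with `epochs` (matrix,
#'   samples x n_epochs), `epoch_len_s`, `fs`, `kept` (logical mask), and
#'   `vc` (NULL until [variance_coefficients()] runs).
#' @export
segment_epochs <- function(rec, epoch_len_s = 0.5, fs = NULL,
                           max_duration_s = 30) {
  if (inherits(rec, "mer_recording")) { x <- rec$samples; fs <- rec$fs }
  else { x <- as.numeric(rec); if (is.null(fs)) stop("fs required") }
  if (epoch_len_s <= 0) stop("epoch_len_s must be positive")
  nmax <- round(max_duration_s * fs)
  if (length(x) > nmax) x <- x[seq_len(nmax)]
  len <- round(epoch_len_s * fs)
  l <- length(x) %/% len
  if (l < 1L) stop("recording shorter than one epoch (",
                   signif(length(x) / fs, 3), " s < ", epoch_len_s, " s)")
  ep <- matrix(x[seq_len(l * len)], nrow = len, ncol = l)
  structure(list(epochs = ep, epoch_len_s = epoch_len_s, fs = fs,
                 kept = rep(TRUE, l), vc = NULL,
                 zero_var = rep(FALSE, l)),
            class = "epoch_array")
}

pop_var <- function(x) mean((x - mean(x))^2)

#' Variance coefficient of consecutive epochs
#'
#' `vc[k] = var(s[k + 1]) / var(s[k])` for epochs 2..l (population
#' variance).  A zero-variance epoch makes its incoming coefficient
#' infinite and flags that epoch for rejection.
#'
#' @param ep An `epoch_array` from [segment_epochs()].
#' @return The epoch array with `vc` (length `n_epochs - 1`) filled in.
#' @export
variance_coefficients <- function(ep) {
  stopifnot(inherits(ep, "epoch_array"))
  l <- ncol(ep$epochs)
  if (l < 2L) stop("need at least 2 epochs for variance coefficients")
  v <- apply(ep$epochs, 2, pop_var)
  ep$zero_var <- v == 0
  ep$vc <- v[-1] / v[-l]   # vc[k-1] belongs to epoch k
  ep
}

#' Discard epochs whose variance coefficient exceeds the critical threshold
#'
#' An epoch is discarded when its incoming variance coefficient is strictly
#' greater than `threshold` (a value exactly equal to the threshold is
#' kept).  The rejection is one-sided: the epoch whose variance jumped is
#' the one removed; the subsequent drop back is not itself a trigger.  The
#' first epoch has no coefficient and is kept unless it has zero variance.
#' Coefficients are computed once on the original sequence and are not
#' re-derived across new junctions after removals.
#'
#' @param ep An `epoch_array`; [variance_coefficients()] is run if needed.
#' @param threshold Critical threshold (default 1.8).
#' @return The epoch array with `kept` updated.
#' @export
reject_epochs <- function(ep, threshold = 1.8) {
  stopifnot(inherits(ep, "epoch_array"))
  if (is.null(ep$vc)) ep <- variance_coefficients(ep)
  l <- ncol(ep$epochs)
  kept <- rep(TRUE, l)
  # infinite vc caused by a zero-variance predecessor does not condemn the
  # following (healthy) epoch; the degenerate epoch itself is dropped below
  kept[which(ep$vc > threshold & !ep$zero_var[-l]) + 1L] <- FALSE
  kept[ep$zero_var] <- FALSE
  ep$kept <- kept
  ep
}

#' Concatenate kept epochs, bridging excised gaps with monotone cubics
#'
#' Kept epochs are concatenated in order.  Wherever one or more epochs were
#' removed between two kept neighbours, a bridge of `bridge_ms` worth of
#' samples is synthesised by monotone piecewise-cubic Hermite interpolation
#' (pchip) through `n_anchor` anchor samples on each side, avoiding
#' concatenation steps.  Leading/trailing removals produce no bridge.
#'
#' @param ep An `epoch_array` after [reject_epochs()].
#' @param bridge_ms Bridge length in ms (default 2).
#' @param n_anchor Anchor samples per side (default 5).
#' @return Numeric vector of cleaned samples.
#' @export
stitch_clean <- function(ep, bridge_ms = 2, n_anchor = 5) {
  stopifnot(inherits(ep, "epoch_array"))
  kept_idx <- which(ep$kept)
  if (!length(kept_idx)) stop("no epochs survive artifact rejection; site unusable")
  nb <- max(1L, round(bridge_ms / 1000 * ep$fs))
  segs <- list()
  prev <- NULL
  out_i <- 1L
  for (k in kept_idx) {
    e <- ep$epochs[, k]
    if (!is.null(prev) && k > prev + 1L) {
      left <- segs[[length(segs)]]
      a <- tail(left, n_anchor)
      b <- head(e, n_anchor)
      xs <- c(seq_len(n_anchor), n_anchor + nb + seq_len(n_anchor))
      f <- splinefun(xs, c(a, b), method = "monoH.FC")
      segs[[length(segs) + 1L]] <- f(n_anchor + seq_len(nb))
    }
    segs[[length(segs) + 1L]] <- e
    prev <- k
  }
  unlist(segs, use.names = FALSE)
}

#' One-call artifact cleaning of a recording
#'
#' @param rec A [mer_recording].
#' @param epoch_len_s,threshold,bridge_ms,n_anchor See the stage functions.
#' @return list(recording = cleaned [mer_recording], n_epochs, n_rejected).
#' @export
clean_recording <- function(rec, epoch_len_s = 0.5, threshold = 1.8,
                            bridge_ms = 2, n_anchor = 5) {
  ep <- reject_epochs(variance_coefficients(
    segment_epochs(rec, epoch_len_s = epoch_len_s)), threshold = threshold)
  x <- stitch_clean(ep, bridge_ms = bridge_ms, n_anchor = n_anchor)
  list(recording = mer_recording(x, rec$fs, rec$trajectory, rec$depth_mm),
       n_epochs = ncol(ep$epochs), n_rejected = sum(!ep$kept))
}
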