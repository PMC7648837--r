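# Shared fixtures and small independent oracles used across the suite.

# epochs with exact population variance v: alternating +/- sqrt(v)
epochs_with_vars <- function(vars, len = 100, fs = 200) {
  stopifnot(len %% 2 == 0)
  x <- unlist(lapply(vars, function(v) rep(c(-1, 1), len / 2) * sqrt(v)))
  segment_epochs(x, epoch_len_s = len / fs, fs = fs)
}

# fraction of truth spikes with a detection within tol, and vice versa
match_spikes <- function(detected, truth, tol = 5e-4) {
  if (!length(truth)) return(list(recall = NA_real_, precision = NA_real_))
  recall <- mean(vapply(truth, function(t) any(abs(detected - t) <= tol),
                        logical(1)))
  precision <- if (!length(detected)) NA_real_ else
    mean(vapply(detected, function(t) any(abs(truth - t) <= tol),
                logical(1)))
  list(recall = recall, precision = precision)
}

# truth unit label (1/2/NA) for each detected spike of a 2-unit site
unit_labels_for <- function(detected, t1, t2, tol = 5e-4) {
  vapply(detected, function(t) {
    d1 <- if (length(t1)) min(abs(t1 - t)) else Inf
    d2 <- if (length(t2)) min(abs(t2 - t)) else Inf
    if (min(d1, d2) > tol) NA_integer_ else if (d1 < d2) 1L else 2L
  }, integer(1))
}

# best 1-1 matching accuracy for a 2-unit ground truth
best_two_unit_accuracy <- function(true_lab, pred_lab) {
  ok <- !is.na(true_lab)
  lt <- true_lab[ok]; lp <- pred_lab[ok]
  cl <- sort(unique(lp[lp > 0]))
  best <- 0
  if (length(cl) >= 2) {
    for (c1 in cl) for (c2 in setdiff(cl, c1))
      best <- max(best, sum((lt == 1 & lp == c1) | (lt == 2 & lp == c2)))
  } else if (length(cl) == 1) {
    best <- max(sum(lt == 1 & lp == cl), sum(lt == 2 & lp == cl))
  }
  best / length(lt)
}

# run the detection-only pipeline on one session and localize it
localize_generated <- function(gen, seed = 99) {
  feats <- list()
  for (key in names(gen$session$recordings)) {
    rec <- gen$session$recordings[[key]]
    cl <- clean_recording(rec)
    f <- bandpass_spike_filter(cl$recording)
    ts <- detect_spikes(f, cl$recording$fs)
    sres <- list(timestamps = ts, final_labels = rep(1L, length(ts)))
    bg <- reconstruct_background(cl$recording$samples, ts, cl$recording$fs,
                                 seed = seed)
    feats[[key]] <- site_features(cl$recording, sres, bg)
  }
  localize_session(feature_table(feats), truth = gen$truth)
}

# a 2-unit STN-like profile for end-to-end sorting tests
two_unit_profile <- function() {
  region_profile("stn", firing_rate_hz = 18, n_units = 2,
                 background_sigma_uv = 4,
                 band_power_uv2 = c(low = 0.3, alpha = 0.3, low_beta = 1,
                                    high_beta = 0.3, gamma = 0.3),
                 isi_shape = 2)
}
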