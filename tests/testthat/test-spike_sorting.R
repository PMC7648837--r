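test_that("detection handles degenerate inputs", {
  expect_length(detect_spikes(numeric(1000), 24000), 0)
  expect_error(detect_spikes(numeric(0), 24000), "empty")
})

test_that("injected templates are detected at their true times", {
  fs <- 24000
  set.seed(61)
  x <- rnorm(fs * 5, 0, 3)
  tpl <- spike_template(1) * 100
  times <- seq(0.05, 4.9, length.out = 100)
  idx <- round(times * fs) + 1L
  for (i in idx) x[(i - 19):(i + 44)] <- x[(i - 19):(i + 44)] + tpl
  f <- bandpass_spike_filter(x, fs)
  ts <- detect_spikes(f, fs)
  m <- match_spikes(ts, times)
  # every template found within +/-0.5 ms, no misses; a handful of extra
  # noise events is inherent to the 4-sigma rule (see the FP-rate test)
  expect_equal(m$recall, 1)
  expect_true(all(vapply(times, function(t) min(abs(ts - t)),
                         numeric(1)) <= 5e-4))
  expect_lte(length(ts) - 100, ceiling(1.9 * 5))
})

test_that("false-positive rate on pure noise matches the reference rate", {
  # independent reference (scipy butter/filtfilt + identical rule) gives
  # 1.36 +/- 0.19 events/s at k = 4 with both-polarity detection; the
  # one-sided < 1/s figure holds only for single-polarity detection
  fs <- 24000
  rates <- vapply(1:20, function(s) {
    set.seed(100 + s)
    f <- bandpass_spike_filter(rnorm(fs * 10, 0, 3), fs = fs)
    length(detect_spikes(f, fs)) / 10
  }, numeric(1))
  expect_gt(mean(rates), 0.9)
  expect_lt(mean(rates), 1.9)
})

test_that("waveform extraction aligns and drops edge spikes", {
  x <- numeric(1000)
  x[500] <- 10
  w <- extract_waveforms(x, (500 - 1) / 1000, fs = 1000)
  expect_equal(dim(w$waveforms), c(1, 64))
  expect_equal(w$waveforms[1, 20], 10)   # extremum at sample 20
  # too close to the end: dropped together with its timestamp
  w2 <- extract_waveforms(x, c((500 - 1) / 1000, (995 - 1) / 1000), fs = 1000)
  expect_equal(dim(w2$waveforms), c(1, 64))
  expect_length(w2$timestamps, 1)
  x[800] <- -8
  w3 <- extract_waveforms(x, c(499, 799) / 1000, fs = 1000)
  expect_equal(dim(w3$waveforms), c(2, 64))
})

test_that("haar features are an orthonormal 4-level decomposition", {
  # constants have zero detail coefficients
  hc <- haar_features(matrix(3, 1, 64))
  expect_equal(hc[1, 5:64], rep(0, 60))
  expect_equal(hc[1, 1:4], rep(3 * 4, 4))   # 16 samples * 3 / 2^2
  # alternating signal concentrates in the level-1 details (last 32)
  ha <- haar_features(matrix(rep(c(1, -1), 32), 1))
  expect_equal(sum(ha[1, 33:64]^2) / sum(ha[1, ]^2), 1, tolerance = 1e-12)
  # Parseval for random waveforms
  set.seed(71)
  W <- matrix(rnorm(20 * 64), 20)
  H <- haar_features(W)
  expect_equal(rowSums(H^2), rowSums(W^2), tolerance = 1e-9)
  # direct pyramid oracle, implemented independently
  naive_haar <- function(x) {
    out <- c()
    for (l in 1:4) {
      d <- a <- numeric(length(x) / 2)
      for (k in seq_along(a)) {
        a[k] <- (x[2 * k - 1] + x[2 * k]) / sqrt(2)
        d[k] <- (x[2 * k - 1] - x[2 * k]) / sqrt(2)
      }
      out <- c(d, out)
      x <- a
    }
    c(x, out)
  }
  expect_equal(H[3, ], naive_haar(W[3, ]), tolerance = 1e-12)
  expect_error(haar_features(matrix(1, 1, 60)), "divisible")
})

test_that("lilliefors statistic matches a brute-force CDF comparison", {
  set.seed(72)
  x <- c(rnorm(60), rnorm(40, 4))
  brute <- function(x) {
    z <- (x - mean(x)) / stats::sd(x)
    n <- length(z)
    worst <- 0
    for (v in sort(z)) {
      emp_hi <- mean(z <= v)
      emp_lo <- mean(z < v)
      worst <- max(worst, abs(emp_hi - pnorm(v)), abs(pnorm(v) - emp_lo))
    }
    worst
  }
  expect_equal(lilliefors_stat(x), brute(x), tolerance = 1e-12)
  expect_identical(lilliefors_stat(rep(2, 10)), 0)
})

test_that("coefficient selection ranks the multimodal coefficient first", {
  set.seed(73)
  F <- matrix(rnorm(200 * 64), 200)
  F[, 17] <- 5 * sign(rnorm(200)) + rnorm(200)   # bimodal +/-5 mixture
  sel <- select_coefficients(F)
  expect_identical(sel[1], 17L)
  expect_length(sel, 10)
  expect_length(select_coefficients(F, n_select = 64), 64)
  F[, 3] <- 7
  expect_length(select_coefficients(F, n_select = 64), 63)
  expect_warning(s0 <- select_coefficients(matrix(1, 50, 64)), "constant")
  expect_length(s0, 0)
  expect_warning(sf <- select_coefficients(F[1:5, ]), "fewer than 10")
})

test_that("the interaction and bond structure follow the SPC equations", {
  # duplicate points at zero distance interact at exactly 1/K
  set.seed(74)
  X <- matrix(rnorm(12 * 2, sd = 0.3), 12)
  X[2, ] <- X[1, ]
  sw <- spc_cluster(X, params = spc_params(K = 5, n_iter = 50,
                                           t_min = 0.01, t_max = 0.02,
                                           t_step = 0.01,
                                           min_cluster_size = 2), seed = 1)
  e_dup <- which(sw$edges[, "i"] == 1 & sw$edges[, "j"] == 2)
  expect_equal(sw$J[e_dup], 1 / 5, tolerance = 1e-12)
  # T -> 0: same-state neighbours always bond; once components coalesce
  # they never separate, so correlations saturate near 1
  cold <- spc_cluster(X, params = spc_params(K = 5, n_iter = 500,
                                             t_min = 0, t_max = 0,
                                             t_step = 0.01,
                                             min_cluster_size = 2), seed = 2)
  expect_gt(mean(cold$edge_corr[, 1]), 0.95)
  expect_gt(min(cold$edge_corr[, 1]), 0.8)
  # T -> Inf: states decorrelate to the 1/q chance level
  hot <- spc_cluster(X, params = spc_params(K = 5, n_iter = 400,
                                            t_min = 1e6, t_max = 1e6,
                                            t_step = 1, q = 20,
                                            min_cluster_size = 2), seed = 3)
  expect_equal(mean(hot$edge_corr[, 1]), 1 / 20, tolerance = 0.05)
  expect_error(spc_cluster(X[1, , drop = FALSE]), "at least 2")
  expect_warning(spc_cluster(matrix(rnorm(8), 4, 2),
                             params = spc_params(K = 11, n_iter = 20,
                                                 t_max = 0.02)),
                 "K reduced")
})

test_that("SPC recovers three separated blobs", {
  for (s in 1:3) {
    set.seed(s)
    X <- rbind(matrix(rnorm(100 * 3), 100), matrix(rnorm(100 * 3, 10), 100),
               matrix(rnorm(100 * 3, -10), 100))
    ct <- choose_temperature(spc_cluster(X, seed = s))
    sizes <- table(ct$final_labels[ct$final_labels > 0])
    expect_length(sizes, 3)
    expect_true(all(sizes >= 95))
  }
})

test_that("SPC labels are invariant to feature order and global scale", {
  set.seed(75)
  X <- rbind(matrix(rnorm(60 * 4), 60), matrix(rnorm(60 * 4, 8), 60))
  p <- spc_params(n_iter = 200)
  a <- choose_temperature(spc_cluster(X, params = p, seed = 9))
  b <- choose_temperature(spc_cluster(3.7 * X[, c(3, 1, 4, 2)],
                                      params = p, seed = 9))
  expect_identical(a$final_labels, b$final_labels)
  expect_identical(a$chosen_temperature, b$chosen_temperature)
})

test_that("degenerate clustering falls back to a single unit", {
  set.seed(76)
  X <- matrix(rnorm(30 * 2), 30)
  sw <- spc_cluster(X, params = spc_params(n_iter = 100,
                                           min_cluster_size = 50), seed = 1)
  expect_warning(ct <- choose_temperature(sw), "fallback")
  expect_identical(ct$final_labels, rep(1L, 30))
})

test_that("sort_spikes handles empty and single-spike traces", {
  res <- sort_spikes(numeric(24000), 24000)
  expect_length(res$timestamps, 0)
  expect_length(res$final_labels, 0)
  x <- rnorm(24000, 0, 1)
  x[12000 + (-19:44)] <- x[12000 + (-19:44)] + 100 * spike_template(1)
  res1 <- sort_spikes(x, 24000)
  expect_length(res1$timestamps, 1)
  expect_identical(res1$final_labels, 1L)
})

test_that("two-unit sites are sorted to the correct units end to end", {
  fs <- 24000
  prof <- two_unit_profile()
  accs <- vapply(1:5, function(s) {
    st <- generate_site(prof, duration_s = 5, fs = fs, seed = s)
    f <- bandpass_spike_filter(st$recording$samples, fs)
    res <- sort_spikes(f, fs, seed = s)
    lt <- unit_labels_for(res$timestamps, st$spike_trains[[1]],
                          st$spike_trains[[2]])
    best_two_unit_accuracy(lt, res$final_labels)
  }, numeric(1))
  expect_gte(mean(accs), 0.9)
})
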