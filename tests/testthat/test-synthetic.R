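test_that("default profiles encode the stated region physiology", {
  p <- default_profiles()
  expect_true(all(p$stn$spike_amp_uv >= 70 & p$stn$spike_amp_uv <= 150))
  expect_identical(p$white_matter$firing_rate_hz, 0)
  expect_identical(names(which.max(p$stn$band_power_uv2)), "low_beta")
  expect_identical(names(which.max(p$snr$band_power_uv2)), "gamma")
  expect_gt(p$stn$firing_rate_hz, p$thalamus_zi$firing_rate_hz)
  expect_gte(p$snr$firing_rate_hz, p$stn$firing_rate_hz)
  sig <- vapply(p, `[[`, numeric(1), "background_sigma_uv")
  expect_true(all(sig >= 2 & sig <= 6))
})

test_that("generate_site is deterministic and validates fs", {
  prof <- default_profiles()$stn
  a <- generate_site(prof, duration_s = 1, fs = 24000, seed = 7)
  b <- generate_site(prof, duration_s = 1, fs = 24000, seed = 7)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$spike_trains, b$spike_trains)
  expect_error(generate_site(prof, duration_s = 1, fs = 60, seed = 1),
               "fs too low")
})

test_that("placed spike count follows the renewal expectation", {
  # rate 50 Hz for 30 s: ~1500 spikes; renewal count sd ~ sqrt(n * CV^2)
  prof <- region_profile("stn", firing_rate_hz = 50, n_units = 1,
                         background_sigma_uv = 3, isi_shape = 1)
  st <- generate_site(prof, duration_s = 30, fs = 24000, seed = 21)
  n <- length(st$spike_trains[[1]])
  cv2 <- ((1 / 50 - 0.001) / (1 / 50))^2   # gamma part of the interval only
  expect_lt(abs(n - 1500), 5 * sqrt(1500 * cv2))
})

test_that("empirical firing rate is unbiased over 100 seeds", {
  rate <- numeric(100)
  for (s in 1:100) {
    set.seed(s)
    rate[s] <- length(gen_spike_train(40, 2, shape = 2)) / 2
  }
  se <- stats::sd(rate) / sqrt(100)
  expect_lt(abs(mean(rate) - 40), 3 * se)
})

test_that("a unit-free, oscillation-free profile gives flat white noise", {
  prof <- region_profile("white_matter", 0, 0, background_sigma_uv = 3,
                         band_power_uv2 = c(low = 0, alpha = 0, low_beta = 0,
                                            high_beta = 0, gamma = 0))
  st <- generate_site(prof, duration_s = 10, fs = 24000, seed = 5)
  x <- st$recording$samples
  expect_equal(stats::sd(x), 3, tolerance = 0.02)
  w <- welch_psd(x, 24000)
  lowm <- mean(w$psd[w$freq >= 100 & w$freq <= 1000])
  highm <- mean(w$psd[w$freq >= 5000 & w$freq <= 9000])
  expect_equal(lowm / highm, 1, tolerance = 0.1)
  expect_length(st$spike_trains, 0)
})

test_that("generate_session lays out 75 sites with coherent ground truth", {
  cfg <- default_session_config(duration_s = 1, artifact_rate = 0)
  gen <- generate_session(cfg, seed = 3)
  expect_length(gen$session$recordings, 75)
  expect_equal(nrow(gen$truth$regions), 75)
  expect_identical(gen$truth$target_trajectory, "central")

  # injected low-beta in the STN span exceeds every non-STN depth on the
  # target trajectory
  tt <- gen$truth$regions[gen$truth$regions$trajectory == "central", ]
  powers <- vapply(paste0("central_", sprintf("%+03d", tt$depth_mm)),
                   function(k) gen$truth$band_power[[k]][["low_beta"]],
                   numeric(1))
  stn <- tt$region == "stn"
  expect_gt(min(powers[stn]), max(powers[!stn]))
  # and it peaks at the true target depth
  expect_equal(tt$depth_mm[which.max(powers)], gen$truth$target_depth_mm)

  expect_true(all(vapply(gen$truth$artifact_windows, nrow, integer(1)) == 0))
  expect_error(generate_session(default_session_config(duration_s = 1,
                                                       target_depth_mm = 4),
                                seed = 1),
               "outside the STN span")
})

test_that("artifacts are additive: spike truth and clean samples unchanged", {
  cfg0 <- default_session_config(duration_s = 1.5, artifact_rate = 0)
  cfg1 <- default_session_config(duration_s = 1.5, artifact_rate = 2)
  g0 <- generate_session(cfg0, seed = 8)
  g1 <- generate_session(cfg1, seed = 8)
  expect_identical(g0$truth$spike_trains, g1$truth$spike_trains)
  key <- "central_+00"
  aw <- g1$truth$artifact_windows[[key]]
  expect_true(all(aw$end_s <= 1.5 & aw$start_s >= 0))
  # windows are pairwise disjoint
  if (nrow(aw) > 1) {
    o <- order(aw$start_s)
    expect_true(all(aw$start_s[o][-1] >= aw$end_s[o][-nrow(aw)]))
  }
  x0 <- g0$session$recordings[[key]]$samples
  x1 <- g1$session$recordings[[key]]$samples
  fs <- 24000
  outside <- rep(TRUE, length(x0))
  if (nrow(aw))
    for (i in seq_len(nrow(aw)))
      outside[(round(aw$start_s[i] * fs) + 1):round(aw$end_s[i] * fs)] <- FALSE
  expect_identical(x0[outside], x1[outside])
  if (nrow(aw)) expect_false(identical(x0[!outside], x1[!outside]))
})
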