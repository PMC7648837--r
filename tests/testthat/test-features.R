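test_that("spiking rates follow the epoch grid", {
  sr <- spike_rates(seq(0.05, 29.95, by = 0.1), 30)
  expect_equal(unname(sr["Mean_SR"]), 10)
  expect_equal(unname(sr["Max_SR"]), 10)
  # 20 spikes bunched into one 0.5 s epoch of a 10 s trace
  sr2 <- spike_rates(seq(3.01, 3.48, length.out = 20), 10)
  expect_equal(unname(sr2["Max_SR"]), 40)
  expect_equal(unname(sr2["Mean_SR"]), 2)
  expect_equal(unname(spike_rates(numeric(0), 10)), c(0, 0))
})

test_that("modal ISI uses 1 ms bins with the tie toward short intervals", {
  expect_equal(modal_isi(rep(10, 30)), 10.5)   # centre of the bin holding 10
  expect_equal(modal_isi(c(rep(5.2, 30), rep(50.4, 10))), 5.5)
  expect_equal(modal_isi(c(rep(5.2, 10), rep(50.4, 10))), 5.5)  # tie rule
  expect_true(is.na(modal_isi(7)))
})

test_that("burst index is the reciprocal modal interval over the rate", {
  expect_equal(burst_index(10, 100), 1)
  expect_equal(burst_index(5, 20), 10)
  expect_equal(burst_index(20, 50), 1)
  expect_true(is.na(burst_index(10, 0)))
})

test_that("LvR closed forms and invariances hold", {
  expect_equal(lvr(rep(10, 50)), 0)
  expect_equal(lvr(c(10, 10), R_ms = 5), 0)
  expect_true(is.na(lvr(10)))
  # scaling all intervals and R together leaves LvR unchanged
  set.seed(91)
  isis <- rexp(200, 1 / 50)
  expect_equal(lvr(isis * 3, R_ms = 15), lvr(isis, R_ms = 5),
               tolerance = 1e-12)
  # Poisson trains sit near 1 (small Monte Carlo; the acceptance suite
  # runs the full 100-replicate version)
  vals <- vapply(1:20, function(s) {
    set.seed(s)
    lvr(diff(sort(runif(600, 0, 30))) * 1000, R_ms = 0)
  }, numeric(1))
  expect_equal(mean(vals), 1, tolerance = 0.1)
})

test_that("band features locate tones and scale with bandwidth", {
  fs <- 200
  t <- (0:(30 * fs - 1)) / fs
  set.seed(92)
  x <- sin(2 * pi * 15 * t) + rnorm(length(t), 0, 0.05)
  bf <- band_features(x, fs = fs)
  expect_identical(bf$name[which.max(bf$max_peak)], "low_beta")
  out_peak <- max(bf$max_peak[!bf$name %in% c("low_beta", "beta")])
  expect_gte(bf$max_peak[bf$name == "low_beta"] / out_peak, 10)
  # all-zero input
  bf0 <- band_features(numeric(fs * 2), fs = fs)
  expect_true(all(bf0$mean_amplitude == 0 & bf0$max_peak == 0 & bf0$rms == 0))
  expect_error(band_features(numeric(10), fs = fs), "shorter")
  # white-noise RMS ratio between gamma (19 bins) and alpha (5 bins)
  r <- vapply(1:10, function(s) {
    set.seed(s)
    b <- band_features(rnorm(30 * fs), fs = fs)
    b$rms[b$name == "gamma"] / b$rms[b$name == "alpha"]
  }, numeric(1))
  expect_equal(median(r), sqrt(19 / 5), tolerance = 0.2)
})

test_that("band features recover the ordering of injected band powers", {
  # rank agreement between injected oscillation power and measured mean
  # amplitude across the five disjoint bands, median over 50 seeds
  fs <- 200   # no spikes synthesised, so a low rate suffices
  prof <- region_profile("stn", firing_rate_hz = 0, n_units = 0,
                         background_sigma_uv = 2,
                         band_power_uv2 = c(low = 0.5, alpha = 1,
                                            low_beta = 2, high_beta = 0.25,
                                            gamma = 1.5))
  # like-for-like: band RMS^2 estimates integrated power, mean amplitude
  # estimates sqrt of power *density* (same power in a wider band is a
  # lower amplitude), so each is ranked against its own injected quantity
  bands <- mer_bands(disjoint = TRUE)
  width <- bands$f_hi - bands$f_lo + 1
  rho <- vapply(1:50, function(s) {
    st <- generate_site(prof, duration_s = 10, fs = fs, seed = 800 + s)
    bf <- band_features(st$recording$samples, bands = bands, fs = fs)
    inj <- unlist(st$band_power_uv2[bf$name])
    dens <- inj / width[match(bf$name, bands$name)]
    c(stats::cor(rank(inj), rank(bf$rms^2), method = "spearman"),
      stats::cor(rank(dens), rank(bf$mean_amplitude), method = "spearman"))
  }, numeric(2))
  expect_equal(unname(apply(rho, 1, median)), c(1, 1), tolerance = 1e-12)
})

test_that("Max_* dominates Mean_* on arbitrary signals", {
  fs <- 200
  for (s in 1:5) {
    set.seed(s)
    bf <- band_features(rnorm(5 * fs) + sin(2 * pi * s * 5 *
                                              (0:(5 * fs - 1)) / fs),
                        fs = fs)
    expect_true(all(bf$max_peak >= bf$mean_amplitude))
  }
})

test_that("site_features assembles the full battery", {
  fs <- 24000
  st <- generate_site(default_profiles()$stn, duration_s = 3, fs = fs,
                      seed = 93)
  rec <- st$recording
  f <- bandpass_spike_filter(rec)
  ts <- detect_spikes(f, fs)
  sres <- list(timestamps = ts, final_labels = rep(1L, length(ts)))
  bg <- reconstruct_background(rec$samples, ts, fs, seed = 2)
  v <- site_features(rec, sres, bg)
  expect_identical(names(v), site_feature_names())
  expect_true(all(is.finite(v)))
  # an STN profile shows its low-beta signature
  expect_gt(v[["Mean_low_Beta"]], v[["Mean_Alpha"]])
  expect_gt(v[["Mean_low_Beta"]], v[["Mean_low_freq"]])
  expect_gte(v[["Max_SR"]], v[["Mean_SR"]])
  expect_error(site_features(rec, NULL, bg), "missing stage")
})

test_that("a silent site yields zero rates and missing ISI statistics", {
  fs <- 24000
  set.seed(94)
  rec <- mer_recording(rnorm(fs * 2, 0, 2), fs, "medial", -8)
  sres <- list(timestamps = numeric(0), final_labels = integer(0))
  bg <- reconstruct_background(rec$samples, numeric(0), fs, seed = 1)
  v <- site_features(rec, sres, bg)
  expect_equal(unname(v[c("Mean_SR", "Max_SR")]), c(0, 0))
  expect_true(all(is.na(v[c("ISI", "BI", "LvR")])))
  expect_true(all(is.finite(v[grep("Beta|Alpha|Gamma|low_freq|RMS",
                                   names(v))])))
})
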