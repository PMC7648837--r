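# Synthetic Ben's-Gun session generator.  Stands in for intraoperative
# recordings that are not publicly deposited: region-dependent firing
# rates and background amplitudes along the electrode track (thalamus/ZI,
# then STN, a thin white-matter layer, then SNr), elevated low-beta
# background oscillation in STN and elevated gamma in SNr, spike
# amplitudes 70-150 uV on a 2-6 uV background, optional exogenous
# artifacts -- all with exact ground truth.

#' Region profile for the generator
#'
#' @param region One of "thalamus_zi", "stn", "white_matter", "snr".
#' @param firing_rate_hz Firing rate per unit (spikes/s).
#' @param n_units Number of simultaneously active units.
#' @param spike_amp_uv Two-element range of unit peak amplitudes (uV).
#' @param background_sigma_uv Baseline Gaussian noise sigma (uV).
#' @param band_power_uv2 Named vector of oscillation power (uV^2) for the
#'   five disjoint bands: low, alpha, low_beta, high_beta, gamma.
#' @param isi_shape Gamma-renewal shape: 1 is Poisson-with-dead-time,
#'   larger is more regular (high-rate SNr firing is the regular extreme).
#' @param refractory_ms Absolute dead time between spikes of one unit.
#' @return list of class `region_profile`.
#' @export
region_profile <- function(region, firing_rate_hz, n_units,
                           spike_amp_uv = c(70, 150),
                           background_sigma_uv = 3,
                           band_power_uv2 = c(low = 0.3, alpha = 0.3,
                                              low_beta = 0.3,
                                              high_beta = 0.3, gamma = 0.3),
                           isi_shape = 1, refractory_ms = 1) {
  stopifnot(firing_rate_hz >= 0, n_units >= 0,
            length(spike_amp_uv) == 2, all(spike_amp_uv > 0),
            background_sigma_uv > 0, all(band_power_uv2 >= 0),
            isi_shape > 0, refractory_ms >= 0)
  need <- c("low", "alpha", "low_beta", "high_beta", "gamma")
  if (!all(need %in% names(band_power_uv2)))
    stop("band_power_uv2 must name all of: ", paste(need, collapse = ", "))
  structure(list(region = region, firing_rate_hz = firing_rate_hz,
                 n_units = as.integer(n_units),
                 spike_amp_uv = sort(spike_amp_uv),
                 background_sigma_uv = background_sigma_uv,
                 band_power_uv2 = band_power_uv2[need],
                 isi_shape = isi_shape, refractory_ms = refractory_ms),
            class = "region_profile")
}

#' Default region profiles
#'
#' Firing rates are literature-shaped free parameters (none are printed
#' for these patients): thalamus/ZI fires slowly on a quiet background,
#' STN faster on a louder background with its largest oscillation power in
#' low beta (13-20 Hz), SNr fastest and most regular with its largest
#' power in gamma (31-49 Hz); white matter is silent.  Spike peak
#' amplitudes are drawn in 70-150 uV, background sigma within 2-6 uV.
#'
#' @return Named list of [region_profile()] objects.
#' @export
default_profiles <- function() {
  list(
    thalamus_zi = region_profile("thalamus_zi", firing_rate_hz = 12,
      n_units = 1, background_sigma_uv = 2.5,
      band_power_uv2 = c(low = 0.3, alpha = 0.3, low_beta = 0.3,
                         high_beta = 0.3, gamma = 0.3),
      isi_shape = 1),
    stn = region_profile("stn", firing_rate_hz = 40, n_units = 1,
      background_sigma_uv = 5,
      band_power_uv2 = c(low = 0.5, alpha = 0.5, low_beta = 4,
                         high_beta = 1, gamma = 0.5),
      isi_shape = 2),
    white_matter = region_profile("white_matter", firing_rate_hz = 0,
      n_units = 0, background_sigma_uv = 2,
      band_power_uv2 = c(low = 0.15, alpha = 0.15, low_beta = 0.15,
                         high_beta = 0.15, gamma = 0.15),
      isi_shape = 1),
    snr = region_profile("snr", firing_rate_hz = 60, n_units = 1,
      background_sigma_uv = 4,
      band_power_uv2 = c(low = 0.4, alpha = 0.4, low_beta = 0.4,
                         high_beta = 0.4, gamma = 4),
      isi_shape = 6))
}

#' Gamma-renewal spike train with dead time
#'
#' Interspike intervals are `refractory + Gamma(shape, scale)` with the
#' scale set so the mean interval is `1/rate`; shape 1 is Poisson with
#' dead time, large shapes are regular.
#'
#' @param rate_hz Firing rate (0 returns an empty train).
#' @param duration_s Train length in seconds.
#' @param shape Gamma shape parameter.
#' @param refractory_ms Dead time in ms.
#' @return Sorted spike times in seconds within (0, duration_s).
#' @export
gen_spike_train <- function(rate_hz, duration_s, shape = 1,
                            refractory_ms = 1) {
  if (rate_hz <= 0) return(numeric(0))
  mean_isi <- 1 / rate_hz
  refr <- refractory_ms / 1000
  if (mean_isi <= refr)
    stop("rate ", rate_hz, " Hz incompatible with ", refractory_ms,
         " ms refractory period")
  mu <- mean_isi - refr
  n_guess <- max(16L, ceiling(duration_s * rate_hz * 1.5 + 4 * sqrt(duration_s * rate_hz)))
  t <- cumsum(refr + rgamma(n_guess, shape = shape, scale = mu / shape))
  while (t[length(t)] < duration_s) {
    t <- c(t, t[length(t)] +
             cumsum(refr + rgamma(n_guess, shape = shape, scale = mu / shape)))
  }
  t[t < duration_s]
}

#' Biphasic extracellular spike template
#'
#' 64 samples at 24 kHz (~2.7 ms) with the main (negative) extremum at
#' sample `peak_sample` and a slower positive rebound; unit variants scale
#' and shift the rebound so that multiple units on one site produce
#' distinguishable shapes.
#'
#' @param unit Small integer selecting a shape variant.
#' @param n_samples,peak_sample Window geometry (64 / 20).
#' @return Numeric template with maximum magnitude 1 at `peak_sample`.
#' @export
spike_template <- function(unit = 1, n_samples = 64, peak_sample = 20) {
  i <- seq_len(n_samples)
  w_main <- 2.0 + 1.4 * ((unit - 1) %% 3)
  w_reb <- 5 + 3 * ((unit - 1) %% 2)
  a_reb <- 0.30 + 0.35 * ((unit - 1) %% 2)
  shift <- 6 + 6 * ((unit - 1) %% 2)
  w <- -exp(-(i - peak_sample)^2 / (2 * w_main^2)) +
    a_reb * exp(-(i - peak_sample - shift)^2 / (2 * w_reb^2))
  w / max(abs(w))
}

# narrow-band Gaussian noise with exactly the requested variance,
# synthesised by brick-wall FFT masking of white noise
band_noise <- function(n, fs, f_lo, f_hi, power_uv2) {
  if (power_uv2 <= 0) return(numeric(n))
  x <- rnorm(n)
  X <- fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)              # two-sided frequency axis
  X[f < f_lo | f > f_hi] <- 0
  y <- Re(fft(X, inverse = TRUE)) / n
  s <- sqrt(mean(y^2))
  if (s == 0) return(numeric(n))
  y * sqrt(power_uv2) / s
}

# all disjoint band components in one pass: the bands are disjoint in
# frequency, so masking one white-noise spectrum gives independent
# components while costing a single forward/inverse FFT pair
multi_band_noise <- function(n, fs, bands, powers) {
  if (all(powers <= 0)) return(numeric(n))
  x <- rnorm(n)
  X <- fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  Y <- complex(n)
  for (b in seq_len(nrow(bands))) {
    pw <- powers[[bands$name[b]]]
    if (pw <= 0) next
    mask <- f >= bands$f_lo[b] & f <= bands$f_hi[b]
    e <- sum(Mod(X[mask])^2) / n^2   # realized variance of the component
    if (e == 0) next
    Y[mask] <- X[mask] * sqrt(pw / e)
  }
  Re(fft(Y, inverse = TRUE)) / n
}

#' Generate one synthetic recording site
#'
#' Background Gaussian noise plus band-limited oscillation components plus
#' biphasic spike waveforms placed at gamma-renewal times (amplitude
#' jittered +/-10% around each unit's drawn peak amplitude).  The same
#' seed reproduces the site bit for bit.
#'
#' @param profile A [region_profile()].
#' @param duration_s Site duration in seconds (default 30).
#' @param fs Sampling rate in Hz (default 24000).
#' @param seed Integer seed.
#' @param trajectory,depth_mm Labels for the returned recording.
#' @param band_power_override Optional named vector replacing the
#'   profile's band powers (used for depth-dependent beta profiles).
#' @return list(recording = [mer_recording], spike_trains = list of spike
#'   time vectors (one per unit), unit_amplitudes, band_power_uv2).
#' @export
generate_site <- function(profile, duration_s = 30, fs = 24000, seed = 1,
                          trajectory = "central", depth_mm = 0,
                          band_power_override = NULL) {
  stopifnot(inherits(profile, "region_profile"), duration_s > 0)
  bands <- mer_bands(disjoint = TRUE)
  powers <- profile$band_power_uv2
  if (!is.null(band_power_override)) powers[names(band_power_override)] <- band_power_override
  if (fs < 2 * max(bands$f_hi))
    stop("fs too low for the synthesized band content")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  n <- round(duration_s * fs)
  x <- rnorm(n, 0, profile$background_sigma_uv) +
    multi_band_noise(n, fs, bands, powers)
  trains <- list()
  amps <- numeric(0)
  if (profile$n_units > 0 && profile$firing_rate_hz > 0) {
    for (u in seq_len(profile$n_units)) {
      tr <- gen_spike_train(profile$firing_rate_hz, duration_s,
                            shape = profile$isi_shape,
                            refractory_ms = profile$refractory_ms)
      tpl <- spike_template(u)
      # each unit draws its peak amplitude from its own slice of the
      # 70-150 uV range, keeping concurrent units distinguishable in scale
      # as well as in shape
      slice <- (profile$spike_amp_uv[2] - profile$spike_amp_uv[1]) /
        profile$n_units
      amp_u <- runif(1, profile$spike_amp_uv[1] + (u - 1) * slice,
                     profile$spike_amp_uv[1] + u * slice)
      idx <- round(tr * fs) + 1L
      ok <- idx - 19L >= 1L & idx + 44L <= n
      tr <- tr[ok]; idx <- idx[ok]
      jit <- runif(length(idx), 0.9, 1.1)
      for (k in seq_along(idx)) {
        w <- (idx[k] - 19L):(idx[k] + 44L)
        x[w] <- x[w] + amp_u * jit[k] * tpl
      }
      trains[[u]] <- tr
      amps[u] <- amp_u
    }
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  list(recording = mer_recording(x, fs, trajectory, depth_mm),
       spike_trains = trains, unit_amplitudes = amps,
       band_power_uv2 = powers)
}

#' Default session configuration for the generator
#'
#' The target trajectory carries the full track order thalamus/ZI (-10..-5
#' mm), white matter (-4), STN (-3..+1), white matter (+2), SNr (+3..+4);
#' the two para-sagittal trajectories a short STN span and no SNr; the
#' remaining two no STN at all.  Injected STN low-beta power peaks at the
#' true target depth (the dorsolateral beta maximum), scaled by
#' `beta_contrast`.
#'
#' @param duration_s Per-site duration (default 30 s; tests reduce it).
#' @param fs Sampling rate (default 24000 Hz).
#' @param target_trajectory,target_depth_mm Ground-truth target (defaults
#'   central, -1 mm; the depth must lie in the STN span).
#' @param beta_contrast Multiplier on the STN low-beta injection (1 =
#'   stated world; the recovery experiment scales it down).
#' @param beta_depth_sigma_mm Width of the within-STN beta depth profile.
#' @param artifact_rate Expected exogenous artifacts per site (Poisson).
#' @param profiles Region profiles (default [default_profiles()]).
#' @return list of class `session_config`.
#' @export
default_session_config <- function(duration_s = 30, fs = 24000,
                                   target_trajectory = "central",
                                   target_depth_mm = -1,
                                   beta_contrast = 1,
                                   beta_depth_sigma_mm = 1.2,
                                   artifact_rate = 0.5,
                                   profiles = default_profiles()) {
  target_trajectory <- match.arg(target_trajectory, MER_TRAJECTORIES)
  depths <- -10:4
  span <- function(tr, regions) data.frame(trajectory = tr, depth_mm = depths,
                                           region = regions,
                                           stringsAsFactors = FALSE)
  full <- c(rep("thalamus_zi", 6), "white_matter", rep("stn", 5),
            "white_matter", rep("snr", 2))
  short <- c(rep("thalamus_zi", 9), "white_matter", rep("stn", 2),
             rep("white_matter", 3))
  none <- c(rep("thalamus_zi", 9), rep("white_matter", 6))
  others <- setdiff(MER_TRAJECTORIES, target_trajectory)
  layout <- rbind(span(target_trajectory, full),
                  span(others[1], short), span(others[2], short),
                  span(others[3], none), span(others[4], none))
  structure(list(duration_s = duration_s, fs = fs,
                 target_trajectory = target_trajectory,
                 target_depth_mm = target_depth_mm,
                 beta_contrast = beta_contrast,
                 beta_depth_sigma_mm = beta_depth_sigma_mm,
                 artifact_rate = artifact_rate,
                 layout = layout, profiles = profiles),
            class = "session_config")
}

#' Generate a full Ben's-Gun session with ground truth
#'
#' 5 trajectories x 15 depths (-10..+4 mm).  Region assignment follows the
#' configured layout; the STN low-beta injection on the target trajectory
#' peaks at the true target depth.  Optional exogenous artifacts
#' (line-frequency bursts and high-variance transients) are added and
#' recorded in the ground truth; they are purely additive, so the spike
#' ground truth is unaffected.
#'
#' @param config A [default_session_config()] (possibly modified).
#' @param seed Integer master seed; per-site seeds are derived from it.
#' @return list(session = [mer_session], truth = ground-truth list with
#'   `regions`, `spike_trains` (per site key), `band_power` (per site),
#'   `artifact_windows` (per site data.frame start_s/end_s/type),
#'   `target_trajectory`, `target_depth_mm`, `seed`).
#' @export
generate_session <- function(config = default_session_config(), seed = 1) {
  stopifnot(inherits(config, "session_config"))
  lay <- config$layout
  tsel <- lay$trajectory == config$target_trajectory & lay$region == "stn"
  if (!config$target_depth_mm %in% lay$depth_mm[tsel])
    stop("target depth ", config$target_depth_mm,
         " outside the STN span of trajectory ", config$target_trajectory)
  recs <- list(); trains <- list(); powers <- list(); arts <- list()
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  for (i in seq_len(nrow(lay))) {
    tr <- lay$trajectory[i]; d <- lay$depth_mm[i]; rg <- lay$region[i]
    prof <- config$profiles[[rg]]
    override <- NULL
    if (rg == "stn") {
      base <- prof$band_power_uv2[["low_beta"]] * config$beta_contrast
      if (tr == config$target_trajectory) {
        g <- 0.4 + 0.6 * exp(-(d - config$target_depth_mm)^2 /
                               (2 * config$beta_depth_sigma_mm^2))
      } else g <- 0.35
      override <- c(low_beta = base * g)
    }
    site_seed <- (seed + 7919 * i) %% 2147483647
    st <- generate_site(prof, duration_s = config$duration_s,
                        fs = config$fs, seed = site_seed,
                        trajectory = tr, depth_mm = d,
                        band_power_override = override)
    key <- site_key(tr, d)
    set.seed((site_seed + 104729) %% 2147483647)
    aw <- inject_artifacts(st$recording, config$artifact_rate)
    recs[[key]] <- aw$recording
    arts[[key]] <- aw$windows
    trains[[key]] <- st$spike_trains
    powers[[key]] <- st$band_power_uv2
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  session <- mer_session(recs, metadata = list(synthetic = TRUE, seed = seed))
  truth <- list(regions = lay, spike_trains = trains,
                band_power = powers, artifact_windows = arts,
                target_trajectory = config$target_trajectory,
                target_depth_mm = config$target_depth_mm, seed = seed)
  list(session = session, truth = truth)
}

# additive exogenous artifacts: 50 Hz line bursts and broadband
# high-variance transients.  Each burst is brief (0.2-0.45 s) and is
# placed inside a single 0.5 s segmentation epoch -- the short exogenous
# interference the one-sided variance-coefficient rule is designed to
# excise; longer boundary-straddling artifacts leave residue under that
# rule (a documented limitation) and are not part of the default world.
inject_artifacts <- function(rec, rate, epoch_len_s = 0.5) {
  n_art <- if (rate > 0) rpois(1, rate) else 0L
  windows <- data.frame(start_s = numeric(0), end_s = numeric(0),
                        type = character(0), stringsAsFactors = FALSE)
  if (n_art < 1) return(list(recording = rec, windows = windows))
  x <- rec$samples; fs <- rec$fs; dur <- rec$duration_s
  n_ep <- floor(dur / epoch_len_s)
  # the variance coefficient is undefined for the first epoch, so the
  # rejection rule cannot screen it; keep injected artifacts where the
  # method under test can in principle find them
  if (n_ep < 2) return(list(recording = rec, windows = windows))
  # non-adjacent epochs: back-to-back artifacts mask each other under the
  # one-sided rule (the variance never drops between them), a limitation
  # documented rather than exercised by the default world
  cand <- 2:n_ep
  epochs <- integer(0)
  while (length(epochs) < n_art && length(cand)) {
    e <- cand[ceiling(runif(1) * length(cand))]
    epochs <- c(epochs, e)
    cand <- setdiff(cand, (e - 1L):(e + 1L))
  }
  for (k in seq_along(epochs)) {
    len <- runif(1, 0.2, 0.45)
    st <- (epochs[k] - 1) * epoch_len_s + runif(1, 0, epoch_len_s - len)
    type <- sample(c("line", "transient"), 1)
    w <- (round(st * fs) + 1L):min(length(x), round((st + len) * fs))
    # exogenous interference dwarfs the neural signal: amplitudes are
    # absolute, large enough to dominate even a spike-rich epoch's variance
    if (type == "line") {
      x[w] <- x[w] + 100 * sin(2 * pi * 50 * (w - 1) / fs)
    } else {
      x[w] <- x[w] + rnorm(length(w), 0, 50)
    }
    windows <- rbind(windows, data.frame(start_s = st, end_s = st + len,
                                         type = type,
                                         stringsAsFactors = FALSE))
  }
  rec$samples <- x
  rec$duration_s <- length(x) / fs
  list(recording = rec, windows = windows)
}
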