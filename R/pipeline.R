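# One-call orchestration: simulate -> clean -> sort -> background ->
# features -> localize, with a flat key=value config, derived stage seeds
# and a manifest, so a run is reproducible bit for bit.

#' Default pipeline configuration
#'
#' Every tunable of every stage, with the documented defaults.  The master
#' seed determines all stage seeds through [stage_seed()].
#'
#' @param seed Master seed.
#' @param input Path of an existing session container (ignored when
#'   `simulate` is TRUE).
#' @return Nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1, input = NULL) {
  structure(list(
    seed = as.integer(seed),
    input = input,
    stages = list(simulate = TRUE, clean = TRUE, sort = TRUE,
                  background = TRUE, features = TRUE, localize = TRUE),
    simulate = list(duration_s = 30, fs = 24000,
                    target_trajectory = "central", target_depth_mm = -1,
                    beta_contrast = 1, beta_depth_sigma_mm = 1.2,
                    artifact_rate = 0.5),
    clean = list(epoch_len_s = 0.5, threshold = 1.8, bridge_ms = 2,
                 n_anchor = 5),
    sort = list(k_thresh = 4, lockout_ms = 1.5, n_select = 10, K = 11,
                n_iter = 500, t_min = 0, t_max = 0.25, t_step = 0.01,
                min_cluster_size = 20),
    background = list(pre_ms = 0.5, post_ms = 2.5, fade_ms = 0.25,
                      lp_hz = 500),
    features = list(epoch_len_s = 0.5, R_ms = 5, welch_window_s = 1)),
    class = "run_config")
}

#' Deterministic per-stage seed derivation
#'
#' `(master + sum of UTF-8 byte values of the stage name) mod (2^31 - 1)`.
#'
#' @param master Master seed.
#' @param stage Stage name.
#' @return Integer seed.
#' @export
stage_seed <- function(master, stage) {
  as.integer((as.numeric(master) + sum(utf8ToInt(stage))) %% 2147483647)
}

flatten_config <- function(x, prefix = NULL) {
  out <- list()
  for (nm in names(x)) {
    key <- if (is.null(prefix)) nm else paste(prefix, nm, sep = ".")
    v <- x[[nm]]
    if (is.list(v)) out <- c(out, flatten_config(v, key))
    else if (!is.null(v)) out[[key]] <- v
  }
  out
}

#' Write a run configuration as a key=value text file
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  fl <- flatten_config(unclass(config))
  writeLines(sprintf("%s=%s", names(fl),
                     vapply(fl, function(v) as.character(v), character(1))),
             path)
  invisible(path)
}

#' Read a key=value run configuration
#'
#' Unknown keys are an error; missing keys keep their defaults.
#' @param path Config file path.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  cfg <- default_run_config()
  known <- names(flatten_config(unclass(cfg)))
  for (p in kv) {
    key <- trimws(p[1]); val <- trimws(paste(p[-1], collapse = "="))
    if (!key %in% known && key != "input")
      stop("unknown config key: ", key)
    path_parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(val))
    parsed <- if (val %in% c("TRUE", "FALSE")) as.logical(val)
      else if (!is.na(num)) num else val
    cfg[[path_parts]] <- parsed
  }
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order, writing every intermediate
#' artifact, the feature CSV, the localization report and a manifest into
#' `out_dir`.  Re-running with an identical config and seed reproduces the
#' feature CSV bit for bit.
#'
#' @param config A `run_config` from [default_run_config()] /
#'   [read_config()].
#' @param out_dir Run directory (created).
#' @param quiet Suppress per-site progress messages.
#' @return list with the session, truth (if simulated), feature table,
#'   localization report and paths, invisibly.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir,
                         quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- config$stages
  truth <- NULL
  if (isTRUE(st$simulate)) {
    sc <- config$simulate
    scfg <- default_session_config(duration_s = sc$duration_s, fs = sc$fs,
                                   target_trajectory = sc$target_trajectory,
                                   target_depth_mm = sc$target_depth_mm,
                                   beta_contrast = sc$beta_contrast,
                                   beta_depth_sigma_mm = sc$beta_depth_sigma_mm,
                                   artifact_rate = sc$artifact_rate)
    gen <- generate_session(scfg, seed = stage_seed(config$seed, "simulate"))
    session <- gen$session
    truth <- gen$truth
    write_session(session, file.path(out_dir, "session"))
    jsonlite::write_json(truth_for_json(truth),
                         file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    if (is.null(config$input))
      stop("simulation disabled and no input container configured")
    session <- read_session(config$input)
  }
  keys <- names(session$recordings)
  fs <- session$fs
  rejections <- data.frame(site = keys, n_epochs = NA_integer_,
                           n_rejected = NA_integer_)
  spikes_tab <- list()
  features <- list()
  sort_seed <- stage_seed(config$seed, "sort")
  bg_seed <- stage_seed(config$seed, "background")
  for (i in seq_along(keys)) {
    key <- keys[i]
    rec <- session$recordings[[key]]
    if (isTRUE(st$clean)) {
      cl <- clean_recording(rec, epoch_len_s = config$clean$epoch_len_s,
                            threshold = config$clean$threshold,
                            bridge_ms = config$clean$bridge_ms,
                            n_anchor = config$clean$n_anchor)
      rec <- cl$recording
      rejections$n_epochs[i] <- cl$n_epochs
      rejections$n_rejected[i] <- cl$n_rejected
    }
    filtered <- bandpass_spike_filter(rec)
    if (isTRUE(st$sort)) {
      sres <- sort_spikes(filtered, fs, k_thresh = config$sort$k_thresh,
                          n_select = config$sort$n_select,
                          params = spc_params(K = config$sort$K,
                                              n_iter = config$sort$n_iter,
                                              t_min = config$sort$t_min,
                                              t_max = config$sort$t_max,
                                              t_step = config$sort$t_step,
                                              min_cluster_size = config$sort$min_cluster_size),
                          seed = (sort_seed + i) %% 2147483647)
    } else {
      ts <- detect_spikes(filtered, fs, k_thresh = config$sort$k_thresh,
                          lockout_ms = config$sort$lockout_ms)
      sres <- list(timestamps = ts,
                   final_labels = rep(1L, length(ts)))
    }
    if (length(sres$timestamps))
      spikes_tab[[key]] <- data.frame(site = key,
                                      timestamp_s = sres$timestamps,
                                      cluster = sres$final_labels)
    if (isTRUE(st$background) || isTRUE(st$features)) {
      bg <- reconstruct_background(rec$samples, sres$timestamps, fs,
                                   seed = (bg_seed + i) %% 2147483647,
                                   pre_ms = config$background$pre_ms,
                                   post_ms = config$background$post_ms,
                                   fade_ms = config$background$fade_ms,
                                   lp_hz = config$background$lp_hz)
      if (isTRUE(st$features))
        features[[key]] <- site_features(rec, sres, bg,
                                         epoch_len_s = config$features$epoch_len_s,
                                         R_ms = config$features$R_ms)
    }
    if (!quiet)
      message(sprintf("[%s] %d spikes, %s epochs rejected", key,
                      length(sres$timestamps),
                      ifelse(is.na(rejections$n_rejected[i]), "-",
                             rejections$n_rejected[i])))
  }
  paths <- list()
  if (isTRUE(st$clean)) {
    paths$rejections <- file.path(out_dir, "rejections.csv")
    data.table::fwrite(rejections, paths$rejections)
  }
  if (length(spikes_tab)) {
    paths$spikes <- file.path(out_dir, "spikes.csv")
    data.table::fwrite(do.call(rbind, spikes_tab), paths$spikes)
  }
  ftab <- NULL; report <- NULL
  if (isTRUE(st$features) && length(features)) {
    paths$features <- file.path(out_dir, "features.csv")
    ftab <- write_feature_table(features, paths$features)
  }
  if (isTRUE(st$localize) && !is.null(ftab)) {
    report <- localize_session(ftab, truth = truth)
    paths$report <- file.path(out_dir, "localization.csv")
    data.table::fwrite(report, paths$report)
    if (!is.null(truth)) {
      roc <- roc_summary(ftab, truth)
      paths$roc <- file.path(out_dir, "roc.csv")
      data.table::fwrite(roc, paths$roc)
    }
  }
  manifest <- list(config = flatten_config(unclass(config)),
                   seed = config$seed,
                   stage_seeds = list(simulate = stage_seed(config$seed, "simulate"),
                                      sort = sort_seed,
                                      background = bg_seed),
                   package_version = as.character(utils::packageVersion("mermap")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(session = session, truth = truth, features = ftab,
                 report = report, paths = paths))
}

# spike trains nested per unit do not serialise cleanly by default
truth_for_json <- function(truth) {
  truth$spike_trains <- lapply(truth$spike_trains, function(units)
    lapply(units, function(u) round(u, 9)))
  truth
}

#' Per-parameter ROC of STN sites against the rest of the track
#'
#' @param features Feature table with key columns.
#' @param truth Ground truth holding the region labels.
#' @param positive_region Region treated as positive class (default stn).
#' @return data.frame parameter/auc/se/n_pos/n_neg.
#' @export
roc_summary <- function(features, truth, positive_region = "stn") {
  reg <- truth$regions$region[match(paste(features$trajectory, features$depth_mm),
                                    paste(truth$regions$trajectory,
                                          truth$regions$depth_mm))]
  pos <- reg == positive_region
  rows <- lapply(site_feature_names(), function(p) {
    v <- features[[p]]
    ok <- !is.na(v)
    if (length(unique(pos[ok])) < 2)
      return(data.frame(parameter = p, auc = NA_real_, se = NA_real_,
                        n_pos = sum(pos[ok]), n_neg = sum(!pos[ok])))
    r <- roc_auc(v[ok], pos[ok])
    data.frame(parameter = p, auc = r$auc, se = r$se, n_pos = r$n_pos,
               n_neg = r$n_neg)
  })
  do.call(rbind, rows)
}
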