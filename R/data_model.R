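#' @useDynLib mermap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats var median rnorm runif rgamma rpois fft splinefun
#'   quantile pnorm pt cor sd
#' @importFrom utils head tail
NULL

#' Electrode trajectories of the five-microelectrode ("Ben's Gun") array
#'
#' Fixed order: this order is also the deterministic tie-break used when two
#' trajectories score identically during target-location prediction.
#' @export
MER_TRAJECTORIES <- c("central", "anterior", "posterior", "medial", "lateral")

#' Names of the 19 automated per-site parameters
#'
#' One spectral mean/max pair per frequency band, the per-band RMS summaries,
#' and the spike-train statistics (modal interspike interval, burst index,
#' LvR, mean and maximum spiking rate).
#' @return Character vector of length 19.
#' @export
site_feature_names <- function() {
  c("Mean_low_freq", "Max_low_freq", "Mean_Alpha", "Max_Alpha",
    "Mean_low_Beta", "Max_low_Beta", "Mean_high_Beta", "Max_high_Beta",
    "Mean_Beta", "Max_Beta", "Mean_Gamma", "Max_Gamma",
    "Mean_RMS", "Max_RMS", "ISI", "BI", "LvR", "Mean_SR", "Max_SR")
}

#' Single-site microelectrode recording
#'
#' @param samples Numeric vector, voltage in microvolts.
#' @param fs Sampling rate in Hz (default sessions use 24000).
#' @param trajectory One of [MER_TRAJECTORIES].
#' @param depth_mm Signed depth in mm relative to the planned target:
#'   negative above (dorsal), 0 at target, positive below (ventral).
#'   Standard sessions use integer depths in -10..4.
#' @return Object of class `mer_recording` with fields `samples`, `fs`,
#'   `trajectory`, `depth_mm`, `duration_s`.
#' @export
mer_recording <- function(samples, fs, trajectory, depth_mm) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar")
  trajectory <- match.arg(trajectory, MER_TRAJECTORIES)
  if (!is.numeric(depth_mm) || length(depth_mm) != 1L)
    stop("depth_mm must be a numeric scalar")
  samples <- as.numeric(samples)
  structure(list(samples = samples, fs = fs, trajectory = trajectory,
                 depth_mm = depth_mm, duration_s = length(samples) / fs),
            class = "mer_recording")
}

#' @export
print.mer_recording <- function(x, ...) {
  cat(sprintf("<mer_recording> %s @ %+d mm: %.2f s at %g Hz (%d samples)\n",
              x$trajectory, as.integer(round(x$depth_mm)), x$duration_s,
              x$fs, length(x$samples)))
  invisible(x)
}

site_key <- function(trajectory, depth_mm) {
  sprintf("%s_%+03d", trajectory, as.integer(round(depth_mm)))
}

#' Session container: one hemisphere's Ben's-Gun recordings
#'
#' At most one recording per (trajectory, depth) pair; all recordings must
#' share one sampling rate.
#'
#' @param recordings List of [mer_recording] objects.
#' @param hemisphere Free-form hemisphere label ("left"/"right").
#' @param metadata Named list of free-form metadata.
#' @return Object of class `mer_session`.
#' @export
mer_session <- function(recordings, hemisphere = "left", metadata = list()) {
  if (!length(recordings)) stop("a session needs at least one recording")
  ok <- vapply(recordings, inherits, logical(1), "mer_recording")
  if (!all(ok)) stop("all elements must be mer_recording objects")
  keys <- vapply(recordings, function(r) site_key(r$trajectory, r$depth_mm),
                 character(1))
  if (anyDuplicated(keys))
    stop("duplicate site(s): ", paste(unique(keys[duplicated(keys)]),
                                      collapse = ", "))
  fss <- vapply(recordings, `[[`, numeric(1), "fs")
  if (length(unique(fss)) != 1L)
    stop("inconsistent sampling rate across sites: ",
         paste(keys[fss != fss[1]], collapse = ", "))
  names(recordings) <- keys
  structure(list(recordings = recordings, hemisphere = hemisphere,
                 metadata = metadata, fs = fss[1]),
            class = "mer_session")
}

#' @export
print.mer_session <- function(x, ...) {
  cat(sprintf("<mer_session> %s hemisphere: %d sites at %g Hz\n",
              x$hemisphere, length(x$recordings), x$fs))
  invisible(x)
}

#' Tabulate the sites of a session
#' @param session A [mer_session].
#' @return data.frame with columns `key`, `trajectory`, `depth_mm`.
#' @export
session_sites <- function(session) {
  data.frame(
    key = names(session$recordings),
    trajectory = vapply(session$recordings, `[[`, character(1), "trajectory"),
    depth_mm = vapply(session$recordings, `[[`, numeric(1), "depth_mm"),
    row.names = NULL, stringsAsFactors = FALSE)
}

# ---- session container I/O ---------------------------------------------
# Open plain-text layout: a directory holding session.json (hemisphere,
# metadata, fs) and one site file per recording.  Each site file carries
# '#'-prefixed header lines (fs, trajectory, depth_mm) followed by one
# sample per line in microvolts.  No vendor format is read.

#' Write a session to an open plain-text container
#'
#' @param session A [mer_session].
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  if (!inherits(session, "mer_session")) stop("not a mer_session")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(hemisphere = session$hemisphere, fs = session$fs,
               metadata = session$metadata,
               sites = names(session$recordings))
  jsonlite::write_json(meta, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (key in names(session$recordings)) {
    r <- session$recordings[[key]]
    f <- file.path(path, paste0(key, ".txt"))
    hdr <- c(sprintf("# fs %.10g", r$fs),
             sprintf("# trajectory %s", r$trajectory),
             sprintf("# depth_mm %d", as.integer(round(r$depth_mm))))
    writeLines(hdr, f)
    data.table::fwrite(list(r$samples), f, append = TRUE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a session from an open plain-text container
#'
#' @param path Directory written by [write_session()] (or assembled by hand
#'   in the same layout).
#' @return A [mer_session]; lossless round trip with [write_session()] to
#'   container numeric precision.
#' @export
read_session <- function(path) {
  if (!dir.exists(path)) stop("no such session container: ", path)
  mf <- file.path(path, "session.json")
  if (!file.exists(mf)) stop("corrupt container (missing session.json): ", path)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  files <- list.files(path, pattern = "\\.txt$", full.names = TRUE)
  if (!length(files)) stop("corrupt container (no site files): ", path)
  recs <- lapply(files, read_site_file)
  keys <- vapply(recs, function(r) site_key(r$trajectory, r$depth_mm),
                 character(1))
  if (anyDuplicated(keys))
    stop("container holds more than one entry for site(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  fss <- vapply(recs, `[[`, numeric(1), "fs")
  if (length(unique(fss)) != 1L)
    stop("inconsistent sampling rate across sites: ",
         paste(keys[fss != fss[1]], collapse = ", "))
  mer_session(recs, hemisphere = meta$hemisphere %||% "left",
              metadata = as.list(meta$metadata))
}

read_site_file <- function(f) {
  hdr <- readLines(f, n = 3L)
  if (length(hdr) < 3L || !all(startsWith(hdr, "#")))
    stop("corrupt site file: ", f)
  gv <- function(key) sub(paste0("^# ", key, " "), "", grep(paste0("^# ", key, " "), hdr, value = TRUE)[1])
  fs <- as.numeric(gv("fs"))
  trajectory <- gv("trajectory")
  depth <- as.numeric(gv("depth_mm"))
  if (is.na(fs) || is.na(depth) || !trajectory %in% MER_TRAJECTORIES)
    stop("corrupt site header in ", f)
  x <- data.table::fread(f, skip = 3L, header = FALSE)
  mer_recording(x[[1]], fs = fs, trajectory = trajectory, depth_mm = depth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the per-site feature table
#'
#' One row per site, the two key columns (`trajectory`, `depth_mm`) followed
#' by one column per automated parameter, named exactly as
#' [site_feature_names()].  Missing values are written as empty cells.
#'
#' @param features Named list: site key -> named numeric vector of the 19
#'   parameters (as produced by [site_features()]); names as returned by
#'   [site_key] are parsed back into the key columns.
#' @param path Output CSV path.
#' @return The feature data.frame, invisibly.
#' @export
write_feature_table <- function(features, path) {
  if (!length(features)) stop("empty feature map")
  df <- feature_table(features)
  data.table::fwrite(df, path, na = "")
  invisible(df)
}

#' Assemble a feature data.frame from a site -> features map
#' @param features Named list keyed by site key; each element a named
#'   numeric vector covering [site_feature_names()].
#' @return data.frame with `trajectory`, `depth_mm` and the 19 parameters.
#' @export
feature_table <- function(features) {
  if (!length(features)) stop("empty feature map")
  nm <- site_feature_names()
  keys <- names(features)
  if (is.null(keys)) stop("features must be a named list keyed by site")
  parts <- strsplit(keys, "_(?=[+-])", perl = TRUE)
  rows <- lapply(seq_along(features), function(i) {
    v <- features[[i]]
    if (!all(nm %in% names(v)))
      stop("feature vector for ", keys[i], " is missing: ",
           paste(setdiff(nm, names(v)), collapse = ", "))
    as.list(v[nm])
  })
  df <- data.frame(trajectory = vapply(parts, `[`, character(1), 1),
                   depth_mm = as.integer(vapply(parts, `[`, character(1), 2)),
                   stringsAsFactors = FALSE)
  cbind(df, do.call(rbind.data.frame, rows))
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path.
#' @return data.frame with key columns and the 19 parameters (NA for blanks).
#' @export
read_feature_table <- function(path) {
  df <- as.data.frame(data.table::fread(path, na.strings = c("", "NA")))
  need <- c("trajectory", "depth_mm", site_feature_names())
  if (!all(need %in% names(df)))
    stop("not a feature table (missing columns): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df
}
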