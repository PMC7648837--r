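# Maximum-parameter target prediction and its evaluation: per-trajectory
# depth prediction, across-trajectory location prediction, detection
# accuracy, ROC/AUC, and Pearson correlations with clinical scores.

#' Predict the target depth along one trajectory
#'
#' Returns the depth at which the parameter is maximal among the depths
#' under consideration (optionally restricted by `region_mask`).  Ties are
#' broken toward the dorsal-most (most negative) depth and flagged.
#'
#' @param values Parameter values, one per depth (NA = missing).
#' @param depths Depths in mm (negative above target).
#' @param region_mask Optional logical mask restricting the candidate
#'   depths (e.g. an SNr span).
#' @return list(depth_mm, tie, n_used); `depth_mm` is NA when no usable
#'   value exists (counted as a failed detection downstream).
#' @export
predict_depth <- function(values, depths, region_mask = NULL) {
  stopifnot(length(values) == length(depths))
  use <- !is.na(values)
  if (!is.null(region_mask)) use <- use & region_mask
  if (!any(use)) return(list(depth_mm = NA_real_, tie = FALSE, n_used = 0L))
  v <- values[use]; d <- depths[use]
  m <- max(v)
  at <- d[v == m]
  list(depth_mm = min(at), tie = length(at) > 1L, n_used = sum(use))
}

#' Predict the target trajectory
#'
#' Each trajectory contributes the parameter value at its own predicted
#' (maximum-parameter) depth; the trajectory with the largest such value is
#' returned.  Ties are broken by the fixed order of [MER_TRAJECTORIES] and
#' flagged.
#'
#' @param best_values Named numeric: best (at-predicted-depth) value per
#'   trajectory; names from [MER_TRAJECTORIES].
#' @return list(trajectory, tie).
#' @export
predict_location <- function(best_values) {
  use <- !is.na(best_values)
  if (sum(use) < 1L) return(list(trajectory = NA_character_, tie = FALSE))
  v <- best_values[use]
  m <- max(v)
  at <- names(v)[v == m]
  ord <- MER_TRAJECTORIES[MER_TRAJECTORIES %in% at]
  list(trajectory = ord[1], tie = length(at) > 1L)
}

#' Detection accuracy of paired predictions
#'
#' @param predictions,truths Paired vectors; a prediction counts as a
#'   success only on exact match (NA never matches).
#' @return list(fraction, string) where `string` is the "x/y" form used in
#'   the report tables.
#' @export
detection_accuracy <- function(predictions, truths) {
  if (!length(predictions) || length(predictions) != length(truths))
    stop("need non-empty paired predictions and truths")
  hit <- !is.na(predictions) & predictions == truths
  list(fraction = mean(hit),
       string = sprintf("%d/%d", sum(hit), length(hit)))
}

#' ROC area under the curve with Hanley-McNeil standard error
#'
#' AUC equals the Mann-Whitney statistic U/(n1 n2) (identical to
#' trapezoidal integration of the ROC curve over all thresholds); ties get
#' half credit.  The standard error follows Hanley & McNeil.
#'
#' @param values Parameter values per site.
#' @param labels Logical (or 0/1): TRUE for the positive (target-region)
#'   class.
#' @return list(auc, se, n_pos, n_neg).
#' @export
roc_auc <- function(values, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]; labels <- labels[ok]
  n1 <- sum(labels); n2 <- sum(!labels)
  if (n1 == 0 || n2 == 0) stop("both classes must be present")
  r <- rank(values)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n2 - 1) * (q2 - auc^2)) / (n1 * n2))
  list(auc = auc, se = se, n_pos = n1, n_neg = n2)
}

#' Pearson correlation with a clinical score, Bonferroni-corrected
#'
#' @param x,y Paired numeric vectors (n >= 3, both nonconstant).
#' @param family_size Number of tests in the comparison family; the
#'   corrected p is `min(1, p * family_size)`.
#' @return list(r, p, p_bonferroni, n).
#' @export
correlate_clinical <- function(x, y, family_size = 1) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) stop("constant vector")
  r <- cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(t), df = n - 2)
  }
  list(r = r, p = p, p_bonferroni = min(1, p * family_size), n = n)
}

#' Localize a session from its feature table
#'
#' Applies the maximum-parameter rule per parameter: the predicted depth on
#' every trajectory and the predicted trajectory.  When ground truth is
#' given, scores STN depth success (predicted depth on the true target
#' trajectory equals the true target depth), SNr depth success (the
#' maximum over the trajectory falls inside the SNr span; a trajectory
#' enters the denominator only when the parameter is computable on at
#' least 2 SNr-span depths), and location success.
#'
#' @param features data.frame as from [feature_table()] /
#'   [read_feature_table()].
#' @param truth Optional ground truth (from [generate_session()]): list
#'   with `target_trajectory`, `target_depth_mm`, `regions` (data.frame
#'   trajectory/depth_mm/region).
#' @param parameters Which parameters to evaluate (default all 19).
#' @return data.frame of class `localization_report`, one row per
#'   parameter: predicted depth per trajectory (wide columns), predicted
#'   trajectory, tie flags, and when truth is given the success flags.
#' @export
localize_session <- function(features, truth = NULL,
                             parameters = site_feature_names()) {
  stopifnot(all(c("trajectory", "depth_mm") %in% names(features)))
  trajs <- MER_TRAJECTORIES[MER_TRAJECTORIES %in% features$trajectory]
  rows <- lapply(parameters, function(p) {
    pd <- lapply(trajs, function(tr) {
      sel <- features$trajectory == tr
      predict_depth(features[[p]][sel], features$depth_mm[sel])
    })
    names(pd) <- trajs
    best <- vapply(trajs, function(tr) {
      sel <- features$trajectory == tr
      d <- pd[[tr]]$depth_mm
      if (is.na(d)) NA_real_
      else features[[p]][sel][match(d, features$depth_mm[sel])]
    }, numeric(1))
    loc <- predict_location(best)
    row <- data.frame(parameter = p, predicted_trajectory = loc$trajectory,
                      location_tie = loc$tie, stringsAsFactors = FALSE)
    for (tr in trajs) {
      row[[paste0("depth_", tr)]] <- pd[[tr]]$depth_mm
      row[[paste0("tie_", tr)]] <- pd[[tr]]$tie
    }
    if (!is.null(truth)) {
      tt <- truth$target_trajectory
      row$depth_success_stn <- !is.na(pd[[tt]]$depth_mm) &&
        pd[[tt]]$depth_mm == truth$target_depth_mm
      row$location_success <- !is.na(loc$trajectory) && loc$trajectory == tt
      snr <- truth$regions$region == "snr" & truth$regions$trajectory == tt
      snr_depths <- truth$regions$depth_mm[snr]
      sel <- features$trajectory == tt
      n_snr_vals <- sum(!is.na(features[[p]][sel]) &
                          features$depth_mm[sel] %in% snr_depths)
      row$snr_evaluable <- length(snr_depths) >= 2 && n_snr_vals >= 2
      row$depth_success_snr <- row$snr_evaluable &&
        !is.na(pd[[tt]]$depth_mm) && pd[[tt]]$depth_mm %in% snr_depths
    }
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("localization_report", class(out))
  out
}

#' Aggregate localization reports over sessions into accuracy tables
#'
#' @param reports List of reports from [localize_session()] (scored against
#'   ground truth).
#' @return data.frame, one row per parameter: STN depth accuracy, location
#'   accuracy and SNr depth accuracy as fractions and "x/y" strings.
#' @export
aggregate_reports <- function(reports) {
  if (!length(reports)) stop("no reports to aggregate")
  pars <- reports[[1]]$parameter
  acc <- function(get, use = NULL) {
    vapply(seq_along(pars), function(i) {
      v <- vapply(reports, function(r) get(r[i, ]), logical(1))
      if (!is.null(use)) {
        u <- vapply(reports, function(r) use(r[i, ]), logical(1))
        v <- v[u]
      }
      if (!length(v)) return(c(NA_real_, 0, 0))
      c(mean(v), sum(v), length(v))
    }, numeric(3))
  }
  stn <- acc(function(r) isTRUE(r$depth_success_stn))
  loc <- acc(function(r) isTRUE(r$location_success))
  snr <- acc(function(r) isTRUE(r$depth_success_snr),
             use = function(r) isTRUE(r$snr_evaluable))
  frac <- function(m) sprintf("%d/%d", as.integer(m[2, ]), as.integer(m[3, ]))
  data.frame(parameter = pars,
             stn_depth_accuracy = stn[1, ],
             stn_depth = frac(stn),
             location_accuracy = loc[1, ],
             location = frac(loc),
             snr_depth_accuracy = snr[1, ],
             snr_depth = frac(snr),
             stringsAsFactors = FALSE)
}
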