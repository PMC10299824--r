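# Per-track feature extraction: time-averaged MSD, anomalous exponent,
# confinement radius, mean frame-to-frame jump.

#' Time-averaged mean squared displacement of one track
#'
#' For each lag tau (in frames) up to `max_lag`, averages the squared
#' Euclidean displacement over *all* same-track pairs of localizations
#' exactly tau frames apart (overlapping pairs; the standard low-variance
#' TA-MSD estimator). Lags with no pair — possible when linking gaps leave
#' no two frames tau apart — are omitted.
#'
#' @param track per-track data frame with columns `frame`, `x`, `y`
#'   (frame-sorted, as produced by the package's readers/simulators).
#' @param max_lag largest lag to evaluate, frames.
#' @return object of class `msd_curve`: list with `lags`, `msd` (um^2) and
#'   `n_pairs`.
#' @export
time_averaged_msd <- function(track, max_lag = NULL) {
  track <- as_track_df(track)
  n <- nrow(track)
  if (n < 2L) abort_validation("time_averaged_msd needs at least 2 localizations")
  if (is.null(max_lag)) max_lag <- max(track$frame) - min(track$frame)
  if (max_lag < 1) abort_validation("max_lag must be >= 1")
  frames <- track$frame
  gapfree <- all(diff(frames) == 1L)
  lags <- integer(0); msd <- double(0); np <- integer(0)
  for (tau in seq_len(min(max_lag, max(frames) - min(frames)))) {
    if (gapfree) {
      i <- seq_len(n - tau); j <- i + tau
    } else {
      j <- match(frames + tau, frames)
      i <- which(!is.na(j)); j <- j[i]
      if (!length(i)) next
    }
    d2 <- (track$x[j] - track$x[i])^2 + (track$y[j] - track$y[i])^2
    lags <- c(lags, tau); msd <- c(msd, mean(d2)); np <- c(np, length(d2))
  }
  structure(list(lags = lags, msd = msd, n_pairs = np), class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("<msd_curve> %d lags, msd range [%.4g, %.4g] um^2\n",
              length(x$lags), min(x$msd), max(x$msd)))
  invisible(x)
}

#' Anomalous diffusion exponent from an MSD curve
#'
#' Fits `log(msd) ~ log(lag)` by ordinary least squares over the lag window
#' and returns the slope, the anomalous exponent alpha (alpha < 1
#' subdiffusive/confined, ~1 Brownian, > 1 directed). Lags with
#' non-positive MSD are excluded; fewer than two usable lags flags the fit
#' as failed rather than erroring, so degenerate tracks can be dropped
#' downstream.
#'
#' @param curve an [time_averaged_msd()] result.
#' @param lag_range inclusive `(min, max)` lag window in frames; default
#'   lags 1-4, the short-lag window appropriate for the short tracks that
#'   dominate single-molecule data.
#' @return list with `alpha`, `log_intercept`, `n_lags`, `fit_ok`.
#' @export
fit_anomalous_exponent <- function(curve, lag_range = c(1, 4)) {
  stopifnot(inherits(curve, "msd_curve"))
  keep <- curve$lags >= lag_range[1] & curve$lags <= lag_range[2] & curve$msd > 0
  if (sum(keep) < 2L)
    return(list(alpha = NA_real_, log_intercept = NA_real_,
                n_lags = sum(keep), fit_ok = FALSE))
  fit <- lm(log(curve$msd[keep]) ~ log(curve$lags[keep]))
  list(alpha = unname(coef(fit)[2L]), log_intercept = unname(coef(fit)[1L]),
       n_lags = sum(keep), fit_ok = TRUE)
}

#' Radius of confinement from an MSD curve
#'
#' Fits the confined-diffusion saturation model
#' `msd(tau) = Rc^2 * (1 - exp(-4 * D * tau * dt / Rc^2))`
#' by nonlinear least squares (Levenberg-Marquardt) and returns `Rc`, the
#' radius of the region the molecule explores (the MSD plateau is `Rc^2`).
#' If the fit fails to converge the fallback is the geometric plateau
#' estimate `sqrt(mean msd over the last quartile of lags)`, flagged in the
#' result.
#'
#' @param curve an [time_averaged_msd()] result with >= 3 lags.
#' @param dt frame interval, seconds.
#' @return list with `r_conf` (um), `D_fit` (um^2/s or `NA`), `converged`.
#' @export
fit_confinement_radius <- function(curve, dt = 0.01) {
  stopifnot(inherits(curve, "msd_curve"))
  if (length(curve$lags) < 3L)
    abort_validation("fit_confinement_radius needs >= 3 lags")
  if (all(curve$msd <= 0))
    return(list(r_conf = 0, D_fit = NA_real_, converged = FALSE))
  df <- data.frame(tau = curve$lags, msd = curve$msd)
  plateau_fallback <- function() {
    tail_lags <- df$tau >= quantile(df$tau, 0.75)
    sqrt(mean(df$msd[tail_lags]))
  }
  rc0 <- sqrt(max(df$msd))
  d0 <- max(df$msd[1L] / (4 * df$tau[1L] * dt), 1e-8)
  fit <- tryCatch(
    minpack.lm::nlsLM(msd ~ Rc^2 * (1 - exp(-4 * D * tau * dt / Rc^2)),
                      data = df, start = list(Rc = rc0, D = d0),
                      lower = c(Rc = 1e-9, D = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(r_conf = plateau_fallback(), D_fit = NA_real_, converged = FALSE))
  est <- coef(fit)
  list(r_conf = unname(est["Rc"]), D_fit = unname(est["D"]), converged = TRUE)
}

#' Mean frame-to-frame jump of one track
#'
#' Mean Euclidean displacement over consecutive-frame pairs only; pairs
#' spanning a linking gap are excluded, since "frame-to-frame" is a
#' physical displacement per frame interval. A track with no
#' consecutive-frame pair returns `NA` (flagged downstream).
#'
#' @param track per-track data frame with `frame`, `x`, `y`.
#' @return mean jump in um, or `NA_real_` if no consecutive pair exists.
#' @export
mean_jump <- function(track) {
  track <- as_track_df(track)
  if (nrow(track) < 2L) abort_validation("mean_jump needs at least 2 localizations")
  consec <- which(diff(track$frame) == 1L)
  if (!length(consec)) return(NA_real_)
  mean(sqrt(diff(track$x)[consec]^2 + diff(track$y)[consec]^2))
}

# Accept either a trackset with one track or a bare per-track data frame.
as_track_df <- function(track) {
  if (inherits(track, "trackset")) {
    if (n_tracks(track) != 1L)
      abort_validation("expected a single track")
    track <- track$tracks
  }
  stopifnot(is.data.frame(track), all(c("frame", "x", "y") %in% names(track)))
  track[order(track$frame), , drop = FALSE]
}

#' Feature extraction configuration
#'
#' @param alpha_lag_range inclusive lag window (frames) for the anomalous
#'   exponent fit.
#' @param max_lag largest MSD lag evaluated per track (capped at the track's
#'   frame span).
#' @param min_duration minimum track duration, frames; tracks below it are
#'   discarded before analysis.
#' @return list of class `feature_config`.
#' @export
feature_config <- function(alpha_lag_range = c(1, 4), max_lag = 50,
                           min_duration = 5) {
  structure(list(alpha_lag_range = alpha_lag_range, max_lag = max_lag,
                 min_duration = min_duration), class = "feature_config")
}

#' Compute the per-track feature record
#'
#' Orchestrates [time_averaged_msd()], [fit_anomalous_exponent()],
#' [fit_confinement_radius()] and [mean_jump()] into the one-row feature
#' record used by the classifier. The motion class is left unset here;
#' classification is a separate stage.
#'
#' @param track per-track data frame (`frame`, `x`, `y`).
#' @param track_id identifier recorded in the output row.
#' @param dt frame interval, seconds.
#' @param config a [feature_config()].
#' @param parent_id identifier of the parent track for butterfly segments,
#'   else `NA`.
#' @return one-row data frame with columns `track_id`, `parent_id`,
#'   `duration`, `alpha`, `r_conf_um`, `mean_jump_um`, `motion_class`,
#'   `fit_ok`.
#' @export
compute_features <- function(track, track_id = "trk", dt = 0.01,
                             config = feature_config(), parent_id = NA_character_) {
  track <- as_track_df(track)
  duration <- nrow(track)
  if (duration < config$min_duration)
    abort_validation(sprintf("track duration %d below minimum %d",
                             duration, config$min_duration))
  mj <- mean_jump(track)
  span <- max(track$frame) - min(track$frame)
  curve <- time_averaged_msd(track, max_lag = min(config$max_lag, span))
  af <- fit_anomalous_exponent(curve, config$alpha_lag_range)
  rc <- if (length(curve$lags) >= 3L) {
    fit_confinement_radius(curve, dt = dt)
  } else {
    list(r_conf = NA_real_, D_fit = NA_real_, converged = FALSE)
  }
  data.frame(track_id = track_id, parent_id = parent_id, duration = duration,
             alpha = af$alpha, r_conf_um = rc$r_conf, mean_jump_um = mj,
             motion_class = NA_character_,
             fit_ok = af$fit_ok && !is.na(mj),
             stringsAsFactors = FALSE)
}

#' Write a feature table
#'
#' Delimited-text schema:
#' `track_id,parent_id,duration,alpha,r_conf_um,mean_jump_um,motion_class,fit_ok`.
#'
#' @param features feature data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  write.table(features, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path file path.
#' @return feature data frame.
#' @export
read_feature_table <- function(path) {
  read.delim(path, sep = ",", stringsAsFactors = FALSE)
}
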