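# Motion-class assignment, butterfly detection/segmentation, quality
# filters and seeded down-sampling.
#
# Class boundaries follow the track classifier conventions:
#   alpha <= 0.7        -> Confined
#   0.7 < alpha < 1     -> Brownian
#   alpha >= 1          -> Directed
# Mixed-mobility ("butterfly") tracks are flagged by an outlier jump and
# split into sub-trajectories that re-enter feature extraction and
# classification; the parent itself is excluded from the final
# two-parameter table.

#' Classification configuration
#'
#' All thresholds of the track-classification pipeline in one place.
#'
#' @param alpha_confined_max upper alpha bound of the Confined class
#'   (inclusive); default 0.7.
#' @param alpha_directed_min lower alpha bound of the Directed class
#'   (inclusive); default 1.0.
#' @param butterfly_rule how an outlier jump is defined: `"relative"`
#'   (jump > mean jump x (1 + threshold); default threshold 1.5, i.e.
#'   2.5x the track's mean jump), `"additive_sd"` (jump > mean +
#'   threshold x s.d. of jumps) or `"absolute"` (jump > threshold um).
#' @param butterfly_threshold threshold parameter of the rule.
#' @param min_duration minimum track duration in frames; default 5.
#' @param confined_jump_max_um maximum mean frame-to-frame jump allowed for
#'   Confined tracks and confined butterfly segments; default 0.1 um
#'   (100 nm).
#' @param downsample_n tracks per down-sampled replicate; default 20000.
#' @param downsample_reps number of down-sampled replicates; default 3.
#' @param seed master seed for the down-sampling streams.
#' @param alpha_lag_range lag window for the alpha fit, passed through to
#'   [feature_config()].
#' @param max_lag largest MSD lag evaluated per track.
#' @return list of class `classify_config`.
#' @export
classify_config <- function(alpha_confined_max = 0.7, alpha_directed_min = 1.0,
                            butterfly_rule = c("relative", "additive_sd", "absolute"),
                            butterfly_threshold = 1.5, min_duration = 5,
                            confined_jump_max_um = 0.1, downsample_n = 20000,
                            downsample_reps = 3, seed = 1L,
                            alpha_lag_range = c(1, 4), max_lag = 50) {
  butterfly_rule <- match.arg(butterfly_rule)
  if (!(alpha_confined_max > 0 && alpha_confined_max < alpha_directed_min))
    abort_validation("need 0 < alpha_confined_max < alpha_directed_min")
  if (butterfly_threshold <= 0) abort_validation("butterfly_threshold must be > 0")
  if (min_duration < 1) abort_validation("min_duration must be >= 1")
  if (confined_jump_max_um <= 0) abort_validation("confined_jump_max_um must be > 0")
  if (downsample_n < 0) abort_validation("downsample_n must be >= 0")
  if (downsample_reps < 1) abort_validation("downsample_reps must be >= 1")
  structure(list(alpha_confined_max = alpha_confined_max,
                 alpha_directed_min = alpha_directed_min,
                 butterfly_rule = butterfly_rule,
                 butterfly_threshold = butterfly_threshold,
                 min_duration = as.integer(min_duration),
                 confined_jump_max_um = confined_jump_max_um,
                 downsample_n = as.integer(downsample_n),
                 downsample_reps = as.integer(downsample_reps),
                 seed = as.integer(seed),
                 alpha_lag_range = alpha_lag_range, max_lag = max_lag),
            class = "classify_config")
}

#' Classify a fitted anomalous exponent
#'
#' @param alpha fitted anomalous exponent(s); vectorized.
#' @param config a [classify_config()].
#' @return character vector: `"Confined"`, `"Brownian"` or `"Directed"`;
#'   `NA` for non-finite alpha (classification refused).
#' @export
classify_alpha <- function(alpha, config = classify_config()) {
  out <- rep(NA_character_, length(alpha))
  ok <- is.finite(alpha)
  out[ok & alpha <= config$alpha_confined_max] <- "Confined"
  out[ok & alpha > config$alpha_confined_max &
        alpha < config$alpha_directed_min] <- "Brownian"
  out[ok & alpha >= config$alpha_directed_min] <- "Directed"
  out
}

# Jump lengths over consecutive-frame steps; step i is between localization
# i and i+1. Steps across linking gaps are NA (never split points).
consecutive_jumps <- function(track) {
  track <- as_track_df(track)
  j <- sqrt(diff(track$x)^2 + diff(track$y)^2)
  j[diff(track$frame) != 1L] <- NA_real_
  j
}

#' Detect butterfly split points in one track
#'
#' A track mixing confined and free behaviour betrays itself by one or more
#' jumps far above its own average jump. Under the default `relative` rule
#' with threshold `t`, step `i` is a split when
#' `jump_i > mean_jump(track) * (1 + t)`; `additive_sd` uses
#' `mean + t * sd` of the jumps and `absolute` a fixed length in um.
#'
#' @param track per-track data frame (`frame`, `x`, `y`).
#' @param config a [classify_config()].
#' @return integer vector of split step indices (step `i` lies between
#'   localizations `i` and `i+1`); empty when no jump qualifies.
#' @export
detect_butterfly_splits <- function(track, config = classify_config()) {
  jumps <- consecutive_jumps(track)
  usable <- !is.na(jumps)
  if (!any(usable)) return(integer(0))
  thr <- switch(config$butterfly_rule,
    relative    = mean(jumps[usable]) * (1 + config$butterfly_threshold),
    additive_sd = mean(jumps[usable]) +
                  config$butterfly_threshold * sd(jumps[usable]),
    absolute    = config$butterfly_threshold)
  if (!is.finite(thr)) return(integer(0))
  which(usable & jumps > thr)
}

#' Segment a butterfly track at its split steps
#'
#' Partitions the localizations at each split step; the split displacement
#' itself belongs to neither segment. Segments shorter than
#' `config$min_duration` are discarded.
#'
#' @param track per-track data frame (`frame`, `x`, `y`).
#' @param splits split step indices from [detect_butterfly_splits()].
#' @param config a [classify_config()].
#' @return list of per-segment data frames; with no splits, a singleton
#'   list holding the original track.
#' @export
segment_butterfly <- function(track, splits, config = classify_config()) {
  track <- as_track_df(track)
  n <- nrow(track)
  if (!length(splits)) return(list(track))
  splits <- sort(unique(as.integer(splits)))
  if (any(splits < 1L | splits >= n))
    abort_validation("split indices must lie between 1 and duration - 1")
  bounds <- c(0L, splits, n)
  segs <- lapply(seq_len(length(bounds) - 1L), function(k) {
    track[(bounds[k] + 1L):bounds[k + 1L], , drop = FALSE]
  })
  segs[vapply(segs, nrow, 1L) >= config$min_duration]
}

#' Discard tracks shorter than the minimum duration
#'
#' Tracks with fewer than `min_duration` localizations (default five
#' frames) carry too little information for MSD fitting and are discarded.
#' Idempotent.
#'
#' @param ts a [trackset()].
#' @param min_duration minimum number of localizations retained.
#' @return filtered [trackset()].
#' @export
apply_duration_filter <- function(ts, min_duration = 5) {
  stopifnot(inherits(ts, "trackset"))
  dur <- track_durations(ts)
  keep <- names(dur)[dur >= min_duration]
  out <- ts
  out$tracks <- ts$tracks[ts$tracks$track_id %in% keep, , drop = FALSE]
  rownames(out$tracks) <- NULL
  out
}

#' Confined-motion jump filter
#'
#' Removes feature rows labelled Confined (whole tracks and confined
#' butterfly segments alike) whose mean frame-to-frame jump exceeds the
#' threshold — by default 100 nm, the cut that strips fast-moving molecules
#' misassigned to the confined class. Rows of other classes pass
#' untouched. Idempotent.
#'
#' @param features feature data frame with assigned `motion_class`.
#' @param max_um threshold, um.
#' @return filtered feature data frame.
#' @export
apply_confined_jump_filter <- function(features, max_um = 0.1) {
  drop <- features$motion_class %in% "Confined" &
    !is.na(features$mean_jump_um) & features$mean_jump_um > max_um
  out <- features[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Randomized down-sampling of the feature table
#'
#' Draws `reps` independent uniform subsets of `n` rows without
#' replacement (all rows when fewer than `n` are available), one per
#' replicate, from seeded streams `seed + 1, ..., seed + reps`.
#' Deterministic given `seed`.
#'
#' @param features feature data frame.
#' @param n rows per replicate; default 20000.
#' @param reps number of replicates; default 3.
#' @param seed master seed.
#' @return list of `reps` feature data frames.
#' @export
downsample_tracks <- function(features, n = 20000, reps = 3, seed = 1L) {
  if (n < 0) abort_validation("n must be >= 0")
  lapply(seq_len(reps), function(r) {
    set.seed(seed + r)
    k <- min(n, nrow(features))
    idx <- sort(sample.int(nrow(features), k))
    out <- features[idx, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Run the full track-classification pipeline
#'
#' Stage order: duration filter -> per-track features -> butterfly
#' detection and segmentation -> segment features -> alpha classification
#' -> confined-jump filter -> randomized down-sampling. Butterfly parents
#' are recorded but excluded from the final table; their qualifying
#' segments are classified in their place. Rows whose alpha fit failed are
#' dropped and counted.
#'
#' @param ts a [trackset()].
#' @param config a [classify_config()].
#' @return object of class `smt_classification`: list with `features`
#'   (final classified feature table), `parents` (butterfly parent
#'   records), `replicates` (down-sampled tables), `log` (stage-by-stage
#'   row counts) and `config`.
#' @export
run_classification <- function(ts, config = classify_config()) {
  stopifnot(inherits(ts, "trackset"), inherits(config, "classify_config"))
  fcfg <- feature_config(alpha_lag_range = config$alpha_lag_range,
                         max_lag = config$max_lag,
                         min_duration = config$min_duration)
  dt <- ts$frame_interval_s
  log <- list(input_tracks = n_tracks(ts))

  kept <- apply_duration_filter(ts, config$min_duration)
  log$after_duration_filter <- n_tracks(kept)
  log$removed_short <- log$input_tracks - log$after_duration_filter

  tracks <- split_tracks(kept)
  feat_rows <- list()
  parent_rows <- list()
  n_butterfly <- 0L
  for (id in names(tracks)) {
    trk <- tracks[[id]]
    splits <- detect_butterfly_splits(trk, config)
    if (length(splits)) {
      n_butterfly <- n_butterfly + 1L
      parent_rows[[id]] <- data.frame(track_id = id, n_splits = length(splits),
                                      duration = nrow(trk), stringsAsFactors = FALSE)
      segs <- segment_butterfly(trk, splits, config)
      for (k in seq_along(segs)) {
        feat_rows[[length(feat_rows) + 1L]] <-
          compute_features(segs[[k]], track_id = sprintf("%s.seg%d", id, k),
                           dt = dt, config = fcfg, parent_id = id)
      }
    } else {
      feat_rows[[length(feat_rows) + 1L]] <-
        compute_features(trk, track_id = id, dt = dt, config = fcfg)
    }
  }
  features <- if (length(feat_rows)) do.call(rbind, feat_rows) else
    empty_feature_table()
  log$butterfly_parents <- n_butterfly
  log$feature_rows <- nrow(features)

  fit_failed <- !features$fit_ok
  log$removed_fit_failed <- sum(fit_failed)
  features <- features[!fit_failed, , drop = FALSE]

  features$motion_class <- classify_alpha(features$alpha, config)

  n_before <- nrow(features)
  features <- apply_confined_jump_filter(features, config$confined_jump_max_um)
  log$removed_confined_jump <- n_before - nrow(features)
  log$final_rows <- nrow(features)
  rownames(features) <- NULL

  replicates <- downsample_tracks(features, n = config$downsample_n,
                                  reps = config$downsample_reps,
                                  seed = config$seed)
  parents <- if (length(parent_rows)) do.call(rbind, parent_rows) else
    data.frame(track_id = character(), n_splits = integer(),
               duration = integer(), stringsAsFactors = FALSE)
  rownames(parents) <- NULL
  structure(list(features = features, parents = parents,
                 replicates = replicates, log = log, config = config),
            class = "smt_classification")
}

empty_feature_table <- function() {
  data.frame(track_id = character(), parent_id = character(),
             duration = integer(), alpha = double(), r_conf_um = double(),
             mean_jump_um = double(), motion_class = character(),
             fit_ok = logical(), stringsAsFactors = FALSE)
}

#' @export
print.smt_classification <- function(x, ...) {
  cat("<smt_classification>\n")
  cat(sprintf("  %d input tracks -> %d classified rows (%d butterfly parents segmented)\n",
              x$log$input_tracks, x$log$final_rows, x$log$butterfly_parents))
  if (nrow(x$features)) {
    tab <- table(x$features$motion_class)
    cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  cat(sprintf("  %d down-sampled replicate(s) of <= %d rows (seed %d)\n",
              length(x$replicates), x$config$downsample_n, x$config$seed))
  invisible(x)
}

#' @export
summary.smt_classification <- function(object, ...) {
  counts <- unlist(object$log)
  cls <- if (nrow(object$features))
    prop.table(table(object$features$motion_class)) else table(character())
  out <- list(stage_counts = counts, class_fractions = cls)
  class(out) <- "summary.smt_classification"
  out
}

#' @export
print.summary.smt_classification <- function(x, ...) {
  cat("Stage counts:\n")
  print(x$stage_counts)
  cat("Class fractions:\n")
  print(round(x$class_fractions, 3))
  invisible(x)
}
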