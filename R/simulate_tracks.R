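# Trajectory simulators with known ground truth.
#
# Four motion classes are generated in 2D at the acquisition frame rate:
#   brownian  — Gaussian steps, per-axis variance 2*D*dt
#   confined  — the same steps, hard-reflected at a circle of radius Rc
#               centred on the start point
#   directed  — drift v*dt along a fixed heading plus diffusion
#   butterfly — confined regime up to switch_frame, then directed, position
#               continuous at the switch
# Independent Gaussian localization error (s.d. sigma_loc per coordinate)
# is added to every reported position.

#' Motion specification for a single simulated track
#'
#' @param motion_class one of `"brownian"`, `"confined"`, `"directed"`,
#'   `"butterfly"`.
#' @param D diffusion coefficient, um^2/s.
#' @param Rc confinement radius, um (confined and butterfly classes).
#' @param v drift speed, um/s (directed class and the directed phase of a
#'   butterfly track).
#' @param heading drift direction, radians.
#' @param sigma_loc localization error s.d. per coordinate, um.
#' @param switch_frame frame at which a butterfly track switches from the
#'   confined to the directed regime; `NULL` means 3/4 of the track length.
#' @param D2 diffusion coefficient of the butterfly directed phase, um^2/s.
#' @return A validated `motion_spec` list.
#' @export
motion_spec <- function(motion_class = c("brownian", "confined", "directed", "butterfly"),
                        D = 0.3, Rc = 0.08, v = 4, heading = 0,
                        sigma_loc = 0.03, switch_frame = NULL, D2 = 0.3) {
  motion_class <- match.arg(motion_class)
  if (!is.numeric(D) || D < 0) abort_validation("D must be >= 0")
  if (motion_class %in% c("confined", "butterfly") && (!is.numeric(Rc) || Rc <= 0))
    abort_validation("Rc must be > 0 for confined/butterfly motion")
  if (motion_class %in% c("directed", "butterfly") && (!is.numeric(v) || v < 0))
    abort_validation("v must be >= 0 for directed/butterfly motion")
  if (!is.numeric(sigma_loc) || sigma_loc < 0) abort_validation("sigma_loc must be >= 0")
  if (!is.null(switch_frame) && (!is.numeric(switch_frame) || switch_frame < 1))
    abort_validation("switch_frame must be a positive frame index")
  structure(list(motion_class = motion_class, D = D, Rc = Rc, v = v,
                 heading = heading, sigma_loc = sigma_loc,
                 switch_frame = switch_frame, D2 = D2),
            class = "motion_spec")
}

# Diffusive 2D walk from `start`, reflected at the circle |p - centre| <= Rc.
# Reflection is radial: an excursion of depth e beyond the boundary is folded
# back to depth e inside it, so true positions never leave the disk.
reflected_walk <- function(n_steps, start, centre, Rc, step_sd) {
  pos <- matrix(0, n_steps + 1L, 2L)
  pos[1L, ] <- start
  if (n_steps == 0L) return(pos)
  dx <- rnorm(n_steps, 0, step_sd)
  dy <- rnorm(n_steps, 0, step_sd)
  for (i in seq_len(n_steps)) {
    p <- pos[i, ] + c(dx[i], dy[i])
    r <- sqrt(sum((p - centre)^2))
    while (r > Rc) {
      p <- centre + (p - centre) * (2 * Rc - r) / r
      r <- abs(2 * Rc - r)
    }
    pos[i + 1L, ] <- p
  }
  pos
}

#' Simulate one 2D trajectory
#'
#' Generates a single track under a [motion_spec()] using the current RNG
#' state (seed upstream with `set.seed()` for reproducibility).
#'
#' @param spec a [motion_spec()].
#' @param n_frames number of localizations (>= 1).
#' @param dt frame interval, seconds.
#' @param start length-2 start position, um.
#' @param track_id identifier for the returned track.
#' @param return_true if `TRUE`, attach the noise-free positions as
#'   attributes `true_x`, `true_y`.
#' @return data frame with columns `track_id`, `frame`, `x`, `y`.
#' @export
simulate_track <- function(spec, n_frames, dt = 0.01, start = c(0, 0),
                           track_id = "sim", return_true = FALSE) {
  stopifnot(inherits(spec, "motion_spec"))
  if (!is.numeric(n_frames) || n_frames < 1) abort_validation("n_frames must be >= 1")
  n_frames <- as.integer(n_frames)
  n_steps <- n_frames - 1L
  step_sd <- sqrt(2 * spec$D * dt)

  pos <- switch(spec$motion_class,
    brownian = {
      cbind(start[1] + cumsum(c(0, rnorm(n_steps, 0, step_sd))),
            start[2] + cumsum(c(0, rnorm(n_steps, 0, step_sd))))
    },
    confined = reflected_walk(n_steps, start, start, spec$Rc, step_sd),
    directed = {
      drift <- spec$v * dt * c(cos(spec$heading), sin(spec$heading))
      cbind(start[1] + cumsum(c(0, rnorm(n_steps, drift[1], step_sd))),
            start[2] + cumsum(c(0, rnorm(n_steps, drift[2], step_sd))))
    },
    butterfly = {
      sw <- spec$switch_frame %||% max(2L, as.integer(round(0.75 * n_frames)))
      if (sw >= n_frames) sw <- n_frames - 1L
      if (sw < 1L) sw <- 1L
      conf <- reflected_walk(sw - 1L, start, start, spec$Rc, step_sd)
      n2 <- n_frames - sw
      drift <- spec$v * dt * c(cos(spec$heading), sin(spec$heading))
      sd2 <- sqrt(2 * spec$D2 * dt)
      last <- conf[nrow(conf), ]
      dir <- cbind(last[1] + cumsum(rnorm(n2, drift[1], sd2)),
                   last[2] + cumsum(rnorm(n2, drift[2], sd2)))
      rbind(conf, dir)
    })

  x <- pos[, 1] + rnorm(n_frames, 0, spec$sigma_loc)
  y <- pos[, 2] + rnorm(n_frames, 0, spec$sigma_loc)
  out <- data.frame(track_id = track_id, frame = 0:(n_frames - 1L), x = x, y = y,
                    stringsAsFactors = FALSE)
  if (return_true) {
    attr(out, "true_x") <- pos[, 1]
    attr(out, "true_y") <- pos[, 2]
  }
  out
}

default_class_params <- function() {
  list(
    brownian  = list(D = 0.3),
    confined  = list(D = 0.1, Rc = 0.08),
    directed  = list(D = 0.01, v = 4),
    butterfly = list(D = 0.1, Rc = 0.08, v = 4, D2 = 0.3)
  )
}

#' Experiment specification for a simulated track set
#'
#' Defines a mixture of motion classes, the track-length law and the
#' acquisition parameters for [simulate_tracks()]. Defaults emulate a
#' chromatin-interacting transcription factor imaged at 100 Hz with ~30 nm
#' localization error: mostly confined and slow-Brownian molecules, a
#' directed minority, and a small mixed-mobility (butterfly) fraction.
#'
#' @param n_tracks number of tracks to generate.
#' @param mixture_weights named non-negative weights over
#'   `brownian`, `confined`, `directed`, `butterfly`; must sum to 1.
#' @param class_params named list of per-class parameter overrides passed to
#'   [motion_spec()] (e.g. `list(confined = list(D = 0.05, Rc = 0.1))`).
#' @param sigma_loc localization error s.d. per coordinate, um.
#' @param length_law list with `mean` (mean track length, frames) and `min`
#'   (minimum length); lengths are `min - 1 + 1 +` geometric. Set `fixed` to
#'   a frame count for constant-length tracks.
#' @param frame_interval_s seconds per frame.
#' @param seed RNG seed.
#' @return A validated `experiment_spec` list.
#' @export
experiment_spec <- function(n_tracks = 1000,
                            mixture_weights = c(brownian = 0.3, confined = 0.4,
                                                directed = 0.2, butterfly = 0.1),
                            class_params = list(),
                            sigma_loc = 0.03,
                            length_law = list(mean = 30, min = 1, fixed = NULL),
                            frame_interval_s = 0.01,
                            seed = 1L) {
  if (!is.numeric(n_tracks) || n_tracks < 0) abort_validation("n_tracks must be >= 0")
  classes <- c("brownian", "confined", "directed", "butterfly")
  w <- mixture_weights[classes]
  w[is.na(w)] <- 0
  names(w) <- classes
  if (any(w < 0)) abort_validation("mixture weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-9) abort_validation("mixture weights must sum to 1")
  params <- modifyList(default_class_params(), class_params)
  length_law <- modifyList(list(mean = 30, min = 1, fixed = NULL), length_law)
  if (is.null(length_law$fixed) && length_law$mean <= length_law$min)
    abort_validation("length_law$mean must exceed length_law$min")
  structure(list(n_tracks = as.integer(n_tracks), mixture_weights = w,
                 class_params = params, sigma_loc = sigma_loc,
                 length_law = length_law, frame_interval_s = frame_interval_s,
                 seed = as.integer(seed)),
            class = "experiment_spec")
}

draw_track_length <- function(law, n) {
  if (!is.null(law$fixed)) return(rep(as.integer(law$fixed), n))
  # geometric residual above the minimum; photobleaching-like
  law$min + rgeom(n, prob = 1 / (law$mean - law$min + 1))
}

#' Simulate a track set with ground truth
#'
#' Draws each track's motion class from the mixture, its length from the
#' length law, and its trajectory from [simulate_track()]. Fully
#' reproducible from `spec$seed`.
#'
#' @param spec an [experiment_spec()].
#' @return list with `trackset` (a [trackset()]) and `truth`, a data frame
#'   keyed by `track_id` giving each track's generating class and
#'   parameters.
#' @export
simulate_tracks <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  set.seed(spec$seed)
  n <- spec$n_tracks
  if (n == 0L) {
    return(list(trackset = trackset(frame_interval_s = spec$frame_interval_s),
                truth = data.frame(track_id = character(), motion_class = character(),
                                   n_frames = integer(), D = double(), Rc = double(),
                                   v = double(), stringsAsFactors = FALSE)))
  }
  classes <- names(spec$mixture_weights)
  cls <- sample(classes, n, replace = TRUE, prob = spec$mixture_weights)
  lens <- draw_track_length(spec$length_law, n)
  ids <- sprintf("trk%0*d", nchar(n), seq_len(n))
  rows <- vector("list", n)
  truth <- data.frame(track_id = ids, motion_class = cls, n_frames = lens,
                      D = NA_real_, Rc = NA_real_, v = NA_real_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    p <- spec$class_params[[cls[i]]]
    ms <- motion_spec(cls[i],
                      D = p$D %||% 0.3, Rc = p$Rc %||% 0.08, v = p$v %||% 4,
                      heading = runif(1, 0, 2 * pi), sigma_loc = spec$sigma_loc,
                      D2 = p$D2 %||% (p$D %||% 0.3))
    start <- runif(2, 0, 10)
    rows[[i]] <- simulate_track(ms, lens[i], dt = spec$frame_interval_s,
                                start = start, track_id = ids[i])
    truth$D[i] <- ms$D
    truth$Rc[i] <- if (cls[i] %in% c("confined", "butterfly")) ms$Rc else NA_real_
    truth$v[i] <- if (cls[i] %in% c("directed", "butterfly")) ms$v else NA_real_
  }
  ts <- trackset(do.call(rbind, rows), frame_interval_s = spec$frame_interval_s)
  list(trackset = ts, truth = truth)
}

#' Simulate a sweep of confined tracks spanning a range of jump sizes
#'
#' Generates noise-free confined tracks whose expected mean frame-to-frame
#' jumps are evenly spaced over `jump_range_um`, by setting each track's
#' diffusion coefficient to `D = jump^2 / (pi * dt)` (the Rayleigh-mean
#' inversion of the 2D diffusive step) and its confinement radius to
#' `rc_factor` times the target jump so confinement bites within the
#' alpha-fitting window. Used to exercise the confined-motion jump filter
#' across its threshold.
#'
#' @param n_tracks number of tracks.
#' @param jump_range_um lower/upper target mean jump, um.
#' @param n_frames frames per track.
#' @param rc_factor confinement radius as a multiple of the target jump.
#' @param dt frame interval, seconds.
#' @param seed RNG seed.
#' @return a [trackset()].
#' @export
simulate_confined_sweep <- function(n_tracks = 500, jump_range_um = c(0.02, 0.2),
                                    n_frames = 100, rc_factor = 1.5,
                                    dt = 0.01, seed = 1L) {
  set.seed(seed)
  jumps <- seq(jump_range_um[1], jump_range_um[2], length.out = n_tracks)
  rows <- lapply(seq_len(n_tracks), function(i) {
    D <- jumps[i]^2 / (pi * dt)
    ms <- motion_spec("confined", D = D, Rc = rc_factor * jumps[i],
                      sigma_loc = 0)
    simulate_track(ms, n_frames, dt = dt, start = runif(2, 0, 10),
                   track_id = sprintf("sweep%03d", i))
  })
  trackset(do.call(rbind, rows), frame_interval_s = dt)
}

#' Simulate a histone H2B calibration track set
#'
#' H2B is overwhelmingly chromatin-incorporated, so its two-parameter
#' distribution anchors the low-mobility gate. The default emulates this:
#' 85% tightly confined tracks (small confinement radius and jumps) plus a
#' 15% mobile Brownian fraction.
#'
#' @param n_tracks number of tracks.
#' @param seed RNG seed.
#' @param confined_weight fraction of confined tracks.
#' @param class_params per-class parameter overrides, as in
#'   [experiment_spec()].
#' @param ... further arguments passed to [experiment_spec()].
#' @return list with `trackset` and `truth`, as [simulate_tracks()].
#' @export
simulate_h2b_reference <- function(n_tracks = 2000, seed = 1L,
                                   confined_weight = 0.85,
                                   class_params = list(
                                     confined = list(D = 0.02, Rc = 0.06),
                                     brownian = list(D = 0.3)),
                                   ...) {
  w <- c(brownian = 1 - confined_weight, confined = confined_weight,
         directed = 0, butterfly = 0)
  spec <- experiment_spec(n_tracks = n_tracks, mixture_weights = w,
                          class_params = class_params, seed = seed, ...)
  simulate_tracks(spec)
}
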