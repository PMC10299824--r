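# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# A trackset holding one straight-line track per requested duration.
trackset_with_durations <- function(durations, dt = 0.01) {
  rows <- do.call(rbind, lapply(seq_along(durations), function(i) {
    d <- durations[i]
    data.frame(track_id = sprintf("t%02d_d%02d", i, d), frame = seq_len(d) - 1L,
               x = 0.01 * (seq_len(d) - 1L), y = 0)
  }))
  trackset(rows, frame_interval_s = dt)
}

# Minimal feature table for filter/gate tests.
make_features <- function(n = 10, alpha = 0.5, r_conf = 0.05, mean_jump = 0.05,
                          motion_class = "Confined") {
  data.frame(track_id = sprintf("t%03d", seq_len(n)),
             parent_id = NA_character_, duration = 100L,
             alpha = rep_len(alpha, n), r_conf_um = rep_len(r_conf, n),
             mean_jump_um = rep_len(mean_jump, n),
             motion_class = rep_len(motion_class, n), fit_ok = TRUE,
             stringsAsFactors = FALSE)
}

# Exact MSD curve from the confined-diffusion saturation model.
model_msd_curve <- function(Rc, D, lags = 1:20, dt = 0.01) {
  structure(list(lags = lags,
                 msd = Rc^2 * (1 - exp(-4 * D * lags * dt / Rc^2)),
                 n_pairs = rep(100L, length(lags))),
            class = "msd_curve")
}

# The well-separated four-class mixture used for recall checks:
# 100 tracks per class, 1000 frames, generator-default motion parameters
# and localization noise.
mixture_fixture <- function(n_per_class = 100, n_frames = 1000, seed = 42) {
  spec <- experiment_spec(
    n_tracks = 4 * n_per_class,
    mixture_weights = c(brownian = 0.25, confined = 0.25,
                        directed = 0.25, butterfly = 0.25),
    length_law = list(fixed = n_frames),
    seed = seed)
  simulate_tracks(spec)
}

# Track-level class recovery: butterfly trues are scored by detection;
# other classes by the majority class among the rows descending from the
# track (whole track or its retained segments).
class_recall <- function(cls, truth) {
  feats <- cls$features
  parent_of <- ifelse(is.na(feats$parent_id), feats$track_id, feats$parent_id)
  sapply(split(truth$track_id, truth$motion_class), function(ids) {
    first <- truth$motion_class[match(ids[1], truth$track_id)]
    if (first == "butterfly") {
      mean(ids %in% cls$parents$track_id)
    } else {
      target <- c(brownian = "Brownian", confined = "Confined",
                  directed = "Directed")[[first]]
      hit <- vapply(ids, function(id) {
        got <- feats$motion_class[parent_of == id]
        length(got) > 0 &&
          names(which.max(table(got)))[1] == target
      }, logical(1))
      mean(hit)
    }
  })
}

# Confined-track sweep whose mean jumps span 20-200 nm.
confined_jump_sweep <- function(n_tracks = 500, seed = 101) {
  simulate_confined_sweep(n_tracks = n_tracks, jump_range_um = c(0.02, 0.2),
                          seed = seed)
}

# 100 tracks per class (confined, brownian, directed), 500 noise-free
# frames each, for alpha-gating soundness checks.
acceptance_alpha_mixture <- function(seed = 11, n_per_class = 100,
                                     n_frames = 500) {
  parts <- lapply(seq_along(c("brownian", "confined", "directed")), function(k) {
    cls <- c("brownian", "confined", "directed")[k]
    w <- setNames(as.numeric(c("brownian", "confined", "directed",
                               "butterfly") == cls),
                  c("brownian", "confined", "directed", "butterfly"))
    out <- simulate_tracks(experiment_spec(
      n_tracks = n_per_class, mixture_weights = w, sigma_loc = 0,
      length_law = list(fixed = n_frames), seed = seed + k))
    out$trackset$tracks$track_id <- paste0(cls, "_", out$trackset$tracks$track_id)
    out$truth$track_id <- paste0(cls, "_", out$truth$track_id)
    out
  })
  list(trackset = trackset(do.call(rbind, lapply(parts,
                                                 function(p) p$trackset$tracks))),
       truth = do.call(rbind, lapply(parts, function(p) p$truth)))
}

# Imputation moment recovery at scale: >= 10,000 imputed cells from a
# N(25, 2^2) log2 matrix with 30% of cells missing completely at random.
imputation_moments <- function(seed = 12, n_proteins = 2500) {
  sim <- simulate_proteomics(proteomics_spec(
    n_proteins = n_proteins, baseline_log2_mean = 25, baseline_log2_sd = 2,
    replicate_sd = 0,
    missing_model = list(type = "mcar", rate = 0.3),
    flag_rates = c(contaminant = 0, reverse = 0, only_by_site = 0),
    seed = seed))
  before <- log2_transform(sim$matrix)
  after <- impute_missing(before, width = 0.3, downshift = 1.8, seed = seed)
  imputation_diagnostics(before, after)
}

# Planted-interactor proteomics fixture: effects added in both bait groups.
planted_proteomics <- function(n_proteins = 1000, n_planted = 20,
                               log2_effect = 3, seed = 7, ...) {
  planted <- data.frame(
    protein = rep(seq_len(n_planted), each = 2L),
    group = rep(c("WT", "R35A"), n_planted),
    log2_effect = log2_effect)
  sim <- simulate_proteomics(proteomics_spec(n_proteins = n_proteins,
                                             planted = planted,
                                             seed = seed, ...))
  sim$planted_ids <- sprintf("P%04d", seq_len(n_planted))
  sim
}
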