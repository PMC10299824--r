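# Configuration, end-to-end orchestration and reproducibility manifests.
#
# One YAML file configures both pipelines; a single master seed fans out to
# named substreams (simulation, imputation, down-sampling) so one number
# reproduces a whole run.

default_pipeline_config <- function() {
  list(
    seed = 1L,
    io = list(
      track_table = NULL,      # input track table; NULL -> simulate
      h2b_table = NULL,        # H2B calibration track table; NULL -> simulate
      protein_groups = NULL,   # MaxQuant-style table; NULL -> simulate
      output_dir = "mobprox_out",
      pixel_size_um = NULL
    ),
    smt = list(
      frame_interval_s = 0.01,
      min_duration = 5,
      alpha_confined_max = 0.7,
      alpha_directed_min = 1.0,
      alpha_lag_range = c(1, 4),
      max_lag = 50,
      butterfly_rule = "relative",
      butterfly_threshold = 1.5,
      confined_jump_max_um = 0.1,
      downsample_n = 20000,
      downsample_reps = 3,
      gate_lo_pct = 75,
      gate_hi_pct = 95,
      sim_n_tracks = 1000,
      sim_h2b_n_tracks = 1000
    ),
    interactome = list(
      fold_min = 2,
      adj_p_max = 0.05,
      impute_width = 0.3,
      impute_downshift = 1.8,
      sd_cutoff = 3,
      differential_cohort = "all",
      var_equal = TRUE,
      sim_n_proteins = 1000
    )
  )
}

check_known_keys <- function(given, defaults, path = "") {
  unknown <- setdiff(names(given), names(defaults))
  if (length(unknown))
    abort_validation(sprintf("unknown config key(s): %s",
                             paste0(path, unknown, collapse = ", ")))
  for (k in names(given)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        is.list(given[[k]]))
      check_known_keys(given[[k]], defaults[[k]], paste0(path, k, "$"))
  }
}

validate_config <- function(cfg) {
  s <- cfg$smt
  if (s$min_duration < 1) abort_validation("smt$min_duration must be >= 1")
  if (s$downsample_n < 0) abort_validation("smt$downsample_n must be >= 0")
  if (!(s$alpha_confined_max > 0 && s$alpha_confined_max < s$alpha_directed_min))
    abort_validation("need 0 < alpha_confined_max < alpha_directed_min")
  if (!(s$gate_lo_pct < s$gate_hi_pct))
    abort_validation("smt$gate_lo_pct must be below smt$gate_hi_pct")
  i <- cfg$interactome
  if (i$fold_min <= 0) abort_validation("interactome$fold_min must be > 0")
  if (i$adj_p_max <= 0 || i$adj_p_max > 1)
    abort_validation("interactome$adj_p_max must be in (0, 1]")
  if (i$impute_width < 0) abort_validation("interactome$impute_width must be >= 0")
  cfg
}

#' Parse a pipeline configuration file
#'
#' Reads a YAML configuration, fills defaults, rejects unknown keys and
#' validates threshold ranges. An empty (or absent `path = NULL`) file
#' yields the full default configuration.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return nested configuration list of class `pipeline_config`.
#' @export
parse_config <- function(path = NULL) {
  defaults <- default_pipeline_config()
  cfg <- defaults
  if (!is.null(path)) {
    if (!file.exists(path)) abort_format(sprintf("config file not found: %s", path))
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    if (!is.list(user)) abort_format("config file must hold a YAML mapping")
    check_known_keys(user, defaults)
    cfg <- modifyList(defaults, user)
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(validate_config(cfg), class = "pipeline_config")
}

# Named substreams derived from one master seed; offsets are arbitrary
# fixed constants, kept < 2^31 for any small master seed.
derive_seed <- function(seed, stream) {
  offs <- c(simulation = 1000L, h2b = 2000L, downsample = 3000L,
            imputation = 4000L, proteomics = 5000L)
  if (!stream %in% names(offs)) abort_validation("unknown seed stream")
  as.integer(seed) + offs[[stream]]
}

run_manifest <- function(config, seeds, counts) {
  list(package = "mobprox",
       version = as.character(packageVersion("mobprox")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       config = unclass(config),
       seeds = seeds,
       counts = counts)
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Run the single-molecule-tracking pipeline end to end
#'
#' Loads (or simulates) a track set, runs the classification pipeline,
#' calibrates LoMC/HiMC gates on the H2B reference (skipped with a warning
#' when no reference is available), summarizes gate occupancy over the
#' down-sampled replicates and writes all artifacts plus a reproducibility
#' manifest to the output directory.
#'
#' @param config a [parse_config()] result (or `NULL` for defaults).
#' @return list with `classification` (an [run_classification()] result),
#'   `gates`, `mobility` (a [summarize_mobility()] result or `NULL`),
#'   `manifest` and `output_dir`; invisibly.
#' @export
run_smt_pipeline <- function(config = parse_config()) {
  if (is.null(config)) config <- parse_config()
  stopifnot(inherits(config, "pipeline_config"))
  io <- config$io; s <- config$smt
  if (!is.null(io$track_table) && !file.exists(io$track_table))
    abort_format(sprintf("input track table not found: %s", io$track_table))

  out_dir <- io$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  seeds <- list(master = config$seed,
                simulation = derive_seed(config$seed, "simulation"),
                h2b = derive_seed(config$seed, "h2b"),
                downsample = derive_seed(config$seed, "downsample"))

  ts <- if (!is.null(io$track_table)) {
    read_track_table(io$track_table, pixel_size_um = io$pixel_size_um,
                     frame_interval_s = s$frame_interval_s)
  } else {
    message("no input track table configured; simulating tracks")
    simulate_tracks(experiment_spec(n_tracks = s$sim_n_tracks,
                                    frame_interval_s = s$frame_interval_s,
                                    seed = seeds$simulation))$trackset
  }

  ccfg <- classify_config(alpha_confined_max = s$alpha_confined_max,
                          alpha_directed_min = s$alpha_directed_min,
                          butterfly_rule = s$butterfly_rule,
                          butterfly_threshold = s$butterfly_threshold,
                          min_duration = s$min_duration,
                          confined_jump_max_um = s$confined_jump_max_um,
                          downsample_n = s$downsample_n,
                          downsample_reps = s$downsample_reps,
                          seed = seeds$downsample,
                          alpha_lag_range = s$alpha_lag_range,
                          max_lag = s$max_lag)
  cls <- run_classification(ts, ccfg)
  write_feature_table(cls$features, file.path(out_dir, "features.csv"))

  gates <- NULL; mobility <- NULL
  h2b_feats <- NULL
  if (!is.null(io$h2b_table)) {
    if (file.exists(io$h2b_table)) {
      h2b <- read_track_table(io$h2b_table, pixel_size_um = io$pixel_size_um,
                              frame_interval_s = s$frame_interval_s)
      h2b_feats <- run_classification(h2b, ccfg)$features
    } else {
      warning(sprintf("H2B calibration table '%s' not found; mobility stage skipped",
                      io$h2b_table))
    }
  } else {
    h2b <- simulate_h2b_reference(n_tracks = s$sim_h2b_n_tracks,
                                  seed = seeds$h2b,
                                  frame_interval_s = s$frame_interval_s)$trackset
    h2b_feats <- run_classification(h2b, ccfg)$features
  }
  if (!is.null(h2b_feats)) {
    gates <- calibrate_gates(h2b_feats, lo_pct = s$gate_lo_pct,
                             hi_pct = s$gate_hi_pct)
    mobility <- summarize_mobility(cls$replicates, gates)
    labeled <- cls$features
    labeled$gate <- assign_gate(labeled, gates)
    write_feature_table(labeled, file.path(out_dir, "features_gated.csv"))
    write.table(mobility$per_replicate,
                file.path(out_dir, "mobility_per_replicate.csv"),
                sep = ",", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(per_gate = mobility$per_gate,
           gates = list(LoMC = gates$LoMC, HiMC = gates$HiMC)),
      file.path(out_dir, "mobility_summary.json"),
      auto_unbox = TRUE, digits = NA)
  }

  manifest <- run_manifest(config, seeds, cls$log)
  write_manifest(manifest, file.path(out_dir, "smt_manifest.json"))
  invisible(list(classification = cls, gates = gates, mobility = mobility,
                 manifest = manifest, output_dir = out_dir))
}

#' Run the interactome-calling pipeline end to end
#'
#' Loads (or simulates) a protein-groups intensity matrix, runs
#' [call_interactors()] and writes the calls table, a JSON summary and a
#' reproducibility manifest.
#'
#' @param config a [parse_config()] result (or `NULL` for defaults).
#' @return list with `calls` (an [call_interactors()] result), `manifest`
#'   and `output_dir`; invisibly.
#' @export
run_interactome_pipeline <- function(config = parse_config()) {
  if (is.null(config)) config <- parse_config()
  stopifnot(inherits(config, "pipeline_config"))
  io <- config$io; icfg <- config$interactome
  out_dir <- io$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  seeds <- list(master = config$seed,
                proteomics = derive_seed(config$seed, "proteomics"),
                imputation = derive_seed(config$seed, "imputation"))

  m <- if (!is.null(io$protein_groups)) {
    if (!file.exists(io$protein_groups))
      abort_format(sprintf("protein-groups table not found: %s", io$protein_groups))
    read_protein_groups(io$protein_groups, canonical_design())
  } else {
    message("no protein-groups table configured; simulating proteomics data")
    simulate_proteomics(proteomics_spec(n_proteins = icfg$sim_n_proteins,
                                        seed = seeds$proteomics))$matrix
  }

  res <- call_interactors(m,
                          fold_min = icfg$fold_min, adj_p_max = icfg$adj_p_max,
                          impute_width = icfg$impute_width,
                          impute_downshift = icfg$impute_downshift,
                          sd_cutoff = icfg$sd_cutoff,
                          differential_cohort = icfg$differential_cohort,
                          var_equal = icfg$var_equal,
                          seed = seeds$imputation)
  write_calls_table(res, file.path(out_dir, "interactome_calls.tsv"))
  jsonlite::write_json(
    list(n_proteins = res$log$after_valid_values,
         n_significant = res$log$significant,
         n_differential = res$log$differential,
         cohort = res$cohort),
    file.path(out_dir, "interactome_summary.json"),
    auto_unbox = TRUE, digits = NA)

  manifest <- run_manifest(config, seeds, res$log)
  write_manifest(manifest, file.path(out_dir, "interactome_manifest.json"))
  invisible(list(calls = res, manifest = manifest, output_dir = out_dir))
}
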