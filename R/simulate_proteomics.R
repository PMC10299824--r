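# Synthetic label-free proteomics with known ground truth.
#
# Intensities are log-normal: per-protein baseline abundance on the log2
# scale plus group effects and replicate noise. Missingness is
# intensity-dependent by default (logistic left-censoring, the MNAR
# behaviour that motivates left-shifted imputation), or can be disabled or
# made completely at random.

#' Specification of a synthetic proximity-labeling experiment
#'
#' Canonical design: groups WT, R35A (baits), TurboID and noDox
#' (controls), four replicates each. Planted interactors receive a log2
#' effect in the named groups — e.g. `+3` in WT and R35A makes a protein an
#' 8-fold interactor over both controls.
#'
#' @param n_proteins number of proteins.
#' @param baseline_log2_mean,baseline_log2_sd mean and s.d. of the
#'   per-protein baseline abundance on the log2 scale (typical LFQ
#'   intensities span ~2^20-2^30).
#' @param replicate_sd within-group replicate s.d. on the log2 scale.
#' @param planted data frame with columns `protein` (integer index or id),
#'   `group`, `log2_effect`; `NULL` for none.
#' @param missing_model list with `type` one of `"logistic"` (left-censored
#'   MNAR: P(missing) = plogis((midpoint - log2 intensity)/scale)),
#'   `"mcar"` (uniform `rate`), or `"none"`.
#' @param flag_rates named rates for `contaminant`, `reverse`,
#'   `only_by_site` flags.
#' @param seed RNG seed.
#' @return list of class `proteomics_spec`.
#' @export
proteomics_spec <- function(n_proteins = 1000,
                            baseline_log2_mean = 25, baseline_log2_sd = 2,
                            replicate_sd = 0.3,
                            planted = NULL,
                            missing_model = list(type = "logistic",
                                                 midpoint = 22, scale = 1,
                                                 rate = 0.3),
                            flag_rates = c(contaminant = 0.02, reverse = 0.02,
                                           only_by_site = 0.02),
                            seed = 1L) {
  if (n_proteins < 0) abort_validation("n_proteins must be >= 0")
  missing_model <- modifyList(list(type = "logistic", midpoint = 22,
                                   scale = 1, rate = 0.3), missing_model)
  if (!missing_model$type %in% c("logistic", "mcar", "none"))
    abort_validation("missing_model$type must be logistic, mcar or none")
  fr <- c(contaminant = 0, reverse = 0, only_by_site = 0)
  fr[names(flag_rates)] <- flag_rates
  if (any(fr < 0 | fr > 1)) abort_validation("flag rates must be in [0, 1]")
  if (!is.null(planted)) {
    stopifnot(is.data.frame(planted),
              all(c("protein", "group", "log2_effect") %in% names(planted)))
    if (!all(planted$group %in% CANONICAL_GROUPS))
      abort_validation("planted groups must be among WT, R35A, TurboID, noDox")
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 replicate_sd = replicate_sd, planted = planted,
                 missing_model = missing_model, flag_rates = fr,
                 seed = as.integer(seed)),
            class = "proteomics_spec")
}

#' The canonical four-group, four-replicate design
#'
#' Sample-to-group mapping for the standard TurboID experiment: groups
#' `WT`, `R35A` (baits), `TurboID` and `noDox` (controls), four replicates
#' each, samples named `<group>_<replicate>`.
#'
#' @return data frame with columns `sample` and `group`.
#' @export
canonical_design <- function() {
  data.frame(sample = paste(rep(CANONICAL_GROUPS, each = 4L), 1:4, sep = "_"),
             group = rep(CANONICAL_GROUPS, each = 4L),
             stringsAsFactors = FALSE)
}

#' Simulate a proximity-labeling intensity matrix with ground truth
#'
#' @param spec a [proteomics_spec()].
#' @return list with `matrix` (an [intensity_matrix()], linear scale, `NA`
#'   for censored cells) and `truth` (planted effects and flags per
#'   protein).
#' @export
simulate_proteomics <- function(spec) {
  stopifnot(inherits(spec, "proteomics_spec"))
  set.seed(spec$seed)
  design <- canonical_design()
  n <- spec$n_proteins
  ids <- sprintf("P%04d", seq_len(n))
  baseline <- rnorm(n, spec$baseline_log2_mean, spec$baseline_log2_sd)
  log2x <- matrix(baseline, n, nrow(design)) +
    matrix(rnorm(n * nrow(design), 0, spec$replicate_sd), n)
  dimnames(log2x) <- list(ids, design$sample)

  planted <- spec$planted
  if (!is.null(planted) && nrow(planted)) {
    pid <- if (is.numeric(planted$protein)) ids[planted$protein] else
      as.character(planted$protein)
    for (k in seq_len(nrow(planted))) {
      cols <- design$group == planted$group[k]
      log2x[pid[k], cols] <- log2x[pid[k], cols] + planted$log2_effect[k]
    }
  }

  mm <- spec$missing_model
  miss <- switch(mm$type,
    none = matrix(FALSE, n, nrow(design)),
    mcar = matrix(runif(n * nrow(design)) < mm$rate, n),
    logistic = matrix(runif(n * nrow(design)) <
                        plogis((mm$midpoint - log2x) / mm$scale), n))
  x <- 2^log2x
  x[miss] <- NA_real_

  flags <- data.frame(
    contaminant = runif(n) < spec$flag_rates["contaminant"],
    reverse = runif(n) < spec$flag_rates["reverse"],
    only_by_site = runif(n) < spec$flag_rates["only_by_site"])

  truth <- data.frame(protein = ids, baseline_log2 = baseline, flags,
                      stringsAsFactors = FALSE)
  if (!is.null(planted) && nrow(planted)) {
    pid <- if (is.numeric(planted$protein)) ids[planted$protein] else
      as.character(planted$protein)
    truth$planted <- truth$protein %in% pid
  } else truth$planted <- FALSE

  list(matrix = intensity_matrix(x, design, flags), truth = truth)
}

#' Write a simulated matrix as a MaxQuant-style protein-groups table
#'
#' Inverse of [read_protein_groups()]: tab-delimited, `Intensity <sample>`
#' columns (missing written as 0), `+` flag columns.
#'
#' @param m an [intensity_matrix()] on the linear scale.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(m, path) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (m$log2) abort_validation("write_protein_groups expects a linear-scale matrix")
  x <- m$intensity
  x[is.na(x)] <- 0
  df <- data.frame(`Protein IDs` = rownames(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (s in colnames(x)) df[[paste("Intensity", s)]] <- x[, s]
  df[["Potential contaminant"]] <- ifelse(m$flags$contaminant, "+", "")
  df[["Reverse"]] <- ifelse(m$flags$reverse, "+", "")
  df[["Only identified by site"]] <- ifelse(m$flags$only_by_site, "+", "")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
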