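# TurboID proximity-labeling differential interactome caller.
#
# Input: a label-free proteomics intensity matrix (proteins x samples)
# with MaxQuant-style QC flags and a four-group design — two bait groups
# (WT, R35A) and two negative controls (TurboID-only ligase, noDox
# uninduced), four replicates each. Pipeline: QC filter -> valid-value
# filter -> log2 -> left-shifted imputation -> dual-control enrichment
# t-tests with BH correction -> significance calling -> WT/R35A
# differential scoring at a mean +/- 3 s.d. cutoff.

CANONICAL_GROUPS <- c("WT", "R35A", "TurboID", "noDox")

#' Construct a proximity-labeling intensity matrix
#'
#' @param intensity numeric matrix, proteins x samples, positive where
#'   present and `NA` where missing; row names are protein ids, column
#'   names sample ids.
#' @param design data frame with columns `sample` and `group` mapping every
#'   matrix column to an experimental group.
#' @param flags data frame (one row per protein) with logical columns
#'   `contaminant`, `reverse`, `only_by_site`; defaults to all-`FALSE`.
#' @return object of class `intensity_matrix`.
#' @export
intensity_matrix <- function(intensity, design, flags = NULL) {
  stopifnot(is.matrix(intensity), is.numeric(intensity))
  if (is.null(rownames(intensity)) || is.null(colnames(intensity)))
    abort_validation("intensity matrix needs row (protein) and column (sample) names")
  stopifnot(is.data.frame(design), all(c("sample", "group") %in% names(design)))
  if (!setequal(design$sample, colnames(intensity)) ||
      anyDuplicated(design$sample))
    abort_validation("design samples must match matrix columns exactly")
  if (any(intensity[!is.na(intensity)] <= 0))
    abort_validation("intensities must be positive where present (use NA for missing)")
  if (is.null(flags)) {
    flags <- data.frame(contaminant = logical(nrow(intensity)),
                        reverse = logical(nrow(intensity)),
                        only_by_site = logical(nrow(intensity)))
  }
  stopifnot(nrow(flags) == nrow(intensity),
            all(c("contaminant", "reverse", "only_by_site") %in% names(flags)))
  rownames(flags) <- rownames(intensity)
  design <- design[match(colnames(intensity), design$sample), , drop = FALSE]
  rownames(design) <- NULL
  structure(list(intensity = intensity, design = design,
                 flags = flags[c("contaminant", "reverse", "only_by_site")],
                 log2 = FALSE),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("<intensity_matrix>%s %d proteins x %d samples, %.1f%% missing\n",
              if (x$log2) " (log2)" else "",
              nrow(x$intensity), ncol(x$intensity),
              100 * mean(is.na(x$intensity))))
  tab <- table(x$design$group)
  cat("  groups:", paste(sprintf("%s(%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

group_cols <- function(m, group) which(m$design$group == group)

require_four_reps <- function(m, groups = unique(m$design$group)) {
  for (g in groups) {
    k <- length(group_cols(m, g))
    if (k != 4L)
      abort_validation(sprintf(
        "group '%s' has %d replicates; the design requires four per group", g, k))
  }
  invisible(TRUE)
}

#' Remove flagged proteins
#'
#' Drops rows flagged as potential contaminant, reverse (decoy) hit, or
#' identified only by a modification site. Idempotent.
#'
#' @param m an [intensity_matrix()].
#' @return filtered [intensity_matrix()].
#' @export
qc_filter <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"))
  bad <- m$flags$contaminant | m$flags$reverse | m$flags$only_by_site
  if (all(bad)) warning("qc_filter removed every protein")
  m$intensity <- m$intensity[!bad, , drop = FALSE]
  m$flags <- m$flags[!bad, , drop = FALSE]
  m
}

#' Keep proteins quantified in all four replicates of some group
#'
#' A protein is retained iff at least one experimental group has a valid
#' (non-missing) value in all four of its replicates. Idempotent.
#'
#' @param m an [intensity_matrix()].
#' @return filtered [intensity_matrix()].
#' @export
valid_values_filter <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"))
  require_four_reps(m)
  groups <- unique(m$design$group)
  complete_in_some <- Reduce(`|`, lapply(groups, function(g) {
    rowSums(!is.na(m$intensity[, group_cols(m, g), drop = FALSE])) == 4L
  }))
  m$intensity <- m$intensity[complete_in_some, , drop = FALSE]
  m$flags <- m$flags[complete_in_some, , drop = FALSE]
  m
}

#' Log2-transform present intensities
#'
#' @param m an [intensity_matrix()] on the linear scale.
#' @return the matrix with `log2` values (missing cells stay missing).
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (m$log2) abort_validation("matrix is already log2-transformed")
  bad <- which(!is.na(m$intensity) & m$intensity <= 0, arr.ind = TRUE)
  if (nrow(bad))
    abort_validation(sprintf("non-positive intensity for protein '%s', sample '%s'",
                             rownames(m$intensity)[bad[1, 1]],
                             colnames(m$intensity)[bad[1, 2]]))
  m$intensity <- log2(m$intensity)
  m$log2 <- TRUE
  m
}

#' Left-shifted imputation of missing log2 intensities
#'
#' Missing values in label-free proteomics are predominantly
#' below-detection (left-censored), so they are imputed — per sample
#' column, following the Perseus convention — from a narrowed, down-shifted
#' normal distribution: `Normal(mean_s - downshift * sd_s,
#' (width * sd_s)^2)`, where `mean_s` and `sd_s` are the observed mean and
#' standard deviation of column `s`. Defaults: width 0.3, downshift 1.8.
#' Observed cells are untouched; the draw is deterministic under `seed`.
#'
#' @param m a log2 [intensity_matrix()].
#' @param width imputation width as a fraction of the observed column s.d.
#' @param downshift downshift in observed-column s.d. units.
#' @param seed RNG seed.
#' @return a complete [intensity_matrix()].
#' @export
impute_missing <- function(m, width = 0.3, downshift = 1.8, seed = 1L) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (!m$log2) abort_validation("impute_missing expects a log2-transformed matrix")
  set.seed(seed)
  x <- m$intensity
  for (s in seq_len(ncol(x))) {
    obs <- x[, s][!is.na(x[, s])]
    miss <- which(is.na(x[, s]))
    if (!length(miss)) next
    if (length(obs) < 2L)
      abort_validation(sprintf(
        "column '%s' has fewer than 2 observed values; cannot impute", colnames(x)[s]))
    mu <- mean(obs); sdev <- sd(obs)
    x[miss, s] <- rnorm(length(miss), mu - downshift * sdev, width * sdev)
  }
  m$intensity <- x
  m
}

#' Imputation quality diagnostics
#'
#' Compares a log2 matrix before and after [impute_missing()] and reports
#' the pooled moments of the imputed cells relative to the observed ones:
#' the standardized downshift `(mean_obs - mean_imp) / sd_obs` and the
#' width ratio `sd_imp / sd_obs`, computed per sample column and pooled
#' with weights proportional to the number of imputed cells. Under the
#' default imputation parameters these should sit near 1.8 and 0.3.
#'
#' @param before log2 [intensity_matrix()] with missing cells.
#' @param after the same matrix after [impute_missing()].
#' @return list with `downshift`, `width_ratio` and `n_imputed`.
#' @export
imputation_diagnostics <- function(before, after) {
  stopifnot(inherits(before, "intensity_matrix"), inherits(after, "intensity_matrix"))
  if (!before$log2 || !after$log2)
    abort_validation("imputation_diagnostics expects log2 matrices")
  if (!identical(dim(before$intensity), dim(after$intensity)))
    abort_validation("matrices must have identical dimensions")
  shift <- ratio <- w <- numeric(0)
  for (s in seq_len(ncol(before$intensity))) {
    miss <- is.na(before$intensity[, s])
    if (sum(miss) < 2L || sum(!miss) < 2L) next
    obs <- before$intensity[!miss, s]
    imp <- after$intensity[miss, s]
    shift <- c(shift, (mean(obs) - mean(imp)) / sd(obs))
    ratio <- c(ratio, sd(imp) / sd(obs))
    w <- c(w, sum(miss))
  }
  if (!length(w)) abort_validation("no column with imputed cells")
  list(downshift = sum(shift * w) / sum(w),
       width_ratio = sum(ratio * w) / sum(w),
       n_imputed = sum(w))
}

#' Per-protein enrichment of a case group over a control group
#'
#' On the complete log2 matrix: `log2FC = mean(case) - mean(control)` and a
#' two-sided two-sample t-test per protein (Student by default, Welch
#' optionally), BH-adjusted across all proteins of the comparison. Zero
#' pooled variance yields p = 1 when the means are equal and the smallest
#' representable p otherwise, flagged in `degenerate`.
#'
#' @param m a complete log2 [intensity_matrix()].
#' @param case,control group labels in the design.
#' @param var_equal `TRUE` for the Student test (default), `FALSE` for
#'   Welch.
#' @return data frame: `protein`, `log2fc`, `p`, `adj_p`, `degenerate`.
#' @export
test_enrichment <- function(m, case, control, var_equal = TRUE) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (!m$log2) abort_validation("test_enrichment expects a log2 matrix")
  if (anyNA(m$intensity))
    abort_validation("matrix must be complete (run impute_missing first)")
  ci <- group_cols(m, case); ki <- group_cols(m, control)
  if (!length(ci)) abort_validation(sprintf("unknown case group '%s'", case))
  if (!length(ki)) abort_validation(sprintf("unknown control group '%s'", control))
  a <- m$intensity[, ci, drop = FALSE]
  b <- m$intensity[, ki, drop = FALSE]
  log2fc <- rowMeans(a) - rowMeans(b)
  p <- numeric(nrow(a)); degen <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    if (var(a[i, ]) + var(b[i, ]) == 0) {
      degen[i] <- TRUE
      p[i] <- if (log2fc[i] == 0) 1 else .Machine$double.xmin
    } else {
      p[i] <- t.test(a[i, ], b[i, ], var.equal = var_equal)$p.value
    }
  }
  data.frame(protein = rownames(m$intensity), log2fc = log2fc, p = p,
             adj_p = p.adjust(p, method = "BH"), degenerate = degen,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call significant interactors against both controls
#'
#' A protein is a significant interactor iff it is more than 2-fold
#' enriched (log2FC > `log2(fold_min)`, strict) against *both* controls and
#' passes adjusted p < `adj_p_max` (strict) in *both* t-tests.
#'
#' @param res_turbo,res_nodox [test_enrichment()] results versus the
#'   TurboID-only and noDox controls.
#' @param fold_min minimum linear fold enrichment; default 2.
#' @param adj_p_max adjusted-p cutoff; default 0.05.
#' @return data frame keyed by `protein` with both comparisons' statistics
#'   and a logical `significant`.
#' @export
call_significant <- function(res_turbo, res_nodox, fold_min = 2, adj_p_max = 0.05) {
  shared <- intersect(res_turbo$protein, res_nodox$protein)
  if (length(shared) < length(res_turbo$protein) ||
      length(shared) < length(res_nodox$protein))
    message(sprintf("call_significant: %d protein(s) absent from one comparison excluded",
                    max(nrow(res_turbo), nrow(res_nodox)) - length(shared)))
  a <- res_turbo[match(shared, res_turbo$protein), ]
  b <- res_nodox[match(shared, res_nodox$protein), ]
  lfc_min <- log2(fold_min)
  data.frame(protein = shared,
             log2fc_vs_turbo = a$log2fc, adj_p_vs_turbo = a$adj_p,
             log2fc_vs_nodox = b$log2fc, adj_p_vs_nodox = b$adj_p,
             significant = a$log2fc > lfc_min & b$log2fc > lfc_min &
                           a$adj_p < adj_p_max & b$adj_p < adj_p_max,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Score differential (bait-preferential) interactors
#'
#' Computes the cohort mean and s.d. of the per-protein WT/R35A log2 fold
#' change and labels values strictly outside mean +/- `sd_cutoff` s.d.:
#' above as `WT_preferential`, below as `R35A_preferential`, else `none`.
#' With zero cohort spread nothing is labelled (warning).
#'
#' @param wt_r35a_log2fc named numeric vector (names are protein ids) of
#'   mean log2 WT minus mean log2 R35A.
#' @param sd_cutoff number of standard deviations; default 3.
#' @return data frame: `protein`, `wt_r35a_log2fc`, `differential`, plus
#'   attributes `cohort_mean` and `cohort_sd`.
#' @export
score_differential <- function(wt_r35a_log2fc, sd_cutoff = 3) {
  if (length(wt_r35a_log2fc) < 2L)
    abort_validation("score_differential needs >= 2 proteins")
  mu <- mean(wt_r35a_log2fc)
  sigma <- sd(wt_r35a_log2fc)
  lab <- rep("none", length(wt_r35a_log2fc))
  if (sigma == 0) {
    warning("zero cohort spread; no differential interactors labelled")
  } else {
    lab[wt_r35a_log2fc > mu + sd_cutoff * sigma] <- "WT_preferential"
    lab[wt_r35a_log2fc < mu - sd_cutoff * sigma] <- "R35A_preferential"
  }
  out <- data.frame(protein = names(wt_r35a_log2fc) %||%
                      as.character(seq_along(wt_r35a_log2fc)),
                    wt_r35a_log2fc = unname(wt_r35a_log2fc),
                    differential = lab, stringsAsFactors = FALSE)
  attr(out, "cohort_mean") <- mu
  attr(out, "cohort_sd") <- sigma
  out
}

#' Run the full interactome-calling pipeline
#'
#' QC filter -> valid-value filter -> log2 -> left-shifted imputation ->
#' enrichment tests of the pooled bait samples (WT + R35A by default)
#' against each control -> dual-control significance calling -> WT/R35A
#' differential scoring. The same imputed matrix serves both control
#' comparisons and the WT/R35A contrast (a single imputation pass).
#'
#' @param m an [intensity_matrix()] on the linear scale.
#' @param case_groups bait groups pooled as the enrichment case.
#' @param fold_min,adj_p_max significance gates (see [call_significant()]).
#' @param impute_width,impute_downshift imputation parameters (see
#'   [impute_missing()]).
#' @param sd_cutoff differential cutoff in cohort s.d. units.
#' @param differential_cohort `"all"` (default) computes the mean/s.d. of
#'   the WT/R35A log2FC over all quantified proteins, `"significant"` over
#'   called interactors only.
#' @param var_equal Student (`TRUE`) or Welch t-tests.
#' @param seed seed of the imputation stream.
#' @return object of class `interactome_calls`: list with `calls` (one row
#'   per protein: enrichment statistics, `significant`, `wt_r35a_log2fc`,
#'   `wt_r35a_p`, `differential`), `log` (stage row counts), `cohort`
#'   (mean/s.d. used by the differential cutoff) and the parameters.
#' @export
call_interactors <- function(m, case_groups = c("WT", "R35A"),
                             fold_min = 2, adj_p_max = 0.05,
                             impute_width = 0.3, impute_downshift = 1.8,
                             sd_cutoff = 3,
                             differential_cohort = c("all", "significant"),
                             var_equal = TRUE, seed = 1L) {
  stopifnot(inherits(m, "intensity_matrix"))
  differential_cohort <- match.arg(differential_cohort)
  require_four_reps(m)
  log <- list(input_proteins = nrow(m$intensity))
  m <- qc_filter(m);            log$after_qc <- nrow(m$intensity)
  m <- valid_values_filter(m);  log$after_valid_values <- nrow(m$intensity)
  if (!nrow(m$intensity)) abort_validation("no proteins left after filtering")
  m <- log2_transform(m)
  m <- impute_missing(m, width = impute_width, downshift = impute_downshift,
                      seed = seed)

  # pooled bait samples vs each control
  mcase <- m
  mcase$design$group[mcase$design$group %in% case_groups] <- ".case"
  res_turbo <- test_enrichment(mcase, ".case", "TurboID", var_equal = var_equal)
  res_nodox <- test_enrichment(mcase, ".case", "noDox", var_equal = var_equal)
  calls <- call_significant(res_turbo, res_nodox,
                            fold_min = fold_min, adj_p_max = adj_p_max)
  log$significant <- sum(calls$significant)

  # WT/R35A contrast for differential scoring and the volcano ordinate
  wt_res <- test_enrichment(m, "WT", "R35A", var_equal = var_equal)
  idx <- match(calls$protein, wt_res$protein)
  calls$wt_r35a_log2fc <- wt_res$log2fc[idx]
  calls$wt_r35a_p <- wt_res$p[idx]

  cohort_idx <- if (differential_cohort == "all") seq_len(nrow(calls)) else
    which(calls$significant)
  if (length(cohort_idx) >= 2L) {
    sc <- score_differential(setNames(calls$wt_r35a_log2fc[cohort_idx],
                                      calls$protein[cohort_idx]),
                             sd_cutoff = sd_cutoff)
    calls$differential <- "none"
    calls$differential[cohort_idx] <- sc$differential
    cohort <- list(mean = attr(sc, "cohort_mean"), sd = attr(sc, "cohort_sd"))
  } else {
    calls$differential <- "none"
    cohort <- list(mean = NA_real_, sd = NA_real_)
    warning("differential cohort too small; no differential labels assigned")
  }
  log$differential <- sum(calls$differential != "none")

  structure(list(calls = calls, log = log, cohort = cohort,
                 params = list(case_groups = case_groups, fold_min = fold_min,
                               adj_p_max = adj_p_max, impute_width = impute_width,
                               impute_downshift = impute_downshift,
                               sd_cutoff = sd_cutoff,
                               differential_cohort = differential_cohort,
                               var_equal = var_equal, seed = seed)),
            class = "interactome_calls")
}

#' @export
print.interactome_calls <- function(x, ...) {
  cat("<interactome_calls>\n")
  cat(sprintf("  %d proteins in -> %d after QC -> %d after valid-value filter\n",
              x$log$input_proteins, x$log$after_qc, x$log$after_valid_values))
  cat(sprintf("  significant interactors: %d; differential: %d (cohort mean %.3g, sd %.3g)\n",
              x$log$significant, x$log$differential, x$cohort$mean, x$cohort$sd))
  invisible(x)
}

#' @export
summary.interactome_calls <- function(object, ...) {
  calls <- object$calls
  out <- list(
    n = nrow(calls),
    significant = sum(calls$significant),
    differential = table(calls$differential),
    cohort = object$cohort,
    top = calls[order(calls$adj_p_vs_turbo), ][seq_len(min(5L, nrow(calls))), ]
  )
  class(out) <- "summary.interactome_calls"
  out
}

#' @export
print.summary.interactome_calls <- function(x, ...) {
  cat(sprintf("%d proteins quantified, %d significant interactors\n",
              x$n, x$significant))
  print(x$differential)
  cat("Top proteins by adjusted p (vs TurboID):\n")
  print(x$top, digits = 3)
  invisible(x)
}

#' Volcano plot of the WT/R35A contrast
#'
#' WT/R35A log2 fold change against -log10 p, with the mean +/- 3 s.d.
#' differential cutoffs as vertical lines; significant interactors filled.
#'
#' @param x an [call_interactors()] result.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.interactome_calls <- function(x, ...) {
  calls <- x$calls
  plot(calls$wt_r35a_log2fc, -log10(calls$wt_r35a_p),
       pch = ifelse(calls$significant, 19, 1),
       col = ifelse(calls$differential == "none", "grey40", "firebrick"),
       xlab = "log2 fold change (WT / R35A)", ylab = "-log10 p", ...)
  if (is.finite(x$cohort$sd)) {
    abline(v = x$cohort$mean + c(-1, 1) * x$params$sd_cutoff * x$cohort$sd,
           lty = 2)
  }
  invisible(x)
}

#' Read a MaxQuant-style protein-groups table
#'
#' Expects a tab-delimited table with one row per protein group, intensity
#' columns named `Intensity <sample>`, and the flag columns
#' `Potential contaminant`, `Reverse` and `Only identified by site`
#' (flagged rows marked `+`). Zero intensities are treated as missing, the
#' MaxQuant convention for unquantified proteins.
#'
#' @param path file path.
#' @param design data frame with `sample` and `group`; samples must match
#'   the `Intensity <sample>` columns.
#' @param id_col column used as protein id.
#' @return an [intensity_matrix()].
#' @export
read_protein_groups <- function(path, design, id_col = "Protein IDs") {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  df <- read.delim(path, sep = "\t", check.names = FALSE, stringsAsFactors = FALSE)
  if (!id_col %in% names(df))
    abort_format(sprintf("id column '%s' not found", id_col))
  ints <- paste("Intensity", design$sample)
  miss <- setdiff(ints, names(df))
  if (length(miss))
    abort_format(sprintf("intensity column(s) missing: %s", paste(miss, collapse = ", ")))
  x <- as.matrix(df[ints])
  colnames(x) <- design$sample
  rownames(x) <- make.unique(as.character(df[[id_col]]))
  x[x == 0] <- NA_real_
  plus <- function(col) {
    if (!col %in% names(df)) return(logical(nrow(df)))
    v <- as.character(df[[col]])          # empty flag columns parse as NA
    !is.na(v) & v == "+"
  }
  flags <- data.frame(contaminant = plus("Potential contaminant"),
                      reverse = plus("Reverse"),
                      only_by_site = plus("Only identified by site"))
  intensity_matrix(x, design, flags)
}

#' Write an interactome calls table
#' @param x an [call_interactors()] result.
#' @param path output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_calls_table <- function(x, path) {
  stopifnot(inherits(x, "interactome_calls"))
  write.table(x$calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
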