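# Two-parameter chromatin-mobility analysis: gates in the
# (radius of confinement, average displacement) plane calibrated on a
# histone H2B reference, per-replicate gate fractions, and condition
# comparison tables.
#
# H2B is essentially fully chromatin-incorporated, so the dense core of
# its two-parameter distribution marks genuinely chromatin-bound motion
# (LoMC, low-mobility chromatin) while its sparse upper tail marks mobile
# molecules (HiMC, high-mobility chromatin). Gates are axis-aligned
# rectangles cut at marginal percentiles of the H2B feature distribution.

#' Calibrate LoMC/HiMC gates on an H2B reference
#'
#' LoMC is the rectangle below the `lo_pct` percentile of both H2B
#' marginals (radius of confinement and mean jump); HiMC the rectangle
#' above the `hi_pct` percentile of both. `lo_pct < hi_pct` keeps the gates
#' disjoint (up to boundary touching in degenerate distributions, resolved
#' in favour of LoMC by [assign_gate()]).
#'
#' @param h2b_features feature table of the H2B calibration set (needs
#'   `r_conf_um` and `mean_jump_um`); at least 100 rows.
#' @param lo_pct percentile (0-100) bounding the LoMC gate; default 75.
#' @param hi_pct percentile bounding the HiMC gate; default 95.
#' @return object of class `mobility_gates`: list of two rectangles, each
#'   with inclusive `r_conf` and `mean_jump` bounds in um.
#' @export
calibrate_gates <- function(h2b_features, lo_pct = 75, hi_pct = 95) {
  ok <- is.finite(h2b_features$r_conf_um) & is.finite(h2b_features$mean_jump_um)
  h2b <- h2b_features[ok, , drop = FALSE]
  if (nrow(h2b) < 100L)
    abort_validation("gate calibration needs >= 100 usable H2B feature rows")
  if (!(lo_pct < hi_pct))
    abort_validation("lo_pct must be strictly below hi_pct (gates would touch)")
  qr <- quantile(h2b$r_conf_um, c(lo_pct, hi_pct) / 100, names = FALSE)
  qj <- quantile(h2b$mean_jump_um, c(lo_pct, hi_pct) / 100, names = FALSE)
  structure(list(
    LoMC = list(r_conf = c(-Inf, qr[1L]), mean_jump = c(-Inf, qj[1L])),
    HiMC = list(r_conf = c(qr[2L], Inf), mean_jump = c(qj[2L], Inf)),
    lo_pct = lo_pct, hi_pct = hi_pct, n_calibration = nrow(h2b)
  ), class = "mobility_gates")
}

#' @export
print.mobility_gates <- function(x, ...) {
  cat("<mobility_gates> (um, inclusive bounds)\n")
  cat(sprintf("  LoMC: r_conf <= %.4g, mean_jump <= %.4g  (P%g of %d H2B rows)\n",
              x$LoMC$r_conf[2], x$LoMC$mean_jump[2], x$lo_pct, x$n_calibration))
  cat(sprintf("  HiMC: r_conf >= %.4g, mean_jump >= %.4g  (P%g)\n",
              x$HiMC$r_conf[1], x$HiMC$mean_jump[1], x$hi_pct))
  invisible(x)
}

in_rect <- function(r, j, rect) {
  r >= rect$r_conf[1] & r <= rect$r_conf[2] &
    j >= rect$mean_jump[1] & j <= rect$mean_jump[2]
}

#' Assign each feature row to a mobility gate
#'
#' Rectangle membership with inclusive boundaries. A row satisfying both
#' gates (possible only when boundaries touch) is labelled LoMC. Rows with
#' missing features are labelled `neither`.
#'
#' @param features feature table with `r_conf_um` and `mean_jump_um`.
#' @param gates a [calibrate_gates()] result.
#' @return character vector of labels: `"LoMC"`, `"HiMC"` or `"neither"`.
#' @export
assign_gate <- function(features, gates) {
  stopifnot(inherits(gates, "mobility_gates"))
  r <- features$r_conf_um
  j <- features$mean_jump_um
  out <- rep("neither", nrow(features))
  ok <- is.finite(r) & is.finite(j)
  hi <- ok & in_rect(r, j, gates$HiMC)
  lo <- ok & in_rect(r, j, gates$LoMC)
  out[hi] <- "HiMC"
  out[lo] <- "LoMC"   # LoMC wins boundary ties
  out
}

#' Summarize gate occupancy over down-sampled replicates
#'
#' Computes the LoMC and HiMC fraction in each replicate, then the mean and
#' sample standard deviation (n-1 denominator) across replicates — the
#' "mean +/- s.d. over down-sampled triplicates" summary of the
#' two-parameter analysis.
#'
#' @param replicates list of feature tables (e.g. from
#'   [downsample_tracks()] or an [run_classification()] result).
#' @param gates a [calibrate_gates()] result.
#' @return object of class `mobility_summary`: list with `per_replicate`
#'   (long data frame: replicate, gate, fraction, n) and `per_gate` (gate,
#'   mean_fraction, sd_fraction).
#' @export
summarize_mobility <- function(replicates, gates) {
  stopifnot(length(replicates) >= 1L)
  per_rep <- do.call(rbind, lapply(seq_along(replicates), function(r) {
    f <- replicates[[r]]
    lab <- if (nrow(f)) assign_gate(f, gates) else character(0)
    data.frame(replicate = r,
               gate = c("LoMC", "HiMC"),
               fraction = if (nrow(f)) c(mean(lab == "LoMC"), mean(lab == "HiMC"))
                          else c(NA_real_, NA_real_),
               n = nrow(f), stringsAsFactors = FALSE)
  }))
  per_gate <- do.call(rbind, lapply(c("LoMC", "HiMC"), function(g) {
    fr <- per_rep$fraction[per_rep$gate == g]
    data.frame(gate = g, mean_fraction = mean(fr),
               sd_fraction = if (length(fr) > 1L) sd(fr) else 0,
               stringsAsFactors = FALSE)
  }))
  structure(list(per_replicate = per_rep, per_gate = per_gate, gates = gates),
            class = "mobility_summary")
}

#' @export
print.mobility_summary <- function(x, ...) {
  cat("<mobility_summary> gate fractions, mean +/- s.d. over",
      length(unique(x$per_replicate$replicate)), "replicate(s)\n")
  for (i in seq_len(nrow(x$per_gate)))
    cat(sprintf("  %s: %.3f +/- %.3f\n", x$per_gate$gate[i],
                x$per_gate$mean_fraction[i], x$per_gate$sd_fraction[i]))
  invisible(x)
}

#' Compare gate occupancy across conditions
#'
#' Emits the tidy long-format table (condition, replicate, gate, fraction)
#' consumed by standard two-way ANOVA routines, plus all pairwise
#' differences of mean gate fractions between conditions.
#'
#' @param summaries named list of [summarize_mobility()] results, one per
#'   condition; at least two.
#' @return list with `long` (per-replicate fractions) and `differences`
#'   (condition_a, condition_b, gate, mean difference a - b).
#' @export
compare_conditions <- function(summaries) {
  if (length(summaries) < 2L)
    abort_validation("compare_conditions needs >= 2 conditions")
  if (is.null(names(summaries)) || any(!nzchar(names(summaries))))
    abort_validation("summaries must be a named list")
  gd <- lapply(summaries, function(s) {
    g <- s$gates
    c(g$LoMC$r_conf[2], g$LoMC$mean_jump[2], g$HiMC$r_conf[1], g$HiMC$mean_jump[1])
  })
  for (k in seq_along(gd)[-1L])
    if (!isTRUE(all.equal(gd[[1L]], gd[[k]])))
      abort_validation("all conditions must use the same calibrated gates")
  long <- do.call(rbind, lapply(names(summaries), function(cond) {
    cbind(condition = cond, summaries[[cond]]$per_replicate,
          stringsAsFactors = FALSE)
  }))
  conds <- names(summaries)
  pairs <- utils::combn(conds, 2L, simplify = FALSE)
  differences <- do.call(rbind, lapply(pairs, function(p) {
    do.call(rbind, lapply(c("LoMC", "HiMC"), function(g) {
      ma <- summaries[[p[1]]]$per_gate
      mb <- summaries[[p[2]]]$per_gate
      data.frame(condition_a = p[1], condition_b = p[2], gate = g,
                 difference = ma$mean_fraction[ma$gate == g] -
                              mb$mean_fraction[mb$gate == g],
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(long) <- rownames(differences) <- NULL
  list(long = long, differences = differences)
}

#' Two-parameter mobility plot
#'
#' 2D histogram of the (radius of confinement, mean jump) plane with the
#' calibrated LoMC/HiMC rectangles overlaid.
#'
#' @param features feature table.
#' @param gates optional [calibrate_gates()] result to overlay.
#' @param nbins histogram bins per axis.
#' @param main plot title.
#' @return invisibly, the binned count matrix.
#' @export
plot_mobility <- function(features, gates = NULL, nbins = 60,
                          main = "Two-parameter mobility") {
  ok <- is.finite(features$r_conf_um) & is.finite(features$mean_jump_um)
  r <- features$r_conf_um[ok]; j <- features$mean_jump_um[ok]
  rb <- seq(0, max(r) * 1.02 + 1e-9, length.out = nbins + 1L)
  jb <- seq(0, max(j) * 1.02 + 1e-9, length.out = nbins + 1L)
  cnt <- table(cut(r, rb), cut(j, jb))
  image(x = rb, y = jb, z = log1p(unclass(cnt)),
        col = hcl.colors(64, "YlGnBu", rev = TRUE),
        xlab = "radius of confinement (um)",
        ylab = "mean frame-to-frame jump (um)", main = main)
  if (!is.null(gates)) {
    abline(v = gates$LoMC$r_conf[2], h = gates$LoMC$mean_jump[2],
           col = "red", lty = 2)
    abline(v = gates$HiMC$r_conf[1], h = gates$HiMC$mean_jump[1],
           col = "darkgreen", lty = 2)
  }
  box()
  invisible(unclass(cnt))
}
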