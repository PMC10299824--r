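# Proteomics simulation, filters, imputation, enrichment testing and
# interactor calling.

complete_matrix <- function(n = 50, seed = 41, ...) {
  simulate_proteomics(proteomics_spec(n_proteins = n, seed = seed,
                                      missing_model = list(type = "none"),
                                      flag_rates = c(contaminant = 0,
                                                     reverse = 0,
                                                     only_by_site = 0), ...))
}

test_that("proteomics simulator honours missingness, effects and flags", {
  sim <- complete_matrix(100)
  expect_false(anyNA(sim$matrix$intensity))
  expect_false(any(unlist(sim$matrix$flags)))

  # planted +3 log2 effect in WT shows up against TurboID
  planted <- data.frame(protein = 1, group = "WT", log2_effect = 3)
  sim <- complete_matrix(200, planted = planted, replicate_sd = 0.2)
  lx <- log2(sim$matrix$intensity)
  wt <- sim$matrix$design$group == "WT"
  tb <- sim$matrix$design$group == "TurboID"
  expect_equal(mean(lx["P0001", wt]) - mean(lx["P0001", tb]), 3, tolerance = 0.5)

  # logistic left-censoring removes low-intensity cells preferentially
  sim <- simulate_proteomics(proteomics_spec(n_proteins = 400, seed = 43))
  lx <- log2(sim$matrix$intensity)
  expect_gt(mean(is.na(sim$matrix$intensity)), 0.01)
  expect_gt(mean(lx[!is.na(lx)]), 24)  # survivors skew high

  # determinism
  a <- simulate_proteomics(proteomics_spec(n_proteins = 50, seed = 9))
  b <- simulate_proteomics(proteomics_spec(n_proteins = 50, seed = 9))
  expect_identical(a$matrix$intensity, b$matrix$intensity)
})

test_that("protein-groups tables round-trip through MaxQuant conventions", {
  sim <- simulate_proteomics(proteomics_spec(n_proteins = 30, seed = 44))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_protein_groups(sim$matrix, path)
  back <- read_protein_groups(path, canonical_design())
  expect_equal(back$intensity, sim$matrix$intensity, tolerance = 1e-10)
  expect_equal(back$flags, sim$matrix$flags)
})

test_that("qc filter removes exactly the flagged rows", {
  sim <- complete_matrix(10)
  m <- sim$matrix
  m$flags$contaminant[1] <- TRUE
  m$flags$reverse[2] <- TRUE
  m$flags$only_by_site[3] <- TRUE
  out <- qc_filter(m)
  expect_equal(nrow(out$intensity), 7L)
  expect_identical(qc_filter(out)$intensity, out$intensity)  # idempotent

  m2 <- sim$matrix
  expect_identical(qc_filter(m2)$intensity, m2$intensity)    # nothing flagged

  m3 <- sim$matrix
  m3$flags$contaminant <- TRUE
  expect_warning(out <- qc_filter(m3), "every protein")
  expect_equal(nrow(out$intensity), 0L)
})

test_that("valid-value rule keeps proteins complete in some group", {
  sim <- complete_matrix(3)
  m <- sim$matrix
  g <- m$design$group
  # P0001: complete in WT only; P0002: 3/4 everywhere; P0003: complete
  m$intensity[1, g != "WT"] <- NA
  for (grp in unique(g)) m$intensity[2, which(g == grp)[1]] <- NA
  out <- valid_values_filter(m)
  expect_equal(rownames(out$intensity), c("P0001", "P0003"))
  expect_identical(valid_values_filter(out)$intensity, out$intensity)

  bad <- m
  bad$design <- m$design[-1, ]
  bad$intensity <- m$intensity[, -1]
  expect_error(valid_values_filter(bad), class = "mobprox_validation_error")
})

test_that("log2 transform maps present values and preserves missing", {
  sim <- complete_matrix(2)
  m <- sim$matrix
  m$intensity[1, 1] <- 8; m$intensity[1, 2] <- 1; m$intensity[2, 3] <- NA
  out <- log2_transform(m)
  expect_equal(out$intensity[1, 1], 3.0)
  expect_equal(out$intensity[1, 2], 0.0)
  expect_true(is.na(out$intensity[2, 3]))

  m$intensity[2, 2] <- 0
  expect_error(intensity_matrix(m$intensity, m$design),
               class = "mobprox_validation_error")
})

test_that("imputation recovers the stated downshift and width moments", {
  set.seed(45)
  n <- 4000
  x <- matrix(rnorm(n * 4, 25, 2), n, 4,
              dimnames = list(sprintf("P%05d", 1:n), paste0("WT_", 1:4)))
  miss <- matrix(runif(n * 4) < 0.3, n, 4)
  xm <- x; xm[miss] <- NA
  m <- intensity_matrix(2^xm, data.frame(sample = paste0("WT_", 1:4),
                                         group = "WT"))
  m <- log2_transform(m)
  out <- impute_missing(m, width = 0.3, downshift = 1.8, seed = 10)

  # observed cells bit-identical; only missing cells differ
  expect_identical(out$intensity[!miss], m$intensity[!miss])
  expect_false(anyNA(out$intensity))
  expect_gt(sum(miss), 4000)

  shift <- width <- numeric(4)
  for (s in 1:4) {
    obs <- m$intensity[!miss[, s], s]
    imp <- out$intensity[miss[, s], s]
    shift[s] <- (mean(obs) - mean(imp)) / sd(obs)
    width[s] <- sd(imp) / sd(obs)
  }
  expect_lt(abs(mean(shift) - 1.8), 0.05)
  expect_lt(abs(mean(width) - 0.3), 0.02)

  # determinism and locality under a repeated seed
  again <- impute_missing(m, seed = 10)
  expect_identical(out$intensity, again$intensity)

  # complete matrix: identity
  full <- impute_missing(out, seed = 11)
  expect_identical(full$intensity, out$intensity)
})

test_that("imputation refuses columns with fewer than two observed values", {
  x <- matrix(c(NA, NA, 20, 21, 22, 23), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  x[1, 1] <- NA
  m <- intensity_matrix(2^x, data.frame(sample = c("s1", "s2"), group = "G"))
  m <- log2_transform(m)
  expect_error(impute_missing(m), "s1", class = "mobprox_validation_error")
})

test_that("enrichment testing matches the standard t formula and BH oracle", {
  sim <- complete_matrix(4, replicate_sd = 0.1)
  m <- log2_transform(sim$matrix)
  # plant a +3 shift in WT for protein 1
  wt <- m$design$group == "WT"
  m$intensity[1, wt] <- m$intensity[1, wt] + 3
  res <- test_enrichment(m, "WT", "TurboID")
  expect_equal(res$log2fc[1], 3, tolerance = 0.5)
  expect_lt(res$p[1], 1e-4)

  # hand-computed Student t as the oracle for one protein
  a <- m$intensity[2, m$design$group == "WT"]
  b <- m$intensity[2, m$design$group == "TurboID"]
  sp <- sqrt((3 * var(a) + 3 * var(b)) / 6)
  tstat <- (mean(a) - mean(b)) / (sp * sqrt(1/4 + 1/4))
  p_hand <- 2 * pt(-abs(tstat), df = 6)
  expect_equal(res$p[2], p_hand, tolerance = 1e-12)

  # identical case/control values: null identity (t = 0 so p = 1)
  m2 <- m
  m2$intensity[, m2$design$group == "TurboID"] <-
    m2$intensity[, m2$design$group == "noDox"]
  res2 <- test_enrichment(m2, "TurboID", "noDox")
  expect_true(all(res2$log2fc == 0))
  expect_true(all(res2$adj_p == 1))

  # zero pooled variance: p = 1 when means agree, minimal p otherwise
  m3 <- m
  m3$intensity[1, ] <- 20                                   # flat row
  m3$intensity[2, ] <- rep(c(22, 20, 20, 20), each = 4)     # flat per group
  res3 <- test_enrichment(m3, "WT", "TurboID")
  expect_true(res3$degenerate[1] && res3$degenerate[2])
  expect_equal(res3$p[1], 1)
  expect_equal(res3$p[2], .Machine$double.xmin)
})

test_that("BH adjustment matches brute force and is monotone", {
  # brute-force step-up BH over the 4 outcomes: all adjust to 0.04
  p <- c(0.01, 0.02, 0.03, 0.04)
  bh_brute <- function(p) {
    m <- length(p); o <- order(p); adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(m); out[o] <- pmin(adj, 1); out
  }
  expect_equal(bh_brute(p), rep(0.04, 4))
  expect_equal(p.adjust(p, "BH"), bh_brute(p))

  set.seed(46)
  praw <- runif(200)^2
  adj <- p.adjust(praw, "BH")
  expect_true(all(adj >= praw))
  expect_true(all(diff(adj[order(praw)]) >= -1e-12))
})

test_that("significance calling enforces the dual-control conjunction", {
  mk <- function(lfc, p) data.frame(protein = "X", log2fc = lfc, p = p / 2,
                                    adj_p = p, degenerate = FALSE)
  sig <- function(ft, fn, pt_, pn) {
    call_significant(mk(ft, pt_), mk(fn, pn))$significant
  }
  expect_true(sig(log2(2.8), log2(4.0), 0.01, 0.02))
  expect_false(sig(log2(1.9), log2(8.0), 0.001, 0.001))  # fails one fold gate
  expect_false(sig(log2(4.0), log2(4.0), 0.2, 0.01))     # fails one p gate
  expect_false(sig(1.0, 2.0, 0.01, 0.01))                # boundary is strict
})

test_that("differential scoring applies the strict +/- 3 s.d. cutoff", {
  vals <- setNames(rep(0.5, 10), sprintf("P%02d", 1:10))
  expect_warning(out <- score_differential(vals), "zero cohort")
  expect_true(all(out$differential == "none"))

  set.seed(47)
  vals <- setNames(c(rnorm(200), -10), c(sprintf("P%03d", 1:200), "OUT"))
  out <- score_differential(vals)
  # brute-force rule evaluation as oracle
  mu <- mean(vals); sigma <- sd(vals)
  expect_equal(unname(out$differential == "R35A_preferential"),
               unname(vals < mu - 3 * sigma))
  expect_equal(sum(out$differential != "none"), 1L)
  expect_equal(out$protein[out$differential != "none"], "OUT")

  # both label directions agree with the strict brute-force rule over
  # random cohorts
  for (seed in 1:3) {
    set.seed(seed)
    v <- rnorm(80, sd = 0.5) + c(rep(0, 78), -6, 6)
    out <- score_differential(setNames(v, sprintf("Q%02d", 1:80)))
    mu <- mean(v); sigma <- sd(v)
    expect_equal(out$differential,
                 ifelse(v > mu + 3 * sigma, "WT_preferential",
                        ifelse(v < mu - 3 * sigma, "R35A_preferential", "none")))
  }
})

test_that("full calling pipeline recovers planted interactors specifically", {
  sim <- planted_proteomics(n_proteins = 600, n_planted = 20, seed = 48)
  res <- call_interactors(sim$matrix, seed = 2)
  calls <- res$calls

  analyzable <- intersect(sim$planted_ids, calls$protein)
  called <- calls$protein[calls$significant]
  recall <- mean(analyzable %in% called)
  expect_gte(recall, 0.9)

  false_calls <- setdiff(called, sim$planted_ids)
  expect_lte(length(false_calls), 0.05 * length(called) + 2)

  # call soundness: every significant protein passes both gates
  sig <- calls[calls$significant, ]
  expect_true(all(sig$log2fc_vs_turbo > 1 & sig$log2fc_vs_nodox > 1))
  expect_true(all(sig$adj_p_vs_turbo < 0.05 & sig$adj_p_vs_nodox < 0.05))

  # determinism of the full pipeline
  res2 <- call_interactors(sim$matrix, seed = 2)
  expect_identical(res$calls, res2$calls)
})

test_that("designs without four replicates per group are rejected", {
  sim <- complete_matrix(5)
  m <- sim$matrix
  m$design <- m$design[-1, ]
  m$intensity <- m$intensity[, -1]
  expect_error(call_interactors(m), class = "mobprox_validation_error")
})
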