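# Gate calibration, assignment, replicate summaries and condition
# comparison.

h2b_features_fixture <- function(n = 400, seed = 31) {
  set.seed(seed)
  make_features(n,
                alpha = runif(n, 0.2, 0.9),
                r_conf = c(abs(rnorm(round(0.85 * n), 0.06, 0.02)),
                           abs(rnorm(n - round(0.85 * n), 0.5, 0.2))),
                mean_jump = c(abs(rnorm(round(0.85 * n), 0.04, 0.01)),
                              abs(rnorm(n - round(0.85 * n), 0.15, 0.05))))
}

test_that("gate calibration matches brute-force percentile counts", {
  h2b <- h2b_features_fixture()
  gates <- calibrate_gates(h2b, lo_pct = 75, hi_pct = 95)

  # brute-force count oracle: rows satisfying both marginal conditions
  qr <- quantile(h2b$r_conf_um, 0.75, names = FALSE)
  qj <- quantile(h2b$mean_jump_um, 0.75, names = FALSE)
  expected_lo <- mean(h2b$r_conf_um <= qr & h2b$mean_jump_um <= qj)
  lab <- assign_gate(h2b, gates)
  expect_equal(mean(lab == "LoMC"), expected_lo)

  # determinism
  expect_identical(gates, calibrate_gates(h2b, 75, 95))
})

test_that("calibration preconditions are enforced", {
  h2b <- h2b_features_fixture(n = 50)
  expect_error(calibrate_gates(h2b), class = "mobprox_validation_error")
  h2b <- h2b_features_fixture(n = 400)
  expect_error(calibrate_gates(h2b, lo_pct = 80, hi_pct = 80),
               class = "mobprox_validation_error")
})

test_that("degenerate calibration keeps the common point in LoMC only", {
  h2b <- make_features(150, r_conf = 0.05, mean_jump = 0.04)
  gates <- calibrate_gates(h2b)
  lab <- assign_gate(h2b, gates)
  expect_true(all(lab == "LoMC"))   # boundary tie resolved to LoMC
})

test_that("gate assignment follows rectangle logic with inclusive bounds", {
  h2b <- h2b_features_fixture()
  gates <- calibrate_gates(h2b)
  pts <- make_features(3,
                       r_conf = c(0.01, gates$HiMC$r_conf[1] + 1,
                                  gates$HiMC$r_conf[1] + 1),
                       mean_jump = c(0.001, gates$HiMC$mean_jump[1] + 1, 0.001))
  expect_equal(assign_gate(pts, gates), c("LoMC", "HiMC", "neither"))

  # boundaries inclusive
  edge <- make_features(1, r_conf = gates$LoMC$r_conf[2],
                        mean_jump = gates$LoMC$mean_jump[2])
  expect_equal(assign_gate(edge, gates), "LoMC")

  # missing features: neither
  nas <- make_features(1, r_conf = NA_real_, mean_jump = 0.01)
  expect_equal(assign_gate(nas, gates), "neither")
})

test_that("mobility summary computes per-replicate fractions and spread", {
  h2b <- h2b_features_fixture()
  gates <- calibrate_gates(h2b)
  inside <- make_features(4, r_conf = 0.01, mean_jump = 0.01)
  outside <- make_features(6, r_conf = gates$LoMC$r_conf[2] * 1.5,
                           mean_jump = 0.01)
  rep1 <- rbind(inside, outside)

  s <- summarize_mobility(list(rep1), gates)
  expect_equal(s$per_replicate$fraction[s$per_replicate$gate == "LoMC"], 0.4)
  expect_equal(s$per_gate$sd_fraction, c(0, 0))

  s3 <- summarize_mobility(list(rep1, rep1, rep1), gates)
  expect_equal(s3$per_gate$sd_fraction, c(0, 0))   # identical replicates
  expect_equal(s3$per_gate$mean_fraction[s3$per_gate$gate == "LoMC"], 0.4)

  hi_only <- make_features(5, r_conf = gates$HiMC$r_conf[1] + 1,
                           mean_jump = gates$HiMC$mean_jump[1] + 1)
  s <- summarize_mobility(list(hi_only), gates)
  expect_equal(s$per_gate$mean_fraction[s$per_gate$gate == "HiMC"], 1.0)

  # fractions bounded and jointly feasible
  expect_true(all(s3$per_replicate$fraction >= 0 & s3$per_replicate$fraction <= 1))
  tot <- tapply(s3$per_replicate$fraction, s3$per_replicate$replicate, sum)
  expect_true(all(tot <= 1 + 1e-12))
})

test_that("feature scaling moves occupancy monotonically between gates", {
  h2b <- h2b_features_fixture()
  gates <- calibrate_gates(h2b)
  set.seed(33)
  base <- make_features(200, r_conf = abs(rnorm(200, 0.1, 0.05)),
                        mean_jump = abs(rnorm(200, 0.06, 0.03)))
  scaled <- base
  scaled$r_conf_um <- scaled$r_conf_um * 3
  scaled$mean_jump_um <- scaled$mean_jump_um * 3

  sa <- summarize_mobility(list(base), gates)
  sb <- summarize_mobility(list(scaled), gates)
  frac <- function(s, g) s$per_gate$mean_fraction[s$per_gate$gate == g]
  expect_lte(frac(sb, "LoMC"), frac(sa, "LoMC"))
  expect_gte(frac(sb, "HiMC"), frac(sa, "HiMC"))

  cmp <- compare_conditions(list(A = sa, B = sb))
  expect_equal(nrow(cmp$long), 4L)
  d <- cmp$differences
  expect_gte(d$difference[d$gate == "LoMC"], 0)  # A - B for LoMC
})

test_that("condition comparison validates inputs and detects identity", {
  h2b <- h2b_features_fixture()
  gates <- calibrate_gates(h2b)
  s <- summarize_mobility(list(make_features(10)), gates)
  expect_error(compare_conditions(list(A = s)), class = "mobprox_validation_error")

  cmp <- compare_conditions(list(A = s, B = s))
  expect_true(all(cmp$differences$difference == 0))

  other_gates <- calibrate_gates(h2b, lo_pct = 60, hi_pct = 90)
  s2 <- summarize_mobility(list(make_features(10)), other_gates)
  expect_error(compare_conditions(list(A = s, B = s2)),
               class = "mobprox_validation_error")
})
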