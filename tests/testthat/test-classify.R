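# Motion-class boundaries, butterfly handling, filters, down-sampling and
# the full classification pipeline.

test_that("alpha class boundaries are exactly as specified", {
  cfg <- classify_config()
  expect_equal(classify_alpha(0.70, cfg), "Confined")   # boundary inclusive
  expect_equal(classify_alpha(0.85, cfg), "Brownian")
  expect_equal(classify_alpha(1.0, cfg), "Directed")    # boundary inclusive
  expect_equal(classify_alpha(c(0.2, 0.9, 1.5), cfg),
               c("Confined", "Brownian", "Directed"))
  expect_true(is.na(classify_alpha(NaN, cfg)))
  expect_true(is.na(classify_alpha(Inf, cfg)))
})

test_that("butterfly detection flags the outlier jump under each rule", {
  # 20 uniform steps of 0.05 um, one 0.5 um jump inserted at step 11
  x <- c(seq(0, 0.5, by = 0.05), seq(1.0, 1.45, by = 0.05))
  trk <- data.frame(frame = seq_along(x) - 1L, x = x, y = 0)

  # brute-force evaluation of the relative rule as the oracle
  jumps <- diff(x)
  expected <- which(jumps > mean(jumps) * 2.5)
  got <- detect_butterfly_splits(trk, classify_config())
  expect_equal(got, expected)
  expect_length(got, 1L)

  uniform <- data.frame(frame = 0:20, x = 0.05 * (0:20), y = 0)
  expect_length(detect_butterfly_splits(uniform, classify_config()), 0L)

  # absolute rule with a 1 um threshold never fires on this track
  cfg_abs <- classify_config(butterfly_rule = "absolute", butterfly_threshold = 1)
  expect_length(detect_butterfly_splits(trk, cfg_abs), 0L)

  # additive_sd rule: oracle mean + 1.5 sd
  cfg_sd <- classify_config(butterfly_rule = "additive_sd")
  expect_equal(detect_butterfly_splits(trk, cfg_sd),
               which(jumps > mean(jumps) + 1.5 * sd(jumps)))
})

test_that("segmentation partitions at split steps and drops short segments", {
  trk <- data.frame(frame = 0:20, x = (0:20) * 0.1, y = 0)
  segs <- segment_butterfly(trk, splits = 10L)
  expect_length(segs, 2L)
  expect_equal(vapply(segs, nrow, 1L), c(10L, 11L))
  # the split displacement belongs to neither segment
  expect_equal(segs[[1]]$frame[10], 9L)
  expect_equal(segs[[2]]$frame[1], 10L)

  expect_length(segment_butterfly(trk, integer(0)), 1L)

  # a 3-point segment is discarded under min_duration 5
  segs <- segment_butterfly(trk, splits = c(3L, 10L))
  expect_equal(vapply(segs, nrow, 1L), c(7L, 11L))

  expect_error(segment_butterfly(trk, splits = 21L),
               class = "mobprox_validation_error")
})

test_that("duration filter keeps five-frame tracks and is idempotent", {
  ts <- trackset_with_durations(1:20)
  kept <- apply_duration_filter(ts, 5)
  expect_equal(n_tracks(kept), 16L)
  expect_equal(min(track_durations(kept)), 5L)
  expect_identical(apply_duration_filter(kept, 5)$tracks, kept$tracks)
  expect_equal(n_tracks(apply_duration_filter(trackset(), 5)), 0L)
})

test_that("confined-jump filter removes only fast confined rows", {
  f <- rbind(make_features(1, mean_jump = 0.12, motion_class = "Confined"),
             make_features(1, mean_jump = 0.12, motion_class = "Brownian"),
             make_features(1, mean_jump = 0.05, motion_class = "Confined"),
             make_features(1, mean_jump = 0.10, motion_class = "Confined"))
  out <- apply_confined_jump_filter(f, 0.1)
  expect_equal(nrow(out), 3L)
  expect_equal(out$motion_class, c("Brownian", "Confined", "Confined"))
  expect_true(all(out$mean_jump_um[out$motion_class == "Confined"] <= 0.1))
  expect_identical(apply_confined_jump_filter(out, 0.1), out)
})

test_that("down-sampling is size-exact, subset-only and seed-deterministic", {
  f <- make_features(100)
  reps <- downsample_tracks(f, n = 30, reps = 3, seed = 5)
  expect_length(reps, 3L)
  expect_true(all(vapply(reps, nrow, 1L) == 30L))
  for (r in reps) expect_true(all(r$track_id %in% f$track_id))
  expect_false(identical(reps[[1]]$track_id, reps[[2]]$track_id))

  again <- downsample_tracks(f, n = 30, reps = 3, seed = 5)
  expect_identical(reps, again)

  # pool smaller than the budget: every replicate holds the full pool
  small <- downsample_tracks(f[1:10, ], n = 20000, reps = 3, seed = 5)
  expect_true(all(vapply(small, nrow, 1L) == 10L))
})

test_that("pipeline handles empty and all-short inputs gracefully", {
  out <- run_classification(trackset(), classify_config())
  expect_equal(nrow(out$features), 0L)

  short <- trackset_with_durations(c(3, 3, 3))
  out <- run_classification(short, classify_config())
  expect_equal(nrow(out$features), 0L)
  expect_equal(out$log$removed_short, 3L)
})

test_that("pipeline recovers generating classes on the well-separated mixture", {
  sim <- mixture_fixture(n_per_class = 50, n_frames = 1000, seed = 42)
  cls <- run_classification(sim$trackset, classify_config(seed = 1))
  rec <- class_recall(cls, sim$truth)
  expect_true(all(rec >= 0.9), info = paste(names(rec), round(rec, 3), collapse = "; "))

  # pipeline postconditions: duration and confined-jump invariants
  expect_true(all(cls$features$duration >= 5))
  conf <- cls$features$motion_class == "Confined"
  expect_true(all(cls$features$mean_jump_um[conf] <= 0.1))
  # classes partition the retained rows
  expect_true(all(cls$features$motion_class %in%
                    c("Confined", "Brownian", "Directed")))
})

test_that("classification is deterministic under a fixed seed", {
  sim <- mixture_fixture(n_per_class = 10, n_frames = 300, seed = 8)
  a <- run_classification(sim$trackset, classify_config(seed = 3))
  b <- run_classification(sim$trackset, classify_config(seed = 3))
  expect_identical(a$features, b$features)
  expect_identical(a$replicates, b$replicates)
})

test_that("configuration invariants are validated", {
  expect_error(classify_config(alpha_confined_max = 1.2),
               class = "mobprox_validation_error")
  expect_error(classify_config(butterfly_threshold = 0),
               class = "mobprox_validation_error")
  expect_error(classify_config(downsample_n = -1),
               class = "mobprox_validation_error")
})
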