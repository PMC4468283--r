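test_that("jitter and shimmer follow their closed forms", {
  expect_equal(jitter(rep(0.010, 8)), 0)
  expect_equal(jitter(rep(c(0.0099, 0.0101), 10)), 0.02, tolerance = 1e-9)
  # periods (10, 10, 13) ms: mean|dT| = 1.5, mean T = 11
  expect_equal(jitter(c(0.010, 0.010, 0.013)), 1.5 / 11, tolerance = 1e-12)
  expect_equal(shimmer(c(1, 1, 1, 1)), 0)
  expect_equal(shimmer(rep(c(0.9, 1.1), 10)), 0.2, tolerance = 1e-9)
  # amplitudes (1, 1, 0.5): mean|dA| = 0.25, mean A = 2.5/3
  expect_equal(shimmer(c(1, 1, 0.5)), 0.25 / (2.5 / 3), tolerance = 1e-12)
  expect_error(jitter(0.01), class = "voq_undefined")
  expect_error(shimmer(1), class = "voq_undefined")
  # scale invariance
  set.seed(5)
  p <- abs(rnorm(20, 0.01, 0.001))
  expect_equal(jitter(p), jitter(p * 17.3), tolerance = 1e-12)
  expect_equal(shimmer(p), shimmer(p * 0.004), tolerance = 1e-12)
})

test_that("local extraction emits exactly 33 named features per word", {
  sv <- fx_clean_voice()
  lf <- extract_local(sv$recording, sv$alignment, sv$track)
  expect_equal(ncol(lf), 33)
  expect_identical(colnames(lf), local_feature_names())
  expect_equal(nrow(lf), nrow(sv$alignment$words))
  expect_true(all(is.finite(lf)))
  # positions are in [0, 1], durations non-negative
  pos <- lf[, grep("Pos", colnames(lf))]
  expect_true(all(pos >= 0 & pos <= 1))
  expect_true(all(lf[, c("DurAbsW", "DurAbsWPW", "PauseBefore",
                         "PauseAfter")] >= 0))
})

test_that("pause features reflect alignment gaps directly", {
  sv <- fx_clean_voice()
  lf <- extract_local(sv$recording, sv$alignment, sv$track)
  # generator uses 0.15 s pauses between words
  expect_equal(unname(lf[1, "PauseAfter"]), 0.15, tolerance = 1e-9)
  expect_equal(unname(lf[2, "PauseBefore"]), 0.15, tolerance = 1e-9)
  expect_true(all(lf[, c("PauseFillBefore", "PauseFillAfter")] == 0))
})

test_that("constant frame energy gives a flat energy regression", {
  fs <- 16000
  sq <- rep(c(1, -1), each = 80, times = 50)  # RMS exactly 1 in every frame
  rec <- new_recording("sq", sq, fs)
  track <- analyze_track(rec)
  aln <- new_alignment(c("eins", "zwei"), c(0, 0.45), c(0.4, 0.79))
  lf <- extract_local(rec, aln, track)
  expect_equal(unname(lf[, "EnRegCoeffW"]), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(lf[, "EnMseRegW"]), c(0, 0), tolerance = 1e-12)
})

test_that("filled pauses split inter-word gaps into silent and filled time", {
  sv <- fx_clean_voice()
  words <- sv$alignment$words
  # inject a filler occupying 0.06 s of the first gap
  labels <- c(words$label[1], "\u00e4h", words$label[-1])
  starts <- c(words$start[1], words$end[1] + 0.04, words$start[-1])
  ends <- c(words$end[1], words$end[1] + 0.10, words$end[-1])
  aln2 <- new_alignment(labels, starts, ends)
  lf <- extract_local(sv$recording, aln2, sv$track)
  expect_equal(nrow(lf), nrow(words))  # filler is not a feature word
  expect_equal(unname(lf[2, "PauseFillBefore"]), 0.06, tolerance = 1e-9)
  expect_equal(unname(lf[2, "PauseBefore"]), 0.15 - 0.06, tolerance = 1e-9)
  expect_equal(unname(lf[1, "PauseFillAfter"]), 0.06, tolerance = 1e-9)
})

test_that("global extraction emits exactly 15 features per window", {
  sv <- fx_clean_voice()
  gf <- extract_global(sv$recording, sv$alignment, sv$track)
  expect_equal(ncol(gf), 15)
  expect_identical(colnames(gf), global_feature_names())
  expect_true(all(gf[, c("MeanJitter", "MeanShimmer")] >= 0))
  expect_lte(gf[1, "RelLenVoicedSignal"] + gf[1, "RelLenUnvoicedSignal"],
             1 + 1e-9)
})

test_that("window plan makes 15-word windows with remainder handling", {
  expect_equal(voqual:::window_plan(10), list(1:10))
  expect_equal(length(voqual:::window_plan(30)), 2)
  # remainder 7 < 8 merges into the last window
  wp <- voqual:::window_plan(37)
  expect_equal(length(wp), 2)
  expect_equal(length(wp[[2]]), 22)
  # remainder 8 stands alone
  wp <- voqual:::window_plan(38)
  expect_equal(length(wp), 3)
  expect_equal(length(wp[[3]]), 8)
})

test_that("an unperturbed pulse train measures zero jitter", {
  sv <- fx_clean_voice()
  gf <- extract_global(sv$recording, sv$alignment, sv$track)
  expect_lt(gf[1, "MeanJitter"], 1e-6)
})

test_that("injected jitter is recovered within the 0.8-1.2x band", {
  sv3 <- synth_voice(f0 = 100, word_plan = default_word_plan(8, 0.4, 0.1),
                     jitter_pct = 3, seed = 5)
  tr3 <- analyze_track(sv3$recording)
  gf3 <- extract_global(sv3$recording, sv3$alignment, tr3)
  expect_gte(gf3[1, "MeanJitter"], 2.4)
  expect_lte(gf3[1, "MeanJitter"], 3.6)
})

test_that("jitter and shimmer estimates are monotone in the injected level", {
  est <- sapply(c(0, 1, 2, 4), function(j) {
    sv <- synth_voice(f0 = 100, word_plan = default_word_plan(8, 0.4, 0.1),
                      jitter_pct = j, seed = 5)
    tr <- analyze_track(sv$recording)
    extract_global(sv$recording, sv$alignment, tr)[1, "MeanJitter"]
  })
  expect_true(all(diff(est) > 0))
  est_s <- sapply(c(0, 5, 10), function(s) {
    sv <- synth_voice(f0 = 100, word_plan = default_word_plan(8, 0.4, 0.1),
                      shimmer_pct = s, seed = 5)
    tr <- analyze_track(sv$recording)
    extract_global(sv$recording, sv$alignment, tr)[1, "MeanShimmer"]
  })
  expect_true(all(diff(est_s) > 0))
})

test_that("time-shifting recording and alignment leaves features unchanged", {
  sv <- fx_clean_voice()
  lf1 <- extract_local(sv$recording, sv$alignment, sv$track)
  shift_s <- 0.25  # a whole number of frame shifts and samples
  rec2 <- sv$recording
  rec2$speech <- c(numeric(shift_s * rec2$speech_rate), rec2$speech)
  rec2$duration <- length(rec2$speech) / rec2$speech_rate
  w <- sv$alignment$words
  aln2 <- new_alignment(w$label, w$start + shift_s, w$end + shift_s)
  tr2 <- analyze_track(rec2)
  lf2 <- extract_local(rec2, aln2, tr2)
  # the very first analysis frame of the unshifted signal has no left
  # context, so values agree to absolute numerical noise, not exactly;
  # position features sit on argmax ties of near-flat contours and are
  # excluded
  # EnNorm is relative to the whole recording's mean energy, which the
  # added silence legitimately changes
  keep <- setdiff(grep("Pos", colnames(lf1), invert = TRUE),
                  grep("EnNorm", colnames(lf1)))
  expect_lt(max(abs(lf2[, keep] - lf1[, keep])), 1e-3)
  expect_equal(unname(lf2[3:6, "DurNormW"]), unname(lf1[3:6, "DurNormW"]),
               tolerance = 1e-9)
  expect_equal(unname(lf2[2:6, "PauseBefore"]), unname(lf1[2:6, "PauseBefore"]),
               tolerance = 1e-9)
})

test_that("aggregation averages words and windows and appends EGG values", {
  l <- matrix(c(0.4, 0.6), nrow = 2, ncol = 33,
              dimnames = list(NULL, local_feature_names()))
  g <- matrix(2, nrow = 1, ncol = 15,
              dimnames = list(NULL, global_feature_names()))
  agg <- aggregate_features(l, g)
  expect_length(agg, 48)
  expect_equal(unname(agg["DurAbsW"]), 0.5)
  # single word: aggregate equals that word's vector
  agg1 <- aggregate_features(l[1, , drop = FALSE], g)
  expect_equal(agg1[local_feature_names()],
               setNames(l[1, ], local_feature_names()))
  # EGG summary appends CFx/CQx
  es <- structure(list(cfx = 2.5, cqx = 4, n_cycles = 100),
                  class = "voq_egg_summary")
  expect_length(aggregate_features(l, g, es), 50)
  # missing-coded F0 entries are skipped, all-missing stays missing
  l[, "F0MeanW"] <- c(NA, 1)
  l[, "F0MaxW"] <- NA
  agg2 <- aggregate_features(l, g)
  expect_equal(unname(agg2["F0MeanW"]), 1)
  expect_true(is.na(agg2["F0MaxW"]))
})
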