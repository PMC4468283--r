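# Shared fixtures, built lazily and cached for the whole test run.
.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# A clean 100 Hz synthetic voice with 6 words, no perturbation.
fx_clean_voice <- function() fixture("clean_voice", function() {
  sv <- synth_voice(f0 = 100, word_plan = default_word_plan(6, 0.4, 0.15),
                    seed = 2)
  sv$track <- analyze_track(sv$recording)
  sv
})

# Voice with 2% injected jitter.
fx_jitter_voice <- function() fixture("jitter_voice", function() {
  sv <- synth_voice(f0 = 100, word_plan = default_word_plan(8, 0.4, 0.1),
                    jitter_pct = 2, seed = 5)
  sv$track <- analyze_track(sv$recording)
  sv
})

# Small in-memory study manifest: 12 recordings over a severity gradient,
# speech + EGG, with matching panel item ids.
fx_manifest <- function(n = 12) fixture(paste0("manifest", n), function() {
  lapply(seq_len(n), function(i) {
    sev <- (i - 1) / (n - 1)
    sv <- synth_voice(f0 = 100 + 8 * i,
                      word_plan = default_word_plan(6, 0.28 + 0.02 * (i %% 3),
                                                    0.08 + 0.02 * (i %% 2)),
                      jitter_pct = 3 * sev, shimmer_pct = 8 * sev,
                      seed = 100 + i, id = sprintf("rec%02d", i))
    egg <- synth_egg(f0 = 100 + 8 * i, contact_quotient_pct = 45 + 10 * sev,
                     cycle_perturb_pct = 4 * sev, duration_s = 2,
                     seed = 200 + i)
    sv$recording$egg <- as.numeric(egg)
    sv$recording$egg_rate <- attr(egg, "sample_rate")
    list(id = sprintf("rec%02d", i), recording = sv$recording,
         alignment = sv$alignment)
  })
})

fx_study <- function() fixture("study", function() {
  man <- fx_manifest()
  sev <- (seq_along(man) - 1) / (length(man) - 1) * 2.5
  panel <- synth_panel(sev, n_raters = 8, rater_noise_sd = 0.5, seed = 42)
  rownames(panel) <- vapply(man, `[[`, "", "id")
  suppressWarnings(
    run_study(man, panel, config = voq_config(cfs_folds = 6), seed = 7))
})

# Independent brute-force oracle for Krippendorff's alpha: enumerate all
# pairable value pairs within items directly.
alpha_oracle <- function(m, metric = "interval") {
  vals <- sort(unique(as.vector(m[!is.na(m)])))
  pairs_o <- NULL
  for (u in seq_len(nrow(m))) {
    r <- m[u, ]; r <- r[!is.na(r)]
    mu <- length(r)
    if (mu < 2) next
    for (a in seq_len(mu)) for (b in seq_len(mu)) if (a != b)
      pairs_o <- rbind(pairs_o, c(r[a], r[b], 1 / (mu - 1)))
  }
  if (is.null(pairs_o)) return(NA_real_)
  n_c <- sapply(vals, function(v) sum(pairs_o[pairs_o[, 1] == v, 3]))
  n_tot <- sum(pairs_o[, 3])
  if (metric == "interval") {
    d2 <- function(a, b) (a - b)^2
  } else {
    cum <- function(a, b) {
      lo <- which(vals == min(a, b)); hi <- which(vals == max(a, b))
      (sum(n_c[lo:hi]) - (n_c[lo] + n_c[hi]) / 2)^2
    }
    d2 <- function(a, b) if (a == b) 0 else cum(a, b)
  }
  Do <- sum(pairs_o[, 3] * mapply(d2, pairs_o[, 1], pairs_o[, 2])) / n_tot
  De <- 0
  for (a in vals) for (b in vals)
    De <- De + n_c[vals == a] * n_c[vals == b] * d2(a, b)
  De <- De / (n_tot * (n_tot - 1))
  1 - Do / De
}

random_small_panel <- function() {
  n_i <- sample(2:5, 1); n_r <- sample(2:4, 1)
  m <- matrix(sample(c(0:3, NA), n_i * n_r, replace = TRUE,
                     prob = c(rep(0.22, 4), 0.12)), n_i, n_r)
  # ensure at least one item with 2+ ratings and 2+ distinct values
  m[1, 1:2] <- c(0, 3)
  m
}

expect_voq_error <- function(expr, class) {
  expect_error(expr, class = class)
}
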