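# Seeded synthetic generators: speech-like audio (glottal pulse train
# through a two-formant resonator, with controllable F0 contour, jitter,
# shimmer, pauses), EGG signals with controllable contact quotient and
# cycle perturbation, rating panels, and feature tables. Every generator is
# a pure function of its spec (seed included); ground truth for parameter-
# recovery tests.

as_f0_fun <- function(f0) {
  if (is.function(f0)) return(f0)
  f0 <- as.numeric(f0)
  function(t) rep(f0[1], length(t))
}

two_formant_filter <- function(x, fs, formants = c(500, 1500),
                               bandwidths = c(80, 120)) {
  for (k in seq_along(formants)) {
    r <- exp(-pi * bandwidths[k] / fs)
    th <- 2 * pi * formants[k] / fs
    a <- c(1, -2 * r * cos(th), r^2)
    b <- (1 - r) * sqrt(1 - 2 * r * cos(2 * th) + r^2)
    x <- as.numeric(signal::filter(b, a, x))
  }
  x
}

#' Synthesize a speech-like recording with a word alignment
#'
#' Voiced words are glottal pulse trains: per-period multiplicative
#' Gaussian perturbations of the period (sd `jitter_pct`) and pulse
#' amplitude (sd `shimmer_pct`), filtered by a fixed two-formant resonator
#' (500/1500 Hz, bandwidths 80/120 Hz). Pauses carry low-level noise at
#' `noise_snr_db` below the voiced RMS. Bit-identical output for equal
#' specs.
#'
#' @param f0 fundamental frequency: a constant in Hz or a function of time
#'   (seconds); must stay within 50-500 Hz.
#' @param word_plan data.frame with columns `label`, `dur` (voiced seconds)
#'   and `pause` (trailing pause seconds).
#' @param jitter_pct,shimmer_pct perturbation standard deviations, percent.
#' @param noise_snr_db pause-noise level below voiced RMS, dB.
#' @param seed integer RNG seed.
#' @param sample_rate output rate, Hz.
#' @param id recording id.
#' @return list(recording = `voq_recording`, alignment = `voq_alignment`);
#'   the recording carries the true pulse times in attribute
#'   `pulse_times`.
#' @export
synth_voice <- function(f0 = 120, word_plan = default_word_plan(),
                        jitter_pct = 0, shimmer_pct = 0, noise_snr_db = 30,
                        seed = 1L, sample_rate = 16000L, id = "synth") {
  f0f <- as_f0_fun(f0)
  fs <- sample_rate
  with_seed(seed, {
    total <- sum(word_plan$dur + word_plan$pause)
    n <- ceiling(total * fs) + fs %/% 10
    imp <- numeric(n)
    pulse_times <- numeric(0)
    t_cursor <- 0
    starts <- ends <- numeric(nrow(word_plan))
    for (w in seq_len(nrow(word_plan))) {
      starts[w] <- t_cursor
      t_end <- t_cursor + word_plan$dur[w]
      t <- t_cursor
      repeat {
        fval <- f0f(t)
        if (!is.finite(fval) || fval < 50 || fval > 500)
          voq_stop("voq_spec_error", "F0 contour leaves 50-500 Hz at t=%.3f", t)
        period <- (1 / fval) * (1 + jitter_pct / 100 * stats::rnorm(1))
        t_next <- t + period
        if (t_next > t_end) break
        amp <- 1 + shimmer_pct / 100 * stats::rnorm(1)
        # sub-sample impulse placement over two samples
        pos <- t * fs
        j <- floor(pos) + 1L
        frac <- pos - (j - 1L)
        if (j <= n) imp[j] <- imp[j] + amp * (1 - frac)
        if (j + 1L <= n) imp[j + 1L] <- imp[j + 1L] + amp * frac
        pulse_times <- c(pulse_times, t)
        t <- t_next
      }
      ends[w] <- t_end
      t_cursor <- t_end + word_plan$pause[w]
    }
    x <- two_formant_filter(imp, fs)
    voiced_rms <- sqrt(mean(x[x != 0]^2))
    noise <- stats::rnorm(n) * voiced_rms * 10^(-noise_snr_db / 20)
    # noise only in the pauses
    in_word <- logical(n)
    for (w in seq_len(nrow(word_plan))) {
      a <- floor(starts[w] * fs) + 1L
      b <- min(n, ceiling(ends[w] * fs))
      in_word[a:b] <- TRUE
    }
    x[!in_word] <- noise[!in_word]
    x <- 0.5 * x / max(abs(x))
    rec <- new_recording(id, x, fs)
    attr(rec, "pulse_times") <- pulse_times
    aln <- new_alignment(word_plan$label, starts, ends)
    list(recording = rec, alignment = aln)
  })
}

#' A small default reading-passage word plan
#' @param n_words number of words.
#' @param dur voiced duration per word (s).
#' @param pause trailing pause per word (s).
#' @export
default_word_plan <- function(n_words = 18, dur = 0.30, pause = 0.12) {
  data.frame(label = sprintf("wort%02d", seq_len(n_words)),
             dur = dur, pause = pause, stringsAsFactors = FALSE)
}

#' Synthesize an electroglottographic signal
#'
#' Per cycle: a smoothed rectangular contact pulse occupying the contact
#' quotient's share of the period (raised-cosine edges, width 5% of the
#' period each); the period is multiplicatively perturbed with sd
#' `cycle_perturb_pct` and the per-cycle contact quotient additively with
#' sd `qx_perturb_pct` percentage points.
#'
#' @param f0 Hz, constant or function of time.
#' @param contact_quotient_pct nominal contact quotient in (0, 100).
#' @param cycle_perturb_pct period perturbation sd, percent.
#' @param qx_perturb_pct contact-quotient perturbation sd, percentage points.
#' @param duration_s signal length, seconds.
#' @param seed integer RNG seed.
#' @param sample_rate Hz (>= 8000).
#' @return numeric waveform with attributes `sample_rate` and
#'   `true_cycles` (data.frame of the generated closure times, periods, cq).
#' @export
synth_egg <- function(f0 = 100, contact_quotient_pct = 50,
                      cycle_perturb_pct = 0, qx_perturb_pct = 0,
                      duration_s = 2, seed = 1L, sample_rate = 16000L) {
  stopifnot(contact_quotient_pct > 0, contact_quotient_pct < 100)
  f0f <- as_f0_fun(f0)
  fs <- sample_rate
  with_seed(seed, {
    n <- ceiling(duration_s * fs)
    x <- numeric(n)
    t <- 0.01
    times <- periods <- cqs <- numeric(0)
    while (TRUE) {
      fval <- f0f(t)
      if (!is.finite(fval) || fval < 50 || fval > 500)
        voq_stop("voq_spec_error", "F0 contour leaves 50-500 Hz at t=%.3f", t)
      period <- (1 / fval) * (1 + cycle_perturb_pct / 100 * stats::rnorm(1))
      if (t + period > duration_s - 0.01) break
      cq <- contact_quotient_pct + qx_perturb_pct * stats::rnorm(1)
      cq <- min(95, max(5, cq)) / 100
      a <- floor(t * fs) + 1L
      b <- min(n, floor((t + period) * fs))
      u <- ((a:b) - 1) / fs - t       # time within the cycle
      x[a:b] <- x[a:b] + contact_pulse(u / period, cq)
      times <- c(times, t); periods <- c(periods, period); cqs <- c(cqs, cq * 100)
      t <- t + period
    }
    if (length(times) < 2)
      voq_stop("voq_spec_error", "signal too short for two EGG cycles")
    structure(x, sample_rate = fs,
              true_cycles = data.frame(closure = times, period = periods,
                                       cq = cqs))
  })
}

# Unit-amplitude contact pulse on cycle phase u in [0, 1): plateau of the
# contact quotient's width with raised-cosine rise/fall (width `edge` each),
# positioned so the half-height points span exactly cq.
contact_pulse <- function(u, cq, edge = 0.05) {
  rise0 <- 0.02
  lo <- rise0; hi <- rise0 + cq
  y <- numeric(length(u))
  y[u >= lo + edge / 2 & u < hi - edge / 2] <- 1
  ramp <- u >= lo - edge / 2 & u < lo + edge / 2
  y[ramp] <- 0.5 * (1 - cos(pi * (u[ramp] - (lo - edge / 2)) / edge))
  fall <- u >= hi - edge / 2 & u < hi + edge / 2
  y[fall] <- 0.5 * (1 + cos(pi * (u[fall] - (hi - edge / 2)) / edge))
  y
}

#' Synthesize a perceptual rating panel
#'
#' rating(item, rater) = clamp(round(true + Gaussian(0, sd)), 0..3),
#' independently per criterion.
#'
#' @param true_scores numeric vector (per item, used for all three
#'   criteria) or items x 3 matrix, values in \[0, 3\].
#' @param n_raters number of raters.
#' @param rater_noise_sd rating-unit noise sd.
#' @param seed integer RNG seed.
#' @return a `voq_panel`.
#' @export
synth_panel <- function(true_scores, n_raters = 19, rater_noise_sd = 0.5,
                        seed = 1L) {
  if (is.null(dim(true_scores)))
    true_scores <- matrix(true_scores, nrow = length(true_scores), ncol = 3)
  stopifnot(all(true_scores >= 0 & true_scores <= 3))
  n_items <- nrow(true_scores)
  with_seed(seed, {
    arr <- array(NA_real_, c(n_items, n_raters, 3),
                 dimnames = list(sprintf("item%03d", seq_len(n_items)),
                                 sprintf("rater%02d", seq_len(n_raters)),
                                 RBH))
    for (k in 1:3)
      arr[, , k] <- pmin(3, pmax(0, round(
        true_scores[, k] + stats::rnorm(n_items * n_raters, 0, rater_noise_sd))))
    new_panel(arr)
  })
}

#' Synthesize a feature table with a linear target
#'
#' Standard-normal feature columns named after `weights`; the target is the
#' weighted sum plus Gaussian noise.
#'
#' @param n number of items.
#' @param weights named numeric vector (zero-weight entries give pure-noise
#'   features).
#' @param noise_sd target noise sd.
#' @param seed integer RNG seed.
#' @return list(table = data.frame(id, features...), target = numeric).
#' @export
synth_feature_table <- function(n, weights, noise_sd = 0, seed = 1L) {
  stopifnot(n >= 2, !is.null(names(weights)))
  with_seed(seed, {
    X <- matrix(stats::rnorm(n * length(weights)), nrow = n,
                dimnames = list(NULL, names(weights)))
    target <- as.numeric(X %*% weights + stats::rnorm(n, 0, noise_sd))
    tbl <- data.frame(id = sprintf("item%03d", seq_len(n)), X,
                      check.names = FALSE, stringsAsFactors = FALSE)
    list(table = tbl, target = target)
  })
}
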