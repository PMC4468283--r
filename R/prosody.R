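# Word-level (local) and window-level (global) prosodic features.
#
# Contexts: W = the current word's interval; WPW = the interval containing
# the second and first word before the current word and the pause between
# them. F0 values enter the features in semitones relative to the
# recording's median voiced F0; energies are short-time RMS values.

#' Local relative jitter of a period sequence
#'
#' Mean absolute successive period difference over the mean period
#' (dimensionless).
#' @param periods cycle durations in seconds (>= 2 values).
#' @export
jitter <- function(periods) rel_perturbation(periods)

#' Local relative shimmer of a cycle-amplitude sequence
#'
#' Mean absolute successive amplitude difference over the mean amplitude.
#' @param amplitudes per-cycle peak amplitudes (>= 2 values).
#' @export
shimmer <- function(amplitudes) rel_perturbation(amplitudes)

# Frames whose centre falls in [t0, t1)
frames_in <- function(track, t0, t1) {
  centre <- track$time + (attr(track, "frame_length") %||% 256L) /
    (attr(track, "sample_rate") %||% 16000L) / 2
  which(centre >= t0 & centre < t1)
}

frame_centres <- function(track) {
  track$time + (attr(track, "frame_length") %||% 256L) /
    (attr(track, "sample_rate") %||% 16000L) / 2
}

# Semitone-normalized F0 contour over voiced frames of the track.
semitone_f0 <- function(track) {
  ref <- stats::median(track$f0, na.rm = TRUE)
  12 * log2(track$f0 / ref)
}

# Energy / duration / F0-regression features of one context interval.
context_features <- function(track, st, t0, t1, n_char, mean_energy, dur_per_char) {
  idx <- frames_in(track, t0, t1)
  centres <- frame_centres(track)[idx]
  en <- track$energy[idx]
  span <- t1 - t0
  out <- list(DurAbs = span,
              DurNorm = span / (n_char * dur_per_char))
  if (length(idx) == 0) {
    out[c("EnRegCoeff", "EnMseReg", "EnAbs", "EnNorm", "EnMean",
          "F0RegCoeff", "F0MseReg")] <- NA_real_
    return(out)
  }
  fit <- linfit(centres, en)
  out$EnRegCoeff <- fit$slope
  out$EnMseReg <- fit$mse
  out$EnAbs <- sum(en)
  out$EnMean <- mean(en)
  out$EnNorm <- out$EnMean / mean_energy
  v <- idx[which(track$voiced[idx])]
  if (length(v) >= 1) {
    ffit <- linfit(frame_centres(track)[v], st[v])
    out$F0RegCoeff <- ffit$slope
    out$F0MseReg <- ffit$mse
  } else {
    out$F0RegCoeff <- NA_real_
    out$F0MseReg <- NA_real_
  }
  out
}

#' Extract the 33 word-level prosodic features
#'
#' One feature vector per (non-filler) word. Pause features come from the
#' alignment gaps (silent time) and filler-labelled intervals (filled
#' time); energy features from the RMS contour; duration absolute and
#' normalized by word length in characters times the recording's mean
#' duration per character; F0 features from the semitone-normalized voiced
#' contour. Word-pause-word (WPW) features of the first two words are
#' imputed with the recording mean of the feature. Words without voiced
#' frames get missing-coded F0 features (skipped at aggregation).
#'
#' @param recording a `voq_recording`.
#' @param alignment a `voq_alignment`.
#' @param track an analyzed `voq_track` (see [analyze_track()]).
#' @param config see [voq_config()].
#' @return matrix of class `voq_local` (words x 33), row names = word labels.
#' @export
extract_local <- function(recording, alignment, track, config = voq_config()) {
  fillers <- config$filler_labels
  words <- alignment$words
  is_fill <- tolower(words$label) %in% tolower(fillers)
  fw <- words[!is_fill, , drop = FALSE]   # feature words
  fillw <- words[is_fill, , drop = FALSE]
  n <- nrow(fw)
  if (n == 0) voq_stop("voq_validation_error", "alignment contains no words")
  st <- semitone_f0(track)
  centres <- frame_centres(track)
  mean_energy <- mean(track$energy)
  dur_per_char <- sum(fw$end - fw$start) / sum(nchar(fw$label))

  filled_between <- function(a, b) {
    if (nrow(fillw) == 0 || b <= a) return(0)
    sum(pmax(0, pmin(fillw$end, b) - pmax(fillw$start, a)))
  }

  feats <- matrix(NA_real_, nrow = n, ncol = 33,
                  dimnames = list(fw$label, local_feature_names()))
  for (i in seq_len(n)) {
    t0 <- fw$start[i]; t1 <- fw$end[i]
    # pauses relative to neighbouring feature words
    if (i > 1) {
      gap <- t0 - fw$end[i - 1]
      fill <- filled_between(fw$end[i - 1], t0)
      feats[i, "PauseBefore"] <- max(0, gap - fill)
      feats[i, "PauseFillBefore"] <- fill
    } else {
      feats[i, c("PauseBefore", "PauseFillBefore")] <- 0
    }
    if (i < n) {
      gap <- fw$start[i + 1] - t1
      fill <- filled_between(t1, fw$start[i + 1])
      feats[i, "PauseAfter"] <- max(0, gap - fill)
      feats[i, "PauseFillAfter"] <- fill
    } else {
      feats[i, c("PauseAfter", "PauseFillAfter")] <- 0
    }
    # current-word context
    cw <- context_features(track, st, t0, t1, nchar(fw$label[i]),
                           mean_energy, dur_per_char)
    for (f in c("EnRegCoeff", "EnMseReg", "EnAbs", "EnNorm", "EnMean",
                "DurAbs", "DurNorm", "F0RegCoeff", "F0MseReg"))
      feats[i, paste0(f, "W")] <- cw[[f]]
    idx <- frames_in(track, t0, t1)
    if (length(idx)) {
      en <- track$energy[idx]
      jmax <- which.max(en)
      feats[i, "EnMaxW"] <- en[jmax]
      feats[i, "EnMaxPosW"] <- pos01(centres[idx][jmax], t0, t1)
    }
    v <- idx[which(track$voiced[idx])]
    if (length(v)) {
      fv <- st[v]; tv <- centres[v]
      feats[i, "F0MeanW"] <- mean(fv)
      feats[i, "F0MaxW"] <- max(fv)
      feats[i, "F0MaxPosW"] <- pos01(tv[which.max(fv)], t0, t1)
      feats[i, "F0MinW"] <- min(fv)
      feats[i, "F0MinPosW"] <- pos01(tv[which.min(fv)], t0, t1)
      feats[i, "F0OnW"] <- fv[1]
      feats[i, "F0OnPosW"] <- pos01(tv[1], t0, t1)
      feats[i, "F0OffW"] <- fv[length(fv)]
      feats[i, "F0OffPosW"] <- pos01(tv[length(tv)], t0, t1)
    }
    # word-pause-word context: the two preceding words plus their pause
    if (i >= 3) {
      w0 <- fw$start[i - 2]; w1 <- fw$end[i - 1]
      nc2 <- nchar(fw$label[i - 2]) + nchar(fw$label[i - 1])
      cp <- context_features(track, st, w0, w1, nc2, mean_energy, dur_per_char)
      for (f in c("EnRegCoeff", "EnMseReg", "EnAbs", "EnNorm", "EnMean",
                  "DurAbs", "DurNorm", "F0RegCoeff", "F0MseReg"))
        feats[i, paste0(f, "WPW")] <- cp[[f]]
    }
  }
  # words 1-2 have no WPW context: impute with the recording mean
  wpw_cols <- grep("WPW$", colnames(feats))
  for (j in wpw_cols) {
    m <- mean(feats[, j], na.rm = TRUE)
    miss <- seq_len(min(2, n))
    feats[miss, j][is.na(feats[miss, j])] <- m
  }
  class(feats) <- c("voq_local", class(feats))
  feats
}

pos01 <- function(t, t0, t1) max(0, min(1, (t - t0) / (t1 - t0)))

# --- pitch-synchronous period/amplitude extraction --------------------------

# Locate per-cycle waveform peaks inside one voiced section, seeded by the
# frame-level F0 contour. Returns interpolated peak times and amplitudes.
section_cycles <- function(x, fs, t0, t1, f0_at) {
  peaks_t <- numeric(0); peaks_a <- numeric(0)
  # guide F0, clamped to the section median: frame estimates right at the
  # voiced-run edges are unreliable and would derail the peak search
  med <- stats::median(f0_at(seq(t0, t1, length.out = 21)))
  if (!is.finite(med) || med <= 0) return(NULL)
  guide <- function(t) {
    v <- f0_at(t)
    if (!is.finite(v)) return(med)
    min(max(v, 0.7 * med), 1.3 * med)
  }
  period <- 1 / guide(t0 + 1e-6)
  # first peak: global max in the first 1.5 periods
  lo <- max(1L, floor(t0 * fs) + 1L)
  hi <- min(length(x), floor((t0 + 1.5 * period) * fs))
  if (hi - lo < 3) return(NULL)
  j <- lo - 1L + which.max(x[lo:hi])
  recent <- numeric(0)  # measured periods; their median steers the search
  repeat {
    pk <- refine_peak(x, j, fs)
    if (length(peaks_t)) {
      p_new <- pk$t - peaks_t[length(peaks_t)]
      if (p_new >= 0.7 * period && p_new <= 1.3 * period) {
        recent <- c(recent, p_new)
        if (length(recent) > 5) recent <- recent[-1]
        period <- stats::median(recent)
      }
    }
    peaks_t <- c(peaks_t, pk$t); peaks_a <- c(peaks_a, pk$a)
    lo <- floor((pk$t + 0.7 * period) * fs) + 1L
    hi <- floor((pk$t + 1.3 * period) * fs) + 1L
    if (hi > min(length(x), floor(t1 * fs))) break
    if (lo >= hi) break
    j <- lo - 1L + which.max(x[lo:hi])
  }
  if (length(peaks_t) < 4) return(NULL)
  # drop onset transient cycles and the final (possibly clipped) one
  keep <- 3:(length(peaks_t) - 1L)
  list(times = peaks_t[keep], amps = peaks_a[keep])
}

refine_peak <- function(x, j, fs) {
  if (j > 1 && j < length(x)) {
    y1 <- x[j - 1]; y2 <- x[j]; y3 <- x[j + 1]
    den <- y1 - 2 * y2 + y3
    d <- if (abs(den) > 1e-300) max(min(0.5 * (y1 - y3) / den, 0.5), -0.5) else 0
    a <- y2 - 0.25 * (y1 - y3) * d
    list(t = (j - 1 + d) / fs, a = a)
  } else list(t = (j - 1) / fs, a = x[j])
}

#' Extract the 15 global prosodic features
#'
#' Features are computed per window of 15 consecutive words (a trailing
#' remainder of at least 8 words forms its own window, a smaller one is
#' merged into the previous window). Jitter and shimmer are means and
#' standard deviations over per-voiced-section values, where the periods
#' come from pitch-synchronous waveform peak picking seeded by the frame
#' F0; section counts and lengths come from [segment_sections()] restricted
#' to the window's time span; `StandDevF0` is over voiced frames, in
#' semitones. Jitter/shimmer are reported in percent.
#'
#' @inheritParams extract_local
#' @return matrix of class `voq_global` (windows x 15).
#' @export
extract_global <- function(recording, alignment, track, config = voq_config()) {
  words <- alignment$words
  words <- words[!(tolower(words$label) %in% tolower(config$filler_labels)), ,
                 drop = FALSE]
  n <- nrow(words)
  win_idx <- window_plan(n, size = 15L, min_last = 8L)
  S_s <- (attr(track, "frame_shift") %||% 160L) /
    (attr(track, "sample_rate") %||% 16000L)
  sections <- segment_sections(track)
  sec_t0 <- (sections$start_frame - 1) * S_s
  sec_t1 <- sections$end_frame * S_s
  st <- semitone_f0(track)
  centres <- frame_centres(track)
  fs <- recording$speech_rate
  f0_fun <- make_f0_interp(track)

  out <- matrix(NA_real_, nrow = length(win_idx), ncol = 15,
                dimnames = list(NULL, global_feature_names()))
  for (w in seq_along(win_idx)) {
    ids <- win_idx[[w]]
    t0 <- words$start[ids[1]]; t1 <- words$end[ids[length(ids)]]
    ov <- which(sec_t1 > t0 & sec_t0 < t1)
    vsec <- ov[sections$voiced[ov]]
    usec <- ov[!sections$voiced[ov]]
    len <- pmin(sec_t1[ov], t1) - pmax(sec_t0[ov], t0)
    vlen <- len[sections$voiced[ov]]
    ulen <- len[!sections$voiced[ov]]
    jit <- shi <- numeric(0)
    for (s in vsec) {
      cyc <- section_cycles(recording$speech, fs,
                            max(sec_t0[s], t0), min(sec_t1[s], t1), f0_fun)
      if (is.null(cyc) || length(cyc$times) < 3) next
      p <- diff(cyc$times)
      jit <- c(jit, 100 * jitter(p))
      shi <- c(shi, 100 * shimmer(cyc$amps))
    }
    vfr <- frames_in(track, t0, t1)
    vfr <- vfr[which(track$voiced[vfr])]
    span <- t1 - t0
    out[w, ] <- c(
      MeanJitter = if (length(jit)) mean(jit) else NA_real_,
      StandDevJitter = if (length(jit)) sd0(jit) else NA_real_,
      MeanShimmer = if (length(shi)) mean(shi) else NA_real_,
      StandDevShimmer = if (length(shi)) sd0(shi) else NA_real_,
      NumVoiced = length(vsec),
      MaxLenVoiced = if (length(vlen)) max(vlen) else 0,
      NumUnvoiced = length(usec),
      MaxLenUnvoiced = if (length(ulen)) max(ulen) else 0,
      RelNumVoicedUnvoiced = length(vsec) / max(1L, length(usec)),
      RelLenVoicedSignal = sum(vlen) / span,
      RelLenUnvoicedSignal = sum(ulen) / span,
      StandDevF0 = if (length(vfr) > 1) stats::sd(st[vfr]) else 0,
      MeanLenVoiced = if (length(vlen)) mean(vlen) else 0,
      MeanLenUnvoiced = if (length(ulen)) mean(ulen) else 0,
      RelLenVoicedUnvoiced = sum(vlen) / max(S_s, sum(ulen))
    )
  }
  class(out) <- c("voq_global", class(out))
  out
}

sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0

window_plan <- function(n, size = 15L, min_last = 8L) {
  if (n <= size) return(list(seq_len(n)))
  n_full <- n %/% size
  rem <- n %% size
  idx <- split(seq_len(n_full * size), rep(seq_len(n_full), each = size))
  idx <- unname(idx)
  if (rem >= min_last) idx <- c(idx, list(n_full * size + seq_len(rem)))
  else if (rem > 0) idx[[n_full]] <- c(idx[[n_full]], n_full * size + seq_len(rem))
  idx
}

make_f0_interp <- function(track) {
  v <- which(track$voiced & is.finite(track$f0))
  if (length(v) < 2) {
    val <- if (length(v)) track$f0[v] else NA_real_
    return(function(t) rep(val, length(t)))
  }
  tc <- frame_centres(track)[v]
  f <- track$f0[v]
  function(t) stats::approx(tc, f, t, rule = 2)$y
}

#' Aggregate word- and window-level features to one recording vector
#'
#' Per-feature mean over words (local) and windows (global), skipping
#' missing-coded entries; CFx/CQx appended when an EGG summary is given.
#'
#' @param locals `voq_local` matrix from [extract_local()].
#' @param globals `voq_global` matrix from [extract_global()].
#' @param egg_summary optional `voq_egg_summary` (see [egg_summary()]).
#' @return named numeric vector of length 48 (plus CFx, CQx when present).
#' @export
aggregate_features <- function(locals, globals, egg_summary = NULL) {
  agg <- function(m) {
    v <- colMeans(m, na.rm = TRUE)
    v[is.nan(v)] <- NA_real_
    v
  }
  out <- c(agg(locals), agg(globals))
  if (!is.null(egg_summary))
    out <- c(out, CFx = egg_summary$cfx, CQx = egg_summary$cqx)
  out
}
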