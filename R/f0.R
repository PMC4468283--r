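# Frame-based analysis of the 16 kHz speech signal: short-time energy,
# voiced/unvoiced decision, F0 estimation by normalized cross-correlation
# with octave-error control, and voiced/unvoiced segmentation.

#' Default analysis configuration
#'
#' @param ... overrides for individual entries.
#' @return list of analysis parameters: 16 ms frames with 10 ms shift,
#'   F0 search range 50-500 Hz, voicing thresholds (`v_thresh` on the
#'   normalized correlation peak, `e_thresh` relative to the recording's
#'   median frame energy), octave-fold tolerance, contact-quotient level,
#'   and the filled-pause label set.
#' @export
voq_config <- function(...) {
  cfg <- list(
    frame_length = 0.016, frame_shift = 0.010,
    f0_min = 50, f0_max = 500,
    v_thresh = 0.45, e_thresh = 0.1,
    octave_tol = 0.04, median_window = 5L,
    cq_level = 0.3, egg_invert = FALSE,
    dEGG_thresh = 0.3,
    filler_labels = c("\u00e4h", "\u00e4hm", "hm"),
    svr_C = 1.0, svr_epsilon = 0.001, svr_tol = 1e-3,
    cfs_folds = 10L, cfs_min_freq = 0.5
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

frame_starts <- function(n, frame_len, shift) {
  if (n < frame_len)
    voq_stop("voq_empty_track", "signal shorter than one frame")
  n_frames <- floor((n - frame_len) / shift) + 1L
  1L + (seq_len(n_frames) - 1L) * shift
}

#' Frame a recording's speech signal
#'
#' @param recording a `voq_recording` (speech at 16 kHz).
#' @param config see [voq_config()].
#' @return a `voq_track` data.frame with one row per frame: `frame`, `time`
#'   (frame start, s), `energy` (RMS), `voiced` (NA until
#'   [detect_voicing()]), `f0` (NA until [estimate_f0()]). Frame geometry is
#'   kept in attributes.
#' @export
frame_signal <- function(recording, config = voq_config()) {
  fs <- recording$speech_rate
  W <- round(config$frame_length * fs)
  S <- round(config$frame_shift * fs)
  x <- recording$speech
  starts <- frame_starts(length(x), W, S)
  idx <- outer(starts, 0:(W - 1L), "+")
  energy <- sqrt(rowMeans(matrix(x[idx], nrow = length(starts))^2))
  track <- data.frame(frame = seq_along(starts),
                      time = (starts - 1L) / fs,
                      energy = energy,
                      voiced = NA, f0 = NA_real_)
  attr(track, "frame_length") <- W
  attr(track, "frame_shift") <- S
  attr(track, "sample_rate") <- fs
  class(track) <- c("voq_track", "data.frame")
  track
}

# Normalized cross-correlation of each frame window against its own
# lag-shifted continuation, over all candidate F0 lags. Returns an
# n_frames x n_lags matrix (0 where the lag runs past the signal).
ncc_matrix <- function(x, starts, W, lags) {
  n <- length(x)
  xp <- c(x, numeric(max(lags) + W))  # zero pad for trailing frames
  idx0 <- outer(starts, 0:(W - 1L), "+")
  X0 <- matrix(xp[idx0], nrow = length(starts))
  e0 <- rowSums(X0^2)
  out <- matrix(0, nrow = length(starts), ncol = length(lags))
  for (j in seq_along(lags)) {
    Xl <- matrix(xp[idx0 + lags[j]], nrow = length(starts))
    el <- rowSums(Xl^2)
    out[, j] <- rowSums(X0 * Xl) / sqrt(pmax(e0 * el, 1e-300))
  }
  # frames whose lagged window would exceed the true signal end are damped
  # proportionally to the missing fraction by the zero padding itself
  out
}

track_ncc <- function(track, recording, config) {
  fs <- attr(track, "sample_rate")
  W <- attr(track, "frame_length")
  S <- attr(track, "frame_shift")
  lags <- seq.int(floor(fs / config$f0_max), ceiling(fs / config$f0_min))
  starts <- 1L + (track$frame - 1L) * S
  list(ncc = ncc_matrix(recording$speech, starts, W, lags), lags = lags)
}

#' Voiced/unvoiced decision per frame
#'
#' A frame is voiced when its normalized autocorrelation peak inside the F0
#' search range reaches `v_thresh` and its energy reaches `e_thresh` times
#' the recording's median frame energy (so the decision is invariant to
#' overall gain).
#'
#' @param track a `voq_track` from [frame_signal()].
#' @param recording the corresponding `voq_recording`.
#' @param config see [voq_config()].
#' @return the track with the `voiced` flags filled in.
#' @export
detect_voicing <- function(track, recording, config = voq_config()) {
  nc <- track_ncc(track, recording, config)
  peak <- apply(nc$ncc, 1, max)
  e_med <- stats::median(track$energy)
  track$voiced <- (peak >= config$v_thresh) &
    (track$energy >= config$e_thresh * e_med) &
    (track$energy > 0)
  attr(track, "ncc") <- nc$ncc
  attr(track, "lags") <- nc$lags
  track
}

#' Fold octave errors in an F0 contour
#'
#' A frame whose F0 lies within `tol` (relative) of double, triple, half or
#' a third of the consensus of both neighbours is folded back to the
#' consensus octave; any change is thus by a factor in \{1/3, 1/2, 2, 3\}.
#' Frames whose neighbours disagree are left alone.
#'
#' @param f0 numeric F0 contour of one voiced run (Hz).
#' @param tol relative tolerance for recognizing an octave relation.
#' @export
correct_octave_jumps <- function(f0, tol = 0.04) {
  n <- length(f0)
  if (n < 3) return(f0)
  out <- f0
  for (i in 2:(n - 1)) {
    a <- out[i - 1]; b <- out[i + 1]
    if (!is.finite(a) || !is.finite(b)) next
    if (abs(a - b) / mean(c(a, b)) > 2 * tol) next  # neighbours disagree
    cons <- mean(c(a, b))
    for (k in c(2, 3, 0.5, 1/3)) {
      if (is.finite(out[i]) && abs(out[i] - k * cons) <= tol * k * cons) {
        out[i] <- out[i] / k
        break
      }
    }
  }
  out
}

#' Estimate F0 on voiced frames
#'
#' Per voiced frame, F0 is the sample rate over the best lag of the
#' normalized cross-correlation within \[f0_min, f0_max\], with parabolic
#' lag interpolation; ties are broken toward the longer lag (biasing
#' against octave-up errors). Octave jumps relative to the neighbour
#' consensus are folded back, then the contour is median-smoothed (window
#' 5) within each voiced run.
#'
#' @inheritParams detect_voicing
#' @return the track with `f0` filled on voiced frames (NA elsewhere).
#' @export
estimate_f0 <- function(track, recording, config = voq_config()) {
  if (all(is.na(track$voiced)))
    track <- detect_voicing(track, recording, config)
  ncc <- attr(track, "ncc")
  lags <- attr(track, "lags")
  if (is.null(ncc)) {
    nc <- track_ncc(track, recording, config)
    ncc <- nc$ncc; lags <- nc$lags
  }
  fs <- attr(track, "sample_rate")
  f0 <- rep(NA_real_, nrow(track))
  vi <- which(track$voiced)
  for (i in vi) {
    row <- ncc[i, ]
    m <- max(row)
    # a periodic frame correlates equally well at every multiple of its
    # period: take the shortest lag among near-maximal local peaks, with
    # exact ties broken toward the longer lag
    nl <- length(row)
    is_peak <- c(FALSE, row[2:(nl - 1)] >= row[1:(nl - 2)] &
                        row[2:(nl - 1)] >= row[3:nl], FALSE)
    cand <- which(is_peak & row >= 0.93 * m)
    j <- if (length(cand)) {
      top <- cand[abs(row[cand] - row[cand[1]]) < 1e-12]
      if (length(top) > 1) max(top) else cand[1]
    } else which.max(row)
    lag <- lags[j]
    if (j > 1 && j < length(lags)) {
      y1 <- row[j - 1]; y2 <- row[j]; y3 <- row[j + 1]
      den <- y1 - 2 * y2 + y3
      if (abs(den) > 1e-12) {
        d <- 0.5 * (y1 - y3) / den
        lag <- lag + max(min(d, 0.5), -0.5)
      }
    }
    f0[i] <- fs / lag
  }
  f0 <- pmin(pmax(f0, config$f0_min), config$f0_max)
  # per voiced run: octave folding, then median smoothing
  r <- rle(track$voiced)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    seg <- starts[k]:ends[k]
    v <- correct_octave_jumps(f0[seg], config$octave_tol)
    if (length(v) >= config$median_window)
      v <- stats::runmed(v, config$median_window, endrule = "median")
    f0[seg] <- v
  }
  track$f0 <- ifelse(track$voiced, f0, NA_real_)
  track
}

#' Segment a track into maximal voiced/unvoiced sections
#'
#' @param track a `voq_track` with voicing flags set.
#' @return data.frame of class `voq_sections`: one row per maximal run with
#'   `start_frame`, `end_frame` (inclusive), `voiced`, `n_frames` and
#'   `length_s` (frames times the frame shift).
#' @export
segment_sections <- function(track) {
  stopifnot(!all(is.na(track$voiced)))
  S <- attr(track, "frame_shift") %||% 160L
  fs <- attr(track, "sample_rate") %||% 16000L
  r <- rle(as.logical(track$voiced))
  ends <- cumsum(r$lengths)
  out <- data.frame(start_frame = ends - r$lengths + 1L,
                    end_frame = ends,
                    voiced = r$values,
                    n_frames = r$lengths)
  out$length_s <- out$n_frames * S / fs
  class(out) <- c("voq_sections", "data.frame")
  out
}

#' Full frame-level analysis of a recording
#'
#' Convenience wrapper: [frame_signal()], [detect_voicing()],
#' [estimate_f0()].
#' @inheritParams detect_voicing
#' @export
analyze_track <- function(recording, config = voq_config()) {
  track <- frame_signal(recording, config)
  track <- detect_voicing(track, recording, config)
  estimate_f0(track, recording, config)
}

#' Write a track dump as TSV (frame, time, energy, voiced, f0)
#' @param track a `voq_track`.
#' @param path output path.
#' @export
write_track <- function(track, path) {
  lines <- c("frame\ttime\tenergy\tvoiced\tf0",
             sprintf("%d\t%s\t%s\t%d\t%s", track$frame,
                     fmt_num(track$time), fmt_num(track$energy),
                     as.integer(track$voiced), fmt_num(track$f0)))
  writeLines(lines, path)
  invisible(path)
}
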