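# Electroglottographic cycle detection and the irregularity summaries
# CFx (cycle-to-cycle variation of the period frequency Fx) and CQx
# (cycle-to-cycle variation of the contact quotient Qx), both in percent.

#' Detect vocal-fold cycles in an EGG signal
#'
#' Closure instants are positive peaks of the differentiated EGG exceeding
#' an adaptive threshold (a fraction of the rolling 95th percentile of the
#' positive dEGG), with a minimum separation of 1/f0_max. Cycles whose
#' implied Fx falls outside \[f0_min, f0_max\] are discarded, and partial
#' cycles at the signal edges are dropped: the analysis is
#' period-synchronous and uses full cycles only.
#'
#' @param egg numeric EGG waveform (increasing vocal-fold contact should
#'   increase amplitude; set `config$egg_invert = TRUE` otherwise).
#' @param sample_rate sampling rate of `egg` in Hz (>= 8000).
#' @param config see [voq_config()].
#' @return object of class `voq_cycles`: data.frame with `closure` (s),
#'   `period` (s), `fx` (Hz) and `qx` (percent, NA until
#'   [contact_quotient()]).
#' @export
detect_cycles <- function(egg, sample_rate, config = voq_config()) {
  fs <- sample_rate
  if (fs < 8000) voq_stop("voq_config_error", "EGG must be sampled >= 8 kHz")
  if (isTRUE(config$egg_invert)) egg <- -egg
  d <- c(diff(egg), 0) * fs
  dpos <- pmax(d, 0)
  thr <- rolling_q95(dpos, fs, win_s = 1.0, hop_s = 0.25) * config$dEGG_thresh
  # local maxima of dEGG above the adaptive threshold
  n <- length(d)
  cand <- which(d[2:(n - 1)] > d[1:(n - 2)] & d[2:(n - 1)] >= d[3:n]) + 1L
  cand <- cand[d[cand] > thr[cand] & d[cand] > 0]
  if (length(cand) < 3)
    voq_stop("voq_empty_series", "fewer than 2 valid EGG cycles")
  # enforce minimum separation, keeping the larger peak
  min_sep <- floor(fs / config$f0_max)
  cand <- cand[order(d[cand], decreasing = TRUE)]
  keep <- logical(0); kept <- integer(0)
  for (j in cand) {
    if (!length(kept) || all(abs(kept - j) >= min_sep)) kept <- c(kept, j)
  }
  kept <- sort(kept)
  # sub-sample refinement of the dEGG peak position
  closure <- vapply(kept, function(j) refine_peak(d, j, fs)$t, 1)
  periods <- diff(closure)
  fx <- 1 / periods
  ok <- fx >= config$f0_min & fx <= config$f0_max
  cyc <- data.frame(closure = closure[-length(closure)][ok],
                    period = periods[ok], fx = fx[ok], qx = NA_real_)
  if (nrow(cyc) < 2)
    voq_stop("voq_empty_series", "fewer than 2 valid EGG cycles")
  attr(cyc, "sample_rate") <- fs
  class(cyc) <- c("voq_cycles", "data.frame")
  cyc
}

rolling_q95 <- function(x, fs, win_s = 1.0, hop_s = 0.25) {
  n <- length(x)
  win <- min(n, round(win_s * fs))
  hop <- max(1L, round(hop_s * fs))
  starts <- seq(1L, max(1L, n - win + 1L), by = hop)
  q <- vapply(starts, function(s)
    stats::quantile(x[s:min(n, s + win - 1L)], 0.95, names = FALSE), 1)
  centres <- starts + win / 2
  if (length(starts) == 1) return(rep(q, n))
  stats::approx(centres, q, seq_len(n), rule = 2)$y
}

#' Per-cycle contact quotient Qx
#'
#' Within each detected cycle the EGG amplitude is normalized to \[0, 1\]
#' between the cycle minimum and maximum; the closed phase is the total
#' time spent above `level` and Qx = closed phase / period x 100.
#' Flat cycles (max = min) are skipped.
#'
#' @param egg the EGG waveform used for [detect_cycles()].
#' @param cycles a `voq_cycles` object.
#' @param level normalized contact threshold in (0, 1); default
#'   `config$cq_level` (0.3).
#' @param config see [voq_config()].
#' @return the cycle series with `qx` filled in.
#' @export
contact_quotient <- function(egg, cycles, level = NULL,
                             config = voq_config()) {
  level <- level %||% config$cq_level
  stopifnot(level > 0, level < 1)
  if (isTRUE(config$egg_invert)) egg <- -egg
  fs <- attr(cycles, "sample_rate")
  qx <- rep(NA_real_, nrow(cycles))
  for (i in seq_len(nrow(cycles))) {
    a <- floor(cycles$closure[i] * fs) + 1L
    b <- min(length(egg), floor((cycles$closure[i] + cycles$period[i]) * fs) + 1L)
    if (b - a < 3) next
    seg <- egg[a:b]
    mn <- min(seg); mx <- max(seg)
    if (mx - mn < 1e-12) next
    norm <- (seg - mn) / (mx - mn)
    qx[i] <- 100 * sum(norm >= level) / length(seg) *
      (length(seg) / fs) / cycles$period[i]
  }
  cycles$qx <- qx
  cycles
}

#' Cycle-to-cycle irregularity of the period frequency (CFx, percent)
#'
#' 100 x mean absolute successive Fx difference over the mean Fx.
#' @param cycles a `voq_cycles` object (>= 2 cycles).
#' @export
cfx <- function(cycles) {
  fx <- cycles$fx
  if (length(fx) < 2) voq_stop("voq_undefined", "need >= 2 cycles for CFx")
  100 * rel_perturbation(fx)
}

#' Cycle-to-cycle irregularity of the contact quotient (CQx, percentage points)
#'
#' Mean absolute successive Qx difference; since Qx is already a percent,
#' CQx is in percentage points.
#' @param cycles a `voq_cycles` object with `qx` computed.
#' @export
cqx <- function(cycles) {
  qx <- cycles$qx[is.finite(cycles$qx)]
  if (length(qx) < 2) voq_stop("voq_undefined", "need >= 2 cycles with Qx")
  mean(abs(diff(qx)))
}

#' Summarize an EGG channel into CFx/CQx
#'
#' Runs [detect_cycles()] and [contact_quotient()] and reduces to the
#' summary pair.
#' @param egg numeric EGG waveform.
#' @param sample_rate its rate in Hz.
#' @param config see [voq_config()].
#' @return object of class `voq_egg_summary`: list(cfx, cqx, n_cycles).
#' @export
egg_summary <- function(egg, sample_rate, config = voq_config()) {
  cyc <- detect_cycles(egg, sample_rate, config)
  cyc <- contact_quotient(egg, cyc, config = config)
  structure(list(cfx = cfx(cyc), cqx = cqx(cyc), n_cycles = nrow(cyc)),
            class = "voq_egg_summary")
}

#' @export
print.voq_egg_summary <- function(x, ...) {
  cat(sprintf("<voq_egg_summary: CFx = %.2f%%, CQx = %.2f, n = %d cycles>\n",
              x$cfx, x$cqx, x$n_cycles))
  invisible(x)
}

#' @export
print.voq_cycles <- function(x, ...) {
  cat(sprintf("<voq_cycles: %d cycles, Fx %.1f-%.1f Hz>\n",
              nrow(x), min(x$fx), max(x$fx)))
  invisible(x)
}
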