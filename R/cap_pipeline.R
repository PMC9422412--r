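## CAP extraction pipeline: offline band-pass, polarity averaging, N1/P1
## peak picking in the 0-10 ms window, baseline estimation and the
## two-times-baseline threshold rule.

# Butterworth biquad cascade (second-order sections) via the bilinear
# transform. A 6th-order high-pass at 200 Hz on a 100 kHz clock is severely
# ill-conditioned as a single transfer function (tiny input perturbations
# are amplified ~1e9-fold); factoring it into conjugate-pole-pair sections
# keeps the recursion numerically benign.
butter_sections <- function(order, fc, fs, type = c("high", "low")) {
  type <- match.arg(type)
  if (order %% 2 != 0) stop("even filter order required")
  t <- tan(pi * fc / fs)  # prewarped edge
  lapply((2 * seq_len(order / 2) - 1) * pi / (2 * order), function(phi) {
    a1 <- 2 * sin(phi)
    d0 <- 1 / t^2 + a1 / t + 1
    d1 <- 2 - 2 / t^2
    d2 <- 1 / t^2 - a1 / t + 1
    b <- if (type == "high") c(1, -2, 1) / t^2 else c(1, 2, 1)
    list(b = b / d0, a = c(1, d1 / d0, d2 / d0))
  })
}

# Zero-phase filtering with odd-reflection padding long enough for the
# 200 Hz edge's transients to die inside the pad, so trace boundaries stay
# clean (naive filtfilt leaks an edge transient several uV into the first
# milliseconds, which would corrupt the baseline window). Operates
# column-wise on a matrix of traces so a whole recording set can be
# filtered in one pass.
zero_phase_filter <- function(sections, x, sample_rate, low_edge) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  pad <- min(n - 1, ceiling(4 * sample_rate / low_edge))
  top <- 2 * matrix(x[1, ], pad, m, byrow = TRUE) - x[seq(pad + 1, 2), , drop = FALSE]
  bot <- 2 * matrix(x[n, ], pad, m, byrow = TRUE) - x[seq(n - 1, n - pad), , drop = FALSE]
  xp <- rbind(top, x, bot)
  one_pass <- function(z, sec) {
    nr <- nrow(z)
    z <- matrix(as.numeric(stats::filter(z, sec$b, method = "convolution",
                                         sides = 1)), nr, m)
    z[1:2, ] <- 0   # convolution start-up NAs, deep inside the pad
    z <- matrix(as.numeric(stats::filter(z, -sec$a[-1], method = "recursive")),
                nr, m)
    z[seq(nr, 1), , drop = FALSE]
  }
  for (sec in sections) {
    xp <- one_pass(xp, sec)   # forward, reversed on return
    xp <- one_pass(xp, sec)   # backward, restored order
  }
  out <- xp[pad + seq_len(n), , drop = FALSE]
  if (vec) as.numeric(out) else out
}

#' Zero-phase offline band-pass filter
#'
#' 6th-order Butterworth band edges at 200 Hz and 5 kHz, implemented as a
#' cascade of second-order sections (high-pass then low-pass), each applied
#' forward-backward (`signal::filtfilt`), so the response is zero-phase and
#' peak latencies are not group-delay shifted. The mean (DC) is removed
#' before filtering. Magnitude per pass follows the Butterworth form
#' `(1 + (f_c/f)^(2*order))^(-1/2)` at the high-pass edge (and its mirror
#' at the low-pass edge); the squared response applies after the
#' forward-backward pass.
#'
#' Being non-causal, the zero-phase filter smears response energy backward
#' in time: the few milliseconds of pre-stimulus trace right before onset
#' are contaminated by large responses, which is why the pipeline keeps a
#' guard gap between the baseline window and stimulus onset (see
#' [analyze_recording_set()]).
#'
#' @param waveform Numeric trace.
#' @param sample_rate Sampling rate, Hz; must exceed `2 * high`.
#' @param low,high Band edges, Hz.
#' @param order Butterworth order per edge.
#' @return Filtered trace, same length.
#' @export
bandpass_offline <- function(waveform, sample_rate, low = 200, high = 5000,
                             order = 6) {
  if (high >= sample_rate / 2 || low <= 0 || low >= high)
    stop("band edges must satisfy 0 < low < high < sample_rate / 2")
  # centre on the median, not the mean: a large CAP occupying a minority of
  # samples would bias the mean and put a DC step (hence a high-pass edge
  # transient) at the trace boundaries, right in the baseline window
  w <- waveform - stats::median(waveform)
  zero_phase_filter(c(butter_sections(order, low, sample_rate, "high"),
                      butter_sections(order, high, sample_rate, "low")),
                    w, sample_rate, low)
}

#' Average condensation and rarefaction responses
#'
#' Sample-wise mean of the two polarity traces; stimulus-following
#' components (the cochlear microphonic) cancel exactly, CAPs are preserved.
#'
#' @param cond_waveform,rare_waveform Equal-length traces.
#' @return Averaged trace.
#' @export
polarity_average <- function(cond_waveform, rare_waveform) {
  if (length(cond_waveform) != length(rare_waveform))
    stop("polarity traces differ in length")
  (cond_waveform + rare_waveform) / 2
}

#' Extract the CAP from an averaged trace
#'
#' Within the 0-10 ms post-onset window, N1 is the global minimum and P1
#' the global maximum occurring after N1; the response size is their
#' peak-to-peak difference.
#'
#' @param averaged_waveform Polarity-averaged (and typically filtered) trace.
#' @param onset_index Sample index of stimulus onset (first post-onset
#'   sample).
#' @param sample_rate Sampling rate, Hz.
#' @param window_ms Analysis window after onset, ms.
#' @return List of class `cap_response`: `n1_latency` and `p1_latency` (ms
#'   re onset), `p2p_amplitude` (µV).
#' @export
extract_cap <- function(averaged_waveform, onset_index, sample_rate,
                        window_ms = c(0, 10)) {
  i0 <- onset_index + round(window_ms[1] / 1000 * sample_rate)
  i1 <- onset_index + round(window_ms[2] / 1000 * sample_rate) - 1
  if (i1 > length(averaged_waveform))
    stop("trace does not cover the analysis window")
  seg <- averaged_waveform[i0:i1]
  i_n1 <- which.min(seg)
  i_p1 <- i_n1 - 1 + which.max(seg[i_n1:length(seg)])
  structure(list(
    n1_latency = (i0 + i_n1 - 1 - onset_index + 0.5) / sample_rate * 1000,
    p1_latency = (i0 + i_p1 - 1 - onset_index + 0.5) / sample_rate * 1000,
    p2p_amplitude = seg[i_p1] - seg[i_n1]
  ), class = "cap_response")
}

#' Baseline amplitude of a trace
#'
#' Peak-to-peak amplitude of the pre-stimulus segment of the same averaged
#' trace; the reference against which the two-times-baseline threshold rule
#' is applied.
#'
#' @param averaged_waveform Trace (already filtered like the analysis
#'   window).
#' @param pre_stimulus_n Number of pre-stimulus samples at the start of the
#'   trace.
#' @param sample_rate Sampling rate, Hz; the segment must span at least 2 ms.
#' @return Baseline peak-to-peak amplitude, µV.
#' @export
estimate_baseline <- function(averaged_waveform, pre_stimulus_n, sample_rate) {
  if (pre_stimulus_n < 2e-3 * sample_rate)
    stop("pre-stimulus segment must span at least 2 ms")
  seg <- averaged_waveform[seq_len(pre_stimulus_n)]
  max(seg) - min(seg)
}

#' CAP threshold from a level series
#'
#' The threshold is the lowest stimulus level whose CAP peak-to-peak
#' amplitude is at least twice the baseline amplitude (inclusive). A
#' numerical floor of 0.1 µV guards the criterion against a degenerate
#' zero baseline. If no level qualifies the cell is censored and the
#' threshold recorded as `max(levels) + l_step` for arithmetic.
#'
#' @param p2p Peak-to-peak amplitudes (µV), one per level, ascending levels.
#' @param baseline Baseline amplitude(s), µV: a scalar, or one value per
#'   level (per-trace baselines).
#' @param levels Stimulus levels, dB SPL, ascending on the lattice.
#' @param l_step Lattice step used for the censored value; defaults to the
#'   level spacing.
#' @return List: `threshold` (dB SPL), `censored` (logical).
#' @export
estimate_threshold <- function(p2p, baseline, levels,
                               l_step = if (length(levels) > 1) diff(levels[1:2]) else 10) {
  if (length(p2p) == 0) stop("empty level series")
  if (length(p2p) != length(levels)) stop("p2p and levels differ in length")
  if (!length(baseline) %in% c(1L, length(levels)))
    stop("baseline must be scalar or one value per level")
  if (is.unsorted(levels, strictly = TRUE)) stop("levels must be ascending")
  criterion <- pmax(2 * baseline, 0.1)
  hit <- which(p2p >= criterion)
  if (length(hit) == 0)
    list(threshold = max(levels) + l_step, censored = TRUE)
  else
    list(threshold = levels[min(hit)], censored = FALSE)
}

#' Thresholds and suprathreshold amplitudes of one recording set
#'
#' Runs the full offline chain on every (frequency, level) cell: polarity
#' averaging, zero-phase 200 Hz - 5 kHz band-pass, baseline estimation on
#' the pre-stimulus segment, N1/P1 extraction in the 0-10 ms window, and
#' the two-times-baseline threshold rule per frequency.
#'
#' Because the zero-phase filter spreads response energy backward in time,
#' the baseline window ends `baseline_guard` seconds before stimulus onset;
#' the default 8 ms guard keeps the backward smear of large CAPs out of the
#' baseline estimate. The threshold criterion uses, per frequency, the
#' median baseline amplitude of the three lowest-level traces
#' (`baseline = "pooled"`, default): those traces are response-free, so
#' their pre-stimulus peak-to-peak is an uncontaminated noise-floor
#' estimate, robust against single-trace excursions and against the
#' residual backward smear that large responses leave even ahead of the
#' guard. `baseline = "per_trace"` applies each trace's own baseline
#' instead.
#'
#' @param rs A [synth_recording_set()] (or a compatible object read from a
#'   bundle).
#' @param low,high,order Band-pass settings, see [bandpass_offline()].
#' @param baseline_guard Gap (s) between the end of the baseline window and
#'   stimulus onset.
#' @param baseline Baseline pooling for the threshold criterion.
#' @return List of class `threshold_matrix`: `ear_id`, `condition`,
#'   `frequencies`, `levels`, `threshold` (dB SPL per frequency),
#'   `censored` (flag per frequency), and `p2p` (matrix level x frequency,
#'   µV).
#' @export
analyze_recording_set <- function(rs, low = 200, high = 5000, order = 6,
                                  baseline_guard = 0.008,
                                  baseline = c("pooled", "per_trace")) {
  baseline <- match.arg(baseline)
  freqs <- rs$grid$frequencies
  levels <- rs$grid$levels
  fs <- rs$sample_rate
  n_pre <- round(rs$pre_stimulus * fs)
  if (high >= fs / 2 || low <= 0 || low >= high)
    stop("band edges must satisfy 0 < low < high < sample_rate / 2")
  n_base <- max(round(2e-3 * fs), n_pre - round(baseline_guard * fs))
  onset <- n_pre + 1
  d <- dim(rs$waveforms)
  # polarity averages of all (level, frequency) cells, filtered in one pass
  avg <- (rs$waveforms[, 1, , ] + rs$waveforms[, 2, , ]) / 2
  avg <- matrix(avg, d[1], d[3] * d[4])
  avg <- sweep(avg, 2, apply(avg, 2, stats::median))
  filt <- zero_phase_filter(c(butter_sections(order, low, fs, "high"),
                              butter_sections(order, high, fs, "low")),
                            avg, fs, low)
  base <- matrix(apply(filt[seq_len(n_base), , drop = FALSE], 2,
                       function(x) max(x) - min(x)),
                 length(levels), length(freqs))
  p2p <- matrix(apply(filt, 2, function(x)
    extract_cap(x, onset, fs)$p2p_amplitude),
    length(levels), length(freqs), dimnames = list(levels, freqs))
  n_quiet <- min(3, length(levels))
  thr <- vapply(seq_along(freqs), function(fi) {
    crit <- if (baseline == "pooled")
      stats::median(base[seq_len(n_quiet), fi]) else base[, fi]
    unlist(estimate_threshold(p2p[, fi], crit, levels))
  }, c(threshold = 0, censored = 0))
  structure(list(ear_id = rs$ear_id, condition = rs$condition,
                 frequencies = freqs, levels = levels,
                 threshold = stats::setNames(thr["threshold", ], freqs),
                 censored = stats::setNames(thr["censored", ] > 0, freqs),
                 p2p = p2p),
            class = "threshold_matrix")
}

#' @export
print.threshold_matrix <- function(x, ...) {
  cat(sprintf("CAP thresholds, %s / %s (%d censored):\n",
              x$ear_id, x$condition, sum(x$censored)))
  print(round(x$threshold))
  invisible(x)
}
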