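#' Build the tone-burst stimulus lattice
#'
#' Constructs the frequency x level stimulus grid used for extracochlear
#' CAP recordings: log-spaced tone-burst frequencies (a fixed number of
#' steps per octave) crossed with a linear ladder of sound pressure levels.
#' Every cell of the grid is presented in both stimulus polarities
#' (condensation and rarefaction) so that the cochlear microphonic can be
#' cancelled by averaging.
#'
#' @param f_min,f_max Lowest and highest tone-burst frequency (Hz).
#'   `f_max/f_min` must be a power of two raised to an integer number of
#'   `steps_per_octave` steps.
#' @param steps_per_octave Number of frequency steps per octave.
#' @param l_min,l_max,l_step Level ladder in dB SPL; `l_step` must divide
#'   `l_max - l_min`.
#' @param burst_duration Tone-burst duration in seconds.
#' @param ramp_duration Cosine rise/fall duration in seconds; the two ramps
#'   may not exceed the burst (`2 * ramp_duration <= burst_duration`).
#' @param sample_rate Sampling rate of the synthesized/recorded waveforms
#'   (Hz). The default 100 kHz keeps the highest stimulus frequency well
#'   below Nyquist before offline filtering.
#' @param n_averages Number of stimulus presentations averaged per trace.
#'
#' @return An object of class `stimulus_grid`: a list with `frequencies`
#'   (Hz, strictly increasing), `levels` (dB SPL), and the burst/sampling
#'   metadata.
#' @export
#' @examples
#' g <- stimulus_grid()
#' length(g$frequencies)  # 17: four octaves at four steps per octave
#' g$frequencies[9]       # 8000 Hz, two octaves above 2 kHz
stimulus_grid <- function(f_min = 2000, f_max = 32000, steps_per_octave = 4,
                          l_min = 0, l_max = 90, l_step = 10,
                          burst_duration = 0.005, ramp_duration = 0.0025,
                          sample_rate = 1e5, n_averages = 20) {
  if (f_min <= 0 || f_max <= 0) stop("frequencies must be positive")
  if (f_max <= f_min) stop("f_max must exceed f_min")
  if (steps_per_octave < 1) stop("steps_per_octave must be >= 1")
  n_steps <- log2(f_max / f_min) * steps_per_octave
  if (abs(n_steps - round(n_steps)) > 1e-8)
    stop("f_max must be an integer number of steps above f_min")
  n_steps <- round(n_steps)
  if (l_step <= 0) stop("l_step must be positive")
  n_lev <- (l_max - l_min) / l_step
  if (abs(n_lev - round(n_lev)) > 1e-8)
    stop("l_step must divide l_max - l_min")
  if (2 * ramp_duration > burst_duration + 1e-12)
    stop("2 * ramp_duration must not exceed burst_duration")
  structure(list(
    frequencies = f_min * 2^((0:n_steps) / steps_per_octave),
    levels = seq(l_min, l_max, by = l_step),
    steps_per_octave = steps_per_octave,
    burst_duration = burst_duration,
    ramp_duration = ramp_duration,
    sample_rate = sample_rate,
    n_averages = n_averages
  ), class = "stimulus_grid")
}

#' @export
print.stimulus_grid <- function(x, ...) {
  cat(sprintf(
    "Stimulus grid: %d frequencies (%.3g-%.3g kHz, %d/octave) x %d levels (%g-%g dB SPL)\n",
    length(x$frequencies), min(x$frequencies) / 1000, max(x$frequencies) / 1000,
    x$steps_per_octave, length(x$levels), min(x$levels), max(x$levels)))
  cat(sprintf("  burst %g ms (ramps %g ms), fs %g kHz, %d averages\n",
              1000 * x$burst_duration, 1000 * x$ramp_duration,
              x$sample_rate / 1000, x$n_averages))
  invisible(x)
}

# Raised-cosine on/off envelope for a burst of n samples with nr ramp samples.
burst_envelope <- function(n, nr) {
  env <- rep(1, n)
  if (nr > 0) {
    up <- 0.5 * (1 - cos(pi * (seq_len(nr) - 0.5) / nr))
    env[seq_len(nr)] <- up
    env[n + 1 - seq_len(nr)] <- up
  }
  env
}

#' Synthesize one tone burst
#'
#' Cosine-ramped sinusoid at a grid frequency. The rarefaction burst is the
#' exact negation of the condensation burst, so averaging responses to the
#' two polarities cancels any component that follows the stimulus waveform
#' (the cochlear microphonic).
#'
#' @param frequency Tone frequency in Hz; must be below Nyquist.
#' @param polarity `+1` (condensation) or `-1` (rarefaction).
#' @param grid A [stimulus_grid()].
#' @return Numeric waveform (unit peak amplitude), `burst_duration` long at
#'   `grid$sample_rate`.
#' @export
tone_burst <- function(frequency, polarity = 1, grid = stimulus_grid()) {
  if (!polarity %in% c(-1, 1)) stop("polarity must be +1 or -1")
  if (frequency >= grid$sample_rate / 2)
    stop("frequency at or above Nyquist for this grid")
  if (frequency <= 0) stop("frequency must be positive")
  n <- round(grid$burst_duration * grid$sample_rate)
  nr <- round(grid$ramp_duration * grid$sample_rate)
  t <- (seq_len(n) - 0.5) / grid$sample_rate
  polarity * sin(2 * pi * frequency * t) * burst_envelope(n, nr)
}
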