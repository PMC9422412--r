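#' Frequency-dependent insertion trauma profile
#'
#' Parameterizes the threshold elevation caused by electrode insertion as a
#' smooth logistic ramp on the log-frequency axis: low (apical) frequencies
#' are spared, frequencies at and basal to the electrode apex are shifted by
#' up to `ts_max` dB. `f_edge` is the frequency of half-maximal shift and
#' `slope_w` the transition width in octaves.
#'
#' @param ts_max Maximal threshold shift (dB), `>= 0`.
#' @param f_edge Frequency of half-maximal shift (Hz); must lie within the
#'   2-32 kHz analysis span.
#' @param slope_w Transition width in octaves (`> 0`): one octave of
#'   log-frequency per logistic unit times `slope_w`.
#' @param cochleostomy_jitter_sd SD (dB) of the small zero-mean threshold
#'   jitter attributed to the cochleostomy condition.
#' @return Object of class `trauma_profile`.
#' @export
trauma_profile <- function(ts_max, f_edge, slope_w = 0.2,
                           cochleostomy_jitter_sd = 2) {
  if (ts_max < 0) stop("ts_max must be >= 0")
  if (slope_w <= 0) stop("slope_w must be > 0")
  if (f_edge < 2000 || f_edge > 32000)
    stop("f_edge must lie within the 2-32 kHz grid span")
  if (cochleostomy_jitter_sd < 0) stop("cochleostomy_jitter_sd must be >= 0")
  structure(list(ts_max = ts_max, f_edge = f_edge, slope_w = slope_w,
                 cochleostomy_jitter_sd = cochleostomy_jitter_sd),
            class = "trauma_profile")
}

#' Threshold shift injected at a given frequency
#'
#' `TS(f) = ts_max * logistic(log2(f / f_edge) / slope_w)`, smooth,
#' non-decreasing in `f`, and bounded in `[0, ts_max]`.
#'
#' @param f Frequency (Hz), vectorized.
#' @param profile A [trauma_profile()].
#' @return Threshold shift(s) in dB.
#' @export
trauma_shift <- function(f, profile) {
  stopifnot(inherits(profile, "trauma_profile"))
  u <- log2(f / profile$f_edge) / profile$slope_w
  profile$ts_max * stats::plogis(u)
}
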