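## Synthetic extracochlear recordings with known ground truth.
##
## Each ear owns a baseline CAP audiogram, a trauma profile injected by the
## electrode insertion, and gain/noise constants. Waveforms are built as
## CAP template + polarity-following cochlear microphonic + Gaussian noise,
## reproducibly from per-ear seeds.

SURGICAL_CONDITIONS <- c("initial", "cochleostomy", "inserted")

# Evaluate an expression with a temporary RNG state; restores .Random.seed.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-ear seed derived from the master seed; kept < 2^31.
ear_seed <- function(master_seed, ear_index) {
  (as.numeric(master_seed) * 1000003 + ear_index * 7919) %% 2147483629
}

condition_seed <- function(seed, condition) {
  k <- match(condition, SURGICAL_CONDITIONS)
  if (is.na(k)) stop("unknown condition: ", condition)
  (as.numeric(seed) + k * 104729) %% 2147483629
}

#' Stylized guinea-pig extracochlear CAP audiogram
#'
#' Baseline threshold template (dB SPL): flat best sensitivity of 30 dB SPL
#' from 8 kHz upward, rising 12 dB per octave toward the low-frequency end
#' (54 dB SPL at 2 kHz). Per-ear offsets and per-frequency jitter are added
#' on top by the cohort generator.
#'
#' @param f Frequency in Hz (vectorized).
#' @return Threshold template in dB SPL.
#' @export
default_audiogram <- function(f) {
  30 + 12 * pmax(0, log2(8000 / f))
}

#' Unit peak-to-peak CAP template
#'
#' Difference-of-gamma shape: an N1 trough followed by a P1 peak. At high
#' sensation levels N1/P1 sit at 1.8/3.0 ms after stimulus onset; latencies
#' increase by 0.5 ms per 20 dB toward threshold (referenced to 60 dB SL).
#' The returned vector is normalized to unit peak-to-peak amplitude so a
#' synthesized CAP of sensation level `sl` has peak-to-peak amplitude
#' exactly `cap_gain * sl` before filtering.
#'
#' @param t Time after stimulus onset, seconds (vectorized; values `<= 0`
#'   give 0).
#' @param sl Sensation level in dB (level above the ear's effective
#'   threshold).
#' @return Numeric template, unit peak-to-peak.
#' @export
cap_template <- function(t, sl) {
  shift_ms <- 0.5 * max(0, 60 - sl) / 20
  n1 <- (1.8 + shift_ms) / 1000
  p1 <- (3.0 + shift_ms) / 1000
  gshape <- function(t, tp, q) {
    out <- numeric(length(t))
    pos <- t > 0
    out[pos] <- (t[pos] / tp)^q * exp(q * (1 - t[pos] / tp))
    out
  }
  w <- -gshape(t, n1, 8) + 0.65 * gshape(t, p1, 6)
  rng <- range(w)
  span <- rng[2] - rng[1]
  if (span > 0) w / span else w
}

#' Ground truth for one synthetic ear
#'
#' Collects everything the generator needs to emit recordings for one ear:
#' the baseline audiogram, the insertion trauma profile, cochleostomy
#' jitter, CAP growth and noise constants, and the ear's seed.
#'
#' @param ear_id Label.
#' @param group `"5Ch"` (shallower) or `"6Ch"` (deeper insertion).
#' @param baseline_thresholds Named numeric, dB SPL per grid frequency,
#'   within `[0, 80]`.
#' @param trauma A [trauma_profile()].
#' @param cochleostomy_jitter Numeric, dB per grid frequency (zero-mean).
#' @param cap_gain CAP peak-to-peak growth, µV per dB above threshold.
#' @param noise_sd SD of Gaussian noise in the averaged trace, µV.
#' @param cm_ref Cochlear-microphonic amplitude at 60 dB SPL, µV (scales as
#'   `10^((level - 60) / 20)`).
#' @param seed Integer seed for this ear's recordings.
#' @param depth_ch1_um Optional arc-length insertion depth of the apical
#'   contact (µm), used for geometry/statistics coupling.
#' @param max_ts_target Optional injected per-ear maximal threshold shift
#'   (dB) the trauma profile was calibrated to.
#' @return Object of class `ear_ground_truth`.
#' @export
ear_ground_truth <- function(ear_id, group, baseline_thresholds, trauma,
                             cochleostomy_jitter = 0 * baseline_thresholds,
                             cap_gain = 4, noise_sd = 0.1, cm_ref = 5,
                             seed = 1, depth_ch1_um = NA_real_,
                             max_ts_target = NA_real_) {
  if (!group %in% c("5Ch", "6Ch")) stop("group must be '5Ch' or '6Ch'")
  if (any(baseline_thresholds < 0 | baseline_thresholds > 80))
    stop("baseline thresholds must lie within [0, 80] dB SPL")
  stopifnot(inherits(trauma, "trauma_profile"),
            length(cochleostomy_jitter) == length(baseline_thresholds))
  structure(list(ear_id = ear_id, group = group,
                 baseline_thresholds = baseline_thresholds,
                 trauma = trauma, cochleostomy_jitter = cochleostomy_jitter,
                 cap_gain = cap_gain, noise_sd = noise_sd, cm_ref = cm_ref,
                 seed = seed, depth_ch1_um = depth_ch1_um,
                 max_ts_target = max_ts_target),
            class = "ear_ground_truth")
}

#' Effective thresholds of an ear under a surgical condition
#'
#' `initial` returns the baseline audiogram; `cochleostomy` adds the ear's
#' fixed zero-mean jitter; `inserted` adds the trauma profile's shift.
#'
#' @param truth An [ear_ground_truth()].
#' @param condition One of `"initial"`, `"cochleostomy"`, `"inserted"`.
#' @param frequencies Frequencies (Hz); defaults to the audiogram's grid.
#' @return Named numeric, dB SPL.
#' @export
effective_thresholds <- function(truth, condition,
                                 frequencies = as.numeric(names(truth$baseline_thresholds))) {
  sel <- match(as.character(frequencies), names(truth$baseline_thresholds))
  if (anyNA(sel))
    stop("frequencies missing from the ear's audiogram: ",
         paste(frequencies[is.na(sel)], collapse = ", "))
  base <- truth$baseline_thresholds[sel]
  jit <- truth$cochleostomy_jitter[sel]
  switch(condition,
    initial = base,
    cochleostomy = base + jit,
    inserted = base + trauma_shift(frequencies, truth$trauma),
    stop("unknown condition: ", condition))
}

#' Synthesize the averaged recordings of one ear under one condition
#'
#' For every (frequency, level, polarity) cell of the grid the averaged
#' trace is built as: CAP template scaled by
#' `cap_gain * max(0, level - effective_threshold)`, plus a cochlear
#' microphonic (a tone at the stimulus frequency, enveloped like the burst,
#' whose sign follows the stimulus polarity), plus Gaussian noise of SD
#' `noise_sd` (the residual noise of the 20-presentation average). The
#' epoch holds a 15 ms pre-stimulus baseline followed by 20 ms after onset;
#' the long pre-stimulus segment leaves a clean baseline window ahead of
#' the zero-phase filter's backward smear.
#'
#' @param truth An [ear_ground_truth()].
#' @param condition Surgical condition label.
#' @param grid A [stimulus_grid()].
#' @param seed Seed; defaults to a deterministic combination of the ear
#'   seed and the condition.
#' @param pre_stimulus Pre-stimulus duration, s.
#' @param post_stimulus Post-onset duration, s (must cover the 10 ms
#'   analysis window).
#' @return Object of class `recording_set`: waveform array indexed
#'   `[time, polarity, level, frequency]` (µV) plus sampling metadata.
#' @export
synth_recording_set <- function(truth, condition, grid = stimulus_grid(),
                                seed = condition_seed(truth$seed, condition),
                                pre_stimulus = 0.015, post_stimulus = 0.020) {
  if (!condition %in% SURGICAL_CONDITIONS)
    stop("unknown condition: ", condition)
  if (post_stimulus < 0.010)
    stop("post-onset epoch must cover the 0-10 ms analysis window")
  fs <- grid$sample_rate
  n_pre <- round(pre_stimulus * fs)
  n_post <- round(post_stimulus * fs)
  n <- n_pre + n_post
  freqs <- grid$frequencies
  levels <- grid$levels
  eff <- effective_thresholds(truth, condition, freqs)
  nb <- round(grid$burst_duration * fs)
  env <- burst_envelope(nb, round(grid$ramp_duration * fs))
  t_post <- (seq_len(n_post) - 0.5) / fs
  burst_idx <- n_pre + seq_len(nb)
  t_burst <- (seq_len(nb) - 0.5) / fs

  wf <- with_local_seed(seed, {
    arr <- array(
      stats::rnorm(n * 2 * length(levels) * length(freqs), 0, truth$noise_sd),
      dim = c(n, 2, length(levels), length(freqs)),
      dimnames = list(NULL, c("condensation", "rarefaction"), levels, freqs))
    for (fi in seq_along(freqs)) {
      cm_tone <- sin(2 * pi * freqs[fi] * t_burst) * env
      for (li in seq_along(levels)) {
        sl <- levels[li] - eff[fi]
        cm <- truth$cm_ref * 10^((levels[li] - 60) / 20) * cm_tone
        cap <- numeric(n_post)
        if (sl > 0)
          cap <- truth$cap_gain * sl * cap_template(t_post, sl)
        for (pi in 1:2) {
          pol <- c(1, -1)[pi]
          arr[n_pre + seq_len(n_post), pi, li, fi] <-
            arr[n_pre + seq_len(n_post), pi, li, fi] + cap
          arr[burst_idx, pi, li, fi] <- arr[burst_idx, pi, li, fi] + pol * cm
        }
      }
    }
    arr
  })
  structure(list(ear_id = truth$ear_id, condition = condition,
                 waveforms = wf, sample_rate = fs,
                 pre_stimulus = pre_stimulus, post_stimulus = post_stimulus,
                 grid = grid),
            class = "recording_set")
}

#' @export
print.recording_set <- function(x, ...) {
  d <- dim(x$waveforms)
  cat(sprintf("Recording set %s / %s: %d freq x %d levels x 2 polarities, %d samples @ %g kHz\n",
              x$ear_id, x$condition, d[4], d[3], d[1], x$sample_rate / 1000))
  invisible(x)
}

#' Cohort configuration
#'
#' Study conditions for the default synthetic cohort: 24 normal-hearing
#' ears, split 12 shallow (5Ch) / 12 deep (6Ch) insertions. Per-ear maximal
#' injected threshold shifts are drawn from normal distributions whose
#' means are the group means of the study (23.0 dB deep, 10.0 dB shallow)
#' and whose SDs are the printed SEMs scaled by `sqrt(group size)`, clipped
#' at 0. Apical-contact depths are drawn per group (5340 +- 306 µm deep,
#' 4448 +- 290 µm shallow); the trauma edge frequency is tied to the depth
#' through the place-frequency map (half-maximal shift half an octave
#' apical of the contact-1 place), so deeper insertions shift lower
#' frequencies.
#'
#' @param n_5ch,n_6ch Ears per group.
#' @param max_ts_mean,max_ts_sem Group mean and SEM (dB) of the per-ear
#'   maximal injected threshold shift, named per group.
#' @param depth_mean,depth_sd Apical-contact (Ch1) arc depth (µm) per group.
#' @param apical_spread_oct Octaves apical of the Ch1 place at which the
#'   injected shift is half-maximal.
#' @param slope_w Trauma transition width, octaves.
#' @param cochleostomy_jitter_sd SD (dB) of the cochleostomy threshold jitter.
#' @param cap_gain,noise_sd,cm_ref Recording constants, see
#'   [ear_ground_truth()].
#' @param audiogram_offset_sd Per-ear audiogram offset SD, dB.
#' @param audiogram_jitter_sd Per-frequency audiogram jitter SD, dB.
#' @param grid A [stimulus_grid()].
#' @param map A [place_frequency_map()] used to couple depth and trauma edge.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_5ch = 12, n_6ch = 12,
                          max_ts_mean = c("5Ch" = 10.0, "6Ch" = 23.0),
                          max_ts_sem = c("5Ch" = 4.5, "6Ch" = 3.5),
                          depth_mean = c("5Ch" = 4448, "6Ch" = 5340),
                          depth_sd = c("5Ch" = 290, "6Ch" = 306),
                          apical_spread_oct = 0.5, slope_w = 0.2,
                          cochleostomy_jitter_sd = 2,
                          cap_gain = 4, noise_sd = 0.1, cm_ref = 5,
                          audiogram_offset_sd = 6, audiogram_jitter_sd = 0.3,
                          grid = stimulus_grid(),
                          map = place_frequency_map()) {
  if (n_5ch + n_6ch < 1) stop("cohort needs at least one ear")
  structure(list(n_5ch = n_5ch, n_6ch = n_6ch,
                 max_ts_mean = max_ts_mean, max_ts_sem = max_ts_sem,
                 depth_mean = depth_mean, depth_sd = depth_sd,
                 apical_spread_oct = apical_spread_oct, slope_w = slope_w,
                 cochleostomy_jitter_sd = cochleostomy_jitter_sd,
                 cap_gain = cap_gain, noise_sd = noise_sd, cm_ref = cm_ref,
                 audiogram_offset_sd = audiogram_offset_sd,
                 audiogram_jitter_sd = audiogram_jitter_sd,
                 grid = grid, map = map),
            class = "cohort_config")
}

#' Generate a synthetic cohort
#'
#' Draws per-ear ground truths (and optionally the three recording sets per
#' ear) from a [cohort_config()]. Per-ear seeds are derived deterministically
#' from `master_seed`, so any ear can be regenerated in isolation.
#'
#' @param config A [cohort_config()].
#' @param master_seed Integer master seed.
#' @param recordings If `TRUE`, attach the three [synth_recording_set()]s
#'   per ear (memory-heavy on the full grid; the analysis pipeline streams
#'   ear by ear instead).
#' @return Object of class `cohort`: list with `truths` (one
#'   [ear_ground_truth()] per ear, 5Ch ears first), `config`, `master_seed`,
#'   and optionally `recordings`.
#' @export
synth_cohort <- function(config = cohort_config(), master_seed = 1,
                         recordings = FALSE) {
  n <- config$n_5ch + config$n_6ch
  groups <- rep(c("5Ch", "6Ch"), c(config$n_5ch, config$n_6ch))
  n_group <- c("5Ch" = config$n_5ch, "6Ch" = config$n_6ch)
  freqs <- config$grid$frequencies
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    g <- groups[i]
    seed_i <- ear_seed(master_seed, i)
    truths[[i]] <- with_local_seed(seed_i, {
      depth <- stats::rnorm(1, config$depth_mean[[g]], config$depth_sd[[g]])
      ts_target <- max(0, stats::rnorm(1, config$max_ts_mean[[g]],
                                       config$max_ts_sem[[g]] * sqrt(n_group[[g]])))
      base <- default_audiogram(freqs) +
        stats::rnorm(1, 0, config$audiogram_offset_sd) +
        stats::rnorm(length(freqs), 0, config$audiogram_jitter_sd)
      base <- pmin(pmax(base, 5), 80)
      names(base) <- freqs
      jit <- stats::setNames(
        stats::rnorm(length(freqs), 0, config$cochleostomy_jitter_sd), freqs)
      f_edge <- place_to_frequency(depth, config$map) *
        2^(-config$apical_spread_oct)
      f_edge <- min(max(f_edge, 2000), 32000)
      rel_max <- stats::plogis(log2(max(freqs) / f_edge) / config$slope_w)
      prof <- trauma_profile(ts_max = ts_target / rel_max, f_edge = f_edge,
                             slope_w = config$slope_w,
                             cochleostomy_jitter_sd = config$cochleostomy_jitter_sd)
      ear_ground_truth(
        ear_id = sprintf("ear%02d", i), group = g,
        baseline_thresholds = base, trauma = prof,
        cochleostomy_jitter = jit, cap_gain = config$cap_gain,
        noise_sd = config$noise_sd, cm_ref = config$cm_ref,
        seed = seed_i, depth_ch1_um = depth, max_ts_target = ts_target)
    })
  }
  out <- structure(list(truths = truths, config = config,
                        master_seed = master_seed),
                   class = "cohort")
  if (recordings)
    out$recordings <- lapply(truths, generate_ear_recordings, grid = config$grid)
  out
}

#' Recordings for all three surgical conditions of one ear
#'
#' @param truth An [ear_ground_truth()].
#' @param grid A [stimulus_grid()].
#' @return Named list of three [synth_recording_set()]s
#'   (`initial`, `cochleostomy`, `inserted`).
#' @export
generate_ear_recordings <- function(truth, grid = stimulus_grid()) {
  out <- lapply(SURGICAL_CONDITIONS, function(cond)
    synth_recording_set(truth, cond, grid))
  names(out) <- SURGICAL_CONDITIONS
  out
}
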