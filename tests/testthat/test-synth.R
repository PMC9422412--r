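test_that("trauma profile is a bounded logistic ramp on the log-frequency axis", {
  pr <- trauma_profile(ts_max = 20, f_edge = 6000, slope_w = 0.3)
  expect_equal(trauma_shift(6000, pr), 10)                 # half-maximal at the edge
  expect_lt(trauma_shift(6000 * 2^(-4 * 0.3), pr), 0.02 * 20)  # apical tail
  expect_gt(trauma_shift(6000 * 2^(8 * 0.3), pr), 0.999 * 20)  # basal saturation
  f <- 2000 * 2^(seq(0, 4, by = 0.25))
  ts <- trauma_shift(f, pr)
  expect_true(all(diff(ts) > 0))
  expect_true(all(ts >= 0 & ts <= 20))
  # monotone in ts_max at every frequency
  pr2 <- trauma_profile(ts_max = 25, f_edge = 6000, slope_w = 0.3)
  expect_true(all(trauma_shift(f, pr2) >= trauma_shift(f, pr)))
  expect_error(trauma_profile(-1, 6000), "ts_max")
  expect_error(trauma_profile(5, 1000), "grid span")
})

make_truth <- function(grid, base = 40, noise_sd = 0, seed = 7, ts_max = 0,
                       cap_gain = 2.5) {
  freqs <- grid$frequencies
  thr <- stats::setNames(rep(base, length(freqs)), freqs)
  ear_ground_truth("earA", "6Ch", thr,
                   trauma_profile(ts_max, 6000, 0.2),
                   cochleostomy_jitter = rep(0, length(freqs)),
                   cap_gain = cap_gain, noise_sd = noise_sd, seed = seed)
}

test_that("recordings are byte-identical for identical seeds", {
  g <- tiny_grid()
  truth <- make_truth(g, noise_sd = 0.4)
  a <- synth_recording_set(truth, "inserted", g, seed = 99)
  b <- synth_recording_set(truth, "inserted", g, seed = 99)
  expect_identical(a$waveforms, b$waveforms)
  c2 <- synth_recording_set(truth, "inserted", g, seed = 100)
  expect_false(identical(a$waveforms, c2$waveforms))
  expect_error(synth_recording_set(truth, "postmortem", g), "condition")
})

test_that("noise-free CAP amplitude follows the level-minus-threshold growth rule", {
  g <- tiny_grid()
  truth <- make_truth(g, base = 40, noise_sd = 0)
  rs <- synth_recording_set(truth, "initial", g)
  fs <- rs$sample_rate
  onset <- round(rs$pre_stimulus * fs) + 1
  # 20 dB above the 40 dB threshold at 8 kHz: p2p = cap_gain * 20 exactly
  # (unit peak-to-peak template), on the unfiltered polarity average
  fi <- which(g$frequencies == 8000)
  li <- which(g$levels == 60)
  avg <- polarity_average(rs$waveforms[, 1, li, fi], rs$waveforms[, 2, li, fi])
  cap <- extract_cap(avg, onset, fs)
  expect_equal(cap$p2p_amplitude, 2.5 * 20, tolerance = 1e-10)
  expect_lt(cap$n1_latency, cap$p1_latency)
  # below threshold: no CAP at all in the noise-free trace
  li0 <- which(g$levels == 30)
  avg0 <- polarity_average(rs$waveforms[, 1, li0, fi], rs$waveforms[, 2, li0, fi])
  expect_equal(extract_cap(avg0, onset, fs)$p2p_amplitude, 0)
})

test_that("below-threshold filtered traces stay at the noise floor", {
  g <- tiny_grid()
  truth <- make_truth(g, base = 70, noise_sd = 0.4, seed = 21)
  rs <- synth_recording_set(truth, "initial", g)
  fs <- rs$sample_rate
  onset <- round(rs$pre_stimulus * fs) + 1
  fi <- which(g$frequencies == 4000)
  li <- which(g$levels == 50)  # 20 dB below threshold
  avg <- polarity_average(rs$waveforms[, 1, li, fi], rs$waveforms[, 2, li, fi])
  filt <- bandpass_offline(avg, fs)
  expect_lt(extract_cap(filt, onset, fs)$p2p_amplitude, 4 * truth$noise_sd)
})

test_that("polarity averaging cancels the cochlear microphonic exactly", {
  g <- tiny_grid()
  # CAP-free (thresholds above the ladder is impossible within [0,80];
  # use level below threshold) and noise-free: traces are pure CM
  truth <- make_truth(g, base = 80, noise_sd = 0)
  rs <- synth_recording_set(truth, "initial", g)
  fi <- which(g$frequencies == 2000)
  li <- which(g$levels == 60)
  cm_amp <- max(abs(rs$waveforms[, 1, li, fi]))
  expect_gt(cm_amp, 1)  # the CM really is there
  resid <- polarity_average(rs$waveforms[, 1, li, fi], rs$waveforms[, 2, li, fi])
  expect_lt(max(abs(resid)), 1e-9 * cm_amp)
})

test_that("cohort generation is deterministic, correctly sized and calibrated", {
  cfg <- cohort_config()
  co <- synth_cohort(cfg, master_seed = 5)
  expect_length(co$truths, 24)
  groups <- vapply(co$truths, `[[`, "", "group")
  expect_equal(unname(table(groups)[c("5Ch", "6Ch")]), c(12L, 12L),
               ignore_attr = TRUE)
  co2 <- synth_cohort(cfg, master_seed = 5)
  expect_identical(co$truths, co2$truths)
  seeds <- vapply(co$truths, `[[`, 0, "seed")
  expect_false(anyDuplicated(seeds) > 0)
  # per-ear recordings: three conditions, reproducible piecewise
  g <- tiny_grid()
  recs <- generate_ear_recordings(co$truths[[1]], g)
  expect_named(recs, c("initial", "cochleostomy", "inserted"))
  again <- synth_recording_set(co$truths[[1]], "inserted", g)
  expect_identical(recs$inserted$waveforms, again$waveforms)
  # cochleostomy injects zero-mean jitter
  jit <- unlist(lapply(co$truths, `[[`, "cochleostomy_jitter"))
  expect_lt(abs(mean(jit)), 3 * cfg$cochleostomy_jitter_sd / sqrt(length(jit)))
  # injected maxima match the group calibration (average over 20 cohorts;
  # the clip at 0 inflates the shallow group's mean slightly)
  targets <- function(ms) {
    co <- synth_cohort(cfg, master_seed = ms)
    tapply(vapply(co$truths, `[[`, 0, "max_ts_target"),
           vapply(co$truths, `[[`, "", "group"), mean)
  }
  tt <- rowMeans(vapply(1:20, targets, c("5Ch" = 0, "6Ch" = 0)))
  # oracle: clipped-normal mean m*pnorm(m/s) + s*dnorm(m/s), s = SEM*sqrt(n)
  clip_mean <- function(m, s) m * pnorm(m / s) + s * dnorm(m / s)
  expect_equal(unname(tt["6Ch"]), clip_mean(23, 3.5 * sqrt(12)), tolerance = 0.12)
  expect_equal(unname(tt["5Ch"]), clip_mean(10, 4.5 * sqrt(12)), tolerance = 0.25)
  # injected maximum equals the shift at the most basal lattice frequency
  tr1 <- co$truths[[24]]
  expect_equal(trauma_shift(32000, tr1$trauma), tr1$max_ts_target,
               tolerance = 1e-6)
})

test_that("effective thresholds are non-decreasing in trauma severity", {
  g <- tiny_grid()
  freqs <- g$frequencies
  base <- stats::setNames(rep(35, length(freqs)), freqs)
  shifts <- vapply(c(0, 5, 12, 25), function(tsm) {
    tr <- ear_ground_truth("e", "6Ch", base,
                           trauma_profile(tsm, 8000, 0.2),
                           cochleostomy_jitter = rep(0, length(freqs)))
    effective_thresholds(tr, "inserted")
  }, numeric(length(freqs)))
  expect_true(all(apply(shifts, 1, function(x) all(diff(x) >= 0))))
})
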