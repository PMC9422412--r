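## End-to-end study pipeline: simulate -> CAP analysis -> geometry ->
## statistics, plus on-disk recording bundles and tabular reports.

#' Analyze a synthetic cohort end to end
#'
#' Streams ear by ear: generates (or takes) the three recording sets,
#' extracts thresholds and suprathreshold amplitudes per condition, and
#' assembles tidy tables of thresholds, threshold shifts (cochleostomy and
#' insertion, both relative to the initial condition) and amplitude changes
#' at the requested levels.
#'
#' @param cohort A [synth_cohort()] result.
#' @param amplitude_levels Levels (dB SPL) for the amplitude-change tables.
#' @param quiet Suppress per-ear progress on stderr.
#' @return Object of class `cohort_analysis`: `thresholds`, `shifts`,
#'   `amplitudes` data.frames, and `ears` (per-ear group, injected depth
#'   and trauma target, measured maximal insertion shift, censored cell
#'   count).
#' @export
analyze_cohort <- function(cohort, amplitude_levels = c(50, 60, 70),
                           quiet = TRUE) {
  stopifnot(inherits(cohort, "cohort"))
  grid <- cohort$config$grid
  thr_rows <- list(); shift_rows <- list(); amp_rows <- list(); ear_rows <- list()
  for (i in seq_along(cohort$truths)) {
    truth <- cohort$truths[[i]]
    t0 <- Sys.time()
    recs <- if (!is.null(cohort$recordings)) cohort$recordings[[i]]
            else generate_ear_recordings(truth, grid)
    tm <- lapply(recs, analyze_recording_set)
    for (cond in names(tm)) {
      thr_rows[[length(thr_rows) + 1]] <- data.frame(
        ear = truth$ear_id, group = truth$group, condition = cond,
        frequency_hz = tm[[cond]]$frequencies,
        threshold_db = unname(tm[[cond]]$threshold),
        censored = unname(tm[[cond]]$censored))
    }
    for (con in c("cochleostomy", "inserted")) {
      ts <- threshold_shift(tm$initial, tm[[con]])
      shift_rows[[length(shift_rows) + 1]] <- data.frame(
        ear = truth$ear_id, group = truth$group, contrast = con, ts)
      amp <- amplitude_change(tm$initial, tm[[con]], amplitude_levels)
      amp_rows[[length(amp_rows) + 1]] <- data.frame(
        ear = truth$ear_id, group = truth$group, contrast = con, amp)
    }
    ins <- threshold_shift(tm$initial, tm$inserted)
    usable <- !ins$censored
    ear_rows[[length(ear_rows) + 1]] <- data.frame(
      ear = truth$ear_id, group = truth$group,
      depth_ch1_um = truth$depth_ch1_um,
      max_ts_target = truth$max_ts_target,
      max_ts_db = if (any(usable)) max(ins$ts_db[usable]) else NA_real_,
      n_censored = sum(tm$inserted$censored))
    if (!quiet)
      message(sprintf("%s analyzed in %.1f s (%d censored cells)",
                      truth$ear_id, as.numeric(Sys.time() - t0, units = "secs"),
                      sum(tm$inserted$censored)))
  }
  structure(list(thresholds = do.call(rbind, thr_rows),
                 shifts = do.call(rbind, shift_rows),
                 amplitudes = do.call(rbind, amp_rows),
                 ears = do.call(rbind, ear_rows),
                 master_seed = cohort$master_seed),
            class = "cohort_analysis")
}

#' Insertion geometry for a synthetic cohort
#'
#' Places each ear's electrode on the default (or a supplied) spiral at the
#' ear's ground-truth apical-contact depth and re-measures it through the
#' projection pipeline, yielding per-ear insertion metrics and the lowest
#' characteristic frequency.
#'
#' @param cohort A [synth_cohort()] result.
#' @param spiral A [build_spiral()].
#' @param map A [place_frequency_map()].
#' @return `data.frame`: `ear`, `group`, `depth_placed_um`,
#'   `depth_ch1_um` (measured), `percent_bm`, `insertion_angle_deg`,
#'   `n_contacts_in`, `lowest_cf_hz`.
#' @export
cohort_geometry <- function(cohort, spiral = build_spiral(),
                            map = place_frequency_map()) {
  rows <- lapply(cohort$truths, function(truth) {
    track <- place_electrode(spiral, truth$depth_ch1_um + 1000)
    met <- measure_insertion(track, spiral)
    data.frame(ear = truth$ear_id, group = truth$group,
               depth_placed_um = truth$depth_ch1_um,
               depth_ch1_um = met$depth_ch1_um,
               percent_bm = met$percent_bm,
               insertion_angle_deg = met$insertion_angle_deg,
               n_contacts_in = met$n_contacts_in,
               lowest_cf_hz = lowest_cf(met, map))
  })
  do.call(rbind, rows)
}

#' Simulate and analyze the default study in one call
#'
#' Convenience wrapper: [synth_cohort()] then [analyze_cohort()] (streaming)
#' then [cohort_geometry()] and [run_study_contrasts()].
#'
#' @param config A [cohort_config()].
#' @param master_seed Integer master seed.
#' @param quiet Suppress progress.
#' @return A `cohort_analysis` with extra elements `geometry` and
#'   `contrasts`.
#' @export
run_cohort_study <- function(config = cohort_config(), master_seed = 1,
                             quiet = TRUE) {
  cohort <- synth_cohort(config, master_seed)
  analysis <- analyze_cohort(cohort, quiet = quiet)
  analysis$geometry <- cohort_geometry(cohort, map = config$map)
  analysis$contrasts <- run_study_contrasts(
    analysis$shifts,
    metrics = analysis$ears[, c("ear", "depth_ch1_um")],
    map = config$map)
  analysis
}

#' Summary tables of an analyzed cohort
#'
#' Tabular twins of the study's figures: grand-average and per-group
#' threshold shift per frequency (mean and SEM over non-censored cells),
#' mean amplitude change per frequency and level, per-ear insertion
#' metrics, and the contrast table.
#'
#' @param analysis A [run_cohort_study()] / [analyze_cohort()] result.
#' @return Named list of data.frames: `ts_grand`, `ts_group`, `amplitude`,
#'   `geometry`, `contrasts` (the latter two `NULL` if absent).
#' @export
report_tables <- function(analysis) {
  sh <- analysis$shifts[analysis$shifts$contrast == "inserted" &
                          !analysis$shifts$censored, , drop = FALSE]
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  summarize_ts <- function(df, by) {
    agg_m <- stats::aggregate(ts_db ~ ., data = df[c(by, "ts_db")], FUN = mean)
    agg_s <- stats::aggregate(ts_db ~ ., data = df[c(by, "ts_db")], FUN = sem)
    agg_n <- stats::aggregate(ts_db ~ ., data = df[c(by, "ts_db")], FUN = length)
    names(agg_m)[names(agg_m) == "ts_db"] <- "mean_ts_db"
    agg_m$sem_ts_db <- agg_s$ts_db
    agg_m$n <- agg_n$ts_db
    agg_m[do.call(order, agg_m[by]), , drop = FALSE]
  }
  ts_grand <- if (nrow(sh)) summarize_ts(sh, "frequency_hz") else
    data.frame(frequency_hz = numeric(), mean_ts_db = numeric(),
               sem_ts_db = numeric(), n = integer())
  ts_group <- if (nrow(sh)) summarize_ts(sh, c("group", "frequency_hz")) else
    data.frame(group = character(), frequency_hz = numeric(),
               mean_ts_db = numeric(), sem_ts_db = numeric(), n = integer())
  amp <- analysis$amplitudes
  amp <- amp[is.finite(amp$d_uv), , drop = FALSE]
  amplitude <- if (nrow(amp))
    stats::aggregate(cbind(d_uv, pct) ~ contrast + frequency_hz + level_db,
                     data = amp, FUN = mean, na.action = stats::na.omit)
  else NULL
  if (nrow(sh) == 0) warning("empty cohort: report tables are empty")
  list(ts_grand = ts_grand, ts_group = ts_group, amplitude = amplitude,
       geometry = analysis$geometry, contrasts = analysis$contrasts)
}

## ---- On-disk recording bundles --------------------------------------------

grid_meta <- function(grid) {
  list(f_min = min(grid$frequencies), f_max = max(grid$frequencies),
       steps_per_octave = grid$steps_per_octave,
       l_min = min(grid$levels), l_max = max(grid$levels),
       l_step = if (length(grid$levels) > 1) diff(grid$levels[1:2]) else 10,
       burst_duration = grid$burst_duration,
       ramp_duration = grid$ramp_duration,
       sample_rate = grid$sample_rate, n_averages = grid$n_averages)
}

grid_from_meta <- function(m) {
  stimulus_grid(m$f_min, m$f_max, m$steps_per_octave, m$l_min, m$l_max,
                m$l_step, m$burst_duration, m$ramp_duration, m$sample_rate,
                m$n_averages)
}

#' Write one ear's recordings to a bundle directory
#'
#' Layout: `<dir>/meta.json` (grid, conditions, sampling metadata) and
#' `<dir>/waveforms.csv` in long format (`condition, frequency_hz,
#' level_db, polarity, sample_index, microvolts`). Metadata round-trips
#' bit-identically; samples are written with six decimals (1e-6 µV).
#'
#' @param recordings Named list of [synth_recording_set()]s (one per
#'   condition).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_recording_bundle <- function(recordings, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create bundle directory: ", dir)
  rs1 <- recordings[[1]]
  meta <- list(ear_id = rs1$ear_id, conditions = names(recordings),
               grid = grid_meta(rs1$grid),
               sample_rate = rs1$sample_rate,
               pre_stimulus = rs1$pre_stimulus,
               post_stimulus = rs1$post_stimulus)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  rows <- lapply(recordings, function(rs) {
    d <- dim(rs$waveforms)
    grid <- expand.grid(sample_index = seq_len(d[1]),
                        polarity = c("condensation", "rarefaction"),
                        level_db = rs$grid$levels,
                        frequency_hz = rs$grid$frequencies,
                        KEEP.OUT.ATTRS = FALSE)
    data.frame(condition = rs$condition,
               frequency_hz = grid$frequency_hz, level_db = grid$level_db,
               polarity = grid$polarity, sample_index = grid$sample_index,
               microvolts = sprintf("%.6f", as.vector(rs$waveforms)))
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "waveforms.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read one ear's recordings from a bundle directory
#'
#' @param dir Bundle directory written by [write_recording_bundle()].
#' @return Named list of `recording_set` objects.
#' @export
read_recording_bundle <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  csv_path <- file.path(dir, "waveforms.csv")
  if (!file.exists(meta_path) || !file.exists(csv_path))
    stop("not a recording bundle: ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  grid <- grid_from_meta(meta$grid)
  df <- utils::read.csv(csv_path)
  n <- max(df$sample_index)
  out <- lapply(meta$conditions, function(cond) {
    sub <- df[df$condition == cond, ]
    # rows were written in array order (time, polarity, level, frequency)
    wf <- array(sub$microvolts,
                dim = c(n, 2, length(grid$levels), length(grid$frequencies)),
                dimnames = list(NULL, c("condensation", "rarefaction"),
                                grid$levels, grid$frequencies))
    structure(list(ear_id = meta$ear_id, condition = cond, waveforms = wf,
                   sample_rate = meta$sample_rate,
                   pre_stimulus = meta$pre_stimulus,
                   post_stimulus = meta$post_stimulus, grid = grid),
              class = "recording_set")
  })
  names(out) <- meta$conditions
  out
}

#' Simulate a cohort and write it as per-ear bundles
#'
#' Writes `<out_dir>/cohort_truth.json` (per-ear ground truth and seeds)
#' and one [write_recording_bundle()] directory per ear. On the default
#' full grid each ear is ~100 MB of CSV; reduce the grid for interchange
#' fixtures and use [run_cohort_study()] for in-memory analysis.
#'
#' @param config A [cohort_config()].
#' @param master_seed Integer master seed.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
simulate_cohort_bundle <- function(config = cohort_config(), master_seed = 1,
                                   out_dir) {
  cohort <- synth_cohort(config, master_seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("unwritable output directory: ", out_dir)
  truth_json <- lapply(cohort$truths, function(tr) {
    list(ear_id = tr$ear_id, group = tr$group, seed = tr$seed,
         depth_ch1_um = tr$depth_ch1_um, max_ts_target = tr$max_ts_target,
         cap_gain = tr$cap_gain, noise_sd = tr$noise_sd, cm_ref = tr$cm_ref,
         baseline_thresholds = as.list(tr$baseline_thresholds),
         cochleostomy_jitter = tr$cochleostomy_jitter,
         trauma = unclass(tr$trauma))
  })
  jsonlite::write_json(list(master_seed = master_seed, ears = truth_json),
                       file.path(out_dir, "cohort_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  for (tr in cohort$truths)
    write_recording_bundle(generate_ear_recordings(tr, config$grid),
                           file.path(out_dir, tr$ear_id))
  invisible(out_dir)
}

#' Analyze a directory of recording bundles
#'
#' Reads every per-ear bundle under `bundle_dir`, runs the CAP pipeline,
#' and writes `thresholds.csv`, `shifts.csv` and `stats.csv` next to them.
#' Ears whose bundle cannot be read are skipped with a warning.
#'
#' @param bundle_dir Directory produced by [simulate_cohort_bundle()].
#' @param out_dir Where to write the CSVs (defaults to `bundle_dir`).
#' @return The `cohort_analysis`-like list, invisibly.
#' @export
analyze_bundle <- function(bundle_dir, out_dir = bundle_dir) {
  truth_path <- file.path(bundle_dir, "cohort_truth.json")
  if (!file.exists(truth_path)) stop("no cohort_truth.json in ", bundle_dir)
  truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
  ears <- truth$ears
  thr_rows <- list(); shift_rows <- list(); skipped <- character()
  for (i in seq_len(nrow(ears))) {
    ear_id <- ears$ear_id[i]
    recs <- tryCatch(read_recording_bundle(file.path(bundle_dir, ear_id)),
                     error = function(e) NULL)
    if (is.null(recs)) { skipped <- c(skipped, ear_id); next }
    tm <- lapply(recs, analyze_recording_set)
    for (cond in names(tm))
      thr_rows[[length(thr_rows) + 1]] <- data.frame(
        ear = ear_id, group = ears$group[i], condition = cond,
        frequency_hz = tm[[cond]]$frequencies,
        threshold_db = unname(tm[[cond]]$threshold),
        censored = unname(tm[[cond]]$censored))
    if (all(c("initial", "inserted") %in% names(tm)))
      for (con in intersect(c("cochleostomy", "inserted"), names(tm)))
        shift_rows[[length(shift_rows) + 1]] <- data.frame(
          ear = ear_id, group = ears$group[i], contrast = con,
          threshold_shift(tm$initial, tm[[con]]))
    else warning("bundle ", ear_id, " misses a condition; partial output")
  }
  if (length(skipped))
    warning("skipped unreadable bundles: ", paste(skipped, collapse = ", "))
  thresholds <- do.call(rbind, thr_rows)
  shifts <- do.call(rbind, shift_rows)
  if (is.null(thresholds)) stop("no readable bundles in ", bundle_dir)
  utils::write.csv(thresholds, file.path(out_dir, "thresholds.csv"),
                   row.names = FALSE)
  stats_df <- NULL
  if (!is.null(shifts)) {
    utils::write.csv(shifts, file.path(out_dir, "shifts.csv"),
                     row.names = FALSE)
    stats_df <- run_study_contrasts(shifts)
    utils::write.csv(stats_df, file.path(out_dir, "stats.csv"),
                     row.names = FALSE)
  }
  invisible(list(thresholds = thresholds, shifts = shifts,
                 contrasts = stats_df, skipped = skipped))
}
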