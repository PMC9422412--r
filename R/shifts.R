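## Threshold shifts, suprathreshold amplitude changes, and the ABR
## normal-hearing inclusion screen.

#' Threshold shift between two surgical conditions
#'
#' `TS(f) = post(f) - pre(f)` on the shared frequency lattice. Censored
#' thresholds enter the arithmetic at `l_max + l_step`; cells censored in
#' either condition keep a flag so group statistics can exclude them.
#'
#' @param pre,post [analyze_recording_set()] results (`threshold_matrix`)
#'   for the same ear on the same lattice.
#' @return `data.frame` with `frequency_hz`, `ts_db`, `censored`.
#' @export
threshold_shift <- function(pre, post) {
  if (!identical(pre$frequencies, post$frequencies) ||
      !identical(pre$levels, post$levels))
    stop("threshold matrices are on different lattices")
  if (!identical(pre$ear_id, post$ear_id))
    stop("threshold matrices belong to different ears")
  data.frame(frequency_hz = pre$frequencies,
             ts_db = unname(post$threshold - pre$threshold),
             censored = unname(pre$censored | post$censored))
}

#' Suprathreshold CAP amplitude change between conditions
#'
#' Per (frequency, level) cell at the requested levels: absolute change
#' `post - pre` (µV) and percent change relative to `pre`. Cells with zero
#' pre-condition amplitude have an undefined percent change, flagged via
#' `pct = NA` while the absolute change is still reported.
#'
#' @param pre,post `threshold_matrix` objects (which carry the full
#'   peak-to-peak matrix) for the same ear and lattice.
#' @param levels Stimulus levels (dB SPL) to compare; all must be on the
#'   lattice.
#' @return `data.frame` with `frequency_hz`, `level_db`, `pre_uv`,
#'   `post_uv`, `d_uv`, `pct`.
#' @export
amplitude_change <- function(pre, post, levels = c(50, 60, 70)) {
  if (!identical(pre$frequencies, post$frequencies) ||
      !identical(pre$levels, post$levels))
    stop("threshold matrices are on different lattices")
  if (!all(levels %in% pre$levels))
    stop("requested level missing from the lattice")
  li <- match(levels, pre$levels)
  out <- expand.grid(frequency_hz = pre$frequencies, level_db = levels,
                     KEEP.OUT.ATTRS = FALSE)
  out$pre_uv <- as.vector(t(pre$p2p[li, , drop = FALSE]))
  out$post_uv <- as.vector(t(post$p2p[li, , drop = FALSE]))
  out$d_uv <- out$post_uv - out$pre_uv
  out$pct <- ifelse(out$pre_uv == 0, NA_real_, 100 * out$d_uv / out$pre_uv)
  out
}

#' ABR normal-hearing inclusion screen
#'
#' Keeps ears whose click ABR threshold is 30 dB SPL (peak equivalent) or
#' better.
#'
#' @param click_thresholds Named numeric vector, dB SPL per ear.
#' @param cutoff Inclusion cutoff, dB SPL.
#' @return Character vector of included ear names.
#' @export
screen_abr <- function(click_thresholds, cutoff = 30) {
  names(click_thresholds)[click_thresholds <= cutoff]
}
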