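## Parametric cochlear spiral, electrode placement and insertion
## morphometry (arc-length depth, percent coverage, insertion angle).

#' Build a parametric cochlear spiral
#'
#' Logarithmic planar spiral with linear elevation:
#' `r(theta) = r0 * exp(-b * theta)`, `z(theta) = c * theta`,
#' `theta` in `[0, 2*pi*turns]`, with `theta = 0` at the basal origin of
#' the basilar-membrane reconstruction (round-window end of the hook
#' region). The raw curve is scaled uniformly so its numeric arc length
#' equals `bm_length`; an arc-length parameterization `s(theta)` and its
#' inverse are tabulated on a dense grid with Newton refinement.
#'
#' The default membrane length of 18 500 µm follows from the
#' species-specific place map: 2.59 mm per octave being ~14% of the
#' cochlear length gives 2.59 / 0.14 = 18.5 mm.
#'
#' @param bm_length Basilar-membrane arc length, µm (hook included).
#' @param turns Total turns of the spiral.
#' @param r0 Basal radius before normalization, µm.
#' @param b Radial decay rate per radian.
#' @param c Elevation per radian before normalization, µm.
#' @param hook_length Arc length of the hook region, µm; its end defines
#'   the summit-point reference for insertion angles.
#' @param n_grid Grid size of the arc-length table.
#' @return Object of class `cochlear_spiral` with accessors
#'   `s_of_theta(theta)` and `theta_of_s(s)`.
#' @export
build_spiral <- function(bm_length = 18500, turns = 4.25, r0 = 1400,
                         b = 0.06, c = 70, hook_length = 1000,
                         n_grid = 20001) {
  if (bm_length <= 0) stop("bm_length must be positive")
  if (turns <= 0 || r0 <= 0 || b <= 0 || c < 0)
    stop("non-physical spiral parameters")
  if (hook_length < 0 || hook_length >= bm_length)
    stop("hook_length must lie within [0, bm_length)")
  theta_max <- 2 * pi * turns
  speed_raw <- function(theta) sqrt(r0^2 * (1 + b^2) * exp(-2 * b * theta) + c^2)
  th <- seq(0, theta_max, length.out = n_grid)
  g <- speed_raw(th)
  h <- th[2] - th[1]
  s_raw <- c(0, cumsum((g[-1] + g[-n_grid]) / 2 * h))
  k <- bm_length / s_raw[n_grid]  # uniform scale: r0, c (and s) scale by k
  r0 <- r0 * k
  c <- c * k
  s_tab <- s_raw * k
  speed <- function(theta) sqrt(r0^2 * (1 + b^2) * exp(-2 * b * theta) + c^2)

  s_of_theta <- function(theta) {
    # grid value plus Simpson correction on the residual subinterval
    i <- pmin(pmax(findInterval(theta, th), 1L), n_grid)
    a <- th[i]
    mid <- (a + theta) / 2
    s_tab[i] + (theta - a) / 6 * (speed(a) + 4 * speed(mid) + speed(theta))
  }
  theta_of_s <- function(s) {
    if (any(s < -1e-9 | s > bm_length * (1 + 1e-9)))
      stop("arc length outside the membrane")
    theta <- stats::approx(s_tab, th, xout = s, rule = 2)$y
    for (it in 1:4) theta <- theta + (s - s_of_theta(theta)) / speed(theta)
    pmin(pmax(theta, 0), theta_max)
  }

  structure(list(bm_length = bm_length, turns = turns, theta_max = theta_max,
                 r0 = r0, b = b, c = c, hook_length = hook_length,
                 theta_ref = theta_of_s(hook_length),
                 s_of_theta = s_of_theta, theta_of_s = theta_of_s,
                 speed = speed),
            class = "cochlear_spiral")
}

#' @export
print.cochlear_spiral <- function(x, ...) {
  cat(sprintf(
    "Cochlear spiral: %.1f mm membrane, %.2f turns, basal radius %.0f um, hook %.0f um\n",
    x$bm_length / 1000, x$turns, x$r0, x$hook_length))
  invisible(x)
}

# 3D point(s) on the spiral at polar angle theta.
spiral_point <- function(spiral, theta) {
  r <- spiral$r0 * exp(-spiral$b * theta)
  cbind(x = r * cos(theta), y = r * sin(theta), z = spiral$c * theta)
}

#' Place the electrode array on a spiral
#'
#' The carrier tip sits at arc depth `tip_depth`; the apical contact Ch1 is
#' 1000 µm basal to the tip and the remaining contacts follow at 700 µm
#' spacing (tip-to-Ch6 span 4.5 mm, Ch1-to-Ch6 span 3.5 mm). Contacts with
#' negative arc depth are extracochlear: they are flagged and placed on the
#' tangent extension beyond the round window.
#'
#' @param spiral A [build_spiral()].
#' @param tip_depth Arc depth of the carrier tip from the basal origin, µm
#'   (`0 <= tip_depth <= bm_length`).
#' @param n_contacts Number of contacts on the carrier.
#' @param contact_spacing Inter-contact arc spacing, µm.
#' @param tip_to_ch1 Arc distance from carrier tip to the apical contact, µm.
#' @return Object of class `electrode_track`: `contacts` data.frame
#'   (`contact_id`, `depth_um`, `x_um`, `y_um`, `z_um`, `intracochlear`;
#'   Ch1 apical first), tip coordinate, and `n_contacts_in`.
#' @export
place_electrode <- function(spiral, tip_depth, n_contacts = 6,
                            contact_spacing = 700, tip_to_ch1 = 1000) {
  if (tip_depth < 0) stop("tip_depth must be >= 0")
  if (tip_depth > spiral$bm_length) stop("tip_depth exceeds the membrane length")
  depths <- tip_depth - tip_to_ch1 - (seq_len(n_contacts) - 1) * contact_spacing
  pts <- matrix(NA_real_, n_contacts, 3, dimnames = list(NULL, c("x", "y", "z")))
  inside <- depths >= 0
  if (any(inside))
    pts[inside, ] <- spiral_point(spiral, spiral$theta_of_s(depths[inside]))
  if (any(!inside)) {
    # tangent extension through the basal origin, pointing out of the cochlea
    p0 <- spiral_point(spiral, 0)
    tangent <- (spiral_point(spiral, 1e-6) - p0) / (spiral$s_of_theta(1e-6))
    pts[!inside, ] <- rep(p0, each = sum(!inside)) +
      depths[!inside] %o% as.numeric(tangent)
  }
  structure(list(
    contacts = data.frame(contact_id = seq_len(n_contacts),
                          depth_um = depths,
                          x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3],
                          intracochlear = inside),
    tip = spiral_point(spiral, spiral$theta_of_s(tip_depth))[1, ],
    tip_depth_um = tip_depth,
    contact_spacing = contact_spacing, tip_to_ch1 = tip_to_ch1,
    n_contacts_in = sum(inside),
    group = if (sum(inside) >= n_contacts) sprintf("%dCh", n_contacts)
            else sprintf("%dCh", sum(inside))
  ), class = "electrode_track")
}

#' @export
print.electrode_track <- function(x, ...) {
  cat(sprintf("Electrode track (%s): %d/%d contacts intracochlear\n",
              x$group, x$n_contacts_in, nrow(x$contacts)))
  print(x$contacts, digits = 6)
  invisible(x)
}

# Nearest on-path point for one 3D coordinate: dense scan + local refinement.
nearest_path_theta <- function(spiral, p, n_scan = 2000) {
  th <- seq(0, spiral$theta_max, length.out = n_scan)
  pts <- spiral_point(spiral, th)
  d2 <- (pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2 + (pts[, 3] - p[3])^2
  i <- which.min(d2)
  lo <- th[max(1, i - 1)]; hi <- th[min(n_scan, i + 1)]
  f <- function(theta) {
    q <- spiral_point(spiral, theta)
    sum((q - p)^2)
  }
  opt <- stats::optimize(f, c(lo, hi), tol = 1e-10)
  list(theta = opt$minimum, dist = sqrt(opt$objective))
}

#' Insertion morphometry of an electrode track
#'
#' Projects the contacts onto the cochlear spiral (nearest-path point; a
#' warning is issued if a contact sits more than `tube_tol` off the path),
#' and derives: the arc-length insertion depth of the reference contact,
#' the percent of basilar-membrane length covered, and the insertion angle.
#' The angle is the accumulated polar angle of the reference contact about
#' the mid-modiolar (z) axis, measured from the perpendicular through the
#' summit point (the basal point where the reconstruction leaves the hook
#' region); it can exceed 360 degrees for deep insertions.
#'
#' @param track An [place_electrode()] result or a track from
#'   [read_contacts()].
#' @param spiral A [build_spiral()]. For tracks read from coordinates the
#'   spiral's z axis must already be the mid-modiolar axis.
#' @param reference Depth endpoint: the apical contact (Ch1, default), the
#'   basal contact, or the carrier tip (only available for placed tracks).
#' @param tube_tol Allowed off-path distance, µm, before a warning.
#' @return Object of class `insertion_metrics`: `depth_ch1_um`,
#'   `depth_reference_um`, `percent_bm`, `insertion_angle_deg`,
#'   `n_contacts_in`, `off_path_um` (per contact), `endpoint_convention`.
#' @export
measure_insertion <- function(track, spiral,
                              reference = c("apical_contact", "basal_contact",
                                            "carrier_tip"),
                              tube_tol = 150) {
  reference <- match.arg(reference)
  cc <- track$contacts[track$contacts$intracochlear, , drop = FALSE]
  if (nrow(cc) < 1) stop("fewer than 1 intracochlear contact")
  proj <- lapply(seq_len(nrow(cc)), function(i)
    nearest_path_theta(spiral, c(cc$x_um[i], cc$y_um[i], cc$z_um[i])))
  theta <- vapply(proj, `[[`, 0, "theta")
  off <- vapply(proj, `[[`, 0, "dist")
  if (any(off > tube_tol))
    warning(sprintf("%d contact(s) more than %g um off the spiral path; using nearest-point projection",
                    sum(off > tube_tol), tube_tol))
  s <- spiral$s_of_theta(theta)
  names(s) <- cc$contact_id
  depth_ch1 <- s[[1]]                      # contacts ordered Ch1 (apical) first
  depth_ref <- switch(reference,
    apical_contact = depth_ch1,
    basal_contact = s[[length(s)]],
    carrier_tip = {
      if (is.null(track$tip_depth_um))
        stop("carrier tip reference requires a placed track")
      track$tip_depth_um
    })
  angle <- (theta[1] - spiral$theta_ref) * 180 / pi
  if (angle < 0) {
    warning("apical contact lies within the hook region; insertion angle floored at 0")
    angle <- 0
  }
  structure(list(depth_ch1_um = depth_ch1,
                 depth_reference_um = depth_ref,
                 contact_depths_um = s,
                 percent_bm = 100 * depth_ref / spiral$bm_length,
                 insertion_angle_deg = angle,
                 n_contacts_in = nrow(cc),
                 off_path_um = stats::setNames(off, cc$contact_id),
                 endpoint_convention = reference),
            class = "insertion_metrics")
}

#' @export
print.insertion_metrics <- function(x, ...) {
  cat(sprintf(
    "Insertion: depth(Ch1) %.1f um, %.1f%% of membrane, angle %.1f deg, %d contacts in (endpoint: %s)\n",
    x$depth_ch1_um, x$percent_bm, x$insertion_angle_deg, x$n_contacts_in,
    x$endpoint_convention))
  invisible(x)
}

#' Read electrode contact coordinates from CSV
#'
#' Entry point for measured (e.g. µCT-derived) contact positions. The CSV
#' must have columns `contact_id, x_um, y_um, z_um` with 1-6 unique
#' contacts; rows are sorted by `contact_id` (Ch1 apical first). With 5
#' rows the track is flagged as a 5Ch (shallower) insertion. Successive
#' 3D contact distances are checked against the nominal 700 µm spacing and
#' reported via attribute `spacing_um`, not enforced.
#'
#' @param csv_path Path to the CSV file.
#' @return An `electrode_track` (without tip or arc depths; use
#'   [measure_insertion()]).
#' @export
read_contacts <- function(csv_path) {
  df <- utils::read.csv(csv_path)
  need <- c("contact_id", "x_um", "y_um", "z_um")
  if (!all(need %in% names(df)))
    stop("contacts CSV must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) < 1 || nrow(df) > 6) stop("contacts CSV must have 1-6 rows")
  if (anyDuplicated(df$contact_id)) stop("duplicate contact_id")
  if (any(!is.finite(as.matrix(df[need])))) stop("malformed coordinate rows")
  df <- df[order(df$contact_id), need]
  spacing <- if (nrow(df) > 1)
    sqrt(diff(df$x_um)^2 + diff(df$y_um)^2 + diff(df$z_um)^2) else numeric(0)
  track <- structure(list(
    contacts = data.frame(df, depth_um = NA_real_, intracochlear = TRUE),
    tip = NULL, tip_depth_um = NULL,
    contact_spacing = 700, tip_to_ch1 = 1000,
    n_contacts_in = nrow(df),
    group = sprintf("%dCh", nrow(df))
  ), class = "electrode_track")
  attr(track, "spacing_um") <- spacing
  track
}
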