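## Place-frequency mapping for the guinea-pig cochlea: the species-specific
## 2.59 mm/octave scaling, plus a full Greenwood-form alternative.

#' Place-frequency map
#'
#' Two interchangeable forms mapping arc-length depth from the cochlear
#' base to characteristic frequency:
#'
#' * `octave`: `f = f_base * 2^(-depth / mm_per_octave)`. The default
#'   `mm_per_octave = 2.59` is the species-specific scaling (2.59 mm, about
#'   14% of the cochlear length, per octave). `f_base = 33.6 kHz` is a
#'   calibration constant chosen so that a 5.34 mm insertion depth maps
#'   near a characteristic frequency of 8.04 kHz; it is not a measured
#'   anchor.
#' * `greenwood`: `f = A * (10^(a * x) - k)` with `x = (L - depth) / L`,
#'   using standard guinea-pig constants `A = 0.35 kHz`, `a = 2.1`,
#'   `k = 0.85`, `L = 18.5 mm`.
#'
#' @param form `"octave"` or `"greenwood"`.
#' @param f_base Octave-form frequency at depth 0 (base), Hz.
#' @param mm_per_octave Cochlear distance per octave, mm.
#' @param A_kHz,a,k,L_mm Greenwood constants (A in kHz, L in mm).
#' @return Object of class `place_frequency_map`.
#' @export
place_frequency_map <- function(form = c("octave", "greenwood"),
                                f_base = 33600, mm_per_octave = 2.59,
                                A_kHz = 0.35, a = 2.1, k = 0.85, L_mm = 18.5) {
  form <- match.arg(form)
  if (f_base <= 0 || mm_per_octave <= 0 || A_kHz <= 0 || a <= 0 || L_mm <= 0)
    stop("map constants must be positive")
  if (k < 0 || k >= 1) stop("k must lie in [0, 1)")
  structure(list(form = form, f_base = f_base, mm_per_octave = mm_per_octave,
                 A_kHz = A_kHz, a = a, k = k, L_mm = L_mm),
            class = "place_frequency_map")
}

map_length_um <- function(map) {
  if (map$form == "greenwood") map$L_mm * 1000 else Inf
}

#' Characteristic frequency at a cochlear place
#'
#' @param depth_um Arc-length depth from the basal origin, µm (vectorized);
#'   must lie within the membrane for the Greenwood form.
#' @param map A [place_frequency_map()].
#' @return Frequency in Hz.
#' @export
place_to_frequency <- function(depth_um, map = place_frequency_map()) {
  if (any(depth_um < 0) || any(depth_um > map_length_um(map)))
    stop("depth outside the membrane")
  if (map$form == "octave")
    map$f_base * 2^(-depth_um / (map$mm_per_octave * 1000))
  else {
    x <- (map$L_mm * 1000 - depth_um) / (map$L_mm * 1000)
    1000 * map$A_kHz * (10^(map$a * x) - map$k)
  }
}

#' Cochlear place of a characteristic frequency
#'
#' Exact inverse of [place_to_frequency()].
#'
#' @param f_hz Frequency in Hz (vectorized); must be within the map's range.
#' @param map A [place_frequency_map()].
#' @return Depth from the basal origin, µm.
#' @export
frequency_to_place <- function(f_hz, map = place_frequency_map()) {
  if (map$form == "octave") {
    if (any(f_hz <= 0) || any(f_hz > map$f_base))
      stop("frequency outside the map range")
    log2(map$f_base / f_hz) * map$mm_per_octave * 1000
  } else {
    f_min <- 1000 * map$A_kHz * (1 - map$k)
    f_max <- 1000 * map$A_kHz * (10^map$a - map$k)
    if (any(f_hz < f_min - 1e-9) || any(f_hz > f_max + 1e-9))
      stop("frequency outside the map range")
    x <- log10(f_hz / (1000 * map$A_kHz) + map$k) / map$a
    map$L_mm * 1000 * (1 - x)
  }
}

#' Convert a frequency extent in octaves to cochlear distance
#'
#' @param octaves Extent in octaves, `>= 0`.
#' @param mm_per_octave Scaling, mm per octave.
#' @return Distance in mm.
#' @export
#' @examples
#' octaves_to_distance(1)    # 2.59 mm, i.e. 2.6 mm to one decimal
#' octaves_to_distance(0.5)  # 1.295 mm, i.e. 1.3 mm
octaves_to_distance <- function(octaves, mm_per_octave = 2.59) {
  if (any(octaves < 0)) stop("octaves must be >= 0")
  octaves * mm_per_octave
}

#' Lowest characteristic frequency reached by an insertion
#'
#' Characteristic frequency at the apical contact's place: the lower edge
#' of the cochlear region covered by the electrode.
#'
#' @param metrics An [measure_insertion()] result, or a depth in µm.
#' @param map A [place_frequency_map()].
#' @return Frequency in Hz.
#' @export
lowest_cf <- function(metrics, map = place_frequency_map()) {
  depth <- if (inherits(metrics, "insertion_metrics"))
    metrics$depth_ch1_um else metrics
  place_to_frequency(depth, map)
}
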