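#' Call archetypes for the synthetic repertoire
#'
#' The pipeline is exercised on synthetic corpora built from ten call
#' archetypes named after the indri vocal types: clacson, grunt, hum, kiss,
#' long tonal call, roar, short tonal call, wheeze, wheezing grunt and
#' songbit. An archetype is a parametric recipe: a duration range, a
#' fundamental-frequency (f0) range and contour, a harmonic count, an
#' optional pulse rate (amplitude modulation, for the low-pitched pulsed
#' calls), an optional noise band (for the broadband noisy calls), and a
#' tonal/noise mixing fraction.
#'
#' The qualitative structure follows the field descriptions: grunts and hums
#' are low-frequency, low-intensity calls whose ranges overlap (hums being
#' the more harmonic, grunts the more pulsed), kisses and wheezes are brief
#' medium-intensity calls that also overlap, roars and the tonal calls carry
#' a chaotic (noisy) component, and songbits are harmonic frequency-modulated
#' song units. All numeric values are invented for the generator — the source
#' analysis published no per-type acoustic measurements — and were fixed once
#' so that the discrete types separate cleanly while the designated graded
#' pairs (grunt/hum, kiss/wheeze) overlap.
#'
#' @param name Archetype name (one of the ten repertoire labels).
#' @param duration_range Length-2 numeric, seconds, `0 < min <= max`.
#' @param f0_range Length-2 numeric, Hz.
#' @param f0_contour One of `"flat"`, `"rising"`, `"falling"`, `"modulated"`.
#' @param n_harmonics Number of harmonic partials (>= 1).
#' @param pulse_rate Amplitude-modulation rate in Hz, or `NA` for unpulsed.
#' @param pulse_depth Modulation depth in `[0, 1]` (0 = no audible pulsing);
#'   a length-2 range is drawn per call, which is how graded pairs blend
#'   into one another.
#' @param noise_band Length-2 numeric band (Hz) for the noise component, or
#'   `NULL`/`NA` for purely tonal types.
#' @param tonal_noise_mix Fraction of energy in the tonal component, in
#'   `[0, 1]` (1 = pure tone stack, 0 = pure band noise); a length-2 range
#'   is drawn per call.
#' @param amplitude_envelope `"rect"` or `"attack_decay"`.
#' @param graded Optional shared-continuum specification for graded pairs: a
#'   list with `u` (the sub-interval of `[0, 1]` this type draws its latent
#'   position from) and endpoint pairs `duration`, `f0`, `mix`, `depth`
#'   (value at `u = 0`, value at `u = 1`; either direction). When present,
#'   one latent `u` is drawn per call and all four parameters are
#'   interpolated from it jointly, so the two members of a pair lie on one
#'   acoustic continuum and blend where their `u` intervals overlap.
#' @return A `call_archetype` object (a validated list).
#' @export
call_archetype <- function(name, duration_range, f0_range,
                           f0_contour = c("flat", "rising", "falling", "modulated"),
                           n_harmonics = 1L, pulse_rate = NA_real_,
                           pulse_depth = 0.45,
                           noise_band = NULL, tonal_noise_mix = 1,
                           amplitude_envelope = c("rect", "attack_decay"),
                           graded = NULL) {
  f0_contour <- match.arg(f0_contour)
  amplitude_envelope <- match.arg(amplitude_envelope)
  stopifnot(length(duration_range) == 2L, length(f0_range) == 2L)
  if (!(duration_range[1] > 0 && duration_range[1] <= duration_range[2]))
    stop("duration_range must satisfy 0 < min <= max")
  if (!(f0_range[1] > 0 && f0_range[1] <= f0_range[2]))
    stop("f0_range must satisfy 0 < min <= max")
  tonal_noise_mix <- range_pair(tonal_noise_mix, "tonal_noise_mix")
  pulse_depth <- range_pair(pulse_depth, "pulse_depth")
  if (any(tonal_noise_mix < 0) || any(tonal_noise_mix > 1))
    stop("tonal_noise_mix must lie in [0, 1]")
  if (any(pulse_depth < 0) || any(pulse_depth > 1))
    stop("pulse_depth must lie in [0, 1]")
  if (!is.null(noise_band) && !all(is.na(noise_band))) {
    stopifnot(length(noise_band) == 2L, noise_band[1] >= 0,
              noise_band[1] < noise_band[2])
  } else {
    noise_band <- NULL
  }
  if (!is.null(graded)) {
    stopifnot(is.list(graded),
              all(c("u", "duration", "f0", "mix", "depth") %in% names(graded)),
              length(graded$u) == 2L, graded$u[1] >= 0, graded$u[2] <= 1,
              graded$u[1] < graded$u[2])
  }
  structure(list(name = name,
                 duration_range = as.numeric(duration_range),
                 f0_range = as.numeric(f0_range),
                 f0_contour = f0_contour,
                 n_harmonics = as.integer(n_harmonics),
                 pulse_rate = as.numeric(pulse_rate),
                 pulse_depth = pulse_depth,
                 noise_band = if (is.null(noise_band)) NULL else as.numeric(noise_band),
                 tonal_noise_mix = tonal_noise_mix,
                 amplitude_envelope = amplitude_envelope,
                 graded = graded),
            class = "call_archetype")
}

# scalar -> degenerate range; validates ordering
range_pair <- function(x, what) {
  x <- as.numeric(x)
  if (length(x) == 1L) x <- c(x, x)
  if (length(x) != 2L || x[1] > x[2])
    stop(what, " must be a scalar or an increasing length-2 range")
  x
}

#' @export
print.call_archetype <- function(x, ...) {
  cat(sprintf("call_archetype '%s': dur %.2f-%.2f s, f0 %g-%g Hz (%s, %d harm)",
              x$name, x$duration_range[1], x$duration_range[2],
              x$f0_range[1], x$f0_range[2], x$f0_contour, x$n_harmonics))
  if (!is.na(x$pulse_rate))
    cat(sprintf(", pulsed @ %g Hz (depth %.2f-%.2f)", x$pulse_rate,
                x$pulse_depth[1], x$pulse_depth[2]))
  if (!is.null(x$noise_band))
    cat(sprintf(", noise %g-%g Hz (tonal mix %.2f-%.2f)",
                x$noise_band[1], x$noise_band[2],
                x$tonal_noise_mix[1], x$tonal_noise_mix[2]))
  cat("\n")
  invisible(x)
}

#' The ten repertoire archetype names
#' @return Character vector of the ten vocal-type labels, in alphabetical
#'   order.
#' @export
archetype_names <- function() {
  c("clacson", "grunt", "hum", "kiss", "long_tonal",
    "roar", "short_tonal", "wheeze", "wheezing_grunt", "songbit")
}

#' Default archetype set
#'
#' Returns the ten archetypes the synthetic corpus is built from. Two pairs
#' are graded by construction — grunt/hum share overlapping f0 and duration
#' ranges, kiss/wheeze share overlapping noise bands and durations — while
#' clacson, songbit, wheezing grunt, roar and the two tonal calls occupy
#' mutually distinct regions of the duration-by-spectrum plane.
#'
#' @return Named list of ten [call_archetype()] objects.
#' @export
default_archetypes <- function() {
  a <- list(
    # discrete, loud mid-frequency alarm honk: dense harmonic stack
    clacson = call_archetype("clacson",
      duration_range = c(0.38, 0.46), f0_range = c(880, 940),
      f0_contour = "falling", n_harmonics = 4L,
      tonal_noise_mix = 0.95, amplitude_envelope = "attack_decay"),
    # graded pair 1a: low-pitched pulsed call, partly noisy. Grunt and hum
    # share one latent continuum (see `graded`): the grunt end is shorter,
    # lower, noisier and strongly pulsed; the hum end longer, cleaner and
    # unpulsed; their u intervals overlap so the middle of the continuum is
    # genuinely ambiguous
    grunt = call_archetype("grunt",
      duration_range = c(0.240, 0.296), f0_range = c(108, 133),
      f0_contour = "flat", n_harmonics = 6L,
      pulse_rate = 27, pulse_depth = c(0.16, 0.38),
      noise_band = c(80, 900), tonal_noise_mix = c(0.48, 0.68),
      graded = list(u = c(0, 0.60), duration = c(0.24, 0.33),
                    f0 = c(108, 148), mix = c(0.48, 0.82),
                    depth = c(0.38, 0.02))),
    # graded pair 1b: the hum ("weak grunt") end of the same continuum —
    # overlapping f0 and duration, cleaner harmonic structure, at most
    # weakly pulsed
    hum = call_archetype("hum",
      duration_range = c(0.291, 0.330), f0_range = c(131, 148),
      f0_contour = "flat", n_harmonics = 6L,
      pulse_rate = 27, pulse_depth = c(0.02, 0.17),
      noise_band = c(80, 900), tonal_noise_mix = c(0.68, 0.82),
      graded = list(u = c(0.575, 1), duration = c(0.24, 0.33),
                    f0 = c(108, 148), mix = c(0.48, 0.82),
                    depth = c(0.38, 0.02))),
    # graded pair 2a: brief mid-high call, tonal plus broadband hiss; kiss
    # and wheeze share a second continuum from short/tonal (kiss end) to
    # longer/noisier (wheeze end)
    kiss = call_archetype("kiss",
      duration_range = c(0.10, 0.15), f0_range = c(2310, 2600),
      f0_contour = "falling", n_harmonics = 2L,
      noise_band = c(1950, 5900), tonal_noise_mix = c(0.37, 0.60),
      amplitude_envelope = "attack_decay",
      graded = list(u = c(0, 0.58), duration = c(0.10, 0.18),
                    f0 = c(2600, 2100), mix = c(0.60, 0.20),
                    depth = c(0, 0))),
    # discrete: long low-mid tonal call with a chaotic component; the
    # longest call in the repertoire by a wide margin
    long_tonal = call_archetype("long_tonal",
      duration_range = c(1.15, 1.35), f0_range = c(280, 320),
      f0_contour = "rising", n_harmonics = 5L,
      noise_band = c(250, 2500), tonal_noise_mix = 0.75),
    # discrete: broadband noisy roar, mid-band mass, weak tonal skeleton
    roar = call_archetype("roar",
      duration_range = c(0.65, 0.80), f0_range = c(210, 240),
      f0_contour = "flat", n_harmonics = 3L,
      noise_band = c(150, 2500), tonal_noise_mix = 0.1),
    # discrete: short tonal call in the top register, chaotic component
    short_tonal = call_archetype("short_tonal",
      duration_range = c(0.14, 0.20), f0_range = c(7200, 7400),
      f0_contour = "falling", n_harmonics = 1L,
      noise_band = c(6800, 8600), tonal_noise_mix = 0.7,
      amplitude_envelope = "attack_decay"),
    # graded pair 2b: the wheeze end of the kiss continuum — overlapping
    # band, noisier and slightly longer
    wheeze = call_archetype("wheeze",
      duration_range = c(0.13, 0.18), f0_range = c(2100, 2390),
      f0_contour = "falling", n_harmonics = 2L,
      noise_band = c(1950, 5900), tonal_noise_mix = c(0.20, 0.43),
      amplitude_envelope = "attack_decay",
      graded = list(u = c(0.42, 1), duration = c(0.10, 0.18),
                    f0 = c(2600, 2100), mix = c(0.60, 0.20),
                    depth = c(0, 0))),
    # discrete: grunt-like pulsed core plus a strong high-band noisy tail
    wheezing_grunt = call_archetype("wheezing_grunt",
      duration_range = c(0.35, 0.50), f0_range = c(100, 150),
      f0_contour = "flat", n_harmonics = 6L,
      pulse_rate = 24, pulse_depth = c(0.35, 0.50),
      noise_band = c(2500, 6500), tonal_noise_mix = c(0.40, 0.50)),
    # discrete: harmonic frequency-modulated song unit in the high register
    songbit = call_archetype("songbit",
      duration_range = c(0.6, 0.9), f0_range = c(1600, 1700),
      f0_contour = "modulated", n_harmonics = 4L,
      tonal_noise_mix = 0.95)
  )
  a[archetype_names()]
}

#' Published per-type sample sizes of the reference corpus
#'
#' The call counts per vocal type in the field corpus the pipeline emulates
#' (3360 calls in total). Used as the default composition of synthetic
#' corpora after proportional scaling.
#'
#' @return Named integer vector over the ten vocal types.
#' @export
reference_counts <- function() {
  c(clacson = 622L, grunt = 1145L, hum = 418L, kiss = 296L,
    long_tonal = 31L, roar = 62L, short_tonal = 44L, wheeze = 150L,
    wheezing_grunt = 297L, songbit = 295L)
}

#' Scale per-type counts proportionally with an exact total
#'
#' Each count is scaled by `factor` and rounded half-up; the largest class
#' then absorbs any remainder so the total equals
#' `round(sum(counts) * factor)` exactly.
#'
#' @param counts Named non-negative integer vector.
#' @param factor Positive scaling factor (e.g. `0.1`).
#' @return Named integer vector with the same names.
#' @export
scale_counts <- function(counts, factor) {
  stopifnot(factor > 0, all(counts >= 0))
  target <- round_half_up(sum(counts) * factor)
  scaled <- vapply(counts * factor, round_half_up, numeric(1))
  rem <- target - sum(scaled)
  if (rem != 0) {
    big <- which.max(counts)
    scaled[big] <- scaled[big] + rem
    if (scaled[big] < 0) stop("scaling remainder cannot be absorbed")
  }
  stats::setNames(as.integer(scaled), names(counts))
}

round_half_up <- function(x) floor(x + 0.5)

#' Default synthetic corpus composition
#'
#' The reference per-type sample sizes scaled to one tenth (336 calls).
#' This is the corpus that emulates the published composition, with its
#' heavy grunt dominance.
#'
#' @return Named integer vector over the ten vocal types (sums to 336).
#' @export
default_counts <- function() scale_counts(reference_counts(), 0.1)

#' Balanced synthetic corpus composition
#'
#' Thirty calls of each vocal type (300 calls), the default corpus of
#' [run_pipeline()]. A balanced design keeps every type's neighborhood
#' structure comparable at desk scale; the imbalanced [default_counts()]
#' corpus instead reproduces the published composition, at the cost of the
#' dominant grunt/hum mass spreading over several clusters.
#'
#' @return Named integer vector over the ten vocal types (sums to 300).
#' @export
balanced_counts <- function() {
  stats::setNames(rep(30L, 10L), archetype_names())
}
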