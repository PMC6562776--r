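#' Synthesize one call from an archetype
#'
#' Draws a duration and an f0 from the archetype's ranges, builds a harmonic
#' stack on the drawn f0 contour (partial amplitudes rolling off as 1/h,
#' random phases), adds band-limited Gaussian noise (white noise whose
#' spectrum is zeroed outside the archetype's noise band — a zero-phase
#' band-pass, so the in-band content is spectrally flat), mixes the two by
#' the archetype's tonal fraction (applied to RMS-normalized components so
#' the fraction is an energy share), applies pulsing and the amplitude
#' envelope, and peak-normalizes to 0.9 full scale.
#'
#' Frequency contours: `rising`/`falling` sweep f0 linearly by +/-25% over
#' the call; `modulated` adds a 5-Hz vibrato of 12% depth (the
#' frequency-modulated song-unit shape).
#'
#' @param archetype A [call_archetype()].
#' @param sample_rate Sampling rate in Hz (default 44100, the rate of the
#'   field recordings the generator stands in for).
#' @param seed Integer seed; the same archetype and seed give a bit-identical
#'   waveform.
#' @return An [audio_clip()].
#' @export
synth_call <- function(archetype, sample_rate = 44100, seed = 1L) {
  stopifnot(inherits(archetype, "call_archetype"))
  nyq <- sample_rate / 2
  if (archetype$f0_range[2] * archetype$n_harmonics > nyq)
    stop(sprintf("archetype '%s': f0 * n_harmonics exceeds Nyquist (%g Hz)",
                 archetype$name, nyq))
  if (!is.null(archetype$noise_band) && archetype$noise_band[2] > nyq)
    stop(sprintf("archetype '%s': noise band exceeds Nyquist", archetype$name))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  if (!is.null(archetype$graded)) {
    # graded types live on one latent continuum: a single u per call drives
    # duration, f0, mix and pulse depth jointly
    g <- archetype$graded
    u <- stats::runif(1, g$u[1], g$u[2])
    lerp <- function(ab) ab[1] + u * (ab[2] - ab[1])
    dur <- lerp(g$duration)
    f0 <- lerp(g$f0)
    mix <- lerp(g$mix)
    depth <- lerp(g$depth)
  } else {
    dur <- stats::runif(1, archetype$duration_range[1], archetype$duration_range[2])
    f0 <- stats::runif(1, archetype$f0_range[1], archetype$f0_range[2])
    mix <- stats::runif(1, archetype$tonal_noise_mix[1], archetype$tonal_noise_mix[2])
    depth <- stats::runif(1, archetype$pulse_depth[1], archetype$pulse_depth[2])
  }
  n <- max(10L, as.integer(round(dur * sample_rate)))
  t <- (seq_len(n) - 1L) / sample_rate

  # instantaneous frequency track, then phase by cumulative sum
  u <- t / t[n]
  f_inst <- switch(archetype$f0_contour,
    flat      = rep(f0, n),
    rising    = f0 * (1 + 0.25 * u),
    falling   = f0 * (1 - 0.25 * u),
    modulated = f0 * (1 + 0.12 * sin(2 * pi * 5 * t)))
  phase <- 2 * pi * cumsum(f_inst) / sample_rate

  tonal <- numeric(n)
  if (mix > 0) {
    # sine-aligned partials: a deterministic crest factor keeps the
    # peak-normalized energy scale stable within a type
    for (h in seq_len(archetype$n_harmonics)) {
      if (max(f_inst) * h >= nyq) break
      tonal <- tonal + (1 / h) * sin(h * phase)
    }
  }
  noise <- numeric(n)
  if (!is.null(archetype$noise_band) && mix < 1) {
    noise <- bandlimited_noise(n, sample_rate, archetype$noise_band)
  }

  x <- numeric(n)
  if (rms(tonal) > 0) x <- x + sqrt(mix) * tonal / rms(tonal)
  if (rms(noise) > 0) x <- x + sqrt(1 - mix) * noise / rms(noise)
  if (all(x == 0)) stop("archetype produced a silent call (mix/band mismatch)")

  if (!is.na(archetype$pulse_rate) && depth > 0) {
    # raised-cosine amplitude modulation: periodic pulsing without clipping;
    # depth varies per call so pulsed and unpulsed types can grade into each
    # other
    x <- x * (1 - depth / 2 + (depth / 2) * cos(2 * pi * archetype$pulse_rate * t))
  }
  if (archetype$amplitude_envelope == "attack_decay") {
    atk <- pmin(1, t / (0.15 * t[n]))
    dec <- exp(-3 * pmax(0, u - 0.5))
    x <- x * atk * dec
  }
  x <- 0.9 * x / max(abs(x))
  audio_clip(x, sample_rate)
}

# white Gaussian noise restricted to [lo, hi) Hz by zeroing out-of-band FFT
# bins (zero-phase band-pass; in-band spectrum stays flat)
bandlimited_noise <- function(n, sample_rate, band) {
  w <- stats::rnorm(n)
  spec <- stats::fft(w)
  f <- (seq_len(n) - 1L) * sample_rate / n
  f_fold <- pmin(f, sample_rate - f)  # frequency of each bin, folded
  keep <- f_fold >= band[1] & f_fold < band[2]
  spec[!keep] <- 0
  Re(stats::fft(spec, inverse = TRUE)) / n
}

rms <- function(x) sqrt(mean(x^2))

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Plan a corpus: file names and labels for given per-type counts
#'
#' Bookkeeping step shared by [synth_corpus()]: expands per-type counts into
#' one manifest row per call, without synthesizing audio.
#'
#' @param counts Named non-negative integer vector; names must be archetype
#'   names.
#' @return A data.frame with columns `file` and `label`; `sum(counts)` rows.
#' @export
plan_corpus <- function(counts) {
  if (length(counts) == 0L || sum(counts) == 0L)
    stop("corpus plan needs at least one call (counts are empty or all zero)")
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be named by archetype")
  if (any(counts < 0)) stop("counts must be non-negative")
  labels <- rep(names(counts), times = counts)
  idx <- unlist(lapply(counts, seq_len), use.names = FALSE)
  data.frame(file = sprintf("%s_%03d.wav", labels, idx),
             label = labels, stringsAsFactors = FALSE)
}

#' Synthesize a labelled call corpus
#'
#' Writes one WAV file per call plus a `manifest.csv` (columns `file,label`)
#' into `out_dir`. Each call gets its own sub-seed drawn from `seed`, so the
#' corpus is bit-identical under a fixed (archetypes, counts, seed) triple.
#'
#' @param counts Named per-type call counts (default [default_counts()],
#'   336 calls).
#' @param seed Master seed for the corpus.
#' @param out_dir Output directory (created if missing).
#' @param archetypes Named list of [call_archetype()] (default
#'   [default_archetypes()]); must cover every name in `counts`.
#' @param sample_rate Sampling rate in Hz.
#' @return A `corpus_manifest`: data.frame with columns `file` (paths,
#'   relative to `out_dir`) and `label`, with attributes `dir`,
#'   `sample_rate` and `seed`.
#' @export
synth_corpus <- function(counts = default_counts(), seed = 1L,
                         out_dir = tempfile("corpus"),
                         archetypes = default_archetypes(),
                         sample_rate = 44100) {
  plan <- plan_corpus(counts)
  missing_arch <- setdiff(unique(plan$label), names(archetypes))
  if (length(missing_arch))
    stop("no archetype for: ", paste(missing_arch, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, nrow(plan))
  for (i in seq_len(nrow(plan))) {
    clip <- synth_call(archetypes[[plan$label[i]]], sample_rate = sample_rate,
                       seed = sub_seeds[i])
    write_wav(clip, file.path(out_dir, plan$file[i]))
  }
  utils::write.csv(plan, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  structure(plan, dir = out_dir, sample_rate = sample_rate,
            seed = as.integer(seed), class = c("corpus_manifest", "data.frame"))
}

#' Read a corpus manifest from disk
#'
#' @param path Path to a `manifest.csv` (columns `file,label`) or to a
#'   directory containing one.
#' @param sample_rate Expected sample rate (stored on the manifest).
#' @return A `corpus_manifest` data.frame.
#' @export
read_manifest <- function(path, sample_rate = 44100) {
  if (dir.exists(path)) path <- file.path(path, "manifest.csv")
  if (!file.exists(path)) stop("no manifest at: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("file", "label") %in% names(df)))
    stop("manifest must have columns file,label")
  structure(df, dir = dirname(path), sample_rate = sample_rate,
            class = c("corpus_manifest", "data.frame"))
}

#' Absolute file paths of a manifest's entries
#' @param manifest A `corpus_manifest`.
#' @return Character vector of paths.
#' @export
manifest_paths <- function(manifest) {
  file.path(attr(manifest, "dir"), manifest$file)
}
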