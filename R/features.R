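#' Feature-extraction configuration
#'
#' The feature set mirrors the portioned band-energy description of calls:
#' each call contributes its overall duration plus, for each of
#' `n_portions` equal-length time portions, the signal energy in each of
#' `n_bands` contiguous equal-width frequency bands tiling
#' `[f_min, f_max)` Hz. At the defaults (10 portions, 15 bands on
#' [50, 15000) Hz) every call yields `1 + 10 * 15 = 151` attributes.
#'
#' @param n_portions Number of equal time portions (default 10).
#' @param f_min,f_max Frequency range analysed, Hz (defaults 50 and 15000).
#' @param n_bands Number of equal-width bands tiling `[f_min, f_max)`
#'   (default 15).
#' @param normalize Peak-normalize each clip to 0.9 full scale before
#'   analysis (default `TRUE`), emulating the level normalization applied to
#'   field recordings before measurement.
#' @return A `feature_config` list.
#' @export
feature_config <- function(n_portions = 10L, f_min = 50, f_max = 15000,
                           n_bands = 15L, normalize = TRUE) {
  stopifnot(n_portions >= 1L, n_bands >= 1L, f_min >= 0, f_min < f_max)
  structure(list(n_portions = as.integer(n_portions), f_min = f_min,
                 f_max = f_max, n_bands = as.integer(n_bands),
                 normalize = isTRUE(normalize)),
            class = "feature_config")
}

#' Split a clip into equal time portions
#'
#' When the sample count is not divisible by `n_portions`, the `r` leftover
#' samples go one each to the first `r` portions, so portion lengths differ
#' by at most one sample and concatenating the portions reproduces the input
#' exactly.
#'
#' @param clip An [audio_clip()].
#' @param n_portions Number of portions.
#' @return List of `n_portions` [audio_clip()] objects.
#' @export
split_portions <- function(clip, n_portions = 10L) {
  n <- length(clip$samples)
  if (n < n_portions)
    stop(sprintf("clip of %d samples cannot be split into %d portions", n, n_portions))
  base <- n %/% n_portions
  r <- n %% n_portions
  len <- rep(base, n_portions) + c(rep(1L, r), rep(0L, n_portions - r))
  ends <- cumsum(len)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_len(n_portions), function(i)
    audio_clip(clip$samples[starts[i]:ends[i]], clip$sample_rate))
}

#' Band energy of a segment
#'
#' Energy of the signal in the frequency band `[f_lo, f_hi)`, defined as the
#' integral of the one-sided power spectral density over the band, scaled so
#' the integral over the full `[0, Nyquist]` range equals
#' `sum(x^2) / sample_rate` (Parseval convention; units amplitude^2 * s).
#' Computation is by rectangular-window periodogram: each DFT bin is
#' assigned to the band containing its centre frequency, bands are half-open
#' on the right so adjacent bands never double-count a bin, except that a
#' band whose upper edge equals the Nyquist frequency also includes the
#' Nyquist bin (so a tiling of `[0, Nyquist)` conserves total energy
#' exactly).
#'
#' @param segment An [audio_clip()].
#' @param f_lo,f_hi Band edges in Hz, `0 <= f_lo < f_hi <= Nyquist`.
#' @return Non-negative scalar energy.
#' @export
band_energy <- function(segment, f_lo, f_hi) {
  nyq <- segment$sample_rate / 2
  if (!(f_lo >= 0 && f_lo < f_hi && f_hi <= nyq + 1e-9))
    stop(sprintf("invalid band [%g, %g) for Nyquist %g Hz", f_lo, f_hi, nyq))
  pg <- periodogram_energies(segment)
  sum(pg$energy[band_bin_mask(pg$freq, f_lo, f_hi, nyq)])
}

# one-sided periodogram energies per bin; sum over all bins == sum(x^2)/fs
periodogram_energies <- function(segment) {
  x <- segment$samples
  n <- length(x)
  fs <- segment$sample_rate
  spec <- stats::fft(x)
  half <- n %/% 2L
  k <- 0:half
  w <- rep(2, half + 1L)
  w[1] <- 1
  if (n %% 2L == 0L) w[half + 1L] <- 1   # Nyquist bin (even n) not doubled
  energy <- w * Mod(spec[k + 1L])^2 / (n * fs)
  list(freq = k * fs / n, energy = energy)
}

band_bin_mask <- function(freq, f_lo, f_hi, nyq) {
  m <- freq >= f_lo & freq < f_hi
  if (abs(f_hi - nyq) <= 1e-9) m <- m | abs(freq - nyq) <= 1e-9
  m
}

#' Extract the portioned band-energy feature vector of a call
#'
#' @param clip An [audio_clip()].
#' @param config A [feature_config()].
#' @return A `feature_vector`: list with `duration` (seconds) and
#'   `band_energies` (an `n_portions x n_bands` matrix). `as.numeric()`
#'   flattens it portion-major: duration first, then
#'   portion 1 bands 1..n_bands, portion 2, and so on (151 values at the
#'   defaults).
#' @export
extract_features <- function(clip, config = feature_config()) {
  nyq <- clip$sample_rate / 2
  if (config$f_max > nyq + 1e-9)
    stop(sprintf("f_max = %g Hz above Nyquist (%g Hz)", config$f_max, nyq))
  if (length(clip$samples) < config$n_portions)
    stop("clip shorter than the number of portions")
  x <- clip
  if (config$normalize && max(abs(x$samples)) > 0)
    x <- audio_clip(0.9 * x$samples / max(abs(x$samples)), x$sample_rate)
  edges <- seq(config$f_min, config$f_max, length.out = config$n_bands + 1L)
  portions <- split_portions(x, config$n_portions)
  bands <- t(vapply(portions, function(p) {
    pg <- periodogram_energies(p)
    vapply(seq_len(config$n_bands), function(b)
      sum(pg$energy[band_bin_mask(pg$freq, edges[b], edges[b + 1L], nyq)]),
      numeric(1))
  }, numeric(config$n_bands)))
  dimnames(bands) <- list(sprintf("p%02d", seq_len(config$n_portions)),
                          sprintf("b%02d", seq_len(config$n_bands)))
  structure(list(duration = clip_duration(clip), band_energies = bands,
                 config = config),
            class = "feature_vector")
}

#' @export
as.double.feature_vector <- function(x, ...) {
  c(x$duration, as.vector(t(x$band_energies)))
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("feature_vector: duration %.3f s + %d x %d band energies (%d attributes)\n",
              x$duration, nrow(x$band_energies), ncol(x$band_energies),
              1L + length(x$band_energies)))
  invisible(x)
}

#' Column names of the flattened feature vector
#' @param config A [feature_config()].
#' @return Character vector `duration, p01_b01, ..` of length
#'   `1 + n_portions * n_bands`.
#' @export
feature_names <- function(config = feature_config()) {
  c("duration",
    as.vector(t(outer(seq_len(config$n_portions), seq_len(config$n_bands),
                      function(p, b) sprintf("p%02d_b%02d", p, b)))))
}

#' Build the feature table of a corpus
#'
#' Extracts features for every manifest entry, in manifest order, failing
#' fast with the offending path if any file is missing or unreadable.
#'
#' @param manifest A `corpus_manifest` (see [synth_corpus()],
#'   [read_manifest()]).
#' @param config A [feature_config()].
#' @return A `feature_table` data.frame with columns `call_id`, `label`,
#'   `duration`, `p01_b01`, .., `p10_b15`.
#' @export
build_feature_table <- function(manifest, config = feature_config()) {
  paths <- manifest_paths(manifest)
  rows <- lapply(seq_along(paths), function(i) {
    if (!file.exists(paths[i]))
      stop("feature extraction failed, missing file: ", paths[i])
    fv <- tryCatch(extract_features(read_wav(paths[i]), config),
                   error = function(e)
                     stop("feature extraction failed for ", paths[i], ": ",
                          conditionMessage(e), call. = FALSE))
    as.numeric(fv)
  })
  mat <- do.call(rbind, rows)
  colnames(mat) <- feature_names(config)
  out <- data.frame(call_id = manifest$file, label = manifest$label,
                    mat, stringsAsFactors = FALSE, check.names = FALSE)
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Numeric feature matrix of a feature table
#' @param table A `feature_table` (or any data.frame with `call_id`/`label`
#'   metadata columns followed by numeric features).
#' @return Numeric matrix, one row per call.
#' @export
feature_matrix <- function(table) {
  meta <- intersect(c("call_id", "label", "cluster"), names(table))
  as.matrix(table[, setdiff(names(table), meta), drop = FALSE])
}
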