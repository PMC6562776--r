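test_that("default archetype set covers the ten vocal types with the expected structure", {
  a <- default_archetypes()
  expect_length(a, 10L)
  expect_setequal(names(a), archetype_names())
  expect_setequal(vapply(a, `[[`, "", "name"), archetype_names())
  # graded pairs share acoustic range
  overlap <- function(r1, r2) max(r1[1], r2[1]) < min(r1[2], r2[2])
  expect_true(overlap(a$grunt$f0_range, a$hum$f0_range))
  expect_true(overlap(a$grunt$duration_range, a$hum$duration_range))
  expect_true(overlap(a$kiss$f0_range, a$wheeze$f0_range))
  expect_true(overlap(a$kiss$noise_band, a$wheeze$noise_band))
  # song units are harmonic and frequency modulated
  expect_gte(a$songbit$n_harmonics, 2L)
  expect_identical(a$songbit$f0_contour, "modulated")
})

test_that("archetype validation rejects inconsistent recipes", {
  expect_error(call_archetype("x", c(0, 1), c(100, 200)), "duration_range")
  expect_error(call_archetype("x", c(0.2, 0.1), c(100, 200)), "duration_range")
  expect_error(call_archetype("x", c(0.1, 0.2), c(100, 200), tonal_noise_mix = 1.2),
               "tonal_noise_mix")
  expect_error(call_archetype("x", c(0.1, 0.2), c(100, 200), noise_band = c(500, 100)))
})

test_that("a pure-tone archetype synthesizes a clip dominated by its f0", {
  tone <- call_archetype("tone", c(0.5, 0.5), c(500, 500), "flat",
                         n_harmonics = 1L, tonal_noise_mix = 1)
  clip <- synth_call(tone, seed = 4)
  total <- band_energy(clip, 50, 15000)
  expect_gt(band_energy(clip, 400, 600) / total, 0.99)
  # spectral peak sits at 500 Hz
  spec <- Mod(fft(clip$samples))^2
  half <- seq_len(length(spec) %/% 2)
  peak_hz <- (which.max(spec[half]) - 1) * clip$sample_rate / length(spec)
  expect_lt(abs(peak_hz - 500), 5)
})

test_that("a pure-noise archetype concentrates its energy in the noise band", {
  noisy <- call_archetype("noisy", c(0.4, 0.4), c(100, 100), "flat",
                          noise_band = c(2000, 6000), tonal_noise_mix = 0)
  clip <- synth_call(noisy, seed = 9)
  expect_gte(band_energy(clip, 2000, 6000) / band_energy(clip, 50, 15000), 0.9)
})

test_that("synthesis is deterministic under a fixed seed and never clips", {
  for (a in default_archetypes()) {
    c1 <- synth_call(a, seed = 11)
    c2 <- synth_call(a, seed = 11)
    expect_identical(c1$samples, c2$samples)
    expect_lte(max(abs(c1$samples)), 1)
    expect_false(identical(c1$samples, synth_call(a, seed = 12)$samples))
    d <- clip_duration(c1)
    expect_gte(d, a$duration_range[1] - 1e-4)
    expect_lte(d, a$duration_range[2] + 1e-4)
  }
})

test_that("archetypes whose harmonics exceed Nyquist are rejected", {
  bad <- call_archetype("bad", c(0.1, 0.2), c(15000, 16000), n_harmonics = 2L)
  expect_error(synth_call(bad, seed = 1), "Nyquist")
})

test_that("corpus plans count calls per label and reject empty requests", {
  plan <- plan_corpus(setNames(rep(30L, 10), archetype_names()))
  expect_equal(nrow(plan), 300L)
  expect_true(all(table(plan$label) == 30L))
  expect_error(plan_corpus(integer(0)), "empty")
  expect_error(plan_corpus(c(grunt = 0L)), "empty|zero")
  expect_error(plan_corpus(c(grunt = -1L, hum = 5L)), "non-negative")
})

test_that("proportional count scaling is exact with round-half-up and remainder absorption", {
  ref <- reference_counts()
  expect_equal(sum(ref), 3360L)
  scaled <- scale_counts(ref, 0.1)
  expect_equal(sum(scaled), 336L)
  # round-half-up everywhere; the largest class (grunts) absorbs the excess
  expect_equal(scaled[["clacson"]], 62L)
  expect_equal(scaled[["grunt"]], 114L)
  expect_equal(scaled[["hum"]], 42L)
  expect_equal(scaled[["long_tonal"]], 3L)
  expect_equal(scaled[["songbit"]], 30L)
  expect_identical(default_counts(), scaled)
  expect_equal(sum(balanced_counts()), 300L)
})

test_that("synthesized corpora are written, readable and bit-identical under a seed", {
  counts <- c(grunt = 2L, kiss = 2L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- synth_corpus(counts, seed = 5, out_dir = d1)
  m2 <- synth_corpus(counts, seed = 5, out_dir = d2)
  expect_equal(nrow(m1), 4L)
  expect_true(all(file.exists(manifest_paths(m1))))
  for (i in seq_len(nrow(m1))) {
    b1 <- readBin(manifest_paths(m1)[i], "raw", 1e6)
    b2 <- readBin(manifest_paths(m2)[i], "raw", 1e6)
    expect_identical(b1, b2)
  }
  # manifest round trip
  m3 <- read_manifest(d1)
  expect_equal(m3$file, m1$file)
  expect_equal(m3$label, m1$label)
})

test_that("WAV write/read round trip preserves the waveform to 16-bit precision", {
  set.seed(2)
  clip <- audio_clip(runif(5000, -0.9, 0.9), 44100)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(clip, path)
  back <- read_wav(path)
  expect_equal(back$sample_rate, 44100)
  expect_lt(max(abs(back$samples - clip$samples)), 1 / 32768 + 1e-9)
})

test_that("extracted features separate discrete types and keep graded pairs closest", {
  counts <- setNames(rep(6L, 10), archetype_names())
  dir <- withr::local_tempdir()
  manifest <- synth_corpus(counts, seed = 3, out_dir = dir)
  feats <- build_feature_table(manifest)
  X <- scale(feature_matrix(feats))
  labs <- feats$label
  cent <- do.call(rbind, lapply(split(as.data.frame(X), labs), colMeans))
  Dc <- as.matrix(dist(cent))
  D <- as.matrix(dist(X))
  # for every discrete type: mean between-type point distance exceeds the
  # mean within-type point distance
  for (ty in c("clacson", "songbit", "wheezing_grunt", "roar", "long_tonal")) {
    inside <- labs == ty
    within <- mean(D[inside, inside][upper.tri(D[inside, inside])])
    between <- mean(D[inside, !inside])
    expect_gt(between, within)
  }
  # the graded pairs have the two smallest between-type centroid distances
  off <- Dc[upper.tri(Dc)]
  names(off) <- outer(rownames(Dc), colnames(Dc),
                      function(a, b) paste(a, b))[upper.tri(Dc)]
  two_smallest <- names(sort(off))[1:2]
  expect_setequal(two_smallest, c("grunt hum", "kiss wheeze"))
})
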