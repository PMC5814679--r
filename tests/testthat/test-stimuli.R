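test_that("AM envelope is low-pass, bounded and seed-deterministic", {
  for (seed in c(1, 7, 23)) {
    e <- make_am_envelope(3, 1000, 7, seed = seed)
    expect_true(all(e$samples >= 0 & e$samples <= 1))
    expect_equal(range(e$samples), c(0, 1))
    sp <- raw_periodogram(e$samples, 1000)
    frac_above <- sum(sp$spec[sp$freq > 7]) / sum(sp$spec)
    expect_lt(frac_above, 0.01)
  }
  expect_identical(make_am_envelope(3, 1000, 7, seed = 5)$samples,
                   make_am_envelope(3, 1000, 7, seed = 5)$samples)
})

test_that("envelopes from different seeds are uncorrelated on average", {
  r <- vapply(1:100, function(i)
    stats::cor(make_am_envelope(3, 1000, 7, seed = i)$samples,
               make_am_envelope(3, 1000, 7, seed = i + 1000)$samples),
    numeric(1))
  expect_lt(abs(mean(r)), 0.05)
  expect_lt(mean(abs(r)), 0.3)
})

test_that("envelope generation validates its arguments", {
  expect_error(make_am_envelope(-1, 1000, 7), class = "avbind_invalid_argument")
  expect_error(make_am_envelope(3, 1000, -2), class = "avbind_invalid_argument")
  expect_error(make_am_envelope(3, 1000, 600), class = "avbind_invalid_argument")
})

test_that("vowel spectrum peaks at the formants and at harmonics of F0", {
  v <- default_vowels()
  flat <- make_am_envelope(1.5, 1000, 7, seed = 3)
  flat$samples <- rep(1, length(flat$samples))   # unmodulated carrier

  # dense harmonic comb (low F0) resolves the formant envelope to +-30 Hz
  dense <- vowel_spec("[u]-dense", 35, v$A1$formants, v$A1$bandwidths)
  w <- synthesize_vowel(dense, flat, 24414)
  ps <- welch_psd(w, 24414, wl = 384)
  peaks <- ps$freq[local_maxima(ps$spec)]
  for (f in dense$formants)
    expect_lt(min(abs(peaks - f)), 30)

  # at the vowel's true F0 the spectrum is a 195-Hz comb: every formant has
  # a dominant nearby harmonic (within F0/2) and adjacent spectral peaks are
  # spaced by F0
  w <- synthesize_vowel(v$A1, flat, 24414)
  ps <- welch_psd(w, 24414, wl = 128)
  peaks <- ps$freq[local_maxima(ps$spec)]
  for (f in v$A1$formants)
    expect_lt(min(abs(peaks - f)), v$A1$f0 / 2)
  fine <- welch_psd(w, 24414, wl = 8192, nfft = 16384)
  lm <- local_maxima(fine$spec)
  lm <- lm[order(fine$spec[lm], decreasing = TRUE)]
  comb <- numeric(0)                       # strongest peaks, >=50 Hz apart
  for (f in fine$freq[lm]) {
    if (!length(comb) || min(abs(comb - f)) > 50) comb <- c(comb, f)
    if (length(comb) == 15) break
  }
  # every strong spectral peak sits on a multiple of F0 = 195 Hz
  expect_true(all(abs(comb - 195 * round(comb / 195)) < 2.5))
  expect_gte(length(unique(round(comb / 195))), 8)
})

test_that("vowel synthesis respects envelope and argument contracts", {
  v <- default_vowels()
  zero_env <- make_am_envelope(1, 1000, 7, seed = 1)
  zero_env$samples <- rep(0, length(zero_env$samples))
  expect_equal(max(abs(synthesize_vowel(v$A1, zero_env, 24414))), 0)
  short_env <- make_am_envelope(0.5, 1000, 7, seed = 1)
  expect_error(synthesize_vowel(v$A1, short_env, 24414, duration = 1),
               class = "avbind_invalid_argument")
  expect_error(synthesize_vowel(v$A1, zero_env, 8000),
               class = "avbind_invalid_argument")
})

test_that("timbre deviants are time-localized and amplitude-neutral", {
  v <- default_vowels()
  env <- make_am_envelope(3, 1000, 7, seed = 4)
  mk <- list(deviant_marker(1.0, "A1", v$A1_deviant))
  w0 <- synthesize_vowel(v$A1, env, 24414)
  w1 <- insert_timbre_deviants(v$A1, mk, env, 24414)
  tt <- (seq_along(w0) - 1) / 24414
  outside <- tt < 1.0 | tt >= 1.2
  expect_identical(w1[outside], w0[outside])
  expect_true(any(w1[!outside] != w0[!outside]))
  # RMS in 50-ms windows inside the epoch within 5% of the no-deviant stream
  for (t0 in seq(1.0, 1.15, by = 0.05)) {
    idx <- tt >= t0 & tt < t0 + 0.05
    rms0 <- sqrt(mean(w0[idx]^2))
    rms1 <- sqrt(mean(w1[idx]^2))
    expect_lt(abs(rms1 - rms0) / rms0, 0.05)
  }
  # no markers: exactly the plain synthesis
  expect_identical(insert_timbre_deviants(v$A1, list(), env, 24414), w0)
})

test_that("deviant formants reach the morph target at the epoch midpoint", {
  v <- default_vowels()
  flat <- make_am_envelope(3, 1000, 7, seed = 3)
  flat$samples <- rep(1, length(flat$samples))
  # dense comb again so the spectral envelope is measurable
  dense <- vowel_spec("[u]-dense", 35, v$A1$formants, v$A1$bandwidths)
  target <- v$A1_deviant
  mk <- list(deviant_marker(1.0, "A1", target))
  w <- insert_timbre_deviants(dense, mk, flat, 24414)
  mid <- w[round(1.06 * 24414):round(1.14 * 24414)]   # 80 ms around t=1.1 s
  ps <- welch_psd(mid, 24414, wl = 512)
  peaks <- ps$freq[local_maxima(ps$spec)]
  expect_lt(min(abs(peaks - target$formants[1])), 35)
  expect_lt(min(abs(peaks - target$formants[2])), 35)
})

test_that("deviant markers are validated", {
  v <- default_vowels()
  env <- make_am_envelope(3, 1000, 7, seed = 4)
  expect_error(deviant_marker(1, "A1", v$A1_deviant, duration = 0.3),
               class = "avbind_invalid_argument")
  overlapping <- list(deviant_marker(1.0, "A1", v$A1_deviant),
                      deviant_marker(1.1, "A1", v$A1_deviant))
  expect_error(insert_timbre_deviants(v$A1, overlapping, env, 24414),
               class = "avbind_invalid_argument")
  late <- list(deviant_marker(2.95, "A1", v$A1_deviant))
  expect_error(insert_timbre_deviants(v$A1, late, env, 24414),
               class = "avbind_invalid_argument")
})

test_that("stimulus sets satisfy their structural invariants", {
  s12 <- fix_stims$A12V1
  s1 <- build_stimulus_set("A1", fix_env1, fix_env2)
  s2 <- build_stimulus_set("A2", fix_env1, fix_env2)
  expect_identical(s12$audio, s1$audio + s2$audio)
  expect_identical(s12$luminance$samples, fix_env1$samples)
  expect_null(s1$luminance)
  # temporally independent pairing: luminance follows the other stream
  expect_identical(fix_stims$A1V2$luminance$samples, fix_env2$samples)
  expect_identical(fix_stims$A1V2$envelopes$A1$samples, fix_env1$samples)
  expect_error(build_stimulus_set("A3V1", fix_env1, fix_env2),
               class = "avbind_invalid_argument")
  e_short <- make_am_envelope(2, 1000, 7, seed = 1)
  expect_error(build_stimulus_set("A1V1", fix_env1, e_short),
               class = "avbind_invalid_argument")
})

test_that("vowel specs are validated", {
  expect_error(vowel_spec("x", -10, c(1, 2, 3, 4) * 100),
               class = "avbind_invalid_argument")
  expect_error(vowel_spec("x", 100, c(400, 300, 500, 600)),
               class = "avbind_invalid_argument")
  expect_error(vowel_spec("x", 100, c(300, 400, 500, 600),
                          bandwidths = c(-1, 1, 1, 1)),
               class = "avbind_invalid_argument")
})
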