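#' Define an artificial vowel
#'
#' A vowel is specified by its fundamental frequency and the centre
#' frequencies and bandwidths of its first four formant resonances. The two
#' default streams (see [default_vowels()]) are \[u\] (F1--F4: 460, 1105,
#' 2857, 4205 Hz, F0 = 195 Hz) and \[a\] (936, 1551, 2975, 4263 Hz,
#' F0 = 175 Hz); their deviant morph targets are \[eps\] (730, 2058, 2857,
#' 4205 Hz) and \[i\] (437, 2761, 2975, 4263 Hz).
#'
#' @param label Character tag, e.g. `"[u]"`.
#' @param f0 Fundamental (voice pitch) frequency in Hz; must be positive.
#' @param formants Numeric vector of four strictly increasing formant centre
#'   frequencies (Hz).
#' @param bandwidths Numeric vector of four positive formant bandwidths (Hz).
#'   Defaults are typical values for cascade vowel synthesis.
#' @return An object of class `avb_vowel`.
#' @export
vowel_spec <- function(label, f0, formants, bandwidths = c(80, 120, 160, 200)) {
  check_scalar(f0, "f0", positive = TRUE)
  if (length(formants) != 4L || any(!is.finite(formants)))
    stop_invalid("formants must be four finite frequencies")
  if (any(diff(formants) <= 0))
    stop_invalid("formants must be strictly increasing")
  if (length(bandwidths) != 4L || any(bandwidths <= 0))
    stop_invalid("bandwidths must be four positive widths")
  structure(
    list(label = label, f0 = f0, formants = as.numeric(formants),
         bandwidths = as.numeric(bandwidths)),
    class = "avb_vowel")
}

#' Default vowel set for the two auditory streams
#'
#' Stream A1 is the vowel \[u\] and stream A2 is \[a\]; `A1_deviant` and
#' `A2_deviant` are the timbre-deviant morph targets (\[eps\] and \[i\]).
#'
#' @return Named list of [vowel_spec()] objects.
#' @export
default_vowels <- function() {
  list(
    A1 = vowel_spec("[u]", 195, c(460, 1105, 2857, 4205)),
    A2 = vowel_spec("[a]", 175, c(936, 1551, 2975, 4263)),
    A1_deviant = vowel_spec("[eps]", 195, c(730, 2058, 2857, 4205)),
    A2_deviant = vowel_spec("[i]", 175, c(437, 2761, 2975, 4263))
  )
}

#' Generate a noisy low-pass amplitude-modulation envelope
#'
#' Draws Gaussian white noise, applies a zero-phase frequency-domain low-pass
#' filter (unity gain up to 0.8 x `cutoff`, raised-cosine roll-off to zero at
#' `cutoff`, zero above), and min-max normalizes the result to \[0, 1\].
#' Because the stop band is exact, the envelope has no spectral power above
#' `cutoff` apart from the DC shift introduced by normalization.
#'
#' @param duration Envelope duration in seconds.
#' @param sample_rate Envelope sample rate in Hz.
#' @param cutoff Low-pass cut-off frequency in Hz (default 7).
#' @param seed Integer seed; identical seeds give bit-identical envelopes.
#' @return An object of class `avb_envelope` with elements `samples` (in
#'   \[0, 1\]), `sample_rate`, `cutoff` and `seed`.
#' @export
make_am_envelope <- function(duration, sample_rate = 1000, cutoff = 7, seed = 1) {
  check_scalar(duration, "duration", positive = TRUE)
  check_scalar(sample_rate, "sample_rate", positive = TRUE)
  check_scalar(cutoff, "cutoff", positive = TRUE)
  if (cutoff >= sample_rate / 2)
    stop_invalid("cutoff must be below the Nyquist frequency")
  n <- round(duration * sample_rate)
  if (n < 4L) stop_invalid("duration too short for the requested sample rate")
  x <- with_seed(seed, stats::rnorm(n))
  f <- (0:(n - 1)) / n * sample_rate
  f <- pmin(f, sample_rate - f)           # two-sided frequency axis
  lo <- 0.8 * cutoff
  h <- ifelse(f <= lo, 1,
              ifelse(f >= cutoff, 0,
                     0.5 * (1 + cos(pi * (f - lo) / (cutoff - lo)))))
  y <- Re(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
  y <- (y - min(y)) / (max(y) - min(y))
  structure(
    list(samples = y, sample_rate = sample_rate, cutoff = cutoff,
         seed = seed, duration = n / sample_rate),
    class = "avb_envelope")
}

# Magnitude response of a single digital two-pole resonator with centre
# frequency F and bandwidth bw, normalized to unity gain at resonance.
resonator_gain <- function(f, centre, bw, audio_rate) {
  r <- exp(-pi * bw / audio_rate)
  th <- 2 * pi * centre / audio_rate
  z <- exp(-1i * 2 * pi * f / audio_rate)
  zp <- exp(-1i * th)
  h <- 1 / Mod((1 - r * exp(1i * th) * z) * (1 - r * exp(-1i * th) * z))
  hp <- 1 / Mod((1 - r * exp(1i * th) * zp) * (1 - r * exp(-1i * th) * zp))
  h / hp
}

# Harmonic amplitudes for a formant configuration: a flat (impulse-train)
# harmonic source shaped by the cascade of four resonators. `formants` may be
# a length-4 vector (static) or a 4-column matrix (one row per output sample,
# time-varying). Returns amplitudes normalized to unit RMS across harmonics so
# instantaneous carrier power is independent of the formant configuration.
harmonic_gains <- function(harmonics, formants, bandwidths, audio_rate) {
  if (is.matrix(formants)) {
    g <- matrix(1, nrow(formants), length(harmonics))
    for (k in 1:4) {
      ctr <- formants[, k]
      r <- exp(-pi * bandwidths[k] / audio_rate)
      th <- 2 * pi * ctr / audio_rate
      z <- exp(-1i * 2 * pi * outer(rep(1, length(ctr)), harmonics) / audio_rate)
      pole <- r * exp(1i * th)
      h <- 1 / Mod((1 - pole * z) * (1 - Conj(pole) * z))
      zp <- exp(-1i * th)
      hp <- 1 / Mod((1 - pole * zp) * (1 - Conj(pole) * zp))
      g <- g * (h / hp)
    }
    g / sqrt(rowSums(g^2))
  } else {
    g <- rep(1, length(harmonics))
    for (k in 1:4)
      g <- g * resonator_gain(harmonics, formants[k], bandwidths[k], audio_rate)
    g / sqrt(sum(g^2))
  }
}

#' Synthesize an amplitude-modulated artificial vowel
#'
#' The carrier is a harmonic comb at the vowel's fundamental frequency whose
#' harmonic amplitudes are shaped by the magnitude response of a cascade of
#' four two-pole formant resonators. The carrier is peak-normalized and then
#' multiplied by the amplitude-modulation envelope (linearly resampled to the
#' audio rate).
#'
#' @param spec A [vowel_spec()].
#' @param envelope An [make_am_envelope()] envelope covering the requested
#'   duration.
#' @param audio_rate Audio sample rate in Hz; must be at least 4 x F4.
#' @param duration Output duration in seconds; defaults to the envelope
#'   duration and may not exceed it.
#' @return Numeric waveform vector with attributes `audio_rate` and `spec`.
#' @export
synthesize_vowel <- function(spec, envelope, audio_rate = 24414,
                             duration = NULL) {
  stopifnot(inherits(spec, "avb_vowel"), inherits(envelope, "avb_envelope"))
  if (audio_rate < 4 * spec$formants[4])
    stop_invalid("audio_rate must be at least 4 x F4")
  if (is.null(duration)) duration <- envelope$duration
  if (duration > envelope$duration + 1e-9)
    stop_invalid("envelope shorter than requested duration")
  n <- round(duration * audio_rate)
  carrier <- vowel_carrier(spec, audio_rate, n)
  env <- resample_linear(envelope$samples, envelope$sample_rate, audio_rate, n)
  wav <- carrier$wave * env
  attr(wav, "audio_rate") <- audio_rate
  attr(wav, "spec") <- spec
  wav
}

# Static harmonic carrier, peak-normalized. Returns the wave plus the scale
# factor so that deviant synthesis can reuse the identical normalization.
vowel_carrier <- function(spec, audio_rate, n) {
  harmonics <- seq_len(max(1L, floor((audio_rate / 2 - 100) / spec$f0))) * spec$f0
  g <- harmonic_gains(harmonics, spec$formants, spec$bandwidths, audio_rate)
  t <- (seq_len(n) - 1) / audio_rate
  wave <- as.vector(cos(2 * pi * outer(t, harmonics)) %*% g)
  peak <- max(abs(wave))
  list(wave = wave / peak, peak = peak, harmonics = harmonics, t = t)
}

#' Mark a timbre deviant epoch
#'
#' A deviant is a 200-ms epoch in which the vowel's first two formants morph
#' smoothly to those of another vowel and back; F3, F4 and the amplitude
#' envelope are unchanged, so neither the acoustic envelope nor the luminance
#' carries information about the deviant.
#'
#' @param onset Epoch onset in seconds from stimulus onset.
#' @param stream `"A1"` or `"A2"`: the auditory stream carrying the deviant.
#' @param morph_target A [vowel_spec()] giving the vowel morphed to at the
#'   epoch midpoint.
#' @param duration Epoch duration in seconds (fixed at 0.2).
#' @return Object of class `avb_deviant`.
#' @export
deviant_marker <- function(onset, stream = c("A1", "A2"), morph_target,
                           duration = 0.2) {
  check_scalar(onset, "onset")
  if (onset < 0) stop_invalid("onset must be non-negative")
  stream <- match.arg(stream)
  if (abs(duration - 0.2) > 1e-12)
    stop_invalid("deviant duration is fixed at 0.200 s")
  stopifnot(inherits(morph_target, "avb_vowel"))
  structure(list(onset = onset, duration = duration, stream = stream,
                 morph_target = morph_target),
            class = "avb_deviant")
}

check_markers <- function(markers, duration) {
  if (length(markers) == 0L) return(invisible(NULL))
  on <- vapply(markers, `[[`, numeric(1), "onset")
  du <- vapply(markers, `[[`, numeric(1), "duration")
  if (any(on + du > duration + 1e-9))
    stop_invalid("deviant markers must lie within the stimulus duration")
  o <- order(on)
  if (length(on) > 1L && any(on[o][-1] < (on + du)[o][-length(on)] - 1e-12))
    stop_invalid("deviant epochs must not overlap")
  invisible(NULL)
}

#' Synthesize a vowel stream containing timbre deviants
#'
#' Outside deviant epochs the output is sample-identical to
#' [synthesize_vowel()] with the same envelope. Inside each epoch, F1 and F2
#' follow a raised-cosine out-and-back trajectory that reaches the morph
#' target at the epoch midpoint; harmonic amplitudes are renormalized to
#' constant instantaneous power so the deviant is amplitude-neutral.
#'
#' @inheritParams synthesize_vowel
#' @param markers List of [deviant_marker()] objects (non-overlapping, inside
#'   the stimulus).
#' @return Numeric waveform vector as in [synthesize_vowel()].
#' @export
insert_timbre_deviants <- function(spec, markers, envelope,
                                   audio_rate = 24414, duration = NULL) {
  stopifnot(inherits(spec, "avb_vowel"), inherits(envelope, "avb_envelope"))
  if (is.null(duration)) duration <- envelope$duration
  check_markers(markers, duration)
  base <- synthesize_vowel(spec, envelope, audio_rate, duration)
  if (length(markers) == 0L) return(base)
  n <- length(base)
  carrier <- vowel_carrier(spec, audio_rate, n)
  env <- resample_linear(envelope$samples, envelope$sample_rate, audio_rate, n)
  for (m in markers) {
    i0 <- floor(m$onset * audio_rate) + 1L
    i1 <- min(n, floor((m$onset + m$duration) * audio_rate))
    idx <- i0:i1
    tt <- carrier$t[idx]
    # raised-cosine morph: 0 at the epoch edges, 1 at the midpoint
    alpha <- 0.5 * (1 - cos(2 * pi * (tt - m$onset) / m$duration))
    ftraj <- matrix(rep(spec$formants, each = length(idx)), ncol = 4)
    for (k in 1:2)
      ftraj[, k] <- spec$formants[k] +
        alpha * (m$morph_target$formants[k] - spec$formants[k])
    g <- harmonic_gains(carrier$harmonics, ftraj, spec$bandwidths, audio_rate)
    seg <- rowSums(cos(2 * pi * outer(tt, carrier$harmonics)) * g)
    base[idx] <- seg / carrier$peak * env[idx]
  }
  base
}

#' Assemble a stimulus condition
#'
#' Builds one of the tested audio-visual conditions from the two stream
#' envelopes: single-stream audio with or without a visual stream (`A1`,
#' `A2`, `A1V1`, `A1V2`, `A2V1`, `A2V2`), or dual-stream mixtures (`A12V1`,
#' `A12V2`, and the no-visual control `A12`). Dual-stream audio is the
#' sample-wise sum of the two stream waveforms; the luminance envelope is
#' sample-identical to the amplitude envelope of the stream named after `V`.
#'
#' @param condition Condition token (see Details).
#' @param envelope_a1,envelope_a2 Stream envelopes ([make_am_envelope()]),
#'   same duration and rate.
#' @param deviants Optional named list with elements `A1` and/or `A2`, each a
#'   list of [deviant_marker()]s to embed in that stream.
#' @param audio_rate Audio sample rate in Hz.
#' @param vowels Named list of vowel specs as from [default_vowels()].
#' @return Object of class `avb_stimulus_set` with elements `condition`,
#'   `audio`, `audio_rate`, `envelopes` (per stream), `luminance` (an
#'   `avb_envelope` or `NULL`), `deviants`, `duration`, `level_spl`.
#' @export
build_stimulus_set <- function(condition, envelope_a1, envelope_a2,
                               deviants = list(), audio_rate = 24414,
                               vowels = default_vowels()) {
  conditions <- c("A1", "A2", "A1V1", "A1V2", "A2V1", "A2V2",
                  "A12V1", "A12V2", "A12")
  if (!is.character(condition) || !(condition %in% conditions))
    stop_invalid("unknown condition token: ", condition)
  stopifnot(inherits(envelope_a1, "avb_envelope"),
            inherits(envelope_a2, "avb_envelope"))
  if (abs(envelope_a1$duration - envelope_a2$duration) > 1e-9 ||
      envelope_a1$sample_rate != envelope_a2$sample_rate)
    stop_invalid("stream envelopes must share duration and sample rate")

  a_streams <- if (grepl("^A12", condition)) c("A1", "A2")
               else substr(condition, 1, 2)
  v_stream <- if (grepl("V1$", condition)) "A1"
              else if (grepl("V2$", condition)) "A2" else NA_character_

  envs <- list(A1 = envelope_a1, A2 = envelope_a2)
  synth_one <- function(s) {
    mk <- deviants[[s]]
    if (is.null(mk) || length(mk) == 0L)
      synthesize_vowel(vowels[[s]], envs[[s]], audio_rate)
    else
      insert_timbre_deviants(vowels[[s]], mk, envs[[s]], audio_rate)
  }
  waves <- lapply(a_streams, synth_one)
  audio <- waves[[1]]
  if (length(waves) == 2L) audio <- audio + waves[[2]]

  structure(
    list(condition = condition,
         audio = as.numeric(audio),
         audio_rate = audio_rate,
         envelopes = envs[a_streams],
         luminance = if (is.na(v_stream)) NULL else envs[[v_stream]],
         visual_stream = v_stream,
         deviants = deviants,
         duration = envelope_a1$duration,
         level_spl = 65),
    class = "avb_stimulus_set")
}

#' @export
print.avb_stimulus_set <- function(x, ...) {
  cat("Stimulus condition", x$condition, "-", x$duration, "s at",
      x$audio_rate, "Hz\n")
  cat("  auditory streams:", paste(names(x$envelopes), collapse = ", "), "\n")
  cat("  luminance:", if (is.null(x$luminance)) "absent"
      else paste("envelope of", x$visual_stream), "\n")
  ndev <- sum(lengths(x$deviants))
  if (ndev) cat("  timbre deviants:", ndev, "\n")
  invisible(x)
}

#' @export
print.avb_envelope <- function(x, ...) {
  cat("AM envelope:", x$duration, "s at", x$sample_rate, "Hz, low-pass",
      x$cutoff, "Hz (seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}
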