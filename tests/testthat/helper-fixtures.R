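# Shared fixtures, built once per test run. Sizes are kept small: 3-s trials
# at the default envelope rate, audio only where a test needs it.

fix_env1 <- make_am_envelope(3, 1000, 7, seed = 11)
fix_env2 <- make_am_envelope(3, 1000, 7, seed = 12)

fix_conditions <- c("A1V1", "A1V2", "A2V1", "A2V2", "A12V1", "A12V2")

# Envelope-only stimulus sets for spiking/LFP simulation: audio synthesis is
# skipped by reusing the structure with a dummy audio channel (the simulators
# consume only envelopes, luminance and deviants).
fix_stims <- local({
  out <- lapply(fix_conditions, build_stimulus_set,
                envelope_a1 = fix_env1, envelope_a2 = fix_env2)
  names(out) <- fix_conditions
  out
})

fix_stims_with <- function(conditions = fix_conditions, deviants = NULL) {
  out <- lapply(conditions, build_stimulus_set, envelope_a1 = fix_env1,
                envelope_a2 = fix_env2, deviants = if (is.null(deviants))
                  list() else deviants)
  names(out) <- conditions
  out
}

# One coherence-sensitive auditory unit reused by several decoding tests.
fix_unit_kappa <- simulate_spiking_unit(
  unit_params(coherence_reliability = 1.5), fix_stims,
  n_trials = 16, seed = 42)

# Random spike trains for count-conservation style oracles.
random_trains <- function(n_trials, rate = 20, duration = 3, seed = 1) {
  with_seed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); expr
  }
  with_seed(seed, lapply(seq_len(n_trials), function(i)
    sort(stats::runif(stats::rpois(1, rate * duration), 0, duration))))
}

# Build a synthetic TFR object directly from a [trials x freq x time] array
# of complex coefficients (for closed-form ITPC oracles).
fake_tfr <- function(coef, frequencies = NULL) {
  nf <- dim(coef)[2]
  nt <- dim(coef)[3]
  if (is.null(frequencies)) frequencies <- seq_len(nf)
  grid <- list(frequencies = frequencies, n_points = nf, cycles = 7)
  class(grid) <- "avb_freq_grid"
  structure(list(coef = coef, grid = grid, sample_rate = 1,
                 valid = matrix(TRUE, nf, nt),
                 times = seq_len(nt) - 1, n_trials = dim(coef)[1]),
            class = "avb_tfr")
}

# Periodogram helper (no taper, no detrend) used as the spectral oracle.
raw_periodogram <- function(x, fs) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0,
                          plot = FALSE, detrend = FALSE, demean = FALSE)
  list(freq = sp$freq, spec = sp$spec)
}

# Welch power spectrum with Hann windows and zero padding, as the formant
# oracle (independent of the synthesis path).
welch_psd <- function(x, fs, wl, nfft = 16384) {
  nseg <- floor(length(x) / wl)
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(wl - 1)) / wl)
  p <- 0
  for (i in seq_len(nseg))
    p <- p + abs(stats::fft(c(x[((i - 1) * wl + 1):(i * wl)] * win,
                              rep(0, nfft - wl))))^2
  list(freq = (0:(nfft / 2 - 1)) * fs / nfft, spec = p[1:(nfft / 2)])
}

local_maxima <- function(spec) which(diff(sign(diff(spec))) == -2) + 1
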