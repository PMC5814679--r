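#' Wavelet analysis frequency grid
#'
#' The default grid covers 2.5 to 45 Hz inclusive in 0.5-Hz steps (86
#' frequency points) with 7-cycle Morlet wavelets.
#'
#' @param fmin,fmax,step Grid limits and spacing in Hz.
#' @param cycles Number of wavelet cycles.
#' @return Object of class `avb_freq_grid` with `frequencies`, `n_points`,
#'   `cycles`.
#' @export
frequency_grid <- function(fmin = 2.5, fmax = 45, step = 0.5, cycles = 7) {
  if (fmin <= 0 || fmax <= fmin || step <= 0)
    stop_invalid("invalid frequency grid")
  frequencies <- seq(fmin, fmax, by = step)
  structure(list(frequencies = frequencies, n_points = length(frequencies),
                 cycles = cycles),
            class = "avb_freq_grid")
}

#' Morlet wavelet time-frequency decomposition
#'
#' Convolves every trial with complex Morlet wavelets (unit energy, Gaussian
#' temporal sd `cycles / (2 pi f)`, truncated at three temporal sd). Edge
#' samples within half a wavelet support of either trace end are flagged per
#' frequency and excluded from all time averages downstream.
#'
#' @param traces Trials x time numeric matrix.
#' @param sample_rate Sampling rate in Hz.
#' @param grid A [frequency_grid()].
#' @param decimate Keep every `decimate`-th coefficient along time (phase
#'   below 45 Hz varies slowly, so moderate decimation loses nothing for
#'   time-averaged statistics; default 1 keeps all samples).
#' @return Object of class `avb_tfr`: complex `coef` array
#'   `[trials, frequencies, time]`, the grid, `valid` (frequencies x time
#'   logical matrix of uncontaminated samples), `times` (seconds).
#' @export
morlet_tfr <- function(traces, sample_rate, grid = frequency_grid(),
                       decimate = 1) {
  if (is.vector(traces)) traces <- matrix(traces, nrow = 1)
  nt <- ncol(traces)
  ntr <- nrow(traces)
  freqs <- grid$frequencies
  sig <- grid$cycles / (2 * pi * freqs)
  half <- ceiling(3 * sig * sample_rate)
  if (nt <= 2 * max(half))
    stop_invalid("trace too short for the lowest frequency wavelet")
  nfft <- stats::nextn(nt + 2 * max(half), 2)
  keep <- seq(1, nt, by = decimate)
  FX <- stats::mvfft(rbind(t(traces), matrix(0, nfft - nt, ntr)))
  coef <- array(0i, c(ntr, length(freqs), length(keep)))
  valid <- matrix(FALSE, length(freqs), length(keep))
  for (j in seq_along(freqs)) {
    tt <- (-half[j]:half[j]) / sample_rate
    w <- exp(-tt^2 / (2 * sig[j]^2)) * exp(2i * pi * freqs[j] * tt)
    w <- w / sqrt(sum(Mod(w)^2))
    wf <- stats::fft(c(w, rep(0, nfft - length(w))))
    cf <- stats::mvfft(FX * wf, inverse = TRUE) / nfft
    coef[, j, ] <- t(cf[half[j] + keep, , drop = FALSE])
    valid[j, ] <- keep > half[j] & keep <= nt - half[j]
  }
  structure(list(coef = coef, grid = grid, sample_rate = sample_rate,
                 valid = valid, times = (keep - 1) / sample_rate,
                 n_trials = ntr),
            class = "avb_tfr")
}

#' @export
print.avb_tfr <- function(x, ...) {
  cat("Morlet TFR:", x$n_trials, "trials x", x$grid$n_points,
      "frequencies x", length(x$times), "time points\n")
  invisible(x)
}

# Unit phasors of a TFR as a (trials) x (freq * time) real pair, plus shape.
tfr_phasors <- function(tfr) {
  z <- tfr$coef
  m <- Mod(z)
  m[m == 0] <- 1
  z / m
}

itpc_profile <- function(values, valid) {
  vapply(seq_len(nrow(values)), function(j) {
    v <- valid[j, ]
    if (!any(v)) NA_real_ else mean(values[j, v])
  }, numeric(1))
}

#' Inter-trial phase coherence
#'
#' `ITPC(t, f) = | mean over trials of exp(i theta_{k,t,f}) |`: the length
#' of the mean unit phasor across trials. 1 means perfectly reproducible
#' phase; uniform random phase gives an expected value of about
#' `sqrt(pi) / (2 sqrt(N))`.
#'
#' @param tfr An [morlet_tfr()] result with at least 2 trials.
#' @return Object of class `avb_itpc`: `values` (frequencies x time, in
#'   \[0, 1\]), `profile` (time-averaged over uncontaminated samples),
#'   `n_trials`, `frequencies`.
#' @export
itpc <- function(tfr) {
  stopifnot(inherits(tfr, "avb_tfr"))
  if (tfr$n_trials < 2) stop_invalid("ITPC needs at least 2 trials")
  z <- tfr_phasors(tfr)
  values <- Mod(colMeans(z))                # average over trials
  dim(values) <- dim(tfr$coef)[2:3]
  structure(list(values = values, profile = itpc_profile(values, tfr$valid),
                 n_trials = tfr$n_trials,
                 frequencies = tfr$grid$frequencies, kind = "within"),
            class = "avb_itpc")
}

# Shared machinery: average of |mean phasor| maps over random draws of N
# trials from the pooled trials of two TFRs. Returns frequencies x time.
shuffled_itpc_values <- function(tfr_a, tfr_b, n_shuffles, seed) {
  nf <- tfr_a$grid$n_points
  ntime <- length(tfr_a$times)
  za <- tfr_phasors(tfr_a); zb <- tfr_phasors(tfr_b)
  n_a <- dim(za)[1]; n_b <- dim(zb)[1]
  N <- min(n_a, n_b)
  P <- rbind(matrix(za, n_a, nf * ntime), matrix(zb, n_b, nf * ntime))
  S <- with_seed(seed, {
    t(vapply(seq_len(n_shuffles), function(i) {
      s <- numeric(n_a + n_b)
      s[sample.int(n_a + n_b, N)] <- 1
      s
    }, numeric(n_a + n_b)))
  })
  Mr <- (S %*% Re(P)) / N
  Mi <- (S %*% Im(P)) / N
  matrix(colMeans(sqrt(Mr^2 + Mi^2)), nf, ntime)
}

#' Across-stimulus inter-trial phase coherence
#'
#' Null ITPC computed over trials drawn at random from two conditions that
#' share the auditory stimulus but differ in the visual stimulus: `N` trials
#' (the smaller condition's count) are drawn from the pooled trials, the
#' ITPC map computed, and the result averaged over `n_shuffles` draws.
#'
#' @param tfr_a,tfr_b TFRs of the two conditions (same grid and length).
#' @param n_shuffles Number of random draws (default 100).
#' @param seed Integer seed.
#' @return An `avb_itpc` of kind `"across"`.
#' @export
across_stimulus_itpc <- function(tfr_a, tfr_b, n_shuffles = 100, seed = 1) {
  stopifnot(inherits(tfr_a, "avb_tfr"), inherits(tfr_b, "avb_tfr"))
  if (!identical(tfr_a$grid$frequencies, tfr_b$grid$frequencies) ||
      length(tfr_a$times) != length(tfr_b$times))
    stop_invalid("TFRs must share grid and time axis")
  if (abs(dim(tfr_a$coef)[1] - dim(tfr_b$coef)[1]) >
      0.5 * max(dim(tfr_a$coef)[1], dim(tfr_b$coef)[1]))
    stop_invalid("trial counts differ by more than half")
  values <- shuffled_itpc_values(tfr_a, tfr_b, n_shuffles, seed)
  structure(list(values = values,
                 profile = itpc_profile(values, tfr_a$valid),
                 n_trials = min(dim(tfr_a$coef)[1], dim(tfr_b$coef)[1]),
                 frequencies = tfr_a$grid$frequencies, kind = "across"),
            class = "avb_itpc")
}

#' Single-stream phase dissimilarity index
#'
#' For each single-stream condition the PDI is the per-frequency difference
#' between the time-averaged within-stimulus ITPC and the across-stimulus
#' ITPC for the matching auditory stream (e.g. `A1V1` against the `A1V1`
#' / `A1V2` shuffle). Values are then averaged over the two stimuli of each
#' coherency grouping: coherent = (`A1V1`, `A2V2`), independent = (`A1V2`,
#' `A2V1`).
#'
#' @param within Named list of `avb_itpc` objects per condition (`A1V1`,
#'   `A1V2`, `A2V1`, `A2V2`).
#' @param across Named list of across-stimulus `avb_itpc` per auditory
#'   stream (`A1`, `A2`).
#' @return Object of class `avb_pdi` (kind `"single-stream"`) with per-
#'   frequency `coherent` and `independent` PDI profiles and `per_condition`
#'   values.
#' @export
single_stream_pdi <- function(within, across) {
  need <- c("A1V1", "A1V2", "A2V1", "A2V2")
  if (!all(need %in% names(within)) || !all(c("A1", "A2") %in% names(across)))
    stop_invalid("within needs all four single-stream conditions; across needs A1 and A2")
  fr <- within[[1]]$frequencies
  for (w in c(within[need], across[c("A1", "A2")]))
    if (!identical(w$frequencies, fr)) stop_invalid("frequency grid mismatch")
  pdi_one <- function(cond) {
    stream <- substr(cond, 1, 2)
    within[[cond]]$profile - across[[stream]]$profile
  }
  per_condition <- vapply(need, pdi_one, numeric(length(fr)))
  structure(list(
    frequencies = fr,
    per_condition = per_condition,
    coherent = rowMeans(per_condition[, c("A1V1", "A2V2")]),
    independent = rowMeans(per_condition[, c("A1V2", "A2V1")]),
    kind = "single-stream"),
    class = "avb_pdi")
}

#' Dual-stream phase dissimilarity index
#'
#' Within-dual ITPC is computed from the `A12V1` and `A12V2` trials
#' separately; across-dual ITPC from random draws mixing the two visual
#' conditions. The PDI is the time-averaged within minus across difference,
#' averaged over the two dual-stream stimuli. Positive values indicate that
#' the visual stream influenced the response time course despite identical
#' acoustics.
#'
#' @param tfr_v1,tfr_v2 TFRs of the `A12V1` and `A12V2` conditions.
#' @param n_shuffles,seed Passed to the across-dual shuffle.
#' @return Object of class `avb_pdi` (kind `"dual-stream"`) with the `pdi`
#'   profile and the per-condition values.
#' @export
dual_stream_pdi <- function(tfr_v1, tfr_v2, n_shuffles = 100, seed = 1) {
  w1 <- itpc(tfr_v1)
  w2 <- itpc(tfr_v2)
  acr <- across_stimulus_itpc(tfr_v1, tfr_v2, n_shuffles, seed)
  per_condition <- cbind(A12V1 = w1$profile - acr$profile,
                         A12V2 = w2$profile - acr$profile)
  structure(list(frequencies = w1$frequencies,
                 per_condition = per_condition,
                 pdi = rowMeans(per_condition),
                 kind = "dual-stream"),
            class = "avb_pdi")
}

#' @export
print.avb_pdi <- function(x, ...) {
  p <- if (!is.null(x$pdi)) x$pdi else x$coherent
  cat(sprintf("%s PDI over %d frequencies; peak %.3f at %.1f Hz\n",
              x$kind, length(x$frequencies), max(p),
              x$frequencies[which.max(p)]))
  invisible(x)
}

#' Significance mask for dissimilarity profiles
#'
#' Per frequency, a paired one-sided t test of within-stimulus against
#' across-stimulus consistency values over recording sites, Bonferroni
#' corrected for the number of frequencies; a frequency counts as
#' significant only within a run of at least `min_adjacent` consecutive
#' significant bins. The PDI magnitude is the sum of the mean PDI over
#' significant frequencies (0 for an empty mask).
#'
#' @param within,across Sites x frequencies matrices of time-averaged
#'   consistency values (at least 3 sites).
#' @param base_alpha Uncorrected level (default 0.05).
#' @param n_freq Number of tests for the Bonferroni correction; defaults to
#'   the number of frequency columns.
#' @param min_adjacent Minimum run length of significant bins (default 2).
#' @return List of class `avb_pdi_significance`: `mask`, `p` (per
#'   frequency), `alpha_corrected`, `pdi_mean`, `magnitude`.
#' @export
pdi_significance <- function(within, across, base_alpha = 0.05,
                             n_freq = ncol(within), min_adjacent = 2) {
  if (!is.matrix(within) || !is.matrix(across) ||
      !all(dim(within) == dim(across)))
    stop_invalid("within and across must be matching sites x frequency matrices")
  if (nrow(within) < 3) stop_invalid("need at least 3 paired samples (sites)")
  alpha_corrected <- base_alpha / n_freq
  d <- within - across
  n <- nrow(d)
  mu <- colMeans(d)
  se <- apply(d, 2, stats::sd) / sqrt(n)
  tstat <- mu / se
  p <- stats::pt(tstat, df = n - 1, lower.tail = FALSE)
  raw <- p < alpha_corrected
  mask <- raw & filter_adjacent(raw, min_adjacent)
  structure(list(mask = mask, p = p, t = tstat,
                 alpha_corrected = alpha_corrected,
                 pdi_mean = mu,
                 magnitude = sum(mu[mask])),
            class = "avb_pdi_significance")
}

# TRUE where a logical vector belongs to a run of >= min_len TRUEs.
filter_adjacent <- function(x, min_len) {
  r <- rle(x)
  r$values <- r$values & r$lengths >= min_len
  inverse.rle(r)
}

#' @export
print.avb_pdi_significance <- function(x, ...) {
  cat(sprintf(
    "PDI significance: %d/%d frequencies (alpha_corrected = %.2g), magnitude %.3f\n",
    sum(x$mask), length(x$mask), x$alpha_corrected, x$magnitude))
  invisible(x)
}

# Normalized power time courses of a TFR, restricted to the per-frequency
# valid window: per trial and frequency the power course is divided by its
# in-window mean, then centred and scaled to unit norm so that inner
# products are Pearson correlations. Returns a list per frequency of
# trials x time matrices (possibly differing widths).
power_courses <- function(tfr) {
  z2 <- Mod(tfr$coef)^2
  nf <- tfr$grid$n_points
  lapply(seq_len(nf), function(j) {
    v <- tfr$valid[j, ]
    P <- z2[, j, v, drop = FALSE]
    P <- matrix(P, dim(z2)[1], sum(v))
    P <- P / rowMeans(P)
    P <- P - rowMeans(P)
    nrm <- sqrt(rowSums(P^2))
    nrm[nrm == 0] <- 1
    P / nrm
  })
}

# Mean pairwise correlation across the rows of a unit-norm matrix.
mean_pairwise_cor <- function(Z) {
  N <- nrow(Z)
  (sum(colSums(Z)^2) - N) / (N * (N - 1))
}

#' Power dissimilarity analysis
#'
#' The phase-dissimilarity pipeline with normalized single-trial power time
#' courses substituted for unit phasors: consistency at each frequency is
#' the mean pairwise Pearson correlation of per-trial power time courses
#' (each divided by its in-window mean), computed within each stimulus and
#' across random mixtures of the two visual conditions, and the index is the
#' within-minus-across difference. With phase-only visual resets this index
#' stays null; it becomes positive only if the visual stream modulates
#' power.
#'
#' @param tfr_a,tfr_b TFRs of two conditions sharing the auditory stimulus.
#' @param n_shuffles,seed Across-shuffle parameters.
#' @return Object of class `avb_pdi` (kind `"power"`) with `pdi` (profile
#'   difference), `within` (average of the two conditions' consistencies)
#'   and `across` profiles.
#' @export
power_dissimilarity <- function(tfr_a, tfr_b, n_shuffles = 100, seed = 1) {
  stopifnot(inherits(tfr_a, "avb_tfr"), inherits(tfr_b, "avb_tfr"))
  if (!identical(tfr_a$grid$frequencies, tfr_b$grid$frequencies))
    stop_invalid("TFRs must share the frequency grid")
  Za <- power_courses(tfr_a)
  Zb <- power_courses(tfr_b)
  nf <- tfr_a$grid$n_points
  n_a <- dim(tfr_a$coef)[1]; n_b <- dim(tfr_b$coef)[1]
  N <- min(n_a, n_b)
  within <- vapply(seq_len(nf), function(j)
    mean(c(mean_pairwise_cor(Za[[j]]), mean_pairwise_cor(Zb[[j]]))),
    numeric(1))
  S <- with_seed(seed, {
    t(vapply(seq_len(n_shuffles), function(i) {
      s <- numeric(n_a + n_b)
      s[sample.int(n_a + n_b, N)] <- 1
      s
    }, numeric(n_a + n_b)))
  })
  across <- vapply(seq_len(nf), function(j) {
    M <- S %*% rbind(Za[[j]], Zb[[j]])      # row sums of each drawn subset
    mean((rowSums(M^2) - N) / (N * (N - 1)))
  }, numeric(1))
  structure(list(frequencies = tfr_a$grid$frequencies,
                 pdi = within - across, within = within, across = across,
                 kind = "power"),
            class = "avb_pdi")
}
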