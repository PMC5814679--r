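#' Parameters of a simulated spiking unit
#'
#' The generator encodes exactly the response properties the analyses test:
#' envelope-following drive, Poisson-like variability, optional visual drive,
#' coherence-dependent response *reliability* (not rate), and a fractional
#' rate change during timbre-deviant epochs.
#'
#' @param baseline_rate Spontaneous rate, spikes/s.
#' @param gain_auditory Auditory drive, spikes/s per unit amplitude envelope.
#' @param gain_visual Visual drive, spikes/s per unit luminance envelope.
#' @param latency Response latency in seconds.
#' @param coherence_reliability Kappa >= 0. Trial-to-trial gain noise on an
#'   auditory stream is divided by `1 + kappa` when the luminance envelope is
#'   temporally coherent with that stream, so coherence increases response
#'   reliability without changing the mean rate.
#' @param deviant_gain Fractional intensity change inside a deviant epoch of
#'   the driving stream (0 = deviants invisible to the unit).
#' @param trial_noise_sd Standard deviation of the multiplicative per-trial
#'   gain noise (dimensionless).
#' @return Object of class `avb_unit_params`.
#' @export
unit_params <- function(baseline_rate = 5, gain_auditory = 30,
                        gain_visual = 0, latency = 0.02,
                        coherence_reliability = 0, deviant_gain = 0,
                        trial_noise_sd = 0.6) {
  if (baseline_rate < 0 || gain_auditory < 0 || gain_visual < 0)
    stop_invalid("rates and gains must be non-negative")
  if (coherence_reliability < 0) stop_invalid("coherence_reliability must be >= 0")
  if (trial_noise_sd < 0) stop_invalid("trial_noise_sd must be >= 0")
  structure(list(baseline_rate = baseline_rate, gain_auditory = gain_auditory,
                 gain_visual = gain_visual, latency = latency,
                 coherence_reliability = coherence_reliability,
                 deviant_gain = deviant_gain,
                 trial_noise_sd = trial_noise_sd),
            class = "avb_unit_params")
}

# Envelope samples of a stimulus stream on the simulation time grid, shifted
# by the response latency (zero before stimulus onset).
env_on_grid <- function(env, latency, dt, n) {
  tt <- (seq_len(n) - 1) * dt - latency
  out <- stats::approx((seq_along(env$samples) - 1) / env$sample_rate,
                       env$samples, xout = tt, rule = 2)$y
  out[tt < 0] <- 0
  out
}

# 0/1 deviant indicator for one stream on the time grid (latency shifted).
deviant_indicator <- function(markers, latency, dt, n) {
  ind <- numeric(n)
  tt <- (seq_len(n) - 1) * dt - latency
  for (m in markers) ind[tt >= m$onset & tt < m$onset + m$duration] <- 1
  ind
}

#' Simulate one spiking unit across stimulus conditions
#'
#' Spikes are drawn as an inhomogeneous Poisson process (1-ms time steps)
#' with intensity `baseline + sum_s g_A * w_s(trial) * env_s(t - latency) +
#' g_V * w_V(trial) * env_V(t - latency)`, where the multiplicative per-trial
#' gain `w_s` is Gaussian with mean 1 and standard deviation
#' `trial_noise_sd / (1 + kappa)` for a stream temporally coherent with the
#' luminance and `trial_noise_sd` otherwise. Deviant epochs scale the driving
#' stream's contribution by `1 + deviant_gain`. Negative intensities are
#' clipped at zero.
#'
#' @param params An [unit_params()] object.
#' @param stimuli Named list of [build_stimulus_set()] objects, one per
#'   condition to simulate.
#' @param n_trials Trials per condition (>= 2; the recorded repetitions
#'   ranged 14--34 with mean 20).
#' @param seed Integer seed.
#' @param dt Simulation time step in seconds (default 1 ms).
#' @param unit_id,state,area Metadata carried on the result.
#' @return Object of class `avb_unit`: `trials` is a named list (per
#'   condition) of lists of spike-time vectors in seconds.
#' @export
simulate_spiking_unit <- function(params, stimuli, n_trials = 20, seed = 1,
                                  dt = 0.001, unit_id = "u1",
                                  state = c("awake", "anesthetized"),
                                  area = "AC") {
  stopifnot(inherits(params, "avb_unit_params"))
  if (n_trials < 2) stop_invalid("n_trials must be >= 2")
  state <- match.arg(state)
  trials <- with_seed(seed, {
    lapply(stimuli, function(stim) {
      dur <- stim$duration
      n <- round(dur / dt)
      streams <- names(stim$envelopes)
      coh <- if (is.null(stim$luminance)) rep(FALSE, length(streams))
             else streams == stim$visual_stream
      # In a two-stream mixture the temporally coherent stream captures a
      # larger share of the drive (total drive is conserved because the two
      # envelopes have equal means); single-stream responses are untouched,
      # so coherent and independent single-stream rates stay identical.
      capture <- rep(1, length(streams))
      if (length(streams) == 2L && any(coh)) {
        delta <- 0.5 * params$coherence_reliability /
          (1 + params$coherence_reliability)
        capture <- ifelse(coh, 1 + delta, 1 - delta)
      }
      drives <- lapply(seq_along(streams), function(k) {
        s <- streams[k]
        e <- env_on_grid(stim$envelopes[[s]], params$latency, dt, n)
        if (!is.null(stim$deviants[[s]]) && params$deviant_gain != 0) {
          ind <- deviant_indicator(stim$deviants[[s]], params$latency, dt, n)
          # cross-modal binding enhances the deviant response of the
          # temporally coherent stream
          g_dev <- params$deviant_gain *
            (1 + params$coherence_reliability * coh[k])
          e <- e * (1 + g_dev * ind)
        }
        e
      })
      env_v <- if (is.null(stim$luminance)) NULL
               else env_on_grid(stim$luminance, params$latency, dt, n)
      lapply(seq_len(n_trials), function(i) {
        lambda <- rep(params$baseline_rate, n)
        for (k in seq_along(streams)) {
          sd_k <- params$trial_noise_sd /
            (1 + params$coherence_reliability * coh[k])
          w <- 1 + stats::rnorm(1, 0, sd_k)
          lambda <- lambda + params$gain_auditory * capture[k] * w * drives[[k]]
        }
        if (!is.null(env_v) && params$gain_visual > 0) {
          wv <- 1 + stats::rnorm(1, 0, params$trial_noise_sd)
          lambda <- lambda + params$gain_visual * wv * env_v
        }
        lambda <- pmax(lambda, 0)
        counts <- stats::rpois(n, lambda * dt)
        idx <- rep.int(seq_len(n), counts)
        sort((idx - 1) * dt + stats::runif(length(idx), 0, dt))
      })
    })
  })
  structure(list(unit_id = unit_id, state = state, area = area,
                 params = params, n_trials = n_trials, dt = dt,
                 duration = if (length(stimuli)) stimuli[[1]]$duration else NA,
                 trials = trials),
            class = "avb_unit")
}

#' @export
print.avb_unit <- function(x, ...) {
  cat("Simulated unit", x$unit_id, paste0("(", x$state, ", ", x$area, ")"),
      "-", length(x$trials), "conditions x", x$n_trials, "trials\n")
  invisible(x)
}

#' Parameters of a simulated LFP site
#'
#' The site model is `1/f^a` background noise plus an auditory evoked
#' component following the summed amplitude envelope, plus a band-limited
#' oscillation whose phase is reset toward a fixed target at luminance rising
#' edges. Resets change the phase *distribution* only; oscillation amplitude
#' is identical across visual conditions, so total power is matched.
#'
#' @param noise_exponent Spectral slope `a` of the background (default 1).
#' @param reset_band Two-element band (Hz) of the resettable oscillation.
#' @param reset_strength Phase concentration in \[0, 1\]: 0 = no reset
#'   (phase stays random), 1 = complete reset to the target phase. Maps to a
#'   von Mises concentration via the inverse of the mean resultant length.
#' @param reset_trigger_threshold Luminance level whose upward crossing
#'   triggers a reset (default 0.5).
#' @param auditory_evoked_gain Evoked amplitude per unit summed envelope.
#' @param osc_amplitude Oscillation amplitude (same units as the noise sd 1).
#' @param power_boost Optional amplitude modulation of the oscillation by the
#'   luminance envelope (`1 + power_boost * env_V(t)`); nonzero values break
#'   power neutrality on purpose (control analyses only).
#' @return Object of class `avb_lfp_params`.
#' @export
lfp_params <- function(noise_exponent = 1, reset_band = c(8, 15),
                       reset_strength = 0, reset_trigger_threshold = 0.5,
                       auditory_evoked_gain = 1, osc_amplitude = 0.7,
                       power_boost = 0) {
  if (reset_strength < 0 || reset_strength > 1)
    stop_invalid("reset_strength must lie in [0, 1]")
  if (length(reset_band) != 2L || reset_band[1] >= reset_band[2] ||
      reset_band[1] < 1 || reset_band[2] > 150)
    stop_invalid("reset_band must be an increasing pair inside [1, 150] Hz")
  structure(list(noise_exponent = noise_exponent, reset_band = reset_band,
                 reset_strength = reset_strength,
                 reset_trigger_threshold = reset_trigger_threshold,
                 auditory_evoked_gain = auditory_evoked_gain,
                 osc_amplitude = osc_amplitude, power_boost = power_boost),
            class = "avb_lfp_params")
}

# von Mises concentration giving mean resultant length R (Fisher's
# approximation), and a Best-Fisher sampler.
vm_kappa_from_r <- function(r) {
  if (r < 1e-8) return(0)
  if (r < 0.53) 2 * r + r^3 + 5 * r^5 / 6
  else if (r < 0.85) -0.4 + 1.39 * r + 0.43 / (1 - r)
  else 1 / (r^3 - 4 * r^2 + 3 * r)
}

rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
        out[i] <- mu + sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  out
}

# Slowly varying random amplitude envelope in [lo, hi] (default 0.5..1.5):
# low-passed Gaussian noise, min-max normalized. Draws from the ambient RNG.
slow_amplitude <- function(n, sample_rate, cutoff = 1.5, lo = 0.5, hi = 1.5) {
  x <- stats::rnorm(n)
  f <- (0:(n - 1)) / n * sample_rate
  f <- pmin(f, sample_rate - f)
  h <- as.numeric(f <= cutoff)
  y <- Re(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
  if (max(y) > min(y)) y <- (y - min(y)) / (max(y) - min(y)) else y[] <- 0.5
  lo + (hi - lo) * y
}

# 1/f^a noise of length n via spectral shaping, unit variance.
pink_noise <- function(n, exponent, sample_rate) {
  f <- (0:(n - 1)) / n * sample_rate
  f <- pmin(f, sample_rate - f)
  shape <- ifelse(f < 1e-9, 0, f^(-exponent / 2))
  x <- stats::rnorm(n)
  y <- Re(stats::fft(stats::fft(x) * shape, inverse = TRUE) / n)
  as.numeric(scale(y))
}

# Upward crossings of `threshold` in an envelope, as sample indices on the
# simulation grid.
rising_edges <- function(env, threshold) {
  above <- env >= threshold
  which(diff(above) == 1) + 1L
}

#' Simulate one LFP recording site across stimulus conditions
#'
#' See [lfp_params()] for the generative model. The phase of the band-limited
#' oscillation is replaced, at each luminance rising edge, by a von Mises
#' draw around a fixed target phase with concentration set by
#' `reset_strength`; transitions are smoothed over 50 ms to avoid broadband
#' splatter.
#'
#' @param params An [lfp_params()] object.
#' @param stimuli Named list of stimulus conditions.
#' @param n_trials Trials per condition.
#' @param seed Integer seed.
#' @param sample_rate LFP sample rate in Hz (>= 300; default 600).
#' @param site_id Metadata tag.
#' @return Object of class `avb_lfp`: `traces` is a named list (per
#'   condition) of trials x time matrices.
#' @export
simulate_lfp_site <- function(params, stimuli, n_trials = 20, seed = 1,
                              sample_rate = 600, site_id = "s1") {
  stopifnot(inherits(params, "avb_lfp_params"))
  if (sample_rate < 300) stop_invalid("sample_rate must be >= 300 Hz")
  fc <- mean(params$reset_band)
  kappa <- vm_kappa_from_r(params$reset_strength)
  traces <- with_seed(seed, {
    lapply(stimuli, function(stim) {
      n <- round(stim$duration * sample_rate)
      tt <- (seq_len(n) - 1) / sample_rate
      env_sum <- Reduce(`+`, lapply(stim$envelopes, function(e)
        resample_linear(e$samples, e$sample_rate, sample_rate, n)))
      env_v <- if (is.null(stim$luminance)) NULL
               else resample_linear(stim$luminance$samples,
                                    stim$luminance$sample_rate, sample_rate, n)
      edges <- if (is.null(env_v)) integer(0)
               else rising_edges(env_v, params$reset_trigger_threshold)
      out <- matrix(0, n_trials, n)
      for (i in seq_len(n_trials)) {
        # Constant-envelope phase slew. A slew's only power signature is the
        # brief instantaneous-frequency excursion during the transition,
        # whose size scales with (phase jump)/(slew duration). Transitions
        # are therefore slow (0.3-0.6 s) and their onsets widely jittered
        # per trial (0-0.5 s), so the residual excursion is both small and
        # not time-locked across trials; the post-transition phase stays
        # trigger-locked, which is what the ITPC analyses detect.
        phase_off <- rep(stats::runif(1, -pi, pi), n)
        if (length(edges) && params$reset_strength > 0) {
          for (e in edges) {
            new_phase <- rvonmises(1, 0, kappa) - 2 * pi * fc * tt[e]
            e0 <- e + round(stats::runif(1, 0, 0.5) * sample_rate)
            ramp_n <- round(stats::runif(1, 0.3, 0.6) * sample_rate)
            if (e0 >= n) next
            j <- e0:min(n, e0 + ramp_n)
            w <- 0.5 * (1 - cos(pi * (j - e0) / ramp_n))
            delta <- (new_phase - phase_off[e0] + pi) %% (2 * pi) - pi
            phase_off[j] <- phase_off[j] + w[seq_along(j)] * delta
            if (max(j) < n) phase_off[(max(j) + 1):n] <- phase_off[e0] + delta
          }
        }
        osc_unit <- cos(2 * pi * fc * tt + phase_off)
        # waxing-and-waning oscillation amplitude, independent across trials
        # and conditions, so resets shape the phase distribution but leave
        # the power statistics untouched
        amp <- params$osc_amplitude * slow_amplitude(n, sample_rate)
        if (!is.null(env_v) && params$power_boost != 0)
          amp <- amp * (1 + params$power_boost * env_v)
        osc <- amp * osc_unit
        out[i, ] <- pink_noise(n, params$noise_exponent, sample_rate) +
          params$auditory_evoked_gain * env_sum + osc
      }
      out
    })
  })
  structure(list(site_id = site_id, traces = traces,
                 sample_rate = sample_rate, band = c(1, 150),
                 params = params, n_trials = n_trials),
            class = "avb_lfp")
}

#' @export
print.avb_lfp <- function(x, ...) {
  cat("Simulated LFP site", x$site_id, "-", length(x$traces),
      "conditions x", x$n_trials, "trials at", x$sample_rate, "Hz\n")
  invisible(x)
}

#' Generate a synthetic population dataset
#'
#' Draws a mixed population of auditory-driven, visual-driven and undriven
#' units (multinomially, by `proportions`), simulates their spiking responses
#' to a shared stimulus set, and simulates LFP recording sites. The result
#' carries a manifest with every seed and the ground-truth class of each
#' unit, so parameter-recovery analyses have an exact reference.
#'
#' @param n_units Number of spiking units.
#' @param proportions Named numeric vector over classes `auditory`, `visual`,
#'   `none`; must sum to 1.
#' @param n_sites Number of LFP sites (0 to skip LFP simulation).
#' @param conditions Character vector of condition tokens to synthesize.
#' @param n_trials Trials per condition per unit/site.
#' @param seed Master seed; all child seeds derive from it.
#' @param duration Trial duration in seconds (the analysis window; default 3).
#' @param kappa `coherence_reliability` given to driven units.
#' @param deviant_gain Deviant rate perturbation given to auditory units.
#' @param deviants Deviant marker lists passed to [build_stimulus_set()];
#'   `NULL` for none. When supplied, each condition in `deviant_conditions`
#'   is synthesized both deviant-free (named `<condition>`) and with
#'   deviants (named `<condition>+dev`).
#' @param deviant_conditions Conditions receiving a `+dev` variant (default:
#'   the dual-stream conditions present).
#' @param unit_params_base [unit_params()] template for driven units;
#'   gains are scaled per class (auditory units get `gain_visual = 0` and
#'   vice versa; `none` units keep the baseline only).
#' @param lfp_params_site [lfp_params()] applied to every site.
#' @param envelope_rate,cutoff Envelope generation parameters.
#' @return Object of class `avb_population` with elements `stimuli`,
#'   `units`, `lfp_sites`, `manifest`.
#' @export
generate_population <- function(n_units = 100,
                                proportions = c(auditory = 0.4, visual = 0.1,
                                                none = 0.5),
                                n_sites = 0,
                                conditions = c("A1V1", "A1V2", "A2V1", "A2V2",
                                               "A12V1", "A12V2"),
                                n_trials = 20, seed = 1, duration = 3,
                                kappa = 1.5, deviant_gain = 0, deviants = NULL,
                                unit_params_base = unit_params(),
                                lfp_params_site = lfp_params(reset_strength = 0.8),
                                envelope_rate = 1000, cutoff = 7,
                                deviant_conditions =
                                  intersect(c("A12V1", "A12V2"), conditions)) {
  if (abs(sum(proportions) - 1) > 1e-8)
    stop_invalid("class proportions must sum to 1")
  env_seeds <- derive_seeds(seed, 2, salt = 101L)
  env1 <- make_am_envelope(duration, envelope_rate, cutoff, env_seeds[1])
  env2 <- make_am_envelope(duration, envelope_rate, cutoff, env_seeds[2])
  stimuli <- list()
  for (cond in conditions) {
    stimuli[[cond]] <- build_stimulus_set(cond, env1, env2,
                                          audio_rate = 24414)
    if (!is.null(deviants) && cond %in% deviant_conditions)
      stimuli[[paste0(cond, "+dev")]] <-
        build_stimulus_set(cond, env1, env2, deviants = deviants,
                           audio_rate = 24414)
  }
  classes <- with_seed(seed + 1L,
    sample(names(proportions), n_units, replace = TRUE, prob = proportions))
  unit_seeds <- derive_seeds(seed, n_units, salt = 202L)
  units <- vector("list", n_units)
  for (i in seq_len(n_units)) {
    p <- unit_params_base
    p$coherence_reliability <- kappa
    p$deviant_gain <- deviant_gain
    if (classes[i] == "auditory") {
      p$gain_visual <- 0
    } else if (classes[i] == "visual") {
      p$gain_visual <- p$gain_auditory
      p$gain_auditory <- 0
      p$deviant_gain <- 0
    } else {
      p$gain_auditory <- 0
      p$gain_visual <- 0
      p$deviant_gain <- 0
    }
    units[[i]] <- simulate_spiking_unit(p, stimuli, n_trials,
                                        seed = unit_seeds[i],
                                        unit_id = sprintf("u%03d", i))
    units[[i]]$class_true <- classes[i]
  }
  lfp_sites <- list()
  if (n_sites > 0) {
    site_seeds <- derive_seeds(seed, n_sites, salt = 303L)
    lfp_sites <- lapply(seq_len(n_sites), function(j)
      simulate_lfp_site(lfp_params_site, stimuli, n_trials,
                        seed = site_seeds[j],
                        site_id = sprintf("s%02d", j)))
  }
  manifest <- list(seed = seed, env_seeds = env_seeds,
                   unit_seeds = unit_seeds, classes = classes,
                   n_trials = n_trials, conditions = conditions,
                   duration = duration, kappa = kappa,
                   deviant_gain = deviant_gain)
  structure(list(stimuli = stimuli, units = units, lfp_sites = lfp_sites,
                 manifest = manifest),
            class = "avb_population")
}

#' @export
print.avb_population <- function(x, ...) {
  cat("Synthetic population:", length(x$units), "units,",
      length(x$lfp_sites), "LFP sites,",
      length(x$manifest$conditions), "conditions x",
      x$manifest$n_trials, "trials\n")
  cat("  classes:", paste(names(table(x$manifest$classes)),
                          table(x$manifest$classes),
                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}
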