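test_that("the default frequency grid has 86 points with 0.5-Hz spacing", {
  g <- frequency_grid()
  expect_equal(g$n_points, 86)
  expect_equal(g$frequencies[1], 2.5)
  expect_equal(g$frequencies[86], 45)
  expect_true(all(abs(diff(g$frequencies) - 0.5) < 1e-12))
  expect_equal(g$cycles, 7)
  expect_error(frequency_grid(10, 5), class = "avbind_invalid_argument")
})

test_that("Morlet coefficients localize frequency and recover phase", {
  fs <- 600
  tt <- (0:(3 * fs - 1)) / fs
  x <- cos(2 * pi * 10 * tt)
  tfr <- morlet_tfr(matrix(x, 1), fs, frequency_grid(2.5, 45, 0.5))
  mid <- which.min(abs(tfr$times - 1.5))
  amp <- Mod(tfr$coef[1, , mid])
  expect_equal(tfr$grid$frequencies[which.max(amp)], 10)
  # analytic-signal oracle: phase of cos(2 pi 10 t) at time t is 2 pi 10 t
  ph <- Arg(tfr$coef[1, which.max(amp), mid])
  expected <- ((2 * pi * 10 * tfr$times[mid] + pi) %% (2 * pi)) - pi
  dphi <- abs(Arg(exp(1i * (ph - expected))))
  expect_lt(dphi, 0.1)
  expect_error(morlet_tfr(matrix(x[1:300], 1), fs),
               class = "avbind_invalid_argument")
})

test_that("ITPC closed forms: identical, antiphase and uniform phases", {
  # identical phases across trials -> ITPC 1 everywhere
  z <- exp(1i * array(rep(runif(4 * 25, -pi, pi), each = 6), c(6, 4, 25)))
  expect_true(all(abs(itpc(fake_tfr(z))$values - 1) < 1e-12))
  # balanced antiphase -> 0
  base <- exp(1i * array(runif(4 * 25, -pi, pi), c(1, 4, 25)))
  z2 <- array(0i, c(6, 4, 25))
  for (k in 1:3) { z2[k, , ] <- base[1, , ]; z2[k + 3, , ] <- -base[1, , ] }
  expect_true(all(itpc(fake_tfr(z2))$values < 1e-12))
  # uniform random phases, N = 20: E[ITPC] = sqrt(pi)/(2 sqrt(20))
  set.seed(8)
  vals <- replicate(40, {
    z <- exp(1i * array(runif(20 * 25, -pi, pi), c(20, 1, 25)))
    mean(itpc(fake_tfr(z))$values)
  })
  expect_equal(mean(vals), sqrt(pi) / (2 * sqrt(20)), tolerance = 0.02 /
                 (sqrt(pi) / (2 * sqrt(20))))
  expect_error(itpc(fake_tfr(array(1i, c(1, 2, 3)))),
               class = "avbind_invalid_argument")
})

test_that("ITPC scales as N^(-1/2) under uniform phases", {
  set.seed(9)
  Ns <- c(8, 16, 32, 64)
  m <- vapply(Ns, function(N) {
    mean(replicate(30, {
      z <- exp(1i * array(runif(N * 40, -pi, pi), c(N, 1, 40)))
      mean(itpc(fake_tfr(z))$values)
    }))
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(m) ~ log(Ns)))[2]
  expect_equal(unname(slope), -0.5, tolerance = 0.1)
})

test_that("ITPC is invariant to trial order and global phase rotation", {
  set.seed(10)
  z <- exp(1i * array(runif(10 * 3 * 20, -pi, pi), c(10, 3, 20)))
  base <- itpc(fake_tfr(z))$values
  perm <- itpc(fake_tfr(z[sample(10), , , drop = FALSE]))$values
  expect_equal(base, perm)
  rot <- itpc(fake_tfr(z * exp(1.23i)))$values
  expect_equal(base, rot)
})

test_that("across-stimulus ITPC matches within for identical statistics", {
  set.seed(11)
  fs <- 600
  mk_traces <- function(seed) {
    p <- lfp_params(reset_strength = 0)
    simulate_lfp_site(p, fix_stims_with("A1"), n_trials = 12,
                      seed = seed)$traces$A1
  }
  g <- frequency_grid(5, 20, 1)
  t1 <- morlet_tfr(mk_traces(1), fs, g, decimate = 4)
  t2 <- morlet_tfr(mk_traces(2), fs, g, decimate = 4)
  acr1 <- across_stimulus_itpc(t1, t2, n_shuffles = 50, seed = 3)
  acr2 <- across_stimulus_itpc(t1, t2, n_shuffles = 50, seed = 3)
  expect_identical(acr1$values, acr2$values)
  # paired within-minus-across difference over sites is centred on zero
  d <- vapply(1:6, function(k) {
    ta <- morlet_tfr(mk_traces(10 + k), fs, g, decimate = 4)
    tb <- morlet_tfr(mk_traces(30 + k), fs, g, decimate = 4)
    acr <- across_stimulus_itpc(ta, tb, n_shuffles = 50, seed = k)
    mean((itpc(ta)$profile + itpc(tb)$profile) / 2 - acr$profile)
  }, numeric(1))
  expect_lt(abs(mean(d)), 2 * stats::sd(d) / sqrt(length(d)) + 0.01)
  t3 <- morlet_tfr(mk_traces(3)[1:3, ], fs, g, decimate = 4)
  expect_error(across_stimulus_itpc(t1, t3),
               class = "avbind_invalid_argument")
})

test_that("PDI algebra: zero for within == across, bounded, antisymmetric", {
  fr <- frequency_grid(5, 10, 1)$frequencies
  mk_itpc <- function(profile) {
    structure(list(values = NULL, profile = profile, n_trials = 10,
                   frequencies = fr, kind = "within"), class = "avb_itpc")
  }
  p <- runif(length(fr))
  within <- list(A1V1 = mk_itpc(p), A1V2 = mk_itpc(p),
                 A2V1 = mk_itpc(p), A2V2 = mk_itpc(p))
  across <- list(A1 = mk_itpc(p), A2 = mk_itpc(p))
  ss <- single_stream_pdi(within, across)
  expect_true(all(ss$coherent == 0) && all(ss$independent == 0))
  q <- runif(length(fr))
  within2 <- lapply(within, function(x) mk_itpc(q))
  ss2 <- single_stream_pdi(within2, across)
  swapped <- single_stream_pdi(
    within = list(A1V1 = mk_itpc(p), A1V2 = mk_itpc(p),
                  A2V1 = mk_itpc(p), A2V2 = mk_itpc(p)),
    across = list(A1 = mk_itpc(q), A2 = mk_itpc(q)))
  expect_equal(ss2$coherent, -swapped$coherent)
  expect_true(all(ss2$coherent >= -1 & ss2$coherent <= 1))
  expect_error(single_stream_pdi(within[1:3], across),
               class = "avbind_invalid_argument")
})

test_that("dual-stream PDI vanishes for degenerate identical trials", {
  fs <- 600
  x <- matrix(rep(sin(2 * pi * 9 * (0:(3 * fs - 1)) / fs), 6), 6,
              byrow = TRUE)
  g <- frequency_grid(5, 15, 1)
  t1 <- morlet_tfr(x, fs, g, decimate = 4)
  dd <- dual_stream_pdi(t1, t1, n_shuffles = 20, seed = 1)
  expect_true(all(abs(dd$pdi) < 1e-9))
})

test_that("visual phase resets raise within over across ITPC in band", {
  p <- lfp_params(reset_strength = 0.9, reset_band = c(8, 15))
  site <- simulate_lfp_site(p, fix_stims[c("A1V1", "A1V2")],
                            n_trials = 16, seed = 33)
  g <- frequency_grid(4, 24, 0.5)
  t1 <- morlet_tfr(site$traces$A1V1, 600, g, decimate = 4)
  t2 <- morlet_tfr(site$traces$A1V2, 600, g, decimate = 4)
  acr <- across_stimulus_itpc(t1, t2, n_shuffles = 60, seed = 2)
  pdi1 <- itpc(t1)$profile - acr$profile
  fr <- g$frequencies
  in_band <- fr >= 9 & fr <= 14
  out_band <- fr <= 6 | fr >= 20
  expect_gt(mean(pdi1[in_band]), 0.05)
  expect_gt(mean(pdi1[in_band]), mean(pdi1[out_band]) + 0.05)
})

test_that("significance rule: Bonferroni level, adjacency, null behaviour", {
  # the corrected level for 43 frequencies prints as 0.0012
  sig <- pdi_significance(matrix(rnorm(43 * 5, 1), 5),
                          matrix(rnorm(43 * 5, 0), 5), n_freq = 43)
  expect_equal(signif(sig$alpha_corrected, 2), 0.0012)
  # an isolated significant frequency is masked out by the adjacency rule
  set.seed(14)
  within <- matrix(rnorm(20 * 10, 0, 0.001), 10, 20)
  within[, 7] <- within[, 7] + 5
  across <- matrix(rnorm(20 * 10, 0, 0.001), 10, 20)
  s <- pdi_significance(within, across)
  expect_true(all(!s$mask))
  expect_equal(s$magnitude, 0)
  # two adjacent significant bins survive
  within[, 8] <- within[, 8] + 5
  s2 <- pdi_significance(within, across)
  expect_true(all(which(s2$mask) == c(7, 8)))
  expect_equal(s2$magnitude, sum(s2$pdi_mean[c(7, 8)]))
  # pure null: flag rate at most base_alpha over replicates
  set.seed(15)
  flags <- replicate(300, {
    w <- matrix(rnorm(86 * 6), 6, 86)
    a <- matrix(rnorm(86 * 6), 6, 86)
    any(pdi_significance(w, a)$mask)
  })
  expect_lte(mean(flags), 0.05)
  expect_error(pdi_significance(within[1:2, ], across[1:2, ]),
               class = "avbind_invalid_argument")
})

test_that("power dissimilarity responds to power, not phase", {
  g <- frequency_grid(6, 20, 1)
  # a condition-specific power boost produces positive power dissimilarity
  pb <- lfp_params(reset_strength = 0, power_boost = 2.5)
  site_b <- simulate_lfp_site(pb, fix_stims[c("A1V1", "A1V2")],
                              n_trials = 16, seed = 44)
  tb1 <- morlet_tfr(site_b$traces$A1V1, 600, g, decimate = 4)
  tb2 <- morlet_tfr(site_b$traces$A1V2, 600, g, decimate = 4)
  pw <- power_dissimilarity(tb1, tb2, n_shuffles = 50, seed = 5)
  fr <- g$frequencies
  in_band <- fr >= 9 & fr <= 14
  expect_gt(mean(pw$pdi[in_band]), 0.03)
  # degenerate identical conditions -> zero
  pw0 <- power_dissimilarity(tb1, tb1, n_shuffles = 30, seed = 6)
  expect_lt(max(abs(pw0$pdi)), 0.05)
  # strong phase resets alone leave power dissimilarity near zero
  # (averaged over a few sites; single sites are noisy)
  pw_p <- rowMeans(vapply(45:47, function(s) {
    pp <- lfp_params(reset_strength = 0.9)
    site_p <- simulate_lfp_site(pp, fix_stims[c("A1V1", "A1V2")],
                                n_trials = 16, seed = s)
    tp1 <- morlet_tfr(site_p$traces$A1V1, 600, g, decimate = 4)
    tp2 <- morlet_tfr(site_p$traces$A1V2, 600, g, decimate = 4)
    power_dissimilarity(tp1, tp2, n_shuffles = 50, seed = 7)$pdi
  }, numeric(length(fr))))
  expect_lt(mean(pw_p[in_band]), 0.06)
  expect_lt(mean(pw_p[in_band]), 0.5 * mean(pw$pdi[in_band]))
})
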