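# Independent brute-force nearest-template oracle: per trial, recompute the
# leave-one-out templates by explicit loops and return the set of classes at
# minimal distance.
brute_force_argmin <- function(groups) {
  X <- do.call(rbind, groups)
  cls <- rep(seq_along(groups), vapply(groups, nrow, integer(1)))
  lapply(seq_len(nrow(X)), function(i) {
    d <- vapply(seq_along(groups), function(k) {
      rows <- which(cls == k)
      if (k == cls[i]) rows <- setdiff(rows, i)
      tmpl <- colMeans(X[rows, , drop = FALSE])
      sum((X[i, ] - tmpl)^2)
    }, numeric(1))
    which(d <= min(d) + 1e-9 * (1 + abs(min(d))))
  })
}

test_that("spike binning conserves counts and uses half-open bins", {
  m <- bin_spikes(list(numeric(0)), c(0, 3), 0.02)
  expect_equal(ncol(m), 150)
  expect_equal(sum(m), 0)
  # spikes at a bin edge go to the later bin; the window end is excluded
  m <- bin_spikes(list(c(0, 0.02, 0.04 - 1e-9, 2.9999, 3.0)), c(0, 3), 0.02)
  expect_equal(m[1, 1], 1L)
  expect_equal(m[1, 2], 2L)
  expect_equal(m[1, 150], 1L)
  expect_equal(sum(m), 4L)
  # random trains: binned total equals in-window spike count
  trains <- random_trains(8, rate = 30, seed = 2)
  m <- bin_spikes(trains, c(0.5, 2.5), 0.02)
  truth <- vapply(trains, function(tr) sum(tr >= 0.5 & tr < 2.5), numeric(1))
  expect_equal(unname(rowSums(m)), truth)
  expect_error(bin_spikes(trains, c(0, 3), 0.021),
               class = "avbind_invalid_argument")
})

test_that("LOOCV classifier matches the exhaustive oracle on random instances", {
  set.seed(99)
  for (rep in 1:300) {
    k <- sample(2:3, 1)
    nb <- sample(2:10, 1)
    groups <- lapply(seq_len(k), function(j)
      matrix(rpois(sample(2:6, 1) * nb, lambda = sample(1:4, 1)), ncol = nb))
    names(groups) <- paste0("c", seq_len(k))
    res <- euclidean_loocv(groups, seed = rep)
    oracle <- brute_force_argmin(groups)
    got <- match(res$assigned, names(groups))
    for (i in seq_along(oracle))
      expect_true(got[i] %in% oracle[[i]])
  }
})

test_that("LOOCV classifier handles separable and degenerate cases", {
  a <- matrix(rep(c(5, 0, 5, 0), 5), nrow = 5, byrow = TRUE)
  b <- matrix(rep(c(0, 5, 0, 5), 5), nrow = 5, byrow = TRUE)
  expect_equal(euclidean_loocv(list(A = a, B = b))$percent_correct, 100)
  # all trials identical in both classes: pure tie-break, 50% on average
  same <- matrix(1, 4, 6)
  scores <- vapply(1:200, function(s)
    euclidean_loocv(list(A = same, B = same), seed = s)$percent_correct,
    numeric(1))
  expect_equal(mean(scores), 50, tolerance = 5)
  expect_error(euclidean_loocv(list(A = a)), class = "avbind_invalid_argument")
  expect_error(euclidean_loocv(list(A = a, B = b[, 1:2])),
               class = "avbind_invalid_argument")
})

test_that("permutation test is reproducible and flags separable data", {
  a <- matrix(rpois(5 * 20, 8), 5, 20)
  b <- a + 10
  p1 <- permutation_null(list(A = a, B = b), n_iter = 200, seed = 3)
  p2 <- permutation_null(list(A = a, B = b), n_iter = 200, seed = 3)
  expect_identical(p1$p, p2$p)
  expect_true(p1$significant)
  expect_equal(p1$observed, 100)
  expect_error(permutation_null(list(A = a, B = b), n_iter = 50),
               class = "avbind_invalid_argument")
})

test_that("label-shuffled decoding converges to chance as trials grow", {
  set.seed(5)
  scores <- vapply(c(20, 80), function(n) {
    X <- matrix(rpois(2 * n * 10, 5), 2 * n, 10)
    mean(vapply(1:10, function(r) {
      idx <- sample.int(2 * n)
      euclidean_loocv(list(A = X[idx[1:n], ], B = X[idx[-(1:n)], ]),
                      seed = r)$percent_correct
    }, numeric(1)))
  }, numeric(1))
  expect_equal(scores[2], 50, tolerance = 6)
  expect_lt(abs(scores[2] - 50), abs(scores[1] - 50) + 6)
})

test_that("unit classification recovers the simulated unit class", {
  u_aud <- simulate_spiking_unit(unit_params(gain_auditory = 30),
                                 fix_stims, n_trials = 16, seed = 7)
  u_vis <- simulate_spiking_unit(unit_params(gain_auditory = 0,
                                             gain_visual = 30),
                                 fix_stims, n_trials = 16, seed = 8)
  cls_a <- classify_unit_discrimination(u_aud, n_iter = 300, seed = 1)
  cls_v <- classify_unit_discrimination(u_vis, n_iter = 300, seed = 1)
  expect_equal(cls_a$label, "auditory-discriminating")
  expect_equal(cls_v$label, "visual-discriminating")
  u_missing <- u_aud
  u_missing$trials$A1V1 <- NULL
  expect_error(classify_unit_discrimination(u_missing),
               class = "avbind_invalid_argument")
})

test_that("dual-stream decoding reports per-condition A1 proportions", {
  d <- decode_dual_stream(fix_unit_kappa, seed = 1)
  expect_named(d$by_condition, c("A12V1", "A12V2"))
  for (r in d$by_condition) {
    expect_equal(r$n, 16)
    expect_equal(r$prop_a1, r$n_a1 / r$n)
  }
  # the coherent visual stream pulls classification toward its stream
  expect_gt(d$by_condition$A12V1$prop_a1, d$by_condition$A12V2$prop_a1)
  u_no_tmpl <- fix_unit_kappa
  u_no_tmpl$trials$A2V2 <- NULL
  expect_error(decode_dual_stream(u_no_tmpl),
               class = "avbind_invalid_argument")
})

test_that("percentage reporting follows the printed conventions", {
  expect_identical(report_percent(19, 23, "whole-truncate"), 82)
  expect_identical(report_percent(6, 23, "whole-truncate"), 26)
  expect_equal(report_percent(91, 271, "one-decimal-round"), 33.6)
  expect_equal(report_percent(210, 532, "one-decimal-round"), 39.5)
  expect_equal(report_percent(0, 10), 0)
  expect_error(report_percent(1, 0), class = "avbind_invalid_argument")
})

test_that("VPI arithmetic, bounds and sign symmetry hold", {
  v <- compute_vpi(list(A12V1 = c(19, 23), A12V2 = c(6, 23)))
  expect_equal(v$pct_a1_given_v1, 82)
  expect_equal(v$pct_a1_given_v2, 26)
  expect_equal(v$vpi, 56)
  expect_equal(compute_vpi(list(A12V1 = c(5, 10), A12V2 = c(5, 10)))$vpi, 0)
  expect_equal(compute_vpi(list(A12V1 = c(23, 23), A12V2 = c(0, 23)))$vpi, 100)
  # swapping the visual labels flips the sign
  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:30, 2, replace = TRUE)
    k <- c(sample(0:n[1], 1), sample(0:n[2], 1))
    a <- compute_vpi(list(A12V1 = c(k[1], n[1]), A12V2 = c(k[2], n[2])))
    b <- compute_vpi(list(A12V1 = c(k[2], n[2]), A12V2 = c(k[1], n[1])))
    expect_equal(a$vpi, -b$vpi)
    expect_true(a$vpi >= -100 && a$vpi <= 100)
  }
})

test_that("VPI permutation test is seeded and detects strong visual coupling", {
  vt1 <- vpi_permutation(fix_unit_kappa, n_iter = 300, seed = 4)
  vt2 <- vpi_permutation(fix_unit_kappa, n_iter = 300, seed = 4)
  expect_identical(vt1$p, vt2$p)
  u_strong <- simulate_spiking_unit(
    unit_params(gain_auditory = 30, gain_visual = 80,
                coherence_reliability = 1.5),
    fix_stims, n_trials = 24, seed = 9)
  expect_lt(vpi_permutation(u_strong, n_iter = 500, seed = 1)$p, 0.05)
})

test_that("coherence contrast exposes scores and evoked rates", {
  cc <- coherence_decoding_contrast(fix_unit_kappa, seed = 2)
  expect_true(cc$coherent_score >= 0 && cc$coherent_score <= 100)
  expect_equal(nrow(cc$rates), 4)
  expect_true(all(cc$rates$max_rate >= cc$rates$mean_rate))
  u2 <- fix_unit_kappa
  u2$trials$A1V2 <- NULL
  expect_error(coherence_decoding_contrast(u2),
               class = "avbind_invalid_argument")
})

test_that("simple-stimulus ANOVA classification matches a sums-of-squares oracle", {
  # balanced 2x2 design, 6 replicates per cell
  set.seed(12)
  aud <- rep(c(0, 0, 1, 1), each = 6)
  vis <- rep(c(0, 1, 0, 1), each = 6)
  counts <- 5 + 8 * aud + rnorm(24, 0, 1)
  res <- classify_simple_unit(counts, aud, vis)
  expect_equal(res$label, "auditory")

  # explicit two-way ANOVA decomposition
  gm <- mean(counts)
  ma <- tapply(counts, aud, mean); mv <- tapply(counts, vis, mean)
  mc <- tapply(counts, interaction(aud, vis), mean)
  ss_a <- 12 * sum((ma - gm)^2)
  ss_v <- 12 * sum((mv - gm)^2)
  ss_cells <- 6 * sum((mc - gm)^2)
  ss_int <- ss_cells - ss_a - ss_v
  ss_err <- sum((counts - mc[interaction(aud, vis)])^2)
  f_oracle <- c(ss_a / 1, ss_v / 1, ss_int / 1) / (ss_err / 20)
  expect_equal(unname(res$F), unname(f_oracle), tolerance = 1e-10)

  # interaction-only pattern is auditory-visual
  counts_i <- 5 + 8 * (aud == vis) + rnorm(24, 0, 1)
  expect_equal(classify_simple_unit(counts_i, aud, vis)$label,
               "auditory-visual")
  expect_error(classify_simple_unit(counts[1:5], aud[1:5], vis[1:5]),
               class = "avbind_invalid_argument")
})
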