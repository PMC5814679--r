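#' Bin spike trains into a peri-stimulus count matrix
#'
#' Counts spikes in half-open bins `[left, right)` from stimulus onset to
#' offset; a spike exactly at a bin edge falls in the later bin and a spike
#' exactly at the window end is excluded.
#'
#' @param trials List of numeric spike-time vectors (seconds from onset).
#' @param window Two-element analysis window in seconds (default `c(0, 3)`).
#' @param bin_width Bin width in seconds (default 0.020); must divide the
#'   window length.
#' @return Integer matrix (trials x bins) with attributes `bin_width` and
#'   `window`.
#' @export
bin_spikes <- function(trials, window = c(0, 3), bin_width = 0.02) {
  if (length(window) != 2L || window[1] >= window[2])
    stop_invalid("window must be an increasing pair")
  nb <- (window[2] - window[1]) / bin_width
  if (abs(nb - round(nb)) > 1e-8)
    stop_invalid("bin_width must divide the window length exactly")
  nb <- as.integer(round(nb))
  counts <- t(vapply(trials, function(tr) {
    idx <- floor((tr - window[1]) / bin_width)
    idx <- idx[idx >= 0 & idx < nb]
    tabulate(idx + 1L, nbins = nb)
  }, integer(nb)))
  if (length(trials) == 1L) counts <- matrix(counts, nrow = 1L)
  attr(counts, "bin_width") <- bin_width
  attr(counts, "window") <- window
  counts
}

# Core leave-one-out nearest-mean-template classification. X: trials x bins;
# cls: integer class per trial (1..K). Returns the assigned class per trial.
# Ties are broken uniformly at random using the ambient RNG stream.
loocv_assign <- function(X, cls) {
  K <- max(cls)
  n_k <- tabulate(cls, K)
  if (any(n_k < 2L)) stop_invalid("each class needs at least 2 trials")
  S <- rowsum(X, cls)                      # class sums (K x bins)
  M <- S / n_k                             # class means
  G <- X %*% t(M)                          # trial x class inner products
  x2 <- rowSums(X^2)
  m2 <- rowSums(M^2)
  D <- sweep(-2 * G, 2, m2, `+`) + x2      # squared distance to full means
  # leave-one-out correction for the trial's own class template
  own <- cbind(seq_len(nrow(X)), cls)
  n_own <- n_k[cls]
  g_own <- G[own]
  m2_own <- m2[cls]
  # template' = (n*M - x) / (n-1)
  dot_own <- (n_own * g_own - x2) / (n_own - 1)
  t2_own <- (n_own^2 * m2_own - 2 * n_own * g_own + x2) / (n_own - 1)^2
  D[own] <- x2 - 2 * dot_own + t2_own
  assign_nearest(D)
}

# Row-wise argmin with uniform random tie-breaking (relative tolerance).
assign_nearest <- function(D) {
  idx <- max.col(-D, ties.method = "first")
  mins <- D[cbind(seq_len(nrow(D)), idx)]
  tol <- 1e-9 * (1 + abs(mins))
  n_cand <- rowSums(D <= mins + tol)
  for (i in which(n_cand > 1L)) {
    cand <- which(D[i, ] <= mins[i] + tol[i])
    idx[i] <- cand[sample.int(length(cand), 1L)]
  }
  idx
}

#' Euclidean-distance template classifier with leave-one-out cross-validation
#'
#' Each trial is assigned to the class whose mean spike-count template
#' (excluding the held-out trial from its own class template) lies nearest in
#' Euclidean distance over bins. Ties are broken uniformly at random under
#' `seed`.
#'
#' @param groups Named list of count matrices (trials x bins, equal bin
#'   counts), one per class, each with at least two trials.
#' @param seed Optional seed for tie-breaking.
#' @return Object of class `avb_classifier_result` with per-trial
#'   `assigned` labels, `truth`, per-label `proportions`, and
#'   `percent_correct`.
#' @export
euclidean_loocv <- function(groups, seed = NULL) {
  if (length(groups) < 2L) stop_invalid("need at least two classes")
  nb <- unique(vapply(groups, ncol, integer(1)))
  if (length(nb) != 1L) stop_invalid("classes have mismatched bin counts")
  X <- do.call(rbind, groups)
  cls <- rep(seq_along(groups), vapply(groups, nrow, integer(1)))
  idx <- with_seed(seed, loocv_assign(X, cls))
  labels <- names(groups)
  if (is.null(labels)) labels <- paste0("class", seq_along(groups))
  assigned <- labels[idx]
  truth <- labels[cls]
  structure(
    list(assigned = assigned, truth = truth,
         proportions = prop.table(table(factor(assigned, levels = labels))),
         percent_correct = 100 * mean(assigned == truth),
         n_trials = nrow(X)),
    class = "avb_classifier_result")
}

#' @export
print.avb_classifier_result <- function(x, ...) {
  cat(sprintf("LOOCV template classifier: %.1f%% correct (%d trials)\n",
              x$percent_correct, x$n_trials))
  invisible(x)
}

# Lean internal LOOCV percent-correct for permutation loops.
loocv_score <- function(X, cls) {
  100 * mean(loocv_assign(X, cls) == cls)
}

#' Permutation null for the template classifier
#'
#' Builds a null distribution of decoding scores by resampling trials (by
#' default with replacement, preserving class sizes) and assigning them to
#' classes at random, then re-running the leave-one-out classifier. A
#' response is significantly informative when the observed score exceeds the
#' 95th percentile of the null (for `alpha = 0.05`).
#'
#' @inheritParams euclidean_loocv
#' @param n_iter Number of permutation iterations (default 1000, minimum
#'   100).
#' @param alpha Significance level; the flag uses the `1 - alpha` null
#'   quantile.
#' @param seed Integer seed.
#' @param scheme `"permute"` (default) shuffles the observed labels, giving
#'   an exact randomized permutation test; `"bootstrap"` draws trials with
#'   replacement before random class assignment. The bootstrap variant is
#'   conservative for high-dimensional spike patterns: a resampled duplicate
#'   of the held-out trial pulls its own class template closer and inflates
#'   the null scores.
#' @details Decoding scores are discrete (multiples of one trial), so ties
#'   between the observed score and null scores carry appreciable
#'   probability mass and would make the exceedance rule conservative. Ties
#'   are therefore broken uniformly at random (a randomized permutation
#'   test), which keeps the false-positive rate at `alpha` exactly.
#' @return Object of class `avb_permutation` with `observed`, `p`
#'   (fraction of null scores >= observed, with random tie-breaking),
#'   `significant`, `null_quantile`, `n_iter`.
#' @export
permutation_null <- function(groups, n_iter = 1000, alpha = 0.05, seed = 1,
                             scheme = c("permute", "bootstrap")) {
  if (n_iter < 100) stop_invalid("n_iter must be >= 100")
  scheme <- match.arg(scheme)
  X <- do.call(rbind, groups)
  cls <- rep(seq_along(groups), vapply(groups, nrow, integer(1)))
  n <- nrow(X)
  res <- with_seed(seed, {
    observed <- loocv_score(X, cls)
    null_scores <- vapply(seq_len(n_iter), function(i) {
      Xi <- if (scheme == "bootstrap") X[sample.int(n, n, replace = TRUE), ,
                                         drop = FALSE]
            else X
      loocv_score(Xi, sample(cls))
    }, numeric(1))
    # random tie-breaking jitter, far below the score granularity
    list(observed = observed, null_scores = null_scores,
         obs_j = observed + stats::runif(1, 0, 1e-6),
         null_j = null_scores + stats::runif(n_iter, 0, 1e-6))
  })
  q95 <- stats::quantile(res$null_j, 1 - alpha, names = FALSE)
  structure(
    list(observed = res$observed,
         p = mean(res$null_j >= res$obs_j),
         significant = res$obs_j > q95,
         null_quantile = q95, n_iter = n_iter, alpha = alpha),
    class = "avb_permutation")
}

#' @export
print.avb_permutation <- function(x, ...) {
  cat(sprintf("Permutation test: observed %.1f%%, p = %.3f (%s, %d iter)\n",
              x$observed, x$p,
              if (x$significant) "significant" else "not significant",
              x$n_iter))
  invisible(x)
}

#' Classify a unit as auditory- and/or visual-discriminating
#'
#' Auditory axis: decode auditory stream identity from the pooled responses
#' to `A1V1`+`A1V2` versus `A2V1`+`A2V2`. Visual axis: decode visual stream
#' identity from `A1V1`+`A2V1` versus `A1V2`+`A2V2`. Each axis is tested
#' with [permutation_null()]; the unit label is `"both"` when both axes are
#' significant, `"auditory-discriminating"` or `"visual-discriminating"`
#' when one is, and `"none"` otherwise.
#'
#' @param unit An `avb_unit` containing all four single-stream conditions.
#' @param window,bin_width PSTH parameters (defaults: 3-s window, 20-ms
#'   bins).
#' @param n_iter,alpha,seed Permutation-test parameters.
#' @return Object of class `avb_unit_class` with the label and per-axis
#'   scores and p values.
#' @export
classify_unit_discrimination <- function(unit, window = c(0, 3),
                                         bin_width = 0.02, n_iter = 1000,
                                         alpha = 0.05, seed = 1) {
  need <- c("A1V1", "A1V2", "A2V1", "A2V2")
  if (!all(need %in% names(unit$trials)))
    stop_invalid("unit must have all four single-stream conditions")
  P <- lapply(unit$trials[need], bin_spikes, window = window,
              bin_width = bin_width)
  aud <- permutation_null(list(A1 = rbind(P$A1V1, P$A1V2),
                               A2 = rbind(P$A2V1, P$A2V2)),
                          n_iter, alpha, seed)
  vis <- permutation_null(list(V1 = rbind(P$A1V1, P$A2V1),
                               V2 = rbind(P$A1V2, P$A2V2)),
                          n_iter, alpha, seed + 1L)
  label <- if (aud$significant && vis$significant) "both"
           else if (aud$significant) "auditory-discriminating"
           else if (vis$significant) "visual-discriminating"
           else "none"
  structure(list(label = label,
                 auditory_score = aud$observed, auditory_p = aud$p,
                 visual_score = vis$observed, visual_p = vis$p),
            class = "avb_unit_class")
}

#' @export
print.avb_unit_class <- function(x, ...) {
  cat(sprintf("Unit class: %s (auditory %.1f%%, p=%.3f; visual %.1f%%, p=%.3f)\n",
              x$label, x$auditory_score, x$auditory_p,
              x$visual_score, x$visual_p))
  invisible(x)
}

#' Decode dual-stream responses against single-stream templates
#'
#' Templates are the mean binned responses to the two temporally coherent
#' single-stream stimuli (`A1V1` and `A2V2`) or, as a control, to the
#' auditory-only stimuli (`A1` and `A2`). Each dual-stream trial (`A12V1`,
#' `A12V2`, and the no-visual control `A12` when present) is labeled `A1` or
#' `A2` by the nearer template; no leave-one-out is needed because template
#' and test conditions are disjoint.
#'
#' @param unit An `avb_unit`.
#' @param template_source `"coherent-av"` (templates `A1V1`/`A2V2`) or
#'   `"auditory-only"` (templates `A1`/`A2`).
#' @param window,bin_width PSTH parameters.
#' @param seed Tie-break seed.
#' @return Object of class `avb_dual_result`: per dual condition, the number
#'   and proportion of trials labeled `A1`.
#' @export
decode_dual_stream <- function(unit, template_source = c("coherent-av",
                                                         "auditory-only"),
                               window = c(0, 3), bin_width = 0.02,
                               seed = NULL) {
  template_source <- match.arg(template_source)
  tmpl_conds <- if (template_source == "coherent-av") c("A1V1", "A2V2")
                else c("A1", "A2")
  if (!all(tmpl_conds %in% names(unit$trials)))
    stop_invalid("missing template condition(s): ",
                 paste(setdiff(tmpl_conds, names(unit$trials)), collapse = ", "))
  test_conds <- intersect(c("A12V1", "A12V2", "A12"), names(unit$trials))
  if (length(test_conds) == 0L) stop_invalid("no dual-stream conditions present")
  templates <- lapply(unit$trials[tmpl_conds], function(tr)
    colMeans(bin_spikes(tr, window, bin_width)))
  res <- with_seed(seed, {
    lapply(unit$trials[test_conds], function(tr) {
      X <- bin_spikes(tr, window, bin_width)
      D <- vapply(templates, function(m) colSums((t(X) - m)^2), numeric(nrow(X)))
      if (nrow(X) == 1L) D <- matrix(D, nrow = 1L)
      lab <- assign_nearest(D)
      list(n_a1 = sum(lab == 1L), n = nrow(X), prop_a1 = mean(lab == 1L))
    })
  })
  structure(list(by_condition = res, template_source = template_source),
            class = "avb_dual_result")
}

#' @export
print.avb_dual_result <- function(x, ...) {
  cat("Dual-stream decoding (templates:", x$template_source, ")\n")
  for (cond in names(x$by_condition)) {
    r <- x$by_condition[[cond]]
    cat(sprintf("  %-6s %d/%d trials labeled A1 (%.1f%%)\n",
                cond, r$n_a1, r$n, 100 * r$prop_a1))
  }
  invisible(x)
}

#' Format a percentage by the reporting convention
#'
#' `"whole-truncate"` truncates toward zero to a whole percent (so 19/23 =
#' 82.6\% prints as 82); `"one-decimal-round"` rounds half away from zero to
#' one decimal (so 91/271 = 33.579\% prints as 33.6). Integer counts are
#' handled in exact integer arithmetic.
#'
#' @param numerator,denominator Counts; the denominator must be positive.
#' @param mode Reporting convention.
#' @return Numeric percentage on the printed scale.
#' @export
report_percent <- function(numerator, denominator,
                           mode = c("whole-truncate", "one-decimal-round")) {
  mode <- match.arg(mode)
  if (denominator <= 0) stop_invalid("denominator must be positive")
  if (mode == "whole-truncate") {
    if (numerator == round(numerator) && denominator == round(denominator))
      (100 * numerator) %/% denominator * sign(denominator)
    else trunc(100 * numerator / denominator)
  } else {
    x <- 1000 * numerator / denominator
    sign(x) * floor(abs(x) + 0.5) / 10
  }
}

#' Visual preference index from a dual-stream decoding result
#'
#' The VPI is the percentage of `A12V1` trials labeled `A1` minus the
#' percentage of `A12V2` trials labeled `A1`. A unit fully driven by the
#' visual stream scores 100; one ignoring it scores about 0. Percentages are
#' formatted by [report_percent()] before subtraction (default:
#' whole-percent truncation, the printed convention).
#'
#' @param dual_result An `avb_dual_result` containing both `A12V1` and
#'   `A12V2`, or a list like `list(A12V1 = c(19, 23), A12V2 = c(6, 23))` of
#'   (labeled-A1, total) counts.
#' @param percent_mode Passed to [report_percent()].
#' @return Object of class `avb_vpi` with `pct_a1_given_v1`,
#'   `pct_a1_given_v2` and `vpi`.
#' @export
compute_vpi <- function(dual_result,
                        percent_mode = c("whole-truncate",
                                         "one-decimal-round")) {
  percent_mode <- match.arg(percent_mode)
  counts <- if (inherits(dual_result, "avb_dual_result")) {
    bc <- dual_result$by_condition
    if (!all(c("A12V1", "A12V2") %in% names(bc)))
      stop_invalid("both dual-stream visual conditions are required")
    list(A12V1 = c(bc$A12V1$n_a1, bc$A12V1$n),
         A12V2 = c(bc$A12V2$n_a1, bc$A12V2$n))
  } else dual_result
  p1 <- report_percent(counts$A12V1[1], counts$A12V1[2], percent_mode)
  p2 <- report_percent(counts$A12V2[1], counts$A12V2[2], percent_mode)
  structure(list(pct_a1_given_v1 = p1, pct_a1_given_v2 = p2,
                 vpi = p1 - p2, percent_mode = percent_mode),
            class = "avb_vpi")
}

#' @export
print.avb_vpi <- function(x, ...) {
  cat(sprintf("VPI = %s (A1|V1: %s%%, A1|V2: %s%%)\n",
              format(x$vpi), format(x$pct_a1_given_v1),
              format(x$pct_a1_given_v2)))
  invisible(x)
}

#' Permutation test for the visual preference index
#'
#' The identities of the single-stream trials used to build the decoding
#' templates are shuffled and the VPI recomputed for each iteration; the
#' p value is the fraction of null |VPI| at least as large as the observed
#' |VPI| (two-sided exceedance). Raw (untruncated) percentages are used
#' inside the test so the null is not discretized by the printing
#' convention.
#'
#' @inheritParams decode_dual_stream
#' @param n_iter Number of shuffles (default 1000).
#' @param alpha Significance level.
#' @param seed Integer seed.
#' @return Object of class `avb_vpi_test` with `observed_vpi`, `p`,
#'   `significant`.
#' @export
vpi_permutation <- function(unit, template_source = c("coherent-av",
                                                      "auditory-only"),
                            window = c(0, 3), bin_width = 0.02,
                            n_iter = 1000, alpha = 0.05, seed = 1) {
  template_source <- match.arg(template_source)
  tmpl_conds <- if (template_source == "coherent-av") c("A1V1", "A2V2")
                else c("A1", "A2")
  if (!all(c(tmpl_conds, "A12V1", "A12V2") %in% names(unit$trials)))
    stop_invalid("required conditions missing")
  T1 <- bin_spikes(unit$trials[[tmpl_conds[1]]], window, bin_width)
  T2 <- bin_spikes(unit$trials[[tmpl_conds[2]]], window, bin_width)
  X1 <- bin_spikes(unit$trials$A12V1, window, bin_width)
  X2 <- bin_spikes(unit$trials$A12V2, window, bin_width)
  vpi_from <- function(m1, m2) {
    d1 <- colSums((t(X1) - m1)^2) - colSums((t(X1) - m2)^2)
    d2 <- colSums((t(X2) - m1)^2) - colSums((t(X2) - m2)^2)
    # exact distance ties count half to each label
    100 * ((mean(d1 < 0) + 0.5 * mean(d1 == 0)) -
           (mean(d2 < 0) + 0.5 * mean(d2 == 0)))
  }
  pool <- rbind(T1, T2)
  n1 <- nrow(T1)
  res <- with_seed(seed, {
    obs <- vpi_from(colMeans(T1), colMeans(T2))
    null <- vapply(seq_len(n_iter), function(i) {
      idx <- sample.int(nrow(pool))
      vpi_from(colMeans(pool[idx[seq_len(n1)], , drop = FALSE]),
               colMeans(pool[idx[-seq_len(n1)], , drop = FALSE]))
    }, numeric(1))
    # VPI values are discrete; break exceedance ties at random so the test
    # stays calibrated (see permutation_null)
    list(obs = obs, null = null,
         p = mean(abs(null) + stats::runif(n_iter, 0, 1e-6) >=
                    abs(obs) + stats::runif(1, 0, 1e-6)))
  })
  structure(list(observed_vpi = res$obs,
                 p = res$p,
                 significant = res$p < alpha,
                 n_iter = n_iter),
            class = "avb_vpi_test")
}

#' @export
print.avb_vpi_test <- function(x, ...) {
  cat(sprintf("VPI permutation test: observed %.1f, p = %.3f (%s)\n",
              x$observed_vpi, x$p,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Coherent versus independent single-stream decoding
#'
#' Scores, with the leave-one-out classifier, the discrimination of the two
#' temporally coherent stimuli (`A1V1` vs `A2V2`) and of the two temporally
#' independent stimuli (`A1V2` vs `A2V1`), and exposes per-condition mean
#' and maximum evoked rates for the rate-control analysis.
#'
#' @inheritParams classify_unit_discrimination
#' @param seed Tie-break seed.
#' @return List of class `avb_coherence_contrast` with `coherent_score`,
#'   `independent_score` and a `rates` data frame (condition, mean_rate,
#'   max_rate in spikes/s).
#' @export
coherence_decoding_contrast <- function(unit, window = c(0, 3),
                                        bin_width = 0.02, seed = NULL) {
  need <- c("A1V1", "A2V2", "A1V2", "A2V1")
  if (!all(need %in% names(unit$trials)))
    stop_invalid("unit must have all four single-stream conditions")
  P <- lapply(unit$trials[need], bin_spikes, window = window,
              bin_width = bin_width)
  coh <- euclidean_loocv(P[c("A1V1", "A2V2")], seed = seed)
  ind <- euclidean_loocv(P[c("A1V2", "A2V1")],
                         seed = if (is.null(seed)) NULL else seed + 1L)
  dur <- window[2] - window[1]
  rates <- do.call(rbind, lapply(need, function(cond) {
    m <- P[[cond]]
    data.frame(condition = cond,
               mean_rate = mean(rowSums(m)) / dur,
               max_rate = max(colMeans(m)) / bin_width)
  }))
  structure(list(coherent_score = coh$percent_correct,
                 independent_score = ind$percent_correct,
                 rates = rates),
            class = "avb_coherence_contrast")
}

#' Classify a unit from responses to simple noise/flash stimuli
#'
#' Two-way ANOVA (factors: auditory stimulus on/off, visual stimulus on/off)
#' on spike counts. A unit is `"auditory"` with a main effect of sound only,
#' `"visual"` with a main effect of light only, `"auditory-visual"` with
#' both main effects or a significant interaction, and `"none"` otherwise
#' (all at `p < alpha`).
#'
#' @param counts Numeric spike counts, one per presentation.
#' @param auditory,visual Logical (or 2-level factor) stimulus-on indicators,
#'   same length as `counts`; every cell needs at least 2 replicates.
#' @param alpha Significance level (default 0.05).
#' @return List of class `avb_simple_class` with the label and the ANOVA
#'   F and p values.
#' @export
classify_simple_unit <- function(counts, auditory, visual, alpha = 0.05) {
  auditory <- factor(auditory)
  visual <- factor(visual)
  if (nlevels(auditory) != 2L || nlevels(visual) != 2L)
    stop_invalid("auditory and visual must each have two levels")
  if (min(table(auditory, visual)) < 2L)
    stop_invalid("each factor cell needs at least 2 replicates")
  fit <- stats::aov(counts ~ auditory * visual)
  tab <- summary(fit)[[1]]
  p <- tab[["Pr(>F)"]][1:3]
  f <- tab[["F value"]][1:3]
  names(p) <- names(f) <- c("auditory", "visual", "interaction")
  sig <- p < alpha
  label <- if (sig[3] || (sig[1] && sig[2])) "auditory-visual"
           else if (sig[1]) "auditory"
           else if (sig[2]) "visual"
           else "none"
  structure(list(label = label, F = f, p = p, alpha = alpha),
            class = "avb_simple_class")
}

#' @export
print.avb_simple_class <- function(x, ...) {
  cat("Simple-stimulus classification:", x$label, "\n")
  print(round(rbind(F = x$F, p = x$p), 4))
  invisible(x)
}
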