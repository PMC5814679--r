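#' Extract matched deviant and control response epochs
#'
#' Bins the 200-ms response epoch covering a timbre deviant (10-ms bins, 20
#' bins) from trials of the deviant-bearing stimulus, and the identical time
#' window from trials of the otherwise-identical no-deviant stimulus. When
#' trial counts differ, the larger set is subsampled at random (seeded) to
#' match.
#'
#' @param deviant_trials,control_trials Lists of spike-time vectors.
#' @param onset Epoch onset in seconds.
#' @param duration Epoch length in seconds (default 0.2).
#' @param bin_width Bin width in seconds (default 0.010).
#' @param trial_duration Full trial length, used to validate the marker.
#' @param seed Subsampling seed.
#' @return Object of class `avb_epochs`: `deviant` and `control` count
#'   matrices (trials x 20 bins) plus the epoch metadata.
#' @export
extract_epochs <- function(deviant_trials, control_trials, onset,
                           duration = 0.2, bin_width = 0.01,
                           trial_duration = 3, seed = 1) {
  if (onset < 0 || onset + duration > trial_duration + 1e-9)
    stop_invalid("epoch lies outside the trial window")
  window <- c(onset, onset + duration)
  dev <- bin_spikes(deviant_trials, window, bin_width)
  ctl <- bin_spikes(control_trials, window, bin_width)
  n <- min(nrow(dev), nrow(ctl))
  if (n < 2L) stop_invalid("need at least 2 trials per condition")
  with_seed(seed, {
    if (nrow(dev) > n) dev <- dev[sample.int(nrow(dev), n), , drop = FALSE]
    if (nrow(ctl) > n) ctl <- ctl[sample.int(nrow(ctl), n), , drop = FALSE]
  })
  structure(list(deviant = dev, control = ctl, onset = onset,
                 duration = duration, bin_width = bin_width),
            class = "avb_epochs")
}

#' Discriminate deviant from no-deviant epochs
#'
#' Applies the leave-one-out Euclidean template classifier to the epoch
#' pair; the discrimination score is the percentage of trials correctly
#' classified and significance is assessed with the 1000-iteration
#' permutation test (95th-percentile criterion).
#'
#' @param epochs An [extract_epochs()] result.
#' @param n_iter,alpha,seed Permutation-test parameters.
#' @return List of class `avb_deviant_test` with `score`, `p`,
#'   `significant`.
#' @export
deviant_discrimination <- function(epochs, n_iter = 1000, alpha = 0.05,
                                   seed = 1) {
  stopifnot(inherits(epochs, "avb_epochs"))
  groups <- list(deviant = epochs$deviant, control = epochs$control)
  perm <- permutation_null(groups, n_iter = n_iter, alpha = alpha,
                           seed = seed)
  structure(list(score = perm$observed, p = perm$p,
                 significant = perm$significant, n_iter = n_iter),
            class = "avb_deviant_test")
}

#' @export
print.avb_deviant_test <- function(x, ...) {
  cat(sprintf("Deviant discrimination: %.1f%% correct, p = %.3f (%s)\n",
              x$score, x$p,
              if (x$significant) "detected" else "not detected"))
  invisible(x)
}

# Coherent/independent grouping of a (deviant stream, visual stream) pair.
deviant_grouping <- function(stream, visual_stream) {
  if (is.na(visual_stream)) return("no-visual")
  if (stream == visual_stream) "coherent" else "independent"
}

#' Summarize timbre-deviant detection for one unit
#'
#' For each deviant marker (up to four: two per auditory stream) and each
#' requested condition, discriminates deviant from no-deviant epochs using
#' the `<condition>+dev` / `<condition>` pair of recordings, then reports
#' per-condition detection counts (`n_detected`, maximum 4) and the mean
#' score over detected deviants, plus coherent/independent grouping (a
#' deviant is `coherent` when its stream matches the visual stream of the
#' condition).
#'
#' @param unit An `avb_unit` whose `trials` contain both `<cond>` and
#'   `<cond>+dev` entries.
#' @param markers List of [deviant_marker()] objects (both streams).
#' @param conditions Conditions to analyse (default: the dual-stream pair).
#' @param n_iter,alpha,seed Permutation-test parameters.
#' @return Object of class `avb_deviant_summary`: `table` (one row per
#'   deviant x condition), `by_condition` (n_detected, mean score over
#'   detected) and `by_grouping` (mean scores for coherent vs independent).
#' @export
summarize_unit_deviants <- function(unit, markers,
                                    conditions = c("A12V1", "A12V2"),
                                    n_iter = 1000, alpha = 0.05, seed = 1) {
  rows <- list()
  k <- 0L
  for (cond in conditions) {
    dev_cond <- paste0(cond, "+dev")
    if (!all(c(cond, dev_cond) %in% names(unit$trials)))
      stop_invalid("unit lacks condition pair ", cond, " / ", dev_cond)
    vis <- if (grepl("V1$", cond)) "A1" else if (grepl("V2$", cond)) "A2"
           else NA_character_
    cond_streams <- if (grepl("^A12", cond)) c("A1", "A2")
                    else substr(cond, 1, 2)
    for (m in markers) {
      if (!(m$stream %in% cond_streams)) next
      k <- k + 1L
      ep <- extract_epochs(unit$trials[[dev_cond]], unit$trials[[cond]],
                           m$onset, trial_duration = unit$duration,
                           seed = seed + k)
      dd <- deviant_discrimination(ep, n_iter = n_iter, alpha = alpha,
                                   seed = seed + 1000L + k)
      rows[[k]] <- data.frame(
        condition = cond, stream = m$stream, onset = m$onset,
        grouping = deviant_grouping(m$stream, vis),
        score = dd$score, p = dd$p, significant = dd$significant)
    }
  }
  tab <- do.call(rbind, rows)
  by_condition <- do.call(rbind, lapply(split(tab, tab$condition), function(d)
    data.frame(condition = d$condition[1],
               n_detected = sum(d$significant),
               mean_score = if (any(d$significant))
                 mean(d$score[d$significant]) else NA_real_)))
  by_grouping <- do.call(rbind, lapply(split(tab, tab$grouping), function(d)
    data.frame(grouping = d$grouping[1],
               n_detected = sum(d$significant),
               mean_score = if (any(d$significant))
                 mean(d$score[d$significant]) else NA_real_)))
  structure(list(table = tab, by_condition = by_condition,
                 by_grouping = by_grouping),
            class = "avb_deviant_summary")
}

#' @export
print.avb_deviant_summary <- function(x, ...) {
  cat("Timbre-deviant summary\n")
  print(x$by_grouping, row.names = FALSE)
  invisible(x)
}
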