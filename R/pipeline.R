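#' Pearson chi-square test on a contingency table
#'
#' Standard Pearson statistic `sum((O - E)^2 / E)` with
#' `(r - 1)(c - 1)` degrees of freedom (no continuity correction), as used
#' to compare deviant-detection proportions between visual conditions.
#'
#' @param counts A 2x2 or larger matrix of counts; every expected count must
#'   be positive.
#' @return List with `statistic`, `df`, `p`, `expected`.
#' @export
proportion_chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (any(dim(counts) < 2L)) stop_invalid("table must be at least 2x2")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected <= 0)) stop_invalid("all expected counts must be positive")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, expected = expected)
}

#' Default timbre-deviant markers
#'
#' Two 200-ms deviants per stream at fixed onsets inside the 3-s analysis
#' window (the original onsets are free parameters of the stimulus).
#'
#' @param vowels Vowel set providing the morph targets.
#' @return Named list with elements `A1` and `A2`, each a list of two
#'   [deviant_marker()]s.
#' @export
default_deviants <- function(vowels = default_vowels()) {
  list(
    A1 = list(deviant_marker(0.8, "A1", vowels$A1_deviant),
              deviant_marker(1.9, "A1", vowels$A1_deviant)),
    A2 = list(deviant_marker(1.3, "A2", vowels$A2_deviant),
              deviant_marker(2.4, "A2", vowels$A2_deviant))
  )
}

#' Full phase-dissimilarity analysis of one LFP site
#'
#' Runs the Morlet decomposition on every available condition and assembles
#' within- and across-stimulus ITPC profiles, single-stream PDI (coherent
#' and independent groupings), dual-stream PDI, and the power dissimilarity
#' analysis.
#'
#' @param lfp An `avb_lfp` site.
#' @param grid A [frequency_grid()].
#' @param n_shuffles,seed Across-stimulus shuffle parameters.
#' @param decimate Time decimation passed to [morlet_tfr()].
#' @return List of class `avb_site_analysis` with elements `single`,
#'   `dual`, `power` (each `avb_pdi` or `NULL`) and `profiles`, a named
#'   list of per-frequency within/across profiles used for population
#'   significance testing.
#' @export
analyze_lfp_site <- function(lfp, grid = frequency_grid(), n_shuffles = 100,
                             seed = 1, decimate = 4) {
  stopifnot(inherits(lfp, "avb_lfp"))
  single_conds <- intersect(c("A1V1", "A1V2", "A2V1", "A2V2"),
                            names(lfp$traces))
  dual_conds <- intersect(c("A12V1", "A12V2"), names(lfp$traces))
  tfrs <- lapply(lfp$traces[c(single_conds, dual_conds)], morlet_tfr,
                 sample_rate = lfp$sample_rate, grid = grid,
                 decimate = decimate)
  out <- list(single = NULL, dual = NULL, power = NULL, profiles = list())
  if (length(single_conds) == 4L) {
    within <- lapply(tfrs[single_conds], itpc)
    across <- list(
      A1 = across_stimulus_itpc(tfrs$A1V1, tfrs$A1V2, n_shuffles, seed),
      A2 = across_stimulus_itpc(tfrs$A2V1, tfrs$A2V2, n_shuffles, seed + 1L))
    out$single <- single_stream_pdi(within, across)
    out$profiles$within_coherent <-
      rowMeans(cbind(within$A1V1$profile, within$A2V2$profile))
    out$profiles$within_independent <-
      rowMeans(cbind(within$A1V2$profile, within$A2V1$profile))
    out$profiles$across_single <-
      rowMeans(cbind(across$A1$profile, across$A2$profile))
    pw1 <- power_dissimilarity(tfrs$A1V1, tfrs$A1V2, n_shuffles, seed + 2L)
    pw2 <- power_dissimilarity(tfrs$A2V1, tfrs$A2V2, n_shuffles, seed + 3L)
    out$power <- structure(
      list(frequencies = pw1$frequencies,
           pdi = rowMeans(cbind(pw1$pdi, pw2$pdi)),
           within = rowMeans(cbind(pw1$within, pw2$within)),
           across = rowMeans(cbind(pw1$across, pw2$across)),
           kind = "power"),
      class = "avb_pdi")
    out$profiles$power_within <- out$power$within
    out$profiles$power_across <- out$power$across
  }
  if (length(dual_conds) == 2L) {
    out$dual <- dual_stream_pdi(tfrs$A12V1, tfrs$A12V2, n_shuffles,
                                seed + 4L)
    w1 <- itpc(tfrs$A12V1); w2 <- itpc(tfrs$A12V2)
    acr <- across_stimulus_itpc(tfrs$A12V1, tfrs$A12V2, n_shuffles,
                                seed + 5L)
    out$profiles$within_dual <- rowMeans(cbind(w1$profile, w2$profile))
    out$profiles$across_dual <- acr$profile
  }
  out$frequencies <- grid$frequencies
  class(out) <- "avb_site_analysis"
  out
}

#' Population significance of a dissimilarity component
#'
#' Assembles the per-site within/across profiles for one analysis component
#' and applies [pdi_significance()] across sites.
#'
#' @param site_analyses List of [analyze_lfp_site()] results.
#' @param component `"single-coherent"`, `"single-independent"`, `"dual"`
#'   or `"power"`.
#' @param ... Passed to [pdi_significance()].
#' @return An `avb_pdi_significance`.
#' @export
population_pdi <- function(site_analyses,
                           component = c("single-coherent",
                                         "single-independent",
                                         "dual", "power"), ...) {
  component <- match.arg(component)
  keys <- switch(component,
    "single-coherent" = c("within_coherent", "across_single"),
    "single-independent" = c("within_independent", "across_single"),
    "dual" = c("within_dual", "across_dual"),
    "power" = c("power_within", "power_across"))
  within <- do.call(rbind, lapply(site_analyses, function(s)
    s$profiles[[keys[1]]]))
  across <- do.call(rbind, lapply(site_analyses, function(s)
    s$profiles[[keys[2]]]))
  if (is.null(within)) stop_invalid("component not present in site analyses")
  pdi_significance(within, across, ...)
}

#' Build a pipeline run configuration
#'
#' A run is fully reproducible from its configuration; all child seeds
#' derive from `seed`.
#'
#' @param n_units,n_sites,proportions,n_trials,kappa,deviant_gain Passed to
#'   [generate_population()].
#' @param seed Master seed.
#' @param with_deviants Embed the [default_deviants()] and run the deviant
#'   analysis.
#' @param conditions Stimulus conditions to simulate.
#' @param bin_width,n_perm,alpha Decoding parameters.
#' @param grid,n_shuffles,decimate LFP analysis parameters.
#' @param output_dir Optional directory for CSV/JSON outputs.
#' @return List of class `avb_run_config`.
#' @export
run_config <- function(n_units = 30, n_sites = 4,
                       proportions = c(auditory = 0.4, visual = 0.1,
                                       none = 0.5),
                       n_trials = 20, seed = 1, kappa = 1,
                       deviant_gain = 0.8, with_deviants = TRUE,
                       conditions = c("A1V1", "A1V2", "A2V1", "A2V2",
                                      "A12V1", "A12V2"),
                       bin_width = 0.02, n_perm = 1000, alpha = 0.05,
                       grid = frequency_grid(), n_shuffles = 100,
                       decimate = 4, output_dir = NULL) {
  structure(as.list(environment()), class = "avb_run_config")
}

#' Run the full analysis pipeline
#'
#' Synthesizes stimuli, simulates a unit and LFP population, and runs every
#' analysis stage: unit classification, dual-stream decoding with VPI and
#' its permutation test, coherent-versus-independent decoding, timbre
#' deviant discrimination, and the LFP phase/power dissimilarity analyses.
#'
#' @param config An [run_config()] object.
#' @return Object of class `avb_report`: `units` (per-unit table),
#'   `deviants` (per-unit deviant summary table or `NULL`), `pdi`
#'   (per-component population significance), `summary` (population counts
#'   with formatted percentages), `config`.
#' @export
run_full_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "avb_run_config"))
  pop <- generate_population(
    n_units = config$n_units, proportions = config$proportions,
    n_sites = config$n_sites, conditions = config$conditions,
    n_trials = config$n_trials, seed = config$seed, kappa = config$kappa,
    deviant_gain = if (config$with_deviants) config$deviant_gain else 0,
    deviants = if (config$with_deviants) default_deviants() else NULL)

  seeds <- derive_seeds(config$seed, config$n_units, salt = 404L)
  unit_rows <- vector("list", config$n_units)
  deviant_rows <- list()
  markers <- if (config$with_deviants) unlist(default_deviants(),
                                              recursive = FALSE)
  for (i in seq_along(pop$units)) {
    u <- pop$units[[i]]
    cls <- classify_unit_discrimination(u, n_iter = config$n_perm,
                                        alpha = config$alpha,
                                        bin_width = config$bin_width,
                                        seed = seeds[i])
    dual <- decode_dual_stream(u, bin_width = config$bin_width,
                               seed = seeds[i])
    vpi <- compute_vpi(dual)
    vt <- vpi_permutation(u, n_iter = config$n_perm, alpha = config$alpha,
                          bin_width = config$bin_width, seed = seeds[i])
    cc <- coherence_decoding_contrast(u, bin_width = config$bin_width,
                                      seed = seeds[i])
    unit_rows[[i]] <- data.frame(
      unit_id = u$unit_id, class_true = u$class_true, class = cls$label,
      auditory_score = cls$auditory_score, visual_score = cls$visual_score,
      prop_a1_v1 = dual$by_condition$A12V1$prop_a1,
      prop_a1_v2 = dual$by_condition$A12V2$prop_a1,
      vpi = vpi$vpi, vpi_p = vt$p, vpi_significant = vt$significant,
      coherent_score = cc$coherent_score,
      independent_score = cc$independent_score)
    if (config$with_deviants && u$class_true == "auditory") {
      ds <- summarize_unit_deviants(u, markers, n_iter = config$n_perm,
                                    alpha = config$alpha, seed = seeds[i])
      d <- ds$table
      d$unit_id <- u$unit_id
      deviant_rows[[length(deviant_rows) + 1L]] <- d
    }
  }
  units_tab <- do.call(rbind, unit_rows)
  deviants_tab <- if (length(deviant_rows)) do.call(rbind, deviant_rows)

  site_analyses <- lapply(seq_along(pop$lfp_sites), function(j)
    analyze_lfp_site(pop$lfp_sites[[j]], grid = config$grid,
                     n_shuffles = config$n_shuffles,
                     seed = config$seed + 7000L + j,
                     decimate = config$decimate))
  pdi <- NULL
  if (length(site_analyses) >= 3L) {
    pdi <- list(
      single_coherent = population_pdi(site_analyses, "single-coherent"),
      single_independent = population_pdi(site_analyses,
                                          "single-independent"),
      dual = population_pdi(site_analyses, "dual"),
      power = population_pdi(site_analyses, "power"))
  }

  n <- nrow(units_tab)
  n_sig_vpi <- sum(units_tab$vpi_significant)
  summary <- list(
    n_units = n,
    n_auditory = sum(units_tab$class == "auditory-discriminating"),
    n_visual = sum(units_tab$class == "visual-discriminating"),
    n_vpi_significant = n_sig_vpi,
    pct_auditory = report_percent(
      sum(units_tab$class == "auditory-discriminating"), n,
      "one-decimal-round"),
    pct_vpi_significant = report_percent(n_sig_vpi, n, "one-decimal-round"),
    mean_coherent_score = mean(units_tab$coherent_score),
    mean_independent_score = mean(units_tab$independent_score))
  if (!is.null(deviants_tab)) {
    det <- table(factor(deviants_tab$grouping,
                        levels = c("coherent", "independent")),
                 factor(deviants_tab$significant, levels = c(TRUE, FALSE)))
    if (all(rowSums(det) > 0) && all(colSums(det) > 0))
      summary$deviant_chi_square <- proportion_chi_square(det)
  }

  report <- structure(
    list(units = units_tab, deviants = deviants_tab, pdi = pdi,
         site_analyses = site_analyses, summary = summary, config = config),
    class = "avb_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' @export
print.avb_report <- function(x, ...) {
  s <- x$summary
  cat("Pipeline report:", s$n_units, "units\n")
  cat(sprintf("  auditory-discriminating: %d (%.1f%%)\n",
              s$n_auditory, s$pct_auditory))
  cat(sprintf("  significant VPI: %d (%.1f%%)\n",
              s$n_vpi_significant, s$pct_vpi_significant))
  cat(sprintf("  decoding: coherent %.1f%% vs independent %.1f%%\n",
              s$mean_coherent_score, s$mean_independent_score))
  if (!is.null(x$pdi))
    cat(sprintf("  dual-stream PDI magnitude: %.3f (%d significant freqs)\n",
                x$pdi$dual$magnitude, sum(x$pdi$dual$mask)))
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Per-unit and per-deviant tables as CSV, PDI profiles as CSV, and the
#' population summary plus configuration as JSON.
#'
#' @param report An `avb_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$units, file.path(dir, "units.csv"),
                   row.names = FALSE)
  if (!is.null(report$deviants))
    utils::write.csv(report$deviants, file.path(dir, "deviants.csv"),
                     row.names = FALSE)
  if (!is.null(report$pdi)) {
    freqs <- report$config$grid$frequencies
    for (comp in names(report$pdi)) {
      p <- report$pdi[[comp]]
      utils::write.csv(
        data.frame(frequency = freqs, pdi = p$pdi_mean, p = p$p,
                   significant = p$mask),
        file.path(dir, paste0("pdi_", comp, ".csv")), row.names = FALSE)
    }
  }
  summ <- report$summary
  summ$deviant_chi_square <- summ$deviant_chi_square[c("statistic", "df", "p")]
  cfg <- report$config
  cfg$grid <- unclass(cfg$grid)
  jsonlite::write_json(list(summary = summ, config = unclass(cfg)),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
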