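#' Write a synthetic population dataset as plain text
#'
#' Spike times are written to `units.json` (full double precision), LFP
#' traces to one CSV per site and condition under `lfp/`, and the manifest
#' (seeds, ground-truth classes, conditions) to `manifest.json`.
#'
#' @param population An `avb_population`.
#' @param dir Output directory (created if needed).
#' @param include_lfp Write the LFP traces (default TRUE).
#' @return Invisibly, `dir`.
#' @export
write_dataset <- function(population, dir, include_lfp = TRUE) {
  stopifnot(inherits(population, "avb_population"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # spike times serialize as %.17g strings: shortest text form that
  # round-trips IEEE doubles exactly (plain JSON numbers lose the last bit)
  units <- lapply(population$units, function(u)
    list(unit_id = u$unit_id, state = u$state, area = u$area,
         class_true = u$class_true, n_trials = u$n_trials,
         duration = u$duration,
         trials = lapply(u$trials, function(cond)
           lapply(cond, function(tr) sprintf("%.17g", tr)))))
  names(units) <- vapply(population$units, `[[`, character(1), "unit_id")
  jsonlite::write_json(units, file.path(dir, "units.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(population$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (include_lfp && length(population$lfp_sites)) {
    lfp_dir <- file.path(dir, "lfp")
    dir.create(lfp_dir, showWarnings = FALSE)
    for (site in population$lfp_sites)
      for (cond in names(site$traces))
        utils::write.csv(site$traces[[cond]],
                         file.path(lfp_dir, paste0(site$site_id, "_",
                                                   cond, ".csv")),
                         row.names = FALSE)
  }
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @return List with `units` (each with a `trials` list of spike-time
#'   vectors), `manifest`, and `lfp_sites` (matrices per site/condition) if
#'   present.
#' @export
read_dataset <- function(dir) {
  units_raw <- jsonlite::read_json(file.path(dir, "units.json"))
  units <- lapply(units_raw, function(u) {
    u$trials <- lapply(u$trials, function(cond)
      lapply(cond, function(tr)
        if (length(tr) == 0L) numeric(0) else as.numeric(unlist(tr)))
    )
    u
  })
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  lfp_dir <- file.path(dir, "lfp")
  lfp_sites <- list()
  if (dir.exists(lfp_dir)) {
    for (f in list.files(lfp_dir, pattern = "\\.csv$")) {
      key <- sub("\\.csv$", "", f)
      lfp_sites[[key]] <- as.matrix(utils::read.csv(file.path(lfp_dir, f)))
    }
  }
  list(units = units, manifest = manifest, lfp_sites = lfp_sites)
}

#' Export a stimulus set as plain-text files
#'
#' The audio waveform and every envelope are written as `(time, value)` CSV
#' files, and a JSON manifest records the condition, sample rates, level
#' and deviant markers.
#'
#' @param stim An `avb_stimulus_set`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_stimulus_set <- function(stim, dir) {
  stopifnot(inherits(stim, "avb_stimulus_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tt <- (seq_along(stim$audio) - 1) / stim$audio_rate
  utils::write.csv(data.frame(time = tt, value = stim$audio),
                   file.path(dir, "audio.csv"), row.names = FALSE)
  for (s in names(stim$envelopes)) {
    e <- stim$envelopes[[s]]
    utils::write.csv(
      data.frame(time = (seq_along(e$samples) - 1) / e$sample_rate,
                 value = e$samples),
      file.path(dir, paste0("envelope_", s, ".csv")), row.names = FALSE)
  }
  if (!is.null(stim$luminance)) {
    e <- stim$luminance
    utils::write.csv(
      data.frame(time = (seq_along(e$samples) - 1) / e$sample_rate,
                 value = e$samples),
      file.path(dir, "luminance.csv"), row.names = FALSE)
  }
  markers <- lapply(unname(unlist(stim$deviants, recursive = FALSE)), function(m)
    list(onset = m$onset, duration = m$duration, stream = m$stream,
         morph_label = m$morph_target$label))
  jsonlite::write_json(
    list(condition = stim$condition, audio_rate = stim$audio_rate,
         duration = stim$duration, level_spl = stim$level_spl,
         visual_stream = stim$visual_stream,
         envelope_seeds = lapply(stim$envelopes, `[[`, "seed"),
         deviants = markers),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
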