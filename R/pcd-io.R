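#' Write / read a PCD pulse-train container
#'
#' The on-disk container is a plain CSV holding the sample matrix (one column
#' per pulse, one row per sample, in volts) plus a JSON metadata sidecar
#' (`<path>.json`) with `sample_rate`, `f` and per-pulse timestamps.
#'
#' @param pulses List of [pulse_record] objects on a common acquisition
#'   (equal length, sample rate and excitation frequency).
#' @param path CSV file path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_pulses_csv <- function(pulses, path) {
  stopifnot(length(pulses) >= 1L,
            all(vapply(pulses, inherits, logical(1), "pulse_record")))
  ns <- vapply(pulses, function(p) length(p$samples), integer(1))
  sr <- vapply(pulses, function(p) p$sample_rate, numeric(1))
  ff <- vapply(pulses, function(p) p$f, numeric(1))
  if (length(unique(ns)) != 1L || length(unique(sr)) != 1L ||
      length(unique(ff)) != 1L)
    stop("invalid-input: pulses must share length, sample_rate and f")
  mat <- vapply(pulses, function(p) p$samples, numeric(ns[1]))
  colnames(mat) <- sprintf("pulse_%03d",
                           vapply(pulses, function(p) p$pulse_index, integer(1)))
  utils::write.csv(mat, path, row.names = FALSE)
  meta <- list(sample_rate = sr[1], f = ff[1],
               pulse_index = vapply(pulses, function(p) p$pulse_index, integer(1)),
               timestamp = vapply(pulses, function(p) p$timestamp, numeric(1)))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pulses_csv
#' @return For `read_pulses_csv()`, a list of [pulse_record] objects.
#' @export
read_pulses_csv <- function(path) {
  mat <- as.matrix(utils::read.csv(path, check.names = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  lapply(seq_len(ncol(mat)), function(i)
    pulse_record(mat[, i], sample_rate = meta$sample_rate, f = meta$f,
                 pulse_index = meta$pulse_index[i],
                 timestamp = meta$timestamp[i]))
}

#' Write per-pulse levels and summed doses for a sonication
#'
#' Writes the per-pulse cavitation-level table as CSV and the summed doses as
#' a JSON summary.
#'
#' @param levels Data frame from [cavitation_level_table()].
#' @param dose A [cavitation_dose].
#' @param csv_path,json_path Output paths.
#' @return `json_path`, invisibly.
#' @export
write_dose_report <- function(levels, dose, csv_path, json_path) {
  utils::write.csv(levels, csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(SCDh = dose$SCDh, SCDu = dose$SCDu, ICD = dose$ICD,
         total = dose$total, n_pulses = dose$n_pulses,
         baseline_subtracted = dose$baseline_subtracted),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(json_path)
}
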