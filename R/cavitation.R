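#' Per-pulse cavitation levels
#'
#' Splits the amplitude spectrum of one PCD pulse into the three cavitation
#' signatures and returns the RMS level (volts) of each:
#'
#' * `dSCDh` -- stable cavitation with harmonics: per harmonic order n, the
#'   maximum spectral amplitude within the peak-search band around n*f; the
#'   level is the time-domain RMS of a signal containing those peak
#'   sinusoids, `sqrt(sum(peak^2) / 2)`.
#' * `dSCDu` -- stable cavitation with ultraharmonics: likewise for m/2*f.
#' * `dICD` -- inertial cavitation (broadband): RMS of the analysis-band
#'   spectrum after zeroing the suppression notches around every harmonic and
#'   ultraharmonic, computed via Parseval as `sqrt(sum(amp^2) / 2)` over the
#'   surviving bins.
#'
#' All three are computed from the same one-sided spectrum, so scaling the
#' waveform by c scales every level by exactly c.
#'
#' @param pulse A [pulse_record].
#' @param scheme A [band_scheme].
#'
#' @return An object of class `cavitation_levels`: a list with `dSCDh`,
#'   `dSCDu`, `dICD` (volts RMS) and `pulse_index`.
#' @export
cavitation_levels <- function(pulse, scheme = band_scheme()) {
  spec <- pulse_spectrum(pulse, scheme)
  freq <- spec$freq
  amp <- spec$amplitude

  hw <- scheme$peak_search_width / 2
  band_peak <- function(f0) {
    sel <- abs(freq - f0) <= hw
    if (!any(sel)) 0 else max(amp[sel])
  }
  fh <- scheme_harmonic_freqs(scheme, pulse$f)
  fu <- scheme_ultraharmonic_freqs(scheme, pulse$f)
  peaks_h <- vapply(fh, band_peak, numeric(1))
  peaks_u <- vapply(fu, band_peak, numeric(1))

  notched <- rep(FALSE, length(freq))
  for (f0 in fh) notched <- notched | abs(freq - f0) <= scheme$harmonic_suppress_width / 2
  for (f0 in fu) notched <- notched | abs(freq - f0) <= scheme$ultraharmonic_suppress_width / 2

  structure(
    list(dSCDh = sqrt(sum(peaks_h^2) / 2),
         dSCDu = sqrt(sum(peaks_u^2) / 2),
         dICD = sqrt(sum(amp[!notched]^2) / 2),
         pulse_index = pulse$pulse_index),
    class = "cavitation_levels")
}

#' @export
print.cavitation_levels <- function(x, ...) {
  cat(sprintf("<cavitation_levels> pulse %d: dSCDh = %.4g V, dSCDu = %.4g V, dICD = %.4g V\n",
              x$pulse_index, x$dSCDh, x$dSCDu, x$dICD))
  invisible(x)
}

#' Per-pulse cavitation levels for a pulse train
#'
#' @param pulses List of [pulse_record] objects.
#' @param scheme A [band_scheme].
#' @return A data frame with one row per pulse: `pulse_index`, `dSCDh`,
#'   `dSCDu`, `dICD`.
#' @export
cavitation_level_table <- function(pulses, scheme = band_scheme()) {
  if (length(pulses) == 0L) stop("empty-input: no pulses supplied")
  rows <- lapply(pulses, function(p) {
    lv <- cavitation_levels(p, scheme)
    data.frame(pulse_index = lv$pulse_index, dSCDh = lv$dSCDh,
               dSCDu = lv$dSCDu, dICD = lv$dICD)
  })
  do.call(rbind, rows)
}

as_level_table <- function(levels) {
  if (is.data.frame(levels)) {
    stopifnot(all(c("dSCDh", "dSCDu", "dICD") %in% names(levels)))
    return(levels)
  }
  if (inherits(levels, "cavitation_levels")) levels <- list(levels)
  stopifnot(is.list(levels), length(levels) > 0L,
            all(vapply(levels, inherits, logical(1), "cavitation_levels")))
  do.call(rbind, lapply(levels, function(lv)
    data.frame(pulse_index = lv$pulse_index, dSCDh = lv$dSCDh,
               dSCDu = lv$dSCDu, dICD = lv$dICD)))
}

#' Cavitation doses over a whole sonication
#'
#' Sums per-pulse cavitation levels over the sonication: each dose (SCDh,
#' SCDu, ICD) is the sum of the corresponding per-pulse levels, and the total
#' dose is SCDh + SCDu + ICD.  If a baseline (control sonication recorded
#' before microbubble injection) is given, the mean per-pulse baseline level
#' is subtracted from each pulse's level, floored at 0, before summation.
#'
#' @param levels Per-pulse levels: a data frame from
#'   [cavitation_level_table()] or a list of [cavitation_levels] objects.
#' @param baseline Optional baseline levels in the same form (from the same
#'   band scheme).
#'
#' @return An object of class `cavitation_dose`: list with `SCDh`, `SCDu`,
#'   `ICD`, `total` (volt-pulses), `n_pulses`, `baseline_subtracted`.
#' @export
cavitation_dose <- function(levels, baseline = NULL) {
  tab <- as_level_table(levels)
  if (nrow(tab) == 0L) stop("empty-input: no cavitation levels supplied")
  cols <- c("dSCDh", "dSCDu", "dICD")
  lv <- as.matrix(tab[cols])
  if (!is.null(baseline)) {
    base_mean <- colMeans(as.matrix(as_level_table(baseline)[cols]))
    lv <- pmax(sweep(lv, 2L, base_mean, "-"), 0)
  }
  dose <- colSums(lv)
  structure(
    list(SCDh = unname(dose[1]), SCDu = unname(dose[2]), ICD = unname(dose[3]),
         total = unname(sum(dose)), n_pulses = nrow(tab),
         baseline_subtracted = !is.null(baseline)),
    class = "cavitation_dose")
}

#' @export
print.cavitation_dose <- function(x, ...) {
  cat(sprintf(
    "<cavitation_dose> %d pulses%s: SCDh = %.4g, SCDu = %.4g, ICD = %.4g, total = %.4g V*pulses\n",
    x$n_pulses, if (x$baseline_subtracted) " (baseline-subtracted)" else "",
    x$SCDh, x$SCDu, x$ICD, x$total))
  invisible(x)
}

#' Pressure-ramp calibration summary
#'
#' Aggregates per-pulse cavitation levels of a PCD calibration (consecutive
#' sonication at monotonically increasing pressures) into per-pressure mean
#' and standard deviation of each level, ordered by ascending pressure.
#'
#' @param pulse_groups Named list mapping acoustic pressure (kPa, as the list
#'   names) to a list of [pulse_record] objects recorded at that pressure.
#' @param scheme A [band_scheme].
#'
#' @return A data frame with one row per pressure step: `pressure_kPa`,
#'   `n_pulses`, and mean/sd columns for `dSCDh`, `dSCDu`, `dICD`.
#' @export
calibration_ramp <- function(pulse_groups, scheme = band_scheme()) {
  stopifnot(is.list(pulse_groups), length(pulse_groups) >= 1L)
  pressures <- as.numeric(names(pulse_groups))
  if (anyNA(pressures))
    stop("configuration error: pulse_groups must be named by numeric pressures (kPa)")
  if (any(vapply(pulse_groups, length, integer(1)) == 0L))
    stop("empty-input: a pressure step has no pulses")
  if (is.unsorted(pressures, strictly = FALSE)) {
    warning("pressure labels are not monotonically increasing; reordering")
  }
  ord <- order(pressures)
  rows <- lapply(ord, function(i) {
    tab <- cavitation_level_table(pulse_groups[[i]], scheme)
    if (nrow(tab) < 2L)
      warning(sprintf("pressure step %g kPa has a single pulse; SD reported as 0",
                      pressures[i]))
    sd0 <- function(v) if (length(v) < 2L) 0 else stats::sd(v)
    data.frame(pressure_kPa = pressures[i], n_pulses = nrow(tab),
               dSCDh_mean = mean(tab$dSCDh), dSCDh_sd = sd0(tab$dSCDh),
               dSCDu_mean = mean(tab$dSCDu), dSCDu_sd = sd0(tab$dSCDu),
               dICD_mean = mean(tab$dICD), dICD_sd = sd0(tab$dICD))
  })
  do.call(rbind, rows)
}
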