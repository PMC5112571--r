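#' PCD pulse record
#'
#' A single passive-cavitation-detection (PCD) tone-burst pulse: the sampled
#' hydrophone voltage trace plus the acquisition metadata needed to interpret
#' its spectrum.
#'
#' @param samples Numeric vector of hydrophone voltages for one pulse.
#' @param sample_rate Sampling rate in Hz. Default 50 MHz (the digitizer rate
#'   used for transcranial PCD monitoring).
#' @param f Excitation (fundamental) frequency of the therapeutic transducer
#'   in Hz. Default 0.5 MHz.
#' @param pulse_index 1-based index of the pulse within its sonication.
#' @param timestamp Pulse onset time in seconds from sonication start.
#'
#' @return An object of class `pulse_record`.
#' @export
pulse_record <- function(samples, sample_rate = 50e6, f = 0.5e6,
                         pulse_index = 1L, timestamp = 0) {
  if (!is.numeric(samples) || length(samples) < 2L)
    stop("invalid-input: `samples` must be a numeric vector of length >= 2")
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("invalid-input: `samples` contains NA/NaN/Inf values")
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop("invalid-input: `sample_rate` must be positive")
  if (!is.numeric(f) || f <= 0)
    stop("invalid-input: excitation frequency `f` must be positive")
  structure(
    list(samples = as.numeric(samples),
         sample_rate = as.numeric(sample_rate),
         f = as.numeric(f),
         pulse_index = as.integer(pulse_index),
         timestamp = as.numeric(timestamp)),
    class = "pulse_record")
}

#' @export
print.pulse_record <- function(x, ...) {
  cat(sprintf(
    "<pulse_record> #%d: %d samples @ %.3g MHz (%.2f ms), f = %.3g MHz, t = %.2f s\n",
    x$pulse_index, length(x$samples), x$sample_rate / 1e6,
    1e3 * length(x$samples) / x$sample_rate, x$f / 1e6, x$timestamp))
  invisible(x)
}

#' Spectral band scheme for cavitation-dose quantification
#'
#' Defines the analysis band and the harmonic / ultraharmonic band layout
#' used to separate stable-cavitation (harmonic n*f and ultraharmonic m/2*f)
#' emissions from broadband (inertial-cavitation) emissions.  Defaults follow
#' the transcranial monitoring scheme for a 0.5 MHz excitation: analysis band
#' 1.25-5.00 MHz, harmonics n = 3..10, ultraharmonics m = 5, 7, ..., 19,
#' per-order peak search within a 20 kHz band, and suppression notches of
#' 360 kHz around each harmonic and 100 kHz around each ultraharmonic when
#' isolating the broadband residual.
#'
#' @param analysis_range Numeric length-2, analysis band `[f_lo, f_hi]` in Hz.
#' @param harmonic_orders Integer vector of harmonic orders n (bands at n*f).
#' @param ultraharmonic_orders Odd integer vector of ultraharmonic orders m
#'   (bands at m/2*f).
#' @param peak_search_width Total width (Hz) of the per-order band within
#'   which the spectral maximum is taken. Default 20 kHz.
#' @param harmonic_suppress_width Total width (Hz) of the notch zeroed around
#'   each harmonic for the broadband residual. Default 360 kHz.
#' @param ultraharmonic_suppress_width Total notch width (Hz) around each
#'   ultraharmonic. Default 100 kHz.
#'
#' @return An object of class `band_scheme`.
#' @export
band_scheme <- function(analysis_range = c(1.25e6, 5.00e6),
                        harmonic_orders = 3:10,
                        ultraharmonic_orders = seq(5L, 19L, by = 2L),
                        peak_search_width = 20e3,
                        harmonic_suppress_width = 360e3,
                        ultraharmonic_suppress_width = 100e3) {
  stopifnot(length(analysis_range) == 2L, analysis_range[1] > 0,
            analysis_range[2] > analysis_range[1],
            peak_search_width > 0, harmonic_suppress_width > 0,
            ultraharmonic_suppress_width > 0)
  if (any(ultraharmonic_orders %% 2L == 0L))
    stop("configuration error: ultraharmonic orders must be odd (bands at m/2*f)")
  structure(
    list(analysis_range = as.numeric(analysis_range),
         harmonic_orders = as.integer(harmonic_orders),
         ultraharmonic_orders = as.integer(ultraharmonic_orders),
         peak_search_width = as.numeric(peak_search_width),
         harmonic_suppress_width = as.numeric(harmonic_suppress_width),
         ultraharmonic_suppress_width = as.numeric(ultraharmonic_suppress_width)),
    class = "band_scheme")
}

#' @export
print.band_scheme <- function(x, ...) {
  cat(sprintf("<band_scheme> analysis %.2f-%.2f MHz; harmonics n = %s; ultraharmonics m = %s\n",
              x$analysis_range[1] / 1e6, x$analysis_range[2] / 1e6,
              paste(range(x$harmonic_orders), collapse = ".."),
              paste(range(x$ultraharmonic_orders), collapse = "..")))
  cat(sprintf("  peak search %.0f kHz; notches %.0f kHz (harmonic) / %.0f kHz (ultraharmonic)\n",
              x$peak_search_width / 1e3, x$harmonic_suppress_width / 1e3,
              x$ultraharmonic_suppress_width / 1e3))
  invisible(x)
}

# Nominal band centre frequencies falling inside the analysis range
# (bands centred outside the range are dropped entirely; bands straddling
# the edge are clipped when the spectrum is restricted).
scheme_harmonic_freqs <- function(scheme, f) {
  fn <- scheme$harmonic_orders * f
  fn[fn >= scheme$analysis_range[1] & fn <= scheme$analysis_range[2]]
}

scheme_ultraharmonic_freqs <- function(scheme, f) {
  fm <- scheme$ultraharmonic_orders / 2 * f
  fm[fm >= scheme$analysis_range[1] & fm <= scheme$analysis_range[2]]
}

#' One-sided amplitude spectrum of a PCD pulse
#'
#' Rectangular-window FFT amplitude spectrum (volts) of a single pulse,
#' restricted to the analysis band of the scheme.  A sinusoid of amplitude A
#' at an exact bin frequency appears with amplitude A.
#'
#' @param pulse A [pulse_record].
#' @param scheme A [band_scheme].
#'
#' @return A data frame with columns `freq` (Hz) and `amplitude` (V), one row
#'   per FFT bin inside the analysis range, with attribute `df` (bin width,
#'   Hz).
#' @export
pulse_spectrum <- function(pulse, scheme = band_scheme()) {
  stopifnot(inherits(pulse, "pulse_record"), inherits(scheme, "band_scheme"))
  if (anyNA(pulse$samples))
    stop("invalid-input: pulse samples contain NA/NaN")
  nyq <- pulse$sample_rate / 2
  if (nyq <= scheme$analysis_range[2])
    stop(sprintf(
      "aliasing error: sample rate %.3g MHz cannot resolve the analysis band up to %.3g MHz",
      pulse$sample_rate / 1e6, scheme$analysis_range[2] / 1e6))
  n <- length(pulse$samples)
  df <- pulse$sample_rate / n
  if (df > 5e3)
    warning(sprintf(
      "frequency resolution %.1f kHz exceeds 5 kHz; peak-search bands may span < 4 bins",
      df / 1e3))
  sp <- stats::fft(pulse$samples)
  half <- seq_len(floor(n / 2) + 1L)           # DC .. Nyquist
  amp <- Mod(sp[half]) / n
  amp[-1L] <- 2 * amp[-1L]                     # one-sided scaling
  if (n %% 2L == 0L) amp[length(amp)] <- amp[length(amp)] / 2
  freq <- (half - 1L) * df
  keep <- freq >= scheme$analysis_range[1] & freq <= scheme$analysis_range[2]
  out <- data.frame(freq = freq[keep], amplitude = amp[keep])
  attr(out, "df") <- df
  out
}
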