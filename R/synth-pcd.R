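#' Synthetic PCD emission specification
#'
#' Describes the spectral content of a synthetic microbubble emission pulse
#' train: harmonic tones (n*f, volumetric bubble oscillation), ultraharmonic
#' tones (m/2*f, shell oscillation), white Gaussian broadband noise (inertial
#' cavitation), plus the transmitted fundamental.  Optional slow sinusoidal
#' amplitude modulation across pulses emulates the breathing-rate periodicity
#' sometimes seen in the cavitation level when large vessels sit in the focus.
#'
#' @param harmonic_amps Named numeric vector: harmonic order n -> amplitude
#'   (V), e.g. `c("3" = 0.5)`.
#' @param ultraharmonic_amps Named numeric vector: odd order m -> amplitude
#'   (V) of the tone at m/2*f.
#' @param broadband_rms RMS (V) of the additive white Gaussian noise.
#' @param fundamental_amp Amplitude (V) of the fundamental tone at f.
#' @param pulse_length Pulse duration in seconds. Default 10 ms.
#' @param n_pulses Number of pulses in the train.
#' @param prf Pulse-repetition frequency in Hz (sets pulse timestamps).
#'   Default 2 Hz.
#' @param modulation Optional list `list(period = <s>, depth = <0..1>)`:
#'   per-pulse amplitude factor `1 + depth * sin(2*pi*t/period)` applied to
#'   all components.
#' @param seed Integer seed; a fixed seed gives bit-identical pulse trains.
#'
#' @return An object of class `emission_spec`.
#' @export
emission_spec <- function(harmonic_amps = numeric(), ultraharmonic_amps = numeric(),
                          broadband_rms = 0, fundamental_amp = 0,
                          pulse_length = 10e-3, n_pulses = 1L, prf = 2,
                          modulation = NULL, seed = 1L) {
  to_named <- function(x, what) {
    if (length(x) == 0L) return(numeric())
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop(sprintf("configuration error: `%s` must be named by integer orders", what))
    if (any(x < 0)) stop(sprintf("configuration error: `%s` must be >= 0", what))
    x
  }
  harmonic_amps <- to_named(harmonic_amps, "harmonic_amps")
  ultraharmonic_amps <- to_named(ultraharmonic_amps, "ultraharmonic_amps")
  if (length(ultraharmonic_amps) &&
      any(as.integer(names(ultraharmonic_amps)) %% 2L == 0L))
    stop("configuration error: ultraharmonic orders must be odd")
  if (broadband_rms < 0 || fundamental_amp < 0)
    stop("configuration error: amplitudes must be >= 0")
  if (pulse_length <= 0 || n_pulses < 1L)
    stop("configuration error: pulse_length must be > 0 and n_pulses >= 1")
  if (!is.null(modulation)) {
    stopifnot(is.list(modulation), modulation$period > 0,
              modulation$depth >= 0, modulation$depth <= 1)
  }
  structure(
    list(harmonic_amps = harmonic_amps,
         ultraharmonic_amps = ultraharmonic_amps,
         broadband_rms = broadband_rms, fundamental_amp = fundamental_amp,
         pulse_length = pulse_length, n_pulses = as.integer(n_pulses),
         prf = prf, modulation = modulation, seed = as.integer(seed)),
    class = "emission_spec")
}

#' Generate a synthetic PCD pulse train
#'
#' Each pulse is a sum of sinusoids at the specified harmonic (n*f) and
#' ultraharmonic (m/2*f) frequencies with independent uniform random phases
#' per component per pulse, plus white Gaussian noise of the stated RMS.
#' Deterministic for a fixed `spec$seed`.
#'
#' @param spec An [emission_spec].
#' @param sample_rate Sampling rate in Hz (must exceed twice the highest
#'   analysis frequency). Default 50 MHz.
#' @param f Excitation frequency in Hz. Default 0.5 MHz.
#'
#' @return List of [pulse_record] objects.
#' @export
generate_pulses <- function(spec, sample_rate = 50e6, f = 0.5e6) {
  stopifnot(inherits(spec, "emission_spec"))
  n <- round(spec$pulse_length * sample_rate)
  if (abs(n - spec$pulse_length * sample_rate) > 0.5 || n < 1024)
    stop("configuration error: pulse_length * sample_rate must be an integer >= 1024")
  freqs <- c(if (spec$fundamental_amp > 0) f,
             as.integer(names(spec$harmonic_amps)) * f,
             as.integer(names(spec$ultraharmonic_amps)) / 2 * f)
  amps <- c(if (spec$fundamental_amp > 0) spec$fundamental_amp,
            unname(spec$harmonic_amps), unname(spec$ultraharmonic_amps))
  keep <- amps > 0
  freqs <- freqs[keep]; amps <- amps[keep]
  t <- seq_len(n) / sample_rate

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  lapply(seq_len(spec$n_pulses), function(i) {
    ts <- (i - 1L) / spec$prf
    gain <- 1
    if (!is.null(spec$modulation))
      gain <- 1 + spec$modulation$depth * sin(2 * pi * ts / spec$modulation$period)
    x <- numeric(n)
    if (length(freqs)) {
      phases <- stats::runif(length(freqs), 0, 2 * pi)
      for (k in seq_along(freqs))
        x <- x + amps[k] * sin(2 * pi * freqs[k] * t + phases[k])
    }
    if (spec$broadband_rms > 0)
      x <- x + stats::rnorm(n, sd = spec$broadband_rms)
    pulse_record(gain * x, sample_rate = sample_rate, f = f,
                 pulse_index = i, timestamp = ts)
  })
}

# Save/restore the global RNG state so seeded generators do not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Pressure-response models for synthetic calibration ramps
#'
#' Built-in maps from acoustic pressure (kPa) to a component amplitude
#' multiplier, emulating the shapes seen in PCD calibration: broadband
#' emission increasing monotonically with pressure, harmonic/ultraharmonic
#' emission rising to a plateau, or onset above a cavitation threshold.
#'
#' @param model `"linear"`, `"plateau"` or `"threshold"`.
#' @param p_ref Reference pressure (kPa) at which the multiplier is 1 for the
#'   linear model; plateau midpoint / onset threshold for the others.
#' @return A function `f(pressure_kPa) -> multiplier`.
#' @export
pressure_response <- function(model = c("linear", "plateau", "threshold"),
                              p_ref = 300) {
  model <- match.arg(model)
  switch(model,
    linear = function(p) p / p_ref,
    plateau = function(p) tanh(p / p_ref),          # saturating growth
    threshold = function(p) pmax(0, (p - p_ref) / p_ref))
}

#' Generate a synthetic PCD calibration ramp
#'
#' Produces pulse groups at monotonically increasing pressures, with each
#' emission component's amplitude scaled by its pressure-response model.
#'
#' @param base_spec An [emission_spec]; its amplitudes are the values at the
#'   response model's reference pressure.
#' @param pressures Strictly increasing pressures in kPa.
#' @param response_model Named list of response functions (from
#'   [pressure_response()] or custom) for components `harmonic`,
#'   `ultraharmonic`, `broadband`; missing entries default to `"linear"`
#'   names are looked up as model names if character.
#' @param sample_rate,f Acquisition parameters passed to [generate_pulses()].
#'
#' @return Named list mapping pressure (kPa) to a list of [pulse_record]s,
#'   suitable for [calibration_ramp()].
#' @export
generate_ramp <- function(base_spec, pressures,
                          response_model = list(harmonic = "plateau",
                                                ultraharmonic = "plateau",
                                                broadband = "linear"),
                          sample_rate = 50e6, f = 0.5e6) {
  stopifnot(inherits(base_spec, "emission_spec"), length(pressures) >= 1L)
  if (is.unsorted(pressures, strictly = TRUE))
    stop("configuration error: pressures must be strictly increasing")
  as_fun <- function(m) {
    if (is.function(m)) return(m)
    if (is.character(m)) return(pressure_response(m))
    stop("configuration error: unknown response model")
  }
  fh <- as_fun(response_model$harmonic %||% "linear")
  fu <- as_fun(response_model$ultraharmonic %||% "linear")
  fb <- as_fun(response_model$broadband %||% "linear")

  out <- lapply(seq_along(pressures), function(i) {
    p <- pressures[i]
    sp <- base_spec
    sp$harmonic_amps <- base_spec$harmonic_amps * fh(p)
    sp$ultraharmonic_amps <- base_spec$ultraharmonic_amps * fu(p)
    sp$broadband_rms <- base_spec$broadband_rms * fb(p)
    sp$seed <- base_spec$seed + i            # independent noise per step
    generate_pulses(sp, sample_rate = sample_rate, f = f)
  })
  names(out) <- as.character(pressures)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
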