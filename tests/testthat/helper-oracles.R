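# Independent oracles used across the suite.

# Brute-force cavitation levels on a small pulse: direct DFT (explicit
# correlation sums, no shared FFT path) and explicit per-order bin
# enumeration for each band.  Only feasible for short pulses.
brute_force_levels <- function(samples, sample_rate, f,
                               scheme = band_scheme()) {
  n <- length(samples)
  stopifnot(n <= 4096)
  k <- 0:floor(n / 2)
  tt <- (seq_len(n) - 1) / n
  # direct DFT, one column per bin
  basis <- exp(-2i * pi * outer(tt, k))
  amp <- 2 * Mod(as.vector(samples %*% basis)) / n
  amp[1] <- amp[1] / 2
  if (n %% 2 == 0) amp[length(amp)] <- amp[length(amp)] / 2
  freq <- k * sample_rate / n

  inband <- which(freq >= scheme$analysis_range[1] &
                    freq <= scheme$analysis_range[2])
  fh <- scheme$harmonic_orders * f
  fh <- fh[fh >= scheme$analysis_range[1] & fh <= scheme$analysis_range[2]]
  fu <- scheme$ultraharmonic_orders / 2 * f
  fu <- fu[fu >= scheme$analysis_range[1] & fu <= scheme$analysis_range[2]]

  peaks <- function(centers, halfwidth) {
    vapply(centers, function(f0) {
      bins <- inband[abs(freq[inband] - f0) <= halfwidth]
      if (!length(bins)) 0 else max(amp[bins])
    }, numeric(1))
  }
  ph <- peaks(fh, scheme$peak_search_width / 2)
  pu <- peaks(fu, scheme$peak_search_width / 2)

  keep <- inband
  for (f0 in fh) keep <- keep[abs(freq[keep] - f0) > scheme$harmonic_suppress_width / 2]
  for (f0 in fu) keep <- keep[abs(freq[keep] - f0) > scheme$ultraharmonic_suppress_width / 2]

  list(dSCDh = sqrt(sum(ph^2) / 2),
       dSCDu = sqrt(sum(pu^2) / 2),
       dICD = sqrt(sum(amp[keep]^2) / 2))
}

# Exact-bin tone pulse: pulse_length is a multiple of 1/gcd so that all
# harmonic and ultraharmonic frequencies of f = 0.5 MHz land on FFT bins.
tone_pulse <- function(freqs, amps, sample_rate = 12.5e6, f = 0.5e6,
                       pulse_length = 2e-3, phases = NULL, index = 1L) {
  n <- round(pulse_length * sample_rate)
  t <- seq_len(n) / sample_rate
  if (is.null(phases)) phases <- rep(pi / 5, length(freqs))
  x <- numeric(n)
  for (i in seq_along(freqs))
    x <- x + amps[i] * sin(2 * pi * freqs[i] * t + phases[i])
  pulse_record(x, sample_rate = sample_rate, f = f, pulse_index = index)
}

# Forward SPGR volumes for a uniform-T1 slab with per-image noise.
uniform_vfa <- function(T1, dims = c(50, 50, 4), snr = Inf,
                        angles = c(5, 10, 15, 20, 35), TR = 10, seed = 1) {
  withr::with_seed(seed, {
    vols <- lapply(angles, function(a) {
      s <- spgr_signal(T1, a, TR)
      x <- array(s, dims)
      if (is.finite(snr)) x <- x + array(rnorm(prod(dims), sd = s / snr), dims)
      volume_grid(x)
    })
    vfa_series(vols, angles, TR)
  })
}

# Constant-value T1 map helper.
const_map <- function(value, dims = c(4, 4, 2), spacing = c(1, 1, 1)) {
  volume_grid(array(value, dims), spacing)
}
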