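test_that("pulse spectrum resolves exact-bin tones with preserved amplitude", {
  p <- tone_pulse(c(1.5e6, 2.0e6), c(0.8, 0.3))
  sp <- pulse_spectrum(p)
  expect_lte(attr(sp, "df"), 5e3)
  expect_true(all(sp$freq >= 1.25e6 & sp$freq <= 5.0e6))
  i1 <- which.min(abs(sp$freq - 1.5e6))
  i2 <- which.min(abs(sp$freq - 2.0e6))
  expect_equal(sp$amplitude[i1], 0.8, tolerance = 0.01)
  expect_equal(sp$amplitude[i2], 0.3, tolerance = 0.01)
  expect_lt(max(sp$amplitude[-c(i1, i2)]), 1e-10)
})

test_that("pulse spectrum of an all-zero pulse is all-zero", {
  p <- pulse_record(numeric(25000), 12.5e6, 0.5e6)
  sp <- pulse_spectrum(p)
  expect_true(all(sp$amplitude == 0))
})

test_that("pulse spectrum rejects aliasing and non-finite samples", {
  p <- tone_pulse(1.5e6, 1, sample_rate = 8e6)   # Nyquist 4 MHz < 5 MHz band top
  expect_error(pulse_spectrum(p), "aliasing")
  expect_error(pulse_record(c(1, NA, 3)), "invalid-input")
  expect_error(pulse_record(c(1, Inf, 3)), "invalid-input")
})

test_that("single tones are classified into the correct band with < 1% cross-talk", {
  scheme <- band_scheme()
  for (n in 3:10) {
    lv <- cavitation_levels(tone_pulse(n * 0.5e6, 1), scheme)
    expect_equal(lv$dSCDh, 1 / sqrt(2), tolerance = 1e-6)
    expect_lt(lv$dSCDu, 0.01 * lv$dSCDh)
    expect_lt(lv$dICD, 0.01 * lv$dSCDh)
  }
  for (m in seq(5, 19, by = 2)) {
    lv <- cavitation_levels(tone_pulse(m / 2 * 0.5e6, 1), scheme)
    expect_equal(lv$dSCDu, 1 / sqrt(2), tolerance = 1e-6)
    expect_lt(lv$dSCDh, 0.01 * lv$dSCDu)
    expect_lt(lv$dICD, 0.01 * lv$dSCDu)
  }
})

test_that("all-zero pulse has zero cavitation levels", {
  lv <- cavitation_levels(pulse_record(numeric(25000), 12.5e6, 0.5e6))
  expect_identical(c(lv$dSCDh, lv$dSCDu, lv$dICD), c(0, 0, 0))
})

test_that("levels are exactly scale-equivariant", {
  base <- tone_pulse(c(1.5e6, 1.75e6, 3.19e6), c(0.5, 0.2, 0.1))
  lv1 <- cavitation_levels(base)
  p2 <- pulse_record(3.5 * base$samples, base$sample_rate, base$f)
  lv2 <- cavitation_levels(p2)
  expect_equal(lv2$dSCDh, 3.5 * lv1$dSCDh, tolerance = 1e-12)
  expect_equal(lv2$dSCDu, 3.5 * lv1$dSCDu, tolerance = 1e-12)
  expect_equal(lv2$dICD, 3.5 * lv1$dICD, tolerance = 1e-12)
})

test_that("harmonic-only pulses leak < 1% into the broadband band", {
  amps <- seq(1, 0.3, length.out = 8)
  p <- tone_pulse(3:10 * 0.5e6, amps)
  lv <- cavitation_levels(p)
  expect_equal(lv$dSCDh, sqrt(sum(amps^2) / 2), tolerance = 1e-6)
  expect_lt(lv$dICD, 0.01 * lv$dSCDh)
})

test_that("Parseval: band energy splits into harmonic, ultraharmonic and broadband parts", {
  # one tone per class: 1.5 MHz (harmonic), 1.75 MHz (ultraharmonic),
  # 3.19 MHz (in the kept broadband gap between suppression notches)
  amps <- c(0.6, 0.4, 0.25)
  p <- tone_pulse(c(1.5e6, 1.75e6, 3.19e6), amps)
  lv <- cavitation_levels(p)
  sp <- pulse_spectrum(p)
  band_rms2 <- sum(sp$amplitude^2) / 2
  expect_equal(lv$dSCDh^2 + lv$dSCDu^2 + lv$dICD^2, band_rms2,
               tolerance = 1e-9)
  expect_equal(band_rms2, sum(amps^2) / 2, tolerance = 1e-9)
})

test_that("levels match a brute-force bin-enumeration oracle on toy pulses", {
  sr <- 12.5e6
  n <- 4000                                   # df = 3.125 kHz
  t <- seq_len(n) / sr
  withr::with_seed(42, {
    for (rep in 1:4) {
      x <- 0.7 * sin(2 * pi * 1.5e6 * t + runif(1, 0, 2 * pi)) +
        0.4 * sin(2 * pi * 2.25e6 * t + runif(1, 0, 2 * pi)) +
        rnorm(n, sd = 0.05)
      p <- pulse_record(x, sr, 0.5e6)
      got <- cavitation_levels(p)
      want <- brute_force_levels(x, sr, 0.5e6)
      expect_equal(got$dSCDh, want$dSCDh, tolerance = 1e-10)
      expect_equal(got$dSCDu, want$dSCDu, tolerance = 1e-10)
      expect_equal(got$dICD, want$dICD, tolerance = 1e-10)
    }
  })
})

test_that("cavitation dose sums per-pulse levels and is additive over concatenation", {
  tab <- data.frame(pulse_index = 1:3, dSCDh = c(1, 2, 3),
                    dSCDu = c(0.1, 0.1, 0.1), dICD = c(0, 1, 0))
  d <- cavitation_dose(tab)
  expect_identical(d$SCDh, 6)
  expect_equal(d$SCDu, 0.3, tolerance = 1e-12)
  expect_identical(d$ICD, 1)
  expect_identical(d$total, d$SCDh + d$SCDu + d$ICD)

  part1 <- tab[1:2, ]; part2 <- tab[3, ]
  d1 <- cavitation_dose(part1); d2 <- cavitation_dose(part2)
  expect_identical(d$SCDh, d1$SCDh + d2$SCDh)
  expect_equal(d$total, d1$total + d2$total, tolerance = 1e-12)
})

test_that("baseline subtraction is per-pulse, floored at zero", {
  lv <- data.frame(pulse_index = 1:2, dSCDh = c(2, 2), dSCDu = c(0, 0),
                   dICD = c(1, 1))
  base <- data.frame(pulse_index = 1:2, dSCDh = c(0.5, 1.5), dSCDu = c(0, 0),
                     dICD = c(1, 1))
  d <- cavitation_dose(lv, baseline = base)
  expect_identical(d$SCDh, 2 * (2 - 1))    # mean baseline 1 per pulse
  expect_identical(d$ICD, 0)               # exact cancellation, floored
  expect_true(d$baseline_subtracted)
  expect_error(cavitation_dose(lv[0, ]), "empty-input")
})

test_that("a 240-pulse train of identical levels gives 240x doses", {
  tab <- data.frame(pulse_index = 1:240, dSCDh = 0.2, dSCDu = 0.05,
                    dICD = 0.01)
  d <- cavitation_dose(tab)
  expect_equal(d$SCDh, 240 * 0.2)
  expect_equal(d$total, 240 * (0.2 + 0.05 + 0.01))
  expect_identical(d$n_pulses, 240L)
})

test_that("calibration ramp reports per-pressure mean and SD in pressure order", {
  p1 <- tone_pulse(1.5e6, 0.5)
  p2 <- tone_pulse(1.5e6, 1.0)
  groups <- list("300" = list(p2, p2), "100" = list(p1, p1))
  expect_warning(ramp <- calibration_ramp(groups), "not monotonically increasing")
  expect_equal(ramp$pressure_kPa, c(100, 300))
  expect_equal(ramp$dSCDh_mean, c(0.5, 1.0) / sqrt(2), tolerance = 1e-6)
  expect_equal(ramp$dSCDh_sd, c(0, 0))

  expect_error(calibration_ramp(list("100" = list())), "empty-input")
  expect_warning(calibration_ramp(list("100" = list(p1))), "single pulse")
})
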