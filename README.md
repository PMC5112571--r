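# cavimap

Quantification chain linking **acoustic cavitation monitoring** during
focused-ultrasound (FUS) blood–brain-barrier (BBB) opening to **MRI-based
drug-delivery outcomes**.

FUS with circulating microbubbles transiently opens the BBB, letting agents
such as gadolinium (a model drug) enter the brain parenchyma. Two questions
drive treatment monitoring: *how much was delivered, and where* (answered by
contrast-enhanced T1 MRI after the sonication), and *can the outcome be
predicted in real time* (answered by passive cavitation detection, PCD,
during the sonication). `cavimap` implements both sides of that chain for
R, plus the targeting geometry and statistics that connect them, and ships
seeded synthetic generators (PCD pulse trains and 3D MRI brain phantoms
with known ground truth) so every stage is testable without animal data.

## What it computes

**Cavitation doses from PCD waveforms.** Each 10 ms tone-burst pulse
(excitation `f` = 0.5 MHz) is Fourier-analysed in the 1.25–5.00 MHz band and
split into harmonic (`n·f`, n = 3…10), ultraharmonic (`m/2·f`,
m = 5, 7, …, 19) and broadband components — the signatures of volumetric
bubble oscillation, shell oscillation, and inertial bubble collapse. Per
pulse, the cavitation level of each class is the RMS amplitude of the
filtered signal (harmonics/ultraharmonics from per-order 20 kHz-band
maxima; broadband after zeroing 360 kHz/100 kHz notches around every
harmonic/ultraharmonic). The cavitation dose of a sonication is the sum of
levels over its pulses:

    SCD_h = Σ_pulses dSCD_h,   SCD_u = Σ dSCD_u,   ICD = Σ dICD,
    total dose = SCD_h + SCD_u + ICD

**Gadolinium delivery from T1 MRI.** T1 maps are fitted from five-flip-angle
SPGR volumes by the standard linearized fit (`S/sinα = E1·S/tanα + c`,
`T1 = −TR/ln E1`), and concentration follows from the relaxation-rate
change

    [Gd] = (1/T1 − 1/T1,0) / r1,        r1 = 4 s⁻¹mM⁻¹ (gadodiamide)

Opening volume is counted from normalized, sham-subtracted post/pre
T1-weighted enhancement inside a 10 × 10 × 32.5 mm VOI on the target minus
its mirror-image contralateral VOI (significant above 80 mm³); the
delivered amount integrates concentration × voxel volume the same way
(0.05 mM over 300 mm³ = 15 nmol = 0.0015 % of a 1 mmol injection). Tissue
is segmented by pre-contrast T1 ranges (blood ≤ 700 ms < white ≤ 1170 ms <
gray ≤ 1800 ms < CSF ≤ 5000 ms), giving per-tissue opening probabilities.

**Targeting accuracy.** Incidence/refraction angles between the planned
trajectory (or observed opening direction) and skull-surface normals from
the smoothed 3D mask gradient, and total/lateral/axial target shift with
respect to the planned focus.

**Outcome statistics.** OLS regression of opening volume / delivered amount
on the total cavitation dose (pooled and per subject) and pooled-variance
two-tailed t-tests between opened and unopened groups.

## Worked example

Synthesize a PCD pulse train, quantify it, then run the full MRI pipeline
on a ground-truth brain phantom at image SNR 50:

```r
library(cavimap)

spec <- emission_spec(harmonic_amps = c("3" = 0.4, "4" = 0.25),
                      ultraharmonic_amps = c("7" = 0.1),
                      broadband_rms = 0.02, n_pulses = 5, seed = 1)
pulses <- generate_pulses(spec)                 # 50 MHz, 10 ms pulses
levels <- cavitation_level_table(pulses)
head(levels, 3)
#>   pulse_index     dSCDh      dSCDu        dICD
#> 1           1 0.3335673 0.07073111 0.002161379
#> 2           2 0.3335631 0.07073996 0.002205762
#> 3           3 0.3335421 0.07068201 0.002208641
cavitation_dose(levels)
#> <cavitation_dose> 5 pulses: SCDh = 1.668, SCDu = 0.3536, ICD = 0.01094, total = 2.032 V*pulses

ph <- build_phantom(phantom_spec(snr = 50, seed = 1))   # truth: 288 mm^3, 20.16 nmol
fit_pre  <- fit_t1(ph$vfa_pre)
fit_post <- fit_t1(ph$vfa_post)
gd  <- gd_concentration(fit_post$t1, fit_pre$t1, r1 = 4)
voi <- voi_spec(center = ph$truth$center)
aca <- mean(gd$concentration$voxels[ph$aca_mask], na.rm = TRUE)
del <- delivered_gd(gd, ph$brain_mask, aca, voi)
enh  <- enhancement_map(ph$t1w_post, ph$t1w_pre, ph$thalamus_mask, ph$aca_mask)
sham <- enhancement_map(ph$t1w_sham_post, ph$t1w_sham_pre, ph$thalamus_mask, ph$aca_mask)
opening_volume(enh, ph$brain_mask, sham, voi, cutoff = "half-max")
#> <opening_report> volume = 288.0 mm^3 (significant at 80 mm^3)
del$gd_delivered_nmol                           # 20.4 (truth 20.16)
del$delivery_efficiency_pct                     # 0.00204 % of 1 mmol injected
```

The injected harmonic tone of amplitude 0.4 V appears as
`dSCDh ≈ 0.4/√2 + ...` (RMS of the per-order peaks), the phantom's 288 mm³
opening is recovered exactly here, and the delivered amount lands within
~1 % of the 20.16 nmol ground truth.

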