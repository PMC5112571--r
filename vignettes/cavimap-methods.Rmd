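---
title: "Methods: from cavitation monitoring to drug-delivery quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from cavitation monitoring to drug-delivery quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cavimap` implements the quantification chain used to characterize
focused-ultrasound (FUS) blood-brain-barrier (BBB) opening in the primate
brain: passive cavitation detection (PCD) on the acoustic side, and
contrast-enhanced T1 MRI on the imaging side, joined by targeting geometry
and outcome statistics. This vignette explains the models, the tunable
parameters, the numerical choices, and what the synthetic generators do and
do not emulate.

## Acoustic side: cavitation levels and doses

During each tone-burst pulse (0.5 MHz excitation, 10 ms pulse length, 2 Hz
repetition), circulating microbubbles emit an acoustic signature recorded by
a confocal hydrophone at 50 MHz. Three signatures are separated in the pulse
spectrum, restricted to the 1.25-5.00 MHz analysis band:

* **Harmonics** (volumetric bubble oscillation) at $n f$, $n = 3 \dots 10$:
  for each order, the maximum spectral amplitude within a 20 kHz search band
  around $n f$ is taken.
* **Ultraharmonics** (shell oscillation) at $\tfrac{m}{2} f$,
  $m = 5, 7, \dots, 19$: likewise.
* **Broadband emission** (inertial cavitation): the spectrum after zeroing
  suppression notches of 360 kHz around every harmonic and 100 kHz around
  every ultraharmonic.

The per-pulse *cavitation level* of each class (`dSCDh`, `dSCDu`, `dICD`, in
volts) is the root-mean-square amplitude of the corresponding filtered
signal. We evaluate the RMS in the frequency domain via Parseval: a signal
reconstructed from $k$ spectral components of amplitudes $a_i$ has RMS
$\sqrt{\sum_i a_i^2 / 2}$. This is identical to inverse-transforming the
filtered spectrum and taking the time-domain RMS, but is simpler and exactly
deterministic; the brute-force bin-enumeration oracle in the test suite
checks the equivalence. The *cavitation dose* of a sonication (`SCDh`,
`SCDu`, `ICD`) is the sum of the per-pulse levels over all pulses, and the
total dose is their sum — the quantity that correlates best with opening
outcomes, since harmonic and ultraharmonic responses saturate at high
pressure while broadband emission keeps growing.

Numerical choices:

* **Window**: rectangular over the full pulse. A 10 ms pulse gives 100 Hz
  bin spacing, so every harmonic and ultraharmonic of a 0.5 MHz excitation
  falls exactly on an FFT bin and spectral leakage vanishes for coherent
  tones; the general leakage floor is controlled by the pulse length. The
  implementation requires a frequency resolution of at most 5 kHz so each
  20 kHz search band spans at least 4 bins.
* **Baseline**: when a pre-microbubble control sonication is supplied, the
  mean per-pulse baseline level is subtracted from each pulse's level and
  floored at zero (negative cavitation is non-physical) before summation.
  Subtracting per-pulse rather than from the summed dose keeps the dose a
  sum of non-negative pulse contributions.
* **Units**: levels in volts and doses in volt-pulses; no absolute pressure
  calibration through the skull is attempted.

The synthetic PCD generator (`generate_pulses()`) emits sums of harmonic and
ultraharmonic sinusoids with independent random phases per component per
pulse, plus white Gaussian noise as the broadband surrogate, optionally with
a slow sinusoidal amplitude modulation across pulses emulating the
breathing-periodic cavitation sometimes observed when large vessels sit in
the focus. White noise is the simplest null with flat band occupancy; real
inertial-cavitation spectra are colored, so absolute `dICD` magnitudes from
the generator are not physiological — only their scaling behaviour is.
Pressure ramps (`generate_ramp()`) scale component amplitudes by built-in
response models: `linear` (broadband grows monotonically with pressure),
`plateau` (harmonic/ultraharmonic saturation, $\tanh$), and `threshold`
(onset above a cavitation threshold).

## Imaging side: T1 relaxometry and gadolinium mapping

Gadodiamide (Gd-DTPA-BMA) does not cross the intact BBB; where FUS opens the
barrier it perfuses tissue and shortens T1. Pre- and post-contrast T1 maps
are fitted from a five-flip-angle spoiled-gradient-echo (SPGR) series
(5/10/15/20/35 degrees, TR = 10 ms) with the standard linearized fit: with
$y = S/\sin\alpha$ and $x = S/\tan\alpha$, the SPGR signal equation

$$S = M_0 \sin\alpha \, \frac{1 - E_1}{1 - E_1\cos\alpha},
\qquad E_1 = e^{-TR/T_1}$$

becomes the line $y = E_1 x + M_0 (1 - E_1)$, fitted per voxel by unweighted
least squares (matching the standard line-fit method). Voxels with slope
outside $(0, 1)$ or fitted T1 outside $(1, 10000)$ ms are flagged invalid
rather than silently zeroed, because $\log E_1$ is numerically unstable
there.

Concentration follows from the relaxation-rate change:

$$[Gd]_c = \frac{1/T_1 - 1/T_{1,0}}{r_1},$$

with relaxivity $r_1 = 4\,\mathrm{s^{-1}mM^{-1}}$ for gadodiamide. Negative
concentrations (noise pushing $T_1 > T_{1,0}$) are clamped to zero and
counted. With concentration in mM and voxel volume in mm^3, the product is
directly in nmol, which makes the delivered-amount arithmetic transparent:
0.05 mM over 300 mm^3 is 15 nmol, i.e. 0.0015% of a 1 mmol injected dose.

Tissue is segmented on the pre-contrast T1 map by half-open intervals
$(\mathrm{lo}, \mathrm{hi}]$: blood (1, 700] ms, white matter (700, 1170] ms,
gray matter (1170, 1800] ms, CSF (1800, 5000] ms. The half-open rule is a
convention choice (the interval endpoints are only quoted as ranges); it
guarantees each voxel gets exactly one label. The boundaries are arguments,
since T1 ranges shift with field strength and species.

## Opening volume and delivered amount

The opening pipeline mirrors standard contrast-enhancement analysis:

1. **Enhancement**: ratio of post- to pre-contrast T1-weighted volumes,
   linearly rescaled so the unsonicated thalamus maps to 0 and the anterior
   cerebral artery (ACA) to 1.
2. **Background removal**: brain masking and subtraction of a sham
   (no-FUS/no-microbubble) enhancement map.
3. **Counting**: voxels above a voxelwise cutoff inside the 10 x 10 x
   32.5 mm volume of interest (VOI) on the target, minus the above-cutoff
   volume in the mirror-image contralateral VOI, floored at zero. An
   opening is called significant above 80 mm^3 (sham mean + 3 SD).
4. **Delivered amount**: the concentration map is vessel-filtered (voxels
   above the ACA concentration set to zero), brain-masked, and integrated
   over the ipsilateral minus contralateral VOI.

Design choices that were genuinely open:

* The per-voxel cutoff defining an "enhanced" voxel is not a printed
  constant; it is exposed as a parameter (default 0: any residual
  enhancement after sham subtraction). For noisy data the package also
  offers `cutoff = "half-max"`: the sham-subtracted map is lightly smoothed
  (sigma 0.6 voxel), the opening's plateau amplitude is estimated as the
  mean of the top quintile-of-maximum voxels in the ipsilateral VOI, voxels
  above half that amplitude are counted, and the half-maximum level is then
  corrected once for the curvature bias of Gaussian blur (a blurred convex
  boundary of equivalent radius $r$ crosses the half level displaced by
  $\approx \phi(0)\,\sigma/r$), using the first-pass volume to estimate
  $r$. This full-width-half-maximum rule is standard lesion volumetry and
  keeps the estimate essentially unbiased from ~90 to ~800 mm^3 at image
  SNR 50.
* The contralateral subtraction is applied to aggregate volume and amount,
  not voxelwise, matching the description of subtracting "the VOI on the
  contralateral side"; the 80 mm^3 significance threshold is applied after
  that subtraction.
* The mid-sagittal mirror plane is a configuration input (`midline` of the
  `voi_spec`); stereotactic registration is out of scope and inputs are
  assumed co-registered.
* Negative aggregate results are floored at zero; the injected dose
  defaults to 1 mmol and is configurable.

## The brain phantom

`build_phantom()` forward-generates everything the pipeline consumes from
known ground truth on a 96 x 96 x 64 grid at 1 mm isotropic (a desk-scale
memory and runtime choice): an ellipsoidal brain with a white-matter core,
central CSF ventricle and a vertical vessel (the intravascular reference),
wrapped in an ellipsoidal skull shell; per-tissue T1 of white 950 ms, gray
1400 ms, blood 400 ms, CSF 3000 ms, each inside its segmentation interval;
an ellipsoidal focal uptake region with 0.07 mM peak added gadolinium by
default (the in-vivo peak concentration magnitude), a 0.015 mM intrinsic
background retention everywhere in brain (which the contralateral
subtraction is designed to cancel), and 0.15 mM in the vessel. Post-contrast
T1 follows $1/T_1 = 1/T_{1,0} + r_1 [Gd]$; T1-weighted volumes are rendered
as the 8-degree, TR = 8.5 ms SPGR signal, and the VFA series at the five
default angles.

Noise is Gaussian on the image magnitude, with the noise SD set per image to
(mean in-brain signal)/SNR — i.e. "SNR 50" means each volume individually
has image SNR 50, the way MRI image quality is usually quoted. A Gaussian
magnitude model is an adequate approximation to Rician noise at these SNRs.
The phantom emulates compartment T1 contrast, reference regions and focal
uptake with exact ground truth; it does **not** emulate gyral anatomy,
partial-volume mixing, B1 inhomogeneity, registration error, or colored
physiological noise — so passing recovery tests demonstrates correctness of
the quantification chain, not in-vivo accuracy.

`build_targeting_phantom()` provides a spherical-shell skull with
analytically known surface normals, plus an opening ellipsoid displaced and
tilted by known amounts, for validating the targeting geometry.

## Targeting geometry

The incidence angle is the angle between the planned trajectory and the
outer skull-surface normal at the beam entry point; the refraction angle is
the angle between the observed opening direction and the inner-surface
normal where the beam leaves the skull. Normals come from the 3D gradient of
the Gaussian-smoothed (sigma 1 voxel, configurable) binary skull mask,
averaged over the nearest surface voxel and its face neighbours; raw binary
gradients are too noisy. Outer and inner surfaces are told apart by growing
the exterior background from the grid border, so an enclosed cavity defines
the inner surface. The entry point is the first trajectory-mask intersection
marching from the transducer side in quarter-voxel steps. Angles are
reported as absolute acute angles (arccos of the absolute dot product),
since sign conventions for reported angles are not fixed.

The opening direction is the first principal axis of the per-slice 2D
centres of mass (slices along the third grid axis by convention), oriented
toward increasing slice index; a single-slice opening yields a centre but an
undefined direction. The target shift decomposes the focus-to-centre-of-mass
displacement into axial (parallel to the trajectory) and lateral
(perpendicular) components, so total^2 = lateral^2 + axial^2 holds to
rounding.

## Statistics

Opening outcomes are related to the total cavitation dose by ordinary least
squares, pooled and per subject (individual fits varied in vivo, so both are
reported); sham and calibration sonications are excluded by default. Group
comparisons (e.g. harmonic dose in opened vs unopened sonications) use the
two-tailed pooled-variance Student's t-test, with significance at p < 0.05.
No multiple-testing correction is applied, matching the original analysis
scope.

## Problem sizes and tolerances used in validation

The test suite and the acceptance script use: 2-10 ms pulses at 12.5-50 MHz
sampling (any rate above twice the 5 MHz band top is valid); 10^4-voxel
slabs for the noisy VFA benchmark (median |T1 error| < 3% at SNR 50 — close
to the analytic error-propagation limit of ~2.8% for this angle set);
phantom openings of roughly 90, 290 and 815 mm^3 recovered within 5% at SNR
50 (the largest is axially elongated, as real FUS openings are, so that it
fits the 10 mm VOI cross-section); 2000 simulated null datasets for the
regression type-I error (accepted in [0.03, 0.07] at alpha = 0.05); sphere
incidence angles within 3 degrees of analytic; opening directions within 2
degrees; and the Pythagorean shift identity to 1e-10. Concentration
round-trips on noiseless phantoms are exact to 1e-6 mM.

## Known limitations

* No B1 or flip-angle calibration errors are modelled; VFA T1 bias from B1
  inhomogeneity is a known in-vivo effect the phantom does not produce.
* The broadband emission model is white noise; colored spectra would change
  the relative per-band noise floors.
* Registration, brain extraction and skull extraction are out of scope:
  masks and co-registered volumes are inputs.
* The delivered-amount estimate inherits the concentration map's negative
  clamping, which is slightly biased upward in pure noise; the contralateral
  subtraction cancels this bias in expectation but not its variance.
* Absolute acoustic pressure at the focus is not estimated; calibration
  ramps are labelled by nominal pressure.
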