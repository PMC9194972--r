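---
title: "Automated surveillance of in-vivo EPID transit images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated surveillance of in-vivo EPID transit images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epidwatch)
```

## The surveillance problem

A transit electronic portal imaging device (EPID) records the megavoltage
beam exiting the patient at every treatment fraction. Because the panel
signal is calibrated (1 CU per monitor unit for a 10 × 10 cm open field),
fraction-to-fraction changes in a transit image reflect exactly two things:
changes in the machine output and changes in the anatomy the beam
traverses. `epidwatch` turns this into a fully automated, zero-workload
per-fraction QA layer: every night, all of the day's portal images are
read, sorted into per-patient courses, reduced to a single percent number
per fraction, and screened by three flag rules.

## The GDSA metric

Gradient-dose segmented analysis (GDSA) compares each fraction to the
*first fraction* of the same course. On the baseline image, a region of
interest (ROI) is segmented that keeps the **high-dose, low-gradient**
pixels; this region approximately coincides with the projection of the
planning target volume onto the panel. The per-fraction summary is

$$\mathrm{GDSA}_\mu = \frac{100}{|R|}\sum_{p \in R}
  \frac{I_f(p) - I_1(p)}{I_1(p)} \; [\%],$$

the mean per-pixel relative difference over the ROI $R$, with the baseline
$I_1$ always in the denominator. Fraction 1 therefore scores exactly 0,
and a uniform output change of $c$ scores exactly $100(c-1)$.

Two details of this definition were genuinely open and are fixed here as
package conventions:

* **ROI construction.** The baseline is lightly Gaussian-smoothed
  (σ = 2 px, to resist hot pixels) before the plateau maximum is taken.
  The ROI keeps pixels above 50% of that maximum whose local relative
  gradient — central differences normalized by the local value, converted
  to %/mm through the pixel pitch — is at most 3 %/mm. All three numbers
  are parameters of `roi_params()`; they are conventions of this
  implementation, not facts about any particular clinic. Whether gradient
  normalization should be per millimeter or per pixel is equally
  convention; %/mm is the default because it is geometry-independent.
* **Pixel-wise vs region-wise averaging.** We average the per-pixel
  relative differences rather than differencing the ROI means; the two
  differ under non-uniform change, and the pixel-wise reading matches the
  metric's description as a mean of pixel differences.
* **Multi-field fractions** combine as the unweighted mean of per-field
  GDSA values, fields paired by their beam label. The ROI is segmented
  once per field on fraction 1 and frozen for the whole course.

A fraction whose field set differs from the baseline's (typically a beam
interruption) would bias the mean high; such fractions are marked
`omitted` and excluded from every downstream statistic. Fraction identity
is the calendar date of acquisition; two sessions on one date are treated
as one fraction — a documented limitation for twice-daily treatments.

## The three flag levels

* **Type-A** (`flag_type_a`): any single complete fraction with
  $|\mathrm{GDSA}_\mu| > 10\%$ — an acute, large delivery error.
* **Type-B** (`flag_type_b`): at least three *consecutive* complete
  fractions with $|\mathrm{GDSA}_\mu| > 3\%$ — a systematic trend such as
  head-and-neck weight loss or tumor shrinkage.
* **Machine** (`machine_output_flags`): the clinic-wide daily mean GDSA
  (over all complete fractions of all patients treated that day) changing
  by more than 1% between *adjacent treated days* — an output or imager
  calibration shift. The daily SD is reported alongside as a measure of
  patient variability.

Conventions fixed here: "deviation of ± X%" is strict magnitude
exceedance (equality does not flag); consecutiveness is counted over
complete fractions in date order, not calendar days; weekend and holiday
gaps do not break day-to-day adjacency; the three Type-B deviations need
not share a sign (a same-sign mode exists behind `flag_config()`). One
Type-B flag is raised per *maximal* qualifying run — not one per sliding
window — and all fractions of the run are recorded as triggers, so an
already-flagged trend does not re-alert every night. Every flag can be
materialized as a report bundle (`build_report()`): a deterministic
`summary.json` with the full trace, a trace plot, and baseline/trigger
difference panels when images are supplied. E-mail and QA-portal upload
are intentionally replaced by this file-based outbox; a deployment can
watch the directory.

## Replan-trigger rules

For head-and-neck courses, where anatomy change dominates, the package
evaluates five threshold rules against the physician's replan decision as
ground truth (`apply_rule`, `evaluate_rules`): one fraction > 3% (A), one
fraction > 2% (B), two fractions > 2% (C), and the last two restricted to
exceedances *before the final five fractions* (D, E). Exceedance is
signed positive — anatomy loss raises the transit signal, and a negative
deviation does not motivate a replan; "two fractions" need not be
consecutive. Tabulated sensitivities and specificities use two-decimal
*truncation* (`truncate_decimal`), the convention evident in the reference
tabulation (105/133 = 0.789 → 0.78).

## The synthetic-image generator

Because clinical portal images cannot be redistributed, validation runs
entirely on synthetic courses (`generate_course`, `simulate_clinic`) with
an analytic ground-truth log. The physics is deliberately first-order:

$$I(p) = \mathrm{CU}_\mathrm{open} \cdot s_f \cdot
  e^{-\mu\, t_f(p)},$$

an open-field fluence attenuated exponentially (μ = 0.05 cm⁻¹ ≈ water at
6 MV) through an elliptical water-equivalent phantom, Gaussian edge blur,
and multiplicative per-pixel Gaussian noise truncated at zero
(flood-field-corrected panels have approximately uniform *relative*
noise). Machine output enters as the per-fraction scale $s_f$ — drift,
acute spikes, sustained trends, or a clinic-wide per-day step — and
anatomy change as a uniform thickness delta $\Delta t$ inside the phantom
shadow. The expected GDSA of fraction $f$ on the plateau is then closed
form:

$$\mathrm{GDSA}_\mu^{\mathrm{expected}} =
  100\left(\frac{s_f}{s_1} e^{-\mu \Delta t_f} - 1\right),$$

which the generator logs per fraction. The default phantom's semi-axes
(300 mm at isocenter) *cover the whole panel projection* so that the
automatically segmented ROI lies on the attenuated plateau where this
formula holds; smaller phantoms render with an unattenuated open-field
ring outside their shadow, which is useful for visual inspection but
places the 50% plateau threshold on the open field instead. The generator
emulates neither scatter, MLC modulation, imager lag, nor localized
anatomy change (a spatially uniform thickness delta is a deliberate
simplification) — so passing tests demonstrate the *analysis chain* is
correct, not that the physics model is clinically complete.

There is one second-order effect worth knowing: with noise on both the
baseline and the fraction, $E[(1+\epsilon_f)/(1+\epsilon_b)] \approx
1 + \sigma^2$, so a noisy relative-difference estimator carries a positive
bias of $100\sigma^2$ percentage points (0.01 pp at 1% pixel noise). This
is far below every threshold but visible when averaging thousands of
synthetic fractions; the validation suite compares step-recovery estimates
at the scale of the estimator's standard error for this reason.

## File formats and interchange

Images are read and written as DICOM RTIMAGE (Explicit VR Little Endian,
16-bit unsigned pixels, per-file rescale slope `max CU / 65535`, which
bounds quantization error at half a slope). The reader validates
modality, identity tags and pixel data, and rejects anything else with
classed errors; a documented text fallback (matrix + JSON sidecar)
provides language-portable fixtures. Identity lives in standard tags —
PatientID, SeriesDescription (plan), RTImageLabel (field),
AcquisitionDate/Time — fixed in one constants table shared by reader and
writer. Sorting uses tags only, never file names. Batch runs are
idempotent: unchanged inputs reproduce byte-identical CSV/JSON artifacts.

## Problem sizes used in validation

The test and validation suites run the full pipeline on scaled-down
geometries (24–48 px matrices over the same 43 × 43 cm panel) — the
analysis is resolution-independent and a whole course renders in
milliseconds at that size, which lets the suite afford 50–100 independent
random seeds per detection scenario: 50 seeds each for the +12% spike,
the 3-fraction +4% trend, and the clean-course false-alarm rate at 0.5%
pixel noise, and 100 seeds for the +1.5% clinic-day output step over 20
patients at 1% noise. Clinical-resolution (1280 × 1280) defaults remain
the package defaults.

## Known limitations

* Errors present already at fraction 1 are invisible by construction —
  the baseline defines them away; so are changes between simulation
  imaging and the first fraction.
* Calendar-date fraction identity folds twice-daily sessions into one
  fraction.
* The daily machine statistic is sensitive to small clinics: a few
  strongly deviating patients can move the daily mean by more than 1%
  without any output change (the reference cohort saw exactly this).
* The generator's uniform-thickness anatomy model cannot produce
  ROI-partial changes; localized-change variants (shrinking ellipse) can
  be composed from `phantom_model()` but are not exercised by the
  acceptance suite.

## A worked example

```{r example, eval = FALSE}
library(epidwatch)

ph  <- phantom_model()
cfg <- course_config(n_fractions = 10, noise_sd_percent = 0.5,
                     geometry = imaging_geometry(matrix_px = c(64, 64)))
sim <- generate_course(ph, cfg, error_injection("TREND", 5, 4, 3))

records <- course_gdsa(sim$series)
flag_type_b(records)          # one TYPE_B flag, fractions 5-7
autoplot(records)             # trace with +/-3% and +/-10% bands
```
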