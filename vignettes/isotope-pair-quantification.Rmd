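---
title: "Isotope-pair MALDI-TOF quantification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotope-pair MALDI-TOF quantification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isopair)
```

## The measurement model

`isopair` quantifies a peptide by co-analyzing it with an internal
standard that is the same molecule except for its N-terminal acetyl group:
the heavy acetyl carries one ¹³C and three ²H, a +4.0222 Da shift
(nominally +4 unit masses). The method rests on three assumptions:

1. **Equal response.** Light and heavy forms have the same probability of
   desorption/ionization and detection, so the ratio of their peak areas
   equals the ratio of their molar amounts in the spot.
2. **Envelope separation.** For peptides up to roughly 1.5 kDa the natural
   isotopologue envelope carries nearly all its abundance at offsets
   k = 0–3, so a +4 spacing leaves the heavy monoisotopic peak essentially
   free of light-envelope signal. `overlap_risk()` reports the residual
   k ≥ 4 abundance; for heavier analytes `correct_overlap` subtracts the
   predicted tail (see below).
3. **Single charge.** MALDI of peptides is dominated by singly charged
   H⁺/Na⁺/K⁺ adducts; multiply charged species are out of scope.

Concentrations then follow from a spiked reference: an assay aliquot mixed
1:1 with a heavy spike of known concentration has
`C_light = ratio × C_spike`. A transwell assay uses two spikes, R-fold
apart (defaults 200 µM donor, 2 µM acceptor, R = 100), and

`T = (ρ_A/ρ_D) (1/R) (V_A^W/V_D^W) × 100 (%)`.

### Dimensional consistency of the ratio form

Writing the measured donor ratio as `ρ_D = C_D/(R·C_spike,A)` and the
acceptor ratio as `ρ_A = C_A/C_spike,A`, substituting into the amount
definition `T = C_A V_A / (C_D V_D) × 100` forces the explicit `1/R`
factor above. An alternative arrangement that treats the `1/R` as already
absorbed into the measured donor ratio is algebraically tempting but,
applied to measured ratios, overstates T by a factor R (400 % instead of
4 % in the worked scenario). We implement the dimensionally consistent
form as the default and keep the other arrangement behind
`transport_maldi(..., as_printed = TRUE)` for auditability; the test suite
pins the default to the amount-based definition to within 1e-9 relative on
simulated assays.

## Envelopes and masses

Isotope masses and abundances (IUPAC 2021) are embedded in the package so
results do not depend on external resources. Envelopes are computed by
per-element convolution over nominal mass offsets k and aggregated in
unit-mass bins, matching what unit-mass-resolved MALDI-TOF can see; the
m/z reported per bin is the abundance-weighted mean of the isotopologues
in it. The computation is checked against exhaustive isotopologue
enumeration for small formulas (≤ 1e-9 per peak). Labeled positions are
modeled as pseudo-elements (¹³C, ²H at abundance 1), not as perturbed
natural abundances, because the labeled positions are chemically defined.
D-amino acids share the composition of their L-forms; the built-in residue
table covers the 20 canonical residues and non-natural residues are
supplied by the user (the packaged `residues_synthetic.csv` is an
illustrative stand-in, not measured chemistry). Adduct m/z includes the
electron-mass correction — sub-mDa correctness costs nothing.

## The synthetic-spectrum generator

`simulate_spectrum()` emulates a reflector-MALDI profile spectrum: every
species × adduct × isotopologue contributes a Gaussian whose area is
molar abundance × adduct fraction × isotopologue abundance ×
`intensity_scale`, with FWHM = m/z / resolution. Defaults: resolving
power 10000 (reflector class for ~1 kDa peptides), sampling step 0.01 Da
(several points per FWHM at 1 kDa, so trapezoidal areas converge), adduct
fractions H:Na:K = 1 : 0.3 : 0.1 (qualitative match to protonation-dominated
spectra of hydrophilic peptides), a constant baseline (2) with additive
Gaussian noise (sd 1) and an optional intensity-proportional noise term
(coefficient 0 by default). Light and heavy species are generated with
identical efficiency — the method's premise, and the reason simulated
spectra are a fair substrate for testing the estimator rather than the
premise itself.

What the generator does **not** emulate: matrix and chemical background
peaks, detector saturation and dead time, calibration drift beyond what
the matching tolerance absorbs, spot-to-spot heterogeneity, isotope
effects on ionization, and in-source decay. Passing tests therefore show
that the computational chain is exact and robust under the stated noise
model, not that real spectra meet the model's assumptions.

Dilution series derive one child seed per member from `(seed, i)` so
members are independent but the whole series reproduces bit-identically.
`simulate_dilution_series()` defaults to the serial 1/3 protocol: 200 µM
through eleven dilutions down to ~1.1 nM, heavy internal standard at twice
the light concentration throughout.

## Peak picking and the ratio estimator

Peaks are local maxima above `snr_threshold` (default 3) times a robust
noise level — 1.4826 × the median absolute deviation of intensities after
excluding the top 5 % — over a median baseline; the strongest candidate
wins within a `window` (default 0.3 Da) exclusion zone. The centroid is
the intensity-weighted mean m/z and the area the trapezoidal integral of
baseline-subtracted intensities within ± window.

Matching assigns, for each offset k = 0..`k_range`−1, the nearest picked
peak within `tol` (default 0.15 Da, unit-mass resolution with calibration
drift) of the theoretical m/z; ties break toward lower m/z and a peak
serves at most one offset. The default `k_range = 3` uses the
high-abundance peaks while staying inside the overlap-free zone the +4
label guarantees for light peptides. Quantification uses **areas**, not
apex heights (an apex mode exists behind `use = "apex"`); by default only
the [M+H]⁺ adduct is summed, since adduct propensity varies spot to spot
even when equal between light and heavy — Na/K can be enabled when spots
are well behaved, and per-adduct ratios are reported alongside the
combined one.

Because the label removes one natural carbon and three natural hydrogens,
the light and heavy envelopes differ slightly; each species' summed area
is therefore normalized by its own theoretical envelope coverage over the
matched offsets before the ratio is formed. This also makes the estimator
robust to an occasional missing offset. Overlap correction
(`correct_overlap = TRUE`) subtracts from the heavy response at offset j
the predicted light contribution `light(k=0) × a(4+j)/a(0)`; it is off by
default because the label design makes it negligible for the target
peptides, and results that would go negative are clipped to zero and
flagged. A spectrum with no heavy match is an error by default ("internal
standard missing"), configurable to `NA` for batch series; a spectrum with
heavy but no light yields ratio 0 with a below-detection flag.

## Transport, permeability, PAMPA

Unit conventions are fixed package-wide: volumes in µL (converted to cm³
internally), time in seconds for Papp and hours for Pe (the 218.3 constant
of the double-sink PAMPA formula expects hours and a base-10 logarithm),
concentrations in µM, amounts in pmol. The transwell membrane area is
required configuration — 1.12 cm² (a standard 12-well insert) by default —
and is echoed in output provenance. Papp uses the single-timepoint
initial-slope form; multi-timepoint slope fitting is out of scope. The
PAMPA formula requires `2 C_A(t) < C_D(t0)`; at or beyond that
equal-concentration equilibrium the single-timepoint form has no finite
solution and the function errors. Classification: poor < 2×10⁻⁶ cm/s ≤
uncertain ≤ 4×10⁻⁶ cm/s < excellent.

## Limit of quantification

Responses are `R_i` = light/heavy ratio (MALDI) or `A×d/V` (HPLC: area ×
fold-dilution / injected volume; this reading of the three symbols is the
one consistent with a dilution-corrected response). The reference mean
excludes the trailing most-dilute members — 1 in MALDI mode, 5 in HPLC
mode, matching the two protocols' different dynamic ranges — and
deviations are `(R_i/R̄ − 1) × 100 %`, thresholded two-sided at 8 % by
default.

The decision rule is a genuine design choice: we call the LOQ as the
lowest concentration such that **every** member at or above it stays
within the threshold (members with missing responses count as failing),
the strictest rule consistent with a series that degrades monotonically at
its dilute end; a per-member rule (lowest individually passing member) is
available via `rule = "per_member"`. If all members pass, the LOQ is the
lowest tested concentration with an explicit "below lowest tested" flag —
the series did not reach the limit. Raising the threshold can only lower
the called concentration, a property the tests exercise.

## Numerical choices and degenerate inputs

* Envelope truncation: patterns are pruned past the last offset reaching
  `truncation` (default 1e-6 for simulation, 1e-8 for quantification) and
  renormalized to sum exactly to 1.
* Gaussians are rendered to ± 8 σ; with step ≤ FWHM/10 the integrated area
  matches the intended area to well within 0.1 %.
* Noiseless spectra have a zero noise estimate; the SNR filter then
  reduces to "apex above baseline", and reported SNR is `Inf`.
* Empty spectra, empty species lists, and m/z windows that exclude all
  peaks are all legal: they produce empty peak lists, zero/baseline-only
  spectra and a recorded warning, never crashes.
* Subtracting compositions below zero, non-positive donor quantities,
  dilution factors ≤ 1, and equilibrium-exceeded PAMPA inputs are errors
  with named messages.

## Problem sizes used in the checks

The packaged tests and the acceptance script run entirely on synthetic
data at desk scale: single spectra of a few thousand grid points, ratio
grids spanning 0.01–100, 200 seeded replicates for the 1 %-noise recovery
rate, and 100 seeded six-member dilution series for the planted-LOQ
recovery rate. These sizes make the stochastic rates stable without
requiring long runs.

## Known limitations

Charge states above +1, fragmentation, fine isotope structure within a
unit-mass bin, TOF detector effects, recalibration and general baseline
estimation beyond a constant-plus-noise model are not modeled. The LOQ
procedure is the dilution-series deviation definition only — formal LOD
(3σ) and calibration-curve (10σ/slope) definitions are different
quantities and deliberately out of scope. Biological conclusions (whether
a given shuttle crosses a given barrier) require wet-lab data; this
package supplies the quantification arithmetic, not the biology.
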