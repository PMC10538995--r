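---
title: "Methods: fiber-type-specific redox quantification and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fiber-type-specific redox quantification and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiberredox)
```

This vignette documents the models and procedures implemented in
`fiberredox`, the assumptions behind them, the parameters that matter,
what the simulators do and do not emulate, and the numerical choices
made where the design was genuinely open.

## The optical redox ratio

Reduced NADH autofluoresces under UV excitation and oxidized
FAD-containing flavoproteins (Fp) under blue excitation; both signals
are dominated by mitochondria. The per-fiber redox state is

$$\mathrm{ratio} = \frac{F_p}{F_p + \mathrm{NADH}} \in [0, 1],$$

dimensionless and scale-invariant: multiplying both intensities by a
common positive factor (exposure, gain, light-source drift affecting
both channels equally) leaves it unchanged. It is undefined only when
both intensities are zero; such fibers are dropped with a warning.

**Aggregation order matters.** The ratio is computed per fiber and then
averaged within type ("mean of ratios"). The alternative — the ratio of
type-mean intensities — is a different estimator (the package asserts
the difference on a constructed counterexample in its tests) and does
not correspond to per-fiber dot plots. `summarise_by_type()` therefore
always averages per-fiber ratios.

**What is not modeled.** NADPH is spectrally indistinguishable from
NADH at these wavelengths, and non-dehydrogenase flavoproteins
contribute to the Fp band; no spectral unmixing is attempted. Collagen
autofluorescence is addressed operationally: the collagen stained-area
fraction (`collagen_fraction()`) quantifies how much stained
extracellular matrix is present so its contribution can be bounded, not
subtracted.

## Per-fiber quantification

The per-fiber "relative intensity" is the mean of interior pixels minus
a scalar background, floored at zero (arbitrary-unit intensities cannot
be negative; floored fibers carry a flag so they remain auditable). The
mean matches standard densitometry; a median option exists for
hotspot-heavy channels. The background is the median intensity of
pixels outside all fiber ROIs after dilating the ROIs by 2 px, which
keeps partial-volume edge pixels out of the estimate; if the dilated
ROIs tile the whole field there is nothing to measure and an explicit
value is required.

Exposure standardization is enforced as a metadata equality check
rather than a numeric correction: intensities acquired under a
different exposure/gain than the section's reference acquisition are
refused unless an explicit rescale factor is configured. This mirrors
acquisition-time standardization instead of attempting to correct for
it computationally. Fibers containing any pixel at the detector's
saturation level are flagged.

SDHA and citrate synthase channels flow through exactly the same
operation (`quantify_fibers()`) under their own channel labels.

## Fiber typing

Fibers are segmented by thresholding each available channel (Otsu on
the pixel intensities, per channel) and taking the union of the
foreground masks, filling holes, and splitting touching fibers by
watershed on the distance transform. Per-channel thresholding is
essential: type IIx fibers are negative on both MHC stains and are
visible only on an autofluorescence channel, so a pooled threshold
would miss them — pass NADH or Fp as the `hint` channel, the in-silico
analogue of tracing fibers on the accompanying autofluorescence image.
A contrast guard (the Otsu split must separate class means by more than
four within-class standard deviations) prevents a blank, noise-only
channel from being split down the middle.

Typing uses per-ROI **median** interior intensity (robust to nuclear
hotspots) against per-channel positivity cutoffs, by default Otsu on
the per-ROI medians (`auto_threshold()`); the cutoff is deterministic
and affine-equivariant, and falls back to a user-supplied value with a
warning when the score distribution is not usefully bimodal. The rules
are: MHC I+/IIa− → I; I−/IIa+ → IIa; double negative → IIx; double
positive → hybrid, excluded from every downstream statistic. A score
exactly at the cutoff counts as negative (conservative positivity).
Fibers clipped by the field of view are flagged and excluded from area
and intensity statistics (their area is censored). The minimum fiber
area (default 500 µm²) rejects debris.

## Capillarization morphometry

Capillaries are detected as connected bright blobs in the
capillary-stain channel within an equivalent-diameter range (default
2–8 µm); oversize blobs are flagged as possible merges and kept as one
detection. The contact graph links a capillary to a fiber when its
centre lies within the contact tolerance of the fiber's nearest pixel.
The default tolerance is 8 µm — about one capillary diameter — chosen
to span the extracellular gap the simulator renders between abutting
fibers (3 px per side at 1.5 µm/px) without bridging to non-adjacent
fibers; it is configurable for other gap widths.

From the graph: CD = capillaries per analyzed mm²; C:F = capillaries /
fibers; CC = mean contact degree over fibers; SF = CC / C:F; CC/FA =
mean of (degree / fiber area) × 1000. The analyzed area is the convex
hull of the fiber pixels, excluding empty image margins. SF = CC / C:F
holds exactly per section by construction; cohort summaries of
per-subject values need not satisfy it, which is documented rather than
asserted. A capillary touching no fiber counts in CD and C:F but
contributes no contacts. The conflicting textual definitions of CC in
the morphometry literature (contacts per fiber vs fibers per capillary)
are resolved in favour of *contacts per fiber*, the reading under which
the SF identity holds.

**Diffusion distances are geometry-first.** The maximal / average O₂
diffusion distance is defined as the distance within which 95 % / 50 %
of a fiber's area is served by its nearest capillary: the 95th / 50th
percentile of the per-pixel distance-to-nearest-capillary distribution
(Euclidean distance transform), × pixel size. A brute-force per-pixel
nearest-capillary search serves as the oracle in the tests and agrees
within 1 px. The regression forms for these distances printed in the
source literature are typographically ambiguous (exponents or operators
were plausibly lost in typesetting), so
`diffusion_distances_regression()` never hard-codes them: the user must
supply the functional form explicitly, and its output is reported
alongside — never instead of — the geometric estimate.

## The synthetic section simulator

`generate_section()` emulates one ×20 field of a vastus lateralis
cross-section. Design choices:

* **Geometry** — Lloyd-relaxed Voronoi tessellation of uniform random
  seeds (4 relaxation iterations on a stride-2 grid), eroded 3 px per
  side to carve the extracellular boundary gap. Convexity is not
  enforced; Voronoi cells are the standard stand-in for near-convex
  fibers. Default 70 fibers on 384 × 384 px at 1.5 µm/px gives fiber
  areas of roughly 2–6 × 10³ µm², the scale observed in adult human
  vastus lateralis.
* **Types** — i.i.d. draws at 45.9/44.5/9.6 % (I/IIa/IIx), the human
  fiber-type distribution, plus a 2 % hybrid rate; hybrids are rendered
  bright in both MHC channels so the exclusion rule is exercised.
* **Intensities** — per-type channel means above a uniform background,
  ordered Fp: I > IIa > IIx and NADH: I ≈ IIa > IIx with redox-ratio
  spacing of ~7–8 % between adjacent types (0.490/0.452/0.418). The
  absolute a.u. scales are free parameters: no published values exist
  for them, only the orderings.
* **Capillaries** — at tessellation junction vertices, each kept with
  probability 0.95, plus capillaries at shared fiber-face midpoints at
  rate 0.25. Junction vertices alone top out near 1.7 per fiber in any
  planar tessellation, while real muscle runs ~2.3 capillaries per
  fiber; face placement (anatomically, capillaries also run along
  fiber boundaries) brings the simulated C:F to ≈ 2.33 (2.17–2.50 over
  seeds), inside the observed human range.
* **Nuclei** — Poisson(3.7) per fiber in a peripheral band (≈ 780/mm²
  at the default geometry), rendered as discs with a minimum
  separation so counts are exactly recoverable at zero noise.
* **Noise** — additive Gaussian (default SD 8 a.u.), clipped at zero
  and at the optional saturation cap: the simplest model that
  exercises background subtraction and saturation flagging. No optical
  PSF, 3-D sectioning or photobleaching is modeled.
* **Determinism** — one integer seed drives the whole simulation via a
  scoped RNG (`withr::with_seed`); identical parameters give
  bit-identical sections and no global RNG state is disturbed.
* **Coordinates** — 1-based (row, col) pixel-centre coordinates
  throughout, the native convention of R matrices and of the installed
  image stack; areas are reported in µm² via pixel_size².

**What passing on simulations shows — and what it does not.** The
simulator plants well-separated type/channel levels (gaps of many
noise SDs), convex fibers and clean stains, so perfect typing accuracy
on it validates the *logic* of segmentation, classification and
bookkeeping, not robustness to real histology (touching fibers with
faint boundaries, uneven illumination, staining artefacts, genuinely
ambiguous hybrids). The per-fiber intensity recovery and morphometry
oracles are exact geometric checks and do transfer; classification
accuracy on real sections will be lower and should be audited against
manual tracing.

## The cohort simulator and the inference layer

`generate_cohort()` produces the long per-subject × timepoint ×
fiber-type table the mixed model assumes, with exactly its additive
structure: grand mean + type effect + time effect + N(0, σ_b) subject
intercept + N(0, σ_e) residual. Defaults encode the target study
design: 19 subjects, three timepoints (baseline, 30 min post-exercise,
3 h post), three fiber types, baseline ratio means spaced 7.2 %
(I over IIa) and 8.0 % (IIa over IIx), σ_b = 0.02, σ_e = 0.015 —
between-subject variation comparable to the planted type effects, a
realistic regime for human biopsy data. Cells can be deleted completely
at random to emulate biopsy-yield-driven missingness.

The model (`fit_redox_lmm()`) is REML via `lme4`/`lmerTest`:
`value ~ timepoint + fiber_type + (1 | subject_id)`, optionally with
interaction or sex (sex can augment or replace time, both supported,
since the published description is ambiguous on this point). The unit
of analysis is the per-subject per-type mean — fibers are aggregated
before modeling because the random structure has participant intercepts
only, no per-fiber nesting. Denominator degrees of freedom are
Satterthwaite (none are stated in the source literature). Pairwise
contrasts are estimated marginal means with Tukey adjustment over the
single factor's pairs; cross-factor contrasts are never pooled into one
family. Percent differences are ratios of marginal means, 100 × (a −
b) / b with the later-listed level as reference b, and their CIs are
the contrast CI endpoints divided by the reference mean — the
"mean-of-per-subject-ratios" alternative is a different estimator and
is not used. Tests are two-sided at α = 0.05.

Numerical edge cases: a genuinely failed optimizer is a fatal error
(after one retry with a second optimizer), but exactly-degenerate
noiseless data — zero residual variance, where the profiled deviance is
flat and the estimates are exact least squares — is downgraded to a
warning; a contrast whose estimate and SE are both numerically zero is
reported as p = 1 (a zero difference known with certainty) rather than
0/0. Spearman correlations use average ranks for ties and the
t-approximation p-value (appropriate with ties); a constant vector has
no rank ordering and yields a missing rho.

## Calibration and cohort QC

The NADH calibration fit is ordinary least squares of per-level mean
intensity on concentration over serial dilutions spanning the
physiological range (1 mM down to 0.01 mM, triplicate per level);
R² is the coefficient of determination and the interassay variability
is defined as the mean over levels of the per-level CV (SD/mean × 100)
— the published figure quotes no formula, so the definition is stated
here explicitly.

Goldberg/Black dietary-plausibility bounds are
PAL × exp(∓ s·(S/100)/√n) with S² = CV²_EI/d + CV²_BMR + CV²_PAL,
exposed with every parameter explicit; they are reciprocal-symmetric
about PAL on the log scale and collapse to PAL at zero CV. The
published cutoffs (cohort 1.18–1.55, individual 0.76–2.41) are honored
as classification defaults but are not recomputable because the
underlying cohort CVs were not published; bounds are inclusive ("between"
read inclusively). BMR is an input column or user-configured model,
never a hard-coded regression — the published coefficients are not
available. HOMA-IR is glucose[mg/dL] × insulin[mU/L] / 405, which
agrees with the molar convention within 0.5 %.

## Problem sizes used in validation

The shipped test-suite and acceptance script validate at deliberately
desk-sized scales, chosen as the smallest sizes at which each property
is sharp: 10–20 sections of ~70 fibers for typing accuracy; 100
sections for the noisy intensity-ordering rate; 10 sections plus a
hand-countable 2-fiber fixture for the morphometry oracle; 200
simulated cohorts for contrast-CI coverage and 500 for null
calibration; 10,000 random pairs for the redox algebra; 1,000 random
vectors for the Spearman oracle. The headline human results that
motivated this package (specific percent differences, p-values and
correlations from biopsy images) derive from data that were never
deposited and are intentionally not asserted anywhere; all assertions
are against planted ground truth.

## Known limitations

* Watershed segmentation assumes near-convex fibers separated by
  darker boundaries; heavily interdigitated or faintly bounded fibers
  will merge or split.
* The simulator's planted separations make classification trivially
  identifiable; it cannot certify performance on real stains.
* Capillary attribution is not fiber-type-specific (the stain-based
  contact graph cannot discern which fiber type a capillary serves).
* No deep-learning segmentation, no IIx antibody modeling (IIx is
  defined by double-negativity), no spectral unmixing of NADPH.
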