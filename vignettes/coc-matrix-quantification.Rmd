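---
title: "Quantifying cumulus–oocyte complex matrix biology: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cumulus-oocyte complex matrix biology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cocmatrix)
```

# Scope and model

Before ovulation the cumulus cells surrounding the oocyte deposit a
hyaluronan (HA)-rich extracellular matrix and the complex expands. Studying
how this process changes with age requires several quantitative readouts on
very different data: ionic-current recordings from solid-state nanopores
(HA size), confocal image stacks (matrix porosity and HA staining),
time-lapse distance series (expansion kinetics), and qPCR array Ct tables
(HA-network gene expression). `cocmatrix` implements these readouts and the
statistics used to compare age groups, together with a synthetic-data module
that generates each input with known ground truth.

# Nanopore HA sizing

**Model.** A polymer translocating a voltage-biased nanopore transiently
blocks ionic current. An event is characterized by its duration τ and its
area (event charge deficit) $A = \int (I_0 - I)\,dt$ in pA·s, where $I_0$ is
the open-pore baseline. $A$ grows monotonically with chain mass, so a
calibration curve built from HA standards maps $A$ to molecular weight (MW).
The calibration is instrument- and buffer-specific and is *input data* here;
`synthetic_power_law_calibration()` ships a stand-in power law
($A = 10^{-4}\,\mathrm{MW}^{1.2}$ pA·s, labelled synthetic) for tests and
examples.

**Detection.** The recorded trace (200 kHz sampling through a 100 kHz 4-pole
Bessel acquisition filter, 200–300 mV bias) is low-pass filtered at 5 kHz
for analysis; baseline and noise σ are estimated robustly (median and
MAD×1.4826, two-pass with provisional events excluded — the estimator is not
prescribed by convention, and a robust choice prevents event contamination).
σ is defined on the *filtered* trace because detection runs there. Events
are excursions ≥ 5σ below baseline; the integration window extends outward
to the 0.2×threshold (≈1σ) return so area is not truncated; events with
duration outside 25 µs–2.5 ms are discarded; a dataset needs ≥ 500 events to
pass QC.

**Numerical choices.**

* The analysis low-pass is a zero-phase FFT-domain filter with *Gaussian*
  magnitude response (−3 dB exactly at the corner, DC gain exactly 1). Zero
  phase keeps event centers unbiased and unit DC gain preserves areas. The
  Gaussian family was chosen over Butterworth because its impulse response is
  positive: a sharper-rolloff magnitude response rings around deep events,
  and those undershoot lobes were detected as spurious small-area events in
  early testing. A Butterworth option remains available.
* Event *duration* is measured between the half-depth (FWHM) crossings, not
  at the outer boundary crossings: a zero-phase filter smears the 1σ return
  crossings symmetrically outward, whereas half-depth crossings stay at the
  true edges for events longer than the filter's transition width
  (~100 µs at 5 kHz). Durations of events near or below that width are
  resolution-limited — at 5 kHz bandwidth a genuine 10 µs event is either
  attenuated below threshold (shallow) or smeared to the filter width
  (deep); no duration estimator can recover it. Tests that check duration
  fidelity to ±2 samples therefore run with a 50 kHz analysis filter or with
  the analysis filter disabled; acceptance-scale recovery runs use 5 kHz.
* The acquisition Bessel filter is applied causally (forward-only), as in
  hardware. At the standard settings (100 kHz corner, 200 kHz sampling) the
  corner sits at Nyquist, where the bilinear transform is singular; the
  filter is then skipped, which also keeps injected event areas exact in the
  generator.
* Calibration mapping is piecewise linear in log–log coordinates (a power-law
  fit is optional); areas below the calibrated range are flagged
  `below-calibration` — nanopores cannot reliably size HA under ~50 kDa —
  and excluded from summaries; above-range areas are excluded by default or
  clamped on request.
* "Weighted average molecular mass" is implemented as the polymer-science
  mass-weighted mean $M_w = \sum m_i^2 / \sum m_i$; the number average $M_n$
  is reported alongside, since the weighting convention is otherwise
  ambiguous.

# Synthetic traces

`gen_trace()` draws Poisson arrivals (exponential gaps plus a 1 ms guard so
events never overlap; impossibly high rates error), samples each event's
true MW from a truncated log-normal mixture, and sets the event's rectangular
dip so that depth × duration equals the calibration inverse of that MW
*exactly* (durations log-uniform in 50 µs–2 ms; depth capped at half the
baseline with the duration recomputed to preserve area; after snapping to
the sample grid the depth is again recomputed so the area stays exact).
Gaussian noise (default 2 pA) is added *before* the acquisition filter, as
on the hardware noise path. The default mixture — 0.65·lognormal(median
150 kDa, σ_log 0.55) + 0.35·lognormal(median 800 kDa, σ_log 0.55), truncated
to 50–5000 kDa — puts ~60% of chains below 300 kDa, the "predominantly
low-molecular-mass" regime of follicular-fluid HA. With these defaults the
shallowest generated events sit above 8 filtered-σ, a comfortably detectable
regime; recovery tests exercise exactly this stated world and are not
evidence about near-threshold performance.

What the generator does *not* emulate: pore clogging, folded translocations
and multi-level events, baseline drift, 1/f and capacitance noise. A green
end-to-end test establishes that detection, area integration, calibration
mapping and summarization are mutually consistent — not that the pipeline
handles every pathology of real recordings.

# Image quantification

Images are plain numeric arrays (rows × cols × z) with a pixel size in
µm/px; the on-disk container is one CSV per channel/z-plane plus a JSON
sidecar (the environment provides no TIFF codec; only the container differs
from common practice, not the information content).

* `segment_coc()`: Otsu threshold on the structural (actin) channel, 3×3
  closing, hole fill, largest connected component.
* `porosity()`: infiltrated = in-mask pixels with particle signal above a
  threshold (per-plane Otsu within the mask by default, or a fixed value for
  reproducibility across an experiment — per-image Otsu is undefined when
  the in-mask histogram is unimodal, i.e. fully excluded or fully
  infiltrated complexes). Porosity and mean intensity are computed per
  z-plane and averaged; z-aggregation is otherwise unspecified in common
  practice.
* `habp_intensity()`: the category value is the **mean of ROI means**, not a
  pixel-pooled mean — ROIs are the unit of assessment; the distinction is
  testable (ROI means {10, 20, 60} give 30).
* `place_rois()`: the conventional manual placement ("ROIs over ~5 adjacent
  cumulus cells" vs same-sized intercellular regions) is replaced by a
  deterministic proxy: candidate in-mask squares scored by DNA-channel mean;
  top scorers become cellular ROIs, bottom scorers intercellular. This is a
  stated convention for reproducibility, not a claim about the manual
  procedure.

The image generator controls the infiltrated fraction by thresholding a
smooth Gaussian random field at the matching in-mask quantile (exact to one
pixel), and adds Poisson-like noise (sd = 0.5·√intensity). It does not model
the optical PSF, 3D cell morphology, or staining heterogeneity.

# Expansion kinetics

Velocity is the signed difference quotient (µm/min); retraction stays
negative. Hourly velocities come from consecutive observations (computed
over the actual elapsed gap if frames are missing). The 4 h windows are the
hourly intervals ending in 1–4, 5–8, 9–12 and 13–16 h; the window velocity
is the **mean of its member hourly velocities** (at exactly hourly sampling
this telescopes to the endpoint quotient, and an `endpoint` option is
provided because the convention is ambiguous). Series may truncate when a
complex expands beyond the well; absent windows are omitted. The logistic
generator (default d_max 75 µm, rate 0.6 h⁻¹, horizon 16 h, noise sd 1 µm)
reproduces the observed scale: overall rate ≈ 0.077 µm/min, and inflection
times of 6.5 h vs 10.5 h shift the peak window from 5–8 h to 9–12 h — the
young/old morphokinetic contrast, qualitatively. Pre/post endpoints
(area, 4-point thickness mean, 0–4 score) are validated inputs;
`compare_groups()` tests the post-minus-pre deltas because baselines differ
between groups (difference-between-differences).

# RT² array analysis

ΔCt normalizes each gene to the arithmetic mean Ct of the five housekeeping
genes in the same sample (equivalent to geometric-mean normalization in
expression space, the GeneGlobe convention). Each replicate experiment pairs
one pooled young with one pooled old sample; ΔΔCt is the old-minus-young
contrast within a replicate, FC = 2^−ΔΔCt, and the reported value is the
arithmetic mean of replicate FCs. Cts above 35 (and undetermined wells) are
floored to 35 *before* any calculation to avoid over-calling fold changes
outside assay sensitivity; the floor is idempotent. Calls: up if avg FC
> 1.5, down if < 1/1.5 ≈ 0.667; on the log2 scale the thresholds are
±log2(1.5) = ±0.585. (A display threshold of −0.599 sometimes quoted for
down-regulation corresponds to log2(0.66), not −log2(1.5); this package uses
the self-consistent −0.585.) Down-regulated genes are also shown as signed
fold regulation (−1/FC) for display, but thresholds always apply to the
decimal FC.

# Statistics

* **Two-group gate:** Shapiro–Wilk on each group at α = 0.05 decides between
  Welch's t-test and Mann–Whitney U. Kolmogorov–Smirnov p-values are
  reported for information only — with two candidate normality tests and no
  stated combination rule, one test must govern, and Shapiro–Wilk has the
  better power at these sample sizes.
* **Nested t-test:** COCs from one animal are correlated, so inference runs
  on cluster (animal) means: Student's t with equal variances and
  df = n_clusters − 2. For balanced designs this equals the nested-ANOVA
  formulation; the variance weighting that commercial implementations apply
  to *unbalanced* clusters is not reproduced — cluster means are the stated
  convention here. Simulation (200 runs, intra-cluster correlation 0.5, no
  effect) shows the nested test holds its size (rejection ∈ [0.01, 0.10])
  while the naive per-observation t-test rejects far above nominal.
* **Box-Cox:** $y_{new} = (y^{\lambda} - 1)/\lambda$ with λ = −0.4242 (the
  value used for follicular-fluid HA polydispersity), strictly increasing,
  with an exact inverse.
* **ANOVA + Tukey:** omnibus F across ≥3 groups, Tukey HSD pairwise
  comparisons, compact letter display via insert-and-absorb (groups sharing
  no letter differ significantly).
* **Categorical:** Fisher's exact test when any expected count is ≤ 5
  (the chi-square approximation needs expected counts above 5; the boundary
  case goes to the exact test), chi-square otherwise; the rule applied is
  recorded.
* **4PL calibration:** least-squares `nls` fit of
  $y = d + (a-d)/(1+(x/c)^b)$ with data-driven starting values (asymptotes
  from the extreme standards, slope from a logit-log regression); inversion
  maps readings to concentrations and flags readings outside the open
  interval between the asymptotes instead of extrapolating.

# Degenerate inputs and tie-breaks

Zero-noise traces make the 5σ threshold vanish; detection then requires an
explicit absolute floor (`abs_floor_pa`) and errors otherwise. Identical
samples give p = 1. Constant groups give F = 0 and a single shared letter.
Equal-area calibration nodes are rejected at construction. ROI placement is
seeded and therefore reproducible; ROIs are square, odd-sized, and must fit
entirely inside the mask.

# Known limitations

* The nanopore path models single-level rectangular events only; folded
  translocations and multi-level substructure are out of scope.
* Sub-50 kDa HA is flagged, never sized — a physical limit of the method,
  mirrored by the calibration contract.
* The nested test's unbalanced-design behavior is the cluster-means
  convention, not a mixed-model fit (`lme4` would be the escalation path).
* Image analysis assumes one COC per field; instance segmentation of
  touching complexes is not attempted.
* The synthetic generators state a *world*, with defaults chosen once to
  match the scales above; green tests certify internal consistency at those
  stated conditions, not performance on real microscopes, arrays, or pores.
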