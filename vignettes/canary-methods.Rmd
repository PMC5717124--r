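---
title: "Methods: exemplar-based risk quantification of pure ground-glass nodules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exemplar-based risk quantification of pure ground-glass nodules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Pulmonary adenocarcinomas that appear as pure ground-glass nodules (GGNs) on
CT range from non-invasive adenocarcinoma in situ (AIS) through minimally
invasive adenocarcinoma (MIA, invasive focus ≤ 5 mm) to invasive
adenocarcinoma (IAC, focus > 5 mm). Histology only becomes available after
resection, so a quantitative image marker of invasiveness has direct
management value.

The marker implemented here is texture-compositional. Local texture is the
9×9 in-plane window of Hounsfield units around a voxel, read as a vector in
ℝ⁸¹. Nine reference textures ("exemplars") are learned from training
patches, each exemplar carries one of nine colour codes, and the colours are
pooled into three risk components:

* **low risk** — blue, green, cyan (the three least dense exemplars),
* **intermediate risk** — pink, yellow,
* **high risk** — violet, indigo, red, orange.

Every in-mask voxel is labelled with the colour of its nearest exemplar
under the similarity $s(x, y) = -\lVert x - y\rVert^2$; a nodule is then
summarised by the absolute (mL) and relative (%) volume of the three
components, and invasiveness is called when the low-risk percentage is at or
below a cutoff (default 45 %, inclusive).

### Assumptions

* The nodule segmentation is given; the package never segments.
* Texture is two-dimensional (in-plane). Section thickness in chest CT
  (0.625–1.5 mm) differs from in-plane spacing, so cross-slice windows
  would mix anisotropic scales.
* Density rank is a meaningful risk proxy in *pure* GGNs: invasive tissue
  is denser than lepidic ground-glass, which is denser than aerated lung.
  The original clinical tool anchored its colour-to-risk map in histological
  correlation; that calibration is not reproducible from published material,
  so this package assigns colours by ascending mean exemplar HU (the
  observable those overlays display) and accepts a user-supplied exemplar
  file to override the mapping.

## Exemplar learning

Affinity propagation (AP) clusters the training patches by
responsibility/availability message passing (implemented in C++), with the
shared preference on the similarity diagonal controlling the number of
clusters. Defaults: damping 0.9, at most 1000 sweeps, convergence after 50
sweeps of an unchanged exemplar set. The preference is tuned by bisection
until exactly nine exemplars emerge, starting from the bracket [minimum
similarity, median similarity]. When training textures form widely separated
tight clusters even the minimum similarity can leave more than nine
exemplars, so the lower end of the bracket is extended geometrically (×4
steps) before tuning is declared infeasible. Two numerical safeguards: a
seeded, vanishingly small jitter ($10^{-12}$ of the similarity range) breaks
the symmetric oscillations AP is known for, and a fully degenerate input
(all pairwise similarities identical) is answered directly with the
net-similarity optimum instead of message passing. Exact ties — midway
patches, equal mean HU — break by the fixed colour order C, B, G, P, Y, O,
R, I, V and by first occurrence, so learning and classification are
deterministic functions of the input and seed.

## Classification and aggregation

Patch windows are edge-clamped (border rows/columns replicated) so voxels
near the image border have well-defined textures, and the window draws on
the full volume: the centre voxel must be inside the segmentation, the
window may reach into surrounding lung. Component volumes use the exact
voxel volume from the (slice, row, column) spacing — no resampling — so the
three absolute volumes sum to the segmented volume to within floating-point
error (tested at 1e-9 relative) and percentages sum to 100 within 1e-6.
Voxel indices are 1-based throughout, R's native convention.

## Synthetic data: what it emulates and what it does not

No patient images ship with the package; two generators make the pipeline
testable.

**Cohort tables** (`simulate_cohort()`). Per-subtype component percentages
are drawn from normal distributions truncated to the published per-subtype
ranges (e.g. AIS low-risk 78.5 ± 17.6 %, range 45.2–100 %), then
renormalised to sum to 100: proportional scaling followed by clamping to the
ranges, with any residual spread over components with slack — so sums are
exact *and* every draw respects its range (the AIS high-risk share stays in
0–0.1 %). Invasive focus sizes are 0 (AIS), uniform on (0, 5] mm (MIA) and
(5, 15] mm (IAC), rank-coupled within subtype to the intermediate-plus-high
share, which reproduces the positive cohort-level Spearman correlation
between focus size and high-risk share without inventing a parametric joint
model. Component mL values apply the percentages to a drawn total volume
(truncated normal with moments summed from the per-component mL summaries);
the published mL and % marginals are therefore both honoured only
approximately through that coupling, as the underlying joint distribution
is unpublished. Because the AIS low-risk range is bounded below at 45.2 %,
every simulated cohort gives specificity = PPV = 1 at the 45 % cutoff —
this is a property of the published distributions, not of a tuned
generator.

**Phantoms** (`simulate_nodule()`). A phantom is aerated-lung background
(HU ~ N(−870, 40)) with an ellipsoidal lepidic nodule (N(−650, 50)) and,
for invasive subtypes, a central solid sphere (N(−150, 80)), smoothed with
a separable Gaussian (0.8 mm). The HU levels are configuration constants
chosen to reproduce the density contrast of the three tissue classes, not
measurements. Default spacing 0.7 × 0.7 mm in-plane, 1.25 mm sections;
diameters drawn near the reported cohort mean 14.4 ± 5.3 mm. Phantoms
contain no vessels, airways, pleural contact or scanner/kernel effects, so
passing end-to-end tests demonstrates internal consistency of the method on
idealised density structure — not clinical performance.

**Training sets** (`simulate_training_set()`). 774 patches from 37 phantoms
(the size of the original exemplar-derivation set) whose lepidic density
sweeps −800 to −150 HU. Patch centres are restricted to nodule interiors
(whole window in-mask): if boundary patches join the training set, exemplars
become spatial-gradient patches and the nearest-exemplar rule loses its
density monotonicity — adding a denser focus could then *raise* the low-risk
share, which contradicts the method's core semantics. With interior-only
training the learned exemplar means span the density axis nearly uniformly
and classification is monotone in density (tested on paired phantoms).

### Resolution limit of the focus

At the default spacing and smoothing, a focus below roughly 2.5 mm changes
at most one or two voxels and is averaged away by the 9×9 window — it is
radiologically occult to this (or any) texture method. End-to-end ordering
checks therefore use detectable MIA foci (3–5 mm); the cohort generator
keeps the full (0, 5] mm range, which is one reason the threshold rule has
modest sensitivity, mirroring the known false-negative MIA case whose
low-risk share sits well above the 45 % cutoff.

## Statistics

Kruskal–Wallis (tie-corrected, chi-square approximation) comes from
`stats::kruskal.test`; degenerate all-equal input returns H = 0, p = 1.
Conover–Iman post-hoc comparisons are implemented from the standard
formula — $t = (\bar R_i - \bar R_j) \big/ \sqrt{S^2 \tfrac{N-1-H}{N-k}
(\tfrac1{n_i} + \tfrac1{n_j})}$ on $N-k$ degrees of freedom — and reported
unadjusted by default (a Bonferroni flag exists); no installed package
provides this test, and the test suite checks it against an independently
coded evaluation. Spearman correlations use mid-ranks with the t
approximation and a Bonferroni family of six by default (three components ×
{volume, percentage}). Diagnostic intervals are exact Clopper–Pearson Beta
quantiles; the choice is forced by the published degenerate bounds, which
equal $(\alpha/2)^{1/n}$ exactly. Metrics with empty denominators are
reported as missing, never as zero.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use: 774 training patches / 37
phantoms for exemplar learning (run once and cached per session), 40
phantom triples for the ordering check, 100 simulated 64-nodule cohorts for
the specificity check, and ≤ 10³-voxel masks for brute-force equivalence —
sizes chosen so the whole suite completes in a few minutes on one core
while keeping every estimate comfortably inside its tolerance. All
randomness flows from explicit integer seeds; the pipeline derives
per-stage substreams (seed × 1000 + stage) and records them in its
manifest, and generators save and restore the caller's RNG state.

## Known limitations

* The colour-to-risk calibration is density-rank-based, not
  histology-anchored; absolute component percentages are therefore not
  comparable to the clinical tool's output on real patients.
* DICOM support covers uncompressed little-endian single-frame CT series
  only; no sequences, no encapsulated transfer syntaxes, no DICOM-RT/SEG.
* Phantom realism is deliberately minimal (no anatomy, no scanner
  modelling); sensitivity estimates on synthetic cohorts reflect the
  generator's assumptions, in particular the sub-resolution focus limit.
* The published per-nodule data behind the threshold table are unavailable,
  so sensitivities at intermediate cutoffs cannot be reproduced — only the
  structural guarantees (monotone sweep, exact intervals, 100 % specificity
  at ≤ 45 %) are checked.
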