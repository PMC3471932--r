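---
title: "Methods: differential mitochondrial toxicity screening with SCRIT vectors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential mitochondrial toxicity screening with SCRIT vectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement model

The package analyses multi-parametric high-content screens of
mitochondrial toxicity. A 96-well plate of HepG2-like cells is imaged in
three fluorescence channels: Hoechst33342 (nuclear segmentation and
morphology), TMRM (mitochondrial membrane potential, MMP), and TO-PRO-3
(plasma-membrane integrity, hence viability). Each segmented cell
contributes seven features: TMRM peripheral integral and max pixel
intensity, Hoechst integral and mean intensity, nuclear area and
circularity, and TO-PRO-3 mean intensity.

Cell populations respond to toxicants with distribution shifts that are
rarely Gaussian and sometimes bimodal, so per-well summaries are built
from distribution comparisons rather than means:

* **Signed KS distance.** For each intensity/morphology feature, the well
  is compared with the plate-pooled negative-control (vehicle) cells via
  the maximum signed difference between empirical CDFs,
  `D = F_ref(x*) - F_sample(x*)` at the point `x*` maximizing the
  absolute difference. `D` is negative when the treated population shifts
  to lower intensities (the FCCP direction for TMRM) and positive for
  increases (the nicardipine-like inverse-TMRM phenotype). `D` is exact
  (computed over all jump points, no asymptotic approximation), lies in
  [-1, 1], and is invariant under monotone transforms of the intensity
  scale -- which is what makes wells and plates comparable without
  further normalization.
* **Viability fraction.** TO-PRO-3 is informative only as a binary
  (membrane compromised or not), so it is gated: the fraction of cells at
  or below the gate is the live fraction, rescaled to `2f - 1` so that
  -1 = all dead and +1 = all live matches the KS range.

A **SCRIT vector** (specialized cell response to induced toxicity)
concatenates these per-well statistics over parameters x growth media x
doses in a fixed order (parameter-major, glucose medium before galactose,
doses ascending). The standard shapes are 40 components (TMRM KS +
viability, 10 doses, 2 media), 60 (adding Hoechst-mean KS), and the
single-dose 7-parameter primary-screen vector of 14 components.

The differential design is the scientific core: galactose-substituted
(glu-) medium forces cells onto oxidative phosphorylation, so compounds
whose toxicity is buffered by glycolysis reveal themselves by the
*difference* between their glu+ and glu- response blocks, not by either
block alone.

## Classification

Compound replicates are clustered as separate items. Pairwise similarity
is the Pearson distance `1 - r` between SCRIT vectors (scale-free, so a
weak but congruent dose-response profile clusters with its stronger
sibling); the single-dose primary screen uses Euclidean distance, where
amplitude *is* the signal. Average-linkage agglomeration (the linkage is
configurable) and classical (eigendecomposition) MDS -- chosen over
stress majorization because it is deterministic -- provide the dendrogram
and the 2-D/3-D maps. Flat clusters at a configurable cut (default k = 5)
are labeled by matching each cluster medoid against analytic reference
fingerprints of the five mechanistic groups (I direct mitochondrial
toxins, II glucose-independent toxins, III glucose-dependent toxins,
IV inactive, V uncouplers); a medoid farther than a Pearson distance of
0.8 from every reference is labeled `other` for manual review.

Two rules guard data quality:

* **Activity cut-off (primary screen).** A compound is active when any of
  its 14 components moves by at least 20% -- |KS| >= 0.2, or a rescaled
  viability change of >= 0.4 against the in-plate control viability
  (20 percentage points of live fraction). The call is made on the
  replicate-mean vector; inactive compounds are assigned group IV.
* **Replicate consistency (secondary screen).** Any replicate pair of a
  compound with Pearson distance > 0.2 flags the whole compound as an
  outlier and removes it from clustering.

Plate quality is tracked by a KS-based Z' factor:
`Z' = 1 - 3(sigma_p + sigma_n) / |mu_p - mu_n|` computed on per-well
|KS| of TMRM peripheral integral for the positive (75 uM FCCP) and
negative (DMSO) control wells, each against the pooled negative control.
Z' here is a reproducibility monitor, not a pass/fail screen statistic.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| segmentation threshold | 2500 | a.u. | fixed instrument protocol value, held constant across a screen |
| smoothing filter | 5 x 5 box | px | protocol low-pass before thresholding |
| nuclear area filter | 20-250 | um^2 | removes debris (<20) and clumps (>250) |
| contour expansion | 4 | px | primary-contour growth before intensity integration |
| peripheral ring | 14 | px | perinuclear band quantifying cytoplasmic TMRM |
| TO-PRO-3 gate fallback | 10^3.25 ~ 1778 | a.u. | default gate when the plate histogram is not convincingly bimodal |
| min cells per well | 50 | cells | wells below are excluded from statistics with a reason |
| activity cut-off | 0.2 | KS units | primary-screen activity rule |
| replicate outlier bound | 0.2 | Pearson distance | secondary-screen consistency rule |
| flat-cut clusters `k` | 5 | -- | the five mechanistic groups; exposed because the cut is a judgment call |

## The synthetic plate simulator

No raw screen data are deposited, so the generator stands in for the
instrument. It is a first-class, tested component, not a fixture:

* Channel intensities are log-normal around Hill-modulated medians
  (`effect x dose^h / (dose^h + ec50^h)`), reflecting positive,
  right-skewed fluorescence distributions. Negative effect values model
  intensity increases (inverse-TMRM; Hoechst condensation).
* Hoechst integral is derived as mean x nuclear pixel area (DNA content
  is approximately conserved under condensation, so condensation raises
  the mean while the integral barely moves).
* TO-PRO-3 is a two-component log-normal mixture with live/dead medians
  10^2.5 and 10^4 a.u. bracketing the 10^3.25 gate; the dead fraction
  follows its own Hill curve.
* Well-to-well effects are log-normal multipliers per channel group:
  sigma 0.07 for TMRM (the volatile, potential-sensitive stain -- the
  reason the plate Z' is TMRM-based), 0.04 for Hoechst, 0.02 for nuclear
  morphology. The TMRM value was chosen, together with the uncoupler's
  glucose-medium TMRM effect (0.60), so that a simulated 48/48 control
  plate at 500 cells/well lands in the 0.6-0.7 control-Z' band the assay
  is expected to reach; this calibration was fixed before the test suite
  and not revisited.
* Six archetypes parameterize the mechanistic groups plus the
  inverse-TMRM phenotype. Group V (uncoupler) is calibrated so that at a
  75 uM saturating dose in glucose about half the cells stay
  TO-PRO-3-negative. Group III uses EC50 3.3 uM with Hill slope 3 so that
  its responses cross the 0.2 activity cut-off only in galactose at doses
  at or above the EC50 -- i.e. it is glucose-dependent by construction at
  the resolution of the 1:3 dose ladder.
* Per-well seeds derive from a stable string hash of (master seed, well
  id, plate salt), so any well can be re-simulated in isolation and
  layout edits elsewhere never change it.

The benchmark (`archetype_benchmark()`) instantiates 3 compounds per
archetype with EC50 multipliers 0.7/1/1.4; group-I compounds additionally
spread their glucose-medium effect sizes by 0.5/1/1.5, since real members
of that class range from respiratory-chain inhibitors with hardly any
glucose-medium response to ionophores that respond equally in both media.
That heterogeneity is what makes the glucose-only truncation experiment
informative: with both media included the common galactose amplification
binds group I together; with glu+ data alone the class scatters.

What the generator does **not** emulate: compound autofluorescence and
marker interference (only an interference flag exists), cell-cycle
structure, optics (PSF, photobleaching, illumination gradients), edge
effects and spatial plate trends, and correlations between channels
beyond the Hoechst mean/area/integral coupling. Tests passing on
synthetic plates therefore validate the statistical machinery and its
calibrated operating points, not image-analysis robustness on real
micrographs.

## Rendering and segmentation

The renderer turns feature rows into field images (1000 x 737 px at
0.5 um/px) so the segmentation stage can be tested end-to-end: nuclei are
anti-aliased disks whose radius/intensity pair is solved jointly so that
the 5x5 smoothing + 2500 a.u. threshold recovers the row's nuclear area
while conserving its integrated intensity (a quadratic with a closed-form
root); TMRM is painted as a perinuclear annulus inside the extraction
ring with one max-pixel hotspot; TO-PRO-3 covers the expanded-contour
footprint so its regional mean survives extraction. Nuclei whose implied
paint intensity falls within ~25% of the threshold have no such solution
-- they are painted at the minimum segmentable intensity, preserving
count and area at the cost of integral fidelity, mirroring the
photometric unreliability of near-threshold nuclei on the instrument.

Segmentation mirrors the instrument protocol: 5x5 box smoothing,
threshold 2500 a.u., connected components, watershed, area filter,
4-px expansion, 14-px peripheral ring. Two implementation choices:

* The watershed is seeded from the **distance transform** of the
  thresholded mask rather than from smoothed-intensity maxima: real and
  rendered nuclei are flat-topped, so touching nuclei produce no
  intensity valley, while the distance map splits them deterministically
  (tolerance 1 px).
* Overlapping expansions/rings of neighbouring cells are resolved by
  geodesic propagation to the nearest label, so no pixel is
  double-counted, and ring and expanded-primary pixel sets are disjoint
  by construction. The max-pixel feature is evaluated over the peripheral
  ring, consistent with its pairing with the peripheral integral; this is
  configurable in principle since the instrument's definition of the
  region is not documented.
* Pixels are treated as square 0.5 um by default; the instrument's
  nominal 0.5 x 0.48 um rectangle is accepted as a configuration.

## Numerical choices and degenerate inputs

* Signed KS: ties in |F_ref - F_sample| resolve to the smallest x;
  empty wells are excluded with a reason rather than scored.
* Gate detection: kernel density (bandwidth 0.1 log10 units, 512 grid
  points); modes below 10% of the tallest are ignored; the valley must
  undercut 80% of the lower mode to accept bimodality, otherwise the
  10^3.25 fallback applies. This replaces per-plate visual gating with a
  deterministic rule.
* Pearson distance of a near-constant vector (component variance
  < 1e-6) is undefined; it is set to 1 with a warning. Flat group-IV-like
  vectors are the expected case; note that vectors containing a viability
  block are never truly constant, because the viability components sit
  near +1 while KS components sit near 0.
* Z' with coinciding control means is reported as failed QC, not a
  number.
* MDS reflections are fixed by making the largest-magnitude coordinate of
  each axis positive; embeddings reduce (with a warning) when the
  geometry supports fewer dimensions than requested.
* Dendrogram tie-breaking follows the deterministic item order of the
  input distance matrix.

## Problem sizes

The test suite simulates the full development conditions: the 48/48
control plate at 500 cells/well for the Z' window, and the five-archetype
benchmark (5 archetypes x 3 compounds x 4 replicates x 10 doses x 2
media, 500 cells/well, one fixed seed) for partition recovery (adjusted
Rand index vs. the generating archetypes), replicate consistency, and the
glucose-only truncation contrast. Smaller plates (1-2 control columns,
100-200 cells/well, 5-dose ladders) cover the remaining mechanics. The
whole suite runs in about a minute on one CPU.

## Known limitations

* Group labels are anchored to analytic archetype fingerprints; on real
  screens the references would instead be in-plate anchors (e.g. FCCP
  controls) plus curated exemplars, and the `other` label exists
  precisely because medoid matching can be inconclusive.
* The 20% activity cut-off and 0.2 replicate bound are inherited
  operating points, not estimated from data; both are exposed as
  arguments.
* KS against a *pooled finite* control carries the pooled sample's own
  well-effect average as a small common bias (order 0.01-0.02 for six
  control wells); per-plate normalization absorbs it for within-plate
  contrasts, but cross-plate comparisons of near-zero KS values should
  not over-interpret differences of that size.
* The renderer conserves count/area/integral only for nuclei painted
  comfortably above the segmentation threshold; photometrically marginal
  nuclei keep count and area only.
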