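---
title: "Methods: behavioral and morphometric endpoints for two-site zebrafish sentinel studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioral and morphometric endpoints for two-site zebrafish sentinel studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shoalmorph)
```

`shoalmorph` implements the analysis of a field protocol in which groups of
six wild zebrafish from each of two sites swim for 3 minutes in a
30.8 cm × 34 cm white tank filmed from above, and every fish is
photographed for 7-landmark morphometrics. This vignette documents the
models, the tunable parameters, the synthetic-data generator, and the
design decisions that were genuinely open.

## Behavioral endpoints

Trajectories arrive as per-frame pixel positions on a common frame grid
(`read_trajectory_table()`, dialects `generic-csv` and `toxtrac`). Three
conventions the source protocol leaves unstated are fixed here:

* **Gap handling.** Trackers lose fish for a few frames at a time. Interior
  detection gaps of at most `max_gap_frames` (default 5) are filled by
  linear interpolation; longer gaps, and gaps touching either end of the
  recording, stay excluded. Excluded frames are removed from both the
  numerator and the denominator of every time-summed endpoint, so metrics
  remain well defined under partial tracking. The detection fraction is
  recorded *before* interpolation and drives the quality gate: a tank is
  analysed only if every fish was detected in at least 80% of frames
  (inclusive — "a minimum of 80%" reads as ≥).
* **Proximity threshold.** Time in proximity counts seconds with at least
  one group member within two body lengths, standardized at 1000 px by the
  protocol; the comparison is inclusive (≤) and applies to the *minimum*
  neighbour distance. An mm-denominated threshold
  (`proximity_config(use_mm = TRUE)`, conventionally twice the mean
  standard length) is provided for other optics.
* **Motion and exploration thresholds.** "In motion" needs a speed
  threshold the protocol does not state: the default is 5 mm/s of
  instantaneous (backward-difference, unsmoothed) speed, about half a body
  length per second for the smaller site's fish, with strict comparison so
  a stationary fish is never in motion even at threshold zero.
  "Exploration" needs a discretization: the arena is partitioned into
  10 mm square cells (edge cells truncated), and the visited area is the
  number of cells containing at least one valid position times the cell
  area, capped at the arena area. Both constants are configurable
  (`activity_config()`) and recorded in every report. The absolute mm²
  scale of exploration depends on the cell size and is therefore not
  comparable across studies that discretized differently; the
  percent-of-arena form is the robust quantity.

Endpoints are computed per fish and collapsed to tank means
(`collapse_to_tank_means()`), the unit of the between-site tests, matching
a design of 12 tanks per site.

## Morphometrics

Seven landmarks per fish — mouth, posterior dorsal skull, anterior dorsal
fin, caudal fin, anterior anal fin, ventral surface, ventral anterior
skull — are read from TPS files (`SCALE=` lines convert to mm; site and
sex come from a sidecar table because the TPS format has no such fields).

* **Size endpoints** are computed on the original mm-scale landmarks:
  standard length is the landmark 1→4 distance; the anterior (1,5,6,7) and
  posterior (2,3,4,5) region areas are absolute shoelace areas of the
  quadrilaterals in digitizing order, with a warning (and signed-area
  diagnostics) if a polygon self-intersects.
* **Shape analysis** uses partial (rotation-only) generalized Procrustes
  superimposition: center, scale to unit centroid size, then iteratively
  rotate to the running consensus with the SVD orthogonal fit, reflections
  disallowed (all photographs share one orientation). Iteration stops when
  the consensus root-mean-square change falls below `tol` (default 1e-10,
  max 100 sweeps); the summed squared residuals are non-increasing across
  sweeps and the result is a fixed point of pairwise ordinary Procrustes
  fits (both properties are tested against an independently coded oracle).
  The aligned shapes are orthogonally projected into the tangent space at
  the consensus; at digitizing-noise levels of variation the projection
  moves coordinates by well under 1e-4, and it can be disabled.
* **Shape PCA.** "Partial warps" are analysed as relative warps with
  uniform weighting, i.e. a PCA of the aligned coordinates flattened to
  14-vectors and centered on the mean shape. The full thin-plate-spline
  bending-energy decomposition is out of scope; with uniform weighting the
  variance fractions PCA reports are the quantity the upstream analysis
  interpreted. Axis signs follow the convention that each loading vector's
  largest-magnitude entry is positive. Superimposition spreads part of a
  single-landmark group difference onto the other landmarks (it removes
  the translation/size/rotation components of any planted displacement),
  so localization statements are checked against the analytic projection
  of the displacement, not against the raw displacement.

## The statistical layer

Behavioral endpoints are compared between sites with Welch two-sample
*t* tests on tank means; `welch_t_from_summary()` recomputes a *t*
statistic from published mean ± SEM summaries, which lets printed results
be checked without raw data. Morphometric tests operate on individual
fish:

* **MANOVA.** Pillai's trace per term of the Population × Sex crossed
  model, from Type II scatter matrices (each main effect adjusted for the
  other; the study's sex ratios differ strongly between sites) against the
  full-model residual scatter. Because the upstream choice of response set
  is ambiguous, the response is the set of shape PCs covering ≥ 99% of
  shape variance by default (`manova_min_variance`). The implementation is
  plain scatter-matrix arithmetic and is tested against hand-computed
  scatters and against `car::Manova`.
* **Two-way ANOVA + Tukey** on the posterior/anterior ratio, Type II sums
  of squares (logged in the output), with Tukey–Kramer comparisons of the
  four Population × Sex cell means.
* **Wilcoxon signed-rank** of posterior vs anterior area: zero differences
  dropped, average ranks for ties, and an *exact* null distribution by
  sign-convolution over the realized (tie-aware) ranks for up to 25 pairs
  — a path base R's implementation does not offer with ties — otherwise a
  continuity-corrected normal approximation with tie-corrected variance.
* **Kruskal–Wallis** on standard length across the four site × sex groups
  (tie-corrected, via `stats::kruskal.test`).

Reported degrees of freedom are always the computed ones; published df
strings inconsistent with the design are treated as typographic artifacts.
No multiple-testing correction is applied across endpoint families, since
the analysis being implemented reports none.

## The synthetic-data generator

The generator exists so every stage can be validated with known ground
truth. Group swimming is a correlated random walk with centroid
attraction: per-frame speeds are gamma(mean `mean_speed_mm_s`, shape
`speed_shape`); the new heading is the direction of
`persistence · (unit heading) + cohesion · min(d/1000 mm, 1) · (unit bearing to centroid)`
plus von Mises noise of concentration `kappa`; walls reflect. The capped
linear spring makes attraction fade as a fish rejoins the group, so the
equilibrium group spread is set by the noise/cohesion balance rather than
collapsing to a point. Each fish consumes its own pre-drawn random
substream, so adding a fish never perturbs the others' draws, and a tank
is bit-reproducible from its seed. Landmark specimens are
`template + group deformation + isotropic noise`, then scaled to a
lognormal standard-length draw, randomly rotated and translated — so GPA
must actually undo the nuisance transforms. The 7-landmark template is a
stylized fish shipped as a text fixture, not a measured consensus.

The reference preset (`reference_study_preset()`) encodes the two-site design:
2 × 12 tanks × 6 fish × 180 s at 30 fps; Site 1 faster (mean frame speed
14 vs 9 mm/s) and much less cohesive (attraction weight 0.2 vs 0.8);
Site 1 larger (median standard length 22/13 mm by sex vs 10/9 mm); equal
sexes in shape at Site 1 but a Site 2 male deformation that shrinks the
posterior/anterior ratio toward ≈ 1.3 against ≈ 1.45–1.65 elsewhere. The
calibration is 20 px/mm, at which the 1000 px proximity standard equals
50 mm ≈ two body lengths of the larger site's fish.

Several generator constants are *matching* constants, fixed once by
design, because the study found **no** site difference in time-in-motion
or exploration and the preset must therefore not plant one:

* Between-tank heterogeneity enters as symmetric (truncated-normal)
  multipliers on mean speed and cohesion. Symmetric multipliers keep
  tank-mean endpoint distributions close to normal, which is also the
  regime the original analysis reports (normally distributed residuals)
  and in which Welch's test is calibrated.
* Site 2's speed-distribution shape (4.593646) and tank-speed spread
  (0.2304974) jointly solve for the same mean *and* between-tank standard
  deviation of time-in-motion as Site 1 (shape 2, spread 0.35) at the
  5 mm/s threshold — matching the mean alone leaves a dispersion mismatch
  that visibly inflates the false-positive rate of the site test. The
  smaller Site 2 spread also mirrors the study's pattern of less variable
  Site 2 tanks.
* Heading persistence and noise (0.82/κ = 3 vs 0.97/κ = 10) equate the
  sites' expected arena coverage: the slower site swims straighter, the
  faster site more tortuously, so expected exploration matches while
  speed, distance, and cohesion contrasts remain planted.

What the generator does **not** emulate: wall-following and thigmotaxis,
burst-and-glide gait structure, tracker identity swaps, body-size-dependent
optics, digitizing operator bias, or any dose–response structure. Passing
recovery tests therefore demonstrates that the analysis chain detects the
planted statistical structure — not that real fish behave like correlated
random walks.

## Validation design and problem sizes

The test suite validates every metric against independent brute-force
per-frame loops (200 randomized 3-fish fixtures), GPA against a
closed-form-rotation fixed-point oracle, and each statistical test against
exact enumeration, permutation, or hand-computed references. Two
simulation studies deserve comment:

* **Null calibration** runs 500 identical-sites studies (both sites share
  one parameter set; no shape, size, or sex effects) and checks that every
  site test's type-I error at α = 0.05 lies in [0.02, 0.08]. Because test
  levels do not depend on recording length, these studies use 40 s at
  10 fps and 18 specimens per group — the tank-mean and specimen sample
  sizes, which do set the levels, are the reference ones. The signed-rank
  test is calibrated on exchangeable pairs (posterior areas of randomly
  paired specimens), the only way to make its null true while the template
  itself has a posterior > anterior asymmetry.
* **Pattern recovery** runs 150 reference-preset studies and requires each
  element of the published qualitative pattern — higher proximity time and
  lower inter-individual distance at Site 2, higher speed and distance at
  Site 1, *no* significant time-in-motion or exploration difference, and
  the Site-2-male ratio depression detected by the interaction plus all
  three Tukey comparisons — to hold in at least 90% of replicates. The
  element-wise criterion is deliberate: the pattern contains two true null
  hypotheses tested at α = 0.05, so even a perfect generator satisfies
  the *joint* pattern in only ≈ 0.95² ≈ 90% of studies in expectation,
  and a joint ≥ 90% requirement would be a coin flip against sampling
  noise rather than a check of the implementation.

## Known limitations

* Exploration's absolute scale is grid-dependent (see above); only the
  percent form and within-study contrasts are meaningful.
* The Pillai F approximation is exact only for single-df terms; for the
  crossed two-level design used here all terms are single-df.
* The exact signed-rank path enumerates up to 25 pairs; beyond that the
  normal approximation is used (with continuity and tie corrections).
* GPA is defined only up to a global rotation; consumers who need a fixed
  orientation should align the consensus to a reference before plotting.
* The trajectory readers assume a single shared frame grid per tank;
  multi-arena exports must be split per tank beforehand.
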