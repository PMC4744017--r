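---
title: "Fixation-map and AOI contrast analysis: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixation-map and AOI contrast analysis: models, conventions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazecontrast)
```

## The scientific problem

Eye-tracking studies of face perception repeatedly ask whether observers
look at own-race and other-race faces differently — a candidate mechanism
for the other-race effect (ORE), the robust finding that people recognize
other-race faces more poorly. Published answers disagree, and one plausible
reason is methodological: fixation differences between face races are
subtle, and the two standard analysis families pool the data very
differently. Area-of-interest (AOI) analyses pool all fixations falling in
a handful of predefined feature rectangles and test a handful of planned
contrasts; spatial density ("heatmap") analyses keep full spatial
resolution but must then correct over thousands of pixel-wise tests.
`gazecontrast` implements both families end to end — together with the
behavioural signal-detection measures of an old/new recognition test and a
synthetic-data generator that emulates the whole design — so the relative
sensitivity of the two families can be exercised under known,
experimenter-controlled effect sizes.

## The data model

All geometry is in degrees of visual angle, origin at the top-left of the
stimulus image, x rightward, y downward. Each face has a rectangular image
frame and seven rectangular AOIs (`left_eye`, `bridge`, `right_eye`, and
nose and mouth each split into halves by x-bisection, so that pre-stimulus
start positions can be placed equidistantly from lateral feature centers).
Rectangles are half-open (`x0 <= x < x1`), so a fixation on a shared
bisection edge belongs to exactly one half and AOI membership is a
partition. Fixations carry their trial's condition labels (face race;
start position left/right/up/down), an ordinal index within trial, and a
duration; test-phase trials additionally carry an old/new judgment and a
reaction time. Fixations landing outside the image frame are kept and
flagged, never silently dropped.

Two analysis windows matter. Study-phase analyses use ordinal fixations
2–5: truncating at the fifth fixation equates the amount of data per
trial, and the first fixation is excluded because it is systematically
short and still tied to the enforced pre-stimulus start position (the
1–5 window is available as an option). Test-phase analyses use every
fixation whose onset (cumulative duration of the preceding fixations)
falls within the 1-second display.

## AOI relative frequencies and planned contrasts

For each participant × race cell (optionally × start position), the
relative frequency of an AOI group ∈ {left eye, bridge, right eye, nose,
mouth, other} is

> (fixations landing in the group) / (total possible fixations),

where the denominator in the study phase is design-determined — trials in
the cell × 4 (the window size), e.g. 16 trials × 4 = 64 — even when a
trial has fewer than five fixations. This keeps denominators independent
of behaviour, so frequencies across groups sum to at most 1, with equality
exactly when no trial is short. In the test phase the 1-second cap makes
the possible count data-dependent, so the default denominator is the
realized number of in-window fixations (a fixed per-trial window is
available and recorded in the output metadata).

Planned contrasts are paired t-tests on per-participant frequencies with
declared one-sided alternatives (own-race > other-race for each eye AOI;
other-race > own-race for nose and mouth), with a paired Hedges' g. The
g standardizer is the d_av convention — the mean of the two condition
standard deviations — with the small-sample correction
J = 1 − 3/(4·df − 1): d_av does not inflate the effect when the paired
conditions are highly correlated, which AOI frequencies are.

## Density maps, alignment, and profiles

Faces differ slightly in geometry, so before mapping, each face is aligned
to a common reference frame by the translation minimizing the sum of
squared differences between its seven AOI centers and the mean centers
across all faces; the minimizer is the closed form
t = mean over AOIs of (reference center − face center). Each windowed
fixation then contributes an isotropic Gaussian of unit mass with
σ = 0.3°, integrated exactly over each pixel cell via CDF differences
(a pixel-center approximation is available; exact integration makes the
quadrature unit tests sharp). Mass falling outside the grid is lost, not
renormalized, and reported (`mass_in_grid`), matching the convention that
out-of-frame fixations stay in the analysis but are invisible in plots.
Duration weighting is off by default and switchable. The default grid is
16° × 16° at 0.0625°/px (256 × 256); all simulation studies and tests in
this package use a 64 × 64 grid of the same extent, which still samples
σ = 0.3° with more than one pixel per standard deviation.

Per-participant condition maps are per-trial sums averaged over trials;
group maps average over participants; contrast maps are per-participant
differences averaged over participants. Profiles collapse a (possibly
signed) map by summation — the y-profile sums over x and shows density
over facial features (eyes/nose/mouth) regardless of laterality — and are
exactly mass-preserving.

## The permutation test

The null hypothesis for a condition contrast is that the distribution of
fixation *locations* is the same in both conditions *for each ordinal
fixation index separately*; first fixations are never compared with third
fixations. Accordingly, the Monte Carlo test pools, within each
participant × ordinal cell, the location tokens of the two conditions
(each token keeps its face's alignment offset baked in, so resampled maps
live in the same aligned frame), randomly reassigns them to conditions
preserving each condition's token count, rebuilds both per-participant
maps, subtracts, and averages across participants. Exchanging locations
rather than pixels means the multiple-comparisons burden does not grow
with map resolution.

Implementation: each token's single-fixation pixel map is precomputed
once; a resampled group-difference map is then a matrix–vector product of
the token-map matrix with a signed weight vector (+1/(n_trials·P) or
−1/(n_trials·P)), so the cost per iteration is additive in tokens and the
whole iteration batch is one BLAS matrix multiply. A naive re-rendering
path exists purely as a correctness oracle; the two agree to 1e−12
(bitwise equality across different floating-point summation orders is not
attainable, and is not scientifically meaningful here). Iterations are
seeded by a counter scheme derived from the master seed, so results are
independent of chunking and evaluation order.

P-values are sign-dependent single tails per pixel: for a positive
observed difference, the fraction of resampled maps at least as large at
that pixel; for a negative one, at least as small; an exactly zero
observed difference gets p = 1 (conservative, well-defined). Monte Carlo
p-values are smoothed as (count + 1)/(n_iter + 1), which keeps them
strictly positive and valid; the exact-enumeration oracle
(`exact_enumeration()`) reports raw proportions, and tests undo the
smoothing before comparing. Thresholding at a per-tail α marks pixels
with p < α and records the two-tailed equivalent 2α (0.01 per tail ↔ 0.02
two-tailed for spatial maps; 0.025 ↔ 0.05 for profiles). Profile p-values
reuse the *same* resampled iterations, collapsed by summation, rather
than drawing a new permutation run.

Multiple comparisons are controlled by Benjamini–Hochberg FDR (q = 0.05)
over the p-values inside an analysis mask: for spatial maps the face
region (pixels whose centers fall inside at least half of the aligned
face frames — roughly half the grid, mirroring the fact that non-face
pixels are not of interest); for profiles, all bins. Cluster-size
correction is out of scope.

## The synthetic-data generator

The generator is the package's definition of the study conditions, not a
tuning dial. Per participant it builds the balanced design — 16 study
trials per race (4 per start position) under self-paced viewing emulated
as 5–9 fixations per trial; a test phase with the 48 studied plus 48 new
faces, studied faces reappearing half with the same and half with the
opposite start position — and simulates each trial from a mixture model:

* **Scanning.** The first fixation lands near the face center, displaced
  toward the start side. Each later fixation draws an AOI-group label from
  a race-specific mixture over {left eye, bridge, right eye, nose, mouth,
  other} — blended, with a weight that starts at `start_pull` = 0.3 for
  the second fixation and halves each ordinal, with a race-*independent*
  start-side distribution — then draws a location from an isotropic
  Gaussian (σ = 0.4°) truncated to the AOI rectangle ("other" is uniform
  over the frame outside all AOIs). Truncation makes the realized AOI
  equal the sampled label, so injected mixture weights are exactly
  recoverable from AOI frequencies; the blending construction puts the
  race effect and the (larger) start-position effect on disjoint
  parameters, so they are independent by construction.
* **Effect sizes.** The default race weights differ by about one
  percentage point in the eye AOIs (own-race higher) and the nose/mouth
  AOIs (other-race higher), calibrated so the paired own- vs other-race
  eye contrast has Hedges' g ≈ 0.2 at the default design — the magnitude
  regime in which AOI analyses detect effects that corrected maps miss.
  This calibration is asserted by a test, not hard-coded.
* **Faces.** Layouts jitter the template's five feature blocks by
  N(0, 0.3²) per face; draws violating the layout invariants or the
  start-point geometry are redrawn. The template leaves 0.4° clearance
  between AOI blocks precisely so that independent block jitter has a
  usable acceptance rate — with edge-sharing AOIs, any relative inward
  shift would overlap. Half of each race's faces are mirrored about the
  vertical midline, emulating left-right-flipped stimuli.
* **Start points.** Lateral start positions are the circumcenters of the
  nearest eye / half-nose / half-mouth centers; the upper (lower) point
  sits on the perpendicular bisector of the eye (mouth-half) centers at a
  distance equal to the mean lateral circumradius. The template's
  proportions (eye separation ≈ 4.3° for a 10° forehead) were chosen so
  this construction is feasible; jittered faces for which it is not are
  rejected like any other invalid draw.
* **Behaviour.** Old/new responses are Bernoulli with race-specific hit
  and false-alarm rates (defaults ordered so d′ is lowest and the
  criterion laxest for Chinese faces, criterion strictest for Caucasian
  faces), shifted per participant on the z scale (SD 0.35) to produce
  realistic between-participant spread — with 16 old + 16 new trials per
  race this puts the paired d′ effect for the own- vs Chinese-face
  contrast near g ≈ 1. Reaction times are log-normal with rare injected
  slow outliers (rate 0.02, ×4) so the RT filter has something to do.

What the generator does *not* emulate: saliency-driven scanning, saccade
kinematics, temporal dependencies between successive fixations beyond the
ordinal-indexed start-side decay, pupil data, calibration drift, or
image-level properties of real face photographs. Passing tests therefore
demonstrate that the analysis machinery behaves correctly under the
design's statistical structure — not that real data would show any
particular effect.

## Behavioural measures

d′ = z(hit rate) − z(false-alarm rate) and criterion
c = −[z(hit) + z(fa)]/2 are computed per participant × race (optionally ×
start position) after correcting extreme rates; the default correction
clamps 0 → 1/(2n) and 1 → 1 − 1/(2n), with a log-linear
(k + 0.5)/(n + 1) alternative, since the literature's choice here is
conventional rather than principled. Reaction times of correct trials are
filtered by excluding values more than 2.5 sample standard deviations
from the cell *median* — implemented exactly as that hybrid rule (mean-
based SD around a median center), not as a MAD rule. Note a property of
this rule worth knowing: with very few trials, a single enormous outlier
inflates the SD enough to survive its own band; exclusion only behaves as
intended at realistic cell sizes. The filter is also only conditionally
idempotent — removing an outlier shrinks the band, so a second pass can
exclude more; the tests verify it reaches a fixed point.

## Numerical and statistical conventions

* Monte Carlo p-values use +1 smoothing; the exact oracle uses raw
  proportions; zero-difference pixels get p = 1.
* BH step-up is computed via `p.adjust(..., "BH")` on in-mask pixels only;
  out-of-mask pixels can never be significant.
* With n_iter = 1,000–2,000 (the desk-scale defaults) the smallest
  achievable p is ≈ 1/n_iter, which is far above the BH threshold
  q/m for a single extreme pixel on a 64 × 64 face mask — so FDR maps on
  null data are empty essentially always at desk scale. Full-scale runs
  (10⁴–10⁵ iterations) are needed before single pixels can survive FDR.
* Seeds: a single master seed; substreams derive by an affine counter
  scheme, making iteration order and chunk size irrelevant.
* Degenerate inputs: empty fixation sets render zero maps; zero-variance
  contrasts return t = 0 with one-tailed p = 0.5 (identical conditions)
  or signed infinite t (constant shift); zero-denominator AOI cells are
  flagged rows, not errors.

## A validity caveat discovered by simulation

The permutation null exchanges fixation locations between conditions
within participant × ordinal cells. If the two conditions' stimuli
*themselves* differ systematically in geometry, that difference is a real
signal attached to the condition labels, and no within-participant
permutation can represent it under the null. In this package's generator
the situation arises naturally: all participants see the same small
race-specific face pools, so per-face AOI jitter becomes a race-correlated
geometry shift shared by every participant (translation alignment removes
only the mean shift, not relative geometry). In simulations with equal
feature weights but jittered faces, the fixed-pixel type-I rate at
per-tail α = 0.01 ran 2–3× nominal, while with identical face geometry it
sat inside the binomial band. The package's null-calibration studies
therefore define the null as *equal feature weights and identical face
geometry*. The broader methodological point carries to real designs: a
race contrast on fixed stimulus sets tests "stimuli + scanning", not
scanning alone, and stimulus-geometry differences between sets can
masquerade as fixation effects at the pixel level.

## Simulation study sizes

The package's verification studies are scaled for a desk machine and are
stated here as the package's conventions: null-calibration, 200 datasets
of 10 participants × 8 trials/condition at 2,000 iterations on the 64 × 64
grid; oracle equivalence, exact enumeration of a 2-participant,
2-tokens-per-cell instance (256 reassignments) against 10⁵ Monte Carlo
iterations; sensitivity ordering, 100 replicates of the full 30-participant
design at 1,000 iterations. The acceptance script
(`scripts/acceptance.R`) re-runs reduced versions of the same studies
(100 null datasets at 1,000 iterations; 40 sensitivity replicates at 500
iterations) together with the behavioural and effect-size summaries.

## Known limitations

* The pipeline regenerates every stage on each run; stage outputs are
  deterministic and hash-recorded in the manifest, so unchanged stages
  reproduce byte-identically, but there is no incremental skip logic.
* Omnibus repeated-measures ANOVAs (with sphericity corrections) are
  deliberately not reimplemented; `relfreq.tsv` is exported in long format
  for any standard ANOVA tool.
* Only translation alignment is supported (no scaling or rotation), as in
  the analysis the package models.
* The EyeLink-style converter is a documented column mapping
  (`read_fixations()` expects the package's TSV dialect); proprietary
  binary formats are out of scope.
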