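# gazecontrast

Condition contrasts for face-viewing eye-tracking experiments, two ways:
pooled **area-of-interest (AOI) statistics** and **pixel-wise permutation
maps** — built to study why the two families can disagree about the same
data.

## The problem

Whether people look at own-race and other-race faces differently is a
long-standing question behind the other-race effect in face recognition,
and published eye-tracking studies disagree. One candidate explanation is
analytic: race-of-face effects on fixation patterns are *subtle* (paired
standardized differences around g ≈ 0.2), and the two standard analysis
families trade spatial resolution against statistical pooling very
differently. `gazecontrast` implements both, end to end, over a common
data model:

* **AOI analysis** — relative fixation frequency per feature region, with
  design-determined denominators: for participant *s*, race *r*, AOI *a*,

  `relfreq(s, r, a) = (# fixations in a) / (trials(s, r) × window size)`,

  e.g. 16 study trials × 4 analyzed fixations = 64 possible fixations.
  Planned one-tailed paired contrasts (own-race > other-race for the
  eyes; the reverse for nose and mouth) with paired Hedges' g (d_av
  standardizer, bias correction `J = 1 − 3/(4·df − 1)`).
* **Spatial density maps** — faces aligned by the translation minimizing
  the summed squared AOI-center differences to the mean geometry; each
  windowed fixation a unit-mass isotropic Gaussian (σ = 0.3°) integrated
  exactly over pixel cells; per-participant difference maps averaged into
  a group contrast.
* **Monte Carlo permutation inference** — the null exchanges fixation
  *locations* between conditions only within participant × ordinal-
  fixation cells; pixel p-values are sign-dependent single tails with
  `(count + 1)/(n_iter + 1)` smoothing; per-tail p < 0.01 thresholds
  (two-tailed 0.02); Benjamini–Hochberg FDR at q < 0.05 inside a
  face-region mask. One-dimensional profile curves (maps summed along an
  axis) reuse the same resampled iterations, thresholded at per-tail
  0.025 (two-tailed 0.05), FDR over all bins. An exact-enumeration oracle
  validates the Monte Carlo machinery on tiny instances.
* **Behavioural measures** — d′ = z(hit) − z(fa) and criterion
  c = −[z(hit) + z(fa)]/2 per participant × race, extreme-rate
  corrections, and reaction-time filtering at 2.5 SD around the cell
  median.
* **A synthetic-data generator** — the full balanced design (30
  participants; 3 face races × 4 pre-stimulus start positions; 48
  self-paced study trials; 96 one-second old/new test trials) from a
  mixture-over-AOIs scanning model with controllable race, start-position
  and recognition effects, including the equidistant start-point geometry
  (circumcenters of lateral feature centers).

Intended users: visual-cognition researchers comparing analysis
strategies for fixation data, and anyone needing a tested reference
implementation of ordinal-exchangeable permutation maps.

## Worked example

```r
library(gazecontrast)

params <- generator_params(seed = 42)   # the study design, defaults as documented
ds <- generate_dataset(params)
ds
#> <gc_dataset> 27406 fixations, 4320 trials, 30 participants, 96 face layouts

# Other-race recognition deficit in the simulated test phase
beh <- behavior_summary(ds)
round(tapply(beh$dprime, beh$race, mean), 2)
#>   african caucasian   chinese
#>      1.56      1.53      1.22

# Planned AOI contrasts on study-phase relative frequencies
rf <- relative_frequencies(ds, "study")          # fixations 2-5, pooled starts
ct <- planned_contrasts(rf, default_contrasts())
ct[3, c("label", "t", "df", "p", "g")]
#>                                      label    t df     p      g
#> 3 left_eye: caucasian vs chinese (greater) 1.08 29 0.145 0.2731

# Permutation statistical map for the same contrast
pt <- permutation_test(ds, "caucasian", "chinese", coarse_grid(), sigma = 0.3,
                       perm_config(n_iter = 1000, seed = 7))
threshold_pmap(pt$pmap, 0.01)
#> <gc_sigmap> p < 0.01 per tail (two-tailed 0.02), 33 significant of 4096 pixels

offs <- alignment_offsets(ds$layouts)
fdr_correct(pt$pmap, face_mask(ds$layouts, offs, coarse_grid()), q = 0.05)
#> <gc_sigmap> q <= 0.05, 0 significant of 4096 pixels

threshold_pmap(profile_pvalues(pt, "y"), 0.025)
#> <gc_sigmap> p < 0.025 per tail (two-tailed 0.05), 3 significant of 64 pixels
```

The numbers tell the methodological story in one run: the injected
own-race eye bias (true paired g ≈ 0.2) shows up as a positive AOI
contrast and as scattered uncorrected map pixels, the FDR-corrected map
is empty, and the vertically collapsed profile — which pools like an AOI
but without predefined regions — retains a few significant bins. Across
replicates the AOI contrast rejects far more often than the corrected map
detects anything (see the acceptance script below), i.e. spatial pooling
buys sensitivity.

`run_pipeline(pipeline_config(...))` orchestrates all stages from one
(optionally YAML) configuration and writes TSV/JSON outputs plus a
hash-recording `manifest.json`; `render_figures()` builds comparable-scale
heatmap figures from a pipeline output directory. A thin command-line
wrapper lives at `inst/scripts/gazecontrast.R`.

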