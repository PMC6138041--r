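---
title: "Methods: simulating and measuring test-retest reliability of a short fMRI control task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and measuring test-retest reliability of a short fMRI control task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boldretest)
```

## The problem

Pharmacological fMRI studies need control tasks whose BOLD readouts are
stable across sessions: if a drug appears to change a control response,
the change may reflect systemic or neurovascular confounds rather than
neural effects, and that inference is only as good as the task's
test-retest reliability.  `boldretest` implements the full analysis chain
used to evaluate such a task — a five-minute event-related paradigm with
auditory, visual, motor and cognitive trials (eye-movement or
working-memory, depending on the variant) plus null trials — across two
scan sessions, together with a cohort simulator whose reliability is
known by construction, so every stage of the chain can be validated
quantitatively.

## Task model

Each run is 100 back-to-back 3 s trials (20 per condition, nulls
included) plus a 10 s trailing buffer: 310 s, or 155 volumes at TR 2 s.
The original task's standardized pseudo-random order is not published,
so `generateSchedule()` ships one canonical permutation drawn once from
a fixed seed under the constraint that no condition repeats more than
three times in a row (which keeps design efficiency reasonable); the
reversed order is its exact reversal.  This sequence is a documented
stand-in, not the original stimulus order.  Stimulus details (tone
frequencies, grating parameters, saccade-target geometry, working-memory
string length) are carried as metadata only (`stimulusParams()`); no
stimulus is rendered.

## Generative model of the simulator

For subject $s$, region $r$ (one region per active condition), the
trait amplitude is drawn once,
$a_{s,r} \sim N(\mu_r, \sigma_b^2)$, and each session $j$ responds with
$a_{s,r} + e_{s,j,r}$, $e \sim N(0, \sigma_w^2)$.  Voxel time-series
inside region $r$ are

$$y(t) = 100 + (a_{s,r} + e_{s,j,r})\, x_r(t) + d(t) + \varepsilon(t),$$

where $x_r$ is the condition boxcar convolved with a canonical
double-gamma HRF (gamma shapes 6 and 16, rate 1, undershoot ratio 1/6,
peak-normalized; peak near 5 s), $d$ is a random linear-plus-quadratic
drift with coefficient SD `driftAmp`, and $\varepsilon$ is AR(1)
Gaussian noise with stationary SD `sigmaN` and lag-one correlation
`ar1Rho`.  The population consistency ICC of the amplitudes is then
exactly $\sigma_b^2 / (\sigma_b^2 + \sigma_w^2)$ (`trueIcc()`), which is
what the voxel-wise estimator should recover when measurement noise is
negligible.

Default values (chosen once, as plausible for a robust 3 T control
task, and not revisited): $\mu_r = 1$ arbitrary signal unit (no
percent-signal-change values are published for this task, so the scale
is arbitrary), $\sigma_b = 0.5$, $\sigma_w = 0.5\sqrt{3/7}$ so that the
population amplitude ICC is 0.7 (matching the >0.7 voxel-wise medians
the task is reported to achieve), `sigmaN = 1`, `ar1Rho = 0.3`,
`driftAmp = 1`, on a 20 x 24 x 20 grid of 3 mm voxels whose affine
centres the grid on the origin so mm-defined ROI spheres work
unchanged.  The default cohort is 15 subjects by 2 sessions.  Head
motion is simulated as a slow Gaussian random walk but enters the
analysis only as confound regressors; images are never resampled, and
no physiological noise or susceptibility artefacts are modelled.  These
omissions mean passing tests certify the *statistical machinery*, not
robustness to every artefact of real acquisitions.

```{r}
vm <- varianceModel()
trueIcc(vm$sigmaB, vm$sigmaW)
```

## First-level model

`buildDesignMatrix()` assembles, per run: the four HRF-convolved
condition regressors (null trials are the implicit baseline; columns are
not mean-centred), their backward-difference temporal derivatives, the
24-parameter extended motion set $\{p, \Delta p, p^2, \Delta p^2\}$, and
a discrete-cosine drift basis with all periods above the 100 s cutoff
(`floor(2 T / 100)` components plus intercept; for 155 volumes at TR
2 s, 6 + 1 columns, 39 in total).  The DCT basis replaces a
running-line high-pass filter because its projection is closed-form and
directly testable.  Fitting is voxel-wise OLS without prewhitening — the
simulated AR(1) correlation is mild, and the reliability statistics
consume effect estimates, not single-run inference — with $t \to z$
conversion through the t CDF evaluated on log scale and capped at
$\pm 38$ where the normal quantile saturates.  Spatial smoothing is a
separable Gaussian at 6 mm FWHM with zero-padded boundaries.  Sessions
are averaged within subject by inverse-variance-weighted fixed effects.

## Group statistics and cluster correction

Group activation is a voxel-wise one-sample t (converted to z) across
subjects — a deliberate simplification of Bayesian mixed-effects
modelling, adequate here because the reliability analyses consume
first-level outputs.  Group inference is one-sided (activation above
baseline), configurable in the sense that the z maps are signed and any
threshold can be applied.  Cluster-extent correction thresholds the z
map at `zThresh` (default 3.1), labels 26-connected clusters, and keeps
those whose extent strictly exceeds the $1-\alpha$ quantile of a
max-cluster-size permutation null (1000 sign-flips of the subject maps,
identity flip included).  The strict inequality plus the quantile
definition give familywise error at or just below alpha; the
discreteness of cluster extents makes the realized rate slightly
conservative, which the acceptance simulation quantifies empirically.

## Reliability statistics

`icc31()` is the two-way mixed-effects, single-measure, *consistency*
intraclass correlation
$(\mathrm{BMS} - \mathrm{EMS}) / (\mathrm{BMS} + (k-1)\mathrm{EMS})$,
with the ANOVA mean squares exposed for inspection.  Negative estimates
are reported as computed — flooring at zero would bias the medians the
pipeline summarises.  Zero-variance input raises a distinct error
rather than silently returning 0.  `iccMap()` applies the two-session
closed form per voxel.

For thresholding, ICC images are standardized with the Fisher
variance-stabilizing transform scaled by $\sqrt{n-3}$
(`iccStandardize()`), which is approximately standard normal under the
null of zero ICC; the exact transform used in the original analyses is
not recoverable, so this standard choice is flagged as an
approximation.  The standardized map is cluster-corrected with the same
extent machinery; because no sign-flip null exists for a correlation,
the permutation null instead re-pairs session-2 subjects at random,
destroying the within-subject correspondence that the ICC measures.
The surviving mask is applied to the *original* ICC image, so the
thresholded map retains interpretable ICC values, summarised by their
median.

Two further summaries probe the relation between activation strength
and reliability: the sweep (`activationMaskedMedians()`) masks the
*unthresholded* ICC image by plain voxel thresholds on the activation z
map at 2.3/3.1/3.7/4.3 (no cluster step — the masks are definitions,
not inferences; cluster-corrected masks can be supplied instead), and
the overlap (`overlapPercentage()`) is the percentage of significant
ICC voxels that are also inside the cluster-corrected activation mask.
ROI analysis extracts mean effects from 5 mm spheres (inclusive
boundary, centre-to-voxel-centre distance in mm; a sphere never comes
back empty — the nearest voxel is kept), computes the ROI ICC with the
standard qualitative bands (>0.75 excellent, 0.6–0.75 good, 0.4–0.59
fair, <0.4 poor), and runs two-sided paired t tests across sessions at
a Bonferroni-corrected alpha (0.05/8 = 0.00625 for the full
two-variant, four-condition family).  The shipped ROI centres are the
synthetic topology's region centres — placeholders that make the ROI
machinery testable; real-data users must supply their own coordinates.

## Numerical and degenerate-input choices

* Ties in medians use standard even-n interpolation; `NA` voxels are
  excluded.
* Empty masks (no surviving voxels, empty sweep rows) are flagged or
  raised as typed errors, never silently zero; the pipeline records
  them as `NA` cells.
* Zero-variance voxels at group level receive the capped z of 38.
* Rank-deficient designs abort with the collinear columns named.
* ICC values are clipped at $\pm(1 - 10^{-7})$ before `atanh`.
* All randomness is driven by per-purpose sub-seeds derived from one
  base seed, so cohorts, permutation nulls and whole pipeline runs are
  bit-reproducible.

## Problem sizes

The package's own validation uses: the full default cohort (15 subjects,
2 sessions, both variants, 155 volumes, 9600 voxels) for the end-to-end
run; 200-subject amplitude-level cohorts for parameter recovery; 200
replicates at n = 15 for the sampling-interval calibration; and 500
pure-noise group datasets (12 subjects, 12 x 12 x 10 voxels, smoothed,
cluster-forming z 2.3, 1000 permutations) for the familywise-error
simulation.  These sizes make the whole suite runnable on a laptop-class
single core.

## Known limitations

The simulator shares one activation topology between the activation and
reliability analyses, so the activation/ICC spatial dissociation seen in
real data (high overlap for sensory conditions, low for motor/cognitive)
is not reproduced by default — overlap percentages on synthetic cohorts
are high.  Reliability of *non-activated* tissue is not modelled (true
ICC is defined only inside regions).  Only two sessions are supported;
ICC(1,1), ICC(2,1) and average-measure forms are out of scope, as is any
comparison against the published group maps, which derive from real
subjects.  With the default true ICC of 0.7 at n = 15, the
cluster-forming cutoff on the standardized scale corresponds to a voxel
ICC of about 0.71, so individual conditions can legitimately produce
empty significance masks in a given simulated cohort; the pipeline
reports these as `NA` rather than forcing a value.
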