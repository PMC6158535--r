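---
title: "Simulating serial detection of camouflaged prey: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating serial detection of camouflaged prey: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camosearch)
```

# The problem

Camouflage research distinguishes three conceptually distinct concealment
strategies: *background matching* (BM), where a target's internal pattern
resembles the background but no pattern element touches the target outline;
*disruptive coloration* (D-RUP), where pattern elements intersect the outline
and destroy its edge information; and *distractive markings* (D-RAC), where a
conspicuous high-contrast marking sits inside an otherwise
background-matching target. Beyond preventing initial detection, these
strategies interact with observer *cognition*: over consecutive encounters
with one prey appearance an observer forms a transient attentional bias (a
*search image*) that speeds detection of that appearance and slows detection
of others (*search-image interference*), the mechanism behind apostatic
selection in predator–prey systems.

`camosearch` implements a complete in-silico version of the serial-detection
task used to study these effects with human observers on touch screens:
stimulus synthesis under the three strategy constraints, the three-phase
experimental design with constrained pseudorandom trial sequences, a
generative observer model producing right-censored capture times, and the
associated mixed-model analysis with likelihood-ratio simplification and
planned contrasts. Because the original human data are not bundled with any
public archive, the package's synthetic observer is the test-bed: it injects
known learning, search-image and interference structure, and the analysis
pipeline is validated by recovering it.

# Stimulus synthesis

## Backgrounds

Targets are sampled from and presented against grayscale bark-like scenes at
the 1920 × 1080 px canvas of the original monitor (the physical 600 × 338 mm
display geometry is metadata only; we model pixels). Users can load their own
photographs (`load_background()`, centre-cropped, Rec. 709 luminance), but
the default is procedural (`generate_synthetic_bark()`), so the pipeline
needs no downloads. The recipe sums three band-limited value-noise layers:

* broad vertically streaked light/dark bands (ridges and furrows;
  horizontal scale 280 px, vertical elongation ×4, tones pushed apart by a
  `tanh` nonlinearity),
* sparse mid-scale blobs of the opposite tone (~2% of pixels at scale
  14 px) — the features that become prey markings,
* low-amplitude fine grain (±10 levels at scale 5 px).

The layer structure is deliberate: marking segmentation (below) binarizes at
the scene's global median, and a prey-sized patch must plausibly contain
*a few, separated* minority-phase components. A texture whose median-crossing
set is space-filling makes interior-only markings (the BM constraint)
unattainable by rejection sampling; sparse blobs on broad bands make all
three constraints reachable with acceptance probabilities of a few percent
or better. The recipe details are configuration (`bark_config()`), not
contract — the only contract is the luminance-spread floor (90th − 10th
percentile ≥ 40 levels, asserted per image) that keeps segmentation
non-degenerate.

The number of distinct backgrounds used in the original task is not
reported (background identity enters the analysis only as a random effect),
so the pool size defaults to 8 per experiment — enough levels for a
variance-component estimate at desk scale — and is configurable.

## Prey targets

Prey are apex-up isosceles triangles rasterized into a 126 × 64 px box
(`triangle_mask()`), textured with a patch copied from a uniformly random
window of the background (`sample_patch()`). Markings are operationalized
as 8-connected components of the minority phase after binarizing the patch
at the source background's global median, discarding components smaller
than 20 px (`segment_markings()`); a component "intersects the outline"
when it overlaps the 1 px boundary ring of the triangle. The binarization
threshold sits on the half-integer grid so that polarity inversion
(v → 255 − v) permutes the two phases exactly and is a bitwise involution.

`make_target()` enforces each strategy by rejection sampling — a fresh
random window per attempt, never an inward translation of markings, which
would create artificial inside edges and inflated interior density:

* **BM**: ≥ 1 marking component, none intersecting the outline. (The
  marking-presence requirement makes "patterns within the prey" literal; a
  featureless patch is not background matching, merely blank, and this is
  what makes constant backgrounds fail BM generation.)
* **D-RUP**: ≥ 1 component intersecting the outline.
* **D-RAC**: a BM-compliant base (0 intersections; components optional)
  plus one randomly shaped spot — the union of 1–3 overlapping ellipses,
  total area 100–300 px, every pixel ≥ 2 px from the boundary ring —
  filled solid black or white, whichever maximizes contrast with the mean
  texture in its 5 px neighbourhood (floor: 60 levels). The spot's size and
  shape distribution is unreported in the source literature; these are
  configurable assumptions (`stimulus_config()`).

Stored edge-intersection counts are recomputed *after* spot compositing, so
re-running segmentation on any stored texture reproduces the stored count
(the self-consistency oracle used in the constraint sweeps). BM and D-RAC
prey have light-on-dark and dark-on-light variants; disruptive prey do not
(the original design names only the other two as inverted), though
`allow_drup_inversion` overrides this.

# Experimental design

Each of three experiments pairs two strategies (A: BM/D-RUP, B: BM/D-RAC,
C: D-RUP/D-RAC). Participants pass through 64 slides in three phases:

1. **learning** (slides 1–32): both types pseudorandomly interleaved,
   balanced 16/16, with no more than two consecutive encounters of a type.
   The exact 16/16 balance is assumed (the source states the run constraint
   and balanced experience) and configurable.
2. **search image** (33–48): a solid 16-run of one type, or a continued
   8/8 interspersed mix (control; same run rule).
3. **test** (49–64): a solid 16-run of one type.

Three search conditions × two test types give six arms; `n_per_arm = 20`
yields 120 participants per experiment and 23 040 presentations overall.
The 10-level *phase treatment* factor (learning; searchA/AB/B;
testA–A … testB–B) encodes each encounter's phase-by-history cell.

Sequences with bounded runs are generated by sequential sampling with a
memoized feasibility look-ahead, so construction never dead-ends and the
sampler provably stays inside the valid set (verified against brute-force
enumeration at reduced length in the tests). Placement is uniform over all
positions keeping the target box on-canvas (centre coordinates, 0-based,
origin top-left). Inversion alternates within eligible prey types with a
random phase per participant; backgrounds rotate round-robin through the
pool with a random per-participant offset. All of these scheduling choices
fill gaps the source leaves open and are configurable.

# The observer model

Capture times are log-normal with a 30 s right-censoring bound. The
expected log capture time of an encounter is

$$\beta_0 + \mu_{type} + \theta\,(s-1) - \sigma_{type}\min(r-1, r_{max})
  + \pi_{prev \to type}\,\delta^{\ell}
  + \gamma_1 \tilde x^2 + \gamma_2 \tilde y^2 + \gamma_3 \tilde x \tilde y
  + u_p + v_b,$$

with $s$ the slide number within phase, $r$ the consecutive same-type run
length, $\ell$ the encounters since the last type switch, $\tilde x,
\tilde y$ screen coordinates standardized to $[-1, 1]$, and
$u_p \sim N(0, \tau_p^2)$, $v_b \sim N(0, \tau_b^2)$ participant and
background intercepts. The switch penalty decays geometrically ($\delta$,
lag capped at 16); interference is demonstrated but its functional form is
not specified in the source, and a geometric fade is the simplest memory
decay consistent with a transient attentional bias.

The `paperlike` scenario encodes the qualitative findings the analysis
should recover: no search-image gain for disruptive prey
($\sigma_{D\text{-}RUP} = 0$), the largest gain for distractive prey, and a
positive distractive-to-disruptive switch penalty
($\pi_{D\text{-}RAC \to D\text{-}RUP} > 0$). The `null` scenario zeroes all
$\sigma$ and $\pi$ and is the reference for test-size calibration.

**Calibration of magnitudes.** Human effect sizes are unknown, so defaults
were sized by power analysis at the study design (120 participants, 64
slides): with $\tau_p = 0.25$ and residual 0.5 log-s, the among-participant
contrast of two test cells has SE ≈ 0.09, so a detectable interference
effect needs a mean test-phase shift near 0.3 log-s — hence
$\pi_{D\text{-}RAC \to D\text{-}RUP} = 0.6$ with $\delta = 0.9$ (mean decay
factor ≈ 0.52 over a 16-slide run). Likewise the position-interaction
coefficient is fitted with SE ≈ 0.025, so $\gamma_3 = 0.08$ (≈ 3 SE) makes
its sign recoverable in ≥ 95% of replicates. Baselines: $\beta_0 = \log 5$ s,
$\mu_{D\text{-}RUP} = 0.3$ (disruptive prey are hardest to find initially),
$\theta = -0.01$ per slide, $\sigma = (0.02, 0, 0.04)$ for (BM, D-RUP,
D-RAC), capped at $r_{max} = 8$. All values are plain configuration
(`observer_params()`).

One known consequence of the geometric-decay form: in the interspersed
control arm the test phase inherits a *diluted* switch penalty (whichever
type ended the search phase is the `prev` type), so the control-versus-solid
contrast carries a smaller but nonzero injected effect rather than exactly
zero. This mirrors reality — controls have mixed recent experience — but it
means only the headline solid-versus-solid contrast is used for strict
size/power calibration.

**Censoring.** Latent times above 30 s are recorded as timeouts with no
capture time (the source does not state how its model handled them;
exclusion is the default, inclusion at the log 30 ceiling is available via
`prepare_trials(..., "ceiling")`). At the default parameterization ~1.5% of
trials censor.

# The statistical pipeline

For each experiment separately, the model of `model_spec()` is fitted to
logged capture times (seconds) by maximum likelihood with `lme4`: quadratic
standardized X and Y with their interaction, the inversion flag, slide
number within phase, the 10-level phase treatment, all two-way interactions
among the last three, and random intercepts for participant and background.
ML rather than REML is used throughout so likelihood-ratio tests between
fixed-effect structures are valid; the final coefficients are reported from
the same ML fit.

Simplification tests exactly three reductions, in order: the
slide-by-phase-treatment interaction, the X-by-Y interaction, and the
inversion factor (with its interactions); a term is dropped at p > 0.05 and
all three tests are always reported.

**Rank deficiency.** In experiments pairing disruptive prey with an
invertible type, the inversion flag is structurally aliased inside the
phase-treatment cells where only disruptive prey occur (prey type itself is
not a model covariate — phase treatment carries it implicitly outside the
learning phase). The full model is therefore *always* rank deficient in
experiments A and C. `fit_model()` drops aliased columns and records their
names (`on_alias = "drop"`, the default); an error naming the aliased terms
is available instead, but as a default it would make the standard
simplification procedure unrunnable on two of the three experiments. A
related caveat: in mixed phases the flag is partially confounded with prey
type, so its LRT behaves as a true size test only in experiment B, where
both types have balanced inverted variants.

**Planned contrasts** (`planned_contrasts()`, catalogue in
`contrast_catalogue()`) estimate differences between phase-treatment level
means adjusted to reference covariates — screen centre, non-inverted, slide
at the 16-slide phase midpoint (8.5) — with standard errors from the
fixed-effect covariance. The catalogue mirrors the two blocks of the
study's comparison table: within-participant (training vs each search
condition; each search condition vs its two test cells) and
among-participant (search-condition pairs; pairs of search histories within
each test-phase prey type). Inference uses the normal approximation by
default (a finite `df` argument accepts a Satterthwaite-style correction
computed elsewhere); with ≥ 110 participants per fitted model the
distinction is negligible, and the calibration suite confirms the realized
test size empirically. No multiplicity correction is applied, matching the
planned-comparison framing; the exact contrast arithmetic behind the
original within-participant block is not printed anywhere, so
phase-treatment-level model contrasts are used for both blocks.

**Realized test size.** One statistical property of the original model is
worth knowing when interpreting its planned comparisons: prey type is not a
covariate (phase treatment carries it only implicitly outside the learning
phase), so when the two camouflage types differ in baseline detectability,
the mixed-type learning and interspersed phases inflate the pooled residual
variance that is then applied to the pure-type test cells. The
among-participant test-cell contrasts are therefore mildly *conservative* —
at the default generator settings (0.3 log-s type difference) the realized
size of the nominal 5% test is about 2–4%, with visibly clipped t tails
(plug-in variance-component estimation couples extreme contrasts to
inflated standard errors). A variant simulation with equal type baselines
is exactly calibrated. The bias is always toward under-rejection, so
significant interference findings are not inflated by it; power is
correspondingly slightly understated.

# Numerical and scale choices

* Capture times are stored as integer milliseconds (the recording
  precision), floored at 1 ms; the response is log seconds.
* Coordinates are standardized before squaring; raw pixel quadratics would
  produce a badly conditioned design matrix.
* `lme4` fits disable the finite-difference derivative check
  (`calc.derivs = FALSE`) and ignore singular-fit boundary warnings; the
  convergence flag in `fit_result` reports the optimizer status honestly.
* LRT statistics are clamped at zero (boundary numerics can produce tiny
  negative differences); identical models give χ² = 0, p = 1.
* All randomness flows through integer seeds; per-stage seeds derive from a
  master seed by a rolling string hash below 2³¹, so stages re-run
  independently and the whole pipeline is bitwise reproducible
  (hash-equal output manifests).

The test and calibration suites use these problem sizes: the full 23 040-row
design for cardinality checks; 500 targets per treatment for the constraint
sweep; 200 null replicates and 100 paperlike replicates of experiment C at
the full 120-participant size for test-size and power checks (the
acceptance script uses 100/60 replicates for its summary rates).

# What passing tests do and do not show

The synthetic observer shares the *structure* the analysis assumes —
log-normal noise, additive effects on the log scale, homogeneous learning
slopes, random intercepts — so parameter-recovery results validate the
pipeline's correctness, not the model's adequacy for human observers. Real
capture-time data bring features the generator deliberately omits: fatigue
drift across the session (the source observed it post hoc; no term is
modelled, matching the original specification), heavy-tailed and
non-stationary residuals, attention lapses, correlated placement effects
from scene content (our position effect depends only on geometry, not on
local background complexity), and any search-rate adaptation (explicitly
out of scope — the source defines no model for it). Likewise the stimulus
constraints operationalize "marking", "intersecting" and "salient" with
specific thresholds (global-median binarization, 20 px minimum area, 1 px
ring, 60-level contrast floor) that are defensible but not unique; all are
configuration, and the re-verification sweep asserts internal consistency,
not perceptual validity.

# Known limitations

* Chromatic stimuli, alternative target shapes, and quantitative camouflage
  metrics (edge-disruption scores, pattern statistics) are out of scope.
* The touch-screen presentation layer (feedback circles, timing of
  inter-slide blanks) is not implemented; only its trial-generation logic
  is.
* Censored trials are excluded from the capture-time model rather than
  modelled by a censored likelihood; at the default ~1.5% censoring rate
  the bias is negligible, but heavy-censoring configurations should use
  survival methods instead.
* The interspersed-control dilution described above makes some secondary
  among-participant contrasts carry small injected effects under
  `paperlike`; they are reported, not calibrated.
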