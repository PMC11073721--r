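---
title: "Drift-diffusion and classical analysis of numerical Stroop rTMS experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drift-diffusion and classical analysis of numerical Stroop rTMS experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stroopddm)
```

## The experiment this package models

In the numerical Stroop task two single digits are shown side by side and
the participant reports, by a left or right button press, which digit is
numerically larger.  The physical font size of the digits either agrees
with the numerical comparison (congruent), contradicts it (incongruent),
or is uninformative (neutral, equal fonts).  Congruent trials are answered
faster and incongruent trials slower; the difference
RT(incongruent) − RT(congruent) is the size congruency effect (SCE), which
splits into a facilitatory component, RT(neutral) − RT(congruent), and an
interference component, RT(incongruent) − RT(neutral).

The experiments this package targets deliver short trains of 10 Hz
repetitive transcranial magnetic stimulation (rTMS) — a triplet of pulses
220, 320 and 420 ms after stimulus onset — over the right intraparietal
sulcus while the task is performed, comparing active stimulation against
an electrical sham, with the order of the two arms counterbalanced across
participants.  A typical session structure is: one 48-trial practice block
(24 congruent, 24 incongruent), four in-scanner task blocks, then on a
second visit a 72-trial practice block and four 72-trial stimulation
blocks, each with equal congruent/incongruent/neutral thirds.

The package provides the full analysis chain for such data — staged trial
cleaning, classical mixed-model and repeated-measures statistics, and a
drift-diffusion decomposition of the response-time distributions — plus a
synthetic-data generator that emulates the design with a known generative
truth, so that every stage can be validated by parameter and effect
recovery rather than by eyeballing.

## The decision model

The core model is the two-boundary Wiener diffusion.  Evidence `X(t)`
accumulates from a starting point `w·a` with drift `v` and unit diffusion
coefficient between absorbing boundaries at 0 and `a`; absorption at the
upper boundary produces the correct response, at the lower an error, and
the response time is the first-passage time plus a non-decision time `t0`
covering stimulus encoding and motor execution.  Fixing the diffusion
coefficient at 1 resolves the usual scaling degeneracy, so all parameters
are reported on that scale.  The model is the three-parameter variant —
drift `v`, boundary separation `a`, non-decision time `t0` — with the
start point fixed at `w = 0.5`: no bias parameter and no across-trial
variability parameters (`sv`, `st0`, `sz`), which are out of scope here.

The defective first-passage density at each boundary is computed by the
standard series expansion of the standardised density, switching between
the small-time and the large-time expansion by the fewer-terms rule, with
term counts chosen from the published truncation-error bounds so that the
absolute error of a returned density value is below 1e-7 (the internal
tolerance is 1e-9).  `absorption_probability()` implements the closed form
`P(correct) = (1 − e^{−2vaw}) / (1 − e^{−2va})` (with `P = w` in the
driftless limit), and the two defective densities integrate to the two
absorption probabilities, summing to one — both facts are exercised by the
test suite over a parameter grid.

Outlier responses are handled by a contaminant mixture: with fixed
probability `p_c = 0.05` a trial is assumed to arise from a different
process that produces a uniformly distributed response time over the
cell's observed RT range with either response equally likely.  The 5% is
an assumption of the analysis, not an estimated quantity.  Each trial
contributes

```
log[(1 − p_c) · f_WFPT(rt, choice | v, a, t0) + p_c · 0.5 · Unif(rt; window)]
```

and the mixture density is floored at 1e-29 before the log so that a
zero-density RT (for instance an RT at or below `t0` from the contaminant
process) cannot contribute `−Inf`.

## Estimation

`ddm_fit()` maximises the summed mixture log-likelihood over `(v, a, t0)`
per condition cell with a multi-start Nelder–Mead simplex (objective
tolerance 1e-6): one start at the EZ-style moment inversion — the closed
form mapping accuracy and the RT mean and variance to `(v, a, t0)` under
the simple diffusion — plus jittered restarts (five starts by default).
Box constraints are enforced by smooth reparameterisation: `a = exp(θ)`
and `t0` mapped through a logistic into its admissible interval.

One estimation choice deserves a note.  When the likelihood contains the
contaminant component, the smallest observed RT can legitimately lie
*below* the true non-decision time (contaminant RTs start at 0.2 s in the
default generator, while realistic `t0` values are 0.25–0.35 s).
Constraining `t0` below the minimum observed RT would therefore bias `t0`
downward in exactly the regime the mixture is meant to handle, so the
upper bound for `t0` is the minimum observed RT only in the pure-diffusion
case (`p_c = 0`); with contaminants present, `t0` is bounded by the
largest observed RT and the mixture likelihood arbitrates trials that an
estimate would strand below `t0`.

Accuracies of exactly 0 or 1 are edge-corrected to `1/(2n)` from the
boundary before the EZ inversion; an exact 0.5 takes the zero-drift
limiting branch, in which the boundary separation comes from the driftless
decision-time variance `a⁴/24`.  All three parameters are estimated
separately per congruency-by-stimulation cell (no sharing across cells),
matching the analysis the package reimplements; cells in which every
response falls on one side are fitted but flagged, since the drift
magnitude is then weakly identified.

At 1000 trials per cell the fits recover generating parameters with median
relative bias below 5% for `v` and `a` and `t0` within 0.02 s (this is an
acceptance criterion of the test suite).  At the 48 trials per cell of the
emulated design, per-cell estimates are markedly noisier and `v` and `a`
are jointly overestimated in high-accuracy cells with few error trials —
a known small-sample property of diffusion ML.  This is worth keeping in
mind when interpreting single-study drift effects at such trial counts;
the group-level inference remains valid but underpowered, which is why the
package's validation of the inference chain is run at the larger cell
sizes where the estimator is well behaved.

## Group inference

`drift_anova()` runs the two-way fully within-subject repeated-measures
ANOVA (Congruency 3 × Stimulation 2) on the participant-by-cell drift
table, reporting F, degrees of freedom, p and partial eta squared per
effect, plus a Greenhouse–Geisser corrected p computed from the
orthonormal-contrast covariance of the cell scores (the emulated analysis
does not state its sphericity handling, so both uncorrected and corrected
p are emitted).  Degrees of freedom are the standard repeated-measures
values — for n participants the interaction has (2, 2(n−1)) df.  Published
analyses of this design sometimes print other denominator df for the same
interaction (e.g. 70 where n = 15 would give 28); such values are not
derivable from the standard within-subject decomposition and the package
makes no attempt to reproduce them.

`posthoc_drift()` compares active against sham within each congruency
level by paired t-tests with n−1 df, reporting unadjusted p (the
convention of the analyses this mirrors) alongside Holm-adjusted p.

The classical arm uses `lmerTest`/`lme4` random-intercept mixed models on
correct-trial RTs (Type III tests, Satterthwaite denominator df — the
method is recorded in every output, since df-approximation conventions
differ across software), `emmeans` Bonferroni-corrected pairwise
post-hocs, and base `aov` Error-strata decompositions for the
within/between ANOVA on the SCE and its components.  The
`rm_anova_within()`/`rm_anova_mixed()` tables are verified against
independent explicit sums-of-squares computations to 1e-10 in the test
suite.  Accuracy is summarised but never modelled when it is at ceiling,
mirroring the two-track (RT vs accuracy) cleaning convention.

The exploratory covariate analysis (`backward_regression()`) is ordinary
least squares with iterative backward elimination; the removal criterion
`p_out` defaults to 0.10, a conventional choice since the emulated
analysis names the method but not its threshold.  With `p_out = 1` the
full model is retained and with `p_out = 0` selection runs to the
intercept-only model, which the tests use as a monotonicity check.

## Cleaning cascades

`clean_practice()` applies, in order: remove missed trials (no response);
remove incorrect trials (RT track only — the accuracy track keeps them);
remove trials with RT above mean + 2.5 SD.  `clean_tms()` prepends the
coil-deviation filter: trials with the coil 3 mm or more from target
(threshold inclusive) are removed first.  Every stage reports rows in,
rows removed and the removal fraction, and the row accounting is chained
and property-tested.

Two conventions were open and are configurable.  The SD basis for the
2.5 SD trim is per participant by default (pooled across that
participant's conditions within a session), with global and
per-participant-per-condition alternatives — per-participant pooling is
the most common convention in this literature.  Group statistics for
participant-level exclusion (mean RT more than 2 group SD above the group
mean in at least 4 of 6 cells; SCE strictly exceeding mean + 2.5 SD)
include the candidate participant, matching the usual wording of such
rules; a leave-one-out option exists but is off by default.

## The synthetic-data generator

`build_design()` reproduces the trial schedule: digits drawn from 1–9 so
that numerical distances 1–8 are all realizable (pairs uniform over the
admissible set, the larger digit's screen side randomised), block
compositions and counts as above, stimulation-arm order alternating
between participants, and the pulse-triplet timing carried as design
metadata.  Congruency is realised as the condition label only — font size
is not modelled numerically.

`generate_dataset()` adds responses: every non-contaminant, non-missed
trial is drawn from the participant- and cell-specific diffusion via the
Euler–Maruyama sampler (step 1 ms by default; the reference sampler used
for oracle comparisons runs at 0.1–0.2 ms, where the discretisation bias
in the body of the RT distribution is well under 1%), contaminant trials
get uniform RTs on [0.2 s, 3.0 s] (a window spanning the plausible
response range; the emulated study specifies none) with random accuracy,
and missed trials carry no RT and never enter any likelihood.

Defaults were chosen once to echo the emulated study's printed summaries:
cell drifts of 3.4 / 2.8 / 2.0 (congruent / neutral / incongruent) with
`a = 1.0`, `t0 = 0.30 s` give cell mean RTs near 440 / 460 / 490 ms and
stimulation-session accuracy near 90%; active stimulation raises the
congruent drift by 0.5 (the robust stimulation effect reported for this
design); miss rate 4%; 2.1% of stimulation trials have coil deviation at
or beyond 3 mm (sub-threshold deviations are half-normal with SD 1.2 mm);
contaminant proportion 5%.  Participant heterogeneity is additive normal
on `(v, a, t0)` with SDs (0.3, 0.1, 0.03), truncated to keep `a > 0` and
`t0 ≥ 0` — the emulated study is silent on this, but without it
group-level inference tests would be unrealistically optimistic.  Practice
is modelled as multiplicative factors on `v` (0.75 → 1.0) and `t0`
(1.30 → 1.0) across the six pre-stimulation timepoints, reproducing the
gradual speed-up across practice blocks.  The in-scanner block length (48
trials) is an analogy with the practice block, as the emulated design does
not print it.

What the generator does not emulate: sequential dependencies between
trials (post-error slowing, cumulative stimulation carry-over), RT
drift within a block (fatigue), response bias, or any interaction between
coil deviation and behaviour (deviation is sampled independently of the
response process).  Recovery tests passing on this generator therefore
validate the estimation and inference chain, not the adequacy of the
three-parameter model for any particular real dataset.

## Problem sizes used in validation

The test suite validates the density engine against a 10^6-path Euler
simulation (step 0.1 ms) at reference parameters, checks normalisation
over a grid of (v, a, w), and runs parameter recovery with 20 replicates
of 1000 trials.  End-to-end effect recovery uses 15 participants and 1000
trials per cell (the size at which a +0.5 drift shift in one cell is
reliably detectable) over 20 seeds, and the matching null calibration uses
200 replicates of a reduced six-participant, 120-trials-per-cell study
with two optimizer restarts — sizes chosen to keep the estimator in its
well-behaved regime for the effect arm while making the null calibration
cheap, since type-I behaviour is insensitive to cell size.

## Known limitations

* The three-parameter model deliberately omits across-trial variability
  and any dual-stage accumulation account; where those matter the drift
  estimates absorb their effects.
* Per-cell ML estimation at a few dozen trials per cell is noisy and
  jointly overestimates `v` and `a` in near-ceiling cells; hierarchical
  estimation across participants would help but is out of scope.
* Mixed-model denominator df follow the Satterthwaite approximation;
  other software's df conventions will not match exactly, which is why the
  method is stamped into the output.
* The backward-selection regression inherits the usual caveats of
  stepwise inference: the final-model p-values are conditional on the
  selection path.
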