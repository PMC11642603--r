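---
title: "Methods: simulating and analysing dyadic drawing experiments"
author: "dyadicdraw"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing dyadic drawing experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The task and the two questions the pipeline answers

The package models a paired drawing task: on every trial a participant and a
virtual partner are each cued to draw a half circle or a half diamond from a
start point at the top of a vertical corridor to an end point at the bottom.
In the *Joint* context the participant must synchronise, reaching the end
point together with the partner; in the *Parallel* context they draw
alongside but independently, keeping their own pace near 2 s.  Crossing the
two cued shapes gives four combinations (CC, DD, CD, DC; first letter the
participant's shape), grouped into *congruent* (CC, DD) and *incongruent*
(CD, DC) trials.  Catch trials, in which the partner draws the non-cued
shape, force the participant to keep the partner's cue in mind.

Two analyses sit on top of this task.  First, a behavioural one: observing
an incongruent movement distorts one's own movement (visuomotor
interference, VMI), and the question is whether acting jointly attenuates
that distortion.  Second, a neural one: multivariate decoding of epoched
EEG from the delay period between cue and movement asks how the upcoming
own and partner actions are represented under the two social contexts.

# Synthetic data generator

The generator is first-class, tested code: it defines the statistical
structure every downstream stage is validated against.

**Design.**  Defaults are the standard session: 6 blocks of 48 trials per
context with 8 catch trials per block, which yields 576 trials, 60 non-catch
trials in each context-by-combination cell and 12 catch trials per cell.
Cue pairs are a block-level property and alternate across blocks, so each
cell sees both cue pairs equally often in designs with an even number of
blocks.  Partner movement durations are uniform on 1.8-2.2 s (Joint) and
1.6-2.4 s (Parallel); the partner's start time tracks the participant's
block-average start time with a +/-100 ms uniform jitter; participant start
times are truncated below the 800 ms deadline.  Joint delta times
(participant end minus partner end) are drawn as N(0.01, 0.051) s and
Parallel drawing durations as N(1.93, 0.15) s, emulating compliant
participants who synchronise well in Joint and slightly undershoot the
instructed 2 s in Parallel.  Catch detection probabilities default to 0.94
(Joint) and 0.92 (Parallel) with a 1% false-alarm rate.

**Trajectories.**  Each trajectory is the arc-length-uniform ideal shape
sampled at 30 Hz for the trial's drawing duration, plus Gaussian jitter
(default SD 5 px) tapered to zero at the anchors.  VMI is injected as an
additive deflection field: the pointwise difference between the partner's
and the participant's ideal shapes, scaled so its maximum equals the
context's `vmi_shift` (defaults: 3 px Joint, 10 px Parallel).  On congruent
trials the field is identically zero, so interference only appears on
incongruent trials — the simplest mechanism that reproduces
context-dependent distortion.  Swap errors (drawing the non-cued shape) and
gross errors (a random-walk scribble) occur with configurable rates
(default 1% each).

**EEG.**  Epochs are condition-mean patterns plus Gaussian noise with one
global spatial-correlation mixing weight (default 0.2); richer noise
(oscillations, artefacts, autocorrelation) is deliberately out of scope.
Patterns are piecewise constant over the ten 200 ms analysis bins, i.e.
their structure lives at the temporal scale the decoding pipeline reads.
The *integrated* preset writes, in the Parallel context, independent "own
shape" and "partner shape" random directions with amplitude `amp`
(default 0.35 noise-SD units, calibrated so group-level decoding
accuracies and effect sizes land in the realistic 0.6-0.75 / d ~ 1 range);
in the Joint context both shares are fused onto the common own-movement
direction with equal weights, so CD and DC receive *exactly* the same
pattern while the CC-DD separation is matched to the Parallel context's.
Simulated subjects receive lognormal amplitude multipliers (SD 0.6 on the
log scale, mean 1), producing the between-subject heterogeneity that makes
group t-tests informative rather than trivially significant.

## A structural constraint of additive pattern models

A point worth stating explicitly, because it bounds what any linear
generator of this kind can emulate.  Write `u` for the difference between
the CC and DD class means and `v` for the difference between CD and DC.
Because the own-movement contrast pools {CC, CD} against {DC, DD} and the
partner-movement contrast pools {CC, DC} against {CD, DD}, their class-mean
differences are `(u + v) / 2` and `(u - v) / 2` respectively — always.
If the Joint incongruent conditions share one pattern (`v = 0`), the
own-movement and partner-movement analyses in Joint have *identical* class
means and identical noise: they are exchangeable processes, and no
classifier can be expected to decode one but not the other.  A pattern in
which own movement is decodable in Joint, partner movement is not, *and*
incongruent combinations are at chance is therefore unreachable in
expectation under any equal-covariance Gaussian pattern model.  The
integrated preset keeps exact sharing (`v = 0`), which reproduces every
other cell of the qualitative result matrix; both own- and partner-movement
decoding in Joint then sit at the same, roughly half-strength level.  Real
neural data that dissociate the two must depart from additivity — a
substantive observation about the encoding, not a simulation detail.

# Trajectory pipeline

Trajectories are resampled to exactly 100 points by fitting the horizontal
and vertical coordinates separately as cubic splines of the sample index
(the spline routine's default endpoint-cubic boundary handling; natural
boundary conditions visibly distort a 30-sample semicircle near its
endpoints) and evaluating at 100 equally spaced index values.

The swap classifier fits the horizontal coordinate as a function of the
monotone vertical progression with least-squares splines of degree 1 and 2,
one interior knot at the rightmost point (first occurrence on ties).  The
C1 quadratic spline cannot reproduce a corner, so half diamonds favour the
degree-1 fit and smooth arcs the degree-2 fit; the label is the lower
residual sum of squares, with ties (a probability-zero event) labelled
circle under a warning.  Pen noise produces small local reversals of the
vertical coordinate; these are clamped to the running maximum with an
infinitesimal tie-breaking ramp.  Paths whose reversal mass exceeds 80% of
the vertical extent are not function-like in the vertical coordinate and
are flagged unclassifiable (random scribbles sit far above this threshold,
realistic noisy shapes far below).

Gross-error screening is an automated proxy for visual inspection: flag a
path whose length exceeds twice the ideal shape length, or whose maximum
pointwise distance from *both* templates exceeds 300 px.  Both thresholds
are exposed as configuration.

Distortion is the unsigned area between a trial's resampled trajectory and
the participant's template (the pointwise mean of all retained instances of
that shape, pooled over conditions).  The closed polygon formed by the
trajectory and the reversed template is split at every crossing of the two
curves and the absolute shoelace areas of the sub-loops are summed, so
opposite-side lobes accumulate instead of cancelling.  The score is
computed on the resampled representation (the only one with matched
lengths), is symmetric, translation invariant, and zero only for identical
curves.  Curves are assumed to traverse the corridor in the same overall
direction, which orders crossings consistently along both.

Pooled distortions are Box-Cox transformed with a single
maximum-likelihood exponent (profile likelihood optimised continuously;
a 0.001-step grid search is used as the test oracle), then modelled with a
linear mixed model `area ~ context * congruency + (1 | subject)` under sum
contrast coding, REML, and Satterthwaite degrees of freedom (random slopes
are omitted, matching the intercept-only specification).  The directional
hypothesis — larger congruency effects (incongruent minus congruent mean
distortion) in Parallel than Joint — is tested with a one-tailed paired
t-test.  Error counts per design cell go into a Poisson GLM with sum
coding to verify screening symmetry.

# Decoding pipeline

Only trials with an accurate representation of the partner's cue enter:
correctly detected catch trials are kept, missed catches and false-alarmed
regular trials are excluded.

For each of the four contrasts (CD vs DC, CC vs DD, own movement, partner
movement) and each context, the pipeline builds 10 supertrials per class by
averaging 4 trials: pure-condition contrasts average four same-condition
trials balanced two-and-two over cue pairs; own/partner contrasts average
one trial from each condition-by-cue-pair cell of the class.  Averaging is
without replacement within one permutation.  Each supertrial is demeaned
per channel over the epoch and averaged into ten 200 ms bins over the 0-2 s
delay window.  Bins are half-open time intervals, so at 128 Hz they hold 25
or 26 samples — time-defined binning is the only reading consistent with
"ten 200 ms bins" at this rate.  The 640-dimensional feature vectors feed a
two-class LDA whose pooled class-centred covariance is shrunk toward the
scaled identity with the Ledoit-Wolf coefficient; the weight vector solves
the shrunk system against the class-mean difference (the least-squares
formulation), with the threshold at the projected midpoint.  For wide data
the solve goes through the Woodbury identity on the Gram matrix, which is
exact and keeps the per-fit cost linear in the feature count.  Accuracy
comes from stratified 5-fold cross-validation (training sets of 16,
test sets of 4, both classes equally represented), and the whole
pipeline — fresh supertrial draw, folds, fit — repeats 100 times
(configurable); the mean over repetitions is the subject's empirical
accuracy.  The null pipeline is identical except that supertrial class
labels are reshuffled, balanced 10/10, in every repetition.  Folds are
re-randomised with each repetition's child seed.

Group inference: one-tailed paired t-tests of empirical versus null
accuracies per contrast and context; two-tailed paired t-tests comparing
empirical accuracies between contexts; Cohen's d and the default JZS Bayes
factor (Cauchy scale 0.707, integrated numerically) accompany each test.

Implementation note: per-trial binned features and per-trial channel means
are precomputed once; a supertrial's demeaned binned features are then the
member average of binned features minus the replicated member-average
channel means.  This is algebraically identical to average-demean-bin on
raw data (both operations are linear) and is asserted to machine precision
in the tests.

# Channelwise decoding and cluster inference

The spatial pipeline reuses the same supertrial, binning, CV and
permutation machinery but restricts the feature vector to one channel's
ten bins (the per-channel feature set mirrors the spatiotemporal pipeline
for symmetry), sharing the supertrial draw and fold assignment across
channels within a permutation.  Per-channel accuracies are tested against
chance with one-sample t statistics, thresholded at the
two-sided-equivalent t for p = 0.05 applied one-sided (only above-chance
decoding is meaningful), clustered over the Delaunay adjacency of the
flattened sensor positions, and summarised by summed t.  Significance comes
from the maximum-cluster-statistic distribution under random per-subject
sign flips of the accuracy deviations (default 1000 permutations; the
cluster p is the fraction of permutations reaching the observed mass).
The bundled montage is a synthetic, idealised 64-sensor layout (concentric
rings, deterministic angular offsets that avoid cocircular degeneracies);
it stands in for a standard 64-electrode arrangement and is labelled as
synthetic in its filename.

# Seeds, determinism and numerical choices

Every source of randomness descends from one master seed through a
counter-based child-seed scheme (`derive_seed`), so designs, trajectories,
epochs and accuracies are bit-identical across reruns.  Degenerate inputs
fail loudly rather than silently: fewer than four distinct pen samples,
missing condition patterns, insufficient cell counts (the error names the
cell), zero-variance t-tests, all-zero count models, non-positive Box-Cox
input, duplicate or collinear sensor positions.  Mixed-model fits that do
not converge return an explicit failure status, and Satterthwaite degrees
of freedom are reported or the fit is refused — residual degrees of freedom
are never silently substituted.

# Problem sizes used by the test suite

The statistical properties are verified at sizes chosen to make the checks
sharp yet quick on a single CPU, and stated here as the package's own
simulation design: group-level null calibration uses 200 simulated
experiments of 6 subjects with a reduced pipeline (16 channels, 32 Hz,
5 supertrials per class, 20 permutations); the integrated-preset recovery
uses 20 subjects at the full 64-channel geometry with 20 permutations;
the VMI recovery uses 100 simulations of 10 subjects with 12 trials per
context and the planted 10 px Parallel shift (and 100 null simulations);
cluster inference uses a planted 6-channel patch over 20 subjects and 200
null experiments at 300 sign-flip permutations.  Monte-Carlo coverage
checks are asserted as binomial bounds on the true rate rather than raw
proportions, so they fail only when a rate is genuinely below its floor.

# Known limitations

The generator's Gaussian equal-covariance patterns cannot dissociate
own- from partner-movement decoding in a context whose incongruent
conditions share a pattern (see the structural constraint above).  The
trajectory noise model is white and isotropic; real pen kinematics have
autocorrelated, speed-dependent noise.  The adaptive practice loop,
EEG preprocessing (filtering, ICA, artifact rejection) and vendor file
formats are out of scope: the pipeline starts from clean epoched data.
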