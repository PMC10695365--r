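---
title: "Methods: simulating and analyzing social behavior in group-housed rodents"
author: "grouptrax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing social behavior in group-housed rodents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grouptrax)
```

# What the package models

grouptrax is a pipeline for studies that ask how individual behavioral
traits relate to the formation of social relationships in small groups of
laboratory rodents. The empirical design it supports is: a battery of five
behavioral tests (glove, open field, novel object, three-chamber, elevated
plus maze) summarized into 13 per-subject indices; video tracking of groups
of four animals in a home cage over nightly sessions across two multi-day
terms; per-subject social interaction indices computed from the trajectories;
and a statistical layer (PCA, ICC consistency, mixed models, correlation
panels) connecting traits to social behavior.

Because raw multi-animal recordings are rarely shareable, every stage is
driven by a synthetic-data module with known ground truth, so the whole
pipeline is testable end to end: the simulator's planted parameters are the
reference against which detection, repair and statistics are validated.

# The movement simulator

`simulateGroup()` runs four agents through a bounded correlated random walk.
At each time-step an agent's drift vector mixes three pulls:

* persistence along the previous heading (fixed weight 0.5),
* attraction toward each group mate, as a unit vector weighted by the
  agent's per-partner attraction weight in [0, 1],
* pull toward a per-agent home-base point (weight `homeAffinity`), placed by
  default at the cage corners, standing in for the tendency of rats to keep
  a home base.

The step direction is the drift angle perturbed by Gaussian noise
(`noiseSd`, radians); step length is exponential with mean `activity` (cm
per time-step), so `activity` is the agent's mean step length. Walls
reflect; after a reflection the heading follows the realized displacement.

Defaults mirror the emulated housing conditions: a 91 × 54 cm cage,
nine-hour sessions, seven days per term. The simulated frame rate defaults
to 5 Hz — a deliberate desk-scale choice rather than a camera's native
rate; all quantities downstream are expressed per second, so the rate only
sets temporal resolution. Familiarity (which cage mate an animal was raised
with) is bookkeeping carried in the container's `colData`: it influences
movement only through whatever attraction weights the caller assigns,
reflecting the design decision that partner preference need not follow
familiarity.

Determinism: each day's trajectories are a pure function of (traits,
config), simulated under a child seed derived from the config seed; the
caller's RNG state is saved and restored.

## What the simulator does not emulate

Thigmotaxis, shelters and feeding sites, circadian activity structure
within a session, body posture and contact types, and the color-marker
failure modes of real video tracking. Corruption rates in
`corruptTracks()` are therefore free parameters, not calibrated to any
particular tracking system. Passing parameter-recovery tests shows the
pipeline's internal consistency on this model class, not performance on any
specific real dataset.

# Track corruption and repair

`corruptTracks()` injects the three failure modes the repair stage targets:
per-animal-frame dropout (Bernoulli), pairwise identity swaps over disjoint
contiguous spans (geometric lengths, mean 10 frames), and single-frame
displacements of 30–60 cm ("jumps"). A ground-truth log is returned;
applying the logged swaps twice restores the input, which the tests use as
an involution check.

`repairTracks()` runs three stages in order:

1. **Identity-swap resolution** (`resolveSwaps()`): per frame, the observed
   positions of the currently valid animals are re-assigned to labels so
   that total displacement from each label's last resolved position is
   minimal (exhaustive assignment over at most four animals). Incumbent
   labels are kept unless an alternative wins by more than `marginCm`
   (default 10 cm). The hysteresis matters: when two animals sit within a
   step length of each other, noise makes the exchanged labels marginally
   cheaper about half the time, and a margin-free assignment introduces
   persistent spurious swaps. A genuine swap displaces each affected animal
   by the inter-animal distance, so any margin above a few step lengths and
   below typical inter-animal distances separates the two cases; when
   animals are closer than the margin, a missed swap is within the accuracy
   tolerance anyway.
2. **Speed gating** (`flagImplausible()`): frames whose implied speed from
   the last valid frame exceeds `maxSpeed` (default 100 cm/s, a generous
   bound for rat locomotion) are invalidated. Swaps are resolved first so
   that genuine swap spans are relabelled rather than flagged away.
3. **Bounded interpolation** (`interpolateGaps()`): invalid runs of at most
   `maxGap` (default 1 s of frames) flanked by valid frames are linearly
   interpolated and marked imputed; longer runs and edge runs stay invalid
   — no extrapolation.

`estimationAccuracy()` scores a repaired session as the fraction of
animal-frames (among frames valid in the reference) within `tol` of the
reference position. The default tolerance of 5 cm is roughly a quarter of
an adult rat's body length; the accuracy definition is an explicit stand-in
for the per-frame position checks used with real tracking, whose exact
criterion is system-specific.

# Behavioral-test indices

The 13 battery items (`batteryItems()`) follow the standard apparatus
conventions built into the zone helpers: an 80 cm open field divided into a
5 × 5 grid of 16 cm blocks with the central nine blocks as the center zone
and the central block as the object zone; a three-chamber arena split into
three equal compartments; an elevated plus maze of two open and two closed
50 × 10 cm arms around a 10 cm hub.

Counting conventions, fixed once and used everywhere: a zone entry is a
transition from outside to inside between consecutive valid frames —
starting inside does not count until the animal exits and re-enters; there
is no minimum dwell (debouncing is left to the sampling rate); the single
tracked point stands in for the head in the object-zone count; an arm entry
is the tracked point crossing the arm's mouth. Open-field and three-chamber
distances and entry counts are divided by the recording duration because
recording lengths vary between subjects; novel-object and three-chamber
indices are test-minus-habituation differences to control for baseline
activity; three-chamber sociability enters as the habituation-corrected
preference ratio (entries into the animal compartment over entries into
both stimulus compartments). Glove-test durations merge overlapping
same-label intervals before summation.

# Social interaction metrics

A dyad is *in proximity* when inter-individual distance is at or below
`thresholdCm`. The default of 20 cm is about one adult body length without
the tail; it is configurable and recorded in the run configuration.
Proximity and non-proximity bouts shorter than `minBoutS` (default 2 s) are
absorbed into the surrounding state, so momentary threshold grazes neither
break a bout nor create one.

Missing data policy: frames where either animal of a dyad is invalid are
excluded from both numerator and denominator, and times are rescaled to the
nominal session duration by the valid fraction. Exclude-and-rescale was
chosen over carry-forward because carrying the last position forward
inflates proximity exactly when tracking fails (e.g. during close contact).
A dyad-day with less than half its frames valid is flagged unusable.

Each proximity onset is one *approach* event and each offset one
*avoidance* event; the session's starting state generates no event. The
mover is the dyad member with the greater path length over the `windowS`
(default 3 s) preceding an onset or following an offset; exact ties keep
the event but mark the mover ambiguous, excluding it from per-subject
counts. Nine per-subject indices result: isolation time, proximity with
the familiar and (mean over the two) unfamiliar partners, and approach and
avoidance counts split the same way plus totals; the totals satisfy
`total = familiar + 2 × unfamiliar_mean` exactly. Published tables of this
design often show seven index rows (dropping the two totals); the package
emits all nine.

Daily indices are averaged over the usable days of each term, with
per-group day exclusions (camera failures) taken from the run
configuration. Because groups differ systematically in overall proximity,
indices are standardized by the group mean (every group × index then has
mean exactly 1); a zero group mean is flagged non-standardizable rather
than divided through.

# Statistics

**PCA.** `pcaBattery()` z-scores columns internally, so the decomposition
is of the correlation matrix; loadings are unit-norm eigenvectors, ordered
by descending eigenvalue, each column sign-oriented so its
largest-magnitude item is positive. Proportions of variance are eigenvalues
over their total and sum to one. Component retention exposes both the
Kaiser criterion (`kaiserCount()`, strictly greater than 1) and a fixed
`nKeep` (default 4), because substantive arguments can override Kaiser in
either direction. `salientAssignment()` applies the salient-loading rule
with cutoff 0.4 on the *absolute* loading — the two-sided reading is
deliberate, since strong negative loadings mark an item as characterizing a
component just as well — and assigns multi-salient items to the component
with the larger |loading|.

**ICC.** `icc3k()` is the two-way mixed, consistency, average-measures
intraclass correlation, computed from the two-way ANOVA without
interaction: ICC(3,k) = (BMS − EMS)/BMS with BMS the between-subject and
EMS the residual mean square. Occasions containing missing values are
dropped column-wise with k adjusted. Negative estimates are reported as
computed (not truncated to zero) for transparency, and classified with
everything below 0.4 as "low"; 0.4–0.7 is "moderate" and above 0.7
"substantial".

**Mixed model.** `lmmFamiliarityLrt()` fits, by maximum likelihood, a
Gaussian random-intercept model of partner proximity on familiarity with a
subject random effect, against the null without familiarity; the LRT
statistic 2(ℓ₁ − ℓ₀) is referred to χ²(1). The unit of analysis is the
directed (subject, partner) pair — each subject contributes one familiar
and two unfamiliar rows — with the subject intercept absorbing individual
sociability; an undirected per-dyad configuration is a reasonable
alternative but conflates the two members' individual effects, so the
directed layout is the default. A familiarity column without variation
returns the degenerate χ² = 0, p = 1; convergence warnings are reported in
the result, never swallowed.

**Correlation panels.** Pearson correlations with Fisher-z 95% confidence
intervals; cells with |r| ≥ 0.4 are flagged moderate-to-high. No multiple
testing correction is applied anywhere — the framing is exploratory and
every p-value is labelled unadjusted. Components listed in `invert`
(default PC3) have their *displayed* values sign-inverted only, the common
convention when an axis's raw loadings point in the counter-intuitive
direction (e.g. "less active" scoring high); the stored `r` is untouched,
and trait-similarity correlations are unaffected since |Δscore| is
sign-invariant.

**Trait similarity.** For each retained component, the correlation between
a dyad's absolute score difference and its standardized proximity time;
directional indices (approaches, avoidances) are excluded from this
analysis by design since similarity is symmetric.

# Recovery-study design and numerical choices

*Noiseless identifiability.* The exact-recovery test plants an orthogonal
loading matrix with disjoint item support, unit row norms, and distinct
column norms (5, 4, 3, 1 items), with latent scores whitened so the sample
covariance is exactly the identity. Under that construction the sample
correlation matrix is exactly `L Lᵀ` with distinct nonzero eigenvalues, so
the eigenvectors are identified up to sign and recovery to 10⁻⁶ is a sharp
test of the PCA path.

*Noisy recovery.* The default simulated battery (`defaultLoadingMatrix()`)
mirrors the emulated design: items load chiefly on their own test's factor
(novel object → exploration, elevated plus maze → boldness, open field →
activity, glove → tameness) with the three-chamber items loading on none,
echoing the empirical finding that sociability does not surface as a major
axis. Recovery at n = 18 subjects and noise SD 0.3 is scored by Tucker
congruence after orthogonal Procrustes alignment of the recovered to the
planted columns. Alignment is the standard choice in factor-recovery
simulation because components with close population eigenvalues (here the
exploration and boldness factors) are only identified up to rotation within
their subspace; per-column matching without alignment measures that
indeterminacy, not recovery quality.

*Debouncing.* Bout absorption works on the run-length encoding, repeatedly
flipping the shortest sub-threshold run; each flip merges three runs, so
the procedure terminates, and flipping the shortest first makes the result
order-independent in the common cases.

*Degenerate inputs.* Constant battery columns are rejected by name; ICC
with no between-subject variance is undefined and classed low; correlation
cells with zero variance or fewer than 4 paired observations are NA and
flagged; subjects with fewer than two partner rows abort the mixed model.

# Problem sizes in the test and acceptance suites

The shipped suites scale sessions down so the full pipeline runs in
minutes: conservation and pipeline determinism checks use 2–10 minute
sessions over 3-day terms; attraction recovery uses 10-minute sessions over
7 days and 20 seeds; repair-floor checks use 10-minute sessions and 10
corruption seeds; the LRT calibration uses 200 simulated datasets of 12
subjects × 3 partners. These sizes are the package's own choices for a
reproducible desk-scale validation; all defaults remain at the full
housing-study scale (nine-hour sessions, seven days).

# Known limitations

* Identity repair uses kinematic continuity only; appearance-based identity
  recovery is out of scope, so long simultaneous occlusions of two animals
  are unrecoverable in principle.
* The movement model has no interaction besides pairwise attraction — no
  avoidance dynamics, no following chains — so avoidance-event statistics
  exercise the detection path, not a behavioral theory of avoidance.
* Statistical worked examples that depend on unreleased raw recordings are
  validated against their published summary tables, not recomputed from
  video.
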