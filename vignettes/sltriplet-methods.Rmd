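---
title: "Measuring statistical learning from triplet streams: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring statistical learning from triplet streams: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sltriplet)
```

## The paradigm

`sltriplet` analyzes triplet-embedded statistical learning (SL)
experiments. In each task, 12 stimuli are grouped into four fixed,
ordered triplets. The familiarization stream concatenates these triplets
in randomized order so the transitional probability is 1 within a triplet
and far lower across triplet boundaries. Children perform an incidental
target-detection task during familiarization (pressing a key whenever the
third element of one designated triplet appears), then a 32-trial
two-alternative forced-choice (2-AFC) test phase contrasting each triplet
with recombination foils.

Four task configurations cross sensory modality with domain: `image`
(visual nonlinguistic), `letter` (visual linguistic), `tone` (auditory
nonlinguistic), `syllable` (auditory linguistic). Visual tasks use a
1000 ms stimulus onset asynchrony (SOA) and 24 repetitions per triplet
(288 events, 96 triplet presentations); auditory tasks use a 480 ms SOA
and 48 repetitions (576 events, 192 presentations). These constants are
frozen in `task_config()` and asserted by the test suite.

Two learning measures are computed per participant and task:

* **Online learning — the RT slope.** Hit latencies are z-scored within
  participant and task, then regressed (OLS) on the target occurrence
  index (1..24 visual, 1..48 auditory). A negative slope means responses
  speed up as the predictive triplet structure is learned. z-scoring
  first removes baseline RT differences between participants, domains,
  and modalities.
* **Offline learning — 2-AFC accuracy**, the proportion of test trials
  where the familiar triplet was chosen; 0.5 is chance.

The **composite SL score** for a task is the mean of the z-normed
reversed slope and the z-normed accuracy, with norms computed over the
whole pooled sample (both diagnostic groups; a `norm_within_group` flag
exists for sensitivity analyses). **Domain composites** average a
participant's four z-normed components (two reversed slopes, two
accuracies) within the linguistic and nonlinguistic domains, using the
components that exist: children who stopped after three tasks, or who
were excluded from RT analyses, contribute whatever they have.

## Scoring keypress logs

A keypress may respond to a target anticipatorily or late, so the
acceptance window spans one stimulus before to two after target onset,
`(-SOA, +2 SOA)`: (−480, +960) ms auditory, (−1000, +2000) ms visual.
Assignment is one-to-one: contested keypresses go to the target with the
smaller absolute latency, ties to the earlier target, deterministically
and order-independently (with the standard designs, windows of successive
targets can at most touch at a boundary point, so arbitration is rarely
exercised; the test suite checks it against an exhaustive matching
oracle anyway). Unassigned keypresses are false alarms, attributed to the
stimulus event whose SOA interval contains them; the false-alarm
denominator is the number of non-target events.

Sensitivity is Grier's nonparametric A′ from the hit and false-alarm
rates (0.5 chance, 1 perfect). Two exclusion rules remove participants
from RT analyses only (never from 2-AFC accuracy): fewer than 6 assigned
hits in a task; then, among the survivors, A′ strictly below the group ×
task mean minus 3 SD. "Valid keypresses" is interpreted as assigned hits,
because only hits carry an RT into the slope; the count rule runs first
and the A′ rule is computed on its survivors, per diagnostic group and
task. Both thresholds are arguments. A stratum with fewer than two
survivors skips the A′ rule with a warning. Re-applying the rules is a
no-op (flags are recomputed from counts and A′, not accumulated).

## The behavioral simulator

`simulate_cohort()` generates complete synthetic datasets — participants,
streams, keypress logs, 2-AFC responses — with known ground truth, so
every downstream stage has a parameter-recovery test bed.

**RT model.** Latencies are linear in target occurrence index on a latent
z scale: `latency = baseline + rt_scale_ms * (b * (t - mean(t)) + e)`,
`e ~ N(0, rt_noise_sd_z)`. The coefficient `b` is calibrated as
`b = s * rt_noise_sd_z / sqrt(1 - s^2 * Var(t))` so that the *expected
OLS slope of the sample-z-normed latencies* equals the nominal true slope
`s`. This matters: sample z-norming divides by the total (trend + noise)
SD, so a naive `b = s * sd` parameterization would make every recovered
slope biased toward zero by a design-dependent factor. With the
calibration, slope recovery is unbiased under the RT model (verified by
Monte Carlo in the test suite).

**Contamination processes.** With probability `anticipation_prob` a hit
is replaced by a guess uniform in the negative half of the window; each
non-target event triggers a false alarm with probability `fa_rate`,
uniform within its SOA interval; hits are emitted with probability
`hit_prob`. These produce realistic hit/FA tallies for A′ and the
exclusion rules. They also attenuate slope estimates — anticipations and
window-captured false alarms are latencies decoupled from the learning
trend, inflating the z-norm denominator — which is a property of the
OLS-on-z measure itself, not of this implementation. Recovery checks that
quantify the RT model therefore run with the contamination processes
off; cohort defaults keep them on.

**Defaults as study conditions.** Group sizes 50 TD / 55 ASD; ages
truncated-normal 8.63 ± 1.89 (TD) and 8.28 ± 1.20 (ASD) on 6–12.6 years;
girls 28/50 and 10/55; about one participant in eight missing one task
completely at random; sentence-recall raw scores 27.26 ± 4.61 (TD) and
19.91 ± 8.18 (ASD) on the 0–32 scale, available for roughly two-thirds of
each group; 26/46 ASD children rated below age level in language. Cell
means of the effect map emulate the qualitative result pattern (a TD
advantage concentrated in the linguistic domain): TD linguistic slope
−0.012 / accuracy 0.61, TD nonlinguistic −0.004 / 0.63, ASD linguistic
−0.004 / 0.55, ASD nonlinguistic −0.006 / 0.61. Between-participant slope
SD is 0.02 z/occurrence — children's slope distributions include many
non-learners, so individual spread is large relative to group means —
and per-participant accuracies are Beta with concentration 40 around the
cell mean. Baseline RT is 450 ± 80 ms with 150 ms per latent z unit and
trial noise 0.4 z.

**Individual-difference structure.** A latent linguistic-ability factor
couples the two linguistic tasks' slope and accuracy draws (Gaussian
copula onto the Beta accuracy marginal, so cell means are untouched),
with correlation 0.7 in TD and 0 in ASD; this reproduces the coupling of
written- and spoken-language SL seen in typical development and its
absence in autism. The same factor drives the sentence-recall coupling
(0.5 ASD, 0.2 TD — TD scores sit near ceiling) and the parent-rated
language level of ASD children.

**What the simulator does not emulate.** RT distributions are Gaussian on
the latent scale (real RTs are right-skewed); misses and false alarms are
time-homogeneous rather than fatigue- or attention-driven; missing tasks
are missing completely at random; 2-AFC trials are conditionally
independent given the participant's accuracy (no item effects, though
the accuracy model estimates item intercepts); there is no session,
device, or web-delivery variability. Passing recovery tests therefore
shows the pipeline's statistics are computed correctly and are powerful
under a plausible behavior model — not that the model captures every
feature of children's data.

## Group-level inference

* **One-sample learning tests**: slopes against 0 (one-tailed, "less"),
  accuracies against 0.5 (one-tailed, "greater"), per group and task. A
  cell constant at the null value returns t = 0, p = 0.5 with a
  `degenerate` note (a constant cell away from the null is an error).
* **Hit-level RT model** (`fit_rt_mixed_model`): z-RT on group × domain ×
  modality × centered trial order (full factorial) plus sex, random
  intercepts for participants with by-participant domain and modality
  slopes.
* **2-AFC accuracy** (`fit_accuracy_mixed_logistic`): trial-level
  logistic regression with the same fixed factorial (no order term), sex,
  random intercepts for participants and items plus by-participant domain
  and modality slopes. Cells with all-identical outcomes raise a
  separation flag; a constant outcome returns a flagged, coefficient-free
  fit.
* **Composite model** (`fit_composite_model`): task-level scores on group
  × domain × modality plus sex with a participant random intercept; an
  `outcome` argument lets the same machinery test, e.g., raw slopes.
* **Development** (`development_analysis`): the continuous model group ×
  domain × centered age, then a median split on pooled age (ties go to
  the younger half — a deterministic rule, logged with subgroup sizes)
  with per-subgroup group × domain models keeping age as a covariate.
* **Correlations** (`correlation_suite`, `partial_correlation`,
  `compare_correlations`): pairwise Pearson correlations between task
  composites within group, partial correlations via the precision-matrix
  identity with `df = n − 2 − k`, Holm adjustment by default
  (Bonferroni and BH available), and the Fisher-z test for comparing two
  independent correlations.
* **Effect sizes and error bars**: Hedges-corrected standardized mean
  differences (`effect_size_g`, correction `1 − 3/(4 df − 1)`), and
  Cousineau-Morey within-group standard errors (`morey_within_se`;
  participant means subtracted, grand mean added, per-condition SE scaled
  by `sqrt(M/(M−1))`).

### Numerical and design choices

* **Factor coding** is sum-to-zero by default with fixed level orders
  (TD, linguistic, auditory, F are the positive poles), so lower-order
  terms are interpretable as main effects in the presence of
  interactions; treatment coding is a switch. Consequently coefficients
  are contrasts on the ±1 scale (a cell-mean difference-in-differences
  divided by 4 for a two-way interaction).
* **Trial order** is centered within task, because the visual and
  auditory designs use different index ranges (1..24 vs 1..48).
* **Degrees of freedom** for linear mixed models use the Satterthwaite
  approximation (`lmerTest`); logistic models report Wald z.
* **Singular fits** trigger a deterministic fallback ladder — drop the
  by-participant modality slope, then the domain slope, then keep the
  intercept-only structure — with the structure actually used recorded
  in the returned object. (With within-participant-task z-normed RTs,
  participant intercept variance is near zero by construction, so the
  ladder is exercised routinely.)
* **Degenerate inputs**: constant outcomes yield flagged
  zero-coefficient fits; a constant covariate (e.g. one-sex subgroups)
  is dropped from the formula; zero-variance latency sets are flagged
  and excluded from slope fitting; identical ages make the median split
  an error.
* **The sex covariate** is included in all group-difference models, as
  group and sex ratio are confounded in the emulated design.

## Monte-Carlo validation and problem sizes

The test suite validates the pipeline end to end at these sizes, chosen
to give stable rates while keeping a default test run comfortable on one
CPU:

* *Design arithmetic*: exact counts for all four task configurations.
* *Oracle equivalence*: OLS slope vs the closed form on 1000 random
  fixtures (agreement ≤ 1e−10); A′ vs an independent coding of the
  formula on the 99 × 99 rate grid; partial correlations vs the
  residual-method oracle.
* *Parameter recovery*: a planted TD-only linguistic slope advantage
  (TD-linguistic true slope −0.030 vs −0.005 elsewhere, accuracies
  equal, contamination and ability coupling off so errors are
  exchangeable and planted values are true z-slopes) recovered — correct
  interaction sign with p < 0.05 — in ≥95% of 200 cohorts at study scale
  (50 TD / 55 ASD). Per-participant slope recovery r > 0.8 with 48
  targets at noise 0.4 z (200 participants).
* *Type-I control*: with identical cell means everywhere, the composite
  group × domain interaction rejects at 0.05 ± 0.03 over 300 null
  cohorts.
* *Exclusion correctness and invariances*: planted fixtures for both
  exclusion rules; composites invariant (≤ 1e−10) to constant shifts of
  all raw RTs; the Fisher-z comparison antisymmetric and zero for equal
  correlations.

Monte-Carlo cohorts share one familiarization stream per task (the
target triplet is still randomized per participant). Stream order is
response-independent, so sharing leaves the distribution of every test
statistic unchanged while cutting simulation cost several-fold; single
cohorts default to per-participant streams.

## Known limitations

* The hit-level RT mixed model is validated on planted single datasets,
  not by a full replicate Monte Carlo (hundreds of random-slope `lmer`
  fits are disproportionate to what they would add); the planted
  slope-advantage recovery runs through the participant-level slope
  model, which estimates the same group × domain contrast.
* Contamination (anticipations, false alarms) attenuates OLS-on-z slope
  estimates; analyses of real data inherit this property of the measure.
* Coefficients depend on the factor coding; numeric agreement with any
  particular published coefficient table is not expected and not a goal.
* The simulator's language-level and sentence-recall couplings are
  phenomenological (a single latent factor), sufficient for exercising
  the correlation analyses but not a developmental model.
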