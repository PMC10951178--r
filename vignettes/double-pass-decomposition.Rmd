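---
title: "Decomposing visual-search misses into stochastic and deterministic errors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing visual-search misses into stochastic and deterministic errors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(doublepass)
library(dplyr)
```

## The question and the model

Observers searching for a clearly visible target (a rotated T among rotated
Ls) still miss it on some fraction of trials. Two qualitatively different
mechanisms can produce such misses. A *stochastic* error strikes at random: a
lapse of attention, a premature response. A *deterministic* error is tied to
the display itself: some configuration — most plausibly a low-contrast target
on a cluttered background — makes the target effectively unfindable, so the
observer would miss it again if the identical display returned.

The double-pass paradigm separates the two by presenting every display twice
and looking at the consistency of the misses. Let `P1` and `P2` be the miss
rates on the first and second appearances of the target-present displays, and
`P12` the proportion of display pairs missed on both appearances. If all
errors are stochastic, the two passes are independent and `P12 = P1 * P2`; if
all errors are deterministic, the same displays fail every time and
`P12 = min(P1, P2)`; mixtures fall strictly between the two bounds.

The generative model behind the quantitative decomposition gives every
target-present display a latent *unfindability* indicator drawn once per
display. An unfindable display (probability `d1` on the first pass) is missed
with certainty; a findable one is missed with the round-specific stochastic
probability `s1` or `s2`. Findable displays never become unfindable, but an
intervention on the second pass (cueing) may convert unfindable displays to
findable ones, so the second-pass unfindability `d2` satisfies `d2 <= d1`.
Collecting terms gives the three observables:

$$P_1 = d_1(1-s_1) + s_1$$
$$P_2 = d_2 + s_2(d_1-d_2) + (1-d_1)\,s_2$$
$$P_{12} = d_2 + s_2(d_1-d_2) + s_1(1-d_1)\,s_2$$

With no intervention, determinism is assumed constant across passes
(`d = d1 = d2`) and the system inverts in closed form:

$$d = \frac{P_{12}-P_1P_2}{1-P_1-P_2+P_{12}},\qquad
  s_1 = \frac{P_1-P_{12}}{1-P_2},\qquad
  s_2 = \frac{P_2-P_{12}}{1-P_1}$$

With a cue on the second pass only, `d2` and `s2` remain uniquely determined
by the same expressions, while `d1` is borrowed from the same participant's
uncued displays (deterministic errors persist when nothing intervenes) and
`s1 = (P1 - d1)/(1 - d1)`. Because the uncued `d` is a noisy estimate, the
borrowed value occasionally exceeds the cued set's `P1`, driving `s1`
negative; such participants are flagged and excluded from parameter
comparisons, mirroring the analysis convention of the paradigm.

`compose_rates()` implements the forward equations, `solve_nocue()` and
`solve_cue()` the two inversions. The round trip is exact to floating
precision, which the test suite asserts over ten thousand random parameter
draws.

### Estimator conventions

Three numerical conventions matter in practice.

* **Near-zero negatives.** With true `d` near 0, sampling noise makes the
  solved `d` slightly negative about half the time. Values in `[-0.002, 0)`
  are rounded up to 0 and flagged `rounded_d`; values below `-0.002` flag the
  estimate `excluded` (`d_below_threshold`). The raw value is always kept
  alongside the flags — recovery simulations must see the uncensored
  estimator, because averaging only the surviving estimates biases the cohort
  mean upward.
* **Degenerate denominators.** `P1 = 1`, `P2 = 1` or
  `1 - P1 - P2 + P12 = 0` (within 1e-9) would send the solver to infinity;
  such cells are flagged `degenerate_denominator` instead. They do not arise
  at realistic miss rates.
* **No silent clipping.** Estimates outside `[0, 1]` are reported as-is with
  flags, never truncated.

## What the simulator emulates

`simulate_participant()` realizes the four-state model literally: per
present display one unfindability draw (persisting across copies, with the
`d1 -> d2` conversion applied only where the second copy is cued), an
independent stochastic draw per trial, and false alarms at `fa_rate` on
absent trials. Each trial records its latent state (`det_miss`,
`unfindable_stoch_miss`, `stoch_miss`, `hit`, `correct_reject`,
`false_alarm`), so tests can check the mechanism and not just the marginal
rates.

Three design dialects are generated by `build_design()` at the published
sizes: 300 displays / 600 trials for the uniform-background task, 256
displays / 512 trials for the controlled-contrast task (2 presence x 2 set
size x 8 signed contrast levels x 4 quadrants, two arrays each), and the
cued variant that splits the 256 displays into noCue–noCue and noCue–Cue
halves at random per participant. Backgrounds for the noisy dialects are
seeded `1/f^1.3` textures synthesized in the frequency domain (white noise
shaped by `f^(-1.3/2)` in amplitude, standardized, mapped to 8-bit grays at
mid-gray mean). The default rendering resolution is 1000 x 1000 pixels,
the size of the pre-generated stimulus dialect; positions and sizes are
expressed as fractions of screen height throughout, because the paradigm
specifies geometry only relative to the screen.

Optionally, a `contrast_link = c(threshold, slope)` makes per-display
unfindability a decreasing logistic function of absolute target-background
contrast, `d1 * plogis((threshold - |T-B|)/slope)`. This reproduces the
qualitative signature of interest — low-contrast targets drive deterministic
errors — and is the mechanism the contrast-stratified analyses are tested
against.

Reaction times are lognormal per cell with a positive set-size slope, slower
absent trials, and a second-pass speed-up on absent trials; outliers
(RT x 10) and motor-correction flags are injected at configurable rates.
These defaults are plausibility choices, not empirical claims: they exist so
the exclusion pipeline has realistic material to act on. What the simulator
deliberately does *not* model: eye movements or any spatial search process,
RT-accuracy coupling, fatigue or drift within a session, and response
timeouts. Passing recovery tests therefore show that the estimation chain is
correct under the model's own assumptions — not that human data obey those
assumptions.

## The exclusion pipeline

`preprocess_cohort()` applies the published exclusion sequence in its listed
order:

1. extreme screen — RTs above 100 s are flagged first, so they cannot
   distort the cell statistics;
2. per-cell trim — within each participant x target x set-size cell (plus
   repetition and cue condition in the cued dialect), RTs strictly outside
   mean ± 2.5 SD are flagged; boundary equality is retained;
3. motor-corrected trials are removed;
4. pair removal — a removed trial always takes the other copy of its display
   with it, so everything downstream sees complete pairs only;
5. participant screening — d' = z(HR) − z(FAR) per participant (boundary
   rates corrected by the half-count rule, 1 -> (n-0.5)/n, 0 -> 0.5/n);
   participants beyond 2.5 SD of the group mean d' are excluded.

Whether the 2.5-SD trim should be computed before or after removing
motor-corrected trials is ambiguous in the source procedure's wording; this
implementation follows the listed order (trim statistics computed with
corrected trials still present) and keeps the stages exposed as separate
functions (`trim_rts()`, `pair_removal()`, `dprime()`,
`screen_participants()`) so the alternative composition is one pipe away.
The bookkeeping identity — outlier % + corrected % + pairing % + remaining %
= 100 — is asserted in the tests.

## Choices made where the design was open

* **Cue split per participant.** The noCue–Cue / noCue–noCue halves are
  re-randomized per simulated participant (the stimulus set itself is fixed,
  as in the pre-generated dialect). The split is an unstratified random
  half, so the two groups can by chance differ in error-prone displays —
  exactly the mechanism that motivates the negative-`s1` exclusion.
* **Participant-level `d1` borrowing.** The cued solver borrows each
  participant's own uncued `d` rather than the group mean; this matches the
  per-participant negative-`s1` exclusion narrative. `decompose_cohort()`
  exposes `group_d1_ref = TRUE` for the group-level alternative.
* **Letter geometry.** A letter is two strokes of length 0.03 screen height;
  stroke width (never specified by the paradigm) is `max(1 px, 0.003 x
  height)`, and the cross stroke is inset by its half-width so a glyph's
  bounding box equals the nominal stroke length exactly. Rendering uses
  butt-capped strokes and no anti-aliasing, keeping it deterministic and
  making geometric assertions exact.
* **Grayscale mapping.** Simulated free-gray letters draw uniformly in
  [-1, 1] and map to 0–255 by `round((g+1)/2 * 255)` (half away from zero) —
  the conversion target stated by the paradigm, with the rounding rule being
  this package's convention.
* **Nominal vs. image-based contrast.** The controlled-contrast dialect
  stores the designed signed level (target gray − nominal background
  gray 128) on each display; `tb_contrast()` computes the image-based value
  (target gray minus the mean gray of a patch of side twice the stroke
  length, target pixels excluded) from rendered stimuli. Analyses use the
  nominal value; the two agree in expectation because the noise background
  is mid-gray on average.
* **Placement sampling.** Letter positions are rejection-sampled at minimum
  separation 0.1 screen height with a 10,000-candidate budget. Greedy
  rejection can corner itself at the dense 36-letter packing, so an
  exhausted run restarts (up to 20 times) before a placement error is
  raised; genuinely infeasible requests still fail quickly.

## Problem sizes used in validation

The test suite validates the analytic round trip over 10,000 random
parameter draws (exact to 1e-12), the forward simulator against the
composition equations at 200,000 display pairs (within 3 Monte-Carlo SEs),
and cohort-scale estimator behavior on 100 replicate cohorts of 20
participants x 128 present pairs — the controlled-contrast experiment's
scale. At that scale a true `d` of 0 yields a non-significant cohort t-test
on the solved `d` in well over 90% of replicates, a true `d` of 0.1 is
detected essentially always, and in cued simulations (`d1 = 0.10`,
`d2 = 0.04`, equal stochastic rates) the paired `d1` vs `d2` comparison is
significant in most replicates while `s1` vs `s2` rejects at the nominal
rate. The cued generating values are the package's worked-example
parameters; the equal stochastic rates encode the scenario under test (a cue
that converts unfindable displays but leaves stochastic misses untouched).

## A compact worked example

```{r example}
design <- build_design("exp3", seed = 42)
truth <- latent_params(d1 = 0.10, d2 = 0.04, s1 = 0.10, s2 = 0.10)
trials <- simulate_cohort(20, design, truth, seed = 42)

prep <- preprocess_cohort(
  trials,
  cells = c("target_present", "set_size", "copy", "cue_condition"))
prep$summary |> round(2)

estimates <- decompose_cohort(prep$trials)
estimates |>
  group_by(condition) |>
  summarise(across(c(d1, d2, s1, s2), \(x) mean(x, na.rm = TRUE)))

cued <- filter(estimates, condition == "noCue-Cue", !excluded)
paired_t(cued$d1, cued$d2)
```

The cued condition's mean `d2` falls well below `d1` (the cue converts
unfindable displays) while the stochastic rates stay put — the same pattern
the decomposition is designed to detect in human data.

## Known limitations

The closed-form solvers are method-of-moments estimators: no likelihood, no
standard errors per participant, and the cohort t-test is the only
inferential layer, by design. The `d1`-borrowing step makes the cued `s1`
estimate noisier than the others and is the sole source of the
negative-`s1` exclusions. Repeated-measures ANOVAs on RTs are deliberately
out of scope; only descriptive per-cell RT summaries (`rt_summary()`) are
produced. Cue animations (dot paths, spiral squares, item boxes) exist as
schedule metadata only and are never rasterized.
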