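---
title: "Models and methods in liftlab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in liftlab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liftlab)
```

liftlab implements, and generates synthetic data for, a grasp-and-lift
paradigm in which fingertip forces and self-scaled weight reports are
collected while the order of light and heavy objects manipulates the
participant's sensorimotor memory, optionally under TMS during the dynamic
loading or static holding phase. This vignette documents the models,
parameter choices and numerical decisions, and what the synthetic data can
and cannot establish.

## Session design

The analyzable backbone of a session is 10 repetitions of each of the 12
cells formed by the four order pairs (LL, HL, LH, HH: previous × current
weight) and three stimulation conditions (dynamic, static, none). A trial
has a defined order pair only if both its own object and the previous
object are the light or heavy analysis weight, so the first trial, each
medium-weight dummy, and each trial following a dummy are non-analyzable.

The dummy placement constraints — never first, never last, never adjacent
to another dummy — are our design inference rather than a stated rule:
with them, 14 dummies invalidate exactly 14 following trials, and together
with the first trial the session arithmetic closes at
120 + 14 + 14 + 1 = 149, matching the published counts. Whether a dummy
could in fact end a real session is unknowable from the printed numbers; we
chose the constraint set under which the arithmetic is exact. For other
repetition counts the dummy count scales proportionally
(`round(1.4 * n_reps)`, minimum 1).

Sequences are found by constrained rejection sampling (capped at 10,000
attempts): the 12 × reps required order-pair transitions are laid down as
random walks over the light/heavy state graph within the runs between
dummies, drawing each step with probability proportional to the remaining
transition counts (an urn scheme that rarely dead-ends); conditions are
then assigned by shuffling exact per-pair condition multisets.
Non-analyzable trials draw a uniformly random condition. Everything is
deterministic given the seed.

## Generative model of a lift

Weights are physical: (cube mass + 120 g manipulandum) × g, giving 2.207,
6.327, 4.287 and 3.728 N for the light, heavy, medium and practice
objects. The first three round to the published 2.2 / 6.3 / 4.3 N; the
practice object is published as 3.8 N, which is inconsistent with a 120 g
manipulandum ("±120 g" in the source description) — we keep the physical
arithmetic and accept 3.7 N for the practice weight, which never enters
analysis.

The expected weight of a lift is a mixture
`W_exp = memory_weight · W_prev + (1 − memory_weight) · W_actual`
(default `memory_weight = 1`: pure one-back sensorimotor memory, the
dominant empirical finding). Load force rises as a minimum-jerk pulse whose
peak rate is `lfr_gain · W_exp` (default 7 /s, placing peak rates in the
25–45 N/s range typical of adult precision-grip lifts at these weights):

* **matched** trials complete one pulse to `W + overshoot` and settle;
* **under-scaled** trials (e.g. LH) stall at `W_exp + overshoot < W`, and
  after a 100 ms reaction latency a corrective second pulse with peak rate
  `correction_gain · lfr_gain · W` (default gain 0.85) completes the lift —
  producing the characteristic double peak in the load-force rate, with the
  corrective peak the larger of the two but smaller than a planned heavy
  lift's, matching the empirical ordering LL < LH < HH;
* **over-scaled** trials (HL) lift off early; braking starts one feedback
  delay (50 ms) after the load force passes the stop level. The settle
  segment is a cubic Hermite interpolant matched to the instantaneous rate
  at braking onset. This matters numerically: with an abrupt
  (zero-derivative) settle, the truncation clips the planned rate peak and
  the extracted first peak under-recovers the planned `lfr_gain · W_prev`
  by ~12%; with rate-matched braking the peak is genuinely attained and
  recovery is within 2% for all four order pairs (a tested property, at a
  5% tolerance).

Grip force leads load force by 50 ms, ramps to the safety margin, then
couples as `GF = gf_lf_ratio · LF + safety_margin` (defaults 1.3 and
0.45 N, chosen so static grip force spans ≈ 3.3 N for light to ≈ 8.7 N for
heavy objects — the magnitude range reported for this paradigm). Sensor
channels split GF and LF equally between the two digits and add i.i.d.
Gaussian noise (default SD 0.05 N per channel).

TMS perturbations are injected where the empirical effects sit:

* dynamic-phase TMS adds a transient extra grip-rate drive (bump with peak
  rate 4 N/s) for both groups — raising peak GFR;
* dynamic-phase TMS in the LO group on heavy objects adds an analogous
  load-rate bump (6 N/s) late in the loading pulse (centred at 58% of the
  pulse), creating the "extra, later peak" that raises peak LFR and its
  time-to-peak without touching the first peak;
* static-phase TMS on heavy objects shifts the weight report by −0.1 N
  equivalent.

Because the grip bump is placed on the final loading pulse, on over-scaled
(HL) trials it lands after the grip-rate maximum and dilutes the dynamic-TMS
effect in that cell; we accept this asymmetry as a property of the stated
world rather than tuning the placement per cell.

Reports are `scale · (W_actual + bias + TMS shift + noise) + offset` with a
participant-specific scale and offset (uniform on [0.5, 3] and [0, 2]),
which makes the z-scoring stage genuinely load-bearing. The
previous-weight bias is `−percept_prev_gain · (W_prev − midpoint)` with
default gain 0.0375, i.e. a ≈ 0.15 N report shift between previous-light
and previous-heavy — about 7% of the light object's weight, inside the
empirically reported 0–19% range (for heavy objects the same absolute shift
is a smaller percentage; the published central values, 7% and 5%, carry
wide intervals and we did not force both).

What the generator does **not** emulate: kinematics and torques, slips and
friction, fatigue or learning drift across the session, non-Gaussian report
distributions, and any genuine neural mechanism of the TMS effects — they
are injected phenomenologically. A green test therefore establishes that
the analysis code recovers the structure the generator puts in, not that
the physiological claims are true.

## Signal processing and event detection

Filtering is a second-order Butterworth low-pass (bilinear transform,
prewarped) at 15 Hz, applied forward and backward. The zero-phase choice is
deliberate: a causal pass would lag every event time by several
milliseconds and bias liftoff detection; the cost is a doubled effective
attenuation order, which we document rather than hide. Edges use odd
reflection padding (9 samples) with constant-history initial conditions, so
a constant trace is a fixed point of the filter (tested to 1e-9).

Threshold crossings use "≥" (so a ramp of 10 N/s crosses 0.1 N at exactly
10 ms) and a 10 ms debounce: the force must stay beyond threshold for the
window (runs truncated by the end of the trace count). The debounce is our
addition — thresholds on noisy channels chatter — and mirrors the paradigm's
own choice of a raised 0.4 N trigger "to avoid responses to small initial
bumps". Derivatives are central differences on the filtered series with
one-sided endpoints.

Peak selection: global maxima take the earliest sample on ties; a local
maximum is a sample strictly greater than both neighbours, with flat-top
plateaus credited to their first sample; the first peak is the earliest
local maximum at least 30% of the global peak, falling back to the global
peak for monotone windows. All windows are half-open `[start, end)`. These
tie-break rules are tested against an exhaustive brute-force scan on 1,000
random traces.

## Perception pipeline

Reports are z-scored per participant with the grand mean **and grand SD**
over included trials. The source protocol names only the grand mean; we
also divide by the SD (the standard z-score) because the published
cell values sit near ±1 for light/heavy, which only a full standardisation
produces. Dummy-weight trials never enter the grand mean or SD, since they
are excluded from analysis. Difference scores follow the protocol:
previous-weight differences are `HL − LL` (current light) and `HH − LH`
(current heavy); TMS differences subtract the no-TMS cell after pooling
over previous weight. The percent-bias transformation uses the same-weight
order pair as baseline (LL for light, HH for heavy).

## Inference protocol

The mixed 2 × 3 × 2 × 2 ANOVA uses the univariate repeated-measures
approach on orthonormal contrast scores, with Type III sums of squares
(indistinguishable from other types in this balanced design, and the
convention of the software family these protocols come from). For each
within effect with ≥ 3 levels, Mauchly's test runs on the pooled
within-group covariance of the contrast scores and, when it rejects at
0.05, both that effect and its group interaction get Greenhouse–Geisser
adjusted degrees of freedom (ε ∈ [1/(k−1), 1], so adjusted df never exceed
the nominal df). Every F statistic is verified in the test suite against
base R's independent `aov` error-strata oracle, and the engine's type-I
rate is calibrated (≈5% ± 2% over 500 null simulations at the reference
design size).

The split rule is mechanical: if any effect involving the group factor is
significant, per-group 3 × 2 × 2 repeated-measures ANOVAs are run (same
engine, one group, error df d·(n−1)); under identical groups this triggers
at the protocol's own false-positive rate, which is a property of the
protocol, not a bug. Bonferroni families are all pairwise contrasts of the
significant effect — the source protocol does not enumerate families, and
all-pairwise is the conservative convention; within-factor pairs use paired
t tests, group pairs independent (Welch) t tests, and constant differences
return p = 1 rather than erroring.

The relation models regress a perceptual quantity on a force covariate with
current weight, TMS condition, group and all interactions as fixed effects,
a random participant intercept, AR(1) residual correlation within
participant, and ML estimation; fixed effects are tested with marginal
(Type III) F tests. For the averaged difference-score models the AR(1)
"order" is the condition index within participant — the protocol prescribes
AR(1) but the records are not sequential, so the ordering is a convention;
we fix it (condition × current-weight sort order) and note that with only
2–6 records per participant the estimated autocorrelation is weakly
identified but harmless. The trial-by-trial variant orders by trial index,
where AR(1) is meaningful. Zero-variance covariates are dropped and
flagged rather than producing a singular fit; other non-convergence is
raised as an error with the message preserved by the pipeline.

Pearson correlations (per group × current weight × stimulation condition,
TMS differences of peak LFR vs. perception) use Fisher-z 95% intervals via
`cor.test`; coverage is property-tested.

## Tolerances and degenerate inputs

* Filter DC preservation 1e-9; impulse-sum 1e-6; derivative accuracy 1e-3
  on a 1 Hz sinusoid at 1 kHz.
* Liftoff recovery: ≤ 2 ms noiseless (the residual is filter smoothing of
  the crossing's curvature), ≤ 10 ms in ≥ 95% of trials at 0.05 N noise.
* Traces shorter than liftoff + 800 ms raise (the static window would be
  undefined); unlifted trials return `lifted = FALSE` rather than erroring.
* z-scoring raises on zero-variance reports; percent bias raises on a zero
  baseline; `pearson_ci` requires n ≥ 4 and non-constant inputs.
* ANOVA requires complete cells (after exclusions); the pipeline records a
  per-dv failure message instead of aborting the run.

## Known limitations

The simulator's TMS effects are additive bumps, not mechanistic; its
previous-weight perceptual bias is linear in previous weight; report noise
is Gaussian. The ANOVA engine assumes a balanced complete-cell design
(guaranteed by the session designer, checked otherwise). The AR(1)
ordering convention for averaged difference scores is one of several
defensible choices. Real-data idiosyncrasies — drift, slips, partial lifts,
heteroscedastic reports — are represented only by the coarse artifact flags.
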