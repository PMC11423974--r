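---
title: "Methods: modelling perceived travel distance with a leaky spatial integrator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling perceived travel distance with a leaky spatial integrator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odoleak)
```

## The behavioural setting

Optic flow alone can drive the feeling of self-motion and, with scale
information, a running estimate of distance travelled. The experiments this
package analyses probe that visual odometer with two complementary tasks in
a virtual corridor. In the *move-to-target* (MTT) task the observer sees a
target at distance $d_0$, the target vanishes, simulated self-motion
begins, and they press a button where they believe the target is; the
response is the self-motion distance $x$ at the press. In the
*adjust-target* (AT) task the observer is first moved through $d_0$ and
then slides a visible target to the felt travel distance; the response is
the adjusted distance. Each trial is summarised by a gain,
$d_0/x$ for MTT and $x/d_0$ for AT, so that in both tasks gain $>1$ means
the observer felt they travelled further than they did. The factorial
design crosses 2 tasks, 4 motion directions (forward, backward, up, down),
3 speeds (1, 3, 5 m/s) and 12 distances (5–40 m), one trial per cell — 288
trials per participant, run in task-by-direction blocks.

## The leaky spatial integrator

The core model holds that perceived distance $s$ accumulates over physical
displacement $x$ with a gain $g$ and leaks in proportion to the
accumulated state:
$$\frac{ds}{dx} = g - \alpha s, \qquad s(0) = 0 .$$
After a displacement $d_0$ (the AT task) the felt distance is
$$p(d_0) = \frac{g}{\alpha}\left(1 - e^{-\alpha d_0}\right),$$
which saturates at $g/\alpha$. In the MTT task the *remembered target
distance* decays while the observer closes in on it,
$\;dD/dx = -g - \alpha D$ from $D(0) = d_0$, and the stop comes at $D = 0$:
$$x(d_0) = \frac{\log(d_0 + g/\alpha) - \log(g/\alpha)}{\alpha}.$$
Both parameters have behavioural signatures: $g$ sets the overall gain
level, while $\alpha > 0$ makes the AT implied gain
$g(1-e^{-\alpha d_0})/(\alpha d_0)$ *fall* with distance and the MTT
implied gain $\alpha d_0 / \log(1 + \alpha d_0 / g)$ *rise* with distance
(errors grow with distance travelled). Note that the MTT *stopping
distance* itself decreases as $\alpha$ grows — the remembered target
decays faster, so the button comes earlier — even though the implied gain
increases; $x \le d_0/g$ always, with equality as $\alpha \to 0$.

`lsi_ode_oracle()` integrates these dynamics numerically (deSolve's
`lsodar`, tolerances $10^{-12}$, root-finding for the MTT zero crossing)
entirely independently of the closed forms; the test suite holds the two
routes together to $10^{-6}$ relative over a $4 \times 4 \times 12$
parameter grid.

## Fitting and the no-leak comparison

Fits operate on cross-participant mean responses at each design distance —
12 AT points and 12 MTT points per direction $\times$ speed cell — and
minimise the *combined* SSE of the two closed forms over $(g, \alpha)$,
with $g > 0$ and $\alpha$ bounded below by the floor
`ALPHA_FLOOR = 1e-6` /m. A trial-level fit would weight cells by their
post-exclusion trial counts and mix participant heterogeneity into the
residual; the mean-level fit matches how the model curves are compared to
group data. Optimisation is bounded quasi-Newton on $(\log g, \alpha)$
multi-started from a coarse grid ($g \in \{0.5, 1, 2, 4\}$,
$\alpha \in \{10^{-6}, 0.01, 0.05, 0.2\}$ — the grid guards against the
ridge that forms along the $\alpha$ floor), followed by a Nelder–Mead
polish at $10^{-12}$ relative tolerance. Exact interpolations (SSE
numerically zero) count as converged even when the line search exits
abnormally on the flat floor of the SSE surface.

The one-parameter comparison model pins $\alpha$ at the floor — "no leak,
just gain" — and is nested in the full model, so its SSE can never be
smaller. Likelihoods come from i.i.d. Gaussian residuals with the variance
profiled out, $\log L = -\tfrac{n}{2}(\log(2\pi\,\mathrm{SSE}/n) + 1)$, a
choice we record explicitly because the likelihood convention is otherwise
underdetermined by an SSE fit; `compare_nested()` therefore also reports
both raw SSEs so any other convention can be substituted. It returns the
ratio $\Lambda = \exp(\log L_{\mathrm{red}} - \log L_{\mathrm{full}})$ and
a $\chi^2_1$ p-value on the deviance, with a recorded caveat: the pinned
$\alpha$ sits on the boundary of its space, so the null deviance is a
50:50 mixture of a point mass at zero and $\chi^2_1$ and the p-value is
conservative. Monte-Carlo calibration in the acceptance suite (1000
no-leak replicates, Gaussian noise) shows rejection rates of 2–4% at
nominal 5%, as that mixture predicts. Goodness of fit is summarised as the
mean squared error between model and mean data, per cell, per direction
(cell MSEs averaged across speeds) and per distance.

Comparing the *same* model across directions (is the integrator a better
description of forward motion?) is not a nested test; the package reports
it as a descriptive MSE comparison by direction.

## Preprocessing

Gains are fenced at the group level within each task $\times$ direction
$\times$ speed $\times$ distance cell: pooling across participants,
trials outside $[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 + 1.5\,\mathrm{IQR}]$ are
flagged. Quartiles use linear interpolation between order statistics
(`stats::quantile` type 7); the convention is recorded in the removal
report so alternatives can be compared. Cells with fewer than 4
observations have undefined fences and pass through unflagged with a
report warning. Flagged trials stay in the data with
`flagged_outlier = TRUE` — downstream stages skip them, but reports remain
auditable. Fencing operates on gains rather than raw distances because
every downstream analysis operates on gains.

A participant is excluded outright when *strictly more than* a quarter of
their trials in a single task are flagged: with 144 trials per task, 36
flagged trials is retained, 37 removed. The strict per-task reading is the
most literal one and makes the planted-contamination fixtures
unambiguous.

The stopping criterion in the MTT task referenced a ball fixed 1.5 m ahead
of the observer (radius 0.25 m, centre 0.25 m below eye height), with a
different surface used per direction (far side forward, near side
backward, top up, bottom down). The exact correction arithmetic is not
fully determined by the published geometry, so the package exposes it as a
per-direction signed offset added to the MTT stop distance
(`reference_ball_offsets()` derives the leading-surface displacements:
forward $+1.75$, backward $-1.25$, up $0$, down $+0.5$ m) with
`geometry = NULL` disabling the correction — the default, since simulated
cohorts have no ball and deposited exports may already be corrected. Gains
are invariant to the distance unit when offsets are scaled consistently.

## The mixed model on gains

Per task, the package fits
$$\text{gain} \sim \text{direction} + \text{speed} + \text{distance} +
(1 + \text{direction} + \text{speed} \mid \text{participant})$$
with lme4 (REML), treatment-coded with forward and 1 m/s as references.
Direction and speed are factors; distance enters as a continuous covariate
(the minimal-parameter reading, recorded in output metadata). No direction
$\times$ speed interaction is included. Distance random slopes are not
entertained: with 144 trials per participant per task they push the model
past a reasonable data-per-parameter ratio, so the selection ladder
(`random_effects_ladder()`) starts from intercept + direction + speed
slopes and tests dropping each slope block by ML likelihood-ratio tests,
keeping the maximal structure that the data support.

Estimation defaults to the *zero-correlation* variant of that structure
(each random term keeps its own variance; correlations between terms are
dropped, via indicator-expanded `||` terms). Two reasons: correlations in
a $7 \times 7$ random-effect covariance are weakly identified from 16
participants and routinely produce singular fits, and the parametric
bootstrap — simulate responses from the fitted model, refit, recompute,
500 times — refits this structure about 20 times faster than the fully
correlated one at indistinguishable fixed-effect estimates. The fully
correlated maximal model remains available (`random = "maximal"`, with an
automatic zero-correlation fallback when singular).

All $\binom{4}{2} = 6$ direction and $\binom{3}{2} = 3$ speed contrasts
are linear combinations of one fit's coefficients (no refitting with
rotated reference levels; the equivalence is asserted in tests via
additivity, estimate(A,C) = estimate(A,B) + estimate(B,C)). CIs are
percentile intervals over the bootstrap draws of those combinations;
draws are shared across the two factors of a fit, the replicate count
travels with every CI, and a contrast is "significant" when its 95% CI
excludes 0. Bootstrap replicates default to 500, seed-controlled.

## The synthetic-data generator

`generate_schedule()` reproduces the factorial skeleton (blocked by task
$\times$ direction, block order and within-block trial order randomised
per participant); `simulate_responses()` inverts the LSI closed forms with:

* **multiplicative lognormal trial noise**, $\varepsilon \sim
  \mathrm{lognormal}(0, \sigma)$, median 1 — responses are positive
  distances whose variability scales with magnitude; the studies report no
  noise model, so this is the simulator's choice and is configurable;
* **participant heterogeneity** as lognormal multipliers on $g$, drawn
  independently per participant for each direction and each speed — this
  induces exactly the random-slope structure the mixed model assumes;
  $\alpha$ stays fixed across participants to keep recovery tests
  identifiable;
* optional **contamination**: each trial's response is multiplied by an
  outlier factor (default 3) with a configurable probability.

Defaults (`default_truth()`): 16 participants, true gains 1.33–2.35 built
from per-direction bases (forward 2.1, backward 1.4, up 1.95, down 1.9)
times speed multipliers (1.12 / 0.97 / 0.95 for 1 / 3 / 5 m/s), leak 0.03
/m everywhere, heterogeneity SD 0.1, noise SD 0.2, no contamination. The
gain magnitudes and ordering mirror the group means reported for real
cohorts (roughly 1.3–2.5, slower speeds higher, backward lowest in MTT);
the noise scale was chosen once to give group-level SDs of the observed
order. Everything derives from an explicit integer seed; the same seed
reproduces a cohort byte for byte.

What the generator does *not* emulate: task-order or block-order
aftereffects, response latencies, vection onset dynamics, direction- or
speed-dependent noise, reference-ball geometry in the simulated responses,
and any leak heterogeneity across participants. Passing recovery tests on
these cohorts therefore demonstrates that the estimation machinery is
correct and well calibrated under the design's structure — not that real
data satisfy the generative assumptions.

## Problem sizes and numerical choices

The test and acceptance workloads use: 100 replicates of a 16-participant
cohort for noisy parameter recovery (median errors ~0.7% on $g$, ~0.0006
on $\alpha$, against acceptance bounds of 5% and 0.01); 1000 replicates
for the no-leak null calibration; 20 null cohorts of 10 participants with
100 bootstrap draws each for the contrast type-I-error check; and 500
bootstrap draws for the planted-shift CI. Degenerate inputs are handled
explicitly: all-equal fence cells flag nothing (IQR = 0), sub-4-trial
cells warn, corrected distances $\le 0$ flag the trial invalid rather than
producing a negative gain, single-participant mixed models error rather
than fit silently, and zero-variance data run through the ladder without
crashing (flagged as degenerate).

## Known limitations

The likelihood for the nested comparison is a modelling convention layered
onto an SSE fit, not derived from a trial-level noise model; the boundary
caveat makes the $\chi^2_1$ p-value conservative rather than exact. Fits
share no parameters across speeds within a direction (independent cells),
and no speed term exists inside the integrator itself — the prediction
functions are deliberately small and pluggable, but no such extension
ships. Whether deposited exports are already ball-corrected cannot be
determined from the published description; the geometry switch exists for
exactly that ambiguity.
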