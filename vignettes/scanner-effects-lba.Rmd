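---
title: "Decomposing scanner-environment effects on decision-making with the LBA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing scanner-environment effects on decision-making with the LBA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scanlba)
```

## The problem

Participants performing a perceptual decision task inside an MRI scanner
respond more slowly than at a desk, and sometimes less accurately. Mean RT
and error rate alone cannot say *why*: at least four latent mechanisms
predict slower scanner responses. This package decomposes the session effect
with the linear ballistic accumulator (LBA) model, whose parameters map onto
the four candidate accounts:

| account            | mechanism                         | LBA signature          |
|--------------------|-----------------------------------|------------------------|
| motor slowing      | response execution takes longer   | non-decision time `t0` up |
| response caution   | more evidence demanded            | threshold `b` up       |
| arousal            | all evidence accumulates faster   | `v_c + v_e` up         |
| attentional focus  | stimulus information extracted worse | `v_c - v_e` down    |

## The model

Each response alternative is a ballistic accumulator. On a trial, accumulator
\(i\) draws a drift rate \(d_i \sim N(v_i, sv_i)\) and a start point
\(k_i \sim U(0, A)\), then rises linearly until some accumulator reaches its
threshold \(b_i\); the first to finish determines the choice, and
RT \(=\) finishing time \(+\ t_0\). The finishing-time distribution of one
accumulator has the closed form

\[
F(t) = 1 + \tfrac{b-A-tv}{A}\Phi(z_1) - \tfrac{b-tv}{A}\Phi(z_2)
       + \tfrac{tsv}{A}\,[\phi(z_1) - \phi(z_2)],
\qquad z_1 = \tfrac{b-A-tv}{tsv},\; z_2 = \tfrac{b-tv}{tsv},
\]

with density \(f(t) = \frac{1}{A}[-v\Phi(z_1) + sv\,\phi(z_1) + v\Phi(z_2) -
sv\,\phi(z_2)]\). The likelihood of responding \(r\) at time \(t\) is the
*defective density* \(g_r(t) = f_r(t - t_0)\prod_{j \ne r}(1 - F_j(t - t_0))\),
which integrates to the choice probability of \(r\) (less than 1, since a
trial on which every sampled drift is negative never terminates). The closed
forms are verified in the test suite against ballistic simulation and
quadrature oracles, which we treat as definitional: any convention mismatch
would surface there.

Because the evidence scale is arbitrary, the drift SD of the error
accumulator in the reference condition is anchored at 1. Thresholds are
parameterized as \(b - A \ge 0\) so the threshold can never sit below the
start-point range; `sv`, `A`, `b - A` and `t0` are estimated on the log
scale.

## Designs, top models, and the model hierarchy

Three random-dot-motion designs are built in: probabilistic cueing (cues
valid on 90 %, 70 %, or uninformative, crossed with motion direction),
speed/neutral/accuracy cueing, and motion coherence (5-80 %) crossed with
inter-trial interval (500 vs 4300 ms). Each design has a *top model* saying
which factors each parameter type may depend on — e.g. in the cueing design
`b - A` varies per accumulator with cue congruence (biased toward / against /
neutral), in the difficulty design drift mean and SD vary with coherence and
response type, and everything may vary with session.

A hierarchy of simpler models is generated by dropping whole factors from a
parameter type's dependence, giving the product lattice of factor subsets:
\(\prod_p 2^{|\mathcal F_p|}\) nodes (256 for the cueing design and 1024 for
each of the other two under the documented factor sets). We formalize
"fixing a parameter across conditions" as whole-factor removal rather than
arbitrary level-merging: it keeps the lattice finite, totally ordered by
nesting, and matches the kinds of best-fitting models such designs report.

Models are fit per participant by maximum likelihood (no pooling). The
search is Nelder-Mead simplex on the unconstrained scale, run in compiled
code, with seeded random restarts plus *warm starts*: the lattice is
traversed in ascending parameter count and each node starts from its
immediately nested predecessors' solutions expanded to the finer cell
structure. Expansion preserves the likelihood exactly, so fitted
log-likelihoods are monotone along nesting chains — a property the test
suite asserts. Starts are ranked by their initial likelihood and only the
best few optimized (`max_starts`); a stalled simplex is restarted from its
incumbent (`nm_cycles`).

An RT at or below `t0` contributes a large finite log-density floor
(\(-10^{10}\)) instead of \(-\infty\), keeping the search well defined near
the boundary without data-dependent box constraints. Non-terminating trials
("none" responses) are excluded from the likelihood with a logged count, and
the non-termination mass is not renormalized, the standard LBA convention.

## Selection and model averaging

Per-participant AIC scores are summed across participants; AIC weights
\(w_i \propto \exp(-\Delta_i/2)\) then weight each model's estimates —
expanded to the top model's cell structure — into model-averaged estimates
that acknowledge selection uncertainty. One weight vector is shared by all
participants (per-participant weighting is available behind a flag). BIC is
computed alongside (with n = the participant's fitted trial count) but never
drives averaging. From the averaged estimates the four diagnostics are
derived per participant and session, collapsing nuisance factors by
unweighted means over their levels (the synthetic designs are balanced, so
weighting would not change anything).

Models whose weight falls below 1e-6 are excluded from the average and the
remaining weights renormalized. Besides the usual Occam's-window argument,
this is a numerical-integrity safeguard: a contribution of weight 1e-15
leaves floating-point dust in the averaged cells, and because the downstream
Bayes factor is scale invariant it would read any *systematically signed*
dust as a consistent session effect no matter how small. With truncation, a
parameter on which every surviving model agrees is exactly constant in the
average.

## Bayes-factor ANOVA

Whether a diagnostic (or mean RT / error rate) differs by session is
quantified by a Bayes factor comparing the full ANOVA model against the
model omitting the term — omitting a main effect also drops interactions
containing it, respecting the model hierarchy. Participant is always an
additive random effect. Under standardized-effect g-priors (sum-to-zero
contrasts; scale 0.5 on fixed effects, 1.0 on the participant effect, each
term's \(g\) drawn from its scaled inverse-chi-square prior) the marginal
likelihood conditional on \(g\) is available in closed form after
integrating the grand mean (flat prior) and the error variance (Jeffreys);
the \(g\)'s are integrated by Monte Carlo with 10,000 draws by default, which
keeps log-BF stable to well under 0.1 at these table sizes. The full and
restricted marginals share one set of \(g\) draws for their common terms
(common random numbers): when a response is nearly degenerate — between-
participant variance orders of magnitude above within-participant variance,
as model-averaged estimates can be — the integrand spikes on rare large
participant-\(g\) draws, and sharing draws lets those spikes cancel in the
ratio instead of inflating one marginal arbitrarily. The closed form
is verified in the tests against direct two-dimensional quadrature, and the
Woodbury-based implementation against a dense-matrix reimplementation.

Exact Bayes-factor values from the original experiments are not
reproducible — they depend on raw participant data that was never deposited —
so this module targets methodological fidelity backed by calibration:
on null tables the median BF falls below 1 with BF < 3 in at least 90 % of
simulations, and a one-SD standardized session effect yields median BF above
10. A BIC-based approximation (`bf_bic_approx`) serves as a direction
cross-check. Error rates are analyzed untransformed by default (a logit
option exists) to match how such data are usually displayed.

## The synthetic-data generator

The generator emulates the three study designs at their trial schedules: 840
behavioral + 240 scanner trials per participant for the two cueing designs
(19 participants; reliable cues valid on 90 % of trials, moderate on 70 %),
and 2 sessions x 2 ITI blocks x 200 trials (= 800) for the difficulty design
(20 participants, session order counterbalanced, coherences appearing
equally often). Participant-level parameters are drawn from Gaussian
populations around the generating means with SD 15 % of each mean, truncated
to validity; the anchored sv cell stays at 1 for everyone because the
evidence scale is arbitrary within participant, so population variability on
it would only relabel, not change, the data-generating process.

Generating means (behavioral session) are `v_c = 2.8`, `v_e = 1.2`,
`sv = 1`, `A = 0.6`, `b - A = 0.6`, `t0 = 0.25 s`, giving mean correct RT
near 0.55 s and accuracy near 0.85 — the qualitative regime of such
experiments, not a claim about any particular dataset. Cueing shifts
`b - A` per congruence class (toward 0.42 < neutral 0.60 < against 0.78);
SAT cueing shifts `b - A` levels (speed 0.3 < neutral 0.6 < accuracy 0.9);
coherence maps to drift as `v_diff = 2.4 (c/80)^{0.7}` with `v_sum = 3`
constant, so the drift difference rises with coherence while overall input
stays flat. ITI and session order are generated inert, matching the absence
of credible effects of either in this paradigm, but are available as effect
knobs.

A session effect is injected as an additive MRI-side shift on the targeted
quantity: `t0` (+0.1 s default), `b - A` (+0.35), `v_c + v_e` (+0.8, moving
both drifts equally), or `v_c - v_e` (-0.8, moving them oppositely). These
magnitudes are chosen once to sit in the clearly-detectable regime for the
study sample sizes. What the generator deliberately does *not* emulate:
sequential dependencies, response-box lag differences between sessions,
fatigue or practice drifts within session, and contaminant (non-decision)
responses. Passing tests therefore show the chain recovers what this
generative world contains, not that real scanner data are this clean.

## Desk-scale study sizes

The heavy validation studies run at sizes chosen for a single CPU and stated
here as the package's own study design: parameter recovery uses 20
participants x 800 trials (the difficulty schedule); model-selection
consistency uses 10 replicates of 8 participants at half the trial schedule
over the reduced 32-node hierarchy (response type locked on the drift
parameters so the simplest nodes still distinguish correct from error
evidence, the lattice varying Session inclusion on each of the five
parameter types); account identification uses 10 participants at half
schedule, and null specificity 10 replicates of 8 participants. Hierarchy
sweeps use one ranked start per node (`max_starts = 1`), which the
warm-start structure makes safe for nesting monotonicity.

## What parameter recovery can and cannot show

At the study's trial counts the drift rates and the threshold
\(b = A + (b - A)\) are well identified (median relative errors near or
below 10 % at 800 trials per participant). The *split* of \(b\) into
start-point range \(A\) and gap \(b - A\) is not: those two trade off along
a nearly flat likelihood direction, and their individual estimates carry
median relative errors of 20 % and more even when the fitted solution
provably dominates the generating parameters in likelihood. Non-decision
time inherits part of that trade-off (median absolute error
\(\approx\) 0.03-0.04 s at 800 trials). This is a property of the model
and design, not of the optimizer — the recovery study in the test suite
verifies ML-dominance of every fit — and it is why the account diagnostics
use \(b\), the drifts, and \(t_0\) rather than \(A\) or \(b-A\) alone.

## Known limitations

* Two-alternative races are the optimized path; m-alternative defective
  densities are supported but fit more slowly through the generic path.
* The hierarchy treats factor dependence as all-or-none per parameter type;
  level-merged intermediate models are out of scope.
* The Bayes-factor ANOVA assumes balanced or near-balanced tables; Type-II/
  III subtleties for badly unbalanced designs are not addressed.
* Model-averaged estimates inherit the usual caveat that averaging across
  parameterizations can blur qualitatively different mechanisms when weights
  are diffuse; the model-score table should be inspected alongside.
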