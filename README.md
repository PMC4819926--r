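# scanlba

Performing a decision task inside an MRI scanner changes behavior: responses
slow down, and error rates sometimes rise. For anyone who models task
behavior collected in the scanner — or compares it with behavioral-lab
sessions — it matters *which* latent mechanism drives that change.
`scanlba` decomposes session effects on random-dot-motion decisions with the
linear ballistic accumulator (LBA) model and adjudicates between four
candidate accounts by their parameter signatures:

| account | signature |
|---|---|
| motor slowing | non-decision time *t*₀ ↑ |
| response caution | threshold *b* ↑ |
| arousal | drift sum *v*_c + *v*_e ↑ |
| attentional focus | drift difference *v*_c − *v*_e ↓ |

The package provides:

* closed-form LBA finishing-time distributions and the defective race
  likelihood (compiled), plus a ballistic trial simulator;
* declarative designs for three paradigms — probabilistic cueing,
  speed-accuracy cueing, and motion coherence × inter-trial interval — with
  their *top models* and the nested model hierarchy obtained by fixing
  parameters across conditions (the product lattice of factor subsets);
* per-participant maximum-likelihood fitting with warm starts up the
  hierarchy, group-summed-AIC model selection, and AIC-weight model
  averaging of parameter estimates;
* default-prior (g-prior, Monte-Carlo integrated) Bayes-factor ANOVAs with
  participant as a random effect, for behavior and for the four model-derived
  diagnostics;
* a synthetic trial generator that emulates the three designs at their
  study trial schedules and injects any of the four session effects.

## Worked example

Simulate a difficulty-design experiment whose only session effect is motor
slowing (+0.1 s non-decision time in the scanner), then run the full chain:
fit the reduced 32-model session hierarchy per participant, model-average by
AIC weight, derive the four diagnostics, and test the Session factor with
Bayes-factor ANOVAs.

```r
library(scanlba)
g <- generate_experiment("difficulty", account = "motor_slowing",
                         n_participants = 6, trials_scale = 0.5, seed = 21)
res <- run_pipeline(g$trials, "difficulty", seed = 42,
                    bf_nsamples = 4000, max_starts = 1)
print(res)
```

```
Session-effect analysis (difficulty design, 6 participants, 32 models)

Top models by group-summed AIC:
  v:R|sv:R|A:1|bA:1|t0:S             dAIC     0.00  w_AIC 0.949
  v:R|sv:R|A:1|bA:S|t0:S             dAIC     7.47  w_AIC 0.023
  v:R|sv:R|A:S|bA:1|t0:S             dAIC     8.24  w_AIC 0.015
  ...

Bayes factors, Session factor (full vs. omitting Session):
  BF_Session (rt_mean) = 3.23e+04
  BF_Session (error_rate) = 0.167
  BF_Session (t0) = 1.6e+03  *flagged*
  BF_Session (b) = 0.385
  BF_Session (v_sum) = 0.989
  BF_Session (v_diff) = 0.447

Supported account(s): motor_slowing
```

Reading the output: the winning model (AIC weight 0.949) lets only
non-decision time vary by session (`t0:S`); mean RT shows massive evidence
for a session effect while the error rate favors the null — and among the
four diagnostics only *t*₀ clears the evidence threshold (BF > 3). The
analysis correctly recovers the injected mechanism and rejects the other
three.

The numbered scripts under `analysis/` run this workflow as a narrative:
`01_simulate.R` (datasets for all designs and accounts), `02_fit.R`
(hierarchy fits), `03_select_average.R` (AIC weights, averaging,
diagnostics), `04_anova.R` (Bayes factors), `05_report.R` (reports and RT
quantile summaries). Outputs land under `results/`.

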