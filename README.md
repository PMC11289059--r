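# prtddm

Simulation and hierarchical drift-diffusion modelling of the
**probabilistic reward task (PRT)**.

The PRT is a two-alternative perceptual judgment: on each trial a
schematic face appears, then a short or long mouth is flashed for 100 ms,
and the participant judges the mouth length. Unbeknownst to them, correct
responses to one mouth (the *rich* stimulus) are rewarded 75% of the
time, the other (*lean*) only 25%. Healthy participants develop a
*response bias* toward the rich option — an objective behavioural index
of reward responsiveness used widely in depression and anhedonia
research. This package provides the full analysis chain for such
experiments, validated end-to-end on synthetic data:

* **Task simulator** — balanced randomised schedules (3 blocks x 96
  trials, 48 rich / 48 lean each), Bernoulli or quota reward delivery,
  and drift-diffusion (DDM) agents that generate realistic choices and
  right-skewed response times.
* **Likelihood core** — numerically stable Wiener first-passage-time
  (WFPT) density with small-time/large-time series switching, exact
  reflection identity, and an Euler–Maruyama forward sampler that serves
  as its independent oracle.
* **Preprocessing** — participant exclusion (accuracy < 50% or > 75%
  single-button responding), the 250–2500 ms RT window, log10 RT and
  arcsine-square-root accuracy transforms, Tukey-fence winsorization.
* **Signal-detection indices** — response bias and discriminability with
  the 0.5 cell correction:

  `log b = 1/2 log10[ (RC+0.5)(LI+0.5) / ((RI+0.5)(LC+0.5)) ]`,
  `log d = 1/2 log10[ (RC+0.5)(LC+0.5) / ((RI+0.5)(LI+0.5)) ]`,

  plus the reward-learning score Δlog b = log b(block 3) − log b(block 1).
* **Hierarchical Bayesian DDM** — per participant and block, drift `v`,
  boundary `a` and non-decision time `t` split by rich/lean trials, and a
  single starting bias `z` estimated on a raw [−4, 4] scale, mapped to
  (0, 1) by the standard-normal CDF with z(lean) = 1 − z(rich).
  Group-level normal priors for drift means (μ = 0, δ = 10), uniform
  priors for the bounded parameters, half-Cauchy (δ = 2.5) SD priors,
  truncated-normal individual levels. Fitted by adaptive
  Metropolis-within-Gibbs MCMC (Rcpp) with split-chain rank-normalised
  R-hat diagnostics.
* **Recovery harness** — the package's acceptance surface: simulate a
  cohort with known parameters, fit, and score the recovery.

## Worked example

```r
library(prtddm)

# simulate a 4-group cohort of DDM agents and run the analysis chain
co  <- simulate_cohort(default_group_specs(), n_per_group = 4, seed = 1)
ex  <- exclude_participants(co$trials)
fl  <- filter_rts(ex$trials)
idx <- sdt_indices(fl$trials)
aggregate(cbind(log_b, log_d) ~ block, idx, mean)
#>   block      log_b     log_d
#> 1     1 0.09745464 0.5006490
#> 2     2 0.12255620 0.6356713
#> 3     3 0.15503998 0.6211705
```

Mean `log b` is positive and grows over blocks — the simulated agents,
whose starting bias is mapped to ~0.53 toward the rich response, show the
response-bias signature the task is designed to elicit; `log d` around
0.5–0.6 corresponds to the mid-70s accuracy regime of the task.

```r
# parameter recovery on a 12-agent cohort (about 3 minutes)
rec <- run_recovery(n_agents = 12, seed = 1,
                    spec = model_spec("reduced", thin = 48))
print(rec)
#> Parameter recovery on 12 agents x 288 trials
#> MCMC: 2 chains, 500 warmup + 500 draws, max R-hat 1.024
#>       r   bias  rmse
#> v 0.824 -0.031 0.191
#> a 0.922  0.009 0.061
#> t 0.972 -0.001 0.010
#> z 0.729 -0.005 0.017
#> Group-mean coverage (95% CI): 12/12 cells
#> Cohort-mean mapped bias: 0.532 [0.514, 0.550]
```

True and estimated drift and boundary correlate at r ≈ 0.8–0.9, and the
cohort-level mapped starting bias (true value 0.53) is recovered with a
95% posterior interval that excludes 0.5 — the model detects the reward-
induced bias.

## Command line

A thin CLI over the same functions ships in `inst/cli/prt.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/prt.R", package="prtddm"))')" \
    simulate --n-per-group 4 --groups star,verbal,face,thumbs --seed 1 --out cohort.csv
```

Subcommands: `simulate`, `preprocess`, `metrics`, `fit`, `recover`,
`wfpt-pdf`.

## Scope

The package models the task, the preprocessing, the indices and the
hierarchical DDM, and validates them by simulation. Mixed-effects group
inference, Bayes-factor analyses and questionnaire instruments are out of
scope, as is any claim about real-participant group differences.
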