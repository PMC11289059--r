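---
title: "Models and methods behind prtddm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind prtddm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific and numerical choices in prtddm:
the task model, the likelihood, the hierarchical prior structure, the
sampler, what the synthetic-data generator does and does not emulate, and
the known limitations. It states no empirical result that the test suite
or the acceptance script does not itself compute.

## The task and its generative model

The probabilistic reward task (PRT) asks for a two-alternative perceptual
judgment (short vs long mouth) under an asymmetric reward schedule: 75%
of correct responses to one stimulus (*rich*) are rewarded, 25% to the
other (*lean*). A session is three blocks of 96 trials, each block holding
exactly 48 rich and 48 lean trials in seeded-random order; which physical
mouth plays the rich role alternates with participant parity, emulating
counterbalancing. Ten training trials precede block 1; they are emitted
with `phase = "training"` and never analysed. Event durations (face
500 ms, mouth 100 ms, feedback 1750 ms, ITI 500 ms) are carried as
metadata only — nothing is presented in real time, and no response
deadline exists anywhere in the simulator (truncation happens only in
preprocessing).

Reward delivery is independent Bernoulli per correct response, because the
schedule is stated as a probability per correct response. Classic
laboratory variants control reward *counts* instead; `reward_mode =
"quota"` provides that variant (an exactly proportioned shuffled pool per
block and stimulus), but Bernoulli is the default.

Synthetic participants are drift-diffusion agents. On each trial evidence
accumulates from a starting point toward one of two boundaries separated
by `a`, with drift `v` and unit diffusion (`s = 1`; `s = 0.1` is
selectable for cross-checks against the older DDM literature). We use
*accuracy coding*: the upper boundary is the correct response on every
trial. The response bias toward the rich *response* is expressed through
the start point: the accumulator starts at `z = Phi(z_raw)` (as a fraction
of `a`) on rich trials and at `1 - z` on lean trials, so a positive
`z_raw` helps rich responses on rich trials and hurts correct (lean)
responses on lean trials — exactly the asymmetry the task induces.
`z_raw` lives on a [-4, 4] scale and is mapped through the
standard-normal CDF.

## The WFPT likelihood

The joint density of boundary and crossing time is evaluated by switching
between the small-time and large-time series expansions of the
first-passage density of a Wiener process, choosing the expansion and its
truncation depth so the absolute density error stays below a tolerance
(default 1e-7). The lower-boundary density is the primitive; the upper
boundary uses the reflection identity v -> -v, z -> 1 - z, applied on the
raw-bias scale in R so that the identity holds bit-for-bit. Decision times
at or below the non-decision time have zero likelihood; the user-facing
`wfpt_logpdf()` raises an error there, while the integrable `wfpt_pdf()`
returns 0.

The forward sampler is an Euler–Maruyama walk (step `dt <= 1e-3` s,
non-termination guard at 20 simulated seconds with a censoring flag). It
is deliberately an *independent* implementation of the same process: the
test suite checks the sampler against the closed-form choice probability
and the density against the sampler (Kolmogorov–Smirnov on 5,000 draws,
and bin-wise histogram agreement), so each side serves as the other's
oracle.

## Preprocessing

The pipeline order is fixed: participant exclusion, then RT filtering,
then transforms/winsorization downstream. Exclusion removes participants
with overall main-task accuracy below 50% or more than 75% of responses
on a single button (both strict; training trials never count). The RT
window keeps trials with 0.250 s <= rt <= 2.500 s (the rule excludes
strictly outside the window, so the bounds survive). Transforms are
log10 for RTs and asin(sqrt(p)) for accuracy proportions. Winsorization
is Tukey-fence replacement (1.5 IQR, per group): the motivation in this
literature is outlier control, and fence replacement is idempotent
because moving points that lie beyond the fences onto them leaves the
quartiles unchanged. A percentile (5/95) variant is available behind a
flag.

## The hierarchical model

Parameters are estimated per participant and block. Drift, boundary and
non-decision time are split by rich/lean trials; one raw bias per
participant-block serves both (lean bias is the complement). Individual
parameters are normal around group-level means specific to each feedback
type x block cell, truncated to the supports a > 0, t in [0, 1], z_raw in
[-4, 4] (drift unbounded). Group-level drift means have normal priors
(location 0, scale 10); group-level a, t, z_raw means have uniform priors
on (0.1, 10), (0.1, 1) and (-4, 4) — the stated intervals are read as
uniform prior bounds *and* hard initialisation ranges, the only reading
that yields a complete prior; all group SDs are half-Cauchy with scale
2.5, cell-specific.

### Sampler

No gradient-based MCMC framework is available in the target environment,
so the model is fitted by adaptive Metropolis-within-Gibbs, written in
C++: a random-walk proposal per scalar parameter, cached per-condition
log-likelihoods, and batch step-size adaptation toward 44% acceptance
during warmup (frozen afterwards, so the post-warmup chain is a valid
Markov chain). Because a random-walk sweep moves less far than a NUTS
iteration, each *stored* draw summarises `thin` full sweeps (default 8;
recovery runs use 48). Chains, warmup and kept draws follow the stated
schemes: 4 chains x 2000/2000 ("paper") and 2 x 500/500 ("reduced").
Determinism: all randomness flows through R's RNG; chain c of a fit with
seed s is seeded `set.seed(base(s) + c)`.

Convergence is summarised by split-chain R-hat, rank-normalised by
default (the maximum of the bulk and folded statistics, matching the
modern reference implementation); the classic Gelman–Rubin variant is
available via `method = "classic"`. The package flags convergence at max
R-hat <= 1.01 — a stricter bar than merely reporting achieved values. A
stuck chain (a parameter whose post-warmup draws never move) raises an
error rather than passing silently.

### Initialisation and numerical edges

Individual non-decision times are initialised below the unit's minimum
RT (otherwise the likelihood is -Inf); boundaries and drifts start in a
broad plausible range with per-chain jitter; group means start at the
cell averages of the individual inits, clamped inside the uniform prior
bounds. Proposals outside a truncation bound are rejected (the prior is
zero there), which keeps every draw inside its support by construction —
asserted on every fit.

## The synthetic cohort and what a green test establishes

`default_group_specs()` encodes the stated world of the simulator: drift
higher for rich than lean trials and rising over blocks (about 1.05 to
1.25 rich, 0.90 to 1.05 lean), boundaries near 1.3, non-decision time
0.28 s, and a mapped starting bias near 0.53 with realistic
between-agent spread (raw SD 0.1, i.e. about 0.04 mapped). These choices
reproduce the published behavioural regime: accuracies in the low-to-high
70s, mean RTs around 0.55–0.62 s with right-skewed distributions, and
positive, growing log b. One deliberate deviation: published tables
report non-decision times near 0.90 s, which is impossible on the
seconds scale of the likelihood given mean RTs near 0.6 s (an apparent
scaling artefact of the original fitting setup); the generator uses
0.28 s, consistent with the RT distributions, and those table values are
not recovery targets.

For parameter recovery, each agent draws *one* parameter set, held
constant across blocks: DDM parameters act as stable traits over a
20-minute session, and published block effects are small relative to
between-participant spread. Drifts and boundaries are uniform over the
plausible region (v in [0.6, 1.6], a in [1.0, 1.6], t in [0.2, 0.35] s;
mapped bias in [0.45, 0.60], normal around 0.53). Recovery is scored at
the level the truth varies — agent x condition, averaging each agent's
per-block posterior means. An earlier design drew parameters
independently per block x condition cell; a per-cell maximum-likelihood
oracle showed that with 48 trials per cell and a true spread of only
0.29, drift recovery is information-bounded near r = 0.65 under that
design, i.e. no estimator could reach the r >= 0.7 criterion — which is
why the trait-stable reading is the coherent one.

What a green recovery test does establish: the full chain (simulation,
preprocessing, likelihood, hierarchy, sampler, extraction) is mutually
consistent, drift and boundary estimates track the truth at r ~ 0.8–0.9,
group means are covered by their posterior intervals, and a cohort-mean
mapped bias of 0.53 is distinguished from 0.5. What it does not
establish: anything about real participants (no contaminant RTs, no
lapses, no learning within blocks, reward feedback does not influence
the agents' parameters — the bias is static, not learned), nor the
original study's group contrasts, which would require the deposited
dataset and the out-of-scope mixed-effects machinery.

The bias-detection property is itself stochastic at n = 12: the cohort's
realised mean bias wobbles around 0.53 by about ±0.012, and the posterior
interval half-width is comparable, so occasional seeds produce an
interval touching 0.5. The acceptance test fixes its seed and passes;
the property should be read as "typically detected", not "always".

## Numerical choices summarised

| Quantity | Value | Why |
|---|---|---|
| WFPT density tolerance | 1e-7 | series truncation error bound |
| Euler step (agents) | 1e-3 s | fast, adequate for behaviour-level sims |
| Euler step (oracle/recovery) | 1e-4 / 2.5e-4 s | discretisation bias negligible vs likelihood SE |
| MH acceptance target | 0.44 | optimal for scalar random-walk updates |
| Adaptation batch | 50 sweeps | standard diminishing-adaptation schedule |
| thin (recovery) | 48 | brings split R-hat near 1.02 at 2x500/500 kept draws |
| convergence flag | max R-hat <= 1.01 | stricter than the reported achieved range |
| reward mode | Bernoulli | schedule stated as per-response probability |
| winsorization | Tukey 1.5 IQR | outlier-motivated, idempotent |

## Known limitations

* The sampler is random-walk based; for much larger cohorts a
  gradient-based sampler would scale better. The `thin` knob trades time
  for effective sample size explicitly.
* The likelihood ignores the RT-window truncation (as did the original
  analysis); with the default generator fewer than 1% of trials are
  affected.
* No inter-trial variability parameters (sv, st, sz) — deliberately, the
  model under study has none.
* Quota-mode rewards are dealt per block independently; long reward
  droughts are not explicitly prevented (the original scheduling detail
  is unknown).
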