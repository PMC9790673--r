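---
title: "Estimating ACT-R memory parameters with a lognormal-drift LBA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating ACT-R memory parameters with a lognormal-drift LBA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actrlba)
library(ggplot2)
```

## The model

ACT-R's declarative memory treats retrieval as a competition between
chunks.  A chunk $i$ with activation $A_i$ is retrieved in time

$$ RT_i = F e^{-A_i} + t_{er}, $$

where $F$ is the latency factor (a positive scaling parameter) and
$t_{er}$ collects the non-retrieval components of the response
(encoding, motor execution).  Among chunks matching a retrieval
request, the one with the highest activation — the shortest retrieval
time — wins.

`actrlba` works with the stochastic version of this race in which

* the activation of chunk $i$ varies from trial to trial,
  $A_{ij} \sim \mathcal N(\mu_i, \sigma_i)$, and
* the latency factor varies from trial to trial,
  $F_j \sim \mathrm{Uniform}[a_F, b_F]$, shared by all chunks within a
  trial.

This process is exactly a linear ballistic accumulator (LBA) race.  In
an LBA, accumulator $i$ starts a trial with evidence
$k \sim \mathrm{Uniform}[0, A]$ and accumulates towards a boundary $d$
at a constant drift rate $v_i$, finishing at $(d - k) / v_i + t_0$.
Identifying the per-trial distance $d - k$ with the latency factor and
the drift rate with $e^{A_{ij}}$ gives the parameter mapping
implemented by `actr_to_lba()` and `lba_to_actr()`:

$$ \bar F = d - A/2, \qquad \mu_i = \ln v_i, \qquad t_{er} = t_0, $$

with $A = R_F$ (the latency-factor range) and $\sigma_i$ equal to the
log-scale spread of the drift distribution.  Because activation is
normal, drift rates are **lognormal** — not the normal drifts of the
classic LBA — and the package's densities are derived for that family.
The mapping gives ACT-R's latency factor a concrete interpretation as
response caution: the distance evidence must travel before a response
is made.

A note on the second identity: we define the mapping on the log scale
(`drift_logmean` $= \mu_i$, `drift_logsd` $= \sigma_i$), which makes
the two generative processes *literally* identical trial by trial;
$v_i = e^{\mu_i}$ is then the median (not the mean) of the drift
distribution, whose mean is $e^{\mu_i + \sigma_i^2/2}$.  The same
distinction applies to `expected_rt()`, which evaluates
$\bar F e^{-\mu} + t_{er}$ — the finishing time of the mean-activation
trajectory; the full expectation over activation noise would be
$\bar F e^{-\mu + \sigma^2/2} + t_{er}$.

## Two race variants

The generative story shares one distance draw across accumulators (all
chunks face the same latency factor in a trial), while the standard
LBA draws an independent start point per accumulator.  The two races
have the same margins but different joint laws whenever $A > 0$, so the
package implements both defective densities and exposes the choice:

* `variant = "independent_start"` — the standard LBA race density,
  $f_c(t)\prod_{j \ne c} (1 - F_j(t))$, built from the closed-form
  single-accumulator density and distribution (`dlba_acc()`,
  `plba_acc()`).  Conditional on the drift $v$, the finishing time is
  uniform, so marginalizing over the lognormal drift reduces both to
  truncated lognormal first moments (`lnorm_partial_expectation()`).
* `variant = "shared_distance"` — the ACT-R race.  Conditional on the
  shared distance $u$, finishing times are independent shifted
  lognormals ($\log(T_i - t_0) \sim \mathcal N(\log u - \mu_i,
  \sigma_i)$), and the conditional race density is averaged over
  $u \sim \mathrm{Uniform}[d - A, d]$ with 64-point Gauss–Legendre
  quadrature.  The integrand is smooth in $u$, and at that order the
  quadrature error sits well below $10^{-6}$ (the package's tests
  compare it against adaptive quadrature).

**Fitting defaults to `independent_start`.** The estimation method this
package implements fit retrieval data with the standard LBA race
density even though the generative story shares the distance.  At the
small latency-factor ranges typical of this domain ($R_F \approx 0.1$)
the two laws are numerically close; both are available, and
`ks_distance()` quantifies how far either is from a given dataset.  In
the $A \to 0$ limit the variants coincide with the lognormal race
(LNR); below $A = 10^{-6}$ the code switches to the exact LNR formulas
to avoid the $0/0$ form of the $1/A$ expressions.

Because the winner of the shared-distance race is simply the chunk
with the larger activation draw, its choice probability has the closed
form $\Phi\!\left((\mu_c - \mu_f) / \sqrt{\sigma_c^2 +
\sigma_f^2}\right)$ (`choice_probability()`), independent of the
latency factor — a useful end-to-end check on both the simulator and
the densities.

## Parameters, units, defaults

| Parameter | Meaning | Units | Typical value |
|---|---|---|---|
| `mu_c`, `mu_f` | mean activation, correct / incorrect chunk | log-odds | $-0.5$, $-1.5$ |
| `sigma_c` | activation noise of the correct chunk | — | fixed at 1 |
| `sigma_f` | activation noise of the incorrect chunk | — | $1.5$ |
| `F_mean` | mean latency factor $\bar F$ (response caution) | s × unit drift | $1$ |
| `F_range` | latency-factor range $R_F = b_F - a_F$ | s × unit drift | $0.1$ |
| `t_er` | non-retrieval time | s | $0.75$ |

Distances ($d$, $A$, $\bar F$) are expressed in seconds × unit drift so
that distance over drift is a time; no separate evidence unit is
exposed.  `sigma_c = 1` is a *scale convention*, not an empirical
claim: multiplying all log-scale parameters by a constant leaves the
likelihood invariant, so one spread must be pinned for the remaining
parameters to be identified.  `fit_mle()` therefore always fixes it.
`F_range = 0` and `sigma = 0` are accepted by the constructors as
deterministic simulation limits but rejected in likelihood
evaluations, where they degenerate.

## Simulated participants

`sample_participant_params()` draws simulated participants from
truncated-normal population distributions centred on plausible values
for a two-choice retrieval-practice task: $\mu_c \sim
\mathcal N^-(-0.5, 0.5)$, $\mu_f \sim \mathcal N^-(-1.5, 0.5)$,
$\sigma_f \sim \mathcal N^+(1.5, 0.5)$, $\bar F \sim \mathcal N^+(1,
0.5)$, $R_F \sim \mathcal N^+(0.1, 0.05)$, $t_{er} \sim
\mathcal N^+(0.75, 0.5)$, with $\sigma_c \equiv 1$.  Truncation is by
rejection sampling (exact; acceptance probability at least one half
for every cell), and joint draws violating $\bar F - R_F/2 > 0$ are
redrawn so the latency factor stays positive.

These population distributions — and the simulator's uniform shared
latency factor and normal activation noise — are what the recovery
study validates the estimator against.  Real retrieval data can
deviate in ways the generator does not emulate: activation drift
within a block (learning or fatigue), sequential effects such as
post-error slowing, contaminant responses, and more than one error
chunk.  A passing recovery study shows the estimator works *when the
model is true*; it does not certify those richer situations.

## Fitting

`fit_mle()` minimizes the negative log race likelihood with
`stats::nlminb()` from `n_restarts` random starting points
(`generate_start()`), keeping the best restart.  Choices a user may
care about:

* **Transform.** The optimizer works on
  $(\mathrm{logit}(t_0/\mathrm{cap}),\ \log A,\ \log(d - A),\ \mu_c,\
  \mu_f,\ \log\sigma_f)$, which enforces $0 < A < d$ and $0 < t_0 <
  \mathrm{cap}$ at every iterate.  The cap is $0.999 \min(rt)$:
  beyond the fastest response the likelihood is flat at the floor, a
  region local optimizers handle poorly.
* **Start ranges.** $t_0 \sim U(0, 0.9\min rt)$, $A \sim U(0.01, 1)$,
  $d - A \sim U(0.2, 3)$, log-means $\sim U(-3, 1)$, $\sigma_f \sim
  U(0.25, 3)$ — wide brackets around the plausible region above.
* **Floor.** Densities are floored at $10^{-10}$ inside the
  likelihood so the objective is finite everywhere; at any reasonable
  optimum the floor is inactive.
* **Convergence bookkeeping.** A restart counts as converged when
  `nlminb` reports success, but non-converged restarts still compete
  on likelihood.  `nlminb` tolerances are its defaults with
  `iter.max = 400`.
* **Determinism.** Given a seed, the full restart schedule is drawn
  up front, so the fit is exactly reproducible and nested restart
  schedules share their prefix (more restarts can only improve the
  best likelihood).

Datasets with a single response label are fitted with a warning and a
flag (`single_response`): nothing constrains the losing accumulator.
This is why the preprocessing rules require at least five errors per
fitted cell.

The likelihood has a genuine soft trade-off ridge: increases in $d$
(hence $\bar F$) can be offset by shifts in $\mu_c, \mu_f$ with little
likelihood cost, so those parameters are estimated with more
variability than $t_{er}$ and $\sigma_f$.  On simulated data the
best-of-restarts estimate routinely attains a *better* likelihood than
the generating parameters while sitting elsewhere on the ridge; this
is a property of the model, not an optimizer failure, and it surfaces
in the recovery study as positively correlated $\mu_c$, $\mu_f$
estimates.

## The recovery study

`run_recovery()` ties everything together: sample participants,
simulate each at several dataset sizes with the shared-distance race,
fit each dataset, and summarize per-parameter mean absolute error and
the Pearson correlation (raw scales, as is conventional) between
original and recovered values.

```{r recovery, eval = FALSE}
res <- run_recovery(n_participants = 10, trial_counts = c(100, 250, 1000),
                    control = fit_control(n_restarts = 50), seed = 1)
summarize_recovery(res)
autoplot(res, "correlation")
```

The default grid — 10 participants, 100/250/1000 trials per
participant, 50 restarts — is a desk-scale study chosen to run in a
few minutes on one core; a full-scale study (25 participants, up to
50,000 trials, 250 restarts) uses the same code with larger arguments.
Correlations for $t_{er}$ and $\sigma_f$ reach 0.9+ by 1000 trials per
participant, and mean recovery accuracy improves with dataset size;
$\mu_c$, $\mu_f$ and $\bar F$ remain noisier for the trade-off reason
above.  All randomness descends from one master seed through a seed
table drawn up front, so the study is reproducible and independent of
evaluation order; failed cells (rare) are flagged and excluded from
summaries with a message.

## Numerical details and edge cases

* Ties in finishing times (a measure-zero event, reachable in the
  deterministic $\sigma = 0$, $R_F = 0$ limits) are resolved in favour
  of the correct-labelled accumulator — deterministic and
  test-stable.
* Survival products in the independent-start density are accumulated
  in log space (`log1p(-F)`), so very late RTs underflow to a zero
  density (then floored) rather than to `NaN`.
* `race_distribution()` integrates the defective densities on a
  log-spaced grid with the trapezoidal rule (4096 points by default,
  cumulative error around $10^{-6}$), which is what `ks_distance()`
  and `autoplot()` interpolate.
* Trial filtering applies its rules in a fixed order — first
  presentation, RT > 30 s, RT < 300 ms, then the per-cell 50-trial
  and 5-error minima — with strict inequalities, so boundary RTs of
  exactly 0.3 or 30 s are retained; the exclusion report reconciles
  exactly with rows in minus rows out, and the result is invariant to
  input row order.
* Trial tables may label errors by pooling: with four answer options
  on screen, all wrong choices map to the single incorrect
  accumulator.  The race code accepts more than two accumulators, but
  the mapping to ACT-R parameters and all fitting are two-choice.

## Known limitations

* Activation is assumed stationary within a fitted block: no
  base-level learning or decay.  The method suits data where
  activations are stable by design (well-learned material, or
  adaptive scheduling that repeats an item whenever its activation
  falls to a threshold).
* Point estimates only — no standard errors or hierarchical pooling;
  with few trials per cell the estimates inherit the full trade-off
  ridge.
* The fitting default deliberately mirrors the established practice
  of using the independent-start density even for shared-distance
  data; for large $A$ the mis-specification grows, and the
  shared-distance variant should be preferred.
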