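# crowdcontext

When does concentrating social influence in a few individuals *help* a crowd
estimate a number, and when does it hurt? `crowdcontext` is an R package for
researchers in collective behavior and computational social science studying
that question. Its premise: the effect of influence centralization is not a
property of the network alone but of the interaction between the network and
the **estimation context** — the distribution of the crowd's initial
estimates.

## What it computes

**Model.** A group of *n* agents holds i.i.d. initial estimates of a positive
truth θ drawn from a context distribution F<sup>θ</sup><sub>μ,σ</sub>
(log-normal, Pareto, log-Laplace, or truncated normal; μ is systematic bias,
σ dispersion/shape). The collective estimate under centralization ω is

> a<sup>n</sup>(ω) = ω·a₁ + (1 − ω)·(1/n) Σᵢ aᵢ,

where agent 1 is the (exchangeably random) central agent; ω coincides with
Freeman's centralization for the implemented class of influence structures,
interpolating the equal-voice crowd (ω = 0) and a dictator (ω = 1).

**Benefit probability.** Ω<sub>n</sub>(ω, F) =
P[ |a<sup>n</sup>(ω) − θ| < |a<sup>n</sup>(0) − θ| ], the probability that the
centralized aggregate is strictly closer to the truth than the simple mean.
`estimate_omega()` computes it by coupled Monte-Carlo simulation;
`omega_lower_bound()` evaluates the analytic lower bound

> Ω<sub>n</sub>(ω, F) ≥ sup<sub>β > θ/(1−ω)</sub> F(β)·(1 − F(nβ)<sup>n−1</sup>),

and `bound_limit_profile()` tracks its large-*n* limit, which for heavy-tailed
families shows phase transitions in σ (limit jumping between 0 and 1/2 or 1).

**Empirical feature.** For trial data, the per-task statistic
R = e<sup>L_LN</sup> / (e<sup>L_LN</sup> + e<sup>L_N</sup>) — the normalized
relative likelihood of maximum-likelihood log-normal vs normal fits to the
pooled initial estimates — measures heavy-tailedness of a task's estimation
context on [0, 1].

**Pipeline.** `fit_context_moderation()` takes a long-format trial table
(individual initial and revised estimates across studies, tasks, groups, with
and without social interaction), builds collective estimates and outcomes,
and fits two mixed-effects moderation models with random intercepts by group
and study: logistic `improved ~ R` on interactive trials, and linear
`z_err ~ R * I` on all trials, where I indicates social interaction. A
positive R coefficient (logistic) and a negative R×I coefficient (linear)
both say: the heavier the tail, the more centralized influence helps.

**Synthetic corpus.** `generate_study()` simulates a multi-study corpus with
planted moderation (thin- and heavy-tailed tasks, weighted-average social
influence, control groups) so the whole pipeline is testable offline.

## Worked example

```r
library(crowdcontext)

# a synthetic 4-study corpus: 1300 trials, 52 tasks, ~58k estimate records
sim <- generate_study(synth_config(), seed = 11)
fit <- fit_context_moderation(sim$trials)
fit
#> Context-moderation analysis of collective estimation
#>   1300 trials analyzed (1092 interactive, 208 control), 52 tasks
#>   improvement ~ R:        b =   1.261  (z = 9.73, p = 2.2e-22)
#>   z-error    ~ R x I:     b =  -0.527  (t = -3.55, p = 0.000402)
```

The positive `improvement ~ R` slope says groups on heavy-tailed tasks
(R → 1) improved after social interaction far more often than groups on
thin-tailed tasks (R → 0); the negative `R x I` interaction says the same
from the error side — interaction *lowers* the standardized revised error
increasingly as R grows, and raises it when R is small. `plot(fit)` draws
the improvement curve and the crossing marginal-error bands; `summary(fit)`
prints full coefficient tables and variance components.

The theory side:

```r
set.seed(42)
estimate_omega(estimation_context("lognormal", 2, 1, 1), n = 50,
               omega = 1/3, reps = 1e5)
#> Omega_50(omega = 0.3333 | lognormal, theta = 2, mu = 1, sigma = 1)
#>   p_hat = 0.6836 (se 0.0015, 100000 reps)

omega_lower_bound(estimation_context("pareto", 2, 0, 2), n = 50, omega = 1/3)
#> Lower bound on Omega_50(omega = 0.3333 | pareto): 0.621969 at beta* = 29.3479

bound_limit_profile(estimation_context("pareto", 2, 0, 2), omega = 1/3)
#> Lower-bound limit profile (pareto, omega = 0.3333): verdict 'to_one'
#>       n    bound
#> 1 1e+02 0.693786
#> 2 1e+03 0.862778
#> 3 1e+04 0.944421
#> 4 1e+05 0.978692
#> 5 1e+06 0.992099
```

An overestimation-biased log-normal crowd of 50 is beaten by a moderately
centralized structure 68% of the time; a heavy Pareto context (σ = 2) drives
the lower bound toward 1 as the group grows — while a thin-tailed context
drives it to 0 (decentralization wins).

For external datasets, `load_trials(path, mapping = ...)` reads a trial CSV
with configurable column names, and `run_full_analysis()` writes the full
report bundle (outcomes, per-task R, model JSONs, marginal effects,
manifest).

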