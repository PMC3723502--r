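# deltamix

Online inference for univariate change-point processes, for researchers
who model adaptive learning in dynamic environments: the exact Bayesian
run-length filter, and a cheap, biologically plausible approximation
built from a small mixture of fixed-learning-rate Delta rules.

## The models

Data arrive one at a time from a conjugate exponential family
(Bernoulli rate, Gaussian mean with known noise, or Gaussian scale with
known mean) whose parameter θ is resampled from its prior at
change-points occurring with hazard rate *h*.  The exact observer
tracks the posterior over the run-length *r* (time since the last
change) and per-run-length sufficient statistics (χ, ν), updated
recursively: run *r* grows to *r + 1* with weight (1 − h) times its
predictive likelihood of the new datum, and mass h re-enters at the
shortest run with the prior predictive.  Its prediction is the
run-length-weighted mixture of conjugate posterior means, propagated
once through the change-point prior.

The reduced observer keeps only N nodes with fixed run-lengths
l₁ < … < l_N.  Node *i* updates a running mean with a *fixed* Delta
rule,

    μᵢ ← μᵢ + αᵢ (u(x) − μᵢ),   αᵢ = min{1 / (lᵢ + ν₀), 1},

and the node weights — an approximate run-length distribution — follow
a transition prior that preserves the expected unit growth of the run
length (advance probability 1/(lᵢ₊₁ − lᵢ)), rescaled by each node's
predictive likelihood.  One node is a plain Delta rule; a handful of
nodes already track the full filter closely at a fraction of the cost.

The package also provides the surrounding study machinery: generators
for change-point data and a bounded predictive-inference task,
Monte-Carlo estimation of ground-truth error with optimisation of node
learning rates, maximum-likelihood fitting of candidate observers to
subject prediction sequences (BIC-scored, decision noise profiled in
closed form), random-effects group model selection with exceedance
probabilities, and model-recovery confusion matrices.

## Worked example

```r
library(deltamix)

fam <- ef_bernoulli()                          # uniform prior: chi0 = 1, nu0 = 2
ds  <- sample_dataset(fam, 1, 2, hazard_spec(0.05), T = 300, seed = 8)

full <- filter_run(full_model(fam, 1, 2, h = 0.05, r_max = 100), ds$x)
red  <- filter_run(reduced_model(fam, 1, 2, h = 0.05,
                                 nodes = log_spaced_nodes(18, 1, 100)), ds$x)

c(full    = mean((full$pred_mean - ds$theta_true)^2),
  reduced = mean((red$pred_mean  - ds$theta_true)^2))
#>       full    reduced
#> 0.03409777 0.03909714
```

The sequence holds a hidden Bernoulli rate that is redrawn from a
uniform prior at change-points (hazard 0.05).  Both observers watch the
0/1 outcomes only; the numbers printed are the mean squared errors of
their one-step-ahead predicted rate against the hidden true rate — the
exact filter is slightly better, the 18-node mixture close behind at
O(N) cost per step.  `filter_run()` also returns per-step filtered
estimates and, optionally, the evolving run-length/node-weight
distribution; `effective_learning_rate()` converts any prediction
trajectory into the per-trial learning rates it implies.

A command-line front end with `simulate`, `infer`, `optimize-lr`,
`fit`, `bms` and `confuse` subcommands lives at
`inst/cli/deltamix.R` (see `?dm_cli`).

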