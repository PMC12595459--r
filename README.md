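# synconsol

Memory consolidation in recurrent attractor networks with multi-factor
synapses.

`synconsol` is an R package for computational neuroscientists studying how
sleep-like replay can reorganize synapses so that stored memories survive
noise. It implements, end to end:

* a binary recurrent network (`N` threshold neurons, nonnegative weights
  `w_ij`, per-neuron inhibitory current `I_inh,i`) storing `M` random
  binary patterns `ξ^μ` (coding level `f`) as attractors;
* a synapse model in which every weight is a product of `z` subsynaptic
  factors, `w_ij = ∏_k u_ijk`, with component 1 a volatile plasticity tag;
* a replay-driven consolidation algorithm that maximizes each neuron's
  signal-to-noise ratio
  `SNR_i(q) = min_μ |I_i^μ| / sqrt(Σ_j w_ij^q)` — the weakest pattern's
  margin over the input-noise scale — by three repeated steps: gated
  plasticity induction during pattern replay
  (`δu_ijk = ±e^{-β|I|} ξ_j w_ij/u_ijk`), budgeted expression
  (`G_i = η / Σ_μ|g|`, a soft argmin over patterns that anneals into
  batch-perceptron support-vector selection), and multiplicative
  homeostatic scaling of all factors to a fixed norm `Σ u² = U0`.
  Consolidation with `z` factors is equivalent to margin maximization
  under an L(2/z) constraint on the weights, so multi-factor synapses
  (`z ≥ 2`) prune connections as a by-product — sparse connectivity from
  purely multiplicative homeostasis;
* neural- and synaptic-noise robustness assays (`tolerated_noise()`),
  where the noise-scaling exponent is `q = 2` for state flips and
  `q = 2 - 2/z` for white noise on the volatile tag (`Δw ∝ √w` for
  two-factor synapses);
* a stochastic simulator of intrinsic synaptic volatility
  (`simulate_synapses()`) producing longitudinal strength tables, with an
  optional homeostatic mode conserving `Σ w^{2/z}`;
* trajectory statistics: the fluctuation-scaling exponent of
  `⟨|Δw|⟩ ∝ w^x` (moving-average log–log fit with synapse-level
  bootstrap; prediction `x = 1 - 1/z`) and the coefficient of variation
  of the population q-norm across time, whose minimizer reads out
  `q_min = 2/z`; plus pruning-vs-weight, response-correlation
  connectivity, tuning sparseness, and per-pattern SNR-change analyses.

## A worked example

Store 10 patterns in a 120-neuron network with two-factor synapses,
consolidate, and measure what changed:

```r
library(synconsol)

patterns <- generate_patterns(N = 120, M = 10, f = 0.5, seed = 1)
wake <- imprint_patterns(patterns, z = 2)      # one-shot Hebbian storage
wake
#> synaptic_state: N = 120 neurons, z = 2 factor(s), density = 0.374
#>   mean live weight = 0.006835, mean I_inh = 0.1557

sleep <- consolidate(wake, patterns,
                     consolidation_config(cycles = 1500, eta = 0.02,
                                          beta_growth = 1.005))
sleep$state
#> synaptic_state: N = 120 neurons, z = 2 factor(s), density = 0.164
#>   mean live weight = 0.006835, mean I_inh = 0.1515

mean(snr(wake, patterns, q = 1))         # 0.065
mean(snr(sleep$state, patterns, q = 1))  # 0.160
```

Consolidation pruned the connectivity from 37% to 16% of possible
connections while the SNR against synaptic noise (`q = 2 - 2/z = 1`)
rose 2.5-fold; every pattern remains a fixed point throughout
(`stability_report()`), and the factor norm `Σ u²` of each neuron is
unchanged to 1e-10. The consolidated network withstands quenched
perturbations of its volatile components up to twice the mean tag value
(`tolerated_noise(..., kind = "synaptic")` returns 2.0 here), where the
merely imprinted network fails almost immediately.

The volatility simulator and the scaling analysis recover the two-factor
signature from 1,000 synapses sampled every 30 min for 24 h:

```r
tab <- simulate_synapses(n = 1000, z = 2, seed = 3)
fluctuation_scaling(tab, n_boot = 100, seed = 4)
#>         branch     slope    slope_se intercept n_pairs
#> 1 potentiation 0.5035402 0.006681989 -3.547285   24058
#> 2   depression 0.4891731 0.007168665 -3.565620   23824
```

Both branches sit on the predicted square-root law (`x = 1 - 1/z = 0.5`).

## Layout

* `R/` — pattern generation and imprinting, network dynamics, the
  consolidation algorithm, noise assays, the volatility simulator,
  trajectory statistics, experiment orchestration, TSV/JSON I/O.
* `tests/testthat/` — unit, property, and end-to-end scientific tests,
  including convex max-margin oracles (dual-space solvers independent of
  the consolidation path) for tiny-instance equivalence checks.
* `vignettes/consolidation-model.Rmd` — the model, its assumptions, all
  tunable parameters, and every numerical design choice.
* `inst/cli/synconsol` — optional thin command-line interface
  (`generate-patterns`, `imprint`, `consolidate`, `perturb-and-recall`,
  `simulate-synapses`, `analyze-scaling`, `analyze-norms`,
  `analyze-pruning`, `analyze-tuning`, `run-experiment`).
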