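---
title: "Two-factor synaptic consolidation: model, algorithm, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-factor synaptic consolidation: model, algorithm, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synconsol)
```

## The model

`synconsol` studies how a recurrent network of `N` binary neurons can store
`M` binary activity patterns as attractors and then reshape its synapses so
that recall survives noise. The circuit dynamics are synchronous threshold
updates: neuron `i` fires at time `t + 1` iff its input current
`I_i = sum_j w_ij s_j(t) - I_inh_i` exceeds zero, with nonnegative excitatory
weights `w_ij` and a per-neuron scalar inhibitory current. Patterns `xi^mu`
have i.i.d. Bernoulli(`f`) entries (coding level `f <= 0.5`); the storage
load is `alpha = M/N`.

The distinctive ingredient is the synapse model: every weight is a product
of `z` nonnegative subsynaptic factors, `w_ij = prod_k u_ijk`, standing for
the molecular components (release probability, receptor density, scaffold
content) whose interaction sets functional strength. Component `u_ij1` is a
volatile plasticity tag; the others are stabler. Plasticity acts on the
factors, never directly on `w`.

Robustness of a stored pattern is quantified per neuron by a
signal-to-noise ratio

    SNR_i(q) = min_mu |I_i^mu| / sqrt(sum_j w_ij^q),

where the numerator is the margin of the weakest pattern and the exponent
`q` encodes the noise type: `q = 2` for neural noise (random flips of the
input states), `q = 2 - 2/z` for intrinsic synaptic noise applied to the
volatile component (on aligned factors a tag perturbation moves the weight
by `~ w^(1 - 1/z)`). Consolidation with `z` factors maximizes `SNR(q = 2/z)`,
so single-component synapses optimize against neural noise and two-factor
synapses against synaptic noise.

## The consolidation algorithm

Each cycle has three steps, all local to a neuron:

1. **Replay.** Every stored pattern is reinstated as the network state; the
   neuron records its margin and accumulates a gated Hebbian signal per
   factor, `delta u_ijk = g * xi_j * (w_ij / u_ijk)`, the gradient of the
   weight with respect to that factor. The gate
   `g = +-exp(-beta * margin)` is largest for the weakest (smallest-margin)
   memory, so weak memories drive the most plasticity.
2. **Expression.** The accumulated signal is expressed with a per-neuron
   learning rate `G_i = eta / sum_mu |g|`, which fixes the total amount of
   expression per cycle to the budget `eta`. Jointly, gate and rate act as
   a *soft argmin*: pattern `mu` receives expression weight
   `eta * softmax(-beta * margin)_mu`. Annealing `beta` turns this smoothly
   into the hard support-vector selection of the batch perceptron. The
   inhibitory current receives the bias-term analogue `-G_i * sum_mu g`.
   Factors are clipped at zero: for `z >= 2` a clipped component prunes the
   connection permanently (the signal `delta = 0` at `u = 0`), while a
   single-component weight may regrow.
3. **Homeostatic scaling.** All incoming factors of a neuron are rescaled
   multiplicatively so that `sum_jk u_ijk^2` returns to its reference value
   `U0_i`. This preserves every surviving weight ratio — the multiplicative
   scaling seen experimentally — yet, expressed in weight space, it holds
   the L(2/z) norm of the weights fixed. Maximizing the margin under that
   constraint is exactly L2-margin maximization for `z = 1` and L1-margin
   maximization for `z = 2`, which is why multi-factor consolidation
   implicitly sparsifies: L1-constrained margin maxima sit on faces of the
   simplex where many weights vanish.

Factor alignment (`u_ij1 = ... = u_ijz`) is not imposed; it emerges, because
the gradient signal `w/u_k` is largest for the smallest factor.

### Sign of the gate

During replay the network state *is* the pattern, so the postsynaptic
activity that carries the sign of the Hebbian term is the reinstated target
`s_i = xi_i^mu`, giving `g = (2 xi_i^mu - 1) exp(-beta * m)` with the signed
margin `m = (2 xi_i^mu - 1) I_i^mu`. Whenever the pattern is a fixed point
this is identical to reading the sign off the momentary current, since then
`sign(I) = 2 xi - 1` and `m = |I|`. We use the reinstated-state form
throughout because it behaves correctly in the transient regime too: if
crosstalk pushes a margin through zero mid-consolidation, the momentary-sign
reading would lock the error in (the gate would *stabilize* the wrong
response, and the soft argmin, seeing a large `|I|`, would never revisit
it), whereas the reinstated-state form repairs it, consistent with the
batch-perceptron account of the algorithm. The exported `gate()` documents
the momentary-current form, which coincides on stable states.

### Numerical choices

* **Expression budget units.** `eta` is dimensionless. Internally the
  per-neuron budget in factor units is `eta * u_scale^(2 - z)` with
  `u_scale = sqrt(U0/(N z))`; for `z = 2` the plasticity signal is already
  proportional to the factors, so the budget is exactly `eta`. The default
  `eta = 0.05` makes per-cycle relative weight changes of a few percent;
  oracle-grade convergence on tiny problems uses `eta <= 0.01`. The
  converged margin deficit scales with `eta` (a constant-budget limit
  cycle), so accuracy is bought with smaller budgets and more cycles.
* **Gate sharpness.** `beta` is initialized per neuron at
  `beta0 / median_mu |I_i^mu|` (default `beta0 = 1`: the gate e-folds at the
  typical margin) and annealed geometrically (`beta_growth`, default 1.02).
  `beta_max` (default 100) caps the total annealing factor: at finite
  sharpness the expression stays averaged over the near-degenerate support
  set, which avoids single-pattern steps hammering individual weights.
* **Softmax stability.** Expression weights are computed as a shifted
  softmax of `-beta * m`, never as the ratio of raw gate values, so the
  algorithm remains exact when `beta * m` is far outside floating-point
  exponent range. Composing `replay_cycle()`, `learning_rate()` and
  `express_and_scale()` reproduces `consolidate()` cycles exactly in the
  moderate-`beta` regime (this identity is tested).
* **Reference norm `U0`.** Fixed per neuron from the state entering
  consolidation; the conservation `sum u^2 = U0` holds after every cycle to
  1e-10 relative (tested exactly).
* **Ties.** No tie-breaking is needed anywhere: the soft argmin distributes
  expression smoothly over equal margins.
* **Dead neurons.** A neuron whose entire factor row reaches zero is frozen
  and excluded from aggregate diagnostics.
* **Stationary-support density.** With a constant budget and sharp
  selection, weights pinned at the nonnegativity boundary flicker between
  zero and a fraction of one expression step, so a snapshot count of
  "nonzero" weights overstates connectivity at any fixed floor. The
  diagnostic `density_settled` instead counts connections that never touch
  exact zero during the final `settle_frac` (default 10%) of cycles:
  membership of the stationary support is step-size-independent, whereas a
  magnitude floor is not. The per-cycle `density` column (floor
  `prune_floor = 1e-3` of the mean live weight) is retained for
  comparability.
* **Measured-neuron subsets.** Each neuron's optimization involves only its
  own incoming factors, so `consolidate(..., neurons = subset)` reproduces
  the corresponding rows of the full run bit for bit (tested); large-`N`
  density ensembles are estimated on a 150-neuron measured subset.

### The multiplicative form near convergence

For `z = 2` the net per-cycle weight change decomposes into a homeostatic
multiple of `w` plus a replay term `~ G * sum_mu g xi_j * w`, i.e. both
terms are proportional to the momentary weight. Empirically this shows as a
strong log–log association between per-cycle `|dw|` and `w` (correlation
~0.9 near convergence) and as a clear contrast with `z = 1`, where `|dw|`
is weight-independent. The *pooled* linear regression of `|dw|` on `w`
through the origin has limited `R^2` (~0.65–0.75), because the replay
coefficient carries the binary presynaptic factor `xi_j` of the currently
selected patterns — an irreducible dispersion across synapses, not a
failure of the multiplicative form. The property tests assert the log–log
form and the `z = 1` vs `z = 2` contrast.

## The intrinsic-volatility simulator

`simulate_synapses()` evolves `n` independent synapses, each a `z`-factor
product. Per step `dt` the volatile tag takes a white-noise step
`sigma * sqrt(dt)`, clipped at zero; stable components relax toward the
common geometric mean at rate `relax` (default 2/h, which equilibrates them
within one sampling interval), the minimal mechanism that keeps factors
aligned while the tag fluctuates.
For `z >= 2` a synapse whose tag hits zero is pruned permanently; a
single-factor weight can leave zero again. Initial strengths are log-normal
(heavy-tailed, like empirical strength distributions; default
`meanlog = 0, sdlog = 1`). Defaults `dt = 0.5` h and `T = 24` h mirror dense
longitudinal imaging protocols; `sigma = 0.05` per sqrt-hour keeps
first-order (aligned-factor) scaling dominant over 24 h. Under these
conditions the fluctuation exponent of `<|dw|>` vs `w` is `1 - 1/z`.
Exponent recovery (two bootstrap SEs on 1,000 synapses) holds in the
alignment-dominated regime: `relax = 2`/h at `sigma = 0.05`, or any
`relax >= 1`/h at `sigma <= 0.03`. Slower relaxation with stronger noise
leaves residual misalignment whose second-order corrections split the
potentiation and depression branches by a few SEs — itself a useful
reminder that measured exponents blend mechanism and sampling.

The homeostatic flag rescales all live strengths after every step so the
population mass `sum_j w_j^(2/z)` is conserved exactly; the q-norm CV
analysis then recovers `q_min = 2/z` by construction, which provides the
positive control for `norm_cv()`.

What the generator does *not* emulate: activity-dependent (extrinsic)
plasticity, inter-synapse correlations (except via the homeostatic
constraint), measurement noise, and temporal averaging by slow sampling.
Tests passing on these synthetic tables therefore certify the estimators
(fluctuation-scaling slopes, `q_min`), not any claim about a particular
experimental dataset; on real data the same operations apply but exponents
blend intrinsic and extrinsic contributions.

## Trajectory and network statistics

* **Fluctuation scaling.** Pairs `(w(t), dw)` at a chosen lag, split into
  potentiation and depression branches; within a branch, pairs are sorted
  by `w`, a centered moving average (default window 101 pairs) smooths
  `(log w, log |dw|)`, and a least-squares line through the averaged curve
  gives the exponent. Raw-pair regression and an RMS-deviation variant are
  provided and agree on clean power laws. Standard errors bootstrap over
  synapses (not time points) to respect within-synapse autocorrelation;
  default 100 replicates. Pairs touching zero are excluded: pruning events
  are analyzed separately by `pruning_vs_weight()`.
* **Norm CV.** `(sum_j w_j^q)^(1/q)` per time point, CV over time, scanned
  over `q` in 0.25–3 (step 0.25, covering `2/z` for `z` in 1–3 and the flat
  tail); `q_min` is the argmin and its SE bootstraps over synapses (default
  1000 replicates, implemented as a single matrix product over multinomial
  resampling weights).
* **Tuning sparseness.** The Treves–Rolls-style selectivity
  `S = (1 - a)/(1 - 1/n)`, `a = (mean r)^2 / mean(r^2)`, computed along
  stimuli, neurons, or time; 0 for uniform response vectors, 1 for one-hot.
  For connectivity analyses the graded-activity proxy is the rectified
  input current; for familiar-vs-novel tuning comparisons responses come
  from `graded_responses()`, a logistic readout of the currents (default
  temperature one tenth of the mean absolute current, shared between the
  stimulus sets being compared). A binary or rectified readout saturates
  the metric for sparse codes — nearly all novel responses sit at exactly
  zero — so only a graded output can express the *sharpening* of familiar
  tuning.
* **Per-pattern SNR.** The weakest *signed* neuron margin normalized by the
  neuron's noise term, so unstable patterns are visibly negative;
  `pattern_snr_change()` regresses the consolidation-induced change on the
  initial value (weak memories gain the most — a ceiling effect — giving a
  negative slope, and longer replay shifts the curve upward).

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen so
the full suite completes on a single CPU: tiny oracle instances (`N <= 15`,
`M <= 4`) for convex cross-checks, `N` in 80–200 for behavioral properties,
`N = 500` with a 150-neuron measured subset for the near-capacity density
experiment, and 400–1000 simulated synapses for the trajectory statistics.
The underlying phenomena (density floor at 1/2, alignment, noise-tolerance
ordering, exponents `1 - 1/z`, `q_min = 2/z`) are not finite-size artifacts,
but quantitative values at these sizes carry finite-size scatter, which is
why the density band is +-5 percentage points and stochastic orderings are
asserted outside two standard errors.

## Known limitations

* The wake-phase imprinting rule is a clipped covariance rule with a
  midpoint threshold — the simplest nonnegative autoassociative rule
  meeting the fixed-point contract; its own capacity is far below the
  perceptron capacity, so near-capacity studies start consolidation from
  partially unstable imprints (reported, not hidden, by
  `imprint_patterns()`).
* Convergence to the max-margin solution is first-order: accuracy is
  limited by the constant expression budget. The 2%-of-oracle margins in
  the tests need small budgets and 10^4-cycle runs on tiny instances.
* Binary neurons, synchronous updates, no explicit inhibitory population;
  the graded-activity proxy is the rectified input current.
* The intrinsic-noise simulator is a minimal mechanism consistent with the
  tag-plus-stable-components picture, not a fitted biophysical model.
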