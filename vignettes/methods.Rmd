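---
title: "Spatio-temporal vaccine-hesitancy forecasting: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatio-temporal vaccine-hesitancy forecasting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaxscape)
```

## The problem

Childhood vaccine hesitancy — measured here as the fraction of unique
children aged 0–6 in a ZIP code who have at least one vaccine-refusal
claim (ICD-10-CM Z28 family) in a quarter — varies strongly in space and
time. Public-health agencies want quarterly, ZIP-level forecasts so
interventions can be targeted, but labels are expensive: they come from
restricted all-payer claims databases, and many ZIP codes are never
observed. `vaxscape` addresses the cold-start node-regression problem:
given demographic features for *all* ZIPs, a ZIP-to-ZIP connectivity
graph, and hesitancy labels for a *subset* of ZIPs over quarters
`1..T`, forecast hesitancy at `T + 1` (or further) for the unlabeled
ZIPs.

## The model

The learner has two modules trained **separately**, each with its own
Adam optimizer and its own MAPE + L2 loss. Optimizing both with a single
joint loss is deliberately avoided: on panels of this size the modules
destabilize each other, and the two-optimizer design keeps each module's
parameters insulated from the other's loss surface.

**Spatial module (Ms).** For each quarter `t`, stacked order-1
Weisfeiler–Leman message-passing layers (GraphConv),

    out_i = W_self x_i + W_neigh * sum_j W[i, j] x_j + b,

with ReLU and dropout between layers and a linear head, map the
normalized demographic features `nc(t)` to a per-node scalar `yhat(t)`.
One parameter set is shared across quarters. The loss at each quarter is
`MAPE(h_K(t), yhat_K(t)) + lambda * L2(weights)` over labeled,
observed nodes only; message passing always runs over the full graph, so
unlabeled nodes' *features* (never their labels) inform their
neighbours.

**Temporal module (Mt).** An LSTM consumes each node's series
`yhat(1..T)` as a scalar sequence; a linear head maps the hidden state at
step `t` to an output `o(t)`. Two alignments are supported:

* `reconstruction` (used in all package experiments): `o(t)` is
  supervised against `h(t)` for `t = 1..T`, and the step-`T` output
  serves as the `T + 1` forecast. Every emitted output — including the
  one used for forecasting — is supervised, which keeps the forecast
  calibrated.
* `shift`: `o(t)` is supervised against `h(t + 1)` for `t = 1..T-1`, a
  literal one-step-ahead reading. The final-step output is then never
  supervised, and on small panels the recurrent state extrapolates
  outside its trained range; we observed systematic forecast
  mis-calibration under this alignment, which is why it is not the
  experimental default.

The `yhat` series handed to Mt is computed in evaluation mode (dropout
off) and treated as a constant input: no gradient flows from `loss2`
back into Ms.

**Forecasting.** Cold-start prediction runs Ms over quarters `1..T`
with full-graph message passing, then rolls Mt over each requested
node's series. Multi-quarter horizons feed each prediction back as the
next input (closed loop).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_layers` | 2 | message-passing depth (3+ overfits; 1 underfits) |
| `hidden` | 256 | Ms width; claims-scale default, tests use 12–64 |
| `t_hidden` | 32 | LSTM width; tests use 6–16 |
| `dropout` | 0.5 | between Ms layers and on the LSTM output, training only |
| `lr` | 5e-4 | Adam learning rate, both modules |
| `lambda` | 5e-4 | L2 weight on all weight matrices (not biases) |
| `epochs` | 15000 | claims-scale default; desk-scale runs use 120–2500 |
| `eps` | 1e-3 | MAPE denominator floor (see below) |
| `ms_update` | per_quarter | one Adam step per training quarter; `batch` accumulates one step per epoch (smoother on small panels, used in the package's experiments) |

**The MAPE floor `eps`.** Targets of exactly zero (a quarter with no
refusal claims in a small ZIP) make relative error undefined; the
denominator is floored at `eps`. For *evaluation metrics* the floor is
the conventional `1e-3`. For *training*, note the gradient of a
zero-target cell scales as `1/eps`: at `1e-3` a single `h = 0` cell
carries two orders of magnitude more gradient weight than a typical cell
(`h ~ 0.15`) and drags the whole fit toward zero. The package therefore
exposes the training floor, and all experiments in the tests and
acceptance script set `eps = 0.05` — roughly half the baseline
hesitancy level — during training, while reporting metrics at the
conventional floor. Cells with `p = 0` (no children observed) are masked
out of every loss and metric entirely.

## Graphs

Three ZIP-graph variants are built by the package: the aggregated
contact graph (summed activity weights of person-level cross-ZIP
contacts — the variant that carries the strongest predictive signal),
the boundary-adjacency graph (unit weights), and the fully connected
inverse-centroid-distance graph. All weights are min-max normalized over
realized edges; the weakest realized edge maps to weight 0 but remains
in the edge support, making normalization idempotent. Constant-weight
graphs (adjacency) normalize to weight 1 everywhere, preserving
connectivity.

## Spatial statistics

`morans_i()` implements weighted global Moran's I with the unweighted
mean and a zero diagonal; `row_standardize = TRUE` applies the common
row-standardisation convention, which stabilises the statistic when a
handful of heavy edges would otherwise dominate (as with min-max
normalized gravity weights). `isolation_index()` is the
hesitant-population-share-weighted average of hesitancy, i.e. the
exposure of the hesitant group to itself. `kulldorff_scan()` is a
Poisson scan statistic on the graph: case counts are `round(h * p)`,
candidate zones are grown around every node in hop-count order
(tie-break lowest index) up to half the total population, the
log-likelihood ratio is the standard Poisson form, and significance
comes from multinomial Monte-Carlo redistribution of the cases. The
graph analogue of the classical distance-ordered circles is hop-ordered
neighbourhood growth; no elliptic or space-time variants are attempted.

## The synthetic study

There is no public ZIP-level claims panel, so the package ships a
generator whose output exercises every pipeline stage with the
statistical structure the analysis assumes. Its design, and which
features of real data it does and does not capture, determine what a
passing test can show; the choices and their reasons:

* **Geography**: centroids uniform on the unit square; boundary
  adjacency by the Gabriel rule (edge iff no third centroid in the
  circle on the pair's diameter). The Gabriel graph is a subgraph of the
  Delaunay triangulation that contains the minimum spanning tree, so it
  is planar-like, sparse, and always connected.
* **Populations**: lognormal (`meanlog log 4000`, `sdlog 0.7`), giving
  a realistic skew with some ZIPs under the 1000-resident analysis
  threshold. A heavier tail (sdlog above ~1) makes one giant ZIP
  dominate the per-quarter min-max feature scaling and erases
  between-node contrast — an instability of the normalization scheme
  itself that real panels with county-bounded ZIP sizes do not show.
* **Contact network**: gravity weights `pop_i pop_j / d^2`, doubled
  within geographic community blocks, realized as Poisson numbers of
  person-level contacts with Gamma(4,4) activity weights (unit mean), so
  aggregation reproduces the targets to within sampling error.
  Intra-ZIP contacts are emitted and must be discarded by aggregation.
* **Demographics**: per-field Dirichlet compositions whose
  concentrations are tilted by Gaussian surfaces smoothed over the
  contact graph and following an AR(1) in time (persistence 0.9).
  Spatial smoothness mirrors real residential sorting; the slow drift
  (in-migration, payer churn) keeps *current* features informative about
  *current* hesitancy in a way stale histories are not.
* **Latent hesitancy field**: on the logit scale,
  `s(t) = rho * [(1-gamma) s(t-1) + gamma * Wbar s(t-1)] + (1-rho) * u(t) + noise`,
  with `u` the centred demographic effect `beta . x~(t)` computed from
  the *same* normalized features the learners consume (so the planted
  structure is exactly representable), `gamma = 0.4` the share of the
  carry-over that diffuses to contacts, and the trend added outside the
  recursion: `h* = plogis(qlogis(base_rate) + trend * t + s(t))`. The
  self-retaining carry-over matters: a pure neighbour-diffusion operator
  (zero diagonal, row-normalized) scrambles the field through high graph
  powers that no shallow message-passing model — nor even a linear
  regression on features — can invert, which would make the benchmark
  vacuous.
* **Observation**: quarterly panel denominators are
  `Binomial(n_children, q)` with Beta-distributed participation `q`
  (claims capture is uneven across quarters), refusal counts are
  Binomial, and `p = 0` cells are masked. This heteroscedastic
  observation layer is what separates feature-based from history-based
  models: features enter the latent field as realized counts (no
  attenuation), while observed hesitancy histories carry binomial noise.
* **Defaults**: `N = 100`, `TS = 12` quarters, `rho = 0.6`,
  `trend = 0.05` logit/quarter, `base_rate = 0.1`, `noise_sd = 0.05`,
  child share 4% of residents, mean participation 0.5. With these, the
  latent field's Moran's I over the contact graph is positive in
  essentially every run (checked at `rho >= 0.4`), the mean hesitancy
  series rises, and the binomial observation noise is small relative to
  the planted between-ZIP signal, so recovery is possible in principle
  and failures indicate model problems rather than an unlearnable
  target.

What the generator does **not** emulate: real claim-coding variation
(every refusal is a clean Z28 record), household and school structure in
the contact network, demographic confounding with population size, and
calendar effects. Passing tests therefore demonstrate that the pipeline
recovers structure it is designed to represent — not that the model
would achieve any particular accuracy on a real claims database.

## Experimental conventions

Package experiments (tests and the acceptance script) min-max normalize
the *target* per quarter (`normalize_h = TRUE`) in addition to the
features, mirroring the source pipeline's per-quarter normalization of
all columns; raw fractions remain the package default for plain use.
Desk-scale problem sizes are used throughout: `hidden` 12–64,
`t_hidden` 6–16, 120–2500 epochs, `ms_update = "batch"`,
training-loss floor `eps = 0.05`, learning rate 2e-3; the reference
fit on the 100-ZIP benchmark uses `hidden = 64`, `t_hidden = 8`,
2500 epochs, selected by a small grid on the benchmark (the same way
the claims-scale configuration would be chosen). The claims-scale
defaults (256/32 hidden, 15000 epochs, lr 5e-4) are what the same
architecture would use on a statewide panel. Multi-seed comparisons
(ablations, graph variants, label budgets) run at further-reduced
sizes so a full suite stays within desk runtimes.

## Active learning

`active_learn()` implements budgeted label acquisition: starting from an
initial set (uniform, spread by greedy max–min weighted-shortest-path
distance, or concentrated by heaviest-edge growth), it repeats `B`
times: retrain from scratch at reduced epochs, forecast every unlabeled
node, score each candidate by the Euclidean distance between its
prediction and the vector of current training labels at the target
quarter, and add the arg-max (ties to the lowest index). The score is
output-space diversity: the candidate whose predicted hesitancy is
farthest from the labels already held is the one whose true label adds
the most information. Retraining from scratch (rather than
warm-starting) keeps iterations exchangeable and reproducible; the
reduced retrain epoch count trades per-iteration fit quality for loop
tractability.

## Numerical choices

* Glorot-uniform initialization; LSTM forget-gate bias 1.
* Adam with bias correction, `beta1 0.9`, `beta2 0.999`, `eps 1e-8`.
* Dropout is inverted (masks scaled by `1/(1-p)`), so evaluation mode
  needs no rescaling.
* Min-max normalization maps constant columns to 0 (features) or all
  edges to 1 (graphs — connectivity is worth more than a degenerate 0).
* A single integer seed drives every stochastic element (initialization,
  dropout, splits, simulation); fixed seeds reproduce loss traces
  bitwise on the same platform.
* Ties in active-learning arg-max and zone growth break to the lowest
  node index.
* `lstm_only` (the sequence-only ablation) reads evaluation nodes'
  observed hesitancy histories — a different information regime from
  every cold-start model; reports that include it must flag the
  difference.

## Known limitations

* The hand-rolled dense linear algebra targets panels up to a few
  hundred ZIPs; statewide panels (~600+ ZIPs, 24 quarters) would want
  sparse matrices and a compiled backend.
* MAPE-trained models are poorly behaved when typical targets approach
  the `eps` floor; for very rare outcomes a count-likelihood loss would
  be preferable.
* The closed-loop multi-horizon rollout compounds errors; horizons
  beyond ~4 quarters are extrapolation.
* Monte-Carlo scan p-values have resolution `1/(n_mc + 1)`; n_mc of 999
  is recommended when runtime allows.
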