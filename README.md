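# vaxscape

Forecasting childhood vaccine hesitancy at the ZIP-code level from
insurance-claims panels, for epidemiologists and public-health analysts
who need quarter-ahead, fine-grained hesitancy maps when only a subset
of ZIP codes is ever labeled.

Hesitancy is measured as the fraction of unique children aged 0–6 in a
ZIP-quarter with at least one vaccine-refusal claim (ICD-10-CM Z28
family). The core estimator is a two-module spatio-temporal learner:

* a **spatial module** M<sub>s</sub> of stacked order-1
  Weisfeiler–Leman message-passing layers (GraphConv),
  `out_i = W_self x_i + W_neigh Σ_j W[i,j] x_j + b`, regressing each
  quarter's demographic features on hesitancy over a weighted ZIP graph,
  and
* a **temporal module** M<sub>t</sub>, an LSTM over each node's series
  of spatial predictions ŷ(1..T), emitting the quarter T+1 forecast,

trained **separately** with per-module Adam optimizers and losses
`MAPE + λ‖W‖²` (no gradient flows between modules). Prediction is
cold-start: unlabeled ZIPs contribute features to message passing but
their hesitancy history is never read. Around the estimator the package
provides:

* graph builders for the three connectivity mechanisms — aggregated
  person-level contacts, geographic adjacency, inverse centroid
  distance — with min-max edge normalization;
* a claims ETL (child filter, Z28 refusal flag, unique-children
  quarterly aggregation, population filter, per-quarter min-max
  normalization, optional PCA);
* budgeted **active learning** that queries the ZIP whose prediction is
  farthest (Euclidean norm) from the current training labels;
* spatial statistics: weighted Moran's I, the isolation index, and a
  Poisson Kulldorff scan for high-hesitancy clusters on a graph;
* baselines (linear regression with neighbour information, MLP,
  GNN-GRU, GCN-LSTM) and ablations (spatial-only, sequence-only);
* a seeded synthetic-data generator (geography, gravity contact
  network, claims records, quarterly panels with planted spatial and
  temporal structure) so the whole pipeline runs without restricted
  claims data.

## Worked example

The package's reference benchmark: a synthetic study of 100 ZIP codes
over 12 quarters whose hesitancy field has positive spatial
autocorrelation over the contact graph (rho = 0.6), a rising trend, and
demographic structure; 70% of ZIPs are labeled and the final quarter of
the 30 held-out ZIPs is forecast cold-start.

```r
library(vaxscape)

sim   <- simulate_study(sim_config(seed = 0))          # N = 100, TS = 12
panel <- normalize_features(sim$panel, normalize_h = TRUE)
split <- train_split(panel, train_frac = 0.7, seed = 0)

fit <- vaxstl(panel, sim$graph, split,
              vaxstl_control(hidden = 64, t_hidden = 8, epochs = 2500,
                             dropout = 0.5, lr = 2e-3, lambda = 5e-3,
                             eps = 0.05, ms_update = "batch",
                             loss2_alignment = "reconstruction"),
              seed = 0)
print(fit)
#> Spatio-temporal hesitancy learner (graphconv + lstm)
#>   100 ZIPs, trained on quarters 1..11, 70 labeled nodes
#>   final losses after 2500 epochs: loss1 = 0.4153, loss2 = 0.3945

ev <- split$eval; ok <- ev[panel$mask[ev, 12]]
regression_metrics(panel$h[ok, 12], predict(fit)[match(ok, ev), 1])
#>   MAPE 7.9976 | MSE 0.01200 | RMSE 0.1095 | MAE 0.0824 | R2 0.6638  (n = 30)
```

`loss1`/`loss2` are the final training losses of the two modules
(MAPE + L2, training floor 0.05). The cold-start forecast explains ~66%
of the between-ZIP variance of the held-out quarter (MAE ~ 0.08 on
the normalized scale). The MAPE column
uses the conventional 1e-3 denominator floor, which explodes on the
zero-valued cells that per-quarter min-max normalization creates (each
quarter's minimum ZIP maps to exactly 0) — MAE, RMSE, and R-squared are
the robust summaries on normalized targets. Spatial structure of the
generated field:

```r
morans_i(sim$truth$h_latent[, 12], sim$graph, row_standardize = TRUE)
#> [1] 0.4887   # similar hesitancy clusters along strong contact edges
isolation_index(sim$panel$h[, 12], sim$panel$p[, 12])
#> [1] 0.4345   # moderate self-exposure of the hesitant population
```

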