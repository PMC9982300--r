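# ccts — continual training of time-aware recurrent classifiers

Clinical time series are long, irregularly sampled, and labeled once at
their final time. A classifier that should be useful *before* the final
time has to score every growing prefix of a record — and each prefix length
is its own data distribution (early-stage vs late-stage physiology).
Training a network on that stream of distributions sequentially makes it
forget the early ones. `ccts` is for researchers studying this continual
setting: it implements a restricted-update training strategy for a
time-aware LSTM, the transfer metrics to judge it, an importance-based
interpretation layer (disease-style staging and marker ranking), and a
synthetic generator with known ground truth to exercise all of it.

## The method in brief

**Model.** A time-aware LSTM: the previous memory `C` is split into a
learned short-term part `C^S = tanh(W_d C + b_d)` and its complement
`C^T = C − C^S`; the short-term part is discounted by
`g(Δ) = 1/ln(e + Δ)` of the elapsed time between observations, and
`C* = C^T + g(Δ)·C^S` feeds the usual gated update. A small MLP head maps
the final hidden state to class probabilities.

**Training (restricted update).** Tasks are the prefix datasets at
increasing cut fractions. Two mechanisms restrict sequential training:

* *Limitation* — an importance-anchored penalty
  `O(θ) = CE(θ) + λ Σᵢ Fᵢ (θᵢ − θᵢ^prev)²`, with `F` the diagonal empirical
  Fisher information accumulated as a running mean over tasks; parameters
  important for earlier distributions are held near their old values.
* *Promotion* — a projection-free online update: a variance-reduced
  recursive gradient estimator `d_m = ∇O_m + (1−ρ_m)(d_{m−1} − G)`, a
  linear-minimization oracle over an L2 ball (`v = c − R·d/‖d‖`), and the
  step `θ ← θ + η_m (v − θ)`, with `ρ_m = η_m = (1/(m+1))^a`.

**Evaluation.** `R[i,j]` scores distribution `j` after task `i` (AUC);
backward/forward transfer summarize forgetting and lookahead benefit;
gradient fluctuation (mean squared sign change of the update-driving
gradient) measures optimization stability; Bonferroni-Dunn critical
differences compare methods by average rank.

**Interpretation.** Per-task Fisher snapshots aggregate by structure —
per input feature, per gate, per neuron. Bayesian online changepoint
detection on the importance trajectory segments training into stages;
per-stage importance ranking yields marker reports.

## Worked example

Two-stage stream whose class signal reverses sign between stages — the
fixture on which naive sequential fine-tuning forgets:

```r
library(ccts)

cfg <- standard_streams(seed = 1)[["forgetting-2d"]]
cfg$n_records <- 200L
train <- generate_dataset(cfg)
cfg_test <- cfg; cfg_test$seed <- cfg$seed + 10000L
test <- generate_dataset(cfg_test)

stream  <- build_prefix_stream(train$dataset, c(0.5, 1))
estream <- build_prefix_stream(test$dataset, c(0.5, 1))
model   <- tlstm_params(input_dim = 10, hidden_dim = 16, seed = 1)

naive <- train_ru(model, stream,
                  ru_config(epochs_per_task = 10, seed = 1,
                            lm_enabled = FALSE, pm_enabled = FALSE),
                  eval_stream = estream)
ru    <- train_ru(model, stream,
                  ru_config(epochs_per_task = 10, seed = 1, lambda = 0.25),
                  eval_stream = estream)

naive$history$accuracy_matrix
#> <accuracy_matrix> 2 tasks x 2 distributions
#>       [,1]  [,2]
#> [1,] 0.884 0.057
#> [2,] 0.287 0.968
ru$history$accuracy_matrix
#> <accuracy_matrix> 2 tasks x 2 distributions
#>       [,1]  [,2]
#> [1,] 0.993 0.665
#> [2,] 0.993 0.939

bwt(naive$history$accuracy_matrix)
#> [1] -0.597539
bwt(ru$history$accuracy_matrix)
#> [1] -0.0006002401
```

Reading: after task 1 both models classify half-length prefixes well
(first diagonal entry). After training on the full-length task, the naive
model's score on the early distribution collapses (`0.884 → 0.287` — the
reversed late signal overwrote the early rule), while the restricted
update holds it (`0.993 → 0.993`) and still reaches `0.939` on the new
distribution. Backward transfer (final-row minus diagonal mean)
summarizes this: strongly negative for naive, near zero for the
restricted update.

The staging side, on a four-stage stream with rotating informative
features:

```r
runs <- staging_benchmark(seeds = 1)
st <- runs[["1"]]$stages
st
#> <stage_assignment> 4 stages over 17 tasks; boundaries: 6, 11, 15
stage_boundary_tasks(runs[["1"]]$truth$stage_boundaries,
                     runs[["1"]]$cut_fractions)
#> [1] 7 11 15
```

The detector recovers the three planted boundaries within one task, giving
four stages; `rank_biomarkers()` on the per-task feature importance then
lists which features carry each stage.

A shell front end wraps the same pipeline
(`inst/scripts/ccts simulate|train|evaluate|interpret|report`).

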