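# humab

Statistical humanness scoring and CDR-preserving humanization of
antibody variable regions.

## What it does, and for whom

Antibodies raised in mice must be *humanized* — mutated toward
human-like sequence statistics while keeping the antigen-binding CDR
loops intact — before they can become therapeutics. Every computational
humanization protocol rests on a **humanness score** that separates
human from non-human variable-region sequences. `humab` is for
antibody engineers and computational immunologists who work with
fixed-length, AHo-numbered VH/VL alignments (149 positions per chain,
298 combined) and want:

* the **MG score**: the log posterior-predictive density of a one-hot
  encoded sequence under a multivariate Gaussian model with a
  Normal-Inverse-Wishart prior, inferred from an aligned learning
  ensemble. Writing $\bar x,\bar C$ for the empirical moments of the
  $M$ encoded learning sequences, $(\eta,U)$ for the uniform-sample
  prior moments and $\lambda\in(0,1]$ for the regularization weight,
  the score of a sequence $y \in \{0,1\}^{20L}$ is

  $$\log p(y\mid X) = \log t_N\!\Big(\tfrac{M}{1-\lambda}+2,\;
  \lambda\eta+(1-\lambda)\bar x,\;
  \big(1+\tfrac{1-\lambda}{M}\big)\langle\Sigma\rangle_{\rm post}\Big),$$

  with $\langle\Sigma\rangle_{\rm post} = \lambda U + (1-\lambda)\bar C
  + \lambda(1-\lambda)(\bar x-\eta)(\bar x-\eta)^\top$. Higher = more
  human-like. Pair correlations between positions — including across
  the VH/VL interface — are part of the model and can be switched off
  (`ablate_correlations()`) to measure their contribution.
* **distance baselines**: $T_k$ (mean Hamming distance to the $k$
  nearest reference sequences), $T_{\rm all}$, and a two-reference
  human-vs-murine score, with optional framework-only masking.
* **calibration**: ROC sweeps, AUC, Youden/MCC threshold selection, and
  validation-AUC selection of $\lambda$.
* **humanization**: steepest descent and simulated-annealing Metropolis
  Monte Carlo on the model energy $E = -\log p(y\mid X)$ with the CDR
  positions frozen, plus the triple comparison of predicted vs
  experimentally humanized sequences.
* **synthetic ensembles**: seeded generators (site profiles, Potts-like
  pairwise couplings, species pairs) so everything above is testable
  without external repertoire downloads.

All user-facing functions take a data frame of sequences first and
return tibbles, so pipelines compose with the pipe; fitted objects have
`tidy()`/`glance()` methods and results have `autoplot()` methods.

## Worked example

Build a synthetic human/murine species pair with strong pairwise
couplings, learn the human model, calibrate it, and humanize a murine
sequence:

```r
library(humab)

pair    <- make_species_pair(L = 30, divergence = 0.2,
                             coupling_strength = 3, seed = 10)
learn_h <- sample_coupled_db(pair$human,  400, "human_learn",  seed = 1)
val_h   <- sample_coupled_db(pair$human,  200, "human_val",    seed = 2)
val_m   <- sample_coupled_db(pair$murine, 200, "murine_val",   seed = 3)
test_h  <- sample_coupled_db(pair$human,  200, "human_test",   seed = 4)
test_m  <- sample_coupled_db(pair$murine, 200, "murine_test",  seed = 5)

sel <- select_lambda(learn_h, val_h, val_m,
                     grid = c(0.02, 0.05, 0.1, 0.2, 0.4))
sel$auc_by_lambda
#> # A tibble: 5 × 2
#>   lambda   auc
#>    <dbl> <dbl>
#> 1   0.02 0.866
#> 2   0.05 0.885
#> 3   0.1  0.898
#> 4   0.2  0.912
#> 5   0.4  0.926

model <- fit_mg(learn_h, sel$lambda, model_id = "human_L30")
model
#> <mg_model> human_L30  L=30  N=600  M=400  lambda=0.4  dof=668.7  ablation=none
#>   mg_max = 623.9754

roc <- roc_curve(mg_score(test_h, model)$mg_score,
                 mg_score(test_m, model)$mg_score)
roc
#> <mg_roc> 200 pos / 200 neg, higher_is_positive
#>   AUC = 0.9226  best threshold = 184.344  Youden = 0.7250  MCC = 0.7261
```

The model separates the two synthetic species with AUC 0.92; the
Youden-optimal threshold (184.3) is then *frozen* and reused on any
later query set:

```r
thr   <- select_threshold(roc)
calls <- classify_sequences(test_m, "mg_one_ref",
                            model = model, threshold = thr)
table(calls$label)
#>     human non-human
#>        32       168
```

168 of the 200 murine test sequences fall below the frozen threshold
(the Youden point trades the remaining 16% false-human rate against
sensitivity on the human side). Humanizing one murine sequence by
steepest descent, with eight positions standing in for the frozen CDRs:

```r
murine <- sample_coupled_db(pair$murine, 1, "murine_query", seed = 99)
traj   <- humanize_sd(model, murine, mask = c(5:8, 20:23))
glance(traj)
#> # A tibble: 1 × 7
#>   method  seed n_accepted best_score hd_final hd_best model_id
#>   <chr>  <int>      <int>      <dbl>    <int>   <int> <chr>
#> 1 SD        NA         23       414.       19      19 human_L30
```

23 accepted mutations raise the MG score monotonically to the nearest
local optimum (413.6), 19 mutations away from the murine origin; the
masked positions are untouched. `tidy(traj)` lists every accepted
mutation in order — the ranked "best next mutations" a conservative
humanization campaign would consider — and `autoplot(traj)` draws the
score-vs-distance trajectory. For real chains, `cdr_mask("VHVL")`
supplies the IMGT/AHo CDR positions and
`humanize_samc(..., schedule = anneal_schedule(preset = "full"))` runs
the complete published annealing schedule.

A thin command-line interface wraps the same functions
(`inst/scripts/humab-cli.R`; subcommands `fit`, `score`, `classify`,
`roc`, `select-lambda`, `humanize-sd`, `humanize-samc`,
`compare-triple`, `synth`), writing TSV/JSON artifacts plus a run
manifest with the seed and model checksum.

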