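# plcpredict

Predicting drug–phospholipid complex formation from molecular
descriptors.

Drug–phospholipid complexation improves the solubility and
bioavailability of poorly water-soluble drugs, but finding out whether a
candidate API and a phospholipid will actually form a complex
(complexation rate ≥ 80%) normally takes wet-lab trials. `plcpredict`
implements an in silico screen for formulation scientists: a
deep-learning pipeline over tabular molecular descriptors of the drug,
the lipid, the solvent and the reaction conditions, built for the
small-and-imbalanced data regime such curated tables live in.

The pipeline, each stage fitted on the training split only:

1. **Min–max normalization** — `x' = (x − x_min)/(x_max − x_min)` per
   descriptor, taming unit disparities (MW in the hundreds of Da vs.
   logP near 0).
2. **VAE minority augmentation** — a fully connected variational
   autoencoder (50–25 rectified encoder, 2-D Gaussian latent, symmetric
   logistic decoder; loss `1000·BCE + KL`, 5000 full-batch Adam steps at
   lr 0.001) generates a 500-row minority pool, from which exactly
   `n_majority − n_minority` rows are drawn to balance the classes.
3. **PCA** — covariance eigendecomposition; keep a fixed k (default 10)
   or the smallest k reaching 85% cumulative explained variance.
4. **Skip-connected 1D-CNN** — kernel-1/stride-1 convolutions widening
   8 → 16 → 32 channels, conv-1 output concatenated onto conv-3 output
   (the skip), max-pool 2, one more convolution, pool, flatten, logistic
   unit; 2500 full-batch Adam steps of binary cross-entropy. The default
   network has 2081 learnable parameters.

Around the core: from-definition SMOTE / ENN / SMOTE-ENN baselines and a
`compare_sampling()` harness that runs every arm through the identical
downstream pipeline; confusion-matrix metrics (accuracy, sensitivity,
specificity, precision, F1) with rank-statistic ROC-AUC; permutation
feature importance on the no-PCA variant; and a seedable synthetic
descriptor-table generator with a closed-form Bayes-accuracy oracle so
every stage is testable without external data. Both neural networks are
trained by hand-derived backpropagation (compiled Armadillo hot loop +
a pure-R reference engine asserted equal in the tests).

## A worked example

```r
library(plcpredict)

# a synthetic formulation table shaped like the curated study data:
# 272 train (179 success / 93 failure), 69 test, 46 descriptors
ds <- simulate_formulations(synthetic_spec(seed = 1))
class_counts(ds$train)
#> # A tibble: 1 × 3
#>   n_success n_failure n_total
#>       <int>     <int>   <int>
#> 1       179        93     272

ds$bayes_accuracy   # closed-form optimum for these conditions
#> [1] 0.9786317

fit <- plc_fit(ds$train, seed = 1)   # normalize -> VAE -> PCA-10 -> CNN
glance(fit)
#> # A tibble: 1 × 5
#>   augment n_balanced     k n_parameters train_accuracy
#>   <chr>        <int> <int>        <int>          <dbl>
#> 1 vae            358    10         2081              1

plc_evaluate(fit, ds$test)
#> # A tibble: 1 × 6
#>   accuracy   auc specificity sensitivity    f1 precision
#>      <dbl> <dbl>       <dbl>       <dbl> <dbl>     <dbl>
#> 1    0.928 0.985        0.84       0.977 0.945     0.915
```

The balanced training set has 358 rows (86 VAE-generated minority rows
added to 272), ten principal components feed a 2081-parameter
classifier, and test accuracy (0.928 here; typically 0.88–0.94 across
seeds) lands within a few points of the 0.978 Bayes bound, with
sensitivity — the screening priority — above specificity. `autoplot()` methods cover the scree plot, both training
histories and the importance ranking; `plot_latent()` draws the 2-D
latent scatter of original vs. generated formulations.

To read your own data instead: `read_descriptor_table("train.csv")`
expects numeric descriptor columns plus a binary label column
(`success`/`failure` or 1/0), with an optional YAML sidecar assigning
descriptors to the `api` / `lipid` / `solvent` / `condition` groups.

A thin command-line interface wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/plc.R", package="plcpredict"))') \
    simulate --seed 1 --out-dir data/
```

with subcommands `simulate`, `augment`, `reduce`, `train`, `predict`,
`evaluate`, `compare-sampling`, `importance`.

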