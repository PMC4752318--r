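# nrlmf

Drug–target interaction (DTI) prediction by **neighborhood regularized
logistic matrix factorization**. Given a binary interaction matrix
**Y** ∈ {0,1}^(m×n) (drugs × targets, 1 = experimentally verified
interaction, 0 = unknown), a drug–drug chemical-similarity matrix
**S**^d and a target–target sequence-similarity matrix **S**^t, the
package learns latent vectors u_i, v_j ∈ R^r for every drug and target
and models the interaction probability of a pair as

    p_ij = exp(u_i v_j') / (1 + exp(u_i v_j'))

Training minimizes the weighted negative log-posterior

    Σ_ij (1 + c·y_ij − y_ij) ln(1 + exp(u_i v_j')) − c·y_ij u_i v_j'
      + ½ tr(U' (λ_d I + α L^d) U) + ½ tr(V' (λ_t I + β L^t) V)

where each observed interaction counts as c ≥ 1 positive examples
(positives are experimentally verified, hence more trustworthy than the
unknown pairs), λ_d, λ_t are Gaussian prior precisions, and L^d, L^t are
graph Laplacians of k-nearest-neighbor similarity graphs that pull each
entity's latent vector toward its K1 most similar peers. Optimization is
alternating AdaGrad. At prediction time a drug or target with no known
interactions (cold start) has its latent vector replaced by the
similarity-weighted mean of its K2 nearest neighbors that do have
interactions.

The package is for computational chemists and bioinformaticians who want
to prioritize candidate interactions from sparse interaction matrices of
the kind distributed with the public enzyme / ion-channel / GPCR /
nuclear-receptor benchmark collections (labeled tab-separated matrices).

Included:

- benchmark-dialect I/O (`read_labeled_matrix()`, `load_dataset()`,
  `write_predictions()`) and dataset summaries (`compute_dataset_stats()`);
- the model: `nrlmf()`, `predict()`, `smooth_latents()`, objective and
  analytic gradients, serialization (`write_nrlmf_model()`);
- the benchmarking protocol: three cross-validation blinding regimes
  (`cvs1` random pairs, `cvs2` whole drugs, `cvs3` whole targets),
  repeated 10-fold CV with AUC/AUPR (`cross_validate()`), grid search,
  paired t-tests, and novel-interaction ranking
  (`rank_novel_interactions()`);
- a synthetic generator with planted low-rank structure
  (`generate_planted_dataset()`, `generate_benchmark_like()`) so
  everything runs and tests without downloads;
- broom-style `tidy()`/`glance()`, ggplot2 `autoplot()`, and a CLI
  (`nrlmf_cli()`, `inst/cli/nrlmf.R`).

## Worked example

```r
library(nrlmf)

# a 60 x 60 synthetic dataset with planted rank-5 structure, ~10% density
sim <- generate_planted_dataset(m = 60, n = 60, seed = 1)
ds  <- sim$dataset
ds
#> <dti_dataset> 60 drugs x 60 targets, 358 known interactions (90.06% sparse)

fit <- nrlmf(ds, nrlmf_hyperparams(r = 50, seed = 1))
fit
#> <nrlmf> 60 drugs x 60 targets, r = 50, 100 iterations
#>   objective: 4044.8084 -> 1761.7440

# pair-blinded 10-fold cross-validation
cv <- cross_validate(ds, nrlmf_hyperparams(r = 50, seed = 1), "cvs1",
                     n_folds = 10, n_repeats = 1, seed = 1)
cv
#> <nrlmf_cv> CVS1, 1 repeats x 10 folds (per_fold aggregation)
#>   auc: 0.918 +/- 0.021
#>   aupr: 0.635 +/- 0.049

# top candidate novel interactions among the unknown pairs
rank_novel_interactions(ds, model = fit, top_n = 5)
#> # A tibble: 5 x 4
#>    rank drug_id target_id probability
#>   <int> <chr>   <chr>           <dbl>
#> 1     1 D004    T050            0.904
#> 2     2 D001    T008            0.904
#> 3     3 D023    T038            0.896
#> 4     4 D048    T035            0.861
#> 5     5 D052    T033            0.829
```

The objective trace drops from 4045 to 1762 over 100 AdaGrad sweeps; the
held-out AUC of 0.918 means a randomly chosen true interaction outranks a
randomly chosen unknown pair 92% of the time, and the ranking surfaces
unknown pairs whose predicted interaction probability is around 0.9 —
the candidates one would send for experimental verification first.

From a shell, the same workflows are available as subcommands:

```sh
Rscript inst/cli/nrlmf.R stats --y Y.tsv --sd Sd.tsv --st St.tsv
Rscript inst/cli/nrlmf.R cv    --y Y.tsv --sd Sd.tsv --st St.tsv --setting cvs1 --out results/
Rscript inst/cli/nrlmf.R rank  --y Y.tsv --sd Sd.tsv --st St.tsv --top-n 30 --out ranking.tsv
```

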