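# mvimpute

Cross-omics imputation of metabolite abundances with a multi-view
variational autoencoder.

Untargeted LC-MS metabolomics panels almost always contain missing values,
and within-omics imputation (filling a metabolite from other metabolites)
is limited by how much of a metabolite's variation its neighbours share.
Blood metabolites are substantially heritable, so whole-genome sequencing
offers an independent route: predict the missing abundance from the
subject's genotypes. `mvimpute` implements that route for researchers with
paired WGS + metabolomics cohorts. Genome-wide variation is encoded as
three per-subject feature views:

- **burden scores** — for each rare variant v, `b(i, v) = r(i) * d(i, v)`,
  where `d(i, v)` is subject i's rare allele count and `r(i)` is the
  PC-adjusted residual of a *template metabolite*, a fully observed
  metabolite chosen (per target) as the one most Pearson-correlated with
  the target on the training subjects;
- **polygenic scores** — weighted allele-dosage sums
  `s(i, t) = Σ_v w(t, v) d(i, v)` over PGS-Catalog-style scoring tables;
- **LD-pruned SNPs** — common-variant dosages after QC (missing rate ≤ 5%,
  Hardy-Weinberg exact-test p ≥ 1e-4), windowed LD pruning (window 50,
  step 5, r² > 0.5 removes the lower-MAF member), and top-variance
  selection.

Each view `X_v` is min-max scaled to [0, 1] and encoded by an MLP pair into
a diagonal-Gaussian posterior `N(μ_v, Σ_v)`. The per-view posteriors are
fused by a product of experts,

    Σ_z = (Σ_v Σ_v⁻¹)⁻¹ ,   μ_z = Σ_z Σ_v Σ_v⁻¹ μ_v ,

sampled with the reparameterization trick `z = μ_z + Σ_z^{1/2} ⊙ ε`, and
decoded back into each view plus a scalar target head for the metabolite
being imputed. Training minimizes the negative evidence lower bound

    L = Σ_v BCE(X_v, X̂_v) + BCE(y, ŷ) + KL( N(μ_z, Σ_z) ‖ N(0, I) ),

with Adam, KL warm-up, and early stopping on a validation split. One model
is trained per metabolite; at test time the target is decoded from the
posterior mean, so imputation is deterministic. Accuracy is reported as
R²-score and MAPE per metabolite, summarized by count/percentage of
metabolites above R² thresholds {0.01, 0.05, 0.1, 0.15, 0.2} and below
MAPE thresholds {0.1, 0.15, 0.2, 0.3}.

A seeded synthetic-cohort generator (LD-blocked common variants, rare
variants, heritable metabolites with a shared non-genetic factor, MCAR
missingness, fully observed templates) makes the entire pipeline runnable
and testable at desk scale without access to any cohort data.

## Worked example

Simulate a 300-subject cohort (30 metabolites, 6 templates), run the full
pipeline, and evaluate on the held-out 20% of subjects:

```r
library(mvimpute)
cfg <- run_config(
  out_dir = "demo_out", seed = 7,
  simulate = simulation_config(n_subjects = 300, n_metabolites = 30,
                               n_templates = 6, seed = 7),
  pipeline = impute_config(template_strategy = "panel",
                           features = feature_options(top_bs = 32, top_pgs = 32,
                                                      top_ld = 120),
                           latent_dim = 16, hidden_width = 32),
  n_pgs_tables = 40)
res <- run_end_to_end(cfg)
print(res$run)
print(res$evaluation$summary)
```

```
imputation_run: 24 models (0 skipped), 6 templates, 240/60 train/test subjects
R2 thresholds:
 threshold count   percent
      0.01     7 29.166667
      0.05     6 25.000000
      0.10     4 16.666667
      0.15     2  8.333333
      0.20     1  4.166667
MAPE thresholds:
 threshold count percent
      0.10    24     100
      0.15    24     100
      0.20    24     100
      0.30    24     100
```

24 per-metabolite models were trained (one per non-template metabolite);
7 of 24 (29%) exceed R² = 0.01 on test subjects — in this small cohort a
third of the metabolites carry recoverable genetic signal (the simulated
heritabilities cycle through 0, 0.3 and 0.6, so a third of them have
none by construction). MAPE is uniformly small because simulated
abundances have a ~10% coefficient of variation. `demo_out/` receives the
imputed matrix (`imputed.tsv`), per-metabolite metrics (`metrics.tsv`),
the threshold summary (`report.json`), a per-metabolite run log, and a
`manifest.json` sufficient to reproduce the run byte-identically.

A thin CLI wrapper with `simulate`, `run` and `evaluate` subcommands is
installed at `inst/cli/mvimpute.R`.

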