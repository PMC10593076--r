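# Shared fixtures, memoised so expensive objects are built once per run.

.fixtures <- new.env(parent = emptyenv())

tiny_dataset <- function() {
  if (is.null(.fixtures$ds)) {
    .fixtures$ds <- simulate_dataset(
      simulation_config(n_subjects = 200, n_common_variants = 60,
                        n_rare_variants = 40, n_metabolites = 12,
                        n_templates = 4, seed = 42),
      n_pgs_tables = 10)
  }
  .fixtures$ds
}

fast_training <- function(seed = 7, ...) {
  training_config(epochs = 60, batch_size = 64, patience = 15,
                  kl_warmup = 20, seed = seed, ...)
}

# a small but complete pipeline run over the tiny dataset
tiny_run <- function() {
  if (is.null(.fixtures$run)) {
    ds <- tiny_dataset()
    .fixtures$run <- train_all(
      ds$genotypes, ds$metabolites, ds$pgs_weights,
      impute_config(template_strategy = "panel", seed = 5,
                    features = feature_options(top_bs = 20, top_pgs = 8,
                                               top_ld = 30),
                    latent_dim = 8, hidden_width = 16,
                    training = fast_training()))
  }
  .fixtures$run
}

# random diagonal Gaussian of dimension d
random_gaussian <- function(d) {
  diag_gaussian(stats::rnorm(d), exp(stats::runif(d, -2, 2)))
}
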