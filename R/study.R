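#' Desk-scale heritability recovery study
#'
#' The package's validation experiment: simulate a cohort with known
#' per-metabolite heritabilities, run the full imputation pipeline
#' (feature engineering, per-metabolite template selection and MVAE
#' training, test-set imputation), and report test-set accuracy stratified
#' by true heritability. With `permute_genotypes = TRUE` the genotype
#' matrix rows are shuffled across subjects before the pipeline runs,
#' destroying every genotype-metabolite association while preserving all
#' marginal distributions -- the negative control under which recovered
#' accuracy should vanish.
#'
#' Default sizes follow the package's desk-scale study conditions: 600
#' subjects, 60 non-template metabolites at heritabilities {0, 0.3, 0.6}
#' (20 each), 10 templates, a 120 common + 80 rare variant genome, views of
#' 32 burden / 32 PGS / 120 LD-SNP features, and a reduced MVAE (latent 16,
#' hidden width 32).
#'
#' @param seed master seed for the whole study.
#' @param permute_genotypes run the negative control instead.
#' @param subset_h2 optionally restrict to metabolites with these true
#'   heritabilities (e.g. `0.6` for the permutation arm).
#' @param sim a [simulation_config()]; its seed is derived from `seed`.
#' @param features a [feature_options()] list (desk-scale view sizes).
#' @param latent_dim,hidden_width reduced MVAE size.
#' @param training a [training_config()].
#' @param n_pgs_tables scoring tables to simulate.
#' @return list with `per_metabolite` (data.frame: metabolite, true
#'   heritability, test R-squared, MAPE, n_test), `medians` (named by
#'   heritability level), and `summary` (an `evaluation_report`).
#' @export
heritability_study <- function(seed = 1, permute_genotypes = FALSE,
                               subset_h2 = NULL,
                               sim = simulation_config(),
                               features = feature_options(top_bs = 32,
                                                          top_pgs = 32,
                                                          top_ld = 120),
                               latent_dim = 16, hidden_width = 32,
                               training = training_config(),
                               n_pgs_tables = 40) {
  sim$seed <- derive_seed(seed, 41L)
  ds <- simulate_dataset(sim, n_pgs_tables = n_pgs_tables)
  genotypes <- ds$genotypes
  if (permute_genotypes) {
    with_seed(derive_seed(seed, 42L), {
      perm <- sample(nrow(genotypes$dosage))
    })
    dper <- genotypes$dosage[perm, , drop = FALSE]
    rownames(dper) <- rownames(genotypes$dosage)
    genotypes <- genotype_panel(dper, chrom = genotypes$variants$chrom,
                                pos = genotypes$variants$pos,
                                ref = genotypes$variants$ref,
                                alt = genotypes$variants$alt)
  }
  metabolites <- ds$metabolites
  h2 <- ds$true_heritability
  if (!is.null(subset_h2)) {
    keep <- union(metabolites$template_ids,
                  names(h2)[h2 %in% subset_h2 &
                              !names(h2) %in% metabolites$template_ids])
    metabolites <- metabolite_panel(
      metabolites$abundance[, colnames(metabolites$abundance) %in% keep,
                            drop = FALSE],
      metabolites$template_ids)
  }
  cfg <- impute_config(template_strategy = "panel",
                       seed = derive_seed(seed, 43L), features = features,
                       latent_dim = latent_dim, hidden_width = hidden_width,
                       training = training)
  run <- train_all(genotypes, metabolites, ds$pgs_weights, cfg)
  imputed <- impute_all(run, genotypes, metabolites)
  ev <- evaluate_imputation(run, imputed, metabolites)
  per <- ev$per_metabolite
  per$true_h2 <- unname(h2[per$metabolite_id])
  medians <- tapply(per$r2, per$true_h2, stats::median, na.rm = TRUE)
  list(per_metabolite = per, medians = medians, summary = ev$summary,
       run = run)
}
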