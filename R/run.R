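#' End-to-end run configuration
#'
#' One document controlling a full simulate -> features -> train -> impute
#' -> evaluate run. All stage seeds are derived deterministically from the
#' single master seed, so a run is a pure function of (config, seed).
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @param simulate a [simulation_config()] (or `NULL` when reading inputs
#'   from files).
#' @param inputs optional list with `genotype_stem`, `metabolite_stem`,
#'   `scoring_dir` pointing at files written by the io helpers.
#' @param pipeline an [impute_config()] (its seed is overridden by the
#'   master seed).
#' @param n_pgs_tables scoring tables to simulate.
#' @param write_inputs whether to write the simulated inputs as TSV.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1, simulate = simulation_config(),
                       inputs = NULL, pipeline = impute_config(),
                       n_pgs_tables = 40, write_inputs = FALSE) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, inputs = inputs, pipeline = pipeline,
                 n_pgs_tables = n_pgs_tables, write_inputs = write_inputs),
            class = "run_config")
}

#' Run the full pipeline end to end
#'
#' Executes (optionally) simulation, feature engineering, per-metabolite
#' training, test-set imputation and evaluation, writing every artifact to
#' `config$out_dir`: the imputed matrix (`imputed.tsv`), per-metabolite
#' metrics (`metrics.tsv`), the threshold summary (`report.json`), the run
#' log (`run_log.tsv`) and a manifest (`manifest.json`) sufficient to rerun
#' the pipeline byte-identically.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the `run`, `imputed`, `evaluation`, and
#'   `out_dir`.
#' @export
run_end_to_end <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$inputs)) {
    genotypes <- read_genotype_tsv(config$inputs$genotype_stem)
    metabolites <- read_metabolite_tsv(config$inputs$metabolite_stem)
    tables <- read_scoring_tables(config$inputs$scoring_dir)
  } else {
    sim_cfg <- config$simulate
    sim_cfg$seed <- derive_seed(config$seed, 31L)
    ds <- simulate_dataset(sim_cfg, n_pgs_tables = config$n_pgs_tables)
    genotypes <- ds$genotypes
    metabolites <- ds$metabolites
    tables <- ds$pgs_weights
    if (isTRUE(config$write_inputs)) {
      write_genotype_tsv(genotypes, file.path(config$out_dir, "genotypes"))
      write_metabolite_tsv(metabolites, file.path(config$out_dir, "metabolites"))
      write_scoring_tables(tables, file.path(config$out_dir, "scores"))
    }
  }

  pipe_cfg <- config$pipeline
  pipe_cfg$seed <- derive_seed(config$seed, 32L)
  run <- train_all(genotypes, metabolites, tables, pipe_cfg)
  imputed <- impute_all(run, genotypes, metabolites)
  ev <- evaluate_imputation(run, imputed, metabolites)

  utils::write.table(
    data.frame(subject_id = rownames(imputed), imputed, check.names = FALSE),
    file.path(config$out_dir, "imputed.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(ev$per_metabolite, file.path(config$out_dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$log, file.path(config$out_dir, "run_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(r2_summary = ev$summary$r2_summary,
         mape_summary = ev$summary$mape_summary,
         n_evaluated = as.list(ev$summary$n_evaluated),
         n_models = length(run$models)),
    file.path(config$out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package_version = as.character(utils::packageVersion("mvimpute")),
    master_seed = config$seed,
    stage_seeds = list(simulate = derive_seed(config$seed, 31L),
                       pipeline = derive_seed(config$seed, 32L)),
    simulate = if (is.null(config$inputs)) unclass(config$simulate) else NULL,
    inputs = config$inputs,
    pipeline = list(m_templates = pipe_cfg$m_templates,
                    template_strategy = pipe_cfg$template_strategy,
                    split_fraction = pipe_cfg$split_fraction,
                    features = pipe_cfg$features,
                    latent_dim = pipe_cfg$latent_dim,
                    hidden_layers = pipe_cfg$hidden_layers,
                    hidden_width = pipe_cfg$hidden_width,
                    training = unclass(pipe_cfg$training)),
    n_pgs_tables = config$n_pgs_tables)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(run = run, imputed = imputed, evaluation = ev,
                 out_dir = config$out_dir))
}
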