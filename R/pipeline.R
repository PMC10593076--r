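#' Choose the template metabolite set
#'
#' Selects `m` fully observed metabolites to serve as the template set. The
#' default strategy clusters the fully observed metabolites into `m` groups
#' by correlation distance (`1 - r`) with partitioning-around-medoids and
#' returns the medoids, maximizing expected best-correlation coverage of
#' the remaining metabolites; `"variance"` returns the top-`m` by variance.
#'
#' @param panel a [metabolite_panel()].
#' @param m number of templates.
#' @param strategy `"medoid"` (default) or `"variance"`.
#' @param subject_ids subjects used to estimate correlations/variances
#'   (training subjects; default all).
#' @return Character vector of `m` metabolite ids (sorted).
#' @export
choose_template_set <- function(panel, m, strategy = c("medoid", "variance"),
                                subject_ids = NULL) {
  stopifnot(inherits(panel, "metabolite_panel"))
  strategy <- match.arg(strategy)
  A <- panel$abundance
  if (!is.null(subject_ids)) A <- A[subject_ids, , drop = FALSE]
  complete <- colnames(A)[colSums(is.na(panel$abundance)) == 0]
  if (length(complete) < m) stop_config("fewer than m fully observed metabolites")
  if (length(complete) == m) return(sort(complete))
  Ac <- A[, complete, drop = FALSE]
  if (strategy == "variance") {
    v <- apply(Ac, 2, stats::var)
    return(sort(top_k_by_variance(v, complete, m)))
  }
  cors <- suppressWarnings(stats::cor(Ac))
  cors[is.na(cors)] <- 0
  d <- stats::as.dist(1 - cors)
  fit <- cluster::pam(d, k = m, pamonce = 0)
  sort(complete[fit$id.med])
}

#' Select the template for one metabolite
#'
#' Returns the template metabolite with the highest (signed) Pearson
#' correlation with the target over training subjects. Ties break
#' lexicographically by template id.
#'
#' @param y_train target abundance vector over training subjects (no
#'   missing values).
#' @param templates training-subject matrix of template metabolites
#'   (columns named by template id).
#' @param absolute rank templates by `|r|` instead of signed `r`, making
#'   anti-correlated templates eligible. Default `FALSE` ("highest
#'   correlation" read literally).
#' @return list with `template_id` and `correlation` (always the signed
#'   correlation of the selected template).
#' @export
select_template <- function(y_train, templates, absolute = FALSE) {
  templates <- as.matrix(templates)
  if (anyNA(y_train)) stop_config("y_train must have no missing values")
  if (length(y_train) < 4) stop_config("at least 4 training subjects required")
  if (stats::sd(y_train) == 0) stop_config("zero-variance target")
  r <- suppressWarnings(as.numeric(stats::cor(y_train, templates)))
  r[is.na(r)] <- -Inf
  key <- if (isTRUE(absolute)) abs(r) else r
  key[!is.finite(r)] <- -Inf
  ord <- order(-key, colnames(templates))
  list(template_id = colnames(templates)[ord[1]], correlation = r[ord[1]])
}

# ---------------------------------------------------------------------------
# View builder: every statistic fitted from training subjects only; applying
# to new subjects reuses the stored selections, coefficients and scalers.
# ---------------------------------------------------------------------------

#' Feature-engineering options
#'
#' @param max_missing,hwe_alpha variant QC thresholds.
#' @param maf_cut common/rare MAF boundary.
#' @param window,step,r2_threshold LD-pruning parameters.
#' @param n_pcs genetic principal components used for residualization.
#' @param top_bs,top_pgs,top_ld per-view feature counts (reference defaults
#'   512 / 512 / 1024).
#' @return list of options for [fit_view_builder()].
#' @export
feature_options <- function(max_missing = 0.05, hwe_alpha = 1e-4,
                            maf_cut = 0.05, window = 50, step = 5,
                            r2_threshold = 0.5, n_pcs = 2,
                            top_bs = 512, top_pgs = 512, top_ld = 1024) {
  list(max_missing = max_missing, hwe_alpha = hwe_alpha, maf_cut = maf_cut,
       window = window, step = step, r2_threshold = r2_threshold,
       n_pcs = n_pcs, top_bs = top_bs, top_pgs = top_pgs, top_ld = top_ld)
}

#' Fit the three-view feature builder on training subjects
#'
#' Runs the full genetics feature-engineering chain -- QC, MAF split, LD
#' pruning, top-variance LD-SNP selection, genetic PCA, polygenic scoring
#' with top-variance selection, and per-template burden-score construction
#' -- fitting every data-dependent quantity (selections, PCA rotation,
#' residualization coefficients, min-max scalers) on the training subjects
#' only.
#'
#' @param genotypes a [genotype_panel()] for all subjects.
#' @param metabolites a [metabolite_panel()] with a non-empty template set.
#' @param tables list of [scoring_table()] objects.
#' @param train_ids training subject ids.
#' @param opts a [feature_options()] list.
#' @return Object of class `view_builder`.
#' @export
fit_view_builder <- function(genotypes, metabolites, tables, train_ids,
                             opts = feature_options()) {
  stopifnot(inherits(genotypes, "genotype_panel"),
            inherits(metabolites, "metabolite_panel"))
  if (!length(metabolites$template_ids)) stop_config("template set is empty")
  # every variant statistic (missing rate, HWE, MAF, allele frequency) is
  # recomputed from the training subjects, so that no fitted quantity can
  # depend on test rows
  meta_all <- genotypes$variants
  train_panel <- genotype_panel(
    genotypes$dosage[train_ids, , drop = FALSE],
    chrom = meta_all$chrom, pos = meta_all$pos,
    ref = meta_all$ref, alt = meta_all$alt)
  qc <- qc_filter_variants(train_panel, opts$max_missing, opts$hwe_alpha)
  halves <- split_by_maf(qc, opts$maf_cut)
  common_tr <- halves$common
  rare_tr <- halves$rare

  pruned_ids <- ld_prune(common_tr, opts$window, opts$step, opts$r2_threshold)
  pruned_tr <- subset_panel(common_tr, variant_ids = pruned_ids)
  v_ld <- apply(pruned_tr$dosage, 2, function(d) stats::var(d, na.rm = TRUE))
  ld_ids <- top_k_by_variance(v_ld, pruned_ids, min(opts$top_ld, length(pruned_ids)))

  pca <- genetic_pca_fit(pruned_tr, n_pcs = opts$n_pcs)

  pgs_fit <- pgs_scores(qc, tables, k = min(opts$top_pgs, length(tables)))

  pcs_tr <- genetic_pca_project(pca, common_tr)
  burden_store <- list()
  for (tid in metabolites$template_ids) {
    y_t <- metabolites$abundance[train_ids, tid]
    coef <- pc_adjust_fit(y_t, pcs_tr)
    res_tr <- pc_adjust_apply(coef, y_t, pcs_tr)
    bf <- burden_features(res_tr, rare_tr, k = min(opts$top_bs, ncol(rare_tr$dosage)))
    burden_store[[tid]] <- list(
      adjust_coef = coef, feature_ids = bf$feature_ids,
      scaler = fit_minmax_scaler(bf$features))
  }

  ld_tr <- common_tr$dosage[, ld_ids, drop = FALSE]
  ld_tr[is.na(ld_tr)] <- 0
  structure(list(
    variant_meta = qc$variants,
    qc_variant_ids = qc$variants$variant_id,
    common_ids = common_tr$variants$variant_id,
    rare_ids = rare_tr$variants$variant_id,
    pruned_ids = pruned_ids, ld_ids = ld_ids,
    pca = pca, tables = tables, pgs_ids = pgs_fit$score_ids,
    burden_store = burden_store,
    scalers = list(pgs = fit_minmax_scaler(pgs_fit$scores[, pgs_fit$score_ids, drop = FALSE]),
                   ld = fit_minmax_scaler(ld_tr)),
    opts = opts, train_ids = train_ids
  ), class = "view_builder")
}

# panel for arbitrary subjects carrying the builder's train-derived variant
# metadata (QC'd variant set)
vb_panel <- function(vb, genotypes, subject_ids, variant_ids) {
  meta <- vb$variant_meta[vb$variant_meta$variant_id %in% variant_ids, ,
                          drop = FALSE]
  structure(list(
    dosage = genotypes$dosage[subject_ids, meta$variant_id, drop = FALSE],
    variants = meta), class = "genotype_panel")
}

#' Build scaled views for a set of subjects
#'
#' Applies a fitted [fit_view_builder()] to arbitrary subjects: regenerates
#' the burden view from the given template metabolite's observed values
#' (PC-adjusted with the stored training coefficients), computes polygenic
#' scores, indexes the LD-SNP dosages, and min-max-scales each view with the
#' stored training scalers.
#'
#' @param vb a `view_builder`.
#' @param genotypes the full [genotype_panel()].
#' @param metabolites the [metabolite_panel()] (template values needed).
#' @param subject_ids subjects to build views for.
#' @param template_id template metabolite supplying the burden view.
#' @return Named list of three scaled matrices: `burden`, `pgs`, `ld`.
#' @export
build_views <- function(vb, genotypes, metabolites, subject_ids, template_id) {
  stopifnot(inherits(vb, "view_builder"))
  store <- vb$burden_store[[template_id]]
  if (is.null(store)) stop_config("unknown template id '%s'", template_id)
  y_t <- metabolites$abundance[subject_ids, template_id]
  if (anyNA(y_t)) stop_config("template '%s' missing for some subjects", template_id)
  common <- vb_panel(vb, genotypes, subject_ids, vb$common_ids)
  rare <- vb_panel(vb, genotypes, subject_ids, vb$rare_ids)
  pcs <- genetic_pca_project(vb$pca, common)
  res <- pc_adjust_apply(store$adjust_coef, y_t, pcs)
  B <- burden_candidates(res, rare)[, store$feature_ids, drop = FALSE]

  qc_panel <- vb_panel(vb, genotypes, subject_ids, vb$qc_variant_ids)
  S <- pgs_score_matrix(qc_panel, vb$tables)[, vb$pgs_ids, drop = FALSE]

  L <- common$dosage[, vb$ld_ids, drop = FALSE]
  L[is.na(L)] <- 0
  list(burden = apply_minmax_scaler(B, store$scaler),
       pgs = apply_minmax_scaler(S, vb$scalers$pgs),
       ld = apply_minmax_scaler(L, vb$scalers$ld))
}

#' Assemble aligned view rows for given subjects
#'
#' Thin indexing layer over precomputed view matrices: picks the burden view
#' of the requested template from a per-template store and aligns all three
#' views on the same subjects. Only the burden view depends on the template.
#'
#' @param template_id template metabolite id.
#' @param burden_store named list (by template id) of burden matrices with
#'   subject rownames.
#' @param pgs_view,ld_view template-independent view matrices.
#' @param subjects subject ids to extract.
#' @return Named list of three aligned matrices.
#' @export
assemble_views <- function(template_id, burden_store, pgs_view, ld_view, subjects) {
  b <- burden_store[[template_id]]
  if (is.null(b)) stop_config("no burden features for template '%s'", template_id)
  if (!all(subjects %in% rownames(b)) || !all(subjects %in% rownames(pgs_view)) ||
      !all(subjects %in% rownames(ld_view))) {
    stop_config("subject misalignment between views")
  }
  list(burden = b[subjects, , drop = FALSE],
       pgs = pgs_view[subjects, , drop = FALSE],
       ld = ld_view[subjects, , drop = FALSE])
}

#' Pipeline configuration
#'
#' @param m_templates size of the template set (reference default 35).
#' @param template_strategy strategy for [choose_template_set()], or
#'   `"panel"` to use the panel's designated template set.
#' @param split_fraction test fraction of subjects (default 0.2).
#' @param min_train minimum training subjects per metabolite (default 20).
#' @param seed master seed for split and per-model training.
#' @param features a [feature_options()] list.
#' @param latent_dim,hidden_layers,hidden_width MVAE architecture.
#' @param training a [training_config()] (its seed is overridden per model).
#' @return list of class `impute_config`.
#' @export
impute_config <- function(m_templates = 35, template_strategy = "panel",
                          split_fraction = 0.2, min_train = 20, seed = 1,
                          features = feature_options(),
                          latent_dim = 64, hidden_layers = 2, hidden_width = 128,
                          training = training_config()) {
  structure(list(m_templates = m_templates, template_strategy = template_strategy,
                 split_fraction = split_fraction, min_train = min_train,
                 seed = as.integer(seed), features = features,
                 latent_dim = latent_dim, hidden_layers = hidden_layers,
                 hidden_width = hidden_width, training = training),
            class = "impute_config")
}

# seeded 80/20 split of subject ids
split_subjects <- function(subject_ids, split_fraction, seed) {
  with_seed(derive_seed(seed, 21L), {
    n_test <- floor(split_fraction * length(subject_ids))
    test <- sort(sample(subject_ids, n_test))
    list(train = setdiff(subject_ids, test), test = test)
  })
}

#' Train one imputation model per non-template metabolite
#'
#' The full training loop: split subjects into training and test sets, fix
#' the template set, fit the view builder on training subjects, then for
#' every non-template metabolite select its best-correlated template, train
#' an MVAE on the three views plus the min-max-scaled target, and package
#' the self-contained per-metabolite model. Metabolites failing
#' preconditions (too few observed training subjects, zero variance) are
#' skipped with a logged reason; failures are isolated per metabolite.
#'
#' @param genotypes a [genotype_panel()].
#' @param metabolites a [metabolite_panel()].
#' @param tables list of [scoring_table()] objects.
#' @param cfg an [impute_config()].
#' @return Object of class `imputation_run`: list with `models` (named
#'   list), `vb` (the fitted view builder), `split`, `template_ids`, `log`
#'   (per-metabolite data.frame), `cfg`.
#' @export
train_all <- function(genotypes, metabolites, tables, cfg = impute_config()) {
  stopifnot(inherits(cfg, "impute_config"))
  subj <- rownames(metabolites$abundance)
  split <- split_subjects(subj, cfg$split_fraction, cfg$seed)

  template_ids <- if (identical(cfg$template_strategy, "panel") &&
                      length(metabolites$template_ids)) {
    metabolites$template_ids
  } else {
    choose_template_set(metabolites, cfg$m_templates,
                        strategy = if (identical(cfg$template_strategy, "panel"))
                          "medoid" else cfg$template_strategy,
                        subject_ids = split$train)
  }
  metabolites <- metabolite_panel(metabolites$abundance, template_ids)
  vb <- fit_view_builder(genotypes, metabolites, tables, split$train,
                         cfg$features)

  targets <- setdiff(colnames(metabolites$abundance), template_ids)
  all_idx <- match(targets, colnames(metabolites$abundance))
  templ_tr <- metabolites$abundance[split$train, template_ids, drop = FALSE]
  models <- list()
  log <- data.frame(metabolite_id = character(), status = character(),
                    template_id = character(), correlation = numeric(),
                    n_train = integer(), final_loss = numeric(),
                    stringsAsFactors = FALSE)
  for (k in seq_along(targets)) {
    mid <- targets[k]
    y_all <- metabolites$abundance[split$train, mid]
    obs <- !is.na(y_all)
    rec <- data.frame(metabolite_id = mid, status = "ok",
                      template_id = NA_character_,
                      correlation = NA_real_, n_train = sum(obs),
                      final_loss = NA_real_, stringsAsFactors = FALSE)
    res <- tryCatch({
      if (sum(obs) < cfg$min_train) stop_config("fewer than %d observed training subjects", cfg$min_train)
      tr_ids <- split$train[obs]
      y_tr <- y_all[obs]
      if (stats::sd(y_tr) == 0) stop_config("zero-variance target")
      sel <- select_template(y_tr, templ_tr[obs, , drop = FALSE])
      views <- build_views(vb, genotypes, metabolites, tr_ids, sel$template_id)
      y_scaler <- fit_minmax_scaler(matrix(y_tr, ncol = 1))
      y_s <- as.numeric(apply_minmax_scaler(matrix(y_tr, ncol = 1), y_scaler))
      arch <- mvae_architecture(vapply(views, ncol, integer(1)),
                                latent_dim = cfg$latent_dim,
                                hidden_layers = cfg$hidden_layers,
                                hidden_width = cfg$hidden_width)
      tc <- cfg$training
      tc$seed <- derive_seed(cfg$seed, 100L + all_idx[k])
      model <- train_mvae(views, y_s, arch, tc)
      list(metabolite_id = mid, template_id = sel$template_id,
           template_cor = sel$correlation, mvae = model,
           y_scaler = y_scaler, n_train = length(tr_ids))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rec$status <- conditionMessage(res)
    } else {
      rec$template_id <- res$template_id
      rec$correlation <- res$template_cor
      rec$final_loss <- res$mvae$final_loss
      models[[mid]] <- res
    }
    log <- rbind(log, rec)
  }
  structure(list(models = models, vb = vb, split = split,
                 template_ids = template_ids, log = log, cfg = cfg),
            class = "imputation_run")
}

#' @export
print.imputation_run <- function(x, ...) {
  cat(sprintf("imputation_run: %d models (%d skipped), %d templates, %d/%d train/test subjects\n",
              length(x$models), sum(x$log$status != "ok"),
              length(x$template_ids), length(x$split$train), length(x$split$test)))
  invisible(x)
}

#' Impute metabolites for a set of subjects
#'
#' For every trained model, regenerates the burden view from its stored
#' template id using the subjects' observed template values, scales all
#' views with the stored training scalers, imputes through the MVAE at the
#' posterior mean, and inverse-transforms to the original abundance scale.
#' Subjects missing the template value are skipped for that metabolite.
#'
#' @param run an [train_all()] result (or list with `models` and `vb`).
#' @param genotypes the [genotype_panel()] covering the subjects.
#' @param metabolites a [metabolite_panel()] carrying template values.
#' @param subject_ids subjects to impute (default: the run's test split).
#' @return subjects-by-metabolites matrix of imputed abundances (original
#'   scale); `NA` where imputation was not possible.
#' @export
impute_all <- function(run, genotypes, metabolites, subject_ids = NULL) {
  if (is.null(subject_ids)) subject_ids <- run$split$test
  models <- run$models
  out <- matrix(NA_real_, length(subject_ids), length(models),
                dimnames = list(subject_ids, names(models)))
  for (mid in names(models)) {
    mod <- models[[mid]]
    t_vals <- metabolites$abundance[subject_ids, mod$template_id]
    usable <- subject_ids[!is.na(t_vals)]
    if (!length(usable)) next
    views <- build_views(run$vb, genotypes, metabolites, usable, mod$template_id)
    yhat_s <- impute_target(mod$mvae, views)
    yhat <- as.numeric(invert_minmax_scaler(matrix(yhat_s, ncol = 1), mod$y_scaler))
    out[usable, mid] <- yhat
  }
  out
}
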