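#' Simulation configuration
#'
#' Parameters of the synthetic cohort generator. The generator emulates the
#' statistical structure the imputation method assumes: LD-blocked common
#' variants, independent rare variants, heritable metabolites with a shared
#' non-genetic factor, MCAR missingness, and a fully observed template
#' subset.
#'
#' @param n_subjects number of subjects.
#' @param n_common_variants,n_rare_variants variant counts.
#' @param ld_block_size variants per LD block (common variants only).
#' @param within_block_r target pairwise dosage correlation within a block,
#'   in `[0, 1)`.
#' @param common_maf_range MAF interval for common variants, within
#'   (0.05, 0.5).
#' @param rare_maf_range MAF interval for rare variants, within (0, 0.05).
#' @param n_metabolites,n_templates metabolite counts (templates are the
#'   first `n_templates` metabolites and are fully observed).
#' @param heritability_levels values in `[0, 1]` cycled over non-template
#'   metabolites.
#' @param metabolite_block_correlation pairwise correlation induced between
#'   the non-genetic parts of any two metabolites via a shared per-subject
#'   factor, in `[0, 1)`. Default 0.1: a modest shared environmental
#'   covariation that keeps genetic and non-genetic signal separable.
#' @param missing_rate MCAR missing fraction for non-template metabolites,
#'   in `[0, 0.05]`.
#' @param n_causal causal variants per metabolite (default 4; an
#'   oligogenic architecture whose per-variant effects are resolvable at
#'   cohort sizes of a few hundred subjects).
#' @param p_causal_rare fraction of causal variants drawn from the rare set
#'   (default 0.25).
#' @param abundance_mean,abundance_sd location/scale of the emitted
#'   abundances (positive scale so percentage errors are well defined).
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 600,
                              n_common_variants = 120,
                              n_rare_variants = 80,
                              ld_block_size = 10,
                              within_block_r = 0.6,
                              common_maf_range = c(0.1, 0.5),
                              rare_maf_range = c(0.005, 0.03),
                              n_metabolites = 70,
                              n_templates = 10,
                              heritability_levels = c(0, 0.3, 0.6),
                              metabolite_block_correlation = 0.1,
                              missing_rate = 0.03,
                              n_causal = 4,
                              p_causal_rare = 0.25,
                              abundance_mean = 10,
                              abundance_sd = 1,
                              seed = 1) {
  cfg <- list(n_subjects = n_subjects, n_common_variants = n_common_variants,
              n_rare_variants = n_rare_variants, ld_block_size = ld_block_size,
              within_block_r = within_block_r,
              common_maf_range = common_maf_range,
              rare_maf_range = rare_maf_range,
              n_metabolites = n_metabolites, n_templates = n_templates,
              heritability_levels = heritability_levels,
              metabolite_block_correlation = metabolite_block_correlation,
              missing_rate = missing_rate, n_causal = n_causal,
              p_causal_rare = p_causal_rare,
              abundance_mean = abundance_mean, abundance_sd = abundance_sd,
              seed = as.integer(seed))
  for (f in c("n_subjects", "n_common_variants", "n_rare_variants",
              "ld_block_size", "n_metabolites", "n_templates", "n_causal")) {
    if (!is_count(cfg[[f]])) stop_config("%s must be a positive integer", f)
  }
  if (!is_fraction(cfg$within_block_r, 0, 1) || cfg$within_block_r >= 1) {
    stop_config("within_block_r must lie in [0, 1)")
  }
  if (length(cfg$common_maf_range) != 2 || diff(cfg$common_maf_range) < 0 ||
      cfg$common_maf_range[1] <= 0.05 || cfg$common_maf_range[2] > 0.5) {
    stop_config("common_maf_range must be an ordered interval within (0.05, 0.5]")
  }
  if (length(cfg$rare_maf_range) != 2 || diff(cfg$rare_maf_range) < 0 ||
      cfg$rare_maf_range[1] <= 0 || cfg$rare_maf_range[2] >= 0.05) {
    stop_config("rare_maf_range must be an ordered interval within (0, 0.05)")
  }
  if (any(cfg$heritability_levels < 0 | cfg$heritability_levels > 1)) {
    stop_config("heritability levels must lie in [0, 1]")
  }
  if (!is_fraction(cfg$metabolite_block_correlation, 0, 1) ||
      cfg$metabolite_block_correlation >= 1) {
    stop_config("metabolite_block_correlation must lie in [0, 1)")
  }
  if (!is_fraction(cfg$missing_rate, 0, 0.05)) {
    stop_config("missing_rate must lie in [0, 0.05]")
  }
  if (cfg$n_templates >= cfg$n_metabolites) {
    stop_config("n_templates must be smaller than n_metabolites")
  }
  structure(cfg, class = "simulation_config")
}

# Latent-Gaussian threshold attenuates correlation: a latent factor with
# correlation rho produces allele (and hence dosage) correlation below rho.
# Invert the tetrachoric relation numerically so that the realized dosage
# correlation matches the requested target at the block's MAF. The orthant
# probability P(X < t, Y < t) under latent correlation rho is evaluated by
# 1-D quadrature.
binorm_orthant <- function(t, rho) {
  if (rho >= 1 - 1e-12) return(stats::pnorm(t))
  f <- function(x) stats::dnorm(x) * stats::pnorm((t - rho * x) / sqrt(1 - rho^2))
  stats::integrate(f, -Inf, t, rel.tol = 1e-10)$value
}

phi_from_latent <- function(rho, maf) {
  t <- stats::qnorm(maf)
  (binorm_orthant(t, rho) - maf^2) / (maf * (1 - maf))
}

latent_rho_for_target <- function(target_r, maf) {
  if (target_r <= 0) return(0)
  upper <- 1 - 1e-9
  if (phi_from_latent(upper, maf) <= target_r) return(upper)
  stats::uniroot(function(r) phi_from_latent(r, maf) - target_r,
                 c(0, upper), tol = 1e-9)$root
}

# one haplotype draw for a block: shared factor + idiosyncratic noise,
# thresholded at the MAF quantile
draw_block_haplotype <- function(n, m, latent_rho, maf) {
  u <- stats::rnorm(n)
  l <- sqrt(latent_rho) * u +
    sqrt(1 - latent_rho) * matrix(stats::rnorm(n * m), n, m)
  (l < stats::qnorm(maf)) + 0
}

#' Simulate a genotype panel
#'
#' Common variants are organized in LD blocks: each block shares one MAF
#' (drawn from `common_maf_range`) and one latent Gaussian factor per
#' haplotype, thresholded at the MAF quantile; the latent loading is
#' calibrated so the pairwise dosage correlation within a block matches
#' `within_block_r` in expectation. Dosage is the sum of two independent
#' haplotype draws, so genotypes satisfy Hardy-Weinberg proportions by
#' construction. Rare variants are mutually independent with MAFs from
#' `rare_maf_range`. Output is deterministic given the config seed.
#'
#' @param config a [simulation_config()].
#' @return A [genotype_panel()]; common variants first (chromosome "1"),
#'   rare variants on chromosome "2".
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(derive_seed(config$seed, 11L), {
    n <- config$n_subjects
    bs <- config$ld_block_size
    n_blocks <- ceiling(config$n_common_variants / bs)
    cols <- vector("list", n_blocks)
    for (b in seq_len(n_blocks)) {
      m <- min(bs, config$n_common_variants - (b - 1) * bs)
      maf <- stats::runif(1, config$common_maf_range[1], config$common_maf_range[2])
      lrho <- if (m > 1) latent_rho_for_target(config$within_block_r, maf) else 0
      cols[[b]] <- draw_block_haplotype(n, m, lrho, maf) +
        draw_block_haplotype(n, m, lrho, maf)
    }
    common <- do.call(cbind, cols)
    rare_maf <- stats::runif(config$n_rare_variants,
                             config$rare_maf_range[1], config$rare_maf_range[2])
    rare <- matrix(stats::rbinom(n * config$n_rare_variants, 2,
                                 rep(rare_maf, each = n)),
                   n, config$n_rare_variants)
    dosage <- cbind(common, rare)
    p_c <- ncol(common); p_r <- ncol(rare)
    colnames(dosage) <- c(sprintf("c%05d", seq_len(p_c)),
                          sprintf("r%05d", seq_len(p_r)))
    rownames(dosage) <- sprintf("S%05d", seq_len(n))
    genotype_panel(dosage,
                   chrom = rep(c("1", "2"), c(p_c, p_r)),
                   pos = c(seq_len(p_c) * 1000, seq_len(p_r) * 1000))
  })
}

#' Simulate heritable metabolites from a genotype panel
#'
#' Each metabolite follows an additive genetic model:
#' \deqn{y = \sqrt{h^2}\, g^* + \sqrt{1-h^2}\,(\sqrt{\rho}\,F +
#'       \sqrt{1-\rho}\,\varepsilon)}
#' where `g*` is the standardized weighted sum of the metabolite's causal
#' dosages (standard-normal effect sizes, rescaled so the genetic variance
#' fraction equals the assigned heritability exactly in the emitted sample),
#' `F` is a per-subject factor shared by all metabolites (inducing pairwise
#' non-genetic correlation `rho`), and `eps` is independent Gaussian noise.
#' Abundances are shifted/scaled to `abundance_mean`/`abundance_sd`.
#' Missing cells are injected completely at random at `missing_rate`,
#' never in template metabolites. Deterministic given the config seed.
#'
#' @param genotypes a [genotype_panel()] from [simulate_genotypes()].
#' @param config the same [simulation_config()].
#' @return list with `panel` (a [metabolite_panel()]), `true_heritability`
#'   (named vector), and `causal_variants` (named list of variant ids).
#' @export
simulate_metabolites <- function(genotypes, config) {
  stopifnot(inherits(genotypes, "genotype_panel"),
            inherits(config, "simulation_config"))
  if (any(config$heritability_levels < 0 | config$heritability_levels > 1)) {
    stop_config("heritability outside [0, 1]")
  }
  with_seed(derive_seed(config$seed, 12L), {
    n <- nrow(genotypes$dosage)
    m <- config$n_metabolites
    ids <- sprintf("met%04d", seq_len(m))
    template_ids <- ids[seq_len(config$n_templates)]
    h2 <- rep_len(config$heritability_levels, m)
    names(h2) <- ids
    is_common <- genotypes$variants$chrom == "1"
    common_ids <- genotypes$variants$variant_id[is_common]
    rare_ids <- genotypes$variants$variant_id[!is_common]
    Fshared <- stats::rnorm(n)
    rho <- config$metabolite_block_correlation
    Y <- matrix(NA_real_, n, m, dimnames = list(rownames(genotypes$dosage), ids))
    causal <- vector("list", m)
    names(causal) <- ids
    for (j in seq_len(m)) {
      n_rare <- min(round(config$n_causal * config$p_causal_rare), length(rare_ids))
      n_comm <- min(config$n_causal - n_rare, length(common_ids))
      cv <- c(sample(common_ids, n_comm), sample(rare_ids, n_rare))
      causal[[j]] <- cv
      beta <- stats::rnorm(length(cv))
      g <- as.numeric(genotypes$dosage[, cv, drop = FALSE] %*% beta)
      sg <- stats::sd(g)
      gstd <- if (sg > 0) (g - mean(g)) / sg else rep(0, n)
      env <- sqrt(rho) * Fshared + sqrt(1 - rho) * stats::rnorm(n)
      y <- sqrt(h2[j]) * gstd + sqrt(1 - h2[j]) * env
      Y[, j] <- config$abundance_mean + config$abundance_sd * y
    }
    if (config$missing_rate > 0 && m > config$n_templates) {
      non_t <- setdiff(ids, template_ids)
      mask <- matrix(stats::runif(n * length(non_t)) < config$missing_rate,
                     n, length(non_t))
      Y[, non_t][mask] <- NA_real_
    }
    list(panel = metabolite_panel(Y, template_ids),
         true_heritability = h2, causal_variants = causal)
  })
}

#' Simulate polygenic scoring tables
#'
#' Each table references a random subset of the panel's common variants with
#' standard-normal effect weights. Most entries use the alternate allele as
#' the effect allele; a 10% minority use the reference allele, exercising
#' the allele-flip path of [pgs_scores()]. Deterministic given `seed`.
#'
#' @param genotypes a [genotype_panel()].
#' @param n_tables number of scoring tables.
#' @param seed integer seed.
#' @param n_variants_range range of entries per table (default 5 to 30).
#' @return list of [scoring_table()] objects.
#' @export
simulate_pgs_weights <- function(genotypes, n_tables, seed,
                                 n_variants_range = c(5, 30)) {
  stopifnot(inherits(genotypes, "genotype_panel"))
  if (!is_count(n_tables)) stop_config("n_tables must be a positive integer")
  with_seed(derive_seed(seed, 13L), {
    meta <- genotypes$variants
    common <- meta[meta$maf >= 0.05, , drop = FALSE]
    if (!nrow(common)) stop_config("no common variants available for scoring tables")
    lapply(seq_len(n_tables), function(t) {
      k <- sample(seq(n_variants_range[1], min(n_variants_range[2], nrow(common))), 1)
      rows <- sort(sample.int(nrow(common), k))
      flip <- stats::runif(k) < 0.1
      scoring_table(sprintf("PGS%04d", t),
                    common$variant_id[rows],
                    ifelse(flip, common$ref[rows], common$alt[rows]),
                    stats::rnorm(k))
    })
  })
}

#' Simulate a full synthetic dataset
#'
#' Convenience wrapper running [simulate_genotypes()],
#' [simulate_metabolites()] and [simulate_pgs_weights()] from one config.
#'
#' @param config a [simulation_config()].
#' @param n_pgs_tables number of scoring tables (default 40).
#' @return list with `genotypes`, `metabolites` (a [metabolite_panel()]),
#'   `true_heritability`, `causal_variants`, `pgs_weights`, `config`.
#' @export
simulate_dataset <- function(config, n_pgs_tables = 40) {
  geno <- simulate_genotypes(config)
  met <- simulate_metabolites(geno, config)
  tables <- simulate_pgs_weights(geno, n_pgs_tables, config$seed)
  list(genotypes = geno, metabolites = met$panel,
       true_heritability = met$true_heritability,
       causal_variants = met$causal_variants,
       pgs_weights = tables, config = config)
}
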