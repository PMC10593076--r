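#' Hardy-Weinberg equilibrium exact test
#'
#' Two-sided exact test of genotype counts against Hardy-Weinberg
#' proportions, conditional on the observed allele counts. The p-value is
#' the total probability of all heterozygote counts (with the same allele
#' counts) whose conditional probability does not exceed that of the
#' observed count. Probabilities are evaluated with the standard stable
#' ratio recurrence over the heterozygote count.
#'
#' @param n_hom_major,n_het,n_hom_minor genotype counts (major homozygote,
#'   heterozygote, minor homozygote). The labelling of the two homozygote
#'   classes does not affect the result.
#' @return p-value in (0, 1]. Monomorphic sites return 1.
#' @export
hwe_exact_test <- function(n_hom_major, n_het, n_hom_minor) {
  counts <- c(n_hom_major, n_het, n_hom_minor)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    stop_config("genotype counts must be nonnegative integers")
  }
  n <- sum(counts)
  if (n < 1) stop_config("at least one genotyped subject required")
  rare <- min(2 * n_hom_major + n_het, 2 * n_hom_minor + n_het)
  if (rare == 0) return(1)

  h_min <- rare %% 2
  hets <- seq.int(h_min, rare, by = 2)
  # Unnormalized conditional probabilities by the ratio recurrence
  # P(h+2)/P(h) = 4 * hom_minor(h) * hom_major(h) / ((h+2)(h+1)),
  # anchored at the modal heterozygote count so large panels neither
  # overflow nor underflow.
  probs <- numeric(length(hets))
  i0 <- which.min(abs(hets - rare * (2 * n - rare) / (2 * n)))
  probs[i0] <- 1
  if (i0 < length(hets)) {
    for (i in seq.int(i0 + 1, length(hets))) {
      h <- hets[i - 1]
      hom_r <- (rare - h) / 2
      hom_c <- n - h - hom_r
      probs[i] <- probs[i - 1] * 4 * hom_r * hom_c / ((h + 2) * (h + 1))
    }
  }
  if (i0 > 1) {
    for (i in seq.int(i0 - 1, 1)) {
      h <- hets[i + 1]
      hom_r <- (rare - h) / 2
      hom_c <- n - h - hom_r
      probs[i] <- probs[i + 1] * h * (h - 1) / (4 * (hom_r + 1) * (hom_c + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hets)]
  if (is.na(p_obs)) stop_config("heterozygote count inconsistent with allele counts")
  p <- sum(probs[probs <= p_obs * (1 + 1e-9)])
  min(1, max(p, .Machine$double.xmin))
}

#' Variant quality-control filter
#'
#' Drops variants with per-variant missing rate above `max_missing` or a
#' Hardy-Weinberg exact-test p-value below `hwe_alpha`. The subject set is
#' unchanged. An empty result is returned with a warning, not an error.
#'
#' @param panel a [genotype_panel()].
#' @param max_missing maximum tolerated missing rate (default 0.05).
#' @param hwe_alpha HWE rejection level (default 1e-4).
#' @return The filtered `genotype_panel`.
#' @export
qc_filter_variants <- function(panel, max_missing = 0.05, hwe_alpha = 1e-4) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (ncol(panel$dosage) == 0) stop_config("empty genotype panel")
  keep <- panel$variants$missing_rate <= max_missing &
    panel$variants$hwe_p >= hwe_alpha
  if (!any(keep)) warning("QC filter removed every variant")
  subset_panel(panel, variant_ids = panel$variants$variant_id[keep])
}

#' Split variants into common and rare by minor allele frequency
#'
#' Variants with MAF >= `maf_cut` are common; variants with 0 < MAF <
#' `maf_cut` are rare. Monomorphic variants (MAF = 0) fall in neither set.
#' The boundary MAF = `maf_cut` is assigned to the common set.
#'
#' @param panel a [genotype_panel()].
#' @param maf_cut MAF threshold in (0, 0.5); default 0.05.
#' @return list with `genotype_panel` elements `common` and `rare`.
#' @export
split_by_maf <- function(panel, maf_cut = 0.05) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (!is_fraction(maf_cut) || maf_cut <= 0 || maf_cut >= 0.5) {
    stop_config("maf_cut must lie in (0, 0.5)")
  }
  maf <- panel$variants$maf
  list(
    common = subset_panel(panel, panel$variants$variant_id[maf >= maf_cut]),
    rare = subset_panel(panel, panel$variants$variant_id[maf < maf_cut & maf > 0])
  )
}

#' Windowed LD pruning
#'
#' Greedy left-to-right scan over windows of `window` consecutive variants
#' (within chromosome), advancing by `step` variants. Inside each window,
#' every retained pair with squared dosage correlation exceeding
#' `r2_threshold` loses its lower-MAF member; on an exact MAF tie the
#' later-positioned variant is removed. The retained set contains no
#' surviving within-window pair above the threshold.
#'
#' @param panel a [genotype_panel()], positionally sorted.
#' @param window window size in variants (default 50).
#' @param step step size in variants (default 5).
#' @param r2_threshold squared-correlation threshold (default 0.5).
#' @return Character vector of retained variant ids (in positional order).
#' @export
ld_prune <- function(panel, window = 50, step = 5, r2_threshold = 0.5) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (!is_count(window) || window < 2) stop_config("window must be an integer >= 2")
  if (!is_count(step)) stop_config("step must be a positive integer")
  meta <- panel$variants
  keep <- rep(TRUE, nrow(meta))
  for (chr in unique(meta$chrom)) {
    idx <- which(meta$chrom == chr)
    p <- length(idx)
    if (p < 2) next
    starts <- seq.int(1, p, by = step)
    for (s in starts) {
      w <- idx[s:min(s + window - 1, p)]
      w <- w[keep[w]]
      if (length(w) < 2) next
      r2 <- suppressWarnings(
        stats::cor(panel$dosage[, w, drop = FALSE],
                   use = "pairwise.complete.obs"))^2
      r2[is.na(r2)] <- 0
      for (a in seq_len(length(w) - 1)) {
        if (!keep[w[a]]) next
        for (b in seq.int(a + 1, length(w))) {
          if (!keep[w[b]]) next
          if (r2[a, b] > r2_threshold) {
            drop <- if (meta$maf[w[a]] < meta$maf[w[b]]) w[a] else w[b]
            keep[drop] <- FALSE
            if (drop == w[a]) break
          }
        }
      }
      if (s + window - 1 >= p) break
    }
  }
  meta$variant_id[keep]
}

# --- genetic principal components ------------------------------------------

# Fit a PCA of the per-variant standardized dosage matrix on the given
# subjects. Missing dosages are mean-imputed per variant; zero-variance
# variants are dropped from the rotation. Sign convention: in each
# rotation column the largest-magnitude loading is positive.
genetic_pca_fit <- function(panel, n_pcs = 2, subject_ids = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  X <- panel$dosage
  if (!is.null(subject_ids)) X <- X[subject_ids, , drop = FALSE]
  if (n_pcs > min(dim(X))) stop_config("n_pcs exceeds matrix rank bound")
  ctr <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- ctr[j]
  scl <- apply(X, 2, stats::sd)
  use <- scl > 0
  Xs <- sweep(X[, use, drop = FALSE], 2, ctr[use], "-")
  Xs <- sweep(Xs, 2, scl[use], "/")
  sv <- svd(Xs, nu = 0, nv = n_pcs)
  rot <- sv$v[, seq_len(n_pcs), drop = FALSE]
  for (k in seq_len(n_pcs)) {
    j <- which.max(abs(rot[, k]))
    if (rot[j, k] < 0) rot[, k] <- -rot[, k]
  }
  list(center = ctr[use], scale = scl[use],
       variant_ids = colnames(panel$dosage)[use],
       rotation = rot, d = sv$d[seq_len(n_pcs)])
}

genetic_pca_project <- function(fit, panel, subject_ids = NULL) {
  X <- panel$dosage[, fit$variant_ids, drop = FALSE]
  if (!is.null(subject_ids)) X <- X[subject_ids, , drop = FALSE]
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- fit$center[j]
  Xs <- sweep(sweep(X, 2, fit$center, "-"), 2, fit$scale, "/")
  scores <- Xs %*% fit$rotation
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  scores
}

#' Genetic principal components
#'
#' Principal components of the per-variant standardized common-variant
#' dosage matrix, ordered by decreasing explained variance, used to adjust
#' metabolite abundances for population stratification. The sign of each
#' component is fixed by making its largest-magnitude variant loading
#' positive.
#'
#' @param panel a [genotype_panel()] of common variants.
#' @param n_pcs number of components (default 2).
#' @return subjects-by-`n_pcs` score matrix.
#' @export
compute_genetic_pcs <- function(panel, n_pcs = 2) {
  fit <- genetic_pca_fit(panel, n_pcs = n_pcs)
  genetic_pca_project(fit, panel)
}

# OLS of y on intercept + PCs; returns coefficients for reuse on new
# subjects. Rank-deficient designs (e.g. constant PCs) drop the aliased
# columns, whose coefficients become 0.
pc_adjust_fit <- function(y, pcs) {
  X <- cbind(1, pcs)
  cf <- stats::lm.fit(X, y)$coefficients
  cf[is.na(cf)] <- 0
  unname(cf)
}

pc_adjust_apply <- function(coef, y, pcs) {
  as.numeric(y - cbind(1, pcs) %*% coef)
}

#' Residualize a metabolite on genetic principal components
#'
#' Ordinary least-squares residuals of an abundance vector on an intercept
#' plus the genetic PCs, removing population-stratification signal before
#' burden scoring. Residuals are mean-zero and orthogonal to each PC.
#'
#' @param metabolite per-subject abundance vector (no missing values).
#' @param pcs subjects-by-k PC score matrix.
#' @return Residual vector.
#' @export
pc_residualize <- function(metabolite, pcs) {
  pcs <- as.matrix(pcs)
  if (length(metabolite) != nrow(pcs)) stop_config("length mismatch")
  if (length(metabolite) < 4) stop_config("at least 4 subjects required")
  if (anyNA(metabolite) || anyNA(pcs)) stop_config("missing values not allowed")
  pc_adjust_apply(pc_adjust_fit(metabolite, pcs), metabolite, pcs)
}

# --- burden scores ----------------------------------------------------------

#' Rare-variant burden score features
#'
#' For each subject i and rare variant v the candidate feature is
#' `b(i, v) = residual(i) * dosage(i, v)`: the PC-adjusted template-metabolite
#' residual multiplied by the subject's rare allele count (missing dosage
#' counted as 0). In region mode, candidates are summed over the variants of
#' each declared region instead. The `k` candidates with the highest variance
#' across the given (training) subjects are retained; ties break
#' lexicographically by feature id.
#'
#' @param residuals per-subject PC-adjusted residual vector of the template
#'   metabolite (aligned to the rows of `rare`).
#' @param rare a [genotype_panel()] of rare variants.
#' @param k number of features to keep (default 512).
#' @param regions optional named character vector mapping variant id to
#'   region id; when given, features are per-region sums.
#' @return list with `features` (subjects-by-k matrix) and `feature_ids`.
#' @export
burden_features <- function(residuals, rare, k = 512, regions = NULL) {
  stopifnot(inherits(rare, "genotype_panel"))
  if (length(residuals) != nrow(rare$dosage)) stop_config("residual length mismatch")
  B <- burden_candidates(residuals, rare, regions)
  v <- apply(B, 2, stats::var)
  if (k > ncol(B)) {
    warning(sprintf("k = %d exceeds %d candidate features; returning all", k, ncol(B)))
    k <- ncol(B)
  }
  if (all(v == v[1])) warning("degenerate variance selection: all candidate variances equal")
  ids <- top_k_by_variance(v, colnames(B), k)
  list(features = B[, ids, drop = FALSE], feature_ids = ids)
}

# candidate burden matrix for arbitrary subjects (no fitting involved)
burden_candidates <- function(residuals, rare, regions = NULL) {
  D <- rare$dosage
  D[is.na(D)] <- 0
  B <- D * residuals
  if (!is.null(regions)) {
    reg <- regions[colnames(B)]
    if (anyNA(reg)) stop_config("regions must cover every rare variant")
    B <- vapply(split(seq_len(ncol(B)), reg),
                function(j) rowSums(B[, j, drop = FALSE]),
                numeric(nrow(B)))
    B <- matrix(B, nrow = nrow(D),
                dimnames = list(rownames(D), names(split(seq_len(ncol(D)), reg))))
  }
  B
}

# --- polygenic scores -------------------------------------------------------

#' Polygenic scores from scoring tables
#'
#' Each score is the weighted sum of allele dosages over the table variants
#' present in the panel. Weights whose effect allele is the panel's
#' reference allele are applied to the flipped dosage `2 - dosage`; entries
#' matching neither panel allele are skipped. Missing dosages are imputed as
#' `2 * alternate-allele frequency`. The `k` scores with the highest
#' variance across subjects are retained (ties lexicographic by score id).
#'
#' @param panel a [genotype_panel()].
#' @param tables list of [scoring_table()] objects.
#' @param k number of scores to keep (default 512; use `Inf` for all).
#' @return list with `scores` (subjects-by-k matrix), `score_ids`, and
#'   `all_scores` (the unselected subjects-by-tables matrix).
#' @export
pgs_scores <- function(panel, tables, k = 512) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (!length(tables)) stop_config("at least one scoring table required")
  S <- pgs_score_matrix(panel, tables)
  v <- apply(S, 2, stats::var)
  k <- min(k, ncol(S))
  ids <- top_k_by_variance(v, colnames(S), k)
  list(scores = S[, ids, drop = FALSE], score_ids = ids, all_scores = S)
}

# score matrix for all tables; per-subject computation, no fitted statistic
pgs_score_matrix <- function(panel, tables) {
  meta <- panel$variants
  # missing dosages imputed as twice the alternate-allele frequency stored
  # in the panel metadata (stable under subject subsetting)
  D <- panel$dosage
  for (j in seq_len(ncol(D))) D[is.na(D[, j]), j] <- 2 * meta$af[j]
  ids <- vapply(tables, function(t) attr(t, "score_id"), character(1))
  S <- matrix(0, nrow(D), length(tables), dimnames = list(rownames(D), ids))
  for (t in seq_along(tables)) {
    tab <- tables[[t]]
    m <- match(tab$variant_id, meta$variant_id)
    hit <- !is.na(m)
    if (!any(hit)) {
      warning(sprintf("scoring table '%s' references no panel variant; score is 0", ids[t]))
      next
    }
    j <- m[hit]
    w <- tab$effect_weight[hit]
    ea <- tab$effect_allele[hit]
    is_alt <- ea == meta$alt[j]
    is_ref <- ea == meta$ref[j]
    usable <- is_alt | is_ref
    j <- j[usable]; w <- w[usable]; flip <- is_ref[usable]
    if (!length(j)) next
    Dsub <- D[, j, drop = FALSE]
    if (any(flip)) Dsub[, flip] <- 2 - Dsub[, flip, drop = FALSE]
    S[, t] <- Dsub %*% w
  }
  S
}

# --- min-max scaling --------------------------------------------------------

#' Min-max feature scaling fitted on training subjects
#'
#' `fit_minmax_scaler()` records the per-feature training minimum and
#' maximum; `apply_minmax_scaler()` maps values to `[0, 1]`, clipping
#' out-of-range (test) values. Constant features map to 0.5. Scaling to
#' `[0, 1]` is what makes the Bernoulli reconstruction likelihood of the
#' autoencoder well defined.
#'
#' @param features numeric matrix (training subjects in rows).
#' @return `fit_minmax_scaler`: list with `min` and `max` per feature.
#' @export
fit_minmax_scaler <- function(features) {
  features <- as.matrix(features)
  list(min = apply(features, 2, min), max = apply(features, 2, max))
}

#' @rdname fit_minmax_scaler
#' @param scaler a fitted scaler.
#' @export
apply_minmax_scaler <- function(features, scaler) {
  features <- as.matrix(features)
  rng <- scaler$max - scaler$min
  out <- sweep(features, 2, scaler$min, "-")
  out <- sweep(out, 2, ifelse(rng > 0, rng, 1), "/")
  out[, rng == 0] <- 0.5
  clamp(out, 0, 1)
}

#' @rdname fit_minmax_scaler
#' @param scaled matrix previously produced by `apply_minmax_scaler`.
#' @export
invert_minmax_scaler <- function(scaled, scaler) {
  scaled <- as.matrix(scaled)
  rng <- scaler$max - scaler$min
  out <- sweep(sweep(scaled, 2, ifelse(rng > 0, rng, 1), "*"), 2, scaler$min, "+")
  out[, rng == 0] <- scaler$min[rng == 0]
  out
}
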