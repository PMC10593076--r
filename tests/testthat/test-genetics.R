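test_that("HWE exact test matches hand-enumerable cases", {
  # monomorphic site: a single outcome
  expect_identical(hwe_exact_test(50, 0, 0), 1)
  expect_identical(hwe_exact_test(0, 0, 30), 1)

  # two minor alleles in two subjects: het count is 0 or 2;
  # P(het=0) = 1/3, P(het=2) = 2/3, observed 0 is the smaller tail
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3, tolerance = 1e-12)

  # a strongly out-of-equilibrium configuration
  expect_equal(hwe_exact_test(57, 14, 50), hwe_oracle(57, 14, 50),
               tolerance = 1e-12)
  expect_error(hwe_exact_test(-1, 2, 3), "nonnegative")
})

test_that("HWE conditional distribution sums to one and p-values are calibrated", {
  for (case in list(c(40, 20), c(101, 75), c(33, 33))) {
    p <- hwe_oracle_probs(case[1], case[2])
    expect_equal(sum(p / sum(p)), 1, tolerance = 1e-12)
  }
  # under HWE-true genotypes the test rejects at ~nominal rate or below
  set.seed(404)
  n <- 150
  pvals <- replicate(1e4, {
    hap <- matrix(rbinom(2 * n, 1, 0.25), ncol = 2)
    d <- rowSums(hap)
    hwe_exact_test(sum(d == 0), sum(d == 1), sum(d == 2))
  })
  expect_lte(mean(pvals < 0.01), 0.02)
  expect_true(all(pvals > 0 & pvals <= 1))
})

test_that("variant QC filter applies both rules and matches a brute-force scan", {
  ds <- tiny_dataset()
  g <- ds$genotypes$dosage[, 1:50]
  set.seed(11)
  g[sample(length(g), 150)] <- NA        # scattered missingness
  g[sample(nrow(g), 20), 3] <- NA        # variant 3 pushed over 5% missing
  g[, 7] <- rep(c(0, 2), length.out = nrow(g))  # het deficit, HWE broken
  panel <- genotype_panel(g)
  qc <- qc_filter_variants(panel, max_missing = 0.05, hwe_alpha = 1e-4)

  keep_oracle <- sapply(seq_len(ncol(g)), function(j) {
    d <- g[, j]
    miss <- mean(is.na(d))
    d <- d[!is.na(d)]
    p <- hwe_oracle(sum(d == 0), sum(d == 1), sum(d == 2))
    miss <= 0.05 && p >= 1e-4
  })
  expect_identical(qc$variants$variant_id,
                   panel$variants$variant_id[keep_oracle])
  expect_false("var00003" %in% qc$variants$variant_id)
  expect_false("var00007" %in% qc$variants$variant_id)
  # complete, in-equilibrium panel passes unchanged
  clean <- tiny_dataset()$genotypes
  expect_equal(ncol(qc_filter_variants(clean)$dosage), ncol(clean$dosage))
})

test_that("MAF split partitions polymorphic variants with boundary to common", {
  d <- cbind(
    rep(c(0, 1), 50),                  # maf 0.25
    c(rep(1, 10), rep(0, 90)),         # maf 0.05, boundary
    c(rep(1, 4), rep(0, 96)),          # maf 0.02, rare
    rep(0, 100)                        # monomorphic
  )
  colnames(d) <- c("a", "b", "c", "m")
  panel <- genotype_panel(d)
  halves <- split_by_maf(panel, maf_cut = 0.05)
  expect_setequal(halves$common$variants$variant_id, c("a", "b"))
  expect_setequal(halves$rare$variants$variant_id, "c")
  # brute-force partition over a random panel
  ds <- tiny_dataset()
  h <- split_by_maf(ds$genotypes)
  maf <- ds$genotypes$variants$maf
  expect_setequal(h$common$variants$variant_id,
                  ds$genotypes$variants$variant_id[maf >= 0.05])
  expect_setequal(h$rare$variants$variant_id,
                  ds$genotypes$variants$variant_id[maf < 0.05 & maf > 0])
  expect_error(split_by_maf(ds$genotypes, maf_cut = 0.6), "maf_cut")
})

test_that("LD pruning keeps the higher-MAF member and matches the greedy oracle", {
  # duplicate columns: the MAF-0.3 copy must survive
  set.seed(2)
  x <- rbinom(400, 2, 0.3)
  y <- x; y[sample(400, 60)] <- rbinom(60, 2, 0.2)  # correlated, lower maf
  d <- cbind(v1 = x, v2 = x, v3 = rbinom(400, 2, 0.2))
  d[1:140, 2] <- pmax(d[1:140, 2] - 1, 0)  # degrade column 2's maf below v1
  panel <- genotype_panel(d)
  stopifnot(panel$variants$maf[1] > panel$variants$maf[2])
  kept <- ld_prune(panel, window = 3, step = 1, r2_threshold = 0.5)
  if (cor(d[, 1], d[, 2])^2 > 0.5) expect_false("v2" %in% kept)
  expect_true("v1" %in% kept)

  # simulated block panel against the quadratic-time oracle
  cfg <- simulation_config(n_subjects = 300, n_common_variants = 60,
                           n_rare_variants = 5, ld_block_size = 6,
                           within_block_r = 0.8, n_metabolites = 4,
                           n_templates = 1, seed = 31)
  g <- simulate_genotypes(cfg)
  kept <- ld_prune(g, window = 10, step = 2, r2_threshold = 0.5)
  expect_identical(kept, ld_prune_oracle(g, window = 10, step = 2,
                                         r2_threshold = 0.5))
  # fixed point: pruning the retained panel removes nothing
  again <- ld_prune(subset_panel(g, variant_ids = kept),
                    window = 10, step = 2, r2_threshold = 0.5)
  expect_identical(again, kept)

  # mutually uncorrelated variants are all retained
  cfg0 <- simulation_config(n_subjects = 500, n_common_variants = 40,
                            n_rare_variants = 5, within_block_r = 0,
                            n_metabolites = 4, n_templates = 1, seed = 32)
  g0 <- simulate_genotypes(cfg0)
  expect_length(ld_prune(g0), ncol(g0$dosage))
  expect_error(ld_prune(g0, window = 1), "window")
})

test_that("genetic PCs match an independent eigendecomposition", {
  ds <- tiny_dataset()
  common <- split_by_maf(ds$genotypes)$common
  pcs <- compute_genetic_pcs(common, n_pcs = 2)
  X <- scale(common$dosage)
  X <- X[, apply(common$dosage, 2, sd) > 0, drop = FALSE]
  eig <- eigen(crossprod(X) / 1, symmetric = TRUE)
  scores <- X %*% eig$vectors[, 1:2]
  for (k in 1:2) {
    expect_equal(abs(unname(pcs[, k])), abs(unname(scores[, k])),
                 tolerance = 1e-8)
  }
  # rank-1 matrix: PC1 carries all the variance
  d1 <- outer(rep(c(0, 1, 2), length.out = 60), rep(1, 5))
  colnames(d1) <- paste0("v", 1:5)
  p1 <- genotype_panel(d1)
  f <- mvimpute:::genetic_pca_fit(p1, n_pcs = 2)
  expect_gt(f$d[1]^2 / sum(f$d^2), 0.999)
  expect_error(compute_genetic_pcs(common, n_pcs = 1e5), "n_pcs")
})

test_that("PC residualization is exact OLS with orthogonal residuals", {
  set.seed(5)
  n <- 120
  pcs <- matrix(rnorm(2 * n), n, 2)
  # exactly linear in the PCs: residuals vanish
  y_lin <- 3 + 2 * pcs[, 1] - pcs[, 2]
  expect_equal(pc_residualize(y_lin, pcs), rep(0, n), tolerance = 1e-10)
  # zero PCs: residuals are the centered metabolite
  y <- rnorm(n)
  expect_equal(pc_residualize(y, matrix(0, n, 2)), y - mean(y),
               tolerance = 1e-10)
  # normal-equations oracle
  r <- pc_residualize(y, pcs)
  X <- cbind(1, pcs)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(r, as.numeric(y - X %*% beta), tolerance = 1e-10)
  expect_lt(abs(sum(r * pcs[, 1])), 1e-8)
  expect_lt(abs(sum(r * pcs[, 2])), 1e-8)
  expect_error(pc_residualize(y[1:3], pcs[1:3, ]), "4 subjects")
})

test_that("burden features multiply residuals into rare dosages and select by variance", {
  ds <- tiny_dataset()
  rare <- split_by_maf(ds$genotypes)$rare
  n <- nrow(rare$dosage)
  set.seed(6)
  res <- rnorm(n)
  bf <- burden_features(res, rare, k = 10)
  # direct definition, and the variance-ranking oracle with id tie-break
  B <- rare$dosage
  B[is.na(B)] <- 0
  B <- B * res
  v <- apply(B, 2, var)
  ids_oracle <- colnames(B)[order(-v, colnames(B))][1:10]
  expect_identical(bf$feature_ids, ids_oracle)
  expect_equal(bf$features, B[, ids_oracle], tolerance = 1e-12)

  # unit residuals reduce the features to the dosage matrix
  bf1 <- burden_features(rep(1, n), rare, k = 5)
  v1 <- apply(B <- {B <- rare$dosage; B[is.na(B)] <- 0; B}, 2, var)
  expect_identical(bf1$feature_ids, colnames(rare$dosage)[order(-v1, colnames(rare$dosage))][1:5])

  # all-zero residuals: degenerate selection, warning raised
  expect_warning(burden_features(rep(0, n), rare, k = 3), "degenerate")
  expect_warning(burden_features(res, rare, k = 1e4), "exceeds")
})

test_that("PGS scoring handles weights, allele flips and missing dosages", {
  ds <- tiny_dataset()
  meta <- ds$genotypes$variants
  vid <- meta$variant_id[5]
  # single-variant table with unit weight on the alternate allele
  t_alt <- scoring_table("alt1", vid, meta$alt[5], 1)
  sc <- pgs_scores(ds$genotypes, list(t_alt), k = 1)
  expect_equal(unname(sc$scores[, 1]), unname(ds$genotypes$dosage[, 5]))
  # effect allele on the reference strand flips the dosage
  t_ref <- scoring_table("ref1", vid, meta$ref[5], 1)
  sc_r <- pgs_scores(ds$genotypes, list(t_ref), k = 1)
  expect_equal(unname(sc_r$scores[, 1]), unname(2 - ds$genotypes$dosage[, 5]))
  # table referencing nothing in the panel scores zero, with warning
  t_none <- scoring_table("none", "absent_variant", "A", 1)
  expect_warning(sc0 <- pgs_scores(ds$genotypes, list(t_none), k = 1),
                 "no panel variant")
  expect_true(all(sc0$scores == 0))

  # ten random tables against independent matrix multiplication + ranking
  tabs <- ds$pgs_weights
  sc10 <- pgs_scores(ds$genotypes, tabs, k = 4)
  manual <- sapply(tabs, function(tab) {
    out <- rep(0, nrow(ds$genotypes$dosage))
    for (i in seq_len(nrow(tab))) {
      j <- match(tab$variant_id[i], meta$variant_id)
      if (is.na(j)) next
      d <- ds$genotypes$dosage[, j]
      if (tab$effect_allele[i] == meta$ref[j]) d <- 2 - d
      else if (tab$effect_allele[i] != meta$alt[j]) next
      out <- out + tab$effect_weight[i] * d
    }
    out
  })
  colnames(manual) <- sapply(tabs, attr, "score_id")
  v <- apply(manual, 2, var)
  ids <- colnames(manual)[order(-v, colnames(manual))][1:4]
  expect_identical(sc10$score_ids, ids)
  expect_equal(unname(sc10$scores), unname(manual[, ids]), tolerance = 1e-12)

  # missing dosages are imputed at twice the alternate-allele frequency
  g <- ds$genotypes$dosage[, 1:3]
  g[1, 1] <- NA
  pan <- genotype_panel(g)
  tm <- scoring_table("m", colnames(g)[1], pan$variants$alt[1], 1)
  scm <- pgs_scores(pan, list(tm), k = 1)
  expect_equal(unname(scm$scores[1, 1]), 2 * pan$variants$af[1])
})

test_that("min-max scaling maps training data into the unit interval and inverts", {
  X <- cbind(a = c(0, 5, 10), b = c(2, 2, 2), c = c(-1, 0, 3))
  sc <- fit_minmax_scaler(X)
  S <- apply_minmax_scaler(X, sc)
  expect_equal(unname(S[2, "a"]), 0.5)
  expect_true(all(S[, "b"] == 0.5))   # constant feature pins to midpoint
  expect_true(all(S >= 0 & S <= 1))
  # algebraic inverse on non-constant features
  set.seed(3)
  R <- matrix(rnorm(60), 20, 3)
  scr <- fit_minmax_scaler(R)
  expect_equal(invert_minmax_scaler(apply_minmax_scaler(R, scr), scr), R,
               tolerance = 1e-10)
  # out-of-range test values are clipped
  expect_equal(apply_minmax_scaler(cbind(a = 99, b = 1, c = -9), sc)[1, ],
               c(a = 1, b = 0.5, c = 0))
})
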