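# Independent oracles used across test files. Each is written from the
# definition of the quantity it checks, by a different route than the
# implementation under test.

# Exact HWE test by direct evaluation of the conditional genotype
# probabilities from the closed-form counting formula (the implementation
# uses a ratio recurrence instead).
hwe_oracle <- function(hom1, het, hom2) {
  n <- hom1 + het + hom2
  r <- min(2 * hom1 + het, 2 * hom2 + het)
  if (r == 0) return(1)
  hets <- seq(r %% 2, r, by = 2)
  logp <- vapply(hets, function(h) {
    hom_r <- (r - h) / 2
    hom_c <- n - h - hom_r
    lfactorial(n) - lfactorial(hom_c) - lfactorial(h) - lfactorial(hom_r) +
      h * log(2) + lfactorial(r) + lfactorial(2 * n - r) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp)
  obs <- p[match(het, hets)]
  sum(p[p <= obs * (1 + 1e-9)]) / sum(p)
}

# conditional genotype probabilities over all heterozygote counts (used for
# the sums-to-one invariant)
hwe_oracle_probs <- function(n, r) {
  hets <- seq(r %% 2, r, by = 2)
  logp <- vapply(hets, function(h) {
    hom_r <- (r - h) / 2
    hom_c <- n - h - hom_r
    lfactorial(n) - lfactorial(hom_c) - lfactorial(h) - lfactorial(hom_r) +
      h * log(2) + lfactorial(r) + lfactorial(2 * n - r) - lfactorial(2 * n)
  }, numeric(1))
  exp(logp)
}

# Quadratic-time greedy LD-pruning oracle: plain nested loops, pairwise
# correlations computed one pair at a time.
ld_prune_oracle <- function(panel, window = 50, step = 5, r2_threshold = 0.5) {
  meta <- panel$variants
  keep <- stats::setNames(rep(TRUE, nrow(meta)), meta$variant_id)
  for (chr in unique(meta$chrom)) {
    idx <- which(meta$chrom == chr)
    if (length(idx) < 2) next
    s <- 1
    repeat {
      w <- idx[s:min(s + window - 1, length(idx))]
      for (a in seq_along(w)) {
        for (b in seq_along(w)) {
          if (b <= a) next
          va <- w[a]; vb <- w[b]
          if (!keep[meta$variant_id[va]] || !keep[meta$variant_id[vb]]) next
          r <- suppressWarnings(stats::cor(panel$dosage[, va], panel$dosage[, vb],
                                           use = "pairwise.complete.obs"))
          if (!is.na(r) && r^2 > r2_threshold) {
            drop <- if (meta$maf[va] < meta$maf[vb]) va else vb
            keep[meta$variant_id[drop]] <- FALSE
          }
        }
      }
      if (s + window - 1 >= length(idx)) break
      s <- s + step
    }
  }
  meta$variant_id[keep[meta$variant_id]]
}

# KL(q || N(0,1)) for a 1-D Gaussian by adaptive quadrature
kl_quadrature <- function(mu, var) {
  s <- sqrt(var)
  f <- function(z) {
    q <- stats::dnorm(z, mu, s)
    q * (stats::dnorm(z, mu, s, log = TRUE) - stats::dnorm(z, log = TRUE))
  }
  stats::integrate(f, mu - 12 * s, mu + 12 * s, rel.tol = 1e-10)$value
}

# density of the normalized product of 1-D Gaussian experts on a grid
poe_grid_density <- function(means, vars, grid) {
  logd <- rep(0, length(grid))
  for (i in seq_along(means)) {
    logd <- logd + stats::dnorm(grid, means[i], sqrt(vars[i]), log = TRUE)
  }
  d <- exp(logd - max(logd))
  d / (sum(d) * (grid[2] - grid[1]))
}
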