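---
title: "Cross-omics metabolite imputation: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-omics metabolite imputation: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mvimpute)
```

## The problem and the model

Mass-spectrometry metabolomics panels contain missing values, and a
metabolite absent from a subject's profile cannot be recovered from that
profile alone. Because blood metabolite levels are substantially
heritable, paired whole-genome genotypes carry independent information
about them. `mvimpute` predicts a missing metabolite from three genetic
feature views plus one fully observed *template* metabolite used as prior
knowledge.

For subject $i$ and view $v \in \{\mathrm{BS}, \mathrm{PGS},
\mathrm{LD}\}$, an encoder MLP pair produces a diagonal-Gaussian
approximate posterior over a shared latent variable $Z \in \mathbb{R}^D$:

$$q_v(Z \mid X_v^{(i)}) = \mathcal{N}\!\left(\mu_v^{(i)},
\Sigma_v^{(i)}\right), \qquad \Sigma_v = \exp(\mathrm{MLP}_v^\Sigma(X_v)),$$

the exponential guaranteeing positive variances. The views are fused by a
product of experts: since a product of Gaussians is Gaussian, the fused
posterior has precision equal to the sum of the expert precisions and a
precision-weighted mean,

$$\Sigma_z = \Big(\sum_v \Sigma_v^{-1}\Big)^{-1}, \qquad
\mu_z = \Sigma_z \sum_v \Sigma_v^{-1} \mu_v.$$

A reparameterized sample $z = \mu_z + \Sigma_z^{1/2} \odot \epsilon$ feeds
per-view sigmoid decoders and a scalar target head. The loss is the
negative evidence lower bound: summed Bernoulli cross-entropy of every
view reconstruction and of the target prediction (all features and the
target are min-max scaled to $[0,1]$, which is what makes the Bernoulli
likelihood well defined), plus the closed-form KL divergence
$\tfrac12\sum_d (\mu_d^2 + \sigma_d^2 - \log \sigma_d^2 - 1)$ of the fused
posterior from the standard-normal prior. At inference the target head is
decoded from the posterior **mean** — no sampling — so imputation is a
deterministic function of the trained model and the inputs. A
Monte-Carlo-free inference rule was chosen deliberately: determinism makes
the pipeline reproducible bit-for-bit and testable against composition
oracles.

One model is trained per target metabolite. The template supplying the
burden-score view is re-selected for every target as the template-set
member with the highest *signed* Pearson correlation on training subjects
("highest correlation" is read literally; an absolute-correlation variant
would also admit anti-correlated templates, and is deliberately not the
default so that the selection criterion matches what the reported
correlation means).

## Feature engineering

Variant QC keeps variants with missing rate ≤ 5% and Hardy–Weinberg
exact-test $p \ge 10^{-4}$; the HWE test is the standard two-sided
tail-mass exact formulation (no mid-p), computed by a stable ratio
recurrence over heterozygote counts. MAF 5% splits common from rare, with
the boundary value assigned to common. LD pruning scans windows of 50
variants advancing by 5, removing the lower-MAF member of any retained
pair with $r^2 > 0.5$ (exact ties drop the later-positioned variant);
windows are measured in variant count, matching the dominant toolchain
convention for "window 50, step 5".

Burden scores are per-variant products $b(i,v) = r(i)\,d(i,v)$ of the
template's PC-adjusted residual with rare allele counts. The alternative
reading — summing over genes or regions — is available via the `regions`
argument of `burden_features()`, but per-variant mode is the default: it
is the only reading that yields enough candidate features for a
top-$k$-by-variance selection with $k$ in the hundreds. Missing dosages
count as 0 in burden mode (absence of an observed rare allele) and are
imputed as twice the alternate-allele frequency in PGS mode (mean
imputation); scoring-table entries whose effect allele is the panel's
reference allele are applied to the flipped dosage $2-d$.

Every data-dependent quantity — QC statistics, MAF split, pruning, PCA
rotation, residualization coefficients, top-$k$ selections, min-max
scalers — is fitted on training subjects only and replayed on test
subjects. This is enforced structurally (`fit_view_builder()` recomputes
all variant statistics from training rows) and asserted in the test suite
by deleting the test subjects, refitting, and requiring bit-identical
artifacts. All top-$k$ selections break ties lexicographically by id, so
selections are deterministic under permutations of input order.

## Training

The optimizer is Adam (learning rate $10^{-3}$, batch 64) for up to 400
epochs with early stopping (patience 40) on a 10% validation split carved
from the training subjects; weights use variance-scaled uniform
initialization and the log-variance head starts at zero (unit variance).
Two schedule choices deserve explanation:

- **KL warm-up.** The KL weight is annealed linearly from 0 to 1 over the
  first 100 epochs. Min-max-scaled continuous features give the Bernoulli
  reconstruction term a high entropy floor, so its encoder gradients are
  weak relative to the KL pull toward the prior; without warm-up the
  optimizer settles into posterior collapse (a near-prior latent code
  carrying a few nats) and the downstream target prediction is no better
  than the training mean. After warm-up the optimized objective is the
  plain unweighted loss.
- **Early-stopping monitor.** By default the monitored quantity is the
  validation cross-entropy of the *target head* (evaluated at the
  posterior mean, hence deterministic), not the full objective. The
  target contributes one term among hundreds of reconstruction terms, so
  the full validation loss is dominated by reconstruction quality and
  nearly uninformative about when imputation stops improving. Monitoring
  the full loss remains available (`monitor = "loss"`).

Numerical guards: log-variances are clamped to $[-10, 10]$, sigmoid
outputs to $[10^{-7}, 1-10^{-7}]$ inside the cross-entropy; a non-finite
loss aborts training with a diagnostic rather than returning silently.
The backward pass is hand-derived; its correctness is pinned by a
finite-difference gradient check in the test suite (relative error
$<10^{-4}$ across every parameter of a small instance).

## The synthetic cohort

The generator emulates the statistical structure the method assumes,
not any particular population:

- **Genotypes.** Common variants come in LD blocks sharing one MAF and one
  latent Gaussian factor per haplotype, thresholded at the MAF quantile;
  dosage is the sum of two independent haplotype draws, so
  Hardy–Weinberg proportions hold by construction. Thresholding a latent
  factor attenuates correlation, so the factor loading is calibrated
  through the tetrachoric relation (numerical inversion of the
  bivariate-normal orthant probability) to make the realized *dosage*
  correlation match the requested `within_block_r`. Rare variants are
  independent.
- **Metabolites.** Each metabolite follows
  $y = \sqrt{h^2}\,g^\* + \sqrt{1-h^2}\,(\sqrt{\rho}\,F +
  \sqrt{1-\rho}\,\varepsilon)$ with $g^\*$ the sample-standardized
  weighted sum of its causal dosages (standard-normal effects), $F$ a
  per-subject factor shared across metabolites, and $\varepsilon$ white
  noise — so the in-sample genetic variance fraction equals the assigned
  heritability exactly, making recovery tests sharp. Abundances are
  emitted on a positive scale (mean 10, unit SD) so percentage errors are
  well defined. Missingness is injected completely at random, never in
  templates. Realistic LC-MS artifacts (batch effects, limit-of-detection
  censoring, non-MCAR missingness) are deliberately out of scope, which
  bounds what passing tests show about real data.
- **Defaults as study conditions.** The desk-scale conditions are 600
  subjects; 120 common variants in 12 blocks of 10 at dosage correlation
  0.6 plus 80 rare variants; 70 metabolites (10 templates) with
  heritabilities cycling through $\{0, 0.3, 0.6\}$; 4 causal variants per
  metabolite (3 common, 1 rare) — an oligogenic architecture whose
  per-variant effects are resolvable at this cohort size; shared-factor
  correlation $\rho = 0.1$; 3% MCAR missingness. $\rho$ is kept modest by
  design: the burden view hands the model the template's observed value
  even for test subjects, so any non-genetic template–target correlation
  of size $\rho$ contributes $\approx \rho^2$ of *non-genetic* test R²;
  at $\rho = 0.1$ that channel is negligible and recovered accuracy can
  be attributed to genetics (the genotype-permutation control verifies
  this directly). Real metabolite panels have stronger correlation
  blocks; on such data the same channel would legitimately help, and
  measured accuracy would partly reflect it.

## The validation study

`heritability_study()` (also run by `scripts/acceptance.R`) simulates the
desk-scale cohort, trains all 60 per-metabolite models with a reduced
architecture (latent 16, hidden width 32 — scaled to the 184-dimensional
view total the desk-scale genome produces), and reports median test R² by
true heritability plus threshold summaries. Expected behaviour: the
$h^2=0$ arm centers on zero, medians increase with heritability, the
$h^2=0.6$ arm recovers a substantial fraction of its heritability (the
information ceiling is below 0.6 because views lose part of the causal
variance to pruning, selection and the latent bottleneck), and the
genotype-permutation control collapses to zero. The reference (full-size)
architecture — 2×128 MLPs, 64-dimensional latent, 512/512/1024 view
features — remains the package default for real cohorts.

## Known limitations

- The target head is an interpretive choice: the fused latent code is
  trained to reconstruct views *and* predict the target jointly; a model
  that reconstructs views only, with imputation read off a view decoder,
  is a plausible alternative the package does not implement.
- The product of experts follows the analytic fusion rule exactly, with
  no universal-prior expert; a prior-expert variant is a known
  alternative in the multi-view VAE literature.
- Min-max scaling plus a Bernoulli likelihood treats continuous features
  as probabilities; a Gaussian decoder likelihood is out of scope.
- Subjects missing a template value cannot be imputed for metabolites
  whose model selected that template; the pipeline logs and skips them.
- MAPE is computed on the original abundance scale after inverse scaling;
  entries with zero truth are excluded (and counted) rather than
  epsilon-guarded, which is transparent for strictly positive abundance
  data but would need revisiting for signed or zero-inflated quantities.
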