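zero_mlp <- function(d_in, hidden, d_out) {
  net <- mvimpute:::mlp_init(d_in, hidden, d_out)
  net$W <- lapply(net$W, function(w) w * 0)
  net
}

test_that("product of experts is the analytic Gaussian product", {
  # single expert passes through unchanged
  q <- diag_gaussian(c(1, -2), c(0.5, 3))
  expect_equal(poe_combine(list(q)), q)
  # equal precisions halve the variance
  e1 <- diag_gaussian(0, 1); e2 <- diag_gaussian(0, 1)
  expect_equal(poe_combine(list(e1, e2)), diag_gaussian(0, 0.5))
  # symmetric means average
  expect_equal(poe_combine(list(diag_gaussian(1, 1), diag_gaussian(3, 1))),
               diag_gaussian(2, 0.5))
  expect_error(poe_combine(list()), "at least one")
  # optional prior expert: equivalent to multiplying in a standard normal
  e <- diag_gaussian(c(1, -1), c(0.5, 2))
  expect_equal(poe_combine(list(e), prior_expert = TRUE),
               poe_combine(list(e, diag_gaussian(c(0, 0), c(1, 1)))))

  set.seed(77)
  grid <- seq(-12, 12, length.out = 2001)
  for (i in 1:20) {
    experts <- lapply(1:3, function(.) random_gaussian(1))
    q <- poe_combine(experts)
    # precision additivity: exact up to one reciprocal rounding
    expect_equal(1 / q$var, sum(sapply(experts, function(e) 1 / e$var)),
                 tolerance = 1e-15)
    # density equals the normalized pointwise product on a grid
    ref <- poe_grid_density(sapply(experts, `[[`, "mean"),
                            sapply(experts, `[[`, "var"), grid)
    got <- dnorm(grid, q$mean, sqrt(q$var))
    expect_lt(sqrt(mean((got - ref)^2)), 1e-6)
    # order invariance
    expect_equal(poe_combine(rev(experts)), q)
  }
})

test_that("reparameterization is location-scale with correct moments", {
  q <- diag_gaussian(c(2, -1), c(4, 9))
  expect_equal(reparameterize(q, c(0, 0)), q$mean)
  q01 <- diag_gaussian(c(0, 0), c(1, 1))
  expect_equal(reparameterize(q01, c(1.3, -0.2)), c(1.3, -0.2))
  set.seed(12)
  z <- replicate(1e5, reparameterize(diag_gaussian(2, 4), rnorm(1)))
  expect_lt(abs(mean(z) - 2), 0.05)
  expect_lt(abs(var(z) - 4), 0.15)
})

test_that("closed-form KL matches quadrature and is a proper divergence", {
  expect_identical(kl_to_standard_normal(diag_gaussian(rep(0, 7), rep(1, 7))), 0)
  expect_equal(kl_to_standard_normal(diag_gaussian(1, 1)), 0.5)
  set.seed(31)
  for (i in 1:10) {
    mu <- rnorm(1); v <- runif(1, 0.1, 10)
    expect_equal(kl_to_standard_normal(diag_gaussian(mu, v)),
                 kl_quadrature(mu, v), tolerance = 1e-6)
  }
  kls <- replicate(1e4, kl_to_standard_normal(random_gaussian(3)))
  expect_true(all(kls >= 0))
  expect_error(diag_gaussian(0, -1), "positive")
})

test_that("encoders and decoders respect their output contracts", {
  vp <- list(enc_mu = zero_mlp(5, c(4), 3), enc_lv = zero_mlp(5, c(4), 3))
  q <- encode_view(runif(5), vp)
  expect_equal(as.numeric(q$mean), rep(0, 3))
  expect_equal(as.numeric(q$var), rep(1, 3))
  # determinism and strict positivity of variances over random inputs
  set.seed(9)
  vp2 <- list(enc_mu = mvimpute:::mlp_init(5, c(8, 8), 3),
              enc_lv = mvimpute:::mlp_init(5, c(8, 8), 3))
  x <- runif(5)
  expect_identical(encode_view(x, vp2), encode_view(x, vp2))
  X <- matrix(runif(1000 * 5), 1000, 5)
  expect_true(all(encode_view(X, vp2)$var > 0))
  expect_error(encode_view(runif(4), vp2), "dimension")

  dec0 <- zero_mlp(3, c(4), 6)
  expect_equal(as.numeric(decode_view(c(1, 2, 3), dec0)), rep(0.5, 6))
  dec <- mvimpute:::mlp_init(3, c(8, 8), 6)
  Z <- matrix(rnorm(1000 * 3), 1000, 3)
  out <- decode_view(Z, dec)
  expect_true(all(out > 0 & out < 1))
  expect_identical(decode_view(Z[1, ], dec), decode_view(Z[1, ], dec))
})

test_that("ELBO loss has the closed forms and matches elementwise summation", {
  qI <- diag_gaussian(rep(0, 4), rep(1, 4))
  x <- c(0, 1, 1, 0, 1)
  eps <- 1e-7
  near <- pmin(pmax(x, eps), 1 - eps)
  expect_lt(elbo_loss(list(x), NULL, list(near), NULL, qI), 1e-5)
  # uniform reconstruction of binary input costs log(2) per element
  L <- 8
  xb <- rep(c(0, 1), 4)
  expect_equal(elbo_loss(list(xb), NULL, list(rep(0.5, L)), NULL, qI),
               L * log(2) + 0, tolerance = 1e-12)
  # brute-force elementwise summation oracle
  set.seed(14)
  views <- list(runif(6), runif(3))
  recs <- list(runif(6, 0.01, 0.99), runif(3, 0.01, 0.99))
  y <- runif(1); yh <- runif(1, 0.1, 0.9)
  q <- random_gaussian(4)
  manual <- 0
  for (v in 1:2) {
    for (j in seq_along(views[[v]])) {
      manual <- manual - views[[v]][j] * log(recs[[v]][j]) -
        (1 - views[[v]][j]) * log(1 - recs[[v]][j])
    }
  }
  manual <- manual - y * log(yh) - (1 - y) * log(1 - yh)
  manual <- manual + 0.5 * sum(q$mean^2 + q$var - log(q$var) - 1)
  expect_equal(elbo_loss(views, y, recs, yh, q), manual, tolerance = 1e-8)
})

test_that("backpropagated gradients agree with central finite differences", {
  set.seed(3)
  arch <- mvae_architecture(view_dims = c(3, 4), latent_dim = 2,
                            hidden_layers = 1, hidden_width = 4)
  params <- mvimpute:::mvae_init_params(arch, 5)
  n <- 5
  X <- list(matrix(runif(n * 3), n, 3), matrix(runif(n * 4), n, 4))
  y <- runif(n)
  eps <- matrix(rnorm(n * 2), n, 2)
  fw <- mvimpute:::mvae_forward(params, X, y, eps)
  gr <- mvimpute:::mvae_backward(params, X, y, fw)
  h <- 1e-5
  paths <- mvimpute:::param_paths(params)
  worst <- 0
  for (p in paths) {
    v <- params[[p]]
    g <- gr[[p]]
    for (i in seq_along(v)) {
      up <- params; up[[p]][i] <- v[i] + h
      dn <- params; dn[[p]][i] <- v[i] - h
      num <- (mvimpute:::mvae_forward(up, X, y, eps)$loss -
                mvimpute:::mvae_forward(dn, X, y, eps)$loss) / (2 * h)
      rel <- abs(num - g[i]) / max(1e-6, abs(num) + abs(g[i]))
      worst <- max(worst, rel)
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("training is deterministic, reduces reconstruction error, and fails a permuted target", {
  set.seed(88)
  n <- 30
  # low-rank binary views: compressible, so reconstruction error can drop
  # far below its initialization without fighting the KL term
  f <- matrix(rnorm(n * 2), n, 2)
  X <- lapply(c(6, 5), function(k) {
    (f %*% matrix(rnorm(2 * k), 2, k) + 0.3 * matrix(rnorm(n * k), n, k) > 0) + 0
  })
  y <- runif(n)
  arch <- mvae_architecture(c(6, 5), latent_dim = 16, hidden_layers = 1,
                            hidden_width = 16)
  cfg <- training_config(epochs = 500, batch_size = 16, patience = 500,
                         kl_warmup = 50, seed = 4, val_fraction = 0.1,
                         monitor = "loss")
  m1 <- train_mvae(X, y, arch, cfg)
  m2 <- train_mvae(X, y, arch, cfg)
  expect_identical(m1$params, m2$params)

  # memorization: final reconstruction BCE well below the initial one
  D <- arch$latent_dim
  zero_eps <- matrix(0, n, D)
  rec0 <- mvimpute:::mvae_forward(m1$init_params, X, y, zero_eps)$rec
  rec1 <- mvimpute:::mvae_forward(m1$params, X, y, zero_eps)$rec
  expect_lt(rec1, 0.5 * rec0)

  # permuted-target control: held-out target BCE no better than the mean
  set.seed(9)
  nper <- 80
  Xp <- list(matrix(runif(nper * 6), nper, 6), matrix(runif(nper * 5), nper, 5))
  yp <- sample(runif(nper))
  tr <- 1:60; te <- 61:80
  mp <- train_mvae(lapply(Xp, function(m) m[tr, ]), yp[tr], arch,
                   training_config(epochs = 80, batch_size = 16,
                                   patience = 20, kl_warmup = 20, seed = 2))
  pred <- impute_target(mp, lapply(Xp, function(m) m[te, ]))
  bce <- function(a, b) -mean(a * log(b) + (1 - a) * log(1 - b))
  bce_model <- bce(yp[te], pred)
  bce_mean <- bce(yp[te], rep(mean(yp[tr]), 20))
  expect_lt(bce_model, bce_mean * 1.05)
})

test_that("training loss decreases across almost all epoch transitions", {
  set.seed(15)
  n <- 40
  X <- list(matrix(runif(n * 5), n, 5), matrix(runif(n * 4), n, 4))
  y <- runif(n)
  arch <- mvae_architecture(c(5, 4), latent_dim = 4, hidden_layers = 1,
                            hidden_width = 8)
  # full-batch, small learning rate, no annealing: near-monotone descent of
  # the deterministic posterior-mean loss
  m <- train_mvae(X, y, arch,
                  training_config(epochs = 120, batch_size = 64,
                                  learning_rate = 2e-4, patience = 200,
                                  kl_warmup = 0, val_fraction = 0,
                                  seed = 3, monitor = "loss"))
  drops <- diff(m$history$val_loss) <= 1e-8
  expect_gte(mean(drops), 0.95)
})

test_that("imputation is deterministic and 0.5 for an untrained zero decoder", {
  arch <- mvae_architecture(c(3, 2), latent_dim = 2, hidden_layers = 1,
                            hidden_width = 4)
  params <- mvimpute:::mvae_init_params(arch, 1)
  params$dec_y <- zero_mlp(2, c(4), 1)
  model <- structure(list(params = params, arch = arch), class = "mvae_model")
  V <- list(matrix(runif(6), 2, 3), matrix(runif(4), 2, 2))
  expect_equal(impute_target(model, V), c(0.5, 0.5))
  expect_identical(impute_target(model, V), impute_target(model, V))
  expect_error(impute_target(model, V[1]), "missing view")
  # Monte-Carlo inference is seeded-deterministic and stays in (0, 1)
  mc1 <- impute_target(model, V, mc_samples = 16, mc_seed = 3)
  mc2 <- impute_target(model, V, mc_samples = 16, mc_seed = 3)
  expect_identical(mc1, mc2)
  expect_true(all(mc1 > 0 & mc1 < 1))
})

test_that("model checkpoints round-trip bit-exactly", {
  set.seed(5)
  n <- 20
  X <- list(matrix(runif(n * 4), n, 4), matrix(runif(n * 3), n, 3))
  y <- runif(n)
  arch <- mvae_architecture(c(4, 3), latent_dim = 3, hidden_layers = 1,
                            hidden_width = 6)
  m <- train_mvae(X, y, arch, training_config(epochs = 10, batch_size = 8,
                                              patience = 10, kl_warmup = 5,
                                              seed = 6))
  path <- tempfile(fileext = ".json")
  save_mvae(m, path)
  m2 <- load_mvae(path)
  expect_identical(m2$params, m$params)
  expect_identical(m2$arch, m$arch)
  expect_identical(impute_target(m2, X), impute_target(m, X))
})
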