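#' Diagonal Gaussian distribution
#'
#' Mean vector and strictly positive diagonal-variance vector; the building
#' block of the per-view variational posteriors and their product-of-experts
#' fusion. Batched use stores `mean` and `var` as n-by-D matrices.
#'
#' @param mean numeric vector (or n-by-D matrix) of means.
#' @param var numeric vector (or matrix) of variances, strictly positive.
#' @return Object of class `diag_gaussian`.
#' @export
diag_gaussian <- function(mean, var) {
  if (any(!is.finite(mean)) || any(!is.finite(var))) {
    stop_config("mean and var must be finite")
  }
  if (any(var <= 0)) stop_config("variances must be strictly positive")
  if (length(mean) != length(var)) stop_config("mean/var dimension mismatch")
  structure(list(mean = mean, var = var), class = "diag_gaussian")
}

#' Product-of-experts fusion of diagonal Gaussians
#'
#' Combines per-view Gaussian posteriors by density multiplication. Per
#' dimension, precisions add and the combined mean is the precision-weighted
#' average:
#' \deqn{\sigma_z^2 = (\sum_v 1/\sigma_v^2)^{-1}, \quad
#'       \mu_z = \sigma_z^2 \sum_v \mu_v/\sigma_v^2.}
#' The combined variance never exceeds the smallest expert variance.
#'
#' @param experts list of [diag_gaussian()] objects of equal dimension.
#' @param prior_expert include an additional standard-normal expert in the
#'   product (the prior-expert formulation common in the multi-view VAE
#'   literature). Default `FALSE`: the plain analytic product.
#' @return A `diag_gaussian` with the fused parameters.
#' @export
poe_combine <- function(experts, prior_expert = FALSE) {
  if (!length(experts)) stop_config("at least one expert required")
  stopifnot(all(vapply(experts, inherits, logical(1), "diag_gaussian")))
  if (isTRUE(prior_expert)) {
    e1 <- experts[[1]]
    experts <- c(experts, list(diag_gaussian(e1$mean * 0, e1$var * 0 + 1)))
  }
  prec <- Reduce(`+`, lapply(experts, function(e) 1 / e$var))
  wmean <- Reduce(`+`, lapply(experts, function(e) e$mean / e$var))
  var_z <- 1 / prec
  diag_gaussian(var_z * wmean, var_z)
}

#' Reparameterized Gaussian sample
#'
#' `z = mean + sqrt(var) * noise` with externally supplied standard-normal
#' noise, so that gradients flow through `mean` and `var`.
#'
#' @param q a [diag_gaussian()].
#' @param noise standard-normal draw, same shape as `q$mean`.
#' @return Latent draw of the same shape.
#' @export
reparameterize <- function(q, noise) {
  stopifnot(inherits(q, "diag_gaussian"))
  if (length(noise) != length(q$mean)) stop_config("noise dimension mismatch")
  q$mean + sqrt(q$var) * noise
}

#' KL divergence to the standard normal
#'
#' Closed form for a diagonal Gaussian q against N(0, I):
#' \deqn{\tfrac12 \sum_d (\mu_d^2 + \sigma_d^2 - \log\sigma_d^2 - 1).}
#' Nonnegative; zero exactly when q is standard normal.
#'
#' @param q a [diag_gaussian()].
#' @return Scalar KL divergence (summed over all elements of `q`).
#' @export
kl_to_standard_normal <- function(q) {
  stopifnot(inherits(q, "diag_gaussian"))
  0.5 * sum(q$mean^2 + q$var - log(q$var) - 1)
}

#' MVAE architecture description
#'
#' Layer sizes of the multi-view variational autoencoder. Defaults follow
#' the reference configuration: separate mean and log-variance encoder MLPs
#' and per-view decoder MLPs, each with 2 hidden layers of 128 units, and a
#' 64-dimensional shared latent space; a decoder-only target head predicts
#' the metabolite from the fused latent code.
#'
#' @param view_dims integer vector of per-view input widths.
#' @param latent_dim latent dimension D (default 64).
#' @param hidden_layers number of hidden layers per MLP (default 2).
#' @param hidden_width units per hidden layer (default 128).
#' @param target_head whether to attach the scalar target decoder.
#' @return Object of class `mvae_architecture`.
#' @export
mvae_architecture <- function(view_dims, latent_dim = 64, hidden_layers = 2,
                              hidden_width = 128, target_head = TRUE) {
  stopifnot(length(view_dims) >= 1, all(view_dims >= 1),
            is_count(latent_dim), is_count(hidden_layers), is_count(hidden_width))
  structure(list(view_dims = as.integer(view_dims),
                 latent_dim = as.integer(latent_dim),
                 hidden_layers = as.integer(hidden_layers),
                 hidden_width = as.integer(hidden_width),
                 target_head = isTRUE(target_head)),
            class = "mvae_architecture")
}

#' Training configuration
#'
#' Optimization settings for [train_mvae()]: adaptive-moment stochastic
#' gradient descent with seeded initialization, mini-batching and early
#' stopping on a validation fraction carved from the training subjects.
#'
#' @param epochs maximum epochs (default 400).
#' @param batch_size mini-batch size (default 64).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed integer seed fixing initialization, batching and sampling.
#' @param patience early-stopping patience in epochs (default 40).
#' @param val_fraction validation fraction of the training set (default 0.1).
#' @param kl_warmup epochs over which the KL weight is annealed linearly
#'   from 0 to 1 (default 100). Warm-up counters posterior collapse -- with
#'   a high-entropy Bernoulli reconstruction floor the KL term otherwise
#'   traps the encoder at an uninformative latent code; the optimized
#'   objective after warm-up is the unweighted loss. Early stopping starts
#'   after warm-up.
#' @param monitor early-stopping criterion evaluated on the validation
#'   subjects at the posterior mean: `"target"` (default when a target head
#'   is trained) keeps the parameters with the lowest validation target
#'   cross-entropy -- the quantity imputation actually uses -- while
#'   `"loss"` monitors the full unweighted objective.
#' @return Object of class `training_config`.
#' @export
training_config <- function(epochs = 400, batch_size = 64, learning_rate = 1e-3,
                            seed = 1, patience = 40, val_fraction = 0.1,
                            kl_warmup = 100, monitor = c("target", "loss")) {
  stopifnot(is_count(epochs), is_count(batch_size), learning_rate > 0,
            is_count(patience), is_fraction(val_fraction, 0, 0.5),
            kl_warmup >= 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 patience = as.integer(patience), val_fraction = val_fraction,
                 kl_warmup = as.integer(kl_warmup), monitor = match.arg(monitor)),
            class = "training_config")
}

LOGVAR_CLAMP <- 10
BCE_EPS <- 1e-7

sigmoid <- function(x) 1 / (1 + exp(-x))

mvae_init_params <- function(arch, seed) {
  with_seed(seed, {
    hid <- rep(arch$hidden_width, arch$hidden_layers)
    params <- list(
      enc_mu = lapply(arch$view_dims, function(d) mlp_init(d, hid, arch$latent_dim)),
      enc_lv = lapply(arch$view_dims, function(d)
        mlp_init(d, hid, arch$latent_dim, zero_last = TRUE)),
      dec = lapply(arch$view_dims, function(d) mlp_init(arch$latent_dim, hid, d))
    )
    if (arch$target_head) params$dec_y <- mlp_init(arch$latent_dim, hid, 1L)
    params
  })
}

#' Encode one view into its Gaussian posterior
#'
#' Runs the view's mean and log-variance MLPs; the log-variance output is
#' clamped to \[-10, 10\] and exponentiated, guaranteeing strictly positive
#' variance.
#'
#' @param x matrix of scaled features in `[0,1]` (subjects in rows) or a
#'   single feature vector.
#' @param view_params list with `enc_mu` and `enc_lv` MLPs for this view.
#' @return A [diag_gaussian()] (batched when `x` is a matrix).
#' @export
encode_view <- function(x, view_params) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(x) != nrow(view_params$enc_mu$W[[1]])) stop_config("view dimension mismatch")
  mu <- mlp_forward(view_params$enc_mu, x)$out
  lv <- clamp(mlp_forward(view_params$enc_lv, x)$out, -LOGVAR_CLAMP, LOGVAR_CLAMP)
  diag_gaussian(mu, exp(lv))
}

#' Decode the shared latent code into a view reconstruction
#'
#' Runs the view's decoder MLP and applies an elementwise sigmoid, so the
#' reconstruction lies in (0, 1) and matches the Bernoulli likelihood on
#' min-max-scaled features.
#'
#' @param z latent matrix (subjects in rows) or single latent vector.
#' @param decoder_params a decoder MLP.
#' @return Reconstruction matrix in (0, 1).
#' @export
decode_view <- function(z, decoder_params) {
  z <- if (is.matrix(z)) z else matrix(z, nrow = 1)
  if (ncol(z) != nrow(decoder_params$W[[1]])) stop_config("latent dimension mismatch")
  stats::plogis(mlp_forward(decoder_params, z)$out)
}

bce_sum <- function(x, xhat) {
  xh <- clamp(xhat, BCE_EPS, 1 - BCE_EPS)
  -sum(x * log(xh) + (1 - x) * log(1 - xh))
}

#' Negative evidence lower bound of the multi-view model
#'
#' The training objective: summed Bernoulli cross-entropy of every view
#' reconstruction and of the target prediction, plus the closed-form KL
#' divergence of the fused posterior from the standard-normal prior.
#' Reconstructions are clamped to `[1e-7, 1 - 1e-7]` before the logarithm.
#'
#' @param views list of scaled view matrices/vectors (entries in `[0,1]`).
#' @param target scaled target values in `[0,1]` (or `NULL` for no head).
#' @param reconstructions list of view reconstructions in (0, 1).
#' @param target_prediction predicted target in (0, 1) (or `NULL`).
#' @param q_joint fused posterior, a [diag_gaussian()].
#' @return Scalar loss (lower is better; minimizing maximizes the ELBO).
#' @export
elbo_loss <- function(views, target, reconstructions, target_prediction, q_joint) {
  stopifnot(length(views) == length(reconstructions))
  rec <- sum(mapply(function(x, xh) bce_sum(unlist(x), unlist(xh)),
                    views, reconstructions))
  if (!is.null(target)) rec <- rec + bce_sum(unlist(target), unlist(target_prediction))
  rec + kl_to_standard_normal(q_joint)
}

# --- joint forward / backward ----------------------------------------------

# One full forward pass over a batch. X_list: scaled view matrices (n x d_v);
# y: n-vector in [0,1] or NULL; eps: n x D noise (zero matrix => posterior
# mean). Returns per-subject mean loss and every intermediate needed by
# mvae_backward.
mvae_forward <- function(params, X_list, y, eps, beta = 1) {
  V <- length(X_list)
  n <- nrow(X_list[[1]])
  enc_mu_c <- enc_lv_c <- vector("list", V)
  mu <- var_ <- lv_raw <- vector("list", V)
  for (v in seq_len(V)) {
    enc_mu_c[[v]] <- mlp_forward(params$enc_mu[[v]], X_list[[v]])
    enc_lv_c[[v]] <- mlp_forward(params$enc_lv[[v]], X_list[[v]])
    lv_raw[[v]] <- enc_lv_c[[v]]$out
    lv <- clamp(lv_raw[[v]], -LOGVAR_CLAMP, LOGVAR_CLAMP)
    mu[[v]] <- enc_mu_c[[v]]$out
    var_[[v]] <- exp(lv)
  }
  prec <- Reduce(`+`, lapply(var_, function(s) 1 / s))
  var_z <- 1 / prec
  mu_z <- var_z * Reduce(`+`, mapply(function(m, s) m / s, mu, var_, SIMPLIFY = FALSE))
  z <- mu_z + sqrt(var_z) * eps

  dec_c <- vector("list", V)
  xhat <- vector("list", V)
  rec <- 0
  for (v in seq_len(V)) {
    dec_c[[v]] <- mlp_forward(params$dec[[v]], z)
    xhat[[v]] <- sigmoid(dec_c[[v]]$out)
    rec <- rec + bce_sum(X_list[[v]], xhat[[v]])
  }
  yhat <- NULL; decy_c <- NULL
  if (!is.null(params$dec_y) && !is.null(y)) {
    decy_c <- mlp_forward(params$dec_y, z)
    yhat <- sigmoid(decy_c$out)
    rec <- rec + bce_sum(y, yhat)
  }
  kl <- 0.5 * sum(mu_z^2 + var_z - log(var_z) - 1)
  list(loss = (rec + beta * kl) / n, rec = rec / n, kl = kl / n, beta = beta,
       enc_mu_c = enc_mu_c, enc_lv_c = enc_lv_c, dec_c = dec_c, decy_c = decy_c,
       mu = mu, var_ = var_, lv_raw = lv_raw, mu_z = mu_z, var_z = var_z,
       z = z, eps = eps, xhat = xhat, yhat = yhat, n = n)
}

# gradient of sigmoid + clamped BCE w.r.t. the decoder logits
bce_logit_grad <- function(x, s) {
  inside <- s > BCE_EPS & s < 1 - BCE_EPS
  (s - x) * inside
}

# Full backward pass matching mvae_forward; returns gradients with the same
# structure as `params`.
mvae_backward <- function(params, X_list, y, fw) {
  V <- length(X_list)
  n <- fw$n
  g <- list(enc_mu = vector("list", V), enc_lv = vector("list", V),
            dec = vector("list", V))
  dz <- matrix(0, n, ncol(fw$z))
  for (v in seq_len(V)) {
    dlogit <- bce_logit_grad(X_list[[v]], fw$xhat[[v]]) / n
    bk <- mlp_backward(params$dec[[v]], fw$dec_c[[v]], dlogit)
    g$dec[[v]] <- bk[c("W", "b")]
    dz <- dz + bk$dX
  }
  if (!is.null(fw$yhat)) {
    dlogit <- bce_logit_grad(matrix(y, ncol = 1), fw$yhat) / n
    bk <- mlp_backward(params$dec_y, fw$decy_c, dlogit)
    g$dec_y <- bk[c("W", "b")]
    dz <- dz + bk$dX
  }
  # KL term (weighted by the warm-up beta) and sampling path
  dmu_z <- dz + fw$beta * fw$mu_z / n
  dvar_z <- dz * fw$eps / (2 * sqrt(fw$var_z)) +
    fw$beta * 0.5 * (1 - 1 / fw$var_z) / n
  # product-of-experts backward
  for (v in seq_len(V)) {
    p_v <- 1 / fw$var_[[v]]
    dmu_v <- dmu_z * fw$var_z * p_v
    dp_v <- dmu_z * fw$var_z * (fw$mu[[v]] - fw$mu_z) - dvar_z * fw$var_z^2
    dvar_v <- -p_v^2 * dp_v
    dlv <- dvar_v * fw$var_[[v]] *
      (abs(fw$lv_raw[[v]]) < LOGVAR_CLAMP)  # clamp gradient gate
    bmu <- mlp_backward(params$enc_mu[[v]], fw$enc_mu_c[[v]], dmu_v)
    blv <- mlp_backward(params$enc_lv[[v]], fw$enc_lv_c[[v]], dlv)
    g$enc_mu[[v]] <- bmu[c("W", "b")]
    g$enc_lv[[v]] <- blv[c("W", "b")]
  }
  g
}

#' Train the multi-view variational autoencoder
#'
#' Minimizes the negative ELBO (view reconstructions + target prediction +
#' KL) by mini-batch Adam. One standard-normal noise draw per subject per
#' step samples the joint product-of-experts posterior. A validation
#' fraction of the training subjects is held out for early stopping; the
#' validation loss is evaluated at the posterior mean, making it
#' deterministic. Everything (initialization, batching, noise, validation
#' split) is fixed by `cfg$seed`.
#'
#' @param views list of scaled view matrices (training subjects in rows).
#' @param target scaled target vector in `[0,1]` (no missing values), or
#'   `NULL` to train without the target head.
#' @param arch an [mvae_architecture()].
#' @param cfg a [training_config()].
#' @return Object of class `mvae_model`: list with `params`, `arch`,
#'   `history` (per-epoch train/validation loss), `best_epoch`,
#'   `final_loss`, `seed`.
#' @export
train_mvae <- function(views, target, arch, cfg = training_config()) {
  stopifnot(inherits(arch, "mvae_architecture"), inherits(cfg, "training_config"))
  views <- lapply(views, as.matrix)
  n <- nrow(views[[1]])
  stopifnot(all(vapply(views, nrow, integer(1)) == n))
  if (!is.null(target)) {
    target <- as.numeric(target)
    if (anyNA(target)) stop_config("missing target values among training subjects")
    stopifnot(length(target) == n)
  }
  D <- arch$latent_dim
  params <- mvae_init_params(arch, cfg$seed)
  init_params <- params

  with_seed(derive_seed(cfg$seed, 1L), {
    n_val <- max(0L, min(n - 2L, floor(cfg$val_fraction * n)))
    val_idx <- if (n_val > 0) sort(sample.int(n, n_val)) else integer()
    tr_idx <- setdiff(seq_len(n), val_idx)
    Xtr <- lapply(views, function(m) m[tr_idx, , drop = FALSE])
    ytr <- if (is.null(target)) NULL else target[tr_idx]
    Xval <- lapply(views, function(m) m[val_idx, , drop = FALSE])
    yval <- if (is.null(target)) NULL else target[val_idx]
    ntr <- length(tr_idx)

    opt <- adam_init(params)
    best <- list(loss = Inf, params = params, epoch = 0L)
    hist <- data.frame(epoch = integer(), train_loss = numeric(),
                       val_loss = numeric())
    wait <- 0L
    for (epoch in seq_len(cfg$epochs)) {
      beta <- if (cfg$kl_warmup > 0) min(1, epoch / cfg$kl_warmup) else 1
      ord <- sample.int(ntr)
      tot <- 0
      nb <- 0
      for (start in seq(1, ntr, by = cfg$batch_size)) {
        b <- ord[start:min(start + cfg$batch_size - 1, ntr)]
        Xb <- lapply(Xtr, function(m) m[b, , drop = FALSE])
        yb <- if (is.null(ytr)) NULL else ytr[b]
        eps <- matrix(stats::rnorm(length(b) * D), length(b), D)
        fw <- mvae_forward(params, Xb, yb, eps, beta = beta)
        if (!is.finite(fw$loss)) {
          stop_config("training aborted: non-finite loss at epoch %d (lr too high?)", epoch)
        }
        gr <- mvae_backward(params, Xb, yb, fw)
        st <- adam_step(params, gr, opt, lr = cfg$learning_rate)
        params <- st$params
        opt <- st$state
        tot <- tot + fw$loss
        nb <- nb + 1
      }
      use_target <- identical(cfg$monitor, "target") && !is.null(target) &&
        !is.null(params$dec_y)
      vloss <- if (n_val > 0) {
        fv <- mvae_forward(params, Xval, yval, matrix(0, length(val_idx), D))
        if (use_target) bce_sum(yval, fv$yhat) / length(val_idx) else fv$loss
      } else {
        # no validation split: monitor the deterministic (posterior-mean)
        # loss over the training subjects
        fv <- mvae_forward(params, Xtr, ytr, matrix(0, ntr, D))
        if (use_target) bce_sum(ytr, fv$yhat) / ntr else fv$loss
      }
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tot / nb,
                                     val_loss = vloss))
      if (vloss < best$loss - 1e-9) {
        best <- list(loss = vloss, params = params, epoch = epoch)
        wait <- 0L
      } else if (epoch > cfg$kl_warmup) {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  })
  structure(list(params = best$params, init_params = init_params, arch = arch,
                 history = hist, best_epoch = best$epoch,
                 final_loss = best$loss, seed = cfg$seed),
            class = "mvae_model")
}

#' @export
print.mvae_model <- function(x, ...) {
  cat(sprintf("mvae_model: %d views (%s) -> latent %d; best epoch %d, val loss %.4f\n",
              length(x$arch$view_dims), paste(x$arch$view_dims, collapse = "+"),
              x$arch$latent_dim, x$best_epoch, x$final_loss))
  invisible(x)
}

#' Impute the target from scaled views
#'
#' Encodes every view, fuses the posteriors by product of experts, and
#' decodes the target head from the posterior mean (no sampling), so
#' inference is deterministic.
#'
#' @param model a trained [train_mvae()] model (or a raw parameter list with
#'   an `arch` attribute-compatible structure).
#' @param views list of scaled view matrices (subjects in rows), in the same
#'   order as at training time.
#' @param mc_samples 0 (default) decodes the posterior mean; a positive
#'   count instead averages predictions over that many seeded posterior
#'   draws (Monte-Carlo inference).
#' @param mc_seed seed for the Monte-Carlo draws.
#' @return Vector of scaled predictions in (0, 1).
#' @export
impute_target <- function(model, views, mc_samples = 0, mc_seed = 1) {
  params <- if (inherits(model, "mvae_model")) model$params else model
  if (is.null(params$dec_y)) stop_config("model has no target head")
  views <- lapply(views, as.matrix)
  if (length(views) != length(params$enc_mu)) stop_config("missing view")
  experts <- lapply(seq_along(views), function(v) {
    encode_view(views[[v]], list(enc_mu = params$enc_mu[[v]],
                                 enc_lv = params$enc_lv[[v]]))
  })
  q <- poe_combine(experts)
  mu_z <- if (is.matrix(q$mean)) q$mean else matrix(q$mean, nrow = 1)
  if (mc_samples > 0) {
    sd_z <- sqrt(if (is.matrix(q$var)) q$var else matrix(q$var, nrow = 1))
    with_seed(mc_seed, {
      acc <- 0
      for (s in seq_len(mc_samples)) {
        z <- mu_z + sd_z * matrix(stats::rnorm(length(mu_z)), nrow(mu_z))
        acc <- acc + decode_view(z, params$dec_y)
      }
    })
    return(as.numeric(acc / mc_samples))
  }
  as.numeric(decode_view(mu_z, params$dec_y))
}

#' Save / load an MVAE model checkpoint
#'
#' Serializes architecture and parameters to a plain-JSON checkpoint that
#' round-trips bit-exactly (numbers are stored at full precision).
#'
#' @param model an `mvae_model`.
#' @param path file path.
#' @return `save_mvae` returns `path` invisibly; `load_mvae` the model.
#' @export
save_mvae <- function(model, path) {
  stopifnot(inherits(model, "mvae_model"))
  # numeric leaves are written as 17-significant-digit strings, which
  # round-trip IEEE doubles exactly
  encode <- function(x) {
    if (is.matrix(x)) list(shape = dim(x), data = sprintf("%.17g", x))
    else if (is.numeric(x)) list(shape = NULL, data = sprintf("%.17g", x))
    else lapply(x, encode)
  }
  payload <- list(arch = unclass(model$arch), params = encode(model$params),
                  best_epoch = model$best_epoch, final_loss = model$final_loss,
                  seed = model$seed)
  jsonlite::write_json(payload, path, auto_unbox = FALSE, null = "null",
                       digits = NA)
  invisible(path)
}

#' @rdname save_mvae
#' @export
load_mvae <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  decode <- function(x) {
    if (is.list(x) && !is.null(names(x)) && "data" %in% names(x)) {
      v <- as.numeric(unlist(x$data))
      if (length(x$shape)) matrix(v, x$shape[[1]], x$shape[[2]]) else v
    } else {
      lapply(x, decode)
    }
  }
  arch <- do.call(mvae_architecture,
                  lapply(payload$arch, function(a) unlist(a)))
  structure(list(params = decode(payload$params), arch = arch,
                 history = NULL, best_epoch = unlist(payload$best_epoch),
                 final_loss = as.numeric(unlist(payload$final_loss)),
                 seed = unlist(payload$seed)),
            class = "mvae_model")
}
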