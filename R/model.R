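# Conditional generator and conditional Wasserstein critic.
#
# The generator maps a protein (trigram-index-encoded sequence, or a
# hand-crafted feature vector) to an assignment vector of per-term scores in
# [0, 1].  The critic scores (protein, assignment) pairs with an unbounded
# scalar; its 1-Lipschitz constraint is enforced softly through a gradient
# penalty evaluated at random interpolates between real and generated
# assignment vectors.  Both networks are explicit computation graphs with
# hand-written backward passes; the gradient penalty needs a second backward
# pass through the critic's own input-gradient, which is implemented in
# closed form below (LeakyReLU networks are piecewise linear, so activation
# masks are locally constant and the double-backward only touches the weight
# matrices of the label branch and trunk).

.pool_len <- function(Lc, size, stride) {
  if (Lc < size) 1L else (Lc - size) %/% stride + 1L
}

#' Generator configuration
#'
#' @param mode `"sequence"` (trigram front end: embedding, dropout, 32
#'   1-D convolution filters, LeakyReLU, average pooling, two dense layers,
#'   Tanh output rescaled to `[0, 1]`) or `"feature"` (three dense LeakyReLU
#'   layers and a Tanh output).
#' @param n_terms number of GO terms `c` (output width).
#' @param max_positions trigram positions per sequence (default 1000).
#' @param vocab index vocabulary: 8000 trigram codes plus the padding code.
#' @param embed_dim embedding width (default 128).
#' @param dropout_rate dropout on the embedding (default 0.2); this is what
#'   makes the generator stochastic during adversarial training.
#' @param n_filters,kernel_size 1-D convolution bank (defaults 32 and 8).
#' @param pool_size,pool_stride average pooling geometry (defaults 64, 32).
#' @param dense_sizes hidden dense widths: two values in sequence mode
#'   (default 512, 256), three in feature mode (default 512, 256, 128).
#' @param feature_dim input dimension in feature mode (e.g. 258).
#' @param alpha LeakyReLU negative slope (default 0.2).
#' @return A `generator_config` list.
#' @export
generator_config <- function(mode = c("sequence", "feature"), n_terms,
                             max_positions = 1000L, vocab = 8001L,
                             embed_dim = 128L, dropout_rate = 0.2,
                             n_filters = 32L, kernel_size = 8L,
                             pool_size = 64L, pool_stride = 32L,
                             dense_sizes = NULL, feature_dim = NULL,
                             alpha = 0.2) {
  mode <- match.arg(mode)
  if (n_terms < 1L) stop("n_terms must be positive")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  if (is.null(dense_sizes))
    dense_sizes <- if (mode == "sequence") c(512L, 256L) else c(512L, 256L, 128L)
  if (mode == "sequence" && length(dense_sizes) != 2L)
    stop("sequence mode takes two dense sizes")
  if (mode == "feature") {
    if (length(dense_sizes) != 3L) stop("feature mode takes three dense sizes")
    if (is.null(feature_dim)) stop("feature mode needs feature_dim")
  }
  cfg <- list(mode = mode, n_terms = as.integer(n_terms),
              max_positions = as.integer(max_positions),
              vocab = as.integer(vocab), embed_dim = as.integer(embed_dim),
              dropout_rate = dropout_rate, n_filters = as.integer(n_filters),
              kernel_size = as.integer(kernel_size),
              pool_size = as.integer(pool_size),
              pool_stride = as.integer(pool_stride),
              dense_sizes = as.integer(dense_sizes),
              feature_dim = if (is.null(feature_dim)) NULL else as.integer(feature_dim),
              alpha = alpha)
  if (mode == "sequence") {
    cfg$conv_len <- cfg$max_positions - cfg$kernel_size + 1L
    if (cfg$conv_len < 1L) stop("kernel_size exceeds max_positions")
    cfg$pooled_len <- .pool_len(cfg$conv_len, cfg$pool_size, cfg$pool_stride)
  }
  structure(cfg, class = "generator_config")
}

#' Critic (discriminator) configuration
#'
#' The condition branch repeats the generator front end (same layer shapes,
#' separate parameters) followed by one dense layer; the assignment vector
#' passes through one dense layer; both feature vectors are concatenated and
#' sent through five dense LeakyReLU layers to a single linear output neuron
#' (no final activation: a Wasserstein critic).
#'
#' @param generator the matching [generator_config()]; front-end geometry and
#'   `n_terms` are taken from it.
#' @param label_branch_size width of the dense layer over assignment vectors.
#' @param cond_size width of the dense layer closing the condition branch.
#' @param trunk_sizes widths of the five trunk layers.
#' @return A `discriminator_config` list.
#' @export
discriminator_config <- function(generator, label_branch_size = 256L,
                                 cond_size = 256L,
                                 trunk_sizes = c(512L, 256L, 128L, 64L, 32L)) {
  if (!inherits(generator, "generator_config"))
    stop("`generator` must be a generator_config")
  if (length(trunk_sizes) != 5L) stop("the trunk has exactly 5 dense layers")
  cfg <- unclass(generator)
  cfg$label_branch_size <- as.integer(label_branch_size)
  cfg$cond_size <- as.integer(cond_size)
  cfg$trunk_sizes <- as.integer(trunk_sizes)
  structure(cfg, class = "discriminator_config")
}

#' Initialise generator parameters
#'
#' Weights are He-uniform, biases zero.  The embedding table is stored
#' channels-first (`embed_dim` x `vocab`) and its padding column is fixed at
#' zero (it never receives gradient), so model output is independent of the
#' amount of right-padding.  Uses the caller's RNG state.
#'
#' @param config a [generator_config()].
#' @return Named list of parameter matrices.
#' @export
init_generator <- function(config) {
  cfg <- config
  if (cfg$mode == "sequence") {
    E <- matrix(runif(cfg$vocab * cfg$embed_dim, -0.05, 0.05),
                cfg$embed_dim, cfg$vocab)
    E[, 1L] <- 0
    flat <- cfg$pooled_len * cfg$n_filters
    d <- cfg$dense_sizes
    list(E = E,
         Wc = .init_mat(cfg$kernel_size * cfg$embed_dim, cfg$n_filters),
         bc = numeric(cfg$n_filters),
         W1 = .init_mat(flat, d[1]), b1 = numeric(d[1]),
         W2 = .init_mat(d[1], d[2]), b2 = numeric(d[2]),
         W3 = .init_mat(d[2], cfg$n_terms), b3 = numeric(cfg$n_terms))
  } else {
    d <- cfg$dense_sizes
    list(W1 = .init_mat(cfg$feature_dim, d[1]), b1 = numeric(d[1]),
         W2 = .init_mat(d[1], d[2]), b2 = numeric(d[2]),
         W3 = .init_mat(d[2], d[3]), b3 = numeric(d[3]),
         W4 = .init_mat(d[3], cfg$n_terms), b4 = numeric(cfg$n_terms))
  }
}

#' Initialise critic parameters
#'
#' @param config a [discriminator_config()].
#' @return Named list of parameter matrices.
#' @export
init_discriminator <- function(config) {
  cfg <- config
  par <- list()
  if (cfg$mode == "sequence") {
    E <- matrix(runif(cfg$vocab * cfg$embed_dim, -0.05, 0.05),
                cfg$embed_dim, cfg$vocab)
    E[, 1L] <- 0
    par$E <- E
    par$Wc <- .init_mat(cfg$kernel_size * cfg$embed_dim, cfg$n_filters)
    par$bc <- numeric(cfg$n_filters)
    par$Wf <- .init_mat(cfg$pooled_len * cfg$n_filters, cfg$cond_size)
  } else {
    par$Wf <- .init_mat(cfg$feature_dim, cfg$cond_size)
  }
  par$bf <- numeric(cfg$cond_size)
  par$Wy <- .init_mat(cfg$n_terms, cfg$label_branch_size)
  par$by <- numeric(cfg$label_branch_size)
  widths <- c(cfg$label_branch_size + cfg$cond_size, cfg$trunk_sizes)
  for (i in 1:5) {
    par[[paste0("Wt", i)]] <- .init_mat(widths[i], widths[i + 1])
    par[[paste0("bt", i)]] <- numeric(widths[i + 1])
  }
  par$wo <- .init_mat(cfg$trunk_sizes[5], 1L)
  par$bo <- 0
  par
}

# Coerce user input into the matrix form the forward passes expect.
.as_model_input <- function(config, x) {
  if (config$mode == "sequence") {
    if (inherits(x, "trigram_encoding")) x <- x$indices
    if (!is.matrix(x)) stop("sequence mode expects an index matrix")
    if (nrow(x) > config$max_positions)
      stop("input has more positions than config$max_positions")
    if (any(x < 0L) || any(x >= config$vocab))
      stop("trigram indices out of range for the configured vocabulary")
    storage.mode(x) <- "integer"
  } else {
    if (inherits(x, "trigram_encoding"))
      stop("feature mode cannot take a trigram encoding")
    x <- as.matrix(x)
    if (ncol(x) != config$feature_dim)
      stop("feature matrix has ", ncol(x), " columns; config expects ",
           config$feature_dim)
    storage.mode(x) <- "double"
  }
  x
}

# drop all-padding tail rows; the conv kernel re-pads explicitly
.trim_idx <- function(idx) {
  nz <- which(rowSums(idx != 0L) > 0L)
  Lb <- if (length(nz)) max(nz) else 1L
  idx[seq_len(Lb), , drop = FALSE]
}

.gen_fwd <- function(par, cfg, x, stochastic) {
  if (cfg$mode == "sequence") .gen_fwd_seq(par, cfg, x, stochastic)
  else .gen_fwd_feat(par, cfg, x, stochastic)
}

.gen_fwd_seq <- function(par, cfg, idx, stochastic) {
  idx <- .trim_idx(idx)
  n <- ncol(idx)
  k <- cfg$kernel_size
  rate <- if (stochastic && cfg$dropout_rate > 0) cfg$dropout_rate else 0
  u <- if (rate > 0) runif(nrow(idx) * cfg$embed_dim * n) else numeric(0)
  X <- embed_fwd(idx, par$E, k - 1L, u, rate)
  Zc <- conv1d_fwd(X, par$Wc, par$bc, k, cfg$conv_len)
  P <- avgpool_lrelu_fwd(Zc, cfg$alpha, cfg$pool_size, cfg$pool_stride)
  H0 <- t(matrix(P, ncol = n))
  f1 <- .dense_fwd(H0, par$W1, par$b1, cfg$alpha)
  f2 <- .dense_fwd(f1$out, par$W2, par$b2, cfg$alpha)
  f3 <- .dense_fwd(f2$out, par$W3, par$b3, linear = TRUE)
  Tt <- tanh(f3$pre)
  list(yhat = (Tt + 1) / 2,
       cache = list(idx = idx, X = X, u = u, rate = rate, Zc = Zc,
                    f1 = f1, f2 = f2, f3 = f3, Tt = Tt, n = n))
}

.gen_bwd_seq <- function(par, cfg, cache, dY) {
  dpre <- dY * 0.5 * (1 - cache$Tt^2)
  g3 <- .dense_bwd(cache$f3, par$W3, dpre, linear = TRUE)
  g2 <- .dense_bwd(cache$f2, par$W2, g3$dInp, cfg$alpha)
  g1 <- .dense_bwd(cache$f1, par$W1, g2$dInp, cfg$alpha)
  dP <- array(t(g1$dInp), dim = c(cfg$pooled_len, cfg$n_filters, cache$n))
  dZc <- avgpool_lrelu_bwd(dP, cache$Zc, cfg$alpha, cfg$pool_size,
                           cfg$pool_stride)
  cb <- conv1d_bwd(cache$X, par$Wc, dZc, cfg$kernel_size)
  dE <- embed_bwd(cache$idx, cb$dX, cache$u, cache$rate, ncol(par$E))
  list(E = dE, Wc = cb$dW, bc = as.numeric(cb$db),
       W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db,
       W3 = g3$dW, b3 = g3$db)
}

.gen_fwd_feat <- function(par, cfg, x, stochastic) {
  if (stochastic && cfg$dropout_rate > 0)
    x <- .dropout(x, cfg$dropout_rate)$X
  f1 <- .dense_fwd(x, par$W1, par$b1, cfg$alpha)
  f2 <- .dense_fwd(f1$out, par$W2, par$b2, cfg$alpha)
  f3 <- .dense_fwd(f2$out, par$W3, par$b3, cfg$alpha)
  f4 <- .dense_fwd(f3$out, par$W4, par$b4, linear = TRUE)
  Tt <- tanh(f4$pre)
  list(yhat = (Tt + 1) / 2,
       cache = list(f1 = f1, f2 = f2, f3 = f3, f4 = f4, Tt = Tt, n = nrow(x)))
}

.gen_bwd_feat <- function(par, cfg, cache, dY) {
  dpre <- dY * 0.5 * (1 - cache$Tt^2)
  g4 <- .dense_bwd(cache$f4, par$W4, dpre, linear = TRUE)
  g3 <- .dense_bwd(cache$f3, par$W3, g4$dInp, cfg$alpha)
  g2 <- .dense_bwd(cache$f2, par$W2, g3$dInp, cfg$alpha)
  g1 <- .dense_bwd(cache$f1, par$W1, g2$dInp, cfg$alpha)
  list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db,
       W3 = g3$dW, b3 = g3$db, W4 = g4$dW, b4 = g4$db)
}

.gen_bwd <- function(par, cfg, cache, dY) {
  if (cfg$mode == "sequence") .gen_bwd_seq(par, cfg, cache, dY)
  else .gen_bwd_feat(par, cfg, cache, dY)
}

#' Generator forward pass
#'
#' @param config a [generator_config()].
#' @param params parameters from [init_generator()] (or trained).
#' @param x a `trigram_encoding`, an index matrix (positions x proteins), or
#'   a feature matrix (proteins x d), matching `config$mode`.
#' @param stochastic keep dropout active (TRUE during adversarial training);
#'   with `FALSE` the pass is deterministic.
#' @return Score matrix, proteins x `n_terms`, entries in `[0, 1]`.
#' @export
generator_forward <- function(config, params, x, stochastic = FALSE) {
  x <- .as_model_input(config, x)
  .gen_fwd(params, config, x, stochastic)$yhat
}

# ---- critic ----------------------------------------------------------------

# Condition branch of the critic.  Deliberately deterministic (no dropout):
# the gradient penalty constrains the critic as a fixed function, which a
# stochastic critic would blur.
.d_cond_fwd <- function(par, cfg, x) {
  if (cfg$mode == "sequence") {
    idx <- .trim_idx(x)
    n <- ncol(idx)
    k <- cfg$kernel_size
    X <- embed_fwd(idx, par$E, k - 1L, numeric(0), 0)
    Zc <- conv1d_fwd(X, par$Wc, par$bc, k, cfg$conv_len)
    P <- avgpool_lrelu_fwd(Zc, cfg$alpha, cfg$pool_size, cfg$pool_stride)
    H0 <- t(matrix(P, ncol = n))
    fd <- .dense_fwd(H0, par$Wf, par$bf, cfg$alpha)
    list(Fc = fd$out,
         cache = list(idx = idx, X = X, Zc = Zc, fd = fd, n = n))
  } else {
    fd <- .dense_fwd(x, par$Wf, par$bf, cfg$alpha)
    list(Fc = fd$out, cache = list(fd = fd, n = nrow(x)))
  }
}

.d_cond_bwd <- function(par, cfg, cache, dFc) {
  gf <- .dense_bwd(cache$fd, par$Wf, dFc, cfg$alpha)
  if (cfg$mode != "sequence")
    return(list(Wf = gf$dW, bf = gf$db))
  dP <- array(t(gf$dInp), dim = c(cfg$pooled_len, cfg$n_filters, cache$n))
  dZc <- avgpool_lrelu_bwd(dP, cache$Zc, cfg$alpha, cfg$pool_size,
                           cfg$pool_stride)
  cb <- conv1d_bwd(cache$X, par$Wc, dZc, cfg$kernel_size)
  dE <- embed_bwd(cache$idx, cb$dX, numeric(0), 0, ncol(par$E))
  list(E = dE, Wc = cb$dW, bc = as.numeric(cb$db), Wf = gf$dW, bf = gf$db)
}

.d_head_fwd <- function(par, cfg, Y, Fc) {
  fy <- .dense_fwd(Y, par$Wy, par$by, cfg$alpha)
  inp <- cbind(fy$out, Fc)
  trunk <- vector("list", 5L)
  for (i in 1:5) {
    trunk[[i]] <- .dense_fwd(inp, par[[paste0("Wt", i)]],
                             par[[paste0("bt", i)]], cfg$alpha)
    inp <- trunk[[i]]$out
  }
  out <- .add_bias(inp %*% par$wo, par$bo)
  list(out = as.numeric(out),
       cache = list(fy = fy, trunk = trunk, Ztop = inp,
                    hy = ncol(fy$out), n = nrow(Y)))
}

.d_head_bwd <- function(par, cfg, cache, dout) {
  dcol <- matrix(dout, ncol = 1L)
  grads <- list(wo = crossprod(cache$Ztop, dcol), bo = sum(dout))
  dcur <- dcol %*% t(par$wo)
  for (i in 5:1) {
    g <- .dense_bwd(cache$trunk[[i]], par[[paste0("Wt", i)]], dcur, cfg$alpha)
    grads[[paste0("Wt", i)]] <- g$dW
    grads[[paste0("bt", i)]] <- g$db
    dcur <- g$dInp
  }
  hy <- cache$hy
  dA <- dcur[, seq_len(hy), drop = FALSE]
  dFc <- dcur[, -seq_len(hy), drop = FALSE]
  gy <- .dense_bwd(cache$fy, par$Wy, dA, cfg$alpha)
  grads$Wy <- gy$dW
  grads$by <- gy$db
  list(grads = grads, dFc = dFc, dY = gy$dInp)
}

# Gradient penalty at the points captured in a head cache: value, per-sample
# input-gradient norms, and the penalty's gradient with respect to the critic
# weights.  LeakyReLU activation masks are locally constant, so the critic's
# input-gradient is the multilinear chain below and the double-backward only
# produces gradients for the weight matrices it contains (label branch,
# trunk, output); biases and the condition branch receive zero almost
# everywhere.
.gp_grads <- function(par, cfg, cache, lambda2) {
  n <- cache$n
  hy <- cache$hy
  alpha <- cfg$alpha
  My <- .lrelu_mask(cache$fy$pre, alpha)
  M <- lapply(cache$trunk, function(f) .lrelu_mask(f$pre, alpha))
  # input-gradient chain  g = dD/dy  per sample
  D <- matrix(par$wo[, 1L], n, length(par$wo[, 1L]), byrow = TRUE)
  C <- vector("list", 5L)
  for (i in 5:1) {
    C[[i]] <- M[[i]] * D
    D <- C[[i]] %*% t(par[[paste0("Wt", i)]])
  }
  Da <- D[, seq_len(hy), drop = FALSE]
  Cy <- My * Da
  G <- Cy %*% t(par$Wy)
  norms <- sqrt(rowSums(G * G))
  penalty <- mean((norms - 1)^2)
  # reverse pass through the (linear) chain above
  U <- ((2 / n) * (norms - 1) / pmax(norms, 1e-12)) * G
  grads <- list(Wy = crossprod(U, Cy))
  hatC <- My * (U %*% par$Wy)
  hatD <- cbind(hatC, matrix(0, n, ncol(D) - hy))
  for (i in 1:5) {
    grads[[paste0("Wt", i)]] <- crossprod(hatD, C[[i]])
    hatD <- M[[i]] * (hatD %*% par[[paste0("Wt", i)]])
  }
  grads$wo <- matrix(colSums(hatD), ncol = 1L)
  if (lambda2 != 1) grads <- lapply(grads, function(g) lambda2 * g)
  list(penalty = penalty, norms = norms, grads = grads)
}

#' Critic forward pass
#'
#' Scores a batch of (protein, assignment-vector) pairs; unbounded real
#' output (Wasserstein critic, no final activation).
#'
#' @param config a [discriminator_config()].
#' @param params parameters from [init_discriminator()] (or trained).
#' @param x protein inputs as in [generator_forward()].
#' @param y assignment matrix (proteins x `n_terms`), scores or binary.
#' @return Numeric vector of critic scores, one per protein.
#' @export
discriminator_forward <- function(config, params, x, y) {
  x <- .as_model_input(config, x)
  y <- as.matrix(y)
  if (ncol(y) != config$n_terms)
    stop("assignment vectors have ", ncol(y), " terms; config expects ",
         config$n_terms)
  cond <- .d_cond_fwd(params, config, x)
  .d_head_fwd(params, config, y, cond$Fc)$out
}

.bce <- function(y, yhat, eps = 1e-7) {
  yc <- pmin(pmax(yhat, eps), 1 - eps)
  -mean(y * log(yc) + (1 - y) * log(1 - yc))
}

.bce_grad <- function(y, yhat, eps = 1e-7) {
  inside <- yhat > eps & yhat < 1 - eps
  g <- (yhat - y) / (yhat * (1 - yhat) * length(y))
  g[!inside] <- 0
  g
}

.check_binary <- function(y) {
  y <- as.matrix(y)
  if (!all(y %in% c(0, 1))) stop("y_true must be binary")
  storage.mode(y) <- "double"
  y
}

#' Generator loss
#'
#' Mean binary cross-entropy between the generated assignment vector and the
#' ground truth, minus `lambda1` times the critic's mean score of the
#' generated pair (the generator's Wasserstein term).  With `lambda1 = 0`
#' this is exactly the BCE objective of the PFP-S ablation.
#'
#' @param d_config,d_params critic configuration and parameters (may be NULL
#'   when `lambda1 = 0`).
#' @param g_config,g_params generator configuration and parameters.
#' @param x protein batch.
#' @param y_true binary annotation matrix for the batch.
#' @param lambda1 weight of the adversarial term (>= 0).
#' @param stochastic generator dropout flag.
#' @return Scalar loss, with attributes `bce` and `wasserstein`.
#' @export
generator_loss <- function(d_config, d_params, g_config, g_params, x, y_true,
                           lambda1, stochastic = FALSE) {
  if (lambda1 < 0) stop("lambda1 must be >= 0")
  y_true <- .check_binary(y_true)
  x <- .as_model_input(g_config, x)
  yhat <- .gen_fwd(g_params, g_config, x, stochastic)$yhat
  bce <- .bce(y_true, yhat)
  wass <- 0
  if (lambda1 > 0) {
    cond <- .d_cond_fwd(d_params, d_config, x)
    wass <- mean(.d_head_fwd(d_params, d_config, yhat, cond$Fc)$out)
  }
  structure(bce - lambda1 * wass, bce = bce, wasserstein = wass)
}

#' Critic loss with gradient penalty
#'
#' `mean D(x, G(x)) - mean D(x, y_true) + lambda2 * mean (||grad_y D(x, yt)||
#' - 1)^2`, where `yt = eps * y_true + (1 - eps) * G(x)` per sample, `eps`
#' uniform on `[0, 1]`, and the gradient is taken with respect to the
#' interpolated assignment vector only (real and fake pairs share the same
#' condition `x`).
#'
#' @inheritParams generator_loss
#' @param lambda2 gradient-penalty weight (>= 0).
#' @param eps optional vector of interpolation draws (one per protein); drawn
#'   uniformly when NULL.
#' @param y_fake optional fixed fake batch overriding `G(x)` (diagnostics).
#' @return Scalar loss with attributes `wasserstein`, `penalty` and
#'   `grad_norms` (per-sample critic gradient norms at the interpolates).
#' @export
discriminator_loss <- function(d_config, d_params, g_config, g_params, x,
                               y_true, lambda2, eps = NULL, y_fake = NULL,
                               stochastic = FALSE) {
  if (lambda2 < 0) stop("lambda2 must be >= 0")
  y_true <- .check_binary(y_true)
  x <- .as_model_input(d_config, x)
  if (is.null(y_fake))
    y_fake <- .gen_fwd(g_params, g_config, x, stochastic)$yhat
  n <- nrow(y_true)
  if (is.null(eps)) eps <- runif(n)
  cond <- .d_cond_fwd(d_params, d_config, x)
  out_f <- .d_head_fwd(d_params, d_config, y_fake, cond$Fc)$out
  out_r <- .d_head_fwd(d_params, d_config, y_true, cond$Fc)$out
  ytil <- eps * y_true + (1 - eps) * y_fake
  head_i <- .d_head_fwd(d_params, d_config, ytil, cond$Fc)
  gp <- .gp_grads(d_params, d_config, head_i$cache, lambda2 = 1)
  structure(mean(out_f) - mean(out_r) + lambda2 * gp$penalty,
            wasserstein = mean(out_f) - mean(out_r),
            penalty = gp$penalty, grad_norms = gp$norms)
}

# one full critic update step: returns loss pieces and parameter grads
.critic_step_grads <- function(d_par, d_cfg, g_par, g_cfg, x, y_true, lambda2,
                               eps, stochastic = TRUE) {
  y_fake <- .gen_fwd(g_par, g_cfg, x, stochastic)$yhat
  n <- nrow(y_true)
  cond <- .d_cond_fwd(d_par, d_cfg, x)
  hf <- .d_head_fwd(d_par, d_cfg, y_fake, cond$Fc)
  hr <- .d_head_fwd(d_par, d_cfg, y_true, cond$Fc)
  ytil <- eps * y_true + (1 - eps) * y_fake
  hi <- .d_head_fwd(d_par, d_cfg, ytil, cond$Fc)
  gp <- .gp_grads(d_par, d_cfg, hi$cache, lambda2)
  bf <- .d_head_bwd(d_par, d_cfg, hf$cache, rep(1 / n, n))
  br <- .d_head_bwd(d_par, d_cfg, hr$cache, rep(-1 / n, n))
  grads <- Map(`+`, bf$grads, br$grads)
  for (k in names(gp$grads)) grads[[k]] <- grads[[k]] + gp$grads[[k]]
  cgrads <- .d_cond_bwd(d_par, d_cfg, cond$cache, bf$dFc + br$dFc)
  grads <- c(grads, cgrads)
  list(grads = grads,
       loss = mean(hf$out) - mean(hr$out) + lambda2 * gp$penalty,
       wasserstein = mean(hf$out) - mean(hr$out),
       penalty = gp$penalty, grad_norm = mean(gp$norms))
}

# one generator update step (lambda1 = 0 gives the PFP-S / pure-BCE update)
.gen_step_grads <- function(d_par, d_cfg, g_par, g_cfg, x, y_true, lambda1,
                            stochastic = TRUE) {
  fw <- .gen_fwd(g_par, g_cfg, x, stochastic)
  yhat <- fw$yhat
  bce <- .bce(y_true, yhat)
  dY <- .bce_grad(y_true, yhat)
  wass <- 0
  if (lambda1 > 0) {
    n <- nrow(y_true)
    cond <- .d_cond_fwd(d_par, d_cfg, x)
    hf <- .d_head_fwd(d_par, d_cfg, yhat, cond$Fc)
    wass <- mean(hf$out)
    dY <- dY - lambda1 * .d_head_bwd(d_par, d_cfg, hf$cache, rep(1 / n, n))$dY
  }
  grads <- .gen_bwd(g_par, g_cfg, fw$cache, dY)
  list(grads = grads, loss = bce - lambda1 * wass, bce = bce,
       wasserstein = wass)
}
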