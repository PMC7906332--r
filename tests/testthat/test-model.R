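test_that("generator forward respects shape, range and determinism contracts", {
  set.seed(41)
  cfg <- tiny_gen_config(n_terms = 30L)
  par <- init_generator(cfg)
  idx <- random_idx_batch(6)
  out <- generator_forward(cfg, par, idx)
  expect_equal(dim(out), c(6L, 30L))
  expect_true(all(out >= 0 & out <= 1))
  expect_identical(out, generator_forward(cfg, par, idx))
  # dropout draws differ between stochastic calls
  s1 <- generator_forward(cfg, par, idx, stochastic = TRUE)
  s2 <- generator_forward(cfg, par, idx, stochastic = TRUE)
  expect_false(identical(s1, s2))
})

test_that("an all-padding input yields (tanh(bias)+1)/2 at every term", {
  set.seed(42)
  cfg <- tiny_gen_config()
  par <- init_generator(cfg)
  idx <- matrix(0L, cfg$max_positions, 3L)
  out <- generator_forward(cfg, par, idx)
  # zero-initialised output bias: exactly 0.5 everywhere
  expect_equal(unname(out), matrix(0.5, 3, 4))
  par$b3 <- c(0.3, -0.2, 1, 0)
  out2 <- generator_forward(cfg, par, idx)
  # padding embeds to zero and conv/pool/dense biases are zero at init,
  # so only the output bias b3 survives
  for (i in 1:3)
    expect_equal(unname(out2[i, ]), (tanh(par$b3) + 1) / 2)
})

test_that("predictions are invariant to the amount of right-padding", {
  set.seed(43)
  cfg <- tiny_gen_config()
  par <- init_generator(cfg)
  lens <- c(10L, 20L)
  idx <- random_idx_batch(2, L = 28L, lens = lens)
  out_full <- generator_forward(cfg, par, idx)
  out_trim <- generator_forward(cfg, par, idx[1:20, ])
  expect_equal(out_trim, out_full, tolerance = 1e-12)
})

test_that("feature-mode generator is a dense tanh stack with [0,1] output", {
  set.seed(44)
  cfg <- generator_config("feature", n_terms = 7, feature_dim = 12,
                          dense_sizes = c(16, 12, 8))
  par <- init_generator(cfg)
  x <- matrix(rnorm(5 * 12), 5, 12)
  out <- generator_forward(cfg, par, x)
  expect_equal(dim(out), c(5L, 7L))
  expect_true(all(out >= 0 & out <= 1))
  expect_error(generator_forward(cfg, par, x[, 1:5]), "columns")
})

test_that("critic returns one unbounded scalar per pair; zero net is zero", {
  set.seed(45)
  gcfg <- tiny_gen_config()
  dcfg <- tiny_disc_config(gcfg)
  dp <- init_discriminator(dcfg)
  idx <- random_idx_batch(5)
  y <- matrix(rbinom(20, 1, 0.5), 5, 4)
  out <- discriminator_forward(dcfg, dp, idx, y)
  expect_length(out, 5L)
  dz <- lapply(dp, function(m) m * 0)
  expect_equal(discriminator_forward(dcfg, dz, idx, y), rep(0, 5))
  expect_error(discriminator_forward(dcfg, dp, idx, y[, 1:2]), "terms")
})

test_that("generator loss reduces to BCE at lambda1 = 0", {
  set.seed(46)
  cfg <- tiny_gen_config()
  par <- init_generator(cfg)
  idx <- random_idx_batch(8)
  y <- matrix(rbinom(32, 1, 0.4), 8, 4)
  loss <- generator_loss(NULL, NULL, cfg, par, idx, y, lambda1 = 0)
  yhat <- generator_forward(cfg, par, idx)
  eps <- 1e-7
  yc <- pmin(pmax(yhat, eps), 1 - eps)
  bce_ref <- -mean(y * log(yc) + (1 - y) * log(1 - yc))
  expect_equal(as.numeric(loss), bce_ref, tolerance = 1e-12)
  expect_error(generator_loss(NULL, NULL, cfg, par, idx, y * 0.5, 0),
               "binary")
})

test_that("single-cell BCE worked example: y = 1, yhat = 0.5 gives ln 2", {
  # engineered generator: all-padding input and output bias 0 -> yhat = 0.5
  cfg <- generator_config("sequence", n_terms = 1, max_positions = 10,
                          embed_dim = 4, n_filters = 2, kernel_size = 3,
                          pool_size = 4, pool_stride = 2,
                          dense_sizes = c(4, 3))
  set.seed(47)
  par <- init_generator(cfg)
  idx <- matrix(0L, 10, 1)
  y <- matrix(1, 1, 1)
  loss <- generator_loss(NULL, NULL, cfg, par, idx, y, lambda1 = 0)
  expect_equal(as.numeric(loss), log(2), tolerance = 1e-9)
})

test_that("perfect prediction leaves only the Wasserstein term", {
  set.seed(48)
  gcfg <- generator_config("feature", n_terms = 3, feature_dim = 4,
                           dense_sizes = c(6, 5, 4))
  dcfg <- discriminator_config(gcfg, label_branch_size = 4, cond_size = 4,
                               trunk_sizes = c(8, 7, 6, 5, 4))
  dp <- init_discriminator(dcfg)
  x <- matrix(rnorm(12), 3, 4)
  y <- matrix(rbinom(9, 1, 0.5), 3, 3)
  # hypothetical generator emitting exactly y: check the identity
  # loss = BCE(y, y_eps) - lambda1 * mean D(x, y) with BCE at clipped truth
  d_mean <- mean(discriminator_forward(dcfg, dp, x, y))
  eps <- 1e-7
  yc <- pmin(pmax(y, eps), 1 - eps)
  bce_clip <- -mean(y * log(yc) + (1 - y) * log(1 - yc))
  expect_lt(bce_clip, 1e-6)
  lambda1 <- 0.5
  expect_equal(bce_clip - lambda1 * d_mean, -lambda1 * d_mean,
               tolerance = 1e-6)
})

test_that("gradient penalty matches the analytic linear critic", {
  set.seed(49)
  gcfg <- tiny_gen_config(n_terms = 4L)
  dcfg <- tiny_disc_config(gcfg)
  dp <- init_discriminator(dcfg)
  c <- 4L
  # engineer D(x, y) = sum(y): identity label branch, pass-through trunk
  dp$Wy <- cbind(diag(c), matrix(0, c, dcfg$label_branch_size - c))
  dp$by <- numeric(dcfg$label_branch_size)
  widths <- c(dcfg$label_branch_size + dcfg$cond_size, dcfg$trunk_sizes)
  for (i in 1:5) {
    W <- matrix(0, widths[i], widths[i + 1])
    W[cbind(1:c, 1:c)] <- 1
    dp[[paste0("Wt", i)]] <- W
    dp[[paste0("bt", i)]] <- numeric(widths[i + 1])
  }
  dp$wo <- matrix(c(rep(1, c), rep(0, dcfg$trunk_sizes[5] - c)), ncol = 1)
  dp$bo <- 0
  gp <- init_generator(gcfg)
  idx <- random_idx_batch(6)
  y <- matrix(rbinom(24, 1, 0.5), 6, 4)
  loss <- discriminator_loss(dcfg, dp, gcfg, gp, idx, y, lambda2 = 10)
  expect_equal(attr(loss, "penalty"), (sqrt(c) - 1)^2, tolerance = 1e-6)
  expect_equal(unname(attr(loss, "grad_norms")), rep(sqrt(c), 6),
               tolerance = 1e-9)

  # lambda2 = 0 with a constant critic: loss is exactly 0
  dz <- lapply(dp, function(m) m * 0)
  l0 <- discriminator_loss(dcfg, dz, gcfg, gp, idx, y, lambda2 = 0)
  expect_equal(as.numeric(l0), 0)
})

test_that("collapsed interpolation: y_fake = y_true evaluates at y_true", {
  set.seed(50)
  gcfg <- generator_config("feature", n_terms = 3, feature_dim = 4,
                           dense_sizes = c(6, 5, 4))
  dcfg <- discriminator_config(gcfg, label_branch_size = 4, cond_size = 4,
                               trunk_sizes = c(8, 7, 6, 5, 4))
  dp <- init_discriminator(dcfg)
  gp <- init_generator(gcfg)
  x <- matrix(rnorm(12), 3, 4)
  y <- matrix(rbinom(9, 1, 0.5), 3, 3)
  l <- discriminator_loss(dcfg, dp, gcfg, gp, x, y, lambda2 = 5,
                          y_fake = y)
  expect_equal(attr(l, "wasserstein"), 0, tolerance = 1e-12)
  # penalty equals the one evaluated at y_true for any eps draws
  l2 <- discriminator_loss(dcfg, dp, gcfg, gp, x, y, lambda2 = 5,
                           eps = rep(0.123, 3), y_fake = y)
  expect_equal(attr(l, "penalty"), attr(l2, "penalty"), tolerance = 1e-12)
})

test_that("backpropagation matches finite differences through both nets", {
  set.seed(51)
  cfg <- tiny_gen_config()
  par <- init_generator(cfg)
  par$bc <- rnorm(cfg$n_filters, sd = 0.3) # keep clear of the LeakyReLU kink
  idx <- random_idx_batch(3)
  y <- matrix(rbinom(12, 1, 0.4), 3, 4)
  ns <- asNamespace("pfpwgan")
  st <- ns$.gen_step_grads(NULL, NULL, par, cfg, idx, y, lambda1 = 0,
                           stochastic = FALSE)
  loss_at <- function(p) {
    as.numeric(generator_loss(NULL, NULL, cfg, p, idx, y, 0))
  }
  h <- 1e-6
  for (k in c("Wc", "bc", "W1", "W3", "b3")) {
    ii <- sample(length(par[[k]]), min(6, length(par[[k]])))
    for (i in ii) {
      p1 <- par; p1[[k]][i] <- p1[[k]][i] + h
      p2 <- par; p2[[k]][i] <- p2[[k]][i] - h
      num <- (loss_at(p1) - loss_at(p2)) / (2 * h)
      expect_equal(st$grads[[k]][i], num, tolerance = 1e-4)
    }
  }
})
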