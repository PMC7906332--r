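# Desk-scale training runs on a miniature benchmark so the whole file stays
# in the tens of seconds.

make_tiny_task <- function(seed = 71, n = 60, n_terms = 12) {
  spec <- synth_spec(n_proteins = n, n_terms = n_terms, dag_depth = 3,
                     seq_len = c(30L, 60L), n_co_pairs = 1L,
                     n_excl_pairs = 1L, seed = seed)
  ds <- sample_proteins(spec)
  enc <- encode_sequences(ds$records,
                          max_positions = max(nchar(ds$records$sequence)) - 2L)
  gen <- generator_config("sequence", n_terms = ncol(ds$annotations),
                          max_positions = nrow(enc$indices), embed_dim = 8L,
                          n_filters = 4L, kernel_size = 6L, pool_size = 16L,
                          pool_stride = 8L, dense_sizes = c(24L, 16L))
  disc <- discriminator_config(gen, label_branch_size = 16L, cond_size = 16L,
                               trunk_sizes = c(32L, 24L, 16L, 12L, 8L))
  list(ds = ds, enc = enc, gen = gen, disc = disc)
}

test_that("train/validation splits are disjoint, exhaustive and reproducible", {
  s <- split_train_validation(1:100, 0.2, seed = 3)
  expect_length(s$validation, 20L)
  expect_length(s$train, 80L)
  expect_setequal(c(s$train, s$validation), 1:100)
  expect_identical(split_train_validation(1:100, 0.2, seed = 3), s)
  expect_false(identical(split_train_validation(1:100, 0.2, seed = 4), s))
  expect_error(split_train_validation(1:100, 0, 1), "fraction")
  expect_error(split_train_validation(1:4, 0.2, 1), "at least 5")
})

test_that("the schedule runs critic_ratio critic updates per generator update", {
  t <- make_tiny_task()
  ctl <- train_config(critic_ratio = 10L, learning_rate = 1e-3,
                      lambda1 = 0.03, batch_size = 16L, max_epochs = 1L,
                      seed = 5)
  fit <- pfp_wgan(t$enc, t$ds$annotations, generator = t$gen,
                  discriminator = t$disc, control = ctl)
  expect_identical(nrow(fit$log$critic), 10L * nrow(fit$log$generator))
  expect_gt(nrow(fit$log$generator), 0L)
})

test_that("the PFP-S ablation trains without any critic machinery", {
  t <- make_tiny_task()
  ctl <- train_config(learning_rate = 1e-3, batch_size = 16L,
                      max_epochs = 2L, seed = 5, ablation_pfp_s = TRUE)
  fit <- pfp_wgan(t$enc, t$ds$annotations, generator = t$gen, control = ctl)
  expect_identical(nrow(fit$log$critic), 0L)
  expect_null(fit$discriminator)
  expect_identical(nrow(fit$log$epochs), 2L)
  # BCE decreases over the run
  bce <- fit$log$generator$bce
  expect_lt(mean(tail(bce, 3)), mean(head(bce, 3)))
})

test_that("training is reproducible under the master seed", {
  t <- make_tiny_task()
  ctl <- train_config(critic_ratio = 3L, learning_rate = 1e-3,
                      lambda1 = 0.03, batch_size = 16L, max_epochs = 1L,
                      seed = 11)
  f1 <- pfp_wgan(t$enc, t$ds$annotations, generator = t$gen,
                 discriminator = t$disc, control = ctl)
  f2 <- pfp_wgan(t$enc, t$ds$annotations, generator = t$gen,
                 discriminator = t$disc, control = ctl)
  expect_equal(f1$log$critic, f2$log$critic)
  expect_equal(f1$log$generator, f2$log$generator)
  expect_equal(f1$generator, f2$generator)
})

test_that("prediction is deterministic, shaped and within [0, 1]", {
  t <- make_tiny_task()
  ctl <- train_config(learning_rate = 1e-3, batch_size = 16L,
                      max_epochs = 1L, seed = 7, ablation_pfp_s = TRUE)
  fit <- pfp_wgan(t$enc, t$ds$annotations, generator = t$gen, control = ctl)
  p1 <- predict(fit, t$enc)
  expect_equal(dim(p1), c(60L, 12L))
  expect_identical(colnames(p1), colnames(t$ds$annotations))
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_identical(p1, predict(fit, t$enc))
  expect_s3_class(fit, "pfp_wgan")
  expect_output(print(fit), "annotator")
  expect_output(print(summary(fit)), "validation Fmax")
})

test_that("with lambda1 = 0 generator updates equal PFP-S updates", {
  t <- make_tiny_task()
  base <- train_config(critic_ratio = 2L, learning_rate = 1e-3, lambda1 = 0,
                       batch_size = 16L, max_epochs = 1L, seed = 13)
  f_gan <- pfp_wgan(t$enc, t$ds$annotations, generator = t$gen,
                    discriminator = t$disc, control = base)
  # critic training consumes RNG, so replay the same batch draws through the
  # loss identity instead: every generator-step loss must equal its BCE
  expect_equal(f_gan$log$generator$loss, f_gan$log$generator$bce,
               tolerance = 1e-12)
  expect_true(all(f_gan$log$generator$wasserstein == 0))
})

test_that("critic gradient norms settle near 1 under the penalty", {
  t <- make_tiny_task(seed = 73)
  ctl <- train_config(critic_ratio = 5L, learning_rate = 1e-3,
                      lambda1 = 0.03, lambda2 = 10, batch_size = 16L,
                      max_epochs = 3L, seed = 17)
  fit <- pfp_wgan(t$enc, t$ds$annotations, generator = t$gen,
                  discriminator = t$disc, control = ctl)
  norms <- fit$log$critic$grad_norm
  late <- tail(norms, 20)
  expect_lt(abs(mean(late) - 1), 0.3)
})

test_that("a trained critic separates real pairs from shuffled labels", {
  t <- make_tiny_task(seed = 83, n = 80)
  ctl <- train_config(critic_ratio = 10L, learning_rate = 1e-3,
                      lambda1 = 0.03, batch_size = 16L, max_epochs = 5L,
                      seed = 29)
  fit <- pfp_wgan(t$enc, t$ds$annotations, generator = t$gen,
                  discriminator = t$disc, control = ctl)
  y <- t$ds$annotations
  set.seed(30)
  y_shuf <- y[sample(nrow(y)), ]
  d_real <- discriminator_forward(fit$d_config, fit$discriminator,
                                  t$enc, y)
  d_shuf <- discriminator_forward(fit$d_config, fit$discriminator,
                                  t$enc, y_shuf)
  expect_gt(mean(d_real), mean(d_shuf))
})

test_that("the learnability floor holds: PFP-S reaches Fmax 0.7 on a tiny task", {
  t <- make_tiny_task(seed = 79, n = 150)
  ctl <- train_config(learning_rate = 1e-3, batch_size = 16L,
                      max_epochs = 10L, seed = 19, ablation_pfp_s = TRUE)
  fit <- pfp_wgan(t$enc, t$ds$annotations, generator = t$gen, control = ctl)
  expect_gte(max(fit$log$epochs$val_fmax), 0.7)
})
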