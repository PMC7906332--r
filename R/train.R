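# Alternating WGAN-GP optimisation: for every generator update the critic is
# updated `critic_ratio` times, each on a freshly drawn minibatch.  Model
# selection is by validation Fmax at the end of each epoch.

#' Training configuration
#'
#' @param critic_ratio critic updates per generator update (default 10).
#' @param learning_rate Adam learning rate.  The default 1e-5 is the value
#'   used for full-scale corpora; desk-scale runs (see
#'   [synth_benchmark_control()]) use 1e-3.
#' @param beta1,beta2 Adam moment decays.
#' @param lambda1 weight of the generator's adversarial term (0.03 for raw
#'   sequences, 1e-5 for hand-crafted features in the reference setting).
#' @param lambda2 gradient-penalty weight (default 10).
#' @param batch_size minibatch size (default 32).
#' @param max_epochs number of epochs; the best-validation-Fmax epoch is kept.
#' @param validation_fraction held-out fraction for model selection
#'   (default 0.2).
#' @param seed master seed; every source of randomness (split, init, dropout,
#'   interpolation draws, batch order) flows from it.
#' @param ablation_pfp_s drop the critic entirely and train the generator on
#'   pure binary cross-entropy (the PFP-S ablation).
#' @return A `train_config` list.
#' @export
train_config <- function(critic_ratio = 10L, learning_rate = 1e-5,
                         beta1 = 0.9, beta2 = 0.999, lambda1 = 0.03,
                         lambda2 = 10, batch_size = 32L, max_epochs = 10L,
                         validation_fraction = 0.2, seed = 1L,
                         ablation_pfp_s = FALSE) {
  if (critic_ratio < 1L) stop("critic_ratio must be >= 1")
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stop("validation_fraction must be in (0, 1)")
  if (lambda1 < 0 || lambda2 < 0) stop("lambda weights must be >= 0")
  structure(list(critic_ratio = as.integer(critic_ratio),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 lambda1 = lambda1, lambda2 = lambda2,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed),
                 ablation_pfp_s = isTRUE(ablation_pfp_s)),
            class = "train_config")
}

#' Reproducible train/validation split
#'
#' @param ids vector of protein indices or identifiers (length >= 5).
#' @param fraction validation fraction in (0, 1).
#' @param seed integer seed; the same seed gives the same split.
#' @return List with `train` and `validation`, disjoint and exhaustive.
#' @export
split_train_validation <- function(ids, fraction = 0.2, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n <- length(ids)
  if (n < 5L) stop("need at least 5 proteins to split")
  set.seed(seed)
  n_val <- max(1L, round(n * fraction))
  if (n_val >= n) n_val <- n - 1L
  val <- sort(sample.int(n, n_val))
  list(train = ids[-val], validation = ids[val])
}

.seq_lengths <- function(x) {
  if (inherits(x, "trigram_encoding")) return(x$lengths)
  colSums(x != 0L)
}

.subset_input <- function(cfg, x, rows) {
  if (cfg$mode == "sequence") x[, rows, drop = FALSE]
  else x[rows, , drop = FALSE]
}

# fixed batch partition; sequence batches are length-bucketed so short
# batches convolve short (padding-invariant by construction)
.make_batches <- function(cfg, x, idx_pool, batch_size) {
  if (cfg$mode == "sequence") {
    lens <- .seq_lengths(x)[idx_pool]
    ord <- idx_pool[order(lens)]
  } else ord <- sample(idx_pool)
  split(ord, ceiling(seq_along(ord) / batch_size))
}

#' Fit the adversarial annotator
#'
#' Trains the conditional generator against the Wasserstein critic (or on
#' pure BCE when `control$ablation_pfp_s`), with `critic_ratio` critic
#' updates per generator update, one Adam optimiser per network, and
#' best-validation-Fmax checkpointing.
#'
#' @param x protein inputs: a `trigram_encoding` (sequence mode) or a numeric
#'   feature matrix, proteins x d (feature mode).
#' @param y binary annotation matrix (proteins x terms, term column names),
#'   already true-path propagated.
#' @param generator a [generator_config()]; a default one is built from the
#'   data when NULL.
#' @param discriminator a [discriminator_config()]; default built from
#'   `generator` when NULL.
#' @param control a [train_config()].
#' @return An object of class `pfp_wgan` with elements `generator` /
#'   `discriminator` (parameters of the best epoch), the configs, the
#'   training log (`log$critic`, `log$generator`, `log$epochs`,
#'   `log$best_epoch`) and the term names.
#' @export
pfp_wgan <- function(x, y, generator = NULL, discriminator = NULL,
                     control = train_config()) {
  y <- .check_binary(y)
  if (is.null(colnames(y))) stop("y needs term column names")
  if (is.null(generator)) {
    if (inherits(x, "trigram_encoding"))
      generator <- generator_config("sequence", n_terms = ncol(y),
                                    max_positions = nrow(x$indices))
    else
      generator <- generator_config("feature", n_terms = ncol(y),
                                    feature_dim = ncol(x))
  }
  if (generator$n_terms != ncol(y))
    stop("generator n_terms (", generator$n_terms,
         ") does not match ncol(y) (", ncol(y), ")")
  use_critic <- !control$ablation_pfp_s
  if (use_critic && is.null(discriminator))
    discriminator <- discriminator_config(generator)
  xin <- .as_model_input(generator, x)
  n <- if (generator$mode == "sequence") ncol(xin) else nrow(xin)
  if (n != nrow(y)) stop("x and y disagree on the number of proteins")

  split <- split_train_validation(seq_len(n), control$validation_fraction,
                                  control$seed)
  set.seed(control$seed + 1L)
  g_par <- init_generator(generator)
  g_opt <- adam_state(g_par)
  if (use_critic) {
    d_par <- init_discriminator(discriminator)
    d_opt <- adam_state(d_par)
  } else d_par <- NULL

  lens_all <- if (generator$mode == "sequence") .seq_lengths(x) else NULL
  batches <- .make_batches(generator, x, split$train, control$batch_size)
  nb <- length(batches)
  x_val <- .subset_input(generator, xin, split$validation)
  y_val <- y[split$validation, , drop = FALSE]

  crit_log <- gen_log <- list()
  epoch_log <- data.frame(epoch = integer(0), val_fmax = numeric(0))
  best <- list(fmax = -Inf, epoch = NA_integer_, g = NULL, d = NULL)
  grid <- threshold_grid()
  gstep <- cstep <- 0L

  for (epoch in seq_len(control$max_epochs)) {
    for (b in sample.int(nb)) {
      if (use_critic) {
        for (j in seq_len(control$critic_ratio)) {
          rows <- batches[[sample.int(nb, 1L)]]
          xb <- .subset_input(generator, xin, rows)
          yb <- y[rows, , drop = FALSE]
          eps <- runif(nrow(yb))
          st <- .critic_step_grads(d_par, discriminator, g_par, generator,
                                   xb, yb, control$lambda2, eps)
          if (!is.finite(st$loss))
            stop("training diverged: non-finite critic loss at critic step ",
                 cstep + 1L, " (epoch ", epoch, ")")
          up <- adam_step(d_par, st$grads, d_opt, control$learning_rate,
                          control$beta1, control$beta2)
          d_par <- up$params; d_opt <- up$state
          cstep <- cstep + 1L
          crit_log[[cstep]] <- c(step = cstep, epoch = epoch, loss = st$loss,
                                 wasserstein = st$wasserstein,
                                 penalty = st$penalty,
                                 grad_norm = st$grad_norm)
        }
      }
      rows <- batches[[b]]
      xb <- .subset_input(generator, xin, rows)
      yb <- y[rows, , drop = FALSE]
      lambda1 <- if (use_critic) control$lambda1 else 0
      st <- .gen_step_grads(d_par, discriminator, g_par, generator,
                            xb, yb, lambda1)
      if (!is.finite(st$loss))
        stop("training diverged: non-finite generator loss at generator step ",
             gstep + 1L, " (epoch ", epoch, ")")
      up <- adam_step(g_par, st$grads, g_opt, control$learning_rate,
                      control$beta1, control$beta2)
      g_par <- up$params; g_opt <- up$state
      gstep <- gstep + 1L
      gen_log[[gstep]] <- c(step = gstep, epoch = epoch, loss = st$loss,
                            bce = st$bce, wasserstein = st$wasserstein)
    }
    scores <- .predict_params(generator, g_par, x_val)
    vf <- fmax(y_val, scores, grid)$fmax
    epoch_log <- rbind(epoch_log, data.frame(epoch = epoch, val_fmax = vf))
    if (vf > best$fmax) {
      best$fmax <- vf; best$epoch <- epoch
      best$g <- .deep_copy(g_par)  # Adam updates mutate in place
      best$d <- if (use_critic) .deep_copy(d_par) else NULL
    }
  }

  structure(list(
    generator = best$g, discriminator = best$d,
    g_config = generator, d_config = if (use_critic) discriminator else NULL,
    control = control, terms = colnames(y),
    split = split,
    log = list(critic = .steplog_df(crit_log),
               generator = .steplog_df(gen_log),
               epochs = epoch_log, best_epoch = best$epoch),
    call = match.call()), class = "pfp_wgan")
}

.steplog_df <- function(entries) {
  if (!length(entries)) return(data.frame())
  as.data.frame(do.call(rbind, entries))
}

# deterministic batched forward pass
.predict_params <- function(cfg, par, xin, batch_size = 128L) {
  n <- if (cfg$mode == "sequence") ncol(xin) else nrow(xin)
  out <- matrix(NA_real_, n, cfg$n_terms)
  for (start in seq(1L, n, by = batch_size)) {
    rows <- start:min(start + batch_size - 1L, n)
    out[rows, ] <- .gen_fwd(par, cfg, .subset_input(cfg, xin, rows),
                            stochastic = FALSE)$yhat
  }
  out
}

#' Predict annotation scores
#'
#' Deterministic forward pass (dropout off) of the best-epoch generator.
#'
#' @param object a fitted [pfp_wgan()] model.
#' @param newdata protein inputs encoded as at training time.
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return Score matrix (proteins x terms) with entries in `[0, 1]`.
#' @export
predict.pfp_wgan <- function(object, newdata, batch_size = 128L, ...) {
  cfg <- object$g_config
  xin <- .as_model_input(cfg, newdata)
  out <- .predict_params(cfg, object$generator, xin, batch_size)
  colnames(out) <- object$terms
  if (inherits(newdata, "trigram_encoding")) rownames(out) <- newdata$ids
  else if (!is.null(rownames(newdata))) rownames(out) <- rownames(newdata)
  out
}

#' @export
print.pfp_wgan <- function(x, ...) {
  cat("Conditional WGAN protein-function annotator",
      if (x$control$ablation_pfp_s) "(PFP-S ablation: BCE only)" else "",
      "\n")
  cat("  mode:", x$g_config$mode, " terms:", x$g_config$n_terms, "\n")
  cat("  generator updates:", nrow(x$log$generator),
      " critic updates:", nrow(x$log$critic), "\n")
  cat("  best epoch:", x$log$best_epoch, " (validation Fmax =",
      sprintf("%.4f", max(x$log$epochs$val_fmax)), ")\n")
  invisible(x)
}

#' @export
summary.pfp_wgan <- function(object, ...) {
  out <- list(
    mode = object$g_config$mode,
    n_terms = object$g_config$n_terms,
    ablation = object$control$ablation_pfp_s,
    epochs = object$log$epochs,
    best_epoch = object$log$best_epoch,
    best_val_fmax = max(object$log$epochs$val_fmax),
    final_gen_loss = utils::tail(object$log$generator$loss, 1L),
    mean_critic_grad_norm =
      if (nrow(object$log$critic)) mean(utils::tail(object$log$critic$grad_norm, 50L))
      else NA_real_)
  class(out) <- "summary.pfp_wgan"
  out
}

#' @export
print.summary.pfp_wgan <- function(x, ...) {
  cat("pfp_wgan fit —", x$mode, "mode,", x$n_terms, "terms",
      if (x$ablation) "(PFP-S ablation)" else "", "\n")
  cat("validation Fmax by epoch:\n")
  print(x$epochs, row.names = FALSE)
  cat("best epoch:", x$best_epoch,
      sprintf("(Fmax = %.4f)", x$best_val_fmax), "\n")
  if (is.finite(x$mean_critic_grad_norm))
    cat(sprintf("mean critic gradient norm (last 50 steps): %.3f\n",
                x$mean_critic_grad_norm))
  invisible(x)
}

#' Training curves
#'
#' Left: per-step generator (and critic) losses; right: validation Fmax per
#' epoch with the selected epoch marked.
#'
#' @param x a fitted [pfp_wgan()] model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pfp_wgan <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  gl <- x$log$generator
  graphics::plot(gl$step, gl$loss, type = "l", xlab = "generator step",
                 ylab = "loss", main = "generator", ...)
  graphics::lines(gl$step, gl$bce, col = "grey60")
  el <- x$log$epochs
  graphics::plot(el$epoch, el$val_fmax, type = "b", xlab = "epoch",
                 ylab = "validation Fmax", main = "model selection", ...)
  graphics::abline(v = x$log$best_epoch, lty = 2)
  invisible(x)
}
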