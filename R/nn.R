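# Minimal dense-network machinery shared by generator and critic.  Parameters
# are named lists of matrices/vectors; batches are n x d matrices.  The
# convolutional front end (embedding lookup, 1-D convolution, average
# pooling) is in src/nn_kernels.cpp.

.lrelu <- function(z, alpha = 0.2) {
  z * ((z > 0) + alpha * (z <= 0))
}

# slope mask (1 or alpha) evaluated at the pre-activation
.lrelu_mask <- function(z, alpha = 0.2) {
  (z > 0) + alpha * (z <= 0)
}

.add_bias <- function(Z, b) sweep(Z, 2L, b, "+")

# He-style uniform init, deterministic under the caller's RNG state
.init_mat <- function(nin, nout) {
  lim <- sqrt(6 / nin)
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

# dense forward with cache: H -> lrelu(H W + b)
.dense_fwd <- function(H, W, b, alpha = 0.2, linear = FALSE) {
  Z <- .add_bias(H %*% W, b)
  if (linear) list(out = Z, pre = Z, inp = H)
  else list(out = .lrelu(Z, alpha), pre = Z, inp = H)
}

# backward of .dense_fwd given dOut; returns grads and dInp
.dense_bwd <- function(cache, W, dOut, alpha = 0.2, linear = FALSE) {
  dZ <- if (linear) dOut else dOut * .lrelu_mask(cache$pre, alpha)
  list(dW = crossprod(cache$inp, dZ), db = colSums(dZ), dInp = dZ %*% t(W))
}

# ---- Adam ------------------------------------------------------------------
# Parameter tensors, m and v are updated IN PLACE (adam_update_inplace), so
# any snapshot of the parameter list must deep-copy (.deep_copy) first.

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    if (is.null(g)) next
    adam_update_inplace(params[[k]], g, state$m[[k]],
                        state$v[[k]], lr, beta1, beta2, bc1, bc2, eps)
  }
  list(params = params, state = state)
}

.deep_copy <- function(params) lapply(params, function(p) p + 0)

# elementwise dropout with inverted scaling; mask drawn from the caller's RNG
.dropout <- function(X, rate) {
  if (rate <= 0) return(list(X = X, mask = NULL))
  mask <- array(runif(length(X)) >= rate, dim = dim(X)) / (1 - rate)
  list(X = X * mask, mask = mask)
}
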