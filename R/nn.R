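# Minimal neural-network primitives: dense layers, MLPs with manual
# backpropagation, Adam, and the loss functions used by the codecs,
# autoencoder and GAN. Everything is deterministic given the caller's RNG
# state and runs on plain BLAS matrix products.

act_fun <- function(name) {
  switch(name,
    tanh = list(f = tanh,
                fp = function(a, z) 1 - a^2,            # phi' in terms of a
                fpp = function(a, z) -2 * a * (1 - a^2)), # phi'' in terms of a
    relu = list(f = function(z) pmax(z, 0),
                fp = function(a, z) (z > 0) + 0,
                fpp = function(a, z) 0 * z),
    linear = list(f = identity,
                  fp = function(a, z) 1 + 0 * z,
                  fpp = function(a, z) 0 * z),
    stop("unknown activation: ", name))
}

dense_init <- function(d_in, d_out) {
  s <- sqrt(6 / (d_in + d_out))
  list(W = matrix(stats::runif(d_in * d_out, -s, s), d_in, d_out),
       b = rep(0, d_out))
}

# sizes: c(d_in, hidden..., d_out); hidden activation `act`, linear output.
mlp_init <- function(sizes, act = "tanh") {
  L <- length(sizes) - 1L
  layers <- vector("list", L)
  for (k in seq_len(L)) layers[[k]] <- dense_init(sizes[k], sizes[k + 1L])
  structure(list(layers = layers, sizes = sizes, act = act), class = "mlp")
}

mlp_forward <- function(net, X, keep_cache = TRUE) {
  phi <- act_fun(net$act)
  L <- length(net$layers)
  A <- vector("list", L + 1L)
  Z <- vector("list", L)
  A[[1L]] <- X
  for (k in seq_len(L)) {
    Z[[k]] <- sweep(A[[k]] %*% net$layers[[k]]$W, 2, net$layers[[k]]$b, "+")
    A[[k + 1L]] <- if (k < L) phi$f(Z[[k]]) else Z[[k]]
  }
  list(out = A[[L + 1L]], cache = if (keep_cache) list(A = A, Z = Z))
}

# dY: adjoint of the output. Returns grads (same shape as net$layers) + dX.
mlp_backward <- function(net, cache, dY) {
  phi <- act_fun(net$act)
  L <- length(net$layers)
  grads <- vector("list", L)
  dA <- dY
  for (k in rev(seq_len(L))) {
    dZ <- if (k < L) dA * phi$fp(cache$A[[k + 1L]], cache$Z[[k]]) else dA
    grads[[k]] <- list(W = crossprod(cache$A[[k]], dZ), b = colSums(dZ))
    dA <- tcrossprod(dZ, net$layers[[k]]$W)
  }
  list(grads = grads, dX = dA)
}

# Gradient of a scalar-output MLP w.r.t. its input, per sample (n x d_in).
mlp_grad_input <- function(net, X) {
  stopifnot(utils::tail(net$sizes, 1) == 1L)
  fw <- mlp_forward(net, X)
  mlp_backward(net, fw$cache, matrix(1, nrow(X), 1))$dX
}

# WGAN-GP penalty and its exact gradient w.r.t. the critic parameters.
# For per-sample input gradient g_i = d D(x_i)/d x_i, the penalty is
#   P = eta * mean_i (||g_i|| - 1)^2 .
# dP/dtheta needs second derivatives; we compute it as a forward-tangent
# pass along v_i = g_i (whose JVP equals ||g_i||^2 / ||g_i||-scaled terms)
# followed by reverse mode over the augmented graph. Smooth activations
# (tanh) give exact gradients; relu gives the a.e. gradient (phi'' = 0).
critic_penalty <- function(net, X, eta) {
  phi <- act_fun(net$act)
  L <- length(net$layers)
  n <- nrow(X)
  fw <- mlp_forward(net, X)
  A <- fw$cache$A; Z <- fw$cache$Z
  # reverse pass for per-sample input gradients
  dA <- matrix(1, n, 1)
  for (k in rev(seq_len(L))) {
    dZ <- if (k < L) dA * phi$fp(A[[k + 1L]], Z[[k]]) else dA
    dA <- tcrossprod(dZ, net$layers[[k]]$W)
  }
  G <- dA
  nrm <- sqrt(rowSums(G^2))
  P <- eta * mean((nrm - 1)^2)
  cvec <- (2 * eta / n) * (nrm - 1) / pmax(nrm, 1e-12)

  # forward tangent along V = G
  Adot <- vector("list", L + 1L)
  S <- vector("list", L)
  Adot[[1L]] <- G
  for (k in seq_len(L)) {
    S[[k]] <- Adot[[k]] %*% net$layers[[k]]$W
    Adot[[k + 1L]] <- if (k < L) phi$fp(A[[k + 1L]], Z[[k]]) * S[[k]] else S[[k]]
  }
  # reverse over the augmented graph; J = sum_i cvec_i * Zdot_L[i]
  grads <- vector("list", L)
  tL <- cvec * matrix(1, n, 1)          # adjoint of Adot[[L+1]] (the JVP)
  grads[[L]] <- list(W = crossprod(Adot[[L]], tL), b = rep(0, ncol(tL)))
  t_adj <- tcrossprod(tL, net$layers[[L]]$W)  # adjoint of Adot[[L]]
  u_adj <- matrix(0, n, ncol(t_adj))          # adjoint of A[[L]]
  if (L > 1L) for (k in rev(seq_len(L - 1L))) {
    fp <- phi$fp(A[[k + 1L]], Z[[k]])
    fpp <- phi$fpp(A[[k + 1L]], Z[[k]])
    ts <- t_adj * fp                              # adjoint of S[[k]]
    q <- u_adj * fp + t_adj * S[[k]] * fpp        # adjoint of Z[[k]]
    grads[[k]] <- list(W = crossprod(A[[k]], q) + crossprod(Adot[[k]], ts),
                       b = colSums(q))
    t_adj <- tcrossprod(ts, net$layers[[k]]$W)
    u_adj <- tcrossprod(q, net$layers[[k]]$W)
  }
  list(value = P, grads = grads, grad_norms = nrm)
}

# ---- Adam ---------------------------------------------------------------

adam_init <- function(params) {
  zero_like <- function(p) if (is.list(p)) lapply(p, zero_like) else p * 0
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in seq_along(p)) {
        r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v)
  state$m <- r$m; state$v <- r$v
  list(params = r$p, state = state)
}

# ---- losses -------------------------------------------------------------

# Weighted binary cross entropy on logits; returns the mean over weight mass
# and the gradient w.r.t. the logits.
bce_logits <- function(logits, target, w = NULL) {
  if (is.null(w)) w <- logits * 0 + 1
  sw <- sum(w)
  if (sw == 0) return(list(value = 0, grad = logits * 0))
  # stable softplus: log(1 + exp(z)) = max(z,0) + log1p(exp(-|z|))
  sp <- pmax(logits, 0) + log1p(exp(-abs(logits)))
  val <- sum(w * (sp - target * logits)) / sw
  list(value = val, grad = w * (sigmoid(logits) - target) / sw)
}

# Weighted mean squared error; gradient w.r.t. pred. Entries with weight 0
# contribute exactly nothing.
mse_masked <- function(pred, target, w = NULL) {
  if (is.null(w)) w <- pred * 0 + 1
  sw <- sum(w)
  if (sw == 0) return(list(value = 0, grad = pred * 0))
  d <- w * (pred - target)
  list(value = sum(d * (pred - target)) / sw, grad = 2 * d / sw)
}

# Softmax cross entropy over rows of `logits` against one-hot rows `target`
# (n x K); row weights `w` (default 1). Mean over weight mass.
softmax_ce <- function(logits, target, w = NULL) {
  n <- nrow(logits)
  if (is.null(w)) w <- rep(1, n)
  sw <- sum(w)
  if (sw == 0) return(list(value = 0, grad = logits * 0, prob = logits * 0))
  zmax <- apply(logits, 1, max)
  ez <- exp(logits - zmax)
  p <- ez / rowSums(ez)
  val <- -sum(w * rowSums(target * log(pmax(p, 1e-300)))) / sw
  list(value = val, grad = w * (p - target) / sw, prob = p)
}

# Binary cross entropy on probabilities, with the exact 0*log(0) = 0
# convention so that a perfect {0,1} prediction scores exactly zero.
bce_prob_exact <- function(p, y, w = NULL) {
  if (is.null(w)) w <- p * 0 + 1
  sw <- sum(w)
  if (sw == 0) return(0)
  term <- function(yy, pp) ifelse(yy == 0, 0, yy * log(pmax(pp, 1e-300)))
  -sum(w * (term(y, p) + term(1 - y, 1 - p))) / sw
}
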