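# Gated recurrent unit with manual backpropagation through time.
# Sequences are batch-major lists: X[[t]] is an n x d_in matrix, t = 1..T.
# Convention: h_t = (1 - z_t) * n_t + z_t * h_{t-1}  (z gate keeps the past).

gru_init <- function(d_in, d_h) {
  g <- function(a, b) {
    s <- sqrt(6 / (a + b))
    matrix(stats::runif(a * b, -s, s), a, b)
  }
  list(Wz = g(d_in, d_h), Uz = g(d_h, d_h), bz = rep(0, d_h),
       Wr = g(d_in, d_h), Ur = g(d_h, d_h), br = rep(0, d_h),
       Wn = g(d_in, d_h), Un = g(d_h, d_h), bn = rep(0, d_h))
}

gru_forward <- function(p, X, h0 = NULL, keep_cache = TRUE) {
  Tn <- length(X)
  n <- nrow(X[[1L]])
  d_h <- ncol(p$Uz)
  h <- if (is.null(h0)) matrix(0, n, d_h) else h0
  H <- vector("list", Tn)
  cache <- if (keep_cache) vector("list", Tn)
  for (t in seq_len(Tn)) {
    x <- X[[t]]
    z <- sigmoid(sweep(x %*% p$Wz + h %*% p$Uz, 2, p$bz, "+"))
    r <- sigmoid(sweep(x %*% p$Wr + h %*% p$Ur, 2, p$br, "+"))
    rn <- r * h
    nn <- tanh(sweep(x %*% p$Wn + rn %*% p$Un, 2, p$bn, "+"))
    hp <- h
    h <- (1 - z) * nn + z * h
    H[[t]] <- h
    if (keep_cache) cache[[t]] <- list(x = x, z = z, r = r, nn = nn,
                                       rn = rn, hprev = hp)
  }
  list(H = H, h_last = h, cache = cache)
}

# dH: list of per-step adjoints of H[[t]] (use zero matrices for unused
# steps), or NULL with dh_last supplying only the final-state adjoint.
gru_backward <- function(p, cache, dH = NULL, dh_last = NULL) {
  Tn <- length(cache)
  n <- nrow(cache[[1L]]$x)
  d_h <- ncol(p$Uz)
  zero <- function(m) m * 0
  g <- list(Wz = zero(p$Wz), Uz = zero(p$Uz), bz = rep(0, d_h),
            Wr = zero(p$Wr), Ur = zero(p$Ur), br = rep(0, d_h),
            Wn = zero(p$Wn), Un = zero(p$Un), bn = rep(0, d_h))
  dX <- vector("list", Tn)
  dh <- if (is.null(dh_last)) matrix(0, n, d_h) else dh_last
  for (t in rev(seq_len(Tn))) {
    if (!is.null(dH)) dh <- dh + dH[[t]]
    cc <- cache[[t]]
    dnn <- dh * (1 - cc$z)
    dz <- dh * (cc$hprev - cc$nn)
    dhp <- dh * cc$z
    dan <- dnn * (1 - cc$nn^2)
    g$Wn <- g$Wn + crossprod(cc$x, dan)
    g$Un <- g$Un + crossprod(cc$rn, dan)
    g$bn <- g$bn + colSums(dan)
    drn <- tcrossprod(dan, p$Un)
    dr <- drn * cc$hprev
    dhp <- dhp + drn * cc$r
    daz <- dz * cc$z * (1 - cc$z)
    g$Wz <- g$Wz + crossprod(cc$x, daz)
    g$Uz <- g$Uz + crossprod(cc$hprev, daz)
    g$bz <- g$bz + colSums(daz)
    dhp <- dhp + tcrossprod(daz, p$Uz)
    dar <- dr * cc$r * (1 - cc$r)
    g$Wr <- g$Wr + crossprod(cc$x, dar)
    g$Ur <- g$Ur + crossprod(cc$hprev, dar)
    g$br <- g$br + colSums(dar)
    dhp <- dhp + tcrossprod(dar, p$Ur)
    dX[[t]] <- tcrossprod(dan, p$Wn) + tcrossprod(daz, p$Wz) +
      tcrossprod(dar, p$Wr)
    dh <- dhp
  }
  list(grads = g, dX = dX, dh0 = dh)
}
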