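#' Gradient penalty of a WGAN-GP critic
#'
#' For each pair of real and generated latents, a random interpolate
#' `e_tilde = eps * e_real + (1 - eps) * e_fake` is drawn with a scalar
#' `eps ~ U(0, 1)` per sample, and the penalty
#' `eta * mean((||grad D(e_tilde)|| - 1)^2)` is returned. A critic with
#' gradient norm exactly 1 everywhere incurs penalty 0; gradient norm 2
#' everywhere with `eta = 10` gives exactly 10.
#'
#' @param critic an `mlp` critic with scalar output.
#' @param e_real,e_fake latent batches of equal size (rows = samples).
#' @param eta penalty weight (> 0; default 10).
#' @param seed seed for the interpolation draws.
#' @return scalar penalty value.
#' @export
gradient_penalty <- function(critic, e_real, e_fake, eta = 10, seed = 1L) {
  stopifnot(nrow(e_real) == nrow(e_fake), eta > 0)
  with_substream(seed, "gp-eps", {
    eps <- stats::runif(nrow(e_real))
  })
  e_t <- eps * e_real + (1 - eps) * e_fake
  critic_penalty(critic, e_t, eta)$value
}

#' Train a WGAN-GP over encoder states
#'
#' The generator maps standard-normal noise `z` (width `d_z`) to synthetic
#' latents; the critic scores latents, maximizing the Wasserstein surrogate
#' `mean D(e) - mean D(e_hat)` minus the gradient penalty, with
#' `critic_steps` critic updates per generator update. Both networks are
#' MLPs (two hidden tanh layers of width `gan_hidden`). Training is
#' bit-reproducible per seed on CPU; the final-epoch checkpoint is returned.
#'
#' @param latents N x d_e matrix of encoder states.
#' @param config a [training_config()].
#' @return a `gan_pair`: generator, critic, and the per-step history of the
#'   critic objective, gradient penalty and generator loss.
#' @export
train_wgan_gp <- function(latents, config) {
  stopifnot(all(is.finite(latents)), inherits(config, "training_config"))
  d_e <- ncol(latents)
  d_z <- config$d_z
  h <- config$gan_hidden
  n <- nrow(latents)
  # train in standardized latent space (per-dimension z-scores); the
  # affine map is stored and inverted at sampling time
  center <- colMeans(latents)
  scale <- pmax(apply(latents, 2, stats::sd), 1e-8)
  latents <- sweep(sweep(latents, 2, center), 2, scale, "/")
  with_substream(config$seed, "gan-init", {
    G <- mlp_init(c(d_z, h, h, d_e), "tanh")
    D <- mlp_init(c(d_e, h, h, 1L), "tanh")
  })
  stG <- adam_init(G$layers)
  stD <- adam_init(D$layers)
  bs <- min(config$gan_batch, n)
  hist <- list(critic = numeric(0), penalty = numeric(0), gen = numeric(0))
  with_substream(config$seed, "gan-train", {
    for (ep in seq_len(config$gan_epochs)) {
      c_acc <- 0; p_acc <- 0; g_acc <- 0; nsteps <- 0
      nbatch <- max(1L, floor(n / bs))
      for (it in seq_len(nbatch)) {
        for (cs in seq_len(config$critic_steps)) {
          idx <- sample.int(n, bs)
          z <- matrix(stats::rnorm(bs * d_z), bs, d_z)
          fake <- mlp_forward(G, z, keep_cache = FALSE)$out
          real <- latents[idx, , drop = FALSE]
          eps <- stats::runif(bs)
          e_t <- eps * real + (1 - eps) * fake
          fw_r <- mlp_forward(D, real)
          fw_f <- mlp_forward(D, fake)
          pen <- critic_penalty(D, e_t, config$eta)
          # critic minimizes: mean D(fake) - mean D(real) + penalty
          gr_r <- mlp_backward(D, fw_r$cache, matrix(-1 / bs, bs, 1))$grads
          gr_f <- mlp_backward(D, fw_f$cache, matrix(1 / bs, bs, 1))$grads
          gsum <- gr_r
          for (k in seq_along(gsum)) {
            gsum[[k]]$W <- gr_r[[k]]$W + gr_f[[k]]$W + pen$grads[[k]]$W
            gsum[[k]]$b <- gr_r[[k]]$b + gr_f[[k]]$b + pen$grads[[k]]$b
          }
          r <- adam_step(D$layers, gsum, stD, lr = config$gan_lr,
                         beta1 = 0.5, beta2 = 0.9)
          D$layers <- r$params; stD <- r$state
          wdist <- mean(fw_r$out) - mean(fw_f$out)
          c_acc <- c_acc + wdist; p_acc <- p_acc + pen$value
          nsteps <- nsteps + 1
        }
        # generator minimizes -mean D(fake)
        z <- matrix(stats::rnorm(bs * d_z), bs, d_z)
        fwG <- mlp_forward(G, z)
        fwD <- mlp_forward(D, fwG$out)
        dfake <- mlp_backward(D, fwD$cache, matrix(-1 / bs, bs, 1))$dX
        gG <- mlp_backward(G, fwG$cache, dfake)$grads
        r <- adam_step(G$layers, gG, stG, lr = config$gan_lr,
                       beta1 = 0.5, beta2 = 0.9)
        G$layers <- r$params; stG <- r$state
        g_acc <- g_acc - mean(fwD$out)
      }
      if (!all(is.finite(c(c_acc, p_acc, g_acc))))
        stop("WGAN-GP diverged at epoch ", ep, "; critic trace: ",
             paste(round(utils::tail(hist$critic, 5), 3), collapse = ", "))
      hist$critic <- c(hist$critic, c_acc / nsteps)
      hist$penalty <- c(hist$penalty, p_acc / nsteps)
      hist$gen <- c(hist$gen, g_acc / nbatch)
    }
  })
  structure(list(G = G, D = D, d_z = d_z, d_e = d_e, center = center,
                 scale = scale, history = hist),
            class = "gan_pair")
}

#' Sample synthetic latents from a trained generator
#'
#' @param gan a `gan_pair` (or bare generator `mlp` with a `d_z` attribute).
#' @param m number of samples (> 0); arbitrary, independent of the training
#'   set size.
#' @param seed seed for the noise draws.
#' @return m x d_e latent matrix.
#' @export
sample_latents <- function(gan, m, seed = 1L) {
  stopifnot(inherits(gan, "gan_pair"))
  if (m <= 0) stop("m must be positive")
  with_substream(seed, "gan-sample", {
    z <- matrix(stats::rnorm(m * gan$d_z), m, gan$d_z)
  })
  out <- mlp_forward(gan$G, z, keep_cache = FALSE)$out
  if (!is.null(gan$center))
    out <- sweep(sweep(out, 2, gan$scale, "*"), 2, gan$center, "+")
  out
}
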