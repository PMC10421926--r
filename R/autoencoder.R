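#' Training configuration for the autoencoder and latent GAN
#'
#' @param lambda balance between the binary-cross-entropy mask terms and the
#'   mean-squared value/time/embedding terms of the reconstruction loss
#'   (must be > 0; default 1).
#' @param d_e latent (encoder-state) width.
#' @param hidden hidden width of the recurrent and feed-forward blocks.
#' @param lr,batch_size,epochs Adam settings for the autoencoder.
#' @param d_z GAN noise width (default `d_e`).
#' @param eta gradient-penalty weight (default 10).
#' @param critic_steps critic updates per generator update (default 5).
#' @param gan_hidden,gan_lr,gan_epochs,gan_batch critic/generator MLP width
#'   and Adam settings.
#' @param cat_epochs training epochs for the categorical codecs.
#' @param seed master seed; all stages derive named substreams from it.
#' @return a `training_config` list.
#' @export
training_config <- function(lambda = 1, d_e = 64L, hidden = 128L, lr = 2e-3,
                            batch_size = 128L, epochs = 60L, d_z = NULL,
                            eta = 10, critic_steps = 5L, gan_hidden = 256L,
                            gan_lr = 1e-4, gan_epochs = 200L, gan_batch = 128L,
                            cat_epochs = 200L, seed = 1L) {
  stopifnot(lambda > 0, eta > 0, d_e >= 1, hidden >= 1, critic_steps >= 1)
  structure(list(lambda = lambda, d_e = as.integer(d_e),
                 hidden = as.integer(hidden), lr = lr,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 d_z = as.integer(d_z %||% d_e), eta = eta,
                 critic_steps = as.integer(critic_steps),
                 gan_hidden = as.integer(gan_hidden), gan_lr = gan_lr,
                 gan_epochs = as.integer(gan_epochs),
                 gan_batch = as.integer(gan_batch),
                 cat_epochs = as.integer(max(cat_epochs, 1L)),
                 seed = as.integer(seed)), class = "training_config")
}

normalize_feature <- function(v, p, seed, name) {
  if (inherits(p, "stochnorm")) normalize_values(v, p, substream_seed(seed, name))
  else minmax_normalize(v, p)
}

renormalize_feature <- function(v, p) {
  if (inherits(p, "stochnorm")) renormalize_values(v, p)
  else minmax_renormalize(v, p)
}

#' Assemble a model-space input bundle from a cohort
#'
#' Numeric features and measurement times are normalized to \[0, 1\] with
#' the fitted per-feature normalizers (jitter draws are seeded per feature,
#' so assembly is deterministic given the master seed); categorical features
#' are embedded with the trained codecs (missing entries go through the
#' missing slot); missing numerics become 0 in model space with mask 0; all
#' sequences are padded to `T_max` with zeros and `step_present = 0`.
#'
#' @param data an `ehr_cohort` (already truncated/padded to the schema's
#'   `max_seq_len`).
#' @param masks its `ehr_masks`.
#' @param norm_params a `stochnorm_set` from [fit_cohort_normalizers()]
#'   fitted on the training split.
#' @param static_codec,temporal_codec trained `ehr_codec`s (`NULL` when the
#'   schema has no features in that scope).
#' @param seed master seed for the normalization jitter.
#' @param mask_modeling if `FALSE` (ablation), masks are excluded from the
#'   model inputs and losses and missing numerics are imputed with the
#'   observed mean in normalized space.
#' @return an `ehr_bundle`: arrays in model space plus the mask channels.
#' @export
assemble_inputs <- function(data, masks, norm_params, static_codec = NULL,
                            temporal_codec = NULL, seed = 1L,
                            mask_modeling = TRUE) {
  sch <- data$schema
  n <- n_records(data)
  tmax <- sch$max_seq_len
  if (!inherits(norm_params, c("stochnorm_set", "minmax_set")))
    stop("unfitted component: norm_params")
  if (length(sch$static_categorical) && is.null(static_codec))
    stop("unfitted component: static_codec")
  if (length(sch$temporal_categorical) && is.null(temporal_codec))
    stop("unfitted component: temporal_codec")

  fill0 <- function(v, m) { v[m == 0] <- 0; v }
  impute_mean <- function(v, m) {
    mu <- if (any(m == 1)) mean(v[m == 1]) else 0.5
    v[m == 0] <- mu
    v
  }
  s_n <- matrix(0, n, length(sch$static_numeric),
                dimnames = list(NULL, sch$static_numeric))
  for (f in sch$static_numeric) {
    vn <- normalize_feature(data$static_num[, f], norm_params[[f]], seed, f)
    s_n[, f] <- if (mask_modeling) fill0(ifelse(is.na(vn), 0, vn), masks$m_sn[, f])
    else impute_mean(ifelse(is.na(vn), 0, vn), masks$m_sn[, f])
  }
  t_n <- array(0, c(n, tmax, length(sch$temporal_numeric)),
               dimnames = list(NULL, NULL, sch$temporal_numeric))
  for (f in sch$temporal_numeric) {
    v <- as.vector(data$temporal_num[, , f])
    vn <- normalize_feature(v, norm_params[[f]], seed, f)
    m <- as.vector(masks$m_tn[, , f]) * as.vector(masks$step_present)
    vn <- ifelse(is.na(vn), 0, vn)
    vn <- if (mask_modeling) fill0(vn, m) else {
      vi <- impute_mean(vn, m)
      fill0(vi, as.vector(masks$step_present))  # padding stays 0
    }
    t_n[, , f] <- vn
  }
  u <- matrix(0, n, tmax)
  uo <- which(masks$step_present == 1)
  u[uo] <- normalize_feature(data$time[uo], norm_params[[sch$time_name]],
                             seed, sch$time_name)

  d_cs <- if (is.null(static_codec)) 0L else static_codec$d_c
  s_ce <- matrix(0, n, d_cs)
  if (d_cs > 0) s_ce <- encode_categoricals(data$static_cat, static_codec)
  d_ct <- if (is.null(temporal_codec)) 0L else temporal_codec$d_c
  t_ce <- array(0, c(n, tmax, d_ct))
  if (d_ct > 0) {
    pres <- which(masks$step_present == 1)  # cell index into n x tmax
    flat <- matrix(NA_character_, length(pres), length(sch$temporal_categorical),
                   dimnames = list(NULL, names(sch$temporal_categorical)))
    for (k in seq_along(sch$temporal_categorical))
      flat[, k] <- data$temporal_cat[, , k][pres]
    emb <- encode_categoricals(flat, temporal_codec)
    for (j in seq_len(d_ct)) {
      slab <- matrix(0, n, tmax)
      slab[pres] <- emb[, j]
      t_ce[, , j] <- slab
    }
  }
  any_sc <- if (ncol(masks$m_sc)) (rowSums(masks$m_sc) > 0) + 0 else rep(0, n)
  any_tc <- if (dim(masks$m_tc)[3]) (apply(masks$m_tc, c(1, 2), sum) > 0) + 0
  else matrix(0, n, tmax)

  structure(list(
    s_n = s_n, s_ce = s_ce, t_n = t_n, t_ce = t_ce, u = u,
    m_sn = masks$m_sn, m_sc = masks$m_sc, m_tn = masks$m_tn,
    m_tc = masks$m_tc, step_present = masks$step_present,
    any_sc = any_sc, any_tc = any_tc,
    schema = sch, mask_modeling = mask_modeling,
    dims = list(p_sn = length(sch$static_numeric), d_cs = d_cs,
                q_sc = length(sch$static_categorical),
                p_tn = length(sch$temporal_numeric), d_ct = d_ct,
                q_tc = length(sch$temporal_categorical), tmax = tmax)
  ), class = "ehr_bundle")
}

# Column layouts of the per-step and static blocks in model space.
ae_layout <- function(dims, mask_modeling) {
  nxt <- function(start, k) if (k > 0) seq.int(start, start + k - 1L) else integer(0)
  p <- dims
  i <- 1L
  si <- list(tn = nxt(i, p$p_tn)); i <- i + p$p_tn
  si$tce <- nxt(i, p$d_ct); i <- i + p$d_ct
  si$u <- nxt(i, 1L); i <- i + 1L
  if (mask_modeling) {
    si$mtn <- nxt(i, p$p_tn); i <- i + p$p_tn
    si$mtc <- nxt(i, p$q_tc); i <- i + p$q_tc
  } else { si$mtn <- integer(0); si$mtc <- integer(0) }
  si$sp <- nxt(i, 1L); i <- i + 1L
  d_step <- i - 1L
  i <- 1L
  st <- list(sn = nxt(i, p$p_sn)); i <- i + p$p_sn
  st$sce <- nxt(i, p$d_cs); i <- i + p$d_cs
  if (mask_modeling) {
    st$msn <- nxt(i, p$p_sn); i <- i + p$p_sn
    st$msc <- nxt(i, p$q_sc); i <- i + p$q_sc
  } else { st$msn <- integer(0); st$msc <- integer(0) }
  d_stat <- i - 1L
  list(step = si, stat = st, d_step = d_step, d_stat = d_stat)
}

ae_init <- function(dims, config, mask_modeling) {
  ly <- ae_layout(dims, mask_modeling)
  h <- config$hidden; d_e <- config$d_e
  with_substream(config$seed, "ae-init", list(
    enc_gru = gru_init(ly$d_step, h),
    enc_stat = dense_init(ly$d_stat, h),
    enc_out = dense_init(2L * h, d_e),
    dec_h0 = dense_init(d_e, h),
    dec_gru = gru_init(d_e, h),
    dec_step = dense_init(h, ly$d_step),
    dec_stat1 = dense_init(d_e, h),
    dec_stat2 = dense_init(h, ly$d_stat)
  ))
}

# Per-step model-space input matrices for a record subset.
ae_step_inputs <- function(bundle, idx, ly) {
  tmax <- bundle$dims$tmax
  n <- length(idx)
  X <- vector("list", tmax)
  for (t in seq_len(tmax)) {
    x <- matrix(0, n, ly$d_step)
    if (length(ly$step$tn)) x[, ly$step$tn] <- bundle$t_n[idx, t, , drop = FALSE]
    if (length(ly$step$tce)) x[, ly$step$tce] <- bundle$t_ce[idx, t, , drop = FALSE]
    x[, ly$step$u] <- bundle$u[idx, t]
    if (length(ly$step$mtn)) x[, ly$step$mtn] <- bundle$m_tn[idx, t, , drop = FALSE]
    if (length(ly$step$mtc)) x[, ly$step$mtc] <- bundle$m_tc[idx, t, , drop = FALSE]
    x[, ly$step$sp] <- bundle$step_present[idx, t]
    X[[t]] <- x
  }
  X
}

ae_static_input <- function(bundle, idx, ly) {
  x <- matrix(0, length(idx), ly$d_stat)
  if (length(ly$stat$sn)) x[, ly$stat$sn] <- bundle$s_n[idx, , drop = FALSE]
  if (length(ly$stat$sce)) x[, ly$stat$sce] <- bundle$s_ce[idx, , drop = FALSE]
  if (length(ly$stat$msn)) x[, ly$stat$msn] <- bundle$m_sn[idx, , drop = FALSE]
  if (length(ly$stat$msc)) x[, ly$stat$msc] <- bundle$m_sc[idx, , drop = FALSE]
  x
}

ae_encode <- function(params, Xs, x_stat, keep_cache = FALSE) {
  g <- gru_forward(params$enc_gru, Xs, keep_cache = keep_cache)
  zs <- sweep(x_stat %*% params$enc_stat$W, 2, params$enc_stat$b, "+")
  a_s <- tanh(zs)
  comb <- cbind(g$h_last, a_s)
  e <- sweep(comb %*% params$enc_out$W, 2, params$enc_out$b, "+")
  list(e = e, g = g, a_s = a_s, comb = comb, x_stat = x_stat)
}

ae_decode <- function(params, e, tmax, keep_cache = FALSE) {
  h0 <- tanh(sweep(e %*% params$dec_h0$W, 2, params$dec_h0$b, "+"))
  Xd <- rep(list(e), tmax)
  g <- gru_forward(params$dec_gru, Xd, h0 = h0, keep_cache = keep_cache)
  Y <- lapply(g$H, function(h) sweep(h %*% params$dec_step$W, 2,
                                     params$dec_step$b, "+"))
  a_d <- tanh(sweep(e %*% params$dec_stat1$W, 2, params$dec_stat1$b, "+"))
  s_out <- sweep(a_d %*% params$dec_stat2$W, 2, params$dec_stat2$b, "+")
  list(Y = Y, s_out = s_out, g = g, h0 = h0, a_d = a_d, e = e)
}

# Training loss on logits plus the adjoints of every decoder output block.
# Returns value, dY (list over steps) and d_s_out.
ae_loss_and_adjoints <- function(dec, bundle, idx, ly, lambda, mask_modeling) {
  tmax <- bundle$dims$tmax
  n <- length(idx)
  sp <- bundle$step_present[idx, , drop = FALSE]
  dY <- lapply(seq_len(tmax), function(t) matrix(0, n, ly$d_step))
  # each term is a mean over the whole minibatch (all steps jointly), so we
  # assemble stacked arrays rather than per-step means
  stack <- function(cols) {
    arr <- array(0, c(n, tmax, length(cols)))
    for (t in seq_len(tmax)) arr[, t, ] <- dec$Y[[t]][, cols, drop = FALSE]
    arr
  }
  unstack_add <- function(cols, grad_arr) {
    for (t in seq_len(tmax))
      dY[[t]][, cols] <<- dY[[t]][, cols] + grad_arr[, t, , drop = TRUE]
  }
  terms <- list()
  # temporal numeric values: mask- and presence-gated MSE
  if (length(ly$step$tn)) {
    w <- if (mask_modeling) bundle$m_tn[idx, , , drop = FALSE] *
      array(sp, dim(bundle$m_tn[idx, , , drop = FALSE])) else
        array(sp, c(n, tmax, bundle$dims$p_tn))
    r <- mse_masked(stack(ly$step$tn), bundle$t_n[idx, , , drop = FALSE], w)
    terms$t_n <- lambda * r$value
    unstack_add(ly$step$tn, lambda * r$grad)
  }
  # temporal categorical embeddings
  if (length(ly$step$tce)) {
    gate <- if (mask_modeling) bundle$any_tc[idx, , drop = FALSE] * sp else sp
    w <- array(gate, c(n, tmax, bundle$dims$d_ct))
    r <- mse_masked(stack(ly$step$tce), bundle$t_ce[idx, , , drop = FALSE], w)
    terms$t_ce <- lambda * r$value
    unstack_add(ly$step$tce, lambda * r$grad)
  }
  # time
  {
    w <- array(sp, c(n, tmax, 1L))
    r <- mse_masked(stack(ly$step$u), array(bundle$u[idx, , drop = FALSE],
                                            c(n, tmax, 1L)), w)
    terms$u <- lambda * r$value
    unstack_add(ly$step$u, lambda * r$grad)
  }
  # temporal mask logits (BCE), presence-gated
  if (length(ly$step$mtn)) {
    w <- array(sp, c(n, tmax, bundle$dims$p_tn))
    r <- bce_logits(stack(ly$step$mtn), bundle$m_tn[idx, , , drop = FALSE], w)
    terms$m_tn <- r$value
    unstack_add(ly$step$mtn, r$grad)
  }
  if (length(ly$step$mtc)) {
    w <- array(sp, c(n, tmax, bundle$dims$q_tc))
    r <- bce_logits(stack(ly$step$mtc), bundle$m_tc[idx, , , drop = FALSE], w)
    terms$m_tc <- r$value
    unstack_add(ly$step$mtc, r$grad)
  }
  # step_present logits over all steps
  {
    r <- bce_logits(stack(ly$step$sp), array(sp, c(n, tmax, 1L)))
    terms$sp <- r$value
    unstack_add(ly$step$sp, r$grad)
  }
  # static blocks
  d_s_out <- matrix(0, n, ly$d_stat)
  if (length(ly$stat$sn)) {
    w <- if (mask_modeling) bundle$m_sn[idx, , drop = FALSE] else NULL
    r <- mse_masked(dec$s_out[, ly$stat$sn, drop = FALSE],
                    bundle$s_n[idx, , drop = FALSE], w)
    terms$s_n <- lambda * r$value
    d_s_out[, ly$stat$sn] <- lambda * r$grad
  }
  if (length(ly$stat$sce)) {
    gate <- if (mask_modeling) bundle$any_sc[idx] else rep(1, n)
    w <- matrix(gate, n, bundle$dims$d_cs)
    r <- mse_masked(dec$s_out[, ly$stat$sce, drop = FALSE],
                    bundle$s_ce[idx, , drop = FALSE], w)
    terms$s_ce <- lambda * r$value
    d_s_out[, ly$stat$sce] <- lambda * r$grad
  }
  if (length(ly$stat$msn)) {
    r <- bce_logits(dec$s_out[, ly$stat$msn, drop = FALSE],
                    bundle$m_sn[idx, , drop = FALSE])
    terms$m_sn <- r$value
    d_s_out[, ly$stat$msn] <- r$grad
  }
  if (length(ly$stat$msc)) {
    r <- bce_logits(dec$s_out[, ly$stat$msc, drop = FALSE],
                    bundle$m_sc[idx, , drop = FALSE])
    terms$m_sc <- r$value
    d_s_out[, ly$stat$msc] <- r$grad
  }
  list(value = sum(unlist(terms)), terms = terms, dY = dY, d_s_out = d_s_out)
}

ae_backward <- function(params, enc, dec, la) {
  tmax <- length(dec$Y)
  # decoder step head
  dW_step <- params$dec_step$W * 0; db_step <- params$dec_step$b * 0
  dH <- vector("list", tmax)
  for (t in seq_len(tmax)) {
    dW_step <- dW_step + crossprod(dec$g$H[[t]], la$dY[[t]])
    db_step <- db_step + colSums(la$dY[[t]])
    dH[[t]] <- tcrossprod(la$dY[[t]], params$dec_step$W)
  }
  bg <- gru_backward(params$dec_gru, dec$g$cache, dH = dH)
  de <- Reduce(`+`, bg$dX)
  # dec_h0
  da_h0 <- bg$dh0 * (1 - dec$h0^2)
  g_dec_h0 <- list(W = crossprod(dec$e, da_h0), b = colSums(da_h0))
  de <- de + tcrossprod(da_h0, params$dec_h0$W)
  # static decoder
  g_dec_stat2 <- list(W = crossprod(dec$a_d, la$d_s_out),
                      b = colSums(la$d_s_out))
  da_d <- tcrossprod(la$d_s_out, params$dec_stat2$W) * (1 - dec$a_d^2)
  g_dec_stat1 <- list(W = crossprod(dec$e, da_d), b = colSums(da_d))
  de <- de + tcrossprod(da_d, params$dec_stat1$W)
  # encoder output
  g_enc_out <- list(W = crossprod(enc$comb, de), b = colSums(de))
  dcomb <- tcrossprod(de, params$enc_out$W)
  h <- ncol(enc$g$h_last)
  dh_last <- dcomb[, seq_len(h), drop = FALSE]
  da_s <- dcomb[, h + seq_len(h), drop = FALSE]
  beg <- gru_backward(params$enc_gru, enc$g$cache, dh_last = dh_last)
  da_sz <- da_s * (1 - enc$a_s^2)
  g_enc_stat <- list(W = crossprod(enc$x_stat, da_sz), b = colSums(da_sz))
  list(enc_gru = beg$grads, enc_stat = g_enc_stat, enc_out = g_enc_out,
       dec_h0 = g_dec_h0, dec_gru = bg$grads,
       dec_step = list(W = dW_step, b = db_step),
       dec_stat1 = g_dec_stat1, dec_stat2 = g_dec_stat2)
}

#' Train the masked sequential autoencoder
#'
#' A GRU encoder consumes per-step concatenations of normalized temporal
#' values, temporal categorical embeddings, normalized time, temporal masks
#' and the step-presence channel; its final state joins a feed-forward
#' static branch and is projected to the latent state `e`. The decoder
#' mirrors this (latent to static heads plus a GRU unrolled for `T_max`
#' steps). Training minimizes the mask-gated reconstruction loss: binary
#' cross entropy on every mask channel plus `lambda` times mean squared
#' error on times, values and embeddings, where entries with mask 0 and
#' padded steps contribute exactly nothing.
#'
#' @param bundle an `ehr_bundle` from [assemble_inputs()].
#' @param config a [training_config()].
#' @return an `ehr_autoencoder`: trained parameters, layout, config and the
#'   per-epoch loss history.
#' @export
train_autoencoder <- function(bundle, config) {
  stopifnot(inherits(bundle, "ehr_bundle"), inherits(config, "training_config"))
  ly <- ae_layout(bundle$dims, bundle$mask_modeling)
  params <- ae_init(bundle$dims, config, bundle$mask_modeling)
  st <- adam_init(params)
  n <- nrow(bundle$s_n)
  history <- numeric(config$epochs)
  last_finite <- params
  X_full <- ae_step_inputs(bundle, seq_len(n), ly)
  x_stat_full <- ae_static_input(bundle, seq_len(n), ly)
  with_substream(config$seed, "ae-train", {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      tot <- 0; nb <- 0
      for (b in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
        Xs <- lapply(X_full, function(m) m[b, , drop = FALSE])
        xs <- x_stat_full[b, , drop = FALSE]
        enc <- ae_encode(params, Xs, xs, keep_cache = TRUE)
        dec <- ae_decode(params, enc$e, bundle$dims$tmax, keep_cache = TRUE)
        la <- ae_loss_and_adjoints(dec, bundle, b, ly, config$lambda,
                                   bundle$mask_modeling)
        if (!is.finite(la$value))
          stop(structure(class = c("synthehr_divergence", "error", "condition"),
                         list(message = "autoencoder loss diverged (NaN)",
                              call = sys.call(), model = last_finite)))
        grads <- ae_backward(params, enc, dec, la)
        r <- adam_step(params, grads, st, lr = config$lr)
        params <- r$params; st <- r$state
        tot <- tot + la$value; nb <- nb + 1
      }
      history[ep] <- tot / nb
      last_finite <- params
    }
  })
  structure(list(params = params, layout = ly, dims = bundle$dims,
                 mask_modeling = bundle$mask_modeling, config = config,
                 history = history, schema = bundle$schema),
            class = "ehr_autoencoder")
}

ae_checksum <- function(model) {
  round(sum(abs(unlist(model$params))) %% 1e6, 6)
}

#' Encode a bundle into latent states
#'
#' @param bundle an `ehr_bundle` compatible with the model's schema.
#' @param model an `ehr_autoencoder`.
#' @return N x d_e latent matrix with a `checksum` attribute tying it to the
#'   encoder parameters.
#' @export
encode_dataset <- function(bundle, model) {
  stopifnot(inherits(model, "ehr_autoencoder"))
  if (!identical(bundle$dims, model$dims))
    stop("schema/bundle mismatch with trained encoder")
  ly <- model$layout
  idx <- seq_len(nrow(bundle$s_n))
  enc <- ae_encode(model$params, ae_step_inputs(bundle, idx, ly),
                   ae_static_input(bundle, idx, ly))
  structure(enc$e, checksum = ae_checksum(model))
}

# Decoder-only forward pass: latent matrix -> model-space prediction bundle
# (mask channels as probabilities).
decode_latents <- function(model, e) {
  stopifnot(inherits(model, "ehr_autoencoder"), ncol(e) == model$config$d_e)
  ly <- model$layout
  dims <- model$dims
  dec <- ae_decode(model$params, e, dims$tmax)
  n <- nrow(e)
  pick_step <- function(cols) {
    arr <- array(0, c(n, dims$tmax, length(cols)))
    for (t in seq_len(dims$tmax)) arr[, t, ] <- dec$Y[[t]][, cols, drop = FALSE]
    arr
  }
  out <- list(
    s_n = dec$s_out[, ly$stat$sn, drop = FALSE],
    s_ce = dec$s_out[, ly$stat$sce, drop = FALSE],
    t_n = pick_step(ly$step$tn),
    t_ce = pick_step(ly$step$tce),
    u = matrix(pick_step(ly$step$u), n, dims$tmax),
    m_sn = if (length(ly$stat$msn)) sigmoid(dec$s_out[, ly$stat$msn, drop = FALSE])
    else matrix(1, n, dims$p_sn),
    m_sc = if (length(ly$stat$msc)) sigmoid(dec$s_out[, ly$stat$msc, drop = FALSE])
    else matrix(1, n, dims$q_sc),
    m_tn = if (length(ly$step$mtn)) sigmoid(pick_step(ly$step$mtn))
    else array(1, c(n, dims$tmax, dims$p_tn)),
    m_tc = if (length(ly$step$mtc)) sigmoid(pick_step(ly$step$mtc))
    else array(1, c(n, dims$tmax, dims$q_tc)),
    step_present = matrix(sigmoid(pick_step(ly$step$sp)), n, dims$tmax)
  )
  out
}

# Per-feature residual standard deviations of the decoder heads on the
# training data: the scale of the Gaussian observation model implied by the
# MSE objective, used by the sampling read-out at synthesis.
residual_sds <- function(model, latents, bundle) {
  pred <- decode_latents(model, latents)
  sp <- bundle$step_present
  d <- bundle$dims
  sd_of <- function(res, w) {
    v <- res[w == 1]
    if (length(v) < 2) 0 else stats::sd(v)
  }
  t_n <- vapply(seq_len(d$p_tn), function(k)
    sd_of(pred$t_n[, , k] - bundle$t_n[, , k], bundle$m_tn[, , k] * sp), 0)
  t_ce <- vapply(seq_len(d$d_ct), function(j)
    sd_of(pred$t_ce[, , j] - bundle$t_ce[, , j], bundle$any_tc * sp), 0)
  s_n <- vapply(seq_len(d$p_sn), function(k)
    sd_of(pred$s_n[, k] - bundle$s_n[, k], bundle$m_sn[, k]), 0)
  s_ce <- vapply(seq_len(d$d_cs), function(j)
    sd_of(pred$s_ce[, j] - bundle$s_ce[, j], bundle$any_sc), 0)
  u <- sd_of(pred$u - bundle$u, sp)
  list(t_n = t_n, t_ce = t_ce, s_n = s_n, s_ce = s_ce, u = u)
}

#' Masked reconstruction loss in probability space
#'
#' The evaluation-side counterpart of the training objective: binary cross
#' entropy (with the exact `0*log(0) = 0` convention, so perfect `{0,1}`
#' mask predictions score zero) over the four mask blocks and the
#' step-presence channel, plus `lambda` times mean squared error over times,
#' numeric values and categorical embeddings. Every MSE term is gated by the
#' target masks: entries with mask 0, and padded steps, contribute exactly
#' nothing, so perturbing them leaves the loss bit-identical.
#'
#' @param pred a prediction bundle as produced by the decoder
#'   (mask channels as probabilities in \[0, 1\]).
#' @param target an `ehr_bundle` of the same shape.
#' @param lambda balance weight (> 0).
#' @return scalar loss.
#' @export
reconstruction_loss <- function(pred, target, lambda = 1) {
  stopifnot(inherits(target, "ehr_bundle"), lambda > 0)
  if (any(!vapply(pred, function(x) all(is.finite(as.numeric(x))), TRUE)))
    stop("non-finite prediction")
  sp <- target$step_present
  n <- nrow(sp); tmax <- ncol(sp)
  d <- target$dims
  sp_tn <- array(sp, c(n, tmax, d$p_tn))
  sp_tc <- array(sp, c(n, tmax, d$q_tc))
  val <- bce_prob_exact(pred$m_sn, target$m_sn) +
    bce_prob_exact(pred$m_sc, target$m_sc) +
    bce_prob_exact(pred$m_tn, target$m_tn, sp_tn) +
    bce_prob_exact(pred$m_tc, target$m_tc, sp_tc) +
    bce_prob_exact(pred$step_present, sp)
  mse <- function(p, t, w) mse_masked(p, t, w)$value
  val + lambda * (
    mse(pred$u, target$u, sp) +
      mse(pred$s_n, target$s_n, target$m_sn) +
      mse(pred$s_ce, target$s_ce, matrix(target$any_sc, n, d$d_cs)) +
      mse(pred$t_n, target$t_n, target$m_tn * sp_tn) +
      mse(pred$t_ce, target$t_ce, array(target$any_tc * sp, c(n, tmax, d$d_ct))))
}
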