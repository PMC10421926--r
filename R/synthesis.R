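#' Derive sequence lengths from decoded step-presence probabilities
#'
#' The per-step presence channel is thresholded at 0.5 and the generated
#' length is the leading run of ones, floored at 1 (the minimum observed
#' sequence length).
#'
#' @param probs N x T_max matrix of probabilities in \[0, 1\].
#' @param t_max maximum length (defaults to `ncol(probs)`).
#' @return integer vector of lengths in `[1, t_max]`.
#' @export
derive_sequence_lengths <- function(probs, t_max = ncol(probs)) {
  stopifnot(all(probs >= 0 & probs <= 1))
  on <- probs >= 0.5
  lens <- apply(on, 1, function(r) {
    z <- which(!r)
    if (!length(z)) length(r) else z[1] - 1L
  })
  pmax(pmin(as.integer(lens), as.integer(t_max)), 1L)
}

#' Generate a synthetic cohort from the trained model components
#'
#' Runs the inference pipeline: sample latents from the generator, decode
#' them with the trained decoder, binarize all mask channels at 0.5, derive
#' sequence lengths from the step-presence channel, decode categorical
#' embeddings with the frozen codec heads, renormalize numerics and times
#' back to the original value space, and emit entries with mask 0 as
#' missing. The mask channel is authoritative for categorical missingness:
#' if the mask says observed but the codec head argmaxes the missing slot,
#' the best non-missing category is taken; if the mask says missing, the
#' entry is missing regardless of the head. Times are sorted non-decreasing
#' within each record. Byte-identical output per seed.
#'
#' @param model an `ehr_generator` from [train_ehr_generator()] (or a list with
#'   members `gan`, `autoencoder`, `norm_params`, `static_codec`,
#'   `temporal_codec`, `schema`).
#' @param m number of synthetic records (> 0).
#' @param seed seed for the noise draws.
#' @param mask_readout how decoded mask probabilities become binary masks:
#'   `"sample"` (default) draws seeded Bernoulli variables from the decoded
#'   probabilities -- the natural read-out of a Bernoulli (BCE-trained) head,
#'   which coincides with thresholding wherever reconstruction is sharp and
#'   preserves missing rates where per-entry missingness is irreducible
#'   noise; `"threshold"` binarizes at 0.5.
#' @param value_readout how decoded numeric/time/embedding heads are read:
#'   `"sample"` (default) draws from the Gaussian observation model implied
#'   by the MSE objective (decoded mean plus seeded noise at the stored
#'   per-feature training residual SD); `"mean"` emits the decoded
#'   conditional mean.
#' @return list with `data` (`ehr_cohort`) and `masks` (`ehr_masks`).
#' @export
synthesize <- function(model, m, seed = 1L,
                       mask_readout = c("sample", "threshold"),
                       value_readout = c("sample", "mean")) {
  mask_readout <- match.arg(mask_readout)
  value_readout <- match.arg(value_readout)
  if (m <= 0) stop("m must be positive")
  sch <- model$schema
  ae <- model$autoencoder
  if (!identical(sch$max_seq_len, ae$dims$tmax))
    stop("component mismatch: schema T_max differs from trained decoder")
  e_hat <- sample_latents(model$gan, m, seed = seed)
  pred <- decode_latents(ae, e_hat)
  tmax <- sch$max_seq_len
  rsd <- model$residual_sd
  if (value_readout == "sample" && !is.null(rsd)) {
    jit <- function(x, s, name) {
      if (all(s == 0)) return(x)
      with_substream(seed, paste0("value-", name), {
        noise <- array(stats::rnorm(length(x)), dim(x))
        if (length(s) > 1)  # per-feature scale on the last array margin
          noise <- sweep(noise, length(dim(x)), s, "*")
        else noise <- noise * s
        x + noise
      })
    }
    if (length(rsd$t_n)) pred$t_n <- jit(pred$t_n, rsd$t_n, "tn")
    if (length(rsd$t_ce)) pred$t_ce <- jit(pred$t_ce, rsd$t_ce, "tce")
    if (length(rsd$s_n)) pred$s_n <- jit(pred$s_n, rsd$s_n, "sn")
    if (length(rsd$s_ce)) pred$s_ce <- jit(pred$s_ce, rsd$s_ce, "sce")
    pred$u <- jit(pred$u, rsd$u, "u")
  }
  binarize <- function(p, name) {
    if (mask_readout == "threshold") (p >= 0.5) + 0
    else with_substream(seed, paste0("mask-", name),
                        (array(stats::runif(length(p)), dim(p)) < p) + 0)
  }
  sp_bin <- binarize(pred$step_present, "sp")
  lens <- derive_sequence_lengths(sp_bin, tmax)
  sp <- matrix(0, m, tmax)
  for (i in seq_len(m)) sp[i, seq_len(lens[i])] <- 1

  m_sn <- binarize(pred$m_sn, "sn")
  m_sc <- binarize(pred$m_sc, "sc")
  m_tn <- binarize(pred$m_tn, "tn") * array(sp, dim(pred$m_tn))
  m_tc <- binarize(pred$m_tc, "tc") * array(sp, dim(pred$m_tc))

  # numerics: renormalize observed entries only
  sn <- matrix(NA_real_, m, length(sch$static_numeric),
               dimnames = list(NULL, sch$static_numeric))
  for (k in seq_along(sch$static_numeric)) {
    f <- sch$static_numeric[k]
    obs <- m_sn[, k] == 1
    sn[obs, k] <- renormalize_feature(clamp(pred$s_n[obs, k], 0, 1),
                                      model$norm_params[[f]])
  }
  tn <- array(NA_real_, c(m, tmax, length(sch$temporal_numeric)),
              dimnames = list(NULL, NULL, sch$temporal_numeric))
  for (k in seq_along(sch$temporal_numeric)) {
    f <- sch$temporal_numeric[k]
    obs <- which(m_tn[, , k] == 1)
    slab <- matrix(NA_real_, m, tmax)
    slab[obs] <- renormalize_feature(clamp(pred$t_n[, , k][obs], 0, 1),
                                     model$norm_params[[f]])
    tn[, , k] <- slab
  }
  # times: renormalize, then sort non-decreasing within the record
  tim <- matrix(NA_real_, m, tmax)
  for (i in seq_len(m)) {
    ui <- renormalize_feature(clamp(pred$u[i, seq_len(lens[i])], 0, 1),
                              model$norm_params[[sch$time_name]])
    tim[i, seq_len(lens[i])] <- sort(ui)
  }

  # categoricals via the frozen codec heads; mask channel authoritative
  sc <- matrix(NA_character_, m, length(sch$static_categorical),
               dimnames = list(NULL, names(sch$static_categorical)))
  if (length(sch$static_categorical)) {
    dec <- decode_categoricals(pred$s_ce, model$static_codec)
    for (k in seq_along(sch$static_categorical)) {
      v <- dec$values[, k]
      need <- m_sc[, k] == 1 & is.na(v)  # mask says observed, head says missing
      if (any(need)) {
        p <- dec$probs[[k]][need, -ncol(dec$probs[[k]]), drop = FALSE]
        v[need] <- sch$static_categorical[[k]][max.col(p, ties.method = "first")]
      }
      v[m_sc[, k] == 0] <- NA
      sc[, k] <- v
    }
  }
  tc <- array(NA_character_, c(m, tmax, length(sch$temporal_categorical)),
              dimnames = list(NULL, NULL, names(sch$temporal_categorical)))
  if (length(sch$temporal_categorical)) {
    pres <- which(sp == 1)
    emb <- matrix(0, length(pres), ae$dims$d_ct)
    for (j in seq_len(ae$dims$d_ct)) emb[, j] <- pred$t_ce[, , j][pres]
    dec <- decode_categoricals(emb, model$temporal_codec)
    for (k in seq_along(sch$temporal_categorical)) {
      v <- dec$values[, k]
      mk <- m_tc[, , k][pres]
      need <- mk == 1 & is.na(v)
      if (any(need)) {
        p <- dec$probs[[k]][need, -ncol(dec$probs[[k]]), drop = FALSE]
        v[need] <- sch$temporal_categorical[[k]][max.col(p, ties.method = "first")]
      }
      v[mk == 0] <- NA
      slab <- matrix(NA_character_, m, tmax)
      slab[pres] <- v
      tc[, , k] <- slab
    }
  }

  data <- ehr_cohort(sch, sprintf("s%06d", seq_len(m)), sn, sc, lens, tim,
                     tn, tc)
  validate_cohort(data)
  list(data = data, masks = derive_masks(data))
}

#' Bucket-ratio matching post-processing
#'
#' A non-trainable refinement of a synthetic numeric sample: the real
#' sample's quantiles define `n_buckets` intervals; synthetic values are
#' reassigned rank-preservingly so that per-bucket proportions match the
#' real proportions (cumulative rounding keeps boundary mismatch below one
#' sample), and within each bucket the output values are draws from the
#' real sample's empirical distribution in that bucket, sorted so the
#' synthetic rank order is preserved. Idempotent for a fixed seed and
#' monotone in the input ranks.
#'
#' @param real_values observed real sample (no `NA`).
#' @param synth_values synthetic sample to adjust (no `NA`).
#' @param n_buckets number of quantile buckets (>= 2); collapsed with a
#'   warning when the real sample has fewer distinct quantile edges.
#' @param seed seed for the within-bucket draws.
#' @return adjusted synthetic sample, same length as `synth_values`.
#' @export
bucket_match_postprocess <- function(real_values, synth_values,
                                     n_buckets = 200L, seed = 1L) {
  stopifnot(length(real_values) > 0, length(synth_values) > 0,
            !anyNA(real_values), !anyNA(synth_values), n_buckets >= 2)
  edges <- stats::quantile(real_values, probs = seq(0, 1, length.out = n_buckets + 1L),
                           names = FALSE)
  uedges <- unique(edges)
  if (length(uedges) < length(edges)) {
    warning("quantile edges collapsed: using ", length(uedges) - 1L,
            " buckets instead of ", n_buckets)
    edges <- uedges
  }
  nb <- length(edges) - 1L
  # bucket of each real value: intervals [e_j, e_{j+1}), last closed
  bucket_of <- function(x) pmin(pmax(findInterval(x, edges,
                                                  rightmost.closed = TRUE), 1L), nb)
  rb <- bucket_of(real_values)
  real_counts <- tabulate(rb, nbins = nb)
  ns <- length(synth_values)
  # target synthetic counts by cumulative rounding of real proportions
  cum_target <- round(cumsum(real_counts) / length(real_values) * ns)
  target <- diff(c(0L, cum_target))
  ord <- order(synth_values)
  out <- numeric(ns)
  pos <- 0L
  with_substream(seed, "bucket-match", {
    for (j in seq_len(nb)) {
      k <- target[j]
      if (k == 0L) next
      pool <- real_values[rb == j]
      draws <- sort(pool[sample.int(length(pool), k, replace = TRUE)])
      out[ord[pos + seq_len(k)]] <- draws
      pos <- pos + k
    }
  })
  out
}
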