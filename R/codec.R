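#' One-hot encode a categorical column with an explicit missing slot
#'
#' Each entry maps to an indicator over the vocabulary plus one trailing
#' "missing" slot, so exactly one slot is set per entry and unobserved
#' entries have a well-defined encoding. The observation mask is still kept
#' separately and remains authoritative at synthesis time.
#'
#' @param values character vector (`NA` = missing).
#' @param vocabulary character vector of allowed categories (ordered).
#' @param feature feature name used in error messages.
#' @return n x (V + 1) binary matrix; columns named by category plus
#'   `".missing"`.
#' @export
one_hot <- function(values, vocabulary, feature = "feature") {
  idx <- match(values, vocabulary)
  bad <- !is.na(values) & is.na(idx)
  if (any(bad)) stop("out-of-vocabulary value '", values[which(bad)[1]],
                     "' for feature '", feature, "'")
  idx[is.na(idx)] <- length(vocabulary) + 1L
  m <- matrix(0, length(values), length(vocabulary) + 1L,
              dimnames = list(NULL, c(vocabulary, ".missing")))
  m[cbind(seq_along(values), idx)] <- 1
  m
}

onehot_block <- function(cat_matrix, vocabs) {
  if (length(vocabs) == 0L) return(matrix(0, nrow(cat_matrix), 0))
  do.call(cbind, lapply(names(vocabs), function(f)
    one_hot(cat_matrix[, f], vocabs[[f]], f)))
}

#' Train a categorical encoder / multi-head decoder codec
#'
#' A single-hidden-layer perceptron encoder maps the concatenated one-hot
#' blocks of K categorical features (each with its missing slot) to a
#' compact `d_c`-dimensional embedding; K linear-softmax decoder heads map
#' the embedding back to per-feature probability vectors. Encoder and heads
#' are trained jointly by the sum over heads of the softmax cross entropy.
#' Separate codecs are trained for static and temporal scopes; the temporal
#' codec is applied per time step with shared weights.
#'
#' @param cat_matrix character matrix of raw values (rows = entries: patients
#'   for static scope, patient-steps for temporal scope), `NA` = missing.
#' @param vocabs named list of vocabularies, one per column of `cat_matrix`.
#' @param d_c embedding width; default `min(16, ceiling(sum(V_k) / 2))`.
#'   A warning is issued if `d_c` does not compress the one-hot width.
#' @param scope `"static"` or `"temporal"`; decoding checks the scope.
#' @param epochs,lr,batch_size optimizer settings (Adam).
#' @param accuracy_floor training fails with an error if round-trip argmax
#'   accuracy on the training entries falls below this floor.
#' @param seed integer seed (initialization and batching).
#' @return an `ehr_codec` with the trained encoder, heads, vocabularies and
#'   loss history (one mean loss per epoch, non-increasing when smoothed).
#' @export
train_codec <- function(cat_matrix, vocabs, d_c = NULL,
                        scope = c("static", "temporal"), epochs = 300L,
                        lr = 1e-2, batch_size = 256L, accuracy_floor = 0.95,
                        seed = 1L) {
  scope <- match.arg(scope)
  stopifnot(length(vocabs) >= 1L, ncol(cat_matrix) == length(vocabs))
  sizes_v <- vapply(vocabs, length, 1L)
  if (is.null(d_c)) d_c <- min(16L, as.integer(ceiling(sum(sizes_v) / 2)))
  stopifnot(d_c >= 1L)
  d_in <- sum(sizes_v + 1L)
  if (d_c >= d_in) warning("d_c (", d_c, ") >= one-hot width (", d_in,
                           "): codec provides no compression")
  X <- onehot_block(cat_matrix, vocabs)
  n <- nrow(X)
  ends <- cumsum(sizes_v + 1L)
  starts <- c(1L, utils::head(ends, -1L) + 1L)

  with_substream(seed, paste0("codec-init-", scope), {
    enc <- mlp_init(c(d_in, 2L * d_c, d_c), "tanh")
    heads <- lapply(seq_along(vocabs), function(k)
      dense_init(d_c, sizes_v[k] + 1L))
  })
  params <- list(enc = enc$layers, heads = heads)
  st <- adam_init(params)
  history <- numeric(epochs)
  with_substream(seed, paste0("codec-train-", scope), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      tot <- 0; nb <- 0
      for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
        enc$layers <- params$enc
        fw <- mlp_forward(enc, X[b, , drop = FALSE])
        emb <- tanh(fw$out)  # bounded embeddings, same scale as [0,1] values
        gparams <- list(enc = NULL, heads = vector("list", length(vocabs)))
        dEmb <- emb * 0
        loss <- 0
        for (k in seq_along(vocabs)) {
          tgt <- X[b, starts[k]:ends[k], drop = FALSE]
          logits <- sweep(emb %*% params$heads[[k]]$W, 2,
                          params$heads[[k]]$b, "+")
          ce <- softmax_ce(logits, tgt)
          loss <- loss + ce$value
          gparams$heads[[k]] <- list(W = crossprod(emb, ce$grad),
                                     b = colSums(ce$grad))
          dEmb <- dEmb + tcrossprod(ce$grad, params$heads[[k]]$W)
        }
        bw <- mlp_backward(enc, fw$cache, dEmb * (1 - emb^2))
        gparams$enc <- bw$grads
        r <- adam_step(params, gparams, st, lr = lr)
        params <- r$params; st <- r$state
        tot <- tot + loss; nb <- nb + 1
      }
      history[ep] <- tot / nb
    }
  })
  codec <- structure(list(scope = scope, vocabs = vocabs, d_c = d_c,
                          enc_sizes = c(d_in, 2L * d_c, d_c),
                          enc = params$enc, heads = params$heads,
                          bounded = TRUE, history = history),
                     class = "ehr_codec")
  acc <- codec_roundtrip_accuracy(codec, cat_matrix)
  if (acc < accuracy_floor)
    stop(sprintf("codec round-trip accuracy %.3f below floor %.3f", acc,
                 accuracy_floor))
  attr(codec, "roundtrip_accuracy") <- acc
  codec
}

codec_mlp <- function(codec) {
  structure(list(layers = codec$enc, sizes = codec$enc_sizes, act = "tanh"),
            class = "mlp")
}

#' Map categorical values to codec embeddings
#'
#' @param cat_matrix character matrix with one column per codec feature
#'   (vocabulary order must match the codec's).
#' @param codec a trained `ehr_codec`.
#' @param scope expected scope; a mismatch with the codec errors.
#' @return numeric matrix, one `d_c` embedding row per input row.
#' @export
encode_categoricals <- function(cat_matrix, codec, scope = codec$scope) {
  stopifnot(inherits(codec, "ehr_codec"))
  if (!identical(scope, codec$scope))
    stop("codec scope mismatch: codec is '", codec$scope, "', data is '",
         scope, "'")
  if (!identical(colnames(cat_matrix), names(codec$vocabs)))
    stop("feature/vocabulary order mismatch with codec")
  X <- onehot_block(cat_matrix, codec$vocabs)
  out <- mlp_forward(codec_mlp(codec), X, keep_cache = FALSE)$out
  if (isTRUE(codec$bounded)) tanh(out) else out
}

#' Decode codec embeddings back to categorical values
#'
#' Each head produces a probability vector over its vocabulary plus the
#' missing slot; the argmax decides the value (ties break to the lower
#' vocabulary index; argmax on the missing slot yields `NA` with mask 0).
#'
#' @param emb numeric matrix of embeddings (width `d_c`).
#' @param codec a trained `ehr_codec`.
#' @return list: `values` character matrix, `masks` binary matrix, `probs`
#'   list of per-head probability matrices.
#' @export
decode_categoricals <- function(emb, codec) {
  stopifnot(inherits(codec, "ehr_codec"), ncol(emb) == codec$d_c)
  K <- length(codec$vocabs)
  vals <- matrix(NA_character_, nrow(emb), K,
                 dimnames = list(NULL, names(codec$vocabs)))
  msk <- matrix(0, nrow(emb), K, dimnames = list(NULL, names(codec$vocabs)))
  probs <- vector("list", K)
  for (k in seq_len(K)) {
    logits <- sweep(emb %*% codec$heads[[k]]$W, 2, codec$heads[[k]]$b, "+")
    p <- softmax_ce(logits, logits * 0)$prob
    idx <- max.col(p, ties.method = "first")
    V <- length(codec$vocabs[[k]])
    obs <- idx <= V
    vals[obs, k] <- codec$vocabs[[k]][idx[obs]]
    msk[, k] <- obs + 0
    probs[[k]] <- p
  }
  list(values = vals, masks = msk, probs = probs)
}

codec_roundtrip_accuracy <- function(codec, cat_matrix) {
  emb <- encode_categoricals(cat_matrix, codec)
  dec <- decode_categoricals(emb, codec)
  same <- (is.na(cat_matrix) & is.na(dec$values)) |
    (!is.na(cat_matrix) & !is.na(dec$values) & cat_matrix == dec$values)
  mean(same)
}

#' Identity codec (ablation: no categorical embedding)
#'
#' Passes the raw one-hot blocks (with missing slots) through unchanged;
#' decoding is per-block argmax. Used by the `categorical_embedding = FALSE`
#' ablation of the training pipeline.
#' @param vocabs named list of vocabularies.
#' @param scope `"static"` or `"temporal"`.
#' @return an `ehr_codec` whose embedding equals the one-hot encoding.
#' @export
identity_codec <- function(vocabs, scope = c("static", "temporal")) {
  scope <- match.arg(scope)
  sizes_v <- vapply(vocabs, length, 1L)
  d_in <- sum(sizes_v + 1L)
  # encoder = identity affine MLP (single linear layer); heads pick blocks
  enc <- list(list(W = diag(d_in), b = rep(0, d_in)))
  ends <- cumsum(sizes_v + 1L)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  heads <- lapply(seq_along(vocabs), function(k) {
    W <- matrix(0, d_in, sizes_v[k] + 1L)
    W[starts[k]:ends[k], ] <- diag(sizes_v[k] + 1L) * 50  # sharp softmax
    list(W = W, b = rep(0, sizes_v[k] + 1L))
  })
  structure(list(scope = scope, vocabs = vocabs, d_c = d_in,
                 enc_sizes = c(d_in, d_in), enc = enc, heads = heads,
                 history = numeric(0)), class = "ehr_codec")
}
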