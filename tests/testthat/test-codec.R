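test_that("one-hot encoding sets exactly one slot including the missing one", {
  expect_equal(unname(one_hot("B", c("A", "B"))[1, ]), c(0, 1, 0))
  expect_equal(unname(one_hot(NA_character_, c("A", "B"))[1, ]), c(0, 0, 1))
  set.seed(1)
  col <- sample(c("A", "B", NA), 50, replace = TRUE)
  blk <- one_hot(col, c("A", "B"))
  expect_true(all(rowSums(blk) == 1))
  expect_error(one_hot("Z", c("A", "B"), "rhythm"), "'Z'.*'rhythm'")
})

test_that("a codec with spare capacity reaches near-perfect round trips", {
  set.seed(2)
  cm <- matrix(sample(c("yes", "no"), 500, TRUE), ncol = 1,
               dimnames = list(NULL, "flag"))
  expect_warning(
    cd <- train_codec(cm, list(flag = c("yes", "no")), d_c = 4,
                      scope = "static", epochs = 150, seed = 3),
    "no compression")
  expect_gt(attr(cd, "roundtrip_accuracy"), 0.99)
  expect_lt(tail(cd$history, 1), cd$history[1])  # optimization sanity

  emb <- encode_categoricals(cm, cd)
  expect_equal(ncol(emb), 4L)
  expect_true(all(abs(emb) <= 1))
  # identical inputs give identical embeddings
  expect_identical(emb[cm[, 1] == "yes", ][1, ], emb[cm[, 1] == "yes", ][2, ])
  dec <- decode_categoricals(emb, cd)
  expect_gt(mean(dec$values == cm, na.rm = TRUE), 0.99)
  # decoder heads emit probability-simplex rows
  expect_true(all(abs(rowSums(dec$probs[[1]]) - 1) < 1e-12))
  expect_true(all(dec$probs[[1]] >= 0))
})

test_that("embeddings separate differing inputs and keep missing stable", {
  g <- tiny_cohort(n = 200, t_max = 4, seed = 4)
  vocabs <- g$data$schema$static_categorical
  cd <- train_codec(g$data$static_cat, vocabs, scope = "static",
                    epochs = 250, seed = 5)
  a <- matrix(c("married", "none", "medicare"), 1,
              dimnames = list(NULL, names(vocabs)))
  b <- a; b[1, 1] <- "single"
  expect_false(isTRUE(all.equal(encode_categoricals(a, cd),
                                encode_categoricals(b, cd))))
  allna <- matrix(NA_character_, 2, 3, dimnames = list(NULL, names(vocabs)))
  e <- encode_categoricals(allna, cd)
  expect_identical(e[1, ], e[2, ])
})

test_that("decoding honors the missing slot and breaks ties low", {
  # hand-built codec: embedding passes through, head logits chosen directly
  cd <- structure(list(
    scope = "static", vocabs = list(v = c("A", "B")), d_c = 3L,
    enc_sizes = c(3L, 3L),
    enc = list(list(W = diag(3), b = rep(0, 3))),
    heads = list(list(W = diag(3) * 1, b = rep(0, 3))),
    bounded = FALSE, history = numeric(0)), class = "ehr_codec")
  # probabilities (0.1, 0.2, 0.7) over (A, B, missing): argmax is missing
  dec <- decode_categoricals(matrix(log(c(0.1, 0.2, 0.7)), 1), cd)
  expect_true(is.na(dec$values[1, 1]))
  expect_equal(unname(dec$masks[1, 1]), 0)
  # exact tie between A and B: lower vocabulary index wins
  dec2 <- decode_categoricals(matrix(c(1, 1, 0), 1), cd)
  expect_equal(unname(dec2$values[1, 1]), "A")
  expect_equal(unname(dec2$masks[1, 1]), 1)
})

test_that("scope and vocabulary-order mismatches fail loudly", {
  g <- tiny_cohort(n = 60, t_max = 4, seed = 6)
  vocabs <- g$data$schema$static_categorical
  cd <- suppressWarnings(train_codec(g$data$static_cat, vocabs,
                                     scope = "static", epochs = 40,
                                     seed = 1, accuracy_floor = 0))
  expect_error(encode_categoricals(g$data$static_cat, cd, scope = "temporal"),
               "scope mismatch")
  swapped <- g$data$static_cat[, c(2, 1, 3)]
  expect_error(encode_categoricals(swapped, cd), "order mismatch")
})

test_that("training loss equals the sum of per-head cross entropies", {
  g <- tiny_cohort(n = 100, t_max = 4, seed = 14)
  vocabs <- g$data$schema$static_categorical
  cd <- train_codec(g$data$static_cat, vocabs, scope = "static",
                    epochs = 200, seed = 2)
  X <- g$data$static_cat[1:20, , drop = FALSE]
  emb <- encode_categoricals(X, cd)
  by_head <- 0
  sizes <- vapply(vocabs, length, 1L)
  for (k in seq_along(vocabs)) {
    tgt <- one_hot(X[, k], vocabs[[k]])
    logits <- sweep(emb %*% cd$heads[[k]]$W, 2, cd$heads[[k]]$b, "+")
    # hand-computed categorical cross entropy
    p <- exp(logits - apply(logits, 1, max))
    p <- p / rowSums(p)
    by_head <- by_head - mean(rowSums(tgt * log(p)))
  }
  via_loss <- sum(vapply(seq_along(vocabs), function(k) {
    tgt <- one_hot(X[, k], vocabs[[k]])
    logits <- sweep(emb %*% cd$heads[[k]]$W, 2, cd$heads[[k]]$b, "+")
    softmax_ce(logits, tgt)$value
  }, 0))
  expect_equal(via_loss, by_head, tolerance = 1e-12)
})

test_that("identity codec is an exact one-hot passthrough", {
  vocabs <- list(a = c("x", "y"), b = c("p", "q", "r"))
  ic <- identity_codec(vocabs, "temporal")
  cm <- cbind(a = c("x", NA, "y"), b = c("q", "r", NA))
  emb <- encode_categoricals(cm, ic)
  expect_equal(ncol(emb), 3 + 4)
  dec <- decode_categoricals(emb, ic)
  expect_identical(is.na(dec$values), is.na(cm))
  expect_true(all(dec$values == cm, na.rm = TRUE))
})
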