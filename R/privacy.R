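# Distance model shared by the attacks: Euclidean on min-max scaled numeric
# features plus Hamming distance on categorical features, combined
# additively. Missing numeric entries are imputed at the scaled midpoint;
# a missing categorical is its own category.

attack_space <- function(ref_flat) {
  lo <- apply(ref_flat$num, 2, function(v) min(v, na.rm = TRUE))
  hi <- apply(ref_flat$num, 2, function(v) max(v, na.rm = TRUE))
  lo[!is.finite(lo)] <- 0; hi[!is.finite(hi)] <- 1
  list(lo = lo, span = pmax(hi - lo, 1e-9))
}

attack_scale <- function(flat, space) {
  X <- sweep(sweep(flat$num, 2, space$lo), 2, space$span, "/")
  X[is.na(X)] <- 0.5
  C <- flat$cat
  C[is.na(C)] <- ".missing"
  list(num = X, cat = C)
}

# n_a x n_b distance matrix between scaled record sets, optionally
# restricted to a subset of numeric / categorical columns.
attack_dist <- function(a, b, num_cols = NULL, cat_cols = NULL) {
  An <- a$num[, num_cols %||% seq_len(ncol(a$num)), drop = FALSE]
  Bn <- b$num[, num_cols %||% seq_len(ncol(b$num)), drop = FALSE]
  d2 <- outer(rowSums(An^2), rowSums(Bn^2), "+") - 2 * tcrossprod(An, Bn)
  D <- sqrt(pmax(d2, 0))
  ci <- cat_cols %||% seq_len(ncol(a$cat))
  for (j in ci) D <- D + outer(a$cat[, j], b$cat[, j], "!=")
  D
}

#' Membership inference attack
#'
#' The adversary holds the synthetic release and a balanced pool of query
#' records, half from the generator's training data and half held out, and
#' predicts membership from the distance to the nearest synthetic record.
#' The decision threshold is chosen to maximize accuracy on the query pool
#' itself (a strongest-adversary upper bound on attack power). The reported
#' balanced accuracy has ideal value 0.5: synthetic data that leak no
#' membership signal make the attack no better than random guessing.
#'
#' @param synth,train_query,holdout_query lists with `data`/`masks`;
#'   `train_query` and `holdout_query` must be the same size.
#' @return an `attack_result` list with `value` (balanced accuracy),
#'   `ideal` (0.5), the per-query nearest distances and configuration.
#' @export
membership_inference <- function(synth, train_query, holdout_query) {
  if (n_records(synth$data) == 0L) stop("empty synthetic set")
  n_t <- n_records(train_query$data)
  n_h <- n_records(holdout_query$data)
  if (n_t != n_h) stop("query sets must be balanced (equal sizes)")
  fs <- flatten_features(synth$data, synth$masks)
  ft <- flatten_features(train_query$data, train_query$masks)
  fh <- flatten_features(holdout_query$data, holdout_query$masks)
  sp <- attack_space(fs)
  s <- attack_scale(fs, sp); t <- attack_scale(ft, sp); h <- attack_scale(fh, sp)
  d_t <- apply(attack_dist(t, s), 1, min)
  d_h <- apply(attack_dist(h, s), 1, min)
  d <- c(d_t, d_h)
  member <- c(rep(1, n_t), rep(0, n_h))
  # accuracy-maximizing threshold: classify member iff distance <= theta
  cand <- c(-Inf, sort(unique(d)))
  acc <- vapply(cand, function(th)
    (sum(d_t <= th) + sum(d_h > th)) / (n_t + n_h), 0)
  best <- max(acc)
  structure(list(attack = "membership_inference", value = best, ideal = 0.5,
                 config = list(distance = "euclidean+hamming",
                               threshold = cand[which.max(acc)]),
                 n = c(train = n_t, holdout = n_h),
                 distances = list(train = d_t, holdout = d_h)),
            class = "attack_result")
}

#' Re-identification attack
#'
#' For each training record the adversary knows a random fraction of its
#' features, finds the nearest synthetic record on the known features, and
#' succeeds if every unknown numeric feature of that synthetic record
#' matches the training record within `tolerance` (in min-max normalized
#' units) and every unknown categorical matches exactly. The baseline
#' replaces the synthetic release with disjoint holdout records: synthetic
#' data are privacy-ideal when the risk does not exceed that baseline.
#'
#' @param synth,train,holdout lists with `data`/`masks`; `train` and
#'   `holdout` must be disjoint cohorts.
#' @param known_fraction fraction of features known to the adversary;
#'   `known_fraction = 1` makes the success criterion vacuous and returns
#'   risk 1 flagged as degenerate.
#' @param tolerance numeric match tolerance in normalized units (>= 0).
#' @param seed seed for the known-feature draws (shared between risk and
#'   baseline, so oracle mode `synth == holdout` gives exact equality).
#' @return an `attack_result` with `value` (risk), `baseline` and config.
#' @export
reidentification_risk <- function(synth, train, holdout, known_fraction = 0.5,
                                  tolerance = 0.05, seed = 1L) {
  if (tolerance < 0) stop("tolerance must be >= 0")
  fl_tr <- flatten_features(train$data, train$masks)
  sp <- attack_space(fl_tr)
  tr <- attack_scale(fl_tr, sp)
  n <- nrow(tr$num)
  p_num <- ncol(tr$num); p_cat <- ncol(tr$cat)
  p <- p_num + p_cat
  if (known_fraction >= 1) {
    return(structure(list(attack = "reidentification", value = 1,
                          baseline = 1, degenerate = TRUE,
                          config = list(known_fraction = 1, tolerance = tolerance),
                          n = c(train = n)), class = "attack_result"))
  }
  k <- max(1L, round(known_fraction * p))
  known <- with_substream(seed, "reid-known", {
    lapply(seq_len(n), function(i) sort(sample.int(p, k)))
  })
  run <- function(release) {
    fl_r <- flatten_features(release$data, release$masks)
    rl <- attack_scale(fl_r, sp)
    hits <- logical(n)
    for (i in seq_len(n)) {
      kn <- known[[i]]
      ncols <- kn[kn <= p_num]
      ccols <- kn[kn > p_num] - p_num
      D <- attack_dist(list(num = tr$num[i, , drop = FALSE],
                            cat = tr$cat[i, , drop = FALSE]), rl,
                       num_cols = if (length(ncols)) ncols else integer(0),
                       cat_cols = if (length(ccols)) ccols else integer(0))
      j <- which.min(D[1, ])
      un_n <- setdiff(seq_len(p_num), ncols)
      un_c <- setdiff(seq_len(p_cat), ccols)
      ok_n <- !length(un_n) ||
        all(abs(tr$num[i, un_n] - rl$num[j, un_n]) <= tolerance)
      ok_c <- !length(un_c) || all(tr$cat[i, un_c] == rl$cat[j, un_c])
      hits[i] <- ok_n && ok_c
    }
    mean(hits)
  }
  structure(list(attack = "reidentification", value = run(synth),
                 baseline = run(holdout), degenerate = FALSE,
                 config = list(known_fraction = known_fraction,
                               tolerance = tolerance,
                               distance = "euclidean+hamming"),
                 n = c(train = n, synth = n_records(synth$data),
                       holdout = n_records(holdout$data))),
            class = "attack_result")
}

knn_scores <- function(fit_scaled, fit_labels, eval_scaled, k, classes) {
  D <- attack_dist(eval_scaled, fit_scaled)
  t(apply(D, 1, function(d) {
    nb <- fit_labels[order(d)[seq_len(k)]]
    vapply(classes, function(cl) mean(nb == cl), 0)
  }))
}

#' Attribute inference attack
#'
#' Two k-nearest-neighbour classifiers predict a sensitive attribute from
#' all other features: one fitted on the synthetic release, one on the real
#' training data; both are evaluated on real held-out records. For binary
#' attributes the AUC is reported; for multi-class attributes the mean of
#' all pairwise one-vs-one AUCs. Synthetic data add no attribute-inference
#' leakage when the synthetic-trained AUC does not exceed the real-trained
#' AUC.
#'
#' @param synth,real_train,real_eval lists with `data`/`masks`.
#' @param attribute feature to infer: a static categorical name or a binary
#'   static numeric name.
#' @param k neighbourhood size (>= 1).
#' @return an `attack_result` with `value` (synthetic-trained AUC) and
#'   `baseline` (real-trained AUC).
#' @export
attribute_inference <- function(synth, real_train, real_eval, attribute,
                                k = 5L) {
  stopifnot(k >= 1)
  get_attr <- function(ch) {
    sch <- ch$data$schema
    if (attribute %in% names(sch$static_categorical)) ch$data$static_cat[, attribute]
    else if (attribute %in% sch$static_numeric)
      as.character(ch$data$static_num[, attribute])
    else stop("attribute not found: ", attribute)
  }
  y_ev <- get_attr(real_eval)
  keep_ev <- !is.na(y_ev)
  if (length(unique(y_ev[keep_ev])) < 2L) stop("attribute constant in real_eval")
  fl_ev <- flatten_features(real_eval$data, real_eval$masks, drop = attribute)
  sp <- attack_space(fl_ev)
  ev <- attack_scale(fl_ev, sp)
  ev <- list(num = ev$num[keep_ev, , drop = FALSE],
             cat = ev$cat[keep_ev, , drop = FALSE])
  y_ev <- y_ev[keep_ev]
  classes <- sort(unique(y_ev))
  one <- function(fit_set) {
    y <- get_attr(fit_set)
    keep <- !is.na(y)
    fl <- flatten_features(fit_set$data, fit_set$masks, drop = attribute)
    sc <- attack_scale(fl, sp)
    sc <- list(num = sc$num[keep, , drop = FALSE],
               cat = sc$cat[keep, , drop = FALSE])
    P <- knn_scores(sc, y[keep], ev, min(k, sum(keep)), classes)
    pairwise_auc(P, y_ev, classes)
  }
  structure(list(attack = "attribute_inference", attribute = attribute,
                 value = one(synth), baseline = one(real_train),
                 config = list(k = k, distance = "euclidean+hamming"),
                 classes = classes),
            class = "attack_result")
}

# Mean pairwise one-vs-one AUC from per-class score columns P (n x C).
pairwise_auc <- function(P, y, classes) {
  if (length(classes) == 2L) {
    return(auc_score(P[, 2] / pmax(P[, 1] + P[, 2], 1e-12), (y == classes[2]) + 0))
  }
  pairs <- utils::combn(seq_along(classes), 2)
  mean(apply(pairs, 2, function(pr) {
    a <- classes[pr[1]]; b <- classes[pr[2]]
    sel <- y %in% c(a, b)
    sc <- P[sel, pr[2]] / pmax(P[sel, pr[1]] + P[sel, pr[2]], 1e-12)
    auc_score(sc, (y[sel] == b) + 0)
  }))
}

#' @export
print.attack_result <- function(x, ...) {
  cat("<attack_result> ", x$attack, ": value=", round(x$value, 4), sep = "")
  if (!is.null(x$baseline)) cat(", baseline=", round(x$baseline, 4), sep = "")
  if (!is.null(x$ideal)) cat(", ideal=", x$ideal, sep = "")
  cat("\n")
  invisible(x)
}
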