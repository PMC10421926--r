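#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Supremum of the absolute difference between the two empirical CDFs,
#' computed over the pooled support (ties handled exactly). Missing entries
#' must be dropped by the caller; empty samples error.
#'
#' @param x,y numeric samples (non-empty, no `NA`).
#' @return the KS statistic in \[0, 1\].
#' @export
ks_statistic <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L || anyNA(x) || anyNA(y))
    stop("ks_statistic needs non-empty samples without NA")
  z <- sort(unique(c(x, y)))
  Fx <- cumsum(tabulate(findInterval(x, z), nbins = length(z))) / length(x)
  Fy <- cumsum(tabulate(findInterval(y, z), nbins = length(z))) / length(y)
  max(abs(Fx - Fy))
}

miss_rate_static <- function(masks, f) mean(masks$m_sn[, f] == 0)

miss_rate_temporal <- function(masks, f) {
  sp <- masks$step_present == 1
  mean(masks$m_tn[, , f][sp] == 0)
}

#' Per-feature statistical similarity table
#'
#' For every numeric feature (static and temporal): mean, standard deviation
#' and missing rate in both cohorts, plus the KS statistic on observed
#' values (missing entries are ignored; missing rates count mask-0 slots
#' within each record's true length only). For every categorical feature:
#' per-category ratios among observed values. Features observed in neither
#' cohort are flagged with statistics omitted; a feature observed nowhere in
#' the synthetic cohort gets missing rate 1 and no KS.
#'
#' @param real,synth lists with `data` and `masks` members (matching schemas).
#' @return a `metric_report` list: `features` (numeric rows) and
#'   `categories` (categorical ratio rows), both data.frames.
#' @export
summary_table <- function(real, synth) {
  sch <- real$data$schema
  if (!identical(sch[-6], synth$data$schema[-6]) ||
      !identical(sch$max_seq_len, synth$data$schema$max_seq_len))
    stop("schemas do not match")
  rows <- list()
  grab <- function(cohort, f, static) {
    if (static) cohort$data$static_num[, f][cohort$masks$m_sn[, f] == 1]
    else cohort$data$temporal_num[, , f][cohort$masks$m_tn[, , f] == 1]
  }
  for (static in c(TRUE, FALSE)) {
    feats <- if (static) sch$static_numeric else sch$temporal_numeric
    for (f in feats) {
      vr <- grab(real, f, static)
      vs <- grab(synth, f, static)
      mr <- if (static) miss_rate_static(real$masks, f) else miss_rate_temporal(real$masks, f)
      ms <- if (static) miss_rate_static(synth$masks, f) else miss_rate_temporal(synth$masks, f)
      rows[[f]] <- data.frame(
        feature = f, type = if (static) "static" else "temporal",
        real_mean = if (length(vr)) mean(vr) else NA_real_,
        real_sd = if (length(vr)) stats::sd(vr) else NA_real_,
        real_miss = mr,
        synth_mean = if (length(vs)) mean(vs) else NA_real_,
        synth_sd = if (length(vs)) stats::sd(vs) else NA_real_,
        synth_miss = ms,
        ks = if (length(vr) && length(vs)) ks_statistic(vr, vs) else NA_real_,
        flag = if (!length(vr) && !length(vs)) "never_observed"
        else if (!length(vs)) "absent_in_synth"
        else if (!length(vr)) "absent_in_real" else "")
    }
  }
  cat_rows <- list()
  ratio <- function(v, lev) {
    v <- v[!is.na(v)]
    if (!length(v)) return(rep(NA_real_, length(lev)))
    as.numeric(table(factor(v, levels = lev)) / length(v))
  }
  for (static in c(TRUE, FALSE)) {
    vocs <- if (static) sch$static_categorical else sch$temporal_categorical
    for (f in names(vocs)) {
      vr <- if (static) real$data$static_cat[, f]
      else real$data$temporal_cat[, , f][real$masks$step_present == 1]
      vs <- if (static) synth$data$static_cat[, f]
      else synth$data$temporal_cat[, , f][synth$masks$step_present == 1]
      cat_rows[[f]] <- data.frame(
        feature = f, category = vocs[[f]],
        type = if (static) "static" else "temporal",
        real_ratio = ratio(vr, vocs[[f]]),
        synth_ratio = ratio(vs, vocs[[f]]))
    }
  }
  structure(list(features = do.call(rbind, rows),
                 categories = if (length(cat_rows)) do.call(rbind, cat_rows)
                 else data.frame()),
            class = "metric_report")
}

#' Rank-based AUC and average precision
#'
#' AUC via the Mann-Whitney statistic with midranks (exact under ties);
#' average precision as the mean of precision at each positive, in
#' descending score order.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1).
#' @return scalar metric.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop("AUC needs both classes")
  r <- rank(scores)
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' @rdname auc_score
#' @export
ap_score <- function(scores, labels) {
  labels <- as.numeric(labels)
  np <- sum(labels == 1)
  if (np == 0) stop("AP needs at least one positive")
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  prec <- cumsum(y) / seq_along(y)
  sum(prec * y) / np
}

# Flatten a cohort into fixed-width feature blocks for non-sequential
# models and distance-based attacks: static numerics; per temporal numeric
# the last observed value, observed mean and observation count; sequence
# length and time span; static categoricals and the last observed temporal
# category as character columns (NA = never observed).
flatten_features <- function(data, masks, drop = character()) {
  sch <- data$schema
  n <- n_records(data)
  num <- list()
  for (f in setdiff(sch$static_numeric, drop)) num[[f]] <- data$static_num[, f]
  for (f in setdiff(sch$temporal_numeric, drop)) {
    v <- data$temporal_num[, , f]
    lastv <- rep(NA_real_, n); mu <- rep(NA_real_, n); cnt <- numeric(n)
    for (i in seq_len(n)) {
      vi <- v[i, seq_len(data$lengths[i])]
      obs <- which(!is.na(vi))
      cnt[i] <- length(obs)
      if (length(obs)) { lastv[i] <- vi[obs[length(obs)]]; mu[i] <- mean(vi[obs]) }
    }
    num[[paste0(f, "__last")]] <- lastv
    num[[paste0(f, "__mean")]] <- mu
    num[[paste0(f, "__n")]] <- cnt
  }
  num[["__seqlen"]] <- as.numeric(data$lengths)
  num[["__tspan"]] <- vapply(seq_len(n), function(i)
    data$time[i, data$lengths[i]] - data$time[i, 1], 0)
  cat <- list()
  for (f in setdiff(names(sch$static_categorical), drop))
    cat[[f]] <- data$static_cat[, f]
  for (f in setdiff(names(sch$temporal_categorical), drop)) {
    v <- data$temporal_cat[, , f]
    lastv <- rep(NA_character_, n)
    for (i in seq_len(n)) {
      vi <- v[i, seq_len(data$lengths[i])]
      obs <- which(!is.na(vi))
      if (length(obs)) lastv[i] <- vi[obs[length(obs)]]
    }
    cat[[paste0(f, "__last")]] <- lastv
  }
  list(num = do.call(cbind, num),
       cat = if (length(cat)) do.call(cbind, cat) else matrix(NA_character_, n, 0),
       base_feature = c(sub("__(last|mean|n)$", "", names(num)),
                        sub("__last$", "", names(cat))))
}

# Numeric design matrix: imputed numerics (reference means) + one-hot
# categoricals with a missing level. `ref` supplies imputation means and
# scaling; defaults to the matrix itself.
design_matrix <- function(flat, ref = flat) {
  X <- flat$num
  mu <- colMeans(ref$num, na.rm = TRUE)
  mu[is.na(mu)] <- 0
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
  if (ncol(flat$cat)) {
    oh <- lapply(seq_len(ncol(flat$cat)), function(j) {
      lev <- sort(unique(c(ref$cat[, j], flat$cat[, j])))
      lev <- lev[!is.na(lev)]
      m <- one_hot(flat$cat[, j], lev)
      colnames(m) <- paste0(colnames(flat$cat)[j], "=", colnames(m))
      m
    })
    X <- cbind(X, do.call(cbind, oh))
  }
  X
}

fit_predict <- function(kind, X_train, y_train, X_test, seed,
                        seq_train = NULL, seq_test = NULL) {
  if (length(unique(y_train)) < 2L) stop("single-class target in training set")
  if (kind == "rf") {
    with_substream(seed, "rf", {
      fit <- randomForest::randomForest(X_train, factor(y_train, levels = c(0, 1)),
                                        ntree = 200)
    })
    as.numeric(stats::predict(fit, X_test, type = "prob")[, "1"])
  } else if (kind == "lr") {
    sdv <- apply(X_train, 2, stats::sd)
    keep <- sdv > 0
    mu <- colMeans(X_train[, keep, drop = FALSE])
    sc <- function(X) sweep(sweep(X[, keep, drop = FALSE], 2, mu), 2,
                            pmax(sdv[keep], 1e-9), "/")
    df <- data.frame(y = y_train, sc(X_train))
    fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                       family = stats::binomial()))
    as.numeric(suppressWarnings(
      stats::predict(fit, data.frame(sc(X_test)), type = "response")))
  } else if (kind == "gru") {
    gru_classifier(seq_train, y_train, seq_test, seed)
  } else stop("unknown model kind: ", kind)
}

# Small GRU classifier over model-space sequences (list of per-step
# matrices); logistic head on the final state, Adam/BCE.
gru_classifier <- function(seq_train, y_train, seq_test, seed, hidden = 32L,
                           epochs = 30L, lr = 5e-3, batch_size = 128L) {
  d_in <- ncol(seq_train$X[[1]])
  with_substream(seed, "gru-clf-init", {
    p <- list(gru = gru_init(d_in, hidden), head = dense_init(hidden, 1L))
  })
  st <- adam_init(p)
  n <- nrow(seq_train$X[[1]])
  with_substream(seed, "gru-clf-train", {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
        Xb <- lapply(seq_train$X, function(m) m[b, , drop = FALSE])
        fw <- gru_forward(p$gru, Xb)
        logit <- sweep(fw$h_last %*% p$head$W, 2, p$head$b, "+")
        l <- bce_logits(logit, matrix(y_train[b], ncol = 1))
        ghead <- list(W = crossprod(fw$h_last, l$grad), b = colSums(l$grad))
        dh <- tcrossprod(l$grad, p$head$W)
        gg <- gru_backward(p$gru, fw$cache, dh_last = dh)
        r <- adam_step(p, list(gru = gg$grads, head = ghead), st, lr = lr)
        p <- r$params; st <- r$state
      }
    }
  })
  fw <- gru_forward(p$gru, seq_test$X, keep_cache = FALSE)
  as.numeric(sigmoid(sweep(fw$h_last %*% p$head$W, 2, p$head$b, "+")))
}

# Model-space sequence tensors for the GRU classifier: min-max scaled
# temporal numerics (reference scaling), masks, scaled time, step_present.
sequence_features <- function(data, masks, ref_data = data, ref_masks = masks) {
  sch <- data$schema
  n <- n_records(data)
  tmax <- sch$max_seq_len
  scal <- lapply(sch$temporal_numeric, function(f) {
    v <- ref_data$temporal_num[, , f][ref_masks$m_tn[, , f] == 1]
    if (length(v) < 2) list(min = 0, span = 1) else
      list(min = min(v), span = max(max(v) - min(v), 1e-9))
  })
  names(scal) <- sch$temporal_numeric
  X <- vector("list", tmax)
  p <- length(sch$temporal_numeric)
  for (t in seq_len(tmax)) {
    m <- matrix(0, n, 2L * p + 2L)
    for (k in seq_len(p)) {
      f <- sch$temporal_numeric[k]
      v <- (data$temporal_num[, t, f] - scal[[f]]$min) / scal[[f]]$span
      v[is.na(v)] <- 0
      m[, k] <- v
      m[, p + k] <- masks$m_tn[, t, f]
    }
    ut <- data$time[, t] / max(ref_data$time, na.rm = TRUE)
    ut[is.na(ut)] <- 0
    m[, 2L * p + 1L] <- ut
    m[, 2L * p + 2L] <- masks$step_present[, t]
    X[[t]] <- m
  }
  list(X = X)
}

#' Train-on-synthetic / test-on-real utility
#'
#' Fits the same predictive model twice -- once on the real training cohort,
#' once on the synthetic cohort -- and evaluates both on the real held-out
#' test set, reporting AUC and average precision per training source.
#' Similar metrics indicate the synthetic data carry the task-relevant
#' signal. `rf` and `lr` consume a flattened feature table (per temporal
#' feature: last observed value, observed mean, observation count, plus
#' static features, with missing summaries imputed by training means);
#' `gru` consumes the padded sequences directly.
#'
#' @param real_train,synth_train,real_test lists with `data`/`masks`.
#' @param target name of a binary static numeric feature (e.g. mortality).
#' @param model_kind `"rf"`, `"lr"` or `"gru"`.
#' @param seed integer seed.
#' @param features optional character vector restricting the base features
#'   used (for subset testing); the target is always excluded.
#' @return data.frame with one row per training source: auc and ap.
#' @export
tstr_utility <- function(real_train, synth_train, real_test, target,
                         model_kind = c("rf", "lr", "gru"), seed = 1L,
                         features = NULL) {
  model_kind <- match.arg(model_kind)
  get_y <- function(ch) {
    y <- ch$data$static_num[, target]
    if (!all(y %in% c(0, 1) | is.na(y)))
      stop("target must be binary")
    y
  }
  # records with a missing target are dropped from the affected set
  drop_na_target <- function(ch) {
    y <- get_y(ch)
    if (!anyNA(y)) return(ch)
    keep <- which(!is.na(y))
    d <- subset_cohort(ch$data, keep)
    list(data = d, masks = derive_masks(d))
  }
  real_train <- drop_na_target(real_train)
  synth_train <- drop_na_target(synth_train)
  real_test <- drop_na_target(real_test)
  y_rt <- get_y(real_train); y_st <- get_y(synth_train); y_te <- get_y(real_test)
  one <- function(train, y_train) {
    if (model_kind == "gru") {
      sq_tr <- sequence_features(train$data, train$masks)
      sq_te <- sequence_features(real_test$data, real_test$masks,
                                 train$data, train$masks)
      sc <- fit_predict("gru", NULL, y_train, NULL, seed,
                        seq_train = sq_tr, seq_test = sq_te)
    } else {
      fl_tr <- flatten_features(train$data, train$masks, drop = target)
      fl_te <- flatten_features(real_test$data, real_test$masks, drop = target)
      if (!is.null(features)) {
        keep_n <- fl_tr$base_feature[seq_len(ncol(fl_tr$num))] %in% c(features, "__seqlen", "__tspan")
        keep_c <- fl_tr$base_feature[ncol(fl_tr$num) + seq_len(ncol(fl_tr$cat))] %in% features
        sel <- function(fl) list(num = fl$num[, keep_n, drop = FALSE],
                                 cat = fl$cat[, keep_c, drop = FALSE])
        fl_tr <- sel(fl_tr); fl_te <- sel(fl_te)
      }
      X_tr <- design_matrix(fl_tr, fl_tr)
      X_te <- design_matrix(fl_te, fl_tr)
      sc <- fit_predict(model_kind, X_tr, y_train, X_te, seed)
    }
    c(auc = auc_score(sc, y_te), ap = ap_score(sc, y_te))
  }
  rbind(data.frame(source = "real", t(one(real_train, y_rt))),
        data.frame(source = "synthetic", t(one(synth_train, y_st))))
}

#' Random-feature-subset utility hypothesis test
#'
#' Repeatedly draws random subsets of `n_features` base features, computes
#' the absolute AUC and AP differences between real-trained and
#' synthetic-trained models (both evaluated on the real test set), and
#' reports the mean absolute differences together with the one-sided
#' one-sample t-test p-value for the null hypothesis that the mean
#' difference is at least `X`. A small p-value rejects that null, i.e.
#' supports fidelity: the typical performance gap is below `X`.
#'
#' @param real_train,synth_train,real_test lists with `data`/`masks`.
#' @param targets character vector of binary target features.
#' @param n_features subset size (must not exceed the candidate pool).
#' @param n_trials number of random subsets (>= 2).
#' @param X fidelity threshold on the mean absolute difference.
#' @param model_kind model for [tstr_utility()].
#' @param seed integer seed.
#' @return data.frame with one row per target.
#' @export
subset_utility_test <- function(real_train, synth_train, real_test, targets,
                                n_features = 30L, n_trials = 10L, X = 0.04,
                                model_kind = "rf", seed = 1L) {
  if (n_trials < 2L) stop("n_trials must be >= 2 (the t-test needs variance)")
  sch <- real_train$data$schema
  rows <- list()
  for (tg in targets) {
    pool <- setdiff(c(sch$static_numeric, names(sch$static_categorical),
                      sch$temporal_numeric, names(sch$temporal_categorical)), tg)
    if (length(pool) < n_features)
      stop("only ", length(pool), " candidate features for subsets of ",
           n_features)
    d_auc <- numeric(n_trials); d_ap <- numeric(n_trials)
    for (tr in seq_len(n_trials)) {
      ok <- FALSE
      for (attempt in 1:5) {
        feats <- with_substream(seed, paste0("subset-", tg, "-", tr, "-", attempt),
                                sample(pool, n_features))
        res <- tryCatch(tstr_utility(real_train, synth_train, real_test, tg,
                                     model_kind, seed = seed + tr,
                                     features = feats),
                        error = function(e) NULL)
        if (!is.null(res)) { ok <- TRUE; break }
        message("degenerate subset redrawn (target ", tg, ", trial ", tr, ")")
      }
      if (!ok) stop("could not draw a non-degenerate feature subset")
      d_auc[tr] <- abs(res$auc[1] - res$auc[2])
      d_ap[tr] <- abs(res$ap[1] - res$ap[2])
    }
    pval <- function(d) one_sample_p_below(d, X)
    rows[[tg]] <- data.frame(target = tg, mean_auc_diff = mean(d_auc),
                             mean_ap_diff = mean(d_ap),
                             p_auc = pval(d_auc), p_ap = pval(d_ap),
                             X = X, n_trials = n_trials)
  }
  do.call(rbind, rows)
}

# One-sided one-sample t test of H0: mean(d) >= X against mean(d) < X.
one_sample_p_below <- function(d, X) {
  n <- length(d)
  s <- stats::sd(d)
  if (s == 0) return(if (mean(d) < X) 0 else 1)
  stats::pt((mean(d) - X) / (s / sqrt(n)), df = n - 1)
}
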