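test_that("KS statistic matches hand-enumerable cases and the brute force", {
  expect_equal(ks_statistic(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks_statistic(1:5, 11:15), 1)
  expect_equal(ks_statistic(c(1, 2, 3), c(1, 2, 2)), 1 / 3)
  expect_error(ks_statistic(numeric(0), 1:3), "non-empty")

  brute_ks <- function(x, y) {
    pts <- c(x, y)
    max(vapply(pts, function(t)
      abs(mean(x <= t) - mean(y <= t)), 0))
  }
  set.seed(8)
  for (i in 1:10) {
    x <- sample(0:9, sample(3:50, 1), replace = TRUE)
    y <- rnorm(sample(3:50, 1))
    expect_equal(ks_statistic(x, y), brute_ks(x, y))
  }
  # agreement with the stats implementation on continuous samples
  x <- rnorm(200); y <- rnorm(150, 0.3)
  expect_equal(ks_statistic(x, y),
               unname(stats::ks.test(x, y)$statistic))
})

test_that("similarity table is exact on a self-comparison", {
  g <- tiny_cohort(n = 60, t_max = 5, seed = 33)
  rep_ <- summary_table(g, g)
  expect_true(all(rep_$features$ks == 0, na.rm = TRUE))
  expect_equal(rep_$features$real_mean, rep_$features$synth_mean)
  expect_equal(rep_$features$real_miss, rep_$features$synth_miss)
  expect_equal(rep_$categories$real_ratio, rep_$categories$synth_ratio)

  # a feature never observed in synth: missing rate 1, KS omitted
  g2 <- g
  g2$data$temporal_num[, , "glucose"] <- NA_real_
  g2$masks <- derive_masks(g2$data)
  rep2 <- summary_table(g, g2)
  row <- rep2$features[rep2$features$feature == "glucose", ]
  expect_equal(row$synth_miss, 1)
  expect_true(is.na(row$ks))
  expect_equal(row$flag, "absent_in_synth")
})

test_that("rank AUC and AP agree with reference implementations", {
  set.seed(9)
  y <- rbinom(300, 1, 0.3)
  s <- y * 0.5 + rnorm(300)
  expect_equal(auc_score(s, y),
               as.numeric(suppressMessages(pROC::auc(y, s))))
  # AP by direct definition on a small hand case
  expect_equal(ap_score(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)),
               mean(c(1 / 1, 2 / 3)))
  expect_error(auc_score(s, rep(1, 300)), "both classes")
})

test_that("the TSTR harness is symmetric and detects planted signal", {
  g <- tiny_cohort(n = 1200, t_max = 6, seed = 41)
  sp <- split_cohort(g$data, 0.5, seed = 1)
  tr <- list(data = sp$train, masks = derive_masks(sp$train))
  te <- list(data = sp$test, masks = derive_masks(sp$test))
  res <- tstr_utility(tr, tr, te, "mortality", "rf", seed = 4)
  expect_equal(res[1, c("auc", "ap")], res[2, c("auc", "ap")],
               ignore_attr = TRUE)

  # planted signal: the real-trained model beats the permutation null by 5
  # null standard deviations (null built by scoring random predictions)
  obs_auc <- res$auc[1]
  y <- te$data$static_num[, "mortality"]
  set.seed(1)
  nulls <- replicate(200, auc_score(rnorm(length(y)), y))
  expect_gt(obs_auc, 0.5 + 5 * stats::sd(nulls))

  # a target independent of all features stays at chance
  g0 <- tiny_cohort(n = 400, t_max = 6, seed = 43, outcome_signal = FALSE)
  sp0 <- split_cohort(g0$data, 0.8, seed = 1)
  tr0 <- list(data = sp0$train, masks = derive_masks(sp0$train))
  te0 <- list(data = sp0$test, masks = derive_masks(sp0$test))
  res0 <- tstr_utility(tr0, tr0, te0, "mortality", "rf", seed = 4)
  y0 <- te0$data$static_num[, "mortality"]
  null_sd0 <- sqrt((sum(y0 == 1) + sum(y0 == 0) + 1) /
                     (12 * sum(y0 == 1) * sum(y0 == 0)))
  expect_lt(abs(res0$auc[1] - 0.5), 4 * null_sd0)

  # the lr and gru model kinds run on the same contract
  res_lr <- tstr_utility(tr, tr, te, "mortality", "lr", seed = 4)
  expect_equal(res_lr$auc[1], res_lr$auc[2])
  res_gru <- tstr_utility(tr, tr, te, "mortality", "gru", seed = 4)
  expect_true(all(res_gru$auc >= 0 & res_gru$auc <= 1))
})

test_that("subset test matches the closed-form one-sample t statistic", {
  # hand-computed: d = (0.05, 0.05, 0.05), X = 0.04 has zero variance and a
  # mean above X: the null 'mean >= X' cannot be rejected
  expect_equal(synthehr:::one_sample_p_below(rep(0.05, 3), 0.04), 1)
  expect_equal(synthehr:::one_sample_p_below(rep(0.01, 3), 0.04), 0)
  set.seed(2)
  d <- abs(rnorm(8, 0.02, 0.01))
  expect_equal(synthehr:::one_sample_p_below(d, 0.04),
               stats::t.test(d, mu = 0.04, alternative = "less")$p.value)

  g <- tiny_cohort(n = 200, t_max = 4, seed = 47)
  sp <- split_cohort(g$data, 0.8, seed = 1)
  tr <- list(data = sp$train, masks = derive_masks(sp$train))
  te <- list(data = sp$test, masks = derive_masks(sp$test))
  expect_error(subset_utility_test(tr, tr, te, "mortality", n_features = 5,
                                   n_trials = 1), "n_trials")
  expect_error(subset_utility_test(tr, tr, te, "mortality", n_features = 99,
                                   n_trials = 2), "candidate features")
  res <- subset_utility_test(tr, tr, te, "mortality", n_features = 5,
                             n_trials = 3, X = 0.04, seed = 3)
  # synthetic == real: all differences vanish and the null is rejected
  expect_equal(res$mean_auc_diff, 0)
  expect_lt(res$p_auc, 0.001)
})
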