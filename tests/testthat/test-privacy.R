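pair_of <- function(data) list(data = data, masks = derive_masks(data))

test_that("membership attack saturates on memorized data and enumerable cases", {
  g <- tiny_cohort(n = 120, t_max = 4, seed = 51)
  idx_t <- 1:40; idx_h <- 41:80
  train_q <- pair_of(subset_cohort(g$data, idx_t))
  hold_q <- pair_of(subset_cohort(g$data, idx_h))
  # synthetic = exact copies of the training queries: distances are zero
  leak <- membership_inference(train_q, train_q, hold_q)
  expect_equal(leak$value, 1.0)
  expect_true(all(leak$distances$train < 1e-6))
  expect_error(membership_inference(train_q, train_q,
                                    pair_of(subset_cohort(g$data, 41:90))),
               "balanced")
  expect_error(membership_inference(pair_of(subset_cohort(g$data, integer(0))),
                                    train_q, hold_q), "empty")
})

test_that("membership attack is at chance for independent synthetic data", {
  g <- tiny_cohort(n = 300, t_max = 4, seed = 53)
  fresh <- generate_cohort(toy_config(n_patients = 300, t_max = 4, seed = 99))
  train_q <- pair_of(subset_cohort(g$data, 1:150))
  hold_q <- pair_of(subset_cohort(g$data, 151:300))
  res <- membership_inference(pair_of(fresh$data), train_q, hold_q)
  sigma <- 0.5 / sqrt(300)
  expect_lt(abs(res$value - 0.5) - 0.5 / 300, 3.5 * sigma + 0.05)
  # the attack never dips below the trivial majority rule
  expect_gte(res$value, 0.5)
})

test_that("re-identification behaves at both extremes and in oracle mode", {
  g <- tiny_cohort(n = 120, t_max = 4, seed = 57)
  tr <- pair_of(subset_cohort(g$data, 1:50))
  ho <- pair_of(subset_cohort(g$data, 51:100))
  # synthetic = copies of train with tolerance 0: every record re-identified
  res <- reidentification_risk(tr, tr, ho, tolerance = 0, seed = 2)
  expect_equal(res$value, 1.0)
  # oracle mode: synthetic := holdout gives risk == baseline exactly
  res2 <- reidentification_risk(ho, tr, ho, tolerance = 0.1, seed = 2)
  expect_identical(res2$value, res2$baseline)
  # risk is monotone non-decreasing in the tolerance
  fresh <- pair_of(generate_cohort(toy_config(n_patients = 80, t_max = 4,
                                              seed = 101))$data)
  risks <- vapply(c(0.02, 0.1, 0.3, 1e6), function(tol)
    reidentification_risk(fresh, tr, ho, tolerance = tol, seed = 3)$value, 0)
  expect_true(all(diff(risks) >= 0))
  # degenerate known fraction
  dg <- reidentification_risk(fresh, tr, ho, known_fraction = 1)
  expect_true(dg$degenerate)
  expect_equal(dg$value, 1.0)
  expect_error(reidentification_risk(fresh, tr, ho, tolerance = -1), ">= 0")
})

test_that("attribute inference is symmetric, calibrated and multi-class exact", {
  g <- tiny_cohort(n = 200, t_max = 4, seed = 61)
  tr <- pair_of(subset_cohort(g$data, 1:100))
  ev <- pair_of(subset_cohort(g$data, 101:200))
  same <- attribute_inference(tr, tr, ev, "gender", k = 5)
  expect_identical(same$value, same$baseline)

  # marital status is independent of every other feature in the generator
  ind <- attribute_inference(tr, tr, ev, "marital_status", k = 5)
  expect_lt(abs(ind$value - 0.5), 0.12)

  expect_error(attribute_inference(tr, tr, ev, "nope"), "not found")
  ev_const <- ev
  ev_const$data$static_cat[, "marital_status"] <- "married"
  ev_const$masks <- derive_masks(ev_const$data)
  expect_error(attribute_inference(tr, tr, ev_const, "marital_status"),
               "constant")
})

test_that("mean pairwise AUC agrees with brute-force enumeration", {
  # 12 evaluation records, 3 classes, hand-set per-class scores
  set.seed(12)
  y <- rep(c("a", "b", "c"), each = 4)
  P <- matrix(runif(36), 12, 3)
  P <- P / rowSums(P)
  got <- synthehr:::pairwise_auc(P, y, c("a", "b", "c"))
  brute_pair <- function(pos, neg, ppos, pneg) {
    s <- P[, ppos] / (P[, ppos] + P[, pneg])
    tot <- 0; n <- 0
    for (i in which(y == pos)) for (j in which(y == neg)) {
      tot <- tot + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
      n <- n + 1
    }
    tot / n
  }
  expected <- mean(c(brute_pair("b", "a", 2, 1),
                     brute_pair("c", "a", 3, 1),
                     brute_pair("c", "b", 3, 2)))
  expect_equal(got, expected)
})

test_that("attacks are deterministic given seeds and configuration", {
  g <- tiny_cohort(n = 90, t_max = 4, seed = 63)
  tr <- pair_of(subset_cohort(g$data, 1:30))
  ho <- pair_of(subset_cohort(g$data, 31:60))
  sy <- pair_of(subset_cohort(g$data, 61:90))
  expect_identical(reidentification_risk(sy, tr, ho, seed = 4),
                   reidentification_risk(sy, tr, ho, seed = 4))
  expect_identical(membership_inference(sy, tr, ho),
                   membership_inference(sy, tr, ho))
  expect_identical(attribute_inference(sy, tr, ho, "gender"),
                   attribute_inference(sy, tr, ho, "gender"))
})
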