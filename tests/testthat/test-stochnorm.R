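test_that("frequency-proportional intervals tile [0,1] with ratio widths", {
  p <- worked_example_params()
  expect_equal(p$value, c(1, 2, 3))
  expect_equal(p$lower, c(0, 0.1, 0.8))
  expect_equal(p$upper, c(0.1, 0.8, 1.0))

  p1 <- fit_normalizer(rep(42, 10))
  expect_equal(nrow(p1), 1L)
  expect_equal(c(p1$lower, p1$upper), c(0, 1))

  p2 <- fit_normalizer(c(5, 5, 9, 9))
  expect_equal(p2$upper, c(0.5, 1.0))

  expect_error(fit_normalizer(numeric(0)), "empty")
  expect_error(fit_normalizer(c(1, NA)), "NA")
})

test_that("normalization draws land in the value's interval", {
  p <- worked_example_params()
  x <- rep(2, 200)
  xn <- normalize_values(x, p, seed = 3)
  expect_true(all(xn >= 0.1 & xn < 0.8))
  # single-unique params: all draws in [0, 1)
  p1 <- fit_normalizer(rep(7, 5))
  y <- normalize_values(rep(7, 100), p1, seed = 1)
  expect_true(all(y >= 0 & y < 1))
  # missing passes through
  expect_true(is.na(normalize_values(c(NA, 2), p, seed = 1)[1]))
  # unseen value errors unless nearest fallback requested
  expect_error(normalize_values(2.5, p, seed = 1), "not in the fitted support")
  near <- normalize_values(2.4, p, seed = 1, nearest = TRUE)
  expect_true(near >= 0.1 && near < 0.8)
})

test_that("renormalization inverts exactly and is total via clipping", {
  p <- worked_example_params()
  expect_equal(renormalize_values(0.5, p), 2)
  expect_equal(renormalize_values(1.37, p), 3)
  expect_equal(renormalize_values(-2, p), 1)
  # boundary x = upper belongs to the next interval; x = 1 to the last
  expect_equal(renormalize_values(c(0.1, 0.8, 1.0), p), c(2, 3, 3))

  set.seed(42)
  for (rep in 1:20) {
    x <- switch(1 + rep %% 3,
                sample(seq(35, 60, by = 5), 60, replace = TRUE),   # grid
                round(rlnorm(60, 2, 0.8), 1),                      # skewed
                rnorm(60))                                         # all-unique
    p <- fit_normalizer(x)
    xn <- normalize_values(x, p, seed = rep)
    expect_identical(renormalize_values(xn, p), x)
  }
})

test_that("normalization is monotone in distribution", {
  set.seed(1)
  x <- sample(c(10, 20, 30), 400, replace = TRUE, prob = c(0.6, 0.3, 0.1))
  p <- fit_normalizer(x)
  xn <- normalize_values(x, p, seed = 2)
  expect_lt(max(xn[x == 10]), min(xn[x == 20]))
  expect_lt(max(xn[x == 20]), min(xn[x == 30]))
})

test_that("normalized marginal is uniform and inverse reproduces the law", {
  set.seed(7)
  x <- sample(c(1, 2, 3), 1e5, replace = TRUE, prob = c(0.1, 0.7, 0.2))
  p <- fit_normalizer(x)
  xn <- normalize_values(x, p, seed = 9)
  # ties arise only from the guard that caps draws just below each upper
  # bound; they are irrelevant to the distance itself
  expect_lt(suppressWarnings(stats::ks.test(xn, "punif"))$statistic, 0.01)

  # renormalize applied to fresh Uniform(0,1) draws reproduces the fitted
  # empirical distribution within multinomial sampling error
  u <- runif(2e4)
  back <- renormalize_values(u, p)
  obs <- table(factor(back, levels = p$value))
  expfreq <- (p$upper - p$lower) * length(u)
  expect_gt(stats::chisq.test(obs, p = expfreq / sum(expfreq))$p.value, 1e-3)
})

test_that("large-n normalized marginal stays within the 3/sqrt(n) band", {
  set.seed(3)
  n <- 5000
  x <- round(rlnorm(n, 3, 0.6))
  p <- fit_normalizer(x)
  xn <- normalize_values(x, p, seed = 4)
  expect_lt(ks_statistic(xn, runif(n)), 3 / sqrt(n) + 3 / sqrt(n))
})

test_that("normalizer serialization round trip is bit-exact", {
  g <- tiny_cohort()
  np <- fit_cohort_normalizers(g$data, g$masks)
  path <- tempfile(fileext = ".json")
  write_normalizers(np, path)
  np2 <- read_normalizers(path)
  expect_identical(lapply(np, as.list), lapply(np2, as.list))
  # single-feature container
  p <- worked_example_params()
  write_normalizers(p, path)
  expect_identical(as.list(read_normalizers(path)), as.list(p))
})

test_that("max_unique caps the parameter count via equal-frequency bins", {
  set.seed(5)
  x <- rnorm(1000)
  p <- fit_normalizer(x, max_unique = 16)
  expect_lte(nrow(p), 16L)
  y <- renormalize_values(normalize_values(p$value, p, seed = 1), p)
  expect_identical(y, p$value)
})
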