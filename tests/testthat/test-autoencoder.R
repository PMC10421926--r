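make_bundle <- function(n = 30, t_max = 4, seed = 15, ...) {
  g <- tiny_cohort(n = n, t_max = t_max, seed = seed, ...)
  np <- fit_cohort_normalizers(g$data, g$masks)
  sc <- suppressWarnings(train_codec(g$data$static_cat,
                                     g$data$schema$static_categorical,
                                     scope = "static", epochs = 60, seed = 2,
                                     accuracy_floor = 0))
  pres <- which(g$masks$step_present == 1)
  flat <- vapply(names(g$data$schema$temporal_categorical), function(k)
    g$data$temporal_cat[, , k][pres], character(length(pres)))
  tc <- suppressWarnings(train_codec(flat, g$data$schema$temporal_categorical,
                                     scope = "temporal", epochs = 60, seed = 2,
                                     accuracy_floor = 0))
  list(bundle = assemble_inputs(g$data, g$masks, np, sc, tc, seed = 10),
       g = g, np = np, sc = sc, tc = tc)
}

test_that("assembled bundles are normalized, masked and deterministic", {
  mk <- make_bundle()
  b <- mk$bundle
  for (blk in c("s_n", "t_n", "u")) {
    expect_true(all(b[[blk]] >= 0 & b[[blk]] <= 1))
  }
  # missing numerics are zero placeholders exactly where the mask is zero
  hole <- which(b$m_tn * array(b$step_present, dim(b$m_tn)) == 0)
  expect_true(all(b$t_n[hole] == 0))
  # padding carries zeros
  pad <- b$step_present == 0
  expect_true(all(b$u[pad] == 0))
  # deterministic given the master seed
  b2 <- assemble_inputs(mk$g$data, mk$g$masks, mk$np, mk$sc, mk$tc, seed = 10)
  expect_identical(b$t_n, b2$t_n)
  expect_identical(b$s_ce, b2$s_ce)
  # a fully observed cohort assembles with all-ones masks
  g0 <- tiny_cohort(n = 10, t_max = 3, seed = 77, miss_override = 0,
                    static_cat_miss = 0)
  np0 <- fit_cohort_normalizers(g0$data, g0$masks)
  sc0 <- identity_codec(g0$data$schema$static_categorical, "static")
  tc0 <- identity_codec(g0$data$schema$temporal_categorical, "temporal")
  b0 <- assemble_inputs(g0$data, g0$masks, np0, sc0, tc0, seed = 1)
  expect_true(all(b0$m_sn == 1) && all(b0$m_sc == 1))
  sp0 <- array(b0$step_present, dim(b0$m_tn))
  expect_true(all(b0$m_tn[sp0 == 1] == 1))
  # unfitted components are named in the error
  expect_error(assemble_inputs(mk$g$data, mk$g$masks, list(), mk$sc, mk$tc),
               "norm_params")
  expect_error(assemble_inputs(mk$g$data, mk$g$masks, mk$np, NULL, mk$tc),
               "static_codec")
})

test_that("reconstruction loss is exact at perfection and gated by masks", {
  mk <- make_bundle()
  b <- mk$bundle
  perfect <- list(s_n = b$s_n, s_ce = b$s_ce, t_n = b$t_n, t_ce = b$t_ce,
                  u = b$u, m_sn = b$m_sn, m_sc = b$m_sc, m_tn = b$m_tn,
                  m_tc = b$m_tc, step_present = b$step_present)
  expect_identical(reconstruction_loss(perfect, b, lambda = 1), 0)

  # flipping predictions where the mask is zero leaves the loss bit-identical
  base <- perfect
  base$t_n <- b$t_n + 0.01
  l0 <- reconstruction_loss(base, b, lambda = 1)
  tampered <- base
  hole <- which(b$m_tn * array(b$step_present, dim(b$m_tn)) == 0)
  tampered$t_n[hole] <- 42
  expect_identical(reconstruction_loss(tampered, b, lambda = 1), l0)

  # single-entry closed form: only one observed value differs by 0.2
  single <- perfect
  k <- which(b$m_sn == 1)[1]
  single$s_n[k] <- b$s_n[k] + 0.2
  expect_equal(reconstruction_loss(single, b, lambda = 1),
               0.2^2 * 1 / sum(b$m_sn), tolerance = 1e-12)

  bad <- perfect; bad$u[1] <- NaN
  expect_error(reconstruction_loss(bad, b), "non-finite")
})

test_that("the loss decomposes into its BCE and lambda-scaled MSE parts", {
  mk <- make_bundle()
  b <- mk$bundle
  set.seed(3)
  pred <- list(
    s_n = b$s_n + rnorm(length(b$s_n), 0, 0.1),
    s_ce = b$s_ce + 0.05, t_n = b$t_n * 0.9, t_ce = b$t_ce,
    u = b$u + 0.02,
    m_sn = clamp(b$m_sn + 0.1, 0, 1), m_sc = b$m_sc,
    m_tn = clamp(b$m_tn - 0.2, 0, 1), m_tc = b$m_tc,
    step_present = b$step_present)
  lam <- 2.5
  n <- nrow(b$s_n); tmax <- ncol(b$u); d <- b$dims
  sp_tn <- array(b$step_present, dim(b$m_tn))
  sp_tc <- array(b$step_present, dim(b$m_tc))
  bce_part <- bce_prob_exact(pred$m_sn, b$m_sn) +
    bce_prob_exact(pred$m_sc, b$m_sc) +
    bce_prob_exact(pred$m_tn, b$m_tn, sp_tn) +
    bce_prob_exact(pred$m_tc, b$m_tc, sp_tc) +
    bce_prob_exact(pred$step_present, b$step_present)
  mse_part <- mse_masked(pred$u, b$u, b$step_present)$value +
    mse_masked(pred$s_n, b$s_n, b$m_sn)$value +
    mse_masked(pred$s_ce, b$s_ce, matrix(b$any_sc, n, d$d_cs))$value +
    mse_masked(pred$t_n, b$t_n, b$m_tn * sp_tn)$value +
    mse_masked(pred$t_ce, b$t_ce,
               array(b$any_tc * b$step_present, dim(b$t_ce)))$value
  expect_equal(reconstruction_loss(pred, b, lambda = lam),
               bce_part + lam * mse_part, tolerance = 1e-12)
})

test_that("full autoencoder gradients match finite differences", {
  mk <- make_bundle(n = 10, t_max = 3, seed = 19)
  b <- mk$bundle
  cfg <- training_config(d_e = 5, hidden = 6, epochs = 1, seed = 3,
                         batch_size = 10)
  ly <- synthehr:::ae_layout(b$dims, TRUE)
  params <- synthehr:::ae_init(b$dims, cfg, TRUE)
  idx <- 1:10
  lossf <- function(pp) {
    enc <- synthehr:::ae_encode(pp, synthehr:::ae_step_inputs(b, idx, ly),
                                synthehr:::ae_static_input(b, idx, ly), TRUE)
    dec <- synthehr:::ae_decode(pp, enc$e, b$dims$tmax, TRUE)
    synthehr:::ae_loss_and_adjoints(dec, b, idx, ly, 1, TRUE)$value
  }
  enc <- synthehr:::ae_encode(params, synthehr:::ae_step_inputs(b, idx, ly),
                              synthehr:::ae_static_input(b, idx, ly), TRUE)
  dec <- synthehr:::ae_decode(params, enc$e, b$dims$tmax, TRUE)
  la <- synthehr:::ae_loss_and_adjoints(dec, b, idx, ly, 1, TRUE)
  gr <- synthehr:::ae_backward(params, enc, dec, la)
  set.seed(11)
  expect_lt(fd_worst_err(lossf, params, gr, n_checks = 25), 1e-5)
})

test_that("training reduces the loss deterministically and encodes per patient", {
  mk <- make_bundle(n = 40, t_max = 4, seed = 25)
  cfg <- training_config(d_e = 10, hidden = 12, epochs = 8, batch_size = 20,
                         lr = 5e-3, seed = 6)
  ae <- train_autoencoder(mk$bundle, cfg)
  expect_lt(tail(ae$history, 1), ae$history[1])
  ae2 <- train_autoencoder(mk$bundle, cfg)
  expect_identical(ae$history, ae2$history)

  lat <- encode_dataset(mk$bundle, ae)
  expect_equal(dim(lat), c(40L, 10L))
  expect_true(all(is.finite(lat)))
  # duplicated record rows produce identical latents
  b2 <- mk$bundle
  for (blk in c("s_n", "s_ce", "m_sn", "m_sc"))
    b2[[blk]][2, ] <- b2[[blk]][1, ]
  for (blk in c("t_n", "t_ce", "m_tn", "m_tc"))
    b2[[blk]][2, , ] <- b2[[blk]][1, , ]
  for (blk in c("u", "step_present", "any_tc"))
    b2[[blk]][2, ] <- b2[[blk]][1, ]
  b2$any_sc[2] <- b2$any_sc[1]
  lat2 <- encode_dataset(b2, ae)
  expect_identical(lat2[1, ], lat2[2, ])
})

test_that("with lambda ~ 0 the numeric heads stay untrained at target variance", {
  mk <- make_bundle(n = 40, t_max = 4, seed = 25)
  cfg <- training_config(lambda = 1e-9, d_e = 10, hidden = 12, epochs = 8,
                         batch_size = 20, lr = 5e-3, seed = 6)
  ae <- train_autoencoder(mk$bundle, cfg)
  lat <- encode_dataset(mk$bundle, ae)
  pred <- synthehr:::decode_latents(ae, lat)
  b <- mk$bundle
  w <- b$m_tn * array(b$step_present, dim(b$m_tn))
  got <- mse_masked(pred$t_n, b$t_n, w)$value
  # untrained linear heads predict ~0; the observed targets average ~0.5,
  # so the MSE sits near E[v^2], well above the target variance
  second_moment <- sum(w * b$t_n^2) / sum(w)
  expect_gt(got, 0.5 * second_moment)
})
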