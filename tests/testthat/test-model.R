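test_that("parameter count: default 536, closed form 426 + 22 d_ff, runtime agreement", {
  cfg <- model_config()
  expect_identical(count_parameters(cfg), 536L)
  expect_identical(n_trainable(init_model_params(cfg, seed = 1)), 536L)
  for (f in c(1L, 2L, 4L, 5L, 8L)) {
    cfg_f <- model_config(d_ff = f)
    expect_identical(count_parameters(cfg_f), 426L + 22L * f)
    expect_identical(n_trainable(init_model_params(cfg_f, seed = 1)),
                     426L + 22L * f)
  }
  expect_identical(count_parameters(model_config(d_ff = 4L)), 514L)
})

test_that("causal mask is lower triangular with the right counts", {
  expect_identical(causal_mask(1), matrix(TRUE, 1, 1))
  m3 <- causal_mask(3)
  expect_equal(rowSums(m3), c(1, 2, 3))
  expect_equal(sum(causal_mask(28)), 406)  # 28 * 29 / 2
  expect_error(causal_mask(0), "at least 1")
})

test_that("scaled dot-product attention matches a brute-force oracle", {
  set.seed(21)
  # identical query/key rows, no mask -> uniform weights
  Q <- matrix(rep(stats::runif(5), each = 4), 4, 5)
  at <- scaled_dot_attention(Q, Q, matrix(stats::rnorm(20), 4, 5))
  expect_equal(at$weights, matrix(0.25, 4, 4), tolerance = 1e-12)

  # a row with a single unmasked position puts all weight there
  mask <- matrix(FALSE, 4, 4); mask[, 1] <- TRUE; mask[2, ] <- TRUE
  at2 <- scaled_dot_attention(matrix(stats::rnorm(20), 4, 5),
                              matrix(stats::rnorm(20), 4, 5),
                              matrix(stats::rnorm(20), 4, 5), mask)
  expect_equal(at2$weights[1, 1], 1)
  expect_true(all(at2$weights[1, 2:4] == 0))

  # random inputs vs the naive elementwise implementation
  for (rep in 1:10) {
    Q <- matrix(stats::rnorm(20), 4, 5)
    K <- matrix(stats::rnorm(20), 4, 5)
    V <- matrix(stats::rnorm(20), 4, 5)
    msk <- if (rep %% 2 == 0) causal_mask(4) else NULL
    got <- scaled_dot_attention(Q, K, V, msk)
    want <- naive_attention(Q, K, V, msk)
    expect_equal(got$weights, want$weights, tolerance = 1e-12)
    expect_equal(got$context, want$context, tolerance = 1e-12)
    expect_equal(rowSums(got$weights), rep(1, 4), tolerance = 1e-12)
    if (!is.null(msk)) expect_true(all(got$weights[!msk] == 0))
  }
})

test_that("forward pass: zero head, masked upper triangle, position-only dependence", {
  cfg <- model_config()
  ds <- fx_dataset(group_idx = c(1, 8), n = 1L, noise = 0, seed = 5)
  p <- init_model_params(cfg, seed = 9)

  p0 <- p; p0$head_w[] <- 0; p0$head_b <- 0
  fw0 <- forward(ds$samples[[1]], p0, cfg)
  expect_true(all(fw0$predictions == 0))

  fw <- forward(ds$samples[[2]], p, cfg)
  for (nm in c("enc_self", "dec_self", "cross")) {
    m <- fw$maps[[nm]]
    expect_true(all(m[upper.tri(m)] == 0))
    expect_equal(rowSums(m), rep(1, 28), tolerance = 1e-9)
    expect_true(all(m >= 0 & m <= 1))
  }

  # all-zero signals: predictions depend on the positional code only, so two
  # different zero-signal samples (control vs drug-free variant) coincide
  zero_sched_a <- treatment_schedule("za", measurement_days = c(-3L, 0L, 4L))
  zero_sched_b <- treatment_schedule("zb",
                                     drug = list(drug_event(1, "isotype")),
                                     measurement_days = c(0L, 9L, 14L))
  pk <- tumor_kinetics_params(lam = 0.05)
  sa <- encode_sample(zero_sched_a, simulate_mean_trajectory(zero_sched_a, pk))
  sb <- encode_sample(zero_sched_b, simulate_mean_trajectory(zero_sched_b, pk))
  expect_identical(forward(sa, p, cfg)$predictions,
                   forward(sb, p, cfg)$predictions)
})

test_that("masked L2 loss: exact values, oracle agreement, empty-mask error", {
  v <- numeric(28); m <- logical(28)
  m[5] <- TRUE; v[5] <- 1
  tgt <- target_sequence(v, m)
  pred <- numeric(28); pred[5] <- 3
  expect_equal(masked_l2_loss(pred, tgt), 4)  # (3 - 1)^2

  expect_equal(masked_l2_loss(v, tgt), 0)

  set.seed(4)
  for (i in 1:20) {
    msk <- logical(28); msk[sample(28, sample(1:8, 1))] <- TRUE
    vals <- numeric(28); vals[msk] <- stats::rnorm(sum(msk))
    tgt_i <- target_sequence(vals, msk)
    pred_i <- stats::rnorm(28)
    oracle <- sum((pred_i[msk] - vals[msk])^2) / sum(msk)
    expect_equal(masked_l2_loss(pred_i, tgt_i), oracle, tolerance = 1e-12)
  }

  expect_error(masked_l2_loss(numeric(28),
                              target_sequence(numeric(28), logical(28))),
               "empty")
})

test_that("compiled training core agrees with the R forward pass and its gradients", {
  cfg <- model_config()
  ds <- fx_dataset(group_idx = c(4, 8), n = 2L, noise = 0.1, seed = 13)
  p <- init_model_params(cfg, seed = 17)
  for (s in ds$samples[1:2]) {
    lg <- pulsarformer:::tf_loss_grad(p, s$radiation_seq, s$drug_seq,
                                      s$target$values, s$target$mask * 1L, TRUE)
    r_loss <- masked_l2_loss(forward(s, p, cfg)$predictions, s$target)
    expect_equal(lg$loss, r_loss, tolerance = 1e-12)
    # analytic gradient vs central differences through the R forward pass,
    # first entry of every parameter tensor
    for (nm in names(p)) {
      ng <- fx_numeric_grad(p, s, nm, 1L, cfg)
      ag <- lg$grads[[nm]][1L]
      expect_equal(ag, ng, tolerance = 1e-4)
    }
  }
})

test_that("degenerate optimizer settings behave as contracts require", {
  ds <- fx_dataset(group_idx = 4, n = 5L, noise = 0, seed = 2)
  cfg <- model_config()

  # lr = 0: parameters unchanged, loss history constant
  tcfg0 <- train_config(lr = 0, epochs = 20L, seed = 6, holdout_n = 0L)
  fit0 <- train(ds, tcfg0, cfg)
  expect_equal(fit0$params, init_model_params(cfg, seed = tcfg0$seed + 1L),
               tolerance = 1e-15, ignore_attr = TRUE)
  expect_equal(diff(range(fit0$history$train_loss)), 0)

  # a batch of 32 duplicates of one sample scores the single-sample loss
  one <- ds$samples[1]
  ds_one <- structure(list(samples = one, vc_scale = ds$vc_scale,
                           groups = one[[1]]$group_id),
                      class = "encoded_dataset")
  ds_dup <- structure(list(samples = rep(one, 32L), vc_scale = ds$vc_scale,
                           groups = one[[1]]$group_id),
                      class = "encoded_dataset")
  tcfg1 <- train_config(lr = 0, epochs = 1L, seed = 6, holdout_n = 0L,
                        train_frac = 0.99)
  l_one <- train(ds_one, tcfg1, cfg)$history$train_loss[1]
  l_dup <- train(ds_dup, tcfg1, cfg)$history$train_loss[1]
  expect_equal(l_dup, l_one, tolerance = 1e-12)
})

test_that("training runs are bitwise reproducible under a fixed seed", {
  ds <- fx_dataset(group_idx = c(3, 4), n = 4L, noise = 0.05, seed = 8)
  tcfg <- train_config(epochs = 30L, seed = 123, holdout_n = 2L)
  fit_a <- train(ds, tcfg)
  fit_b <- train(ds, tcfg)
  expect_identical(fit_a$params, fit_b$params)
  expect_identical(fit_a$history, fit_b$history)
  expect_identical(fit_a$split, fit_b$split)

  fit_c <- train(ds, train_config(epochs = 30L, seed = 124, holdout_n = 2L))
  expect_false(identical(fit_a$params, fit_c$params))
})

test_that("the split honors the train fraction and keeps holdout inside the test set", {
  ds <- fx_dataset(group_idx = c(1, 3, 4), n = 10L, noise = 0.02, seed = 31)
  tcfg <- train_config(epochs = 1L, seed = 2, holdout_n = 4L)
  fit <- train(ds, tcfg)
  expect_length(fit$split$train, 24L)  # 80% of 30, stratified 8 per group
  expect_length(fit$split$test, 6L)
  expect_length(fit$split$holdout, 4L)
  expect_true(all(fit$split$holdout %in% fit$split$test))
  expect_length(intersect(fit$split$train, fit$split$test), 0L)
  gid <- vapply(ds$samples, function(s) s$group_id, character(1))
  expect_equal(unname(table(gid[fit$split$train])), rep(8L, 3L), ignore_attr = TRUE)
})
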