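test_that("loss matches its closed forms", {
  expect_equal(bce_l2_loss(1, 0.5), -log(0.5), tolerance = 1e-6)
  expect_equal(bce_l2_loss(c(1, 0), c(1, 0)), 0, tolerance = 1e-6)
  expect_equal(bce_l2_loss(0, 0.5, kernels = list(matrix(1, 2, 2)),
                           lambda = 0.1),
               -log(0.5) + 0.4, tolerance = 1e-6)
  # perfect prediction bounded by the clipping floor
  expect_lt(bce_l2_loss(c(1, 1, 0), c(1, 1, 0)), 1e-6)
  # any nonzero kernel strictly increases the penalized loss
  base <- bce_l2_loss(c(1, 0), c(0.8, 0.2))
  expect_gt(bce_l2_loss(c(1, 0), c(0.8, 0.2),
                        kernels = list(matrix(0.01, 1, 1)), lambda = 0.1),
            base)
  expect_error(bce_l2_loss(c(1, 0), 0.5), "shapes differ")
  expect_error(bce_l2_loss(0.5, 0.5), "binary")
})

test_that("analytic gradients agree with finite differences everywhere", {
  cfg <- tiny_model_config("full", l2_lambda = 1e-3)
  m <- build_model(cfg, seed = 3)
  # randomize biases so no ReLU pre-activation sits on the kink
  set.seed(42)
  for (nm in names(m$params)) {
    if (grepl("_b$", nm)) {
      m$params[[nm]] <- m$params[[nm]] + rnorm(length(m$params[[nm]]), sd = 0.3)
    }
    if (grepl("^conv.*_W$", nm)) m$params[[nm]] <- m$params[[nm]] * 1.5
  }
  store <- random_store(4, cfg, seed = 1)
  cfgl <- sublocr:::cpp_config(cfg)
  lg <- sublocr:::net_loss_grads(m$params, cfgl, store$indices, store$pssm,
                                 store$labels * 1.0)
  expect_gt(lg$loss, 0)
  h <- 1e-5
  for (nm in names(m$params)) {
    q_pick <- sample(seq_along(m$params[[nm]]), min(4, length(m$params[[nm]])))
    for (q in q_pick) {
      pp <- m$params; pp[[nm]][q] <- pp[[nm]][q] + h
      lp <- sublocr:::net_loss_grads(pp, cfgl, store$indices, store$pssm,
                                     store$labels * 1.0)$loss
      pm <- m$params; pm[[nm]][q] <- pm[[nm]][q] - h
      lm <- sublocr:::net_loss_grads(pm, cfgl, store$indices, store$pssm,
                                     store$labels * 1.0)$loss
      num <- (lp - lm) / (2 * h)
      ana <- lg$grads[[nm]][q]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4)
    }
  }
})

test_that("training is deterministic under a fixed seed", {
  cfg <- tiny_model_config("blstm_conv1")
  store <- random_store(20, cfg, seed = 2, with_pssm = FALSE)
  tc <- training_config(epochs = 3, batch_size = 8, learning_rate = 2e-3,
                        seed = 5)
  m1 <- train_model(build_model(cfg, seed = 7), store, tc)
  m2 <- train_model(build_model(cfg, seed = 7), store, tc)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  expect_length(m1$history, 3L)
  # training reduces the loss on this seeded fixture
  expect_lt(m1$history[3], m1$history[1])
})

test_that("a single example can be driven to near-zero loss", {
  cfg <- tiny_model_config("blstm")
  store <- random_store(1, cfg, seed = 3, with_pssm = FALSE)
  m <- build_model(cfg, seed = 1)
  m <- train_model(m, store, training_config(epochs = 300, batch_size = 1,
                                             learning_rate = 0.02, seed = 1))
  expect_lt(tail(m$history, 1), 0.05)
})

test_that("a large L2 coefficient shrinks the convolution kernels", {
  cfg0 <- tiny_model_config("conv2", l2_lambda = 0)
  store <- random_store(12, cfg0, seed = 4)
  norm_of <- function(lambda) {
    m <- build_model(tiny_model_config("conv2", l2_lambda = lambda), seed = 2)
    tc <- training_config(epochs = 10, batch_size = 4, learning_rate = 5e-3,
                          l2_lambda = lambda, seed = 9)
    m <- train_model(m, store, tc)
    sqrt(sum(vapply(grep("^conv.*_W$", names(m$params), value = TRUE),
                    function(nm) sum(m$params[[nm]]^2), numeric(1))))
  }
  expect_lt(norm_of(10), norm_of(0))
})

test_that("non-finite parameters surface as a divergence error", {
  cfg <- tiny_model_config("blstm")
  store <- random_store(4, cfg, seed = 6, with_pssm = FALSE)
  m <- build_model(cfg, seed = 1)
  m$params$dense_W[1] <- NaN
  expect_error(train_model(m, store, training_config(epochs = 2,
                                                     batch_size = 2)),
               "epoch 1")
})

test_that("early stopping halts once the loss stops improving", {
  cfg <- tiny_model_config("blstm")
  store <- random_store(6, cfg, seed = 8, with_pssm = FALSE)
  # freezing every parameter pins the loss, so patience must trigger
  m <- train_model(build_model(cfg, seed = 2), store,
                   training_config(epochs = 50, batch_size = 6,
                                   early_stop_patience = 3, seed = 3,
                                   freeze = c("lstm", "dense_W", "dense_b")))
  expect_lte(length(m$history), 5L)
  expect_lt(length(m$history), 50L)
})

test_that("staged training freezes the encoder first, then fine-tunes", {
  cfg <- tiny_model_config("blstm_conv1")
  store <- random_store(12, cfg, seed = 5, with_pssm = FALSE)
  m0 <- build_model(cfg, seed = 4)
  tc <- training_config(epochs = 1, batch_size = 4, seed = 9)
  # frozen stage alone must not touch any LSTM parameter
  tc_frozen <- tc; tc_frozen$freeze <- "lstm"; tc_frozen$epochs <- 2L
  m1 <- train_model(m0, store, tc_frozen)
  for (nm in grep("^lstm", names(m0$params), value = TRUE)) {
    expect_identical(m1$params[[nm]], m0$params[[nm]])
  }
  expect_false(identical(m1$params$dense_W, m0$params$dense_W))
  # the full staged run fine-tunes the LSTM in stage two
  m2 <- train_staged(m0, store, tc, epochs_frozen = 2, epochs_joint = 2,
                     restart_every = 2)
  expect_length(m2$history, 4L)
  expect_false(identical(m2$params$lstm1_f_W, m0$params$lstm1_f_W))
  # deterministic under the same seed
  m3 <- train_staged(m0, store, tc, epochs_frozen = 2, epochs_joint = 2,
                     restart_every = 2)
  expect_identical(m2$params, m3$params)
})

test_that("cross-validation honors the protocol and its aggregation", {
  gen <- generate_dataset(synthetic_config(n_proteins = 24, n_locations = 3,
                                           length_mean = 60, length_sd = 6,
                                           length_min = 40, seed = 5))
  cfg <- tiny_model_config("full")
  tc <- training_config(epochs = 2, batch_size = 8, seed = 1)
  cv <- run_cross_validation(gen$data, gen$pssms, cfg, tc, k = 2,
                             encoding = encoding_config(l_max = 24))
  expect_length(cv$folds, 2L)
  all_test <- unlist(lapply(cv$folds, `[[`, "test_ids"))
  expect_setequal(all_test, gen$data$ids)
  expect_length(all_test, 24L)
  for (f in cv$folds) {
    r <- f$report
    expect_true(r$ranking_loss >= 0 && r$ranking_loss <= 1)
    expect_true(r$coverage >= 1 && r$coverage <= 3)
    expect_true(r$average_precision > 0 && r$average_precision <= 1)
    ok <- stats::na.omit(r$per_label$auc)
    expect_true(all(ok >= 0 & ok <= 1))
    okm <- stats::na.omit(r$per_label$mcc)
    expect_true(all(okm >= -1 & okm <= 1))
  }
  # the aggregate is exactly the mean of the fold metrics
  for (metric in cv$aggregate$metric) {
    per_fold <- vapply(cv$folds, function(f) f$report[[metric]], numeric(1))
    expect_equal(cv$aggregate$mean[cv$aggregate$metric == metric],
                 mean(per_fold), tolerance = 1e-12)
  }
  # identical protocol -> identical aggregate, regardless of input order
  perm <- sample(24)
  data_perm <- gen$data[perm]
  cv2 <- run_cross_validation(data_perm, gen$pssms, cfg, tc, k = 2,
                              encoding = encoding_config(l_max = 24))
  expect_equal(cv2$aggregate, cv$aggregate, tolerance = 1e-12)
})
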