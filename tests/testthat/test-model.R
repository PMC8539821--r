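test_that("activations match their closed forms", {
  expect_equal(relu(-2), 0)
  expect_equal(relu(0), 0)
  expect_equal(relu(3.5), 3.5)
  expect_equal(relu(c(-1, 2)), c(0, 2))
  expect_error(relu(c(1, NA)))
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(log(3)), 0.75)
  expect_equal(sigmoid(1000), 1)     # stable, no overflow
  expect_equal(sigmoid(-1000), 0)
  expect_true(all(diff(sigmoid(seq(-5, 5, 0.5))) > 0))
})

test_that("convolve2d is the stated valid cross-correlation", {
  expect_equal(convolve2d(matrix(1, 3, 3), matrix(1, 2, 2)),
               matrix(4, 2, 2))
  x <- matrix(rnorm(20), 4, 5)
  expect_equal(convolve2d(x, matrix(1)), x)        # identity kernel
  expect_equal(convolve2d(x, matrix(0, 2, 2)), matrix(0, 3, 4))
  expect_error(convolve2d(matrix(1, 2, 2), matrix(1, 3, 3)), "larger")
  # triple-loop oracle on random instances
  set.seed(5)
  for (rep in 1:10) {
    x <- matrix(rnorm(36), 6, 6)
    k <- matrix(rnorm(9), 3, 3)
    ref <- matrix(0, 4, 4)
    for (i in 1:4) for (j in 1:4) {
      acc <- 0
      for (m in 1:3) for (n in 1:3) {
        acc <- acc + k[m, n] * x[i + m - 1, j + n - 1]
      }
      ref[i, j] <- acc
    }
    expect_equal(convolve2d(x, k), ref, tolerance = 1e-10)
  }
})

test_that("default configuration is the published architecture", {
  cfg <- model_config("full", n_labels = 14)
  expect_equal(cfg$l_max, 1000L)
  expect_equal(cfg$lstm_layers, 2L)
  expect_equal(2L * cfg$lstm_hidden, 256L)  # concatenated BLSTM width
  expect_equal(cfg$conv_kernel_counts, c(256L, 128L, 64L, 32L))
  expect_equal(cfg$conv_kernel_sizes,
               list(c(4L, 3L), c(3L, 3L), c(3L, 3L), c(3L, 3L)))
  expect_equal(cfg$pool_size, c(2L, 2L))
})

test_that("conv stack geometry follows the closed-form size arithmetic", {
  cfg <- model_config("conv2", n_labels = 14, l_max = 1000)
  g <- conv_stack_geometry(1000, 43, cfg)
  # 1000 -> conv(4) 997 -> pool 498 -> conv(3) 496 -> 248 -> 246 -> 123 -> 121
  expect_equal(g$dims[, 1], c(1000L, 498L, 248L, 123L, 121L))
  # 43 -> 41 -> 20 -> 18 -> 9 -> 7 -> 3 -> 1
  expect_equal(g$dims[, 2], c(43L, 20L, 9L, 3L, 1L))
  expect_equal(g$flat_size, 121L * 1L * 32L)
  # spatial collapse errors name the offending layer
  small <- model_config("conv2", n_labels = 3, l_max = 4)
  expect_error(conv_stack_geometry(4, 43, small), "layer 1")
  expect_error(build_model(model_config("blstm_conv1", n_labels = 3,
                                        l_max = 4)),
               "layer 1")
})

test_that("building is deterministic and prediction respects the contract", {
  cfg <- tiny_model_config("full")
  m1 <- build_model(cfg, seed = 5)
  m2 <- build_model(cfg, seed = 5)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(cfg, seed = 6)
  expect_false(identical(m1$params, m3$params))

  ecfg <- encoding_config(l_max = 24)
  oh <- one_hot_encode("MKVLITGAGGFLGSHLCERLL", ecfg)
  ps <- normalize_pssm(matrix(rnorm(21 * 42), 21, 42), ecfg)
  s <- predict_scores(m1, oh, ps)
  expect_length(s, 3L)
  expect_true(all(s > 0 & s < 1))
  # multi-label scores are NOT softmax-normalized
  expect_false(isTRUE(all.equal(sum(s), 1)))
  # PSSM-using variants demand a PSSM
  expect_error(predict_scores(m1, oh), "requires a PSSM")
  mb <- build_model(tiny_model_config("blstm"), seed = 1)
  expect_length(predict_scores(mb, oh), 3L)
})

test_that("batch prediction equals per-item prediction", {
  cfg <- tiny_model_config("full")
  m <- build_model(cfg, seed = 2)
  store <- random_store(6, cfg, seed = 8)
  S <- predict(m, store)
  ecfg <- encoding_config(l_max = 24)
  for (i in seq_len(6)) {
    oh <- structure(list(values = {
      v <- matrix(0L, 24, 23)
      nz <- which(store$indices[i, ] > 0)
      v[cbind(nz, store$indices[i, nz])] <- 1L
      v
    }, true_length = max(which(store$indices[i, ] > 0))),
    class = "subloc_onehot")
    ps <- structure(list(values = store$pssm[, , i], true_length = 24L),
                    class = "subloc_pssm")
    expect_equal(unname(S[i, ]), unname(predict_scores(m, oh, ps)),
                 tolerance = 1e-12)
  }
})

test_that("permuting the label head permutes scores identically", {
  cfg <- tiny_model_config("conv2")
  m <- build_model(cfg, seed = 9)
  store <- random_store(3, cfg, seed = 3)
  S <- predict(m, store)
  p <- c(3, 1, 2)
  m2 <- m
  m2$params$dense_W <- m$params$dense_W[, p]
  m2$params$dense_b <- m$params$dense_b[p]
  expect_equal(unname(predict(m2, store)), unname(S[, p]), tolerance = 1e-12)
})

test_that("engine conv stack matches the plain-R reference forward pass", {
  cfg <- tiny_model_config("conv2")
  m <- build_model(cfg, seed = 21)
  # nonzero biases move pre-activations off the ReLU boundary
  set.seed(1)
  for (nm in names(m$params)) {
    if (grepl("_b$", nm)) m$params[[nm]] <- rnorm(length(m$params[[nm]]), sd = 0.2)
  }
  store <- random_store(2, cfg, seed = 14)
  S <- predict(m, store)
  for (i in 1:2) {
    flat <- ref_conv_stack(store$pssm[, , i], m$params, "conv2_", cfg)
    logits <- drop(flat %*% m$params$dense_W) + m$params$dense_b
    expect_equal(unname(S[i, ]), unname(sigmoid(logits)), tolerance = 1e-10)
  }
})

test_that("BLSTM encoding matches a plain-R recurrence and its bounds", {
  cfg <- model_config("blstm", n_labels = 2, l_max = 7, lstm_layers = 1,
                      lstm_hidden = 3)
  m <- build_model(cfg, seed = 4)
  oh <- one_hot_encode("MKVLITG", encoding_config(l_max = 7))
  H <- blstm_encode(m, oh)
  expect_equal(dim(H), c(7L, 6L))
  expect_true(all(abs(H) < 1))
  X <- oh$values * 1.0
  Hf <- ref_lstm(X, m$params$lstm1_f_W, m$params$lstm1_f_U,
                 m$params$lstm1_f_b)
  Hb <- ref_lstm(X, m$params$lstm1_b_W, m$params$lstm1_b_U,
                 m$params$lstm1_b_b, reverse = TRUE)
  expect_equal(H, cbind(Hf, Hb), tolerance = 1e-12)

  # zero parameters -> all-zero encoding (tanh(0) = 0)
  m0 <- m
  for (nm in names(m0$params)) m0$params[[nm]][] <- 0
  expect_true(all(blstm_encode(m0, oh) == 0))

  # two stacked layers still bounded, and deeper output differs
  cfg2 <- model_config("blstm", n_labels = 2, l_max = 7, lstm_layers = 2,
                       lstm_hidden = 3)
  m2 <- build_model(cfg2, seed = 4)
  H2 <- blstm_encode(m2, oh)
  expect_true(all(abs(H2) < 1))
  expect_error(blstm_encode(build_model(tiny_model_config("conv2"), 1),
                            oh), "no BLSTM")
})

test_that("reversing the input swaps the directional halves when tied", {
  cfg <- model_config("blstm", n_labels = 2, l_max = 6, lstm_layers = 1,
                      lstm_hidden = 4)
  m <- build_model(cfg, seed = 13)
  # tie the backward direction to the forward parameters
  m$params$lstm1_b_W <- m$params$lstm1_f_W
  m$params$lstm1_b_U <- m$params$lstm1_f_U
  m$params$lstm1_b_b <- m$params$lstm1_f_b
  ecfg <- encoding_config(l_max = 6)
  seq <- "MKVLIT"
  rev_seq <- paste(rev(strsplit(seq, "")[[1]]), collapse = "")
  H <- blstm_encode(m, one_hot_encode(seq, ecfg))
  Hr <- blstm_encode(m, one_hot_encode(rev_seq, ecfg))
  swapped <- Hr[6:1, c(5:8, 1:4)]
  expect_equal(H, swapped, tolerance = 1e-12)
})

test_that("checkpoints survive a save/load round trip", {
  cfg <- tiny_model_config("blstm")
  m <- build_model(cfg, seed = 11, vocabulary = c("N", "C", "E"))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  back <- load_model(path)
  expect_identical(back$params, m$params)
  expect_identical(back$vocabulary, m$vocabulary)
  oh <- one_hot_encode("MKWVTF", encoding_config(l_max = 24))
  expect_identical(predict_scores(back, oh), predict_scores(m, oh))
})
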