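# Network architecture: configuration, parameter initialization, forward
# prediction. The numerical engine (BLSTM, conv stacks, dense head, Adam)
# lives in src/net.cpp; this file owns the architecture contract.

#' Rectified linear activation
#'
#' `max(0, x)`, elementwise.
#'
#' @param x Numeric vector/matrix of finite values.
#' @return Same shape as `x`.
#' @export
relu <- function(x) {
  if (any(!is.finite(x))) stop("relu requires finite input")
  pmax(x, 0)
}

#' Logistic sigmoid
#'
#' `exp(x) / (exp(x) + 1)`, elementwise, computed stably for large `|x|`.
#'
#' @param x Numeric vector/matrix.
#' @return Values in `(0, 1)`, same shape as `x`.
#' @export
sigmoid <- function(x) {
  out <- x
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

#' Valid 2-D convolution (cross-correlation)
#'
#' `C[i, j] = sum_{m,n} kernel[m, n] * input[i + m - 1, j + n - 1]` — the
#' index form used throughout this architecture (no kernel flip), with
#' "valid" extent only.
#'
#' @param input H x W numeric matrix.
#' @param kernel h x w numeric matrix, `h <= H`, `w <= W`.
#' @return (H - h + 1) x (W - w + 1) matrix.
#' @export
#' @examples
#' convolve2d(matrix(1, 3, 3), matrix(1, 2, 2))  # 2 x 2 matrix of 4s
convolve2d <- function(input, kernel) {
  input <- as.matrix(input)
  kernel <- as.matrix(kernel)
  H <- nrow(input); W <- ncol(input)
  h <- nrow(kernel); w <- ncol(kernel)
  if (h > H || w > W) {
    stop("kernel (", h, " x ", w, ") larger than input (", H, " x ", W, ")")
  }
  out <- matrix(0, H - h + 1, W - w + 1)
  for (m in seq_len(h)) {
    for (n in seq_len(w)) {
      out <- out + kernel[m, n] *
        input[m:(m + H - h), n:(n + W - w), drop = FALSE]
    }
  }
  out
}

.VARIANTS <- c("full", "blstm", "blstm_conv1", "conv2")

#' Model configuration
#'
#' Architecture of the four ablation variants:
#' * `blstm` — 2-layer bidirectional LSTM; final directional hidden states
#'   feed the dense head.
#' * `blstm_conv1` — the BLSTM's per-position state matrix (`l_max` x 2h)
#'   is treated as an image and passed through ConvNet1 (4 convolution
#'   layers with 3 interleaved 2x2 max-pooling layers, ReLU throughout).
#' * `conv2` — the PSSM (`l_max` x 43) alone through an identically shaped
#'   ConvNet2.
#' * `full` — ConvNet1 and ConvNet2 outputs concatenated, flattened, then
#'   the dense head.
#' Each variant ends in one fully connected layer to `n_labels` logits and
#' an elementwise sigmoid, so scores are independent per-location
#' probabilities (never softmax-normalized).
#'
#' Defaults are the published architecture: kernels 256/128/64/32 with
#' sizes 4x3 then 3x3 three times, 2 BLSTM layers whose concatenated width
#' is 256 (128 per direction), `l_max` 1000.
#'
#' @param variant One of `"full"`, `"blstm"`, `"blstm_conv1"`, `"conv2"`.
#' @param n_labels Number of locations (>= 2).
#' @param l_max Fixed input length; must match the [encoding_config()] used.
#' @param lstm_layers Number of stacked bidirectional LSTM layers.
#' @param lstm_hidden Hidden units per direction in each LSTM layer.
#' @param conv_kernel_counts Integer vector of length 4: kernels per
#'   convolution layer.
#' @param conv_kernel_sizes List of 4 `c(height, width)` kernel sizes.
#' @param pool_size 2-vector, max-pooling window (= stride) after
#'   convolution layers 1-3.
#' @param dense_hidden Width of an optional ReLU dense layer before the
#'   output layer; 0 (default) connects features directly to the logits.
#' @param l2_lambda Coefficient of the L2 penalty on convolution kernels
#'   (the penalty applies to kernels only, not LSTM or dense weights).
#' @return List of class `subloc_model_config`.
#' @export
model_config <- function(variant = .VARIANTS, n_labels, l_max = 1000L,
                         lstm_layers = 2L, lstm_hidden = 128L,
                         conv_kernel_counts = c(256L, 128L, 64L, 32L),
                         conv_kernel_sizes = list(c(4L, 3L), c(3L, 3L),
                                                  c(3L, 3L), c(3L, 3L)),
                         pool_size = c(2L, 2L), dense_hidden = 0L,
                         l2_lambda = 1e-4) {
  variant <- match.arg(variant)
  n_labels <- as.integer(n_labels)
  if (is.na(n_labels) || n_labels < 2L) stop("n_labels must be >= 2")
  if (length(conv_kernel_counts) != 4L || any(conv_kernel_counts < 1L)) {
    stop("conv_kernel_counts must be 4 positive integers")
  }
  if (length(conv_kernel_sizes) != 4L ||
      any(vapply(conv_kernel_sizes, length, 1L) != 2L)) {
    stop("conv_kernel_sizes must be a list of 4 (height, width) pairs")
  }
  if (l2_lambda < 0) stop("l2_lambda must be >= 0")
  if (lstm_layers < 1L || lstm_hidden < 1L) {
    stop("lstm_layers and lstm_hidden must be positive")
  }
  structure(list(
    variant = variant, n_labels = n_labels, l_max = as.integer(l_max),
    lstm_layers = as.integer(lstm_layers),
    lstm_hidden = as.integer(lstm_hidden),
    conv_kernel_counts = as.integer(conv_kernel_counts),
    conv_kernel_sizes = lapply(conv_kernel_sizes, as.integer),
    pool_size = as.integer(pool_size),
    dense_hidden = as.integer(dense_hidden),
    l2_lambda = l2_lambda
  ), class = "subloc_model_config")
}

#' Output geometry of the convolution stack
#'
#' Closed-form size arithmetic for the 4-conv / 3-pool stack: each valid
#' convolution shrinks a dimension by `kernel - 1`, each pool divides it by
#' the pool size (floor). Errors if any spatial dimension collapses to zero,
#' naming the offending layer.
#'
#' @param height,width Input image size.
#' @param config A [model_config()].
#' @return List with `dims` (5 x 2 matrix: input then the size after each
#'   conv[+pool] block) and `flat_size`
#'   (`final_h * final_w * last_kernel_count`).
#' @export
conv_stack_geometry <- function(height, width, config) {
  dims <- matrix(0L, nrow = 5L, ncol = 2L)
  dims[1, ] <- c(height, width)
  h <- height; w <- width
  for (c in 1:4) {
    kh <- config$conv_kernel_sizes[[c]][1]
    kw <- config$conv_kernel_sizes[[c]][2]
    h <- h - kh + 1L
    w <- w - kw + 1L
    if (h < 1L || w < 1L) {
      stop("conv layer ", c, " collapses the input to ", h, " x ", w,
           "; increase l_max or shrink kernels")
    }
    if (c <= 3L) {
      h <- h %/% config$pool_size[1]
      w <- w %/% config$pool_size[2]
      if (h < 1L || w < 1L) {
        stop("pool after conv layer ", c, " collapses the input to ",
             h, " x ", w, "; increase l_max or shrink kernels")
      }
    }
    dims[c + 1L, ] <- c(h, w)
  }
  list(dims = dims, flat_size = h * w * config$conv_kernel_counts[4])
}

# Which branches a variant wires up.
variant_uses <- function(variant) {
  switch(variant,
    blstm       = list(lstm = TRUE,  conv1 = FALSE, conv2 = FALSE),
    blstm_conv1 = list(lstm = TRUE,  conv1 = TRUE,  conv2 = FALSE),
    conv2       = list(lstm = FALSE, conv1 = FALSE, conv2 = TRUE),
    full        = list(lstm = TRUE,  conv1 = TRUE,  conv2 = TRUE)
  )
}

# Feature width entering the dense head.
dense_input_size <- function(config) {
  uses <- variant_uses(config$variant)
  f <- 0L
  if (config$variant == "blstm") f <- 2L * config$lstm_hidden
  if (uses$conv1) {
    f <- f + conv_stack_geometry(config$l_max, 2L * config$lstm_hidden,
                                 config)$flat_size
  }
  if (uses$conv2) {
    f <- f + conv_stack_geometry(config$l_max, 43L, config)$flat_size
  }
  f
}

glorot <- function(nin, nout, nrow, ncol) {
  a <- sqrt(6 / (nin + nout))
  matrix(runif(nrow * ncol, -a, a), nrow, ncol)
}

init_conv_branch <- function(prefix, width, config) {
  params <- list()
  cin <- 1L
  for (c in 1:4) {
    kh <- config$conv_kernel_sizes[[c]][1]
    kw <- config$conv_kernel_sizes[[c]][2]
    k <- config$conv_kernel_counts[c]
    fan_in <- kh * kw * cin
    # He initialization for the ReLU conv layers
    params[[paste0(prefix, c, "_W")]] <-
      matrix(rnorm(fan_in * k, sd = sqrt(2 / fan_in)), fan_in, k)
    params[[paste0(prefix, c, "_b")]] <- rep(0, k)
    cin <- k
  }
  params
}

#' Build an (untrained) model
#'
#' Allocates and deterministically initializes all parameters of the
#' configured variant: Glorot-uniform LSTM input/recurrent weights with the
#' forget-gate bias at 1, He-normal convolution kernels, Glorot dense
#' weights, zero biases. Validates the conv/pool geometry against `l_max`
#' before allocating.
#'
#' @param config A [model_config()].
#' @param seed Integer seed; the same seed gives bitwise-identical
#'   parameters.
#' @param vocabulary Optional location vocabulary stored with the model
#'   (length must equal `n_labels`).
#' @return Object of class `subloc_model`: list with `config`, `params`
#'   (named list of numeric matrices/vectors), `vocabulary`, `metadata`
#'   (`n_parameters`), `trained`, `history`.
#' @export
build_model <- function(config, seed = 1L, vocabulary = NULL) {
  stopifnot(inherits(config, "subloc_model_config"))
  if (!is.null(vocabulary) && length(vocabulary) != config$n_labels) {
    stop("vocabulary length does not match n_labels")
  }
  uses <- variant_uses(config$variant)
  f_in <- dense_input_size(config)  # validates geometry
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  params <- list()
  if (uses$lstm) {
    h <- config$lstm_hidden
    for (l in seq_len(config$lstm_layers)) {
      nin <- if (l == 1L) 23L else 2L * h
      for (d in c("f", "b")) {
        # Input-to-hidden weights at ~unit variance (uniform on [-2, 2]):
        # the first layer sees one-hot rows (effective fan-in 1, so
        # fan-in-scaled schemes leave the states far too small to drive
        # the convolution stack) and deeper layers see bounded (-1, 1)
        # states.
        params[[sprintf("lstm%d_%s_W", l, d)]] <-
          matrix(runif(nin * 4 * h, -2, 2), nin, 4 * h)
        params[[sprintf("lstm%d_%s_U", l, d)]] <- glorot(h, 4 * h, h, 4 * h)
        bias <- rep(0, 4 * h)
        bias[(h + 1):(2 * h)] <- 1  # forget gate open at start
        params[[sprintf("lstm%d_%s_b", l, d)]] <- bias
      }
    }
  }
  if (uses$conv1) {
    params <- c(params,
                init_conv_branch("conv1_", 2L * config$lstm_hidden, config))
  }
  if (uses$conv2) {
    params <- c(params, init_conv_branch("conv2_", 43L, config))
  }
  if (config$dense_hidden > 0L) {
    params$dense1_W <- glorot(f_in, config$dense_hidden,
                              f_in, config$dense_hidden)
    params$dense1_b <- rep(0, config$dense_hidden)
    params$dense2_W <- glorot(config$dense_hidden, config$n_labels,
                              config$dense_hidden, config$n_labels)
    params$dense2_b <- rep(0, config$n_labels)
  } else {
    params$dense_W <- glorot(f_in, config$n_labels, f_in, config$n_labels)
    params$dense_b <- rep(0, config$n_labels)
  }
  n_par <- sum(vapply(params, length, 1L))
  structure(list(config = config, params = params,
                 vocabulary = vocabulary,
                 metadata = list(n_parameters = n_par),
                 trained = FALSE, history = NULL),
            class = "subloc_model")
}

#' @export
print.subloc_model <- function(x, ...) {
  cat(sprintf("subloc_model [%s], %s, %d labels, l_max %d, %s parameters\n",
              x$config$variant, if (x$trained) "trained" else "untrained",
              x$config$n_labels, x$config$l_max,
              format(x$metadata$n_parameters, big.mark = ",")))
  invisible(x)
}

# Config list handed to the C++ engine.
cpp_config <- function(config) {
  list(
    variant = match(config$variant, .VARIANTS) - 1L,  # 0 full, 1 blstm, ...
    l_max = config$l_max, n_labels = config$n_labels,
    lstm_layers = config$lstm_layers, lstm_hidden = config$lstm_hidden,
    kernel_counts = config$conv_kernel_counts,
    kernel_sizes = do.call(rbind, config$conv_kernel_sizes),
    pool = config$pool_size, dense_hidden = config$dense_hidden,
    l2_lambda = config$l2_lambda
  )
}

# Coerce assorted inputs to a 1 x l_max index row (0 = padding).
as_index_row <- function(onehot, config) {
  if (inherits(onehot, "subloc_onehot")) {
    n <- onehot$true_length
    idx <- integer(config$l_max)
    if (n > 0L) {
      head_rows <- onehot$values[seq_len(n), , drop = FALSE]
      idx[seq_len(n)] <- max.col(head_rows)
      idx[seq_len(n)][rowSums(head_rows) == 0L] <- 0L  # all-zero rows stay padding
    }
    if (nrow(onehot$values) != config$l_max) {
      stop("one-hot matrix has ", nrow(onehot$values),
           " rows but the model expects l_max = ", config$l_max)
    }
    idx
  } else {
    stop("expected a subloc_onehot object")
  }
}

as_pssm_values <- function(pssm, config) {
  if (!inherits(pssm, "subloc_pssm")) stop("expected a subloc_pssm object")
  if (nrow(pssm$values) != config$l_max) {
    stop("PSSM has ", nrow(pssm$values),
         " rows but the model expects l_max = ", config$l_max)
  }
  pssm$values
}

#' Per-location probability scores for one protein
#'
#' Runs the variant's forward pass. The scores are independent sigmoid
#' probabilities, one per location; they are not normalized to sum to 1.
#'
#' @param model A [build_model()] result (trained or not).
#' @param onehot [one_hot_encode()] output matching the model's `l_max`.
#' @param pssm [normalize_pssm()] output; required iff the variant uses the
#'   PSSM branch (`conv2`, `full`).
#' @return Numeric vector of length `n_labels`, values in (0, 1), named by
#'   the model's vocabulary when present.
#' @export
predict_scores <- function(model, onehot, pssm = NULL) {
  stopifnot(inherits(model, "subloc_model"))
  uses <- variant_uses(model$config$variant)
  if (uses$conv2 && is.null(pssm)) {
    stop("variant '", model$config$variant, "' requires a PSSM")
  }
  idx <- matrix(as_index_row(onehot, model$config), nrow = 1L)
  parr <- if (uses$conv2) {
    array(as_pssm_values(pssm, model$config),
          dim = c(model$config$l_max, 43L, 1L))
  } else {
    array(0, dim = c(1L, 1L, 1L))
  }
  s <- net_predict(model$params, cpp_config(model$config), idx, parr, 1L)
  # sigmoid saturates to exactly 0/1 in double precision for |logit| > ~37;
  # keep the probability contract open-interval
  s <- pmin(pmax(as.numeric(s), 1e-12), 1 - 1e-12)
  if (!is.null(model$vocabulary)) names(s) <- as.character(model$vocabulary)
  s
}

#' Batch prediction over an encoded store
#'
#' @param object A `subloc_model`.
#' @param store An [encode_dataset()] result (ids, index matrix, PSSM array).
#' @param batch_size Forward-pass batch size.
#' @param ... Unused.
#' @return n x n_labels score matrix, rows named by protein id.
#' @export
predict.subloc_model <- function(object, store, batch_size = 64L, ...) {
  uses <- variant_uses(object$config$variant)
  if (uses$conv2 && is.null(store$pssm)) {
    stop("variant '", object$config$variant,
         "' requires PSSMs in the encoded store")
  }
  parr <- if (uses$conv2) store$pssm else array(0, dim = c(1L, 1L, 1L))
  s <- net_predict(object$params, cpp_config(object$config), store$indices,
                   parr, as.integer(batch_size))
  s <- pmin(pmax(s, 1e-12), 1 - 1e-12)
  rownames(s) <- store$ids
  colnames(s) <- if (!is.null(object$vocabulary))
    as.character(object$vocabulary) else colnames(store$labels)
  s
}

#' BLSTM encoding of one protein
#'
#' Per-position concatenation of the forward and backward final-layer
#' hidden states (`lstm_hidden` each). Every element lies strictly in
#' (-1, 1) because `h_t = sigmoid(.) * tanh(C_t)`.
#'
#' @param model A `subloc_model` whose variant uses the BLSTM branch.
#' @param onehot [one_hot_encode()] output matching `l_max`.
#' @return `l_max` x `2 * lstm_hidden` numeric matrix (forward states in
#'   the first half of the columns).
#' @export
blstm_encode <- function(model, onehot) {
  stopifnot(inherits(model, "subloc_model"))
  if (!variant_uses(model$config$variant)$lstm) {
    stop("variant '", model$config$variant, "' has no BLSTM branch")
  }
  idx <- matrix(as_index_row(onehot, model$config), nrow = 1L)
  net_blstm_forward(model$params, cpp_config(model$config), idx)
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the configuration, vocabulary and training
#' history, so a reloaded model predicts identically.
#'
#' @param model A `subloc_model`.
#' @param path Checkpoint path (`.rds`).
#' @return `load_model`: the restored `subloc_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "subloc_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "subloc_model")) stop("not a subloc_model checkpoint")
  model
}
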