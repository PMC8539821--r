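# Loss, the training loop, and the cross-validation ablation harness.

#' Training configuration
#'
#' Hyperparameters of the optimization loop. Defaults: Adam at learning
#' rate 1e-3, 60 epochs, batch size 32, L2 coefficient 1e-4, binarization
#' threshold 0.5 for F1/MCC (ranking metrics and AUC always use raw
#' scores), global gradient-norm clipping at 5.
#'
#' @param epochs Number of passes over the training set (>= 1).
#' @param batch_size Minibatch size (>= 1).
#' @param learning_rate Adam step size (> 0).
#' @param optimizer Only `"adam"` is provided.
#' @param l2_lambda Coefficient of the L2 penalty on convolution kernels
#'   applied during training.
#' @param seed Integer seed driving parameter init surrogates and the
#'   per-epoch shuffles; fixed seed means bitwise-reproducible training.
#' @param early_stop_patience Optional: stop when the training loss has not
#'   improved for this many epochs. `NULL` disables.
#' @param threshold Score binarization threshold for F1/MCC, in (0,1).
#' @param clip_norm Global gradient-norm clip; 0 disables.
#' @param adam_eps Adam denominator constant. Parameters whose gradients
#'   are persistently tiny (e.g. recurrent weights behind a deep
#'   convolution stack early in training) take near-full-size noise steps
#'   under the conventional 1e-8; a larger value scales their steps down
#'   with the gradient instead.
#' @param freeze Character vector of parameter names (or the shorthand
#'   `"lstm"` for every LSTM weight) excluded from updates. Freezing the
#'   whole BLSTM turns it into a fixed random sequence encoder whose state
#'   images are computed once and cached, which both stabilizes and speeds
#'   up the first stage of [train_staged()].
#' @param shuffle Reshuffle example order every epoch.
#' @return List of class `subloc_training_config`.
#' @export
training_config <- function(epochs = 60L, batch_size = 32L,
                            learning_rate = 1e-3, optimizer = "adam",
                            l2_lambda = 1e-4, seed = 1L,
                            early_stop_patience = NULL, threshold = 0.5,
                            clip_norm = 5, adam_eps = 1e-4,
                            freeze = character(0), shuffle = TRUE) {
  if (epochs < 1L) stop("epochs must be >= 1")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (!identical(optimizer, "adam")) {
    stop("unsupported optimizer '", optimizer, "'")
  }
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (l2_lambda < 0) stop("l2_lambda must be >= 0")
  structure(list(
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    learning_rate = learning_rate, optimizer = optimizer,
    l2_lambda = l2_lambda, seed = as.integer(seed),
    early_stop_patience = if (is.null(early_stop_patience)) 0L
                          else as.integer(early_stop_patience),
    threshold = threshold, clip_norm = clip_norm,
    adam_eps = adam_eps, freeze = as.character(freeze),
    shuffle = isTRUE(shuffle)
  ), class = "subloc_training_config")
}

#' Binary cross-entropy loss with L2 kernel penalty
#'
#' `-(1/n) sum(y log yhat + (1 - y) log(1 - yhat)) + lambda * sum(omega^2)`
#' where n is the number of label terms and omega ranges over the supplied
#' convolution kernels. Predicted scores are clipped to
#' `[1e-7, 1 - 1e-7]` so the logs stay finite.
#'
#' @param y Binary vector or matrix of true labels.
#' @param y_hat Scores in (0, 1), same shape as `y`.
#' @param kernels List of numeric arrays (convolution kernels) entering the
#'   penalty; the penalty never covers LSTM or dense weights.
#' @param lambda Non-negative penalty coefficient.
#' @return Non-negative scalar.
#' @export
#' @examples
#' bce_l2_loss(1, 0.5)  # -log(0.5) = 0.6931
bce_l2_loss <- function(y, y_hat, kernels = list(), lambda = 0) {
  if (!identical(dim(y), dim(y_hat)) || length(y) != length(y_hat)) {
    stop("y and y_hat shapes differ")
  }
  if (!all(y %in% c(0, 1))) stop("y must be binary (0/1)")
  if (lambda < 0) stop("lambda must be >= 0")
  eps <- 1e-7
  p <- pmin(pmax(y_hat, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p)) +
    lambda * sum(vapply(kernels, function(k) sum(k^2), numeric(1)))
}

#' Encode a protein set for the network
#'
#' Converts every protein to the fixed-length index representation of its
#' one-hot matrix and (when PSSMs are supplied) to a normalized
#' `l_max` x 43 PSSM slice, bundled with the binary labels.
#'
#' @param data A [annotated_protein_set()].
#' @param pssms Named list (by protein id) of raw n x 42/43 PSSM matrices or
#'   [normalize_pssm()] results; `NULL` when no PSSM branch will be used.
#' @param config An [encoding_config()].
#' @return List of class `subloc_store`: `ids`, `indices` (n x l_max
#'   integer, 0 = padding), `pssm` (l_max x 43 x n array or `NULL`),
#'   `labels` (n x L), `vocabulary`, `l_max`.
#' @export
encode_dataset <- function(data, pssms = NULL, config = encoding_config()) {
  stopifnot(inherits(data, "subloc_proteins"))
  n <- length(data$ids)
  indices <- matrix(0L, nrow = n, ncol = config$l_max)
  for (i in seq_len(n)) {
    idx <- sequence_to_indices(data$sequences[[i]], config)
    m <- min(length(idx), config$l_max)
    indices[i, seq_len(m)] <- idx[seq_len(m)]
  }
  pssm_arr <- NULL
  if (!is.null(pssms)) {
    missing_ids <- setdiff(data$ids, names(pssms))
    if (length(missing_ids)) {
      stop("missing PSSM for id(s): ",
           paste(utils::head(missing_ids, 10), collapse = ", "))
    }
    pssm_arr <- array(0, dim = c(config$l_max, 43L, n))
    for (i in seq_len(n)) {
      p <- pssms[[data$ids[i]]]
      if (!inherits(p, "subloc_pssm")) p <- normalize_pssm(p, config)
      pssm_arr[, , i] <- as_pssm_values(p, config)
    }
  }
  structure(list(ids = data$ids, indices = indices, pssm = pssm_arr,
                 labels = data$labels, vocabulary = data$vocabulary,
                 l_max = config$l_max),
            class = "subloc_store")
}

#' Subset an encoded store by protein id
#'
#' @param store An [encode_dataset()] result.
#' @param ids Character vector of protein ids to keep (order respected).
#' @return A `subloc_store` restricted to `ids`.
#' @export
store_subset <- function(store, ids) {
  pos <- match(ids, store$ids)
  if (anyNA(pos)) stop("unknown id(s) in store subset")
  structure(list(
    ids = store$ids[pos],
    indices = store$indices[pos, , drop = FALSE],
    pssm = if (!is.null(store$pssm)) store$pssm[, , pos, drop = FALSE],
    labels = store$labels[pos, , drop = FALSE],
    vocabulary = store$vocabulary, l_max = store$l_max
  ), class = "subloc_store")
}

#' Train a model
#'
#' Minimizes the binary cross-entropy plus L2 kernel penalty with Adam.
#' Fully deterministic for a fixed `config$seed` (parameter initialization
#' comes from [build_model()]'s own seed; the per-epoch shuffles come from
#' this one). Divergence (non-finite loss) raises an error naming the
#' epoch.
#'
#' @param model An (untrained or trained) `subloc_model`.
#' @param store An [encode_dataset()] result; must contain PSSMs when the
#'   variant uses them, and its `l_max` and label count must match the
#'   model.
#' @param config A [training_config()].
#' @return The trained `subloc_model` with `$history` set to the per-epoch
#'   mean training loss.
#' @export
train_model <- function(model, store, config = training_config()) {
  stopifnot(inherits(model, "subloc_model"),
            inherits(store, "subloc_store"),
            inherits(config, "subloc_training_config"))
  n <- length(store$ids)
  if (n < 1L) stop("no training examples")
  if (store$l_max != model$config$l_max) {
    stop("store l_max ", store$l_max, " does not match model l_max ",
         model$config$l_max)
  }
  if (ncol(store$labels) != model$config$n_labels) {
    stop("store has ", ncol(store$labels), " labels but model expects ",
         model$config$n_labels)
  }
  uses <- variant_uses(model$config$variant)
  if (uses$conv2 && is.null(store$pssm)) {
    stop("variant '", model$config$variant,
         "' requires PSSMs in the encoded store")
  }
  # start the output bias at the label base rates: the head then spends its
  # first updates on per-location signal instead of learning the prior
  if (!model$trained) {
    prior <- stats::qlogis(pmin(pmax(colMeans(store$labels), 1e-3), 1 - 1e-3))
    if (model$config$dense_hidden > 0L) {
      model$params$dense2_b <- prior
    } else {
      model$params$dense_b <- prior
    }
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  orders <- t(vapply(seq_len(config$epochs), function(e) {
    if (config$shuffle) sample.int(n) else seq_len(n)
  }, integer(n)))
  cfgl <- cpp_config(model$config)
  cfgl$l2_lambda <- config$l2_lambda
  freeze <- config$freeze
  if ("lstm" %in% freeze) {
    freeze <- union(setdiff(freeze, "lstm"),
                    grep("^lstm", names(model$params), value = TRUE))
  }
  unknown <- setdiff(freeze, names(model$params))
  if (length(unknown)) {
    stop("cannot freeze unknown parameter(s): ",
         paste(unknown, collapse = ", "))
  }
  parr <- if (uses$conv2) store$pssm else array(0, dim = c(1L, 1L, 1L))
  res <- net_train(model$params, cfgl, store$indices, parr,
                   store$labels * 1.0,
                   list(epochs = config$epochs,
                        batch_size = config$batch_size,
                        learning_rate = config$learning_rate,
                        beta1 = 0.9, beta2 = 0.999, adam_eps = config$adam_eps,
                        clip_norm = config$clip_norm,
                        patience = config$early_stop_patience,
                        freeze = freeze),
                   orders)
  model$params <- res$params
  model$trained <- TRUE
  model$history <- as.numeric(res$history)
  if (is.null(model$vocabulary)) model$vocabulary <- store$vocabulary
  model
}

#' Two-stage training for the BLSTM-fed variants
#'
#' Stage one trains the convolution stacks and dense head against the
#' frozen, randomly initialized BLSTM — a reservoir-style fixed encoder
#' whose state images are cached, so these epochs are cheap. Stage two
#' unfreezes everything and fine-tunes jointly. Training the readout
#' before the recurrent encoder avoids the failure mode where
#' noise-driven updates to the recurrent weights (whose early gradients
#' carry no signal through the still-random convolution stack) wash out
#' the state images before the readout can lock onto them. For variants
#' without a BLSTM branch the two stages collapse into ordinary training
#' for `epochs_frozen + epochs_joint` epochs.
#'
#' Both stages run in short chunks with a fresh Adam state (and shuffle
#' stream) per chunk — warm restarts. The restarts act as a cheap
#' annealing schedule (the bias-corrected first steps after a restart are
#' conservative) and give the readout several independent chances to lock
#' onto the signal; empirically they improve held-out ranking quality at
#' a fixed epoch budget.
#'
#' @param model An untrained `subloc_model`.
#' @param store An [encode_dataset()] result.
#' @param config A [training_config()]; its `epochs` field is ignored in
#'   favor of the two stage lengths.
#' @param epochs_frozen Stage-one epochs (frozen BLSTM).
#' @param epochs_joint Stage-two epochs (all parameters).
#' @param restart_every Chunk length in epochs; each chunk restarts Adam
#'   and draws a fresh shuffle stream (`config$seed` + chunk index).
#' @param joint_learning_rate Optional distinct learning rate for the
#'   joint stage; the default `NULL` keeps `config$learning_rate`. Once
#'   the readout is aligned, the joint stage tolerates — and benefits
#'   from — a larger step size than the frozen stage.
#' @return The trained model; `$history` concatenates all chunks.
#' @export
train_staged <- function(model, store, config = training_config(),
                         epochs_frozen = 10L, epochs_joint = 15L,
                         restart_every = 3L, joint_learning_rate = NULL) {
  uses <- variant_uses(model$config$variant)
  chunks_of <- function(total) {
    if (total <= 0L) return(integer(0))
    n_chunks <- max(1L, ceiling(total / restart_every))
    base <- total %/% n_chunks
    sizes <- rep(as.integer(base), n_chunks)
    extra <- total - base * n_chunks
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    sizes
  }
  plan <- if (uses$lstm) {
    c(rep(TRUE, length(chunks_of(epochs_frozen))),
      rep(FALSE, length(chunks_of(epochs_joint))))
  } else {
    rep(FALSE, length(chunks_of(epochs_frozen + epochs_joint)))
  }
  sizes <- if (uses$lstm) {
    c(chunks_of(epochs_frozen), chunks_of(epochs_joint))
  } else {
    chunks_of(epochs_frozen + epochs_joint)
  }
  history <- numeric(0)
  for (k in seq_along(sizes)) {
    cfg <- config
    cfg$epochs <- sizes[k]
    cfg$seed <- config$seed + k - 1L
    if (plan[k]) {
      cfg$freeze <- union(config$freeze, "lstm")
    } else if (!is.null(joint_learning_rate)) {
      cfg$learning_rate <- joint_learning_rate
    }
    model <- train_model(model, store, cfg)
    history <- c(history, model$history)
  }
  model$history <- history
  model
}

#' k-fold cross-validation over a dataset
#'
#' The complete evaluation protocol: partition the proteins into k folds,
#' train the configured variant on k-1 folds, score the held-out fold with
#' the metrics module, and aggregate. Labels with no positive (or no
#' negative) example in a test fold get `NA` for AUC/F1/MCC and are
#' excluded from macro-averages; fold results record which.
#'
#' @param data A [annotated_protein_set()].
#' @param pssms Named list of per-protein PSSMs (see [encode_dataset()]);
#'   required when the variant uses the PSSM branch.
#' @param model_config A [model_config()] whose `n_labels` matches the data.
#' @param train_config A [training_config()]; its seed also fixes the fold
#'   assignment, so reruns are identical.
#' @param k Number of folds (default 5).
#' @param encoding An [encoding_config()] with `l_max` matching the model.
#' @return Object of class `subloc_cv`: `folds` (per fold: `fold_index`,
#'   the [evaluate_all()] report, `history`, `test_ids`), and `aggregate`
#'   (data.frame metric/mean/sd across folds).
#' @export
run_cross_validation <- function(data, pssms = NULL, model_config,
                                 train_config = training_config(), k = 5L,
                                 encoding = encoding_config(
                                   l_max = model_config$l_max)) {
  stopifnot(inherits(data, "subloc_proteins"))
  if (model_config$n_labels != length(data$vocabulary)) {
    stop("model n_labels does not match dataset vocabulary")
  }
  store <- encode_dataset(data, pssms, encoding)
  folds <- cross_validation_folds(data, k, seed = train_config$seed)
  results <- vector("list", k)
  for (f in seq_len(k)) {
    train_ids <- sort(folds[[f]]$train)
    test_ids <- sort(folds[[f]]$test)
    model <- build_model(model_config, seed = train_config$seed + f,
                         vocabulary = data$vocabulary)
    model <- train_model(model, store_subset(store, train_ids), train_config)
    scores <- predict(model, store_subset(store, test_ids))
    report <- evaluate_all(store$labels[test_ids, , drop = FALSE], scores,
                           threshold = train_config$threshold)
    results[[f]] <- list(fold_index = f, report = report,
                         history = model$history, test_ids = test_ids)
  }
  metric_names <- c("macro_f1", "macro_mcc", "macro_auc",
                    "ranking_loss", "coverage", "average_precision")
  vals <- vapply(results, function(r) {
    unlist(r$report[metric_names])
  }, numeric(length(metric_names)))
  aggregate <- data.frame(
    metric = metric_names,
    mean = rowMeans(vals),
    sd = apply(vals, 1L, stats::sd)
  )
  structure(list(folds = results, aggregate = aggregate, k = k),
            class = "subloc_cv")
}

#' @export
print.subloc_cv <- function(x, digits = 4, ...) {
  cat(sprintf("%d-fold cross-validation\n", x$k))
  agg <- x$aggregate
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-18s %.*f +/- %.*f\n", agg$metric[i],
                digits, agg$mean[i], digits, agg$sd[i]))
  }
  invisible(x)
}
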