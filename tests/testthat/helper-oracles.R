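# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (explicit loops, no shared code with the package
# internals) so they can arbitrate.

oracle_ranking_loss <- function(y, s) {
  total <- 0
  for (i in seq_len(nrow(y))) {
    bad <- 0; pairs <- 0
    for (k in seq_len(ncol(y))) for (l in seq_len(ncol(y))) {
      if (y[i, k] == 1 && y[i, l] == 0) {
        pairs <- pairs + 1
        if (s[i, k] <= s[i, l]) bad <- bad + 1
      }
    }
    total <- total + bad / pairs
  }
  total / nrow(y)
}

oracle_coverage <- function(y, s) {
  total <- 0
  for (i in seq_len(nrow(y))) {
    worst <- 0
    for (j in seq_len(ncol(y))) {
      if (y[i, j] == 1) {
        rank_j <- 0
        for (k in seq_len(ncol(y))) if (s[i, k] >= s[i, j]) rank_j <- rank_j + 1
        worst <- max(worst, rank_j)
      }
    }
    total <- total + worst
  }
  total / nrow(y)
}

oracle_average_precision <- function(y, s) {
  total <- 0
  for (i in seq_len(nrow(y))) {
    acc <- 0; npos <- 0
    for (j in seq_len(ncol(y))) {
      if (y[i, j] == 1) {
        npos <- npos + 1
        above <- 0; above_true <- 0
        for (k in seq_len(ncol(y))) {
          if (s[i, k] >= s[i, j]) {
            above <- above + 1
            if (y[i, k] == 1) above_true <- above_true + 1
          }
        }
        acc <- acc + above_true / above
      }
    }
    total <- total + acc / npos
  }
  total / nrow(y)
}

oracle_auc <- function(y, s) {
  wins <- 0; pairs <- 0
  for (i in which(y == 1)) for (j in which(y == 0)) {
    pairs <- pairs + 1
    if (s[i] > s[j]) wins <- wins + 1
    else if (s[i] == s[j]) wins <- wins + 0.5
  }
  if (pairs == 0) return(NA_real_)
  wins / pairs
}

oracle_f1 <- function(y, yhb) {
  tp <- sum(y == 1 & yhb == 1)
  2 * tp / (2 * tp + sum(y == 0 & yhb == 1) + sum(y == 1 & yhb == 0))
}

# random multi-label instance where every row has >= 1 positive and >= 1
# negative; optionally quantized scores so ties occur
random_instance <- function(n, L, tie_prone = FALSE) {
  y <- matrix(0L, n, L)
  for (i in seq_len(n)) {
    npos <- sample.int(L - 1L, 1L)
    y[i, sample.int(L, npos)] <- 1L
  }
  s <- matrix(runif(n * L), n, L)
  if (tie_prone) s <- round(s * 4) / 4
  list(y = y, s = s)
}

# reference single-direction LSTM (gate order i, f, g, o) in plain R
ref_lstm <- function(X, W, U, b, reverse = FALSE) {
  T_ <- nrow(X); h <- nrow(U)
  sig <- function(z) 1 / (1 + exp(-z))
  H <- matrix(0, T_, h)
  hp <- rep(0, h); cp <- rep(0, h)
  steps <- if (reverse) T_:1 else 1:T_
  for (t in steps) {
    a <- drop(X[t, ] %*% W + hp %*% U) + b
    i <- sig(a[1:h]); f <- sig(a[(h + 1):(2 * h)])
    g <- tanh(a[(2 * h + 1):(3 * h)]); o <- sig(a[(3 * h + 1):(4 * h)])
    cp <- f * cp + i * g
    hp <- o * tanh(cp)
    H[t, ] <- hp
  }
  H
}

# reference conv stack (single-channel image in, engine kernel layout) in R
ref_conv_stack <- function(img, params, prefix, config) {
  chans <- list(img)
  for (cl in 1:4) {
    kh <- config$conv_kernel_sizes[[cl]][1]
    kw <- config$conv_kernel_sizes[[cl]][2]
    K <- config$conv_kernel_counts[cl]
    W <- params[[paste0(prefix, cl, "_W")]]
    b <- params[[paste0(prefix, cl, "_b")]]
    cin <- length(chans)
    out <- vector("list", K)
    for (k in seq_len(K)) {
      acc <- 0
      for (cc in seq_len(cin)) {
        kern <- matrix(0, kh, kw)
        for (j in seq_len(kw)) for (i in seq_len(kh)) {
          kern[i, j] <- W[i + kh * (j - 1) + kh * kw * (cc - 1), k]
        }
        acc <- acc + convolve2d(chans[[cc]], kern)
      }
      out[[k]] <- pmax(acc + b[k], 0)
    }
    if (cl <= 3) {
      ph <- config$pool_size[1]; pw <- config$pool_size[2]
      out <- lapply(out, function(m) {
        oh <- nrow(m) %/% ph; ow <- ncol(m) %/% pw
        p <- matrix(0, oh, ow)
        for (a in seq_len(oh)) for (d in seq_len(ow)) {
          p[a, d] <- max(m[((a - 1) * ph + 1):(a * ph),
                           ((d - 1) * pw + 1):(d * pw)])
        }
        p
      })
    }
    chans <- out
  }
  unlist(lapply(chans, as.vector))  # channels-last flatten, column-major
}

# temp FASTA + label fixtures; the tempdir must outlive this helper, so it
# is anchored in the caller's frame
write_tiny_dataset <- function(dir = NULL,
                               ids = c("p1", "p2", "p3"),
                               seqs = c("MKV", "ACDEF", "GHIKL"),
                               labels = c("Nucleus", "Nucleus,Cytoplasm",
                                          "Cytoplasm")) {
  if (is.null(dir)) dir <- withr::local_tempdir(.local_envir = parent.frame())
  fasta <- file.path(dir, "t.fasta")
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), fasta)
  lab <- file.path(dir, "t.tsv")
  writeLines(paste(ids, labels, sep = "\t"), lab)
  list(fasta = fasta, labels = lab, dir = dir)
}

# tiny but fully wired model configuration (all four conv layers + 2 BLSTM
# layers survive the geometry at l_max = 24 with narrow kernels)
tiny_model_config <- function(variant, n_labels = 3, l_max = 24,
                              l2_lambda = 0) {
  model_config(variant, n_labels = n_labels, l_max = l_max,
               lstm_layers = 2, lstm_hidden = 4,
               conv_kernel_counts = c(2, 2, 2, 2),
               conv_kernel_sizes = list(c(2, 1), c(2, 1), c(2, 1), c(2, 1)),
               l2_lambda = l2_lambda)
}

random_store <- function(n, config, n_labels = 3, seed = 1,
                         with_pssm = TRUE) {
  set.seed(seed)
  idx <- matrix(sample(0:23, n * config$l_max, replace = TRUE),
                n, config$l_max)
  idx[, 1:5] <- pmax(idx[, 1:5, drop = FALSE], 1L)
  y <- matrix(0L, n, n_labels)
  for (i in seq_len(n)) y[i, sample.int(n_labels, sample(1:2, 1))] <- 1L
  structure(list(
    ids = sprintf("r%03d", seq_len(n)), indices = idx,
    pssm = if (with_pssm)
      array(rnorm(config$l_max * 43 * n), dim = c(config$l_max, 43, n)),
    labels = y, vocabulary = paste0("L", seq_len(n_labels)),
    l_max = config$l_max
  ), class = "subloc_store")
}
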