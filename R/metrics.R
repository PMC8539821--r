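# Multi-label ranking metrics and per-label binary metrics, exactly as the
# standard printed formulas define them. Ties are handled as the formulas'
# non-strict inequalities dictate: a tie between a true and a false label
# counts as a ranking violation, and ranks are counted inclusively.

check_ys <- function(y, s) {
  y <- as.matrix(y)
  s <- as.matrix(s)
  if (!identical(dim(y), dim(s))) {
    stop("label matrix is ", nrow(y), " x ", ncol(y),
         " but score matrix is ", nrow(s), " x ", ncol(s))
  }
  if (!all(y %in% c(0, 1))) stop("labels must be binary (0/1)")
  if (!all(is.finite(s))) stop("scores must be finite")
  list(y = y, s = s)
}

#' Ranking loss
#'
#' Mean, over proteins, of the fraction of (true label, false label) pairs
#' the score vector orders incorrectly; a tie counts as a violation. 0 is a
#' perfect ranking, 1 a fully inverted one. The per-protein denominator is
#' `||y_i||_0 * (L - ||y_i||_0)`, so every row needs at least one positive
#' and one negative label.
#'
#' @param y n x L binary label matrix.
#' @param s n x L score matrix (same shape, finite).
#' @return Scalar in `[0, 1]`.
#' @export
#' @examples
#' ranking_loss(matrix(c(1, 0, 0), 1), matrix(c(0.2, 0.9, 0.1), 1))  # 0.5
ranking_loss <- function(y, s) {
  v <- check_ys(y, s)
  per_row <- vapply(seq_len(nrow(v$y)), function(i) {
    pos <- v$s[i, v$y[i, ] == 1]
    neg <- v$s[i, v$y[i, ] == 0]
    if (length(pos) == 0L || length(neg) == 0L) {
      stop("row ", i, " has no positive or no negative label; ",
           "ranking loss is undefined")
    }
    sum(outer(pos, neg, `<=`)) / (length(pos) * length(neg))
  }, numeric(1))
  mean(per_row)
}

#' Coverage
#'
#' Mean, over proteins, of how deep one must descend the score-sorted label
#' list to include every true label: the maximum over true labels j of the
#' 1-based inclusive rank `|{k : s_ik >= s_ij}|`. Ranges from the mean
#' number of true labels (perfect) up to L.
#'
#' @inheritParams ranking_loss
#' @return Scalar `>= 1`.
#' @export
coverage <- function(y, s) {
  v <- check_ys(y, s)
  per_row <- vapply(seq_len(nrow(v$y)), function(i) {
    truej <- which(v$y[i, ] == 1)
    if (length(truej) == 0L) stop("row ", i, " has no positive label")
    max(vapply(truej, function(j) sum(v$s[i, ] >= v$s[i, j]), numeric(1)))
  }, numeric(1))
  mean(per_row)
}

#' Label-ranking average precision
#'
#' Mean, over proteins, of the average over true labels j of the fraction
#' of true labels among all labels ranked at or above j (ties inclusive).
#' 1 when every true label outranks every false one.
#'
#' @inheritParams ranking_loss
#' @return Scalar in `(0, 1]`.
#' @export
average_precision <- function(y, s) {
  v <- check_ys(y, s)
  per_row <- vapply(seq_len(nrow(v$y)), function(i) {
    truej <- which(v$y[i, ] == 1)
    if (length(truej) == 0L) stop("row ", i, " has no positive label")
    mean(vapply(truej, function(j) {
      at_or_above <- v$s[i, ] >= v$s[i, j]
      sum(at_or_above & v$y[i, ] == 1) / sum(at_or_above)
    }, numeric(1)))
  }, numeric(1))
  mean(per_row)
}

#' Binary confusion counts
#'
#' @param y,y_hat_bin Binary vectors of equal length (truth, prediction).
#' @return Named list `tp`, `tn`, `fp`, `fn`; the four counts sum to the
#'   vector length.
#' @export
binary_confusion <- function(y, y_hat_bin) {
  if (length(y) != length(y_hat_bin)) stop("length mismatch")
  if (!all(y %in% c(0, 1)) || !all(y_hat_bin %in% c(0, 1))) {
    stop("inputs must be binary (0/1)")
  }
  list(tp = sum(y == 1 & y_hat_bin == 1),
       tn = sum(y == 0 & y_hat_bin == 0),
       fp = sum(y == 0 & y_hat_bin == 1),
       fn = sum(y == 1 & y_hat_bin == 0))
}

#' F1 score from confusion counts
#'
#' Harmonic mean of precision `tp/(tp+fp)` and recall `tp/(tp+fn)`.
#' Undefined (no predicted positives or no actual positives) is reported as
#' `NA`, never imputed as 0.
#'
#' @param conf List with `tp`, `tn`, `fp`, `fn` (see [binary_confusion()]).
#' @return Scalar in `[0, 1]`, or `NA` when undefined.
#' @export
f1_score <- function(conf) {
  tp <- conf$tp; fp <- conf$fp; fn <- conf$fn
  if ((tp + fp) == 0 || (tp + fn) == 0) return(NA_real_)
  if (tp == 0) return(0)
  ppv <- tp / (tp + fp)
  tpr <- tp / (tp + fn)
  2 * ppv * tpr / (ppv + tpr)
}

#' Matthews correlation coefficient from confusion counts
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`; 1 is a perfect
#' prediction, -1 an inverted one. Undefined when any marginal sum is zero;
#' reported as `NA`.
#'
#' @inheritParams f1_score
#' @return Scalar in `[-1, 1]`, or `NA` when undefined.
#' @export
mcc <- function(conf) {
  tp <- as.numeric(conf$tp); tn <- as.numeric(conf$tn)
  fp <- as.numeric(conf$fp); fn <- as.numeric(conf$fn)
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom2 == 0) return(NA_real_)
  (tp * tn - fp * fn) / sqrt(denom2)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random positive
#' outscores a random negative, ties contributing 1/2 — identical to the
#' trapezoidal area under the ROC curve. Undefined for single-class input;
#' reported as `NA`.
#'
#' @param y Binary truth vector.
#' @param s Numeric score vector of the same length.
#' @return Scalar in `[0, 1]`, or `NA` when undefined.
#' @export
auc <- function(y, s) {
  if (length(y) != length(s)) stop("length mismatch")
  if (!all(y %in% c(0, 1))) stop("labels must be binary (0/1)")
  npos <- sum(y == 1)
  nneg <- sum(y == 0)
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(s, ties.method = "average")
  (sum(r[y == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Full multi-label evaluation report
#'
#' Per-location F1, MCC (scores binarized at `threshold`) and AUC (raw
#' scores), their macro-averages over the locations where they are defined,
#' and the three ranking metrics on raw scores.
#'
#' @param y n x L binary label matrix (columns may be named by location).
#' @param s n x L score matrix.
#' @param threshold Binarization threshold for F1/MCC, in (0,1).
#' @return Object of class `subloc_report`: list with `per_label`
#'   (data.frame label/f1/mcc/auc; `NA` marks undefined), `macro_f1`,
#'   `macro_mcc`, `macro_auc`, `ranking_loss`, `coverage`,
#'   `average_precision`, `threshold`, `n`, and `undefined_labels`.
#' @export
evaluate_all <- function(y, s, threshold = 0.5) {
  v <- check_ys(y, s)
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  L <- ncol(v$y)
  labs <- colnames(v$y)
  if (is.null(labs)) labs <- paste0("L", seq_len(L))
  yhb <- (v$s >= threshold) * 1L
  per <- lapply(seq_len(L), function(j) {
    conf <- binary_confusion(v$y[, j], yhb[, j])
    c(f1 = f1_score(conf), mcc = mcc(conf), auc = auc(v$y[, j], v$s[, j]))
  })
  per <- do.call(rbind, per)
  per_label <- data.frame(label = labs, per, row.names = NULL)
  undef <- labs[apply(per, 1L, anyNA)]
  structure(list(
    per_label = per_label,
    macro_f1 = mean(per[, "f1"], na.rm = TRUE),
    macro_mcc = mean(per[, "mcc"], na.rm = TRUE),
    macro_auc = mean(per[, "auc"], na.rm = TRUE),
    ranking_loss = ranking_loss(v$y, v$s),
    coverage = coverage(v$y, v$s),
    average_precision = average_precision(v$y, v$s),
    threshold = threshold, n = nrow(v$y),
    undefined_labels = undef
  ), class = "subloc_report")
}

#' @export
print.subloc_report <- function(x, digits = 4, ...) {
  cat(sprintf("Multi-label evaluation on %d proteins, %d locations\n",
              x$n, nrow(x$per_label)))
  cat(sprintf("  ranking loss       %.*f\n", digits, x$ranking_loss))
  cat(sprintf("  coverage           %.*f\n", digits, x$coverage))
  cat(sprintf("  average precision  %.*f\n", digits, x$average_precision))
  cat(sprintf("  macro F1 / MCC / AUC (threshold %.2f): %.*f / %.*f / %.*f\n",
              x$threshold, digits, x$macro_f1, digits, x$macro_mcc,
              digits, x$macro_auc))
  if (length(x$undefined_labels)) {
    cat("  undefined (excluded from macro):",
        paste(x$undefined_labels, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read / write score or label matrices as TSV with ids and location header
#'
#' Interchange format of the evaluation tools: first column `id`, remaining
#' columns one per location in vocabulary order.
#'
#' @param path File path.
#' @return `read_score_tsv`: numeric matrix with protein row names and
#'   location column names.
#' @export
read_score_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          colClasses = c("character", rep(NA, 0)))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' @param scores Numeric matrix, rows named by protein id, columns by
#'   location.
#' @rdname read_score_tsv
#' @export
write_score_tsv <- function(scores, path) {
  df <- data.frame(id = rownames(scores), scores, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
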