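test_that("ranking metrics reproduce worked examples including ties rules", {
  # ranking loss
  expect_equal(ranking_loss(matrix(c(1, 0, 0), 1), matrix(c(0.9, 0.5, 0.1), 1)), 0)
  expect_equal(ranking_loss(matrix(c(1, 0, 0), 1), matrix(c(0.2, 0.9, 0.1), 1)), 0.5)
  expect_equal(ranking_loss(matrix(c(0, 1), 1), matrix(c(0.9, 0.1), 1)), 1)
  # a tie between a true and false label counts as a violation
  expect_equal(ranking_loss(matrix(c(1, 0), 1), matrix(c(0.4, 0.4), 1)), 1)
  # coverage
  expect_equal(coverage(matrix(c(0, 1, 0), 1), matrix(c(0.1, 0.9, 0.2), 1)), 1)
  expect_equal(coverage(matrix(c(1, 0, 1), 1), matrix(c(0.9, 0.8, 0.1), 1)), 3)
  expect_equal(coverage(matrix(1, 2, 4), matrix(runif(8), 2, 4)), 4)
  # average precision
  expect_equal(average_precision(matrix(c(1, 0, 1, 0), 1),
                                 matrix(c(0.9, 0.8, 0.7, 0.1), 1)),
               (1 + 2 / 3) / 2)
  expect_equal(average_precision(matrix(c(1, 1, 0, 0), 1),
                                 matrix(c(0.9, 0.8, 0.3, 0.2), 1)), 1)
  # single true label at rank r among distinct scores -> 1/r
  y <- matrix(c(0, 0, 1, 0), 1)
  s <- matrix(c(0.9, 0.8, 0.5, 0.1), 1)
  expect_equal(average_precision(y, s), 1 / 3)
})

test_that("degenerate rows raise rather than silently misreport", {
  expect_error(ranking_loss(matrix(c(1, 1), 1), matrix(c(0.2, 0.4), 1)))
  expect_error(ranking_loss(matrix(c(0, 0), 1), matrix(c(0.2, 0.4), 1)))
  expect_error(coverage(matrix(c(0, 0), 1), matrix(c(0.2, 0.4), 1)))
  expect_error(average_precision(matrix(c(0, 0), 1), matrix(c(0.2, 0.4), 1)))
  expect_error(ranking_loss(matrix(1, 1, 2), matrix(0.5, 2, 2)), "x")
})

test_that("binary metrics match closed forms and mark undefined as NA", {
  conf <- binary_confusion(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(conf, list(tp = 1L, tn = 1L, fp = 1L, fn = 1L))
  expect_equal(sum(unlist(conf)), 4L)
  expect_equal(binary_confusion(c(1, 0), c(1, 0)),
               list(tp = 1L, tn = 1L, fp = 0L, fn = 0L))
  expect_equal(binary_confusion(c(1, 0), c(0, 1)),
               list(tp = 0L, tn = 0L, fp = 1L, fn = 1L))
  expect_error(binary_confusion(c(1, 2), c(1, 0)), "binary")

  expect_equal(f1_score(list(tp = 1, fp = 1, fn = 1, tn = 0)), 0.5)
  expect_equal(f1_score(list(tp = 3, fp = 0, fn = 0, tn = 2)), 1)
  expect_equal(f1_score(list(tp = 0, fp = 2, fn = 3, tn = 1)), 0)
  expect_true(is.na(f1_score(list(tp = 0, fp = 0, fn = 0, tn = 4))))

  expect_equal(mcc(list(tp = 2, tn = 2, fp = 1, fn = 1)), 1 / 3)
  expect_equal(mcc(list(tp = 5, tn = 5, fp = 0, fn = 0)), 1)
  expect_equal(mcc(list(tp = 0, tn = 0, fp = 5, fn = 5)), -1)
  expect_true(is.na(mcc(list(tp = 0, tn = 4, fp = 0, fn = 0))))

  expect_equal(auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.2)), 1)
  expect_equal(auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.3, 0.2)), 0.75)
  expect_equal(auc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_true(is.na(auc(c(1, 1), c(0.2, 0.4))))
})

test_that("all metrics agree with brute-force enumeration on random cases", {
  set.seed(20)
  for (rep in 1:60) {
    inst <- random_instance(n = sample(2:8, 1), L = sample(2:6, 1),
                            tie_prone = rep %% 2 == 0)
    expect_equal(ranking_loss(inst$y, inst$s),
                 oracle_ranking_loss(inst$y, inst$s), tolerance = 1e-10)
    expect_equal(coverage(inst$y, inst$s),
                 oracle_coverage(inst$y, inst$s), tolerance = 1e-10)
    expect_equal(average_precision(inst$y, inst$s),
                 oracle_average_precision(inst$y, inst$s), tolerance = 1e-10)
    j <- sample(ncol(inst$y), 1)
    if (length(unique(inst$y[, j])) == 2) {
      expect_equal(auc(inst$y[, j], inst$s[, j]),
                   oracle_auc(inst$y[, j], inst$s[, j]), tolerance = 1e-10)
    }
    yhb <- (inst$s[, j] >= 0.5) * 1
    conf <- binary_confusion(inst$y[, j], yhb)
    f <- f1_score(conf)
    if (!is.na(f)) expect_equal(f, oracle_f1(inst$y[, j], yhb),
                                tolerance = 1e-10)
  }
})

test_that("metric structure: monotonicity, permutation and transform invariance", {
  set.seed(31)
  for (rep in 1:20) {
    inst <- random_instance(n = 5, L = 5)
    # permuting label columns jointly leaves every metric unchanged
    p <- sample(5)
    expect_equal(ranking_loss(inst$y[, p], inst$s[, p]),
                 ranking_loss(inst$y, inst$s))
    expect_equal(coverage(inst$y[, p], inst$s[, p]),
                 coverage(inst$y, inst$s))
    expect_equal(average_precision(inst$y[, p], inst$s[, p]),
                 average_precision(inst$y, inst$s))
    # AUC invariant under strictly monotone transforms
    j <- which(colSums(inst$y) %in% 1:4)[1]
    if (!is.na(j)) {
      expect_equal(auc(inst$y[, j], inst$s[, j]),
                   auc(inst$y[, j], qlogis(inst$s[, j] * 0.98 + 0.01)))
    }
    # raising a true label's score (no ties crossed) never hurts
    i <- sample(5, 1)
    truej <- which(inst$y[i, ] == 1)[1]
    s2 <- inst$s
    gap <- min(c(1.5, s2[i, s2[i, ] > s2[i, truej]])) # stay below next score
    s2[i, truej] <- s2[i, truej] + 0.49 * (gap - s2[i, truej])
    expect_lte(ranking_loss(inst$y, s2), ranking_loss(inst$y, inst$s))
    expect_lte(coverage(inst$y, s2), coverage(inst$y, inst$s))
    expect_gte(average_precision(inst$y, s2) + 1e-12,
               average_precision(inst$y, inst$s))
    # RL + pairwise agreement = 1 on tie-free instances
    agree <- 1 - oracle_ranking_loss(inst$y, inst$s)
    expect_equal(ranking_loss(inst$y, inst$s) + agree, 1)
  }
})

test_that("evaluate_all composes the per-metric results", {
  set.seed(7)
  inst <- random_instance(n = 6, L = 4)
  colnames(inst$y) <- paste0("Loc", 1:4)
  rep_all <- evaluate_all(inst$y, inst$s, threshold = 0.5)
  expect_equal(rep_all$ranking_loss, ranking_loss(inst$y, inst$s))
  expect_equal(rep_all$coverage, coverage(inst$y, inst$s))
  expect_equal(rep_all$average_precision, average_precision(inst$y, inst$s))
  for (j in 1:4) {
    expect_equal(rep_all$per_label$auc[j], auc(inst$y[, j], inst$s[, j]))
  }
  # perfect predictions: scores = labels nudged into (0,1)
  sp <- inst$y * 0.8 + 0.1
  perfect <- evaluate_all(inst$y, sp)
  expect_equal(perfect$ranking_loss, 0)
  expect_equal(perfect$average_precision, 1)
  expect_equal(perfect$coverage, mean(rowSums(inst$y)))
  expect_equal(perfect$macro_f1, 1)
  expect_equal(perfect$macro_mcc, 1)
  expect_equal(perfect$macro_auc, 1)
  # undefined labels are excluded, not imputed
  y1 <- cbind(inst$y[, 1:3], ConstPos = 1L)  # constant-positive label
  s1 <- cbind(inst$s[, 1:3], runif(6))
  r1 <- evaluate_all(y1, s1)
  expect_true("ConstPos" %in% r1$undefined_labels)
  expect_true(is.na(r1$per_label$auc[4]))
  expect_false(anyNA(c(r1$macro_f1, r1$macro_auc)))
  expect_error(evaluate_all(inst$y, inst$s[, 1:3]))
  expect_error(evaluate_all(inst$y, inst$s, threshold = 1.2))
})

test_that("score/label TSV round trip preserves ids and values", {
  path <- withr::local_tempfile()
  s <- matrix(runif(6), 2, 3,
              dimnames = list(c("p1", "p2"), c("Nucleus", "Cytoplasm", "ER")))
  write_score_tsv(s, path)
  back <- read_score_tsv(path)
  expect_equal(back, s, tolerance = 1e-12)
})
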