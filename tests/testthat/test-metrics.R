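test_that("perfect probabilities score 1 on every metric", {
  y <- rep(core_classes(), each = 5)
  probs <- t(vapply(y, function(cl) {
    p <- rep(0.04, 4); p[as.integer(cl)] <- 0.88; p
  }, numeric(4)))
  colnames(probs) <- core_classes()
  mr <- compute_multiclass_metrics(y, probs)
  for (nm in c("auroc", "auprc", "accuracy", "balanced_accuracy",
               "precision", "f1", "kappa"))
    expect_equal(mr[[nm]], 1, tolerance = 1e-12)
  expect_equal(mr$kappa_band, "almost perfect")
})

test_that("kappa matches the closed form on a symmetric binary confusion", {
  # confusion [[45, 5], [5, 45]]: po = 0.9, pe = 0.5, kappa = 0.8
  y <- rep(c("1", "2"), each = 50)
  pred <- c(rep("1", 45), rep("2", 5), rep("1", 5), rep("2", 45))
  expect_equal(cohens_kappa(y, pred), 0.8)
  expect_equal(kappa_band(0.8), "substantial")
  expect_equal(kappa_band(0.81), "almost perfect")
  expect_equal(kappa_band(-0.1), "no agreement")
})

test_that("uniform probabilities on balanced classes sit at chance", {
  set.seed(10)
  y <- sample(rep(core_classes(), each = 50))
  probs <- matrix(runif(800, 0.24, 0.26), 200, 4,
                  dimnames = list(NULL, core_classes()))
  mr <- compute_multiclass_metrics(y, probs)
  expect_lt(abs(mr$accuracy - 0.25), 0.1)
  expect_lt(abs(mr$kappa), 0.1)
  expect_lt(abs(mr$auroc - 0.5), 0.1)
})

test_that("binary panels compute BA, FPR and FNR by construction", {
  y <- c(rep("1", 10), rep("2", 10))
  pred <- c(rep("1", 8), "2", "2", rep("2", 6), rep("1", 4))
  pan <- compute_binary_class_metrics(y, pred, "1")
  sens <- 0.8; spec <- 0.6
  expect_equal(unname(pan["balanced_accuracy"]), (sens + spec) / 2)
  expect_equal(unname(pan["fnr"]), 1 - sens)
  expect_equal(unname(pan["fpr"]), 1 - spec)

  perfect <- compute_binary_class_metrics(y, y, "1")
  expect_equal(unname(perfect["fpr"]), 0)
  expect_equal(unname(perfect["fnr"]), 0)

  never <- compute_binary_class_metrics(y, rep("2", 20), "1")
  expect_equal(unname(never["fnr"]), 1)
  expect_equal(unname(never["fpr"]), 0)
})

test_that("weighted metrics match independent brute-force computations", {
  set.seed(11)
  for (rep_i in 1:3) {
    y <- sample(core_classes(), 200, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
    pred <- ifelse(runif(200) < 0.6, y, sample(core_classes(), 200, TRUE))
    mr <- compute_multiclass_metrics(y, pred)
    # brute-force weighted F1 and macro recall
    f1s <- recs <- ws <- numeric()
    for (cl in core_classes()) {
      tp <- sum(y == cl & pred == cl)
      fp <- sum(y != cl & pred == cl)
      fn <- sum(y == cl & pred != cl)
      prec <- if (tp + fp) tp / (tp + fp) else 0
      rec <- tp / (tp + fn)
      f1s <- c(f1s, if (prec + rec) 2 * prec * rec / (prec + rec) else 0)
      recs <- c(recs, rec)
      ws <- c(ws, sum(y == cl))
    }
    expect_equal(mr$f1, sum(f1s * ws) / sum(ws), tolerance = 1e-12)
    expect_equal(mr$balanced_accuracy, mean(recs), tolerance = 1e-12)
    # brute-force kappa from the confusion matrix
    cm <- table(y, pred)
    po <- sum(diag(cm)) / 200
    pe <- sum(rowSums(cm) * colSums(cm)) / 200^2
    expect_equal(mr$kappa, (po - pe) / (1 - pe), tolerance = 1e-12)
  }
})

test_that("kappa is invariant under simultaneous class relabeling", {
  set.seed(12)
  y <- sample(core_classes(), 100, replace = TRUE)
  pred <- sample(core_classes(), 100, replace = TRUE)
  relab <- c("1" = "4", "2" = "3", "3" = "1", "4" = "2")
  expect_equal(cohens_kappa(y, pred),
               cohens_kappa(relab[y], relab[pred]))
})

test_that("one-vs-rest AUROC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  y <- sample(core_classes(), 120, replace = TRUE)
  probs <- matrix(runif(480), 120, 4, dimnames = list(NULL, core_classes()))
  probs <- probs / rowSums(probs)
  mr <- compute_multiclass_metrics(y, probs)
  ref <- sapply(core_classes(), function(cl)
    as.numeric(pROC::auc(pROC::roc(y == cl, probs[, cl], quiet = TRUE,
                                   direction = "<"))))
  w <- sapply(core_classes(), function(cl) sum(y == cl))
  expect_equal(mr$auroc, sum(ref * w) / sum(w), tolerance = 1e-10)
})

test_that("degenerate label vectors are rejected", {
  expect_error(compute_multiclass_metrics(rep("1", 10), rep("1", 10)),
               "single class")
})
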