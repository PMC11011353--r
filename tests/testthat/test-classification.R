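test_that("Cohen's kappa matches hand computations and degenerate rules", {
  expect_equal(cohen_kappa(diag(3) * 4), 1)
  expect_equal(cohen_kappa(matrix(2, 3, 3)), 0)
  # [[3,1],[2,4]]: p_o = 7/10, p_e = (4*5 + 6*5)/100 = 0.5 -> kappa = 0.4
  expect_equal(cohen_kappa(matrix(c(3, 2, 1, 4), 2, 2)), 0.4)
  # degenerate single-cell mass
  expect_equal(cohen_kappa(matrix(c(5, 0, 0, 0), 2, 2)), 1)
  expect_equal(cohen_kappa(matrix(c(0, 5, 0, 0), 2, 2)), 0)
  expect_error(cohen_kappa(matrix(1, 2, 3)), "square")
})

test_that("the study's worked confusion matrix yields accuracy 10/11 and kappa 86/97", {
  # 11 test samples (Control 2, PFIC 3, BiliaryAtresia 2, ALGS 2, AATD 2),
  # one PFIC case predicted as biliary atresia, all others correct
  lv <- c("Control", "PFIC", "BiliaryAtresia", "ALGS", "AATD")
  conf <- matrix(0L, 5, 5, dimnames = list(truth = lv, predicted = lv))
  diag(conf) <- c(2L, 2L, 2L, 2L, 2L)
  conf["PFIC", "BiliaryAtresia"] <- 1L
  expect_equal(sum(conf), 11)
  acc <- sum(diag(conf)) / sum(conf)
  expect_equal(acc, 10 / 11)
  # closed form: p_o = 10/11, p_e = (2*2 + 3*2 + 2*3 + 2*2 + 2*2)/121 = 24/121
  expect_equal(cohen_kappa(conf), 86 / 97, tolerance = 1e-12)
  expect_equal(round(cohen_kappa(conf), 4), 0.8866)
})

test_that("one-vs-rest AUC follows the rank statistic with ties at 1/2", {
  # scores (0.9, 0.8, 0.4, 0.3), labels (+,-,+,-): 3 of 4 pairs concordant
  pm <- cbind(pos = c(0.9, 0.8, 0.4, 0.3))
  pm <- cbind(pm, neg = 1 - pm[, 1])
  y <- factor(c("pos", "neg", "pos", "neg"), levels = c("pos", "neg"))
  auc <- multiclass_auc(pm, y)
  expect_equal(unname(auc$per_class["pos"]), 0.75)
  # perfect one-hot probabilities -> AUC 1 everywhere
  y3 <- factor(rep(c("A", "B", "C"), each = 2))
  onehot <- t(vapply(as.integer(y3), function(i) replace(numeric(3), i, 1),
                     numeric(3)))
  colnames(onehot) <- levels(y3)
  expect_true(all(multiclass_auc(onehot, y3)$per_class == 1))
  # label-independent constant probabilities -> all ties -> AUC 1/2
  flat <- matrix(1 / 3, 6, 3, dimnames = list(NULL, levels(y3)))
  expect_true(all(multiclass_auc(flat, y3)$per_class == 0.5))
  # a class absent from y_true is NA and excluded from the macro with warning
  y_miss <- factor(rep(c("A", "B"), 3), levels = c("A", "B", "C"))
  expect_warning(res <- multiclass_auc(flat, y_miss), "undefined")
  expect_true(is.na(res$per_class["C"]))
  expect_equal(res$macro, 0.5)
  expect_error(multiclass_auc(matrix(2, 2, 2,
    dimnames = list(NULL, c("A", "B"))), factor(c("A", "B"))), "sum to 1")
})

test_that("rank-statistic AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  for (i in 1:5) {
    score <- round(runif(30), 2) # rounding induces ties
    y <- factor(sample(c("pos", "neg"), 30, replace = TRUE),
                levels = c("pos", "neg"))
    pm <- cbind(pos = score, neg = 1 - score)
    mine <- multiclass_auc(pm, y)$per_class["pos"]
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = y == "pos", predictor = score,
      quiet = TRUE, direction = "<"
    )))
    expect_equal(unname(mine), ref, tolerance = 1e-12)
  }
})

test_that("all seven classifiers separate wide-margin blobs perfectly", {
  blobs <- split_blobs(make_blobs(n_per_class = 11, sep = 8, sd = 0.4))
  models <- train_classifiers(blobs$X_train, blobs$y_train, seed = 5)
  expect_length(models, 7)
  expect_setequal(names(models), pf_algorithms())
  loocv <- tidy(models)
  expect_true(all(loocv$loocv_accuracy == 1))
  report <- evaluate_classifiers(models, blobs$X_test, blobs$y_test)
  expect_equal(nrow(report$metrics), 7)
  expect_true(all(report$metrics$accuracy == 1))
  expect_true(all(report$metrics$kappa == 1))
  expect_true(all(report$metrics$macro_auc == 1))
  # confusion row sums = test class sizes; accuracy = trace/total
  for (conf in report$confusion) {
    expect_equal(unname(rowSums(conf)), rep(3, 3))
  }
})

test_that("evaluation metrics stay internally consistent on noisy data", {
  set.seed(9)
  n <- 24
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("F", 1:4)))
  y <- factor(rep(c("A", "B", "C"), each = 8))
  X[, 1] <- as.integer(y) + rnorm(n, 0, 0.6)
  models <- train_classifiers(X, y, algorithms = c("random_forest", "naive_bayes"),
                              seed = 3)
  Xt <- matrix(rnorm(12 * 4), 12, 4, dimnames = list(NULL, paste0("F", 1:4)))
  yt <- factor(rep(c("A", "B", "C"), each = 4))
  Xt[, 1] <- as.integer(yt) + rnorm(12, 0, 0.6)
  report <- evaluate_classifiers(models, Xt, yt)
  for (alg in names(report$confusion)) {
    conf <- report$confusion[[alg]]
    met <- report$metrics[report$metrics$algorithm == alg, ]
    expect_equal(met$accuracy, sum(diag(conf)) / sum(conf))
    expect_equal(unname(rowSums(conf)), as.vector(table(yt)))
    expect_equal(met$kappa, cohen_kappa(conf))
  }
  expect_error(evaluate_classifiers(models, Xt[0, , drop = FALSE], yt[0]),
               "empty test")
})

test_that("final-model importance localizes a class-specific marker", {
  set.seed(30)
  cs <- c(Control = 7, PFIC = 12, BiliaryAtresia = 7, ALGS = 7, AATD = 7)
  y <- factor(rep(names(cs), cs))
  n <- length(y)
  X <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, c("SERPINA1_like", paste0("F", 1:5))))
  # elevated only in AATD, echoing alpha-1-antitrypsin accumulation
  X[y == "AATD", 1] <- X[y == "AATD", 1] + 4
  # give remaining features some class signal so the forest has structure
  X[y == "PFIC", 2] <- X[y == "PFIC", 2] + 3
  X[y == "Control", 3] <- X[y == "Control", 3] + 3
  fm <- final_model_importance(X, y, seed = 11)
  imp <- tidy(fm)
  expect_equal(nrow(imp), 6)
  row1 <- imp[imp$protein_id == "SERPINA1_like", ]
  per_class <- vapply(paste0("importance_", levels(y)),
                      function(cl) row1[[cl]], numeric(1))
  expect_equal(names(which.max(per_class)), "importance_AATD")
  # a pure-noise feature is near zero overall
  expect_lt(imp$overall_importance[imp$protein_id == "F5"],
            row1$overall_importance)
})

test_that("classical MDS reproduces intrinsically low-dimensional distances", {
  # unit-edge tetrahedron in 3D
  tet <- rbind(
    c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
    c(0.5, sqrt(3) / 6, sqrt(6) / 3)
  )
  rownames(tet) <- paste0("s", 1:4)
  emb <- mds_embedding(tet, n_dims = 3)
  d_emb <- dist(as.matrix(emb[, c("MDS1", "MDS2", "MDS3")]))
  expect_equal(as.vector(d_emb), rep(1, 6), tolerance = 1e-6)
  expect_equal(unname(colMeans(as.matrix(emb[, 2:4]))), rep(0, 3),
               tolerance = 1e-9)
  expect_error(mds_embedding(tet[1:3, ], n_dims = 3), "at least 4")
})
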