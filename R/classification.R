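#' The seven benchmark classifier families
#'
#' @return Character vector of the supported algorithm names.
#' @export
pf_algorithms <- function() {
  c("random_forest", "extreme_gradient_boosting", "naive_bayes",
    "k_nearest_neighbors", "support_vector_machine",
    "logistic_regression", "linear_discriminant_analysis")
}

# ---- per-algorithm fit/predict backends -----------------------------------
# Each backend returns list(fit, predict_proba(newdata) -> samples x levels
# probability matrix with columns ordered as levels(y)).

fit_one <- function(algorithm, X, y, params, seed) {
  lv <- levels(y)
  align <- function(pm) {
    out <- matrix(0, nrow(pm), length(lv), dimnames = list(NULL, lv))
    out[, colnames(pm)] <- pm
    out
  }
  switch(
    algorithm,
    random_forest = {
      fit <- ranger::ranger(x = X, y = y, num.trees = 500,
                            mtry = min(params$mtry, ncol(X)),
                            probability = TRUE, seed = seed, num.threads = 1)
      list(fit = fit, predict_proba = function(newX) {
        align(predict(fit, data = newX, num.threads = 1)$predictions)
      })
    },
    extreme_gradient_boosting = {
      dtr <- xgboost::xgb.DMatrix(as.matrix(X), label = as.integer(y) - 1L)
      fit <- xgboost::xgb.train(
        params = list(objective = "multi:softprob", num_class = length(lv),
                      max_depth = params$max_depth, eta = 0.3,
                      nthread = 1, verbosity = 0),
        data = dtr, nrounds = 50
      )
      list(fit = fit, predict_proba = function(newX) {
        pm <- predict(fit, xgboost::xgb.DMatrix(as.matrix(newX)))
        if (!is.matrix(pm)) pm <- matrix(pm, ncol = length(lv), byrow = TRUE)
        colnames(pm) <- lv
        pm
      })
    },
    naive_bayes = {
      fit <- e1071::naiveBayes(x = as.data.frame(X), y = y,
                               laplace = params$laplace)
      list(fit = fit, predict_proba = function(newX) {
        align(predict(fit, as.data.frame(newX), type = "raw"))
      })
    },
    k_nearest_neighbors = {
      fit <- caret::knn3(x = as.matrix(X), y = y,
                         k = min(params$k, nrow(X)))
      list(fit = fit, predict_proba = function(newX) {
        align(predict(fit, as.matrix(newX), type = "prob"))
      })
    },
    support_vector_machine = {
      fit <- with_seed(seed, e1071::svm(
        x = as.matrix(X), y = y, kernel = "radial",
        cost = params$cost, gamma = params$gamma,
        probability = TRUE
      ))
      list(fit = fit, predict_proba = function(newX) {
        pr <- predict(fit, as.matrix(newX), probability = TRUE)
        align(attr(pr, "probabilities"))
      })
    },
    logistic_regression = {
      # ridge-penalized multinomial; glmnet warns on tiny per-class counts
      # during LOOCV folds, which is expected at these sample sizes
      fit <- suppressWarnings(
        glmnet::glmnet(as.matrix(X), y, family = "multinomial",
                       alpha = 0, lambda = params$lambda)
      )
      list(fit = fit, predict_proba = function(newX) {
        pm <- predict(fit, as.matrix(newX), type = "response")[, , 1]
        if (is.null(dim(pm))) pm <- matrix(pm, nrow = 1, dimnames = list(NULL, names(pm)))
        align(pm)
      })
    },
    linear_discriminant_analysis = {
      fit <- MASS::lda(x = as.data.frame(X), grouping = y)
      list(fit = fit, predict_proba = function(newX) {
        align(predict(fit, as.data.frame(newX))$posterior)
      })
    },
    stop_pf(paste0("unknown algorithm: ", algorithm))
  )
}

default_grid <- function(algorithm, X) {
  p <- ncol(X)
  switch(
    algorithm,
    random_forest = lapply(unique(c(max(1L, floor(sqrt(p))),
                                    max(1L, floor(p / 3)))),
                           function(m) list(mtry = m)),
    extreme_gradient_boosting = lapply(c(2, 4, 6),
                                       function(d) list(max_depth = d)),
    naive_bayes = list(list(laplace = 0)),
    k_nearest_neighbors = lapply(c(3, 5, 7), function(k) list(k = k)),
    support_vector_machine = {
      # kernel widths: median-pairwise-distance heuristic and the 1/p default
      dmed <- median(dist(as.matrix(X)))
      g_med <- if (is.finite(dmed) && dmed > 0) 1 / (2 * dmed^2) else 1 / max(1, p)
      gammas <- unique(c(1 / max(1, p), g_med))
      unlist(lapply(c(1, 10, 100), function(cst) {
        lapply(gammas, function(g) list(cost = cst, gamma = g))
      }), recursive = FALSE)
    },
    logistic_regression = lapply(c(0.01, 0.1, 1),
                                 function(l) list(lambda = l)),
    linear_discriminant_analysis = list(list())
  )
}

loocv_accuracy <- function(algorithm, X, y, params, seed) {
  n <- nrow(X)
  correct <- logical(n)
  for (i in seq_len(n)) {
    yi <- droplevels(y[-i])
    if (nlevels(yi) < 2) return(NA_real_)
    mdl <- tryCatch(
      fit_one(algorithm, X[-i, , drop = FALSE], yi, params,
              seed = substream_seed(seed, i)),
      error = function(e) NULL
    )
    if (is.null(mdl)) return(NA_real_)
    pm <- mdl$predict_proba(X[i, , drop = FALSE])
    correct[i] <- colnames(pm)[which.max(pm[1, ])] == as.character(y[i])
  }
  mean(correct)
}

#' Train the seven-classifier benchmark with LOOCV tuning
#'
#' Each algorithm is tuned over a small fixed hyperparameter grid by
#' leave-one-out cross-validated accuracy on the training samples (n
#' held-out fits per grid point), then refit on all training samples.
#' Every fitted model exposes class-probability predictions.
#'
#' @param data Samples-by-features data frame or matrix (panel features).
#' @param y Factor of class labels (every class present).
#' @param algorithms Subset of [pf_algorithms()].
#' @param seed Integer seed.
#' @return An object of class `classifier_set`: named list of fitted
#'   models, each with elements `algorithm`, `fit`, `params`,
#'   `loocv_accuracy`, `predict_proba`.
#' @export
train_classifiers <- function(data, y, algorithms = pf_algorithms(), seed = 1) {
  X <- as.matrix(data)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop_pf("need at least two classes in training data")
  if (anyNA(X)) stop_pf("training data must not contain missing values")
  bad <- setdiff(algorithms, pf_algorithms())
  if (length(bad)) stop_pf(paste0("unknown algorithm(s): ", paste(bad, collapse = ", ")))

  models <- lapply(seq_along(algorithms), function(a) {
    alg <- algorithms[a]
    grid <- default_grid(alg, X)
    accs <- vapply(seq_along(grid), function(g) {
      loocv_accuracy(alg, X, y, grid[[g]],
                     seed = substream_seed(seed, a, g))
    }, numeric(1))
    best <- if (all(is.na(accs))) 1L else which.max(accs)
    mdl <- fit_one(alg, X, y, grid[[best]], seed = substream_seed(seed, a, 0L))
    list(algorithm = alg, fit = mdl$fit, params = grid[[best]],
         loocv_accuracy = accs[best], predict_proba = mdl$predict_proba)
  })
  names(models) <- algorithms
  structure(models, levels = levels(y), class = "classifier_set")
}

#' Evaluate trained classifiers on held-out test samples
#'
#' For each algorithm: predicted labels (probability argmax) give the
#' confusion matrix (rows = truth, columns = prediction), accuracy
#' (trace over total) and Cohen's kappa; the class-probability matrix
#' gives one-vs-rest AUC per class and their unweighted macro average.
#'
#' @param models A `classifier_set` from [train_classifiers()].
#' @param data Test samples-by-features table (disjoint from training).
#' @param y Factor of true test labels.
#' @return An object of class `classifier_report`: list with `metrics`
#'   (tibble: algorithm, accuracy, kappa, macro_auc, auc_<class>...),
#'   `confusion` (named list of confusion matrices) and `probabilities`
#'   (named list of probability matrices).
#' @export
evaluate_classifiers <- function(models, data, y) {
  stopifnot(inherits(models, "classifier_set"))
  X <- as.matrix(data)
  if (nrow(X) == 0) stop_pf("empty test set")
  lv <- attr(models, "levels")
  y <- factor(as.character(y), levels = lv)
  if (anyNA(y)) stop_pf("test labels outside the training classes")

  rows <- list(); confs <- list(); probs <- list()
  for (alg in names(models)) {
    pm <- models[[alg]]$predict_proba(X)
    pred <- factor(colnames(pm)[max.col(pm, ties.method = "first")], levels = lv)
    conf <- table(truth = y, predicted = pred)
    auc <- multiclass_auc(pm, y)
    rows[[alg]] <- tibble::tibble(
      algorithm = alg,
      accuracy = sum(diag(conf)) / sum(conf),
      kappa = cohen_kappa(conf),
      macro_auc = auc$macro,
      !!!setNames(as.list(auc$per_class), paste0("auc_", names(auc$per_class)))
    )
    confs[[alg]] <- unclass(conf)
    probs[[alg]] <- pm
  }
  structure(
    list(metrics = dplyr::bind_rows(rows), confusion = confs,
         probabilities = probs, levels = lv),
    class = "classifier_report"
  )
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement: `(p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o` = trace/total and chance agreement `p_e` from the
#' products of row and column marginals. In the degenerate case `p_e = 1`
#' (all mass in a single row/column product), kappa is defined as 1 when
#' agreement is also perfect and 0 otherwise.
#'
#' @param confusion Square non-negative matrix, rows = truth, columns =
#'   prediction.
#' @return Kappa in [-1, 1].
#' @export
cohen_kappa <- function(confusion) {
  m <- as.matrix(confusion)
  if (nrow(m) != ncol(m)) stop_pf("confusion matrix must be square")
  total <- sum(m)
  if (total <= 0) stop_pf("confusion matrix must have positive total")
  p_o <- sum(diag(m)) / total
  p_e <- sum(rowSums(m) * colSums(m)) / total^2
  if (isTRUE(all.equal(p_e, 1))) return(if (isTRUE(all.equal(p_o, 1))) 1 else 0)
  (p_o - p_e) / (1 - p_e)
}

#' One-vs-rest multiclass AUC from class probabilities
#'
#' Per class, the binary one-vs-rest AUC computed with the Wilcoxon rank
#' statistic (tied scores count 1/2); the macro AUC is the unweighted
#' mean over classes that have both positives and negatives in `y_true`.
#' Classes missing one side are `NA`, excluded from the macro average
#' with a warning.
#'
#' @param probabilities Samples-by-classes matrix of class probabilities
#'   (rows sum to ~1), columns named by class.
#' @param y_true Factor of true labels.
#' @return List with `per_class` (named numeric) and `macro` (scalar).
#' @export
multiclass_auc <- function(probabilities, y_true) {
  pm <- as.matrix(probabilities)
  if (is.null(colnames(pm))) stop_pf("probability columns must be named by class")
  rs <- rowSums(pm)
  if (any(abs(rs - 1) > 1e-4)) {
    stop_pf("probability rows must sum to 1")
  }
  y_true <- as.factor(y_true)
  per_class <- vapply(colnames(pm), function(cl) {
    pos <- y_true == cl
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) return(NA_real_)
    r <- rank(pm[, cl])
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
  if (anyNA(per_class)) {
    warn(paste0("AUC undefined (no positives or no negatives) for: ",
                paste(names(per_class)[is.na(per_class)], collapse = ", ")))
  }
  list(per_class = per_class, macro = mean(per_class, na.rm = TRUE))
}

#' Final random-forest model with overall and per-class importance
#'
#' Fits a single random forest on all samples restricted to the panel
#' features and reports permutation importance (mean decrease in
#' accuracy, unscaled): overall and computed on each class's samples
#' separately.
#'
#' @param data All samples-by-panel-features table.
#' @param y Factor of class labels.
#' @param seed Integer seed.
#' @param n_trees Trees in the forest.
#' @return An object of class `final_model`: list with `importance`
#'   (tibble: protein_id, overall_importance, importance_<class>...) and
#'   `fit` (the randomForest object).
#' @export
final_model_importance <- function(data, y, seed = 1, n_trees = 500) {
  X <- as.data.frame(data)
  y <- droplevels(as.factor(y))
  fit <- with_seed(seed, randomForest::randomForest(
    x = X, y = y, ntree = n_trees, importance = TRUE
  ))
  imp <- randomForest::importance(fit, scale = FALSE)
  lv <- levels(y)
  tab <- tibble::tibble(
    protein_id = rownames(imp),
    overall_importance = pmax(imp[, "MeanDecreaseAccuracy"], 0)
  )
  for (cl in lv) tab[[paste0("importance_", cl)]] <- imp[, cl]
  structure(list(importance = tab, fit = fit), class = "final_model")
}

#' Classical multidimensional scaling of panel-feature profiles
#'
#' Torgerson MDS on the Euclidean distances between sample profiles;
#' coordinates are centered at the origin.
#'
#' @param data Samples-by-features table (rownames = sample ids).
#' @param n_dims Embedding dimension (default 3).
#' @param y Optional class labels attached as a column.
#' @return A tibble: sample_id, MDS1..MDS`n_dims` (and `class_label` if
#'   `y` given).
#' @export
mds_embedding <- function(data, n_dims = 3, y = NULL) {
  X <- as.matrix(data)
  if (nrow(X) < n_dims + 1) {
    stop_pf(sprintf("need at least %d samples for a %d-dimensional embedding",
                    n_dims + 1, n_dims))
  }
  coords <- cmdscale(dist(X), k = n_dims)
  colnames(coords) <- paste0("MDS", seq_len(n_dims))
  out <- tibble::as_tibble(coords)
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(X) %||% as.character(seq_len(nrow(X)))),
    out
  )
  if (!is.null(y)) out$class_label <- as.character(y)
  out
}

#' @export
tidy.classifier_report <- function(x, ...) x$metrics

#' @export
glance.classifier_report <- function(x, ...) {
  best <- x$metrics[which.max(x$metrics$kappa), ]
  tibble::tibble(
    n_algorithms = nrow(x$metrics),
    best_algorithm = best$algorithm,
    best_accuracy = best$accuracy,
    best_kappa = best$kappa,
    min_accuracy = min(x$metrics$accuracy),
    min_macro_auc = min(x$metrics$macro_auc)
  )
}

#' @export
tidy.classifier_set <- function(x, ...) {
  tibble::tibble(
    algorithm = names(x),
    loocv_accuracy = vapply(x, function(m) m$loocv_accuracy, numeric(1))
  )
}

#' @export
tidy.final_model <- function(x, ...) x$importance

#' @export
print.classifier_report <- function(x, ...) {
  cat("# Classifier benchmark on the held-out test set\n")
  print(x$metrics, ...)
  invisible(x)
}

#' Plot per-algorithm test metrics
#'
#' @param object A `classifier_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.classifier_report <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object$metrics[, c("algorithm", "accuracy", "kappa", "macro_auc")],
    -"algorithm", names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$algorithm, y = .data$value,
                                  fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Plot an MDS embedding colored by class
#'
#' @param embedding Tibble from [mds_embedding()] with a `class_label`
#'   column.
#' @param dims Which two dimensions to draw.
#' @return A ggplot object.
#' @export
plot_mds <- function(embedding, dims = c("MDS1", "MDS2")) {
  ggplot2::ggplot(embedding,
                  ggplot2::aes(x = .data[[dims[1]]], y = .data[[dims[2]]],
                               colour = .data$class_label)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(colour = "Class")
}
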