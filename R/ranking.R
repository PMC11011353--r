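#' Configuration for the iterative random-forest ranking algorithm
#'
#' @param n_outer_rounds Outer rounds: the full feature set is restored
#'   this many times (30 restores the feature set 29 times after the
#'   first pass).
#' @param drop_fraction Fraction of the least-important surviving features
#'   eliminated at each inner step (at least one is always removed).
#' @param n_trees Trees per forest fit.
#' @param importance_kind `"impurity"` (mean decrease in node impurity,
#'   the randomForest-lineage default) or `"permutation"`.
#' @param seed Master seed; substreams per (round, step, fit) make the
#'   run reproducible and order-stable.
#' @return A list of class `ranking_config`.
#' @export
ranking_config <- function(n_outer_rounds = 30, drop_fraction = 0.2,
                           n_trees = 500,
                           importance_kind = c("impurity", "permutation"),
                           seed = 1) {
  importance_kind <- match.arg(importance_kind)
  stopifnot(n_outer_rounds >= 1, n_trees >= 1)
  if (drop_fraction <= 0 || drop_fraction >= 1) {
    stop_pf("drop_fraction must lie in (0, 1)")
  }
  structure(
    list(n_outer_rounds = as.integer(n_outer_rounds),
         drop_fraction = drop_fraction,
         n_trees = as.integer(n_trees),
         importance_kind = importance_kind,
         seed = as.integer(seed)),
    class = "ranking_config"
  )
}

#' Random-forest variable importance from one ensemble fit
#'
#' One forest (bootstrap per tree, ~sqrt(p) candidate features per split)
#' fitted with \pkg{ranger}; returns one non-negative importance per
#' feature. Deterministic given the seed (single-threaded fit).
#'
#' @param X Numeric samples-by-features matrix (no missing values).
#' @param y Factor of class labels (>= 2 classes).
#' @param n_trees Number of trees.
#' @param importance_kind `"impurity"` or `"permutation"`.
#' @param seed Integer seed for the fit.
#' @return Named numeric vector of importances (negative permutation
#'   importances are floored at zero).
#' @export
importance_once <- function(X, y, n_trees = 500,
                            importance_kind = "impurity", seed = 1) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop_pf("y must contain at least two classes")
  X <- as.matrix(X)
  if (anyNA(X)) stop_pf("X must not contain missing values")
  constant <- apply(X, 2, function(v) all(v == v[1]))
  if (all(constant)) {
    return(setNames(rep(0, ncol(X)), colnames(X)))
  }
  fit <- ranger::ranger(
    x = X, y = y,
    num.trees = n_trees,
    importance = importance_kind,
    seed = seed,
    num.threads = 1,
    respect.unordered.factors = "ignore"
  )
  imp <- fit$variable.importance[colnames(X)]
  pmax(imp, 0)
}

#' Augment a feature matrix with shadow variables
#'
#' Doubles the feature space: for each original feature a shadow copy is
#' added whose values are independently permuted across samples,
#' destroying any association with the labels while preserving the
#' marginal distribution.
#'
#' @param X Numeric samples-by-features matrix.
#' @param seed Seed for the permutations.
#' @return A list: `X_aug` (samples x 2p matrix) and `pairing` (named
#'   character vector mapping each original feature to its shadow column).
#' @export
augment_with_shadows <- function(X, seed = 1) {
  X <- as.matrix(X)
  if (ncol(X) < 1) stop_pf("need at least one feature")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  shadows <- with_seed(seed, {
    apply(X, 2, function(v) v[sample.int(length(v))])
  })
  shadows <- matrix(shadows, nrow = nrow(X))
  colnames(shadows) <- paste0(".shadow.", colnames(X))
  pairing <- setNames(colnames(shadows), colnames(X))
  list(X_aug = cbind(X, shadows), pairing = pairing)
}

#' Original-versus-shadow importance hits
#'
#' For each original feature, 1 if its importance strictly exceeds its own
#' shadow's importance, else 0 (ties count as misses).
#'
#' @param importances Named importance vector over the augmented (2p)
#'   feature set.
#' @param pairing Named map original -> shadow column, as returned by
#'   [augment_with_shadows()].
#' @return Named integer 0/1 vector over the original features.
#' @export
shadow_hit_vector <- function(importances, pairing) {
  orig <- names(pairing)
  if (!all(orig %in% names(importances)) ||
      !all(pairing %in% names(importances))) {
    stop_pf("pairing refers to features absent from the importance vector")
  }
  hits <- as.integer(importances[orig] > importances[pairing])
  setNames(hits, orig)
}

#' Drop the least important fraction of features
#'
#' Removes `max(1, floor(drop_fraction * p))` features with the smallest
#' importance. Ties are broken by protein id: among equally unimportant
#' features the later id (descending order) is dropped first, giving a
#' total deterministic order.
#'
#' @param feature_set Character vector of surviving feature ids.
#' @param importances Named importance vector covering `feature_set`.
#' @param drop_fraction Fraction to drop per step.
#' @return The retained feature ids (original order preserved).
#' @export
eliminate_least_important <- function(feature_set, importances, drop_fraction) {
  p <- length(feature_set)
  if (p < 2) stop_pf("cannot eliminate from fewer than two features")
  n_drop <- max(1L, as.integer(floor(drop_fraction * p)))
  imp <- importances[feature_set]
  ord <- order(imp, -rank(feature_set, ties.method = "first"))
  drop <- feature_set[ord[seq_len(n_drop)]]
  feature_set[!feature_set %in% drop]
}

#' Exact binomial upper-tail probability
#'
#' P(X >= hits) for X ~ Binomial(trials, prob); returns exactly 1 when
#' hits = 0. Vectorized over `hits`/`trials`.
#'
#' @param hits Number of successes observed (0 <= hits <= trials).
#' @param trials Number of trials.
#' @param prob Success probability under the null, in (0, 1).
#' @return Upper-tail probabilities in (0, 1].
#' @export
binomial_upper_tail <- function(hits, trials, prob) {
  if (any(prob <= 0 | prob >= 1)) stop_pf("prob must lie in (0, 1)")
  if (any(hits < 0) || any(trials < 0) || any(hits > trials)) {
    stop_pf("need 0 <= hits <= trials")
  }
  pbinom(hits - 1, trials, prob, lower.tail = FALSE)
}

#' Iterative random-forest feature ranking with shadow variables
#'
#' The core ranking algorithm. Each of `n_outer_rounds` rounds starts from
#' the full feature set and repeats, until a single feature remains:
#' (1) fit a forest on the surviving features and accumulate each
#' survivor's importance; (2) fit a second forest on the survivors plus
#' one permuted shadow copy per survivor, and record a shadow hit (1/0)
#' for each survivor whose importance strictly beats its own shadow's;
#' (3) eliminate the least important `drop_fraction` of survivors (at
#' least one), recording retention 1/0 for every feature — eliminated
#' features keep collecting retention zeros for the rest of the round.
#' Features accumulate importance and shadow hits only while retained.
#' Finally each feature gets an exact binomial upper-tail p-value on its
#' accumulated shadow hits with null success probability 1/2 (original
#' versus its own shadow is symmetric under exchangeability).
#'
#' @param x Normalized [abundance_tbl()] (typically restricted to the
#'   training samples), or a samples-by-features numeric matrix.
#' @param meta Sample metadata covering the samples of `x` (ignored when
#'   `x` is a matrix and `y` is given).
#' @param config A [ranking_config()].
#' @param y Optional factor of labels, required when `x` is a matrix.
#' @return A tibble of class `ranking_tbl`, one row per feature, sorted by
#'   `cumulative_importance` descending (ties: `shadow_hits` descending,
#'   then protein id ascending): columns `rank`, `protein_id`,
#'   `cumulative_importance`, `shadow_hits`, `shadow_trials`,
#'   `retention_hits`, `retention_trials`, `p_value`.
#' @export
rank_features <- function(x, meta = NULL, config = ranking_config(), y = NULL) {
  if (inherits(x, "abundance_tbl")) {
    assert_scale(x, "normalized", "rank_features")
    y <- group_labels_for(x, meta)
    X <- t(abundance_matrix(x))
  } else {
    X <- as.matrix(x)
    if (is.null(y)) stop_pf("y is required when x is a matrix")
    y <- droplevels(as.factor(y))
  }
  if (nlevels(droplevels(as.factor(y))) < 2) stop_pf("need >= 2 classes")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  features <- colnames(X)
  p <- length(features)

  cum_imp <- setNames(numeric(p), features)
  sh_hits <- setNames(integer(p), features)
  sh_trials <- setNames(integer(p), features)
  ret_hits <- setNames(integer(p), features)
  ret_trials <- setNames(integer(p), features)

  for (round in seq_len(config$n_outer_rounds)) {
    current <- features
    step <- 0L
    while (length(current) > 1L) {
      step <- step + 1L
      Xc <- X[, current, drop = FALSE]

      imp1 <- importance_once(
        Xc, y, n_trees = config$n_trees,
        importance_kind = config$importance_kind,
        seed = substream_seed(config$seed, round, step, 1L)
      )
      cum_imp[current] <- cum_imp[current] + imp1[current]

      aug <- augment_with_shadows(Xc, seed = substream_seed(config$seed, round, step, 3L))
      imp2 <- importance_once(
        aug$X_aug, y, n_trees = config$n_trees,
        importance_kind = config$importance_kind,
        seed = substream_seed(config$seed, round, step, 2L)
      )
      hits <- shadow_hit_vector(imp2, aug$pairing)
      sh_hits[current] <- sh_hits[current] + hits[current]
      sh_trials[current] <- sh_trials[current] + 1L

      current <- eliminate_least_important(current, imp1, config$drop_fraction)

      ret_trials <- ret_trials + 1L
      ret_hits[current] <- ret_hits[current] + 1L
    }
  }

  out <- tibble::tibble(
    protein_id = features,
    cumulative_importance = unname(cum_imp),
    shadow_hits = unname(sh_hits),
    shadow_trials = unname(sh_trials),
    retention_hits = unname(ret_hits),
    retention_trials = unname(ret_trials),
    p_value = binomial_upper_tail(unname(sh_hits), unname(sh_trials), 0.5)
  )
  out <- out[order(-out$cumulative_importance, -out$shadow_hits, out$protein_id), ]
  out$rank <- seq_len(nrow(out))
  out <- out[, c("rank", setdiff(names(out), "rank"))]
  structure(out,
            config = config,
            class = c("ranking_tbl", class(tibble::tibble())))
}

#' @export
glance.ranking_tbl <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(
    n_features = nrow(x),
    n_outer_rounds = cfg$n_outer_rounds,
    drop_fraction = cfg$drop_fraction,
    n_trees = cfg$n_trees,
    importance_kind = cfg$importance_kind,
    min_p_value = min(x$p_value)
  )
}

#' Plot cumulative importances from a ranking table
#'
#' @param object A `ranking_tbl` from [rank_features()].
#' @param top_n Number of top-ranked features to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ranking_tbl <- function(object, top_n = 20, ...) {
  d <- utils::head(tibble::as_tibble(object), top_n)
  d$protein_id <- factor(d$protein_id, levels = rev(d$protein_id))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cumulative_importance,
                                  y = .data$protein_id)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Cumulative importance", y = NULL,
                  title = sprintf("Top %d features by cumulative importance", nrow(d)))
}
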