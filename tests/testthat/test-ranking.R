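test_that("a perfect separator dominates single-fit importance", {
  set.seed(4)
  n <- 30; p <- 51
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- sprintf("F%02d", seq_len(p))
  y <- factor(rep(c("A", "B", "C"), each = 10))
  X[, 1] <- as.integer(y) # identical to the class label
  imp <- importance_once(X, y, n_trees = 200, seed = 7)
  expect_length(imp, p)
  expect_true(all(imp >= 0))
  expect_equal(names(which.max(imp)), "F01")
})

test_that("constant features get zero importance and single-class labels fail", {
  X <- matrix(1, 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- factor(rep(c("A", "B"), each = 5))
  expect_equal(unname(importance_once(X, y)), c(0, 0, 0))
  expect_error(importance_once(matrix(rnorm(10), 5, 2), factor(rep("A", 5))),
               "two classes")
})

test_that("feature importance is tied to names, not column positions", {
  set.seed(12)
  X <- matrix(rnorm(30 * 6), 30, 6, dimnames = list(NULL, paste0("F", 1:6)))
  y <- factor(rep(c("A", "B"), each = 15))
  X[, 4] <- as.integer(y) + rnorm(30, 0, 0.1) # dominant separator at position 4
  imp1 <- importance_once(X, y, n_trees = 300, seed = 5)
  perm <- c(4, 2, 6, 1, 3, 5)
  imp2 <- importance_once(X[, perm], y, n_trees = 300, seed = 5)
  expect_setequal(names(imp1), names(imp2))
  # the dominant feature dominates under any column order, and its
  # importance is stable across the reordered ensemble draw
  expect_equal(names(which.max(imp1)), "F4")
  expect_equal(names(which.max(imp2)), "F4")
  expect_equal(unname(imp1["F4"]), unname(imp2["F4"]), tolerance = 0.2)
})

test_that("shadow augmentation doubles the features and preserves marginals", {
  set.seed(3)
  X <- matrix(rnorm(12 * 5), 12, 5, dimnames = list(NULL, paste0("F", 1:5)))
  aug <- augment_with_shadows(X, seed = 9)
  expect_equal(ncol(aug$X_aug), 10)
  expect_length(aug$pairing, 5)
  for (f in colnames(X)) {
    expect_equal(sort(aug$X_aug[, aug$pairing[[f]]]), sort(X[, f]))
  }
})

test_that("shadow columns decorrelate from the labels", {
  set.seed(10)
  n <- 40
  y_ind <- rep(c(0, 1), each = n / 2)
  v <- y_ind + rnorm(n, 0, 0.2) # strongly label-associated feature
  X <- matrix(v, n, 1, dimnames = list(NULL, "F1"))
  cors <- vapply(1:100, function(s) {
    aug <- augment_with_shadows(X, seed = s)
    cor(aug$X_aug[, 2], y_ind)
  }, numeric(1))
  expect_gt(abs(cor(v, y_ind)), 0.9)
  expect_lt(abs(mean(cors)), 3 / sqrt(n))
})

test_that("shadow hits require strictly beating one's own shadow", {
  imp <- c(a = 3, b = 1, .shadow.a = 2, .shadow.b = 2)
  pairing <- c(a = ".shadow.a", b = ".shadow.b")
  expect_equal(shadow_hit_vector(imp, pairing), c(a = 1L, b = 0L))
  # exact tie -> 0
  imp2 <- c(a = 2, .shadow.a = 2)
  expect_equal(shadow_hit_vector(imp2, c(a = ".shadow.a")), c(a = 0L))
  expect_error(shadow_hit_vector(imp[1:2], pairing), "absent")
})

test_that("null shadow hits are symmetric: hit rate near 1/2", {
  set.seed(6)
  n <- 30; p <- 50
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("F%02d", 1:p)))
  y <- factor(rep(c("A", "B"), each = n / 2))
  hits <- matrix(0L, 30, p)
  for (trial in 1:30) {
    aug <- augment_with_shadows(X, seed = trial)
    imp <- importance_once(aug$X_aug, y, n_trees = 100, seed = 1000 + trial)
    hits[trial, ] <- shadow_hit_vector(imp, aug$pairing)
  }
  rate <- mean(hits)
  expect_gte(rate, 0.45)
  expect_lte(rate, 0.55)
})

test_that("elimination drops max(1, floor(fraction * p)) with the stated tie-break", {
  feats <- sprintf("P%02d", 1:10)
  imp <- setNames(10:1, feats)
  expect_length(eliminate_least_important(feats, imp, 0.2), 8)
  expect_length(eliminate_least_important(feats[1:2], imp[1:2], 0.2), 1)
  # 5484 features at fraction 0.2 -> 5484 - 1096 = 4388 retained
  big <- sprintf("P%05d", 1:5484)
  kept <- eliminate_least_important(big, setNames(runif(5484), big), 0.2)
  expect_length(kept, 4388)
  # all-tied importances: later ids are dropped first
  tied <- setNames(rep(1, 5), sprintf("P%d", 1:5))
  expect_equal(eliminate_least_important(names(tied), tied, 0.2),
               sprintf("P%d", 1:4))
  expect_error(eliminate_least_important("P1", c(P1 = 1), 0.2), "fewer than two")
})

test_that("binomial upper tail matches closed forms and the tail-sum oracle", {
  expect_equal(binomial_upper_tail(30, 30, 0.5), 0.5^30, tolerance = 1e-12)
  expect_equal(binomial_upper_tail(0, 30, 0.5), 1)
  expect_equal(binomial_upper_tail(15, 30, 0.5),
               binom_tail_oracle(15, 30, 0.5), tolerance = 1e-12)
  expect_equal(round(binomial_upper_tail(15, 30, 0.5), 4), 0.5722)
  expect_error(binomial_upper_tail(5, 3, 0.5), "hits")
  expect_error(binomial_upper_tail(1, 3, 0), "prob")
})

test_that("rank_features returns a complete, deterministic ranking table", {
  set.seed(14)
  X <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(NULL, c("Pa", "Pb", "Pc")))
  y <- factor(rep(c("A", "B"), each = 10))
  cfg <- ranking_config(n_outer_rounds = 2, n_trees = 50, seed = 3)
  rk <- rank_features(X, config = cfg, y = y)
  expect_s3_class(rk, "ranking_tbl")
  expect_equal(nrow(rk), 3)
  expect_setequal(rk$rank, 1:3)
  # every feature is shadow-tested at least once per outer round
  expect_true(all(rk$shadow_trials >= cfg$n_outer_rounds))
  expect_true(all(rk$shadow_hits <= rk$shadow_trials))
  expect_equal(rk$p_value,
               binomial_upper_tail(rk$shadow_hits, rk$shadow_trials, 0.5))
  # identical input and config -> identical table
  expect_identical(tibble::as_tibble(rank_features(X, config = cfg, y = y)),
                   tibble::as_tibble(rk))
  expect_equal(glance(rk)$n_features, 3)
})

test_that("retention bookkeeping spans every inner step of every round", {
  set.seed(15)
  p <- 10
  X <- matrix(rnorm(20 * p), 20, p, dimnames = list(NULL, sprintf("P%02d", 1:p)))
  y <- factor(rep(c("A", "B"), each = 10))
  rk <- rank_features(X, config = ranking_config(n_outer_rounds = 3,
                                                 n_trees = 50, seed = 2), y = y)
  # inner steps per round are identical for all features: p=10 shrinks
  # 10 -> 8 -> 7(6.4) ... deterministic count, same trials everywhere
  expect_equal(length(unique(rk$retention_trials)), 1)
  expect_true(all(rk$retention_hits <= rk$retention_trials))
  # eliminations happen: not every feature is retained at every step
  expect_true(any(rk$retention_hits < rk$retention_trials))
})

test_that("a planted perfect separator earns rank 1 and a tiny p-value", {
  set.seed(16)
  n <- 30; p <- 101
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("F%03d", 1:p)))
  y <- factor(rep(c("A", "B", "C"), each = 10))
  X[, 1] <- as.integer(y) + rnorm(n, 0, 0.05)
  rk <- rank_features(X, config = ranking_config(n_outer_rounds = 3,
                                                 n_trees = 100, seed = 4), y = y)
  expect_equal(rk$protein_id[rk$rank == 1], "F001")
  expect_lt(rk$p_value[rk$rank == 1], 0.001)
})
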