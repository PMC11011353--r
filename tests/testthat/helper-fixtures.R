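# Shared fixtures, built in code.

# Tiny two-batch study: 3 proteins, 2 samples + 1 internal standard per
# batch, log2 values chosen for hand-checkable IS differences.
toy_two_batch <- function() {
  log2m <- matrix(
    c(  # s1   s2   IS1   s3   s4   IS2
      20.0, 21.0, 20.5, 22.0, 23.0, 22.5,
      18.0, 18.5, 18.0, 19.0, 19.5, 19.0,
      25.0, 24.0, 24.5, 26.0, 25.0, 25.5
    ),
    nrow = 3, byrow = TRUE,
    dimnames = list(paste0("P", 1:3), c("s1", "s2", "IS1", "s3", "s4", "IS2"))
  )
  meta <- tibble::tibble(
    sample_id = colnames(log2m),
    class_label = c("A", "B", NA, "A", "B", NA),
    batch = c(1, 1, 1, 2, 2, 2),
    is_internal_standard = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE)
  )
  list(
    raw = abundance_tbl(2^log2m, scale = "raw"),
    log2 = abundance_tbl(log2m, scale = "log2"),
    log2m = log2m,
    meta = meta
  )
}

# Normalized-scale abundance_tbl straight from a proteins-by-samples matrix,
# for exercising stages downstream of preprocessing on hand-built values.
as_normalized <- function(m) {
  abundance_tbl(m, scale = "normalized", is_standardized = TRUE)
}

# Independent exact binomial upper-tail oracle: term-by-term log-space
# summation, no calls to pbinom/dbinom.
binom_tail_oracle <- function(hits, trials, prob) {
  if (hits == 0) return(1)
  ks <- hits:trials
  terms <- exp(lchoose(trials, ks) + ks * log(prob) + (trials - ks) * log1p(-prob))
  sum(terms)
}

# Small multiclass dataset with wide-margin Gaussian blobs per class.
# Centers are axis-aligned (class i is shifted by +sep on feature i), so
# every class is linearly separable on a dedicated coordinate with margin
# far above the noise sd.
make_blobs <- function(n_per_class = 8, p = 6, classes = c("A", "B", "C"),
                       sep = 8, sd = 0.5, seed = 99) {
  stopifnot(p >= length(classes))
  centers <- matrix(0, length(classes), p)
  for (i in seq_along(classes)) centers[i, i] <- sep
  withr::with_seed(seed, {
    X <- do.call(rbind, lapply(seq_along(classes), function(i) {
      matrix(rnorm(n_per_class * p, sd = sd), n_per_class, p) +
        matrix(centers[i, ], n_per_class, p, byrow = TRUE)
    }))
    colnames(X) <- paste0("F", seq_len(p))
    rownames(X) <- sprintf("S%02d", seq_len(nrow(X)))
    list(X = X, y = factor(rep(classes, each = n_per_class)))
  })
}

# Split a blob draw into train/test, holding out the `n_test` points
# closest to each class centroid. Interior test points keep the cluster
# extremes in training, so exact tree splits placed at observed cluster
# boundaries interpolate rather than extrapolate.
split_blobs <- function(blobs, n_test = 3) {
  y <- blobs$y
  test_idx <- unlist(lapply(levels(y), function(cl) {
    idx <- which(y == cl)
    ctr <- colMeans(blobs$X[idx, , drop = FALSE])
    d <- sqrt(colSums((t(blobs$X[idx, , drop = FALSE]) - ctr)^2))
    idx[order(d)[seq_len(n_test)]]
  }))
  list(X_train = blobs$X[-test_idx, , drop = FALSE], y_train = y[-test_idx],
       X_test = blobs$X[test_idx, , drop = FALSE], y_test = y[test_idx])
}
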