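#' Stratified train/test partition of the samples
#'
#' Per class, `ceil(train_fraction * n_class)` samples are drawn without
#' replacement into the training set, capped at `n_class - 1` so that
#' every class keeps at least one test sample; the remainder form the
#' test set. With the study's class sizes (12, 7, 7, 7, 7) and a 0.7
#' fraction this reproduces the 29-train / 11-test split exactly.
#'
#' @param meta Sample metadata; internal-standard rows are ignored.
#' @param train_fraction Fraction of each class assigned to training.
#' @param seed Integer seed.
#' @return A list with character vectors `train_ids` and `test_ids`.
#' @export
stratified_partition <- function(meta, train_fraction = 0.7, seed = 1) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_pf("train_fraction must lie in (0, 1)")
  }
  meta <- tibble::as_tibble(meta)
  if ("is_internal_standard" %in% names(meta)) {
    meta <- meta[!meta$is_internal_standard, ]
  }
  tab <- table(meta$class_label)
  if (any(tab < 2)) {
    stop_pf(paste0("every class needs >= 2 samples to split; too small: ",
                   paste(names(tab)[tab < 2], collapse = ", ")))
  }
  classes <- names(tab)
  train_ids <- with_seed(seed, {
    unlist(lapply(classes, function(cl) {
      ids <- meta$sample_id[meta$class_label == cl]
      n_cl <- length(ids)
      n_train <- min(ceiling(train_fraction * n_cl), n_cl - 1L)
      ids[sample.int(n_cl, n_train)]
    }), use.names = FALSE)
  })
  list(
    train_ids = meta$sample_id[meta$sample_id %in% train_ids],
    test_ids = meta$sample_id[!meta$sample_id %in% train_ids]
  )
}

#' Stability selection over repeated stratified partitions
#'
#' Runs [rank_features()] on the training subset of each of `B`
#' independent stratified partitions, records each partition's top-`k`
#' features, and aggregates per-protein hit counts. Hit counts are tested
#' against an exact binomial null (see [stability_pvalues()]) and
#' Benjamini-Hochberg adjusted over the union set of proteins that ever
#' entered a top-k.
#'
#' @param x Normalized [abundance_tbl()] (case/control samples).
#' @param meta Sample metadata.
#' @param B Number of partitions.
#' @param k Top-list size per partition.
#' @param config A [ranking_config()]; its seed is overridden per
#'   partition by a substream of `seed`.
#' @param train_fraction Per-class training fraction.
#' @param seed Master seed.
#' @return An object of class `stability_result`: list with `table`
#'   (tibble: protein_id, hit_count, p_value, adjusted_p), `partitions`
#'   (list of train/test/top-k per partition), and scalars `B`, `P`, `k`,
#'   `p_hat`, `train_fraction`, `seed`.
#' @export
run_stability <- function(x, meta, B = 100, k = 20,
                          config = ranking_config(),
                          train_fraction = 0.7, seed = 1) {
  assert_scale(x, "normalized", "run_stability")
  P <- nrow(x)
  stopifnot(B >= 1)
  if (k > P) stop_pf("k cannot exceed the number of proteins")
  partitions <- vector("list", B)
  counts <- setNames(integer(0), character(0))
  for (b in seq_len(B)) {
    part <- stratified_partition(meta, train_fraction,
                                 seed = substream_seed(seed, 7L, b))
    x_train <- new_abundance_tbl(
      x[, c("protein_id", part$train_ids), drop = FALSE],
      scale = "normalized", is_standardized = TRUE
    )
    cfg_b <- config
    cfg_b$seed <- substream_seed(seed, 11L, b)
    rk <- rank_features(x_train, meta, config = cfg_b)
    top_k <- rk$protein_id[seq_len(k)]
    partitions[[b]] <- list(partition_index = b,
                            train_ids = part$train_ids,
                            test_ids = part$test_ids,
                            top_k_ids = top_k)
    for (id in top_k) {
      counts[id] <- (if (id %in% names(counts)) counts[[id]] else 0L) + 1L
    }
  }
  counts <- counts[order(names(counts))]
  pv <- stability_pvalues(counts, P = P, B = B, k = k)
  tab <- tibble::tibble(
    protein_id = names(counts),
    hit_count = as.integer(unname(counts)),
    p_value = unname(pv),
    adjusted_p = adjust_pvalues(unname(pv))
  )
  tab <- tab[order(tab$adjusted_p, -tab$hit_count, tab$protein_id), ]
  structure(
    list(table = tab, partitions = partitions,
         B = B, P = P, k = k, p_hat = k / P,
         train_fraction = train_fraction, seed = seed),
    class = "stability_result"
  )
}

#' Binomial p-values for stability-selection hit counts
#'
#' The null hit probability is the total number of top-k slots divided by
#' the number of protein-partition pairs: `p_hat = (k * B) / (P * B) =
#' k / P`. Each protein's hit count is then tested with the exact
#' upper-tail binomial probability P(X >= hits), X ~ Binomial(B, p_hat).
#' The null treats partition hits as independent Bernoulli draws; the
#' ~70% sample overlap between partitions makes this an approximation,
#' reproduced as defined.
#'
#' @param hit_counts Named integer vector of per-protein top-k hit counts.
#' @param P Total number of proteins ranked.
#' @param B Number of partitions.
#' @param k Top-list size.
#' @return Named numeric vector of p-values.
#' @export
stability_pvalues <- function(hit_counts, P, B, k) {
  if (sum(hit_counts) != k * B) {
    stop_pf(sprintf("hit counts sum to %d but k * B = %d",
                    sum(hit_counts), k * B))
  }
  p_hat <- k / P
  setNames(binomial_upper_tail(as.numeric(hit_counts), B, p_hat),
           names(hit_counts))
}

#' Extract the final protein panel from a stability result
#'
#' Filters to proteins with adjusted p-value at most `alpha`, sorts by
#' (adjusted_p ascending, hit_count descending, protein_id ascending) and
#' truncates to the `k` most significant.
#'
#' @param stab A `stability_result` from [run_stability()].
#' @param alpha Significance level on the adjusted p-values.
#' @param k Maximum panel size (defaults to the stability run's k).
#' @return A tibble of class `panel_tbl` with the selected rows, carrying
#'   `alpha`, `k`, `B`, `seed` as attributes. An empty significant set
#'   yields an empty panel with a warning.
#' @export
select_panel <- function(stab, alpha = 0.05, k = stab$k) {
  stopifnot(inherits(stab, "stability_result"))
  sig <- stab$table[stab$table$adjusted_p <= alpha, ]
  if (nrow(sig) == 0) {
    warn("no protein passes the adjusted significance threshold; empty panel")
  }
  sig <- sig[order(sig$adjusted_p, -sig$hit_count, sig$protein_id), ]
  out <- head(sig, k)
  structure(out,
            alpha = alpha, k = k, B = stab$B, seed = stab$seed,
            class = c("panel_tbl", class(tibble::tibble())))
}

#' @export
tidy.stability_result <- function(x, ...) x$table

#' @export
glance.stability_result <- function(x, ...) {
  tibble::tibble(
    B = x$B, P = x$P, k = x$k, p_hat = x$p_hat,
    n_union = nrow(x$table),
    n_significant = sum(x$table$adjusted_p <= 0.05)
  )
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf(
    "# Stability selection: B = %d partitions, k = %d, P = %d proteins (p_hat = %.4g)\n",
    x$B, x$k, x$P, x$p_hat
  ))
  cat(sprintf("# %d proteins entered a top-%d at least once; %d significant at adjusted p <= 0.05\n",
              nrow(x$table), x$k, sum(x$table$adjusted_p <= 0.05)))
  print(x$table, ...)
  invisible(x)
}

#' Plot stability-selection hit counts
#'
#' @param object A `stability_result`.
#' @param top_n Number of proteins to display, by hit count.
#' @param alpha Significance threshold used for coloring.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stability_result <- function(object, top_n = 30, alpha = 0.05, ...) {
  d <- head(object$table[order(-object$table$hit_count), ], top_n)
  d$protein_id <- factor(d$protein_id, levels = rev(d$protein_id))
  d$significant <- d$adjusted_p <= alpha
  ggplot2::ggplot(d, ggplot2::aes(x = .data$hit_count, y = .data$protein_id,
                                  fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = object$B * object$p_hat,
                        linetype = "dashed") +
    ggplot2::labs(x = sprintf("Top-%d hits over %d partitions", object$k, object$B),
                  y = NULL, fill = sprintf("adj. p <= %g", alpha))
}
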