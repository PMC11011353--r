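#' Benjamini-Hochberg adjustment of p-values
#'
#' Step-up false-discovery-rate control (the field default for
#' proteome-wide testing), delegated to [stats::p.adjust()]. Values are
#' validated to lie in [0, 1] first.
#'
#' @param p Numeric vector of p-values.
#' @param method Adjustment method; default `"BH"`.
#' @return Adjusted p-values, capped at 1 and monotone in rank.
#' @export
adjust_pvalues <- function(p, method = "BH") {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop_pf("p-values must lie in [0, 1] and be non-missing")
  }
  p.adjust(p, method = method)
}

group_labels_for <- function(x, meta) {
  meta <- tibble::as_tibble(meta)
  meta <- meta[match(sample_ids(x), meta$sample_id), ]
  if (any(is.na(meta$sample_id))) stop_pf("samples absent from metadata")
  if (any(meta$is_internal_standard)) {
    stop_pf("internal-standard samples must be removed before testing (run the preprocessing chain)")
  }
  factor(meta$class_label)
}

#' Per-protein one-way ANOVA across all classes
#'
#' Fixed-effects one-way ANOVA F-test per protein on the normalized log2
#' abundances, with Benjamini-Hochberg adjustment across proteins.
#' Proteins with zero variance across all samples get F = 0 and p = 1
#' (kept, so output rows align with input proteins).
#'
#' @param x Normalized [abundance_tbl()].
#' @param meta Sample metadata for the case/control samples.
#' @return A tibble: `protein_id`, `statistic` (F), `p_value`,
#'   `adjusted_p`, and one `mean_<class>` column per class.
#' @export
anova_across_groups <- function(x, meta) {
  assert_scale(x, "normalized", "anova_across_groups")
  y <- group_labels_for(x, meta)
  tab <- table(y)
  if (length(tab) < 2) stop_pf("need at least two classes")
  if (any(tab < 2)) {
    stop_pf(paste0("every class needs >= 2 samples; too small: ",
                   paste(names(tab)[tab < 2], collapse = ", ")))
  }
  m <- abundance_matrix(x)
  res <- apply(m, 1, function(v) {
    if (isTRUE(all.equal(var(v), 0)) || var(v) == 0) {
      return(c(statistic = 0, p_value = 1))
    }
    ft <- tryCatch(oneway.test(v ~ y, var.equal = TRUE),
                   error = function(e) NULL)
    if (is.null(ft) || is.na(ft$p.value)) c(statistic = 0, p_value = 1)
    else c(statistic = unname(ft$statistic), p_value = ft$p.value)
  })
  means <- do.call(cbind, lapply(levels(y), function(cl) {
    unname(rowMeans(m[, y == cl, drop = FALSE]))
  }))
  colnames(means) <- paste0("mean_", levels(y))
  out <- tibble::tibble(
    protein_id = rownames(m),
    statistic = unname(res["statistic", ]),
    p_value = unname(res["p_value", ]),
    adjusted_p = adjust_pvalues(unname(res["p_value", ]))
  )
  dplyr::bind_cols(out, tibble::as_tibble(means))
}

#' Welch t-test of control versus pooled cases per protein
#'
#' Two-sided Welch (unequal-variance) t-test of the control class against
#' all other classes pooled, per protein, with Benjamini-Hochberg
#' adjustment. `log2fc` is the case mean minus the control mean (data are
#' already in log2).
#'
#' @param x Normalized [abundance_tbl()].
#' @param meta Sample metadata.
#' @param control Label of the control class (default `"Control"`).
#' @return A tibble: `protein_id`, `statistic` (t), `p_value`,
#'   `adjusted_p`, `log2fc`, `mean_control`, `mean_case`.
#' @export
ttest_control_vs_case <- function(x, meta, control = "Control") {
  assert_scale(x, "normalized", "ttest_control_vs_case")
  y <- group_labels_for(x, meta)
  if (!control %in% levels(y)) {
    stop_pf(paste0("control label '", control, "' not found in metadata"))
  }
  grp <- factor(ifelse(y == control, "control", "case"), levels = c("control", "case"))
  if (any(table(grp) < 2)) stop_pf("both groups need >= 2 samples")
  m <- abundance_matrix(x)
  ctrl <- grp == "control"
  res <- apply(m, 1, function(v) {
    if (var(v) == 0) return(c(statistic = 0, p_value = 1))
    tt <- tryCatch(t.test(v[!ctrl], v[ctrl]), error = function(e) NULL)
    if (is.null(tt) || is.na(tt$p.value)) c(statistic = 0, p_value = 1)
    else c(statistic = unname(tt$statistic), p_value = tt$p.value)
  })
  mean_control <- rowMeans(m[, ctrl, drop = FALSE])
  mean_case <- rowMeans(m[, !ctrl, drop = FALSE])
  tibble::tibble(
    protein_id = rownames(m),
    statistic = unname(res["statistic", ]),
    p_value = unname(res["p_value", ]),
    adjusted_p = adjust_pvalues(unname(res["p_value", ])),
    log2fc = unname(mean_case - mean_control),
    mean_control = unname(mean_control),
    mean_case = unname(mean_case)
  )
}
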