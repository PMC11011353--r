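#' Remove contaminant proteins and proteins with missing values
#'
#' Complete-case filtering at the protein level: a protein is retained only
#' if it is not flagged as a contaminant and has no missing cell in any
#' column (internal standards included). Proteins absent from the
#' annotation table default to non-contaminant. Row order is preserved.
#'
#' @param x Raw-scale [abundance_tbl()].
#' @param annot Data frame with columns `protein_id`, `is_contaminant`.
#' @param missing_policy `"any"` (default) drops proteins missing in any
#'   column; `"all"` drops only proteins missing everywhere.
#' @return A raw-scale `abundance_tbl` restricted to retained proteins,
#'   with attributes `n_contaminant` / `n_missing` giving removal counts.
#' @export
filter_proteins <- function(x, annot, missing_policy = c("any", "all")) {
  assert_scale(x, "raw", "filter_proteins")
  missing_policy <- match.arg(missing_policy)
  annot <- tibble::as_tibble(annot)
  stopifnot(all(c("protein_id", "is_contaminant") %in% names(annot)))

  contam_ids <- annot$protein_id[annot$is_contaminant %in% TRUE]
  is_contam <- x$protein_id %in% contam_ids

  m <- abundance_matrix(x)
  n_miss <- rowSums(is.na(m))
  has_missing <- if (missing_policy == "any") n_miss > 0 else n_miss == ncol(m)

  keep <- !is_contam & !has_missing
  if (!any(keep)) {
    stop_pf(sprintf(
      "all %d proteins removed (%d contaminant, %d with missing values)",
      nrow(x), sum(is_contam), sum(has_missing)
    ))
  }
  out <- new_abundance_tbl(x[keep, , drop = FALSE], scale = "raw")
  attr(out, "n_contaminant") <- sum(is_contam)
  attr(out, "n_missing") <- sum(has_missing)
  out
}

#' Log2-transform a raw abundance table
#'
#' @param x Raw-scale [abundance_tbl()] with strictly positive values.
#' @return The table with values replaced by their base-2 logarithm
#'   (scale `"log2"`).
#' @export
log2_transform <- function(x) {
  assert_scale(x, "raw", "log2_transform")
  m <- abundance_matrix(x)
  bad <- which(!is.na(m) & m <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_pf(sprintf(
      "non-positive abundance for protein '%s', sample '%s'",
      rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]
    ))
  }
  rebuild_abundance(log2(m), scale = "log2")
}

#' Standardize against each batch's internal-standard channel
#'
#' For every protein and every non-internal-standard sample, subtracts the
#' log2 value of that sample's batch internal standard. Because a batch
#' effect that is multiplicative on the raw scale is an additive offset in
#' log2 common to all of the batch's channels (pool included), this
#' subtraction cancels it exactly. The internal-standard columns are
#' consumed and dropped from the output.
#'
#' @param x Log2-scale [abundance_tbl()].
#' @param meta Sample metadata (see [validate_metadata()]); each batch must
#'   have exactly one internal-standard sample.
#' @return A log2-scale `abundance_tbl` of the case/control samples only,
#'   flagged as IS-standardized.
#' @export
standardize_by_internal_standard <- function(x, meta) {
  assert_scale(x, "log2", "standardize_by_internal_standard")
  meta <- validate_metadata(meta)
  m <- abundance_matrix(x)
  missing_meta <- setdiff(colnames(m), meta$sample_id)
  if (length(missing_meta)) {
    stop_pf(paste0("samples absent from metadata: ", paste(missing_meta, collapse = ", ")))
  }
  meta <- meta[match(colnames(m), meta$sample_id), ]
  is_cols <- which(meta$is_internal_standard)
  if (!length(is_cols)) stop_pf("no internal-standard samples found in the matrix")
  is_by_batch <- setNames(colnames(m)[is_cols], as.character(meta$batch[is_cols]))
  keep <- which(!meta$is_internal_standard)
  ref <- m[, is_by_batch[as.character(meta$batch[keep])], drop = FALSE]
  out <- m[, keep, drop = FALSE] - ref
  rebuild_abundance(out, scale = "log2", is_standardized = TRUE)
}

#' Median-normalize sample columns
#'
#' Shifts each sample column additively so that its median equals the
#' grand median of all pre-shift sample medians. Column medians are exactly
#' equal afterwards; the common value is fixed for reproducibility even
#' though downstream tree ensembles are invariant to per-column shifts.
#'
#' @param x IS-standardized log2-scale [abundance_tbl()].
#' @return An `abundance_tbl` with scale `"normalized"`.
#' @export
median_normalize <- function(x) {
  assert_scale(x, "log2", "median_normalize")
  if (!isTRUE(attr(x, "is_standardized"))) {
    stop_pf("median_normalize() expects internal-standard standardized input",
            class = "panelforest_scale_error")
  }
  m <- abundance_matrix(x)
  if (ncol(m) == 0 || nrow(m) == 0) return(rebuild_abundance(m, scale = "normalized"))
  med <- apply(m, 2, median, na.rm = TRUE)
  target <- median(med)
  out <- sweep(m, 2, med - target)
  rebuild_abundance(out, scale = "normalized")
}

#' Run the full preprocessing chain
#'
#' Convenience wrapper: [filter_proteins()] then [log2_transform()] then
#' [standardize_by_internal_standard()] then [median_normalize()].
#'
#' @param x Raw-scale [abundance_tbl()].
#' @param meta Sample metadata.
#' @param annot Protein annotation (`protein_id`, `is_contaminant`);
#'   `NULL` means no contaminants.
#' @return A normalized `abundance_tbl` of case/control samples.
#' @export
preprocess_abundance <- function(x, meta, annot = NULL) {
  if (is.null(annot)) {
    annot <- tibble::tibble(protein_id = x$protein_id, is_contaminant = FALSE)
  }
  x |>
    filter_proteins(annot) |>
    log2_transform() |>
    standardize_by_internal_standard(meta) |>
    median_normalize()
}
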