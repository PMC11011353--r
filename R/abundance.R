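#' Protein abundance tables
#'
#' An `abundance_tbl` is a tibble holding a proteins-by-samples abundance
#' matrix: the first column, `protein_id`, gives unique protein (group)
#' identifiers and every remaining column is one sample's numeric
#' abundances. Missing measurements are `NA`. A `scale` attribute tracks
#' where the table sits in the preprocessing chain (`"raw"` reporter-style
#' intensities, `"log2"`, or `"normalized"`), so the pipeline stages can
#' refuse to run out of order.
#'
#' @param x A data frame whose first column is `protein_id`, or a numeric
#'   matrix with proteins as rownames and samples as colnames.
#' @param scale One of `"raw"`, `"log2"`, `"normalized"`.
#' @param is_standardized Has internal-standard standardization been applied?
#'
#' @return A tibble of class `abundance_tbl`.
#' @export
#' @examples
#' m <- matrix(2^rnorm(6, 20), 3, 2,
#'             dimnames = list(paste0("P", 1:3), c("s1", "s2")))
#' abundance_tbl(m, scale = "raw")
abundance_tbl <- function(x, scale = c("raw", "log2", "normalized"),
                          is_standardized = FALSE) {
  scale <- match.arg(scale)
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      stop_pf("matrix input needs protein rownames and sample colnames")
    }
    x <- tibble::as_tibble(x, rownames = "protein_id")
  }
  x <- tibble::as_tibble(x)
  if (!identical(names(x)[1], "protein_id")) {
    stop_pf("first column must be `protein_id`")
  }
  x$protein_id <- as.character(x$protein_id)
  if (anyDuplicated(x$protein_id)) {
    dup <- unique(x$protein_id[duplicated(x$protein_id)])
    stop_pf(paste0("duplicate protein ids: ", paste(head(dup, 5), collapse = ", ")))
  }
  if (anyDuplicated(names(x))) stop_pf("duplicate sample ids in header")
  for (nm in names(x)[-1]) {
    if (!is.numeric(x[[nm]])) stop_pf(paste0("non-numeric abundance column: ", nm))
  }
  new_abundance_tbl(x, scale = scale, is_standardized = is_standardized)
}

new_abundance_tbl <- function(x, scale, is_standardized = FALSE) {
  structure(
    x,
    scale = scale,
    is_standardized = is_standardized,
    class = c("abundance_tbl", class(tibble::tibble()))
  )
}

#' @rdname abundance_tbl
#' @export
abn_scale <- function(x) attr(x, "scale") %||% NA_character_

#' @rdname abundance_tbl
#' @export
sample_ids <- function(x) setdiff(names(x), "protein_id")

#' @rdname abundance_tbl
#' @export
protein_ids <- function(x) x$protein_id

#' Extract the numeric matrix (proteins x samples) from an abundance table
#'
#' @param x An `abundance_tbl`.
#' @return A numeric matrix with protein rownames and sample colnames.
#' @export
abundance_matrix <- function(x) {
  m <- as.matrix(x[, setdiff(names(x), "protein_id"), drop = FALSE])
  rownames(m) <- x$protein_id
  m
}

# Rebuild an abundance_tbl from a modified matrix, carrying flags forward.
rebuild_abundance <- function(m, scale, is_standardized = FALSE) {
  abundance_tbl(m, scale = scale, is_standardized = is_standardized)
}

assert_scale <- function(x, expected, op) {
  if (!inherits(x, "abundance_tbl")) {
    stop_pf(paste0(op, "() expects an abundance_tbl; see abundance_tbl()"))
  }
  if (!identical(abn_scale(x), expected)) {
    stop_pf(paste0(
      op, "() requires scale = '", expected, "' input but got '",
      abn_scale(x), "'; pipeline stages must run in order ",
      "(filter -> log2 -> internal standard -> median normalization)"
    ), class = "panelforest_scale_error")
  }
  invisible(x)
}

#' @export
print.abundance_tbl <- function(x, ...) {
  cat(sprintf(
    "# Abundance table: %d proteins x %d samples [scale: %s%s]\n",
    nrow(x), length(sample_ids(x)), abn_scale(x),
    if (isTRUE(attr(x, "is_standardized"))) ", IS-standardized" else ""
  ))
  NextMethod()
}

#' Validate a sample metadata table
#'
#' Checks the sample metadata contract used throughout the pipeline:
#' columns `sample_id`, `class_label`, `batch`, `is_internal_standard`;
#' unique sample ids; exactly one internal-standard sample per batch;
#' internal-standard rows carry no class label.
#'
#' @param meta A data frame of sample metadata.
#' @return The metadata as a tibble, invisibly validated.
#' @export
validate_metadata <- function(meta) {
  meta <- tibble::as_tibble(meta)
  need <- c("sample_id", "class_label", "batch", "is_internal_standard")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop_pf(paste0("metadata missing columns: ", paste(miss, collapse = ", ")))
  if (anyDuplicated(meta$sample_id)) stop_pf("duplicate sample ids in metadata")
  is_tab <- table(meta$batch[meta$is_internal_standard])
  all_batches <- unique(meta$batch)
  bad <- setdiff(as.character(all_batches), names(is_tab)[is_tab == 1])
  if (length(bad)) {
    stop_pf(paste0(
      "each batch needs exactly one internal-standard sample; offending batch(es): ",
      paste(bad, collapse = ", ")
    ))
  }
  if (any(!is.na(meta$class_label[meta$is_internal_standard]))) {
    stop_pf("internal-standard samples must not carry a class label")
  }
  meta
}
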