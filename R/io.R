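# Tab-separated readers/writers for the exchange formats used throughout:
# an abundance matrix (first column protein ids, header row of sample ids,
# empty cells or "NA" missing), sample metadata and protein annotation.

#' Read a protein abundance table from tab-separated text
#'
#' @param path File path: first column `protein_id`, remaining columns one
#'   per sample; empty cells or `NA` are missing values.
#' @param scale Scale flag to attach (files written by [write_abundance_table()]
#'   round-trip their scale via the `#scale=` header comment; this argument
#'   is the fallback).
#' @return An [abundance_tbl()].
#' @export
read_abundance_table <- function(path, scale = "raw") {
  first <- readLines(path, n = 1)
  if (startsWith(first, "#scale=")) {
    hdr <- strsplit(sub("^#scale=", "", first), ";is_standardized=")[[1]]
    scale <- hdr[1]
    is_std <- identical(hdr[2], "TRUE")
  } else {
    is_std <- FALSE
  }
  d <- readr::read_tsv(path, comment = "#", na = c("", "NA"),
                       show_col_types = FALSE, progress = FALSE)
  pr <- readr::problems(d)
  if (nrow(pr) > 0) {
    stop_pf(sprintf("malformed abundance file (%d parsing problem(s), first at row %d: %s)",
                    nrow(pr), pr$row[1], pr$expected[1]))
  }
  names(d)[1] <- "protein_id"
  abundance_tbl(d, scale = scale, is_standardized = is_std)
}

#' @rdname read_abundance_table
#' @param x An `abundance_tbl` to write.
#' @export
write_abundance_table <- function(x, path) {
  stopifnot(inherits(x, "abundance_tbl"))
  writeLines(sprintf("#scale=%s;is_standardized=%s", abn_scale(x),
                     isTRUE(attr(x, "is_standardized"))), path)
  readr::write_tsv(tibble::as_tibble(x), path, append = TRUE,
                   col_names = TRUE, na = "NA")
  invisible(path)
}

#' Read or write sample metadata / protein annotation tables
#'
#' @param path Tab-separated file with columns `sample_id`, `class_label`,
#'   `batch`, `is_internal_standard` (metadata) or `protein_id`,
#'   `is_contaminant` (annotation).
#' @return A validated tibble.
#' @export
read_sample_metadata <- function(path) {
  d <- readr::read_tsv(path, na = c("", "NA"), show_col_types = FALSE,
                       progress = FALSE)
  d$is_internal_standard <- as.logical(d$is_internal_standard)
  d$class_label <- as.character(d$class_label)
  validate_metadata(d)
}

#' @rdname read_sample_metadata
#' @param meta Metadata tibble to write.
#' @export
write_sample_metadata <- function(meta, path) {
  readr::write_tsv(tibble::as_tibble(meta), path, na = "NA")
  invisible(path)
}

#' @rdname read_sample_metadata
#' @export
read_protein_annotation <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("protein_id", "is_contaminant") %in% names(d)))
  d$is_contaminant <- as.logical(d$is_contaminant)
  if (anyDuplicated(d$protein_id)) stop_pf("duplicate protein ids in annotation")
  tibble::as_tibble(d)
}

#' @rdname read_sample_metadata
#' @param annot Annotation tibble to write.
#' @export
write_protein_annotation <- function(annot, path) {
  readr::write_tsv(tibble::as_tibble(annot), path, na = "NA")
  invisible(path)
}

#' Write a synthetic dataset to a directory as tab-separated text
#'
#' @param dataset A list as returned by [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_abundance_table(dataset$abundance, file.path(dir, "abundance.tsv"))
  write_sample_metadata(dataset$metadata, file.path(dir, "metadata.tsv"))
  write_protein_annotation(dataset$annotation, file.path(dir, "annotation.tsv"))
  if (!is.null(dataset$truth)) {
    readr::write_tsv(dataset$truth, file.path(dir, "truth.tsv"))
  }
  invisible(dir)
}
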