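#' Configuration for the synthetic TMT-like data generator
#'
#' Defaults emulate a four-batch TMT study of cholestatic liver tissue:
#' five classes (Control 7, PFIC 12, BiliaryAtresia 7, ALGS 7, AATD 7 —
#' 40 case/control samples), one pooled internal-standard channel per
#' batch, ~10^3 log-normal protein abundances, multiplicative batch
#' effects, a configurable set of planted class-discriminative proteins,
#' sporadic missing values, and flagged contaminants.
#'
#' @param n_proteins Number of protein groups.
#' @param class_sizes Named integer vector: samples per class label.
#' @param n_batches Number of TMT batches; each contributes one
#'   internal-standard (pooled) channel.
#' @param n_planted Number of planted class-discriminative proteins.
#' @param effect_log2 Mean log2 shift of a planted protein in its class.
#' @param batch_sd_log2 SD of per-protein, per-batch log2 offsets
#'   (multiplicative batch effect on the raw scale).
#' @param noise_sd_log2 SD of per-cell log2 measurement noise.
#' @param missing_rate Probability a sample cell is missing (never applied
#'   to internal-standard columns).
#' @param contaminant_rate Probability a protein is flagged contaminant.
#' @param seed Integer seed; identical config + seed gives bitwise-identical
#'   output.
#'
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_proteins = 1000,
                         class_sizes = c(Control = 7, PFIC = 12,
                                         BiliaryAtresia = 7, ALGS = 7,
                                         AATD = 7),
                         n_batches = 4,
                         n_planted = 30,
                         effect_log2 = 2,
                         batch_sd_log2 = 0.5,
                         noise_sd_log2 = 0.3,
                         missing_rate = 0.005,
                         contaminant_rate = 0.02,
                         seed = 20240326) {
  stopifnot(n_proteins >= 1, n_batches >= 1)
  if (is.null(names(class_sizes)) || any(!nzchar(names(class_sizes)))) {
    stop_pf("class_sizes must be a named vector of per-class sample counts")
  }
  if (any(class_sizes < 2)) {
    stop_pf("every class needs >= 2 samples (stratified splitting requires a train and a test representative)")
  }
  if (n_planted > n_proteins) stop_pf("n_planted cannot exceed n_proteins")
  if (n_planted < 0) stop_pf("n_planted must be non-negative")
  if (effect_log2 <= 0) stop_pf("effect_log2 must be positive")
  if (batch_sd_log2 < 0) stop_pf("batch_sd_log2 must be non-negative")
  if (noise_sd_log2 <= 0) stop_pf("noise_sd_log2 must be positive")
  if (missing_rate < 0 || missing_rate >= 1) stop_pf("missing_rate must be in [0, 1)")
  if (contaminant_rate < 0 || contaminant_rate >= 1) stop_pf("contaminant_rate must be in [0, 1)")
  structure(
    list(
      n_proteins = as.integer(n_proteins),
      class_sizes = class_sizes,
      n_batches = as.integer(n_batches),
      n_planted = as.integer(n_planted),
      effect_log2 = effect_log2,
      batch_sd_log2 = batch_sd_log2,
      noise_sd_log2 = noise_sd_log2,
      missing_rate = missing_rate,
      contaminant_rate = contaminant_rate,
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' Generate a synthetic multi-batch abundance dataset with planted markers
#'
#' Simulates a raw-scale (strictly positive) proteins-by-samples table.
#' Baseline log2 abundances are drawn N(20, 2) per protein (log-normal
#' dynamic range typical of reporter intensities). Planted proteins have
#' their assigned class's mean shifted by `effect_log2` in log2 space,
#' classes being assigned round-robin so every class has markers. Batch
#' effects are per-protein, per-batch log2 offsets — i.e. multiplicative
#' on the raw scale, exactly the structure internal-standard
#' standardization removes. Each batch gains one internal-standard column:
#' the per-protein geometric mean of that batch's (noise-free of missing)
#' samples, mimicking a pooled channel. Missing cells (`NA`) are placed
#' completely at random in sample columns only.
#'
#' Samples are interleaved across classes and dealt to batches round-robin,
#' so batch sizes differ by at most one and every batch mixes classes.
#'
#' @param config A [synth_config()].
#' @return A list with elements `abundance` (raw-scale [abundance_tbl()]),
#'   `metadata` (tibble: sample_id, class_label, batch,
#'   is_internal_standard), `annotation` (tibble: protein_id,
#'   is_contaminant) and `truth` (tibble: protein_id, class, effect_log2 —
#'   the planted ground truth).
#' @export
#' @examples
#' d <- generate_dataset(synth_config(n_proteins = 50, n_planted = 5))
#' d$abundance
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  cs <- config$class_sizes
  classes <- names(cs)
  p <- config$n_proteins
  n <- sum(cs)
  nb <- config$n_batches

  protein_id <- sprintf("PROT%05d", seq_len(p))

  # interleave classes (round-robin) so batch assignment mixes classes
  per_class_ids <- lapply(classes, function(cl) {
    sprintf("%s_%02d", cl, seq_len(cs[[cl]]))
  })
  names(per_class_ids) <- classes
  order_idx <- order(unlist(lapply(cs, seq_len), use.names = FALSE),
                     rep(seq_along(cs), cs))
  sample_id <- unlist(per_class_ids, use.names = FALSE)[order_idx]
  sample_class <- rep(classes, cs)[order_idx]
  batch <- rep_len(seq_len(nb), n)

  with_seed(config$seed, {
    baseline <- rnorm(p, mean = 20, sd = 2)
    batch_delta <- matrix(rnorm(p * nb), p, nb) * config$batch_sd_log2
    noise <- matrix(rnorm(p * n), p, n) * config$noise_sd_log2
    miss_u <- matrix(runif(p * n), p, n)
    contam <- runif(p) < config$contaminant_rate
    planted_idx <- if (config$n_planted > 0) sample.int(p, config$n_planted) else integer(0)
  })

  planted_class <- if (length(planted_idx)) {
    classes[((seq_along(planted_idx) - 1L) %% length(classes)) + 1L]
  } else {
    character(0)
  }

  log2m <- matrix(baseline, p, n) + batch_delta[, batch, drop = FALSE] + noise
  for (i in seq_along(planted_idx)) {
    in_class <- sample_class == planted_class[i]
    log2m[planted_idx[i], in_class] <- log2m[planted_idx[i], in_class] + config$effect_log2
  }

  # internal standard: per-batch geometric mean on the raw scale, i.e.
  # the arithmetic mean in log2 space, computed before missingness
  is_log2 <- vapply(seq_len(nb), function(b) {
    rowMeans(log2m[, batch == b, drop = FALSE])
  }, numeric(p))

  raw <- 2^log2m
  raw[miss_u < config$missing_rate] <- NA_real_
  is_raw <- 2^is_log2

  is_ids <- sprintf("IS_%d", seq_len(nb))
  values <- cbind(raw, is_raw)
  colnames(values) <- c(sample_id, is_ids)
  rownames(values) <- protein_id

  metadata <- tibble::tibble(
    sample_id = c(sample_id, is_ids),
    class_label = c(sample_class, rep(NA_character_, nb)),
    batch = c(batch, seq_len(nb)),
    is_internal_standard = c(rep(FALSE, n), rep(TRUE, nb))
  )
  annotation <- tibble::tibble(
    protein_id = protein_id,
    is_contaminant = contam
  )
  truth <- tibble::tibble(
    protein_id = protein_id[planted_idx],
    class = planted_class,
    effect_log2 = rep(config$effect_log2, length(planted_idx))
  )

  list(
    abundance = abundance_tbl(values, scale = "raw"),
    metadata = validate_metadata(metadata),
    annotation = annotation,
    truth = truth
  )
}
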