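#' Configuration for the end-to-end panel-discovery pipeline
#'
#' Defaults reproduce the study settings: 70% stratified training
#' fraction, B = 100 partitions, top-k = 20, alpha = 0.05 and 30 outer
#' ranking rounds.
#'
#' @param control_label Label of the control class.
#' @param train_fraction Per-class training fraction for every partition.
#' @param B Number of stability partitions.
#' @param k Top-list and maximum panel size.
#' @param alpha Adjusted-significance threshold for panel membership.
#' @param ranking A [ranking_config()].
#' @param algorithms Classifiers to benchmark (see [pf_algorithms()]).
#' @param run_differential Also run the ANOVA and control-vs-case t-test?
#' @param seed Master seed for the whole run.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(control_label = "Control",
                            train_fraction = 0.7,
                            B = 100, k = 20, alpha = 0.05,
                            ranking = ranking_config(),
                            algorithms = pf_algorithms(),
                            run_differential = TRUE,
                            seed = 1) {
  stopifnot(B >= 1, k >= 1, alpha > 0, alpha < 1,
            inherits(ranking, "ranking_config"))
  structure(
    list(control_label = control_label, train_fraction = train_fraction,
         B = as.integer(B), k = as.integer(k), alpha = alpha,
         ranking = ranking, algorithms = algorithms,
         run_differential = run_differential, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full panel-discovery pipeline
#'
#' Preprocess -> (optional differential testing) -> stability selection
#' over B stratified partitions -> panel extraction -> one fresh
#' stratified partition (its seed a distinct substream of the master
#' seed) for final classifier training/testing -> seven-classifier
#' evaluation -> final all-samples random-forest importance -> 3-D MDS
#' embedding. When `out_dir` is given, every stage's table is written as
#' tab-separated text together with a JSON manifest (config, seed,
#' per-stage dimensions, per-partition sample ids) sufficient to
#' reproduce the run.
#'
#' @param abundance Raw-scale [abundance_tbl()] (or path to one).
#' @param meta Sample metadata tibble (or path).
#' @param annot Protein annotation tibble, path, or `NULL`.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for artifacts.
#' @return An object of class `pipeline_result`: list with elements
#'   `normalized`, `differential` (or NULL), `stability`, `panel`,
#'   `final_partition`, `models`, `report`, `final_model`, `mds`,
#'   `manifest`.
#' @export
run_pipeline <- function(abundance, meta, annot = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(abundance)) abundance <- read_abundance_table(abundance)
  if (is.character(meta)) meta <- read_sample_metadata(meta)
  if (is.character(annot)) annot <- read_protein_annotation(annot)

  stage <- function(name) message(sprintf("[panelforest] %s", name))

  stage("preprocessing")
  norm <- preprocess_abundance(abundance, meta, annot)

  differential <- NULL
  if (isTRUE(config$run_differential)) {
    stage("differential testing (ANOVA + control vs case t-test)")
    differential <- list(
      anova = anova_across_groups(norm, meta),
      ttest = ttest_control_vs_case(norm, meta, control = config$control_label)
    )
  }

  stage(sprintf("stability selection (B = %d partitions, k = %d)", config$B, config$k))
  stab <- run_stability(norm, meta, B = config$B, k = config$k,
                        config = config$ranking,
                        train_fraction = config$train_fraction,
                        seed = config$seed)

  stage("panel extraction")
  panel <- select_panel(stab, alpha = config$alpha, k = config$k)
  if (nrow(panel) == 0) stop_pf("pipeline aborted at panel extraction: empty panel")

  stage("final train/test partition and classifier benchmark")
  # distinct substream so the evaluation split is none of the B stability
  # partitions
  final_part <- stratified_partition(meta, config$train_fraction,
                                     seed = substream_seed(config$seed, 104729L))
  m <- abundance_matrix(norm)
  Xp <- t(m[panel$protein_id, , drop = FALSE])
  meta_cc <- meta[!meta$is_internal_standard, ]
  y_all <- setNames(meta_cc$class_label, meta_cc$sample_id)
  X_train <- Xp[final_part$train_ids, , drop = FALSE]
  X_test <- Xp[final_part$test_ids, , drop = FALSE]
  y_train <- factor(y_all[final_part$train_ids])
  y_test <- factor(y_all[final_part$test_ids], levels = levels(y_train))

  models <- train_classifiers(X_train, y_train,
                              algorithms = config$algorithms,
                              seed = substream_seed(config$seed, 224737L))
  report <- evaluate_classifiers(models, X_test, y_test)

  stage("final all-samples model and MDS embedding")
  final_model <- final_model_importance(
    Xp, factor(y_all[rownames(Xp)]),
    seed = substream_seed(config$seed, 350377L)
  )
  mds <- mds_embedding(Xp, n_dims = 3, y = y_all[rownames(Xp)])

  manifest <- list(
    package_version = as.character(utils::packageVersion("panelforest")),
    seed = config$seed,
    config = config[setdiff(names(config), "ranking")],
    ranking = unclass(config$ranking),
    dims = list(
      input = c(proteins = nrow(abundance), samples = length(sample_ids(abundance))),
      normalized = c(proteins = nrow(norm), samples = length(sample_ids(norm))),
      panel = nrow(panel)
    ),
    final_partition = final_part,
    stability_partitions = lapply(stab$partitions, function(p) {
      p[c("partition_index", "train_ids", "test_ids")]
    })
  )

  result <- structure(
    list(normalized = norm, differential = differential, stability = stab,
         panel = panel, final_partition = final_part, models = models,
         report = report, final_model = final_model, mds = mds,
         manifest = manifest),
    class = "pipeline_result"
  )

  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  result
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_abundance_table(result$normalized, file.path(out_dir, "normalized.tsv"))
  if (!is.null(result$differential)) {
    readr::write_tsv(result$differential$anova, file.path(out_dir, "anova.tsv"))
    readr::write_tsv(result$differential$ttest, file.path(out_dir, "ttest.tsv"))
  }
  readr::write_tsv(result$stability$table, file.path(out_dir, "stability.tsv"))
  readr::write_tsv(tibble::as_tibble(result$panel), file.path(out_dir, "panel.tsv"))
  readr::write_tsv(result$report$metrics, file.path(out_dir, "classifier_metrics.tsv"))
  for (alg in names(result$report$confusion)) {
    conf <- as.data.frame.matrix(result$report$confusion[[alg]])
    readr::write_tsv(tibble::as_tibble(conf, rownames = "truth"),
                     file.path(out_dir, sprintf("confusion_%s.tsv", alg)))
  }
  readr::write_tsv(result$final_model$importance,
                   file.path(out_dir, "final_model_importance.tsv"))
  readr::write_tsv(result$mds, file.path(out_dir, "mds.tsv"))
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("# panelforest pipeline result\n")
  cat(sprintf("#   normalized matrix: %d proteins x %d samples\n",
              nrow(x$normalized), length(sample_ids(x$normalized))))
  cat(sprintf("#   stability: B = %d, union = %d, significant = %d\n",
              x$stability$B, nrow(x$stability$table),
              sum(x$stability$table$adjusted_p <= 0.05)))
  cat(sprintf("#   panel: %d proteins\n", nrow(x$panel)))
  best <- x$report$metrics[which.max(x$report$metrics$kappa), ]
  cat(sprintf("#   best classifier: %s (accuracy %.3f, kappa %.3f)\n",
              best$algorithm, best$accuracy, best$kappa))
  invisible(x)
}
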