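#' Configuration for the end-to-end malignancy-scoring pipeline
#'
#' Bundles the data source (a [generator_config()] or input paths), every
#' stage threshold, and the run seed. All thresholds default to the
#' pipeline's canonical values: QC 200/7000 genes and 20% mitochondrial
#' counts, FDR < 0.01 with |log2FC| >= 0.5, oriented AUC > 0.60, ten
#' cross-validation folds. One global seed fans out to stage seeds by fixed
#' offsets (generator +0, train/test split +1, CV folds +2) so each stage is
#' independently reproducible.
#'
#' @param generator A [generator_config()], or `NULL` when reading from disk.
#' @param input_10x_dir Directory with `matrix.mtx`/`features.tsv`/
#'   `barcodes.tsv`/`labels.tsv` (used when `generator` is `NULL`).
#' @param input_values_kind Scale flag of the on-disk matrix.
#' @param annotation_path Optional localization TSV for the
#'   secreted/membrane flag (see [load_annotation()]).
#' @param qc A [qc_thresholds()].
#' @param fdr_max,min_abs_log2fc DEG filter thresholds.
#' @param pseudocount Pseudocount for [log2_fold_change()].
#' @param auc_min Strict oriented-AUC floor of the ROC screen.
#' @param n_folds Cross-validation folds.
#' @param lambda_rule Penalty selection rule (see [select_lambda()]).
#' @param target_support Support size for `lambda_rule = "target_support"`.
#' @param train_fraction Fraction of cells (stratified) used for training;
#'   the remainder is held out for evaluation. `1` trains and evaluates on
#'   all cells.
#' @param target_sum [lognormalize()] library-size target.
#' @param seed Global run seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(generator = generator_config(),
                            input_10x_dir = NULL,
                            input_values_kind = "counts",
                            annotation_path = NULL,
                            qc = qc_thresholds(),
                            fdr_max = 0.01,
                            min_abs_log2fc = 0.5,
                            pseudocount = 1,
                            auc_min = 0.60,
                            n_folds = 10,
                            lambda_rule = c("cv_min", "cv_1se",
                                            "target_support"),
                            target_support = NULL,
                            train_fraction = 0.7,
                            target_sum = 1e4,
                            seed = 1L) {
  lambda_rule <- match.arg(lambda_rule)
  if (is.null(generator) && is.null(input_10x_dir)) {
    stop("either `generator` or `input_10x_dir` must be given", call. = FALSE)
  }
  stopifnot(train_fraction > 0, train_fraction <= 1)
  structure(
    list(generator = generator, input_10x_dir = input_10x_dir,
         input_values_kind = input_values_kind,
         annotation_path = annotation_path, qc = qc, fdr_max = fdr_max,
         min_abs_log2fc = min_abs_log2fc, pseudocount = pseudocount,
         auc_min = auc_min, n_folds = n_folds, lambda_rule = lambda_rule,
         target_support = target_support, train_fraction = train_fraction,
         target_sum = target_sum, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full malignancy-scoring pipeline
#'
#' Executes QC filtering, normalization, the Wilcoxon DEG screen, the
#' per-gene AUC screen, optional secreted/membrane annotation, scaling,
#' cross-validated L1 logistic selection, the final logistic fit, Youden
#' cut-point choice, and evaluation on the held-out split (or the training
#' cells when `train_fraction = 1`). When `out_dir` is given, writes
#' `deg.tsv`, `roc.tsv` (gene-panel style, ranked by oriented AUC),
#' `path.tsv`, `model.json`, `scores.tsv`, `metrics.json` and
#' `manifest.json` (config, seed and the stage gene-count funnel); the
#' manifest contains no timestamps, so reruns reproduce it byte-for-byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return A list of class `scms_run`: `data` (post-QC normalized
#'   `cell_matrix`), `removed_cells`, `train_cells`/`test_cells`, `deg`,
#'   `deg_hits`, `roc`, `cv` (the cross-validated path), `selection`,
#'   `model`, `scores` (held-out cells), `metrics`, `funnel`, `manifest`.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(
#'   generator = generator_config(n_malignant = 150, n_normal = 600,
#'                                n_noise_genes = 60, seed = 5),
#'   qc = qc_thresholds(min_genes = 5, max_genes = 7000),
#'   n_folds = 5, seed = 5)
#' run <- run_scms_pipeline(cfg)
#' run$metrics
#' }
#' @export
run_scms_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  raw <- stage("input", {
    if (!is.null(config$generator)) {
      simulate_cells(config$generator)
    } else {
      read_cell_matrix_10x(config$input_10x_dir,
                           values_kind = config$input_values_kind)
    }
  })
  n_cells_in <- n_cells(raw)

  qc <- stage("qc", qc_filter(raw, config$qc))
  norm <- stage("normalize", {
    if (qc$matrix$values_kind == "counts") {
      lognormalize(qc$matrix, config$target_sum)
    } else {
      qc$matrix
    }
  })

  split <- stage("split", {
    stratified_split(norm$cells$label, config$train_fraction,
                     seed = config$seed + 1L)
  })
  train <- subset_cells(norm, cells = norm$cells$cell_id[split])
  test <- if (all(split)) train else {
    subset_cells(norm, cells = norm$cells$cell_id[!split])
  }

  deg <- stage("deg", deg_screen(train, pseudocount = config$pseudocount))
  deg_hits <- deg_filter(deg, config$fdr_max, config$min_abs_log2fc)
  if (nrow(deg_hits) == 0) {
    stop("pipeline stage 'deg' failed: no genes pass the DEG filter",
         call. = FALSE)
  }

  roc <- stage("roc", roc_screen(train, deg_hits$gene, config$auc_min))
  if (nrow(roc) == 0) {
    stop("pipeline stage 'roc' failed: no genes pass the AUC screen",
         call. = FALSE)
  }
  roc <- dplyr::left_join(roc,
                          dplyr::select(deg_hits, "gene",
                                        abs_log2fc = "log2fc"),
                          by = "gene") |>
    dplyr::mutate(abs_log2fc = abs(.data$abs_log2fc))
  if (!is.null(config$annotation_path)) {
    annot <- stage("annotate", load_annotation(config$annotation_path))
    roc <- dplyr::left_join(
      roc,
      dplyr::select(annot, "gene", "secreted_or_membrane"),
      by = "gene")
  }

  scaling <- stage("scaling", fit_scaling(train))
  cand <- roc$gene
  scaled_train <- apply_scaling(train, scaling[scaling$gene %in% cand, ])
  cv <- stage("select", cv_l1_logistic(
    t(scaled_train$values), malignant_indicator(scaled_train),
    n_folds = config$n_folds, seed = config$seed + 2L
  ))
  selection <- stage("select", select_lambda(cv, config$lambda_rule,
                                             support = config$target_support))
  if (length(selection$selected_genes) == 0) {
    stop("pipeline stage 'select' failed: empty model at the chosen lambda",
         call. = FALSE)
  }

  model <- stage("fit", fit_final_logistic(
    apply_scaling(train, scaling[scaling$gene %in% selection$selected_genes, ])
  ))
  train_scores <- score_cells(model, train)
  model <- set_cutoff(model, choose_cutoff(train_scores$scms,
                                           train$cells$label))
  metrics <- stage("evaluate", evaluate_model(model, test))
  model$training_metrics <- as.list(evaluate_model(model, train))
  scores <- score_cells(model, test)

  funnel <- tibble::tibble(
    stage = c("input_cells", "qc_cells", "train_cells", "genes",
              "deg_genes", "auc_genes", "selected_genes"),
    n = c(n_cells_in, n_cells(qc$matrix), n_cells(train), n_genes(raw),
          nrow(deg_hits), nrow(roc), length(selection$selected_genes))
  )
  manifest <- list(
    config = serialize_config(config),
    seed = config$seed,
    funnel = stats::setNames(as.list(funnel$n), funnel$stage),
    chosen_lambda = selection$chosen_lambda,
    metrics = as.list(metrics)
  )

  run <- structure(
    list(data = norm, removed_cells = qc$removed,
         train_cells = train$cells$cell_id, test_cells = test$cells$cell_id,
         deg = deg, deg_hits = deg_hits, roc = roc, cv = cv,
         selection = selection, model = model, scores = scores,
         metrics = metrics, funnel = funnel, manifest = manifest),
    class = "scms_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.scms_run <- function(x, ...) {
  cat("<scms_run>\n")
  cat("  funnel:", paste(sprintf("%s=%d", x$funnel$stage, x$funnel$n),
                         collapse = ", "), "\n")
  cat(sprintf("  held-out auc %.4f, sensitivity %.3f, specificity %.3f\n",
              x$metrics$auc, x$metrics$sensitivity, x$metrics$specificity))
  invisible(x)
}

stratified_split <- function(labels, train_fraction, seed) {
  if (train_fraction >= 1) return(rep(TRUE, length(labels)))
  train <- logical(length(labels))
  withr::with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      n_train <- max(1, round(length(idx) * train_fraction))
      train[sample(idx, n_train)] <- TRUE
    }
  })
  if (all(train) || !any(train)) {
    stop("degenerate train/test split; adjust `train_fraction`", call. = FALSE)
  }
  train
}

serialize_config <- function(config) {
  gen <- config$generator
  list(
    generator = if (is.null(gen)) NULL else {
      g <- unclass(gen)
      g$informative_genes <- as.list(g$informative_genes)
      g
    },
    input_10x_dir = config$input_10x_dir,
    input_values_kind = config$input_values_kind,
    annotation_path = config$annotation_path,
    qc = unclass(config$qc),
    fdr_max = config$fdr_max, min_abs_log2fc = config$min_abs_log2fc,
    pseudocount = config$pseudocount, auc_min = config$auc_min,
    n_folds = config$n_folds, lambda_rule = config$lambda_rule,
    target_support = config$target_support,
    train_fraction = config$train_fraction, target_sum = config$target_sum,
    seed = config$seed
  )
}

#' Rebuild a pipeline configuration from a run manifest
#'
#' @param path `manifest.json` written by [run_scms_pipeline()].
#' @return A [pipeline_config()] reproducing the run.
#' @export
config_from_manifest <- function(path) {
  doc <- jsonlite::read_json(path)
  cfg <- doc$config
  gen <- NULL
  if (!is.null(cfg$generator)) {
    g <- cfg$generator
    gen <- generator_config(
      n_malignant = g$n_malignant, n_normal = g$n_normal,
      informative_genes = tibble::tibble(
        gene = unlist(g$informative_genes$gene),
        target_auc = unlist(g$informative_genes$target_auc),
        direction = unlist(g$informative_genes$direction)
      ),
      n_noise_genes = g$n_noise_genes,
      zero_inflation_rate = g$zero_inflation_rate,
      base_mean = g$base_mean, base_sd = g$base_sd,
      mito_shape1 = g$mito_shape1, mito_shape2 = g$mito_shape2,
      values_kind = g$values_kind, seed = g$seed
    )
  }
  pipeline_config(
    generator = gen,
    input_10x_dir = cfg$input_10x_dir,
    input_values_kind = cfg$input_values_kind %||% "counts",
    annotation_path = cfg$annotation_path,
    qc = qc_thresholds(cfg$qc$min_genes, cfg$qc$max_genes,
                       cfg$qc$max_mito_fraction),
    fdr_max = cfg$fdr_max, min_abs_log2fc = cfg$min_abs_log2fc,
    pseudocount = cfg$pseudocount, auc_min = cfg$auc_min,
    n_folds = cfg$n_folds, lambda_rule = cfg$lambda_rule,
    target_support = cfg$target_support,
    train_fraction = cfg$train_fraction, target_sum = cfg$target_sum,
    seed = cfg$seed
  )
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(run$deg, file.path(out_dir, "deg.tsv"))
  readr::write_tsv(run$roc, file.path(out_dir, "roc.tsv"))
  readr::write_tsv(
    tibble::tibble(lambda = run$cv$lambda,
                   cv_mean_deviance = run$cv$cv_mean_deviance,
                   cv_se = run$cv$cv_se, nonzero = run$cv$nonzero),
    file.path(out_dir, "path.tsv"))
  write_scms_model(run$model, file.path(out_dir, "model.json"))
  readr::write_tsv(run$scores, file.path(out_dir, "scores.tsv"))
  jsonlite::write_json(as.list(run$metrics),
                       file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
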