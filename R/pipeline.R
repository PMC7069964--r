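# End-to-end orchestration: cohort (simulated or loaded) -> network-based
# feature selection -> feature encoding -> unimodal + bimodal neural
# training and benchmarks -> evaluation at the 0.5 and Youden cutoffs ->
# survival analysis of the predicted risk groups. Cutoffs are derived on
# the validation split and frozen before touching the test split.

#' Pipeline configuration
#'
#' Exactly one of `simulate` (a [sim_config()]) or `paths` (a named list
#' with `expr`, `clinical`, `survival`, and optional `splits`,
#' `interactome`) must be given.
#'
#' @param simulate a [sim_config()] for a synthetic cohort, or `NULL`.
#' @param paths input file paths for a real cohort, or `NULL`.
#' @param k candidates per anchor in feature selection.
#' @param r_threshold network edge cutoff.
#' @param alpha survival-filter significance level.
#' @param literature_genes anchor biomarker symbols.
#' @param tspec a [train_spec()].
#' @param benchmarks benchmark kinds to train (subset of knn/rf/svm).
#' @param reclassify also evaluate at the Youden cutoff (default TRUE).
#' @param seed global seed, fanned out to the stages.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = sim_config(), paths = NULL,
                            k = 30L, r_threshold = 0.6, alpha = 0.01,
                            literature_genes = literature_biomarkers(),
                            tspec = train_spec(), benchmarks = "rf",
                            reclassify = TRUE, seed = 1L) {
  if (is.null(simulate) == is.null(paths)) {
    stopf("provide exactly one of 'simulate' or 'paths'")
  }
  structure(list(simulate = simulate, paths = paths, k = as.integer(k),
                 r_threshold = r_threshold, alpha = alpha,
                 literature_genes = literature_genes, tspec = tspec,
                 benchmarks = benchmarks, reclassify = isTRUE(reclassify),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_log <- function(run, name, t0) {
  elapsed <- as.numeric(proc.time()[3] - t0)
  message(sprintf("[prognet] stage %-18s %6.1fs", name, elapsed))
  c(run, stats::setNames(list(elapsed), name))
}

#' Run the full prognostic pipeline
#'
#' Executes all stages on one cohort and returns a run report holding the
#' cohort, the selected biomarker panel, the trained models, per-model
#' metrics at both cutoffs, risk-group survival analyses and a
#' reproducibility manifest. When `out_dir` is given, metrics, ROC curves,
#' KM curves and the manifest are also written there as plain-text files.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for artifacts.
#' @return object of class `prognet_run`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) stopf("config must be a pipeline_config")
  stages <- list()
  t0 <- proc.time()[3]

  # --- cohort ---------------------------------------------------------------
  bundle <- if (!is.null(config$simulate)) {
    assemble_cohort(config$simulate)
  } else {
    p <- config$paths
    load_cohort(p$expr, p$clinical, p$survival, p$splits %||% NULL,
                p$interactome %||% NULL)
  }
  if (is.null(bundle$splits)) {
    bundle$splits <- assign_splits(colnames(bundle$expression),
                                   seed = config$seed)
  }
  stages <- stage_log(stages, "cohort", t0)

  # --- feature selection ----------------------------------------------------
  panel <- run_feature_selection(bundle,
                                 literature_genes = config$literature_genes,
                                 k = config$k,
                                 r_threshold = config$r_threshold,
                                 alpha = config$alpha)
  stages <- stage_log(stages, "feature_selection", t0)

  # --- encoding and labels --------------------------------------------------
  ids_of <- function(s) bundle$splits$sample_id[bundle$splits$split == s]
  train_ids <- ids_of("train")
  val_ids <- ids_of("validation")
  test_ids <- ids_of("test")
  expr_block <- encode_expression(bundle$expression, panel, train_ids)
  clin_block <- encode_clinical(bundle$clinical, train_ids)
  labels <- five_year_label(bundle$survival)
  lab <- stats::setNames(as.integer(labels$label == "dead"), labels$sample_id)
  usable <- stats::setNames(labels$usable, labels$sample_id)
  use_ids <- function(ids) ids[usable[ids]]
  tr <- use_ids(train_ids)
  va <- use_ids(val_ids)
  te <- use_ids(test_ids)
  if (length(tr) == 0L || length(va) == 0L || length(te) == 0L) {
    stopf("a split has no usable five-year labels")
  }
  stages <- stage_log(stages, "encode", t0)

  # --- model training -------------------------------------------------------
  p_expr <- ncol(expr_block$values)
  p_clin <- ncol(clin_block$values)
  micro <- train_unimodal(
    build_network(branch_spec(p_expr, seed = config$seed)),
    block_rows(expr_block, tr), lab[tr],
    block_rows(expr_block, va), lab[va], config$tspec)
  clin <- train_unimodal(
    build_network(branch_spec(p_clin, hidden_widths = c(18, 18, 18, 18),
                              seed = config$seed + 1L)),
    block_rows(clin_block, tr), lab[tr],
    block_rows(clin_block, va), lab[va], config$tspec)
  bimodal <- train_bimodal(
    micro, clin,
    block_rows(expr_block, tr), block_rows(clin_block, tr), lab[tr],
    block_rows(expr_block, va), block_rows(clin_block, va), lab[va],
    config$tspec, seed = config$seed + 2L)
  models <- list(microarray_dnn = micro, clinical_dnn = clin,
                 bimodal_dnn = bimodal)
  comb_tr <- cbind(block_rows(expr_block, tr), block_rows(clin_block, tr))
  for (kind in config$benchmarks) {
    models[[paste0("combined_", kind)]] <-
      train_benchmark(kind, comb_tr, lab[tr], seed = config$seed + 3L)
  }
  stages <- stage_log(stages, "train", t0)

  # --- evaluation -----------------------------------------------------------
  score_for <- function(nm, ids) {
    model <- models[[nm]]
    if (inherits(model, "prognet_nn") && model$type == "bimodal") {
      predict_risk(model, list(micro = block_rows(expr_block, ids),
                               clinical = block_rows(clin_block, ids)))
    } else if (nm == "clinical_dnn") {
      predict_risk(model, block_rows(clin_block, ids))
    } else if (inherits(model, "prognet_nn")) {
      predict_risk(model, block_rows(expr_block, ids))
    } else {
      predict_risk(model, cbind(block_rows(expr_block, ids),
                                block_rows(clin_block, ids)))
    }
  }
  metrics <- list()
  cutoffs <- list()
  test_scores <- list()
  for (nm in names(models)) {
    s_val <- score_for(nm, va)
    s_test <- score_for(nm, te)
    test_scores[[nm]] <- s_test
    roc_test <- roc_and_auc(s_test, lab[te])
    cut <- if (config$reclassify) {
      youden_cutoff(roc_and_auc(s_val, lab[va]))
    } else {
      list(cutoff = 0.5, youden_j = NA_real_)
    }
    cutoffs[[nm]] <- cut
    for (cc in unique(c(0.5, cut$cutoff))) {
      m <- classification_metrics(classify_at(s_test, cc), lab[te])
      metrics[[length(metrics) + 1L]] <- data.frame(
        model = nm,
        cutoff_type = if (cc == 0.5) "original" else "youden",
        cutoff = cc, auc = roc_test$auc, accuracy = m$accuracy,
        precision = m$precision, recall = m$recall, f1 = m$f1,
        stringsAsFactors = FALSE)
    }
    if (config$reclassify && cut$cutoff == 0.5) {
      # Youden cutoff coincides with 0.5: duplicate the row for a stable shape
      m <- classification_metrics(classify_at(s_test, 0.5), lab[te])
      metrics[[length(metrics) + 1L]] <- data.frame(
        model = nm, cutoff_type = "youden", cutoff = 0.5,
        auc = roc_test$auc, accuracy = m$accuracy, precision = m$precision,
        recall = m$recall, f1 = m$f1, stringsAsFactors = FALSE)
    }
  }
  metrics <- do.call(rbind, metrics)
  stages <- stage_log(stages, "evaluate", t0)

  # --- survival analysis ----------------------------------------------------
  surv_test <- bundle$survival[bundle$survival$sample_id %in% test_ids, ]
  survival_results <- list()
  for (nm in names(models)) {
    s_full <- score_for(nm, surv_test$sample_id)
    for (ct in if (config$reclassify) c("original", "youden") else "original") {
      cc <- if (ct == "original") 0.5 else cutoffs[[nm]]$cutoff
      survival_results[[paste(nm, ct, sep = ".")]] <-
        risk_group_survival(s_full, cc, surv_test)
    }
  }
  stages <- stage_log(stages, "survival", t0)

  manifest <- list(
    package_version = as.character(utils::packageVersion("prognet")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    stages = names(stages),
    stage_seconds = stages,
    n_samples = ncol(bundle$expression),
    n_usable = c(train = length(tr), validation = length(va),
                 test = length(te)),
    panel = panel$combined
  )
  run <- structure(
    list(config = config, bundle = bundle, panel = panel, models = models,
         cutoffs = cutoffs, metrics = metrics, test_scores = test_scores,
         survival = survival_results, manifest = manifest,
         labels = labels),
    class = "prognet_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# Write the plain-text artifacts of a run.
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(metrics = run$metrics,
         cutoffs = lapply(run$cutoffs, function(x) x["cutoff"]),
         hazard_ratios = lapply(run$survival, function(s) {
           if (isTRUE(s$degenerate)) return(NULL)
           list(hr = s$cox$hr, ci_lower = s$cox$ci_lower,
                ci_upper = s$cox$ci_upper, logrank_p = s$logrank$p_value)
         })),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (nm in names(run$survival)) {
    s <- run$survival[[nm]]
    if (isTRUE(s$degenerate)) next
    km <- rbind(cbind(group = "high", s$km_high),
                cbind(group = "low", s$km_low))
    utils::write.table(km,
                       file.path(out_dir, paste0("km_", gsub("[^A-Za-z0-9_.]", "_", nm), ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}

#' Summarize a pipeline run
#'
#' @param run a `prognet_run`.
#' @return data.frame: one row per model x cutoff with AUC, accuracy,
#'   precision, recall, F1 and (where available) the risk-group hazard
#'   ratio and log-rank p-value.
#' @export
report_summary <- function(run) {
  if (!inherits(run, "prognet_run")) stopf("run must be a prognet_run")
  out <- run$metrics
  out$hr <- NA_real_
  out$logrank_p <- NA_real_
  for (i in seq_len(nrow(out))) {
    key <- paste(out$model[i], out$cutoff_type[i], sep = ".")
    s <- run$survival[[key]]
    if (!is.null(s) && !isTRUE(s$degenerate)) {
      out$hr[i] <- s$cox$hr
      out$logrank_p[i] <- s$logrank$p_value
    }
  }
  out
}

#' @export
print.prognet_run <- function(x, ...) {
  cat("prognet pipeline run\n")
  print(x$panel)
  cat("\nTest-set performance:\n")
  print(format(report_summary(x), digits = 4), row.names = FALSE)
  invisible(x)
}
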