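# Cohort container, file I/O, validation and feature encoding.
#
# File dialects: expression as TSV (genes in rows, first column gene_id,
# header row of sample IDs); clinical and survival as CSV; interactome as
# 2- or 3-column TSV (gene_a, gene_b[, weight]); splits as CSV
# (sample_id, split); ground truth as a JSON sidecar. UTF-8, '.' decimal.

#' Construct and validate a cohort bundle
#'
#' Checks that expression, clinical, survival and split components cover
#' exactly the same sample IDs, that categorical fields use the supported
#' enumerations, and that all expression values are finite.
#'
#' @param expression numeric genes x samples matrix with dimnames.
#' @param clinical data.frame: sample_id, age, sex, stage.
#' @param survival data.frame: sample_id, time_months, event.
#' @param splits data.frame: sample_id, split; or `NULL`.
#' @param interactome optional data.frame: gene_a, gene_b (and weight).
#' @param truth optional ground-truth list (synthetic cohorts).
#' @return object of class `cohort_bundle`.
#' @export
new_cohort_bundle <- function(expression, clinical, survival, splits = NULL,
                              interactome = NULL, truth = NULL) {
  validate_expression(expression)
  validate_clinical(clinical)
  validate_survival(survival)
  ids <- colnames(expression)
  for (comp in list(clinical = clinical, survival = survival)) {
    if (!setequal(comp$sample_id, ids)) {
      stopf("sample IDs differ between expression and a tabular component")
    }
  }
  clinical <- clinical[match(ids, clinical$sample_id), , drop = FALSE]
  survival <- survival[match(ids, survival$sample_id), , drop = FALSE]
  rownames(clinical) <- rownames(survival) <- NULL
  if (!is.null(splits)) {
    if (!setequal(splits$sample_id, ids)) {
      stopf("split assignment does not cover exactly the cohort samples")
    }
    if (anyDuplicated(splits$sample_id)) {
      stopf("a sample appears in more than one split")
    }
    splits <- splits[match(ids, splits$sample_id), , drop = FALSE]
    splits$split <- factor(as.character(splits$split),
                           levels = c("train", "validation", "test"))
    if (anyNA(splits$split)) stopf("unknown split label; use train/validation/test")
    rownames(splits) <- NULL
  }
  if (!is.null(interactome)) interactome <- canonical_interactome(interactome)
  structure(
    list(expression = expression, clinical = clinical, survival = survival,
         splits = splits, interactome = interactome, truth = truth),
    class = "cohort_bundle"
  )
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("Cohort bundle: %d genes x %d samples\n",
              nrow(x$expression), ncol(x$expression)))
  if (!is.null(x$splits)) {
    tb <- table(x$splits$split)
    cat(sprintf("  splits: train %d / validation %d / test %d\n",
                tb[["train"]], tb[["validation"]], tb[["test"]]))
  }
  cat(sprintf("  events observed: %d of %d\n",
              sum(x$survival$event), nrow(x$survival)))
  if (!is.null(x$interactome)) {
    cat(sprintf("  interactome: %d edges\n", nrow(x$interactome)))
  }
  if (!is.null(x$truth)) cat("  ground truth attached (synthetic cohort)\n")
  invisible(x)
}

validate_expression <- function(expression) {
  if (!is.matrix(expression) || !is.numeric(expression)) {
    stopf("expression must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(expression)) || is.null(colnames(expression))) {
    stopf("expression needs gene row names and sample column names")
  }
  if (anyDuplicated(rownames(expression))) {
    stopf("duplicate gene symbols in expression matrix")
  }
  if (anyDuplicated(colnames(expression))) {
    stopf("duplicate sample IDs in expression matrix")
  }
  if (any(!is.finite(expression))) {
    stopf("expression contains missing or non-finite values")
  }
  invisible(expression)
}

validate_clinical <- function(clinical) {
  need <- c("sample_id", "age", "sex", "stage")
  if (!all(need %in% names(clinical))) {
    stopf("clinical table needs columns: %s", paste(need, collapse = ", "))
  }
  bad <- which(!clinical$sex %in% c("male", "female"))
  if (length(bad)) {
    stopf("clinical row %d (sample %s): sex '%s' not in {male, female}",
          bad[1], clinical$sample_id[bad[1]], clinical$sex[bad[1]])
  }
  bad <- which(!clinical$stage %in% stage_levels())
  if (length(bad)) {
    stopf("clinical row %d (sample %s): stage '%s' not in {%s}",
          bad[1], clinical$sample_id[bad[1]], clinical$stage[bad[1]],
          paste(stage_levels(), collapse = ", "))
  }
  bad <- which(!is.finite(clinical$age) | clinical$age < 0 | clinical$age > 120)
  if (length(bad)) {
    stopf("clinical row %d (sample %s): age %s outside [0, 120]",
          bad[1], clinical$sample_id[bad[1]], clinical$age[bad[1]])
  }
  invisible(clinical)
}

validate_survival <- function(survival) {
  need <- c("sample_id", "time_months", "event")
  if (!all(need %in% names(survival))) {
    stopf("survival table needs columns: %s", paste(need, collapse = ", "))
  }
  if (any(!is.finite(survival$time_months) | survival$time_months < 0)) {
    stopf("survival times must be non-negative and finite")
  }
  if (!all(survival$event %in% c(0L, 1L))) {
    stopf("event flags must be 0 (censored) or 1 (death)")
  }
  invisible(survival)
}

canonical_interactome <- function(interactome) {
  need <- c("gene_a", "gene_b")
  if (!all(need %in% names(interactome))) {
    stopf("interactome needs columns gene_a, gene_b")
  }
  a <- pmin(interactome$gene_a, interactome$gene_b)
  b <- pmax(interactome$gene_a, interactome$gene_b)
  keep <- a != b # drop self-loops
  out <- data.frame(gene_a = a[keep], gene_b = b[keep],
                    stringsAsFactors = FALSE)
  if ("weight" %in% names(interactome)) {
    w <- interactome$weight[keep]
    if (any(!is.finite(w) | w < 0 | w > 1)) {
      stopf("interactome weights must lie in [0, 1]")
    }
    out$weight <- w
  }
  out[!duplicated(pair_key(out$gene_a, out$gene_b)), , drop = FALSE]
}

#' Write a cohort bundle to a directory
#'
#' @param bundle a `cohort_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr_df <- data.frame(gene_id = rownames(bundle$expression),
                        bundle$expression, check.names = FALSE,
                        stringsAsFactors = FALSE)
  utils::write.table(expr_df, file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(bundle$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(bundle$survival, file.path(dir, "survival.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(bundle$splits)) {
    utils::write.csv(bundle$splits, file.path(dir, "splits.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  if (!is.null(bundle$interactome)) {
    utils::write.table(bundle$interactome, file.path(dir, "interactome.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bundle$truth)) {
    truth <- bundle$truth
    truth$true_log_hr <- as.list(truth$true_log_hr)
    truth$true_biomarker_thresholds <- as.list(truth$true_biomarker_thresholds)
    truth$subtype <- as.list(truth$subtype)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a reference interactome edge list
#'
#' @param path TSV file with columns gene_a, gene_b and optional weight.
#' @return canonicalized data.frame of unique undirected pairs.
#' @export
read_interactome <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  canonical_interactome(tab)
}

#' Load a cohort from files
#'
#' Reads the expression/clinical/survival (and optional splits and
#' interactome) files, validates each component, drops samples missing any
#' clinical field (with a message), and aligns everything on the
#' intersection of sample IDs.
#'
#' @param expr_path expression TSV (genes in rows, first column gene_id).
#' @param clinical_path clinical CSV.
#' @param survival_path survival CSV.
#' @param splits_path optional splits CSV.
#' @param interactome_path optional interactome TSV.
#' @return a `cohort_bundle`.
#' @export
load_cohort <- function(expr_path, clinical_path, survival_path,
                        splits_path = NULL, interactome_path = NULL) {
  expr_df <- utils::read.delim(expr_path, check.names = FALSE,
                               stringsAsFactors = FALSE)
  if (names(expr_df)[1] != "gene_id") {
    stopf("expression file must have 'gene_id' as its first column")
  }
  expression <- as.matrix(expr_df[, -1, drop = FALSE])
  rownames(expression) <- expr_df$gene_id
  storage.mode(expression) <- "double"
  validate_expression(expression)

  clinical <- utils::read.csv(clinical_path, stringsAsFactors = FALSE)
  incomplete <- !stats::complete.cases(
    clinical[, intersect(c("sample_id", "age", "sex", "stage"),
                         names(clinical)), drop = FALSE])
  if (any(incomplete)) {
    message(sprintf("dropping %d sample(s) with incomplete clinical data",
                    sum(incomplete)))
    clinical <- clinical[!incomplete, , drop = FALSE]
  }
  validate_clinical(clinical)
  survival <- utils::read.csv(survival_path, stringsAsFactors = FALSE)
  validate_survival(survival)

  ids <- intersect(colnames(expression), clinical$sample_id)
  ids <- intersect(ids, survival$sample_id)
  splits <- NULL
  if (!is.null(splits_path)) {
    splits <- utils::read.csv(splits_path, stringsAsFactors = FALSE)
    ids <- intersect(ids, splits$sample_id)
  }
  if (length(ids) == 0L) stopf("no sample IDs shared by all components")

  expression <- expression[, ids, drop = FALSE]
  clinical <- clinical[match(ids, clinical$sample_id), , drop = FALSE]
  survival <- survival[match(ids, survival$sample_id), , drop = FALSE]
  if (!is.null(splits)) {
    splits <- splits[match(ids, splits$sample_id), , drop = FALSE]
  }
  interactome <- if (!is.null(interactome_path)) {
    read_interactome(interactome_path)
  }
  new_cohort_bundle(expression, clinical, survival, splits, interactome)
}

# ---------------------------------------------------------------------------
# Feature blocks

#' Construct a feature block
#'
#' A feature block is a samples x features numeric matrix together with
#' per-feature centering/scaling statistics learned on the training split
#' only (population SD, divisor n). Constant training columns are flagged
#' and given scale 1 so they pass through unchanged.
#'
#' @param values samples x features numeric matrix (row names = sample IDs).
#' @param center,scale per-feature statistics (scale 1 / center 0 leaves a
#'   column untouched).
#' @param constant logical flags for constant training columns.
#' @return object of class `feature_block`.
#' @keywords internal
new_feature_block <- function(values, center, scale, constant) {
  structure(
    list(sample_ids = rownames(values), feature_names = colnames(values),
         values = sweep(sweep(values, 2, center, "-"), 2, scale, "/"),
         scaler_stats = data.frame(feature = colnames(values),
                                   center = center, scale = scale,
                                   constant = constant)),
    class = "feature_block"
  )
}

#' Encode clinical covariates as model features
#'
#' Produces 7 columns: age z-scored with training-split mean and population
#' SD, sex as 0/1 (male = 1), and a one-hot encoding of the five tumour
#' stage categories.
#'
#' @param clinical clinical data.frame (sample_id, age, sex, stage).
#' @param train_ids sample IDs of the training split (scaler fitted here).
#' @return a `feature_block` over all samples in `clinical`.
#' @export
encode_clinical <- function(clinical, train_ids) {
  validate_clinical(clinical)
  if (length(train_ids) == 0L) stopf("train_ids must be non-empty")
  if (!all(train_ids %in% clinical$sample_id)) {
    stopf("train_ids not all present in the clinical table")
  }
  stage_cols <- paste0("stage_", gsub("/", ".", stage_levels()))
  onehot <- matrix(0, nrow(clinical), length(stage_levels()),
                   dimnames = list(clinical$sample_id, stage_cols))
  onehot[cbind(seq_len(nrow(clinical)),
               match(clinical$stage, stage_levels()))] <- 1
  values <- cbind(
    age = clinical$age,
    sex_male = as.numeric(clinical$sex == "male"),
    onehot
  )
  rownames(values) <- clinical$sample_id
  tr <- values[clinical$sample_id %in% train_ids, , drop = FALSE]
  center <- c(mean(tr[, "age"]), rep(0, ncol(values) - 1L))
  s_age <- pop_sd(tr[, "age"])
  constant <- apply(tr, 2, function(x) pop_sd(x) == 0)
  scale <- c(if (s_age > 0) s_age else 1, rep(1, ncol(values) - 1L))
  new_feature_block(values, center, scale, constant)
}

#' Encode panel gene expression as model features
#'
#' One column per panel gene, z-scored with training-split mean and
#' population SD; constant training columns are flagged and left unscaled.
#'
#' @param expression genes x samples matrix.
#' @param panel a [biomarker_panel()] or character vector of gene symbols.
#' @param train_ids sample IDs of the training split.
#' @return a `feature_block` over all samples.
#' @export
encode_expression <- function(expression, panel, train_ids) {
  genes <- if (inherits(panel, "biomarker_panel")) panel$combined else panel
  missing <- setdiff(genes, rownames(expression))
  if (length(missing)) {
    stopf("panel genes missing from expression matrix: %s",
          paste(missing, collapse = ", "))
  }
  if (length(train_ids) == 0L) stopf("train_ids must be non-empty")
  if (!all(train_ids %in% colnames(expression))) {
    stopf("train_ids not all present in the expression matrix")
  }
  values <- t(expression[genes, , drop = FALSE])
  tr <- values[rownames(values) %in% train_ids, , drop = FALSE]
  center <- colMeans(tr)
  sds <- apply(tr, 2, pop_sd)
  constant <- sds == 0
  scale <- ifelse(constant, 1, sds)
  center[constant] <- 0
  new_feature_block(values, center, scale, constant)
}

#' Extract feature-block rows for a set of samples
#'
#' @param block a `feature_block`.
#' @param ids sample IDs; the returned matrix follows this order.
#' @return numeric matrix of scaled feature values.
#' @export
block_rows <- function(block, ids) {
  idx <- match(ids, block$sample_ids)
  if (anyNA(idx)) stopf("feature block is missing requested samples")
  block$values[idx, , drop = FALSE]
}
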