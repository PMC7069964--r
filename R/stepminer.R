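# StepMiner: adaptive dichotomization of a gene's expression profile.
#
# A one-step (rising) function is fitted to the sorted expression values:
# every split position k partitions the sorted vector into a low block
# (values 1..k) and a high block (values k+1..n), each approximated by its
# mean.  The split minimizing the residual sum of squares defines the
# threshold, taken as the midpoint of the two block means.  Patients above
# the threshold are biomarker+, the rest biomarker-.

#' Fit a one-step function to an expression vector
#'
#' Sorts `values` ascending and finds the split position `k` (1..n-1)
#' minimizing the step-fit sum of squared errors
#' \deqn{SSE(k) = \sum_{i \le k} (v_i - \bar v_{low})^2 +
#'               \sum_{i > k} (v_i - \bar v_{high})^2.}
#' Ties in SSE are broken toward the smallest `k`. The dichotomization
#' threshold is the midpoint of the low and high block means. A constant
#' vector has no valid step and is flagged degenerate.
#'
#' @param values numeric vector of expression values, length >= 2, finite.
#' @param gene_id optional gene symbol carried through to the result.
#' @return an object of class `step_fit`: a list with elements `gene_id`,
#'   `threshold`, `split_index`, `low_mean`, `high_mean`, `sse`,
#'   `degenerate`.
#' @examples
#' fit_step(c(1, 1, 1, 5, 5))
#' @export
fit_step <- function(values, gene_id = NA_character_) {
  if (!is.numeric(values) || length(values) < 2) {
    stopf("fit_step() needs a numeric vector of length >= 2")
  }
  if (any(!is.finite(values))) {
    stopf("fit_step() requires finite values (gene %s)", gene_id)
  }
  v <- sort(values)
  n <- length(v)
  if (v[1] == v[n]) {
    return(structure(
      list(gene_id = gene_id, threshold = NA_real_, split_index = NA_integer_,
           low_mean = v[1], high_mean = v[1], sse = 0, degenerate = TRUE),
      class = "step_fit"
    ))
  }
  # SSE(k) decomposes into prefix/suffix sums of squares minus block-mean
  # corrections; vectorized over all n-1 candidate splits.
  k <- seq_len(n - 1L)
  cs <- cumsum(v)
  cs2 <- cumsum(v^2)
  tot <- cs[n]
  tot2 <- cs2[n]
  sse_low <- cs2[k] - cs[k]^2 / k
  sse_high <- (tot2 - cs2[k]) - (tot - cs[k])^2 / (n - k)
  sse <- sse_low + sse_high
  # smallest split index among numerically tied minima (the prefix-sum
  # decomposition carries ~1e-15 relative noise, so exact ties are compared
  # with a scale-aware tolerance)
  tol <- 1e-9 * max(1, tot2)
  best <- which(sse <= min(sse) + tol)[1]
  low_mean <- cs[best] / best
  high_mean <- (tot - cs[best]) / (n - best)
  structure(
    list(
      gene_id = gene_id,
      threshold = (low_mean + high_mean) / 2,
      split_index = as.integer(best),
      low_mean = low_mean,
      high_mean = high_mean,
      sse = max(sse[best], 0),
      degenerate = FALSE
    ),
    class = "step_fit"
  )
}

#' @export
print.step_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("StepMiner fit (degenerate: constant values)\n")
  } else {
    cat(sprintf(
      "StepMiner fit%s: threshold %.4f (low mean %.4f, high mean %.4f, split %d, SSE %.4g)\n",
      if (is.na(x$gene_id)) "" else paste0(" for ", x$gene_id),
      x$threshold, x$low_mean, x$high_mean, x$split_index, x$sse
    ))
  }
  invisible(x)
}

#' Dichotomize patients by a biomarker gene
#'
#' Fits a step function to the gene's expression across all samples and
#' labels each sample `"biomarker+"` when its value is strictly greater
#' than the threshold, `"biomarker-"` otherwise. Both subgroups are
#' non-empty by construction of the optimal split.
#'
#' @param expression numeric matrix, genes x samples, with gene symbols as
#'   row names and sample IDs as column names.
#' @param gene_id gene symbol present in `expression`.
#' @return named character vector of labels (`"biomarker-"` /
#'   `"biomarker+"`), one per sample, with the `step_fit` attached as
#'   attribute `"fit"`.
#' @export
dichotomize <- function(expression, gene_id) {
  if (!gene_id %in% rownames(expression)) {
    stopf("gene %s not present in the expression matrix", gene_id)
  }
  v <- expression[gene_id, ]
  fit <- fit_step(v, gene_id = gene_id)
  if (fit$degenerate) {
    stopf("StepMiner fit for %s is degenerate (constant expression); drop this biomarker",
          gene_id)
  }
  labels <- ifelse(v > fit$threshold, "biomarker+", "biomarker-")
  names(labels) <- colnames(expression)
  attr(labels, "fit") <- fit
  labels
}
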