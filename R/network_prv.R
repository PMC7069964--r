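# Subgroup interaction networks, prognosis relevance values (PRV), and the
# overlap + survival-filter feature selection.
#
# For each anchor biomarker, patients are dichotomized by StepMiner and a
# co-expression network is built inside each subgroup: an interactome pair
# becomes an edge when the absolute within-subgroup Pearson correlation
# reaches a threshold, weighted by |r|. A gene's PRV is the weighted
# symmetric-difference degree between the biomarker+ and biomarker-
# networks: the sum over its interactome pairs of |w+ - w-| with absent
# edges weighted 0. Genes ranked high for every anchor and significant in a
# log-rank survival test form the novel biomarker list.

#' Build a subgroup co-expression interaction network
#'
#' For every interactome pair with both genes measured, computes the
#' Pearson correlation across the given samples and keeps the pair as an
#' edge when `|r| >= r_threshold`, with weight `|r|`. Pairs involving a
#' zero-variance gene are excluded (with a message).
#'
#' @param expression genes x samples matrix.
#' @param sample_subset sample IDs defining the subgroup (>= 3).
#' @param interactome data.frame gene_a/gene_b (canonicalized internally).
#' @param r_threshold absolute-correlation cutoff in (0, 1).
#' @param label optional subgroup label (e.g. "biomarker+").
#' @param anchor optional anchoring biomarker symbol.
#' @return object of class `interaction_network`: list with `anchor`,
#'   `label`, `nodes`, `edges` (gene_a, gene_b, weight).
#' @export
build_subgroup_network <- function(expression, sample_subset, interactome,
                                   r_threshold = 0.6, label = NA_character_,
                                   anchor = NA_character_) {
  if (length(sample_subset) < 3L) {
    stopf("subgroup has %d samples; need at least 3 for correlations",
          length(sample_subset))
  }
  if (!(r_threshold > 0 && r_threshold < 1)) {
    stopf("r_threshold must lie in (0, 1)")
  }
  if (!all(sample_subset %in% colnames(expression))) {
    stopf("sample_subset contains samples absent from the expression matrix")
  }
  inter <- canonical_interactome(interactome)
  measured <- inter$gene_a %in% rownames(expression) &
    inter$gene_b %in% rownames(expression)
  inter <- inter[measured, , drop = FALSE]
  sub <- expression[, sample_subset, drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  flat <- names(sds)[sds == 0]
  if (length(flat)) {
    message(sprintf("excluding edges of %d zero-variance gene(s) in subgroup %s",
                    length(flat), label))
  }
  usable <- !(inter$gene_a %in% flat) & !(inter$gene_b %in% flat)
  inter <- inter[usable, , drop = FALSE]
  r <- vapply(seq_len(nrow(inter)), function(i) {
    stats::cor(sub[inter$gene_a[i], ], sub[inter$gene_b[i], ])
  }, numeric(1))
  keep <- abs(r) >= r_threshold
  structure(
    list(
      anchor = anchor, label = label, nodes = rownames(expression),
      n_samples = length(sample_subset),
      edges = data.frame(gene_a = inter$gene_a[keep],
                         gene_b = inter$gene_b[keep],
                         weight = abs(r[keep]), stringsAsFactors = FALSE)
    ),
    class = "interaction_network"
  )
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("Interaction network (%s%s): %d nodes, %d edges, %d samples\n",
              if (is.na(x$anchor)) "" else paste0(x$anchor, " "),
              x$label, length(x$nodes), nrow(x$edges), x$n_samples))
  invisible(x)
}

#' Compute prognosis relevance values from a network pair
#'
#' PRV(g) is the weighted symmetric-difference degree of `g` between the
#' biomarker+ and biomarker- networks: the sum over undirected pairs
#' involving `g` of the absolute edge-weight difference, where a pair
#' absent from a network has weight 0. Genes are ranked by descending PRV,
#' ties broken lexicographically by symbol.
#'
#' @param net_plus,net_minus `interaction_network` objects over the same
#'   node universe.
#' @return object of class `prv_table`: data.frame with columns `gene`,
#'   `prv`, `rank`, plus attribute `anchor`.
#' @export
compute_prv <- function(net_plus, net_minus) {
  if (!setequal(net_plus$nodes, net_minus$nodes)) {
    stopf("the two networks must share the same node universe")
  }
  w <- function(net) {
    stats::setNames(net$edges$weight,
                    pair_key(net$edges$gene_a, net$edges$gene_b))
  }
  wp <- w(net_plus)
  wm <- w(net_minus)
  keys <- union(names(wp), names(wm))
  dw <- abs(ifelse(keys %in% names(wp), wp[keys], 0) -
              ifelse(keys %in% names(wm), wm[keys], 0))
  prv <- stats::setNames(rep(0, length(net_plus$nodes)),
                         sort(net_plus$nodes))
  if (length(keys)) {
    parts <- strsplit(keys, "|", fixed = TRUE)
    for (i in seq_along(keys)) {
      prv[parts[[i]][1]] <- prv[parts[[i]][1]] + dw[i]
      prv[parts[[i]][2]] <- prv[parts[[i]][2]] + dw[i]
    }
  }
  ord <- order(-prv, names(prv))
  out <- data.frame(gene = names(prv)[ord], prv = unname(prv[ord]),
                    rank = seq_along(prv), stringsAsFactors = FALSE)
  attr(out, "anchor") <- net_plus$anchor
  class(out) <- c("prv_table", "data.frame")
  out
}

#' Select top-ranked candidate genes from a PRV table
#'
#' The anchoring biomarker itself is removed before ranking so it cannot
#' select itself; the remaining genes are ordered by descending PRV (ties
#' lexicographic) and at most the first `k` are returned. By default only
#' genes with a strictly positive PRV are candidates — a gene whose
#' incident edges are identical in the two subgroup networks shows no
#' network difference and carries no evidence; `include_zero = TRUE`
#' restores the plain top-k behaviour.
#'
#' @param prv a `prv_table`.
#' @param k maximum number of candidates (default 30).
#' @param anchor anchoring biomarker symbol to exclude (defaults to the
#'   table's anchor attribute).
#' @param include_zero keep zero-PRV genes as candidates (default FALSE).
#' @return character vector of up to `k` gene symbols.
#' @export
select_candidates <- function(prv, k = 30L, anchor = attr(prv, "anchor"),
                              include_zero = FALSE) {
  tab <- prv[!(prv$gene %in% anchor), , drop = FALSE]
  if (!include_zero) tab <- tab[tab$prv > 0, , drop = FALSE]
  tab <- tab[order(-tab$prv, tab$gene), , drop = FALSE]
  tab$gene[seq_len(min(k, nrow(tab)))]
}

#' Intersect candidate lists across anchors
#'
#' @param candidate_lists list of character vectors (one per anchor).
#' @return character vector: genes present in every list, sorted.
#' @export
intersect_lists <- function(candidate_lists) {
  if (length(candidate_lists) == 0L) stopf("need at least one candidate list")
  sort(Reduce(intersect, candidate_lists))
}

#' Filter candidate genes by survival significance
#'
#' Each gene is dichotomized by its own StepMiner threshold and the two
#' subgroups are compared with a log-rank test; genes with p < `alpha`
#' (raw, no multiplicity correction) are retained. Genes with degenerate
#' step fits are dropped with a message. `method = "cox"` uses the Wald
#' p-value of a univariate Cox fit on the same dichotomy instead.
#'
#' @param genes candidate gene symbols.
#' @param expression genes x samples matrix.
#' @param survival survival data.frame (sample_id, time_months, event)
#'   aligned to the expression columns.
#' @param alpha significance level (default 0.01).
#' @param method "logrank" (default) or "cox".
#' @return character vector of retained genes (input order).
#' @export
survival_filter <- function(genes, expression, survival, alpha = 0.01,
                            method = c("logrank", "cox")) {
  method <- match.arg(method)
  if (!setequal(survival$sample_id, colnames(expression))) {
    stopf("survival table and expression matrix cover different samples")
  }
  survival <- survival[match(colnames(expression), survival$sample_id), ]
  keep <- logical(length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    fit <- fit_step(expression[g, ], gene_id = g)
    if (fit$degenerate) {
      message(sprintf("dropping %s: degenerate StepMiner fit", g))
      next
    }
    grp <- expression[g, ] > fit$threshold
    p <- if (method == "logrank") {
      logrank(survival$time_months, survival$event, grp)$p_value
    } else {
      cox_univariate(grp, survival$time_months, survival$event)$p_value
    }
    keep[i] <- is.finite(p) && p < alpha
  }
  genes[keep]
}

#' Assemble a biomarker panel
#'
#' @param literature_genes ordered literature biomarker symbols.
#' @param novel_genes ordered novel biomarker symbols (disjoint from the
#'   literature list).
#' @return object of class `biomarker_panel`: list with `literature_genes`,
#'   `novel_genes`, `combined`.
#' @export
biomarker_panel <- function(literature_genes, novel_genes = character(0)) {
  if (length(intersect(literature_genes, novel_genes))) {
    stopf("literature and novel gene lists must be disjoint")
  }
  structure(
    list(literature_genes = as.character(literature_genes),
         novel_genes = as.character(novel_genes),
         combined = c(as.character(literature_genes),
                      as.character(novel_genes))),
    class = "biomarker_panel"
  )
}

#' @export
print.biomarker_panel <- function(x, ...) {
  cat(sprintf("Biomarker panel: %d genes (%d literature + %d novel)\n",
              length(x$combined), length(x$literature_genes),
              length(x$novel_genes)))
  cat("  literature:", paste(x$literature_genes, collapse = ", "), "\n")
  if (length(x$novel_genes)) {
    cat("  novel:     ", paste(x$novel_genes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Run the full network-based feature selection
#'
#' For every literature anchor: dichotomize patients with StepMiner, build
#' the biomarker+ and biomarker- co-expression networks restricted to the
#' interactome, compute PRVs and keep the top `k` candidates. Candidates
#' appearing for every anchor are then filtered by survival significance;
#' survivors become the novel biomarker list of the returned panel.
#'
#' @param bundle a `cohort_bundle`.
#' @param interactome edge list (defaults to the bundle's interactome).
#' @param literature_genes anchor biomarkers (default
#'   [literature_biomarkers()]).
#' @param k candidates per anchor (default 30).
#' @param r_threshold network edge cutoff (default 0.6).
#' @param alpha survival-filter significance level (default 0.01).
#' @param filter_method "logrank" (default) or "cox".
#' @return a `biomarker_panel` with attributes `prv_tables` (per anchor)
#'   and `overlap` (the pre-filter intersection).
#' @export
run_feature_selection <- function(bundle, interactome = bundle$interactome,
                                  literature_genes = literature_biomarkers(),
                                  k = 30L, r_threshold = 0.6, alpha = 0.01,
                                  filter_method = c("logrank", "cox")) {
  filter_method <- match.arg(filter_method)
  if (is.null(interactome)) stopf("no interactome available")
  expr <- bundle$expression
  missing <- setdiff(literature_genes, rownames(expr))
  if (length(missing)) {
    stopf("literature genes missing from expression matrix: %s",
          paste(missing, collapse = ", "))
  }
  prv_tables <- list()
  candidates <- list()
  for (g in literature_genes) {
    labels <- dichotomize(expr, g)
    plus_ids <- names(labels)[labels == "biomarker+"]
    minus_ids <- names(labels)[labels == "biomarker-"]
    net_plus <- build_subgroup_network(expr, plus_ids, interactome,
                                       r_threshold, "biomarker+", g)
    net_minus <- build_subgroup_network(expr, minus_ids, interactome,
                                        r_threshold, "biomarker-", g)
    prv <- compute_prv(net_plus, net_minus)
    prv_tables[[g]] <- prv
    candidates[[g]] <- select_candidates(prv, k = k, anchor = g)
  }
  overlap <- intersect_lists(candidates)
  overlap <- setdiff(overlap, literature_genes)
  if (length(overlap) == 0L) {
    warnf("candidate lists have an empty overlap; panel contains only literature genes")
    novel <- character(0)
  } else {
    novel <- survival_filter(overlap, expr, bundle$survival, alpha,
                             method = filter_method)
  }
  panel <- biomarker_panel(literature_genes, novel)
  attr(panel, "prv_tables") <- prv_tables
  attr(panel, "overlap") <- overlap
  panel
}
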