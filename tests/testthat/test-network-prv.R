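# Subgroup networks, PRV computation and the feature-selection chain.

toy_expr <- function(mat, samples = NULL) {
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(mat)))
  colnames(mat) <- samples
  mat
}

test_that("subgroup networks apply the correlation threshold and interactome mask", {
  set.seed(3)
  n <- 40
  x <- rnorm(n)
  expr <- toy_expr(rbind(
    A = x,
    B = 2 * x + rnorm(n, sd = 1e-6),   # r -> 1 with A
    C = rnorm(n),
    D = 2 * x + rnorm(n, sd = 1e-6)    # correlated with A but NOT in interactome
  ))
  inter <- data.frame(gene_a = c("A", "A"), gene_b = c("B", "C"))
  net <- build_subgroup_network(expr, colnames(expr), inter, r_threshold = 0.6)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$gene_a, "A")
  expect_equal(net$edges$gene_b, "B")
  expect_gt(net$edges$weight, 0.99)
})

test_that("edge inclusion matches a hand Pearson computation", {
  expr <- toy_expr(rbind(X = c(1, 2, 3), Y = c(1, 2, 4)))
  inter <- data.frame(gene_a = "X", gene_b = "Y")
  r <- cor(c(1, 2, 3), c(1, 2, 4))
  expect_equal(r, 0.9820, tolerance = 1e-4)
  net_lo <- build_subgroup_network(expr, colnames(expr), inter, r_threshold = 0.6)
  expect_equal(nrow(net_lo$edges), 1L)
  expect_equal(net_lo$edges$weight, r, tolerance = 1e-12)
  net_hi <- build_subgroup_network(expr, colnames(expr), inter, r_threshold = 0.99)
  expect_equal(nrow(net_hi$edges), 0L)
})

test_that("degenerate subgroups are rejected and flat genes excluded", {
  expr <- toy_expr(rbind(A = c(1, 2, 3, 4), B = c(2, 2, 2, 2)))
  inter <- data.frame(gene_a = "A", gene_b = "B")
  expect_error(build_subgroup_network(expr, colnames(expr)[1:2], inter),
               "at least 3")
  expect_message(
    net <- build_subgroup_network(expr, colnames(expr), inter,
                                  label = "biomarker-"),
    "zero-variance")
  expect_equal(nrow(net$edges), 0L)
})

make_net <- function(edges, nodes, label = "biomarker+", anchor = "ANCH") {
  structure(list(anchor = anchor, label = label, nodes = nodes,
                 n_samples = 10L, edges = edges),
            class = "interaction_network")
}

test_that("PRV is the weighted symmetric-difference degree", {
  nodes <- c("g", "a", "b", "ANCH")
  plus <- make_net(data.frame(gene_a = c("a", "b"), gene_b = c("g", "g"),
                              weight = c(1.0, 0.8)), nodes)
  minus <- make_net(data.frame(gene_a = "a", gene_b = "g", weight = 1.0),
                    nodes, label = "biomarker-")
  prv <- compute_prv(plus, minus)
  expect_equal(prv$prv[prv$gene == "g"], 0.8)
  expect_equal(prv$prv[prv$gene == "b"], 0.8)
  expect_equal(prv$prv[prv$gene == "a"], 0)
  expect_equal(sort(prv$rank), 1:4)

  # identical networks give all-zero PRV
  same <- compute_prv(plus, plus)
  expect_true(all(same$prv == 0))

  # swapping the subgroups leaves every PRV unchanged
  swapped <- compute_prv(minus, plus)
  expect_equal(swapped$prv[match(prv$gene, swapped$gene)], prv$prv)

  expect_error(compute_prv(plus, make_net(minus$edges, c("g", "a"))),
               "node universe")
})

test_that("candidate selection excludes the anchor and breaks ties lexicographically", {
  nodes <- c("ANCH", "B", "A", "C", "D", "E")
  plus <- make_net(data.frame(gene_a = c("A", "B", "ANCH"),
                              gene_b = c("C", "C", "D"),
                              weight = c(0.9, 0.9, 0.95)), nodes)
  minus <- make_net(data.frame(gene_a = character(0), gene_b = character(0),
                               weight = numeric(0)), nodes,
                    label = "biomarker-")
  prv <- compute_prv(plus, minus)
  # PRVs: C 1.8, D 0.95 (via its anchor edge), A = B = 0.9, ANCH 0.95, E 0
  expect_false("ANCH" %in% select_candidates(prv, k = 5))
  expect_identical(select_candidates(prv, k = 2), c("C", "D"))
  # A and B tie at 0.9; the lexicographically smaller symbol takes the slot
  expect_identical(select_candidates(prv, k = 3)[3], "A")
  # zero-PRV genes are not candidates by default, but include_zero keeps them
  expect_false("E" %in% select_candidates(prv, k = 10))
  expect_setequal(select_candidates(prv, k = 10, include_zero = TRUE),
                  setdiff(nodes, "ANCH"))
})

test_that("list intersection is strict", {
  expect_setequal(intersect_lists(list(c("a", "b", "c"), c("b", "c", "d"),
                                       c("c", "b"))), c("b", "c"))
  expect_length(intersect_lists(list(c("a", "b"), character(0))), 0)
  expect_setequal(intersect_lists(rep(list(c("x", "y")), 7)), c("x", "y"))
  expect_error(intersect_lists(list()), "at least one")
})

test_that("the survival filter keeps planted genes and respects alpha", {
  cfg <- sim_config(n_samples = 600L, n_genes = 20L, n_planted_prognostic = 2L,
                    effect_log_hr = log(2), stage_log_hr = 0, age_log_hr = 0,
                    n_interactome_edges = 30L, seed = 77)
  ex <- simulate_expression(cfg)
  cs <- simulate_clinical_survival(cfg, ex$expression, ex$truth)
  genes <- c(ex$truth$planted_prognostic_genes, "BG001", "BG002")
  kept <- survival_filter(genes, ex$expression, cs$survival, alpha = 0.01)
  expect_true(all(ex$truth$planted_prognostic_genes %in% kept))
  # alpha = 1 keeps every non-degenerate gene
  expect_setequal(survival_filter(genes, ex$expression, cs$survival, alpha = 1),
                  genes)
})

test_that("feature selection recovers planted genes and stays quiet under null", {
  b <- assemble_cohort(quick_config(seed = 15))
  panel <- suppressMessages(run_feature_selection(b))
  expect_gte(length(intersect(panel$novel_genes,
                              b$truth$planted_prognostic_genes)), 6)
  expect_identical(panel$literature_genes, literature_biomarkers())

  b0 <- assemble_cohort(quick_config(seed = 16, network_effect = 0,
                                     effect_log_hr = 0))
  expect_warning(p0 <- suppressMessages(run_feature_selection(b0)),
                 "empty overlap|literature genes")
  expect_length(p0$novel_genes, 0)
})

test_that("panel construction enforces disjointness", {
  p <- biomarker_panel(c("A", "B"), c("C"))
  expect_identical(p$combined, c("A", "B", "C"))
  expect_error(biomarker_panel(c("A", "B"), c("B")), "disjoint")
})
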