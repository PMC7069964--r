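# Synthetic cohort generator.
#
# Emulates the statistical structure the prognostic pipeline assumes:
# log2-scale expression with bimodal marginals for anchor biomarker genes,
# subgroup-dependent co-expression for planted gene pairs (shared latent
# factors switched on by a common tumour-subtype indicator), clinical
# covariates with an early-stage-dominated category mix, and exponential
# proportional-hazards survival with independent exponential censoring.

#' Literature biomarker genes used as subgroup anchors
#'
#' Seven single-gene biomarkers repeatedly reported as prognostic in
#' non-small cell lung cancer; they anchor the biomarker+/- subgroup
#' networks.
#' @return character vector of 7 gene symbols.
#' @export
literature_biomarkers <- function() {
  c("EPCAM", "HIF1A", "PKM", "PTK7", "ALCAM", "CADM1", "SLC2A1")
}

# Default symbols for planted prognostic genes in the simulator. These are
# genes with documented prognostic relevance in lung adenocarcinoma; in the
# simulator they are synthetic stand-ins carrying the planted effects.
planted_gene_names <- function(n) {
  pool <- c("CUL1", "CUL3", "EGFR", "ELAVL1", "GRB2", "NRF1", "RNF2", "RPA2")
  if (n <= length(pool)) return(pool[seq_len(n)])
  c(pool, sprintf("NOVEL%02d", seq_len(n - length(pool))))
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic cohort generator. Defaults describe
#' a lung-adenocarcinoma-like cohort of 512 patients split 256/85/171 into
#' training/validation/test, with 7 bimodal anchor biomarkers (mode
#' separation 4 log2 units, unit within-mode SD), 8 planted prognostic
#' genes forming 4 differential co-expression pairs (within-pair Pearson
#' correlation `network_effect` in the biomarker-high subtype, 0 in the
#' other), a per-SD hazard ratio of 1.5 for each planted gene, modest stage
#' and age effects, a baseline hazard giving ~69% five-year survival for a
#' typical patient, and ~30% independent censoring.
#'
#' @param n_samples number of patients.
#' @param n_genes total number of genes (anchors + planted + background).
#' @param biomarker_genes symbols of the anchor biomarker genes.
#' @param n_planted_prognostic number of genes given a true survival effect
#'   and differential co-expression.
#' @param bimodal_gap separation (log2 units) between anchor low/high modes.
#' @param network_effect within-pair Pearson correlation planted in the
#'   biomarker-high subtype for differential pairs; 0 disables planting.
#' @param baseline_hazard events per month for a typical patient.
#' @param effect_log_hr log hazard ratio per standard deviation of each
#'   planted gene's expression.
#' @param stage_log_hr log hazard ratio per tumour-stage step (IA -> III/IV).
#' @param age_log_hr log hazard ratio per decade of age above the cohort
#'   midpoint.
#' @param censor_rate expected fraction of patients censored.
#' @param split_fractions train/validation/test fractions summing to 1.
#' @param n_interactome_edges number of reference interactome edges
#'   (planted pairs plus random background pairs).
#' @param seed integer seed controlling the whole cohort.
#' @return object of class `sim_config` (a named list).
#' @export
sim_config <- function(n_samples = 512L,
                       n_genes = 200L,
                       biomarker_genes = literature_biomarkers(),
                       n_planted_prognostic = 8L,
                       bimodal_gap = 4,
                       network_effect = 0.85,
                       baseline_hazard = 0.0062,
                       effect_log_hr = log(1.5),
                       stage_log_hr = 0.35,
                       age_log_hr = 0.15,
                       censor_rate = 0.3,
                       split_fractions = c(0.5, 0.166, 0.334),
                       n_interactome_edges = 600L,
                       seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    biomarker_genes = as.character(biomarker_genes),
    n_planted_prognostic = as.integer(n_planted_prognostic),
    bimodal_gap = bimodal_gap, network_effect = network_effect,
    baseline_hazard = baseline_hazard, effect_log_hr = effect_log_hr,
    stage_log_hr = stage_log_hr, age_log_hr = age_log_hr,
    censor_rate = censor_rate, split_fractions = split_fractions,
    n_interactome_edges = as.integer(n_interactome_edges),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_samples < 1L || cfg$n_genes < 1L) {
    stopf("n_samples and n_genes must be positive")
  }
  n_special <- length(cfg$biomarker_genes) + cfg$n_planted_prognostic
  if (cfg$n_genes < n_special) {
    stopf("n_genes (%d) must cover anchors plus planted genes (%d)",
          cfg$n_genes, n_special)
  }
  if (cfg$n_planted_prognostic < 0L) stopf("n_planted_prognostic must be >= 0")
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1) {
    stopf("censor_rate must be in [0, 1)")
  }
  if (length(cfg$split_fractions) != 3L || any(cfg$split_fractions < 0) ||
      abs(sum(cfg$split_fractions) - 1) > 1e-9) {
    stopf("split_fractions must be three non-negative numbers summing to 1")
  }
  if (cfg$baseline_hazard <= 0) stopf("baseline_hazard must be positive")
  invisible(cfg)
}

# Gene universe: anchors first, then planted prognostic genes, then
# background genes BG001, BG002, ...
sim_gene_names <- function(cfg) {
  planted <- planted_gene_names(cfg$n_planted_prognostic)
  n_bg <- cfg$n_genes - length(cfg$biomarker_genes) - length(planted)
  c(cfg$biomarker_genes, planted,
    sprintf("BG%03d", seq_len(n_bg)))
}

#' Simulate a gene-expression matrix with planted network structure
#'
#' Draws a common binary tumour-subtype indicator per sample. Anchor
#' biomarker genes follow a two-component Gaussian mixture tied to the
#' subtype (means `6` and `6 + bimodal_gap`, unit SD), so StepMiner can
#' recover the subtype. Planted prognostic genes are paired; within the
#' biomarker-high subtype each pair shares a latent factor giving Pearson
#' correlation `network_effect`, while in the other subtype the pair is
#' independent; marginals stay standard normal around a constant mean, so
#' the planted signal is purely a co-expression difference. All remaining
#' genes are independent Gaussian noise.
#'
#' @param config a [sim_config()].
#' @param seed optional override of `config$seed`.
#' @return list with `expression` (genes x samples matrix), `truth` (a
#'   partial ground-truth list: planted genes, planted pair set, true
#'   per-gene log HRs, anchor thresholds, subtype indicator).
#' @export
simulate_expression <- function(config, seed = config$seed) {
  validate_sim_config(config)
  local_seed(seed + 1L, {
    n <- config$n_samples
    genes <- sim_gene_names(config)
    samples <- sprintf("S%04d", seq_len(n))
    anchors <- config$biomarker_genes
    planted <- planted_gene_names(config$n_planted_prognostic)

    subtype <- stats::rbinom(n, 1L, 0.5)
    expr <- matrix(stats::rnorm(length(genes) * n, mean = 8, sd = 1),
                   nrow = length(genes), ncol = n,
                   dimnames = list(genes, samples))

    mu_low <- 6
    for (g in anchors) {
      expr[g, ] <- mu_low + config$bimodal_gap * subtype + stats::rnorm(n)
    }

    edges <- character(0)
    pair_list <- list()
    if (config$n_planted_prognostic > 0L && config$network_effect > 0) {
      rho <- config$network_effect
      k <- length(planted)
      # consecutive planted genes pair up; an odd leftover pairs with the
      # first background gene
      partners <- if (k %% 2L == 0L) {
        split(planted, rep(seq_len(k / 2), each = 2))
      } else {
        c(split(planted[-k], rep(seq_len((k - 1) / 2), each = 2)),
          list(c(planted[k], sprintf("BG%03d", 1L))))
      }
      on_idx <- subtype == 1L
      for (pr in partners) {
        f <- stats::rnorm(sum(on_idx))
        for (g in pr) {
          e <- stats::rnorm(n)
          x <- e
          x[on_idx] <- sqrt(rho) * f + sqrt(1 - rho) * e[on_idx]
          expr[g, ] <- 8 + x
        }
        pair_list[[length(pair_list) + 1L]] <- sort(pr)
      }
      edges <- vapply(pair_list, function(p) pair_key(p[1], p[2]), "")
    } else if (config$n_planted_prognostic > 0L) {
      # no network effect: planted genes are plain noise (already drawn)
    }

    true_log_hr <- stats::setNames(rep(0, length(genes)), genes)
    true_log_hr[planted] <- config$effect_log_hr

    truth <- list(
      planted_prognostic_genes = planted,
      planted_edge_differences = pair_list,
      planted_edge_keys = edges,
      true_log_hr = true_log_hr,
      true_biomarker_thresholds = stats::setNames(
        rep(mu_low + config$bimodal_gap / 2, length(anchors)), anchors),
      subtype = stats::setNames(subtype, samples)
    )
    list(expression = expr, truth = truth)
  })
}

stage_levels <- function() c("IA", "IB", "IIA", "IIB", "III/IV")

# Stage frequencies resembling an early-stage surgical ADC cohort.
stage_probs <- function() c(0.49, 0.34, 0.03, 0.09, 0.05)

#' Simulate clinical covariates and survival outcomes
#'
#' Ages are uniform on 32-86 years, sex is balanced, and tumour stage is
#' drawn with early-stage-dominated frequencies. Event times are
#' exponential under a proportional-hazards model whose linear predictor
#' sums the planted per-gene effects (on training-free, cohort-standardized
#' expression), a per-stage-step effect and a per-decade age effect.
#' Censoring times are independent exponentials whose rate is calibrated by
#' root finding so the expected censored fraction equals `censor_rate`.
#'
#' @param config a [sim_config()].
#' @param expression genes x samples matrix from [simulate_expression()].
#' @param truth ground-truth list from [simulate_expression()].
#' @param seed optional override of `config$seed`.
#' @return list with `clinical` (data.frame: sample_id, age, sex, stage)
#'   and `survival` (data.frame: sample_id, time_months, event).
#' @export
simulate_clinical_survival <- function(config, expression, truth,
                                       seed = config$seed) {
  validate_sim_config(config)
  planted <- truth$planted_prognostic_genes
  if (!all(planted %in% rownames(expression))) {
    stopf("planted genes missing from the expression matrix: %s",
          paste(setdiff(planted, rownames(expression)), collapse = ", "))
  }
  local_seed(seed + 2L, {
    n <- config$n_samples
    samples <- colnames(expression)
    age <- stats::runif(n, 32, 86)
    sex <- ifelse(stats::rbinom(n, 1L, 0.5) == 1L, "male", "female")
    stage <- sample(stage_levels(), n, replace = TRUE, prob = stage_probs())

    lp <- rep(0, n)
    for (g in planted) {
      x <- expression[g, ]
      s <- pop_sd(x)
      if (s > 0) lp <- lp + truth$true_log_hr[g] * (x - mean(x)) / s
    }
    stage_ord <- match(stage, stage_levels()) - 1L
    lp <- lp + config$stage_log_hr * (stage_ord - mean(stage_ord))
    lp <- lp + config$age_log_hr * (age - 59) / 10

    lambda <- config$baseline_hazard * exp(lp)
    t_event <- stats::rexp(n, rate = lambda)
    if (config$censor_rate > 0) {
      # expected censored fraction for exponential censoring at rate mu is
      # mean(mu / (lambda + mu)); solve for mu
      f <- function(log_mu) {
        mu <- exp(log_mu)
        mean(mu / (lambda + mu)) - config$censor_rate
      }
      log_mu <- stats::uniroot(f, lower = log(min(lambda)) - 20,
                               upper = log(max(lambda)) + 20)$root
      t_cens <- stats::rexp(n, rate = exp(log_mu))
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    } else {
      time <- t_event
      event <- rep(1L, n)
    }
    list(
      clinical = data.frame(sample_id = samples, age = age, sex = sex,
                            stage = stage, stringsAsFactors = FALSE),
      survival = data.frame(sample_id = samples, time_months = time,
                            event = event, stringsAsFactors = FALSE)
    )
  })
}

#' Simulate a reference interactome
#'
#' The planted differential pairs are always included; the remainder are
#' distinct random gene pairs, so most interactome edges carry no subgroup
#' difference.
#'
#' @param config a [sim_config()].
#' @param truth ground-truth list from [simulate_expression()].
#' @param seed optional override of `config$seed`.
#' @return data.frame with columns `gene_a`, `gene_b` (canonical order).
#' @export
simulate_interactome <- function(config, truth, seed = config$seed) {
  genes <- sim_gene_names(config)
  local_seed(seed + 4L, {
    keys <- truth$planted_edge_keys
    want <- max(config$n_interactome_edges, length(keys))
    guard <- 0L
    while (length(keys) < want && guard < 50L) {
      m <- 2L * (want - length(keys))
      a <- sample(genes, m, replace = TRUE)
      b <- sample(genes, m, replace = TRUE)
      ok <- a != b
      keys <- unique(c(keys, pair_key(a[ok], b[ok])))
      guard <- guard + 1L
    }
    keys <- keys[seq_len(want)]
    parts <- strsplit(keys, "|", fixed = TRUE)
    data.frame(
      gene_a = vapply(parts, `[[`, "", 1L),
      gene_b = vapply(parts, `[[`, "", 2L),
      stringsAsFactors = FALSE
    )
  })
}

#' Assign train/validation/test splits
#'
#' Shuffles sample IDs and cuts at the rounded cumulative fractions; any
#' rounding remainder lands in training and no sample is dropped.
#'
#' @param sample_ids character vector of sample IDs.
#' @param fractions three non-negative fractions summing to 1.
#' @param seed integer seed.
#' @return data.frame with columns `sample_id`, `split` (factor
#'   train/validation/test).
#' @export
assign_splits <- function(sample_ids, fractions = c(0.5, 0.166, 0.334),
                          seed = 1L) {
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stopf("fractions must be three non-negative numbers summing to 1")
  }
  n <- length(sample_ids)
  local_seed(seed + 3L, {
    perm <- sample(sample_ids)
    cuts <- round(cumsum(fractions) * n)
    cuts[3] <- n # every sample assigned; remainder folded into training
    sizes <- diff(c(0L, cuts))
    if (any(sizes < 0)) sizes <- pmax(sizes, 0L)
    split <- rep(c("train", "validation", "test"), times = sizes)
    out <- data.frame(sample_id = perm, split = factor(
      split, levels = c("train", "validation", "test")),
      stringsAsFactors = FALSE)
    out <- out[match(sample_ids, out$sample_id), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Generate a complete synthetic cohort
#'
#' Runs the expression, clinical/survival, interactome and split
#' generators under the configuration seed and assembles an aligned cohort
#' bundle with ground truth attached. Identical configurations (including
#' the seed) give identical bundles.
#'
#' @param config a [sim_config()].
#' @return object of class `cohort_bundle`: list with `expression`,
#'   `clinical`, `survival`, `splits`, `interactome`, `truth`.
#' @examples
#' bundle <- assemble_cohort(sim_config(n_samples = 64, n_genes = 30,
#'                                      n_interactome_edges = 60))
#' table(bundle$splits$split)
#' @export
assemble_cohort <- function(config) {
  validate_sim_config(config)
  ex <- simulate_expression(config)
  cs <- simulate_clinical_survival(config, ex$expression, ex$truth)
  inter <- simulate_interactome(config, ex$truth)
  splits <- assign_splits(colnames(ex$expression), config$split_fractions,
                          seed = config$seed)
  new_cohort_bundle(
    expression = ex$expression,
    clinical = cs$clinical,
    survival = cs$survival,
    splits = splits,
    interactome = inter,
    truth = ex$truth
  )
}
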