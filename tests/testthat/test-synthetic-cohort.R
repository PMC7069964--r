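# Synthetic cohort generator: determinism, planted structure, survival
# calibration and split logic.

test_that("identical configurations give bitwise-identical cohorts", {
  b1 <- assemble_cohort(quick_config(seed = 3))
  b2 <- assemble_cohort(quick_config(seed = 3))
  expect_identical(b1$expression, b2$expression)
  expect_identical(b1$clinical, b2$clinical)
  expect_identical(b1$survival, b2$survival)
  expect_identical(b1$splits, b2$splits)
  b3 <- assemble_cohort(quick_config(seed = 4))
  expect_false(identical(b1$expression, b3$expression))
})

test_that("anchor biomarkers are bimodal with a StepMiner-recoverable threshold", {
  cfg <- sim_config(n_samples = 1000L, n_genes = 40L, bimodal_gap = 4,
                    n_interactome_edges = 100L, seed = 9)
  ex <- simulate_expression(cfg)
  for (g in cfg$biomarker_genes[1:3]) {
    fit <- fit_step(ex$expression[g, ])
    expect_gt(fit$threshold, 8 - 0.3)   # modes at 6 and 10 -> midpoint 8
    expect_lt(fit$threshold, 8 + 0.3)
    agree <- mean((ex$expression[g, ] > fit$threshold) == (ex$truth$subtype == 1))
    expect_gte(agree, 0.95)             # planted-signal recoverability
  }
})

test_that("planted pairs have the promised within-subgroup correlations", {
  cfg <- sim_config(n_samples = 1000L, n_genes = 40L,
                    n_interactome_edges = 100L, seed = 12)
  ex <- simulate_expression(cfg)
  on <- ex$truth$subtype == 1
  for (pair in ex$truth$planted_edge_differences) {
    r_on <- cor(ex$expression[pair[1], on], ex$expression[pair[2], on])
    r_off <- cor(ex$expression[pair[1], !on], ex$expression[pair[2], !on])
    expect_gte(abs(r_on), 0.8)
    expect_lte(abs(r_off), 0.2)
  }
})

test_that("network_effect = 0 plants no edge differences", {
  ex <- simulate_expression(quick_config(seed = 2, network_effect = 0))
  expect_length(ex$truth$planted_edge_differences, 0)
})

test_that("censoring behaves as configured", {
  cfg0 <- quick_config(seed = 6, censor_rate = 0)
  ex <- simulate_expression(cfg0)
  cs <- simulate_clinical_survival(cfg0, ex$expression, ex$truth)
  expect_true(all(cs$survival$event == 1L))

  cfg <- sim_config(n_samples = 4000L, n_genes = 20L, n_planted_prognostic = 4L,
                    censor_rate = 0.4, n_interactome_edges = 40L, seed = 6)
  ex <- simulate_expression(cfg)
  cs <- simulate_clinical_survival(cfg, ex$expression, ex$truth)
  expect_equal(mean(cs$survival$event == 0L), 0.4, tolerance = 0.1)
})

test_that("a planted per-SD hazard ratio is recovered by a Cox fit", {
  cfg <- sim_config(n_samples = 2000L, n_genes = 12L, n_planted_prognostic = 1L,
                    effect_log_hr = log(2), censor_rate = 0.2,
                    stage_log_hr = 0, age_log_hr = 0,
                    n_interactome_edges = 20L, seed = 31)
  ex <- simulate_expression(cfg)
  cs <- simulate_clinical_survival(cfg, ex$expression, ex$truth)
  g <- ex$truth$planted_prognostic_genes[1]
  x <- ex$expression[g, cs$survival$sample_id]
  z <- (x - mean(x)) / sd(x)
  fit <- survival::coxph(survival::Surv(cs$survival$time_months,
                                        cs$survival$event) ~ z)
  hr <- exp(unname(coef(fit)))
  expect_gte(hr, 1.8)
  expect_lte(hr, 2.2)
  # cross-check against the grid-search partial-likelihood oracle on a
  # binary split of the same covariate
  grp <- as.integer(z > 0)
  fit2 <- cox_univariate(grp, cs$survival$time_months, cs$survival$event)
  ora <- oracle_cox_loghr(grp[1:400], cs$survival$time_months[1:400],
                          cs$survival$event[1:400])
  fit3 <- cox_univariate(grp[1:400], cs$survival$time_months[1:400],
                         cs$survival$event[1:400])
  expect_equal(fit3$log_hr, ora, tolerance = 1e-3)
  expect_gt(fit2$hr, 1)
})

test_that("null effects give calibrated log-rank rejection on StepMiner splits", {
  # with all effects zero, dichotomizing by any gene must not separate
  # survival beyond chance
  rej <- 0
  n_rep <- 120
  for (i in seq_len(n_rep)) {
    cfg <- sim_config(n_samples = 120L, n_genes = 10L, n_planted_prognostic = 0L,
                      effect_log_hr = 0, stage_log_hr = 0, age_log_hr = 0,
                      network_effect = 0, n_interactome_edges = 15L,
                      seed = 5000 + i)
    ex <- simulate_expression(cfg)
    cs <- simulate_clinical_survival(cfg, ex$expression, ex$truth)
    lab <- dichotomize(ex$expression, "BG001")
    p <- logrank(cs$survival$time_months, cs$survival$event,
                 lab == "biomarker+")$p_value
    rej <- rej + (p < 0.05)
  }
  expect_gte(rej / n_rep, 0.005)
  expect_lte(rej / n_rep, 0.11)
})

test_that("split sizes follow the configured fractions without dropping samples", {
  ids <- sprintf("P%03d", 1:512)
  sp <- assign_splits(ids, c(0.5, 0.166, 0.334), seed = 1)
  expect_equal(as.vector(table(sp$split)), c(256L, 85L, 171L))
  expect_setequal(sp$sample_id, ids)

  all_train <- assign_splits(ids[1:20], c(1, 0, 0), seed = 1)
  expect_true(all(all_train$split == "train"))

  sp2 <- assign_splits(ids, c(0.5, 0.166, 0.334), seed = 1)
  expect_identical(sp, sp2)
  expect_error(assign_splits(ids, c(0.5, 0.4, 0.2)), "summing to 1")
})

test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(n_samples = 0), "positive")
  expect_error(sim_config(n_genes = 10, n_planted_prognostic = 8), "cover")
  expect_error(sim_config(censor_rate = 1.2), "censor_rate")
  expect_error(
    simulate_clinical_survival(quick_config(),
                               matrix(0, 2, 2, dimnames = list(c("A", "B"), c("s1", "s2"))),
                               list(planted_prognostic_genes = "ZZZ",
                                    true_log_hr = c(ZZZ = 1))),
    "missing")
})
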