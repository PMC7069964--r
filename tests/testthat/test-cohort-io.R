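# Cohort I/O: validation, alignment, round-trips and feature encoding.

test_that("a simulated bundle round-trips through the on-disk formats", {
  b <- assemble_cohort(quick_config(seed = 8))
  dir <- withr::local_tempdir()
  write_cohort(b, dir)
  b2 <- load_cohort(file.path(dir, "expression.tsv"),
                    file.path(dir, "clinical.csv"),
                    file.path(dir, "survival.csv"),
                    file.path(dir, "splits.csv"),
                    file.path(dir, "interactome.tsv"))
  expect_equal(b2$expression[rownames(b$expression), colnames(b$expression)],
               b$expression, tolerance = 1e-12)
  expect_equal(b2$survival$time_months, b$survival$time_months,
               tolerance = 1e-12)
  expect_identical(as.character(b2$splits$split), as.character(b$splits$split))
  expect_setequal(pair_keys <- paste(b2$interactome$gene_a, b2$interactome$gene_b),
                  paste(b$interactome$gene_a, b$interactome$gene_b))
})

test_that("components are aligned by intersecting sample IDs", {
  b <- assemble_cohort(quick_config(seed = 9))
  dir <- withr::local_tempdir()
  write_cohort(b, dir)
  # drop some samples from the clinical file only
  cl <- read.csv(file.path(dir, "clinical.csv"))
  cl <- cl[-(1:5), ]
  write.csv(cl, file.path(dir, "clinical.csv"), row.names = FALSE)
  b2 <- load_cohort(file.path(dir, "expression.tsv"),
                    file.path(dir, "clinical.csv"),
                    file.path(dir, "survival.csv"))
  expect_equal(ncol(b2$expression), ncol(b$expression) - 5L)
  expect_setequal(colnames(b2$expression), cl$sample_id)
  # loading the already-aligned bundle again changes nothing
  dir2 <- withr::local_tempdir()
  write_cohort(b2, dir2)
  b3 <- load_cohort(file.path(dir2, "expression.tsv"),
                    file.path(dir2, "clinical.csv"),
                    file.path(dir2, "survival.csv"))
  expect_equal(dim(b3$expression), dim(b2$expression))
})

test_that("malformed categories and values are rejected with row context", {
  b <- assemble_cohort(quick_config(seed = 10))
  dir <- withr::local_tempdir()
  write_cohort(b, dir)
  cl <- read.csv(file.path(dir, "clinical.csv"))
  cl$stage[3] <- "II"
  write.csv(cl, file.path(dir, "clinical.csv"), row.names = FALSE)
  expect_error(
    load_cohort(file.path(dir, "expression.tsv"),
                file.path(dir, "clinical.csv"),
                file.path(dir, "survival.csv")),
    "stage 'II'")

  bad_clin <- b$clinical
  bad_clin$age[1] <- 150
  expect_error(new_cohort_bundle(b$expression, bad_clin, b$survival),
               "age")
  bad_surv <- b$survival
  bad_surv$event[2] <- 3L
  expect_error(new_cohort_bundle(b$expression, b$clinical, bad_surv),
               "event")
  dup <- b$expression[c(1, 1, 2), ]
  expect_error(new_cohort_bundle(dup, b$clinical, b$survival), "duplicate")
})

test_that("samples with incomplete clinical data are dropped with a message", {
  b <- assemble_cohort(quick_config(seed = 11))
  dir <- withr::local_tempdir()
  write_cohort(b, dir)
  cl <- read.csv(file.path(dir, "clinical.csv"))
  cl$age[2] <- NA
  write.csv(cl, file.path(dir, "clinical.csv"), row.names = FALSE)
  expect_message(
    b2 <- load_cohort(file.path(dir, "expression.tsv"),
                      file.path(dir, "clinical.csv"),
                      file.path(dir, "survival.csv")),
    "incomplete clinical")
  expect_equal(ncol(b2$expression), ncol(b$expression) - 1L)
})

test_that("clinical encoding produces the 7 documented columns", {
  clin <- data.frame(
    sample_id = paste0("s", 1:4),
    age = c(60, 70, 55, 80),
    sex = c("male", "female", "male", "female"),
    stage = c("IA", "IB", "III/IV", "IA"),
    stringsAsFactors = FALSE
  )
  fb <- encode_clinical(clin, train_ids = c("s1", "s2"))
  expect_equal(ncol(fb$values), 7L)
  # population-SD z-scoring: training ages {60, 70} -> exactly -1, +1
  expect_equal(unname(fb$values[1:2, "age"]), c(-1, 1))
  # stage IA vs IB rows differ in exactly the two one-hot positions
  d <- fb$values[1, ] != fb$values[2, ]
  expect_equal(sum(d[grep("stage", names(d))]), 2)
  expect_equal(unname(fb$values[, "sex_male"]), c(1, 0, 1, 0))
})

test_that("constant clinical columns are flagged and passed through", {
  clin <- data.frame(sample_id = paste0("s", 1:3), age = c(50, 60, 70),
                     sex = rep("male", 3), stage = rep("IA", 3),
                     stringsAsFactors = FALSE)
  fb <- encode_clinical(clin, train_ids = clin$sample_id)
  st <- fb$scaler_stats
  expect_true(st$constant[st$feature == "sex_male"])
  expect_equal(st$scale[st$feature == "sex_male"], 1)
  expect_equal(unname(fb$values[, "sex_male"]), rep(1, 3))
})

test_that("expression encoding scales on the training split only", {
  b <- assemble_cohort(quick_config(seed = 13))
  train_ids <- b$splits$sample_id[b$splits$split == "train"]
  panel <- biomarker_panel(literature_biomarkers(),
                           b$truth$planted_prognostic_genes)
  fb <- encode_expression(b$expression, panel, train_ids)
  expect_equal(ncol(fb$values), 15L)
  tr <- fb$values[rownames(fb$values) %in% train_ids, ]
  expect_true(all(abs(colMeans(tr)) < 1e-8))
  expect_true(all(abs(apply(tr, 2, function(x) sqrt(mean((x - mean(x))^2))) - 1) < 1e-6))
  # test-split columns are not centred in general (no leakage of test stats)
  te <- fb$values[!(rownames(fb$values) %in% train_ids), ]
  expect_gt(max(abs(colMeans(te))), 1e-4)

  single <- encode_expression(b$expression, "EPCAM", train_ids)
  expect_equal(ncol(single$values), 1L)
  expect_error(encode_expression(b$expression, c("EPCAM", "NOPE"), train_ids),
               "NOPE")
})
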