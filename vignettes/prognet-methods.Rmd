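---
title: "Methods: network-based biomarker selection and bimodal survival classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-based biomarker selection and bimodal survival classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

prognet implements a prognostic-stratification workflow for non-small cell
lung cancer (NSCLC) cohorts profiled by expression microarrays: a
network-based feature selector identifies a compact panel of prognostic
genes, a bimodal neural classifier combines the panel with routine clinical
covariates to predict five-year overall survival, and the predicted risk
groups are validated with standard survival statistics. This vignette
explains each model, its assumptions, the tunable parameters, and the
design choices made where the method left room for interpretation.

## The feature selector

### StepMiner dichotomization

Many cancer biomarkers show bimodal expression: a tumour either expresses
the gene or it does not. `fit_step()` fits a one-step function to the
sorted expression values of a gene: every split position `k` partitions the
sorted vector into a low and a high block, each approximated by its mean,
and the split minimizing the residual sum of squares

$$SSE(k) = \sum_{i \le k} (v_i - \bar v_{low})^2 + \sum_{i > k} (v_i - \bar v_{high})^2$$

is selected. The dichotomization threshold is the midpoint of the two block
means, so `dichotomize()` labels a patient biomarker+ exactly when the
expression is strictly above the threshold. Decisions worth stating
explicitly:

* **Two-way split only.** StepMiner variants with an "intermediate" band
  exist; the pipeline needs a strict two-way patient split, so no margin
  band is used.
* **Ties.** Equal-SSE splits resolve to the smallest split index. Because
  the vectorized prefix-sum evaluation carries ~1e-15 relative float noise,
  ties are compared with a scale-aware tolerance (1e-9 relative); the unit
  suite checks exact agreement with an exhaustive-search oracle.
* **Boundary.** A value exactly at the threshold is biomarker−.
* **Degeneracy.** A constant vector has no valid step; the fit is flagged
  and callers drop the gene.

The threshold is translation- and positive-scale-equivariant, so the
labelling is invariant under affine renormalizations of a gene.

### Subgroup networks and the prognosis relevance value

For each of the seven literature anchor biomarkers (*EPCAM*, *HIF1A*,
*PKM*, *PTK7*, *ALCAM*, *CADM1*, *SLC2A1*), patients are dichotomized and a
co-expression network is built inside each subgroup
(`build_subgroup_network()`): a gene pair from a reference interactome
becomes an edge when its absolute within-subgroup Pearson correlation
reaches `r_threshold` (default 0.6), weighted by |r|. Restricting edges to
a curated interactome keeps the networks biologically interpretable and
controls the number of correlations tested.

The prognosis relevance value of a gene (`compute_prv()`) is its weighted
symmetric-difference degree between the biomarker+ and biomarker−
networks:

$$PRV(g) = \sum_{(g,h)\ \in\ \text{interactome}} \bigl| w_{+}(g,h) - w_{-}(g,h) \bigr|,$$

with absent edges carrying weight 0. PRV is non-negative, zero exactly when
the gene's incident weighted edges coincide in the two networks, and
symmetric under swapping the subgroups. *This operationalization is an
interpretation*: the source method defines PRV only as a measure of
per-gene difference between the paired networks, deferring the formula to
supplementary material; the weighted symmetric-difference degree is the
minimal statistic consistent with that description, and it is what all
documentation and tests of this package mean by PRV.

### Candidate ranking, overlap and survival filter

Per anchor, genes are ranked by descending PRV (ties broken
lexicographically, so results are reproducible) and the top `k = 30`
become candidates. Two deliberate choices:

* the anchor gene is excluded from its own ranking, so a biomarker cannot
  select itself; and
* genes with PRV exactly 0 are not candidates (`include_zero = FALSE`). A
  zero-PRV gene shows no network difference whatsoever; padding the top-30
  with such genes (which lexicographic tie-breaking would otherwise do
  whenever fewer than 30 genes show any difference) would make the
  cross-anchor overlap meaningless and would destroy the null calibration
  of the selector. `k` is therefore a maximum, not a guaranteed length.

Candidates surviving the strict intersection across all seven anchor lists
(`intersect_lists()`) are filtered for survival relevance
(`survival_filter()`): each gene is dichotomized by its own StepMiner
threshold and the two subgroups are compared with a log-rank test; genes
with raw p < 0.01 are retained. The source method states only
"significance for survival (p < 0.01)"; the log-rank test on the
StepMiner dichotomy is the package's choice (configurable to a univariate
Cox Wald test), and no multiplicity correction is applied, matching the
stated raw threshold. The retained genes join the seven literature anchors
as the biomarker panel.

## Classifiers

### Feature encoding

Expression features are the panel genes, z-scored per gene with the
training-split mean and population SD (divisor *n*; fixed for exact
reproducibility of the scaler). Clinical features are 7 columns: z-scored
age, sex as 0/1, and a one-hot encoding of tumour stage over the five
categories IA, IB, IIA, IIB, III/IV (stages III and IV are collapsed, as
is common in early-stage surgical cohorts where they are rare). Scalers
are fitted on the training split only, never on validation or test data;
constant training columns are flagged and passed through unscaled.

### Unimodal and bimodal networks

The expression classifier is a feed-forward network with four hidden
layers of 40 ReLU units; the clinical classifier has four hidden layers of
18 units; each ends in one logistic output unit interpreted as the
probability of death within five years. The integrative (bimodal) network
concatenates the fourth hidden layers of the two branches (40 + 18 = 58
units) and stacks two further hidden layers of 32 units before the
logistic output — about 9,700 parameters in total. Training:

* binary cross-entropy plus an L2 penalty on weight matrices
  (`l2_penalty`, default 1e-4; the source states L2 regularization without
  a value),
* Nadam with learning rate 0.006, mini-batches of 20, at most 100 epochs,
* early stopping when the validation loss has not improved for 30 epochs,
  with restoration of the best-epoch weights,
* **branch pre-training**: the bimodal network's branches are initialized
  from the trained unimodal weights (heads discarded), the post-merge
  layers freshly initialized, then all weights are fine-tuned jointly with
  both inputs fed simultaneously. With zero fine-tuning epochs the branch
  weights equal the unimodal weights exactly, which the tests assert.

Everything is plain R matrix algebra, single-threaded and exactly
reproducible from the seeds: two runs with the same data and seeds give
bitwise-identical weights. No class re-weighting is applied — the workflow
handles label imbalance post hoc through reclassification (below).

### Benchmarks

`train_benchmark()` fits KNN (Euclidean, k = 1..30), random forest
(maximum tree depth ⌈p/3⌉ for p input features, 100/300/500 trees; the
`ranger` backend is used because it exposes a depth limit) and an RBF
SVM (cost 0.1–100, kernel width γ 0.005–0.5), selecting hyper-parameters
by mean AUC over stratified 10-fold cross-validation of the training set;
ties resolve to the earlier (simpler) grid entry. The exact RF/SVM grids
are package defaults within the stated constraints and are overridable.

## Evaluation and reclassification

`roc_and_auc()` sweeps every unique score as a threshold with the rule
"predict death when score ≥ threshold" and integrates the curve by the
trapezoid rule, which equals the Mann–Whitney pairwise-concordance
probability with ties counted one half (asserted property). Death is the
positive class throughout.

Because five-year survivors dominate such cohorts, a 0.5 cutoff
under-calls deaths. `youden_cutoff()` maximizes Youden's
J = sensitivity + specificity − 1 over thresholds; ties resolve to the
smaller (more sensitive) cutoff. In the pipeline the cutoff is computed on
the **validation** split and then frozen before it touches test data (the
derivation split is not specified by the source method; validation avoids
test leakage). When the Youden cutoff falls below 0.5, recall at the new
cutoff can only rise — the monotone reclassification property the tests
check.

## Survival analysis

Five-year labels follow the stated rule: alive if overall survival exceeds
60 months, dead if a death is observed at or before 60 months. The rule is
silent about patients censored before 60 months; they cannot be labelled
either way, so the package excludes them from classifier training and
scoring (`usable = FALSE`) while keeping them in every Kaplan–Meier,
log-rank and Cox computation, which handle censoring natively. Predicted
risk groups (high = predicted dead at the active cutoff) are compared on
the full test-split survival data with KM curves truncated at 60 months, a
two-group log-rank test, and a univariate Cox proportional-hazards fit
(Breslow tie handling — ties are rare in continuous simulations — and Wald
95% intervals). These are computed by the `survival` package behind the
prognet API; the test suite cross-checks the Cox fit against an
independent grid-search maximizer of the Breslow partial likelihood and
the KM curve against a hand product-limit oracle.

## The synthetic cohort generator

Real NSCLC microarray cohorts cannot ship with a package, so
`assemble_cohort()` generates cohorts with exactly the structure the
pipeline assumes, plus ground truth for testing:

* **Subtype and anchors.** Each patient has a latent binary tumour
  subtype. All seven anchor biomarkers are two-component Gaussian mixtures
  tied to that *common* subtype (means 6 and 6 + `bimodal_gap`, unit SD;
  default gap 4 log2 units). The shared subtype is deliberate: it is what
  allows the same genes to rank high for all seven anchors, mirroring the
  seven-list overlap at the heart of the selector. With gap ≥ 3 within-mode
  SDs, StepMiner recovers the subtype for ≥ 95% of patients.
* **Planted network differences.** The `n_planted_prognostic` genes
  (default 8) pair up; within the biomarker-high subtype each pair shares
  a latent factor giving Pearson correlation `network_effect` (default
  0.85), while in the other subtype the genes are independent. Marginals
  stay standard normal, so the planted signal is purely a co-expression
  difference — PRV ≈ 0.85 for planted genes, ≈ 0 for everything else.
  Pairing planted genes among themselves (rather than with non-prognostic
  partners) keeps the post-overlap candidate set free of genes that would
  then be removed by the survival filter only stochastically.
* **Clinical covariates.** Age uniform on 32–86 years, balanced sex, and
  stage drawn with early-stage-dominated frequencies
  (IA 49%, IB 34%, IIA 3%, IIB 9%, III/IV 5%), resembling surgical
  adenocarcinoma cohorts.
* **Survival.** Event times are exponential under a proportional-hazards
  model: log-hazard = log(`baseline_hazard`) + Σ per-gene effects on
  cohort-standardized planted-gene expression + `stage_log_hr` per stage
  step + `age_log_hr` per decade above the midpoint. Defaults:
  `effect_log_hr = log(1.5)` per SD and gene (a moderate, realistic
  per-gene effect; larger values make the outcome nearly deterministic),
  `stage_log_hr = 0.35`, `age_log_hr = 0.15`, and
  `baseline_hazard = 0.0062`/month so a baseline patient has ≈ 69%
  five-year survival, matching the survivor-dominated label imbalance the
  reclassification step exists to handle. Censoring is independent
  exponential, with its rate calibrated by root finding so the expected
  censored fraction equals `censor_rate` (default 0.3). The censoring
  model is a stand-in — nothing is claimed about any real cohort's
  censoring distribution.
* **Splits.** 512 patients are shuffled and cut at the rounded cumulative
  fractions (0.5, 0.166, 0.334), giving the 256/85/171
  training/validation/test layout; rounding remainders land in training
  and no patient is ever dropped.

The generator is exactly reproducible: identical configurations (including
the seed) give bitwise-identical cohorts.

**What the generator does not emulate:** probe-level noise, batch effects
between merged series, correlated clinical covariates (e.g. stage–age
dependence), non-proportional hazards, informative censoring, and
interactome errors. Tests passing on synthetic cohorts therefore validate
the algorithmic machinery and its statistical calibration, not clinical
performance on real data.

## Problem sizes and numerical choices

The default experiment sizes are chosen to be statistically meaningful at
desk scale: the standard cohort is 512 patients × 200 genes with a
600-edge interactome; recovery experiments use 1,000 patients; null
calibrations use 50–500 replicates of smaller cohorts (120–300 patients);
the integration experiment trains the three networks on 10 seeds.
Numerical details: probabilities are clipped at 1e-12 in the
cross-entropy; He-normal initialization; validation-loss improvements
smaller than 1e-12 do not reset early-stopping patience; the step-fit and
Youden tie rules are as documented above; survival times are in months
everywhere, with the five-year horizon at 60 months.

## Known limitations

* The PRV formula is an interpretation (see above); a different
  supplementary definition could rank genes differently on real data.
* The selector's overlap step assumes the anchor biomarkers reflect a
  shared underlying stratification; anchors tracking unrelated subtypes
  would intersect to an empty candidate set and the panel would fall back
  to the literature genes (a warning is raised).
* Five-year labels discard patients censored early, shrinking the
  training set as censoring grows; the survival analyses do not.
* The neural networks are small and CPU-friendly by design; no GPU path
  exists, and no attempt is made to reproduce any externally trained
  weights.
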