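# prognet

Prognostic stratification of non-small cell lung cancer (NSCLC) from gene
expression and clinical data. The package is aimed at computational
biologists who want a fully reproducible implementation of a
network-based biomarker selector coupled to a bimodal (expression +
clinical) neural survival classifier, with the survival statistics needed
to validate the resulting risk groups — and at method developers who need
a synthetic cohort generator with planted, recoverable signal to test
such pipelines end to end.

## What it implements

**Feature selection.** For each of seven literature NSCLC biomarkers
(*EPCAM*, *HIF1A*, *PKM*, *PTK7*, *ALCAM*, *CADM1*, *SLC2A1*), patients
are split into biomarker− / biomarker+ subgroups by StepMiner: a one-step
function is fitted to the sorted expression values, minimizing

    SSE(k) = Σ_{i≤k} (v_i − v̄_low)² + Σ_{i>k} (v_i − v̄_high)²

over all split positions, with the threshold at the midpoint of the block
means. Co-expression networks restricted to a reference interactome are
built inside each subgroup (edge iff |Pearson r| ≥ 0.6, weight |r|), and
every gene gets a prognosis relevance value (PRV) — the weighted
symmetric-difference degree between the paired networks:

    PRV(g) = Σ_{(g,h) ∈ interactome} | w₊(g,h) − w₋(g,h) |.

Top-30 PRV candidates per anchor are intersected across all seven
anchors, then filtered by a log-rank test on each gene's own StepMiner
dichotomy (raw p < 0.01). Survivors join the seven anchors as the
biomarker panel.

**Classification.** Panel expression (z-scored) feeds a feed-forward
network (4 × 40 ReLU units); clinical features (age, sex, one-hot stage —
7 columns) feed a second network (4 × 18). The bimodal network
concatenates the two fourth hidden layers (58 units), stacks 2 × 32 units
and a logistic output, initializes its branches from the trained unimodal
weights, and fine-tunes jointly (binary cross-entropy + L2, Nadam at
learning rate 0.006, batches of 20, ≤ 100 epochs, early stopping with
patience 30). KNN / random forest / SVM benchmarks are tuned by
stratified 10-fold CV. Cutoffs for reclassification come from the Youden
index (J = sensitivity + specificity − 1) on the validation split.

**Survival validation.** Five-year labels (alive iff survival > 60
months), Kaplan–Meier curves, log-rank tests and univariate Cox
proportional-hazards fits (Breslow ties, Wald intervals) on the predicted
high/low-risk groups.

All of it runs on a bundled synthetic cohort generator (512 patients,
256/85/171 train/validation/test by default) with planted co-expression
differences and survival effects, so every stage is testable without any
data download. See `vignettes/prognet-methods.Rmd` for the models,
assumptions and design decisions in detail.

## Worked example

```r
library(prognet)

fit_step(c(1, 1, 1, 5, 5))
#> StepMiner fit: threshold 3.0000 (low mean 1.0000, high mean 5.0000, split 3, SSE 0)

cfg    <- sim_config(seed = 1)          # 512-patient synthetic cohort
bundle <- assemble_cohort(cfg)
bundle
#> Cohort bundle: 200 genes x 512 samples
#>   splits: train 256 / validation 85 / test 171
#>   events observed: 361 of 512
#>   interactome: 600 edges
#>   ground truth attached (synthetic cohort)

panel <- run_feature_selection(bundle)
panel
#> Biomarker panel: 15 genes (7 literature + 8 novel)
#>   literature: EPCAM, HIF1A, PKM, PTK7, ALCAM, CADM1, SLC2A1
#>   novel:      CUL1, CUL3, EGFR, ELAVL1, GRB2, NRF1, RNF2, RPA2
```

The selector recovered all 8 genes carrying planted network + survival
signal (here they use the default synthetic stand-in symbols) and none of
the 177 background genes. Running the whole pipeline — training the
unimodal, bimodal and benchmark models, evaluating at the 0.5 and Youden
cutoffs, and stratifying test-set survival:

```r
run <- run_pipeline(pipeline_config(simulate = cfg, seed = 1))
report_summary(run)
#>           model cutoff_type cutoff    auc accuracy precision recall     f1    hr logrank_p
#>  microarray_dnn    original 0.5000 0.7525   0.6519    0.5467 0.6613 0.5985 2.923 3.588e-09
#>  microarray_dnn      youden 0.5083 0.7525   0.6456    0.5405 0.6452 0.5882 2.841 8.761e-09
#>    clinical_dnn    original 0.5000 0.5160   0.5886    0.4634 0.3065 0.3689 1.519 3.464e-02
#>    clinical_dnn      youden 0.3436 0.5160   0.4747    0.3846 0.5645 0.4575 1.193 3.422e-01
#>     bimodal_dnn    original 0.5000 0.7500   0.6835    0.5882 0.6452 0.6154 3.167 1.489e-10
#>     bimodal_dnn      youden 0.2763 0.7500   0.6013    0.4949 0.7903 0.6087 3.244 7.189e-09
#>     combined_rf    original 0.5000 0.7633   0.7342    0.7083 0.5484 0.6182 3.153 2.174e-10
#>     combined_rf      youden 0.4485 0.7633   0.6835    0.5968 0.5968 0.5968 2.885 2.156e-09
```

Reading the table: `auc` is the test-split area under the ROC curve
(death = positive class); each model appears at the original 0.5 cutoff
and at its validation-derived Youden cutoff. Where the Youden cutoff
falls below 0.5 (e.g. the bimodal network's 0.2763), more patients are
called high-risk, recall rises (0.6452 → 0.7903) at some cost in
precision — the intended trade under survivor-dominated labels. `hr` is
the Cox hazard ratio between the predicted high- and low-risk groups on
the full test-split survival data (censored patients included), and
`logrank_p` the corresponding log-rank test: the bimodal network's risk
groups separate with HR ≈ 3.2, p ≈ 1e-10.

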