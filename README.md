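# tmaquant

Semi-automated DAB signal quantification and biomarker evaluation for
tissue microarrays (TMAs), in R.

## What problem this solves

Evaluating a candidate immunohistochemistry biomarker on a TMA means
answering, per antibody: *does the stained area differ between patient
groups, and how well does it discriminate them?* `tmaquant` implements
that workflow end to end for cohorts of matched high-risk (HR) and
low-risk (LR) patients, each contributing several tumour cores imaged
as individual RGB tiles:

1. **Quantify** each core with two pixel-value thresholds on the 8-bit
   intensity map: AmtT = #{pixels < t_tissue} (any non-background
   pixel) and AmtS = #{pixels < t_signal} (DAB-positive pixels). The
   per-core expression statistic is the area fraction
   **AmtS/AmtT ∈ [0, 1]**.
2. **Train** the threshold pair per antibody on a labelled subset
   (default 10 HR + 10 LR cores) by exhaustive grid search, selecting
   the pair that maximises the OLS regression slope of ratio on group
   (with the pair's R² reported as the fit score), then apply it
   unchanged to every core for that antibody.
3. **Evaluate** each marker: Mann-Whitney U (exact by full enumeration
   for small samples, tie-corrected normal otherwise), empirical ROC,
   AUC ± SE (DeLong placements or the Hanley–McNeil closed form with
   q₁ = a/(2−a), q₂ = 2a²/(1+a)), the Youden operating point
   (J = se + sp − 1), likelihood ratios LR⁺ = se/(1−sp),
   LR⁻ = (1−se)/sp and post-test probabilities from a caller-supplied
   pretest probability.
4. **Combine** two markers by logistic regression, reporting the share
   of cores correctly classified at probability 0.5 and the combined
   AUC.
5. **Report**: mountain plots (HR ratios ascending, LR descending),
   overlaid ROC curves, and machine-readable CSV/JSON tables.

Because raw patient TMA images are rarely shareable, the package also
ships a **synthetic cohort generator** (`generate_cohort()`) that
renders H-DAB-like core images with a hierarchical logit-normal signal
model (matched pairs, patient- and core-level variation), so the whole
pipeline is testable and demonstrable without any download. See the
methods vignette (`vignettes/tma-dab-quantification.Rmd`) for the model
and every numerical choice.

## Worked example

Simulate a 20-patient cohort, train thresholds on a random 10 + 10 core
subset, quantify every core and evaluate the marker:

```r
library(tmaquant)

cfg <- cohort_config(n_pairs = 10, cores_per_patient = 4,
                     image_side = 128, core_diameter = 115, seed = 42)
cohort <- generate_cohort(cfg)

ids <- sample_training_set(cohort$metadata, n_hr = 10, n_lr = 10, seed = 43)
tr <- train_thresholds(cohort$images[ids],
                       cohort$metadata$group[match(ids, cohort$metadata$core_id)])
sprintf("t_tissue=%d t_signal=%d (fit R2 = %.3f)",
        tr$best$t_tissue, tr$best$t_signal, tr$fit_score)
#> "t_tissue=150 t_signal=115 (fit R2 = 0.175)"

q <- quantify_cohort(cohort$images, cohort$metadata, tr$best)
rep <- evaluate_marker(q, "marker_x", pretest_p = 0.005)
print(as.data.frame(rep$summary), digits = 3)
#>     marker n_hr n_lr   u       p criterion   se    sp     j lr_pos lr_neg     a
#> 1 marker_x   40   40 467 0.00138      0.43 0.65 0.775 0.425   2.89  0.452 0.708
#>     se_a method posttest_pos posttest_neg
#> 1 0.0593 delong       0.0143      0.00226
```

Reading the numbers: the trained pair classifies pixels below 150 as
tissue and below 115 as DAB signal; HR cores have significantly higher
stained-area fractions than LR cores (Mann-Whitney p = 0.0014); at the
Youden-optimal cutoff of 0.43 the marker reaches 65% sensitivity and
77.5% specificity; the empirical AUC is 0.708 ± 0.059; and with a 0.5%
pretest probability, a positive call raises the probability of
high-risk disease to 1.4%.

## Command line

The installed script drives the same functions as subcommands
(`simulate`, `train-thresholds`, `quantify`, `evaluate`, `report`,
`run-all`):

```sh
CLI="$(Rscript -e 'cat(system.file("cli/tma_pipeline.R", package = "tmaquant"))')"
CFG="$(Rscript -e 'cat(system.file("extdata/demo_config.yaml", package = "tmaquant"))')"
Rscript "$CLI" run-all --config "$CFG" --out runs/demo
```

`run-all` writes per-marker datasets (`cores.csv`, images,
`thresholds.json`, `quantification.csv`), `marker_report.csv/.json`,
`combination_report.csv/.json`, figures, and a `manifest.json` echoing
the configuration and seeds. Runs are byte-deterministic given the
config, and the individual subcommands reproduce a `run-all` exactly
because every stage communicates through its files.

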