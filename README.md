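# cogmob

Covariate-adjusted rank correlation of cognitive and mobility measures with
hierarchical FDR control.

## What it does

Aging cohorts commonly collect a battery of cognitive test scores (executive
function, processing speed, memory, language) alongside wearable-sensor
mobility metrics (gait speed, stride-to-stride variability, turn duration,
sit-to-stand transitions). Which cognitive measures relate to which mobility
measures, once age and gender are accounted for, is a multiple-testing
problem with hundreds of correlated hypotheses on a modest sample.

`cogmob` implements the full pipeline:

1. **Transformation** — each variable is transformed toward normality by the
   best member of a fixed catalog (identity, shifted log/sqrt, reciprocal,
   Box–Cox, rank-based inverse normal), selected by the Shapiro–Wilk
   statistic; order-reversing transforms are multiplied by −1.
2. **Outlier removal** — each variable is regressed on age and gender, and
   cells whose Bonferroni-corrected p-value for the externally studentized
   residual is strictly below 4/n are set missing (cell-wise; subjects are
   never dropped).
3. **Limited-range exclusion** — variables whose most frequent value covers
   at least 80% of non-missing observations are excluded.
4. **Association** — every (cognitive, motor) pair is tested by partial
   Spearman correlation: both rank vectors are residualized on age and
   gender, and the residuals are correlated.
5. **Two-stage multiple testing** — pairs are grouped into hypothesis
   families, one per (motor variable × cognitive domain). Families are
   screened by their Simes p-value at α = 0.05 (strict); within each
   selected family, Benjamini–Hochberg runs at q = 0.05.

A synthetic cohort generator with ground truth (planted links with exact
population partial Spearman correlations, injected outlier cells, degenerate
variables) and a Monte-Carlo harness for operating characteristics
(family selection rate, empirical FDR, power, recovery rates) are included,
along with CSV/JSON/YAML I/O and a publication-style report writer. The
methods vignette (`vignettes/two-stage-association.Rmd`) documents the
statistical details, the generator's assumptions, and known caveats of the
two-stage procedure.

## Worked example

```r
library(cogmob)

ce <- simulateCohort(generatorConfig(seed = 7))  # defaults: n = 124,
ce                                               # ages 27-80, 56.5% female
#> CohortExperiment: 124 subjects, 30 cognitive and 22 motor variables
#>   cognitive domains: executive, speed, memory, language
#>   motor domains:     variability, transition, turn, asymmetry, rhythm, pace
#>   ground truth attached (synthetic cohort)

rep <- runPipeline(ce)
rep
#> AssociationReport: 84 hypothesis families, 9 selected (Simes p < 0.05 )
#>    10 association(s) at within-family BH level 0.05
#>  cognitive_domain         cognitive_id motor_domain             motor_id    rho adjusted_p
#>         executive      wcst_persev_err  variability st_stride_regularity -0.257     0.0477
#>         executive        paper_folding         turn    turn_yaw_duration -0.306     0.0067
#>             speed             waisr_ds  variability st_stride_regularity  0.250     0.0379
#>             speed      digit_symbol_rt  variability   st_stride_time_var -0.275     0.0150
#>             speed letter_comparison_rt         turn    turn_yaw_duration  0.286     0.0100
#>            memory       srt_last_trial  variability st_stride_regularity  0.238     0.0412
#>          language     category_fluency  variability dt_stride_regularity -0.266     0.0213
#>          language             synonyms    asymmetry     dt_step_symmetry -0.272     0.0169
#>          language     category_fluency         pace      tug_ap_duration -0.227     0.0469
#>          language             antonyms         pace      tug_ap_duration -0.223     0.0469
```

The default generator plants three links of partial correlation 0.30–0.35;
at n = 124 the pipeline recovers some but not all of them (here
`paper_folding ~ turn_yaw_duration`), and a single cohort's report also
contains chance findings — which is exactly why the package ships a
Monte-Carlo harness instead of inviting conclusions from one draw:

```r
oc <- estimateOperatingCharacteristics(scenarioConfig("signal"),
                                       nReplicates = 500, seed = 2)
oc@familySelectionRate  # ~1: families with a planted 0.5 link at n = 500
oc@empiricalFdr         # ~0.03, below the nominal q = 0.05
oc@power                # ~1
```

Reports and cohorts round-trip through plain text:

```r
writeReport(rep, "report.tsv")  # plus report_families.tsv audit log
writeCohort(ce, "cohort_dir")   # data.csv, meta.csv, covariates.csv, truth.json
ce2 <- readCohort("cohort_dir/data.csv", "cohort_dir/meta.csv",
                  "cohort_dir/covariates.csv")
```

## License

MIT (see `LICENSE`).
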