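# cnexpress

Integrative analysis of DNA copy number and gene expression in tumor
cohorts, with downstream prioritization of copy-number-associated
transcripts by case/control status and survival.

## The problem

Tumor genomes carry segmental copy-number aberrations (CNAs). A gene inside
an amplified or deleted segment may change expression in proportion to its
DNA dosage, and such dosage-driven transcripts are candidate drivers of
tumor progression. Given (a) a per-SNP copy-number ratio matrix from a SNP
array, (b) an expression matrix from an expression array on the same
tumors, and (c) an independent case/control cohort with survival follow-up,
`cnexpress` answers, in order:

1. Where is the genome amplified or deleted, and how much of it?
   (fused-lasso segmentation; gain/loss calls at ratio 0.93/1.07 or a
   stringent 0.7/1.4 preset)
2. What is each transcript's DNA copy number? (mean of the segmented ratios
   of overlapping SNPs, or of the closest 5 / all SNPs within 250 kb)
3. Which transcripts' expression tracks their copy number? (per-transcript
   Huber robust regression `Y = b0 + b·X + e` of renormalized log2
   expression on log2 copy number, two-sided t test with N−2 df,
   Benjamini–Hochberg FDR, π₀-based signal-proportion estimate,
   six-bin dose–response summary, Bonferroni genome scan)
4. Are the selected transcripts enriched for case/control and survival
   signal in an independent cohort? (regression Z-scores; permutation
   enrichment against 1000 random same-size sets)
5. Do they improve survival prediction over clinical stage? (first two
   principal components of the flagged sets in Cox models, jackknife
   leave-one-out risk scores, 2-year time-dependent ROC of
   Heagerty–Lumley–Pepe, paired-bootstrap AUC comparison)

A synthetic-data module (`simulate_study()` and friends) generates
two-cohort studies with segmental CNAs, dosage-responsive transcripts,
case/control shifts and proportional-hazards survival signal, all with
recorded ground truth; the test suite uses it for calibration and recovery
checks. See the methods vignette (`vignettes/cnexpress-methods.Rmd`) for
models, assumptions and design decisions.

## Worked example

```r
library(cnexpress)

study  <- simulate_study(seed = 1)            # 3000 SNPs, 2000 transcripts,
                                              # 20 tumors + 148/45 cohort
report <- run_pipeline(study, pipeline_config(seed = 1))
```

The report (written as `report.json` when `out_dir` is given) contains, for
this seed:

```
retained: 1465 of 2000 (73.2%)            # transcripts passing the 4 filters
mapped >=5 SNPs: 94.9 %                   # transcripts with >=5 informative SNPs
genome altered: 28.5 - 81.9 %             # per-sample CNA burden
FDR<1% transcripts: 467 of 1452           # copy-number-associated transcripts
signal proportion: 32.5 %                 # estimated fraction with real dosage
                                          #   signal (30% was planted)
enrichment p (case/control, survival): 0.000999 0.041
AUC:  stage 0.70   pc_cc 0.78   stage_pc_cc 0.86
      pc_surv 0.95  stage_pc_surv 0.96
stage+PC vs stage p: 0.025, 0.001         # paired bootstrap at 24 months
```

Reading it: about a third of tested transcripts show a real dosage signal
(matching the planted 30%), the 467 FDR-selected transcripts are strongly
enriched for case/control signal in the independent cohort, and adding
their PC risk scores to AJCC stage raises the 2-year survival AUC from 0.70
to 0.86–0.96. The stage-alone Cox model estimates HR 1.84 (95% CI
1.28–2.64) per stage unit against a planted HR of 2.

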