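# tsrquant

Automated tumor-stroma ratio (TSR) quantification for pancreatic-cancer
whole-slide images, end to end: epithelium label generation from CK8/18-DAB
immunohistochemistry by color deconvolution, two-stage epithelium /
tumor-epithelium segmentation with patient-level five-fold cross-validation
and sliding-window inference, alpha-hull delineation of the tumor bulk,
whole-bulk TSR computation, and TSR-based survival analysis. A synthetic
slide-and-cohort generator with exact ground truth makes every stage
testable without any clinical data.

**Who it is for.** Computational-pathology researchers who want a
reproducible, fully inspectable reference pipeline for whole-bulk TSR
quantification and its downstream survival statistics, and who need a
controlled synthetic world in which each stage's recovery can be measured
exactly.

## The statistic at the core

In pancreatic ductal adenocarcinoma the tumor is dominated by desmoplastic
stroma, and the stroma fraction is a candidate prognostic marker.
Classical field-of-view TSR scoring fails in PDAC because the tumor is
heterogeneous, so `tsrquant` computes the ratio across the *entire* tumor
bulk of a section:

    TSR = A_stroma / (A_stroma + A_tumor_epithelium),   measured inside the bulk

where the bulk is the alpha shape (a concave hull: Delaunay triangles kept
iff circumradius <= 1/alpha) of the segmented tumor-epithelium pixels.
High TSR means stroma-rich. Per patient, the slide with the highest TSR
enters a ridge-logistic horizon classifier (death within 6 / 12 / 18
months, five-fold cross-validated AUC) and a Kaplan-Meier stratification at
the cohort-mean TSR with a log-rank test.

## Worked example

```r
library(tsrquant)

# a synthetic slide whose true stroma fraction inside the tumor is 0.7
recipe <- slide_recipe(canvas = c(768, 768), target_stroma_frac = 0.7, seed = 42)
s <- generate_slide(recipe)
s$realized_stroma_frac            # 0.701 — generator hits the target

# stage 1-2: tissue mask, then epithelium labels from the paired IHC image
tis <- tissue_mask(s$he)
epi <- epithelium_mask_from_ihc(s$ihc, tis)
dice(epi, s$truth$epithelium)     # 1.00 — deconvolution recovers the marker

# bulk from the tumor epithelium, stroma inside it, then the ratio
bulk   <- bulk_from_mask(s$truth$tumor_epithelium, alpha = 0.008, stride = 8)
dice(bulk$mask, s$truth$tumor_blob)  # 0.989
stroma <- segment_stroma(s$he, bulk$mask, s$truth$stroma)
compute_tsr(s$truth$tumor_epithelium, stroma, bulk$mask,
            slide_id = "demo", alpha = 0.008)
#> TSRReport [demo]: TSR = 0.711 (stroma_epi)
#>   stroma 132165 um^2, tumor epithelium 53696 um^2, bulk 185861 um^2

# survival: a 200-patient cohort whose hazard rises with TSR (beta = 2)
co <- generate_cohort(cohort_recipe(200, beta = 2, censor_rate = 0.3, seed = 42))
d <- co$clinical; d$tsr <- d$true_tsr
auc <- cv_auc(make_horizon_labels(d, 6), k = 5, seed = 42)
sprintf("6-month AUC: %.2f +/- %.2f", auc$mean_auc, auc$sd_auc)
#> "6-month AUC: 0.70 +/- 0.04"
km <- tsr_km(d)                   # stratify at the cohort-mean TSR
sprintf("log-rank p = %.2g", km$p_value)
#> "log-rank p = 1.6e-06"
```

The measured TSR (0.711) recovers the recipe target 0.7 to ~0.01: the
alpha hull slightly overshoots the true blob in its concave notches, adding
a sliver of external stroma. The cross-validated AUC of 0.70 and the
significant log-rank split reflect the simulated hazard ratio of ~4.5
across the TSR range; a `beta = 0` cohort yields chance-level AUC.

A full pipeline run (synthesis -> tissue -> IHC labels -> two training
stages -> inference -> bulk -> stroma -> TSR -> survival -> evaluation),
with per-stage manifests and resumability:

```r
cfg <- default_config(out_dir = "tsr_run", seed = 1)
run_pipeline(cfg)                  # writes tsr.csv, survival.json, evaluate.json
```

or from the shell via `inst/cli/tsrquant run-all --config cfg.json`.

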