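---
title: "Methods: automated tumor-stroma ratio quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated tumor-stroma ratio quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Pancreatic ductal adenocarcinoma (PDAC) is dominated by a dense desmoplastic
stroma, and the relative amount of stroma versus tumor cells — the
tumor-stroma ratio (TSR) — is a candidate prognostic marker. Manual TSR
scoring selects a single stroma-rich field of view and estimates the stroma
fraction in 10% increments; in PDAC this is unreliable because the tumor
microenvironment is highly heterogeneous. `tsrquant` implements a
whole-bulk alternative: segment the epithelial (tumor-cell) compartment,
delineate the tumor bulk geometrically, segment stroma inside it, and report

$$\mathrm{TSR} \;=\; \frac{A_\text{stroma}}{A_\text{stroma} + A_\text{tumor epithelium}}
\quad\text{measured across the entire tumor bulk,}$$

so that high values mean stroma-rich. The ratio feeds two survival
analyses: a horizon classifier (ridge-logistic regression on TSR plus
clinical covariates, with patient-level five-fold cross-validated AUC at 6,
12 and 18 months) and Kaplan-Meier stratification at the cohort-mean TSR.

The denominator is a genuine modeling choice: whole-bulk TSR
distributions in PDAC skew toward very high values (cohort means above 0.7,
medians above 0.85 are typical of this desmoplastic cancer), and the
clinical reading is that *higher* TSR carries *higher* risk — both only
consistent with stroma-fraction semantics. We therefore default to
`stroma / (stroma + tumor epithelium)` and exclude other bulk tissue
(lumina, necrosis stand-ins) from the denominator; `denominator = "bulk"`
switches to dividing by the whole bulk area.

## Pipeline stages and their assumptions

1. **Tissue-background segmentation** (`tissue_mask`): a classical detector
   — a pixel is tissue when it is darker than a near-white cut (default
   gray 240) or more saturated than an Otsu cut, followed by morphological
   closing (disk radius 2 px) and hole filling. Learned tissue detectors
   exist but none is available in the supported environment; a classical
   detector is deterministic, adequate on both
   synthetic fixtures and real H&E, and makes the mask invariant to
   padding the slide with white glass (the Otsu statistics exclude
   near-white pixels).
2. **Epithelium label generation from IHC** (`epithelium_mask_from_ihc`):
   CK8/18 is an epithelial marker visualized with DAB (brown) over a
   hematoxylin counterstain, so the DAB concentration image obtained by
   color deconvolution is an epithelium map. We use the optical-density
   transform $OD = -\log_{10}(\max(I,1)/I_0)$ with base-10 logarithm and
   the standard published H-DAB absorption vectors (hematoxylin
   (0.650, 0.704, 0.286), DAB (0.268, 0.570, 0.776)); the third basis row
   is their normalized cross product. No universal DAB threshold exists
   (in practice it is tuned per staining batch); our reproducible default
   is Otsu restricted to tissue pixels, with a fixed-value escape hatch, plus
   removal of objects below 50 px at 1.0 um/px (mild cleanup for staining
   artifacts, exposed as a parameter).
3. **Two-stage segmentation** (`train_segnet`, `predict_wsi`): an
   epithelium network (2 classes) is trained on tiles labeled by stage 2;
   its whole-slide predictions, masked with a coarse tumor-bulk
   annotation, yield tumor/normal epithelium labels
   (`generate_tumor_epithelium_labels`) on which the second, 3-class
   network is trained. Tiles are 512 x 512 px at 1.0 um/px; augmentation
   applies flips, blur (sigma 0.5-1.5), HSV jitter (<= 0.05), contrast and
   brightness (<= 20%) each with probability 0.5; splits are always by
   patient (`kfold_split`, five folds).
4. **Tumor bulk** (`alpha_shape`, `bulk_from_mask`): the alpha shape of the
   segmented tumor-epithelium pixel centers — Delaunay triangles kept iff
   their circumradius is at most $1/\alpha$, dissolved into polygons.
   Alpha 0 reduces to the convex hull.
5. **Stroma within the bulk** (`segment_stroma`): a third, multi-tissue
   classifier (background / stroma / epithelium) restricted to the bulk.
   Pre-trained multi-tissue networks (typically trained on colorectal
   H&E) are not available here; the stand-in is trained on synthetic truth
   labels. Passing a
   ready-made mask instead of a model gives the oracle plumbing path used
   for accounting tests.
6. **TSR and survival** (`compute_tsr`, `select_slide`,
   `make_horizon_labels`, `cv_auc`, `km_estimate`): per patient the slide
   with the highest TSR is kept (lexicographic slide-id tie-break,
   recorded). Horizons convert months to days at 30.44 d/month.

## The segmentation backend

No deep-learning framework exists in the supported execution environment
(neither an R nor a Python torch/keras build), so an encoder-decoder
network cannot be trained here. The package's
segmentation backend is a multi-scale filter-bank pixel classifier in the
ilastik tradition: per channel, Gaussian-smoothed intensities and local
standard deviations over a dyadic scale pyramid (`depth` scales, sigma
$2^0 \dots 2^{depth-1}$ px; `width` selects one or both statistics), feeding
a multinomial ridge-logistic head (glmnet). The scale pyramid plays the
encoder role, full-resolution prediction the decoder role. Everything
around the classifier is exactly what a network backend would use and is
contract-tested: per-fold training with patient-level splits, JSON
checkpoints, sliding-window whole-slide inference (window 512, overlap 128)
with per-pixel mean blending over covering windows, mean ensembling over
fold models, background forcing outside the tissue mask, and argmax
tie-breaks toward the lower class code.

Two consequences are worth naming. First, training is a closed-form convex
fit: there are no epochs, so "epoch" budgets in scaled-down training runs
are met trivially, and training is deterministic given the sampling seed.
Second, the classifier's capacity is far below a U-Net's; it succeeds on
the synthetic world because the generator renders compartments that are
separable by color and local texture. A green segmentation test therefore
establishes the correctness of the pipeline *plumbing* (labels, folds,
inference, ensembling), not state-of-the-art segmentation of real H&E.

## The synthetic world

`generate_slide` renders a paired pseudo-H&E / pseudo-IHC slide with exact
ground truth. One roughly circular tissue region of textured stroma
(eosin-pink, low-frequency texture field, Gaussian noise) carries a compact
tumor blob whose boundary is an irregular radial polygon (cosine harmonics,
relative roughness 0.06). Tumor epithelium is rendered as solid,
hyperchromatic elliptical nests placed only inside the blob — a poorly
differentiated, lumen-free morphotype; nests are additionally seeded along
the blob boundary (an infiltrative invasion front), which keeps the alpha
hull of the epithelium tracking the true bulk margin. Normal glands are
ring-shaped (epithelial rim around an empty lumen) and live only outside
the blob, so the tumor / normal distinction is learnable from geometry and
hyperchromasia. Because tumor nests have no lumina, every blob pixel is
either stroma or tumor epithelium, and the blob's stroma fraction equals
the TSR computed from truth masks — the generator's placement loop iterates
until the realized fraction is within 0.005 of the recipe target (the
contract tolerance is 0.03). Wall-to-wall nests cannot tile the blob, so
targets below a 0.05 stroma floor raise an infeasibility error.

The pseudo-IHC image is synthesized through the package's own Beer-Lambert
stain model: DAB concentration 0.85 on epithelium, hematoxylin 0.30-0.35 on
tissue, Gaussian concentration noise, then 8-bit quantization. Label
generation by deconvolution + Otsu is therefore provably near-perfect by
construction (calibration Dice >= 0.95) — this mirrors the near-perfect
epithelium ground truth a staining-restaining protocol yields, and it is a
calibration property of the generator, not evidence about real IHC.

What the generator does *not* emulate: nuclei, scanner artifacts, stain
variation between laboratories, registration error between the H&E and IHC
sections (pairs are pixel-aligned by construction), necrosis, lymphocyte
aggregates, and the duodenal epithelium that causes false positives in
practice. Green end-to-end tests therefore validate the method's internal
consistency, not its clinical performance.

**Cohort model.** `generate_cohort` draws a true TSR per patient from
Uniform(0.2, 0.95) and survival from a proportional-hazards model with
exponential baseline: hazard $\lambda_i = \lambda_0 e^{\beta\,TSR_i}$ with
$\lambda_0 = 1/500$ days$^{-1}$ and $\beta = 2$ by default, so stroma-rich
patients die earlier (hazard ratio $e^{1.5} \approx 4.5$ across the TSR
range), matching the clinical direction of effect. Censoring is an
independent exponential whose rate is root-solved so the expected censored
fraction matches the request (default 0.3). $\beta = 0$ yields the null
world used to check that the AUC machinery does not hallucinate signal.
Ages are Normal(66, 9) clipped to 35-90; categorical covariates are drawn
with realistic imbalance. All randomness flows from one seed per call.

## Numerical choices

- **Coordinates.** 0-based (row, col), half-open windows; polygons in
  (x, y) = (col, row) level-0 pixels; pixel (r, c) center at
  (c + 0.5, r + 0.5). Rasterization decides membership by the pixel-center
  even-odd rule with centers exactly on an edge counted *in* — a
  deterministic tie-break that also makes mask -> polygon -> mask round
  trips exact for rectilinear boundaries.
- **Out-of-bounds reads pad with white** (255), matching H&E glass.
- **Alpha units.** Alpha is in 1/pixels at the segmentation spacing. The
  conventional value 0.038 (circumradius 26.3 px at 1.0 um/px) matches
  cellular-scale segmentations of real slides and is the package default.
  The synthetic generator's nests are an order of magnitude coarser than
  cells (radius 10-22 px, inter-nest spacing up to ~100 px at stroma
  fraction 0.9), so pipeline defaults and acceptance runs use the
  scale-matched alpha 0.008 (circumradius 125 px, about 1.5x the sparsest
  stated nest spacing). This value follows from the generator's stated
  geometry, not from tuning against test outcomes.
- **Delaunay robustness.** Bowyer-Watson with coordinates normalized to a
  unit box; because floating-point incircle tests can drop slivers at
  near-collinear hull points, the triangulation boundary is convexified
  afterwards (a true Delaunay boundary is convex), which makes
  "alpha = 0 equals the convex hull" exact to machine precision.
- **Otsu.** Histogram with 256 bins between the data extremes; the cut
  maximizes between-class variance; pixels strictly above are foreground.
- **Quantiles.** ROI Dice summaries report median and IQR = Q3 - Q1 with
  linear-interpolation quantiles (R type 7).
- **Kaplan-Meier.** Standard product-limit estimator (via the survival
  package); subjects censored at t leave the risk set after t. For the
  censored toy {6, 6, 6, 7, 10} / {1, 1, 0, 1, 0} this gives S(6) = 0.6
  and S(7) = 0.3.
- **Horizon labels.** Dead within the horizon -> 1; survived past it -> 0;
  censored at or before it -> excluded (switchable to label-0 via
  `censored_as_alive`), because labeling unobserved patients alive biases
  toward the negative class.
- **Degenerate inputs.** Fewer than 3 distinct or collinear points give an
  empty alpha shape with a warning; an empty tumor-epithelium mask gives an
  empty bulk; TSR with neither stroma nor tumor epithelium in the bulk is
  an error, not a number.

## File formats

The execution environment provides no R bindings for PNG or TIFF, so the
package carries a minimal PNG codec (8-bit gray/RGB, non-interlaced; all
five scanline filters on read) built on base R's zlib bindings, and
represents multiresolution slides as a manifest-driven pyramid directory of
per-level PNGs. Annotations are GeoJSON FeatureCollections in level-0 pixel
coordinates with rings explicitly closed on write; masks are grayscale PNGs
with a JSON sidecar carrying spacing and the class-code table; clinical
tables are CSV with a documented header contract.

## Known limitations

- The filter-bank classifier cannot reproduce U-Net-grade segmentation of
  real histology; on real slides the package's value is the surrounding
  pipeline (label generation, bulk geometry, TSR accounting, survival).
- Stain vectors are fixed, not estimated from the image; H&E stain
  normalization is out of scope.
- Vendor WSI containers (MRXS/NDPI/SVS) and JPEG2000 are not read.
- The alpha-hull bulk inherits the segmentation's errors; disconnected
  epithelium at very high stroma fractions fragments the hull unless alpha
  is scale-matched.
- Survival analyses are associational: the synthetic cohort's hazard model
  is the package's own stated world.
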