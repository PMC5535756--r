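# ccvnuclei

Classification of segmented 64×64 single-nucleus image patches (normal
vs. abnormal hepatocellular-carcinoma cells) from hand-crafted
features, with a contour-irregularity statistic — the **concave–convex
variation (CCV)** — used to reweight each classifier's posterior
probabilities.

Pathologists read nuclear atypia largely from shape: a normal nucleus
has an approximately convex outline, an abnormal one is lobed and
irregular. `ccvnuclei` turns that prior into a correction step. For a
traced nucleus contour split into four curves at its bounding-box
tangent points, slopes `k = (y1−y2)/(x1−x2)` from each curve's anchor
to its 2-pixel-interval samples form a slope vector `K`; CCV is the
number of adjacent opposite-sign pairs in the signs of `ΔK`, summed
over the four curves (e.g. the sign pattern `[+,+,−,−,+,−]` counts 3).
With class means `m1 = mean(CCV_normal)` and `m2 = mean(CCV_abnormal)`
from training masks, a test sample's initial posterior `p` is updated
to `p' = min(1, ω·p)`, where `ω ∈ [0.8, 1.2]` is a continuous
piecewise-linear function of the sample's CCV (1.2 at the regular
extreme and 0.8 at the irregular extreme for initially-normal calls,
and the mirror image for initially-abnormal calls;
`ω_normal + ω_abnormal ≡ 2`). If `p' < 1/2`, the label flips.

The package provides, as separately usable modules:

* a synthetic patch generator (star-convex polar shapes with
  controllable lobes/noise; two-level textures with chromatin-like
  smoothed noise) standing in for non-public hospital data;
* bilateral filtering and Moore-neighbour contour tracing;
* a feature bank: intensity statistics, mask morphology, GLCM
  statistics (ASM/ENT/CON/COR/IDM), cellwise LBP histograms, aggregated
  SIFT keypoint descriptors, Tamura coarseness/contrast/directionality;
* sparse-contribution (SC) feature selection: min–max normalisation,
  Pearson redundancy pruning, contrast mapping to [−1,1], unit-circle
  contribution scoring `C(x) = Σ ±(1−√(1−x²))`, thresholding and
  sparsification;
* three probability classifiers behind one contract: an extreme
  learning machine fitted by Moore–Penrose pseudoinverse (implemented
  here), linear SVM and random forest (standard backends);
* metrics (ACC/SEN/SPE/P/R/F1), PR/ROC curves with trapezoidal AUC,
  and an experiment driver.

## Worked example

```r
library(ccvnuclei)

ex <- run_experiment(experiment_config(seed = 1))
ex$metrics
#>   classifier variant   ACC  SEN  SPE     P    R    F1 auc_roc auc_pr
#> 1        elm    base 0.910 0.92 0.90 0.902 0.92 0.911   0.975  0.976
#> 2        elm     ccv 0.970 0.97 0.97 0.970 0.97 0.970   0.996  0.996
#> 3        svm    base 1.000 1.00 1.00 1.000 1.00 1.000   1.000  1.000
#> 4        svm     ccv 1.000 1.00 1.00 1.000 1.00 1.000   1.000  1.000
#> 5         rf    base 0.995 1.00 0.99 0.990 1.00 0.995   1.000  1.000
#> 6         rf     ccv 0.995 1.00 0.99 0.990 1.00 0.995   1.000  1.000
```

Each row is one classifier evaluated on 100 test patches per class
(200/class training), `base` before and `ccv` after the posterior
reweighting. On this benchmark the adjustment lifts the weakest
classifier (ELM) from 91% to 97% accuracy and leaves the already
saturated SVM/RF results unchanged — the intended behaviour: CCV
corrects low-confidence mistakes whose contour evidence contradicts
the initial call.

The pieces compose individually:

```r
ds    <- generate_dataset(100, seed = 1)        # 200 labelled patches
ccvs  <- vapply(ds, function(p) ccv_of_mask(p$mask), integer(1))
model <- fit_ccv_model(ccvs, patch_labels(ds))  # m1 ~ 1.8, m2 ~ 7.9
weight_normal(c(2, 5, 9), model)                # 1.2 ... 0.8
```

A command-line wrapper lives in `inst/scripts/ccv_pipeline.R`
(`generate` and `pipeline` subcommands).

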