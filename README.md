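# maskedlbp

Face verification under disguise: detect which face patches are occluded by
accessories, and match only the rest.

Accessories — sunglasses, scarves, wigs, caps, masks — do more than hide
facial detail: a matcher that compares an eye region against dark plastic is
being fed actively misleading evidence. `maskedlbp` implements a two-stage
verification pipeline for this setting:

1. **Patch classification.** A face, normalized to a canonical 130 × 150
   raster, is tessellated into a 5 × 5 grid of 26 × 30 patches. Each patch
   `P` is described by the *intensity and texture encoder*

   `ITE(P) = [ hist_int(P) ‖ hist_LBP(P) ]  ∈ ℝ⁵¹²`,

   the concatenation of its 256-bin intensity histogram and its 256-bin
   local-binary-pattern histogram (basic 8-neighbour LBP, ≥ convention,
   clockwise from top-left, MSB first). An RBF-kernel SVM — hyper-parameters
   by grid search with subject-grouped 5-fold cross-validation — scores each
   patch; `score < τ` means *biometric* (usable facial appearance), otherwise
   *non-biometric* (accessory). Per-face decisions form the flag matrix `F`.

2. **Masked matching.** For a gallery–probe pair, the pair mask
   `δ(i,j) = [F_g(i,j) = biometric] ∧ [F_p(i,j) = biometric]` keeps only the
   patches both images agree on, and the verification distance is

   `D(g, p) = mean over δ-true patches of χ²(hist_LBP(g, ij), hist_LBP(p, ij))`,

   with `χ²(a, b) = Σ (a−b)²/(a+b+ε)`. A pair with no usable patch is
   rejected outright. Acceptance is `D ≤ θ`; sweeping `θ` yields the ROC,
   GAR at fixed FAR, and the EER.

The package also ships the full evaluation protocol (per-subject
gallery/probe splits, three masking arms, FAR/GAR/accuracy from response
counts, disguised-region error analysis on the 5 × 5 grid) and a seeded
synthetic disguised-face generator with ground-truth patch annotations, so
the whole pipeline is exercisable without access to restricted face
databases. See the vignette `vignettes/masked-face-verification.Rmd` for the
design rationale and the generator's scope.

Audience: biometrics / face-recognition researchers who need an
occlusion-aware patch-based baseline, and anyone who needs a reproducible
occlusion fixture with exact ground truth.

## Worked example

A small end-to-end run (10 synthetic subjects, 5 train / 5 test; a reduced
3 × 3 SVM grid keeps it at a couple of minutes):

```r
library(maskedlbp)

spec <- synthetic_spec(n_subjects = 10, n_train_subjects = 5,
                       total_images = NULL, seed = 7)
ds <- generate_dataset(spec)
nrow(ds$manifest)
#> [1] 76

cfg <- run_config(cost_grid = 2^c(1, 5, 9), gamma_grid = 2^c(-7, -3, 1),
                  seed = 3)
model <- fit_dataset_classifier(ds, cfg)
model
#> patch_classifier: RBF SVM (cost=2, gamma=0.0078125), tau=-0.3741 at 'biometric_recall'

test <- dataset_patch_data(ds, "test", cfg)
pred <- classify_patch(score_patch(model, test$descriptors), model$tau)
round(mean(pred == test$labels), 3)   # flag recovery vs ground truth
#> [1] 0.765

for (arm in c("predicted", "ground_truth", "all")) {
  ex <- verification_experiment(ds, arm, model = model, config = cfg)
  cat(sprintf("%-13s GAR@1%%FAR = %5.1f%%   EER = %4.1f%%\n",
              arm, 100 * gar_at_far(ex$roc, 0.01), 100 * eer(ex$roc)))
}
#> predicted     GAR@1%FAR =  85.0%   EER = 15.0%
#> ground_truth  GAR@1%FAR = 100.0%   EER =  0.0%
#> all           GAR@1%FAR =  40.2%   EER = 13.7%
```

Reading the numbers: with ground-truth occlusion masks, genuine pairs of
these heavily disguised faces verify essentially perfectly at 1% false
accept rate, while the plain-LBP baseline (`all` patches) manages 40%;
SVM-predicted flags recover most of the gap. Flag recovery (76.5% here) is
limited at this toy scale by threshold calibration across only 5 training
subjects — at the full 75-subject composition it sits around 95%.

A file-based interface with the same stages is available as a CLI
(`inst/scripts/maskedlbp.R`): `synth`, `train`, `flags`, `match`,
`evaluate`, configured by a single JSON file.

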