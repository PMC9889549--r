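# attnfusion

Attention-based multimodal fusion for disease-risk classification from
paired 3D image volumes and tabular clinical records, in pure R.

Risk prediction of brain degeneration (Alzheimer's disease, diabetes
mellitus) increasingly combines two very different data modalities: a
volumetric scan (e.g., a T1-weighted MRI) and an electronic health
record — a short vector of demographic, laboratory and
cognitive-assessment features. Simple fusion strategies (concatenating,
adding, or attending once over pooled features) ignore the *intra-modal*
dependencies among pixels and slices and the *inter-modal* dependencies
between image content and clinical context. `attnfusion` implements an
encoder–decoder framework that models both:

* an **intra-modal encoder** — spatial self-attention over the
  `H'×W'` positions of each feature-map slice,

  `S_{j,i} = softmax_i( K(v_i)ᵀ Q(v_j) )`,   `M̂_j = Σ_i V(v_i) S_{j,i}`,

  plus temporal self-attention along the `D'` slice axis, with `K, Q, V`
  as 1×1×1 convolutions, the streams summed; the clinical record is
  embedded by a fully connected layer into the same `C`-dimensional
  space and broadcast over the grid;
* an **inter-modal encoder** — bidirectional cross-attention per slice:
  each modality's query scores the opposite modality's keys (*affinity*),
  and the attended opposite-modality values are added to the local
  representation as a residual (*aggregation*,
  `Agg_j = Σ_{i∈Ω_j} A_{i,j} Ω̂_{i,j} + H_j`); slices are then
  spatially pooled into fused matrices `M, S ∈ R^{D'×C}`;
* a **disease-oriented decoder** — a learnable classification query
  `X_d ∈ R^{K×C}` drives two multi-head attention layers over `M` and
  `S`; their sum is flattened through one fully connected layer into
  `K` class probabilities, trained with cross-entropy under SGD
  (momentum 0.9, weight decay 1e-4, polynomial learning-rate decay
  `0.01·(1 − iter/total)^0.9`).

The package also ships a synthetic paired-cohort generator whose class
signal can be planted in the image only, in the record only, or split
across both so that *only* a fusing model can recover it; a seeded
training engine with stratified k-fold cross-validation; ablation
(SAM/TAM/CAM), head-count-sweep and fusion-baseline comparators
(early/intermediate/late fusion, single-modality models); macro
one-vs-rest multiclass metrics (sensitivity, accuracy, specificity,
AUROC); attention-map export to NIfTI with orthogonal PNG overlays;
and a command-line interface. Everything — including the 3D
convolutions, attention blocks and their backward passes — is
implemented in base R matrix code and verified against brute-force
oracles and finite-difference gradients.

## Worked example

Simulate a 60-subject cohort whose label is carried by the intensity of
a planted hyperintense blob, cross-validate the full model, then fit
and predict:

```r
library(attnfusion)

ds  <- generate_dataset(synth_config(n_samples = 60,
                                     signal_mode = "image_only", seed = 1))
cv  <- cross_validate(ds, train_config(n_folds = 3, seed = 1))
cv$report
#> Cross-validated metrics (mean ± std over folds):
#>   sensitivity  0.917 ± 0.024
#>   accuracy     0.917 ± 0.024
#>   specificity  0.917 ± 0.024
#>   auroc        0.990 ± 0.008

fit <- train_model(ds, train_config(n_folds = 3, seed = 1))
fit
#> <risk_model> proposed fusion, K = 2, C = 12, 6 heads, 5846 parameters
#>   attention blocks: SAM + TAM + CAM
#>   trained 160 iterations, final loss 0.0003

head(predict(fit, ds), 3)
#> # A tibble: 3 × 4
#>   subject_id .pred_class  .pred_0  .pred_1
#> 1 S0001                0 0.998    0.00170
#> 2 S0002                1 0.000475 1.000
#> 3 S0003                0 1.000    0.000478
```

The report reads as in a clinical ML paper: mean ± std over folds of
macro one-vs-rest sensitivity/specificity/AUROC and overall accuracy.
`run_ablation()`, `head_sweep()` and `compare_fusion_variants()` return
tidy tibbles with `autoplot()` methods; `attention_saliency()` /
`export_attention_map()` produce per-voxel attention maps.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/attnfusion simulate --out data/ --seed 1
Rscript inst/cli/attnfusion train --data data/ --out fit/
Rscript inst/cli/attnfusion evaluate --data data/ --model fit/model.rds --out eval/
```

## Package layout

| where | what |
|---|---|
| `R/synth-data.R` | paired-cohort simulator, NIfTI/CSV/JSON round-trip |
| `R/backbone.R` | pluggable 3D CNN backbones |
| `R/intra-modal.R`, `R/inter-modal.R` | spatial/temporal self-attention, cross-attention affinity + aggregation |
| `R/decoder.R` | multi-head attention decoder, classification query, loss |
| `R/train.R` | SGD engine, CV, ablation / head-sweep / fusion comparators |
| `R/metrics.R` | confusion, macro one-vs-rest metrics, fold aggregation |
| `R/saliency.R`, `R/cli.R` | attention-map export, command line |
| `vignettes/attention-fusion.Rmd` | the methods vignette: model, assumptions, calibration of the generator, design decisions |
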