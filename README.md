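# liverseg

Automatic liver segmentation for 2D CT slices, with no user interaction:
gray-level co-occurrence (GLCM) texture features feed an **auto-context
cascade** of AdaBoost pixel classifiers, and the resulting prior
probability map drives a **prior-guided random walker** that settles the
boundary.  The package also provides the standard segmentation evaluation
metrics (VOE, RVD, ASD, RMSD, MSD) with their challenge scoring, and a
synthetic abdominal-phantom generator so the whole pipeline can be trained,
run and evaluated without any external data.

## The method in brief

For every pixel, 12 co-occurrence statistics over 8 patch offsets give a
96-dimensional appearance vector.  Stage 0 of the cascade is discrete
AdaBoost (decision stumps) on appearance alone; its margin H becomes a
probability through p = e^H / (e^H + e^-H).  Each later stage u = 1..U is
trained on appearance **plus context**: probabilities of the previous
stage's map sampled along 8 rays at 45° intervals at radii {3, 6, 9, 12,
15}, so the cascade progressively exploits the spatial layout of the liver
hypothesis.  The final map seeds a random walker whose edge weights fuse
intensity and probability differences,

    w_ij = exp(-beta * ((1 - alpha) (G_i - G_j)^2 + alpha (P_i - P_j)^2)) + eps,

and unseeded pixels are resolved by a sparse harmonic (Dirichlet) solve;
labels threshold the potential at 1/2.  Where a neighboring organ shares
the liver's intensity, the probability term cuts the contact that intensity
alone cannot.

## Worked example

```r
library(liverseg)

# synthesize a cohort: 6 training slices, 2 held-out
ds  <- generate_dataset(6, 2, phantom_spec(), seed = 1)

# fit the auto-context cascade (stage 0 + U = 4 context stages)
mod <- liver_prior_model(ds$train, rng_seed = 1)
mod
#> Auto-context liver prior model
#>   stages: 5 (U = 4 context iterations)
#>   appearance features: 96 | context features: 41
#>   trained on 6 case(s), 2000 pixels/class/case

# segment a held-out slice and evaluate it
te  <- ds$test[[1]]
seg <- rw_segment(te$image, mod)
seg
#> Segmentation: 3297 liver pixels (20.1% of image)
#>   seeds: 3297 liver / 13087 background; solver residual 0

dice(te$truth_mask, seg$mask)
#> [1] 0.9710877
seg_metrics(te$truth_mask, seg$mask, te$spec$spacing)
#> VOE 5.62%  RVD 2.00%  ASD 1.26 mm  RMSD 3.21 mm  MSD 24.33 mm
challenge_scores(seg_metrics(te$truth_mask, seg$mask, te$spec$spacing))
#> Challenge scores: VOE 78  RVD 89  ASD 68  RMSD 55  MSD 68  | total 72
```

A Dice of 0.97 means predicted mask and truth coincide almost everywhere;
the VOE/RVD columns report volume disagreement in percent, the three
distance columns summarize boundary error in millimetres (at this phantom's
1 mm pixels the maximum distance is dominated by a single boundary notch),
and a challenge score of 75 marks typical human-rater accuracy on the
reference scale.

A thin command-line wrapper covers the same pipeline
(`inst/cli/liverseg.R` with subcommands `simulate`, `train`, `predict`,
`segment`, `evaluate`, `score`), reading/writing PNG, NIfTI and MetaImage
files with physical pixel spacing.

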