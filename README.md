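# gaitnorm

Normalization and evaluation of 2D gait skeleton keypoint sequences from
freehand single-camera video.

## What problem this solves

Pediatric movement disorders with overlapping phenotypes — early-onset
ataxia (EOA) and developmental coordination disorder (DCD) — are assessed
from routine clinical gait videos: a child walks towards and away from a
single handheld camera (typically 1280×720 at 25 fps) and a pose
estimator (AlphaPose with PoseFlow tracking, COCO-17 layout) converts
each frame into 17 keypoints with confidence scores. Distance-based gait
features such as walking-base width are clinically informative, but raw
pixel distances are incomparable across frames: the skeleton's apparent
size changes with distance from the camera, and its position jitters with
the handheld camera.

`gaitnorm` implements a two-step normalization that removes both
artefacts, plus everything needed around it: a reader for AlphaPose
result files, confidence-based frame cleaning, the evaluation metrics
that rank the scaling variants, and a seeded synthetic gait simulator
with known ground truth.

## The method

For skeleton $S_i$ of frame $i$ (of $N$), with left/right shoulder
$(x^{Ls}, y^{Ls})$, $(x^{Rs}, y^{Rs})$:

$$X'''_{S_i} = \frac{w_0}{w_{S_i}}\Bigl(X_{S_i} - \frac{x^{Ls}_{S_i}+x^{Rs}_{S_i}}{2}\Bigr) + x_0,\qquad
  Y'''_{S_i} = \frac{h_0}{h_{S_i}}\Bigl(Y_{S_i} - \frac{y^{Ls}_{S_i}+y^{Rs}_{S_i}}{2}\Bigr) + y_0$$

i.e. shift the mid-shoulder point to the origin (cancels camera jitter),
rescale by a segment reference $w_0 = \overline{w_{S_i}}$,
$h_0 = \overline{h_{S_i}}$ over the frame's own scale (cancels
camera-distance size change), and recentre at $(x_0, y_0) = (640, 200)$.
Seven rules define $(w_{S_i}, h_{S_i})$: four anisotropic bounding-box
variants (`BoN` over all keypoints, `S` shoulders, `H` hips, `LS_RH`
left-shoulder/right-hip) and three isotropic single-distance variants
(`LS_RH_d` left-shoulder→right-hip, `MS_MH_d` mid-shoulder→mid-hip, `ASH`
the mean of the two shoulder→opposite-hip diagonals). Only the isotropic
rules are per-frame similarity transforms and therefore preserve every
joint angle; they are the recommended ones. Normalization quality is
judged by the mean absolute angle error (12 joint/limb angles) and the
mean variance of bilateral pair distances (shoulders, wrists, hips,
ankles), with Mann–Whitney U tests between clinical groups. See the
vignette (`vignettes/gait-normalization.Rmd`) for the full account.

## Worked example

```r
library(gaitnorm)

# simulate an ataxic child walking towards the camera
sim <- simulate_gait(synthetic_gait_config(n_frames = 100,
                                           profile = "EOA", seed = 7))
sim$segment
#> Gait segment: 100 frames x 17 keypoints
#>    participant = sim-EOA-7, group = EOA, direction = towards, label = synthetic
#>   frames 0 .. 99 ; mean confidence 0.859

nrm <- normalize_segment(sim$segment, "ASH")
var(pair_distance_series(sim$segment, "shoulders"))  # 267.0988
var(pair_distance_series(nrm, "shoulders"))          # 2.150769
angle_error(sim$segment, nrm)$overall                # 1.000001e-13
```

The shoulder-distance variance of 267 px² in the raw track is almost
entirely the camera-distance artefact (shoulders are rigid in the coronal
plane); `ASH` normalization collapses it to ~2 px² (residual keypoint
noise) while changing no angle (error ~1e-13 degrees).

A full study-shaped run — cleaning, all seven methods, group tests:

```r
study <- synthetic_study(n_per_group = 2, n_frames = 60, seed = 1)
res <- run_pipeline(pipeline_config(synthetic = study))
res
#> Pipeline run: 24 segments, 1440 frames read, 258 removed by cleaning
#> Likelihood: 0.840 before -> 0.884 after cleaning
#>   paired t(23) = 12.89, p = 5.26e-12
#>
#> Mean absolute angle error (degrees):
#>   method overall
#>      BoN   2.229
#>        S   4.548
#>        H   5.532
#>    LS_RH   1.374
#>  LS_RH_d   0.000
#>  MS_MH_d   0.000
#>      ASH   0.000
#>
#> Mean variance of pair distance (px^2):
#>    method shoulders   wrists    hips   ankles
#>  original   275.126 4778.575 136.855 3739.667
#>  ...
#>       ASH     2.085 4116.501   1.938 3530.367
```

Reading: anisotropic methods distort angles (up to 5.5° mean error for
`H`); the isotropic methods distort none. After `ASH` the rigid pairs
(shoulders, hips) drop to a few px² while the wrists/ankles — the
clinical signal — retain their variance.

Clinical AlphaPose output is processed the same way: pass the result
JSONs and a segment-annotation CSV (columns `participant_id`, `group`,
`direction`, `segment_label`, `start_frame`, `end_frame`) to
`pipeline_config(input = ..., annotations = ...)`. A thin command-line
wrapper is available in `exec/gaitnorm`
(`simulate` / `normalize` / `evaluate` / `run`).

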