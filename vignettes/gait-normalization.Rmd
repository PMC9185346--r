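---
title: "Normalizing 2D gait skeletons from freehand video: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalizing 2D gait skeletons from freehand video: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitnorm)
```

## The problem

Clinical gait recordings of children with movement disorders — early-onset
ataxia (EOA), developmental coordination disorder (DCD) — are routinely
captured with a single handheld camera in the coronal plane. Modern pose
estimators turn each frame into 17 keypoints (COCO layout: nose, eyes,
ears, shoulders, elbows, wrists, hips, knees, ankles) with a confidence
score per keypoint. Distance-based gait features (walking-base width,
wrist separation) are clinically informative, but two artefacts make raw
pixel distances incomparable across frames:

1. the skeleton's apparent size changes monotonically as the child walks
   towards or away from the camera, and
2. the skeleton's position jitters with the handheld camera.

`gaitnorm` implements a two-step normalization that removes both, seven
variants of its scaling rule, and the metrics used to judge them.

## The normalization

Let $S_i$ be the skeleton of frame $i$ ($i = 1,\dots,N$) with coordinates
$(X_{S_i}, Y_{S_i})$, and let $Ls$, $Rs$ denote the left and right
shoulder.

**Step 1 — position shifting.** Every frame is translated so the
mid-shoulder point is the origin:
$X'_{S_i} = X_{S_i} - \tfrac{x^{Ls}_{S_i}+x^{Rs}_{S_i}}{2}$, and likewise
for $Y$. This cancels camera translation (jitter) exactly.

**Step 2 — size scaling.** Each frame is rescaled by a segment-level
reference over a frame-level scale,
$X''_{S_i} = \tfrac{w_0}{w_{S_i}} X'_{S_i}$,
$Y''_{S_i} = \tfrac{h_0}{h_{S_i}} Y'_{S_i}$, where $(w_{S_i}, h_{S_i})$
are the frame's scaling width/height under one of seven methods and
$w_0 = \tfrac1N \sum_i w_{S_i}$, $h_0 = \tfrac1N \sum_i h_{S_i}$ are their
means over the segment. Finally the skeleton is recentred at a fixed
offset $(x_0, y_0)$, by default $(640, 200)$ for 1280×720 video (the
offset is configurable because it is resolution-specific).

The seven scaling methods:

| method | $w_{S_i}$ | $h_{S_i}$ | kind |
|---|---|---|---|
| `BoN` | x-extent of all 17 keypoints | y-extent of all 17 | anisotropic |
| `S` | $\lvert x^{Ls}-x^{Rs}\rvert$ | $\lvert y^{Ls}-y^{Rs}\rvert$ | anisotropic |
| `H` | $\lvert x^{Lh}-x^{Rh}\rvert$ | $\lvert y^{Lh}-y^{Rh}\rvert$ | anisotropic |
| `LS_RH` | $\lvert x^{Ls}-x^{Rh}\rvert$ | $\lvert y^{Ls}-y^{Rh}\rvert$ | anisotropic |
| `LS_RH_d` | $\lVert Ls - Rh\rVert_2$ | $= w$ | isotropic |
| `MS_MH_d` | $\lVert \text{mid-shoulder} - \text{mid-hip}\rVert_2$ | $= w$ | isotropic |
| `ASH` | $\tfrac12(\lVert Ls-Rh\rVert + \lVert Rs-Lh\rVert)$ | $= w$ | isotropic |

The isotropic methods apply one factor to both axes, so they are
per-frame similarity transforms: **every joint angle is preserved
exactly** (to float precision). The anisotropic methods stretch x and y
differently and distort angles; the `S` and `H` methods are additionally
fragile because the height of a level shoulder or hip line passes through
zero in frontal walking.

### What the normalization does and does not guarantee

Frames of one segment that differ only by a similarity transform map to
*identical* output frames — this is the sense in which camera distance and
jitter are removed, and the tests assert it at 1e-9 px. Note a subtlety:
applying arbitrary per-frame scalings to a segment rescales the reference
$w_0 = \overline{w_{S_i}}$ itself, so the output as a whole dilates about
$(x_0, y_0)$ by the ratio of references. Invariance therefore holds
*modulo the segment's global size unit*, which is an arbitrary convention
(it cancels in any within-segment comparison); per-frame variability, the
quantity that corrupts distance features, is removed exactly. The
normalization is also idempotent: normalized input is its own fixed point.

### Numerical choices

* Degeneracy guard `eps = 1e-6` px on $w_{S_i}, h_{S_i}$: below pixel
  quantization any scale is meaningless. Frames under the guard either
  abort (`on_degenerate = "error"`, default) or are dropped from both the
  reference mean and the output with a warning (`"skip"`). The pipeline
  defaults to `"skip"` because `S`/`H` provably produce near-zero heights
  on real frontal gait.
* Frame scales are always computed from the original (unshifted)
  coordinates; all seven rules are translation-invariant, so this is
  equivalent and stated only for determinism. Reference means are taken
  over the frames retained after cleaning, within one segment, never
  pooled across segments.
* Output coordinates may leave the nominal image; they are not clipped,
  since clipping would corrupt distances.
* Conditioning: a frame whose scale is tiny (e.g. hips separated by
  microns under `H`) is magnified by $w_0/w_{S_i}$, and float error in the
  input is magnified with it. The 1e-9 px reproducibility properties hold
  on well-conditioned skeletons (bilateral landmarks separated by pixels,
  as in real data), not at adversarial near-degeneracy.

## Cleaning

Frames where body parts are occluded or lost carry unreliable keypoints
and are excluded before analysis, detected through confidence scores. A
frame is removed when any *required* keypoint (default: both shoulders
and both hips — the anchors every scaling rule needs) falls below
`min_keypoint_confidence` (default 0.3), or when fewer than
`min_fraction_valid` (default 0.5) of all 17 keypoints reach it. These
defaults are this package's choices; removal is idempotent and monotone
in the threshold. Likelihood summaries average all confidences per unit
(default: one segment; optionally one participant-direction recording)
and report mean and SD ($n-1$ denominator) across units; a paired t-test
compares before/after cleaning per unit.

## Evaluation metrics

**Mean absolute angle error.** Twelve angles per frame: four relative
joint angles (left/right elbow: wrist→elbow vs elbow→shoulder; left/right
knee: hip→knee vs knee→ankle, each in $[0,180]$ via the normalized dot
product) and eight absolute angles (the same eight limb vectors against
the horizontal, undirected, in $[0,180)$). Errors between a segment and
its normalization are minimal circular differences — wrapped into
$[0,90]$ for the undirected absolute angles so that 179° vs 1° counts as
2°, not 178° — averaged over frames, then over segments, then over the 12
angles. The aggregation order is a reporting choice (the differences
between orders are second-order); it is recorded in the report settings.
The screen-down y axis affects no metric: all are signless.

**Mean variance of pair distance.** Per segment, the variance (sample,
$n-1$; a global switch to $n$ exists for sensitivity checks) of the
per-frame Euclidean distance between a bilateral pair — shoulders,
wrists, hips, ankles — then the mean across segments, optionally per
clinical group. Good normalization drives shoulder/hip variance toward 0
(rigid in the coronal plane) while *retaining* wrist/ankle variance,
which carries the clinical signal (EOA gait is more variable).

**Group tests.** Mann–Whitney U (authored here: exact two-sided p by
enumeration of the rank-sum distribution when $n_x+n_y \le 12$ with no
ties, otherwise normal approximation with tie and continuity
corrections) compares per-segment variances between groups. The sampling
unit is the segment: with 5 participants × 4 segments per group that
gives 20 observations per group, the scale on which U statistics in the
40–70 range arise; per-participant units are available but leave U ≤ 25.
No multiple-testing correction is applied by default (the tests rank
methods rather than confirm hypotheses); Holm correction is available via
`p_adjust = "holm"`. The exact p agrees with the normal approximation to
within 0.02 when both samples have ≥ 5 observations — not for smaller
samples, where the approximation can be off by > 0.1.

**Keypoint dispersion.** Per keypoint: SD of x, SD of y, and RMS radius
about its centroid, quantifying the contraction of keypoint clouds after
normalization.

## The synthetic generator

Every stage is testable without clinical data through a seeded simulator
(`synthetic_gait_config()`, `simulate_gait()`, `synthetic_study()`):

* **Canonical walker** (body frame): a rigid torso (shoulder width 2.0,
  hip width 1.4, trunk 3.0 units; upper/lower arm 1.4/1.3, thigh/shank
  1.8/1.7; 28 px per unit ≈ a 180 px child at reference distance) with a
  gentle sinusoidal torso roll (4°), arms and legs swinging laterally as
  sinusoids (20°/25° at 1 Hz, 25 fps).
* **Clinical profiles**: `EOA` walks with enlarged, dysmetric excursions
  (swing ×1.3), high cycle-to-cycle amplitude variability (SD 0.35),
  per-frame limb-angle noise (6°) and irregular lateral foot placement
  (SD 0.18 units); `CON` is regular (1.0 / 0.05 / 1° / 0.03); `DCD` sits
  between (1.1 / 0.15 / 2.5° / 0.08). The group contrast — larger wrist
  and ankle distance variance in EOA than CON — is therefore structural,
  not a sampling accident: cycle variability alone proved weaker than its
  own sampling noise, so the profile also widens the mean excursion,
  which matches ataxic phenomenology.
* **Weak-perspective camera**: per-frame uniform scaling along a
  monotone ramp (walking towards: 1→2 by default), translation to an
  image anchor plus Gaussian handheld jitter (SD 2 px), additive keypoint
  noise (SD 1 px), keypoint confidences centred at 0.90 (SD 0.05),
  occlusion bursts depressing 8 keypoints to ≤ 0.25 in ~12% of frames,
  and 2% keypoint dropout at confidence exactly 0. A full pinhole model
  and out-of-plane rotation are deliberately excluded: per-frame uniform
  scaling is exactly the variability class the normalization is built to
  remove, so test failures indict the implementation, not model mismatch.
* **Determinism**: one master seed; per-frame and per-cycle substreams
  are derived from it, so runs are bit-reproducible and early frames are
  unchanged when a segment is extended.

`synthetic_study()` assembles the target study design — three groups × 5
participants × 2 directions × 2 segments = 60 segments, with mild
between-child body-size spread — and is what `scripts/acceptance.R` and
the examples run. Problem sizes in the shipped tests (segments of 40–250
frames, 100-replicate group comparisons) were chosen as the smallest
sizes at which the properties are comfortably resolved.

What the simulator does **not** emulate: sagittal-dominant arm swing
(lateral excursions are stylized and larger than in real coronal-plane
video, so distance variances come out larger in px² than on clinical
recordings, and the all-keypoint bounding box (`BoN`) is more
swing-dominated than in reality), pose-estimator bias structure,
re-identification errors, and 3D kinematics. Passing tests demonstrate
the geometry and statistics are right, not that clinical effect sizes
are reproduced.

## Known limitations

* No temporal smoothing of trajectories and no pixel-to-meter
  calibration: both are outside scope; distances stay in (normalized)
  pixels, so only variability-type features, not absolute lengths, are
  interpretable.
* Anisotropic methods distort angles by construction; `S` and `H`
  additionally hit degenerate frames in frontal gait. They are retained
  for comparison, not recommended.
* The direction label (towards/away) comes from the annotation table;
  only a trivial heuristic (sign of the apparent-size trend) is available
  when annotations are absent.
* Group tests are rank-based and uncorrected by default; with 20
  segments per group they are screening tools, not confirmatory tests.
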