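---
title: "Methods: SUVR/SRP preprocessing, hierarchical ensemble CNNs, and phantom validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SUVR/SRP preprocessing, hierarchical ensemble CNNs, and phantom validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Differential diagnosis among Alzheimer's disease (AD), dementia with Lewy
bodies (DLB), mixed AD/DLB pathology, and healthy controls (HC) from
FDG-PET is difficult because the three dementia groups share a large part
of their metabolic signature — relative hypermetabolism in motor cortex,
pallidum and cerebellum, and hypometabolism in parietal and lateral
temporal cortex — while the features that separate them (the occipital
deficit of DLB, the medial-temporal deficit of AD) are comparatively
subtle, and Mixed pathology carries both. `fdgensemble` implements a
complete pipeline for this four-class problem: intensity normalization,
covariance-style residual profiles, an ensemble of small 3D CNNs combined
by a clinically motivated three-step decision rule, and Grad-CAM saliency
reporting against a labeled atlas.

Because clinical FDG-PET cohorts cannot ship with a package, the pipeline
is exercised end to end on synthetic brain phantoms whose class
signatures are planted by construction, so every stage can be validated
as a recovery problem with a known ground truth.

# Image preprocessing

**SUVR.** Each PET volume is divided by its mean intensity over the
cerebellar gray-matter reference region and masked to the brain:
$\mathrm{SUVR}(v) = I(v) / \overline{I}_{\mathrm{cereb}}$. This removes
per-subject global intensity scale (dose, scanner gain); by construction
the mean SUVR over the reference region is exactly 1. No spatial
smoothing is applied anywhere in the pipeline — unsmoothed images carry
the discriminative high-frequency pattern, and the additive unsmoothed
noise of the phantom generator matches that regime.

**Group gray-matter mask.** Per subject, a striatal mask (putamen +
caudate) is merged into the gray-matter probability map by voxelwise
maximum ("integrated" is read as a union-style merge, the weakest
operation consistent with the intent); the merged maps are averaged over
*training* subjects, and voxels below 30% of the maximum of the averaged
map are excluded. Whether the mask should be built on training subjects
only is an open choice; we use train-only to rule out any leakage of
test-set anatomy into preprocessing. The threshold is exposed
(`threshold_frac`, default 0.30) and mask size is monotone non-increasing
in it.

**SRP (subject residual profiles).** Log-SUVR values are doubly centered:
first each subject's whole-brain mean log-SUVR is subtracted (over the
brain mask), then the per-voxel mean of these subject-centered fields
over the training cohort (over the GM mask). In matrix form, with
$L_{sv} = \log \mathrm{SUVR}_{sv}$:

$$\mathrm{SRP}_{sv} = \left(L_{sv} - \tfrac1{|B|}\sum_{v'\in B} L_{sv'}\right) - \mu_v,
\qquad \mu_v = \tfrac1{S}\sum_s \left(L_{sv} - \tfrac1{|B|}\sum_{v'} L_{sv'}\right)$$

This is the scaled-subprofile-model double centering; the package treats
the log scale as canonical for both centering terms (a `center_scale =
"linear"` variant is exposed but not the tested default, since the
whole-brain mean of a log field is the established convention in the SRP
literature). The voxel-mean profile $\mu_v$ is fit on training subjects
only, persisted, and applied unchanged to validation and test subjects —
a deliberate, acknowledged approximation for out-of-sample centering,
since at test time the subject's group is unknown. SUVR values that are
nonpositive inside the mask (introduced by brain masking) are floored at
$10^{-6}$ before the log, with a warning and a count.

An independent oracle (a ten-line log / row-center / column-center matrix
computation) reproduces `compute_srp` elementwise to $10^{-10}$ on toy
cohorts, and the training-cohort per-voxel SRP mean is zero by
construction.

# The phantom generator

The generator is first-class, tested code; it defines the study
conditions for every downstream claim.

* **Atlas.** An ellipsoidal brain with a white-matter core; subcortical
  nuclei (pallidum, putamen, caudate, hippocampus, amygdala) as paired
  balls inside the core; cortical regions (cerebellar GM, occipital,
  parietal, frontal, paired motor and lateral-temporal cortex, plus
  unlabeled background GM) as weighted-Voronoi cells of anatomically
  arranged seeds. Deterministic given the seed (small jitter only);
  every region holds at least 27 voxels so each can carry a 3×3×3
  feature.
* **Baseline.** Gray matter 100 intensity units, white matter 60,
  outside 0 — arbitrary but fixed so cortical SUVR sits near 1 after
  cerebellar normalization.
* **Class signatures.** Multiplicative per-region factors (HC ≡ 1). All
  dementia classes share motor/pallidum/cerebellar factors > 1 and
  parietal/lateral-temporal factors < 1 at full effect
  (1.20/1.20/1.10 and 0.80/0.82); AD adds hippocampus 0.78, DLB adds
  occipital 0.72, and Mixed composes the shared component with both
  disease-specific deviations multiplicatively — the simplest model of a
  brain carrying both pathologies, and it keeps every Mixed factor
  between (or equal to) the AD and DLB extremes. Deviations scale
  linearly with the `effect` parameter.
* **Subject model.** `pet = global_scale × baseline × factor + N(0, noise_sd)`,
  clipped at zero. The per-subject global scale is uniform on
  [0.8, 1.2] — exactly the nuisance SUVR must remove — and the default
  noise SD of 5 units is 5% of the cortical baseline, with no spatial
  correlation (matching the no-smoothing regime).

What the phantoms deliberately do not model: anatomy-realistic cortical
geometry, partial-volume effects, scanner point-spread, registration
error, or inter-subject anatomical variability. Consequences: passing
recovery tests demonstrates that the pipeline's statistics, learning and
decision machinery work as specified on data of the declared structure;
they say nothing about clinical accuracy on real FDG-PET, where the
listed effects dominate the difficulty.

# Networks

The binary backbone is a deliberately small 3D CNN: five 3×3×3
convolution stages with strides (2,2,2,2,1) and channel widths
(8, 16, 32, 64, 128), each followed by instance normalization and ReLU; a
context module; global average pooling; and a final 128 → 2 linear
layer. On the canonical 96×112×96 grid (2 mm MNI-like) the feature map
entering pooling is 128 × (6, 7, 6); on any grid with axes divisible by
16 it is the grid divided by 16. The context module aggregates
multi-scale spatial context through three parallel dilated 3×3×3
branches (dilations 1, 2, 4; 64 channels each) merged by a 1×1×1
convolution back to 128 channels — its internal layout is a design
choice; the normative contract is 128 channels in, 128 out, shape
preserved, at least two receptive-field branches with gradient flowing to
all of them.

A feature extractor is a trained backbone truncated after the context
module plus a fresh He-initialized 3×3×3 stride-2 convolution (128
channels). Its padding is chosen per axis: even extents get padding 1
(output n/2), odd extents padding 0 (output (n−1)/2), which yields
exactly (1,0,1) and 6×7×6 → 3×3×3 on the canonical grid; a degenerate
axis of extent 1 is padded to keep extent 1. The multiclass model
concatenates six extractor outputs — the three SUVR-trained backbones
consume the SUVR image, the three SRP-trained ones the SRP image — into
768 channels, pools to a 768-vector, and reduces 768 → 384 → 50 → 3
through linear layers with ReLU and dropout 0.5 after the 384 and 50
layers (the dropout rate is a package choice).

Everything is implemented in vectorized base R: convolution is im2col
(a cached gather-index plan) followed by a BLAS matrix product, with a
hand-derived backward pass; instance normalization, ReLU, pooling,
linear layers, dropout, softmax cross-entropy and Adam likewise. All
backward passes are verified against central finite differences in the
test suite, including end-to-end probes through the full backbone. At
phantom scale (32³ voxels) a forward+backward pass costs ~30 ms, which
keeps full ensemble training on a single CPU in minutes.

# Training

Per-class splits are 70/10/20 train/val/test by largest-remainder
apportionment. Each binary model trains only on its two classes;
the multiclass head trains only on AD/DLB/Mixed. Augmentation —
same-class mix-up with a uniform weight, horizontal flip along the
declared left-right axis (axis 1), and rotation up to ±10° about a random
grid axis — applies to training samples only, each technique firing
independently with probability 0.10 per sample per epoch (the
per-technique reading of the stated 10%; exposed as config). Mix-up
keeps labels hard because partners share a class; for the multiclass
model the same draw is applied consistently to the SUVR and SRP images.

Optimization is Adam with learning rate 1e-3, batch size 8, up to 30
epochs, early stopping with patience 8, checkpoint selection by
validation loss. These budgets are package choices (the method itself
fixes only the loss): at phantom scale and these learning rates every
binary task converges well inside 30 epochs, and the smaller budget keeps
a full 5-fold cross-validation tractable on one CPU. By default the
multiclass stage trains only the added convolutions and the head
(`freeze_extractors = TRUE`); unfrozen end-to-end training is implemented
and exposed but not the tested default, since with frozen donors the six
context outputs can be cached per subject and only recomputed when an
augmentation fires.

Determinism: the cohort, splits, weight draws, shuffling and augmentation
all derive from explicit integer seeds; two runs with one seed coincide
exactly on one machine (bit-level results may differ across BLAS
implementations).

5-fold cross-validation keeps the test split fixed, rotates stratified
folds over the remaining pool, and refits the preprocessing statistics
(GM mask, voxel-mean profile) per fold on that fold's training portion
only — the no-leakage invariant is enforced structurally and tested.

# The hierarchical ensemble

Step 1 sends the SUVR image to the AD·HC and Mixed·HC models and the SRP
image to the DLB·HC model — the pairing reflects which image type carries
each group's signature best. A subject is HC only if all three vote HC.
Step 2 runs the multiclass model; DLB is final. Step 3 delegates the
AD/Mixed decision to the AD·Mixed specialist, overriding the multiclass
preference between those two. The rule is implemented as a pure function
and checked exhaustively against an independently coded oracle over all
8 × 3 × 2 step-outcome combinations.

The hard-gated ensemble has no native continuous output, so ROC analysis
uses composed chain scores: `HC = ∏ p_HC`, `DLB = (1−HC)·p_mc(DLB)`,
`AD = (1−HC)·(1−p_mc(DLB))·p_am(AD)`, Mixed analogously. The scores sum
to one whenever each model's probabilities do. This composition is a
package invention (flagged as such, isolated in `class_scores()` so it
can be swapped). One caveat discovered in analysis: the argmax of the
composed scores is only guaranteed to agree with the hard decision path
when each model is *decisive* — with three marginal HC votes (each just
above 0.5) the HC product can drop below a downstream score even though
the hard rule says HC. The property suite therefore asserts agreement
for per-model confidence ≥ 0.9, where it holds provably.

Per-class metrics are one-vs-rest sensitivity/specificity/PPV/NPV from
the final labels (undefined denominators reported as `NaN`, absent
classes as `NA`, never as 0), AUROC from the composed scores, and
across folds the mean with a normal-approximation 95% CI
(mean ± 1.96·sd/√5 — the CI method is a package choice).

# Saliency

Grad-CAM targets the last convolutional feature map of each binary
model, the context-module output. Because only pooling and a linear
layer follow, the gradient of a class logit with respect to that map is
exact in closed form ($W_{c,k}/N$ per channel), so the channel weights
are not approximated. Maps are rectified, upsampled to the input grid by
trilinear interpolation, averaged over the correctly classified test
subjects of each class, masked to the brain, and min-max normalized to
[0, 1]; normalization happens after averaging so that the single 0.7
reporting threshold applies to class-level maps. Subject-level upsampling
before averaging is equivalent to the reverse order, both being linear.
Regions with any voxel above threshold are reported with laterality
relative to the axis-1 midline (lower indices are the declared left;
"bilateral" when both sides exceed threshold), sorted by peak saliency.
The multiclass model is excluded from saliency reporting. A constant map
normalizes to all-zero with a warning; a class with no correctly
classified subject is reported absent, not zero.

At 32³ the context output is 2×2×2, so class-level maps are coarse
(eight interpolated octants); localization claims at this scale are
correspondingly coarse and are asserted as planted-region containment
and an inside-versus-outside mean contrast, not as voxel-accurate
boundaries.

# Numerical and degenerate-input choices

* Grids must match exactly (shape and spacing); there is no resampling.
* Non-finite voxels are rejected at volume construction and at read
  time, with a count.
* SUVR requires a nonempty reference with positive mean; empty masks,
  empty cohorts and missing classes raise errors rather than degrading.
* Instance normalization uses ε = 1e-5; a spatially degenerate feature
  map (extent 1) normalizes to its bias, which only arises on grids
  smaller than the networks are intended for.
* Largest-remainder apportionment breaks ties toward the earlier split
  (train before val before test).
* The `fired` attribute on augmented samples exists for diagnostics and
  frequency auditing.

# Problem sizes used in the validation suite

The recovery experiment trains the full ensemble (seven binary models +
multiclass head) on a 32³ phantom cohort of 40/40/40/20 subjects per
class at effect 0.7 and noise SD 5, evaluating one-vs-rest AUROC of the
composed scores and per-class sensitivity on the held-out test split.
The saliency experiment trains AD·HC on SUVR at effect 1.0 (40 AD / 20
HC) and checks planted-region localization at threshold 0.7. Unit and
property tests run on 16³–32³ grids and toy matrix cohorts. These sizes
are the package's chosen validation scale: large enough for the planted
effects to be recoverable, small enough that the whole suite runs on an
ordinary single-CPU machine.

# Known limitations

* Phantoms are geometric, not anatomical; no claim transfers to clinical
  data without retraining and revalidation.
* The backbone's per-stage channel widths and the context module's
  internal structure are package choices satisfying the stated shape
  contracts; a different realization meeting the same contracts would be
  equally valid.
* Pretrained amyloid-PET backbone weights are supported only as an
  optional donor-bundle load path (all layers except the final linear);
  no weights ship with the package, and He initialization is the
  default.
* The composed ROC scores are one reasonable continuous surrogate for a
  hard-gated ensemble, not the only one.
* Training is single-threaded R; the implementation is sized for phantom
  grids, not for full-resolution clinical volumes.
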