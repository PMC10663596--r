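---
title: "Unsupervised diffusion-MRI anomaly detection: models, phantom and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised diffusion-MRI anomaly detection: models, phantom and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Diffusion-weighted MRI measures water diffusion along many gradient
directions; each voxel carries C attenuation values in [0, 1] that encode
tissue microstructure. Infiltrating tumors alter diffusivity beyond their
margins visible on conventional T1/FLAIR, so a model of *healthy* diffusion
signal can delineate anomalies — including early infiltration — without any
tumor labels. This package implements two such models, trained exclusively
on healthy volumes, plus the thresholding, post-processing and evaluation
machinery needed to turn voxelwise scores into binary segmentations and
numbers.

Everything is exercisable end-to-end on a built-in phantom, because real
patient dMRI of this kind is rarely shareable. The phantom is a stand-in,
not a simulation of any specific dataset; what it can and cannot show is
discussed at the end.

## Model 1: denoising variational autoencoder

`build_dae()` constructs a 3D convolutional VAE with a *linear* latent
space: strided convolutions (kernel 3, stride 2), each followed by
instance-style normalization and LeakyReLU (negative slope 0.01); a flat
latent vector of size n with mean and log-variance heads; a mirrored
transposed-convolution decoder; sigmoid or linear output. The loss
(`dae_loss()`) is

$$ L = \mathrm{MSE} + \omega \left[ -\tfrac{1}{2n} \sum_j
   (1 + \log\Sigma_j - \mu_j^2 - \Sigma_j) \right], $$

with default $\omega = 1.22\times10^{-5}$ — small enough that the model
optimizes reconstruction first and uses the KL only as a mild regularizer.
Training (`train_dae()`) uses Adam with per-epoch learning-rate decay
$\gamma = 0.95$ (500 epochs and batch size 4 as full-scale defaults), and
keeps the checkpoint with the lowest validation loss.

Design choices a reader should know about:

- **Exact layer widths are ours.** The published account of this
  architecture family leaves the per-layer table to supplementary material;
  we default to four encoder stages of 32-64-128-256 channels and expose
  everything in `dae_config()`. The normalization type per convolution is
  likewise unspecified in the sources this design follows; we use
  instance normalization (no affine parameters), which behaves identically
  at batch size 1 and in inference.
- **Training target.** The DAE is trained as a plain autoencoder of clean
  healthy volumes. The "denoising" that matters happens at test time, when
  out-of-distribution tissue fails to reconstruct.
- **Inference uses the posterior mean** (no latent sampling), so anomaly
  maps are deterministic.
- **Padding.** Inputs are zero-padded to the nearest grid divisible by
  $2^{\text{stages}}$ and outputs cropped back; padding voxels never enter
  the loss.
- **Initial learning rate** is not pinned by the recipe we follow; the
  package default is $10^{-4}$, and the desk-scale study below uses
  $3\times10^{-3}$, both config-exposed.

The anomaly score is the channel-summed absolute residual
(`residual_map()`): residuals are summed over channels *first* and the
absolute value taken *after*, so zero-mean per-channel noise cancels while
consistent signal shifts survive. Residual maps are min-max normalized over
the evaluation mask by default (`normalize_scores()`) so that fixed
thresholds like 0.3 are comparable across subjects; the rescaling is
monotone and leaves AUC unchanged. Whether to rescale is config-exposed
because raw-scale thresholding is also defensible.

## Model 2: RecDiscNet

`build_recdisc()` pairs a reconstruction network (the same autoencoder
family, non-variational, sigmoid output) with a discrimination network: a
two-scale 3D U-Net that consumes the channel concatenation of corrupted
input and reconstruction (2C channels) and emits one logit per voxel. The
loss (`recdisc_loss()`) is

$$ L = \mathrm{MSE} + \omega \left[ -\tfrac{1}{n} \sum_i
   \big(p_1 \hat y_i \log \sigma(y_i) + (1-\hat y_i)
   \log(1 - \sigma(y_i))\big) \right], $$

computed over in-brain voxels only, in log-sum-exp form so saturated logits
stay finite. $\omega$ and $p_1$ are not pinned by the recipe; defaults are
$\omega = 1$ and $p_1 = n_{\mathrm{neg}}/n_{\mathrm{pos}}$ per volume
(standard imbalance compensation), both exposed. Joint optimization of the
summed loss is the default — the discriminator's input gradient flows back
into the reconstruction net through the concatenation — with a sequential
two-step mode (`mode = "sequential"`) available, since either reading of a
"two-step approach" is defensible. The anomaly map is the sigmoid output
directly; no residual is computed.

At full resolution the U-Net mixes channels pointwise (1³ convolutions)
and keeps its 3³ spatial context at half and quarter resolution; this keeps
the im2col working set of the full-resolution layers small without
changing the output contract (one logit per input voxel).

## Just-out-of-distribution injection

`corrupt()` inpaints ellipsoidal noise patches into healthy volumes:

- 0, 1 or 2 patches with probabilities 0.2 / 0.6 / 0.2;
- ellipsoid centers drawn uniformly from in-brain voxels; painted voxels
  are clipped to the brain (patches may straddle tissue boundaries but
  never paint background); the same spatial support applies to every
  channel;
- noise values from a normal or uniform family anchored to the subject's
  pooled in-brain signal mean and SD (`brain_statistics()`), with the mean
  either full or halved; structure either iid per voxel and channel
  ("random"), one draw per channel ("directional"), or one draw per voxel
  ("isotropic"); "mix" resolves per patch;
- `augment()` expands each subject to four corrupted copies.

Ambiguities resolved here, all config-exposed: the uniform "range equal to
the SD" is read as *total width* $\sigma$ (i.e. $m \pm \sigma/2$), with an
$m \pm \sigma$ switch; CSF counts toward the brain statistics by default;
sampled values are clipped to [0, 1] so corrupted inputs stay in the
models' input range (clipping can be disabled for distribution
inspection); ellipsoid semi-axes default to Uniform(2, 8) voxels at the
32-voxel phantom scale, scaled proportionally with the grid, and
orientations are uniform over SO(3) via sine-corrected Euler angles.

## Thresholding and post-processing

Five strategies (`select_threshold()`), two of them supervised:

- **fixed**: 0.5 for RecDisc output (half the [0, 1] range), 0.3 for
  normalized DAE residuals (sensitive to small deviations);
- **Otsu** over a 256-bin histogram of masked scores (bin count is our
  choice; ties resolve to the lowest qualifying edge);
- **pooled-maximum** $T = \max(I * f_{\mathrm{local}})$ with a cubic mean
  kernel, 16 voxels at acquisition scale. Only fully supported window
  positions count (no padding — padding would dilute the maximum toward
  the brain edge); a non-overlapping block mode is available since the
  stride is not pinned by the formula;
- **Youden** ($\max$ TPR − FPR) and **Dice-optimal**, both exhaustive scans
  over candidate cuts (midpoints between consecutive unique scores; above
  $10^5$ voxels a 512-point quantile grid). These require groundtruth and
  are reported only to compare architectures.

Binarization uses strict `>` (documented; the sources are silent).
`morphological_opening()` erodes then dilates with a full 3³ cube,
removing isolated misclassified voxels; it is idempotent and
anti-extensive, and the test suite checks it against a brute-force oracle.

## Evaluation

All metrics are restricted to white + gray matter (`evaluation_mask()`);
CSF/ventricles and background are excluded. `dice()` returns
$2|A\cap B|/(|A|+|B|)$, defining two empty masks as Dice 1 (degenerate but
possible on lesion-free phantoms; such subjects are excluded from AUC
instead). `roc_auc()` uses the rank/Mann–Whitney formulation (ties = rank
averaging), pooled over voxels within a subject; per-subject AUCs are then
aggregated as unweighted mean ± population SD, matching the convention of
reporting "mean ± SD across subjects". `fold_split()` implements 7-fold
cross-validation (28 subjects → 4 per fold, each fold validating once);
`crossvalidate()` trains per fold and scores each held-out evaluation
subject with its round-robin-assigned fold's model — the mapping of
evaluation subjects to folds is our choice, since the reference design
evaluates on a disjoint patient group.

## The phantom

`simulate_dwi()` builds nested-ellipsoid anatomy (GM shell, WM core, two
CSF ventricles), per-tissue axially symmetric diffusion tensors
(WM MD 0.75·10⁻³ mm²/s, FA 0.75; GM 0.85·10⁻³, FA 0.10; CSF 3.0·10⁻³,
FA 0 — textbook adult values), a smooth WM fiber field tangent to
concentric shells, and evaluates $S = S_0 e^{-b\,g^\top D g}$ per
direction on a single shell (b = 1000 s/mm², quasi-uniform hemisphere
directions via a spherical Fibonacci layout, one b0). Magnitude noise is
Rician (σ = 0.02 · S₀ — magnitude MRI noise is Rician, not Gaussian), and
volumes are normalized by the b0-ratio convention: each DW channel is
divided by the b0 channel inside the brain and clipped to [0, 1]; the b0
channel is consumed and the networks see only the C diffusion-weighted
channels. Per-subject normalization (vs per-dataset) is our choice and a
config switch. Lesions are ellipsoids with multiplied MD (default ×1.8)
and scaled FA (×0.3) — a coarse stand-in for tumor/edema-altered
diffusivity; there is no accepted parametric lesion model in these terms,
so the multipliers are configuration, not truth. `make_cohort()` jitters
geometry (±5%), noise (±20%) and lesion placement across subjects.

## Desk-scale study conditions

`phantom_study()` fixes the conditions used by the test suite and the
acceptance script: 32 × 32 × 20 voxels, 8 channels, 28 healthy training
subjects, 6 held-out lesioned and 6 held-out corrupted subjects; DAE with
latent 16 and 8-16 channels trained 50 epochs (lr 3·10⁻³, γ = 0.97);
RecDiscNet with the same backbone and an 8-16 U-Net trained 12 epochs with
mix/half injection and ×4 augmentation; pooled-max kernel 8 voxels (the
16-voxel acquisition-scale kernel spans ≈ 0.18 of the 90-voxel grid;
8 voxels is the closest match on a 32-voxel grid). These sizes were chosen
once as a desk-scale rendition of the full design and are stated here so
the reported numbers are interpretable; larger grids, 64 channels and the
full 500-epoch recipe remain available through the configs.

## Numerical choices and degenerate inputs

Instance-norm $\epsilon = 10^{-5}$; latent log-variances clamped to
[−15, 15]; BCE in log-sum-exp form; Adam ($\beta_1 = 0.9$,
$\beta_2 = 0.999$, $\epsilon = 10^{-8}$); He-style weight initialization;
log-variance head initialized near zero so early KL is small. Constant
maps are rejected by Otsu and by min-max normalization; empty masks are
rejected by `restrict_map()` and `brain_statistics()`; degenerate
ellipsoid draws (semi-axis < 1 voxel) are redrawn and counted; NaN losses
abort training with diagnostics. All seeded entry points save and restore
the caller's RNG state.

## What passing tests do and do not show

The phantom has smooth geometry, piecewise-constant tensors, a single
shell, no susceptibility or motion artifacts, no gyrification, and lesions
that differ from tissue far more cleanly than infiltrating glioma margins
do. Consequently the desk-scale AUC/Dice figures are *sanity checks of the
machinery* — that the models learn healthy structure, that anomalies score
higher than healthy tissue, that thresholds and morphology behave — not
estimates of clinical performance. On real data the separations are much
weaker, per-subject variance much larger, and preprocessing (distortion
correction, registration, masking) becomes part of the problem; those
steps are explicitly out of scope here, as the package assumes
preprocessed, registered, masked input.
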