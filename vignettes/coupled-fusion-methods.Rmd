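---
title: "Coupled reconstruction and fusion of multi-modal medical images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled reconstruction and fusion: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Multi-modal medical image fusion (MMIF) combines co-registered images from
different scanners — MR and CT, or an anatomical scan with a SPECT/PET
pseudo-color map — into a single image that retains the complementary
content of both: the smooth tissue contrast ("base", low-frequency) of one
modality and the edges and texture ("detail", high-frequency) of the other.
There is no ground-truth fused image, which makes both training and
evaluation unusual: training must be driven by unsupervised quality
surrogates, and evaluation by reference-free fusion metrics.

`cirf` implements a coupled two-branch strategy. A single shared encoder
decomposes each source image into base and detail feature stacks. The
*fusion branch* sums the two sources' features type-by-type, fuses them with
dedicated blocks, and decodes a fused image. The *reconstruction branch*
pushes each (optionally masked) source through the same encoder and its own
decoder, and is scored against the original image. Both branches train
simultaneously through one optimizer; at inference the reconstruction branch
is cut off entirely.

## Architecture

All tensors use the R layout `[H, W, C, N]`; the canonical NCHW description
`[N, C, H, W]` maps onto it with channels third. Input sides must be
divisible by 32 (one stem pooling stage times the 8-pixel ViT patching,
with margin for the decoder's internal downsampling).

**Parallel decomposition encoder (PDE).** A stem (7x7 convolution 1->32,
3x3 convolution, 2x2 average pooling) halves resolution. Two branches
follow:

* the ViT branch raises to 64 channels, patchifies at 8x8, adds learned
  positional embeddings, and runs 6 pre-norm transformer blocks (4 heads,
  10% dropout) split as 3 + 3 across two interaction stacks;
* the CNN branch runs 3x3 convolution + batch-norm cells at 64 channels.

From the second stack the branches exchange information: CNN features are
average-pooled to the patch grid, flattened and layer-normalized, then added
to the tokens; tokens are reshaped to the grid, bilinearly interpolated to
the CNN resolution, batch-normalized and added to the CNN features.
Transposed convolutions (8x8 stride 8 then 2x2 stride 2 for the token
branch; 2x2 stride 2 for the CNN branch) restore both outputs to input
resolution, 64 channels each: the base and detail feature stacks.

**Base fusion block (BFB).** A lite-transformer-style block on the summed
base features: half the channels model local context through two 3x3
convolutions, the other half are pooled to a coarse grid (at most 16x16),
run through 2-head self-attention and a gated linear unit, and interpolated
back; the concatenation is projected 1x1 and added residually.

**Detail fusion block (DFB).** A residual fusion CNN on the summed detail
features: two convolution + batch-norm cells with an ELU between them, a
convolutional residual line from input to output, and a final ReLU6. The
ReLU6 caps every output at 6, which bounds the dynamic range and guards the
detail path against gradient explosion — this bound is a hard contract
tested with inputs scaled by 100.

**Decoders (DFD / DRD).** Both decoders consume the 128-channel
concatenation of a base and a detail stack and produce a `[0,1]` image
through a sigmoid head. They are transformer decoders in the Restormer
style: channel-wise layer norm, transposed (channel) attention with
L2-normalized queries/keys and a learned per-head temperature, and a
gated-dconv feed-forward network. The two decoders are architecturally
identical but share no parameters; the encoder, in contrast, is one object
reachable from both branches.

## Losses

Reconstruction (supervised), per source $k$:
$$L_{rec,k} = L_{MSE} + \alpha\,(1 - \mathrm{SSIM}) + \beta\,L_{SG},
\qquad Loss_1 = \mu\,(L_{rec,1} + L_{rec,2})$$
where $L_{SG}$ is the mean absolute difference of Sobel gradient
magnitudes over the valid (unpadded) interior — insensitive to constant
offsets by construction. The printed form of the total reconstruction loss
is ambiguous about whether $\mu$ multiplies one or both per-source terms;
since $\mu$ is a scale balance for the whole reconstruction term against
the fusion term, it is applied to the sum.

Fusion (unsupervised): four terms, each "one minus a normalized average"
of a quality score of the triple $(A, B, F)$:
$$Loss_2 = \lambda\,(L_{MI} + L_{SCD}) + (1-\lambda)\,(L_{SSIM} + L_{QABF})$$

The normalizations, which the loss definition leaves open, are fixed
analytic ranges rather than per-batch min-max (a per-batch normalization
would make the loss non-stationary across steps):

* SSIM and the two SCD correlations are mapped from $[-1,1]$ to $[0,1]$
  via $(x+1)/2$ and averaged over sources;
* QAB/F is already in $[0,1]$;
* mutual information is normalized by symmetric uncertainty,
  $2 I(S;F) / (H(S) + H(F)) \in [0,1]$.

Total: $Loss_{total} = (1-\sigma) Loss_1 + \sigma Loss_2$, affine in
$\sigma$, with exact reductions at $\sigma \in \{0, 1\}$ that the tests
verify as gradient-flow statements (fusion-only modules receive exactly
zero gradient at $\sigma = 0$, the reconstruction decoder at $\sigma = 1$).

**Differentiable surrogates.** The evaluation-grade metrics are not all
smooth, so the loss uses surrogates: mutual information through
kernel-weighted soft histograms (32 bins, Gaussian bandwidth 1/32);
edge preservation through Sobel convolutions, smooth absolute values
($\sqrt{x^2 + \varepsilon^2}$, $\varepsilon = 10^{-6}$) and atan2
orientations folded modulo $\pi$; SSIM and SCD are natively
differentiable. The QAB/F surrogate tracks the exact metric to about
$10^{-4}$ on structured images. The soft-histogram NMI sits roughly 0.08
*below* a hard 32-bin NMI — one bin width of kernel smoothing blurs the
joint histogram — which is acceptable for a loss (it preserves ordering)
but worth knowing when reading logged `l_mi` values: they do not reach 0
even for identical images.

**Hyper-parameter defaults.** $\lambda = 0.3$ (the value that performs best
across datasets in the ablations), $\sigma = 0.2$ and masking ratio 0.1 as
the Atlas-style preset; IXI/RIRE-style presets use masking 0 and
$\sigma = 0.2$ / $0.4$. $\alpha$, $\beta$, $\mu$ are nowhere stated by the
source method and default to 1, exposed in the configuration. The ablation
text is internally inconsistent about the Atlas masking ratio (it argues
for 0.1, then says 0, then uses 0.1 in later tables); both presets are
shipped and neither is endorsed.

## Training

Every step runs *both* branches: fusion on the original pair
($T_1^o, T_2^o$), reconstruction on masked-or-original inputs
($T_k^{m/o}$; masking is patch-wise, 16x16 patches filled with 0, the
granularity and fill value being the standard masked-image-modeling
choice since the source method states neither). One Adam optimizer
(lr $10^{-4}$ by default, $\beta_1 = 0.9$, $\beta_2 = 0.999$, no schedule —
none is published) updates all parameters simultaneously; there is no
alternating or two-stage schedule, which is the point of the coupled
design. Everything stochastic — initialization, data order, masking,
dropout — derives from the single config seed, and two identical runs
produce bit-identical logs.

## Synthetic phantoms

The generator draws a latent "anatomy" of 6–10 random anisotropic Gaussian
structures over a background gradient and renders two modalities:
A is a blurred, smoothly shaded tissue-contrast map (low-frequency rich,
like T1 MR); B mixes the same latent with its Sobel edge map and fine
latent-modulated texture (high-frequency rich, like T2 MR or a CT bone
window). The pseudo-color profile wraps B in a hot colormap to exercise
the YUV path (BT.601; only luma is fused, chroma passes through). Across
seeds the modalities correlate at about 0.9 — co-registered anatomy —
while B carries systematically more gradient energy.

What the phantoms do *not* emulate: scanner noise statistics, bias fields,
partial-volume effects, anatomical plausibility, or registration error.
Passing tests on phantoms demonstrate that the machinery — decomposition,
fusion, coupled optimization, metric computation — behaves as specified,
not that the trained weights transfer to clinical images.

## Numerical choices

* Metrics evaluate on the 8-bit scale (x255), with PSNR's peak fixed at
  255 and MI on 256-bin histograms (log base 2).
* The QAB/F sigmoid constants are the standard published ones
  ($\Gamma_g = 0.9994, k_g = -15, \delta_g = 0.5$;
  $\Gamma_\alpha = 0.9879, k_\alpha = -22, \delta_\alpha = 0.8$), with each
  sigmoid normalized by its value at perfect preservation so that
  $F = A = B$ scores exactly 1.
* VIFF is the mean over the two sources of pixel-domain multi-scale visual
  information fidelity (4 scales, Gaussian low-pass + downsample-by-2,
  noise variance 2). The pyramid low-pass uses same-padding so that four
  scales remain usable from 32 px up; the local-statistics windows are
  valid-mode.
* rSFe uses four directional first differences with the diagonals weighted
  $1/\sqrt{2}$, against a reference built from the element-wise maximum of
  the absolute source differences.
* Degenerate cases: zero-variance Pearson operands in SCD count as 0;
  all-constant sources give QAB/F 0 with a warning and make rSFe an error;
  PSNR of a perfect fusion is `Inf`.
* Batch norm uses $\varepsilon = 10^{-5}$ and momentum 0.1; layer norm
  $\varepsilon = 10^{-5}$; attention temperature is learned per head in the
  decoders.
* Initialization: Kaiming-uniform for convolutions, truncated normal
  (sd 0.02) for transformer and positional weights; the decoders' sigmoid
  heads start near zero so the first fused outputs sit around 0.5 rather
  than saturated.

## Design choices where the description was open

* **[4,64,256,256] reading.** The encoder output shape is read as *each
  branch* producing 64 channels, giving the 128-channel concatenations the
  decoders consume.
* **ViT depth.** "Stack depth 6" is read as 6 transformer blocks total
  across the two interaction stacks (3 + 3), keeping the encoder light.
* **8x8 patches** (the method section's number) take precedence over the
  16x16 mentioned in background material.
* **Positional embeddings** are learned at the configured image size and
  bilinearly interpolated when the model runs at another resolution, so one
  model serves both 64 px training and 256 px contract checks.
* **Desk-scale widths.** The encoder's CNN cells use one convolution per
  stack, the decoders run their transformer blocks at half resolution
  (stride-2 embed, 2x2 transposed convolution back up), upsampling uses
  2x2 stride-2 transposed convolutions, and GELU is the sigmoid
  approximation. These choices keep a full coupled training step tractable
  on one CPU without touching any stated contract (shapes, the ReLU6 cap,
  weight sharing, swap symmetry).
* **Engine.** The networks run on a package-internal reverse-mode autodiff
  tape with C++ im2row/col convolution kernels; its gradients are verified
  against central differences throughout the test suite, including an
  end-to-end conv + batch-norm + attention composite.

## Problem sizes used in the shipped experiments

The test suite trains the coupled model for 200 Adam steps (lr $10^{-3}$,
a deliberately brisk desk-scale rate; the $10^{-4}$ default mirrors the
published GPU-scale setting) on 32 synthetic 64x64 pairs with batch size 4,
and checks that the mean total loss over the last 10 steps falls below half
the mean over the first 10, and that the trained model's QAB/F on 10
held-out phantoms beats the untrained model's. Architecture contracts are
verified at the full 256x256, batch-4 working size in evaluation mode.
These sizes are the package's chosen study conditions for a CPU-only
reproduction; they are far below the published training scale (thousands of
pairs, hundreds of epochs, A100 hardware), which is why no attempt is made
to reproduce the published per-dataset metric tables.

## Known limitations

* Double precision only; no accelerator support; batch sizes beyond ~4 at
  256 px are memory-hungry.
* The soft-MI loss term has a constant downward bias (above) and the
  surrogate QAB/F shares the exact metric's zero-padding border effects.
* 16-bit output is supported through TIFF only (the PNG writer available
  to the package is 8-bit).
* Windowed metrics (SSIM, VIFF, QAB/F) are not exactly translation
  covariant on finite images; the drift is bounded by the border-window
  fraction and measured in the tests.
* The synthetic phantoms are stationary in contrast behaviour across the
  image; real multi-modal pairs show spatially varying, sometimes
  contradictory contrast (e.g. CT bone vs MR soft tissue), which only the
  real datasets can exercise.
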