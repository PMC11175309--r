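# cirf — coupled reconstruction and fusion of multi-modal medical images

`cirf` fuses pairs of co-registered medical images — MR/CT grayscale pairs,
or an anatomical image with a SPECT/PET pseudo-color map — into a single
image that keeps the complementary content of both sources. It is aimed at
researchers in medical image analysis who need (a) a trainable fusion model
that runs on plain CPU R, and (b) an evaluation-grade implementation of the
eight standard fusion-quality metrics.

## The method

A shared **parallel decomposition encoder** splits each source image
\(T_k\) into *base* features \(\Phi_k^B\) (low-frequency structure, from a
ViT branch) and *detail* features \(\Phi_k^D\) (edges and texture, from a
CNN branch), the two branches exchanging information between their stacks:

    base:   psi_B = F_b(Phi_1^B + Phi_2^B)     (lite-transformer block)
    detail: psi_D = F_d(Phi_1^D + Phi_2^D)     (residual fusion CNN, ReLU6-capped)
    fused:  T_f   = D_f([psi_B ; psi_D])       (transformer decoder)

Training couples this **fusion branch** (scored by an unsupervised loss
built from differentiable MI, SCD, SSIM and QAB/F surrogates) with a
**reconstruction branch** (the same encoder plus its own decoder,
reconstructing each — optionally patch-masked — source, scored by
MSE + SSIM + gradient loss):

    Loss_total = (1 - sigma) * mu * (L_rec,1 + L_rec,2)
               + sigma * [ lambda * (L_MI + L_SCD) + (1 - lambda) * (L_SSIM + L_QABF) ]

Both branches update simultaneously through one Adam optimizer; at
inference the reconstruction branch is cut off. Defaults: lambda = 0.3,
sigma = 0.2, masking ratio 0.1.

The evaluation suite implements SD, PSNR, SCD, MI, SSIM, QAB/F, VIFF and
rSFe on the 8-bit intensity scale, each verified against independent
brute-force oracles in the tests.

Everything runs on a package-internal reverse-mode autodiff engine with
C++ convolution kernels — no external deep-learning framework is required.

## A worked example

```r
library(cirf)

# two synthetic co-registered modalities sharing one anatomy:
# A smooth/low-frequency, B edge- and texture-rich
pairs   <- lapply(0:31,    function(i) synth_pair(i, size = 64))
heldout <- lapply(100:109, function(i) synth_pair(i, size = 64))

cfg <- train_config(
  weights      = loss_weights(lambda = 0.3, sigma = 0.2, mask_ratio = 0.1),
  model        = model_config(image_size = 64),
  image_size   = 64,
  batch_size   = 4,
  learning_rate = 1e-3,
  n_epochs     = 25,
  seed         = 0
)
res <- train(pairs, cfg)          # ~13 min on one CPU

log <- res$log
mean(log$total[1:10])             # 2.423483  (mean total loss, first 10 steps)
mean(log$total[191:200])          # 0.2978091 (last 10 steps: well under half)

p <- heldout[[1]]
f <- fuse(p$a, p$b, res$model)    # [0,1] matrix, same size as the sources
print(evaluate_all(p$a, p$b, f))
#> sd       60.5156
#> psnr     25.2776
#> scd       1.4778
#> mi        8.0888
#> ssim      0.9227
#> qabf      0.8025
#> viff      0.6232
#> rsfe     -0.1846
```

The metric row reads: the fused image has healthy 8-bit contrast (SD), a
25 dB mean PSNR against the two sources, captures correlated difference
structure from both (SCD approaching its ceiling of 2), shares ~8 bits of
information with them (MI), and preserves about 80% of the sources' edge
information (QAB/F); the slightly negative rSFe says the briefly-trained
model still loses a little fine spatial frequency rather than inventing
noise. Across the 10 held-out phantoms, mean QAB/F rises from 0.089
(untrained weights) to 0.819 after these 200 steps.

Pseudo-color sources go through YUV automatically: only luma is fused,
chroma is carried through (`infer()` returns RGB for such pairs).

A command-line interface wraps the same functions:

```sh
cirf synth    --out data/ --n 32 --size 64 --seed 0
cirf train    --data data/ --out run/ --config cfg.yaml
cirf fuse     --ckpt run/model.rds --a a.png --b b.png --out f.png
cirf evaluate --a a.png --b b.png --f f.png --csv metrics.csv
```

(after installation the script lives at `system.file("exec", "cirf", package = "cirf")`).

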