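# mdftn: multisource low-dose CT denoising

Low-dose CT (LDCT) trades patient radiation for noise; supervised denoisers
learn to map an LDCT slice back to its normal-dose (NDCT) counterpart.
Scanners from different manufacturers, however, produce LDCT images with
very different noise magnitudes and textures, and a network trained on one
source degrades on the next — while training one network per source wastes
scarce paired data. This package is for researchers who want to study that
multisource setting end to end on a laptop: it implements the
multi-encoder deep feature transformation network (MDFTN) together with a
physics-based multisource phantom simulator, so every component is
exercisable without clinical data.

## The model

For $n$ imaging sources, MDFTN couples $n$ encoder/decoder pairs through
one shared bottleneck:

* **Per-source encoders** $E_k$ (residual U-Net stems, two average-pooling
  downsamplings, channels $c \to 2c \to 4c$) map each source's batch to
  features $F_k \in \mathbb{R}^{H/4 \times W/4 \times 4c}$.
* **Shared bottleneck (DFTM)**: $F_{share} = C(\mathrm{cat}[F_1,\dots,F_n])$
  — concatenation and a $3\times3$ compression convolution — refined by four
  stacked feature transformation modules, each the residual
  squeeze-and-excitation block
  $F_{DM} = F_{CP}(F) \otimes \sigma\{SE[F_{CP}(F)]\} + F$.
* **Per-source decoders** (transposed-convolution upsampling, SEKG
  attention producing per-position, per-channel $3\times3$ kernel weights
  $\Theta \in (0,1)$ applied to unfolded neighbourhoods, skip
  concatenation, residual stages) reconstruct each source's denoised batch.
* **Collaborative training**: one joint backward pass through the summed
  per-source objectives
  $L_{total} = \sum_s [\,\alpha L_1 + \lambda\,(1-\mathrm{SSIM})\,]$
  (defaults $\alpha = 1$, $\lambda = 0.001$), so each step updates all
  branches and couples every source through the shared features.

The convolutional engine (forward passes, reverse-mode gradients, Adam) is
implemented in the package itself over BLAS-backed Rcpp kernels; analytic
gradients — including the SSIM loss term — are validated against finite
differences in the test suite. Ablation variants (single-source, no-FTM,
no-SEKG, RED-CNN backbone) and the SSIM-weight sweep are built in.

The simulator generates "manufacturers": random ellipse phantoms are
forward-projected (parallel beam), degraded with count-domain quantum +
electronic noise ($N \sim \mathrm{Poisson}(I_0 e^{-p}) +
\mathcal{N}(0,\sigma_e^2)$), and reconstructed by filtered back-projection
with per-source filters (ram-lak / shepp-logan / hann), giving aligned
LDCT/NDCT pairs with source-specific noise magnitude *and* texture.

## Worked example

```r
library(mdftn)

## 1. Simulate a three-source corpus (50 pairs per source, 64 x 64)
man <- build_multisource_corpus(
  "corpus", n_pairs_per_source = 50,
  profiles = low_dose_study_profiles(64),
  phantom  = phantom_spec(size = 64, n_ellipses = 6),
  rng_seed = 11)

## 2. How bad is the low-dose input?
evaluate_dataset(NULL, man)
#> Per-source image quality (mean +/- SD):
#>   A          n=  5  PSNR  24.89 +/-  0.19 dB  SSIM 0.3607 +/- 0.0091  RMSE 0.0569 +/- 0.0012
#>   B          n=  5  PSNR  28.16 +/-  0.12 dB  SSIM 0.5012 +/- 0.0079  RMSE 0.0391 +/- 0.0005
#>   C          n=  5  PSNR  28.89 +/-  0.29 dB  SSIM 0.5545 +/- 0.0153  RMSE 0.0359 +/- 0.0012

## 3. Fit the reduced network by joint collaborative training
fit <- mdftn(man,
             model = mdftn_config(base_channels = 16),
             train = train_config(epochs = 5, batch_size = 8,
                                  patch_size = 32, initial_lr = 1e-3,
                                  lr_decay = 0.5, lr_period = 2,
                                  steps_per_epoch = 80, seed = 7))
fit
#> Multisource LDCT denoiser (MDFTN, mdftn-unet backbone)
#>   sources: A, B, C
#>   parameters: 698,332  (base 16, bottleneck 64, FTMs 4, SEKG on)
#>   trained 5 epoch(s); best validation at epoch 5

## 4. Denoising gain on held-out test slices, per source
evaluate_dataset(fit, man)
#> Per-source image quality (mean +/- SD):
#>   A          n=  5  PSNR  32.67 +/-  0.09 dB  SSIM 0.8833 +/- 0.0032  RMSE 0.0233 +/- 0.0002
#>   B          n=  5  PSNR  33.03 +/-  0.13 dB  SSIM 0.8814 +/- 0.0032  RMSE 0.0223 +/- 0.0003
#>   C          n=  5  PSNR  31.30 +/-  0.20 dB  SSIM 0.8680 +/- 0.0053  RMSE 0.0272 +/- 0.0006

## 5. Denoise a single new slice with source A's branch
pair <- load_manifest_pair(man[1, ], attr(man, "dir"))
den  <- predict(fit, pair, source_id = "A")
plot(fit)       # validation PSNR / RMSE per epoch and source
```

The PSNR numbers read as: the low-dose inputs of the three simulated
scanners sit at about 24.9 / 28.2 / 28.9 dB against their normal-dose
references; after five epochs of joint training the denoised outputs reach
about 32.7 / 33.0 / 31.3 dB — gains of +7.8 / +4.9 / +2.4 dB on every
source simultaneously from one model. (Exact values depend on the BLAS;
those above are from the run that produced this README.)

A command-line interface wrapping the same functions is installed at
`inst/cli/mdftn.R` with subcommands `simulate`, `train`, `denoise`,
`evaluate`, `ablate`, and `lambda-sweep`.

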