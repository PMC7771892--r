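# fpmsda

Background correction and denoising for **Fourier Ptychographic Microscopy
(FPM)** by **structure-dependent amplification (SdA)**, with the simulation,
phase-retrieval and evaluation machinery needed to study it end to end on
synthetic data.

## The problem

FPM reconstructs a high-resolution complex image o(x, y) from many
low-resolution intensity frames captured under oblique coherent illumination
from an LED array. Each LED at illumination NA
`NA_ill = sin(atan(r / h))` shifts the object spectrum by a wavevector
`|k| = NA_ill / λ`, and the microscope records

```
I_k(x) = | F⁻¹ [ P(u) · O(u − k) ] |²
```

with `P` the circular pupil of radius `NA_obj / λ`. Frames with
`NA_ill > NA_obj` are *darkfield* (DF): they carry only scattered light, have
low counts and are dominated by the camera background (offset b, Gaussian
read noise σ, Poisson shot noise). Any uncorrected DF background is injected
into the recovered spectrum at the frame's wavevector; summed over hundreds
of DF frames this produces the characteristic high-frequency "orange-peel"
artefact. The classical fixes trade resolution against artefacts:

* **mean** — subtract the mean background in a structure-free region: leaves
  half-clipped noise everywhere, artefacts grow with σ;
* **mean + 3σ** — subtract `mean + 3·sd`: removes 99.7 % of a Gaussian
  background but also the weak DF signal, blurring the reconstruction;
* **rolling ball** — morphological background estimate, same trade-off.

## Structure-dependent amplification

SdA sidesteps the trade-off by classifying pixels as *object* (scatterers,
which generate the DF signal) or *background*, and boosting object pixels
before thresholding, so that the threshold removes only background:

1. `M` — background mask: Otsu-binarize the on-axis brightfield frame,
   dilate the object class with a disc `s1` (default 20 px at ~200 px
   frames), complement. `S2 = max(S1 − mean[S1(M)], 0)` per DF frame.
2. `I_BF` — binary object map from the reciprocal of the summed BF frames
   (minus its maximum over `M`, thresholded at 0, dilated by a disc `s2` ≈ 8 px).
3. `I_DF` — amplification map: summed DF frames minus their background mean,
   clamped at 0.
4. Amplify: `A = S2 · (I_DF · I_BF + I_BF^C)`; threshold:
   `S2′ = max(A · I_BF − (mean + 3·sd of A over M), 0)`.
5. `S3` — restore original intensities where `S2′ > 0` (keeps all object
   information); `S4` — for frames with signal-to-background ratio
   `SBR = mean(S2 on I_BF) / mean(S2 on M) < 1`, rescale
   `S2′ / max(S2′) · max(S2)` instead (suppresses residual background at
   some resolution cost).
6. Reconstruct with the sequential Gauss–Newton spectrum update, feeding
   **S4 to iterations 1..N−1 and S3 to the final iteration**.

An optional locally-masked median filter (`medianEdgeFilter`) cleans residual
artefacts confined to object rims.

## Worked example

Simulate a USAF-style bar target through a 177-LED filled-circle array
(15×15 grid, 2.6 mm pitch, 39 mm circle, NA 0.2, 532 nm), degrade with
offset 500, Poisson noise and Gaussian noise σ = 1000 at a full-scale
exposure of 5·10⁴ counts, correct with each method and reconstruct
(N = 10):

```r
library(fpmsda)
cfg <- list(
  geometry = list(ledGridN = 15, ledPitch = 2.6, circleDiameter = 39,
                  arrayHeight = 50, wavelength = 532, objectiveNA = 0.2,
                  falloffExponent = 4),
  object = list(kind = "bars", shape = 128, pixelSize = 0.4,
                barPeriods = c(8, 6, 4, 3)),
  noise = list(offset = 500, gaussianSigmas = 1000, poissonGain = 1),
  correction = list(methods = c("mean", "mean3sigma", "sda"),
                    s1Radius = 6, s2Radius = 3),
  reconstruction = list(nIterations = 10, lrShape = 48, exposure = 5e4))
report <- runExperiment(cfg, seed = 1)
print(report, digits = 3)
#>   sigma     method  ssim  mse snrDb contrast
#> 1    NA  reference 1.000    0  45.2    0.875
#> 2  1000       mean 0.352 1170  18.1    0.851
#> 3  1000 mean3sigma 0.542 2150  30.9    0.430
#> 4  1000        sda 0.567  998  29.5    0.685
```

Reading the table: `ssim`/`mse` compare each reconstructed amplitude with
the noise-free reference reconstruction inside the bar region; `snrDb` is
`20·log10(mean/sd)` in a homogeneous background rectangle; `contrast` is the
mean Michelson contrast across the bar groups. The 'mean' correction keeps
contrast (0.85) but its residual background wrecks the SNR (18 dB); the
'mean + 3σ' correction keeps the SNR (31 dB) but halves the contrast
(0.43); SdA achieves both at once (29.5 dB, 0.69) and the lowest MSE.

Lower-level entry points: `makeBarTarget()` / `makeTextureObject()`,
`simulateStack()`, `degradeStack()`, `sdaCorrect()`, `globalSubtract()`,
`rollingBallSubtract()`, `fpmReconstruct()`, `medianEdgeFilter()`, and the
metric functions `imageSSIM()`, `imageMSE()`, `snrDb()`, `lineContrast()`,
`radialPowerSpectrum()`. A command-line wrapper with `make-fixture`,
`simulate`, `correct`, `reconstruct`, `evaluate` and `run-experiment`
subcommands lives at `inst/cli/fpmsda.R`.

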