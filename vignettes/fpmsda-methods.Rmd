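---
title: "Methods: structure-dependent amplification for FPM background correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-dependent amplification for FPM background correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the science it implements: the
forward model, the SdA correction and its parameters, what the synthetic
scenes do and do not emulate, and the numerical choices made where the
method leaves them open.

## Forward model and assumptions

A thin sample is modelled as a complex transmission function
$o(x,y) = a(x,y)\,e^{i\phi(x,y)}$ on a high-resolution (HR) grid of pixel
size $\Delta x$ (µm). An LED at lateral offset $r$ (mm) and height $h$ (mm)
illuminates it as a plane wave of numerical aperture
$\mathrm{NA}_\mathrm{ill} = \sin(\arctan(r/h))$, shifting the object
spectrum by $k = \mathrm{NA}_\mathrm{ill}/\lambda$ (µm$^{-1}$). The
microscope transmits the circular passband $|u| \le \mathrm{NA}_obj/\lambda$
and the camera records the squared modulus on a low-resolution (LR) grid cut
from the same field of view:

* DC-centered discrete Fourier transforms throughout; the LR frame is a
  centred `lrShape`-sized window of the shifted HR spectrum, masked by the
  pupil, inverse-transformed; wavevectors are rounded to the nearest
  frequency pixel (the rounding error is far below the pupil radius).
* The pupil is an ideal unit-amplitude circular aperture — no aberrations
  are modelled and none are recovered.
* Intensities are normalised so that a unit-amplitude flat object produces
  an on-axis frame equal to `exposure` counts: `exposure` is the
  full-transmission brightfield level of the virtual camera.
* An optional $\cos^n\theta$ radiant fall-off scales each frame
  (`falloffExponent`); $n = 4$ corresponds to a bare Lambertian LED (one
  emission cosine, two obliquity cosines, one distance factor) and larger
  values additionally mimic forward-directed sample scattering. It is off
  by default in `simulateStack()` and set to 4 in the shipped experiment
  configuration, because the depressed signal of high-angle darkfield
  frames is precisely the regime a background correction has to survive.
* Validity of the discretisation is enforced exactly: every shifted LR
  window must fit inside the HR grid (no spectral wrap-around), and the
  pupil radius must lie within the LR frequency grid with at least two
  frequency pixels. The wrap-around check is the sharp condition; a
  conservative multiple-of-upsampling-factor rule would force needlessly
  large HR grids at these problem sizes.

Sensor degradation (`degradeStack`) applies, per frame,
`clip(offset + gain · Poisson(I/gain) + N(0, σ²), ≥ 0)`. Drawing the
Poisson variate on the photo-electron scale `I/gain` and rescaling makes the
shot-noise SNR grow as the square root of the signal, as for a real camera;
`gain = 0` disables shot noise. Per-frame random streams are derived
deterministically from one integer seed, so a degraded stack is a pure
function of (stack, noise model).

## The SdA correction

`sdaCorrect()` implements the seven-step pipeline described in the README.
Decisions taken where the formulation is terse:

* **Mask orientation.** The background mask `M` is the complement of the
  dilated object class, so that `mean[S(M)]` is always a background
  statistic. The object class of the Otsu split is the class with the
  smaller pixel count — dark absorbing structures on a bright field in the
  usual stained-specimen case; the rule also covers bright-object samples
  (a message is emitted when that branch is taken).
* **Consistency of `M` with `I_BF`.** The reciprocal-sum object map is a
  finer classifier than the on-axis Otsu mask. Before the amplification
  stage, pixels that `I_BF` marks as object are removed from `M`, so a
  pixel is never simultaneously background and object and background
  statistics are never contaminated.
* **Zero-valued BF-sum pixels.** The reciprocal in the `I_BF` construction
  is undefined where the summed brightfield is 0; such pixels are treated
  as maximally absorbing (assigned the largest finite reciprocal) and
  logged.
* **Scales.** `I_DF` enters the amplification at raw scale: only the set of
  surviving pixels matters, because step 6 restores original intensities
  (S3) or rescales relative to `max(S2′)` (S4). The `max(S2)` factor of the
  S4 rescaling uses the *pre-amplification* S2 so rescaled frames return to
  physical counts.
* **Thresholds.** The S2′ threshold uses `mean + 3·sd` over `M` with the
  sample standard deviation; background regions contain thousands of
  pixels, so the n−1 convention is immaterial. `SBR = 1` frames take the
  rescaling branch; a frame whose S2′ is identically zero in that branch is
  emitted empty with a warning.
* **Structuring elements** are discrete Euclidean discs (a pixel belongs
  iff its centre distance is ≤ the radius). The defaults s1 = 20 px and
  s2 = 8 px follow usage on ~200 px frames and should be scaled roughly
  with the frame size (the shipped 48 px LR experiments use 6 and 3).
* **Otsu binarization** is computed on a 256-bin histogram over the frame's
  full dynamic range, maximising between-class variance over the clean
  partition (bins 1..i against i+1..256), ties resolved to the midpoint of
  the first and last maximising bins.

## Phase retrieval

`fpmReconstruct()` is the sequential second-order (Gauss–Newton) spectrum
update with a fixed ideal pupil:
$O(k) \leftarrow O(k) + s\,\frac{|P|\,P^{*}}{\max|P|\,(|P|^2+\delta)}(\Psi'-\Psi)$,
with step $s = 1$ and regulariser $\delta = 10^{-3}$ of $\max|P|^2$ by
default. Frames are visited in ascending illumination NA (centre-out), the
standard order that seeds low frequencies before refining high ones. The
initial estimate is the upsampled on-axis brightfield amplitude with zero
phase, band-limited to the on-axis pupil: the modulus of a band-limited
field is itself not band-limited, and nothing beyond the pupil is informed
by that frame, so the excess is masked rather than left to linger in
regions no measurement updates. Explicit initial estimates are likewise
trimmed to the synthetic NA. The per-iteration residual
$\sum\|\sqrt{I} - |\Psi|\|^2$ is recorded before each update.

The schedule object maps iterations to stack roles; the SdA default is S4
for iterations 1..N−1 and S3 for the last, so the artefact-suppressing
stack shapes convergence and the information-preserving stack has the final
word. N is exposed as configuration (default 10); the comparison studies
here use N = 10, by which residuals on noise-free data have fallen by five
to six orders of magnitude.

Global scale and phase of an FPM reconstruction are unconstrained (the
camera gain is unknown to the reconstructor); `alignFields()` resolves both
by a least-squares complex factor before any pointwise comparison.

## Synthetic scenes: what they emulate, what they do not

`makeBarTarget()` builds a resolution-chart-style target: three-bar groups
(bar length five times the bar width) in both orientations at the requested
pixel pitches, dark bars (amplitude 0.1) on a bright field, occupying a few
percent of the canvas with generous blank regions — the layout of a real
chart, which matters because SdA's premise is that scatterers are spatially
localised. The phase is the amplitude scaled to $[0, \pi]$ (implemented as
$\pi\,a/\max a$, which remains defined for constant fixtures). Metadata
records, per group, a contrast profile crossing the bars, plus a
homogeneous SNR rectangle and an MSE crop window, so evaluation regions are
fixture-defined rather than hand-picked per figure. `makeTextureObject()`
is a seeded procedural phantom with a 1/f-type spectrum and sharp-edged
patches, standing in for a natural test image.

The default study conditions, used by the acceptance tests and
`scripts/acceptance.R`, are: 128 px HR grid at 0.4 µm pixels, 48 px LR
frames, a 15×15 LED grid at 2.6 mm pitch restricted to a 39 mm filled
circle (177 LEDs, 153 after hybrid exclusion), height 50 mm, λ = 532 nm,
NA 0.2 (synthetic NA ≈ 0.55 with the finest 3 px bar group just inside
it), exposure 5·10⁴ counts — a 16-bit sensor operated near full scale, so
that Gaussian σ ≤ 1500 is a darkfield-scale perturbation, not a
brightfield one — offset 500 counts, Poisson gain 1, cos⁴ fall-off, SdA
radii 6/3. These sizes keep a full method-comparison sweep under a minute
while reproducing the qualitative regime of interest: darkfield SBR
spanning roughly 1–6, the 'mean' correction degrading monotonically with
σ, and 'mean + 3σ' discarding the finest bar groups.

What the simulations do **not** model: vignetting, partial coherence,
sample thickness, aberrated pupils, LED spectral width, hot pixels or
fixed-pattern noise, and the wavefront-curvature origin of hybrid frames —
hybrid frames are generated and excluded by a purely geometric NA band
(half-width 0.02 NA) because the physical detection rule is instrument
specific. Passing tests on these scenes therefore demonstrates the
correction logic and its orderings, not camera-specific performance.

## Known limitations

* Frames are classified hybrid geometrically; on a real instrument the
  BF/DF boundary inside a frame would need to be detected from the data.
* The rolling-ball baseline is the classical ball-structuring-element
  grayscale opening; its radius is a free parameter swept by the user, as
  no principled value exists for coherent darkfield speckle.
* `I_BF` is recomputed per illumination wavelength in multi-channel use;
  no cross-channel consistency is enforced.
* The S4 rescaling assumes at least one surviving object pixel per
  low-SBR frame; frames that lose every pixel are emitted empty (with a
  warning) rather than imputed.
* SSIM is computed with a uniform 7×7 window, standard constants
  (K₁ = 0.01, K₂ = 0.03) and the reference maximum as dynamic range, over
  valid windows only; the SNR convention is 20·log₁₀(mean/sd) on amplitude
  images (configurable to 10·log₁₀ for power quantities).
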