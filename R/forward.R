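#' Construct a camera noise model
#'
#' @param offset constant background offset, counts (>= 0)
#' @param gaussianSigma additive white Gaussian (read) noise sd, counts
#' @param poissonGain counts per photo-electron; 0 disables shot noise
#' @param seed integer seed; the degradation is a deterministic function
#'   of (stack, model) including this seed
#' @return a [NoiseModel-class]
#' @export
NoiseModel <- function(offset = 0, gaussianSigma = 0, poissonGain = 0,
                       seed = 1L) {
  if (offset < 0 || gaussianSigma < 0)
    stop("noise parameters must be non-negative")
  new("NoiseModel", offset = as.numeric(offset),
      gaussianSigma = as.numeric(gaussianSigma),
      poissonGain = as.numeric(poissonGain), seed = as.integer(seed))
}

## pupil mask and spectrum-shift bookkeeping shared by the forward model
## and the reconstructor
pupilGrid <- function(object, geometry, lrShape) {
  nHR <- dim(amplitude(object))
  if (nHR[1] != nHR[2]) stop("HR object must be square")
  N <- nHR[1]
  m <- as.integer(lrShape)
  if (m >= N) stop("lrShape must be smaller than the HR grid")
  dx <- pixelSize(object)
  df <- 1 / (N * dx)                       # frequency resolution, 1/um
  rPix <- (objectiveNA(geometry) / wavelengthUm(geometry)) / df
  if (rPix < 2)
    stop("configuration error: pupil radius below 2 frequency pixels")
  cm <- gridCentre(m)
  if (rPix > min(cm - 1L, m - cm))
    stop("configuration error: pupil radius exceeds the LR frequency grid")
  d <- seq_len(m) - cm
  pupil <- (outer(d^2, d^2, "+") <= rPix^2) * 1
  k <- waveVectors(geometry)
  shift <- round(k / df)                   # frequency-pixel shift per LED
  cN <- gridCentre(N)
  ## exact no-wrap condition: every shifted LR window must fit the HR grid
  lo <- cN + shift - (cm - 1L)
  hi <- cN + shift + (m - cm)
  if (any(lo < 1L) || any(hi > N))
    stop("configuration error: HR grid too small for the maximum ",
         "illumination angle (passband window would wrap around)")
  list(N = N, m = m, cN = cN, cm = cm, df = df, rPix = rPix,
       pupil = pupil, shift = shift)
}

#' Simulate a low-resolution FPM image stack
#'
#' Coherent image formation for every LED: the DC-centered HR object
#' spectrum is shifted by the LED's illumination wavevector (rounded to
#' the nearest frequency pixel), cropped to the centred LR window,
#' masked by the ideal circular pupil of radius objectiveNA / lambda and
#' inverse-transformed; the recorded frame is the squared modulus. With
#' this normalisation a unit-amplitude, flat-phase object yields an
#' on-axis frame of constant value `exposure`, so `exposure` is the
#' full-transmission brightfield level in counts.
#'
#' @param object a [ComplexObject-class] (square grid)
#' @param geometry an [FPMGeometry-class]
#' @param lrShape LR frame side length in pixels (< HR side)
#' @param exposure counts at full transmission (default 1)
#' @param falloffExponent optional cos^n illumination fall-off with the
#'   LED inclination angle (0 = off). A bare Lambertian LED gives n = 4
#'   (emission cosine, two obliquity cosines and the distance factor);
#'   larger n additionally models forward-directed sample scattering,
#'   which depresses high-angle darkfield signal
#' @return an [ImageStack-class] with role S1 (noise-free), one frame
#'   per LED in LED order
#' @export
simulateStack <- function(object, geometry, lrShape, exposure = 1,
                          falloffExponent = 0) {
  pg <- pupilGrid(object, geometry, lrShape)
  O <- fft2c(complexField(object))
  labels <- frameLabels(geometry)
  n <- length(geometry)
  fr <- array(0, c(pg$m, pg$m, n))
  a2 <- (pg$m / pg$N)^4                    # uniform-object normalisation
  fall <- if (falloffExponent > 0)
    sqrt(1 - illuminationNA(geometry)^2)^falloffExponent else rep(1, n)
  for (i in seq_len(n)) {
    rows <- pg$cN + pg$shift[i, 1] + (seq_len(pg$m) - pg$cm)
    cols <- pg$cN + pg$shift[i, 2] + (seq_len(pg$m) - pg$cm)
    psi <- ifft2c(O[rows, cols] * pg$pupil)
    fr[, , i] <- Mod(psi)^2 * a2 * exposure * fall[i]
  }
  new("ImageStack", frames = fr, ledIndex = seq_len(n), role = "S1",
      labels = labels)
}

#' Apply sensor degradation to a stack
#'
#' Each frame f becomes
#' `clip(offset + gain * Poisson(f / gain) + N(0, sigma^2), >= 0)`;
#' with `poissonGain = 0` the Poisson step passes f through unchanged.
#' Per-frame random streams are derived deterministically from the model
#' seed, so identical inputs give bit-identical outputs.
#'
#' @param stack a raw S1 [ImageStack-class]
#' @param noise a [NoiseModel-class]
#' @return a degraded S1 [ImageStack-class]
#' @export
degradeStack <- function(stack, noise) {
  if (stackRole(stack) != "S1")
    stop("degradation applies to raw S1 stacks")
  fr <- frames(stack)
  d <- dim(fr)
  out <- fr
  for (i in seq_len(d[3])) {
    f <- fr[, , i]
    set.seed(frameSeed(noise@seed, i))
    if (noise@poissonGain > 0) {
      f <- stats::rpois(length(f), as.vector(f) / noise@poissonGain) *
        noise@poissonGain
      f <- matrix(f, d[1], d[2])
    }
    if (noise@gaussianSigma > 0)
      f <- f + matrix(stats::rnorm(length(f), 0, noise@gaussianSigma),
                      d[1], d[2])
    out[, , i] <- pmax(f + noise@offset, 0)
  }
  new("ImageStack", frames = out, ledIndex = ledIndex(stack), role = "S1",
      labels = frameLabels(stack))
}
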