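# Shared miniature scenes built in code. Sizes are kept small so the
# whole suite runs quickly; the acceptance tests use the full desk-scale
# study conditions instead.

smallGeometry <- function(n = 5, pitch = 5.5, height = 50, na = 0.2,
                          band = 0.02) {
  FPMGeometry(ledGrid(n, pitch), arrayHeight = height, wavelength = 532,
              objectiveNA = na, hybridBand = band)
}

# the frozen desk-scale study conditions used by the acceptance suite
studyGeometry <- function() {
  FPMGeometry(ledGrid(15, 2.6, circleDiameter = 39), arrayHeight = 50,
              wavelength = 532, objectiveNA = 0.2)
}

studyObject <- function() {
  makeBarTarget(128, barPeriods = c(8, 6, 4, 3), pixelSize = 0.4)
}

studyConfig <- function(sigmas, methods) {
  list(
    geometry = list(ledGridN = 15, ledPitch = 2.6, circleDiameter = 39,
                    arrayHeight = 50, wavelength = 532, objectiveNA = 0.2,
                    falloffExponent = 4),
    object = list(kind = "bars", shape = 128, pixelSize = 0.4,
                  barPeriods = c(8, 6, 4, 3)),
    noise = list(offset = 500, gaussianSigmas = sigmas, poissonGain = 1),
    correction = list(methods = methods, s1Radius = 6, s2Radius = 3),
    reconstruction = list(nIterations = 10, lrShape = 48, exposure = 5e4))
}

tinyConfig <- function(sigmas = 300, methods = "mean") {
  list(
    geometry = list(ledGridN = 5, ledPitch = 5.5, arrayHeight = 50,
                    wavelength = 532, objectiveNA = 0.2),
    object = list(kind = "bars", shape = 64, pixelSize = 0.4,
                  barPeriods = c(6, 4)),
    noise = list(offset = 200, gaussianSigmas = sigmas, poissonGain = 1),
    correction = list(methods = methods, s1Radius = 4, s2Radius = 2),
    reconstruction = list(nIterations = 4, lrShape = 32, exposure = 2e4))
}

# a small absorbing-disc scene with known object support: bright
# background frame plus darkfield frames whose signal sits inside the
# disc; used by the SdA exactness and invariant tests
discScene <- function(size = 32, discRadius = 5, nDF = 4, bg = 1000,
                      discValue = 100, seed = 1) {
  ctr <- size / 2
  d <- outer((seq_len(size) - ctr)^2, (seq_len(size) - ctr)^2, "+")
  disc <- d <= discRadius^2
  bf <- matrix(bg, size, size)
  bf[disc] <- discValue
  set.seed(seed)
  dfs <- lapply(seq_len(nDF), function(i) {
    f <- matrix(0, size, size)
    inner <- which(d <= (discRadius - 1)^2)
    pick <- sample(inner, max(3L, length(inner) %/% 3L))
    f[pick] <- stats::runif(length(pick), 50, 400)
    f
  })
  geom <- FPMGeometry(rbind(c(0, 0), cbind(20 + 3 * seq_len(nDF), 0)),
                      arrayHeight = 50, wavelength = 532, objectiveNA = 0.2)
  list(stack = ImageStack(c(list(bf), dfs), c("BF", rep("DF", nDF))),
       geometry = geom, disc = disc, bf = bf, dfs = dfs)
}

cropRegion <- function(x, r) {
  x[r[1]:(r[1] + r[3] - 1L), r[2]:(r[2] + r[4] - 1L), drop = FALSE]
}

# independent slow 2-D DFT via explicit transform matrices (no fft)
directDFT2 <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  F1 <- exp(-2i * pi * outer(0:(n1 - 1), 0:(n1 - 1)) / n1)
  F2 <- exp(-2i * pi * outer(0:(n2 - 1), 0:(n2 - 1)) / n2)
  F1 %*% x %*% F2
}
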