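#' Construct a complex object
#'
#' @param amplitude non-negative real matrix
#' @param phase real matrix in radians, same shape; defaults to the
#'   amplitude scaled to [0, pi] (phase = pi * amplitude / max), the
#'   standard coupling for simulated absorbing specimens
#' @param pixelSize pixel pitch, um
#' @param metadata optional list of annotations
#' @return a [ComplexObject-class]
#' @export
ComplexObject <- function(amplitude, phase = NULL, pixelSize = 1,
                          metadata = list()) {
  amplitude <- as.matrix(amplitude)
  if (is.null(phase)) phase <- scalePhase(amplitude)
  new("ComplexObject", amplitude = amplitude, phase = as.matrix(phase),
      pixelSize = as.numeric(pixelSize), metadata = metadata)
}

## phase = amplitude scaled to [0, pi]
scalePhase <- function(amplitude) {
  m <- max(amplitude)
  if (m <= 0) return(amplitude * 0)
  pi * amplitude / m
}

#' Complex field of an object
#' @param object a ComplexObject
#' @return complex matrix amplitude * exp(i * phase)
#' @export
complexField <- function(object) {
  object@amplitude * exp(1i * object@phase)
}

#' Synthetic bar-chart resolution target
#'
#' A resolution-test-chart style fixture: dark three-bar groups (both
#' orientations) at the requested pixel pitches on a bright background,
#' with the phase coupled to the amplitude (scaled to [0, pi]). The
#' metadata records, per group, the bar period and a line-profile
#' crossing the bars (for Michelson contrast), plus a homogeneous
#' background rectangle for SNR measurements and a crop window covering
#' the bar area for MSE.
#'
#' @param shape side length in pixels (square)
#' @param barPeriods bar periods in pixels (one dark bar + one gap = one
#'   period); each must be >= 2 px to be representable
#' @param pixelSize pixel pitch, um
#' @param barAmplitude amplitude of the dark bars (background is 1)
#' @return a [ComplexObject-class] with `bars`, `snrRegion` and
#'   `cropRegion` metadata
#' @examples
#' obj <- makeBarTarget(128, barPeriods = c(12, 8, 6), pixelSize = 0.4)
#' objectMetadata(obj)$snrRegion
#' @export
makeBarTarget <- function(shape = 256L, barPeriods = c(16, 12, 8, 6, 4, 3),
                          pixelSize = 0.4, barAmplitude = 0.1) {
  shape <- as.integer(shape)
  if (any(barPeriods < 2))
    stop("bar periods below 2 pixels cannot be represented (aliasing)")
  amp <- matrix(1, shape, shape)
  margin <- max(8L, shape %/% 10L)
  bars <- vector("list", length(barPeriods))
  ## USAF-style three-bar groups: bar width = period / 2, length 5x the
  ## width; horizontal-bar groups in a left column, vertical-bar groups
  ## in a right column, stacked with blank separation
  r0 <- margin + 1L
  cLeft <- margin + 1L
  cRight <- margin + 1L + ((shape - 2L * margin) * 2L) %/% 5L
  maxRow <- r0
  for (g in seq_along(barPeriods)) {
    p <- barPeriods[g]
    bw <- max(1L, floor(p / 2))        # dark bar width
    len <- 5L * bw                     # bar length
    groupExtent <- as.integer(round(2 * p + bw))
    if (r0 + max(groupExtent, len) > shape - margin)
      stop("bar groups do not fit: enlarge shape or drop periods")
    ## horizontal bars (run along columns)
    for (b in 0:2) {
      rr <- r0 + round(b * p) + seq_len(bw) - 1L
      amp[rr, cLeft:(cLeft + len - 1L)] <- barAmplitude
    }
    ## vertical bars (run along rows)
    for (b in 0:2) {
      cc <- cRight + round(b * p) + seq_len(bw) - 1L
      amp[r0:(r0 + len - 1L), cc] <- barAmplitude
    }
    ## contrast profile across the vertical bars
    prow <- r0 + len %/% 2L
    pcols <- cRight:(cRight + as.integer(3 * p) - 1L)
    bars[[g]] <- list(period = p,
                      profile = cbind(row = rep(prow, length(pcols)),
                                      col = pcols))
    adv <- max(groupExtent, len) + max(4L, as.integer(p))
    maxRow <- max(maxRow, r0 + max(groupExtent, len))
    r0 <- r0 + adv
  }
  ## homogeneous SNR rectangle in the blank area below the groups
  snrTop <- min(maxRow + margin %/% 2L, shape - margin %/% 2L - 1L)
  md <- list(
    bars = bars,
    snrRegion = c(row = snrTop, col = margin,
                  height = shape - snrTop - margin %/% 2L,
                  width = shape - 2L * margin),
    cropRegion = c(row = max(1L, margin - 4L), col = max(1L, margin - 4L),
                   height = min(shape, maxRow + 4L) - max(1L, margin - 4L) + 1L,
                   width = shape - 2L * max(1L, margin - 4L) + 1L)
  )
  ComplexObject(amp, pixelSize = pixelSize, metadata = md)
}

#' Seeded procedural texture object
#'
#' A reproducible textured phantom with natural-image statistics: a
#' 1/f-weighted random field overlaid with sharp-edged patches, its
#' amplitude normalised to [0, 1] and the phase coupled to the amplitude
#' (scaled to [0, pi]). Serves the role of a natural test image in
#' simulations without shipping one.
#'
#' @param shape side length in pixels (>= 64)
#' @param seed integer seed; fully determines the object
#' @param pixelSize pixel pitch, um
#' @param alpha spectral fall-off exponent of the smooth component
#' @return a [ComplexObject-class]
#' @export
makeTextureObject <- function(shape = 256L, seed = 1L, pixelSize = 0.4,
                              alpha = 1.6) {
  shape <- as.integer(shape)
  if (shape < 64L) stop("texture objects require shape >= 64")
  set.seed(as.integer(seed))
  w <- matrix(stats::rnorm(shape^2), shape, shape) +
    1i * matrix(stats::rnorm(shape^2), shape, shape)
  c0 <- gridCentre(shape)
  d <- seq_len(shape) - c0
  rad <- sqrt(outer(d^2, d^2, "+"))
  filt <- 1 / (1 + rad)^alpha
  smooth <- Re(ifft2c(w * filt)) * shape
  ## sharp-edged patches from a second, coarser field
  w2 <- matrix(stats::rnorm(shape^2), shape, shape) +
    1i * matrix(stats::rnorm(shape^2), shape, shape)
  coarse <- Re(ifft2c(w2 / (1 + rad)^2.5)) * shape
  patches <- (coarse > stats::quantile(coarse, 0.6)) * 1
  amp <- 0.65 * (smooth - min(smooth)) / diff(range(smooth)) + 0.35 * patches
  amp <- (amp - min(amp)) / diff(range(amp))
  ComplexObject(amp, pixelSize = pixelSize,
                metadata = list(seed = as.integer(seed)))
}
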