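## Structure-dependent amplification (SdA): classify pixels of the raw
## darkfield frames into "object" (scatterers, carrying signal) and
## "background", differentially boost object pixels using the data
## redundancy of the stack, threshold the background away, and restore
## (S3) or rescale (S4) the surviving pixels.

#' Background mask from the on-axis brightfield frame
#'
#' Otsu-binarizes the normal-incidence BF frame, dilates the object
#' class with a Euclidean disc of radius `s1Radius` (reclassifying
#' object-adjacent pixels out of the background), and returns the
#' complement: TRUE on structure-free background pixels. A radius of 20
#' pixels is the default for ~200 px frames; scale it with the frame
#' size.
#'
#' @param bfFrame on-axis brightfield intensity frame (non-constant)
#' @param s1Radius disc radius in pixels
#' @return logical matrix M (TRUE = background)
#' @export
buildBackgroundMask <- function(bfFrame, s1Radius = 20L) {
  if (s1Radius < 1L) stop("s1Radius must be a positive integer")
  obj <- otsuObjectMask(bfFrame)
  M <- dilateDisc(obj, s1Radius) == 0
  if (!any(M))
    stop("mask construction failed: no background pixels remain ",
         "(s1Radius too large for this frame?)")
  M
}

#' Initial mean-background subtraction (S1 -> S2)
#'
#' Subtracts from every darkfield frame its mean over the background
#' mask M and clamps at zero; brightfield frames pass through
#' unchanged. Hybrid frames must already have been excluded.
#'
#' @param stack raw S1 [ImageStack-class] without HYBRID frames
#' @param M logical background mask
#' @return an S2 [ImageStack-class]
#' @export
subtractInitialBackground <- function(stack, M) {
  if (!any(M)) stop("background mask M is empty")
  if (any(frameLabels(stack) == "HYBRID"))
    stop("exclude HYBRID frames before background subtraction")
  fr <- frames(stack)
  for (i in dfIndices(stack))
    fr[, , i] <- pmax(fr[, , i] - mean(fr[, , i][M]), 0)
  restack(stack, fr, "S2")
}

#' Binary object map from the brightfield sum (I_BF)
#'
#' The reciprocal of the summed BF frames highlights absorbing
#' structures; subtracting its maximum over the background mask leaves
#' positive values only on object pixels, which are then dilated with a
#' disc of radius `s2Radius` to fill holes and weak edges. Zero-valued
#' pixels of the BF sum (where the reciprocal is undefined) are treated
#' as maximally absorbing, i.e. assigned the largest finite reciprocal.
#'
#' @param stack S2 [ImageStack-class] with at least one BF frame
#' @param M logical background mask
#' @param s2Radius disc radius in pixels (default 8 for ~200 px frames)
#' @return 0/1 matrix
#' @export
computeObjectMap <- function(stack, M, s2Radius = 8L) {
  bf <- bfIndices(stack)
  if (!length(bf)) stop("object map requires at least one BF frame")
  B <- apply(frames(stack)[, , bf, drop = FALSE], c(1, 2), sum)
  recip <- matrix(Inf, nrow(B), ncol(B))
  recip[B > 0] <- 1 / B[B > 0]
  if (any(B == 0)) {
    message(sprintf("%d zero-valued BF-sum pixel(s) treated as maximal reciprocal",
                    sum(B == 0)))
    recip[B == 0] <- max(recip[B > 0])
  }
  recip <- recip - max(recip[M])
  dilateDisc(recip > 0, s2Radius)
}

#' Amplification map from the darkfield sum (I_DF)
#'
#' Sum of all darkfield frames minus its mean over the background mask,
#' clamped at zero: large where scatterers contribute signal across the
#' stack, zero on background.
#'
#' @param stack S2 [ImageStack-class] with at least one DF frame
#' @param M logical background mask
#' @return non-negative matrix
#' @export
computeAmplificationMap <- function(stack, M) {
  if (!any(M)) stop("background mask M is empty")
  df <- dfIndices(stack)
  if (!length(df)) stop("amplification map requires at least one DF frame")
  D <- apply(frames(stack)[, , df, drop = FALSE], c(1, 2), sum)
  pmax(D - mean(D[M]), 0)
}

#' Amplify, suppress and rebuild the corrected stacks (S3, S4)
#'
#' Per darkfield frame f of the S2 stack: amplify object pixels,
#' `A = f * (I_DF * I_BF + (1 - I_BF))`; threshold at the amplified
#' background level, `S2' = max(A * I_BF - (mean + 3 sd of A over M), 0)`;
#' restore original intensities on the surviving support,
#' `S3 = f where S2' > 0, else 0`; and compute the frame's
#' signal-to-background ratio `SBR = mean(f on I_BF) / mean(f on M)`.
#' Frames with SBR > 1 enter S4 unchanged from S3; low-SBR frames are
#' instead rescaled, `S4 = S2' / max(S2') * max(f)` on the surviving
#' support, which suppresses residual background at the cost of
#' resolution. Brightfield frames pass through to both stacks.
#'
#' @param stack S2 [ImageStack-class]
#' @param maps an [SdAMaps-class]
#' @return list with elements `S3`, `S4` (ImageStacks) and `sbr`
#'   (named per-DF-frame vector)
#' @export
amplifyAndBuildStacks <- function(stack, maps) {
  M <- backgroundMask(maps)
  Ibf <- objectMap(maps)
  Idf <- amplificationMap(maps)
  fr <- frames(stack)
  s3 <- fr
  s4 <- fr
  dfi <- dfIndices(stack)
  sbrv <- stats::setNames(numeric(length(dfi)), as.character(dfi))
  comp <- 1 - Ibf
  for (j in seq_along(dfi)) {
    i <- dfi[j]
    f <- fr[, , i]
    A <- f * (Idf * Ibf + comp)
    bg <- A[M]
    thr <- mean(bg) + 3 * stats::sd(bg)
    s2p <- pmax(A * Ibf - thr, 0)
    keep <- s2p > 0
    s3f <- ifelse(keep, f, 0)
    mBg <- mean(f[M])
    mObj <- mean(f[Ibf == 1])
    sbrv[j] <- if (mBg == 0) Inf else mObj / mBg
    s3[, , i] <- s3f
    if (sbrv[j] > 1) {
      s4[, , i] <- s3f
    } else if (max(s2p) == 0) {
      warning(sprintf("frame %d: S2' is all zero in the low-SBR branch; emitting an empty frame", i))
      s4[, , i] <- 0 * f
    } else {
      s4[, , i] <- ifelse(keep, s2p / max(s2p) * max(f), 0)
    }
  }
  list(S3 = restack(stack, s3, "S3"), S4 = restack(stack, s4, "S4"),
       sbr = sbrv)
}

#' Full SdA correction of a raw stack
#'
#' Runs the complete pipeline: hybrid-frame exclusion, background mask
#' from the on-axis BF frame, initial mean subtraction (S2), object and
#' amplification maps, and the dual corrected stacks. Pixels the finer
#' object map I_BF classifies as object are removed from the background
#' mask before the amplification stage, so background statistics are
#' never contaminated by object pixels.
#'
#' @param stack raw S1 [ImageStack-class]
#' @param geometry the matching [FPMGeometry-class]
#' @param s1Radius,s2Radius disc radii in pixels (defaults 20 and 8,
#'   appropriate for ~200 px frames; scale with frame size)
#' @return list with elements `S2`, `S3`, `S4` ([ImageStack-class]) and
#'   `maps` ([SdAMaps-class])
#' @examples
#' obj <- makeBarTarget(96, barPeriods = c(8, 6), pixelSize = 0.4)
#' geom <- FPMGeometry(ledGrid(5, pitch = 5.5), arrayHeight = 50,
#'                     wavelength = 532, objectiveNA = 0.2)
#' raw <- simulateStack(obj, geom, lrShape = 48, exposure = 1e4)
#' noisy <- degradeStack(raw, NoiseModel(offset = 100, gaussianSigma = 50))
#' cor <- sdaCorrect(noisy, geom, s1Radius = 6, s2Radius = 3)
#' stackRole(cor$S3); stackRole(cor$S4)
#' @export
sdaCorrect <- function(stack, geometry, s1Radius = 20L, s2Radius = 8L) {
  stack <- suppressMessages(excludeHybridFrames(stack))
  M <- buildBackgroundMask(onAxisFrame(stack, geometry), s1Radius)
  s2 <- subtractInitialBackground(stack, M)
  Ibf <- computeObjectMap(s2, M, s2Radius)
  M <- M & !(Ibf == 1)
  if (!any(M))
    stop("mask construction failed: object map covers the whole background")
  Idf <- computeAmplificationMap(s2, M)
  maps <- new("SdAMaps", backgroundMask = M, objectMap = Ibf,
              amplificationMap = Idf, sbr = numeric(),
              s1Radius = as.numeric(s1Radius), s2Radius = as.numeric(s2Radius))
  out <- amplifyAndBuildStacks(s2, maps)
  maps@sbr <- out$sbr
  list(S2 = s2, S3 = out$S3, S4 = out$S4, maps = maps)
}
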