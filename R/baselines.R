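## Reference background-correction methods against which SdA is
## compared: global 'mean' and 'mean + 3 sigma' subtraction, and the
## rolling-ball morphological baseline. All of them act on darkfield
## frames only; brightfield frames pass through unchanged.

#' Global background subtraction ('mean' and 'mean + 3 sigma')
#'
#' Per darkfield frame f: `max(f - (mean + k * sd over M), 0)`.
#' `kSigma = 0` is the conventional 'mean' correction (average over a
#' structure-free region); `kSigma = 3` removes 99.7% of a Gaussian
#' background at the cost of suppressing weak darkfield signal.
#'
#' @param stack S1 [ImageStack-class] (hybrid frames excluded)
#' @param M logical background mask (structure-free pixels)
#' @param kSigma number of background standard deviations added to the
#'   subtracted level (0 or 3 in the standard variants)
#' @return corrected [ImageStack-class] (role S2)
#' @export
globalSubtract <- function(stack, M, kSigma = 0) {
  if (!any(M)) stop("background mask M is empty")
  fr <- frames(stack)
  for (i in dfIndices(stack)) {
    f <- fr[, , i]
    bg <- f[M]
    fr[, , i] <- pmax(f - (mean(bg) + kSigma * stats::sd(bg)), 0)
  }
  restack(stack, fr, "S2")
}

## grayscale erosion/dilation with a non-flat ball structuring element,
## vectorised over structuring-element offsets; pixels whose
## neighbourhood extends beyond the frame use the valid part only
ballProfile <- function(radius) {
  d <- seq(-radius, radius)
  h2 <- radius^2 - outer(d^2, d^2, "+")
  h <- sqrt(pmax(h2, 0))
  h[h2 < 0] <- NA
  h
}

grayMorph <- function(f, h, op = c("erode", "dilate")) {
  op <- match.arg(op)
  r <- (nrow(h) - 1L) / 2L
  n <- dim(f)
  out <- matrix(if (op == "erode") Inf else -Inf, n[1], n[2])
  for (a in -r:r) for (b in -r:r) {
    hv <- h[a + r + 1L, b + r + 1L]
    if (is.na(hv)) next
    ri <- max(1L, 1L - a):min(n[1], n[1] - a)
    ci <- max(1L, 1L - b):min(n[2], n[2] - b)
    shifted <- f[ri + a, ci + b, drop = FALSE]
    if (op == "erode")
      out[ri, ci] <- pmin(out[ri, ci], shifted - hv)
    else
      out[ri, ci] <- pmax(out[ri, ci], shifted + hv)
  }
  out
}

#' Rolling-ball background estimate
#'
#' Grayscale opening of a frame with a ball-shaped (non-flat)
#' structuring element of the given radius: the classical geometric
#' background surface traced by a ball rolling under the intensity
#' landscape. Structures narrower than the ball are left out of the
#' background.
#'
#' @param f numeric matrix
#' @param radius ball radius in pixels (>= 1, smaller than the frame)
#' @return background matrix of the same shape
#' @export
rollingBallBackground <- function(f, radius) {
  if (radius < 1) stop("rolling-ball radius must be >= 1")
  if (2 * radius + 1 > min(dim(f)))
    stop("rolling-ball radius larger than the frame")
  h <- ballProfile(radius)
  grayMorph(grayMorph(f, h, "erode"), h, "dilate")
}

#' Rolling-ball background subtraction
#'
#' Subtracts the rolling-ball background estimate from every darkfield
#' frame and clamps at zero. The radius is a tunable, conventionally
#' swept with the best-performing value kept.
#'
#' @param stack S1 [ImageStack-class]
#' @param radius ball radius in pixels
#' @return corrected [ImageStack-class] (role S2)
#' @export
rollingBallSubtract <- function(stack, radius) {
  fr <- frames(stack)
  for (i in dfIndices(stack))
    fr[, , i] <- pmax(fr[, , i] - rollingBallBackground(fr[, , i], radius), 0)
  restack(stack, fr, "S2")
}
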