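## Internal numerics shared across modules: DC-centered 2-D Fourier
## transforms, disc structuring elements and small image helpers.

#' Quadrant swaps for DC-centered spectra
#'
#' `fftShift2` moves the DC component of a 2-D FFT to the grid centre
#' (index floor(n/2)+1 along each axis); `ifftShift2` is its inverse,
#' also correct for odd sizes.
#'
#' @param x matrix
#' @return matrix of the same shape
#' @export
fftShift2 <- function(x) {
  n <- dim(x)
  i <- c(seq_len(ceiling(n[1] / 2)) + floor(n[1] / 2), seq_len(floor(n[1] / 2)))
  j <- c(seq_len(ceiling(n[2] / 2)) + floor(n[2] / 2), seq_len(floor(n[2] / 2)))
  x[order(i), order(j), drop = FALSE]
}

#' @rdname fftShift2
#' @export
ifftShift2 <- function(x) {
  n <- dim(x)
  i <- c(seq_len(ceiling(n[1] / 2)) + floor(n[1] / 2), seq_len(floor(n[1] / 2)))
  j <- c(seq_len(ceiling(n[2] / 2)) + floor(n[2] / 2), seq_len(floor(n[2] / 2)))
  x[i, j, drop = FALSE]
}

## DC-centered forward / inverse 2-D DFT (ifft2c normalised by 1/N)
fft2c <- function(x) fftShift2(stats::fft(x))
ifft2c <- function(X) stats::fft(ifftShift2(X), inverse = TRUE) / length(X)

## centre index of a DC-centered grid of size n
gridCentre <- function(n) floor(n / 2) + 1L

#' Discrete Euclidean disc structuring element
#'
#' Square 0/1 kernel of side 2*radius+1; a pixel belongs to the disc iff
#' its centre distance is <= radius.
#'
#' @param radius disc radius in pixels (>= 0)
#' @return 0/1 matrix
#' @export
discKernel <- function(radius) {
  radius <- as.integer(radius)
  stopifnot(radius >= 0L)
  d <- seq(-radius, radius)
  k <- outer(d^2, d^2, "+") <= radius^2
  storage.mode(k) <- "double"
  k
}

## binary dilation with a Euclidean disc (EBImage grayscale dilation on
## a 0/1 image with a flat kernel)
dilateDisc <- function(mask, radius) {
  m <- mask * 1
  if (radius < 1L) return(m)
  EBImage::dilate(m, discKernel(radius))
}

#' Otsu threshold of an image
#'
#' 256-bin histogram threshold over the frame's full dynamic range,
#' maximising the between-class variance over all cut points (bins
#' 1..i against i+1..levels; equivalently minimising the within-class
#' variance). Ties are resolved to the midpoint of the first and last
#' maximising bins. Pixels strictly above the returned value form one
#' class.
#'
#' @param x numeric matrix, non-constant
#' @param levels number of histogram bins
#' @return threshold on the intensity scale of `x`
#' @export
otsuThreshold <- function(x, levels = 256L) {
  r <- range(x)
  if (!all(is.finite(r)) || r[1] == r[2])
    stop("Otsu threshold undefined for a constant or non-finite image")
  breaks <- seq(r[1], r[2], length.out = levels + 1L)
  h <- hist.default(as.vector(x), breaks = breaks, plot = FALSE)
  counts <- as.double(h$counts)
  mids <- as.double(h$mids)
  len <- length(counts)
  w1 <- cumsum(counts)
  w2 <- w1[len] - w1
  cm <- counts * mids
  m1 <- cumsum(cm)
  m2 <- m1[len] - m1
  bc <- rep(NA_real_, len)
  ok <- w1 > 0 & w2 > 0
  bc[ok] <- (w1 * w2 * (m2 / w2 - m1 / w1)^2)[ok]
  maxi <- which(bc == max(bc, na.rm = TRUE))
  (mids[maxi[1]] + mids[maxi[length(maxi)]]) / 2
}

## class with the smaller pixel count is taken as "object" (dark
## absorbing structures on a bright background by default; the rule
## also handles bright-object samples)
otsuObjectMask <- function(x, levels = 256L) {
  t <- otsuThreshold(x, levels)
  below <- x <= t
  if (sum(below) <= sum(!below)) below else {
    message("object class brighter than background: taking the smaller Otsu class as object")
    !below
  }
}

## fast box mean over w x w windows, valid region only (rows/cols
## cropped by (w-1)/2 on each side), via integral images
boxMeanValid <- function(x, w) {
  n <- dim(x)
  ## S[i+1, j+1] = sum of x[1:i, 1:j]
  S <- matrix(0, n[1] + 1L, n[2] + 1L)
  cs <- apply(x, 2L, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = n[1])
  S[-1L, -1L] <- t(apply(cs, 1L, cumsum))
  i <- seq_len(n[1] - w + 1L)
  j <- seq_len(n[2] - w + 1L)
  (S[i + w, j + w, drop = FALSE] - S[i, j + w, drop = FALSE] -
     S[i + w, j, drop = FALSE] + S[i, j, drop = FALSE]) / (w * w)
}

#' Align one complex field to another
#'
#' Resolves the global phase (and, optionally, scale) ambiguity of a
#' phase-retrieval result by the least-squares complex factor
#' c = <ref, x> / <x, x>, returning c * x. With `scale = FALSE` only the
#' unit-modulus phase factor is applied.
#'
#' @param x complex matrix to align
#' @param ref complex reference of the same shape
#' @param scale also match the global amplitude scale?
#' @return aligned complex matrix
#' @export
alignFields <- function(x, ref, scale = TRUE) {
  stopifnot(identical(dim(x), dim(ref)))
  c0 <- sum(Conj(x) * ref) / sum(Mod(x)^2)
  if (!scale && Mod(c0) > 0) c0 <- c0 / Mod(c0)
  c0 * x
}

## deterministic per-frame seed stream derived from one global seed
frameSeed <- function(seed, frame) {
  as.integer((as.numeric(seed) * 48271 + frame * 16807) %% 2147483647)
}
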