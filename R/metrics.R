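#' Mean squared error between two images
#' @param test,reference equal-shape numeric matrices
#' @return mean squared pixel difference
#' @export
imageMSE <- function(test, reference) {
  if (!identical(dim(test), dim(reference)))
    stop("shape mismatch between test and reference")
  mean((test - reference)^2)
}

#' Structural similarity index (SSIM)
#'
#' Mean SSIM over uniform `window` x `window` neighbourhoods (valid
#' windows only), with the standard stabilising constants
#' C1 = (K1 L)^2, C2 = (K2 L)^2 where L is the dynamic range (the
#' reference maximum by default, since the reference is the noise-free
#' reconstruction).
#'
#' @param test,reference equal-shape numeric matrices
#' @param window odd window side, default 7
#' @param dataRange dynamic range L; default `max(reference)`
#' @param K1,K2 SSIM constants (0.01, 0.03)
#' @return mean SSIM in [-1, 1]
#' @export
imageSSIM <- function(test, reference, window = 7L,
                      dataRange = max(reference), K1 = 0.01, K2 = 0.03) {
  if (!identical(dim(test), dim(reference)))
    stop("shape mismatch between test and reference")
  if (min(dim(test)) < window)
    stop("images smaller than the SSIM window")
  C1 <- (K1 * dataRange)^2
  C2 <- (K2 * dataRange)^2
  mx <- boxMeanValid(test, window)
  my <- boxMeanValid(reference, window)
  mxx <- boxMeanValid(test^2, window)
  myy <- boxMeanValid(reference^2, window)
  mxy <- boxMeanValid(test * reference, window)
  ## unbiased (n-1) moment estimates as in the standard implementation
  np <- window^2
  cf <- np / (np - 1)
  vx <- cf * (mxx - mx^2)
  vy <- cf * (myy - my^2)
  cxy <- cf * (mxy - mx * my)
  s <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
  mean(s)
}

#' SSIM and MSE of a reconstruction against a reference
#'
#' Amplitude and phase are compared separately in practice; this helper
#' compares one real-valued channel.
#'
#' @param test,reference equal-shape numeric matrices
#' @param ... passed to [imageSSIM()]
#' @return list with elements `ssim` and `mse`
#' @export
compareImages <- function(test, reference, ...) {
  list(ssim = imageSSIM(test, reference, ...),
       mse = imageMSE(test, reference))
}

#' Signal-to-noise ratio of a homogeneous region, in dB
#'
#' The logarithmic ratio of the mean to the standard deviation of the
#' pixel values: `20 log10(mean / sd)` for amplitude images (the
#' default) or `10 log10` for intensity/power conventions. Invariant
#' under positive scaling of the region.
#'
#' @param region numeric matrix or vector of pixel values from a
#'   structure-free area (non-constant, positive mean)
#' @param convention "amplitude" (20 log10) or "power" (10 log10)
#' @return SNR in dB
#' @export
snrDb <- function(region, convention = c("amplitude", "power")) {
  convention <- match.arg(convention)
  m <- mean(region)
  s <- stats::sd(as.vector(region))
  if (s == 0) stop("undefined SNR: region has zero standard deviation")
  if (m <= 0) stop("undefined SNR: region mean must be positive")
  k <- if (convention == "amplitude") 20 else 10
  k * log10(m / s)
}

#' Average Michelson contrast along bar-profile lines
#'
#' Each profile (a set of pixel coordinates crossing a bar group,
#' with a known bar period in pixels) is split into consecutive
#' one-period windows; the Michelson contrast
#' `(Imax - Imin) / (Imax + Imin)` is computed per window and averaged
#' over windows and profiles. Flat profiles give 0.
#'
#' @param amplitude image matrix
#' @param profiles list of profiles, each a list with elements `profile`
#'   (n x 2 matrix of row/col pixel coordinates) and `period` (pixels),
#'   as produced in [makeBarTarget()] metadata
#' @return mean contrast in [0, 1]
#' @export
lineContrast <- function(amplitude, profiles) {
  one <- function(p) {
    v <- amplitude[cbind(p$profile[, 1], p$profile[, 2])]
    per <- max(2L, as.integer(round(p$period)))
    nw <- length(v) %/% per
    if (nw < 1L) stop("profile must cross at least one full bar period")
    cw <- vapply(seq_len(nw), function(w) {
      seg <- v[((w - 1L) * per + 1L):(w * per)]
      hi <- max(seg); lo <- min(seg)
      if (hi + lo == 0) 0 else (hi - lo) / (hi + lo)
    }, numeric(1))
    mean(cw)
  }
  mean(vapply(profiles, one, numeric(1)))
}

#' Azimuthally averaged power spectrum
#'
#' Power of the DC-centered 2-D spectrum averaged over annuli one
#' frequency pixel wide; the abscissa is spatial frequency in 1/um,
#' the ordinate log10 of the mean power (with a small floor to keep
#' empty bands finite).
#'
#' @param amplitude square image matrix (padded to square otherwise)
#' @param pixelSize pixel pitch, um
#' @return data.frame with columns `freq` (1/um), `power` and `logPower`
#' @export
radialPowerSpectrum <- function(amplitude, pixelSize) {
  n <- dim(amplitude)
  if (n[1] != n[2]) {
    N <- max(n)
    padded <- matrix(0, N, N)
    padded[seq_len(n[1]), seq_len(n[2])] <- amplitude
    amplitude <- padded
    n <- c(N, N)
  }
  N <- n[1]
  P <- Mod(fft2c(amplitude))^2
  c0 <- gridCentre(N)
  d <- seq_len(N) - c0
  k <- round(sqrt(outer(d^2, d^2, "+")))
  kmax <- floor(N / 2)
  keep <- k <= kmax
  power <- as.vector(tapply(P[keep], k[keep], mean))
  kk <- sort(unique(as.vector(k[keep])))
  df <- 1 / (N * pixelSize)
  floorP <- max(power) * 1e-15
  data.frame(freq = kk * df, power = power,
             logPower = log10(pmax(power, floorP)))
}

#' Full metrics report for one reconstruction
#'
#' @param test reconstructed amplitude
#' @param reference reference amplitude (same grid); NULL skips SSIM/MSE
#' @param snrRegion c(row, col, height, width) homogeneous rectangle, or
#'   NULL
#' @param profiles bar profiles for [lineContrast()], or NULL
#' @param pixelSize pixel pitch, um
#' @param cropRegion optional c(row, col, height, width) window to which
#'   SSIM/MSE are restricted
#' @return a [MetricsReport-class]
#' @export
metricsReport <- function(test, reference = NULL, snrRegion = NULL,
                          profiles = NULL, pixelSize = 1,
                          cropRegion = NULL) {
  ss <- NA_real_; ms <- NA_real_; sn <- NA_real_; ct <- NA_real_
  if (!is.null(reference)) {
    a <- test; b <- reference
    if (!is.null(cropRegion)) {
      a <- cropRect(a, cropRegion)
      b <- cropRect(b, cropRegion)
    }
    cmp <- compareImages(a, b)
    ss <- cmp$ssim; ms <- cmp$mse
  }
  if (!is.null(snrRegion)) sn <- snrDb(cropRect(test, snrRegion))
  if (!is.null(profiles)) ct <- lineContrast(test, profiles)
  new("MetricsReport", ssim = ss, mse = ms, snrDb = sn, contrast = ct,
      radialSpectrum = radialPowerSpectrum(test, pixelSize))
}

cropRect <- function(x, r) {
  x[r[1]:(r[1] + r[3] - 1L), r[2]:(r[2] + r[4] - 1L), drop = FALSE]
}
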