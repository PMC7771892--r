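#' Construct a reconstruction schedule
#'
#' @param nIterations number of full sweeps N (default 10)
#' @param stackRoles stack role per iteration; the default SdA schedule
#'   feeds the rescaled S4 stack to iterations 1..N-1 and the
#'   intensity-preserving S3 stack to the final iteration. A single role
#'   is recycled to all iterations.
#' @param frameOrder integer permutation of frame positions, or NULL
#'   for ascending illumination NA (centre-out)
#' @param stepSize update step size (default 1)
#' @param delta Gauss-Newton regularizer relative to max |P|^2
#'   (default 1e-3)
#' @return a [ReconSchedule-class]
#' @export
ReconSchedule <- function(nIterations = 10L, stackRoles = NULL,
                          frameOrder = NULL, stepSize = 1, delta = 1e-3) {
  nIterations <- as.integer(nIterations)
  if (is.null(stackRoles))
    stackRoles <- if (nIterations == 1L) "S3" else
      c(rep("S4", nIterations - 1L), "S3")
  if (length(stackRoles) == 1L)
    stackRoles <- rep(stackRoles, nIterations)
  new("ReconSchedule", nIterations = nIterations,
      stackRoles = as.character(stackRoles),
      frameOrder = as.integer(frameOrder %||% integer()),
      stepSize = as.numeric(stepSize), delta = as.numeric(delta))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sequential Gauss-Newton FPM reconstruction
#'
#' Recovers a high-resolution complex field from low-resolution
#' intensity stacks. Per iteration, per frame (default order: ascending
#' illumination NA), the current HR spectrum estimate is forward-
#' projected through the frame's pupil passband, the modulus of the
#' low-resolution field is replaced by the square root of the measured
#' intensity, and the passband is updated with the sequential
#' second-order (Gauss-Newton) rule
#' `O(k) <- O(k) + step * |P| conj(P) (Psi' - Psi) / (max|P| (|P|^2 + delta))`
#' with the pupil P fixed (ideal circular aperture, no aberration
#' recovery). The schedule may substitute a differently corrected stack
#' per iteration; the SdA default uses S4 for iterations 1..N-1 and S3
#' for the last. The per-iteration residual
#' `sum ||sqrt(I_meas) - |forward|||^2` is recorded before each frame
#' update.
#'
#' The global scale/phase of the result is arbitrary (set by the
#' initialisation, an upsampled on-axis BF amplitude with zero phase);
#' use [alignFields()] before pointwise comparisons.
#'
#' @param stacks a single [ImageStack-class] or a named list of stacks
#'   keyed by role (e.g. `list(S3 = ..., S4 = ...)`), all sharing shape
#'   and LED indexing
#' @param object a [ComplexObject-class] supplying the HR grid and pixel
#'   size (its content is ignored unless used as `init`), or a list
#'   `list(shape =, pixelSize =)`
#' @param geometry an [FPMGeometry-class]
#' @param schedule a [ReconSchedule-class]
#' @param init optional [ComplexObject-class] initial estimate; NULL
#'   initialises from the upsampled on-axis BF amplitude with zero phase
#' @return a [ReconResult-class]
#' @export
fpmReconstruct <- function(stacks, object, geometry,
                           schedule = ReconSchedule(), init = NULL) {
  if (is(stacks, "ImageStack")) {
    stacks <- stats::setNames(list(stacks), stackRole(stacks))
    ## a single stack serves every scheduled role
    schedule@stackRoles <- rep(names(stacks), schedule@nIterations)
  }
  roles <- unique(schedule@stackRoles)
  missingRoles <- setdiff(roles, names(stacks))
  if (length(missingRoles))
    stop("schedule requests stack role(s) not provided: ",
         paste(missingRoles, collapse = ", "))
  ref <- stacks[[roles[1]]]
  if (any(vapply(stacks, function(s) any(frameLabels(s) == "HYBRID"),
                 logical(1))))
    stop("exclude HYBRID frames before reconstruction")
  for (s in stacks[-1]) {
    if (!identical(dim(frames(s)), dim(frames(ref))) ||
        !identical(ledIndex(s), ledIndex(ref)))
      stop("all stacks must share shape and LED indexing")
  }
  if (is.list(object) && !is(object, "ComplexObject"))
    object <- ComplexObject(matrix(1, object$shape, object$shape),
                            pixelSize = object$pixelSize)
  sub <- subsetGeometry(geometry, ledIndex(ref))
  pg <- pupilGrid(object, sub, dim(frames(ref))[1])
  naIll <- illuminationNA(sub)
  coverage <- checkCoverage(pg, naIll, objectiveNA(geometry))
  ord <- if (length(schedule@frameOrder)) schedule@frameOrder else
    order(naIll)
  ## initial HR spectrum: zero-padded spectrum of the upsampled on-axis
  ## BF amplitude (zero phase)
  O <- matrix(0i, pg$N, pg$N)
  dN <- seq_len(pg$N) - pg$cN
  if (is.null(init)) {
    ## the modulus of a band-limited field is not band-limited, so the
    ## upsampled BF amplitude is confined to the on-axis pupil support
    ## (nothing beyond it is informed by the on-axis frame)
    a0 <- sqrt(onAxisFrame(ref, geometry))
    A0 <- fft2c(a0) * (pg$N / pg$m)^2 * pg$pupil
    rows <- pg$cN + (seq_len(pg$m) - pg$cm)
    O[rows, rows] <- A0
  } else {
    ## explicit initial estimates are trimmed to the synthetic NA: no
    ## measurement constrains anything beyond it
    O <- fft2c(complexField(init))
    rSynth <- (objectiveNA(geometry) + max(naIll)) /
      wavelengthUm(geometry) / pg$df
    O[outer(dN^2, dN^2, "+") > rSynth^2] <- 0i
  }
  P <- pg$pupil
  denom <- Mod(P)^2 + schedule@delta    # |P|max = 1 for the ideal pupil
  upd <- schedule@stepSize * Mod(P) * Conj(P) / denom
  a <- (pg$m / pg$N)^2                  # LR/HR amplitude normalisation
  res <- numeric(schedule@nIterations)
  eps <- .Machine$double.eps
  for (it in seq_len(schedule@nIterations)) {
    fr <- frames(stacks[[schedule@stackRoles[it]]])
    for (i in ord) {
      rows <- pg$cN + pg$shift[i, 1] + (seq_len(pg$m) - pg$cm)
      cols <- pg$cN + pg$shift[i, 2] + (seq_len(pg$m) - pg$cm)
      W <- O[rows, cols]
      psi <- a * ifft2c(P * W)
      meas <- sqrt(fr[, , i])
      res[it] <- res[it] + sum((meas - Mod(psi))^2)
      psiNew <- meas * psi / (Mod(psi) + eps)
      dW <- fft2c(psiNew - psi) / a
      O[rows, cols] <- W + upd * dW
    }
  }
  new("ReconResult", field = ifft2c(O), residuals = res,
      syntheticNA = objectiveNA(geometry) + max(naIll),
      pixelSize = pixelSize(object))
}

## geometry restricted to the LEDs a stack actually contains
subsetGeometry <- function(geometry, idx) {
  FPMGeometry(geometry@ledPositions[idx, , drop = FALSE],
              geometry@arrayHeight, geometry@wavelength,
              geometry@objectiveNA, geometry@hybridBand)
}

## warn (not error) if neighbouring passbands leave radial gaps
checkCoverage <- function(pg, naIll, objNA) {
  kr <- sqrt(rowSums(pg$shift^2))
  kr <- sort(unique(c(0, kr)))
  gaps <- diff(kr) > 2 * pg$rPix
  if (any(gaps))
    warning("passband coverage gap: neighbouring illumination angles do not overlap")
  invisible(!any(gaps))
}

#' Band-limited version of a complex object
#'
#' Applies the circular low-pass of the given NA to the object's
#' complex field: the reconstruction target of a noise-free round trip,
#' since frequencies beyond the synthetic NA are never measured.
#'
#' @param object a [ComplexObject-class]
#' @param na band-limit numerical aperture
#' @param wavelength wavelength in nm
#' @return complex matrix
#' @export
bandLimitField <- function(object, na, wavelength) {
  u <- complexField(object)
  N <- nrow(u)
  df <- 1 / (N * pixelSize(object))
  r <- (na / (wavelength * 1e-3)) / df
  d <- seq_len(N) - gridCentre(N)
  mask <- (outer(d^2, d^2, "+") <= r^2) * 1
  ifft2c(fft2c(u) * mask)
}
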