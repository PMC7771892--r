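#' LED-array illumination geometry
#'
#' Describes the planar LED array of an FPM microscope: lateral LED
#' positions (mm), the distance between array and sample plane (mm), the
#' illumination wavelength (nm) and the objective numerical aperture.
#' Each LED illuminates the sample as a plane wave whose transverse
#' spatial frequency is \code{NA_ill / lambda}; LEDs are classified as
#' brightfield (BF), darkfield (DF) or HYBRID depending on where their
#' illumination NA falls relative to the objective NA. The HYBRID band is
#' a small NA half-width around the objective NA inside which a single
#' frame contains both BF and DF regions (due to wavefront curvature on a
#' real instrument) and must be excluded before reconstruction.
#'
#' @slot ledPositions numeric matrix, one row per LED, columns x and y
#'   lateral offsets in mm
#' @slot arrayHeight distance from LED plane to sample, mm
#' @slot wavelength illumination wavelength, nm
#' @slot objectiveNA objective numerical aperture
#' @slot hybridBand NA half-width of the hybrid classification band
#'
#' @seealso [waveVectors()], [illuminationNA()], [frameLabels()]
#' @export
setClass("FPMGeometry",
  representation(
    ledPositions = "matrix",
    arrayHeight = "numeric",
    wavelength = "numeric",
    objectiveNA = "numeric",
    hybridBand = "numeric"
  )
)

setValidity("FPMGeometry", function(object) {
  msg <- character()
  p <- object@ledPositions
  if (!is.numeric(p) || ncol(p) != 2L || nrow(p) < 1L)
    msg <- c(msg, "ledPositions must be a numeric matrix with columns (x, y)")
  if (length(object@arrayHeight) != 1L || !is.finite(object@arrayHeight) ||
      object@arrayHeight <= 0)
    msg <- c(msg, "arrayHeight must be a single positive number (mm)")
  if (length(object@wavelength) != 1L || !is.finite(object@wavelength) ||
      object@wavelength <= 0)
    msg <- c(msg, "wavelength must be a single positive number (nm)")
  if (length(object@objectiveNA) != 1L || object@objectiveNA <= 0 ||
      object@objectiveNA >= 1)
    msg <- c(msg, "objectiveNA must lie in (0, 1)")
  if (length(object@hybridBand) != 1L || object@hybridBand < 0)
    msg <- c(msg, "hybridBand must be a non-negative number")
  if (length(msg)) msg else TRUE
})

#' Complex object field
#'
#' A high-resolution complex transmission function: non-negative real
#' amplitude and a phase map in radians on the same grid, with a physical
#' pixel size in micrometres. Fixture generators couple the phase to the
#' amplitude (phase scaled to [0, pi]) as is conventional for simulated
#' stained-specimen targets.
#'
#' @slot amplitude non-negative real matrix
#' @slot phase real matrix (radians), same shape as amplitude
#' @slot pixelSize pixel pitch in micrometres
#' @slot metadata free-form list (fixture annotations such as bar-group
#'   profiles and homogeneous regions)
#' @export
setClass("ComplexObject",
  representation(
    amplitude = "matrix",
    phase = "matrix",
    pixelSize = "numeric",
    metadata = "list"
  ),
  prototype(metadata = list())
)

setValidity("ComplexObject", function(object) {
  msg <- character()
  if (!identical(dim(object@amplitude), dim(object@phase)))
    msg <- c(msg, "amplitude and phase must have identical shape")
  if (any(object@amplitude < 0))
    msg <- c(msg, "amplitude must be non-negative")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number (um)")
  if (length(msg)) msg else TRUE
})

#' Camera degradation model
#'
#' Sensor model applied to noise-free frames: a constant background
#' offset (stray light + dark current, counts), Poisson shot noise drawn
#' on the photo-electron scale (frame / gain, then rescaled by the gain
#' in counts per photo-electron; gain 0 disables shot noise) and additive
#' white Gaussian read noise. The seed fully determines the degradation.
#'
#' @slot offset constant background in counts (>= 0)
#' @slot gaussianSigma read-noise standard deviation in counts (>= 0)
#' @slot poissonGain counts per photo-electron; 0 disables Poisson noise
#' @slot seed integer seed
#' @export
setClass("NoiseModel",
  representation(
    offset = "numeric",
    gaussianSigma = "numeric",
    poissonGain = "numeric",
    seed = "integer"
  )
)

setValidity("NoiseModel", function(object) {
  msg <- character()
  if (object@offset < 0) msg <- c(msg, "offset must be >= 0")
  if (object@gaussianSigma < 0) msg <- c(msg, "gaussianSigma must be >= 0")
  if (object@poissonGain < 0) msg <- c(msg, "poissonGain must be >= 0")
  if (length(msg)) msg else TRUE
})

.stackRoles <- c("S1", "S2", "S2prime", "S3", "S4")

#' Ordered stack of low-resolution intensity frames
#'
#' Non-negative real 2-D intensity frames stored as a height x width x n
#' array, with the LED index each frame was captured under and its BF /
#' DF / HYBRID label. The \code{role} slot records where the stack sits
#' in the correction pipeline: \code{S1} raw, \code{S2} after initial
#' mean-background subtraction, \code{S2prime} after amplification and
#' thresholding, \code{S3} original intensities restored on the surviving
#' support, \code{S4} with low-SBR frames rescaled. Only raw \code{S1}
#' stacks may still contain HYBRID frames.
#'
#' @slot frames numeric array (rows x cols x n)
#' @slot ledIndex integer vector, one LED index per frame
#' @slot role one of S1, S2, S2prime, S3, S4
#' @slot labels character vector, per-frame BF / DF / HYBRID
#' @export
setClass("ImageStack",
  representation(
    frames = "array",
    ledIndex = "integer",
    role = "character",
    labels = "character"
  )
)

setValidity("ImageStack", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3L)
    msg <- c(msg, "frames must be a 3-D array (rows x cols x n)")
  else {
    n <- d[3L]
    if (length(object@ledIndex) != n)
      msg <- c(msg, "ledIndex must have one entry per frame")
    if (length(object@labels) != n)
      msg <- c(msg, "labels must have one entry per frame")
  }
  if (!all(object@labels %in% c("BF", "DF", "HYBRID")))
    msg <- c(msg, "labels must be BF, DF or HYBRID")
  if (length(object@role) != 1L || !(object@role %in% .stackRoles))
    msg <- c(msg, sprintf("role must be one of %s",
                          paste(.stackRoles, collapse = ", ")))
  else if (object@role != "S1" && any(object@labels == "HYBRID"))
    msg <- c(msg, "only raw S1 stacks may carry HYBRID frames")
  if (any(!is.finite(object@frames)))
    msg <- c(msg, "frames must be finite")
  else if (any(object@frames < 0))
    msg <- c(msg, "frames must be non-negative")
  if (length(msg)) msg else TRUE
})

#' SdA classification and amplification maps
#'
#' The intermediate images of the structure-dependent amplification
#' pipeline: the background mask \code{M} (TRUE on structure-free
#' pixels), the binary object map \code{I_BF} derived from the
#' reciprocal brightfield sum, the non-negative amplification map
#' \code{I_DF} from the darkfield sum, and the per-darkfield-frame
#' signal-to-background ratios. A pixel is never simultaneously
#' background and object.
#'
#' @slot backgroundMask logical matrix M
#' @slot objectMap 0/1 matrix I_BF
#' @slot amplificationMap non-negative matrix I_DF
#' @slot sbr numeric vector, SBR per DF frame (named by frame position)
#' @slot s1Radius,s2Radius structuring-element radii used (pixels)
#' @export
setClass("SdAMaps",
  representation(
    backgroundMask = "matrix",
    objectMap = "matrix",
    amplificationMap = "matrix",
    sbr = "numeric",
    s1Radius = "numeric",
    s2Radius = "numeric"
  )
)

setValidity("SdAMaps", function(object) {
  msg <- character()
  if (!is.logical(object@backgroundMask))
    msg <- c(msg, "backgroundMask must be logical")
  if (!all(object@objectMap %in% c(0, 1)))
    msg <- c(msg, "objectMap must be 0/1-valued")
  if (any(object@amplificationMap < 0))
    msg <- c(msg, "amplificationMap must be non-negative")
  if (identical(dim(object@backgroundMask), dim(object@objectMap)) &&
      any(object@backgroundMask & object@objectMap == 1))
    msg <- c(msg, "a pixel may not be both background (M) and object (I_BF)")
  if (length(msg)) msg else TRUE
})

#' Reconstruction schedule
#'
#' Controls the sequential phase-retrieval sweep: the number of
#' iterations N, which corrected stack feeds each iteration (the SdA
#' default uses the rescaled S4 stack for iterations 1..N-1 and the
#' intensity-preserving S3 stack for the final iteration), the frame
#' order within a sweep (NULL = ascending illumination NA), the update
#' step size and the Gauss-Newton regularizer.
#'
#' @slot nIterations number of full sweeps N (>= 1)
#' @slot stackRoles character vector of length N mapping iteration to
#'   stack role
#' @slot frameOrder integer permutation of frames, or length 0 for the
#'   default ascending-NA order
#' @slot stepSize positive update step
#' @slot delta positive regularizer (relative to max |P|^2)
#' @export
setClass("ReconSchedule",
  representation(
    nIterations = "integer",
    stackRoles = "character",
    frameOrder = "integer",
    stepSize = "numeric",
    delta = "numeric"
  )
)

setValidity("ReconSchedule", function(object) {
  msg <- character()
  if (object@nIterations < 1L) msg <- c(msg, "nIterations must be >= 1")
  if (length(object@stackRoles) != object@nIterations)
    msg <- c(msg, "stackRoles must map every iteration to a stack role")
  if (!all(object@stackRoles %in% .stackRoles))
    msg <- c(msg, "stackRoles must be stack role names")
  if (object@stepSize <= 0) msg <- c(msg, "stepSize must be positive")
  if (object@delta <= 0) msg <- c(msg, "delta must be positive")
  if (length(msg)) msg else TRUE
})

#' Phase-retrieval result
#'
#' The recovered high-resolution complex field, the per-iteration data
#' residual sum ||sqrt(I_meas) - |forward|||^2 and the synthetic NA
#' (objective NA + maximum illumination NA used), which sets the
#' frequency cutoff of the reconstruction.
#'
#' @slot field complex matrix (HR grid)
#' @slot residuals numeric vector, one entry per iteration
#' @slot syntheticNA objective NA plus maximum illumination NA used
#' @slot pixelSize HR pixel size, um
#' @export
setClass("ReconResult",
  representation(
    field = "matrix",
    residuals = "numeric",
    syntheticNA = "numeric",
    pixelSize = "numeric"
  )
)

setValidity("ReconResult", function(object) {
  msg <- character()
  if (!is.complex(object@field)) msg <- c(msg, "field must be complex")
  if (any(object@residuals < 0)) msg <- c(msg, "residuals must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Image-quality report
#'
#' Metric bundle for one reconstruction against a reference: SSIM, MSE,
#' SNR in dB over a homogeneous region, mean Michelson line contrast,
#' and the azimuthally averaged power spectrum (frequency in 1/um,
#' log10 power).
#'
#' @slot ssim structural similarity in [-1, 1] (NA if not computed)
#' @slot mse mean squared error (>= 0)
#' @slot snrDb signal-to-noise ratio, dB
#' @slot contrast mean Michelson contrast in [0, 1]
#' @slot radialSpectrum data.frame with columns freq (1/um) and logPower
#' @export
setClass("MetricsReport",
  representation(
    ssim = "numeric",
    mse = "numeric",
    snrDb = "numeric",
    contrast = "numeric",
    radialSpectrum = "data.frame"
  ),
  prototype(ssim = NA_real_, mse = NA_real_, snrDb = NA_real_,
            contrast = NA_real_,
            radialSpectrum = data.frame(freq = numeric(), logPower = numeric()))
)

## ---- show methods ----

setMethod("show", "FPMGeometry", function(object) {
  lab <- frameLabels(object)
  cat(sprintf(
    "FPMGeometry: %d LEDs, height %.4g mm, lambda %.4g nm, NA %.3g\n",
    nrow(object@ledPositions), object@arrayHeight, object@wavelength,
    object@objectiveNA))
  cat(sprintf("  labels: %d BF, %d DF, %d HYBRID (band +/- %.3g NA)\n",
              sum(lab == "BF"), sum(lab == "DF"), sum(lab == "HYBRID"),
              object@hybridBand))
  cat(sprintf("  illumination NA range: [%.3g, %.3g]\n",
              min(illuminationNA(object)), max(illuminationNA(object))))
})

setMethod("show", "ComplexObject", function(object) {
  d <- dim(object@amplitude)
  cat(sprintf(
    "ComplexObject: %d x %d px, pixel %.4g um, amplitude [%.3g, %.3g], phase [%.3g, %.3g] rad\n",
    d[1], d[2], object@pixelSize,
    min(object@amplitude), max(object@amplitude),
    min(object@phase), max(object@phase)))
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("ImageStack (role %s): %d frames of %d x %d px\n",
              object@role, d[3], d[1], d[2]))
  cat(sprintf("  labels: %d BF, %d DF, %d HYBRID\n",
              sum(object@labels == "BF"), sum(object@labels == "DF"),
              sum(object@labels == "HYBRID")))
})

setMethod("show", "SdAMaps", function(object) {
  cat(sprintf(
    "SdAMaps: %d x %d px, %.1f%% background (M), %.1f%% object (I_BF)\n",
    nrow(object@backgroundMask), ncol(object@backgroundMask),
    100 * mean(object@backgroundMask), 100 * mean(object@objectMap == 1)))
  if (length(object@sbr))
    cat(sprintf("  SBR over %d DF frames: median %.3g, %d frame(s) with SBR <= 1\n",
                length(object@sbr), stats::median(object@sbr),
                sum(object@sbr <= 1)))
})

setMethod("show", "ReconResult", function(object) {
  d <- dim(object@field)
  cat(sprintf("ReconResult: %d x %d px complex field, synthetic NA %.3g\n",
              d[1], d[2], object@syntheticNA))
  if (length(object@residuals))
    cat(sprintf("  residual: %.4g -> %.4g over %d iteration(s)\n",
                object@residuals[1], object@residuals[length(object@residuals)],
                length(object@residuals)))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport: SSIM %.4g, MSE %.4g, SNR %.4g dB, contrast %.4g\n",
              object@ssim, object@mse, object@snrDb, object@contrast))
})

## ---- simple accessors ----

#' @rdname fpmsda-generics
#' @export
setMethod("amplitude", "ComplexObject", function(object) object@amplitude)

#' @rdname fpmsda-generics
#' @export
setMethod("phase", "ComplexObject", function(object) object@phase)

#' @rdname fpmsda-generics
#' @export
setMethod("pixelSize", "ComplexObject", function(object) object@pixelSize)

#' @rdname fpmsda-generics
#' @export
setMethod("pixelSize", "ReconResult", function(object) object@pixelSize)

#' @rdname fpmsda-generics
#' @export
setMethod("objectMetadata", "ComplexObject", function(object) object@metadata)

#' @rdname fpmsda-generics
#' @export
setMethod("frames", "ImageStack", function(object) object@frames)

#' @rdname fpmsda-generics
#' @export
setMethod("nFrames", "ImageStack", function(object) dim(object@frames)[3L])

#' @rdname fpmsda-generics
#' @export
setMethod("stackRole", "ImageStack", function(object) object@role)

#' @rdname fpmsda-generics
#' @export
setMethod("ledIndex", "ImageStack", function(object) object@ledIndex)

#' @rdname fpmsda-generics
#' @export
setMethod("frameLabels", "ImageStack", function(object) object@labels)

#' @rdname fpmsda-generics
#' @export
setMethod("backgroundMask", "SdAMaps", function(object) object@backgroundMask)

#' @rdname fpmsda-generics
#' @export
setMethod("objectMap", "SdAMaps", function(object) object@objectMap)

#' @rdname fpmsda-generics
#' @export
setMethod("amplificationMap", "SdAMaps", function(object) object@amplificationMap)

#' @rdname fpmsda-generics
#' @export
setMethod("sbr", "SdAMaps", function(object) object@sbr)

#' @rdname fpmsda-generics
#' @export
setMethod("reconField", "ReconResult", function(object) object@field)

#' @rdname fpmsda-generics
#' @export
setMethod("syntheticNA", "ReconResult", function(object) object@syntheticNA)

#' @describeIn ReconResult per-iteration data residuals
#' @param object a ReconResult
#' @export
setMethod("residuals", "ReconResult", function(object) object@residuals)

#' Extract a single frame
#'
#' @param x an ImageStack
#' @param i frame position
#' @return numeric matrix
#' @export
setMethod("[[", "ImageStack", function(x, i) x@frames[, , i])
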