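## Stack and field I/O: multi-page 32-bit TIFF with a JSON sidecar
## carrying LED indices, labels, role and the intensity scale.
##
## The tiff package stores 32-bit pages as unsigned integers on [0, 1]
## with an asymmetric quantisation (write ~ trunc(x * (2^32 - 1)), read
## = k / 2^32) that drifts by one code per generation if used naively.
## Values are therefore quantised here onto the k / 2^32 grid (relative
## step 2^-31 at half scale, finer than float32) and written at
## mid-step, which the library maps back to exactly k; storage is then
## deterministic and write-read is the identity after the first
## quantisation.

.quantWrite <- function(pages, path, scale) {
  enc <- lapply(pages, function(p) (round(p / scale * 2^32) + 0.5) / (2^32 - 1))
  tiff::writeTIFF(enc, path, bits.per.sample = 32L, compression = "none")
}

.quantRead <- function(path, scale) {
  lapply(tiff::readTIFF(path, all = TRUE),
         function(p) round(p * 2^32) / 2^32 * scale)
}

## power-of-two scale keeping values within [0, 1/2] of the code range
.quantScale <- function(mx) {
  if (mx <= 0) 1 else 2^(floor(log2(mx)) + 2)
}

#' Write an image stack as multi-page 32-bit TIFF
#'
#' Frames are stored as 32-bit pages in LED order, quantised on a
#' power-of-two scale (recorded in the JSON sidecar `<path>.json`
#' together with LED indices, per-frame labels, LED positions and the
#' stack role) with a relative precision of 2^-31 — finer than 32-bit
#' float. Reading back reproduces the quantised values exactly, so any
#' write-read cycle after the first is bit-exact.
#'
#' @param stack an [ImageStack-class]
#' @param path output TIFF path (sidecar written to `<path>.json`)
#' @param geometry optional [FPMGeometry-class]; stores LED positions in
#'   the sidecar
#' @return `path`, invisibly
#' @export
writeStackTIFF <- function(stack, path, geometry = NULL) {
  fr <- frames(stack)
  scale <- .quantScale(max(fr))
  pages <- lapply(seq_len(nFrames(stack)), function(i) fr[, , i])
  .quantWrite(pages, path, scale)
  side <- list(role = stackRole(stack), scale = scale,
               ledIndex = ledIndex(stack), labels = frameLabels(stack))
  if (!is.null(geometry)) {
    side$ledPositions <- unname(ledPositions(geometry)[ledIndex(stack), ,
                                                       drop = FALSE])
    side$wavelength <- geometry@wavelength
    side$objectiveNA <- geometry@objectiveNA
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image stack written by [writeStackTIFF()]
#'
#' @param path TIFF path with `<path>.json` sidecar
#' @return an [ImageStack-class]
#' @export
readStackTIFF <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- .quantRead(path, side$scale)
  fr <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  new("ImageStack", frames = fr, ledIndex = as.integer(side$ledIndex),
      role = side$role, labels = as.character(side$labels))
}

#' Write a complex field as a two-page TIFF (amplitude, phase)
#'
#' Pages are 32-bit; the amplitude is quantised on a power-of-two scale
#' and the phase mapped from [-pi, pi] onto the same grid, both
#' recorded in the sidecar.
#'
#' @param field complex matrix or [ReconResult-class]
#' @param path output path
#' @param metadata extra fields merged into the JSON sidecar
#' @return `path`, invisibly
#' @export
writeFieldTIFF <- function(field, path, metadata = list()) {
  if (is(field, "ReconResult")) {
    metadata <- c(metadata, list(syntheticNA = syntheticNA(field),
                                 residuals = residuals(field),
                                 pixelSize = pixelSize(field)))
    field <- reconField(field)
  }
  amp <- Mod(field)
  ph <- Arg(field)
  scale <- .quantScale(max(amp))
  .quantWrite(list(amp, (ph + pi) * scale / (4 * pi)), path, scale)
  side <- c(list(scale = scale, pages = c("amplitude", "phase")), metadata)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a complex field written by [writeFieldTIFF()]
#'
#' @param path TIFF path with sidecar
#' @return complex matrix with attribute `metadata`
#' @export
readFieldTIFF <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- .quantRead(path, side$scale)
  amp <- pages[[1]]
  ph <- pages[[2]] * 4 * pi / side$scale - pi
  out <- amp * exp(1i * ph)
  attr(out, "metadata") <- side
  out
}

#' Load and validate an experiment configuration
#'
#' YAML (or JSON) configuration with sections `geometry` (ledGridN,
#' ledPitch, optional circleDiameter, arrayHeight, wavelength,
#' objectiveNA, optional hybridBand), `object` (kind = "bars" or
#' "texture", shape, pixelSize, optional barPeriods / seed /
#' barAmplitude), `noise` (offset, gaussianSigmas vector, poissonGain),
#' `correction` (methods subset of mean, mean3sigma, rollingball, sda;
#' s1Radius, s2Radius, optional rollingBallRadius) and `reconstruction`
#' (nIterations, lrShape, exposure). Missing or malformed keys raise a
#' schema error naming every offending key.
#'
#' @param path YAML/JSON file path, or a pre-built list
#' @return validated configuration list
#' @export
readExperimentConfig <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  bad <- character()
  need <- function(section, keys) {
    if (is.null(cfg[[section]])) {
      bad <<- c(bad, section)
      return()
    }
    miss <- keys[!keys %in% names(cfg[[section]])]
    if (length(miss)) bad <<- c(bad, paste0(section, ".", miss))
  }
  need("geometry", c("ledGridN", "ledPitch", "arrayHeight", "wavelength",
                     "objectiveNA"))
  need("object", c("kind", "shape", "pixelSize"))
  need("noise", c("offset", "gaussianSigmas", "poissonGain"))
  need("correction", c("methods", "s1Radius", "s2Radius"))
  need("reconstruction", c("nIterations", "lrShape", "exposure"))
  if (length(bad))
    stop("invalid experiment config; missing or invalid keys: ",
         paste(bad, collapse = ", "))
  okMethods <- c("mean", "mean3sigma", "rollingball", "sda")
  badM <- setdiff(cfg$correction$methods, okMethods)
  if (length(badM))
    stop("invalid experiment config; missing or invalid keys: ",
         paste0("correction.methods (", paste(badM, collapse = ", "), ")"))
  if (!cfg$object$kind %in% c("bars", "texture"))
    stop("invalid experiment config; missing or invalid keys: object.kind")
  cfg
}
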