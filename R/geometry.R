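#' Construct an LED-array geometry
#'
#' @param ledPositions numeric matrix (n x 2) of lateral LED offsets in
#'   mm, or a 2-column data.frame
#' @param arrayHeight LED plane to sample distance, mm (> 0)
#' @param wavelength illumination wavelength, nm (> 0)
#' @param objectiveNA objective numerical aperture in (0, 1)
#' @param hybridBand NA half-width of the hybrid BF/DF band (default
#'   0.02): LEDs with |NA_ill - objectiveNA| < hybridBand produce frames
#'   containing both BF and DF regions and are labelled HYBRID
#' @return an [FPMGeometry-class] object
#' @examples
#' g <- FPMGeometry(ledGrid(5, pitch = 4), arrayHeight = 50,
#'                  wavelength = 532, objectiveNA = 0.2)
#' table(frameLabels(g))
#' @export
FPMGeometry <- function(ledPositions, arrayHeight, wavelength, objectiveNA,
                        hybridBand = 0.02) {
  if (is.data.frame(ledPositions)) ledPositions <- as.matrix(ledPositions)
  if (!is.matrix(ledPositions) || ncol(ledPositions) != 2L)
    stop("ledPositions must be an n x 2 matrix of (x, y) offsets in mm")
  storage.mode(ledPositions) <- "double"
  if (!is.finite(arrayHeight) || arrayHeight <= 0)
    stop("invalid geometry: arrayHeight must be positive")
  if (!is.finite(wavelength) || wavelength <= 0)
    stop("invalid geometry: wavelength must be positive")
  new("FPMGeometry", ledPositions = ledPositions,
      arrayHeight = as.numeric(arrayHeight),
      wavelength = as.numeric(wavelength),
      objectiveNA = as.numeric(objectiveNA),
      hybridBand = as.numeric(hybridBand))
}

#' Regular LED grid positions
#'
#' An n x n square grid of LED positions centred on the optical axis
#' (odd n places an LED exactly on axis), optionally restricted to a
#' filled circle as in common FPM arrays.
#'
#' @param n LEDs per side
#' @param pitch LED spacing, mm
#' @param circleDiameter if finite, keep only LEDs within this diameter
#'   (mm) of the axis
#' @return matrix of (x, y) positions in mm
#' @export
ledGrid <- function(n, pitch, circleDiameter = Inf) {
  offs <- (seq_len(n) - (n + 1) / 2) * pitch
  pos <- as.matrix(expand.grid(x = offs, y = offs))
  keep <- sqrt(rowSums(pos^2)) <= circleDiameter / 2
  pos[keep, , drop = FALSE]
}

#' @rdname fpmsda-generics
#' @details `illuminationNA` returns sin(atan(r/h)) per LED, the
#'   numerical aperture of its plane-wave illumination.
#' @export
setMethod("illuminationNA", "FPMGeometry", function(object) {
  r <- sqrt(rowSums(object@ledPositions^2))
  sin(atan2(r, object@arrayHeight))
})

#' @rdname fpmsda-generics
#' @details `waveVectors` returns an n x 2 matrix of transverse spatial
#'   frequencies (kx, ky) in 1/um: the unit direction from LED to sample
#'   times NA_ill / lambda.
#' @export
setMethod("waveVectors", "FPMGeometry", function(object) {
  p <- object@ledPositions
  r <- sqrt(rowSums(p^2))
  na <- sin(atan2(r, object@arrayHeight))
  lambdaUm <- object@wavelength * 1e-3
  ## an LED at +x illuminates with a wavevector tilted towards -x; the
  ## passband centre displacement is opposite in sign, and only the sign
  ## convention (not any result) changes: keep k parallel to the LED offset
  k <- matrix(0, nrow(p), 2L, dimnames = list(NULL, c("kx", "ky")))
  nz <- r > 0
  k[nz, ] <- p[nz, , drop = FALSE] / r[nz] * (na[nz] / lambdaUm)
  k
})

#' @rdname fpmsda-generics
#' @details `frameLabels` on a geometry classifies every LED: BF iff
#'   NA_ill <= objectiveNA - hybridBand, DF iff NA_ill >= objectiveNA +
#'   hybridBand, HYBRID otherwise.
#' @export
setMethod("frameLabels", "FPMGeometry", function(object) {
  na <- illuminationNA(object)
  ifelse(na <= object@objectiveNA - object@hybridBand, "BF",
         ifelse(na >= object@objectiveNA + object@hybridBand, "DF", "HYBRID"))
})

#' @describeIn FPMGeometry number of LEDs
#' @param x an FPMGeometry
#' @export
setMethod("length", "FPMGeometry", function(x) nrow(x@ledPositions))

#' LED positions of a geometry
#' @param geometry an FPMGeometry
#' @return n x 2 matrix in mm
#' @export
ledPositions <- function(geometry) geometry@ledPositions

#' Objective numerical aperture of a geometry
#' @param geometry an FPMGeometry
#' @export
objectiveNA <- function(geometry) geometry@objectiveNA

#' Illumination wavelength in micrometres
#' @param geometry an FPMGeometry
#' @export
wavelengthUm <- function(geometry) geometry@wavelength * 1e-3
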