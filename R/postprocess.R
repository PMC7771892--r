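#' Locally masked median filter around object edges
#'
#' Optional cleanup of residual edge artefacts on a reconstructed
#' amplitude. The filter region R is confined to object rims: pixels
#' inside the (upsampled) object map I_BF but outside the
#' Otsu-binarized reconstructed object dilated by a disc of radius
#' `s3Radius` -- so genuine object edges are never blurred. Inside R
#' the amplitude is replaced by its local median; outside R it is
#' untouched.
#'
#' @param amplitude reconstructed amplitude matrix
#' @param IBF 0/1 object map (LR grid or reconstruction grid; upsampled
#'   by nearest neighbour if smaller)
#' @param s3Radius dilation radius in pixels (default 3)
#' @param window odd median window side (default 3)
#' @return filtered amplitude, same shape; attribute `region` holds R
#' @export
medianEdgeFilter <- function(amplitude, IBF, s3Radius = 3L, window = 3L) {
  stopifnot(window %% 2 == 1)
  n <- dim(amplitude)
  IBF <- upsampleNearest(IBF, n)
  objBin <- tryCatch(otsuObjectMask(amplitude) * 1,
                     error = function(e) amplitude * 0)
  R <- (IBF == 1) & (dilateDisc(objBin, s3Radius) == 0)
  out <- amplitude
  if (any(R)) {
    half <- (window - 1L) %/% 2L
    idx <- which(R, arr.ind = TRUE)
    for (q in seq_len(nrow(idx))) {
      i <- idx[q, 1]; j <- idx[q, 2]
      ri <- max(1L, i - half):min(n[1], i + half)
      ci <- max(1L, j - half):min(n[2], j + half)
      out[i, j] <- stats::median(amplitude[ri, ci])
    }
  }
  attr(out, "region") <- R
  out
}

## nearest-neighbour upsampling of a map to a target grid
upsampleNearest <- function(x, n) {
  x <- as.matrix(x)
  if (identical(dim(x), as.integer(n))) return(x)
  ri <- pmin(nrow(x), pmax(1L, round((seq_len(n[1]) - 0.5) * nrow(x) / n[1] + 0.5)))
  ci <- pmin(ncol(x), pmax(1L, round((seq_len(n[2]) - 0.5) * ncol(x) / n[2] + 0.5)))
  x[ri, ci, drop = FALSE]
}
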