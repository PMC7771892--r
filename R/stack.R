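#' Construct an image stack
#'
#' @param frames 3-D array (rows x cols x n) or list of equal-shape
#'   matrices of non-negative intensities
#' @param labels per-frame BF / DF / HYBRID labels
#' @param ledIndex per-frame LED index (default 1..n)
#' @param role pipeline role, default "S1" (raw)
#' @return an [ImageStack-class]
#' @export
ImageStack <- function(frames, labels, ledIndex = NULL, role = "S1") {
  if (is.list(frames)) {
    d <- dim(frames[[1]])
    if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1))))
      stop("all frames must share one shape")
    frames <- array(unlist(frames), c(d, length(frames)))
  }
  n <- dim(frames)[3L]
  if (is.null(ledIndex)) ledIndex <- seq_len(n)
  new("ImageStack", frames = frames, ledIndex = as.integer(ledIndex),
      role = role, labels = as.character(labels))
}

## internal: rebuild a stack with new frames and/or role
restack <- function(stack, frames, role) {
  new("ImageStack", frames = frames, ledIndex = ledIndex(stack),
      role = role, labels = frameLabels(stack))
}

#' Remove hybrid BF/DF frames from a stack
#'
#' Frames whose illumination NA falls within the hybrid band contain
#' both brightfield and darkfield regions and defeat any global
#' background estimate; they are excluded prior to correction and
#' reconstruction (with sufficient passband overlap this leaves no gap
#' in the recovered spectrum). Relative frame order is preserved and
#' the number of removed frames is reported.
#'
#' @param stack an [ImageStack-class] with per-frame labels
#' @return the filtered [ImageStack-class] with an attribute
#'   `removed` giving the number of excluded frames
#' @export
excludeHybridFrames <- function(stack) {
  keep <- frameLabels(stack) != "HYBRID"
  if (!any(frameLabels(stack)[keep] == "BF"))
    stop("unusable dataset: no brightfield frames remain after hybrid exclusion")
  out <- new("ImageStack", frames = frames(stack)[, , keep, drop = FALSE],
             ledIndex = ledIndex(stack)[keep], role = stackRole(stack),
             labels = frameLabels(stack)[keep])
  removed <- sum(!keep)
  if (removed > 0)
    message(sprintf("excluded %d hybrid frame(s)", removed))
  attr(out, "removed") <- removed
  out
}

#' On-axis brightfield frame of a stack
#'
#' The frame captured under the LED with the smallest illumination NA
#' (normal incidence for a centred array); must be a BF frame.
#'
#' @param stack an [ImageStack-class]
#' @param geometry the matching [FPMGeometry-class]
#' @return numeric matrix
#' @export
onAxisFrame <- function(stack, geometry) {
  na <- illuminationNA(geometry)[ledIndex(stack)]
  i <- which.min(na)
  if (frameLabels(stack)[i] != "BF")
    stop("the lowest-angle frame is not brightfield; check the geometry")
  frames(stack)[, , i]
}

## frame indices by label
bfIndices <- function(stack) which(frameLabels(stack) == "BF")
dfIndices <- function(stack) which(frameLabels(stack) == "DF")
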