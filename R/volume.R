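#' Scalar value at a grid vertex
#'
#' Returns the stored scalar at vertex \code{(i, j, k)}. Indices are 0-based,
#' consistent with the world mapping vertex \code{(i,j,k)} ->
#' \code{(i dx, j dy, k dz)}; valid ranges are \code{0 <= i < Ex} etc.
#'
#' @param volume a [ScalarVolume-class].
#' @param index integer(3) 0-based vertex index \code{(i, j, k)}.
#' @return The scalar at that vertex.
#' @examples
#' vol <- scalarVolume(array(7, c(4, 4, 4)))
#' vertexValue(vol, c(3, 0, 0))
#' @rdname vertexValue
#' @export
setMethod("vertexValue", signature("ScalarVolume", "numeric"),
          function(volume, index) {
  if (length(index) != 3L || any(index != round(index)))
    stop("index must be an integer triple (i, j, k)")
  ext <- dim(volume@values)
  axes <- c("x", "y", "z")
  bad <- which(index < 0 | index >= ext)
  if (length(bad))
    stop(sprintf("vertex index out of range on %s axis: %d not in [0, %d]",
                 axes[bad[1]], as.integer(index[bad[1]]), ext[bad[1]] - 1L))
  volume@values[index[1] + 1L, index[2] + 1L, index[3] + 1L]
})

#' Map gray values to optical properties
#'
#' Piecewise-linear interpolation of color and opacity between the transfer
#' function's control points, clamped to the first/last control point outside
#' the covered gray range. Vectorized over \code{gray}.
#'
#' @param tf a [TransferFunction-class].
#' @param gray numeric vector of gray values.
#' @return A list with \code{color} (matrix, one row per input gray, one
#'   column per channel) and \code{opacity} (numeric vector in [0, 1]).
#' @examples
#' tf <- transferFunction(c(0, 50, 100), c(0, 0.2, 1), c(0, 0.1, 1))
#' applyTransfer(tf, 75)  # color 0.6, opacity 0.55
#' @rdname applyTransfer
#' @export
setMethod("applyTransfer", signature("TransferFunction", "numeric"),
          function(tf, gray) {
  nch <- ncol(tf@color)
  color <- matrix(0, nrow = length(gray), ncol = nch)
  for (ch in seq_len(nch))
    color[, ch] <- stats::approx(tf@gray, tf@color[, ch], xout = gray,
                                 rule = 2)$y
  opacity <- stats::approx(tf@gray, tf@opacity, xout = gray, rule = 2)$y
  # clamp against fp drift so downstream opacity invariants hold exactly
  opacity <- pmin(pmax(opacity, 0), 1)
  list(color = color, opacity = opacity)
})

#' A simple CT-like grayscale transfer function
#'
#' Convenience default: fully transparent below `lo`, ramping linearly to
#' white and opacity `alphaMax` at `hi`. Gray units follow whatever scale the
#' volume uses (phantoms default to a 0--3000 CT-like range).
#'
#' @param lo gray value where the ramp starts (default 300).
#' @param hi gray value of full intensity (default 2000).
#' @param alphaMax opacity at `hi` (default 0.8).
#' @return A [TransferFunction-class].
#' @examples
#' tf <- rampTransferFunction()
#' @export
rampTransferFunction <- function(lo = 300, hi = 2000, alphaMax = 0.8) {
  transferFunction(gray = c(lo, hi), color = c(0, 1),
                   opacity = c(0, alphaMax))
}
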