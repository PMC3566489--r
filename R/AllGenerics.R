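#' @rdname vertexValue
#' @export
setGeneric("vertexValue", function(volume, index) standardGeneric("vertexValue"))

#' @rdname applyTransfer
#' @export
setGeneric("applyTransfer", function(tf, gray) standardGeneric("applyTransfer"))

#' @rdname clipToVolume
#' @export
setGeneric("clipToVolume", function(ray, volume) standardGeneric("clipToVolume"))

#' @rdname generatePhantom
#' @export
setGeneric("generatePhantom", function(spec) standardGeneric("generatePhantom"))

#' @rdname closedForm
#' @export
setGeneric("closedForm", function(spec, points) standardGeneric("closedForm"))

#' Accessors for ScalarVolume
#'
#' \code{volumeValues} returns the vertex array, \code{volumeSpacing} the
#' per-axis spacing in mm, \code{volumeExtents} the vertex counts
#' \code{(Ex, Ey, Ez)}, and \code{volumeBox} the upper corner of the world
#' bounding box \code{((Ex-1) dx, (Ey-1) dy, (Ez-1) dz)} (the lower corner is
#' the origin).
#'
#' @param volume a [ScalarVolume-class].
#' @return See description; numeric array or numeric(3).
#' @examples
#' vol <- scalarVolume(array(1, c(3, 3, 3)), spacing = c(1, 2, 3))
#' volumeBox(vol)  # c(2, 4, 6)
#' @name volume-accessors
NULL

#' @rdname volume-accessors
#' @export
volumeValues <- function(volume) volume@values

#' @rdname volume-accessors
#' @export
volumeSpacing <- function(volume) volume@spacing

#' @rdname volume-accessors
#' @export
volumeExtents <- function(volume) dim(volume@values)

#' @rdname volume-accessors
#' @export
volumeBox <- function(volume) (dim(volume@values) - 1L) * volume@spacing

#' Accessors for Ray
#'
#' @param ray a [Ray-class].
#' @return numeric(3) origin/direction, or numeric(1) step in mm.
#' @name ray-accessors
NULL

#' @rdname ray-accessors
#' @export
rayOrigin <- function(ray) ray@origin

#' @rdname ray-accessors
#' @export
rayDirection <- function(ray) ray@direction

#' @rdname ray-accessors
#' @export
rayStep <- function(ray) ray@step

#' Accessors for OpCount
#'
#' @param x an [OpCount-class].
#' @return integer count.
#' @name opcount-accessors
NULL

#' @rdname opcount-accessors
#' @export
additions <- function(x) x@additions

#' @rdname opcount-accessors
#' @export
multiplications <- function(x) x@multiplications

#' @describeIn OpCount-class sum of two tallies
#' @param e1,e2 operands
#' @export
setMethod("+", signature("OpCount", "OpCount"), function(e1, e2) {
  opCount(e1@additions + e2@additions,
          e1@multiplications + e2@multiplications)
})

#' @describeIn OpCount-class scale a tally by a nonnegative integer
#' @export
setMethod("*", signature("OpCount", "numeric"), function(e1, e2) {
  stopifnot(length(e2) == 1L, e2 >= 0, e2 == round(e2))
  opCount(e1@additions * e2, e1@multiplications * e2)
})

#' @describeIn OpCount-class scale a tally by a nonnegative integer
#' @export
setMethod("*", signature("numeric", "OpCount"), function(e1, e2) e2 * e1)

setMethod("show", "ScalarVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("ScalarVolume: %d x %d x %d vertexes, spacing %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  value range [%.4g, %.4g]\n",
              min(object@values), max(object@values)))
})

setMethod("show", "TransferFunction", function(object) {
  cat(sprintf("TransferFunction: %d control points, gray [%g, %g], %d color channel(s)\n",
              length(object@gray), object@gray[1],
              object@gray[length(object@gray)], ncol(object@color)))
})

setMethod("show", "Ray", function(object) {
  cat(sprintf("Ray: O = (%g, %g, %g), zeta = (%.4f, %.4f, %.4f), step %g mm\n",
              object@origin[1], object@origin[2], object@origin[3],
              object@direction[1], object@direction[2], object@direction[3],
              object@step))
})

setMethod("show", "OpCount", function(object) {
  cat(sprintf("OpCount: %d additions, %d multiplications\n",
              object@additions, object@multiplications))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec '%s': %d x %d x %d vertexes, spacing %g x %g x %g mm, seed %d\n",
              object@kind, object@extents[1], object@extents[2],
              object@extents[3], object@spacing[1], object@spacing[2],
              object@spacing[3], object@seed))
})
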