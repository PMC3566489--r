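#' @import methods
NULL

#' Scalar volume on a regular grid
#'
#' A 3D scalar field sampled on a regular grid of vertexes. Vertex
#' \code{(i, j, k)} (0-based, as in all geometry in this package) sits at world
#' position \code{(i * dx, j * dy, k * dz)} in millimetres, with the world
#' origin at vertex \code{(0, 0, 0)}. The cells between neighbouring vertexes
#' are voxels; a grid with \code{Ex x Ey x Ez} vertexes has
#' \code{(Ex-1) x (Ey-1) x (Ez-1)} voxels and occupies the axis-aligned box
#' \code{[0, (Ex-1) dx] x [0, (Ey-1) dy] x [0, (Ez-1) dz]}.
#'
#' @slot values 3D numeric array of vertex scalars, indexed (in R, 1-based)
#'   along x, y, z.
#' @slot spacing numeric(3), per-axis vertex spacing in mm, all > 0.
#'
#' @seealso [scalarVolume()], [volumeValues()], [volumeSpacing()],
#'   [volumeExtents()], [volumeBox()], [vertexValue()]
#' @export
setClass("ScalarVolume",
  slots = c(values = "array", spacing = "numeric"))

setValidity("ScalarVolume", function(object) {
  msgs <- character()
  d <- dim(object@values)
  if (length(d) != 3L)
    msgs <- c(msgs, "values must be a 3D array")
  else if (any(d < 2L))
    msgs <- c(msgs, "each axis needs at least 2 vertexes (one voxel)")
  if (length(object@spacing) != 3L)
    msgs <- c(msgs, "spacing must have length 3")
  else if (!all(is.finite(object@spacing)) || any(object@spacing <= 0))
    msgs <- c(msgs, "spacing must be finite and strictly positive")
  if (!is.numeric(object@values))
    msgs <- c(msgs, "values must be numeric")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ScalarVolume
#'
#' @param values 3D numeric array of vertex scalars (x, y, z order; at least
#'   2 vertexes per axis).
#' @param spacing numeric(3), vertex spacing in mm per axis (default 1 mm).
#' @return A [ScalarVolume-class] object.
#' @examples
#' vol <- scalarVolume(array(0, c(4, 4, 4)), spacing = c(0.5, 0.5, 1))
#' volumeExtents(vol)
#' @export
scalarVolume <- function(values, spacing = c(1, 1, 1)) {
  new("ScalarVolume", values = values, spacing = as.numeric(spacing))
}

#' Piecewise-linear transfer function
#'
#' Maps a scalar gray value to optical properties (color and opacity) by
#' linear interpolation between control points, clamped to the first/last
#' control point outside the covered gray range. Color may be a single
#' luminance channel or three RGB channels; samplers and the compositor are
#' channel-agnostic.
#'
#' @slot gray numeric, strictly increasing control-point gray values (>= 2).
#' @slot color numeric matrix, one row per control point, 1 or 3 columns,
#'   entries in [0, 1].
#' @slot opacity numeric, per-control-point opacity in [0, 1].
#'
#' @seealso [transferFunction()], [applyTransfer()]
#' @export
setClass("TransferFunction",
  slots = c(gray = "numeric", color = "matrix", opacity = "numeric"))

setValidity("TransferFunction", function(object) {
  msgs <- character()
  n <- length(object@gray)
  if (n < 2L)
    msgs <- c(msgs, "at least 2 control points are required")
  if (n >= 2L && any(diff(object@gray) <= 0))
    msgs <- c(msgs, "control-point gray values must be strictly increasing")
  if (nrow(object@color) != n)
    msgs <- c(msgs, "color must have one row per control point")
  if (!ncol(object@color) %in% c(1L, 3L))
    msgs <- c(msgs, "color must have 1 (luminance) or 3 (RGB) columns")
  if (any(object@color < 0 | object@color > 1))
    msgs <- c(msgs, "color components must lie in [0, 1]")
  if (length(object@opacity) != n)
    msgs <- c(msgs, "opacity must have one value per control point")
  if (any(object@opacity < 0 | object@opacity > 1))
    msgs <- c(msgs, "opacity must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Construct a TransferFunction
#'
#' @param gray numeric, strictly increasing control-point gray values.
#' @param color numeric vector (luminance) or matrix with 1 or 3 columns,
#'   values in [0, 1].
#' @param opacity numeric in [0, 1], one value per control point.
#' @return A [TransferFunction-class] object.
#' @examples
#' tf <- transferFunction(gray = c(0, 100), color = c(0, 1), opacity = c(0, 1))
#' applyTransfer(tf, 50)
#' @export
transferFunction <- function(gray, color, opacity) {
  if (is.null(dim(color))) color <- matrix(as.numeric(color), ncol = 1L)
  new("TransferFunction", gray = as.numeric(gray), color = color,
      opacity = as.numeric(opacity))
}

#' View ray
#'
#' A ray with world-space origin (mm), unit direction vector
#' \eqn{\zeta = (r, m, n)}, and a regular sampling distance \eqn{\delta} (mm)
#' between consecutive sample points. Directions are normalized at
#' construction so ray distances t are metric (mm).
#'
#' @slot origin numeric(3), world origin in mm.
#' @slot direction numeric(3), unit direction (norm 1 within 1e-9).
#' @slot step numeric(1), sampling distance in mm, > 0.
#'
#' @seealso [ray()], [clipToVolume()], [samplePositions()]
#' @export
setClass("Ray",
  slots = c(origin = "numeric", direction = "numeric", step = "numeric"))

setValidity("Ray", function(object) {
  msgs <- character()
  if (length(object@origin) != 3L || !all(is.finite(object@origin)))
    msgs <- c(msgs, "origin must be a finite numeric(3)")
  if (length(object@direction) != 3L || !all(is.finite(object@direction)))
    msgs <- c(msgs, "direction must be a finite numeric(3)")
  else if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-9)
    msgs <- c(msgs, "direction must be unit length (within 1e-9)")
  if (length(object@step) != 1L || !is.finite(object@step) ||
      object@step <= 0)
    msgs <- c(msgs, "step must be a single positive number")
  if (length(msgs)) msgs else TRUE
})

#' Construct a Ray
#'
#' The direction is normalized here; a zero direction is an error.
#'
#' @param origin numeric(3), world origin in mm.
#' @param direction numeric(3), any nonzero direction; normalized internally.
#' @param step sampling distance in mm (default 0.3).
#' @return A [Ray-class] object.
#' @examples
#' r <- ray(c(0.5, -1, 0.5), c(0, 1, 0))
#' @export
ray <- function(origin, direction, step = 0.3) {
  direction <- as.numeric(direction)
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm == 0)
    stop("ray direction must be a nonzero vector")
  new("Ray", origin = as.numeric(origin), direction = direction / nrm,
      step = as.numeric(step))
}

#' Arithmetic-operation tally
#'
#' Counts of additions and multiplications executed by a sampling pathway,
#' under the convention: subtraction counts as an addition, division as a
#' multiplication, and floor/comparison/assignment are free. Counts are
#' structure-determined: they do not depend on input values.
#'
#' @slot additions nonnegative integer count.
#' @slot multiplications nonnegative integer count.
#'
#' @seealso [opCount()], [countTrilinearPoint()], [countSegmentPoints()]
#' @export
setClass("OpCount",
  slots = c(additions = "integer", multiplications = "integer"))

setValidity("OpCount", function(object) {
  if (length(object@additions) != 1L || length(object@multiplications) != 1L)
    return("additions and multiplications must be single integers")
  if (object@additions < 0L || object@multiplications < 0L)
    return("counts must be nonnegative")
  TRUE
})

#' Construct an OpCount
#'
#' @param additions nonnegative integer.
#' @param multiplications nonnegative integer.
#' @return An [OpCount-class] object.
#' @examples
#' opCount(17, 16) + opCount(4, 2)
#' @export
opCount <- function(additions = 0L, multiplications = 0L) {
  new("OpCount", additions = as.integer(additions),
      multiplications = as.integer(multiplications))
}

#' Specification of a synthetic phantom volume
#'
#' Describes a test volume with a known closed form, so samplers and the
#' renderer can be validated without clinical data. Analytic kinds
#' (\code{constant}, \code{affine}, \code{trilinear}, \code{sphere},
#' \code{shell}, \code{gaussian_blob}) have an exact closed form evaluable at
#' arbitrary points; \code{head_like} is a deterministic CT-like composite
#' (ellipsoidal bone shell around smooth soft tissue) controlled by the seed.
#'
#' @slot kind character, one of constant, affine, trilinear, sphere, shell,
#'   gaussian_blob, head_like.
#' @slot extents integer(3), vertex counts per axis (each >= 2).
#' @slot spacing numeric(3), vertex spacing in mm.
#' @slot params named list of kind-specific parameters.
#' @slot seed integer, seed for any randomized component.
#'
#' @seealso [phantomSpec()], [generatePhantom()], [closedForm()]
#' @export
setClass("PhantomSpec",
  slots = c(kind = "character", extents = "integer", spacing = "numeric",
            params = "list", seed = "integer"))

.phantomKinds <- c("constant", "affine", "trilinear", "sphere", "shell",
                   "gaussian_blob", "head_like")

setValidity("PhantomSpec", function(object) {
  msgs <- character()
  if (length(object@kind) != 1L || !object@kind %in% .phantomKinds)
    msgs <- c(msgs, paste0("kind must be one of: ",
                           paste(.phantomKinds, collapse = ", ")))
  if (length(object@extents) != 3L || any(object@extents < 2L))
    msgs <- c(msgs, "extents must be integer(3), each >= 2")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msgs <- c(msgs, "spacing must be numeric(3), strictly positive")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PhantomSpec
#'
#' Default extents and spacing give a reduced-scale CT-like grid
#' (64 x 64 x 37 vertexes at 0.486 x 0.486 x 0.700 mm) with anisotropic
#' z-spacing, so spacing-dependent behavior is exercised by default.
#'
#' @param kind phantom kind (see [PhantomSpec-class]).
#' @param extents integer(3) vertex counts.
#' @param spacing numeric(3) spacing in mm.
#' @param params named list of kind parameters:
#'   \describe{
#'     \item{constant}{\code{value} (default 1000).}
#'     \item{affine}{\code{intercept}, \code{coef} (length 3) for
#'       \eqn{a + bx + cy + dz}.}
#'     \item{trilinear}{\code{coef}, length 8, for
#'       \eqn{a + bx + cy + dz + exy + fyz + gxz + hxyz}.}
#'     \item{sphere}{\code{center}, \code{radius}, \code{inside},
#'       \code{outside}.}
#'     \item{shell}{\code{center}, \code{rInner}, \code{rOuter},
#'       \code{value}, \code{interior}, \code{outside}.}
#'     \item{gaussian_blob}{\code{center}, \code{sigma} (scalar or length 3),
#'       \code{amplitude}.}
#'     \item{head_like}{\code{center}, \code{semiaxes}, \code{shellFrac},
#'       \code{bone}, \code{tissue}, \code{nBumps}.}
#'   }
#' @param seed integer seed for randomized components (head_like bumps).
#' @return A [PhantomSpec-class] object.
#' @examples
#' spec <- phantomSpec("affine", extents = c(8, 8, 8), spacing = c(1, 1, 1),
#'                     params = list(intercept = 1, coef = c(2, 3, 5)))
#' vol <- generatePhantom(spec)
#' vertexValue(vol, c(1, 1, 1))  # 1 + 2 + 3 + 5
#' @export
phantomSpec <- function(kind,
                        extents = c(64L, 64L, 37L),
                        spacing = c(0.486, 0.486, 0.700),
                        params = list(),
                        seed = 1L) {
  new("PhantomSpec", kind = kind, extents = as.integer(extents),
      spacing = as.numeric(spacing), params = params, seed = as.integer(seed))
}
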