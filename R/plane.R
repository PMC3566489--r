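#' Choose the plane-cluster axis for a ray direction
#'
#' Returns the axis with the largest absolute direction component, which is
#' guaranteed nonzero so every cluster plane is crossed transversally and the
#' bracketing of sample points is densest. Ties break deterministically
#' x -> y -> z. When a direction component is zero, the cluster along another
#' axis must be used; this rule handles that automatically.
#'
#' @param direction numeric(3), nonzero ray direction.
#' @return One of \code{"x"}, \code{"y"}, \code{"z"}.
#' @examples
#' chooseAxis(c(0, 1, 0))        # "y"
#' chooseAxis(c(1, 1, 0) / sqrt(2))  # "x" (tie-break)
#' @export
chooseAxis <- function(direction) {
  direction <- as.numeric(direction)
  if (length(direction) != 3L || all(direction == 0) ||
      !all(is.finite(direction)))
    stop("direction must be a finite nonzero numeric(3)")
  c("x", "y", "z")[which.max(abs(direction))]
}

.axisIndex <- function(axis) {
  i <- match(axis, c("x", "y", "z"))
  if (is.na(i)) stop("axis must be one of 'x', 'y', 'z'")
  i
}

#' Ray intersections with a grid-plane cluster
#'
#' The equidistant parallel planes perpendicular to \code{axis} sit at
#' \code{j * spacing[axis]} for plane indices \code{j = 0 .. extent-1}. For a
#' ray \code{O + t zeta} with nonzero direction component \code{m} along the
#' axis, the intersection with plane j is at ray distance
#' \code{t_j = (j * spacing - O[axis]) / m}; the other two coordinates follow
#' from the ray equation. Only intersections within the clipped ray segment
#' and inside the box cross-section are kept, sorted by increasing t (so
#' entry/exit roles follow ray order even when \code{m < 0} makes t decrease
#' with j).
#'
#' @param ray a [Ray-class].
#' @param volume a [ScalarVolume-class].
#' @param axis cluster axis, \code{"x"}, \code{"y"} or \code{"z"}.
#' @return A data.frame with one row per intersection, sorted by \code{t}:
#'   \code{plane} (plane index j), \code{t} (ray distance, mm), \code{Vx},
#'   \code{Vy}, \code{Vz} (world coordinates; the cluster-axis coordinate is
#'   exactly \code{j * spacing}), and \code{v1}, \code{v2} (0-based owning
#'   voxel indices along the two transverse axes, in x<y<z order, floored
#'   with the upper-boundary clamp). Zero rows when the ray misses the box or
#'   crosses no plane inside it.
#' @examples
#' vol <- scalarVolume(array(0, c(2, 2, 2)))
#' planeIntersections(ray(c(0.5, -1, 0.5), c(0, 1, 0)), vol, "y")
#' @export
planeIntersections <- function(ray, volume, axis) {
  a <- .axisIndex(axis)
  m <- ray@direction[a]
  if (m == 0)
    stop("ray direction has zero component along the cluster axis; ",
         "use chooseAxis() to pick a valid axis")
  empty <- data.frame(plane = integer(), t = numeric(), Vx = numeric(),
                      Vy = numeric(), Vz = numeric(), v1 = integer(),
                      v2 = integer())
  seg <- clipToVolume(ray, volume)
  if (is.null(seg)) return(empty)
  ext <- dim(volume@values)
  sp <- volume@spacing
  hi <- volumeBox(volume)
  tol <- 1e-9 * max(1, max(hi))
  j <- 0:(ext[a] - 1L)
  t <- (j * sp[a] - ray@origin[a]) / m
  keep <- t >= seg[1] - tol & t <= seg[2] + tol
  j <- j[keep]; t <- t[keep]
  if (!length(j)) return(empty)
  P <- cbind(ray@origin[1] + t * ray@direction[1],
             ray@origin[2] + t * ray@direction[2],
             ray@origin[3] + t * ray@direction[3])
  P[, a] <- j * sp[a]  # on-plane coordinate is exact by construction
  tr <- setdiff(1:3, a)
  inside <- P[, tr[1]] >= -tol & P[, tr[1]] <= hi[tr[1]] + tol &
            P[, tr[2]] >= -tol & P[, tr[2]] <= hi[tr[2]] + tol
  j <- j[inside]; t <- t[inside]; P <- P[inside, , drop = FALSE]
  if (!length(j)) return(empty)
  P[, tr[1]] <- pmin(pmax(P[, tr[1]], 0), hi[tr[1]])
  P[, tr[2]] <- pmin(pmax(P[, tr[2]], 0), hi[tr[2]])
  v1 <- pmin(floor(P[, tr[1]] / sp[tr[1]]), ext[tr[1]] - 2L)
  v2 <- pmin(floor(P[, tr[2]] / sp[tr[2]]), ext[tr[2]] - 2L)
  ord <- order(t)
  data.frame(plane = as.integer(j[ord]), t = t[ord],
             Vx = P[ord, 1], Vy = P[ord, 2], Vz = P[ord, 3],
             v1 = as.integer(v1[ord]), v2 = as.integer(v2[ord]))
}

#' Three-vertex face interpolation at plane intersections
#'
#' Interpolates the scalar at an on-plane point from three vertexes of its
#' owning voxel face: the base vertex I0 and its two in-plane neighbours
#' (+first transverse axis, +second transverse axis), as
#' \code{I0 + (I1 - I0) f1 + (I3 - I0) f2} with \code{f1, f2} the fractional
#' in-plane coordinates. This is deliberately a planar (affine) formula, not
#' bilinear: the face's fourth (diagonal) corner is unused, so fields with an
#' in-plane cross term are approximated (exactly reproduced are fields affine
#' on the face).
#'
#' @param volume a [ScalarVolume-class].
#' @param intersections data.frame from [planeIntersections()] (any subset of
#'   rows).
#' @param axis the cluster axis the intersections were computed for.
#' @return numeric vector, one interpolated scalar per intersection row.
#' @examples
#' vol <- scalarVolume(array(seq_len(8), c(2, 2, 2)))
#' ix <- planeIntersections(ray(c(0.5, -1, 0.5), c(0, 1, 0)), vol, "y")
#' faceInterpolate(vol, ix, "y")
#' @export
faceInterpolate <- function(volume, intersections, axis) {
  a <- .axisIndex(axis)
  if (!nrow(intersections)) return(numeric())
  ext <- dim(volume@values)
  sp <- volume@spacing
  tr <- setdiff(1:3, a)
  Vcols <- c("Vx", "Vy", "Vz")
  f1 <- intersections[[Vcols[tr[1]]]] / sp[tr[1]] - intersections$v1
  f2 <- intersections[[Vcols[tr[2]]]] / sp[tr[2]] - intersections$v2
  idx0 <- matrix(0L, nrow(intersections), 3L)
  idx0[, a] <- intersections$plane
  idx0[, tr[1]] <- intersections$v1
  idx0[, tr[2]] <- intersections$v2
  lin <- function(idx) volume@values[1L + idx[, 1] +
                                     ext[1] * (idx[, 2] + ext[2] * idx[, 3])]
  I0 <- lin(idx0)
  idx1 <- idx0; idx1[, tr[1]] <- idx1[, tr[1]] + 1L
  idx3 <- idx0; idx3[, tr[2]] <- idx3[, tr[2]] + 1L
  I1 <- lin(idx1)
  I3 <- lin(idx3)
  I0 + (I1 - I0) * f1 + (I3 - I0) * f2
}

#' Definite-proportion interpolation along a ray segment
#'
#' Linear interpolation of a property between the bracketing entry/exit
#' intersections E and Q at ray distances \code{tE < tQ}:
#' \code{I(t) = IE + ((t - tE) / (tQ - tE)) (IQ - IE)}. Endpoints reproduce
#' \code{IE} and \code{IQ} exactly. Vectorized over \code{t}.
#'
#' @param t numeric, ray distances in \code{[tE, tQ]} (mm).
#' @param tE,tQ ray distances of the entry and exit intersections, mm,
#'   \code{tQ > tE}.
#' @param IE,IQ interpolated properties at E and Q.
#' @return numeric, one value per \code{t}.
#' @examples
#' segmentSample(1.5, tE = 1, tQ = 2, IE = 10, IQ = 20)  # 15
#' @export
segmentSample <- function(t, tE, tQ, IE, IQ) {
  if (tQ == tE) stop("degenerate segment: tQ equals tE")
  if (any(t < tE - 1e-12 | t > tQ + 1e-12))
    stop("sample position outside the segment [tE, tQ]")
  IE + ((t - tE) / (tQ - tE)) * (IQ - IE)
}

#' Plane-cluster sampling of a ray
#'
#' The fast sampling pathway: compute all ray/plane intersections once per
#' ray, interpolate the scalar at each intersection from three face vertexes
#' ([faceInterpolate()]), then obtain each requested sample position from its
#' bracketing intersection pair by definite-proportion division
#' ([segmentSample()]). Positions before the first or after the last
#' intersection -- the sliver between box entry/exit and the nearest plane --
#' extrapolate linearly from the nearest bracketing pair, which is continuous
#' and exact on affine fields. If the clipped segment crosses no cluster
#' plane at all (a corner-grazing ray), all samples are \code{NA}.
#'
#' @param volume a [ScalarVolume-class].
#' @param ray a [Ray-class].
#' @param positions numeric, sorted ascending ray distances within the
#'   clipped segment (mm), e.g. from [samplePositions()].
#' @param axis \code{"auto"} (dominant-component choice via [chooseAxis()])
#'   or an explicit \code{"x"}, \code{"y"}, \code{"z"} override.
#' @return numeric vector of sampled scalars, one per position.
#' @examples
#' vol <- scalarVolume(array(seq_len(27), c(3, 3, 3)))
#' r <- ray(c(1.2, -1, 0.7), c(0, 1, 0))
#' planeSampleRay(vol, r, samplePositions(clipToVolume(r, vol), r))
#' @export
planeSampleRay <- function(volume, ray, positions, axis = "auto") {
  if (identical(axis, "auto")) axis <- chooseAxis(ray@direction)
  inter <- planeIntersections(ray, volume, axis)
  .planeSamplePositions(positions, inter$t,
                        faceInterpolate(volume, inter, axis))
}

# Bracket each position among intersection distances tInter (sorted) and
# apply the definite-proportion formula. Positions outside [t_first, t_last]
# (the sliver between box entry/exit and the nearest plane) extrapolate
# linearly from the nearest bracketing pair -- continuous, and exact on
# affine fields, which clamping to the endpoint value would not be. NA when
# the ray crosses no plane.
.planeSamplePositions <- function(positions, tInter, Ivals) {
  n <- length(tInter)
  if (n == 0L) return(rep(NA_real_, length(positions)))
  if (n == 1L) return(rep(Ivals, length(positions)))
  i <- pmin(pmax(findInterval(positions, tInter), 1L), n - 1L)
  w <- (positions - tInter[i]) / (tInter[i + 1L] - tInter[i])
  Ivals[i] + w * (Ivals[i + 1L] - Ivals[i])
}
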