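#' Locate the voxel containing a world point
#'
#' Floor division of world coordinates by the spacing gives the 0-based voxel
#' index \code{i = floor(x / dx)} etc.; the local coordinates
#' \code{xn = (x - i dx) / dx} etc. lie in [0, 1]. Points exactly on the upper
#' box boundary of an axis clamp to the last voxel with local coordinate 1
#' (the plain floor rule would index a voxel that does not exist there).
#' Vectorized over rows of a point matrix.
#'
#' @param volume a [ScalarVolume-class].
#' @param points numeric(3) or an n x 3 matrix of world points (mm), all
#'   inside the box (inclusive boundaries, with 1e-9-relative slack for fp).
#' @return A list with \code{index} (n x 3 integer matrix of 0-based voxel
#'   indices, \code{0 <= i <= Ex-2} etc.) and \code{local} (n x 3 matrix of
#'   local coordinates in [0, 1]).
#' @examples
#' vol <- scalarVolume(array(0, c(8, 8, 8)), spacing = c(0.5, 0.5, 0.5))
#' locateVoxel(vol, c(1.25, 2.5, 3.5))
#' @export
locateVoxel <- function(volume, points) {
  points <- .asPointMatrix(points)
  sp <- volume@spacing
  hi <- volumeBox(volume)
  tol <- 1e-9 * max(1, max(hi))
  out <- points < -tol | sweep(points, 2, hi + tol, `>`)
  if (any(out)) {
    bad <- which(rowSums(out) > 0)[1]
    stop(sprintf("point (%g, %g, %g) lies outside the volume box",
                 points[bad, 1], points[bad, 2], points[bad, 3]))
  }
  # nudge boundary-straddling fp noise back into the box before flooring
  points <- pmin(pmax(points, 0), matrix(hi, nrow(points), 3, byrow = TRUE))
  scaled <- sweep(points, 2, sp, `/`)
  idx <- floor(scaled)
  idx <- pmin(idx, matrix(dim(volume@values) - 2L, nrow(points), 3,
                          byrow = TRUE))  # upper-boundary clamp
  local <- scaled - idx
  storage.mode(idx) <- "integer"
  list(index = idx, local = local)
}

#' Trilinear interpolation at world points
#'
#' The traditional sampling baseline: locate each point's voxel, then chain
#' three nested linear interpolations over the eight corner values
#' \code{I0..I7} -- along z (\code{F1 = I0 + zn (I3 - I0)},
#' \code{F2 = I1 + zn (I2 - I1)}, \code{F3 = I5 + zn (I6 - I5)},
#' \code{F4 = I4 + zn (I7 - I4)}), then x (\code{F5 = F1 + xn (F2 - F1)},
#' \code{F6 = F4 + xn (F3 - F4)}), then y (\code{F = F5 + yn (F6 - F5)}).
#' The corner layout is \code{I0=(i,j,k)}, \code{I1=(i+1,j,k)},
#' \code{I2=(i+1,j,k+1)}, \code{I3=(i,j,k+1)}, \code{I4=(i,j+1,k)},
#' \code{I5=(i+1,j+1,k)}, \code{I6=(i+1,j+1,k+1)}, \code{I7=(i,j+1,k+1)} --
#' the unique assignment consistent with that chain. Exact on trilinear
#' fields; reproduces vertex values exactly; continuous across voxel faces.
#'
#' @inheritParams locateVoxel
#' @return numeric vector of interpolated scalars, one per point.
#' @examples
#' vol <- scalarVolume(array(5, c(4, 4, 4)))
#' trilinearSample(vol, c(1.5, 0.25, 2.75))  # 5
#' @export
trilinearSample <- function(volume, points) {
  points <- .asPointMatrix(points)
  loc <- locateVoxel(volume, points)
  .trilinearFromLocation(volume, loc)
}

# Eq-chain evaluation given a locateVoxel() result; vectorized gather.
.trilinearFromLocation <- function(volume, loc) {
  ext <- dim(volume@values)
  vals <- volume@values
  i <- loc$index[, 1]; j <- loc$index[, 2]; k <- loc$index[, 3]
  xn <- loc$local[, 1]; yn <- loc$local[, 2]; zn <- loc$local[, 3]
  lin <- function(ii, jj, kk) vals[1L + ii + ext[1] * (jj + ext[2] * kk)]
  I0 <- lin(i,      j,      k)
  I1 <- lin(i + 1L, j,      k)
  I2 <- lin(i + 1L, j,      k + 1L)
  I3 <- lin(i,      j,      k + 1L)
  I4 <- lin(i,      j + 1L, k)
  I5 <- lin(i + 1L, j + 1L, k)
  I6 <- lin(i + 1L, j + 1L, k + 1L)
  I7 <- lin(i,      j + 1L, k + 1L)
  F1 <- I0 + zn * (I3 - I0)
  F2 <- I1 + zn * (I2 - I1)
  F3 <- I5 + zn * (I6 - I5)
  F4 <- I4 + zn * (I7 - I4)
  F5 <- F1 + xn * (F2 - F1)
  F6 <- F4 + xn * (F3 - F4)
  F5 + yn * (F6 - F5)
}

.asPointMatrix <- function(points) {
  if (is.null(dim(points))) {
    stopifnot(length(points) == 3L)
    points <- matrix(points, ncol = 3L)
  }
  stopifnot(ncol(points) == 3L)
  points
}
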