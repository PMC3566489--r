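#' Arithmetic-operation counting
#'
#' The cost comparison between the two sampling pathways is made with an
#' instrumented counter: the sampling formulas are re-executed scalar by
#' scalar with every addition-class operation (addition, subtraction) and
#' every multiplication-class operation (multiplication, division) routed
#' through a tallying cell. Floor, comparison and assignment are free. Counts
#' are structure-determined -- identical for any input values -- which the
#' test suite asserts.
#'
#' @name op-counting
NULL

# Tallying cell: a tiny mutable environment threaded through the
# instrumented formula evaluations.
newTally <- function() {
  e <- new.env(parent = emptyenv())
  e$add <- 0L
  e$mul <- 0L
  e
}
tAdd <- function(ctr, x, y) { ctr$add <- ctr$add + 1L; x + y }
tSub <- function(ctr, x, y) { ctr$add <- ctr$add + 1L; x - y }
tMul <- function(ctr, x, y) { ctr$mul <- ctr$mul + 1L; x * y }
tDiv <- function(ctr, x, y) { ctr$mul <- ctr$mul + 1L; x / y }
tallyCount <- function(ctr) opCount(ctr$add, ctr$mul)

# Instrumented voxel location: per axis one floor division, one
# vertex-position multiply, one subtraction and one division -> (1, 3).
.locateCounted <- function(volume, point, ctr) {
  sp <- volume@spacing
  idx <- integer(3)
  local <- numeric(3)
  for (ax in 1:3) {
    i <- floor(tDiv(ctr, point[ax], sp[ax]))
    xi <- tMul(ctr, i, sp[ax])
    local[ax] <- tDiv(ctr, tSub(ctr, point[ax], xi), sp[ax])
    idx[ax] <- i
  }
  list(index = idx, local = local)
}

# Instrumented interpolation chain: 7 lerps of 2 additions + 1
# multiplication each.
.lerpCounted <- function(ctr, a, b, w)
  tAdd(ctr, a, tMul(ctr, w, tSub(ctr, b, a)))

.trilinearCounted <- function(volume, point, ctr) {
  loc <- .locateCounted(volume, point, ctr)
  i <- loc$index[1]; j <- loc$index[2]; k <- loc$index[3]
  xn <- loc$local[1]; yn <- loc$local[2]; zn <- loc$local[3]
  v <- function(ii, jj, kk) volume@values[ii + 1L, jj + 1L, kk + 1L]
  I0 <- v(i,      j,      k)
  I1 <- v(i + 1L, j,      k)
  I2 <- v(i + 1L, j,      k + 1L)
  I3 <- v(i,      j,      k + 1L)
  I4 <- v(i,      j + 1L, k)
  I5 <- v(i + 1L, j + 1L, k)
  I6 <- v(i + 1L, j + 1L, k + 1L)
  I7 <- v(i,      j + 1L, k + 1L)
  F1 <- .lerpCounted(ctr, I0, I3, zn)
  F2 <- .lerpCounted(ctr, I1, I2, zn)
  F3 <- .lerpCounted(ctr, I5, I6, zn)
  F4 <- .lerpCounted(ctr, I4, I7, zn)
  F5 <- .lerpCounted(ctr, F1, F2, xn)
  F6 <- .lerpCounted(ctr, F4, F3, xn)
  .lerpCounted(ctr, F5, F6, yn)
}

#' Operation count of one traditional trilinear sample
#'
#' Runs the instrumented trilinear pathway (voxel location plus the
#' three-axis interpolation chain) on one strictly interior point and returns
#' the tally: 17 additions and 16 multiplications per point, of which the
#' voxel-location step contributes 3 additions and 9 multiplications (see
#' [countVoxelLocation()]). The interpolated value agrees with
#' [trilinearSample()] (asserted in the test suite).
#'
#' @param volume a [ScalarVolume-class].
#' @param point numeric(3), a world point strictly inside the box.
#' @return An [OpCount-class].
#' @examples
#' vol <- scalarVolume(array(rnorm(64), c(4, 4, 4)))
#' countTrilinearPoint(vol, c(1.3, 1.7, 2.1))  # 17 additions, 16 mults
#' @export
countTrilinearPoint <- function(volume, point) {
  .checkInterior(volume, point)
  ctr <- newTally()
  .trilinearCounted(volume, point, ctr)
  tallyCount(ctr)
}

#' Operation count of the voxel-location sub-step
#'
#' The instrumented tally of converting one world point to its voxel index
#' and local coordinates: 3 additions and 9 multiplications (per axis, one
#' floor division, one vertex-position multiplication, one subtraction and
#' one normalizing division).
#'
#' @inheritParams countTrilinearPoint
#' @return An [OpCount-class].
#' @export
countVoxelLocation <- function(volume, point) {
  .checkInterior(volume, point)
  ctr <- newTally()
  .locateCounted(volume, point, ctr)
  tallyCount(ctr)
}

#' Operation count of a traditionally sampled ray
#'
#' Each of the n sample points is located and interpolated independently,
#' with no reuse between points, so the cost is n times the per-point tally:
#' n x (17 additions, 16 multiplications). Six points spread over two voxels
#' cost 102 additions and 96 multiplications.
#'
#' @param nPoints nonnegative integer number of sample points.
#' @return An [OpCount-class].
#' @examples
#' countTrilinearRay(6)  # 102 additions, 96 multiplications
#' @export
countTrilinearRay <- function(nPoints) {
  if (length(nPoints) != 1L || nPoints < 0 || nPoints != round(nPoints))
    stop("nPoints must be a single nonnegative integer")
  opCount(17L, 16L) * nPoints
}

# Instrumented definite-proportion evaluation (one sample position).
.segmentCounted <- function(t, tE, tQ, IE, IQ, ctr) {
  tAdd(ctr, IE,
       tMul(ctr,
            tDiv(ctr, tSub(ctr, t, tE), tSub(ctr, tQ, tE)),
            tSub(ctr, IQ, IE)))
}

#' Operation count of definite-proportion segment sampling
#'
#' Each evaluation of the segment formula
#' \code{IE + ((t - tE)/(tQ - tE)) (IQ - IE)} costs 4 additions (three
#' subtractions and the final addition) and 2 multiplications (the division
#' and the product), each sample position independent: n x (4, 2). Six
#' positions cost 24 additions and 12 multiplications.
#'
#' @param nPoints nonnegative integer number of sample positions.
#' @return An [OpCount-class].
#' @examples
#' countSegmentPoints(6)  # 24 additions, 12 multiplications
#' @export
countSegmentPoints <- function(nPoints) {
  if (length(nPoints) != 1L || nPoints < 0 || nPoints != round(nPoints))
    stop("nPoints must be a single nonnegative integer")
  opCount(4L, 2L) * nPoints
}

#' Instrumented tally of segment sampling at given positions
#'
#' Runs the instrumented definite-proportion formula at each position between
#' a precomputed entry/exit pair and returns the total tally (which equals
#' [countSegmentPoints()] of the number of positions; the values equal
#' [segmentSample()]).
#'
#' @param t numeric, sample positions within \code{[tE, tQ]}.
#' @inheritParams segmentSample
#' @return An [OpCount-class].
#' @examples
#' countSegmentSample(seq(1.1, 1.9, length.out = 6), 1, 2, 10, 20)
#' @export
countSegmentSample <- function(t, tE, tQ, IE, IQ) {
  ctr <- newTally()
  for (ti in t) .segmentCounted(ti, tE, tQ, IE, IQ, ctr)
  tallyCount(ctr)
}

#' Instrumented trilinear values alongside their tally
#'
#' Shadow implementation used by the tests: evaluates the trilinear chain
#' point by point through the tallying cell and returns both the values and
#' the total count, so structural counts and instrumented counts can be
#' compared on the same run.
#'
#' @param volume a [ScalarVolume-class].
#' @param points n x 3 matrix (or numeric(3)) of strictly interior points.
#' @return list with \code{values} (numeric(n)) and \code{count}
#'   ([OpCount-class]).
#' @export
trilinearSampleCounted <- function(volume, points) {
  points <- .asPointMatrix(points)
  ctr <- newTally()
  vals <- numeric(nrow(points))
  for (r in seq_len(nrow(points))) {
    .checkInterior(volume, points[r, ])
    vals[r] <- .trilinearCounted(volume, points[r, ], ctr)
  }
  list(values = vals, count = tallyCount(ctr))
}

#' Operation count of sampling one plane intersection point
#'
#' Tally for deriving one intersection point and its face-interpolated
#' property under this package's convention: the plane-distance formula
#' costs 1 addition and 2 multiplications, the two ray-equation coordinates
#' 2 additions and 2 multiplications, the owning-voxel floor divisions 2
#' multiplications, and the three-vertex face interpolation 6 additions and
#' 2 multiplications (reusing the floor-division quotients for the in-plane
#' fractions). Total 9 additions and 8 multiplications per intersection
#' point. This per-point tally is reported for comparison tables; no
#' published pair of totals for two intersection points is asserted against
#' it, because reuse conventions differ between accountings.
#'
#' @return An [OpCount-class]: 9 additions, 8 multiplications.
#' @examples
#' countIntersectionPoint()
#' @export
countIntersectionPoint <- function() {
  # t_j = (j*dy - yo)/m            -> 1 add, 2 mul
  # Vi = xo + r t ; Vk = zo + n t  -> 2 add, 2 mul
  # i = [Vi/dx] ; k = [Vk/dz]      -> 2 mul (floor free)
  # IE = I0 + (I1-I0)(Vi/dx - i) + (I3-I0)(Vk/dz - k)
  #   quotients reused            -> 6 add, 2 mul
  opCount(1L + 2L + 6L, 2L + 2L + 2L + 2L)
}

#' Cost-comparison table for the two sampling pathways
#'
#' For a scenario of \code{nPoints} sample positions bracketed by one
#' entry/exit intersection pair, tabulates the arithmetic cost of the
#' traditional pathway (every point located and trilinearly interpolated
#' independently) against the plane-cluster pathway (two intersection points
#' plus definite-proportion division per sample position).
#'
#' @param nPoints number of sample positions (default 6).
#' @return A data.frame with columns \code{pathway}, \code{component},
#'   \code{additions}, \code{multiplications}.
#' @examples
#' opCountTable(6)
#' @export
opCountTable <- function(nPoints = 6L) {
  tri <- countTrilinearRay(nPoints)
  ixn <- countIntersectionPoint() * 2
  seg <- countSegmentPoints(nPoints)
  tot <- ixn + seg
  data.frame(
    pathway = c("traditional", "plane", "plane", "plane"),
    component = c(sprintf("%d trilinear points", nPoints),
                  "2 intersection points (E, Q)",
                  sprintf("%d segment points", nPoints),
                  "total"),
    additions = c(additions(tri), additions(ixn), additions(seg),
                  additions(tot)),
    multiplications = c(multiplications(tri), multiplications(ixn),
                        multiplications(seg), multiplications(tot)))
}

.checkInterior <- function(volume, point) {
  hi <- volumeBox(volume)
  if (any(point <= 0) || any(point >= hi))
    stop("point must be strictly inside the volume box")
  invisible(TRUE)
}
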