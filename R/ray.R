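#' Clip a ray against the volume bounding box
#'
#' Slab-method intersection of the ray with the world box
#' \code{[0, (Ex-1) dx] x [0, (Ey-1) dy] x [0, (Ez-1) dz]}. The entry distance
#' is clamped to >= 0 (the traversal starts at the ray origin at the
#' earliest). A miss is a value, not an error.
#'
#' @param ray a [Ray-class].
#' @param volume a [ScalarVolume-class].
#' @return numeric(2) \code{c(tEnter, tExit)} in mm with
#'   \code{tEnter <= tExit}, or \code{NULL} when the ray misses the box.
#' @examples
#' vol <- scalarVolume(array(0, c(2, 2, 2)))
#' clipToVolume(ray(c(0.5, -1, 0.5), c(0, 1, 0)), vol)  # c(1, 2)
#' @rdname clipToVolume
#' @export
setMethod("clipToVolume", signature("Ray", "ScalarVolume"),
          function(ray, volume) {
  lo <- c(0, 0, 0)
  hi <- volumeBox(volume)
  o <- ray@origin
  d <- ray@direction
  tmin <- 0
  tmax <- Inf
  for (ax in 1:3) {
    if (d[ax] == 0) {
      if (o[ax] < lo[ax] || o[ax] > hi[ax]) return(NULL)
    } else {
      t1 <- (lo[ax] - o[ax]) / d[ax]
      t2 <- (hi[ax] - o[ax]) / d[ax]
      if (t1 > t2) { tmp <- t1; t1 <- t2; t2 <- tmp }
      tmin <- max(tmin, t1)
      tmax <- min(tmax, t2)
      if (tmin > tmax) return(NULL)
    }
  }
  c(tmin, tmax)
})

#' Regular sample positions along a clipped ray
#'
#' The arithmetic progression \code{tEnter, tEnter + step, ...} up to and
#' including the largest value \code{<= tExit}; increasing t, so the
#' viewer-near sample comes first. A boundary tie (a sample landing exactly on
#' \code{tExit}, up to fp slack) resolves to inside.
#'
#' @param segment numeric(2) \code{c(tEnter, tExit)} from [clipToVolume()].
#' @param ray a [Ray-class]; its \code{step} is the sampling distance in mm.
#' @return numeric vector of ray distances (mm), length >= 1.
#' @examples
#' samplePositions(c(1, 2), ray(c(0, 0, 0), c(1, 0, 0), step = 0.3))
#' # 1.0 1.3 1.6 1.9
#' @export
samplePositions <- function(segment, ray) {
  stopifnot(length(segment) == 2L, segment[1] <= segment[2])
  span <- segment[2] - segment[1]
  n <- floor(span / ray@step + 1e-9)
  segment[1] + ray@step * (0:n)
}

#' Orthographic ray bundle for an output image
#'
#' One ray per output pixel, all sharing the normalized view direction
#' (orthographic projection). Origins lie on a regular grid on a plane outside
#' the volume box, centered on the volume center. The in-plane frame is
#' deterministic: with \code{a = +z} (or \code{a = +x} when
#' \code{|zeta . z| > 0.9}), \code{u = normalize(zeta x a)} and
#' \code{v = u x zeta}.
#'
#' @param volume a [ScalarVolume-class].
#' @param viewDir numeric(3), nonzero view direction (normalized internally).
#' @param width,height image size in pixels (>= 1).
#' @param pixelPitch in-plane distance between adjacent ray origins, mm.
#' @param step sampling distance along each ray, mm (default 0.3).
#' @return A list of [Ray-class] objects in row-major image order (row 1
#'   first), with attributes \code{width}, \code{height}, \code{u}, \code{v}.
#' @examples
#' vol <- scalarVolume(array(0, c(8, 8, 8)))
#' rays <- orthographicRays(vol, c(0, 1, 0), 2, 2, pixelPitch = 1)
#' length(rays)  # 4
#' @export
orthographicRays <- function(volume, viewDir, width, height, pixelPitch,
                             step = 0.3) {
  viewDir <- as.numeric(viewDir)
  nrm <- sqrt(sum(viewDir^2))
  if (!is.finite(nrm) || nrm == 0) stop("view direction must be nonzero")
  zeta <- viewDir / nrm
  stopifnot(width >= 1, height >= 1, pixelPitch > 0)
  a <- if (abs(zeta[3]) > 0.9) c(1, 0, 0) else c(0, 0, 1)
  u <- .cross3(zeta, a)
  u <- u / sqrt(sum(u^2))
  v <- .cross3(u, zeta)
  center <- volumeBox(volume) / 2
  standoff <- sqrt(sum(volumeBox(volume)^2)) / 2 + 1
  base <- center - zeta * standoff
  du <- (seq_len(width) - (width + 1) / 2) * pixelPitch
  dv <- (seq_len(height) - (height + 1) / 2) * pixelPitch
  rays <- vector("list", width * height)
  idx <- 1L
  for (py in seq_len(height)) {
    for (px in seq_len(width)) {
      rays[[idx]] <- ray(base + u * du[px] + v * dv[py], zeta, step = step)
      idx <- idx + 1L
    }
  }
  attr(rays, "width") <- as.integer(width)
  attr(rays, "height") <- as.integer(height)
  attr(rays, "u") <- u
  attr(rays, "v") <- v
  rays
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
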