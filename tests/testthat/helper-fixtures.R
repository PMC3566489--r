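# Fixtures shared across test files: small phantoms with known closed forms
# and the independent oracles the samplers are checked against.

affineSpec <- function(extents = c(8, 8, 8), spacing = c(1, 1, 1),
                       intercept = 1, coef = c(2, 3, 5)) {
  phantomSpec("affine", extents = extents, spacing = spacing,
              params = list(intercept = intercept, coef = coef))
}

trilinearSpec <- function(coef = c(1, 2, 3, 5, 7, 11, 13, 17),
                          extents = c(6, 6, 6), spacing = c(1, 1, 1)) {
  phantomSpec("trilinear", extents = extents, spacing = spacing,
              params = list(coef = coef))
}

constantVolume <- function(value = 7, extents = c(4, 4, 4),
                           spacing = c(1, 1, 1)) {
  scalarVolume(array(value, extents), spacing = spacing)
}

# Independent 8-weight trilinear oracle: sum over corners of I_v * w_v.
trilinearOracle <- function(volume, point) {
  sp <- volumeSpacing(volume)
  ext <- volumeExtents(volume)
  i <- pmin(floor(point / sp), ext - 2)
  f <- point / sp - i
  val <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[1] else 1 - f[1]) *
         (if (dy) f[2] else 1 - f[2]) *
         (if (dz) f[3] else 1 - f[3])
    val <- val + w * vertexValue(volume, i + c(dx, dy, dz))
  }
  val
}

# On-face bilinear oracle (uses all four face corners); kept to document
# where the three-vertex face formula deliberately differs.
bilinearFaceOracle <- function(volume, inter, axis) {
  a <- match(axis, c("x", "y", "z"))
  tr <- setdiff(1:3, a)
  sp <- volumeSpacing(volume)
  V <- c(inter$Vx, inter$Vy, inter$Vz)
  f1 <- V[tr[1]] / sp[tr[1]] - inter$v1
  f2 <- V[tr[2]] / sp[tr[2]] - inter$v2
  base <- integer(3)
  base[a] <- inter$plane
  base[tr[1]] <- inter$v1
  base[tr[2]] <- inter$v2
  d1 <- c(0L, 0L, 0L); d1[tr[1]] <- 1L
  d2 <- c(0L, 0L, 0L); d2[tr[2]] <- 1L
  vertexValue(volume, base) * (1 - f1) * (1 - f2) +
    vertexValue(volume, base + d1) * f1 * (1 - f2) +
    vertexValue(volume, base + d2) * (1 - f1) * f2 +
    vertexValue(volume, base + d1 + d2) * f1 * f2
}

# Dense-march clipping oracle: walk the ray at a fine step and report the
# first/last positions inside the box.
clipOracle <- function(r, volume, fine = rayStep(r) / 100) {
  hi <- volumeBox(volume)
  tmax <- sum(abs(rayOrigin(r))) + sum(hi) + 10
  ts <- seq(0, tmax, by = fine)
  P <- cbind(rayOrigin(r)[1] + ts * rayDirection(r)[1],
             rayOrigin(r)[2] + ts * rayDirection(r)[2],
             rayOrigin(r)[3] + ts * rayDirection(r)[3])
  inside <- P[, 1] >= 0 & P[, 1] <= hi[1] &
            P[, 2] >= 0 & P[, 2] <= hi[2] &
            P[, 3] >= 0 & P[, 3] <= hi[3]
  if (!any(inside)) return(NULL)
  c(ts[which(inside)[1]], ts[rev(which(inside))[1]])
}

rayPoints <- function(r, ts) {
  cbind(rayOrigin(r)[1] + ts * rayDirection(r)[1],
        rayOrigin(r)[2] + ts * rayDirection(r)[2],
        rayOrigin(r)[3] + ts * rayDirection(r)[3])
}

randomInteriorPoints <- function(volume, n, margin = 1e-3) {
  hi <- volumeBox(volume)
  cbind(runif(n, margin, hi[1] - margin),
        runif(n, margin, hi[2] - margin),
        runif(n, margin, hi[3] - margin))
}
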