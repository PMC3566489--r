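test_that("cluster axis choice takes the dominant component with x>y>z tie-break", {
  expect_equal(chooseAxis(c(0, 1, 0)), "y")
  expect_equal(chooseAxis(c(0.9, 0.1, 0.1)), "x")
  expect_equal(chooseAxis(c(1, 1, 0) / sqrt(2)), "x")
  expect_equal(chooseAxis(c(0, 1, 1)), "y")
  expect_equal(chooseAxis(c(0, 0, -2)), "z")
  expect_error(chooseAxis(c(0, 0, 0)), "nonzero")
})

test_that("plane intersections match the hand-worked axial case", {
  vol <- scalarVolume(array(0, c(2, 2, 2)))
  ix <- planeIntersections(ray(c(0.5, -1, 0.5), c(0, 1, 0)), vol, "y")
  expect_equal(ix$t, c(1, 2))
  expect_equal(ix$plane, c(0L, 1L))
  expect_equal(ix$Vx, c(0.5, 0.5))
  expect_equal(ix$Vy, c(0, 1))
  expect_equal(ix$Vz, c(0.5, 0.5))

  # grazing the box edge: intersections on the boundary with voxel (0, ., 0)
  graze <- planeIntersections(ray(c(0, -1, 0), c(0, 1, 0)), vol, "y")
  expect_equal(nrow(graze), 2L)
  expect_equal(graze$Vx, c(0, 0))
  expect_equal(graze$v1, c(0L, 0L))
  expect_equal(graze$v2, c(0L, 0L))

  miss <- planeIntersections(ray(c(5, -1, 0.5), c(0, 1, 0)), vol, "y")
  expect_equal(nrow(miss), 0L)

  expect_error(planeIntersections(ray(c(0.5, -1, 0.5), c(0, 1, 0)), vol, "x"),
               "chooseAxis")
})

test_that("intersections satisfy the plane and ray equations simultaneously", {
  set.seed(17)
  vol <- scalarVolume(array(0, c(7, 6, 5)), spacing = c(0.486, 0.486, 0.7))
  for (i in 1:25) {
    o <- runif(3, -3, 6)
    d <- rnorm(3)
    r <- ray(o, d, step = 0.3)
    ax <- chooseAxis(rayDirection(r))
    a <- match(ax, c("x", "y", "z"))
    ix <- planeIntersections(r, vol, ax)
    if (!nrow(ix)) next
    V <- cbind(ix$Vx, ix$Vy, ix$Vz)
    # plane residual: on-axis coordinate sits on plane j
    expect_lt(max(abs(V[, a] - ix$plane * volumeSpacing(vol)[a])), 1e-9)
    # ray residual: V = O + t * zeta on every coordinate
    P <- rayPoints(r, ix$t)
    expect_lt(max(abs(V - P)), 1e-9)
    expect_true(!is.unsorted(ix$t))
  }
})

test_that("negative direction components keep intersections in ray order", {
  vol <- scalarVolume(array(0, c(4, 4, 4)))
  r <- ray(c(1.5, 4, 1.5), c(0.1, -1, 0.05))
  ix <- planeIntersections(r, vol, "y")
  expect_true(!is.unsorted(ix$t))
  expect_equal(ix$plane, c(3L, 2L, 1L, 0L))  # planes crossed high to low
})

test_that("face interpolation is the literal three-vertex formula", {
  # face values I0=0, I1=4 (+x), I3=8 (+z); fractions (0.5, 0.25) -> 4.0
  vals <- array(0, c(2, 2, 2))
  vals[1, 1, 1] <- 0; vals[2, 1, 1] <- 4; vals[1, 1, 2] <- 8
  vol <- scalarVolume(vals)
  ix <- data.frame(plane = 0L, t = 1, Vx = 0.5, Vy = 0, Vz = 0.25,
                   v1 = 0L, v2 = 0L)
  expect_equal(faceInterpolate(vol, ix, "y"), 0 + 4 * 0.5 + 8 * 0.25)

  # identity at a vertex
  ix0 <- data.frame(plane = 0L, t = 1, Vx = 0, Vy = 0, Vz = 0,
                    v1 = 0L, v2 = 0L)
  expect_equal(faceInterpolate(vol, ix0, "y"), 0)

  # the diagonal corner is deliberately unused: a bilinear oracle disagrees
  diagv <- array(0, c(2, 2, 2))
  diagv[2, 1, 2] <- 1  # the face's fourth corner
  vd <- scalarVolume(diagv)
  ixc <- data.frame(plane = 0L, t = 1, Vx = 0.5, Vy = 0, Vz = 0.5,
                    v1 = 0L, v2 = 0L)
  expect_equal(faceInterpolate(vd, ixc, "y"), 0)
  expect_equal(bilinearFaceOracle(vd, ixc, "y"), 0.25)
})

test_that("face interpolation deviates from bilinear by a quarter of the cross term", {
  # in-plane cross term x*z with coefficient h: at a face center the
  # three-vertex formula drops exactly h/4 relative to the field
  h <- 2
  spec <- trilinearSpec(coef = c(0, 0, 0, 0, 0, 0, h, 0), extents = c(3, 3, 3))
  vol <- generatePhantom(spec)
  ixc <- data.frame(plane = 1L, t = 1, Vx = 0.5, Vy = 1, Vz = 0.5,
                    v1 = 0L, v2 = 0L)
  planar <- faceInterpolate(vol, ixc, "y")
  exact <- closedForm(spec, c(0.5, 1, 0.5))
  expect_equal(exact - planar, h / 4)
  expect_equal(bilinearFaceOracle(vol, ixc, "y"), exact)
})

test_that("segment sampling interpolates between entry and exit", {
  expect_equal(segmentSample(1, 1, 2, 10, 20), 10)
  expect_equal(segmentSample(2, 1, 2, 10, 20), 20)
  expect_equal(segmentSample(1.5, 1, 2, 10, 20), 15)
  expect_error(segmentSample(0.5, 1, 2, 10, 20), "outside")
  expect_error(segmentSample(1, 1, 1, 10, 20), "degenerate")
})

test_that("plane sampling of a ray is exact on affine fields", {
  spec <- affineSpec(extents = c(8, 8, 8))
  vol <- generatePhantom(spec)
  set.seed(23)
  for (i in 1:10) {
    r <- ray(runif(3, -2, 2), rnorm(3), step = 0.4)
    seg <- clipToVolume(r, vol)
    if (is.null(seg)) next
    ax <- chooseAxis(rayDirection(r))
    if (nrow(planeIntersections(r, vol, ax)) < 2) next  # unbracketable graze
    ts <- samplePositions(seg, r)
    got <- planeSampleRay(vol, r, ts)
    expect_equal(got, closedForm(spec, rayPoints(r, ts)), tolerance = 1e-9)
    # and agrees with the trilinear baseline (both exact there)
    expect_equal(got, trilinearSample(vol, rayPoints(r, ts)),
                 tolerance = 1e-9)
  }
})

test_that("plane sampling reproduces constants and honors intersection incidence", {
  vol <- constantVolume(42, extents = c(5, 5, 5))
  r <- ray(c(1.3, -1, 2.1), c(0.2, 1, 0.1), step = 0.3)
  ts <- samplePositions(clipToVolume(r, vol), r)
  expect_equal(planeSampleRay(vol, r, ts), rep(42, length(ts)))

  # a position exactly on an intersection returns that face value
  spec <- affineSpec()
  aff <- generatePhantom(spec)
  r2 <- ray(c(0.5, -1, 0.5), c(0, 1, 0))
  ix <- planeIntersections(r2, aff, "y")
  face <- faceInterpolate(aff, ix, "y")
  got <- planeSampleRay(aff, r2, ix$t[2])
  expect_equal(got, face[2])
})

test_that("bracketed plane samples lie within their segment's face values", {
  set.seed(31)
  vol <- scalarVolume(array(runif(6^3, 0, 100), c(6, 6, 6)))
  r <- ray(c(2.1, -1, 3.2), c(0.15, 1, -0.2), step = 0.23)
  ts <- samplePositions(clipToVolume(r, vol), r)
  ix <- planeIntersections(r, vol, "y")
  face <- faceInterpolate(vol, ix, "y")
  got <- planeSampleRay(vol, r, ts)
  inside <- ts >= ix$t[1] & ts <= ix$t[nrow(ix)]
  for (s in which(inside)) {
    k <- findInterval(ts[s], ix$t)
    k <- min(max(k, 1), nrow(ix) - 1)
    expect_gte(got[s], min(face[k], face[k + 1]) - 1e-12)
    expect_lte(got[s], max(face[k], face[k + 1]) + 1e-12)
  }
})
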