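test_that("phantom vertexes satisfy their closed forms exactly", {
  con <- generatePhantom(phantomSpec("constant", extents = c(4, 4, 4),
                                     spacing = c(1, 1, 1),
                                     params = list(value = 100)))
  expect_true(all(volumeValues(con) == 100))

  spec <- affineSpec()
  aff <- generatePhantom(spec)
  expect_equal(vertexValue(aff, c(1, 1, 1)), 11)
  g <- as.matrix(expand.grid(0:7, 0:7, 0:7))
  stored <- volumeValues(aff)[g + 1]
  expect_equal(stored, closedForm(spec, g), tolerance = 1e-12)

  # anisotropic spacing enters the closed form through world coordinates
  spec2 <- affineSpec(spacing = c(0.5, 1, 2))
  aff2 <- generatePhantom(spec2)
  expect_equal(vertexValue(aff2, c(1, 1, 1)),
               closedForm(spec2, c(0.5, 1, 2)))
})

test_that("sphere and shell phantoms separate inside from outside", {
  spec <- phantomSpec("sphere", extents = c(9, 9, 9), spacing = c(1, 1, 1),
                      params = list(center = c(4, 4, 4), radius = 2,
                                    inside = 100, outside = 0))
  vol <- generatePhantom(spec)
  expect_equal(vertexValue(vol, c(4, 4, 4)), 100)
  expect_equal(vertexValue(vol, c(4, 4, 7)), 0)   # distance 3 > R
  expect_equal(vertexValue(vol, c(4, 4, 6)), 100) # distance 2 = R inclusive
  expect_equal(closedForm(spec, c(4, 4, 6.001)), 0)

  sh <- phantomSpec("shell", extents = c(9, 9, 9), spacing = c(1, 1, 1),
                    params = list(center = c(4, 4, 4), rInner = 2, rOuter = 3,
                                  value = 2000, interior = 50, outside = 0))
  expect_equal(closedForm(sh, c(4, 4, 4)), 50)
  expect_equal(closedForm(sh, c(4, 4, 6.5)), 2000)
  expect_equal(closedForm(sh, c(4, 4, 7.5)), 0)
})

test_that("closed forms evaluate off-grid and reject non-analytic kinds", {
  spec <- affineSpec()
  expect_equal(closedForm(spec, c(0.5, 0.25, 0.75)), 6.5)
  tri <- trilinearSpec(coef = c(0, 0, 0, 0, 0, 0, 0, 2))
  expect_equal(closedForm(tri, c(1, 1, 1)), 2)
  head <- phantomSpec("head_like", extents = c(8, 8, 8))
  expect_error(closedForm(head, c(1, 1, 1)), "no closed form")
})

test_that("trilinear sampling of phantoms matches the closed form at random points", {
  set.seed(41)
  spec <- affineSpec(extents = c(6, 7, 8), spacing = c(0.486, 0.486, 0.7))
  vol <- generatePhantom(spec)
  pts <- randomInteriorPoints(vol, 100)
  expect_equal(trilinearSample(vol, pts), closedForm(spec, pts),
               tolerance = 1e-9)
})

test_that("head_like phantoms are bit-identical for identical specs and seeded", {
  a <- generatePhantom(phantomSpec("head_like", extents = c(12, 12, 9),
                                   seed = 7L))
  b <- generatePhantom(phantomSpec("head_like", extents = c(12, 12, 9),
                                   seed = 7L))
  c <- generatePhantom(phantomSpec("head_like", extents = c(12, 12, 9),
                                   seed = 8L))
  expect_identical(volumeValues(a), volumeValues(b))
  expect_false(identical(volumeValues(a), volumeValues(c)))
  # bone shell bright, exterior empty
  expect_equal(vertexValue(a, c(0, 0, 0)), 0)
  expect_gte(max(volumeValues(a)), 2000)
})

test_that("phantom generation does not disturb the global RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generatePhantom(phantomSpec("head_like", extents = c(6, 6, 6))))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("unknown phantom kinds are rejected at construction", {
  expect_error(phantomSpec("cube"), "kind must be one of")
})
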