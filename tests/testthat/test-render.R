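test_that("a constant opaque volume renders a uniform image", {
  vol <- constantVolume(1000, extents = c(8, 8, 8))
  tf <- transferFunction(c(0, 1000), c(0, 0.8), c(0, 1))
  out <- renderVolume(vol, tf, renderConfig(viewDir = c(0, 1, 0),
                                            width = 6, height = 6,
                                            pixelPitch = 0.9, step = 0.5))
  # every ray hits the box head-on; the first fully opaque sample wins
  expect_true(all(abs(out$image - 0.8) < 1e-12))
  expect_equal(out$log$raysHit, 36L)
})

test_that("a fully transparent volume renders to zero", {
  vol <- constantVolume(0, extents = c(6, 6, 6))
  tf <- transferFunction(c(0, 1000), c(0, 1), c(0, 1))
  out <- renderVolume(vol, tf, renderConfig(width = 4, height = 4, step = 1))
  expect_true(all(out$image == 0))
})

test_that("both samplers render affine phantoms pixelwise identically", {
  vol <- generatePhantom(affineSpec(extents = c(12, 12, 12),
                                    intercept = 100, coef = c(20, 30, 50)))
  tf <- transferFunction(c(0, 2000), c(0, 1), c(0, 0.5))
  cfg <- renderConfig(viewDir = c(0.2, 1, 0.4), width = 12, height = 12,
                      step = 0.5)
  cmp <- compareSamplers(vol, tf, cfg)
  expect_lt(max(abs(cmp$traditional$image - cmp$plane$image)), 1e-6)
})

test_that("the two samplers are close on a smooth blob", {
  vol <- generatePhantom(phantomSpec("gaussian_blob", extents = c(24, 24, 17),
                                     spacing = c(0.486, 0.486, 0.7)))
  tf <- rampTransferFunction(lo = 200, hi = 1800, alphaMax = 0.6)
  cfg <- renderConfig(viewDir = c(0.3, 1, 0.2), width = 24, height = 24,
                      step = 0.3 * 0.486)
  cmp <- compareSamplers(vol, tf, cfg)
  expect_lt(cmp$nrmse, 0.02)
  expect_gt(diff(range(cmp$traditional$image)), 0)  # non-degenerate scene
})

test_that("rendering is deterministic for a fixed configuration", {
  vol <- generatePhantom(phantomSpec("head_like", extents = c(12, 12, 9)))
  tf <- rampTransferFunction()
  cfg <- renderConfig(viewDir = c(0.1, 1, 0.3), width = 8, height = 8,
                      step = 0.5, sampler = "plane")
  a <- renderVolume(vol, tf, cfg)
  b <- renderVolume(vol, tf, cfg)
  expect_identical(a$image, b$image)
  # and written images are byte-identical
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "a.png"); p2 <- file.path(dir, "b.png")
  writeImage(a$image, p1, maxValue = 1)
  writeImage(b$image, p2, maxValue = 1)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("pre- and post-classification agree on linear transfer segments", {
  vol <- generatePhantom(affineSpec(extents = c(10, 10, 10),
                                    intercept = 200, coef = c(30, 40, 20)))
  tf <- transferFunction(c(0, 2000), c(0, 1), c(0, 0.4))
  base <- renderConfig(viewDir = c(0.1, 1, 0.2), width = 8, height = 8,
                       step = 0.6, classify = "pre")
  post <- base; post$classify <- "post"
  a <- renderVolume(vol, tf, base)
  b <- renderVolume(vol, tf, post)
  expect_equal(a$image, b$image, tolerance = 1e-9)
})

test_that("the run log records the configuration and axis actually used", {
  vol <- generatePhantom(phantomSpec("sphere", extents = c(8, 8, 8),
                                     spacing = c(1, 1, 1)))
  tf <- rampTransferFunction(lo = 100, hi = 1000)
  out <- renderVolume(vol, tf, renderConfig(viewDir = c(0, 0, 1),
                                            width = 4, height = 4, step = 1,
                                            sampler = "plane"))
  expect_equal(out$log$axis, "z")
  expect_equal(out$log$sampler, "plane")
  expect_equal(out$log$config$width, 4L)
})
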