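test_that("instrumented trilinear tallies split into location and interpolation", {
  vol <- generatePhantom(affineSpec())
  p <- c(1.3, 1.7, 2.1)
  full <- countTrilinearPoint(vol, p)
  expect_equal(additions(full), 17L)
  expect_equal(multiplications(full), 16L)

  loc <- countVoxelLocation(vol, p)
  expect_equal(additions(loc), 3L)
  expect_equal(multiplications(loc), 9L)

  # the interpolation chain is the remainder: 14 additions, 7 multiplications
  expect_equal(additions(full) - additions(loc), 14L)
  expect_equal(multiplications(full) - multiplications(loc), 7L)

  expect_error(countTrilinearPoint(vol, c(0, 1, 1)), "strictly inside")
})

test_that("per-ray traditional cost is n independent per-point costs", {
  expect_equal(additions(countTrilinearRay(6)), 102L)
  expect_equal(multiplications(countTrilinearRay(6)), 96L)
  expect_equal(additions(countTrilinearRay(0)), 0L)
  expect_equal(additions(countTrilinearRay(1)), 17L)
  expect_equal(multiplications(countTrilinearRay(1)), 16L)
  expect_error(countTrilinearRay(-1), "nonnegative")
})

test_that("segment-formula cost is 4 additions and 2 multiplications per point", {
  expect_equal(additions(countSegmentPoints(6)), 24L)
  expect_equal(multiplications(countSegmentPoints(6)), 12L)
  expect_equal(additions(countSegmentPoints(1)), 4L)
  expect_equal(multiplications(countSegmentPoints(1)), 2L)
  expect_equal(additions(countSegmentPoints(0)), 0L)
})

test_that("intersection-point tally follows the package's stated convention", {
  one <- countIntersectionPoint()
  expect_equal(additions(one), 9L)
  expect_equal(multiplications(one), 8L)
  two <- one * 2
  expect_equal(additions(two), 18L)
  expect_equal(multiplications(two), 16L)
})

test_that("counts are structure-determined: identical on random inputs", {
  set.seed(13)
  tallies <- replicate(10, {
    vol <- scalarVolume(array(runif(4^3, 0, 100), c(4, 4, 4)),
                        spacing = runif(3, 0.3, 2))
    hi <- volumeBox(vol)
    p <- runif(3, 0.01, 0.99) * hi
    cnt <- countTrilinearPoint(vol, p)
    c(additions(cnt), multiplications(cnt))
  })
  expect_true(all(tallies[1, ] == 17L))
  expect_true(all(tallies[2, ] == 16L))

  segTallies <- replicate(10, {
    tE <- runif(1); tQ <- tE + runif(1, 0.1, 1)
    cnt <- countSegmentSample(runif(6, tE, tQ), tE, tQ, runif(1), runif(1))
    c(additions(cnt), multiplications(cnt))
  })
  expect_true(all(segTallies[1, ] == 24L))
  expect_true(all(segTallies[2, ] == 12L))
})

test_that("instrumented shadow runs reproduce the real samplers' values", {
  set.seed(29)
  vol <- scalarVolume(array(rnorm(5^3), c(5, 5, 5)), spacing = c(0.7, 1, 0.5))
  pts <- randomInteriorPoints(vol, 6)
  shadow <- trilinearSampleCounted(vol, pts)
  expect_equal(shadow$values, trilinearSample(vol, pts), tolerance = 1e-12)
  # structural count for 6 points equals the instrumented tally
  expect_equal(additions(shadow$count), additions(countTrilinearRay(6)))
  expect_equal(multiplications(shadow$count),
               multiplications(countTrilinearRay(6)))

  ts <- seq(1.1, 1.9, length.out = 6)
  segCnt <- countSegmentSample(ts, 1, 2, 10, 20)
  expect_equal(additions(segCnt), additions(countSegmentPoints(6)))
  expect_equal(multiplications(segCnt),
               multiplications(countSegmentPoints(6)))
})

test_that("the comparison table totals its components", {
  tab <- opCountTable(6)
  expect_equal(tab$additions[tab$component == "total"],
               sum(tab$additions[tab$pathway == "plane" &
                                 tab$component != "total"]))
  expect_equal(tab$additions[tab$pathway == "traditional"], 102)
  expect_equal(tab$multiplications[tab$pathway == "traditional"], 96)
})

test_that("OpCount arithmetic validates its operands", {
  expect_equal(additions(opCount(3, 9) + opCount(14, 7)), 17L)
  expect_error(opCount(-1, 0), "nonnegative")
  expect_error(opCount(2, 2) * 1.5)
})
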