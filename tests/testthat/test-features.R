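test_that("one-hot food-type vectors are orthonormal and validated", {
  v <- oneHot("avocado")
  expect_equal(sum(v), 1)
  expect_equal(which(v == 1), match("avocado", foodLabels()))
  H <- t(vapply(foodLabels(), oneHot, numeric(15)))
  expect_equal(unname(H %*% t(H)), diag(15))
  expect_error(oneHot("container"), "not a food type")
  expect_error(oneHot("pizza"), "accepted labels")
  expect_equal(oneHot("  Yam "), oneHot("yam"))
})

test_that("food region ratio sums instances of a category", {
  plate <- rectMask(0, 0, 40, 25)  # 1000 px
  f1 <- rectMask(5, 5, 20, 25, category = "yam")   # 500 px
  expect_equal(foodRegionRatio(f1, plate), 0.5)
  a <- rectMask(5, 5, 10, 20, category = "yam")    # 200 px
  b <- rectMask(20, 5, 12, 25, category = "yam")   # 300 px
  expect_equal(foodRegionRatio(list(a, b), plate), 0.5)
  expect_equal(foodRegionRatio(list(), plate), 0)
})

test_that("pixel counts track mask geometry", {
  expect_equal(pixelCount(rectMask(0, 0, 10, 10)), 100)
  disc <- discMask(100, 100, 30)
  expect_lt(abs(pixelCount(disc) / (pi * 30^2) - 1), 0.02)
  half <- discMask(100, 100, 15)
  expect_lt(abs(pixelCount(half) / pixelCount(disc) - 0.25), 0.01)
})

test_that("plate aspect ratio matches the covariance-eigenvalue oracle", {
  # rotationally symmetric disc: equal singular values
  disc <- discMask(100, 100, 60)
  expect_equal(plateAspectRatio(disc), 1, tolerance = 0.02)
  # filled ellipse, semi-axes 100 and 50: PAR = a/b = 2
  ell <- ellipseMask(150, 150, 100, 50)
  par <- plateAspectRatio(ell)
  expect_equal(par, 2, tolerance = 0.04)
  # independent oracle: sqrt of the covariance eigenvalue ratio
  p <- maskPixels(ell)
  ev <- eigen(stats::cov(p), only.values = TRUE)$values
  expect_equal(par, sqrt(ev[1] / ev[2]), tolerance = 0.02 * par)
  # rotating the same ellipse leaves PAR unchanged
  rot <- ellipseMask(150, 150, 100, 50, angle = 37 * pi / 180)
  expect_equal(plateAspectRatio(rot), par, tolerance = 0.02)
})

test_that("PAR is invariant to translation and scaling and >= 1", {
  ell <- ellipseMask(120, 120, 80, 55)
  par <- plateAspectRatio(ell)
  expect_gte(par, 1)
  shifted <- instanceMask("f1", "container",
                          sweep(maskPixels(ell), 2, c(40L, 13L), "+"))
  expect_equal(plateAspectRatio(shifted), par, tolerance = 1e-12)
  small <- ellipseMask(60, 60, 40, 27.5)
  expect_equal(plateAspectRatio(small), par, tolerance = 0.03)
  # degenerate (collinear) masks are rejected
  line <- instanceMask("f1", "container",
                       cbind(row = 0:20, col = rep(3L, 21)))
  expect_error(plateAspectRatio(line), "degenerate")
})

test_that("AWR lookup returns the calibrated values", {
  tab <- defaultAwrTable()
  expect_equal(awrLookup("beef stew", tab), 2.3)
  expect_equal(awrLookup("yam", tab), 3.5)
  expect_equal(awrLookup("Avocado", tab), 2.0)
  expect_error(awrLookup("pizza", tab), "no AWR value")
})

test_that("AWR calibration is a through-origin regression", {
  expect_equal(calibrateAwr(c(10, 20), c(23, 46)), 2.3)
  set.seed(12)
  areas <- runif(200, 5, 80)
  weights <- 3.5 * areas + rnorm(200, 0, 1)
  expect_equal(calibrateAwr(areas, weights), 3.5, tolerance = 0.1)
  expect_error(calibrateAwr(10, 35), "insufficient")
  expect_error(calibrateAwr(c(0, 0), c(1, 2)), "zero")
})

test_that("assembled features share frame-level NP, PAR, VC", {
  plate <- discMask(100, 100, 50)
  yam <- discMask(85, 90, 12, category = "yam")
  stew <- discMask(115, 110, 10, category = "beef stew")
  fv <- assembleFeatures(list(plate, yam, stew), vc = 400,
                         defaultAwrTable())
  expect_named(fv, c("beef stew", "yam"))
  expect_equal(fv$yam@np, fv$`beef stew`@np)
  expect_equal(fv$yam@par, fv$`beef stew`@par)
  expect_equal(fv$yam@vc, 400)
  expect_equal(fv$yam@frr, pixelCount(yam) / pixelCount(plate))
  # no food on the container: empty list
  expect_length(assembleFeatures(list(plate), 400, defaultAwrTable()), 0)
  expect_error(assembleFeatures(list(yam), 400, defaultAwrTable()),
               "without container")
  # several containers: the largest is the reference plate
  small_plate <- discMask(40, 40, 10, instance_id = "2")
  expect_warning(
    fv2 <- assembleFeatures(list(small_plate, plate, yam), 400,
                            defaultAwrTable()),
    "largest")
  expect_equal(fv2$yam@np, pixelCount(plate))
})

test_that("generator scenes reproduce configured area fractions", {
  cfg <- sceneConfig(tilt_deg = 20,
                     food_layout = c(yam = 0.3, "beef stew" = 0.2))
  fr <- generateFrame(cfg, seed = 5, render_depth = FALSE)
  fv <- assembleFeatures(fr$masks, vc = fr$truth$vc, defaultAwrTable())
  expect_equal(fv$yam@frr, 0.3, tolerance = 0.02)
  expect_equal(fv$`beef stew`@frr, 0.2, tolerance = 0.02)
})

test_that("PAR of tilted plates approximates 1/cos(tilt)", {
  for (tilt in c(0, 30, 45, 60)) {
    cfg <- sceneConfig(tilt_deg = tilt, food_layout = c(yam = 0.1))
    fr <- generateFrame(cfg, seed = 4 + tilt, render_depth = FALSE)
    par <- plateAspectRatio(fr$masks[[1]])
    expect_equal(par, 1 / cos(tilt * pi / 180),
                 tolerance = 0.05 / cos(tilt * pi / 180))
  }
  # top-down views give smaller PAR than tilted views
  cfg0 <- sceneConfig(tilt_deg = 0, food_layout = c(yam = 0.1))
  cfg60 <- sceneConfig(tilt_deg = 60, food_layout = c(yam = 0.1))
  expect_lt(
    plateAspectRatio(generateFrame(cfg0, 1, render_depth = FALSE)$masks[[1]]),
    plateAspectRatio(generateFrame(cfg60, 1, render_depth = FALSE)$masks[[1]]))
})
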