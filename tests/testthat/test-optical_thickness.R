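test_that("phase to OPL conversion", {
  expect_equal(phaseToOpl(0, 550), 0)
  expect_equal(phaseToOpl(2 * pi, 550), 550)
  expect_equal(phaseToOpl(pi, 550), 275)
  expect_error(phaseToOpl(1, -5), "positive")
})

test_that("thickness index recovers closed-form plateau contrast", {
  # nucleolus plateau 1.0 rad on a 0.4 rad nucleoplasm, lambda 550 nm
  ph <- matrix(0.4, 100, 100)
  rr <- sqrt(outer((1:100 - 40)^2, (1:100 - 40)^2, `+`))
  ph[rr <= 8] <- 1.0
  ti <- thicknessIndex(ph, c(40, 40), c(40, 70))
  expect_equal(ti$index, (1.0 - 0.4) * 550 / (2 * pi), tolerance = 1e-9)
  expect_equal(round(ti$index, 2), 52.52)
  # direct mean over the enumerated disc pixels
  dn <- nucleoDHM:::.discPixels(c(40, 40), 12, c(100, 100))
  db <- nucleoDHM:::.discPixels(c(40, 70), 12, c(100, 100))
  expect_equal(length(dn[, 1]), 12)
  expect_equal(ti$index,
               mean(phaseToOpl(ph[dn], 550)) - mean(phaseToOpl(ph[db], 550)))
})

test_that("index is zero on uniform images, offset-invariant, linear, antisymmetric", {
  set.seed(6)
  ph <- matrix(stats::runif(4900, 0, 2), 70, 70)
  u <- matrix(0.7, 70, 70)
  expect_equal(thicknessIndex(u, c(20, 20), c(50, 50))$index, 0)
  i0 <- thicknessIndex(ph, c(20, 20), c(50, 50))$index
  # global offset leaves the index unchanged
  i_off <- thicknessIndex(ph + 3, c(20, 20), c(50, 50))$index
  expect_equal(i_off, i0, tolerance = 1e-9)
  # scaling the phase scales the index
  i_sc <- thicknessIndex(2.5 * ph, c(20, 20), c(50, 50))$index
  expect_equal(i_sc, 2.5 * i0, tolerance = 1e-9)
  # swapping the discs negates the index
  i_sw <- thicknessIndex(ph, c(50, 50), c(20, 20))$index
  expect_equal(i_sw, -i0, tolerance = 1e-12)
})

test_that("nucleolus center defaults to the brightest phase pixel in the mask", {
  ph <- matrix(0.2, 50, 50)
  ph[17, 23] <- 1.5
  mask <- matrix(0L, 50, 50); mask[10:25, 15:30] <- 1L
  ti <- thicknessIndex(ph, NULL, c(40, 40), nucleolus_mask = mask)
  expect_equal(ti$center, c(17, 23))
  expect_error(thicknessIndex(ph, NULL, c(40, 40),
                              nucleolus_mask = matrix(0L, 50, 50)),
               "empty")
})

test_that("disc placement errors when clipped by the boundary", {
  ph <- matrix(1, 30, 30)
  expect_error(thicknessIndex(ph, c(1, 1), c(15, 15)), "clipped")
  expect_error(thicknessIndex(ph, c(15, 15), c(30, 30)), "clipped")
})

test_that("cytoplasmic index recovers plateau contrast at the 5 um offset", {
  # nucleus disc, cytoplasm plateau 0.2 rad, empty background
  H <- 200
  ph <- matrix(0, H, H)
  rr <- sqrt(outer((1:H - 70)^2, (1:H - 70)^2, `+`))
  nmask <- matrix(0L, H, H); nmask[rr <= 30] <- 1L
  ph[rr <= 95] <- 0.2        # cell footprint
  ph[rr <= 30] <- 0.8        # nucleus itself
  ci <- cytoplasmIndex(ph, nmask, cellfree_center = c(180, 180))
  expect_equal(ci$index, 0.2 * 550 / (2 * pi), tolerance = 1e-9)
  expect_equal(round(ci$index, 2), 17.51)
  # chosen disc sits about 5 um (33 px at 0.151 um/px) from the boundary
  d <- sqrt(sum((ci$center - c(70, 70))^2)) - 30
  expect_lt(abs(d - 5 / 0.151), 1.5)

  # doubling the pixel size halves the offset in pixels; plateau index same
  opt2 <- opticsConfig(binning = 2)
  ci2 <- cytoplasmIndex(ph, nmask, c(180, 180), optics = opt2)
  d2 <- sqrt(sum((ci2$center - c(70, 70))^2)) - 30
  expect_lt(abs(d2 - 5 / 0.302), 1.5)
  expect_equal(ci2$index, ci$index, tolerance = 1e-9)

  expect_equal(cytoplasmIndex(matrix(1, H, H), nmask, c(180, 180))$index, 0)
})

test_that("dose-response arithmetic reproduces gradual percent increases", {
  pc <- percentChange(c(control = 78.19, medium = 85.58, high = 103.2),
                      "control")
  expect_equal(unname(round(pc["medium"], 2)), 9.45)
  expect_equal(unname(round(pc["high"], 2)), 31.99)  # "~32%"
})
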