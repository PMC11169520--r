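test_that("an empty scene renders constant backgrounds and empty truth", {
  sc <- new("SyntheticScene", dims = c(64, 64), phase_scale = 4,
            nuclei = data.frame(), nucleoli = data.frame(),
            mitotic = data.frame(), noise_sigma = 0,
            background = c(dapi = 0.08, dapi_nucleus = 0.75, gfp = 0.01,
                           gfp_nucleoplasm = 0.05, phase = 0,
                           phase_nucleoplasm = 0.4, dapi_ring = 0),
            seed = 1)
  g <- generateTriplet(sc)
  expect_equal(unique(as.numeric(dapi(g$triplet))), 0.08)
  expect_equal(unique(as.numeric(gfp(g$triplet))), 0.01)
  expect_equal(unique(as.numeric(phase(g$triplet))), 0)
  expect_equal(nrow(g$truth), 0)
})

test_that("rendering is bit-identical for a fixed seed", {
  sc <- randomScene(n_nuclei = 2, dims = c(256, 256),
                    nucleus_semi_range = c(30, 40), noise_sigma = 0.03,
                    seed = 7)
  g1 <- generateTriplet(sc)
  g2 <- generateTriplet(sc)
  expect_identical(dapi(g1$triplet), dapi(g2$triplet))
  expect_identical(gfp(g1$triplet), gfp(g2$triplet))
  expect_identical(phase(g1$triplet), phase(g2$triplet))
  # and the scene itself regenerates identically
  sc2 <- randomScene(n_nuclei = 2, dims = c(256, 256),
                     nucleus_semi_range = c(30, 40), noise_sigma = 0.03,
                     seed = 7)
  expect_identical(sc@nuclei, sc2@nuclei)
  expect_identical(sc@nucleoli, sc2@nucleoli)
})

test_that("ground-truth counts and areas come from the analytic supports", {
  g <- generateTriplet(two_cell_scene())
  expect_equal(g$truth$count, c(2L, 3L))
  # direct pixel enumeration of the analytic supports (r < 1.1 R)
  sc <- two_cell_scene()
  for (k in 1:5) {
    q <- sc@nucleoli[k, ]
    cnt <- 0
    for (r in floor(q$row - 12):ceiling(q$row + 12))
      for (c in floor(q$col - 12):ceiling(q$col + 12))
        if (sqrt((r - q$row)^2 + (c - q$col)^2) < 1.1 * q$radius)
          cnt <- cnt + 1
    expect_equal(sum(g$nucleolus_labels == k), cnt)
  }
  expect_equal(sum(g$truth$area_px), sum(g$nucleolus_labels > 0))
})

test_that("scene validity rejects a nucleolus outside its parent", {
  sc <- two_cell_scene()
  bad <- sc@nucleoli
  bad$row[1] <- 320   # center of nucleus 2, parent still 1
  expect_error(
    new("SyntheticScene", dims = sc@dims, phase_scale = 4,
        nuclei = sc@nuclei, nucleoli = bad, mitotic = data.frame(),
        noise_sigma = 0, background = sc@background, seed = 1),
    "inside its parent")
  small <- sc@nucleoli
  small$radius[1] <- 1
  expect_error(
    new("SyntheticScene", dims = sc@dims, phase_scale = 4,
        nuclei = sc@nuclei, nucleoli = small, mitotic = data.frame(),
        noise_sigma = 0, background = sc@background, seed = 1),
    "radii")
})

test_that("noise-free DAPI histogram is bimodal with a clean valley", {
  g <- generateTriplet(randomScene(n_nuclei = 4, seed = 2))
  d <- normalizeDapi(dapi(g$triplet))
  expect_silent(thr <- bimodalThreshold(d))
  expect_gt(thr, 0.15)
  expect_lt(thr, 0.6)
})

test_that("phase equals the plateau exactly inside nucleoli (noise-free)", {
  sc <- two_cell_scene()
  g <- generateTriplet(sc)
  ph <- phase(g$triplet)
  s <- sc@phase_scale
  prow <- (seq_len(nrow(ph)) - 1) * s + (s + 1) / 2
  pcol <- (seq_len(ncol(ph)) - 1) * s + (s + 1) / 2
  for (k in 1:5) {
    q <- sc@nucleoli[k, ]
    hit <- which(outer((prow - q$row)^2, (pcol - q$col)^2, `+`) <=
                   (0.7 * q$radius)^2, arr.ind = TRUE)
    expect_gt(nrow(hit), 0)
    expect_true(all(ph[hit] == q$phase_plateau))
  }
})

test_that("sphere projection ratio follows N^(1/3)", {
  expect_equal(sphereProjectionRatio(1), 1)
  expect_equal(sphereProjectionRatio(8), 2)
  expect_error(sphereProjectionRatio(0), "integer")
  expect_error(sphereProjectionRatio(2.5), "integer")
  # Monte-Carlo style rasterization oracle for N = 4: discs of equal
  # total sphere volume, pixel-counted at high resolution
  rasterize_discs <- function(n, V = 1, res = 400) {
    r3 <- (3 * V / (4 * pi * n))^(1 / 3)
    px <- r3 * res
    one <- sum(outer((-ceiling(px) - 1):(ceiling(px) + 1),
                     (-ceiling(px) - 1):(ceiling(px) + 1),
                     function(i, j) i^2 + j^2) <= px^2)
    n * one
  }
  ratio <- rasterize_discs(4) / rasterize_discs(1)
  expect_equal(ratio, sphereProjectionRatio(4), tolerance = 0.01)
})
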