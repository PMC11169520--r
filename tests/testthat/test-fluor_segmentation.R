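# A radial raised-cosine bump on a quiet background, peak value `peak`
# at (row, col), half-maximum radius R.
bump_image <- function(dims, row, col, R, peak, base = 0) {
  rr <- sqrt(outer((seq_len(dims[1]) - row)^2,
                   (seq_len(dims[2]) - col)^2, `+`))
  base + (peak - base) * nucleoDHM:::.bump_profile(rr, R)
}

test_that("DAPI normalization rescales to [0, 1] and preserves ranks", {
  expect_equal(normalizeDapi(matrix(c(0, 2, 4, 8), 2, 2)),
               matrix(c(0, 0.25, 0.5, 1), 2, 2))
  expect_equal(unique(as.numeric(normalizeDapi(matrix(3, 4, 4)))), 1)
  set.seed(1)
  x <- matrix(stats::runif(400, 0, 1e4), 20, 20)
  y <- normalizeDapi(x)
  expect_equal(max(y), 1)
  expect_identical(order(x), order(y))
  expect_error(normalizeDapi(matrix(0, 3, 3)), "degenerate")
})

test_that("bimodal threshold finds the inter-mode minimum", {
  # empty valley between two tight clusters forces the threshold inside
  set.seed(2)
  img <- matrix(c(stats::runif(5000, 0.18, 0.22),
                  stats::runif(5000, 0.78, 0.82)), 100, 100)
  thr <- bimodalThreshold(img)
  expect_gt(thr, 0.25); expect_lt(thr, 0.75)

  # two-Gaussian mixture against a brute-force histogram scan oracle
  set.seed(1)
  x <- c(stats::rnorm(5e4, 0.25, 0.05), stats::rnorm(5e4, 0.75, 0.05))
  x <- pmin(pmax(x, 0), 1)
  img <- matrix(x, 250, 400)
  thr <- bimodalThreshold(img)
  counts <- tabulate(pmin(256, floor(img * 256) + 1), 256)
  locmax <- which(counts > c(-1, counts[-256]) &
                    counts >= c(counts[-1], -1) & counts > 0)
  top2 <- locmax[order(counts[locmax], decreasing = TRUE)][1:2]
  lo <- min(top2); hi <- max(top2)
  between <- (lo + 1):(hi - 1)
  cand <- between[counts[between] == min(counts[between])]
  scan_bin <- cand[(length(cand) + 1) %/% 2]
  expect_equal(thr, (scan_bin - 0.5) / 256)

  expect_error(bimodalThreshold(matrix(0.5, 10, 10)), "unimodal")
})

test_that("nucleus segmentation recovers a single ellipse and applies the size filter", {
  mk_dapi <- function(a, b) {
    sc <- new("SyntheticScene", dims = c(300, 300), phase_scale = 4,
              nuclei = data.frame(row = 150, col = 150, a = a, b = b,
                                  theta = 0, dapi_level = 0.8),
              nucleoli = data.frame(), mitotic = data.frame(),
              noise_sigma = 0,
              background = c(dapi = 0.08, dapi_nucleus = 0.75, gfp = 0.01,
                             gfp_nucleoplasm = 0.05, phase = 0,
                             phase_nucleoplasm = 0.4, dapi_ring = 0),
              seed = 1)
    generateTriplet(sc)
  }
  g <- mk_dapi(45, 36)   # ~5089 px
  mask <- segmentNuclei(dapi(g$triplet))
  lab <- nucleoDHM:::cpp_label8(mask)
  expect_equal(max(lab), 1)
  covered <- sum(mask == 1 & g$nucleus_mask == 1) / sum(g$nucleus_mask)
  expect_gte(covered, 0.95)

  # well below the 2000 px cut even after smoothing widens the contour
  g2 <- mk_dapi(20, 16)  # ~1005 px
  expect_equal(sum(segmentNuclei(dapi(g2$triplet))), 0)

  expect_error(segmentNuclei(matrix(0.3, 100, 100)), "unimodal")
})

test_that("GFP standardization hits the reference statistics and is affine-invariant", {
  set.seed(3)
  gfp <- matrix(stats::runif(10000, 0, 800), 100, 100)
  nmask <- matrix(0L, 100, 100); nmask[30:70, 30:70] <- 1L
  p <- segParams()
  std <- standardizeGfp(gfp, nmask, dataset_max = 800)
  expect_equal(mean(std[nmask == 1]), p@gfp_ref_mean, tolerance = 1e-12)
  expect_equal(stats::sd(std[nmask == 1]), p@gfp_ref_sd, tolerance = 1e-12)

  # identity: nucleus pixels already at the reference statistics
  base <- gfp / 800
  ref <- (base - mean(base[nmask == 1])) / stats::sd(base[nmask == 1]) *
    p@gfp_ref_sd + p@gfp_ref_mean
  expect_equal(standardizeGfp(ref, nmask, dataset_max = 1), ref,
               tolerance = 1e-9)

  # gain/offset invariance on nucleus pixels
  std2 <- standardizeGfp(3.7 * gfp + 40, nmask, dataset_max = 800)
  expect_equal(std2[nmask == 1], std[nmask == 1], tolerance = 1e-9)

  expect_error(standardizeGfp(gfp, matrix(0L, 100, 100), 800), "empty")
  expect_error(standardizeGfp(matrix(5, 10, 10), matrix(1L, 10, 10), 10),
               "variance")
})

gauss_bump <- function(dims, row, col, sd, peak) {
  rr2 <- outer((seq_len(dims[1]) - row)^2, (seq_len(dims[2]) - col)^2, `+`)
  peak * exp(-rr2 / (2 * sd^2))
}

test_that("seed detection finds isolated and merged bumps", {
  img <- gauss_bump(c(80, 80), 40, 40, 8, 0.5)
  ss <- detectSeeds(img)
  expect_equal(nrow(seeds(ss)), 1)
  expect_equal(seeds(ss)$row, 40)   # the analytic peak pixel
  expect_equal(seeds(ss)$col, 40)
  expect_equal(seeds(ss)$intensity, 0.5)

  # two bumps on a plinth: joined at low thresholds, separated above it
  img2 <- pmax(gauss_bump(c(90, 120), 45, 40, 6, 0.5),
               gauss_bump(c(90, 120), 45, 80, 6, 0.4))
  plinth <- matrix(0, 90, 120); plinth[35:55, 30:90] <- 0.12
  img2 <- pmax(img2, plinth)
  ss2 <- detectSeeds(img2)
  expect_equal(nrow(seeds(ss2)), 2)
  expect_setequal(round(seeds(ss2)$intensity, 3), c(0.5, 0.4))
  # brute-force component counts: merged at t0, split at the top threshold
  expect_equal(max(nucleoDHM:::cpp_label8((img2 >= 0.083) + 0L)), 1)
  expect_equal(max(nucleoDHM:::cpp_label8((img2 >= 0.3) + 0L)), 2)

  expect_equal(nrow(seeds(detectSeeds(matrix(0.05, 50, 50)))), 0)
})

test_that("threshold genealogy is monotone: containment and non-decreasing count", {
  g <- generateTriplet(randomScene(n_nuclei = 3, seed = 4))
  nmask <- segmentNuclei(dapi(g$triplet))
  gstd <- standardizeGfp(gfp(g$triplet), nmask, dataset_max = 1)
  ss <- detectSeeds(gstd)
  h <- ss@history
  for (i in seq_len(length(h) - 1)) {
    expect_gte(length(h[[i + 1]]), length(h[[i]]))
    parents <- h[[i]]
    for (child in h[[i + 1]]) {
      inside <- vapply(parents, function(p) all(child %in% p), logical(1))
      expect_equal(sum(inside), 1)
    }
  }
  # regions never disappear: every parent has at least one descendant
  for (i in seq_len(length(h) - 1)) {
    for (p in h[[i]]) {
      has_child <- any(vapply(h[[i + 1]], function(ch) all(ch %in% p),
                              logical(1)))
      expect_true(has_child)
    }
  }
})

test_that("region growing equals a superlevel-set flood with hole filling", {
  img <- bump_image(c(70, 70), 35, 35, 15, 0.6)
  reg <- growRegion(img, c(35, 35), 0.15)
  oracle <- bfs_flood(img, c(35, 35), 0.15)
  expect_identical(reg, bfs_fill_holes(oracle))

  # stop above the seed intensity: flagged empty region
  reg2 <- growRegion(img, c(35, 35), 0.7)
  expect_equal(sum(reg2), 0)
  expect_true(isTRUE(attr(reg2, "flagged")))

  # bright annulus around a dim core: the core is included by hole filling
  rr <- sqrt(outer((1:60 - 30)^2, (1:60 - 30)^2, `+`))
  ann <- ifelse(rr >= 8 & rr <= 14, 0.8, 0.02)
  reg3 <- growRegion(ann, c(30, 22), 0.5)
  expect_equal(reg3[30, 30], 1L)            # hole filled
  flood <- bfs_flood(ann, c(30, 22), 0.5)
  expect_equal(flood[30, 30], 0L)           # not reachable by flood alone
  expect_identical(reg3, bfs_fill_holes(flood))
})

test_that("counting stop applies max(alpha * I_seed, tau)", {
  expect_equal(countingStop(0.5), 0.425)
  expect_equal(countingStop(0.16), 0.15)
  expect_equal(countingStop(1.0), 0.85)
  expect_equal(countingStop(c(0.5, 0.16)), c(0.425, 0.15))
})

test_that("mitosis screen discards large dim regions only", {
  # flat plateau of controllable area and max intensity around the seed
  mk <- function(area_side, level) {
    img <- matrix(0.01, 120, 120)
    img[seq_len(area_side) + 10, seq_len(area_side) + 10] <- level
    img
  }
  expect_equal(mitosisFilter(mk(35, 0.20), c(20, 20)), "discard") # 1225 px
  expect_equal(mitosisFilter(mk(35, 0.30), c(20, 20)), "keep")
  expect_equal(mitosisFilter(mk(28, 0.20), c(20, 20)), "keep")    # 784 px
})

test_that("nucleolus masks: counts match truth, counting within area, outside-nucleus excluded", {
  g <- generateTriplet(two_cell_scene())
  nmask <- segmentNuclei(dapi(g$triplet))
  gstd <- standardizeGfp(gfp(g$triplet), nmask, dataset_max = 1)
  nl <- segmentNucleoli(gstd, nmask)
  expect_equal(max(nucleoDHM:::cpp_label8(nl$counting)), 5)
  rec <- extractFeatures(nmask, nl$counting, nl$area, 0.151,
                         seeds = nl$seeds[nl$seeds$kept, ])
  sc <- two_cell_scene()
  map <- matchSceneNuclei(nmask, sc)
  expect_equal(rec$nucleolus_count[match(map, rec$nucleus_label)],
               c(2L, 3L))

  # every counting region is contained in an area region
  clab <- nucleoDHM:::cpp_label8(nl$counting)
  for (l in seq_len(max(clab)))
    expect_true(all(nl$area[clab == l] == 1L))

  # a bright blob outside every nucleus never reaches the masks
  gstd2 <- gstd
  gstd2[5:15, 5:15] <- 0.6
  nl2 <- segmentNucleoli(gstd2, nmask)
  expect_equal(sum(nl2$counting[5:15, 5:15]), 0)
  expect_equal(sum(nl2$area[5:15, 5:15]), 0)
})

test_that("cluster and border filter matches solidity and is idempotent", {
  mk_mask <- function() {
    m <- matrix(0L, 200, 200)
    rr <- function(r0, c0, rad) {
      w <- which(outer((1:200 - r0)^2, (1:200 - c0)^2, `+`) <= rad^2)
      m[w] <<- 1L
    }
    rr(50, 50, 25)                       # isolated disc: kept
    rr(140, 60, 22); rr(140, 98, 22)     # dumbbell: removed
    m[1:20, 150:180] <- 1L               # touches the top edge: removed
    m
  }
  m <- mk_mask()
  out <- removeClusteredAndBorder(m, NULL)
  expect_equal(sort(out$removed$reason), c("border", "clustered"))
  lab <- nucleoDHM:::cpp_label8(out$nucleus_mask)
  expect_equal(max(lab), 1)
  # the survivor is the isolated disc
  expect_equal(out$nucleus_mask[50, 50], 1L)
  # idempotent
  out2 <- removeClusteredAndBorder(out$nucleus_mask, NULL)
  expect_identical(out2$nucleus_mask, out$nucleus_mask)
  expect_equal(nrow(out2$removed), 0)
})

test_that("rasterized hull area matches the brute-force separating-line oracle", {
  set.seed(9)
  for (k in 1:6) {
    m <- matrix(0L, 40, 40)
    for (b in 1:3) {
      r0 <- sample(10:30, 1); c0 <- sample(10:30, 1)
      rad <- sample(4:8, 1)
      m[which(outer((1:40 - r0)^2, (1:40 - c0)^2, `+`) <= rad^2)] <- 1L
    }
    lab <- nucleoDHM:::cpp_label8(m)
    for (l in seq_len(max(lab))) {
      idx <- which(lab == l)
      r <- (idx - 1) %% 40 + 1; c <- (idx - 1) %/% 40 + 1
      expect_equal(nucleoDHM:::.hullAreaPx(r, c), brute_hull_area(r, c))
    }
  }
})
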