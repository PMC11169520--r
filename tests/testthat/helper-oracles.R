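# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: plain-R breadth-first floods, pairwise
# separating-line hull rasterization, a hand-rolled IEEE-754 float32
# encoder, and brute-force tallies.

# Breadth-first superlevel-set flood (8-connectivity), no hole filling.
bfs_flood <- function(img, seed, thr) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0L, H, W)
  if (img[seed[1], seed[2]] < thr) return(out)
  queue <- matrix(seed, ncol = 2)
  out[seed[1], seed[2]] <- 1L
  while (nrow(queue) > 0) {
    p <- queue[1, , drop = FALSE]
    queue <- queue[-1, , drop = FALSE]
    for (dr in -1:1) for (dc in -1:1) {
      r <- p[1] + dr; c <- p[2] + dc
      if (r >= 1 && r <= H && c >= 1 && c <= W &&
          out[r, c] == 0L && img[r, c] >= thr) {
        out[r, c] <- 1L
        queue <- rbind(queue, c(r, c))
      }
    }
  }
  out
}

# Fill enclosed background of a binary mask by flooding the background
# from the border (4-neighbour background flood, complement convention).
bfs_fill_holes <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  outside <- matrix(0L, H, W)
  queue <- NULL
  for (r in 1:H) for (c in c(1, W))
    if (mask[r, c] == 0L) { queue <- rbind(queue, c(r, c)); outside[r, c] <- 1L }
  for (c in 1:W) for (r in c(1, H))
    if (mask[r, c] == 0L && outside[r, c] == 0L) {
      queue <- rbind(queue, c(r, c)); outside[r, c] <- 1L
    }
  while (!is.null(queue) && nrow(queue) > 0) {
    p <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      r <- p[1] + d[1]; c <- p[2] + d[2]
      if (r >= 1 && r <= H && c >= 1 && c <= W &&
          mask[r, c] == 0L && outside[r, c] == 0L) {
        outside[r, c] <- 1L
        queue <- rbind(queue, c(r, c))
      }
    }
  }
  filled <- mask
  filled[outside == 0L] <- 1L
  filled
}

# Rasterized convex-hull area by brute force: a bounding-box pixel is
# outside the hull iff some line through two boundary pixels of the set
# separates it from the whole set.
brute_hull_area <- function(rows, cols) {
  n <- length(rows)
  if (n <= 2) return(n)
  # boundary pixels suffice to define the hull
  key <- paste(rows, cols)
  is_boundary <- vapply(seq_len(n), function(i) {
    nb <- paste(rows[i] + c(-1, 1, 0, 0), cols[i] + c(0, 0, -1, 1))
    !all(nb %in% key)
  }, logical(1))
  br <- rows[is_boundary]; bc <- cols[is_boundary]
  gr <- seq(min(rows), max(rows)); gc <- seq(min(cols), max(cols))
  gx <- rep(gr, times = length(gc)); gy <- rep(gc, each = length(gr))
  outside <- rep(FALSE, length(gx))
  m <- length(br)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    ar <- br[i]; ac <- bc[i]; br_ <- br[j]; bc_ <- bc[j]
    # signed area cross products against the whole set
    s_set <- (br_ - ar) * (cols - ac) - (bc_ - ac) * (rows - ar)
    if (all(s_set <= 0)) {
      s_grid <- (br_ - ar) * (gy - ac) - (bc_ - ac) * (gx - ar)
      outside <- outside | (s_grid > 1e-9)
    } else if (all(s_set >= 0)) {
      s_grid <- (br_ - ar) * (gy - ac) - (bc_ - ac) * (gx - ar)
      outside <- outside | (s_grid < -1e-9)
    }
  }
  sum(!outside)
}

# Hand-rolled IEEE-754 binary32 little-endian encoder (round-to-nearest-
# even), independent of writeBin's float conversion.
encode_float32_le <- function(x) {
  out <- raw(0)
  for (v in x) {
    if (v == 0) { out <- c(out, as.raw(c(0, 0, 0, 0))); next }
    s <- if (v < 0) 1L else 0L
    a <- abs(v)
    e <- floor(log2(a))
    frac <- a / 2^e
    if (frac >= 2) { e <- e + 1; frac <- a / 2^e }
    mant <- round((frac - 1) * 2^23)
    if (mant == 2^23) { mant <- 0; e <- e + 1 }
    bits <- s * 2^31 + (e + 127) * 2^23 + mant
    b <- integer(4)
    for (k in 1:4) { b[k] <- bits %% 256; bits <- bits %/% 256 }
    out <- c(out, as.raw(b))
  }
  out
}

# A random smooth nonnegative field in [0, 1] for flood-oracle tests.
random_field <- function(n, seed) {
  set.seed(seed)
  f <- matrix(stats::runif(n * n), n, n)
  f <- nucleoDHM:::cpp_gauss_blur(f, 2.5)
  f <- f - min(f)
  f / max(f)
}

# Standard segmentation run used by several test files.
run_fluor <- function(scene) {
  g <- generateTriplet(scene)
  nmask <- segmentNuclei(dapi(g$triplet))
  gstd <- standardizeGfp(gfp(g$triplet), nmask, dataset_max = 1)
  nl <- segmentNucleoli(gstd, nmask)
  filt <- removeClusteredAndBorder(nmask, nl)
  rec <- extractFeatures(filt$nucleus_mask, filt$nucleolus_masks$counting,
                         filt$nucleolus_masks$area, 0.151,
                         seeds = nl$seeds[nl$seeds$kept, , drop = FALSE])
  list(g = g, nmask = nmask, gstd = gstd, nl = nl, filt = filt, rec = rec)
}

# Deterministic DL fixture: one nucleus with 2-4 well-separated nucleoli
# per 128 x 128 frame, phase at full fluorescence resolution.
dl_fixture <- function(n, seed0 = 1, dims = c(128, 128)) {
  semi <- round(dims[1] * c(0.19, 0.27))
  rad <- pmax(2, dims[1] * c(0.04, 0.07))
  lapply(seq_len(n), function(s) {
    sc <- randomScene(n_nuclei = 1, dims = dims, phase_scale = 1,
                      nucleoli_range = c(2, 4),
                      nucleus_semi_range = semi,
                      radius_range = rad, seed = seed0 + s - 1)
    g <- generateTriplet(sc)
    list(img = preprocessPhase(phase(g$triplet), depth = 3),
         lab = (g$nucleolus_labels > 0) + 0L,
         count = g$truth$count)
  })
}

# Hand-built two-nucleus scene reused by several blocks.
two_cell_scene <- function(noise = 0) {
  nuclei <- data.frame(row = c(120, 320), col = c(130, 330),
                       a = c(50, 55), b = c(45, 48), theta = c(0, 0.4),
                       dapi_level = c(0.8, 0.7))
  nucleoli <- data.frame(
    parent = c(1, 1, 2, 2, 2),
    row = c(100, 140, 300, 340, 320),
    col = c(110, 150, 310, 330, 355),
    radius = c(7, 8, 6, 7, 6),
    gfp_peak = c(0.7, 0.6, 0.8, 0.65, 0.75),
    phase_plateau = c(1.0, 1.1, 0.9, 1.2, 1.0))
  new("SyntheticScene", dims = c(450, 450), phase_scale = 4,
      nuclei = nuclei, nucleoli = nucleoli, mitotic = data.frame(),
      noise_sigma = noise,
      background = c(dapi = 0.08, dapi_nucleus = 0.75, gfp = 0.01,
                     gfp_nucleoplasm = 0.05, phase = 0,
                     phase_nucleoplasm = 0.4, dapi_ring = 0),
      seed = 7)
}

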