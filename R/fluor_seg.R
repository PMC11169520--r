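#' Normalize a DAPI image to [0, 1]
#'
#' Divides every pixel by the image's own maximum so the dynamic range
#' becomes [0, 1].
#'
#' @param dapi nonnegative intensity matrix with a positive maximum.
#' @return Matrix in [0, 1] with maximum exactly 1.
#' @export
normalizeDapi <- function(dapi) {
  stopifnot(is.matrix(dapi))
  if (any(dapi < 0)) stop("DAPI intensities must be nonnegative")
  mx <- max(dapi)
  if (mx <= 0)
    stop(.cond("nucleoDHM_degenerate_input",
               "degenerate DAPI image: all pixels are zero"))
  dapi / mx
}

.cond <- function(class, msg) {
  structure(class = c(class, "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

.hist256 <- function(x) {
  idx <- pmin(256L, floor(pmin(pmax(x, 0), 1) * 256) + 1L)
  tabulate(idx, nbins = 256L)
}

.localMaxima <- function(counts) {
  n <- length(counts)
  left <- c(-1, counts[-n]); right <- c(counts[-1], -1)
  which(counts > left & counts >= right & counts > 0)
}

#' Bimodal histogram threshold
#'
#' Finds the separating threshold of a bimodal intensity distribution:
#' the image (optionally Gaussian-smoothed first) is binned into a 256-bin
#' histogram on [0, 1]; the two dominant modes are the two highest
#' histogram local maxima separated by a genuine dip, and the threshold is
#' the bin-center abscissa of the lowest bin strictly between them. In
#' DAPI images the background and nucleus intensities form the two modes.
#'
#' @param img matrix with values in [0, 1].
#' @param sigma optional Gaussian smoothing applied to the image before
#'   histogramming (0 = none; the image, not the histogram, is smoothed).
#' @return Threshold in (0, 1).
#' @section Errors: a unimodal (or constant) histogram raises a condition
#'   of class \code{"nucleoDHM_no_threshold"}; callers may fall back to
#'   Otsu (as \code{\link{segmentNuclei}} does when the two modes exist
#'   but no interior minimum separates them).
#' @export
bimodalThreshold <- function(img, sigma = 0) {
  stopifnot(is.matrix(img), all(img >= 0), all(img <= 1))
  if (sigma > 0) img <- cpp_gauss_blur(img, sigma)
  counts <- .hist256(img)
  peaks <- .localMaxima(counts)
  if (length(peaks) < 2)
    stop(.cond("nucleoDHM_no_threshold",
               "histogram is unimodal: no bimodal threshold exists"))
  peaks <- peaks[order(counts[peaks], decreasing = TRUE)]
  p1 <- peaks[1]
  p2 <- NA_integer_
  for (cand in peaks[-1]) {
    lo <- min(p1, cand); hi <- max(p1, cand)
    if (hi - lo < 2) next
    valley <- min(counts[(lo + 1):(hi - 1)])
    if (valley < min(counts[p1], counts[cand])) { p2 <- cand; break }
  }
  if (is.na(p2))
    stop(.cond("nucleoDHM_no_threshold",
               "no interior minimum separates the two dominant modes"))
  lo <- min(p1, p2); hi <- max(p1, p2)
  between <- (lo + 1):(hi - 1)
  # an empty valley ties many bins at the minimum: take the middle one
  cand <- between[counts[between] == min(counts[between])]
  bin <- cand[(length(cand) + 1) %/% 2]
  (bin - 0.5) / 256
}

.otsu256 <- function(img) {
  counts <- .hist256(img)
  p <- counts / sum(counts)
  mids <- (seq_len(256) - 0.5) / 256
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[256]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

.brush <- function(r) EBImage::makeBrush(2L * as.integer(r) + 1L, "disc")

#' Segment nuclei from a DAPI image
#'
#' The nucleus pipeline: normalize to [0, 1]; Gaussian-smooth (sigma
#' \code{dapi_gauss_sigma}); threshold at the bimodal-histogram minimum
#' (Otsu fallback, with a warning, when the two modes are not separated by
#' an interior minimum); morphological closing (disc radius
#' \code{dapi_close_radius}) to fill small holes and smooth the contour;
#' removal of connected regions smaller than \code{dapi_min_area} pixels;
#' final dilation (disc radius \code{dapi_dilate_radius}).
#'
#' @param dapi nonnegative DAPI intensity matrix.
#' @param params a \linkS4class{SegParams}.
#' @return 0/1 integer matrix (1 = nucleus).
#' @export
segmentNuclei <- function(dapi, params = segParams()) {
  norm <- normalizeDapi(dapi)
  sm <- cpp_gauss_blur(norm, params@dapi_gauss_sigma)
  sm <- pmin(pmax(sm, 0), 1)   # guard float round-off at the range ends
  thr <- tryCatch(bimodalThreshold(sm, sigma = 0),
                  nucleoDHM_no_threshold = function(e) {
                    if (grepl("unimodal", conditionMessage(e))) stop(e)
                    warning("bimodal threshold not found (",
                            conditionMessage(e),
                            "); falling back to Otsu", call. = FALSE)
                    .otsu256(sm)
                  })
  mask <- (sm > thr) + 0L
  mask <- .as01(EBImage::closing(mask, .brush(params@dapi_close_radius)))
  lab <- cpp_label8(mask)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    keep <- which(sizes >= params@dapi_min_area)
    mask <- matrix(as.integer(lab %in% keep & lab > 0), nrow(mask), ncol(mask))
  }
  mask <- .as01(EBImage::dilate(mask, .brush(params@dapi_dilate_radius)))
  mask
}

.as01 <- function(m) {
  m <- (as.matrix(m) > 0.5) + 0L
  storage.mode(m) <- "integer"
  m
}

#' Standardize a GFP image against nucleus-pixel statistics
#'
#' The GFP image is first divided by the dataset-wide maximum intensity,
#' then affinely mapped so that the mean and standard deviation of the
#' pixels inside the nuclei equal the configured reference statistics
#' (\code{gfp_ref_mean}, \code{gfp_ref_sd}; defaults 0.12 and 0.08). This
#' removes image-to-image gain and offset variation, putting the
#' seed-detection thresholds (0.083-0.3) and region-growing stops on a
#' common scale.
#'
#' @param gfp nonnegative GFP intensity matrix.
#' @param nucleus_mask 0/1 matrix from \code{\link{segmentNuclei}}.
#' @param dataset_max maximum GFP intensity across the dataset; if
#'   \code{NULL} (single-image mode) the per-image maximum is used and a
#'   message is emitted.
#' @param params a \linkS4class{SegParams} (for the reference statistics).
#' @return Standardized matrix; on nucleus pixels, mean
#'   \code{gfp_ref_mean} and sd \code{gfp_ref_sd}.
#' @export
standardizeGfp <- function(gfp, nucleus_mask, dataset_max = NULL,
                           params = segParams()) {
  stopifnot(identical(dim(gfp), dim(nucleus_mask)))
  if (sum(nucleus_mask) == 0)
    stop("empty nucleus mask: cannot standardize GFP")
  if (is.null(dataset_max)) {
    dataset_max <- max(gfp)
    message("standardizeGfp: single-image mode, using per-image maximum ",
            signif(dataset_max, 6), " as dataset maximum")
  }
  if (dataset_max <= 0) stop("'dataset_max' must be positive")
  x <- gfp / dataset_max
  nuc <- x[nucleus_mask == 1]
  m <- mean(nuc); s <- stats::sd(nuc)
  if (!is.finite(s) || s == 0)
    stop("zero variance of nucleus pixels: cannot standardize GFP")
  (x - m) / s * params@gfp_ref_sd + params@gfp_ref_mean
}

#' Detect nucleolus seeds by increasing-threshold local-maximum analysis
#'
#' Iterates an increasing ladder of thresholds from \code{t0} to \code{tN}
#' in steps of \code{t_step} (the last step is clamped so the ladder ends
#' exactly at \code{tN}). At each threshold the image is binarized and
#' cleaned by an opening (disc \code{open_radius}) followed by a closing
#' (disc \code{close_radius}). Regions form a genealogy: each region at a
#' higher threshold is a subset of a region at the lower threshold, a
#' region may split into subregions, and a region that would vanish is
#' retained as its last nonempty version. The seed of each final
#' subregion is its intensity maximum (ties broken by smallest (row, col)).
#'
#' @param gfp_std standardized GFP matrix (see \code{\link{standardizeGfp}}).
#' @param params a \linkS4class{SegParams}.
#' @return A \linkS4class{SeedSet}; zero seeds when the whole image lies
#'   below \code{t0}.
#' @export
detectSeeds <- function(gfp_std, params = segParams()) {
  th <- seq(params@t0, params@tN, by = params@t_step)
  if (th[length(th)] < params@tN) th <- c(th, params@tN)
  H <- nrow(gfp_std); W <- ncol(gfp_std)
  regions <- NULL
  history <- vector("list", length(th))
  for (i in seq_along(th)) {
    bin <- (gfp_std >= th[i]) + 0L
    if (any(bin > 0)) {
      bin <- .as01(EBImage::opening(bin, .brush(params@open_radius)))
      bin <- .as01(EBImage::closing(bin, .brush(params@close_radius)))
    }
    lab <- cpp_label8(bin)
    if (is.null(regions)) {
      nlab <- max(lab)
      regions <- if (nlab > 0) split(which(lab > 0), lab[lab > 0]) else list()
      regions <- unname(regions)
    } else {
      nxt <- list()
      for (reg in regions) {
        sub <- lab[reg]
        if (any(sub > 0)) {
          children <- split(reg[sub > 0], sub[sub > 0])
          nxt <- c(nxt, unname(children))
        } else {
          nxt <- c(nxt, list(reg))   # no disappearance: keep frozen
        }
      }
      regions <- nxt
    }
    history[[i]] <- regions
  }
  if (length(regions) == 0)
    return(new("SeedSet",
               seeds = data.frame(row = integer(0), col = integer(0),
                                  intensity = numeric(0)),
               history = history, thresholds = th))
  seeds <- do.call(rbind, lapply(regions, function(reg) {
    vals <- gfp_std[reg]
    mx <- max(vals)
    cand <- reg[vals == mx]
    r <- (cand - 1L) %% H + 1L
    c <- (cand - 1L) %/% H + 1L
    o <- order(r, c)[1]
    data.frame(row = r[o], col = c[o], intensity = mx)
  }))
  new("SeedSet", seeds = seeds, history = history, thresholds = th)
}

#' Grow a region from a seed down to a stopping intensity
#'
#' Region growing implemented as a superlevel-set flood fill: the
#' connected set (8-connectivity) of pixels with intensity >=
#' \code{stop_threshold} that contains the seed, with enclosed holes
#' filled afterwards. This is equivalent to iteratively accreting
#' adjacent pixels until the stopping intensity is reached, but
#' deterministic by construction.
#'
#' @param gfp_std standardized GFP matrix.
#' @param seed c(row, col) of the seed pixel.
#' @param stop_threshold stopping intensity.
#' @return 0/1 integer matrix. If the seed itself lies below the stop
#'   threshold the region is empty and carries attribute
#'   \code{flagged = TRUE}.
#' @export
growRegion <- function(gfp_std, seed, stop_threshold) {
  stopifnot(length(seed) == 2)
  r <- as.integer(seed[1]); c <- as.integer(seed[2])
  if (gfp_std[r, c] < stop_threshold) {
    out <- matrix(0L, nrow(gfp_std), ncol(gfp_std))
    attr(out, "flagged") <- TRUE
    return(out)
  }
  bin <- (gfp_std >= stop_threshold) + 0L
  lab <- cpp_label8(bin)
  out <- (lab == lab[r, c]) + 0L
  storage.mode(out) <- "integer"
  .as01(EBImage::fillHull(out))
}

#' Stopping threshold of the counting region-growing pass
#'
#' The counting pass stops at \code{max(alpha * I_seed, tau)}; the area
#' pass stops at the constant \code{tau}. With the default alpha = 0.85
#' and tau = 0.15 the counting regions hug the bright cores (keeping
#' neighbouring nucleoli apart) while the area regions extend to the
#' fainter shoulders.
#'
#' @param I_seed standardized seed intensity (vectorised).
#' @param params a \linkS4class{SegParams}.
#' @return Stopping threshold(s).
#' @examples
#' countingStop(0.5)          # 0.425
#' countingStop(0.16)         # 0.15 (tau branch)
#' @export
countingStop <- function(I_seed, params = segParams()) {
  pmax(params@alpha * I_seed, params@tau)
}

#' Mitosis screen for a seed
#'
#' Mitotic cells have no well-formed nucleoli: their GFP signal is dim but
#' extended. The screen grows the seed with the permissive stop
#' \code{tau_mitosis} and discards the seed iff the grown region has area
#' > \code{mitosis_min_area} pixels AND maximum intensity <
#' \code{mitosis_max_intensity}; a discarded seed contributes to neither
#' output mask.
#'
#' @param gfp_std standardized GFP matrix.
#' @param seed c(row, col).
#' @param params a \linkS4class{SegParams}.
#' @return \code{"keep"} or \code{"discard"}.
#' @export
mitosisFilter <- function(gfp_std, seed, params = segParams()) {
  reg <- growRegion(gfp_std, seed, params@tau_mitosis)
  area <- sum(reg)
  if (area == 0) return("keep")
  mx <- max(gfp_std[reg == 1])
  if (area > params@mitosis_min_area && mx < params@mitosis_max_intensity)
    "discard" else "keep"
}

#' Segment nucleoli: counting mask and area mask
#'
#' Runs seed detection, screens each seed for mitosis, grows every kept
#' seed twice -- once with the counting stop \code{max(alpha * I_seed,
#' tau)} and once with the area stop \code{tau} -- and multiplies both
#' union masks element-wise by the nucleus mask so that structures outside
#' nuclei are discarded.
#'
#' @param gfp_std standardized GFP matrix.
#' @param nucleus_mask 0/1 matrix from \code{\link{segmentNuclei}}.
#' @param params a \linkS4class{SegParams}.
#' @return A list of class \code{"NucleolusMasks"}: \code{counting} and
#'   \code{area} (0/1 matrices), \code{seeds} (data.frame with row, col,
#'   intensity, stop_counting, kept) and \code{seed_set} (the
#'   \linkS4class{SeedSet}).
#' @export
segmentNucleoli <- function(gfp_std, nucleus_mask, params = segParams()) {
  stopifnot(identical(dim(gfp_std), dim(nucleus_mask)))
  ss <- detectSeeds(gfp_std, params)
  sd_df <- seeds(ss)
  counting <- matrix(0L, nrow(gfp_std), ncol(gfp_std))
  area <- counting
  kept <- logical(nrow(sd_df))
  stops <- countingStop(sd_df$intensity, params)
  for (k in seq_len(nrow(sd_df))) {
    seed <- c(sd_df$row[k], sd_df$col[k])
    if (mitosisFilter(gfp_std, seed, params) == "discard") next
    kept[k] <- TRUE
    counting <- pmax(counting, growRegion(gfp_std, seed, stops[k]))
    area <- pmax(area, growRegion(gfp_std, seed, params@tau))
  }
  counting <- counting * nucleus_mask
  area <- area * nucleus_mask
  storage.mode(counting) <- "integer"; storage.mode(area) <- "integer"
  sd_df$stop_counting <- stops
  sd_df$kept <- kept
  structure(list(counting = counting, area = area, seeds = sd_df,
                 seed_set = ss),
            class = "NucleolusMasks")
}

#' @export
print.NucleolusMasks <- function(x, ...) {
  cat("NucleolusMasks:", sum(x$seeds$kept), "of", nrow(x$seeds),
      "seeds kept;", sum(x$counting), "counting px,", sum(x$area),
      "area px\n")
  invisible(x)
}

# Rasterized convex-hull area of a pixel set (pixel-center-in-polygon,
# boundary inclusive). Degenerate (collinear) sets fall back to the pixel
# count so that solidity stays <= 1.
.hullAreaPx <- function(rows, cols) {
  n <- length(rows)
  if (n <= 2) return(n)
  ch <- grDevices::chull(cols, rows)
  if (length(ch) <= 2) return(n)
  xv <- cols[ch]; yv <- rows[ch]
  gr <- seq(min(rows), max(rows)); gc <- seq(min(cols), max(cols))
  gx <- rep(gc, each = length(gr)); gy <- rep(gr, times = length(gc))
  inp <- pracma::inpolygon(gx, gy, xv, yv, boundary = TRUE)
  max(sum(inp), n)
}

#' Remove clustered and border-touching nuclei
#'
#' Isolated nuclei are convex and roughly elliptical; overlapping nuclei
#' of clustered cells form concave shapes. For each connected nucleus
#' region the solidity (region area / rasterized convex-hull area) is
#' computed; regions with solidity below \code{convexity_min_ratio}
#' (default 0.95), and regions touching any image edge, are removed
#' together with the nucleoli they contain. The operation is idempotent.
#'
#' @param nucleus_mask 0/1 matrix.
#' @param nucleolus_masks a \code{"NucleolusMasks"} list (or NULL to
#'   filter only the nucleus mask).
#' @param params a \linkS4class{SegParams}.
#' @return A list: \code{nucleus_mask}, \code{nucleolus_masks} (filtered),
#'   and \code{removed} (data.frame: label, area, solidity, reason).
#' @export
removeClusteredAndBorder <- function(nucleus_mask, nucleolus_masks = NULL,
                                     params = segParams()) {
  H <- nrow(nucleus_mask); W <- ncol(nucleus_mask)
  lab <- cpp_label8(nucleus_mask)
  removed <- data.frame(label = integer(0), area = integer(0),
                        solidity = numeric(0), reason = character(0))
  nm <- nucleus_mask
  cm <- if (!is.null(nucleolus_masks)) nucleolus_masks$counting else NULL
  am <- if (!is.null(nucleolus_masks)) nucleolus_masks$area else NULL
  for (l in seq_len(max(lab))) {
    idx <- which(lab == l)
    r <- (idx - 1L) %% H + 1L
    c <- (idx - 1L) %/% H + 1L
    border <- any(r == 1L | r == H | c == 1L | c == W)
    sol <- length(idx) / .hullAreaPx(r, c)
    if (border || sol < params@convexity_min_ratio) {
      nm[idx] <- 0L
      if (!is.null(cm)) { cm[idx] <- 0L; am[idx] <- 0L }
      removed <- rbind(removed, data.frame(
        label = l, area = length(idx), solidity = sol,
        reason = if (border) "border" else "clustered"))
    }
  }
  if (!is.null(nucleolus_masks)) {
    nucleolus_masks$counting <- cm
    nucleolus_masks$area <- am
  }
  list(nucleus_mask = nm, nucleolus_masks = nucleolus_masks,
       removed = removed)
}
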