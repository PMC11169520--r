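#' Generate a random ground-truthed scene
#'
#' Draws a scene of non-overlapping elliptical interphase nuclei, each
#' holding one or more nucleoli, plus optional mitotic cells (large, dim
#' GFP over condensed DAPI), optional border-truncated nuclei and optional
#' overlapping (clustered) nucleus pairs. Geometry and photometry defaults
#' emulate fibrillarin-GFP HeLa fields at 0.151 um/pixel rendered at a
#' reduced frame size: nuclei with semi-axes 38-55 px, 1-4 nucleoli per
#' nucleus with half-maximum radii 5-10 px, and a phase channel at 1/4 of
#' the fluorescence resolution.
#'
#' @param n_nuclei number of interphase nuclei.
#' @param dims c(rows, cols) of the fluorescence frame.
#' @param phase_scale integer phase-channel downsampling factor.
#' @param nucleoli_range integer range of nucleoli per nucleus.
#' @param radius_range nucleolus half-maximum radius range (px).
#' @param gfp_peak_range raw GFP peak range of nucleolar bumps.
#' @param phase_plateau_range nucleolar phase plateau range (radians).
#' @param n_mitotic number of mitotic cells.
#' @param n_border number of border-truncated nuclei (in addition to
#'   \code{n_nuclei}).
#' @param n_cluster_pairs number of overlapping nucleus pairs (each adds
#'   two nuclei).
#' @param noise_sigma additive Gaussian noise sd (per channel).
#' @param nucleus_semi_range nucleus semi-axis range (px).
#' @param seed RNG seed; identical seeds give bit-identical scenes.
#' @return A \linkS4class{SyntheticScene}.
#' @examples
#' sc <- randomScene(n_nuclei = 2, seed = 1)
#' sc
#' @export
randomScene <- function(n_nuclei = 5, dims = c(512, 512), phase_scale = 4,
                        nucleoli_range = c(1, 4), radius_range = c(5, 10),
                        gfp_peak_range = c(0.5, 0.9),
                        phase_plateau_range = c(0.8, 1.2),
                        n_mitotic = 0, n_border = 0, n_cluster_pairs = 0,
                        noise_sigma = 0, nucleus_semi_range = c(38, 55),
                        seed = 1) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  semi_lo <- nucleus_semi_range[1]; semi_hi <- nucleus_semi_range[2]
  margin <- semi_hi + 8
  centers <- matrix(numeric(0), ncol = 2)
  nuclei <- data.frame()
  place <- function(row, col, a, b, theta, level) {
    rbind(nuclei, data.frame(row = row, col = col, a = a, b = b,
                             theta = theta, dapi_level = level))
  }
  draw_interior <- function() {
    for (try in 1:400) {
      r <- stats::runif(1, min(margin, dims[1] - margin),
                        max(margin, dims[1] - margin))
      c <- stats::runif(1, min(margin, dims[2] - margin),
                        max(margin, dims[2] - margin))
      if (nrow(centers) == 0 ||
          all(sqrt((centers[, 1] - r)^2 + (centers[, 2] - c)^2) >
              2 * semi_hi + 12))
        return(c(r, c))
    }
    stop("could not place nucleus; frame too crowded")
  }
  for (k in seq_len(n_nuclei)) {
    rc <- draw_interior()
    centers <- rbind(centers, rc)
    nuclei <- place(rc[1], rc[2], stats::runif(1, semi_lo, semi_hi),
                    stats::runif(1, semi_lo, semi_hi),
                    stats::runif(1, 0, pi), stats::runif(1, 0.65, 0.85))
  }
  for (k in seq_len(n_border)) {
    side <- sample(4, 1)
    a <- stats::runif(1, semi_lo, semi_hi); b <- stats::runif(1, semi_lo, semi_hi)
    dd <- dims[side %% 2 + 1]
    pos <- stats::runif(1, min(margin, dd - margin), max(margin, dd - margin))
    rc <- switch(side, c(1 + a * 0.3, pos), c(dims[1] - a * 0.3, pos),
                 c(pos, 1 + b * 0.3), c(pos, dims[2] - b * 0.3))
    centers <- rbind(centers, rc)
    nuclei <- place(rc[1], rc[2], a, b, 0, stats::runif(1, 0.65, 0.85))
  }
  for (k in seq_len(n_cluster_pairs)) {
    rc <- draw_interior()
    centers <- rbind(centers, rc)
    a <- stats::runif(1, semi_lo, semi_hi)
    # overlapping but clearly dumbbell-shaped: union solidity ~0.92 < 0.95
    off <- a * 1.75
    ang <- stats::runif(1, 0, 2 * pi)
    rc2 <- rc + off * c(cos(ang), sin(ang))
    centers <- rbind(centers, rc2)
    lvl <- stats::runif(1, 0.65, 0.85)
    nuclei <- place(rc[1], rc[2], a, a, 0, lvl)
    nuclei <- place(rc2[1], rc2[2], a, a, 0, lvl)
  }
  nucleoli <- data.frame()
  for (k in seq_len(nrow(nuclei))) {
    nn <- sample(seq(nucleoli_range[1], nucleoli_range[2]), 1)
    placed <- matrix(numeric(0), ncol = 3)   # row, col, radius
    p <- nuclei[k, ]
    for (m in seq_len(nn)) {
      R <- stats::runif(1, radius_range[1], radius_range[2])
      ok <- FALSE
      for (try in 1:300) {
        u <- stats::runif(1, -0.68, 0.68) * p$a
        v <- stats::runif(1, -0.68, 0.68) * p$b
        r <- p$row + u * cos(p$theta) - v * sin(p$theta)
        c <- p$col + u * sin(p$theta) + v * cos(p$theta)
        # well-separated: shoulders (1.1 R) must not touch, plus clearance
        sep <- nrow(placed) == 0 ||
          all(sqrt((placed[, 1] - r)^2 + (placed[, 2] - c)^2) >
              1.1 * (placed[, 3] + R) + 6)
        inside <- r > 2 && r < dims[1] - 1 && c > 2 && c < dims[2] - 1
        if (sep && inside) { ok <- TRUE; break }
      }
      if (!ok) next   # skip an unplaceable nucleolus; truth follows
      placed <- rbind(placed, c(r, c, R))
      nucleoli <- rbind(nucleoli, data.frame(
        parent = k, row = r, col = c, radius = R,
        gfp_peak = stats::runif(1, gfp_peak_range[1], gfp_peak_range[2]),
        phase_plateau = stats::runif(1, phase_plateau_range[1],
                                     phase_plateau_range[2])))
    }
  }
  mitotic <- data.frame()
  for (k in seq_len(n_mitotic)) {
    rc <- draw_interior()
    centers <- rbind(centers, rc)
    mitotic <- rbind(mitotic, data.frame(
      row = rc[1], col = rc[2], radius = stats::runif(1, 26, 34),
      gfp_level = 0.2, dapi_level = 0.9))
  }
  new("SyntheticScene", dims = dims, phase_scale = phase_scale,
      nuclei = nuclei, nucleoli = nucleoli, mitotic = mitotic,
      noise_sigma = noise_sigma,
      background = c(dapi = 0.08, dapi_nucleus = 0.75, gfp = 0.01,
                     gfp_nucleoplasm = 0.05, phase = 0,
                     phase_nucleoplasm = 0.4, dapi_ring = 0),
      seed = seed)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Evaluate the raised-cosine radial profile: 1 on [0, 0.9R], cosine
# shoulder to 0 at 1.1R. The half-maximum radius is exactly R.
.bump_profile <- function(r, R) {
  p <- r * 0   # preserves matrix shape when r is a matrix
  core <- r <= 0.9 * R
  sh <- r > 0.9 * R & r < 1.1 * R
  p[core] <- 1
  p[sh] <- 0.5 * (1 + cos(pi * (r[sh] - 0.9 * R) / (0.2 * R)))
  p
}

# Squared normalized elliptical radius (0 at center, 1 on the boundary).
.ellipse_rho2 <- function(rows, cols, p) {
  dr <- outer(rows - p$row, rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - p$col)
  u <- dr * cos(p$theta) + dc * sin(p$theta)
  v <- -dr * sin(p$theta) + dc * cos(p$theta)
  (u / p$a)^2 + (v / p$b)^2
}

.inside_ellipse <- function(rows, cols, p) {
  .ellipse_rho2(rows, cols, p) <= 1
}

#' Render a synthetic correlative triplet with ground truth
#'
#' Renders the DAPI, GFP and phase channels of a scene plus the noise-free
#' ground truth: DAPI is a background level with brighter nucleus ellipses
#' (bimodal histogram), GFP is a dim nucleoplasm with raised-cosine
#' nucleolar bumps reaching \code{gfp_peak}, and phase is a nucleoplasm
#' plateau with hard nucleolar plateaus at \code{phase_plateau}, rendered
#' at 1/\code{phase_scale} of the fluorescence resolution. Gaussian noise
#' of sd \code{noise_sigma} is then added per channel (clamped at zero for
#' the fluorescence channels).
#'
#' @param scene a \linkS4class{SyntheticScene}.
#' @param optics an \linkS4class{OpticsConfig} attached to the triplet.
#' @return A list with elements \code{triplet}
#'   (\linkS4class{ImageTriplet}), \code{nucleus_mask} (0/1 matrix over
#'   interphase nuclei), \code{nucleolus_labels} (integer matrix labelling
#'   each nucleolar disc of radius R), \code{truth} (data.frame: cell,
#'   count, area_px = ground-truth disc support per cell) and
#'   \code{nucleolus_truth} (data.frame: per-nucleolus center, radius,
#'   plateau).
#' @export
generateTriplet <- function(scene, optics = opticsConfig()) {
  validObject(scene)
  H <- scene@dims[1]; W <- scene@dims[2]
  bg <- scene@background
  dapi <- matrix(bg["dapi"], H, W)
  gfp <- matrix(bg["gfp"], H, W)
  nucleus_mask <- matrix(0L, H, W)
  nuclei <- scene@nuclei
  for (k in seq_len(nrow(nuclei))) {
    p <- nuclei[k, ]
    r0 <- max(1, floor(p$row - max(p$a, p$b))); r1 <- min(H, ceiling(p$row + max(p$a, p$b)))
    c0 <- max(1, floor(p$col - max(p$a, p$b))); c1 <- min(W, ceiling(p$col + max(p$a, p$b)))
    if (r0 > r1 || c0 > c1) next
    rho2 <- .ellipse_rho2(r0:r1, c0:c1, p)
    ins <- rho2 <= 1
    # quadratic chromatin falloff: per-nucleus intensities spread
    # continuously over [0.7, 1] x dapi_level, so the pooled nucleus
    # histogram forms one broad mode rather than per-nucleus spikes
    dapi[r0:r1, c0:c1][ins] <- p$dapi_level * (1 - 0.3 * rho2[ins])
    gfp[r0:r1, c0:c1][ins] <- bg["gfp_nucleoplasm"]
    nucleus_mask[r0:r1, c0:c1][ins] <- 1L
  }
  nl <- scene@nucleoli
  nucleolus_labels <- matrix(0L, H, W)
  area_px <- integer(nrow(nuclei))
  for (k in seq_len(nrow(nl))) {
    q <- nl[k, ]
    Rout <- 1.1 * q$radius
    r0 <- max(1, floor(q$row - Rout)); r1 <- min(H, ceiling(q$row + Rout))
    c0 <- max(1, floor(q$col - Rout)); c1 <- min(W, ceiling(q$col + Rout))
    dr <- outer((r0:r1) - q$row, rep(1, c1 - c0 + 1))
    dc <- outer(rep(1, r1 - r0 + 1), (c0:c1) - q$col)
    rr <- sqrt(dr^2 + dc^2)
    p <- .bump_profile(rr, q$radius)
    blk <- gfp[r0:r1, c0:c1]
    val <- bg["gfp_nucleoplasm"] + (q$gfp_peak - bg["gfp_nucleoplasm"]) * p
    gfp[r0:r1, c0:c1] <- pmax(blk, val)
    supp <- rr < 1.1 * q$radius   # support of the rendered bump
    lbl <- nucleolus_labels[r0:r1, c0:c1]
    lbl[supp] <- k
    nucleolus_labels[r0:r1, c0:c1] <- lbl
    area_px[q$parent] <- area_px[q$parent] + sum(supp)
    if (bg["dapi_ring"] > 0) {
      ring <- rr > q$radius & rr <= 1.25 * q$radius
      dblk <- dapi[r0:r1, c0:c1]
      dblk[ring] <- pmin(1, dblk[ring] * (1 + bg["dapi_ring"]))
      dapi[r0:r1, c0:c1] <- dblk
    }
  }
  mt <- scene@mitotic
  for (k in seq_len(nrow(mt))) {
    q <- mt[k, ]
    r0 <- max(1, floor(q$row - q$radius)); r1 <- min(H, ceiling(q$row + q$radius))
    c0 <- max(1, floor(q$col - q$radius)); c1 <- min(W, ceiling(q$col + q$radius))
    dr <- outer((r0:r1) - q$row, rep(1, c1 - c0 + 1))
    dc <- outer(rep(1, r1 - r0 + 1), (c0:c1) - q$col)
    rho2 <- (dr^2 + dc^2) / q$radius^2
    ins <- rho2 <= 1
    dapi[r0:r1, c0:c1][ins] <- q$dapi_level * (1 - 0.3 * rho2[ins])
    gfp[r0:r1, c0:c1][ins] <- pmax(gfp[r0:r1, c0:c1][ins], q$gfp_level)
  }
  # phase at reduced resolution, evaluated at block centers
  s <- scene@phase_scale
  ph <- floor(H / s); pw <- floor(W / s)
  prow <- (seq_len(ph) - 1) * s + (s + 1) / 2
  pcol <- (seq_len(pw) - 1) * s + (s + 1) / 2
  phase <- matrix(bg["phase"], ph, pw)
  for (k in seq_len(nrow(nuclei))) {
    p <- nuclei[k, ]
    ins <- .inside_ellipse(prow, pcol, p)
    phase[ins] <- bg["phase_nucleoplasm"]
  }
  for (k in seq_len(nrow(mt))) {
    q <- mt[k, ]
    dr <- outer(prow - q$row, rep(1, pw))
    dc <- outer(rep(1, ph), pcol - q$col)
    phase[sqrt(dr^2 + dc^2) <= q$radius] <- bg["phase_nucleoplasm"]
  }
  for (k in seq_len(nrow(nl))) {
    q <- nl[k, ]
    dr <- outer(prow - q$row, rep(1, pw))
    dc <- outer(rep(1, ph), pcol - q$col)
    phase[sqrt(dr^2 + dc^2) <= q$radius] <- q$phase_plateau
  }
  if (scene@noise_sigma > 0) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(as.integer(scene@seed) + 104729L)
    dapi <- pmax(dapi + matrix(stats::rnorm(H * W, 0, scene@noise_sigma), H, W), 0)
    gfp <- pmax(gfp + matrix(stats::rnorm(H * W, 0, scene@noise_sigma), H, W), 0)
    phase <- phase + matrix(stats::rnorm(ph * pw, 0, scene@noise_sigma), ph, pw)
  }
  counts <- if (nrow(nl) > 0) as.integer(tabulate(nl$parent, nrow(nuclei)))
            else integer(nrow(nuclei))
  truth <- data.frame(cell = seq_len(nrow(nuclei)),
                      count = counts, area_px = area_px)
  list(
    triplet = imageTriplet(dapi, gfp, phase, optics,
                           id = paste0("synthetic-seed", scene@seed)),
    nucleus_mask = nucleus_mask,
    nucleolus_labels = nucleolus_labels,
    truth = truth,
    nucleolus_truth = nl
  )
}

#' Match scene nuclei to labelled mask regions
#'
#' Maps each nucleus of a scene to the connected-region label of a
#' segmented (or ground-truth) nucleus mask by looking up the label at
#' the nucleus center. Nuclei whose center falls on background (missed
#' nuclei) map to NA.
#'
#' @param nucleus_mask 0/1 matrix.
#' @param scene the \linkS4class{SyntheticScene} that generated it.
#' @return Integer vector, one label (or NA) per scene nucleus.
#' @export
matchSceneNuclei <- function(nucleus_mask, scene) {
  lab <- cpp_label8(nucleus_mask)
  vapply(seq_len(nrow(scene@nuclei)), function(k) {
    r <- round(scene@nuclei$row[k]); c <- round(scene@nuclei$col[k])
    if (r < 1 || r > nrow(lab) || c < 1 || c > ncol(lab))
      return(NA_integer_)
    l <- lab[r, c]
    if (l == 0) NA_integer_ else l
  }, integer(1))
}

#' Projected-area ratio of N equal-volume spheres
#'
#' If a fixed volume V is split into N identical spheres, each has radius
#' proportional to (V/N)^(1/3), so the summed projected (disc) area is
#' proportional to N * (V/N)^(2/3) = V^(2/3) * N^(1/3). The ratio of the
#' summed projected area of N spheres to that of the single sphere of
#' volume V is therefore N^(1/3) -- the reason the mean nucleolar area per
#' cell grows only slowly with the number of nucleoli if they arise by
#' splitting a conserved volume.
#'
#' @param n_spheres integer >= 1 (vectorised).
#' @return N^(1/3), dimensionless.
#' @examples
#' sphereProjectionRatio(8)  # 2
#' @export
sphereProjectionRatio <- function(n_spheres) {
  if (any(n_spheres < 1) || any(n_spheres != round(n_spheres)))
    stop("'n_spheres' must be an integer >= 1")
  n_spheres^(1 / 3)
}
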