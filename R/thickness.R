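#' Convert phase shift to optical path length
#'
#' OPL (nm) = phase (radians) * lambda (nm) / (2 * pi), elementwise. The
#' optical path length at a pixel is the physical thickness of the object
#' times its refractive-index contrast against the medium.
#'
#' @param phase_rad numeric matrix or vector of phase shifts (radians).
#' @param wavelength_nm illumination wavelength (nm).
#' @return OPL in nm, same shape as the input.
#' @examples
#' phaseToOpl(2 * pi, 550)  # 550
#' @export
phaseToOpl <- function(phase_rad, wavelength_nm) {
  if (!is.numeric(wavelength_nm) || wavelength_nm <= 0)
    stop("'wavelength_nm' must be positive")
  stopifnot(all(is.finite(phase_rad)))
  phase_rad * wavelength_nm / (2 * pi)
}

# The n pixels nearest a center in Euclidean distance, ties broken by
# (row, col). Errors when the disc would be clipped by the image boundary.
.discPixels <- function(center, n, dims) {
  r0 <- center[1]; c0 <- center[2]
  rad <- ceiling(sqrt(n / pi)) + 2L
  dr <- rep(-rad:rad, times = 2L * rad + 1L)
  dc <- rep(-rad:rad, each = 2L * rad + 1L)
  rr <- round(r0) + dr; cc <- round(c0) + dc
  d2 <- (rr - r0)^2 + (cc - c0)^2
  o <- order(d2, rr, cc)[seq_len(n)]
  rr <- rr[o]; cc <- cc[o]
  if (any(rr < 1 | rr > dims[1] | cc < 1 | cc > dims[2]))
    stop("sampling disc clipped by the image boundary")
  cbind(rr, cc)
}

#' Nucleolar optical-thickness index
#'
#' The index is the mean OPL over a disc of \code{disc_area_px} pixels
#' (default 12) centered on the nucleolus minus the mean OPL over an
#' equal-sized background disc. The nucleolus center defaults to the pixel
#' of highest phase within the supplied nucleolus mask (the brightest spot
#' is the nucleolar center in a phase image). Adding a constant to the
#' whole phase image leaves the index unchanged; scaling the phase scales
#' the index.
#'
#' @param phase_img phase matrix (radians).
#' @param nucleolus_center c(row, col), or NULL to locate it from
#'   \code{nucleolus_mask}.
#' @param background_center c(row, col) of the background disc (adjacent
#'   nucleoplasm by default convention; see \code{\link{cytoplasmIndex}}
#'   for the cell-free variant).
#' @param params a \linkS4class{ThicknessParams}.
#' @param optics an \linkS4class{OpticsConfig} (wavelength).
#' @param nucleolus_mask optional 0/1 matrix used to auto-locate the
#'   center.
#' @return A list: \code{opl_nucleolus}, \code{opl_background},
#'   \code{index} (all nm), \code{center}, \code{background_center}.
#' @export
thicknessIndex <- function(phase_img, nucleolus_center = NULL,
                           background_center, params = thicknessParams(),
                           optics = opticsConfig(), nucleolus_mask = NULL) {
  validObject(params)
  if (is.null(nucleolus_center)) {
    if (is.null(nucleolus_mask))
      stop("supply 'nucleolus_center' or 'nucleolus_mask'")
    idx <- which(nucleolus_mask == 1)
    if (length(idx) == 0) stop("empty nucleolus mask")
    vals <- phase_img[idx]
    best <- idx[which.max(vals)]
    nucleolus_center <- c((best - 1L) %% nrow(phase_img) + 1L,
                          (best - 1L) %/% nrow(phase_img) + 1L)
  }
  opl <- phaseToOpl(phase_img, wavelengthNm(optics))
  dn <- .discPixels(nucleolus_center, params@disc_area_px, dim(phase_img))
  db <- .discPixels(background_center, params@disc_area_px, dim(phase_img))
  on <- mean(opl[dn])
  ob <- mean(opl[db])
  list(opl_nucleolus = on, opl_background = ob, index = on - ob,
       center = as.numeric(nucleolus_center),
       background_center = as.numeric(background_center))
}

#' Place the nucleoplasm background disc for a nucleolus
#'
#' Chooses the background disc center for the "nucleoplasm" mode: the
#' pixel inside the nucleus, outside every nucleolar area region (with a
#' small safety margin), nearest to the nucleolus center (ties by
#' (row, col)).
#'
#' @param nucleolus_center c(row, col).
#' @param nucleus_mask,area_mask aligned 0/1 matrices at phase resolution.
#' @param margin_px pixels of clearance from the area mask.
#' @return c(row, col).
#' @export
nucleoplasmBackgroundCenter <- function(nucleolus_center, nucleus_mask,
                                        area_mask, margin_px = 2) {
  excl <- area_mask
  if (margin_px > 0)
    excl <- .as01(EBImage::dilate(excl, .brush(margin_px)))
  cand <- which(nucleus_mask == 1 & excl == 0)
  if (length(cand) == 0) stop("no nucleoplasm pixel available")
  H <- nrow(nucleus_mask)
  r <- (cand - 1L) %% H + 1L
  c <- (cand - 1L) %/% H + 1L
  d2 <- (r - nucleolus_center[1])^2 + (c - nucleolus_center[2])^2
  o <- order(d2, r, c)[1]
  c(r[o], c[o])
}

#' Cytoplasmic optical-thickness index
#'
#' Mean OPL over a disc of \code{disc_area_px} pixels placed in the
#' cytoplasm at approximately \code{cytoplasm_offset_um} from the nucleus
#' boundary, minus the mean OPL over an equal disc at a cell-free
#' position.
#'
#' @param phase_img phase matrix (radians), aligned with
#'   \code{nucleus_mask}.
#' @param nucleus_mask 0/1 matrix.
#' @param cellfree_center c(row, col) of the cell-free reference disc.
#' @param params a \linkS4class{ThicknessParams}.
#' @param optics an \linkS4class{OpticsConfig} (wavelength and pixel
#'   size; the offset in um is converted to pixels with
#'   \code{\link{pixelSizeUm}}).
#' @return As \code{\link{thicknessIndex}}, with \code{center} the chosen
#'   cytoplasmic position.
#' @export
cytoplasmIndex <- function(phase_img, nucleus_mask, cellfree_center,
                           params = thicknessParams(),
                           optics = opticsConfig()) {
  stopifnot(identical(dim(phase_img), dim(nucleus_mask)))
  if (sum(nucleus_mask) == 0) stop("empty nucleus mask")
  offset_px <- params@cytoplasm_offset_um / pixelSizeUm(optics)
  d <- EBImage::distmap(1 - nucleus_mask)
  d <- as.matrix(d)
  cand <- which(nucleus_mask == 0 & d > 0)
  if (length(cand) == 0) stop("no cytoplasmic placement available")
  H <- nrow(phase_img)
  r <- (cand - 1L) %% H + 1L
  c <- (cand - 1L) %/% H + 1L
  score <- abs(d[cand] - offset_px)
  o <- order(score, r, c)[1]
  center <- c(r[o], c[o])
  opl <- phaseToOpl(phase_img, wavelengthNm(optics))
  dc_ <- .discPixels(center, params@disc_area_px, dim(phase_img))
  df_ <- .discPixels(cellfree_center, params@disc_area_px, dim(phase_img))
  oc <- mean(opl[dc_]); of <- mean(opl[df_])
  list(opl_nucleolus = oc, opl_background = of, index = oc - of,
       center = as.numeric(center),
       background_center = as.numeric(cellfree_center))
}
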