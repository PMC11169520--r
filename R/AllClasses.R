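#' @useDynLib nucleoDHM, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Optics and calibration configuration
#'
#' Holds the optical parameters needed to convert camera pixels to physical
#' size and phase shift to optical path length: camera pixel edge (um),
#' binning factor, objective / lens / C-mount magnifications and the
#' illumination wavelength (nm).
#'
#' @slot camera_pixel_um physical camera pixel edge in micrometres.
#' @slot binning integer binning factor (>= 1).
#' @slot objective_mag objective magnification.
#' @slot lens_mag lens magnification.
#' @slot c_mount C-mount magnification.
#' @slot wavelength_nm illumination wavelength in nanometres (300-1000).
#' @export
setClass("OpticsConfig",
  representation(
    camera_pixel_um = "numeric",
    binning = "numeric",
    objective_mag = "numeric",
    lens_mag = "numeric",
    c_mount = "numeric",
    wavelength_nm = "numeric"
  ),
  prototype(
    camera_pixel_um = 4.54, binning = 1, objective_mag = 20,
    lens_mag = 1.5, c_mount = 1, wavelength_nm = 550
  )
)

setValidity("OpticsConfig", function(object) {
  v <- c(object@camera_pixel_um, object@binning, object@objective_mag,
         object@lens_mag, object@c_mount, object@wavelength_nm)
  if (any(!is.finite(v)) || any(v <= 0))
    return("all optics fields must be finite and strictly positive")
  if (object@binning != round(object@binning) || object@binning < 1)
    return("'binning' must be an integer >= 1")
  if (object@wavelength_nm < 300 || object@wavelength_nm > 1000)
    return("'wavelength_nm' must lie in [300, 1000]")
  TRUE
})

#' Construct an OpticsConfig
#'
#' Defaults correspond to a Retiga R3 camera (4.54 um pixels, binning 1)
#' behind a 20x objective with a 1.5x lens and 1x C-mount, illuminated at
#' 550 nm.
#'
#' @param camera_pixel_um camera pixel edge (um).
#' @param binning integer binning factor.
#' @param objective_mag objective magnification.
#' @param lens_mag lens magnification.
#' @param c_mount C-mount magnification.
#' @param wavelength_nm illumination wavelength (nm).
#' @return An \linkS4class{OpticsConfig} object.
#' @examples
#' oc <- opticsConfig()
#' pixelSizeUm(oc)
#' @export
opticsConfig <- function(camera_pixel_um = 4.54, binning = 1,
                         objective_mag = 20, lens_mag = 1.5, c_mount = 1,
                         wavelength_nm = 550) {
  new("OpticsConfig", camera_pixel_um = camera_pixel_um, binning = binning,
      objective_mag = objective_mag, lens_mag = lens_mag, c_mount = c_mount,
      wavelength_nm = wavelength_nm)
}

#' @describeIn opticsConfig illumination wavelength accessor (nm).
#' @param object an \code{OpticsConfig}.
#' @export
wavelengthNm <- function(object) object@wavelength_nm

setMethod("show", "OpticsConfig", function(object) {
  cat("OpticsConfig:", object@camera_pixel_um, "um px, binning",
      object@binning, ", mags", object@objective_mag, "x",
      object@lens_mag, "x", object@c_mount,
      ", lambda", object@wavelength_nm, "nm\n")
  cat("  image pixel size:", signif(pixelSizeUm(object), 5), "um/pixel\n")
})

#' Aligned DAPI / GFP / phase image triplet
#'
#' One field of view of correlative DHM-fluorescence microscopy: a DAPI
#' image (DNA-rich nucleoplasm), a GFP image (nucleolar marker such as
#' fibrillarin) and a DHM phase image in radians. DAPI and GFP share
#' dimensions; the phase image may be coarser (to be spline-upsampled).
#'
#' @slot dapi nonnegative intensity matrix.
#' @slot gfp nonnegative intensity matrix, same dimensions as \code{dapi}.
#' @slot phase phase-shift matrix in radians (any finite sign).
#' @slot optics an \linkS4class{OpticsConfig}.
#' @slot id free-text identifier.
#' @export
setClass("ImageTriplet",
  representation(
    dapi = "matrix", gfp = "matrix", phase = "matrix",
    optics = "OpticsConfig", id = "character"
  )
)

setValidity("ImageTriplet", function(object) {
  if (!identical(dim(object@dapi), dim(object@gfp)))
    return("'dapi' and 'gfp' must have identical dimensions")
  if (any(!is.finite(object@dapi)) || any(!is.finite(object@gfp)) ||
      any(!is.finite(object@phase)))
    return("all image grids must be finite")
  if (any(object@dapi < 0) || any(object@gfp < 0))
    return("fluorescence intensities must be nonnegative")
  TRUE
})

#' Construct an ImageTriplet
#'
#' @param dapi,gfp nonnegative intensity matrices of identical dimensions.
#' @param phase phase-shift matrix (radians); dimensions may differ.
#' @param optics an \linkS4class{OpticsConfig}.
#' @param id free-text identifier.
#' @return An \linkS4class{ImageTriplet}.
#' @export
imageTriplet <- function(dapi, gfp, phase, optics = opticsConfig(),
                         id = "triplet") {
  new("ImageTriplet", dapi = dapi, gfp = gfp, phase = phase,
      optics = optics, id = id)
}

#' @rdname imageTriplet
#' @param object an \code{ImageTriplet}.
#' @export
dapi <- function(object) object@dapi
#' @rdname imageTriplet
#' @export
gfp <- function(object) object@gfp
#' @rdname imageTriplet
#' @export
phase <- function(object) object@phase
#' @rdname imageTriplet
#' @export
optics <- function(object) object@optics

setMethod("show", "ImageTriplet", function(object) {
  cat("ImageTriplet '", object@id, "': fluorescence ",
      nrow(object@dapi), "x", ncol(object@dapi), ", phase ",
      nrow(object@phase), "x", ncol(object@phase), "\n", sep = "")
})

#' Tuned constants of the fluorescence segmentation pipeline
#'
#' Every constant of the nucleus and nucleolus segmentation, with defaults
#' tuned for fibrillarin-GFP / DAPI images: Gaussian sigma 3 px and 2000 px
#' minimum region for nuclei; threshold ladder 0.083 to 0.3 in steps of
#' 0.025 for seed detection; region-growing stops max(alpha * I_seed, tau)
#' with alpha = 0.85, tau = 0.15; mitosis screen at tau_mitosis = 0.11
#' (area > 1000 px and max intensity < 0.25); solidity cutoff 0.95 for
#' clustered nuclei.
#'
#' @slot dapi_gauss_sigma Gaussian smoothing sigma for DAPI (px).
#' @slot dapi_close_radius disc radius of the closing after thresholding.
#' @slot dapi_min_area minimum nucleus region area (px).
#' @slot dapi_dilate_radius disc radius of the final dilation.
#' @slot t0,tN,t_step seed-detection threshold ladder (standardized scale).
#' @slot open_radius,close_radius per-threshold morphology disc radii.
#' @slot alpha,tau counting/area region-growing stop parameters.
#' @slot tau_mitosis stop threshold of the mitosis screen.
#' @slot mitosis_min_area,mitosis_max_intensity mitosis discard rule.
#' @slot convexity_min_ratio solidity cutoff for clustered-nucleus removal.
#' @slot gfp_ref_mean,gfp_ref_sd reference nucleus-pixel statistics that
#'   GFP standardization maps onto (see \code{\link{standardizeGfp}}).
#' @export
setClass("SegParams",
  representation(
    dapi_gauss_sigma = "numeric", dapi_close_radius = "numeric",
    dapi_min_area = "numeric", dapi_dilate_radius = "numeric",
    t0 = "numeric", tN = "numeric", t_step = "numeric",
    open_radius = "numeric", close_radius = "numeric",
    alpha = "numeric", tau = "numeric", tau_mitosis = "numeric",
    mitosis_min_area = "numeric", mitosis_max_intensity = "numeric",
    convexity_min_ratio = "numeric",
    gfp_ref_mean = "numeric", gfp_ref_sd = "numeric"
  ),
  prototype(
    dapi_gauss_sigma = 3, dapi_close_radius = 3, dapi_min_area = 2000,
    dapi_dilate_radius = 2, t0 = 0.083, tN = 0.3, t_step = 0.025,
    open_radius = 2, close_radius = 3, alpha = 0.85, tau = 0.15,
    tau_mitosis = 0.11, mitosis_min_area = 1000,
    mitosis_max_intensity = 0.25, convexity_min_ratio = 0.95,
    gfp_ref_mean = 0.12, gfp_ref_sd = 0.08
  )
)

setValidity("SegParams", function(object) {
  if (!(object@t0 > 0 && object@t0 < object@tN && object@tN <= 1))
    return("need 0 < t0 < tN <= 1")
  if (object@t_step <= 0) return("'t_step' must be positive")
  if (!(object@alpha > 0 && object@alpha <= 1))
    return("'alpha' must lie in (0, 1]")
  if (object@tau < object@t0) return("'tau' must be >= t0")
  radii <- c(object@dapi_close_radius, object@dapi_dilate_radius,
             object@open_radius, object@close_radius)
  if (any(radii <= 0) || any(radii != round(radii)))
    return("morphology radii must be positive integers")
  if (object@dapi_min_area <= 0 || object@mitosis_min_area <= 0)
    return("area parameters must be positive")
  if (object@gfp_ref_sd <= 0) return("'gfp_ref_sd' must be positive")
  TRUE
})

#' Construct segmentation parameters
#'
#' @param ... named values overriding the defaults documented in
#'   \linkS4class{SegParams}.
#' @return A \linkS4class{SegParams} object.
#' @examples
#' p <- segParams(alpha = 0.9)
#' p@alpha
#' @export
segParams <- function(...) new("SegParams", ...)

setMethod("show", "SegParams", function(object) {
  cat("SegParams: thresholds", object@t0, "..", object@tN, "step",
      object@t_step, "| alpha", object@alpha, "tau", object@tau,
      "tau_mitosis", object@tau_mitosis, "\n")
  cat("  nuclei: sigma", object@dapi_gauss_sigma, ", min area",
      object@dapi_min_area, "px, solidity >=", object@convexity_min_ratio,
      "\n")
})

#' Seeds and threshold genealogy from local-maximum detection
#'
#' @slot seeds data.frame with columns \code{row}, \code{col},
#'   \code{intensity} (the standardized seed intensity I_seed), one row per
#'   final subregion.
#' @slot history list, one element per threshold, each a list of integer
#'   vectors of pixel linear indices (the region partition at that
#'   threshold).
#' @slot thresholds numeric vector of thresholds actually used.
#' @export
setClass("SeedSet",
  representation(seeds = "data.frame", history = "list",
                 thresholds = "numeric")
)

setMethod("show", "SeedSet", function(object) {
  cat("SeedSet:", nrow(object@seeds), "seeds over",
      length(object@thresholds), "thresholds [",
      object@thresholds[1], "..",
      object@thresholds[length(object@thresholds)], "]\n")
})

#' @rdname detectSeeds
#' @param object a \code{SeedSet}.
#' @export
seeds <- function(object) object@seeds

#' Parameters of the optical-thickness index
#'
#' @slot disc_area_px number of pixels of the sampling disc (default 12,
#'   the pixels nearest the chosen center).
#' @slot background_mode "nucleoplasm" (reference disc inside the same
#'   nucleus, outside nucleoli) or "extranuclear" (outside the nucleus).
#' @slot cytoplasm_offset_um distance from the nucleus boundary at which
#'   the cytoplasmic disc is placed (um).
#' @export
setClass("ThicknessParams",
  representation(disc_area_px = "numeric", background_mode = "character",
                 cytoplasm_offset_um = "numeric"),
  prototype(disc_area_px = 12, background_mode = "nucleoplasm",
            cytoplasm_offset_um = 5)
)

setValidity("ThicknessParams", function(object) {
  if (object@disc_area_px < 1) return("'disc_area_px' must be >= 1")
  if (!object@background_mode %in% c("nucleoplasm", "extranuclear"))
    return("'background_mode' must be 'nucleoplasm' or 'extranuclear'")
  if (object@cytoplasm_offset_um <= 0)
    return("'cytoplasm_offset_um' must be positive")
  TRUE
})

#' Construct thickness-index parameters
#' @param ... named values overriding \linkS4class{ThicknessParams} defaults.
#' @export
thicknessParams <- function(...) new("ThicknessParams", ...)

#' Ground-truth geometry of a synthetic correlative scene
#'
#' Describes elliptical nuclei with bimodal DAPI contrast, nucleolar discs
#' rendered as raised-cosine GFP bumps and phase plateaus, optional mitotic
#' cells (large dim GFP blobs over condensed DAPI), and additive Gaussian
#' noise. Rendering is deterministic given \code{seed}.
#'
#' @slot dims c(rows, cols) of the fluorescence images.
#' @slot phase_scale integer downsampling factor of the phase channel.
#' @slot nuclei data.frame: row, col, a, b (semi-axes px), theta (rad),
#'   dapi_level.
#' @slot nucleoli data.frame: parent (nucleus index), row, col, radius (px,
#'   half-maximum radius), gfp_peak, phase_plateau (rad).
#' @slot mitotic data.frame: row, col, radius, gfp_level, dapi_level.
#' @slot noise_sigma additive Gaussian noise sd per channel.
#' @slot background named numeric: dapi, gfp, phase baselines and the
#'   in-nucleus baselines (dapi_nucleus, gfp_nucleoplasm, phase_nucleoplasm).
#' @slot seed RNG seed used when rendering noise.
#' @export
setClass("SyntheticScene",
  representation(
    dims = "numeric", phase_scale = "numeric",
    nuclei = "data.frame", nucleoli = "data.frame", mitotic = "data.frame",
    noise_sigma = "numeric", background = "numeric", seed = "numeric"
  )
)

setValidity("SyntheticScene", function(object) {
  if (length(object@dims) != 2 || any(object@dims < 8))
    return("'dims' must be two values >= 8")
  if (object@phase_scale < 1 ||
      object@phase_scale != round(object@phase_scale))
    return("'phase_scale' must be a positive integer")
  if (object@noise_sigma < 0) return("'noise_sigma' must be >= 0")
  nl <- object@nucleoli
  if (nrow(nl) > 0) {
    if (any(nl$radius < 2)) return("nucleolus radii must be >= 2 px")
    nu <- object@nuclei
    if (any(nl$parent < 1 | nl$parent > nrow(nu)))
      return("nucleolus 'parent' out of range")
    for (k in seq_len(nrow(nl))) {
      p <- nu[nl$parent[k], ]
      dr <- nl$row[k] - p$row; dc <- nl$col[k] - p$col
      u <- dr * cos(p$theta) + dc * sin(p$theta)
      v <- -dr * sin(p$theta) + dc * cos(p$theta)
      if ((u / p$a)^2 + (v / p$b)^2 > 1)
        return("every nucleolus center must lie inside its parent ellipse")
    }
  }
  TRUE
})

setMethod("show", "SyntheticScene", function(object) {
  cat("SyntheticScene:", nrow(object@nuclei), "nuclei,",
      nrow(object@nucleoli), "nucleoli,", nrow(object@mitotic),
      "mitotic cells;", object@dims[1], "x", object@dims[2],
      "px, phase 1/", object@phase_scale, ", noise sd",
      object@noise_sigma, "\n")
})
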