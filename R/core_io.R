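#' Image pixel size in micrometres per pixel
#'
#' Physical size of one image pixel: camera pixel edge times binning,
#' divided by the product of objective, lens and C-mount magnifications.
#' With the default optics (4.54 um camera pixels, binning 1, 20 x 1.5 x 1)
#' this is 0.151 um/pixel.
#'
#' @param optics an \linkS4class{OpticsConfig}.
#' @return Pixel size in um/pixel.
#' @examples
#' pixelSizeUm(opticsConfig())  # 0.1513
#' @export
pixelSizeUm <- function(optics) {
  validObject(optics)
  optics@camera_pixel_um * optics@binning /
    (optics@objective_mag * optics@lens_mag * optics@c_mount)
}

#' Read a raw phase-shift export
#'
#' DHM phase images are exported as headerless binary files holding the
#' per-pixel phase shift in radians. The default dialect is little-endian
#' 32-bit float, row-major; both are overridable so other exports are one
#' argument away.
#'
#' @param path file path.
#' @param shape integer c(rows, cols).
#' @param dtype element type, "float32" or "float64".
#' @param endian byte order, "little" or "big".
#' @param order "row" (row-major, default) or "col".
#' @return A rows x cols numeric matrix of finite phase shifts (radians).
#' @seealso [writePhaseBinary()]
#' @export
readPhaseBinary <- function(path, shape, dtype = "float32",
                            endian = "little", order = "row") {
  stopifnot(length(shape) == 2, all(shape >= 1))
  width <- switch(dtype, float32 = 4L, float64 = 8L,
                  stop("unsupported dtype: ", dtype))
  n <- as.integer(shape[1]) * as.integer(shape[2])
  sz <- file.size(path)
  if (is.na(sz) || sz != n * width)
    stop("phase file size (", sz, " bytes) does not match shape ",
         shape[1], "x", shape[2], " of ", dtype)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, what = "numeric", n = n, size = width, endian = endian)
  if (any(!is.finite(v)))
    stop("phase file contains non-finite values")
  if (order == "row") matrix(v, nrow = shape[1], byrow = TRUE)
  else matrix(v, nrow = shape[1])
}

#' Write a raw phase-shift export
#'
#' Inverse of [readPhaseBinary()]; round-trips bit-exactly for float32
#' inputs representable at that precision.
#'
#' @param phase numeric matrix (radians).
#' @param path file path.
#' @inheritParams readPhaseBinary
#' @return Invisibly, \code{path}.
#' @export
writePhaseBinary <- function(phase, path, dtype = "float32",
                             endian = "little", order = "row") {
  stopifnot(is.matrix(phase), all(is.finite(phase)))
  width <- switch(dtype, float32 = 4L, float64 = 8L,
                  stop("unsupported dtype: ", dtype))
  v <- if (order == "row") as.numeric(t(phase)) else as.numeric(phase)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(v, con, size = width, endian = endian)
  invisible(path)
}

#' Read and write 16-bit fluorescence TIFFs
#'
#' Fluorescence channels are stored as 16-bit integer TIFFs. On read the
#' integer counts are returned as a numeric matrix; on write the matrix is
#' stored as 16-bit integers (values must lie in [0, 65535]).
#'
#' @param path file path.
#' @return \code{readFluorTiff}: numeric matrix of counts.
#' @export
readFluorTiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3) img <- img[, , 1]
  storage.mode(img) <- "double"
  img
}

#' @rdname readFluorTiff
#' @param img numeric matrix of integer counts in [0, 65535].
#' @export
writeFluorTiff <- function(img, path) {
  stopifnot(all(img >= 0), all(img <= 65535))
  tiff::writeTIFF(round(img) / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask 0/1 matrix.
#' @param path file path.
#' @export
writeMaskPng <- function(mask, path) {
  stopifnot(all(mask %in% c(0, 1)))
  png::writePNG(mask + 0, path)
  invisible(path)
}

#' @rdname writeMaskPng
#' @export
readMaskPng <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  m <- (img > 0.5) + 0L
  storage.mode(m) <- "integer"
  m
}

#' Read or write the pipeline configuration file
#'
#' A YAML file with two blocks: \code{optics} (the
#' \linkS4class{OpticsConfig} fields) and \code{seg} (the
#' \linkS4class{SegParams} fields). Missing fields fall back to defaults.
#'
#' @param path YAML file path.
#' @return \code{readConfig}: list with elements \code{optics} and
#'   \code{seg}.
#' @export
readConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  oc <- do.call(opticsConfig, as.list(cfg$optics %||% list()))
  sp <- do.call(segParams, as.list(cfg$seg %||% list()))
  list(optics = oc, seg = sp)
}

#' @rdname readConfig
#' @param optics an \linkS4class{OpticsConfig}.
#' @param seg a \linkS4class{SegParams}.
#' @export
writeConfig <- function(optics, seg, path) {
  sn <- slotNames("SegParams")
  segl <- lapply(sn, function(s) slot(seg, s)); names(segl) <- sn
  on <- slotNames("OpticsConfig")
  opl <- lapply(on, function(s) slot(optics, s)); names(opl) <- on
  yaml::write_yaml(list(optics = opl, seg = segl), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
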