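# Beer-Lambert color deconvolution of H-DAB brightfield images.
#
# Image conventions: RGB images are H x W x 3 integer arrays (row-major,
# origin top-left, channels R,G,B, values 0..255); single-stain channels
# are H x W matrices. Optical density is per-channel absorbance
# -log10(I/I0); stain amounts add linearly in OD space.

validateRGB <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L) {
    stop("image must be an H x W x 3 array (got ",
         paste(dim(image), collapse = "x"), ")", call. = FALSE)
  }
  if (dim(image)[3] != 3L) {
    stop("image must have exactly 3 channels (R,G,B); got ",
         dim(image)[3], call. = FALSE)
  }
  if (any(!is.finite(image)) || any(image < 0) || any(image > 255) ||
      any(image != round(image))) {
    stop("image must contain 8-bit integer intensities in [0,255]",
         call. = FALSE)
  }
  invisible(image)
}

#' Convert an RGB brightfield image to optical density
#'
#' Applies the Beer-Lambert transform per channel,
#' \code{OD_c = -log10(I_c / I0_c)}, where \code{I0} is the intensity of
#' the unattenuated background illumination. Transmitted intensities are
#' floored (default at 1 count) before the logarithm so fully dark pixels
#' map to the finite 8-bit cap \code{-log10(floor/255)} (about 2.4065),
#' and pixels brighter than the background are clamped to zero OD.
#'
#' @param image H x W x 3 integer array, values 0..255.
#' @param background per-channel background intensity \code{I0}; values in
#'   (0, 255]. Default 255 on all channels.
#' @param floor minimum transmitted intensity substituted before the log.
#' @return H x W x 3 array of non-negative optical densities.
#' @seealso \code{\link{deconvolve}}, \code{\link{estimateStainVector}}
#' @export
#' @examples
#' px <- array(c(26L, 26L, 26L), dim = c(1, 1, 3))
#' rgbToOD(px)[1, 1, ]   # -log10(26/255) on each channel
rgbToOD <- function(image, background = c(255, 255, 255), floor = 1) {
  validateRGB(image)
  background <- rep_len(as.numeric(background), 3L)
  if (any(!is.finite(background)) || any(background <= 0) ||
      any(background > 255)) {
    stop("background intensities must lie in (0, 255]", call. = FALSE)
  }
  if (!is.finite(floor) || floor <= 0) {
    stop("'floor' must be positive", call. = FALSE)
  }
  od <- array(0, dim = dim(image))
  for (ch in 1:3) {
    od[, , ch] <- pmax(-log10(pmax(image[, , ch], floor) / background[ch]), 0)
  }
  od
}

#' Estimate a stain OD vector from a single-stain calibration image
#'
#' Given a calibration image containing only one stain (for example a
#' control slide stained with DAB but no counterstain), returns the
#' unit-normalized mean optical-density triplet over the selected pixels.
#' This is the single-stain calibration procedure used to determine the
#' per-chromogen absorbance direction.
#'
#' @param image H x W x 3 calibration image.
#' @param mask optional H x W logical matrix selecting the stained
#'   region; default uses every pixel.
#' @param background per-channel background intensity, as in
#'   \code{\link{rgbToOD}}.
#' @return Unit numeric(3) OD vector named R, G, B.
#' @export
estimateStainVector <- function(image, mask = NULL,
                                background = c(255, 255, 255)) {
  od <- rgbToOD(image, background = background)
  if (is.null(mask)) {
    mask <- matrix(TRUE, nrow = dim(image)[1], ncol = dim(image)[2])
  }
  if (!is.logical(mask) || !all(dim(mask) == dim(image)[1:2])) {
    stop("mask must be a logical matrix matching the image", call. = FALSE)
  }
  if (!any(mask)) stop("mask selects no pixels", call. = FALSE)
  odm <- cbind(od[, , 1][mask], od[, , 2][mask], od[, , 3][mask])
  v <- colMeans(odm)
  nv <- sqrt(sum(v^2))
  if (nv < 1e-8) {
    stop("degenerate calibration: selected pixels carry no absorbance",
         call. = FALSE)
  }
  stats::setNames(v / nv, c("R", "G", "B"))
}

#' Build a two-stain unmixing system
#'
#' Completes the hematoxylin/DAB pair with a complementary third vector
#' (cross product with negative components zeroed, then renormalized) and
#' inverts the row-stacked stain matrix. The complementary channel should
#' be nearly empty after unmixing a genuine two-stain image and serves as
#' a separation-quality diagnostic.
#'
#' @param hematoxylin,dab numeric(3) OD vectors (need not be normalized;
#'   components must be non-negative and the vectors not collinear).
#' @return A \code{\linkS4class{StainSystem}}.
#' @seealso \code{\link{defaultStainSystem}}, \code{\link{deconvolve}}
#' @export
#' @examples
#' buildStainSystem(c(1, 0, 0), c(0, 1, 0))
buildStainSystem <- function(hematoxylin, dab) {
  normv <- function(v, what) {
    v <- as.numeric(v)
    if (length(v) != 3L || any(!is.finite(v)) || any(v < 0)) {
      stop(what, " must be 3 non-negative finite numbers", call. = FALSE)
    }
    n <- sqrt(sum(v^2))
    if (n < 1e-12) stop(what, " must be non-zero", call. = FALSE)
    v / n
  }
  h <- normv(hematoxylin, "hematoxylin")
  d <- normv(dab, "dab")
  cp <- c(h[2] * d[3] - h[3] * d[2],
          h[3] * d[1] - h[1] * d[3],
          h[1] * d[2] - h[2] * d[1])
  if (sqrt(sum(cp^2)) < 1e-8) {
    stop("stain vectors are collinear; unmixing matrix is singular",
         call. = FALSE)
  }
  if (all(cp <= 0)) cp <- -cp   # orientation is arbitrary; keep it physical
  cp <- pmax(cp, 0)
  ncp <- sqrt(sum(cp^2))
  if (ncp < 1e-12) {
    stop("complementary vector vanished after zeroing negatives",
         call. = FALSE)
  }
  cp <- cp / ncp
  M <- rbind(h, d, cp)
  new("StainSystem", hematoxylin = h, dab = d, complementary = cp,
      unmixMatrix = solve(M))
}

#' Default H-DAB stain system
#'
#' The widely used hematoxylin/DAB optical-density vectors of Ruifrok &
#' Johnston's color-deconvolution calibration: hematoxylin
#' (0.650, 0.704, 0.286) and DAB (0.269, 0.568, 0.778), unit-normalized.
#' Suitable for standard DAB + hematoxylin slides; re-calibrate with
#' \code{\link{estimateStainVector}} when the staining protocol differs.
#'
#' @return A \code{\linkS4class{StainSystem}}.
#' @export
defaultStainSystem <- function() {
  buildStainSystem(c(0.650, 0.704, 0.286), c(0.269, 0.568, 0.778))
}

#' Unmix an optical-density image into per-stain densities
#'
#' Right-multiplies each OD triplet by the inverse stain matrix, giving
#' the per-pixel amount of each stain. The operation is exact linear
#' algebra: no regularization, and small negative densities arising from
#' noise are preserved (they are clamped only when rendering 8-bit
#' channel images).
#'
#' @param od H x W x 3 optical-density array from \code{\link{rgbToOD}}.
#' @param system a \code{\linkS4class{StainSystem}}.
#' @return Named list of H x W density matrices:
#'   \code{hematoxylin}, \code{dab}, \code{complementary}.
#' @export
deconvolve <- function(od, system = defaultStainSystem()) {
  if (!is.array(od) || length(dim(od)) != 3L || dim(od)[3] != 3L) {
    stop("od must be an H x W x 3 array", call. = FALSE)
  }
  stopifnot(is(system, "StainSystem"))
  h <- dim(od)[1]; w <- dim(od)[2]
  dens <- matrix(od, ncol = 3L) %*% system@unmixMatrix
  list(
    hematoxylin = matrix(dens[, 1], h, w),
    dab = matrix(dens[, 2], h, w),
    complementary = matrix(dens[, 3], h, w)
  )
}

#' Render a stain-density field as an 8-bit intensity image
#'
#' Inverse Beer-Lambert display transform
#' \code{I = round(255 * 10^(-max(d, 0)))}, clamped to [0, 255]: zero
#' density maps to 255 (no stain, lightest shade) and increasing density
#' darkens monotonically towards 0.
#'
#' @param density H x W numeric matrix of stain amounts.
#' @return H x W integer matrix, values 0..255.
#' @export
#' @examples
#' densityToIntensity(matrix(c(0, 1), 1))  # 255 and 26
densityToIntensity <- function(density) {
  if (!is.matrix(density) || any(!is.finite(density))) {
    stop("density must be a finite numeric matrix", call. = FALSE)
  }
  img <- round(255 * 10^(-pmax(density, 0)))
  img[img < 0] <- 0
  img[img > 255] <- 255
  storage.mode(img) <- "integer"
  img
}

#' Residual summary of the complementary channel
#'
#' Tallies the intensity histogram of the reconstructed complementary
#' image. With well-calibrated stain vectors the complementary channel of
#' a two-stain image is essentially empty, so the count of pixels at
#' intensity 255 is a separation-quality diagnostic: the higher, the
#' cleaner the unmixing.
#'
#' @param channel H x W integer matrix (8-bit complementary image).
#' @return List with \code{countAt255} and the 256-bin \code{histogram}.
#' @export
complementaryResidual <- function(channel) {
  if (!is.matrix(channel) || any(channel < 0) || any(channel > 255) ||
      any(channel != round(channel))) {
    stop("channel must be an 8-bit intensity matrix", call. = FALSE)
  }
  h <- tabulate(as.integer(channel) + 1L, nbins = 256L)
  list(countAt255 = h[256L], histogram = stats::setNames(h, 0:255))
}
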