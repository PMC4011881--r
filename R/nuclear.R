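# Nuclear-marker scoring: threshold-derived masks over the DAB channel.

#' Select stained pixels of a DAB channel by intensity threshold
#'
#' Dark-object convention: a pixel is selected when its DAB intensity is
#' less than or equal to \code{threshold}, since DAB-positive nuclei are
#' dark on the reconstructed channel. (Note this is the opposite of
#' selecting bright objects; raising the threshold selects more pixels.)
#'
#' @param dab H x W integer matrix, reconstructed DAB channel.
#' @param threshold integer in [0, 255]; pixels with intensity <=
#'   threshold are selected.
#' @return H x W logical matrix.
#' @export
#' @examples
#' m <- thresholdMask(matrix(c(40L, 240L), 1), 180)
#' sum(m)  # 1
thresholdMask <- function(dab, threshold) {
  if (!is.matrix(dab)) stop("dab must be a matrix", call. = FALSE)
  threshold <- as.numeric(threshold)
  if (length(threshold) != 1L || !is.finite(threshold) ||
      threshold < 0 || threshold > 255) {
    stop("threshold must be a single value in [0, 255]", call. = FALSE)
  }
  dab <= threshold
}

#' Otsu threshold of an 8-bit channel
#'
#' Maximizes the between-class variance of the 256-bin intensity
#' histogram over all cut points; the returned threshold \code{t} is
#' meant for \code{\link{thresholdMask}}, i.e. the dark class is
#' \code{intensity <= t}. Ties are broken towards the lowest cut point,
#' making the result deterministic. A constant image has no separating
#' cut; its single intensity is returned with a warning.
#'
#' @param dab H x W integer matrix, values 0..255.
#' @return Integer threshold in [0, 255].
#' @export
autoThreshold <- function(dab) {
  if (!is.matrix(dab) || any(dab < 0) || any(dab > 255) ||
      any(dab != round(dab))) {
    stop("dab must be an 8-bit intensity matrix", call. = FALSE)
  }
  h <- tabulate(as.integer(dab) + 1L, nbins = 256L)
  total <- sum(h)
  lv <- which(h > 0) - 1L
  if (length(lv) == 1L) {
    warning("constant image: no separating threshold exists")
    return(lv)
  }
  w0 <- cumsum(h)                       # pixels at intensity <= t
  m0 <- cumsum(h * (0:255))             # intensity mass <= t
  w1 <- total - w0
  mu0 <- ifelse(w0 > 0, m0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (m0[256L] - m0) / w1, 0)
  sigmaB <- w0 * w1 * (mu0 - mu1)^2     # between-class variance, t = 0..255
  sigmaB[256L] <- 0                     # cut after 255 puts all in one class
  as.integer(which.max(sigmaB) - 1L)
}

#' Score a nuclear-marker image
#'
#' Nuclear workflow: deconvolve the image, select the DAB-positive
#' (brown-stained) nuclear areas on the reconstructed DAB channel with an
#' intensity threshold, then profile and score only the selected pixels.
#' The threshold is user-defined by design, matching interactive
#' practice; pass \code{"auto"} for an unattended Otsu default.
#'
#' @param image H x W x 3 integer RGB array.
#' @param system a \code{\linkS4class{StainSystem}}.
#' @param threshold integer in [0, 255], or \code{"auto"} for
#'   \code{\link{autoThreshold}}.
#' @param zones zone definition table.
#' @param background per-channel background intensity I0.
#' @return As \code{\link{scoreImage}}, plus \code{mask} (the logical
#'   selection) and \code{threshold} (the value used).
#' @export
scoreNuclear <- function(image, system = defaultStainSystem(),
                         threshold = "auto", zones = defaultZones(),
                         background = c(255, 255, 255)) {
  od <- rgbToOD(image, background = background)
  dens <- deconvolve(od, system)
  dab <- densityToIntensity(dens$dab)
  if (identical(threshold, "auto")) {
    threshold <- autoThreshold(dab)
  }
  mask <- thresholdMask(dab, threshold)
  if (!any(mask)) {
    stop("no stained nuclei selected at threshold ", threshold,
         "; choose a higher threshold manually", call. = FALSE)
  }
  profile <- zoneProfile(dab, mask = mask, zones = zones)
  list(report = computeScore(profile),
       profile = profile,
       dab = dab,
       mask = mask,
       threshold = threshold)
}
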