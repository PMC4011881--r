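# Four-zone pixel profiling and score assignment for the DAB channel.

#' Default scoring zones of the DAB intensity scale
#'
#' The calibrated partition of the 8-bit DAB intensity axis into four
#' scoring zones: high positive 0-60, positive 61-120, low positive
#' 121-180, negative 181-235 (bounds inclusive), with zone weights 4, 3,
#' 2 and 1. Intensities 236-255 predominantly represent fatty tissue or
#' blank areas and are excluded from scoring.
#'
#' @return \code{data.frame} with columns \code{zone}, \code{low},
#'   \code{high}, \code{weight}, one row per zone in tier order.
#' @seealso \code{\link{zoneProfile}}, \code{\link{computeScore}}
#' @export
#' @examples
#' defaultZones()
defaultZones <- function() {
  data.frame(
    zone = scoreTiers(),
    low = c(0L, 61L, 121L, 181L),
    high = c(60L, 120L, 180L, 235L),
    weight = c(4L, 3L, 2L, 1L),
    stringsAsFactors = FALSE
  )
}

validateZones <- function(zones) {
  need <- c("zone", "low", "high", "weight")
  if (!is.data.frame(zones) || !all(need %in% names(zones))) {
    stop("zones must be a data.frame with columns zone, low, high, weight",
         call. = FALSE)
  }
  if (any(zones$low > zones$high) || any(zones$low < 0) ||
      any(zones$high > 255)) {
    stop("zone bounds must satisfy 0 <= low <= high <= 255", call. = FALSE)
  }
  o <- order(zones$low)
  if (any(zones$high[o][-nrow(zones)] >= zones$low[o][-1])) {
    stop("zones must not overlap", call. = FALSE)
  }
  invisible(zones)
}

# first intensity of the exclusion band implied by a zone table
zoneExclusionLow <- function(zones) max(zones$high) + 1L

#' Profile a DAB channel image into scoring zones
#'
#' Computes the 256-bin intensity histogram of the (optionally masked)
#' DAB channel and the pixel count in each scoring zone; pixels above the
#' last zone's upper bound fall in the exclusion band and are kept out of
#' the scoring denominator.
#'
#' @param dab H x W integer matrix, the reconstructed DAB image (0 =
#'   darkest stain, 255 = unstained).
#' @param mask optional H x W logical matrix restricting the profile
#'   (for example a nuclear selection); must select at least one pixel.
#' @param zones zone definition table; see \code{\link{defaultZones}}.
#' @return A \code{\linkS4class{ZoneProfile}}.
#' @export
#' @examples
#' dab <- matrix(30L, 10, 10)
#' zoneProfile(dab)
zoneProfile <- function(dab, mask = NULL, zones = defaultZones()) {
  if (!is.matrix(dab) || any(dab < 0) || any(dab > 255) ||
      any(dab != round(dab))) {
    stop("dab must be an 8-bit intensity matrix", call. = FALSE)
  }
  validateZones(zones)
  if (!is.null(mask)) {
    if (!is.logical(mask) || !all(dim(mask) == dim(dab))) {
      stop("mask must be a logical matrix matching the image", call. = FALSE)
    }
    if (!any(mask)) {
      stop("empty selection: mask selects no pixels", call. = FALSE)
    }
    vals <- dab[mask]
  } else {
    vals <- as.vector(dab)
  }
  h <- tabulate(as.integer(vals) + 1L, nbins = 256L)
  zc <- vapply(seq_len(nrow(zones)), function(i) {
    sum(h[(zones$low[i] + 1L):(zones$high[i] + 1L)])
  }, numeric(1))
  names(zc) <- zones$zone
  total <- length(vals)
  new("ZoneProfile",
      histogram = as.numeric(h),
      zoneCounts = zc,
      excludedCount = total - sum(zc),
      maskPixels = total,
      zones = zones)
}

#' Assign the four-tier score from a zone profile
#'
#' If one zone holds at least \code{majorityPercent} (default 66) percent
#' of the scored pixels, that zone's tier is assigned directly (majority
#' rule) and the numeric score is the zone weight. Otherwise the numeric
#' score is the percentage-weighted mean of the zone weights,
#' \code{sum(percent_z * weight_z) / 100}, and the tier is the zone whose
#' weight is nearest (ties round up towards the stronger tier). Excluded
#' pixels are removed from the denominator before percentages are taken.
#'
#' @param profile a \code{\linkS4class{ZoneProfile}} with at least one
#'   scored pixel.
#' @param majorityPercent zone percentage at or above which the majority
#'   rule fires (inclusive).
#' @return A \code{\linkS4class{ScoreReport}}.
#' @export
#' @examples
#' p <- zoneProfile(matrix(c(rep(30L, 40), rep(90L, 30),
#'                           rep(150L, 20), rep(208L, 10)), 10))
#' computeScore(p)   # weighted formula -> 3.0, "positive"
computeScore <- function(profile, majorityPercent = 66) {
  stopifnot(is(profile, "ZoneProfile"))
  total <- totalScored(profile)
  if (total <= 0) {
    stop("no scorable pixels: all ", profile@maskPixels,
         " considered pixels fall in the excluded intensity band (",
         zoneExclusionLow(profile@zones), "-255); check staining or mask",
         call. = FALSE)
  }
  zones <- profile@zones
  pct <- 100 * profile@zoneCounts / total
  excludedPercent <- 100 * profile@excludedCount / profile@maskPixels
  if (any(pct >= majorityPercent)) {
    i <- which.max(pct)
    report <- new("ScoreReport",
                  percentages = pct,
                  numericScore = as.numeric(zones$weight[i]),
                  label = zones$zone[i],
                  decision = "majority_rule",
                  excludedPercent = excludedPercent)
    return(report)
  }
  s <- sum(pct * zones$weight) / 100
  # nearest-weight label; .5 rounds up towards the stronger tier
  w <- sort(unique(zones$weight))
  idx <- findInterval(s, w[-length(w)] + 0.5) + 1L
  label <- zones$zone[match(w[idx], zones$weight)]
  new("ScoreReport",
      percentages = pct,
      numericScore = s,
      label = label,
      decision = "weighted_formula",
      excludedPercent = excludedPercent)
}

#' Score a cytoplasmic-marker image end to end
#'
#' Full pipeline: Beer-Lambert OD transform, color deconvolution,
#' reconstruction of the 8-bit DAB channel, zone profiling and score
#' assignment. For nuclear markers use \code{\link{scoreNuclear}}, which
#' restricts the profile to DAB-positive nuclei first.
#'
#' @param image H x W x 3 integer RGB array (see
#'   \code{\link{readRGBImage}}).
#' @param system a \code{\linkS4class{StainSystem}}.
#' @param mask optional H x W logical matrix restricting scoring.
#' @param zones zone definition table.
#' @param background per-channel background intensity I0.
#' @return List with \code{report} (\code{\linkS4class{ScoreReport}}),
#'   \code{profile} (\code{\linkS4class{ZoneProfile}}), \code{dab} (the
#'   reconstructed DAB channel) and \code{channels} (all three 8-bit
#'   single-stain images).
#' @export
scoreImage <- function(image, system = defaultStainSystem(), mask = NULL,
                       zones = defaultZones(),
                       background = c(255, 255, 255)) {
  od <- rgbToOD(image, background = background)
  dens <- deconvolve(od, system)
  channels <- lapply(dens, densityToIntensity)
  profile <- zoneProfile(channels$dab, mask = mask, zones = zones)
  list(report = computeScore(profile),
       profile = profile,
       dab = channels$dab,
       channels = channels)
}
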