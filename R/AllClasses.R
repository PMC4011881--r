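#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Four-tier score labels
#'
#' The fixed tier order used throughout the package: high positive (3+),
#' positive (2+), low positive (1+), negative (0). Contingency tables,
#' zone definitions and score reports all use this order.
#'
#' @return Character vector of the four tier names.
#' @export
#' @examples
#' scoreTiers()
scoreTiers <- function() {
  c("high_positive", "positive", "low_positive", "negative")
}

#' StainSystem: a two-chromogen unmixing system
#'
#' Holds the unit optical-density vectors of hematoxylin and DAB, the
#' completed complementary (residual) vector, and the inverse unmixing
#' matrix used for color deconvolution. Construct with
#' \code{\link{buildStainSystem}} or \code{\link{defaultStainSystem}}.
#'
#' @slot hematoxylin unit OD vector (R, G, B absorbance fractions).
#' @slot dab unit OD vector of the DAB chromogen.
#' @slot complementary unit residual vector orthogonalized against the
#'   two stains (negative components zeroed, then renormalized).
#' @slot unmixMatrix inverse of the row-stacked stain matrix; right
#'   multiplication of an OD triplet row vector yields stain densities.
#'
#' @export
setClass("StainSystem",
  representation(
    hematoxylin = "numeric",
    dab = "numeric",
    complementary = "numeric",
    unmixMatrix = "matrix"
  )
)

setValidity("StainSystem", function(object) {
  msgs <- character()
  for (nm in c("hematoxylin", "dab", "complementary")) {
    v <- slot(object, nm)
    if (length(v) != 3L || any(!is.finite(v))) {
      msgs <- c(msgs, sprintf("'%s' must be 3 finite numbers", nm))
      next
    }
    if (any(v < 0)) {
      msgs <- c(msgs, sprintf("'%s' has negative components", nm))
    }
    if (abs(sqrt(sum(v^2)) - 1) > 1e-9) {
      msgs <- c(msgs, sprintf("'%s' is not unit length", nm))
    }
  }
  M <- stainMatrix(object)
  U <- object@unmixMatrix
  if (!all(dim(U) == c(3L, 3L)) || any(!is.finite(U))) {
    msgs <- c(msgs, "'unmixMatrix' must be a finite 3x3 matrix")
  } else if (length(msgs) == 0L &&
             max(abs(U %*% M - diag(3))) > 1e-8) {
    msgs <- c(msgs, "'unmixMatrix' is not the inverse of the stain matrix")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn StainSystem the 3x3 matrix whose rows are the hematoxylin,
#'   DAB and complementary unit OD vectors (in that order).
#' @param object,x a \code{StainSystem}.
#' @export
stainMatrix <- function(object) {
  m <- rbind(object@hematoxylin, object@dab, object@complementary)
  dimnames(m) <- list(c("hematoxylin", "dab", "complementary"),
                      c("R", "G", "B"))
  m
}

#' @describeIn StainSystem the inverse unmixing matrix.
#' @export
unmixMatrix <- function(object) object@unmixMatrix

setMethod("show", "StainSystem", function(object) {
  cat("StainSystem (H-DAB optical density vectors)\n")
  print(round(stainMatrix(object), 4))
})

#' ZoneProfile: pixel-intensity profile of a DAB channel image
#'
#' The 256-bin intensity histogram of a (possibly masked) reconstructed
#' DAB image together with per-zone pixel counts over the four scoring
#' zones and the count of pixels in the excluded high-intensity band
#' (fatty tissue / blank areas). Construct with \code{\link{zoneProfile}}.
#'
#' @slot histogram 256 bin counts, intensities 0..255.
#' @slot zoneCounts pixel count per zone, named by tier.
#' @slot excludedCount pixels in the exclusion band.
#' @slot maskPixels total pixels considered (whole image or mask).
#' @slot zones the zone definition table the profile was built with.
#'
#' @seealso \code{\link{computeScore}}, \code{\link{defaultZones}}
#' @export
setClass("ZoneProfile",
  representation(
    histogram = "numeric",
    zoneCounts = "numeric",
    excludedCount = "numeric",
    maskPixels = "numeric",
    zones = "data.frame"
  )
)

setValidity("ZoneProfile", function(object) {
  msgs <- character()
  if (length(object@histogram) != 256L || any(object@histogram < 0)) {
    msgs <- c(msgs, "'histogram' must be 256 non-negative counts")
  }
  if (any(object@zoneCounts < 0) || object@excludedCount < 0) {
    msgs <- c(msgs, "counts must be non-negative")
  }
  if (sum(object@zoneCounts) + object@excludedCount != object@maskPixels) {
    msgs <- c(msgs, "zone counts + excluded count must equal total pixels")
  }
  if (sum(object@histogram) != object@maskPixels) {
    msgs <- c(msgs, "histogram must sum to total pixels")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn ZoneProfile per-zone pixel counts.
#' @param object a \code{ZoneProfile}.
#' @export
zoneCounts <- function(object) object@zoneCounts

#' @describeIn ZoneProfile pixels falling in the scoring zones
#'   (denominator of the zone percentages).
#' @export
totalScored <- function(object) sum(object@zoneCounts)

#' @describeIn ZoneProfile pixels in the excluded band.
#' @export
excludedCount <- function(object) object@excludedCount

#' @describeIn ZoneProfile the 256-bin intensity histogram
#'   (names are intensities "0".."255").
#' @export
intensityHistogram <- function(object) {
  stats::setNames(object@histogram, 0:255)
}

setMethod("show", "ZoneProfile", function(object) {
  cat("ZoneProfile over", object@maskPixels, "pixels\n")
  tab <- data.frame(
    zone = names(object@zoneCounts),
    pixels = object@zoneCounts,
    percent = if (totalScored(object) > 0)
      round(100 * object@zoneCounts / totalScored(object), 2) else NA_real_,
    row.names = NULL
  )
  print(tab)
  cat("excluded (", zoneExclusionLow(object@zones), "-255): ",
      object@excludedCount, " pixels\n", sep = "")
})

#' ScoreReport: automated four-tier scoring decision
#'
#' Per-zone pixel percentages, the numeric weighted score, the assigned
#' tier label and the decision path (majority rule or weighted formula).
#' Construct with \code{\link{computeScore}}, \code{\link{scoreImage}} or
#' \code{\link{scoreNuclear}}.
#'
#' @slot percentages per-zone percentage of scored pixels.
#' @slot numericScore the zone weight (majority rule) or the
#'   percentage-weighted mean zone weight.
#' @slot label assigned tier.
#' @slot decision \code{"majority_rule"} or \code{"weighted_formula"}.
#' @slot excludedPercent percentage of considered pixels that fell in the
#'   excluded band (not part of the scoring denominator).
#'
#' @export
setClass("ScoreReport",
  representation(
    percentages = "numeric",
    numericScore = "numeric",
    label = "character",
    decision = "character",
    excludedPercent = "numeric"
  )
)

setValidity("ScoreReport", function(object) {
  msgs <- character()
  if (any(object@percentages < 0)) {
    msgs <- c(msgs, "percentages must be non-negative")
  }
  if (abs(sum(object@percentages) - 100) > 1e-9) {
    msgs <- c(msgs, "percentages must sum to 100")
  }
  if (!object@label %in% names(object@percentages)) {
    msgs <- c(msgs, "label must be one of the zone names")
  }
  if (!object@decision %in% c("majority_rule", "weighted_formula")) {
    msgs <- c(msgs, "unknown decision path")
  }
  if (!is.finite(object@numericScore)) {
    msgs <- c(msgs, "numeric score must be finite")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn ScoreReport the assigned tier label.
#' @param object a \code{ScoreReport}.
#' @export
scoreLabel <- function(object) object@label

#' @describeIn ScoreReport the numeric score.
#' @export
numericScore <- function(object) object@numericScore

#' @describeIn ScoreReport per-zone percentages of scored pixels.
#' @export
zonePercentages <- function(object) object@percentages

setMethod("show", "ScoreReport", function(object) {
  cat("IHC score log\n")
  for (nm in names(object@percentages)) {
    cat(sprintf("  %-14s %6.2f %%\n", paste0(nm, ":"),
                object@percentages[[nm]]))
  }
  cat(sprintf("  %-14s %6.2f %%\n", "excluded:", object@excludedPercent))
  cat(sprintf("Score: %.3f  ->  %s  (%s)\n", object@numericScore,
              object@label, gsub("_", " ", object@decision)))
})

#' ContingencyTable: paired four-tier score counts of two raters
#'
#' A 4x4 table of sample counts cross-classified by the four-tier scores
#' of two raters (for example a pathologist and the automated scorer),
#' rows and columns in the fixed tier order of \code{\link{scoreTiers}}.
#'
#' @slot counts 4x4 non-negative integer matrix; rows are rater 1.
#' @slot raters names of the two raters (row rater, column rater).
#'
#' @seealso \code{\link{cohenKappa}}, \code{\link{percentAgreement}},
#'   \code{\link{readContingencyTable}}
#' @export
setClass("ContingencyTable",
  representation(counts = "matrix", raters = "character")
)

setValidity("ContingencyTable", function(object) {
  cnt <- object@counts
  msgs <- character()
  if (!all(dim(cnt) == c(4L, 4L))) {
    msgs <- c(msgs, "'counts' must be a 4x4 matrix")
  } else {
    if (any(!is.finite(cnt)) || any(cnt < 0) || any(cnt != round(cnt))) {
      msgs <- c(msgs, "'counts' must be non-negative integers")
    }
    if (sum(cnt) <= 0) msgs <- c(msgs, "grand total must be positive")
  }
  if (length(object@raters) != 2L) {
    msgs <- c(msgs, "'raters' must name exactly two raters")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a ContingencyTable
#'
#' @param counts 4x4 matrix of counts, rows and columns in the order of
#'   \code{\link{scoreTiers}} (rows: first rater, columns: second rater).
#' @param raters character(2), names of the two raters.
#' @return A \code{\linkS4class{ContingencyTable}}.
#' @export
#' @examples
#' ContingencyTable(diag(c(5, 8, 6, 2)), raters = c("manual", "automated"))
ContingencyTable <- function(counts, raters = c("rater1", "rater2")) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(4L, 4L))) {
    stop("'counts' must be a 4x4 matrix in tier order", call. = FALSE)
  }
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(scoreTiers(), scoreTiers())
  new("ContingencyTable", counts = counts, raters = as.character(raters))
}

#' @describeIn ContingencyTable the 4x4 count matrix.
#' @param object a \code{ContingencyTable}.
#' @export
tableCounts <- function(object) object@counts

setMethod("show", "ContingencyTable", function(object) {
  cat(sprintf("ContingencyTable: %s (rows) vs %s (columns), n = %d\n",
              object@raters[1], object@raters[2], sum(object@counts)))
  print(object@counts)
})
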