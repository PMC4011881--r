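# Ground-truth synthetic image generation by forward Beer-Lambert
# composition. Every pipeline stage can be tested against known density
# fields without real slides.

# run expr with a local RNG stream; global .Random.seed is untouched
withLocalSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' SyntheticSpec: recipe for a ground-truth synthetic IHC image
#'
#' Per-pixel hematoxylin and DAB density fields plus rendering
#' parameters. \code{\link{renderSynthetic}} forward-composes the fields
#' through the Beer-Lambert model into an 8-bit RGB image and reports the
#' exact ground truth alongside. Build directly with
#' \code{\link{syntheticSpec}} or via the fixture helpers
#' \code{\link{makeZoneMixture}} and \code{\link{makeNuclearBlobs}}.
#'
#' @slot height,width image dimensions in pixels.
#' @slot hemaField,dabField H x W non-negative density matrices.
#' @slot noiseSigma sd of additive Gaussian intensity noise (8-bit
#'   counts), applied per channel after the forward transform.
#' @slot seed RNG seed; rendering is bit-reproducible given the spec.
#' @slot system the \code{\linkS4class{StainSystem}} whose vectors
#'   compose the image.
#' @slot background per-channel illumination intensity I0.
#' @slot nuclearMask ground-truth nuclei mask, or NULL for non-nuclear
#'   fixtures.
#' @slot maskThreshold DAB-intensity threshold known to reproduce
#'   \code{nuclearMask} (NA when not applicable).
#' @slot intendedLabel the tier the generator intends, or NA to derive it
#'   from the noise-free DAB intensities.
#'
#' @export
setClass("SyntheticSpec",
  representation(
    height = "numeric",
    width = "numeric",
    hemaField = "matrix",
    dabField = "matrix",
    noiseSigma = "numeric",
    seed = "numeric",
    system = "StainSystem",
    background = "numeric",
    nuclearMask = "matrixOrNULL",
    maskThreshold = "numeric",
    intendedLabel = "character"
  )
)

setValidity("SyntheticSpec", function(object) {
  msgs <- character()
  dm <- c(object@height, object@width)
  if (any(dm < 1)) msgs <- c(msgs, "height and width must be >= 1")
  for (nm in c("hemaField", "dabField")) {
    f <- slot(object, nm)
    if (!all(dim(f) == dm)) {
      msgs <- c(msgs, sprintf("'%s' must be height x width", nm))
    } else if (any(!is.finite(f)) || any(f < 0)) {
      msgs <- c(msgs, sprintf("'%s' must be non-negative and finite", nm))
    }
  }
  if (object@noiseSigma < 0) msgs <- c(msgs, "noiseSigma must be >= 0")
  if (length(object@background) != 3L || any(object@background <= 0) ||
      any(object@background > 255)) {
    msgs <- c(msgs, "background must be 3 values in (0, 255]")
  }
  if (!is.null(object@nuclearMask) &&
      !all(dim(object@nuclearMask) == dm)) {
    msgs <- c(msgs, "nuclearMask must match the image dimensions")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec %dx%d, noise sd %.2f, seed %d%s\n",
    object@height, object@width, object@noiseSigma, object@seed,
    if (!is.null(object@nuclearMask))
      sprintf(", nuclear (%d mask px)", sum(object@nuclearMask)) else ""))
})

#' Construct a synthetic-image recipe
#'
#' @param height,width image dimensions.
#' @param hemaField,dabField non-negative density fields; scalars are
#'   recycled to the full image.
#' @param noiseSigma sd of additive Gaussian intensity noise (counts).
#' @param seed RNG seed for the noise.
#' @param system stain system used for forward composition.
#' @param background per-channel illumination I0.
#' @return A \code{\linkS4class{SyntheticSpec}}.
#' @export
#' @examples
#' sp <- syntheticSpec(8, 8, hemaField = 0.3, dabField = 0.8)
#' renderSynthetic(sp)$truth$zoneFractions
syntheticSpec <- function(height, width, hemaField = 0, dabField = 0,
                          noiseSigma = 0, seed = 1,
                          system = defaultStainSystem(),
                          background = c(255, 255, 255)) {
  expand <- function(f) {
    if (is.matrix(f)) f else matrix(as.numeric(f), height, width)
  }
  new("SyntheticSpec",
      height = height, width = width,
      hemaField = expand(hemaField), dabField = expand(dabField),
      noiseSigma = noiseSigma, seed = seed, system = system,
      background = rep_len(as.numeric(background), 3L),
      nuclearMask = NULL, maskThreshold = NA_real_,
      intendedLabel = NA_character_)
}

#' Render a synthetic spec into an RGB image plus ground truth
#'
#' Forward Beer-Lambert composition: per pixel and channel,
#' \code{I_c = round(I0_c * 10^-(A_H v_Hc + A_D v_Dc) + e)} with
#' \code{e ~ N(0, noiseSigma)}, clamped to [0, 255]. The truth records
#' the exact DAB density field, the noise-free DAB intensities, the zone
#' fractions they imply, the intended tier and (for nuclear fixtures) the
#' ground-truth mask and a workable threshold.
#'
#' @param spec a \code{\linkS4class{SyntheticSpec}}.
#' @param zones zone table used to derive the truth fractions/label.
#' @return List with \code{image} (H x W x 3 integer array) and
#'   \code{truth} (list: \code{dabDensity}, \code{dabIntensity},
#'   \code{zoneFractions}, \code{excludedFraction}, \code{intendedLabel},
#'   \code{nuclearMask}, \code{maskThreshold}).
#' @export
renderSynthetic <- function(spec, zones = defaultZones()) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  M <- stainMatrix(spec@system)
  h <- spec@height; w <- spec@width
  od <- cbind(as.vector(spec@hemaField), as.vector(spec@dabField)) %*%
    M[1:2, , drop = FALSE]
  img <- array(0L, dim = c(h, w, 3L))
  noise <- if (spec@noiseSigma > 0) {
    withLocalSeed(spec@seed,
                  matrix(stats::rnorm(h * w * 3L, 0, spec@noiseSigma),
                         ncol = 3L))
  } else {
    matrix(0, nrow = h * w, ncol = 3L)
  }
  for (ch in 1:3) {
    v <- round(spec@background[ch] * 10^(-od[, ch]) + noise[, ch])
    v[v < 0] <- 0
    v[v > 255] <- 255
    img[, , ch] <- matrix(as.integer(v), h, w)
  }
  dabInt <- densityToIntensity(spec@dabField)
  prof <- zoneProfile(dabInt, zones = zones)
  fracs <- zoneCounts(prof) / prof@maskPixels
  label <- spec@intendedLabel
  if (is.na(label)) {
    label <- if (totalScored(prof) > 0) scoreLabel(computeScore(prof))
             else NA_character_
  }
  list(
    image = img,
    truth = list(
      dabDensity = spec@dabField,
      dabIntensity = dabInt,
      zoneFractions = fracs,
      excludedFraction = prof@excludedCount / prof@maskPixels,
      intendedLabel = label,
      nuclearMask = spec@nuclearMask,
      maskThreshold = spec@maskThreshold
    )
  )
}

# intensity midpoints used for in-zone density targets
zoneMidpoints <- function(zones = defaultZones()) {
  m <- floor((zones$low + zones$high) / 2)
  stats::setNames(c(m, 248L), c(zones$zone, "excluded"))
}

# integer apportionment by largest remainder: sum(result) == n
apportion <- function(fractions, n) {
  target <- fractions * n
  base <- floor(target)
  left <- n - sum(base)
  if (left > 0) {
    o <- order(target - base, decreasing = TRUE)
    base[o[seq_len(left)]] <- base[o[seq_len(left)]] + 1
  }
  base
}

#' Zone-mixture fixture: pixels placed mid-zone in requested fractions
#'
#' Builds a spec whose noise-free DAB intensities land in each scoring
#' zone with the requested pixel fractions. Densities are the inverse
#' intensity transform of the zone midpoints (30, 90, 150, 208 for the
#' default zones; 248 for the excluded band), so fixtures sit far from
#' zone boundaries; pixel positions are a seeded random permutation.
#' Unrequested mass goes to the excluded band. A constant hematoxylin
#' counterstain is overlaid.
#'
#' @param fractions named numeric, names among
#'   \code{c(scoreTiers(), "excluded")}, each in [0, 1], sum at most 1.
#' @param size image side length (square image).
#' @param seed RNG seed for pixel placement.
#' @param hemaDensity constant counterstain density.
#' @param noiseSigma intensity noise sd; fixtures default to noise-free.
#' @param system,background forwarded to \code{\link{syntheticSpec}}.
#' @return A \code{\linkS4class{SyntheticSpec}}.
#' @export
#' @examples
#' sp <- makeZoneMixture(c(high_positive = 0.4, positive = 0.3,
#'                         low_positive = 0.2, negative = 0.1), size = 32)
#' renderSynthetic(sp)$truth$zoneFractions
makeZoneMixture <- function(fractions, size = 64, seed = 1,
                            hemaDensity = 0.35, noiseSigma = 0,
                            system = defaultStainSystem(),
                            background = c(255, 255, 255)) {
  mids <- zoneMidpoints()
  if (is.null(names(fractions)) ||
      !all(names(fractions) %in% names(mids))) {
    stop("fractions must be named by zone (or 'excluded')", call. = FALSE)
  }
  if (any(fractions < 0) || any(fractions > 1) || sum(fractions) > 1 + 1e-12) {
    stop("fractions must lie in [0, 1] and sum to at most 1", call. = FALSE)
  }
  full <- stats::setNames(numeric(length(mids)), names(mids))
  full[names(fractions)] <- fractions
  full["excluded"] <- full["excluded"] + max(1 - sum(fractions), 0)
  n <- size * size
  counts <- apportion(full, n)
  dens <- -log10(mids / 255)
  vals <- rep(dens, counts)
  vals <- withLocalSeed(seed, sample(vals))
  sp <- syntheticSpec(size, size,
                      hemaField = hemaDensity,
                      dabField = matrix(vals, size, size),
                      noiseSigma = noiseSigma, seed = seed,
                      system = system, background = background)
  sp
}

#' Nuclear-blob fixture: stained nuclei on an unstained background
#'
#' Scatters round nuclei of uniform (disk) or Gaussian-profile DAB
#' density on a lightly DAB-tinted background with a constant
#' hematoxylin counterstain. Nucleus intensity is the midpoint of the
#' requested zone, so the intended tier is known by construction; the
#' ground-truth mask is the union of the blob disks and the recorded
#' \code{maskThreshold} (nucleus intensity + 20) separates nuclei from
#' background on the reconstructed DAB channel.
#'
#' @param height,width image dimensions.
#' @param nBlobs number of nuclei.
#' @param radius nucleus radius in pixels.
#' @param zone intended tier of the nuclei, one of
#'   \code{\link{scoreTiers}}.
#' @param profile \code{"disk"} (uniform density, default) or
#'   \code{"gaussian"} (soft-edged; density decays with radial distance,
#'   so edge pixels are lighter than the intended zone midpoint).
#' @param bgIntensity DAB intensity of the background (default 240,
#'   i.e. inside the excluded band, emulating blank/fatty areas).
#' @param hemaDensity constant counterstain density.
#' @param noiseSigma intensity noise sd (default 2 counts, a typical
#'   camera read noise).
#' @param seed RNG seed for blob placement and noise.
#' @param system,background forwarded to \code{\link{syntheticSpec}}.
#' @return A \code{\linkS4class{SyntheticSpec}} with ground-truth
#'   \code{nuclearMask}, \code{maskThreshold} and \code{intendedLabel}.
#' @export
makeNuclearBlobs <- function(height = 96, width = 96, nBlobs = 6,
                             radius = 7, zone = "high_positive",
                             profile = c("disk", "gaussian"),
                             bgIntensity = 240, hemaDensity = 0.35,
                             noiseSigma = 2, seed = 1,
                             system = defaultStainSystem(),
                             background = c(255, 255, 255)) {
  profile <- match.arg(profile)
  zone <- match.arg(zone, scoreTiers())
  mids <- zoneMidpoints()
  m <- mids[[zone]]
  peak <- -log10(m / 255)
  bg <- -log10(bgIntensity / 255)
  dab <- matrix(bg, height, width)
  mask <- matrix(FALSE, height, width)
  rows <- row(dab); cols <- col(dab)
  centers <- withLocalSeed(seed, cbind(
    round(stats::runif(nBlobs, radius + 1, height - radius)),
    round(stats::runif(nBlobs, radius + 1, width - radius))
  ))
  for (b in seq_len(nBlobs)) {
    r2 <- (rows - centers[b, 1])^2 + (cols - centers[b, 2])^2
    inside <- r2 <= radius^2
    mask <- mask | inside
    if (profile == "disk") {
      dab[inside] <- peak
    } else {
      g <- peak * exp(-r2 / (2 * (radius / 2)^2))
      dab[inside] <- pmax(dab[inside], g[inside])
    }
  }
  sp <- syntheticSpec(height, width, hemaField = hemaDensity,
                      dabField = dab, noiseSigma = noiseSigma,
                      seed = seed, system = system,
                      background = background)
  sp@nuclearMask <- mask
  sp@maskThreshold <- min(m + 20, 235)
  sp@intendedLabel <- zone
  validObject(sp)
  sp
}
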