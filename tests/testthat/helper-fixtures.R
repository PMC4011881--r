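# Shared fixtures and independent oracles.

tiers <- scoreTiers()

loadAgreementTable <- function(stem, raters = c("rater1", "rater2")) {
  readContingencyTable(
    system.file("extdata", paste0(stem, ".csv"), package = "ihcscore"),
    raters = raters)
}

# Miscalibrated stain system: the DAB vector rotated `degrees` out of
# the true stain plane (away from the complementary axis), the direction
# in which genuine stain leaks into the complementary channel with
# positive density. In-plane rotations leave the stain plane (and hence
# the complementary coordinate) untouched, so they cannot model the
# residual contamination of badly calibrated vectors.
rotateOffPlane <- function(system, degrees) {
  th <- degrees * pi / 180
  d2 <- pmax(cos(th) * system@dab - sin(th) * system@complementary, 0)
  buildStainSystem(system@hematoxylin, d2)
}

# per-pixel reference loop for zone counting (independent of zoneProfile)
naiveZoneCounts <- function(vals, zones) {
  out <- stats::setNames(numeric(nrow(zones)), zones$zone)
  excluded <- 0
  for (px in vals) {
    hit <- FALSE
    for (i in seq_len(nrow(zones))) {
      if (px >= zones$low[i] && px <= zones$high[i]) {
        out[i] <- out[i] + 1
        hit <- TRUE
        break
      }
    }
    if (!hit) excluded <- excluded + 1
  }
  list(zoneCounts = out, excluded = excluded)
}

# exhaustive between-class variance maximization over all 256 cut points
bruteForceOtsu <- function(vals) {
  best <- -1
  bestT <- 0L
  for (t in 0:255) {
    lo <- vals[vals <= t]
    hi <- vals[vals > t]
    if (length(lo) == 0L || length(hi) == 0L) next
    sb <- length(lo) * length(hi) *
      (mean(lo) - mean(hi))^2 / length(vals)^2
    if (sb > best + 1e-12) {
      best <- sb
      bestT <- t
    }
  }
  bestT
}

# forward-compose an RGB image directly from density fields (exact copy
# of the Beer-Lambert model, kept independent of renderSynthetic)
composeRGB <- function(hema, dab, system = defaultStainSystem(),
                       background = c(255, 255, 255), quantize = TRUE) {
  M <- stainMatrix(system)
  od <- outer(as.vector(hema), M[1, ]) + outer(as.vector(dab), M[2, ])
  img <- array(0, dim = c(nrow(hema), ncol(hema), 3))
  for (ch in 1:3) {
    v <- background[ch] * 10^(-od[, ch])
    if (quantize) v <- pmin(pmax(round(v), 0), 255)
    img[, , ch] <- v
  }
  if (quantize) storage.mode(img) <- "integer"
  img
}
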