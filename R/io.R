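# File input/output: images, stain configs, reports.

#' Read a brightfield RGB photomicrograph
#'
#' Reads JPEG, PNG, TIFF (via EBImage) or uncompressed 24-bit BMP into
#' the package's H x W x 3 integer convention (row-major, origin
#' top-left, values 0..255). An alpha channel is stripped with a
#' warning; grayscale input is rejected (scoring requires color).
#' Higher-bit-depth images are rescaled to 8-bit on read.
#'
#' @param path image file path.
#' @return H x W x 3 integer array.
#' @export
readRGBImage <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "bmp") return(readBMP(path))
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) {
    stop("grayscale image: scoring requires a 3-channel RGB image",
         call. = FALSE)
  }
  if (dim(a)[3] == 4L) {
    warning("stripping alpha channel")
    a <- a[, , 1:3, drop = FALSE]
  }
  if (dim(a)[3] != 3L) {
    stop("expected 3 color channels, found ", dim(a)[3], call. = FALSE)
  }
  # EBImage stores x (column) first; transpose to row-major H x W
  out <- aperm(a, c(2L, 1L, 3L))
  out <- round(out * 255)
  storage.mode(out) <- "integer"
  validateRGB(out)
}

# minimal reader for uncompressed 24-bit BMP (BITMAPINFOHEADER, BI_RGB);
# no R package on hand reads BMP
readBMP <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2L)
  if (!identical(as.integer(magic), c(0x42L, 0x4DL))) {
    stop("not a BMP file: ", path, call. = FALSE)
  }
  readBin(con, "raw", 8L)                       # file size + reserved
  dataOffset <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  headerSize <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (headerSize < 40L) stop("unsupported BMP header", call. = FALSE)
  w <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hRaw <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  topDown <- hRaw < 0
  h <- abs(hRaw)
  readBin(con, "integer", 1L, size = 2L, endian = "little")  # planes
  bpp <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  compression <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (bpp != 24L || compression != 0L) {
    stop("only uncompressed 24-bit BMP is supported", call. = FALSE)
  }
  seek(con, dataOffset)
  rowBytes <- ((24 * w + 31) %/% 32) * 4       # rows padded to 4 bytes
  px <- readBin(con, "raw", rowBytes * h)
  out <- array(0L, dim = c(h, w, 3L))
  for (r in seq_len(h)) {
    rowStart <- (r - 1L) * rowBytes
    triplets <- as.integer(px[rowStart + seq_len(3L * w)])
    destRow <- if (topDown) r else h - r + 1L   # BMP rows are bottom-up
    out[destRow, , 1L] <- triplets[seq(3L, by = 3L, length.out = w)]  # B,G,R
    out[destRow, , 2L] <- triplets[seq(2L, by = 3L, length.out = w)]
    out[destRow, , 3L] <- triplets[seq(1L, by = 3L, length.out = w)]
  }
  validateRGB(out)
}

#' Write a single-stain channel image
#'
#' Writes an 8-bit intensity matrix (for example the reconstructed DAB
#' channel or a nuclear mask) as grayscale PNG or TIFF.
#'
#' @param channel H x W integer matrix in [0, 255], or a logical mask
#'   (written as 0/255).
#' @param path output path; format chosen from the extension
#'   (png or tif/tiff).
#' @return The path, invisibly.
#' @export
writeChannelImage <- function(channel, path) {
  if (is.logical(channel)) {
    channel <- matrix(as.integer(channel) * 255L,
                      nrow(channel), ncol(channel))
  }
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "tif", "tiff")) {
    stop("unsupported output format: ", ext, call. = FALSE)
  }
  EBImage::writeImage(t(channel) / 255, path,
                      type = if (ext == "png") "png" else "tiff")
  invisible(path)
}

#' Read stain vectors and background from a JSON config
#'
#' Expected fields: \code{hematoxylin} and \code{dab} (each 3 numbers,
#' the per-channel OD fractions) and optionally \code{background} (3
#' numbers, defaulting to 255 per channel).
#'
#' @param path JSON file path.
#' @return List with \code{system} (\code{\linkS4class{StainSystem}})
#'   and \code{background} (numeric(3)).
#' @export
readStainConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$hematoxylin) || is.null(cfg$dab)) {
    stop("config must provide 'hematoxylin' and 'dab' vectors",
         call. = FALSE)
  }
  bg <- if (is.null(cfg$background)) c(255, 255, 255)
        else rep_len(as.numeric(cfg$background), 3L)
  list(system = buildStainSystem(cfg$hematoxylin, cfg$dab),
       background = bg)
}

#' Write a score report (and profile) as JSON
#'
#' Machine-readable counterpart of the on-screen scoring log: zone
#' percentages, numeric score, tier label, decision path, excluded
#' percentage and, when a profile is given, zone counts and the 256-bin
#' histogram.
#'
#' @param report a \code{\linkS4class{ScoreReport}}.
#' @param path output JSON path.
#' @param profile optional \code{\linkS4class{ZoneProfile}} to embed.
#' @return The path, invisibly.
#' @export
writeScoreReport <- function(report, path, profile = NULL) {
  out <- list(
    percentages = as.list(report@percentages),
    numeric_score = report@numericScore,
    label = report@label,
    decision = report@decision,
    excluded_percent = report@excludedPercent
  )
  if (!is.null(profile)) {
    out$zone_counts <- as.list(zoneCounts(profile))
    out$excluded_count <- excludedCount(profile)
    out$mask_pixels <- profile@maskPixels
    out$histogram <- unname(profile@histogram)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Export a zone profile's histogram as CSV
#'
#' Two columns, \code{intensity} (0..255) and \code{count}.
#'
#' @param profile a \code{\linkS4class{ZoneProfile}}.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeHistogramCSV <- function(profile, path) {
  utils::write.csv(
    data.frame(intensity = 0:255, count = profile@histogram),
    path, row.names = FALSE)
  invisible(path)
}
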