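# Image input/output. Working representation: numeric matrix [row, col]
# with nominal range [0, 255] after load-normalization.

.pngBitDepth <- function(path) {
  # IHDR bit depth is the 25th byte of the file (after the 8-byte signature,
  # 4-byte length, 4-byte "IHDR", 8 bytes width/height).
  hdr <- readBin(path, "raw", n = 25)
  if (length(hdr) < 25) stop("not a PNG file: ", path, call. = FALSE)
  as.integer(hdr[25])
}

.luminance <- function(a) {
  if (length(dim(a)) == 2) return(a)
  if (length(dim(a)) == 3) {
    k <- dim(a)[3]
    if (k == 1) return(a[, , 1])
    # RGB(A): Rec. 601 luminance, alpha ignored
    return(0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3])
  }
  stop("unsupported image array layout", call. = FALSE)
}

#' Read a grayscale image
#'
#' Reads an 8- or 16-bit PNG or TIFF image as a numeric matrix (rows = y,
#' columns = x). RGB images are collapsed by luminance. Values are restored
#' to the file's native integer scale and then normalized: if the dynamic
#' range exceeds [0, 255] the image is min-max rescaled to [0, 255]
#' (an out-of-range constant image maps to 127.5), otherwise values are
#' kept as-is, so 8-bit images round-trip exactly.
#'
#' @param path path to a PNG or TIFF file.
#' @return numeric matrix with values in [0, 255].
#' @export
readGrayImage <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    vals <- .luminance(a) * (2^.pngBitDepth(path) - 1)
  } else if (ext %in% c("tif", "tiff")) {
    a <- tiff::readTIFF(path, as.is = TRUE)
    vals <- .luminance(a)
    if (max(vals) <= 1 && is.double(a)) vals <- vals * 255  # float TIFF
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
  if (length(vals) == 0 || any(dim(vals) == 0))
    stop("zero-size image: ", path, call. = FALSE)
  vals <- round(vals)
  mn <- min(vals); mx <- max(vals)
  if (mn < 0 || mx > 255) {
    if (mx == mn) vals[] <- 127.5
    else vals <- (vals - mn) / (mx - mn) * 255
  }
  storage.mode(vals) <- "double"
  vals
}

#' Write a grayscale image as 8-bit PNG
#'
#' Values are clipped to [0, 255] and rounded.
#'
#' @param img numeric matrix in [0, 255].
#' @param path output path.
#' @export
writeGrayImage <- function(img, path) {
  stopifnot(is.matrix(img))
  ok <- try(png::writePNG(round(.clip255(img)) / 255, target = path),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("cannot write image: ", path, call. = FALSE)
  invisible(path)
}

#' Write a binary mask as 8-bit PNG
#'
#' @param mask matrix with values in {0, 1}.
#' @param path output path.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is.matrix(mask))
  if (!all(mask %in% c(0, 1)))
    stop("mask values must be in {0, 1}", call. = FALSE)
  writeGrayImage(mask * 255, path)
}

#' Read a binary mask from an image file
#'
#' @param path path to a PNG/TIFF mask (any value > 127 is foreground).
#' @return matrix with values in {0, 1}.
#' @export
readMask <- function(path) {
  img <- readGrayImage(path)
  (img > 127) + 0
}
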