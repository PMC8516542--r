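# Internal helpers shared across modules.
#
# Coordinate convention used throughout the package: x = column, y = row,
# both 0-based, pixel centers at integer coordinates; angles in degrees,
# measured from the +x axis, increasing toward +y (image convention, y
# pointing down). R matrices are stored [row, col] 1-based, so a point
# (x, y) addresses pixels[y + 1, x + 1].

.assertGrayImage <- function(img, minSide = 16L, what = "image") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (nrow(img) < minSide || ncol(img) < minSide)
    stop(what, " must be at least ", minSide, "x", minSide, " pixels",
         call. = FALSE)
  if (!all(is.finite(img)))
    stop(what, " contains non-finite values", call. = FALSE)
  invisible(TRUE)
}

.clip255 <- function(x) pmin(pmax(x, 0), 255)

# Shift a matrix by (dy, dx) with replicate borders: result[r, c] =
# m[r + dy, c + dx] clamped to valid indices.
.shiftRep <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dy, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dx, 1L), nc)
  m[ri, ci, drop = FALSE]
}

.gaussKernel1d <- function(sigma, maxRadius = Inf) {
  r <- max(1L, min(as.integer(ceiling(4 * sigma)), maxRadius))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

# Separable Gaussian smoothing with replicate borders (FFT convolution via
# EBImage). Kernel is truncated at 4 sigma and renormalized; on small
# images the truncation radius is further capped so the kernel fits.
.gaussSmooth <- function(img, sigma) {
  cap <- (min(dim(img)) - 1L) %/% 2L
  g <- .gaussKernel1d(sigma, cap)
  EBImage::filter2(img, outer(g, g), boundary = "replicate")
}

# Bilinear interpolation at real 0-based coordinates (x = col, y = row).
# Coordinates are clamped to the image domain.
.bilinear <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(x, 0), nc - 1)
  y <- pmin(pmax(y, 0), nr - 1)
  x0 <- pmin(floor(x), nc - 2); y0 <- pmin(floor(y), nr - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- img[cbind(y0 + 1, x0 + 1)]
  i01 <- img[cbind(y0 + 1, x0 + 2)]
  i10 <- img[cbind(y0 + 2, x0 + 1)]
  i11 <- img[cbind(y0 + 2, x0 + 2)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

# Wrap an angular difference (degrees) to [0, 180].
.angDiff <- function(a, b) {
  d <- abs(a - b) %% 360
  ifelse(d > 180, 360 - d, d)
}

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.logStage <- function(stage, ...) {
  msg <- paste0("[coroseg] ", stage, ": ",
                paste(vapply(list(...), format, character(1)), collapse = " "))
  message(msg)
}
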