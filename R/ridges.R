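# Ridge point detection on the enhanced image. A ridge point approximates
# a local intensity maximum transverse to the vessel: inside the pixel
# cell [(x, y), (x+1, y+1)] the gradient (dot product across diagonal
# neighbor pairs) changes sign, both Hessian eigenvalues are negative on
# all four cell corners, and the enhanced intensity clears a gray
# threshold. A single-pass neighbor-count prefilter then removes
# scattered detections.

#' Detect ridge points
#'
#' The gradient and eigenvalue fields are taken per pixel at the winning
#' scale of the vesselness sweep (slots of the [VesselnessMap-class]);
#' screening uses the enhanced response. Pixel (x, y) is a ridge point iff
#' (a) grad(x,y) . grad(x+1,y+1) < 0 or grad(x+1,y) . grad(x,y+1) < 0, (b)
#' lambda1 < 0 and lambda2 < 0 at all four pixels (x+m, y+n), m,n in
#' {0,1}, and (c) response(x,y) > gray_threshold. Border rows/columns are
#' excluded.
#'
#' @param vmap a [VesselnessMap-class].
#' @param gray_threshold screening floor on the [0, 255] response.
#' @return data.frame with columns `x`, `y` (0-based integer pixel
#'   coordinates), `dirx`, `diry` (along-vessel unit direction); the image
#'   dimensions are attached as attribute `imdim`.
#' @export
detectRidgePoints <- function(vmap, gray_threshold = 10) {
  stopifnot(is(vmap, "VesselnessMap"))
  gx <- vmap@gx; gy <- vmap@gy
  nr <- nrow(gx); nc <- ncol(gx)
  sh <- function(m, dy, dx) .shiftRep(m, dy, dx)
  # dot products of gradient vectors across the two cell diagonals
  d1 <- gx * sh(gx, 1, 1) + gy * sh(gy, 1, 1)
  d2 <- sh(gx, 0, 1) * sh(gx, 1, 0) + sh(gy, 0, 1) * sh(gy, 1, 0)
  # A pixel sitting exactly on a symmetric ridge line has zero transverse
  # derivative g.v2 (the along-vessel component need not vanish on a
  # tapering vessel), so the strict product test sees a 0 instead of a
  # sign change there. Count such pixels directly, and give the products
  # a deadband against floating-point noise.
  g2 <- gx^2 + gy^2
  tol2 <- (1e-6 * sqrt(max(g2)))^2
  s2 <- gx * vmap@v1y - gy * vmap@v1x  # g . v2, with v2 = (v1y, -v1x)
  transZero <- abs(s2) < 1e-4 * max(abs(s2), 1e-12)
  signFlip <- d1 < -tol2 | d2 < -tol2 | transZero
  # Height-ridge condition: strict transverse curvature (lambda2 < 0).
  # The along-vessel eigenvalue of a tube is ~0 and its sign is not
  # informative (it turns slightly positive where another branch's skirt
  # creates a saddle along the vessel, e.g. for ~20 px past a junction);
  # what separates ridge lines from blobs is the blobness ratio
  # |lambda1|/|lambda2|, capped here at 0.25.
  tolL <- 1e-6 * max(abs(vmap@lambda2))
  neg <- vmap@lambda2 < 0 &
    abs(vmap@lambda1) < pmax(tolL, 0.25 * abs(vmap@lambda2))
  allNeg <- neg & sh(neg, 0, 1) & sh(neg, 1, 0) & sh(neg, 1, 1)
  keep <- signFlip & allNeg & (vmap@response > gray_threshold)
  keep[c(1, nr), ] <- FALSE
  keep[, c(1, nc)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  out <- data.frame(x = idx[, "col"] - 1L, y = idx[, "row"] - 1L,
                    dirx = vmap@v1x[idx], diry = vmap@v1y[idx])
  attr(out, "imdim") <- c(nr, nc)
  out
}

#' Prefilter scattered ridge points
#'
#' For each ridge point P, N_R(P) counts the other input ridge points
#' within Euclidean distance `radius`; P is kept iff N_R(P) >= tau_R.
#' Counting is a single pass against the input set (not iterated), so the
#' output is a subset of the input but the filter is not idempotent.
#'
#' @param ridges data.frame from [detectRidgePoints()].
#' @param tau_R minimum neighbor count, >= 0.
#' @param radius neighborhood radius in pixels, > 0 (default 3, keeping
#'   8-connected ridge chains while removing isolated speckle).
#' @return filtered data.frame (same columns and `imdim` attribute).
#' @export
filterScatteredRidges <- function(ridges, tau_R = 3L, radius = 3.0) {
  stopifnot(tau_R >= 0, radius > 0)
  n <- nrow(ridges)
  if (n == 0 || tau_R == 0) return(ridges)
  # bucket points on a coarse grid; only neighboring buckets can hold
  # points within `radius`
  cell <- ceiling(radius)
  cx <- ridges$x %/% cell; cy <- ridges$y %/% cell
  key <- paste(cx, cy)
  buckets <- split(seq_len(n), key)
  nR <- integer(n)
  for (i in seq_len(n)) {
    cnt <- 0L
    for (ox in -1:1) for (oy in -1:1) {
      b <- buckets[[paste(cx[i] + ox, cy[i] + oy)]]
      if (is.null(b)) next
      d2 <- (ridges$x[b] - ridges$x[i])^2 + (ridges$y[b] - ridges$y[i])^2
      cnt <- cnt + sum(d2 <= radius^2)
    }
    nR[i] <- cnt - 1L  # exclude the point itself
  }
  out <- ridges[nR >= tau_R, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "imdim") <- attr(ridges, "imdim")
  out
}
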