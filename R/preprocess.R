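# Preprocessing chain: collaborative block-matching denoising, unsharp
# masking, contrast-limited adaptive histogram equalization. Applied in
# that order before vesselness enhancement.

# Orthonormal DCT-II matrix of size n.
.dctMatrix <- function(n) {
  k <- 0:(n - 1)
  D <- sqrt(2 / n) * cos(pi * outer(k, 2 * k + 1) / (2 * n))
  D[1, ] <- D[1, ] / sqrt(2)
  D
}

#' Collaborative block-matching denoising
#'
#' Simplified two-stage collaborative filter for additive Gaussian noise:
#' image blocks on a coarse grid are matched by L2 distance within a search
#' window, each block is hard-thresholded in the 2D DCT domain, matched
#' groups are averaged (the collaborative step), and the overlapping group
#' estimates are aggregated with weights proportional to the inverse
#' retained-coefficient count. `noise_sigma = 0` returns the input
#' unchanged.
#'
#' @param img numeric matrix in [0, 255].
#' @param noise_sigma assumed noise standard deviation on the [0, 255]
#'   scale.
#' @param block_size block side in pixels.
#' @param search_window half-size of the block-matching search window, px.
#' @param max_group maximum number of blocks per group.
#' @return denoised matrix, clipped to [0, 255].
#' @export
denoiseImage <- function(img, noise_sigma = 10, block_size = 8L,
                         search_window = 16L, max_group = 8L) {
  .assertGrayImage(img)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (block_size > search_window)
    stop("block_size must not exceed search_window", call. = FALSE)
  if (noise_sigma == 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  B <- as.integer(block_size)
  if (B > min(nr, nc)) stop("block larger than image", call. = FALSE)
  stride <- max(1L, B %/% 2L)

  gr <- unique(c(seq(1L, nr - B + 1L, by = stride), nr - B + 1L))
  gc <- unique(c(seq(1L, nc - B + 1L, by = stride), nc - B + 1L))
  pos <- expand.grid(r = gr, c = gc)                  # grid block top-lefts
  base <- (pos$c - 1L) * nr + pos$r                   # linear index
  offs <- as.vector(outer(0:(B - 1L), nr * (0:(B - 1L)), "+"))
  idx <- outer(base, offs, "+")                       # nblk x B^2
  blocks <- matrix(img[idx], nrow(idx), ncol(idx))

  K <- kronecker(.dctMatrix(B), .dctMatrix(B))        # 2D DCT on vec(X)
  tb <- blocks %*% t(K)
  thr <- 2.7 * noise_sigma
  keep <- abs(tb) >= thr
  keep[, 1] <- TRUE                                   # DC always kept
  nret <- rowSums(keep)
  filt <- (tb * keep) %*% K                           # inverse (orthonormal)

  # block matching on the grid: candidate offsets are grid-stride multiples
  ngr <- length(gr); ngc <- length(gc)
  gi <- rep(seq_len(ngr), times = ngc)
  gj <- rep(seq_len(ngc), each = ngr)
  span <- max(1L, as.integer(search_window) %/% stride)
  offsets <- expand.grid(oi = -span:span, oj = -span:span)
  nb <- nrow(blocks)
  dmat <- matrix(Inf, nb, nrow(offsets))
  cand <- matrix(NA_integer_, nb, nrow(offsets))
  for (o in seq_len(nrow(offsets))) {
    ci <- gi + offsets$oi[o]; cj <- gj + offsets$oj[o]
    ok <- ci >= 1 & ci <= ngr & cj >= 1 & cj <= ngc
    tgt <- (cj - 1L) * ngr + ci
    tgt[!ok] <- NA_integer_
    cand[, o] <- tgt
    w <- which(ok)
    if (length(w))
      dmat[w, o] <- rowSums((blocks[w, , drop = FALSE] -
                             blocks[tgt[w], , drop = FALSE])^2)
  }
  matchTol <- B^2 * (3 * noise_sigma)^2
  ord <- t(apply(dmat, 1, order))[, seq_len(min(max_group, ncol(dmat))),
                                  drop = FALSE]
  rows <- rep(seq_len(nb), each = ncol(ord))
  cols <- as.vector(t(ord))
  memb <- cand[cbind(rows, cols)]
  good <- !is.na(memb) & dmat[cbind(rows, cols)] <= matchTol
  rows <- rows[good]; memb <- memb[good]

  gsum <- rowsum(filt[memb, , drop = FALSE], rows)
  gcnt <- as.vector(rowsum(rep(1, length(rows)), rows))
  gblk <- gsum / gcnt                                 # collaborative mean
  gret <- as.vector(rowsum(nret[memb], rows)) / gcnt
  refs <- as.integer(rownames(gsum))
  wts <- 1 / (1 + gret)

  est <- numeric(nr * nc); wsum <- numeric(nr * nc)
  tgtIdx <- as.vector(idx[refs, , drop = FALSE])
  vals <- as.vector(gblk * wts)
  wrep <- as.vector(matrix(wts, length(refs), B^2))
  acc <- rowsum(cbind(vals, wrep), tgtIdx)
  at <- as.integer(rownames(acc))
  est[at] <- acc[, 1]; wsum[at] <- acc[, 2]
  out <- img
  covered <- wsum > 0
  out[covered] <- est[covered] / wsum[covered]
  .clip255(matrix(out, nr, nc))
}

#' Unsharp masking
#'
#' Sharpens by adding back the high-frequency residual: the low-pass image
#' is subtracted from the input to form the mask g_mask = I - lowpass(I),
#' and the output is g = I + k * g_mask, clipped to [0, 255]. The low-pass
#' filter is a mean filter with replicate borders. `k = 0` is the identity.
#'
#' @param img numeric matrix.
#' @param k enlarge coefficient, >= 0.
#' @param kernel_size odd mean-filter size >= 3, pixels.
#' @return sharpened matrix in [0, 255].
#' @export
unsharpMask <- function(img, k = 1.5, kernel_size = 9L) {
  stopifnot(is.matrix(img), all(is.finite(img)))
  if (k < 0) stop("k must be >= 0", call. = FALSE)
  ks <- as.integer(kernel_size)
  if (ks %% 2L == 0L || ks < 3L)
    stop("kernel_size must be odd and >= 3", call. = FALSE)
  .clip255(.umRaw(img, k, ks))
}

# Unclipped unsharp mask (exactly linear: um(a*I) = a*um(I)).
.umRaw <- function(img, k, ks) {
  h <- (ks - 1L) %/% 2L
  lp <- matrix(0, nrow(img), ncol(img))
  for (dy in -h:h) for (dx in -h:h) lp <- lp + .shiftRep(img, dy, dx)
  lp <- lp / ks^2
  img + k * (img - lp)
}

#' Clip a histogram with redistribution
#'
#' Bins exceeding the clip limit are truncated and the excess is
#' redistributed equally among all bins; because redistribution can push
#' bins back over the limit, the rule is iterated until the residual excess
#' falls below one count (or 16 iterations). The total count is conserved.
#'
#' @param hist numeric vector of non-negative bin counts.
#' @param clip_limit_count clip limit in counts, > 0.
#' @return clipped histogram with the same sum.
#' @export
clipHistogram <- function(hist, clip_limit_count) {
  stopifnot(is.numeric(hist), all(hist >= 0))
  if (clip_limit_count <= 0)
    stop("clip_limit_count must be > 0", call. = FALSE)
  h <- as.numeric(hist)
  for (i in 1:16) {
    excess <- sum(pmax(h - clip_limit_count, 0))
    if (excess < 1) break
    h <- pmin(h, clip_limit_count) + excess / length(h)
  }
  h
}

#' Contrast-limited adaptive histogram equalization
#'
#' The image is divided into a tile grid; each tile's histogram is clipped
#' (see [clipHistogram()]; the limit is `clip_limit` times the uniform bin
#' height) and turned into a CDF mapping to [0, 255]. Each pixel is mapped
#' by bilinear interpolation between the mappings of the four surrounding
#' tile centers.
#'
#' @param img numeric matrix in [0, 255].
#' @param clip_limit clip limit as a multiple of the uniform bin height,
#'   >= 1. Large values reduce to plain adaptive histogram equalization.
#' @param tile_rows,tile_cols tile grid size.
#' @param n_bins number of histogram bins.
#' @return equalized matrix in [0, 255].
#' @export
clahe <- function(img, clip_limit = 2.5, tile_rows = 8L, tile_cols = 8L,
                  n_bins = 256L) {
  stopifnot(is.matrix(img), all(is.finite(img)))
  nr <- nrow(img); nc <- ncol(img)
  if (tile_rows > nr || tile_cols > nc)
    stop("tile grid larger than image", call. = FALSE)
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  if (clip_limit < 1) stop("clip_limit must be >= 1", call. = FALSE)
  tr <- as.integer(tile_rows); tc <- as.integer(tile_cols)
  nb <- as.integer(n_bins)

  bin <- pmin(pmax(floor(img / 256 * nb), 0), nb - 1)  # 0-based bin index
  rb <- round(seq(0, nr, length.out = tr + 1))         # tile row breaks
  cb <- round(seq(0, nc, length.out = tc + 1))
  ctrR <- (rb[-1] + rb[-(tr + 1)] - 1) / 2             # 0-based centers
  ctrC <- (cb[-1] + cb[-(tc + 1)] - 1) / 2

  maps <- matrix(0, nb, tr * tc)                       # per-tile mapping
  for (i in seq_len(tr)) for (j in seq_len(tc)) {
    rows <- (rb[i] + 1):rb[i + 1]; cols <- (cb[j] + 1):cb[j + 1]
    b <- bin[rows, cols]
    n <- length(b)
    h <- tabulate(as.vector(b) + 1L, nbins = nb)
    h <- clipHistogram(h, clip_limit * n / nb)
    maps[, (j - 1L) * tr + i] <- 255 * cumsum(h) / n
  }

  out <- matrix(0, nr, nc)
  # interpolation cells: between consecutive tile centers, clamped outside
  rEdges <- c(0, floor(ctrR) + 1, nr)                  # cell row boundaries
  cEdges <- c(0, floor(ctrC) + 1, nc)
  for (ci in seq_len(tr + 1)) for (cj in seq_len(tc + 1)) {
    r0 <- rEdges[ci]; r1 <- rEdges[ci + 1]
    c0 <- cEdges[cj]; c1 <- cEdges[cj + 1]
    if (r1 <= r0 || c1 <= c0) next
    rows <- (r0 + 1):r1; cols <- (c0 + 1):c1
    iT <- max(ci - 1L, 1L); iB <- min(ci, tr)          # tile rows above/below
    jL <- max(cj - 1L, 1L); jR <- min(cj, tc)
    y <- rows - 1; x <- cols - 1
    wy <- if (iT == iB) rep(0, length(y)) else
      (y - ctrR[iT]) / (ctrR[iB] - ctrR[iT])
    wx <- if (jL == jR) rep(0, length(x)) else
      (x - ctrC[jL]) / (ctrC[jR] - ctrC[jL])
    wy <- pmin(pmax(wy, 0), 1); wx <- pmin(pmax(wx, 0), 1)
    b <- bin[rows, cols] + 1L
    WY <- matrix(wy, length(y), length(x))
    WX <- matrix(wx, length(y), length(x), byrow = TRUE)
    mTL <- matrix(maps[cbind(as.vector(b), (jL - 1L) * tr + iT)],
                  length(y), length(x))
    mTR <- matrix(maps[cbind(as.vector(b), (jR - 1L) * tr + iT)],
                  length(y), length(x))
    mBL <- matrix(maps[cbind(as.vector(b), (jL - 1L) * tr + iB)],
                  length(y), length(x))
    mBR <- matrix(maps[cbind(as.vector(b), (jR - 1L) * tr + iB)],
                  length(y), length(x))
    out[rows, cols] <- (1 - WY) * ((1 - WX) * mTL + WX * mTR) +
      WY * ((1 - WX) * mBL + WX * mBR)
  }
  .clip255(out)
}
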