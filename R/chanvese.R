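# Region-based active-contour segmentation (Chan-Vese piecewise-constant
# model). The level-set field w is positive inside the contour, negative
# outside, zero on it. The energy is
#   F = u * integral delta(w) |grad w|        (contour length)
#     + v * integral H(w)                     (inside area)
#     + lambda0 * integral (I - c0)^2 (1 - H(w))   (outside fit)
#     + lambdab * integral (I - cb)^2 H(w)         (inside fit)
# minimized by explicit gradient descent on the regularized
# Euler-Lagrange form, with periodic signed-distance reinitialization.

#' Regularized Heaviside and delta functions
#'
#' Smooth arctangent regularization: H_eps(w) = (1 + (2/pi) atan(w /
#' eps)) / 2, with H_eps(0) = 1/2 and limits 0 / 1 at -/+ infinity.
#' `deltaReg` is its exact derivative.
#'
#' @param w level-set values (scalar or matrix).
#' @param epsilon regularization width in pixels, > 0.
#' @return values in (0, 1) (`heavisideReg`) or > 0 (`deltaReg`).
#' @export
heavisideReg <- function(w, epsilon = 1.5) {
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  0.5 * (1 + (2 / pi) * atan(w / epsilon))
}

#' @rdname heavisideReg
#' @export
deltaReg <- function(w, epsilon = 1.5) {
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  (epsilon / pi) / (epsilon^2 + w^2)
}

#' Region means of the two-phase partition
#'
#' cb is the H-weighted (inside) mean, c0 the (1-H)-weighted (outside)
#' mean. A degenerate all-inside or all-outside field assigns the global
#' mean to the empty region.
#'
#' @param img numeric matrix.
#' @param w level-set field, same shape.
#' @param epsilon Heaviside regularization width.
#' @return list with `c0` (outside) and `cb` (inside).
#' @export
regionMeans <- function(img, w, epsilon = 1.5) {
  stopifnot(identical(dim(img), dim(w)))
  H <- heavisideReg(w, epsilon)
  sIn <- sum(H); sOut <- sum(1 - H)
  gm <- mean(img)
  cb <- if (sIn > 1e-9) sum(img * H) / sIn else gm
  c0 <- if (sOut > 1e-9) sum(img * (1 - H)) / sOut else gm
  list(c0 = c0, cb = cb)
}

#' Energy of a level-set configuration
#'
#' Discrete sums of the four energy terms; the length term uses
#' delta_eps(w) |grad w| with central differences.
#'
#' @param img numeric matrix.
#' @param w level-set field.
#' @param means list with `c0`, `cb` (see [regionMeans()]).
#' @param u,v,lambda0,lambdab term weights.
#' @param epsilon Heaviside regularization width.
#' @return list with `length_term`, `area_term`, `outside_term`,
#'   `inside_term`, `total`.
#' @export
cvEnergy <- function(img, w, means, u = 0.2 * 255^2, v = 0,
                     lambda0 = 1, lambdab = 1, epsilon = 1.5) {
  stopifnot(identical(dim(img), dim(w)))
  H <- heavisideReg(w, epsilon)
  dl <- deltaReg(w, epsilon)
  wx <- (.shiftRep(w, 0, 1) - .shiftRep(w, 0, -1)) / 2
  wy <- (.shiftRep(w, 1, 0) - .shiftRep(w, -1, 0)) / 2
  gm <- sqrt(wx^2 + wy^2)
  lt <- u * sum(dl * gm)
  at <- v * sum(H)
  ot <- lambda0 * sum((img - means$c0)^2 * (1 - H))
  it <- lambdab * sum((img - means$cb)^2 * H)
  list(length_term = lt, area_term = at, outside_term = ot,
       inside_term = it, total = lt + at + ot + it)
}

#' Initial level-set field
#'
#' `checkerboard`: w = sin(pi x / p) sin(pi y / p) with period `p` (both
#' signs present, seeds contours everywhere). `circle`: signed distance to
#' the given circle, positive inside.
#'
#' @param shape integer c(rows, cols).
#' @param kind "checkerboard" or "circle".
#' @param period checkerboard half-period in pixels.
#' @param center circle center c(x, y), 0-based; defaults to the image
#'   center.
#' @param radius circle radius in pixels; defaults to a quarter of the
#'   smaller side.
#' @return level-set matrix.
#' @export
initLevelSet <- function(shape, kind = c("checkerboard", "circle"),
                         period = 16, center = NULL, radius = NULL) {
  kind <- match.arg(kind)
  nr <- shape[1]; nc <- shape[2]
  x <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  y <- matrix(0:(nr - 1), nr, nc)
  if (kind == "checkerboard") {
    sin(pi * x / period) * sin(pi * y / period)
  } else {
    if (is.null(center)) center <- c((nc - 1) / 2, (nr - 1) / 2)
    if (is.null(radius)) radius <- min(nr, nc) / 4
    radius - sqrt((x - center[1])^2 + (y - center[2])^2)
  }
}

# Rebuild w as an (approximate) signed distance to its current zero level
# using exact Euclidean distance transforms on the sign mask.
.reinitSignedDistance <- function(w) {
  inside <- w > 0
  if (all(inside) || !any(inside)) return(w)
  dIn <- as.matrix(EBImage::distmap(inside + 0))
  dOut <- as.matrix(EBImage::distmap(1 - inside))
  ifelse(inside, dIn - 0.5, -(dOut - 0.5))
}

#' Evolve the level-set field
#'
#' Explicit gradient descent: dw/dt = delta_eps(w) * (u * div(grad w /
#' |grad w|) - v - lambdab (I - cb)^2 + lambda0 (I - c0)^2), with region
#' means recomputed each iteration and |grad w| floored at 1e-8 in the
#' curvature term. Every `reinit_every` iterations w is rebuilt as a
#' signed distance to its zero level. Stops at `max_iter` or when the
#' relative change of the total energy stays below `tol` for 5 consecutive
#' iterations.
#'
#' Numerics: the energy is invariant (up to a constant factor) under
#' jointly rescaling the image to [0, 1] and the weights by 255^2, so the
#' descent is performed on the normalized intensities — this keeps the
#' explicit step stable at the default dt with weights stated on the
#' [0, 255] scale. The recorded energy history is on the original scale.
#'
#' @param img numeric matrix.
#' @param w0 initial level-set field (see [initLevelSet()]).
#' @param u,v,lambda0,lambdab energy weights.
#' @param epsilon Heaviside regularization width.
#' @param dt descent step size.
#' @param max_iter iteration cap.
#' @param tol relative energy-change stopping tolerance.
#' @param reinit_every signed-distance reinitialization period.
#' @return list with the final field `w` and `history`, a data.frame of
#'   per-iteration energy terms.
#' @export
evolveLevelSet <- function(img, w0, u = 0.2 * 255^2, v = 0, lambda0 = 1,
                           lambdab = 1, epsilon = 1.5, dt = 0.5,
                           max_iter = 500L, tol = 1e-5,
                           reinit_every = 50L) {
  stopifnot(identical(dim(img), dim(w0)), dt > 0, epsilon > 0)
  w <- w0
  scl <- 255
  imgS <- img / scl                 # descent on normalized intensities
  uS <- u / scl^2; vS <- v / scl^2  # (identical energy landscape)
  hist <- vector("list", max_iter)
  prevE <- NA_real_
  calm <- 0L
  for (it in seq_len(max_iter)) {
    # means over the sharp partition: the H_eps-weighted means mix in
    # near-contour pixels of the other phase, which biases the fit badly
    # when structures are only a few epsilon wide (thin vessels)
    ins <- w > 0
    gmn <- mean(imgS)
    mns <- list(cb = if (any(ins)) mean(imgS[ins]) else gmn,
                c0 = if (any(!ins)) mean(imgS[!ins]) else gmn)
    wx <- (.shiftRep(w, 0, 1) - .shiftRep(w, 0, -1)) / 2
    wy <- (.shiftRep(w, 1, 0) - .shiftRep(w, -1, 0)) / 2
    wxx <- .shiftRep(w, 0, 1) - 2 * w + .shiftRep(w, 0, -1)
    wyy <- .shiftRep(w, 1, 0) - 2 * w + .shiftRep(w, -1, 0)
    wxy <- (.shiftRep(w, 1, 1) - .shiftRep(w, 1, -1) -
            .shiftRep(w, -1, 1) + .shiftRep(w, -1, -1)) / 4
    g2 <- wx^2 + wy^2
    curv <- (wxx * wy^2 - 2 * wx * wy * wxy + wyy * wx^2) /
      (g2^1.5 + 1e-8)
    fit <- lambda0 * (imgS - mns$c0)^2 - lambdab * (imgS - mns$cb)^2
    # The fit forcing acts on all level sets (the regularized delta scales
    # only the geometric terms): a diagonally preconditioned descent of
    # the same energy that keeps far-from-contour pixels mobile, so the
    # evolution is not trapped by its initialization.
    w <- w + dt * (deltaReg(w, epsilon) * (uS * curv - vS) + fit)
    if (!all(is.finite(w)))
      stop("level-set evolution diverged (non-finite field) at iteration ",
           it, "; reduce dt", call. = FALSE)
    # energy recorded before reinitialization: reinit reshapes w without
    # moving the contour, but changes the regularized terms
    mns2 <- regionMeans(img, w, epsilon)
    en <- cvEnergy(img, w, mns2, u, v, lambda0, lambdab, epsilon)
    if (reinit_every > 0 && it %% reinit_every == 0L)
      w <- .reinitSignedDistance(w)
    hist[[it]] <- c(iter = it, length_term = en$length_term,
                    area_term = en$area_term,
                    outside_term = en$outside_term,
                    inside_term = en$inside_term, total = en$total)
    if (!is.na(prevE)) {
      rel <- abs(en$total - prevE) / max(abs(prevE), 1e-12)
      calm <- if (rel < tol) calm + 1L else 0L
      if (calm >= 5L) { hist <- hist[seq_len(it)]; break }
    }
    prevE <- en$total
    if (it == max_iter) hist <- hist[seq_len(it)]
  }
  list(w = w, history = as.data.frame(do.call(rbind, hist)))
}

# Closed sub-pixel contours of the zero level of w (marching squares with
# linear interpolation). Rings at the border are closed through a padded
# negative frame.
.zeroContours <- function(w) {
  nr <- nrow(w); nc <- ncol(w)
  pad <- matrix(-abs(max(abs(w))) - 1, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- w
  # contourLines indexes z[x, y]: transpose so x = column, y = row
  cl <- grDevices::contourLines(x = seq(-1, nc), y = seq(-1, nr),
                                z = t(pad), levels = 0)
  lapply(cl, function(l) {
    xy <- cbind(x = l$x, y = l$y)
    if (nrow(xy) > 1 &&
        (xy[1, 1] != xy[nrow(xy), 1] || xy[1, 2] != xy[nrow(xy), 2]))
      xy <- rbind(xy, xy[1, , drop = FALSE])
    xy
  })
}

#' Segment an image with the Chan-Vese model
#'
#' Runs [initLevelSet()] + [evolveLevelSet()] and extracts the binary mask
#' {w > 0} and the closed sub-pixel contours of the zero level. With
#' v = 0 and lambda0 = lambdab the energy is invariant to swapping the
#' inside/outside labels, so the sign of w is canonicalized to make the
#' inside the brighter phase (vessels are bright in the enhanced image);
#' the returned partition is therefore init-independent.
#'
#' @param img numeric matrix (typically the vesselness-enhanced image).
#' @param init "circle" (default: a small circle seeded at the brightest
#'   pixel) or "checkerboard".
#' @param ... passed to [evolveLevelSet()] and [initLevelSet()]
#'   (`period`, `center`, `radius`).
#' @return list with `mask` (binary matrix), `contours` (list of closed
#'   polyline matrices, 0-based x/y columns), `w`, `history`.
#' @export
segmentVessels <- function(img, init = "circle", ...) {
  .assertGrayImage(img)
  if (max(img) == min(img)) {
    warning("constant image: nothing to segment (degenerate empty mask)",
            call. = FALSE)
    return(list(mask = matrix(0, nrow(img), ncol(img)), contours = list(),
                w = matrix(-1, nrow(img), ncol(img)),
                history = data.frame()))
  }
  dots <- list(...)
  initArgs <- dots[names(dots) %in% c("period", "center", "radius")]
  evoArgs <- dots[!names(dots) %in% c("period", "center", "radius")]
  if (init == "circle" && is.null(initArgs$center)) {
    # default: seed a small circle at the brightest pixel — certainly
    # inside a vessel on an enhanced image, so the inside mean starts
    # high and the contour grows outward into the bright phase
    k <- arrayInd(which.max(img), dim(img))
    initArgs$center <- c(k[2] - 1, k[1] - 1)
    if (is.null(initArgs$radius)) initArgs$radius <- 5
  }
  w0 <- do.call(initLevelSet, c(list(shape = dim(img), kind = init),
                                initArgs))
  res <- do.call(evolveLevelSet, c(list(img = img, w0 = w0), evoArgs))
  # canonical labeling: inside (w > 0) is the brighter phase
  inside <- res$w > 0
  if (any(inside) && any(!inside) &&
      mean(img[inside]) < mean(img[!inside]))
    res$w <- -res$w
  mask <- (res$w > 0) + 0
  if (!any(mask == 1)) {
    warning("empty segmentation mask", call. = FALSE)
    contours <- list()
  } else {
    contours <- .zeroContours(res$w)
  }
  .logStage("chanvese",
            sprintf("iters=%d mask_px=%d contours=%d",
                    nrow(res$history), sum(mask), length(contours)))
  list(mask = mask, contours = contours, w = res$w, history = res$history)
}
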