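# Multiscale Hessian vesselness enhancement. The similarity function
# responds to bright tubular structures: for ordered Hessian eigenvalues
# |lambda1| <= |lambda2| it is zero unless lambda2 < 0, and otherwise
#   V = exp(-RB^2 / (2 beta^2)) * exp(-2 m^2 / lambda2^2)
#       * (1 - exp(-SH^2 / (2 c^2))),
# with RB = |lambda1|/|lambda2| (blobness) and SH = sqrt(lambda1^2 +
# lambda2^2) (Hessian norm). The per-pixel response is the maximum over a
# sweep of Gaussian scales with sigma^gamma derivative normalization.

#' Gaussian Hessian at one scale
#'
#' Smooths the image with a Gaussian of standard deviation `sigma`
#' (replicate borders) and applies central second differences, multiplying
#' each field by `sigma^gamma_norm` (scale normalization). `Hxy` equals
#' `Hyx` by construction.
#'
#' @param img numeric matrix.
#' @param sigma Gaussian scale, > 0 and at most min(dim)/4.
#' @param gamma_norm normalization exponent (2 makes cross-scale maxima
#'   comparable).
#' @return list with matrices `hxx`, `hxy`, `hyy` and the smoothed image
#'   `smoothed`.
#' @export
hessianAtScale <- function(img, sigma, gamma_norm = 2) {
  stopifnot(is.matrix(img), all(is.finite(img)))
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (sigma > min(dim(img)) / 4)
    stop("sigma too large for image size", call. = FALSE)
  s <- .gaussSmooth(img, sigma)
  sc <- sigma^gamma_norm
  # x = column, y = row
  hxx <- (.shiftRep(s, 0, 1) - 2 * s + .shiftRep(s, 0, -1)) * sc
  hyy <- (.shiftRep(s, 1, 0) - 2 * s + .shiftRep(s, -1, 0)) * sc
  hxy <- (.shiftRep(s, 1, 1) - .shiftRep(s, 1, -1) -
          .shiftRep(s, -1, 1) + .shiftRep(s, -1, -1)) / 4 * sc
  list(hxx = hxx, hxy = hxy, hyy = hyy, smoothed = s)
}

#' Ordered eigendecomposition of a symmetric 2x2 Hessian
#'
#' Closed-form eigenvalues ordered by absolute value (|lambda1| <=
#' |lambda2|); when the magnitudes tie, the more negative value is taken as
#' lambda2 (the ridge eigenvalue). `v2` is the unit eigenvector of lambda2
#' (cross-vessel direction), `v1` the orthogonal along-vessel direction.
#' All arguments may be equal-shaped matrices.
#'
#' @param hxx,hxy,hyy Hessian entries (scalars or matrices).
#' @return list with `lambda1`, `lambda2`, `v1x`, `v1y`, `v2x`, `v2y`.
#' @export
eigenOrdered <- function(hxx, hxy, hyy) {
  half <- (hxx + hyy) / 2
  disc <- sqrt(((hxx - hyy) / 2)^2 + hxy^2)
  muA <- half + disc
  muB <- half - disc              # muB <= muA, so muB is the more negative
  swap <- abs(muA) > abs(muB)     # tie -> keep muB (more negative) as lambda2
  lam2 <- ifelse(swap, muA, muB)
  lam1 <- ifelse(swap, muB, muA)
  # eigenvector of lam2: rows of (H - lam2 I) are orthogonal to it
  ax <- hxy; ay <- lam2 - hxx
  bx <- lam2 - hyy; by <- hxy
  useB <- (ax^2 + ay^2) < (bx^2 + by^2)
  vx <- ifelse(useB, bx, ax)
  vy <- ifelse(useB, by, ay)
  nrm <- sqrt(vx^2 + vy^2)
  degen <- nrm < 1e-12            # isotropic: any orthonormal pair
  vx <- ifelse(degen, 1, vx / pmax(nrm, 1e-12))
  vy <- ifelse(degen, 0, vy / pmax(nrm, 1e-12))
  list(lambda1 = lam1, lambda2 = lam2,
       v1x = -vy, v1y = vx, v2x = vx, v2y = vy)
}

#' Single-scale vesselness from ordered eigenvalues
#'
#' @param lambda1,lambda2 ordered eigenvalues (|lambda1| <= |lambda2|);
#'   scalars or matrices.
#' @param beta blobness sensitivity, > 0.
#' @param c structureness sensitivity, > 0.
#' @param m curvature floor parameter; 0 disables the middle factor.
#' @return vesselness in [0, 1); zero wherever lambda2 >= 0.
#' @export
vesselnessSingleScale <- function(lambda1, lambda2, beta = 0.5, c = 20,
                                  m = 0) {
  stopifnot(beta > 0, c > 0, m >= 0)
  rb2 <- ifelse(lambda2 == 0, 0, (lambda1 / lambda2)^2)
  sh2 <- lambda1^2 + lambda2^2
  mid <- if (m == 0) 1 else ifelse(lambda2 == 0, 0,
                                   exp(-2 * m^2 / lambda2^2))
  v <- exp(-rb2 / (2 * beta^2)) * mid * (1 - exp(-sh2 / (2 * c^2)))
  ifelse(lambda2 < 0, v, 0)
}

#' Multiscale vesselness enhancement
#'
#' Sweeps `n_scales` Gaussian scales uniformly spaced in
#' [`sigma_min`, `sigma_max`] and takes the per-pixel maximum single-scale
#' vesselness. The input must already have bright vessels (invert dark
#' images first). The returned [VesselnessMap-class] carries, at each
#' pixel's winning scale, the Hessian eigenvalues, the along-vessel
#' eigenvector and the smoothed-image gradient, which the ridge detector
#' and the tracker consume.
#'
#' @param img numeric matrix, bright-vessel polarity.
#' @param beta,c,m similarity-function parameters (see
#'   [vesselnessSingleScale()]).
#' @param sigma_min,sigma_max,n_scales scale sweep.
#' @param gamma_norm derivative normalization exponent.
#' @return a [VesselnessMap-class]; its `response` is rescaled to [0, 255].
#' @export
vesselnessMultiscale <- function(img, beta = 0.5, c = 20, m = 0,
                                 sigma_min = 1, sigma_max = 10,
                                 n_scales = 10L, gamma_norm = 2) {
  .assertGrayImage(img)
  if (n_scales < 1) stop("n_scales must be >= 1", call. = FALSE)
  scales <- if (n_scales == 1) sigma_min else
    seq(sigma_min, sigma_max, length.out = n_scales)
  nr <- nrow(img); nc <- ncol(img)
  best <- matrix(-1, nr, nc)
  out <- list(sigma = matrix(scales[1], nr, nc),
              lambda1 = matrix(0, nr, nc), lambda2 = matrix(0, nr, nc),
              v1x = matrix(1, nr, nc), v1y = matrix(0, nr, nc),
              gx = matrix(0, nr, nc), gy = matrix(0, nr, nc))
  for (s in scales) {
    h <- hessianAtScale(img, s, gamma_norm)
    e <- eigenOrdered(h$hxx, h$hxy, h$hyy)
    v <- vesselnessSingleScale(e$lambda1, e$lambda2, beta, c, m)
    upd <- v > best
    best[upd] <- v[upd]
    out$sigma[upd] <- s
    out$lambda1[upd] <- e$lambda1[upd]
    out$lambda2[upd] <- e$lambda2[upd]
    out$v1x[upd] <- e$v1x[upd]
    out$v1y[upd] <- e$v1y[upd]
    gx <- (.shiftRep(h$smoothed, 0, 1) - .shiftRep(h$smoothed, 0, -1)) / 2
    gy <- (.shiftRep(h$smoothed, 1, 0) - .shiftRep(h$smoothed, -1, 0)) / 2
    out$gx[upd] <- gx[upd]
    out$gy[upd] <- gy[upd]
  }
  raw <- pmax(best, 0)
  mx <- max(raw); mn <- min(raw)
  resp <- if (mx > mn) (raw - mn) / (mx - mn) * 255 else matrix(0, nr, nc)
  new("VesselnessMap", response = resp, raw = raw, sigma = out$sigma,
      lambda1 = out$lambda1, lambda2 = out$lambda2,
      v1x = out$v1x, v1y = out$v1y, gx = out$gx, gy = out$gy,
      scales = scales)
}
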