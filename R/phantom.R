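# Synthetic tubular-tree phantoms with exact ground truth. Branches are
# quadratic Bezier curves with a Gaussian cross-section whose width tapers
# linearly along the branch; the phantom emulates the look of a
# contrast-filled vessel tree (curvilinear branches, uneven illumination,
# additive noise, low-contrast distal segments) with analytically known
# centerlines, widths, bifurcations and mask.

#' Phantom specification
#'
#' @param size image size c(rows, cols).
#' @param branches list of branches; each branch is a list with `p0`,
#'   `p1`, `p2` (quadratic Bezier control points, c(x, y), 0-based, inside
#'   the image), `w0`, `w1` (start/end half-width in px, >= 1) and `peak`
#'   (peak intensity contrast).
#' @param background_level background gray level.
#' @param illumination_gradient c(gx, gy): linear shading, gray levels per
#'   pixel.
#' @param noise_sigma additive Gaussian noise std.
#' @param vessel_polarity "bright" or "dark".
#' @param rng_seed integer seed for the noise.
#' @return list of class `phantomSpec`.
#' @export
phantomSpec <- function(size = c(256L, 256L), branches = list(),
                        background_level = 30,
                        illumination_gradient = c(0, 0), noise_sigma = 0,
                        vessel_polarity = "bright", rng_seed = 1L) {
  stopifnot(vessel_polarity %in% c("bright", "dark"), noise_sigma >= 0)
  for (b in branches) {
    stopifnot(all(c("p0", "p1", "p2", "w0", "w1", "peak") %in% names(b)))
    if (b$w0 < 1 || b$w1 < 1) stop("half-widths must be >= 1", call. = FALSE)
    for (p in list(b$p0, b$p1, b$p2))
      if (p[1] < 0 || p[1] > size[2] - 1 || p[2] < 0 || p[2] > size[1] - 1)
        stop("control points must lie inside the image", call. = FALSE)
  }
  structure(list(size = as.integer(size), branches = branches,
                 background_level = background_level,
                 illumination_gradient = illumination_gradient,
                 noise_sigma = noise_sigma,
                 vessel_polarity = vessel_polarity,
                 rng_seed = as.integer(rng_seed)),
            class = "phantomSpec")
}

.bezier <- function(b, t) {
  cbind((1 - t)^2 * b$p0[1] + 2 * (1 - t) * t * b$p1[1] + t^2 * b$p2[1],
        (1 - t)^2 * b$p0[2] + 2 * (1 - t) * t * b$p1[2] + t^2 * b$p2[2])
}

# Arc-length resampling of a quadratic Bezier at the given spacing.
# Returns x, y, s (arc length) and the local half-width.
.sampleBranch <- function(b, spacing) {
  t0 <- seq(0, 1, length.out = 512)
  q <- .bezier(b, t0)
  seg <- sqrt(diff(q[, 1])^2 + diff(q[, 2])^2)
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  sNew <- seq(0, L, by = spacing)
  if (sNew[length(sNew)] < L) sNew <- c(sNew, L)
  tNew <- stats::approx(s, t0, xout = sNew, ties = "ordered")$y
  qq <- .bezier(b, tNew)
  data.frame(x = qq[, 1], y = qq[, 2], s = sNew,
             width = b$w0 + (b$w1 - b$w0) * sNew / max(L, 1e-9))
}

#' Render a phantom with ground truth
#'
#' Pixel intensity is background + illumination +/- the per-branch maximum
#' of peak * exp(-dist^2 / (2 (halfwidth/2)^2)) (sign per polarity), then
#' additive Gaussian noise (seeded, reproducible). The ground truth is
#' computed analytically from the Bezier curves: dense centerlines (0.5 px
#' spacing) with local half-widths, the binary mask {distance to nearest
#' centerline <= local half-width}, and bifurcations (points where a
#' branch starts on another branch).
#'
#' @param spec a [phantomSpec()].
#' @return list with `image` (matrix, [0, 255]) and `truth`
#'   (a [PhantomTruth-class]).
#' @export
renderPhantom <- function(spec) {
  stopifnot(inherits(spec, "phantomSpec"))
  nr <- spec$size[1]; nc <- spec$size[2]
  xg <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  yg <- matrix(0:(nr - 1), nr, nc)
  img <- spec$background_level + spec$illumination_gradient[1] * xg +
    spec$illumination_gradient[2] * yg
  contrib <- matrix(0, nr, nc)
  mask <- matrix(FALSE, nr, nc)
  centerlines <- list()

  for (b in spec$branches) {
    fine <- .sampleBranch(b, 0.25)
    d2 <- matrix(Inf, nr, nc)
    hw <- matrix(1, nr, nc)
    rad <- ceiling(2.5 * max(b$w0, b$w1)) + 1L
    for (i in seq_len(nrow(fine))) {
      cx <- fine$x[i]; cy <- fine$y[i]
      c0 <- max(0L, floor(cx) - rad); c1 <- min(nc - 1L, ceiling(cx) + rad)
      r0 <- max(0L, floor(cy) - rad); r1 <- min(nr - 1L, ceiling(cy) + rad)
      rows <- (r0:r1) + 1L; cols <- (c0:c1) + 1L
      dd <- outer((r0:r1) - cy, (c0:c1) - cx,
                  function(a, b2) a^2 + b2^2)
      win <- d2[rows, cols]
      upd <- dd < win
      if (any(upd)) {
        win[upd] <- dd[upd]
        d2[rows, cols] <- win
        hwin <- hw[rows, cols]
        hwin[upd] <- fine$width[i]
        hw[rows, cols] <- hwin
      }
    }
    contrib <- pmax(contrib, b$peak * exp(-d2 / (2 * (hw / 2)^2)))
    mask <- mask | (d2 <= hw^2)
    centerlines[[length(centerlines) + 1L]] <-
      .sampleBranch(b, 0.5)[, c("x", "y", "width")]
  }

  img <- img + if (spec$vessel_polarity == "bright") contrib else -contrib
  img <- .clip255(img)
  if (spec$noise_sigma > 0) {
    noise <- .withSeed(spec$rng_seed,
                       matrix(stats::rnorm(nr * nc, 0, spec$noise_sigma),
                              nr, nc))
    img <- .clip255(img + noise)
  }

  # bifurcations: a branch whose start lies on another branch's centerline
  bx <- numeric(0); by <- numeric(0)
  if (length(spec$branches) > 1) {
    for (i in seq_along(spec$branches)) {
      p0 <- spec$branches[[i]]$p0
      for (j in seq_along(spec$branches)) {
        if (i == j) next
        cl <- centerlines[[j]]
        dmin <- min((cl$x - p0[1])^2 + (cl$y - p0[2])^2)
        startD <- sum((spec$branches[[j]]$p0 - p0)^2)
        if (dmin <= 1 && startD > 1) { # on branch j, not a shared root
          bx <- c(bx, p0[1]); by <- c(by, p0[2])
          break
        }
      }
    }
    if (length(bx) > 1) {             # deduplicate coincident junctions
      keep <- rep(TRUE, length(bx))
      for (i in seq_along(bx)[-1])
        if (any(((bx[seq_len(i - 1)] - bx[i])^2 +
                 (by[seq_len(i - 1)] - by[i])^2)[keep[seq_len(i - 1)]] <= 4))
          keep[i] <- FALSE
      bx <- bx[keep]; by <- by[keep]
    }
  }

  truth <- new("PhantomTruth", centerlines = centerlines,
               bifurcations = data.frame(x = bx, y = by),
               mask = mask + 0)
  list(image = img, truth = truth)
}

#' Stock phantoms used throughout the test surface
#'
#' `straightTubePhantom`: one horizontal tube, 256x256, half-width 3,
#' contrast 120 over background 30. `sTubePhantom`: a curved S-shaped
#' tube. `yTreePhantom`: a trunk and two child branches opening 40 degrees
#' apart. `noisyYTreePhantom`: the Y tree with additive noise and an
#' illumination gradient, dark-vessel polarity (exercises the full
#' preprocessing chain).
#'
#' @param noise_sigma,rng_seed noise level and seed.
#' @param polarity vessel polarity.
#' @return a [phantomSpec()].
#' @export
straightTubePhantom <- function(noise_sigma = 0, rng_seed = 1L,
                                polarity = "bright") {
  phantomSpec(size = c(256L, 256L),
              branches = list(list(p0 = c(20, 128), p1 = c(128, 128),
                                   p2 = c(236, 128), w0 = 3, w1 = 3,
                                   peak = 120)),
              background_level = 30, noise_sigma = noise_sigma,
              vessel_polarity = polarity, rng_seed = rng_seed)
}

#' @rdname straightTubePhantom
#' @export
sTubePhantom <- function(noise_sigma = 0, rng_seed = 1L,
                         polarity = "bright") {
  phantomSpec(size = c(256L, 256L),
              branches = list(list(p0 = c(30, 60), p1 = c(200, 90),
                                   p2 = c(60, 200), w0 = 4, w1 = 2.5,
                                   peak = 120)),
              background_level = 30, noise_sigma = noise_sigma,
              vessel_polarity = polarity, rng_seed = rng_seed)
}

#' @rdname straightTubePhantom
#' @export
yTreePhantom <- function(noise_sigma = 0, rng_seed = 1L,
                         polarity = "bright") {
  # Trunk along +x with two children sharing its endpoint: the main
  # vessel continues straight and the side branch leaves at a 40-degree
  # branch angle (typical coronary morphology: a side branch departs
  # from a continuing main vessel).
  j <- c(120, 128)
  len <- 100
  a <- 40 * pi / 180
  e2 <- j + len * c(cos(a), sin(a))
  phantomSpec(size = c(256L, 256L),
              branches = list(
                list(p0 = c(20, 128), p1 = c(70, 128), p2 = j,
                     w0 = 3.5, w1 = 3, peak = 120),
                list(p0 = j, p1 = j + c(len / 2, 0), p2 = j + c(len, 0),
                     w0 = 3, w1 = 2.5, peak = 120),
                list(p0 = j, p1 = (j + e2) / 2, p2 = e2,
                     w0 = 3, w1 = 2.5, peak = 120)),
              background_level = 30, noise_sigma = noise_sigma,
              vessel_polarity = polarity, rng_seed = rng_seed)
}

#' @rdname straightTubePhantom
#' @export
noisyYTreePhantom <- function(noise_sigma = 15, rng_seed = 1L) {
  sp <- yTreePhantom(polarity = "dark")
  sp$background_level <- 200
  sp$illumination_gradient <- c(-0.08, 0.05)
  sp$noise_sigma <- noise_sigma
  sp$rng_seed <- as.integer(rng_seed)
  sp
}
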