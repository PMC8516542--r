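# Adaptive centerline tracking. From a seed ridge point, the tracker
# searches for gray maxima on arcs of radius d ahead of the current
# direction, guarded by an intensity floor (stop at vessel ends) and a
# visited-point count (stop loops). Accepted points are recentred using
# the segmentation contour, and a fan-ring search around each point
# detects new branches, which are tracked breadth-first.

# Argmax of bilinearly interpolated intensity over an arc. Ties are broken
# by smaller |angular offset|, then smaller signed offset. Returns NULL if
# no sample lies inside the image.
.arcArgmax <- function(img, p, d, centerAngle, halfWidth, stepDeg) {
  off <- seq(-halfWidth, halfWidth, by = stepDeg)
  ang <- (centerAngle + off) * pi / 180
  sx <- p[1] + d * cos(ang)
  sy <- p[2] + d * sin(ang)
  ok <- sx >= 0 & sx <= ncol(img) - 1 & sy >= 0 & sy <= nrow(img) - 1
  if (!any(ok)) return(NULL)
  vals <- rep(-Inf, length(off))
  vals[ok] <- .bilinear(img, sx[ok], sy[ok])
  mx <- max(vals)
  cand <- which(vals >= mx - 1e-12)
  best <- cand[order(abs(off[cand]), off[cand])][1]
  list(point = c(sx[best], sy[best]),
       angle = (centerAngle + off[best]) %% 360,
       offset = off[best], intensity = vals[best],
       degenerate = sum(vals >= mx - 1e-12) == sum(ok))
}

#' Select a seed ridge point
#'
#' Uniform random choice from the detected ridge points, deterministic for
#' a fixed seed; the caller's RNG state is untouched.
#'
#' @param ridges data.frame of ridge points (see [detectRidgePoints()]).
#' @param rng_seed integer seed.
#' @return one-row data.frame.
#' @export
selectSeed <- function(ridges, rng_seed = 1L) {
  if (nrow(ridges) == 0) stop("no ridge points", call. = FALSE)
  i <- .withSeed(rng_seed, sample.int(nrow(ridges), 1L))
  ridges[i, , drop = FALSE]
}

#' Initial bidirectional tracking directions
#'
#' The forward point P+ is the gray maximum on the full circle of radius
#' `d` around the seed; the backward point P- is the gray maximum on the
#' arc of half-width `delta_theta` centered on the direction opposite the
#' forward one.
#'
#' @param img enhanced intensity matrix (bright vessels).
#' @param p seed point c(x, y), 0-based.
#' @param d search radius in pixels.
#' @param delta_theta backward arc half-angle, degrees.
#' @param I0 intensity floor; an all-background circle is an error.
#' @param arc_step_deg arc sampling step, degrees.
#' @return list with `p_plus`, `u_plus`, `theta_plus`, `p_minus`,
#'   `u_minus`, `theta_minus`.
#' @export
initialDirections <- function(img, p, d = 5, delta_theta = 45, I0 = 10,
                              arc_step_deg = 1) {
  stopifnot(length(p) == 2)
  if (p[1] - d < 0 || p[1] + d > ncol(img) - 1 ||
      p[2] - d < 0 || p[2] + d > nrow(img) - 1)
    stop("search circle does not fit in the image", call. = FALSE)
  fw <- .arcArgmax(img, p, d, centerAngle = 180, halfWidth = 180,
                   stepDeg = arc_step_deg)
  if (is.null(fw) || fw$intensity <= I0)
    stop("seed not on vessel", call. = FALSE)
  if (fw$degenerate) {
    warning("degenerate circle search: all samples tie", call. = FALSE)
    th <- 0
    fw$point <- c(p[1] + d, p[2])
  } else th <- fw$angle
  uPlus <- c(cos(th * pi / 180), sin(th * pi / 180))
  bw <- .arcArgmax(img, p, d, centerAngle = th + 180,
                   halfWidth = delta_theta, stepDeg = arc_step_deg)
  uMinus <- (bw$point - p) / sqrt(sum((bw$point - p)^2))
  list(p_plus = fw$point, u_plus = uPlus, theta_plus = th,
       p_minus = bw$point, u_minus = uMinus, theta_minus = bw$angle)
}

#' Single tracking step
#'
#' Searches the arc of radius `d` and half-angle `delta_theta` around the
#' current direction for the intensity maximum, and accepts it if it
#' clears the intensity floor and is not surrounded by `tau_P` or more
#' previously accepted points within `np_radius` (loop guard).
#'
#' @param img enhanced intensity matrix.
#' @param p_cur current point c(x, y).
#' @param theta_cur current direction angle, degrees.
#' @param accepted matrix of previously accepted points (columns x, y).
#' @param d,delta_theta,I0,tau_P,np_radius,arc_step_deg tracking
#'   parameters.
#' @return list with `status` ("ok", "border", "intensity" or "loop") and,
#'   when accepted, `point` and `theta`.
#' @export
trackStep <- function(img, p_cur, theta_cur, accepted, d = 5,
                      delta_theta = 45, I0 = 10, tau_P = 4L,
                      np_radius = 5, arc_step_deg = 1) {
  res <- .arcArgmax(img, p_cur, d, theta_cur, delta_theta, arc_step_deg)
  if (is.null(res)) return(list(status = "border"))
  if (res$intensity <= I0) return(list(status = "intensity"))
  if (!is.null(accepted) && nrow(accepted) > 0) {
    d2 <- (accepted[, 1] - res$point[1])^2 +
      (accepted[, 2] - res$point[2])^2
    if (sum(d2 <= np_radius^2) >= tau_P) return(list(status = "loop"))
  }
  list(status = "ok", point = res$point, theta = res$angle)
}

#' Contour-based center adjustment
#'
#' Casts rays from the current point along both perpendiculars of the
#' tracking direction (0.25 px steps, up to `max_ray`), finds the two mask
#' exits by linear interpolation, and moves the point to the chord
#' midpoint; the direction is re-aimed from the previous point. If the
#' point is outside the mask or a ray finds no exit, the state is returned
#' unchanged with `adjusted = FALSE`.
#'
#' @param mask binary matrix ({0, 1}).
#' @param p_cur,p_prev current and previous points c(x, y).
#' @param u_cur current unit direction.
#' @param max_ray maximum ray length, pixels.
#' @param max_shift maximum accepted displacement, pixels. Adjustment is a
#'   small correction for points that drift off-center; a larger midpoint
#'   displacement means the chord spans a junction or a neighboring
#'   structure rather than one vessel cross-section, and the state is
#'   returned unchanged.
#' @return list with `p`, `u`, `theta` (degrees), `adjusted`.
#' @export
centerAdjust <- function(mask, p_cur, p_prev, u_cur, max_ray = 20,
                         max_shift = 2) {
  normal <- c(-u_cur[2], u_cur[1])
  unchanged <- list(p = p_cur, u = u_cur,
                    theta = atan2(u_cur[2], u_cur[1]) * 180 / pi,
                    adjusted = FALSE)
  if (.bilinear(mask, p_cur[1], p_cur[2]) < 0.5) return(unchanged)
  castRay <- function(dir) {
    s <- seq(0.25, max_ray, by = 0.25)
    vx <- p_cur[1] + s * dir[1]
    vy <- p_cur[2] + s * dir[2]
    inb <- vx >= 0 & vx <= ncol(mask) - 1 & vy >= 0 & vy <= nrow(mask) - 1
    vals <- rep(0, length(s))
    vals[inb] <- .bilinear(mask, vx[inb], vy[inb])
    k <- which(vals < 0.5)[1]
    if (is.na(k)) return(NULL)
    v0 <- if (k == 1) .bilinear(mask, p_cur[1], p_cur[2]) else vals[k - 1]
    s0 <- if (k == 1) 0 else s[k - 1]
    frac <- (v0 - 0.5) / max(v0 - vals[k], 1e-12)
    sc <- s0 + 0.25 * frac
    p_cur + sc * dir
  }
  g1 <- castRay(normal)
  g2 <- castRay(-normal)
  if (is.null(g1) || is.null(g2)) return(unchanged)
  pNew <- (g1 + g2) / 2
  if (sqrt(sum((pNew - p_cur)^2)) > max_shift) return(unchanged)
  dv <- pNew - p_prev
  nrm <- sqrt(sum(dv^2))
  if (nrm < 1e-9) return(unchanged)
  uNew <- dv / nrm
  list(p = pNew, u = uNew, theta = atan2(uNew[2], uNew[1]) * 180 / pi,
       adjusted = TRUE)
}

#' Fan-ring bifurcation detection
#'
#' Searches the annular sector of radii (`r1`, `r2`) and half-angle
#' `delta_theta_prime` around the current direction for a ridge point P_b
#' whose bearing differs from the current and previous directions by more
#' than `tau1` / `tau2` degrees, lies farther than `d`, and has fewer than
#' `tau_B` recorded bifurcations within `nb_radius`. Among qualifying
#' candidates the one with maximal enhanced intensity is returned.
#'
#' @param ridges data.frame of (filtered) ridge points.
#' @param img enhanced intensity matrix (for candidate ranking).
#' @param p_cur current point c(x, y).
#' @param theta_cur,theta_prev current and previous direction angles,
#'   degrees.
#' @param bifs matrix of recorded bifurcation points (columns x, y), may
#'   be NULL.
#' @param r1,r2,delta_theta_prime,tau1,tau2,d,tau_B,nb_radius parameters.
#' @return NULL, or a list with `pb` (the ridge point, c(x, y)) and `u`
#'   (unit direction from the current point to it).
#' @export
detectBifurcation <- function(ridges, img, p_cur, theta_cur, theta_prev,
                              bifs = NULL, r1 = 7, r2 = 12,
                              delta_theta_prime = 135, tau1 = 45,
                              tau2 = 30, d = 5, tau_B = 2L,
                              nb_radius = 12) {
  if (nrow(ridges) == 0) return(NULL)
  dx <- ridges$x - p_cur[1]
  dy <- ridges$y - p_cur[2]
  dist <- sqrt(dx^2 + dy^2)
  thetaB <- atan2(dy, dx) * 180 / pi
  offK <- .angDiff(thetaB, theta_cur)
  sel <- dist >= r1 & dist <= r2 & offK <= delta_theta_prime &
    offK > tau1 & .angDiff(thetaB, theta_prev) > tau2 & dist > d
  if (!is.null(bifs) && nrow(bifs) > 0 && any(sel)) {
    for (i in which(sel)) {
      nB <- sum((bifs[, 1] - ridges$x[i])^2 +
                (bifs[, 2] - ridges$y[i])^2 <= nb_radius^2)
      if (nB >= tau_B) sel[i] <- FALSE
    }
  }
  if (!any(sel)) return(NULL)
  cand <- which(sel)
  ints <- img[cbind(ridges$y[cand] + 1, ridges$x[cand] + 1)]
  best <- cand[which.max(ints)]
  pb <- c(ridges$x[best], ridges$y[best])
  u <- (pb - p_cur) / sqrt(sum((pb - p_cur)^2))
  list(pb = pb, u = u)
}

# Track one branch from (p_prev -> p_cur); registers points, performs
# center adjustment and bifurcation detection, pushes new branches on the
# FIFO queue held in `env`. Returns the branch point data.frame.
.trackBranch <- function(env, p_prev, p_cur, theta_prev, theta_cur,
                         cfg, firstAccepted = TRUE) {
  pts <- list()
  repeat {
    adj <- centerAdjust(env$mask, p_cur, p_prev,
                        c(cos(theta_cur * pi / 180),
                          sin(theta_cur * pi / 180)),
                        cfg$track_max_ray, cfg$track_max_shift)
    p_cur <- adj$p
    if (adj$adjusted) theta_cur <- adj$theta
    if (env$nAcc >= cfg$track_max_points) { env$truncated <- TRUE; break }
    env$nAcc <- env$nAcc + 1L
    env$acc[env$nAcc, ] <- p_cur
    pts[[length(pts) + 1L]] <- c(p_cur, as.numeric(adj$adjusted))

    bf <- detectBifurcation(env$ridges, env$img, p_cur, theta_cur,
                            theta_prev,
                            bifs = if (env$nBif > 0)
                              env$bif[seq_len(env$nBif), , drop = FALSE]
                            else NULL,
                            r1 = cfg$track_r1, r2 = cfg$track_r2,
                            delta_theta_prime = cfg$track_delta_theta_prime,
                            tau1 = cfg$track_tau1, tau2 = cfg$track_tau2,
                            d = cfg$track_d, tau_B = cfg$track_tau_B,
                            nb_radius = cfg$track_nb_radius)
    if (!is.null(bf)) {
      if (env$nBif == nrow(env$bif))
        env$bif <- rbind(env$bif, matrix(NA_real_, nrow(env$bif), 2))
      env$nBif <- env$nBif + 1L
      env$bif[env$nBif, ] <- p_cur        # junction estimate: the tracking
      thB <- atan2(bf$u[2], bf$u[1]) * 180 / pi  # point where the branch
      env$queue[[length(env$queue) + 1L]] <-     # was found
        list(p_prev = p_cur, p_cur = bf$pb,
             theta_prev = thB, theta_cur = thB)
    }

    st <- trackStep(env$img, p_cur, theta_cur,
                    env$acc[seq_len(env$nAcc), , drop = FALSE],
                    d = cfg$track_d, delta_theta = cfg$track_delta_theta,
                    I0 = cfg$track_I0, tau_P = cfg$track_tau_P,
                    np_radius = cfg$track_np_radius,
                    arc_step_deg = cfg$track_arc_step_deg)
    if (st$status != "ok") break
    p_prev <- p_cur; theta_prev <- theta_cur
    p_cur <- st$point; theta_cur <- st$theta
  }
  if (length(pts) == 0) return(NULL)
  m <- do.call(rbind, pts)
  data.frame(x = m[, 1], y = m[, 2], adjusted = m[, 3] > 0)
}

# Seeded, deterministic seed choice for pipeline runs: walks a seeded
# permutation of the ridge points and returns the first from which the
# bidirectional initial search succeeds (circle inside the image, circle
# samples above the intensity floor).
.selectWorkingSeed <- function(img, ridges, config) {
  if (nrow(ridges) == 0) stop("no ridge points", call. = FALSE)
  ord <- .withSeed(config$rng_seed, sample.int(nrow(ridges)))
  for (i in ord) {
    ok <- tryCatch({
      initialDirections(img, c(ridges$x[i], ridges$y[i]),
                        d = config$track_d,
                        delta_theta = config$track_delta_theta,
                        I0 = config$track_I0,
                        arc_step_deg = config$track_arc_step_deg)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (ok) return(ridges[i, , drop = FALSE])
  }
  stop("no ridge point can initialize tracking", call. = FALSE)
}

#' Track the vessel skeleton
#'
#' Runs [initialDirections()] at the seed, tracks forward and backward as
#' two half-branches merged through the seed, and tracks every branch
#' found by [detectBifurcation()] in FIFO order (away from its parent).
#' Each accepted point is recentred with [centerAdjust()]. Tracking
#' terminates when the queue is empty or `track_max_points` is reached.
#'
#' @param img enhanced intensity matrix (bright vessels, [0, 255]).
#' @param mask binary segmentation mask used for center adjustment.
#' @param ridges data.frame of filtered ridge points.
#' @param seed seed point: a one-row data.frame from [selectSeed()] or a
#'   numeric c(x, y).
#' @param config a [pipelineConfig()] list.
#' @return a [Skeleton-class].
#' @export
trackVessels <- function(img, mask, ridges, seed,
                         config = pipelineConfig()) {
  if (is.data.frame(seed)) seed <- c(seed$x[1], seed$y[1])
  seed <- as.numeric(seed)
  env <- new.env(parent = emptyenv())
  env$img <- img; env$mask <- mask; env$ridges <- ridges
  env$acc <- matrix(NA_real_, config$track_max_points, 2)
  env$nAcc <- 0L
  env$bif <- matrix(NA_real_, 1024L, 2)
  env$nBif <- 0L
  env$queue <- list()
  env$truncated <- FALSE

  ini <- initialDirections(img, seed, d = config$track_d,
                           delta_theta = config$track_delta_theta,
                           I0 = config$track_I0,
                           arc_step_deg = config$track_arc_step_deg)
  env$nAcc <- 1L
  env$acc[1, ] <- seed
  fwd <- .trackBranch(env, seed, ini$p_plus, ini$theta_plus,
                      ini$theta_plus, config)
  bwd <- .trackBranch(env, seed, ini$p_minus, ini$theta_minus,
                      ini$theta_minus, config)
  seedRow <- data.frame(x = seed[1], y = seed[2], adjusted = FALSE)
  main <- rbind(if (!is.null(bwd)) bwd[rev(seq_len(nrow(bwd))), ],
                seedRow, fwd)
  rownames(main) <- NULL
  branches <- list(main)

  while (length(env$queue) > 0) {
    job <- env$queue[[1]]
    env$queue <- env$queue[-1]
    if (env$truncated) break
    br <- .trackBranch(env, job$p_prev, job$p_cur, job$theta_prev,
                       job$theta_cur, config)
    if (!is.null(br)) branches[[length(branches) + 1L]] <- br
  }

  bifDf <- if (env$nBif > 0)
    data.frame(x = env$bif[seq_len(env$nBif), 1],
               y = env$bif[seq_len(env$nBif), 2])
  else data.frame(x = numeric(0), y = numeric(0))
  .logStage("track",
            sprintf("branches=%d points=%d bifurcations=%d truncated=%s",
                    length(branches), env$nAcc, env$nBif, env$truncated))
  new("Skeleton", branches = branches, bifurcations = bifDf,
      seed = seed, truncated = env$truncated)
}
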