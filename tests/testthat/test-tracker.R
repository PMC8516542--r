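# Shared bar fixture: bright horizontal tube, centerline row 47 (0-based).
barResp <- local({
  bar <- gaussBarImage(nr = 96, nc = 192, row = 47, s = 3)
  responseMap(vesselnessMultiscale(bar))
})

test_that("seed selection is uniform and deterministic", {
  ridges <- data.frame(x = 1:10, y = rep(0, 10), dirx = 1, diry = 0)
  expect_equal(selectSeed(ridges[3, ], 99)$x, 3)
  s1 <- selectSeed(ridges, 42)
  s2 <- selectSeed(ridges, 42)
  expect_identical(s1, s2)
  expect_error(selectSeed(ridges[0, ], 1), "no ridge points")

  draws <- vapply(1:10000, function(s) selectSeed(ridges, s)$x, numeric(1))
  freq <- tabulate(draws, 10) / 10000
  expect_true(all(abs(freq - 0.1) <= 0.02))

  # the caller's RNG stream is untouched
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(selectSeed(ridges, 7)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("initial directions on a bar are opposite and axis-aligned", {
  ini <- initialDirections(barResp, c(96, 47), d = 5, delta_theta = 45,
                           I0 = 10)
  th <- ini$theta_plus %% 360
  expect_true(min(abs(th - 0), abs(th - 180), abs(th - 360)) <= 1)
  expect_lte(sum(ini$u_plus * ini$u_minus), -0.99)

  # seed 2 px off the centerline: the circle's gray maximum sits on the
  # centerline, i.e. at arcsin(2/5) = 23.6 deg from the bar axis
  ini2 <- initialDirections(barResp, c(96, 49), d = 5)
  ang <- atan2(ini2$u_plus[2], ini2$u_plus[1]) * 180 / pi
  expect_lte(min(abs(ang), abs(abs(ang) - 180)),
             asin(2 / 5) * 180 / pi + 2)

  # constant image above the floor: degenerate tie -> angle 0 + warning
  cst <- matrix(100, 64, 64)
  expect_warning(iniC <- initialDirections(cst, c(32, 32), d = 5),
                 "degenerate")
  expect_equal(iniC$theta_plus, 0)

  expect_error(initialDirections(barResp, c(2, 2), d = 5), "circle")
  dark <- matrix(1, 64, 64)
  expect_error(initialDirections(dark, c(32, 32), d = 5, I0 = 10),
               "not on vessel")
})

test_that("a tracking step follows the bar and honors both guards", {
  st <- trackStep(barResp, c(96, 47), 0, NULL)
  expect_equal(st$status, "ok")
  expect_lte(abs(st$point[2] - 47), 1)
  expect_equal(sqrt(sum((st$point - c(96, 47))^2)), 5, tolerance = 1e-9)
  expect_lte(min(st$theta %% 360, 360 - st$theta %% 360), 1)

  # arc entirely in background: stops with the intensity condition
  st2 <- trackStep(barResp, c(96, 20), 90, NULL)
  expect_equal(st2$status, "intensity")

  # tau_P prior points around the candidate: loop guard fires
  prior <- cbind(101 + c(0, 1, -1, 0), 47 + c(0, 1, 0, -1))
  st3 <- trackStep(barResp, c(96, 47), 0, prior, tau_P = 4L, np_radius = 5)
  expect_equal(st3$status, "loop")

  # arc beyond the border terminates
  st4 <- trackStep(barResp, c(190, 47), 0, NULL)
  expect_equal(st4$status, "border")
})

test_that("center adjustment moves points to the chord midpoint", {
  mask <- matrix(0, 64, 96)
  mask[30:36, ] <- 1       # width-7 tube, axis row 32 (0-based)
  adj <- centerAdjust(mask, c(50, 34), c(45, 34), c(1, 0))
  expect_true(adj$adjusted)
  expect_lte(abs(adj$p[2] - 32), 0.5)
  expect_equal(adj$p[1], 50)

  onAxis <- centerAdjust(mask, c(50, 32), c(45, 32), c(1, 0))
  expect_lte(abs(onAxis$p[2] - 32), 0.25)

  # point outside the mask: unchanged, flagged
  off <- centerAdjust(mask, c(50, 10), c(45, 10), c(1, 0))
  expect_false(off$adjusted)
  expect_equal(off$p, c(50, 10))

  # rays that never exit (mask everywhere): unchanged, flagged
  solid <- matrix(1, 64, 96)
  full <- centerAdjust(solid, c(50, 32), c(45, 32), c(1, 0), max_ray = 20)
  expect_false(full$adjusted)

  # displacements beyond max_shift are rejected (junction-like chords)
  lop <- matrix(0, 64, 96)
  lop[25:40, ] <- 1                    # wide, strongly off-center chord
  big <- centerAdjust(lop, c(50, 39), c(45, 39), c(1, 0), max_shift = 2)
  expect_false(big$adjusted)
})

test_that("fan-ring bifurcation detection honors every condition", {
  ridges <- data.frame(x = c(60, 58), y = c(56, 41),
                       dirx = 1, diry = 0)
  img <- matrix(100, 96, 96)
  # candidate 1: distance 10 at ~+53 deg off theta_k = 0 -> qualifies
  bf <- detectBifurcation(ridges, img, p_cur = c(54, 48), theta_cur = 0,
                          theta_prev = 0)
  expect_equal(bf$pb, c(60, 56))
  expect_equal(sum(bf$u^2), 1, tolerance = 1e-9)

  # distance 4 < d = 5 is rejected regardless of angles
  near <- data.frame(x = 54, y = 44, dirx = 1, diry = 0)
  expect_null(detectBifurcation(near, img, c(54, 48), 0, 0, r1 = 2,
                                r2 = 12))

  # angle gap below tau1 is rejected
  shallow <- data.frame(x = 64, y = 51, dirx = 1, diry = 0)
  expect_null(detectBifurcation(shallow, img, c(54, 48), 0, 0))

  # tau_B recorded bifurcations nearby block re-detection
  bifs <- matrix(c(59, 55, 61, 57), 2, 2, byrow = TRUE)
  expect_null(detectBifurcation(ridges[1, ], img, c(54, 48), 0, 0,
                                bifs = bifs, tau_B = 2L))
})

test_that("no bifurcations are reported on a straight tube", {
  ph <- renderPhantom(straightTubePhantom())
  vm <- vesselnessMultiscale(ph$image)
  r <- filterScatteredRidges(detectRidgePoints(vm, 10))
  cfg <- pipelineConfig(vessel_polarity = "bright")
  sk <- trackVessels(responseMap(vm), truthMask(ph$truth), r,
                     c(128, 128), cfg)
  expect_equal(nrow(bifurcations(sk)), 0)
  expect_length(branches(sk), 1)

  ce <- centerlineError(sk, ph$truth)
  expect_gte(ce$coverage, 0.9)
  expect_lte(ce$mean_dist, 1)
})

test_that("tracking respects step length and the loop-guard bookkeeping", {
  ph <- renderPhantom(straightTubePhantom())
  vm <- vesselnessMultiscale(ph$image)
  r <- filterScatteredRidges(detectRidgePoints(vm, 10))
  cfg <- pipelineConfig(vessel_polarity = "bright")
  sk <- trackVessels(responseMap(vm), truthMask(ph$truth), r,
                     c(128, 128), cfg)
  b <- branches(sk)[[1]]
  seg <- sqrt(diff(b$x)^2 + diff(b$y)^2)
  # arc radius d before adjustment, +- the center-adjust displacement cap
  expect_true(all(seg >= cfg$track_d - 2 * cfg$track_max_shift - 1e-6))
  expect_true(all(seg <= cfg$track_d + 2 * cfg$track_max_shift + 1e-6))

  pts <- cbind(skeletonPoints(sk)$x, skeletonPoints(sk)$y)
  # post-hoc N_P audit in acceptance order (branch build order here)
  for (i in seq_len(nrow(pts))) {
    if (i == 1) next
    nP <- sum((pts[seq_len(i - 1), 1] - pts[i, 1])^2 +
              (pts[seq_len(i - 1), 2] - pts[i, 2])^2 <=
              cfg$track_np_radius^2)
    expect_lt(nP, cfg$track_tau_P)
  }
})

test_that("tracking is deterministic and the point budget truncates", {
  ph <- renderPhantom(straightTubePhantom())
  vm <- vesselnessMultiscale(ph$image)
  r <- filterScatteredRidges(detectRidgePoints(vm, 10))
  cfg <- pipelineConfig(vessel_polarity = "bright")
  seed <- selectSeed(r, 5)
  a <- trackVessels(responseMap(vm), truthMask(ph$truth), r, seed, cfg)
  b <- trackVessels(responseMap(vm), truthMask(ph$truth), r, seed, cfg)
  expect_identical(branches(a), branches(b))
  expect_identical(bifurcations(a), bifurcations(b))

  tiny <- pipelineConfig(vessel_polarity = "bright", track_max_points = 5L)
  tr <- trackVessels(responseMap(vm), truthMask(ph$truth), r, seed, tiny)
  expect_true(tr@truncated)
  expect_lte(nrow(skeletonPoints(tr)), 5)
})
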