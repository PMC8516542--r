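# Evaluation metrics against phantom ground truth.

.flattenTruth <- function(truth) {
  do.call(rbind, lapply(centerlines(truth), function(b) cbind(b$x, b$y)))
}

.minDists <- function(a, b) {
  # for each row of a, distance to the nearest row of b (both n x 2)
  vapply(seq_len(nrow(a)), function(i)
    sqrt(min((b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2)), numeric(1))
}

# Densify an ordered branch polyline at the given spacing, so that the
# skeleton is treated as a curve (tracking points are a sparse sampling of
# it, one step radius apart).
.densify <- function(pts, spacing = 0.5) {
  if (nrow(pts) < 2) return(pts)
  out <- list(pts[1, , drop = FALSE])
  for (i in seq_len(nrow(pts) - 1)) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    nseg <- max(1L, ceiling(len / spacing))
    t <- seq_len(nseg) / nseg
    out[[i + 1]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  do.call(rbind, out)
}

#' Centerline accuracy of a skeleton
#'
#' `mean_dist`: mean distance from the skeleton's tracking points to the
#' nearest truth centerline point. `coverage`: fraction of truth
#' centerline points lying within `cover_tol` px of the skeleton curve
#' (each branch's ordered points are interpolated as a polyline, since
#' tracking samples the centerline one step radius apart). `hausdorff`:
#' maximum of the two directed nearest-neighbor distances (tracking
#' points vs. truth, truth vs. skeleton polyline).
#'
#' @param skel a [Skeleton-class], or a matrix/data.frame of points with
#'   columns x, y (treated as one ordered polyline).
#' @param truth a [PhantomTruth-class].
#' @param cover_tol coverage tolerance in px.
#' @return list with `mean_dist`, `hausdorff`, `coverage`.
#' @export
centerlineError <- function(skel, truth, cover_tol = 2) {
  if (is(skel, "Skeleton")) {
    sp <- skeletonPoints(skel)
    pts <- cbind(sp$x, sp$y)
    curve <- do.call(rbind, lapply(branches(skel), function(b)
      .densify(cbind(b$x, b$y))))
  } else {
    pts <- as.matrix(skel[, c("x", "y")])
    curve <- .densify(pts)
  }
  tr <- .flattenTruth(truth)
  if (is.null(pts) || nrow(pts) == 0 || nrow(tr) == 0)
    stop("empty skeleton or truth", call. = FALSE)
  dST <- .minDists(pts, tr)
  dTS <- .minDists(tr, curve)
  list(mean_dist = mean(dST),
       hausdorff = max(max(dST), max(dTS)),
       coverage = mean(dTS <= cover_tol))
}

# Merge detections into clusters of mutual distance <= tol
# (single linkage), replacing each cluster by its centroid.
.mergeDetections <- function(pts, tol) {
  n <- nrow(pts)
  if (n <= 1) return(pts)
  grp <- seq_len(n)
  find <- function(i) { while (grp[i] != i) i <- grp[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if ((pts[i, 1] - pts[j, 1])^2 + (pts[i, 2] - pts[j, 2])^2 <= tol^2) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) grp[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  t(vapply(unique(roots), function(r)
    colMeans(pts[roots == r, , drop = FALSE]), numeric(2)))
}

#' Bifurcation detection score
#'
#' Detections within `tol` of each other are first merged to their
#' centroids, then matched one-to-one to truth points greedily (closest
#' pairs first, within `tol`). `recall` = matched / truth count;
#' `precision` = matched / detection count. With no detections precision
#' is 1 (no false alarms); with no truth points recall is 1.
#'
#' @param detected matrix/data.frame of detected points (columns x, y).
#' @param truth matrix/data.frame of true points (columns x, y).
#' @param tol matching tolerance in px, > 0.
#' @return list with `recall`, `precision`, `n_matched`.
#' @export
bifurcationScore <- function(detected, truth, tol = 5) {
  stopifnot(tol > 0)
  toMat <- function(p) {
    if (is.data.frame(p)) p <- as.matrix(p[, c("x", "y")])
    if (is.null(p)) p <- matrix(numeric(0), 0, 2)
    matrix(as.numeric(p), ncol = 2)
  }
  det <- toMat(detected); tru <- toMat(truth)
  if (nrow(det) > 0) det <- .mergeDetections(det, tol)
  if (nrow(det) == 0 || nrow(tru) == 0) {
    return(list(recall = if (nrow(tru) == 0) 1 else 0,
                precision = if (nrow(det) == 0) 1 else 0,
                n_matched = 0L))
  }
  dm <- outer(seq_len(nrow(det)), seq_len(nrow(tru)),
              function(i, j) sqrt((det[i, 1] - tru[j, 1])^2 +
                                  (det[i, 2] - tru[j, 2])^2))
  usedD <- rep(FALSE, nrow(det)); usedT <- rep(FALSE, nrow(tru))
  matched <- 0L
  repeat {
    dm2 <- dm
    dm2[usedD, ] <- Inf; dm2[, usedT] <- Inf
    if (all(!is.finite(dm2)) || min(dm2) > tol) break
    k <- arrayInd(which.min(dm2), dim(dm2))
    usedD[k[1]] <- TRUE; usedT[k[2]] <- TRUE
    matched <- matched + 1L
  }
  list(recall = matched / nrow(tru), precision = matched / nrow(det),
       n_matched = matched)
}
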