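#' @import methods
NULL

#' Multiscale vesselness result
#'
#' Holds the multiscale Hessian vesselness response of an image together
#' with the per-pixel fields at the winning (argmax) scale that downstream
#' modules consume: the Hessian eigenvalues, the along-vessel eigenvector,
#' and the smoothed-image gradient.
#'
#' All slots are matrices of the input image's shape except `scales`.
#' `response` is the multiscale maximum rescaled to [0, 255]; `raw` is the
#' unscaled maximum in [0, 1).
#'
#' @slot response numeric matrix, enhanced image in [0, 255].
#' @slot raw numeric matrix, unscaled vesselness maximum.
#' @slot sigma numeric matrix, per-pixel argmax scale.
#' @slot lambda1,lambda2 numeric matrices, ordered Hessian eigenvalues
#'   (|lambda1| <= |lambda2|) at the argmax scale.
#' @slot v1x,v1y numeric matrices, along-vessel unit eigenvector at the
#'   argmax scale.
#' @slot gx,gy numeric matrices, gradient of the Gaussian-smoothed image at
#'   the argmax scale.
#' @slot scales numeric vector of scales swept.
#' @exportClass VesselnessMap
setClass("VesselnessMap",
  representation(response = "matrix", raw = "matrix", sigma = "matrix",
                 lambda1 = "matrix", lambda2 = "matrix",
                 v1x = "matrix", v1y = "matrix",
                 gx = "matrix", gy = "matrix", scales = "numeric"),
  validity = function(object) {
    d <- dim(object@response)
    for (s in c("raw", "sigma", "lambda1", "lambda2", "v1x", "v1y",
                "gx", "gy")) {
      if (!identical(dim(slot(object, s)), d))
        return(paste0("slot '", s, "' shape differs from response"))
    }
    if (length(object@scales) < 1) return("no scales")
    if (any(object@scales <= 0)) return("scales must be positive")
    TRUE
  })

#' Tracked vessel skeleton
#'
#' Ordered centerline points grouped into branches, plus the bifurcation
#' points and the seed the tracking started from. Coordinates are
#' real-valued (sub-pixel), x = column, y = row, 0-based.
#'
#' Each branch is a data.frame with columns `x`, `y`, `adjusted` (logical:
#' whether center adjustment moved the point). `bifurcations` is a
#' data.frame with columns `x`, `y`: the tracking points on the parent
#' vessel at which a new branch was found (junction estimates).
#'
#' @slot branches list of data.frames (x, y, adjusted).
#' @slot bifurcations data.frame (x, y).
#' @slot seed numeric length-2 (x, y).
#' @slot truncated logical, TRUE if tracking stopped at the point budget.
#' @exportClass Skeleton
setClass("Skeleton",
  representation(branches = "list", bifurcations = "data.frame",
                 seed = "numeric", truncated = "logical"),
  validity = function(object) {
    if (length(object@seed) != 2) return("seed must be length-2 (x, y)")
    for (b in object@branches) {
      if (!is.data.frame(b) || nrow(b) < 1)
        return("every branch must be a non-empty data.frame")
      if (!all(c("x", "y", "adjusted") %in% names(b)))
        return("branch columns must be x, y, adjusted")
    }
    if (!all(c("x", "y") %in% names(object@bifurcations)))
      return("bifurcations must have columns x, y")
    TRUE
  })

#' Phantom ground truth
#'
#' Exact ground truth for a rendered synthetic phantom: dense per-branch
#' centerline polylines (0.5 px spacing) with local half-widths, the true
#' bifurcation points, and the binary vessel mask.
#'
#' @slot centerlines list of data.frames (x, y, width) per branch.
#' @slot bifurcations data.frame (x, y).
#' @slot mask integer/numeric matrix in {0, 1}.
#' @exportClass PhantomTruth
setClass("PhantomTruth",
  representation(centerlines = "list", bifurcations = "data.frame",
                 mask = "matrix"),
  validity = function(object) {
    if (!all(object@mask %in% c(0, 1))) return("mask must be binary")
    for (b in object@centerlines)
      if (!all(c("x", "y", "width") %in% names(b)))
        return("centerline columns must be x, y, width")
    TRUE
  })

#' @describeIn Skeleton-class branches accessor
#' @param object a `Skeleton`
#' @export
setGeneric("branches", function(object) standardGeneric("branches"))
#' @export
setMethod("branches", "Skeleton", function(object) object@branches)

#' @describeIn Skeleton-class bifurcation points accessor
#' @export
setGeneric("bifurcations", function(object) standardGeneric("bifurcations"))
#' @export
setMethod("bifurcations", "Skeleton", function(object) object@bifurcations)
#' @export
setMethod("bifurcations", "PhantomTruth", function(object) object@bifurcations)

#' @describeIn Skeleton-class seed point accessor
#' @export
setGeneric("seedPoint", function(object) standardGeneric("seedPoint"))
#' @export
setMethod("seedPoint", "Skeleton", function(object) object@seed)

#' @describeIn VesselnessMap-class enhanced image accessor
#' @param object a `VesselnessMap`
#' @export
setGeneric("responseMap", function(object) standardGeneric("responseMap"))
#' @export
setMethod("responseMap", "VesselnessMap", function(object) object@response)

#' @describeIn VesselnessMap-class argmax-scale map accessor
#' @export
setGeneric("scaleMap", function(object) standardGeneric("scaleMap"))
#' @export
setMethod("scaleMap", "VesselnessMap", function(object) object@sigma)

#' @describeIn PhantomTruth-class centerline polylines accessor
#' @param object a `PhantomTruth`
#' @export
setGeneric("centerlines", function(object) standardGeneric("centerlines"))
#' @export
setMethod("centerlines", "PhantomTruth", function(object) object@centerlines)

#' @describeIn PhantomTruth-class binary vessel mask accessor
#' @export
setGeneric("truthMask", function(object) standardGeneric("truthMask"))
#' @export
setMethod("truthMask", "PhantomTruth", function(object) object@mask)

#' All skeleton points as one data.frame
#'
#' @param skel a `Skeleton`
#' @return data.frame with columns branch_id, order, x, y, adjusted.
#' @export
skeletonPoints <- function(skel) {
  stopifnot(is(skel, "Skeleton"))
  out <- lapply(seq_along(skel@branches), function(i) {
    b <- skel@branches[[i]]
    data.frame(branch_id = i, order = seq_len(nrow(b)),
               x = b$x, y = b$y, adjusted = b$adjusted)
  })
  do.call(rbind, out)
}

setMethod("show", "VesselnessMap", function(object) {
  cat("VesselnessMap:", nrow(object@response), "x", ncol(object@response),
      "pixels,", length(object@scales), "scales in [",
      min(object@scales), ",", max(object@scales), "]\n")
  cat("  response range [", round(min(object@response), 2), ",",
      round(max(object@response), 2), "]\n")
})

setMethod("show", "Skeleton", function(object) {
  np <- sum(vapply(object@branches, nrow, integer(1)))
  cat("Skeleton:", length(object@branches), "branches,", np, "points,",
      nrow(object@bifurcations), "bifurcations\n")
  cat("  seed (x, y) = (", round(object@seed[1], 2), ",",
      round(object@seed[2], 2), ")",
      if (isTRUE(object@truncated)) " [truncated]" else "", "\n", sep = "")
})

setMethod("show", "PhantomTruth", function(object) {
  np <- sum(vapply(object@centerlines, nrow, integer(1)))
  cat("PhantomTruth:", length(object@centerlines), "branches,", np,
      "centerline points,", nrow(object@bifurcations), "bifurcations,",
      sum(object@mask), "mask pixels\n")
})
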