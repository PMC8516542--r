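# Skeleton and ground-truth serialization. JSON is written with a small
# fixed-format serializer (6 decimal places) so that identical skeletons
# always produce byte-identical files.

.fmtNum <- function(x) sprintf("%.6f", x)

.jsonPoint <- function(x, y, extra = "") {
  paste0('{"x":', .fmtNum(x), ',"y":', .fmtNum(y), extra, "}")
}

#' Write a skeleton to JSON
#'
#' Schema: `{"branches": [[{"x":..,"y":..,"adjusted":bool}, ...], ...],
#' "bifurcations": [{"x":..,"y":..}, ...], "seed": {"x":..,"y":..}}`.
#' Coordinates are sub-pixel, x = column, y = row, 0-based, written with 6
#' decimal places. Equal skeletons produce byte-identical files.
#'
#' @param skel a non-empty [Skeleton-class].
#' @param path output path.
#' @export
writeSkeleton <- function(skel, path) {
  stopifnot(is(skel, "Skeleton"))
  if (length(branches(skel)) == 0)
    stop("empty skeleton", call. = FALSE)
  brs <- vapply(branches(skel), function(b) {
    paste0("[", paste0(mapply(function(x, y, a)
      .jsonPoint(x, y, paste0(',"adjusted":', if (a) "true" else "false")),
      b$x, b$y, b$adjusted), collapse = ","), "]")
  }, character(1))
  bf <- bifurcations(skel)
  bifs <- if (nrow(bf) > 0)
    paste0(mapply(.jsonPoint, bf$x, bf$y), collapse = ",") else ""
  sd <- seedPoint(skel)
  txt <- paste0('{"branches":[', paste0(brs, collapse = ","),
                '],"bifurcations":[', bifs,
                '],"seed":', .jsonPoint(sd[1], sd[2]), "}")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(txt), con)
  invisible(path)
}

#' Read a skeleton from JSON
#'
#' @param path path written by [writeSkeleton()] (or following its
#'   schema).
#' @return a [Skeleton-class].
#' @export
readSkeleton <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  brs <- lapply(j$branches, function(b) {
    b <- as.data.frame(b)
    if (is.null(b$adjusted)) b$adjusted <- FALSE
    b[, c("x", "y", "adjusted")]
  })
  bf <- if (length(j$bifurcations) > 0) as.data.frame(j$bifurcations)
        else data.frame(x = numeric(0), y = numeric(0))
  new("Skeleton", branches = brs, bifurcations = bf,
      seed = c(j$seed$x, j$seed$y), truncated = FALSE)
}

#' Write skeleton points as CSV
#'
#' Columns: branch_id, order, x, y, is_bifurcation (1 if the point
#' coincides with a recorded bifurcation within 0.5 px).
#'
#' @param skel a [Skeleton-class].
#' @param path output path.
#' @export
writeSkeletonCSV <- function(skel, path) {
  stopifnot(is(skel, "Skeleton"))
  sp <- skeletonPoints(skel)
  bf <- bifurcations(skel)
  isB <- rep(0L, nrow(sp))
  if (nrow(bf) > 0) {
    for (i in seq_len(nrow(sp)))
      if (any((bf$x - sp$x[i])^2 + (bf$y - sp$y[i])^2 <= 0.25)) isB[i] <- 1L
  }
  out <- data.frame(branch_id = sp$branch_id, order = sp$order,
                    x = .fmtNum(sp$x), y = .fmtNum(sp$y),
                    is_bifurcation = isB)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write ridge points as CSV
#'
#' Columns: x, y, dir_x, dir_y.
#'
#' @param ridges data.frame from [detectRidgePoints()].
#' @param path output path.
#' @export
writeRidgesCSV <- function(ridges, path) {
  out <- data.frame(x = ridges$x, y = ridges$y,
                    dir_x = .fmtNum(ridges$dirx),
                    dir_y = .fmtNum(ridges$diry))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write phantom ground truth to JSON
#'
#' Same schema as [writeSkeleton()] plus a `width` field per centerline
#' point.
#'
#' @param truth a [PhantomTruth-class].
#' @param path output path.
#' @export
writeTruth <- function(truth, path) {
  stopifnot(is(truth, "PhantomTruth"))
  brs <- vapply(centerlines(truth), function(b) {
    paste0("[", paste0(mapply(function(x, y, w)
      .jsonPoint(x, y, paste0(',"width":', .fmtNum(w))),
      b$x, b$y, b$width), collapse = ","), "]")
  }, character(1))
  bf <- bifurcations(truth)
  bifs <- if (nrow(bf) > 0)
    paste0(mapply(.jsonPoint, bf$x, bf$y), collapse = ",") else ""
  txt <- paste0('{"branches":[', paste0(brs, collapse = ","),
                '],"bifurcations":[', bifs, "]}")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(txt), con)
  invisible(path)
}

#' Read phantom ground truth from JSON
#'
#' @param path path written by [writeTruth()].
#' @return a [PhantomTruth-class] (with an empty mask slot).
#' @export
readTruth <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  cls <- lapply(j$branches, function(b) as.data.frame(b))
  bf <- if (length(j$bifurcations) > 0) as.data.frame(j$bifurcations)
        else data.frame(x = numeric(0), y = numeric(0))
  new("PhantomTruth", centerlines = cls, bifurcations = bf,
      mask = matrix(0, 1, 1))
}
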