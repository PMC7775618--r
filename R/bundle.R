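#' Construct a streamline bundle
#'
#' A bundle is a set of streamlines, each an ordered polyline of 3D
#' coordinates in scanner (world) millimetre space, together with the
#' isotropic voxel size of the source image grid. All shape descriptors in
#' this package are computed from this representation.
#'
#' @param streamlines list of numeric matrices, each `m_i x 3`, with
#'   `m_i >= 2` rows of finite mm coordinates.
#' @param voxel_size_mm positive scalar, isotropic grid spacing of the
#'   source image in mm (default 1).
#' @param label optional bundle name.
#' @return an object of class `tract_bundle`.
#' @export
#' @examples
#' b <- tract_bundle(list(cbind(0:10, 0, 0)), voxel_size_mm = 1, label = "toy")
#' n_streamlines(b)
tract_bundle <- function(streamlines, voxel_size_mm = 1, label = NULL) {
  if (!is.list(streamlines) || length(streamlines) < 1L)
    stop("a bundle needs at least one streamline")
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 1L ||
      !is.finite(voxel_size_mm) || voxel_size_mm <= 0)
    stop("voxel_size_mm must be a positive scalar")
  streamlines <- lapply(streamlines, function(s) {
    s <- as.matrix(s)
    storage.mode(s) <- "double"
    if (ncol(s) != 3L) stop("each streamline must be an m x 3 matrix")
    if (nrow(s) < 2L) stop("each streamline needs at least 2 points")
    if (!all(is.finite(s))) stop("streamline coordinates must be finite")
    dimnames(s) <- NULL
    s
  })
  structure(
    list(streamlines = streamlines,
         voxel_size_mm = as.numeric(voxel_size_mm),
         label = label),
    class = "tract_bundle")
}

#' @export
print.tract_bundle <- function(x, ...) {
  npts <- vapply(x$streamlines, nrow, integer(1))
  cat("<tract_bundle>",
      if (!is.null(x$label)) paste0(" '", x$label, "'") else "", "\n", sep = "")
  cat("  streamlines: ", length(x$streamlines),
      "  points: ", sum(npts),
      "  voxel size: ", x$voxel_size_mm, " mm\n", sep = "")
  invisible(x)
}

#' Number of streamlines in a bundle
#' @param bundle a `tract_bundle`.
#' @return integer count.
#' @export
n_streamlines <- function(bundle) {
  stopifnot(inherits(bundle, "tract_bundle"))
  length(bundle$streamlines)
}

#' Extract the two endpoints of every streamline
#'
#' @param bundle a `tract_bundle`.
#' @return a list with `first` and `last`, each an `n x 3` matrix of the
#'   first and last point of each streamline.
#' @export
bundle_endpoints <- function(bundle) {
  stopifnot(inherits(bundle, "tract_bundle"))
  first <- t(vapply(bundle$streamlines, function(s) s[1L, ], numeric(3)))
  last  <- t(vapply(bundle$streamlines, function(s) s[nrow(s), ], numeric(3)))
  list(first = first, last = last)
}

# Stack all points of a bundle into one matrix (row-bound).
all_points <- function(bundle) {
  do.call(rbind, bundle$streamlines)
}
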