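#' Construct a voxel set
#'
#' A voxel set is the discrete representation of a bundle (or of an end
#' surface): a set of unique integer voxel coordinates on a grid whose
#' spacing is `base_voxel_size_mm / scale`. The default scale of 2 halves
#' the effective spacing, which reduces discretization error in the volume
#' and area descriptors; every metric computed from a voxel set accounts for
#' this scaling.
#'
#' @param coords integer matrix `N x 3` of voxel coordinates (rows need not
#'   be unique; duplicates are removed).
#' @param scale positive integer coordinate multiplier applied before
#'   rounding (default 2).
#' @param base_voxel_size_mm source grid spacing in mm.
#' @return an object of class `voxel_set` with fields `coords` (unique
#'   rows), `scale`, `base_voxel_size_mm`.
#' @export
voxel_set <- function(coords, scale = 2L, base_voxel_size_mm = 1) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an N x 3 matrix")
  if (nrow(coords) < 1L) stop("a voxel set needs at least one voxel")
  storage.mode(coords) <- "integer"
  if (anyNA(coords)) stop("voxel coordinates must be finite integers")
  coords <- unique(coords)
  dimnames(coords) <- NULL
  if (scale < 1L) stop("scale must be a positive integer")
  if (base_voxel_size_mm <= 0) stop("base_voxel_size_mm must be positive")
  structure(list(coords = coords,
                 scale = as.integer(scale),
                 base_voxel_size_mm = as.numeric(base_voxel_size_mm)),
            class = "voxel_set")
}

#' @export
print.voxel_set <- function(x, ...) {
  cat("<voxel_set> ", nrow(x$coords), " unique voxels, spacing ",
      voxel_spacing(x), " mm (scale ", x$scale, ")\n", sep = "")
  invisible(x)
}

#' Effective grid spacing of a voxel set in mm
#' @param vox a `voxel_set`.
#' @return scalar mm.
#' @export
voxel_spacing <- function(vox) {
  stopifnot(inherits(vox, "voxel_set"))
  vox$base_voxel_size_mm / vox$scale
}

# Round half away from zero (standard voxel binning; R's round() is
# round-half-even, which would alternate bins).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Map mm coordinates to integer voxel coordinates at the given scale.
mm_to_voxel <- function(pts, scale, base_voxel_size_mm) {
  m <- round_half_away(pts * scale / base_voxel_size_mm)
  storage.mode(m) <- "integer"
  m
}

#' Voxelize a bundle
#'
#' Converts a bundle to its set of unique voxel coordinates: coordinates are
#' multiplied by `scale / voxel_size`, rounded to the nearest integer, and
#' deduplicated. The bundle is first resampled so that consecutive points
#' are closer than the effective spacing, which guarantees each streamline's
#' voxel trace is connected.
#'
#' @param bundle a [tract_bundle].
#' @param scale positive integer coordinate multiplier (default 2).
#' @return a [voxel_set].
#' @export
voxelize_bundle <- function(bundle, scale = 2L) {
  stopifnot(inherits(bundle, "tract_bundle"))
  eff <- bundle$voxel_size_mm / scale
  bundle <- resample_max_step(bundle, eff)
  vox <- mm_to_voxel(all_points(bundle), scale, bundle$voxel_size_mm)
  voxel_set(vox, scale = scale, base_voxel_size_mm = bundle$voxel_size_mm)
}

#' Convert a voxel set to a dense binary volume
#'
#' @param vox a [voxel_set].
#' @param pad number of zero voxels to pad on every side (default 1, so
#'   boundary voxels have zero neighbors inside the array).
#' @return an object of class `binary_volume`: a 0/1 integer array plus the
#'   `origin` voxel coordinate of array index (1,1,1) and the source
#'   spacing/scale bookkeeping.
#' @export
as_binary_volume <- function(vox, pad = 1L) {
  stopifnot(inherits(vox, "voxel_set"))
  lo <- apply(vox$coords, 2L, min) - pad
  hi <- apply(vox$coords, 2L, max) + pad
  dims <- hi - lo + 1L
  arr <- array(0L, dim = dims)
  idx <- sweep(vox$coords, 2L, lo - 1L, "-")
  arr[idx] <- 1L
  structure(list(data = arr, origin = as.integer(lo),
                 scale = vox$scale,
                 base_voxel_size_mm = vox$base_voxel_size_mm),
            class = "binary_volume")
}

#' Recover the voxel set of the 1-voxels of a binary volume
#' @param vol a `binary_volume`.
#' @return a [voxel_set].
#' @export
as_voxel_set <- function(vol) {
  stopifnot(inherits(vol, "binary_volume"))
  idx <- which(vol$data == 1L, arr.ind = TRUE)
  voxel_set(sweep(idx, 2L, vol$origin - 1L, "+"),
            scale = vol$scale, base_voxel_size_mm = vol$base_voxel_size_mm)
}

# 6- and 26-neighborhood offsets.
neighbor_offsets <- function(connectivity = 6L) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  if (connectivity == 6L) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
          c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else {
    g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    g[rowSums(abs(g)) > 0L, , drop = FALSE]
  }
}

# Encode voxel triples as scalar keys for fast set membership. Coordinates
# are first shifted to be nonnegative; the products stay far below 2^53.
encode_coords <- function(coords, lo, dims) {
  (coords[, 1L] - lo[1L]) +
    (coords[, 2L] - lo[2L]) * dims[1L] +
    (coords[, 3L] - lo[3L]) * dims[1L] * dims[2L]
}

#' Extract the surface voxels of a binary volume
#'
#' A surface voxel is a 1-voxel with at least one zero-valued neighbor under
#' the chosen connectivity. Face (6) connectivity is the default, matching
#' the morphological definition used for the surface-area descriptor.
#'
#' @param vol a `binary_volume` (or a [voxel_set], converted internally).
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @return a [voxel_set] containing only the surface voxels.
#' @export
surface_voxels <- function(vol, connectivity = 6L) {
  if (inherits(vol, "voxel_set")) vol <- as_binary_volume(vol)
  stopifnot(inherits(vol, "binary_volume"))
  vox <- as_voxel_set(vol)
  coords <- vox$coords
  lo <- apply(coords, 2L, min) - 2L
  dims <- apply(coords, 2L, max) - lo + 3L
  keys <- encode_coords(coords, lo, dims)
  off <- neighbor_offsets(connectivity)
  on_surface <- rep(FALSE, nrow(coords))
  for (j in seq_len(nrow(off))) {
    nb <- sweep(coords, 2L, off[j, ], "+")
    on_surface <- on_surface | !(encode_coords(nb, lo, dims) %in% keys)
    if (all(on_surface)) break
  }
  voxel_set(coords[on_surface, , drop = FALSE],
            scale = vol$scale, base_voxel_size_mm = vol$base_voxel_size_mm)
}

#' Connected components of a voxel set
#'
#' Partitions the voxels into connected components under the chosen
#' neighborhood, sorted largest first (ties broken by the smallest
#' lexicographic minimum coordinate). 26-connectivity is the default
#' because voxelized end-surface sheets frequently connect only diagonally.
#'
#' @param vox a [voxel_set] (or `binary_volume`).
#' @param connectivity 6 or 26.
#' @return a list of [voxel_set] objects, largest first.
#' @export
connected_components <- function(vox, connectivity = 26L) {
  if (inherits(vox, "binary_volume")) vox <- as_voxel_set(vox)
  stopifnot(inherits(vox, "voxel_set"))
  coords <- vox$coords
  n <- nrow(coords)
  lo <- apply(coords, 2L, min) - 2L
  dims <- apply(coords, 2L, max) - lo + 3L
  keys <- encode_coords(coords, lo, dims)
  off <- neighbor_offsets(connectivity)
  edges <- vector("list", nrow(off))
  for (j in seq_len(nrow(off))) {
    nb <- sweep(coords, 2L, off[j, ], "+")
    hit <- match(encode_coords(nb, lo, dims), keys)
    sel <- !is.na(hit)
    edges[[j]] <- cbind(which(sel), hit[sel])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(rbind(edges, cbind(seq_len(n), seq_len(n))),
                                   directed = FALSE)
  memb <- igraph::components(g)$membership[seq_len(n)]
  comp_sets <- unname(split(seq_len(n), memb))
  # order: size desc, then smallest lexicographic min-coordinate
  min_coord <- t(vapply(comp_sets, function(ix) {
    cc <- coords[ix, , drop = FALSE]
    cc[order(cc[, 1L], cc[, 2L], cc[, 3L])[1L], ]
  }, integer(3)))
  ord <- order(-lengths(comp_sets), min_coord[, 1L], min_coord[, 2L], min_coord[, 3L])
  lapply(comp_sets[ord], function(ix)
    voxel_set(coords[ix, , drop = FALSE],
              scale = vox$scale, base_voxel_size_mm = vox$base_voxel_size_mm))
}

#' Export a binary volume or density map as NIfTI
#'
#' Requires the RNifti package. The image grid uses the effective spacing
#' of the voxel set (base voxel size / scale).
#'
#' @param vol a `binary_volume` or the `volume` field of a density map.
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(vol, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI export")
  stopifnot(inherits(vol, "binary_volume"))
  sp <- vol$base_voxel_size_mm / vol$scale
  img <- RNifti::asNifti(vol$data * 1)
  RNifti::pixdim(img) <- rep(sp, 3L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
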