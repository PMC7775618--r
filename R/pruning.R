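#' Voxel-wise streamline density of a bundle
#'
#' Counts, at every voxel of the (scaled) grid, the number of distinct
#' streamlines with at least one point rounding into that voxel. A
#' streamline crossing a voxel repeatedly still counts once there.
#'
#' @param bundle a [tract_bundle].
#' @param scale voxelization scale (default 2).
#' @return a list of class `density_map`: `coords` (integer `N x 3` matrix
#'   of occupied voxels), `count` (streamline count per voxel), `scale`,
#'   `base_voxel_size_mm`.
#' @export
density_map <- function(bundle, scale = 2L) {
  stopifnot(inherits(bundle, "tract_bundle"))
  eff <- bundle$voxel_size_mm / scale
  bundle <- resample_max_step(bundle, eff)
  per_sl <- lapply(bundle$streamlines, function(s)
    unique(mm_to_voxel(s, scale, bundle$voxel_size_mm)))
  vox <- do.call(rbind, per_sl)
  lo <- apply(vox, 2L, min) - 1L
  dims <- apply(vox, 2L, max) - lo + 2L
  keys <- encode_coords(vox, lo, dims)
  tab <- table(keys)
  ukeys <- as.numeric(names(tab))
  coords <- cbind(ukeys %% dims[1L],
                  (ukeys %/% dims[1L]) %% dims[2L],
                  ukeys %/% (dims[1L] * dims[2L]))
  coords <- sweep(coords, 2L, lo, "+")
  storage.mode(coords) <- "integer"
  structure(list(coords = coords, count = as.integer(tab),
                 scale = as.integer(scale),
                 base_voxel_size_mm = bundle$voxel_size_mm,
                 per_streamline_keys = lapply(per_sl, encode_coords, lo, dims),
                 key_lo = lo, key_dims = dims, keys = ukeys),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat("<density_map> ", nrow(x$coords), " voxels, counts ",
      min(x$count), "-", max(x$count), "\n", sep = "")
  invisible(x)
}

#' Topology-informed pruning of a bundle
#'
#' Iteratively removes noisy streamlines using the voxel-wise streamline
#' density: white-matter pathways form bundles or sheets, so a streamline
#' passing through a voxel supported by almost no other streamline is
#' likely a spurious connection. Each iteration recomputes the density map
#' and removes every streamline that touches at least one voxel whose
#' count is at or below `low_density_threshold`; iteration stops early at a
#' fixed point (an iteration that removes nothing).
#'
#' If an iteration would empty the bundle, pruning stops before it: with
#' `keep_last = TRUE` (default) the last non-empty bundle is returned with
#' a warning (thin bundles can otherwise vanish entirely), otherwise an
#' error reports the iteration at which the bundle would have emptied.
#'
#' @param bundle a [tract_bundle].
#' @param iterations maximum number of pruning passes (default 20).
#' @param low_density_threshold voxel streamline-count at or below which a
#'   voxel is "low-density" (default 1, i.e. voxels supported by a single
#'   streamline).
#' @param scale voxelization scale for the density map (default 2).
#' @param keep_last return the last non-empty bundle (with a warning)
#'   instead of erroring when pruning would remove everything.
#' @return a [tract_bundle] whose streamline set is a subset of the input,
#'   with attribute `iterations_run`.
#' @export
tip_prune <- function(bundle, iterations = 20L, low_density_threshold = 1L,
                      scale = 2L, keep_last = TRUE) {
  stopifnot(inherits(bundle, "tract_bundle"))
  if (iterations < 1L) stop("iterations must be >= 1")
  current <- bundle
  ran <- 0L
  for (it in seq_len(iterations)) {
    dm <- density_map(current, scale = scale)
    low_keys <- dm$keys[dm$count <= low_density_threshold]
    if (length(low_keys) == 0L) break          # fixed point
    touches_low <- vapply(dm$per_streamline_keys,
                          function(k) any(k %in% low_keys), logical(1))
    if (!any(touches_low)) break               # fixed point
    if (all(touches_low)) {
      msg <- paste0("pruning iteration ", it, " would remove all ",
                    n_streamlines(current), " remaining streamline(s)")
      if (keep_last) { warning(msg, "; returning the last non-empty bundle"); break }
      stop(msg)
    }
    current <- tract_bundle(current$streamlines[!touches_low],
                            voxel_size_mm = current$voxel_size_mm,
                            label = current$label)
    ran <- it
  }
  attr(current, "iterations_run") <- ran
  current
}

#' Export a density map as NIfTI
#'
#' @param dm a `density_map`.
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_density_nifti <- function(dm, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI export")
  stopifnot(inherits(dm, "density_map"))
  lo <- apply(dm$coords, 2L, min) - 1L
  dims <- apply(dm$coords, 2L, max) - lo + 2L
  arr <- array(0L, dim = dims)
  arr[sweep(dm$coords, 2L, lo - 1L, "-")] <- dm$count
  sp <- dm$base_voxel_size_mm / dm$scale
  img <- RNifti::asNifti(arr * 1)
  RNifti::pixdim(img) <- rep(sp, 3L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
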