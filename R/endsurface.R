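#' Partition streamline endpoints into two end surfaces
#'
#' Streamline point order is arbitrary (antegrade or retrograde), so the
#' two termination fields of a bundle cannot be read off the first/last
#' points directly. This constrained two-cluster iteration fixes that: it
#' starts with every first point in cluster 1 and every last point in
#' cluster 2, then repeatedly recomputes the two cluster mean coordinates
#' and, for each streamline, picks whichever of the two admissible
#' endpoint-to-cluster pairings has the smaller summed distance to the
#' means (ties keep the current pairing), until no endpoint changes
#' cluster. Exactly one endpoint per streamline sits in each cluster at
#' every iteration.
#'
#' The converged endpoint clusters are voxelized (same scale convention as
#' [voxelize_bundle()]) into the unique voxel sets E1 and E2. E1 is the
#' cluster with the larger mean coordinate along the axis of largest
#' inter-mean separation (axis ties resolved z, then y, then x).
#'
#' @param bundle a [tract_bundle]; every streamline must have distinct
#'   first and last points.
#' @param scale voxelization scale (default 2).
#' @param max_iter iteration cap (default 100).
#' @return a list of class `end_surface_pair`: `e1`, `e2` ([voxel_set]s),
#'   `first_in_e1` (logical per streamline: is the first point's cluster
#'   E1?), `separation_axis` (`"x"`, `"y"` or `"z"`), `iterations`,
#'   `converged`.
#' @export
cluster_endpoints <- function(bundle, scale = 2L, max_iter = 100L) {
  stopifnot(inherits(bundle, "tract_bundle"))
  ep <- bundle_endpoints(bundle)
  if (any(rowSums((ep$first - ep$last)^2) == 0))
    stop("streamline with coincident endpoints; end surfaces undefined")
  n <- nrow(ep$first)
  first_in_1 <- rep(TRUE, n)   # initialization: all v(1) -> cluster 1
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    c1 <- rbind(ep$first[first_in_1, , drop = FALSE],
                ep$last[!first_in_1, , drop = FALSE])
    c2 <- rbind(ep$last[first_in_1, , drop = FALSE],
                ep$first[!first_in_1, , drop = FALSE])
    m1 <- colMeans(c1)
    m2 <- colMeans(c2)
    if (all(abs(m1 - m2) < 1e-12)) {
      # coincident means: every pairing ties, so distances cannot separate
      # the clusters. Orient each streamline along the axis of largest
      # endpoint variance instead (larger coordinate -> cluster 1).
      ax <- which.max(apply(rbind(ep$first, ep$last), 2L, stats::var))
      new_assign <- ep$first[, ax] >= ep$last[, ax]
      if (all(new_assign == first_in_1)) { converged <- TRUE; break }
      first_in_1 <- new_assign
      next
    }
    d_f1 <- sqrt(rowSums(sweep(ep$first, 2L, m1)^2))  # first -> mean 1
    d_f2 <- sqrt(rowSums(sweep(ep$first, 2L, m2)^2))
    d_l1 <- sqrt(rowSums(sweep(ep$last, 2L, m1)^2))
    d_l2 <- sqrt(rowSums(sweep(ep$last, 2L, m2)^2))
    cost_fwd <- d_f1 + d_l2    # first -> 1, last -> 2
    cost_rev <- d_f2 + d_l1    # the swap
    new_assign <- ifelse(cost_fwd < cost_rev, TRUE,
                         ifelse(cost_rev < cost_fwd, FALSE, first_in_1))
    if (all(new_assign == first_in_1)) { converged <- TRUE; break }
    first_in_1 <- new_assign
  }
  if (!converged)
    warning("endpoint clustering did not converge in ", max_iter, " iterations")
  p1 <- rbind(ep$first[first_in_1, , drop = FALSE],
              ep$last[!first_in_1, , drop = FALSE])
  p2 <- rbind(ep$last[first_in_1, , drop = FALSE],
              ep$first[!first_in_1, , drop = FALSE])
  vs <- bundle$voxel_size_mm
  e1 <- voxel_set(mm_to_voxel(p1, scale, vs), scale = scale, base_voxel_size_mm = vs)
  e2 <- voxel_set(mm_to_voxel(p2, scale, vs), scale = scale, base_voxel_size_mm = vs)
  gap <- abs(colMeans(e1$coords) - colMeans(e2$coords))
  # axis of largest inter-mean distance; ties prefer z, then y, then x
  axis <- order(gap, c(1, 2, 3), decreasing = TRUE)[1L]
  if (colMeans(e1$coords)[axis] < colMeans(e2$coords)[axis]) {
    tmp <- e1; e1 <- e2; e2 <- tmp
    first_in_1 <- !first_in_1
  }
  structure(list(e1 = e1, e2 = e2, first_in_e1 = first_in_1,
                 separation_axis = c("x", "y", "z")[axis],
                 iterations = iter, converged = converged),
            class = "end_surface_pair")
}

#' @export
print.end_surface_pair <- function(x, ...) {
  cat("<end_surface_pair> E1: ", nrow(x$e1$coords), " voxels, E2: ",
      nrow(x$e2$coords), " voxels, separation axis ", x$separation_axis,
      " (", x$iterations, " iteration(s))\n", sep = "")
  invisible(x)
}

#' Area of an end surface
#'
#' Number of end-surface voxels times the squared effective spacing.
#'
#' @param e a [voxel_set] holding one end surface.
#' @return scalar square mm.
#' @export
end_surface_area <- function(e) {
  stopifnot(inherits(e, "voxel_set"))
  nrow(e$coords) * voxel_spacing(e)^2
}

#' Radius of an end surface
#'
#' Models the end surface as a filled disk: for a uniform distribution on a
#' disk the mean distance to the center is 2/3 of the radius, so the radius
#' is estimated as 1.5 times the mean Euclidean distance (mm) of the
#' end-surface voxels to their mean coordinate.
#'
#' @param e a [voxel_set] holding one end surface.
#' @return scalar mm (0 for a single voxel).
#' @export
end_surface_radius <- function(e) {
  stopifnot(inherits(e, "voxel_set"))
  1.5 * mean_distance_to_center(e)
}

# Mean Euclidean distance (mm) of a voxel set's voxels to their centroid.
mean_distance_to_center <- function(e) {
  mm <- e$coords * voxel_spacing(e)
  ctr <- colMeans(mm)
  mean(sqrt(rowSums(sweep(mm, 2L, ctr)^2)))
}

#' Irregularity of an end surface
#'
#' `pi * radius^2 / area`: 1 for an ideal disk, larger for any protrusion,
#' intrusion, or fragmentation of the termination field.
#'
#' @param radius_mm end-surface radius in mm.
#' @param area_mm2 end-surface area in square mm.
#' @return dimensionless scalar.
#' @export
end_surface_irregularity <- function(radius_mm, area_mm2) {
  if (area_mm2 <= 0) stop("end-surface irregularity is undefined for zero area")
  pi * radius_mm^2 / area_mm2
}

#' Isolate the trunk of a bundle
#'
#' The largest connected component of each end surface defines a region of
#' interest; the trunk is the sub-bundle of streamlines whose E1-side
#' endpoint voxel lies in the E1 ROI and whose E2-side endpoint voxel lies
#' in the E2 ROI. Trunk volume is the voxelized volume of that sub-bundle.
#'
#' @param bundle a [tract_bundle].
#' @param surfaces an `end_surface_pair` from [cluster_endpoints()].
#' @param scale voxelization scale (default 2; must match the one used for
#'   the surfaces).
#' @param component_connectivity connectivity for the connected-component
#'   analysis (default 26).
#' @return a list of class `trunk_result`: `trunk_streamlines` (integer
#'   indices into the bundle), `trunk_bundle` (a [tract_bundle], or NULL if
#'   empty), `trunk_volume_mm3`.
#' @export
trunk <- function(bundle, surfaces, scale = 2L, component_connectivity = 26L) {
  stopifnot(inherits(bundle, "tract_bundle"),
            inherits(surfaces, "end_surface_pair"))
  roi1 <- connected_components(surfaces$e1, connectivity = component_connectivity)[[1L]]
  roi2 <- connected_components(surfaces$e2, connectivity = component_connectivity)[[1L]]
  ep <- bundle_endpoints(bundle)
  vs <- bundle$voxel_size_mm
  vox_first <- mm_to_voxel(ep$first, scale, vs)
  vox_last  <- mm_to_voxel(ep$last, scale, vs)
  vox_e1 <- vox_first
  vox_e1[!surfaces$first_in_e1, ] <- vox_last[!surfaces$first_in_e1, ]
  vox_e2 <- vox_last
  vox_e2[!surfaces$first_in_e1, ] <- vox_first[!surfaces$first_in_e1, ]
  in_roi <- function(v, roi) {
    lo <- pmin(apply(v, 2L, min), apply(roi$coords, 2L, min)) - 1L
    dims <- pmax(apply(v, 2L, max), apply(roi$coords, 2L, max)) - lo + 2L
    encode_coords(v, lo, dims) %in% encode_coords(roi$coords, lo, dims)
  }
  keep <- in_roi(vox_e1, roi1) & in_roi(vox_e2, roi2)
  idx <- which(keep)
  if (length(idx) == 0L) {
    warning("empty trunk: no streamline terminates in both largest components")
    return(structure(list(trunk_streamlines = integer(0), trunk_bundle = NULL,
                          trunk_volume_mm3 = 0),
                     class = "trunk_result"))
  }
  tb <- tract_bundle(bundle$streamlines[idx], voxel_size_mm = vs,
                     label = bundle$label)
  vol <- bundle_volume(voxelize_bundle(tb, scale = scale))
  structure(list(trunk_streamlines = idx, trunk_bundle = tb,
                 trunk_volume_mm3 = vol),
            class = "trunk_result")
}
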