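#' Mean streamline length of a bundle
#'
#' The length descriptor: the mean over streamlines of the summed
#' consecutive-point Euclidean distances (polyline arc length), in mm.
#'
#' @param bundle a [tract_bundle].
#' @return scalar mm.
#' @export
bundle_length <- function(bundle) {
  stopifnot(inherits(bundle, "tract_bundle"))
  lens <- vapply(bundle$streamlines, streamline_length, numeric(1))
  if (any(lens == 0)) warning("bundle contains zero-length streamline(s)")
  mean(lens)
}

streamline_length <- function(s) {
  m <- nrow(s)
  sum(sqrt(rowSums((s[-1L, , drop = FALSE] - s[-m, , drop = FALSE])^2)))
}

#' Mean endpoint span of a bundle
#'
#' The span descriptor: the mean over streamlines of the Euclidean distance
#' between the first and last point, in mm.
#'
#' @param bundle a [tract_bundle].
#' @return scalar mm.
#' @export
bundle_span <- function(bundle) {
  stopifnot(inherits(bundle, "tract_bundle"))
  ep <- bundle_endpoints(bundle)
  mean(sqrt(rowSums((ep$first - ep$last)^2)))
}

#' Curl of a bundle
#'
#' Curl is length divided by span, with range `[1, Inf)`: a straight bundle
#' has curl 1 and curvier bundles have larger values (for a circular arc of
#' subtended angle `a`, curl is `a / (2 sin(a/2))`).
#'
#' @param length_mm bundle length in mm.
#' @param span_mm bundle span in mm; must be positive (a closed loop has no
#'   defined curl).
#' @return dimensionless scalar.
#' @export
curl <- function(length_mm, span_mm) {
  if (span_mm <= 0) stop("curl is undefined for zero span (closed loop)")
  length_mm / span_mm
}

#' Voxelized volume of a bundle
#'
#' Volume is the number of unique voxels times the effective per-voxel
#' volume `(voxel_size / scale)^3`, in cubic mm.
#'
#' @param vox a [voxel_set] (e.g. from [voxelize_bundle()]).
#' @return scalar cubic mm.
#' @export
bundle_volume <- function(vox) {
  stopifnot(inherits(vox, "voxel_set"))
  nrow(vox$coords) * voxel_spacing(vox)^3
}

#' Cylinder-model diameter of a bundle
#'
#' Models the bundle as a cylinder of the measured volume and length:
#' `diameter = 2 sqrt(volume / (pi * length))`, in mm.
#'
#' @param volume_mm3 bundle volume in cubic mm.
#' @param length_mm bundle length in mm.
#' @return scalar mm.
#' @export
bundle_diameter <- function(volume_mm3, length_mm) {
  if (length_mm <= 0) stop("diameter is undefined for zero length")
  if (volume_mm3 <= 0) stop("diameter is undefined for zero volume")
  2 * sqrt(volume_mm3 / (pi * length_mm))
}

#' Elongation of a bundle
#'
#' Length divided by the cylinder-model diameter.
#'
#' @param length_mm bundle length in mm.
#' @param diameter_mm cylinder-model diameter in mm.
#' @return dimensionless scalar.
#' @export
elongation <- function(length_mm, diameter_mm) {
  if (diameter_mm <= 0) stop("elongation is undefined for zero diameter")
  length_mm / diameter_mm
}

#' Voxelized surface area of a bundle
#'
#' The number of surface voxels (1-voxels with at least one zero neighbor,
#' 6-connectivity by default) times the squared effective spacing, in square
#' mm. The two end ("innervation") caps are part of this surface.
#'
#' @param vox a [voxel_set].
#' @param connectivity neighborhood used for surface detection (6 or 26).
#' @return scalar square mm.
#' @export
bundle_surface_area <- function(vox, connectivity = 6L) {
  stopifnot(inherits(vox, "voxel_set"))
  surf <- surface_voxels(as_binary_volume(vox), connectivity = connectivity)
  nrow(surf$coords) * voxel_spacing(vox)^2
}

#' Irregularity of a bundle
#'
#' Surface area divided by the lateral surface of the model cylinder,
#' `pi * diameter * length`. An ideal continuous cylinder (caps included)
#' gives `1 + diameter / (2 length)`; values well above that indicate a
#' less compact, more convoluted surface.
#'
#' @param surface_area_mm2 bundle surface area in square mm.
#' @param diameter_mm cylinder-model diameter in mm.
#' @param length_mm bundle length in mm.
#' @return dimensionless scalar.
#' @export
irregularity <- function(surface_area_mm2, diameter_mm, length_mm) {
  if (diameter_mm <= 0 || length_mm <= 0)
    stop("irregularity is undefined for zero diameter or length")
  surface_area_mm2 / (pi * diameter_mm * length_mm)
}

#' The canonical shape-descriptor names
#'
#' The 15 per-bundle descriptors, in canonical column order.
#' @return character vector of length 15.
#' @export
shape_descriptor_names <- function() {
  c("length_mm", "span_mm", "curl", "diameter_mm", "elongation",
    "volume_mm3", "trunk_volume_mm3", "surface_area_mm2",
    "area_e1_mm2", "area_e2_mm2", "radius_e1_mm", "radius_e2_mm",
    "irregularity", "irregularity_e1", "irregularity_e2")
}

#' Compute the full shape profile of a bundle
#'
#' Chains resampling, voxelization, surface extraction, endpoint
#' clustering, and trunk isolation to produce the 15 canonical descriptors
#' for one bundle: length, span, curl, diameter, elongation, volume, trunk
#' volume, surface area, the two end-surface areas and radii, and the
#' bundle and end-surface irregularities. Deterministic given the bundle
#' and settings.
#'
#' @param bundle a [tract_bundle].
#' @param scale voxelization scale (default 2).
#' @param surface_connectivity connectivity for surface-voxel detection
#'   (default 6).
#' @param component_connectivity connectivity for end-surface connected
#'   components (default 26).
#' @return a one-row data.frame with columns `label`, `n_streamlines`, and
#'   the 15 descriptors named as in [shape_descriptor_names()].
#' @export
#' @examples
#' b <- make_cylinder(length_mm = 40, diameter_mm = 6, n_streamlines = 150,
#'                    seed = 1)
#' compute_profile(b)
compute_profile <- function(bundle, scale = 2L,
                            surface_connectivity = 6L,
                            component_connectivity = 26L) {
  stopifnot(inherits(bundle, "tract_bundle"))
  len <- bundle_length(bundle)
  spn <- bundle_span(bundle)
  if (spn < 0.1)
    stop("bundle span below 0.1 mm (closed loop?); curl and end surfaces undefined")
  vox <- voxelize_bundle(bundle, scale = scale)
  vol <- bundle_volume(vox)
  dia <- bundle_diameter(vol, len)
  area <- bundle_surface_area(vox, connectivity = surface_connectivity)
  ends <- cluster_endpoints(bundle, scale = scale)
  tr <- trunk(bundle, ends, scale = scale,
              component_connectivity = component_connectivity)
  res <- data.frame(
    label = if (is.null(bundle$label)) NA_character_ else bundle$label,
    n_streamlines = n_streamlines(bundle),
    length_mm = len,
    span_mm = spn,
    curl = curl(len, spn),
    diameter_mm = dia,
    elongation = elongation(len, dia),
    volume_mm3 = vol,
    trunk_volume_mm3 = tr$trunk_volume_mm3,
    surface_area_mm2 = area,
    area_e1_mm2 = end_surface_area(ends$e1),
    area_e2_mm2 = end_surface_area(ends$e2),
    radius_e1_mm = end_surface_radius(ends$e1),
    radius_e2_mm = end_surface_radius(ends$e2),
    irregularity = irregularity(area, dia, len),
    stringsAsFactors = FALSE)
  res$irregularity_e1 <- end_surface_irregularity(res$radius_e1_mm, res$area_e1_mm2)
  res$irregularity_e2 <- end_surface_irregularity(res$radius_e2_mm, res$area_e2_mm2)
  res
}

#' Shape profiles for a collection of bundles
#'
#' @param bundles list of [tract_bundle] objects (names used as labels when
#'   the bundles carry none).
#' @param ... passed to [compute_profile()].
#' @return a data.frame with one row per bundle.
#' @export
compute_profiles <- function(bundles, ...) {
  stopifnot(is.list(bundles), length(bundles) >= 1L)
  rows <- lapply(seq_along(bundles), function(i) {
    b <- bundles[[i]]
    if (is.null(b$label) && !is.null(names(bundles)))
      b$label <- names(bundles)[i]
    compute_profile(b, ...)
  })
  do.call(rbind, rows)
}
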