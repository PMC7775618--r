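# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Sample points uniformly in a disk
#'
#' Uniform sampling over a filled disk by square-root inversion of the
#' radial CDF. This is the transverse sampler behind [make_cylinder()] and
#' the calibration behind the end-surface radius model: the mean distance
#' of uniform disk points to the center is 2/3 of the radius.
#'
#' @param n number of points.
#' @param radius disk radius.
#' @param seed optional RNG seed.
#' @return `n x 2` matrix of coordinates.
#' @export
runif_disk <- function(n, radius, seed = NULL) {
  with_seed(seed, {
    r <- radius * sqrt(stats::runif(n))
    theta <- stats::runif(n, 0, 2 * pi)
    cbind(r * cos(theta), r * sin(theta))
  })
}

apply_pose <- function(pts, rotation = NULL, translation = c(0, 0, 0)) {
  if (!is.null(rotation)) pts <- pts %*% t(rotation)
  sweep(pts, 2L, translation, "+")
}

#' Synthetic cylindrical bundle with known descriptors
#'
#' Generates `n_streamlines` parallel straight streamlines along the x
#' axis (before the optional pose), with transverse positions uniform over
#' the disk of the given diameter. All descriptors have closed forms,
#' attached as the `ground_truth` attribute: length = span = L, curl = 1,
#' diameter = D, elongation = L/D, volume = pi D^2 L / 4, surface area
#' (lateral plus caps) = pi D L + pi D^2 / 2, end-surface radius = D / 2.
#'
#' @param length_mm cylinder length L (mm).
#' @param diameter_mm cylinder diameter D (mm).
#' @param n_streamlines number of streamlines.
#' @param point_spacing_mm axial point spacing (default 0.4 mm, below the
#'   0.5 mm effective voxel spacing at scale 2 so voxel traces are
#'   connected without further resampling).
#' @param rotation optional 3x3 rotation matrix.
#' @param translation optional length-3 translation (mm).
#' @param flip_fraction fraction of streamlines stored in reversed point
#'   order (default 0), to exercise orientation-invariance.
#' @param voxel_size_mm source grid spacing (default 1).
#' @param seed RNG seed for reproducibility.
#' @param label bundle name.
#' @return a [tract_bundle] with attribute `ground_truth`.
#' @export
make_cylinder <- function(length_mm, diameter_mm, n_streamlines,
                          point_spacing_mm = 0.4, rotation = NULL,
                          translation = c(0, 0, 0), flip_fraction = 0,
                          voxel_size_mm = 1, seed = NULL, label = "cylinder") {
  stopifnot(length_mm > 0, diameter_mm > 0, n_streamlines >= 1)
  with_seed(seed, {
    npts <- ceiling(length_mm / point_spacing_mm) + 1L
    x <- seq(0, length_mm, length.out = npts)
    yz <- runif_disk(n_streamlines, diameter_mm / 2)
    flip <- stats::runif(n_streamlines) < flip_fraction
    sls <- lapply(seq_len(n_streamlines), function(i) {
      s <- cbind(x, yz[i, 1L], yz[i, 2L])
      if (flip[i]) s <- s[rev(seq_len(nrow(s))), , drop = FALSE]
      apply_pose(s, rotation, translation)
    })
    b <- tract_bundle(sls, voxel_size_mm = voxel_size_mm, label = label)
    attr(b, "ground_truth") <- list(
      length_mm = length_mm, span_mm = length_mm, curl = 1,
      diameter_mm = diameter_mm, elongation = length_mm / diameter_mm,
      volume_mm3 = pi * diameter_mm^2 * length_mm / 4,
      surface_area_mm2 = pi * diameter_mm * length_mm + pi * diameter_mm^2 / 2,
      end_radius_mm = diameter_mm / 2)
    b
  })
}

#' Synthetic circular-arc ("C-shaped") bundle with known curl
#'
#' The centerline is a circular arc of the given radius and subtended
#' angle in the xy plane; each streamline is offset within a disk of the
#' tube diameter (radially and along z), so the mean centerline geometry
#' is preserved. Ground truth (attached as `ground_truth`): length =
#' radius x angle, span = 2 radius sin(angle/2), curl = angle /
#' (2 sin(angle/2)).
#'
#' @param radius_mm arc radius (mm).
#' @param angle_rad subtended angle in radians, in (0, 2 pi).
#' @param tube_diameter_mm diameter of the streamline tube (mm).
#' @param n_streamlines number of streamlines.
#' @param point_spacing_mm arc-length point spacing (default 0.4 mm).
#' @param voxel_size_mm source grid spacing (default 1).
#' @param seed RNG seed.
#' @param label bundle name.
#' @return a [tract_bundle] with attribute `ground_truth`.
#' @export
make_arc <- function(radius_mm, angle_rad, tube_diameter_mm = 2,
                     n_streamlines = 50, point_spacing_mm = 0.4,
                     voxel_size_mm = 1, seed = NULL, label = "arc") {
  stopifnot(radius_mm > 0, angle_rad > 0, angle_rad < 2 * pi,
            tube_diameter_mm > 0, n_streamlines >= 1)
  with_seed(seed, {
    npts <- ceiling(radius_mm * angle_rad / point_spacing_mm) + 1L
    theta <- seq(0, angle_rad, length.out = npts)
    off <- runif_disk(n_streamlines, tube_diameter_mm / 2)
    sls <- lapply(seq_len(n_streamlines), function(i) {
      r <- radius_mm + off[i, 1L]
      cbind(r * cos(theta), r * sin(theta), off[i, 2L])
    })
    b <- tract_bundle(sls, voxel_size_mm = voxel_size_mm, label = label)
    attr(b, "ground_truth") <- list(
      length_mm = radius_mm * angle_rad,
      span_mm = 2 * radius_mm * sin(angle_rad / 2),
      curl = angle_rad / (2 * sin(angle_rad / 2)))
    b
  })
}

#' Perturbed test-retest copies of a bundle
#'
#' Emulates the noise structure of repeat scans: two independently
#' perturbed copies of the same underlying bundle, each with isotropic
#' Gaussian coordinate jitter and an independent random fraction of
#' streamlines dropped. With zero jitter and zero drop the copies are
#' identical, so descriptor ICC over any cohort is 1; increasing jitter
#' relative to between-subject variation drives ICC toward 0.
#'
#' @param bundle a [tract_bundle].
#' @param jitter_mm standard deviation of the per-coordinate jitter (mm).
#' @param drop_fraction fraction of streamlines dropped in each copy,
#'   in `[0, 1)`.
#' @param seed RNG seed.
#' @return a list with elements `test` and `retest`, both [tract_bundle]s.
#' @export
make_retest_pair <- function(bundle, jitter_mm = 0, drop_fraction = 0,
                             seed = NULL) {
  stopifnot(inherits(bundle, "tract_bundle"),
            jitter_mm >= 0, drop_fraction >= 0, drop_fraction < 1)
  with_seed(seed, {
    perturb <- function() {
      sls <- bundle$streamlines
      n <- length(sls)
      n_drop <- floor(drop_fraction * n)
      if (n_drop > 0 && n - n_drop >= 1)
        sls <- sls[-sample.int(n, n_drop)]
      sls <- lapply(sls, function(s)
        s + matrix(stats::rnorm(length(s), 0, jitter_mm), nrow(s), 3L))
      tract_bundle(sls, voxel_size_mm = bundle$voxel_size_mm,
                   label = bundle$label)
    }
    list(test = perturb(), retest = perturb())
  })
}

#' Append isolated stray streamlines to a bundle
#'
#' Adds short straight streamlines displaced from the bundle centroid by
#' `offset_mm` in random transverse directions. When the offset exceeds
#' the bundle's extent the strays share no voxel with the dense core, so
#' topology-informed pruning at density threshold 1 removes exactly these;
#' a stray placed at offset 0 may merge with the core and is not
#' guaranteed to be removed.
#'
#' @param bundle a [tract_bundle].
#' @param n_strays number of strays to append.
#' @param offset_mm displacement of each stray from the bundle centroid;
#'   should exceed the bundle's radius for the non-overlap guarantee.
#' @param stray_length_mm length of each stray (default 20).
#' @param point_spacing_mm point spacing (default 0.4).
#' @param seed RNG seed.
#' @return a [tract_bundle] with attribute `stray_indices` giving the
#'   positions of the appended strays.
#' @export
add_stray_streamlines <- function(bundle, n_strays, offset_mm,
                                  stray_length_mm = 20,
                                  point_spacing_mm = 0.4, seed = NULL) {
  stopifnot(inherits(bundle, "tract_bundle"), n_strays >= 0, offset_mm >= 0)
  if (n_strays == 0L) return(bundle)
  with_seed(seed, {
    ctr <- colMeans(all_points(bundle))
    npts <- ceiling(stray_length_mm / point_spacing_mm) + 1L
    t01 <- seq(-0.5, 0.5, length.out = npts)
    strays <- lapply(seq_len(n_strays), function(i) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      v <- stats::rnorm(3); v <- v - sum(v * u) * u; v <- v / sqrt(sum(v^2))
      start <- ctr + offset_mm * u
      t(vapply(t01, function(s) start + s * stray_length_mm * v, numeric(3)))
    })
    out <- tract_bundle(c(bundle$streamlines, strays),
                        voxel_size_mm = bundle$voxel_size_mm,
                        label = bundle$label)
    attr(out, "ground_truth") <- attr(bundle, "ground_truth")
    attr(out, "stray_indices") <- n_streamlines(bundle) + seq_len(n_strays)
    out
  })
}

#' A 14-bundle synthetic cohort member
#'
#' Generates one subject's worth of bundles: 7 left/right pairs mixing
#' straight cylinders and C-shaped arcs with subject-specific sizes, named
#' after association pathways for familiarity. Used to exercise the full
#' profile-plus-statistics pipeline without any imaging data.
#'
#' @param subject_scale multiplicative size factor for this subject
#'   (default 1).
#' @param n_streamlines streamlines per bundle (default 200).
#' @param seed RNG seed.
#' @return a named list of 14 [tract_bundle]s.
#' @export
make_bundle_set <- function(subject_scale = 1, n_streamlines = 200,
                            seed = NULL) {
  with_seed(seed, {
    specs <- list(
      AF  = list(kind = "arc", radius = 30, angle = 2.2, tube = 6),
      C   = list(kind = "arc", radius = 40, angle = 2.8, tube = 5),
      FAT = list(kind = "cyl", L = 50, D = 9),
      IFOF = list(kind = "cyl", L = 90, D = 7),
      ILF = list(kind = "cyl", L = 70, D = 7),
      SLF = list(kind = "cyl", L = 65, D = 8),
      UF  = list(kind = "arc", radius = 22, angle = 2.5, tube = 6))
    out <- list()
    for (side in c("L", "R")) {
      for (nm in names(specs)) {
        sp <- specs[[nm]]
        sd_i <- sample.int(.Machine$integer.max %/% 2L, 1L)
        b <- if (sp$kind == "cyl") {
          make_cylinder(sp$L * subject_scale, sp$D * subject_scale,
                        n_streamlines, seed = sd_i,
                        label = paste0(nm, "_", side))
        } else {
          make_arc(sp$radius * subject_scale, sp$angle,
                   sp$tube * subject_scale, n_streamlines, seed = sd_i,
                   label = paste0(nm, "_", side))
        }
        out[[paste0(nm, "_", side)]] <- b
      }
    }
    out
  })
}
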