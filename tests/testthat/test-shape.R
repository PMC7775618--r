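test_that("length, span, and curl have their analytic values", {
  straight <- tract_bundle(list(rbind(c(0, 0, 0), c(100, 0, 0))))
  expect_equal(bundle_length(straight), 100)
  expect_equal(bundle_span(straight), 100)
  expect_equal(curl(100, 100), 1)

  two <- tract_bundle(list(rbind(c(0, 0, 0), c(80, 0, 0)),
                           rbind(c(0, 5, 0), c(120, 5, 0))))
  expect_equal(bundle_length(two), 100)

  theta <- seq(0, pi, length.out = 2000)
  semi <- tract_bundle(list(cbind(50 * cos(theta), 50 * sin(theta), 0)))
  expect_equal(bundle_length(semi), pi * 50, tolerance = 1e-3)
  expect_equal(bundle_span(semi), 100, tolerance = 1e-9)
  expect_equal(curl(bundle_length(semi), bundle_span(semi)), pi / 2,
               tolerance = 1e-3)
  expect_equal(curl(150, 100), 1.5)
  expect_error(curl(10, 0), "undefined")
})

test_that("diameter, elongation, and irregularity algebra is exact", {
  # volume = pi r^2 L with r = 5, L = 100 inverts to diameter 10
  expect_equal(bundle_diameter(pi * 25 * 100, 100), 10)
  expect_equal(bundle_diameter(100, 100), 2 * sqrt(100 / (100 * pi)))
  expect_equal(elongation(100, 10), 10)
  expect_equal(elongation(7, 7), 1)
  expect_error(elongation(10, 0), "undefined")
  # ideal continuous cylinder with caps: irregularity 1 + D / (2L)
  L <- 100; D <- 10
  area <- pi * D * L + pi * D^2 / 2
  expect_equal(irregularity(area, D, L), 1 + D / (2 * L))
  expect_equal(irregularity(2 * pi * D * L, D, L), 2)
})

test_that("volume and surface area follow the voxel-count definitions", {
  v <- voxel_set(rbind(c(0, 0, 0)), scale = 2L, base_voxel_size_mm = 1)
  expect_equal(bundle_volume(v), 0.125)
  expect_equal(bundle_surface_area(v), 0.25)
  cube <- voxel_set(as.matrix(expand.grid(1:5, 1:5, 1:5)),
                    scale = 2L, base_voxel_size_mm = 1)
  expect_equal(bundle_surface_area(cube), 98 * 0.25)
})

test_that("synthetic cylinders recover their parameters", {
  # cross-sectional density of 3 streamlines per effective voxel cell
  for (cfg in list(c(50, 5), c(100, 10))) {
    L <- cfg[1]; D <- cfg[2]
    b <- make_cylinder(L, D, round(3 * pi * D^2), seed = 13)
    expect_equal(bundle_length(b), L, tolerance = 2e-2)
    vox <- voxelize_bundle(b)
    vol <- bundle_volume(vox)
    expect_equal(vol, pi * D^2 * L / 4, tolerance = 0.1)
    dia <- bundle_diameter(vol, bundle_length(b))
    expect_equal(dia, D, tolerance = 5e-2)
    expect_equal(elongation(bundle_length(b), dia), L / D, tolerance = 7e-2)
  }
})

test_that("surface area approaches the analytic cylinder surface when saturated", {
  # surface needs a hole-free volume: saturate the cross-section (about 10
  # streamlines per voxel cell) so only staircase discretization remains
  L <- 50; D <- 10
  b <- make_cylinder(L, D, round(10 * pi * D^2), seed = 14)
  sa <- bundle_surface_area(voxelize_bundle(b))
  expect_equal(sa, pi * D * L + pi * D^2 / 2, tolerance = 0.25)
})

test_that("a star cross-section bundle is more irregular than a round one", {
  # equal-volume bundles: circular disk vs 4-armed star cross-section
  set.seed(17)
  L <- 40
  x <- seq(0, L, by = 0.4)
  star_pts <- function(n) {
    out <- matrix(0, 0, 2)
    while (nrow(out) < n) {
      p <- matrix(runif(2 * n, -6, 6), ncol = 2)
      keep <- (abs(p[, 1]) < 1.2) | (abs(p[, 2]) < 1.2)
      out <- rbind(out, p[keep, , drop = FALSE])
    }
    out[seq_len(n), ]
  }
  yz_star <- star_pts(1200)
  star <- tract_bundle(lapply(seq_len(nrow(yz_star)), function(i)
    cbind(x, yz_star[i, 1], yz_star[i, 2])), label = "star")
  round_b <- make_cylinder(L, 6, 1200, seed = 18)
  prof_star <- compute_profile(star)
  prof_round <- compute_profile(round_b)
  expect_gt(prof_star$irregularity, prof_round$irregularity)
})

test_that("profiles carry 15 descriptors and are order-invariant", {
  b <- make_cylinder(40, 6, 300, seed = 21)
  p <- compute_profile(b)
  expect_true(all(shape_descriptor_names() %in% names(p)))
  expect_length(shape_descriptor_names(), 15L)
  expect_true(all(is.finite(unlist(p[shape_descriptor_names()]))))
  expect_equal(p$curl, 1, tolerance = 1e-9)
  expect_lte(p$trunk_volume_mm3, p$volume_mm3)
  expect_lte(p$span_mm, p$length_mm + 1e-9)
  # permuting streamline order changes nothing
  b2 <- tract_bundle(b$streamlines[sample(n_streamlines(b))],
                     voxel_size_mm = 1, label = b$label)
  p2 <- compute_profile(b2)
  expect_equal(p2[shape_descriptor_names()], p[shape_descriptor_names()])
})

test_that("descriptors transform correctly under rigid motion and scaling", {
  b <- make_cylinder(40, 6, round(3 * pi * 36), seed = 25)
  p <- compute_profile(b)
  # rigid translation + rotation: exact for polyline metrics, within
  # discretization tolerance for voxel metrics
  R <- rotation_z(0.7)
  moved <- tract_bundle(lapply(b$streamlines, function(s)
    sweep(s %*% t(R), 2, c(12.3, -4.5, 6.7), "+")), voxel_size_mm = 1)
  pm <- compute_profile(moved)
  expect_equal(pm$length_mm, p$length_mm, tolerance = 1e-9)
  expect_equal(pm$span_mm, p$span_mm, tolerance = 1e-9)
  expect_equal(pm$curl, p$curl, tolerance = 1e-9)
  expect_equal(pm$volume_mm3, p$volume_mm3, tolerance = 0.1)
  # uniform scaling by s of object and grid together: lengths scale s,
  # areas s^2, volumes s^3, curl and elongation unchanged (exactly, since
  # the voxelization pattern is identical)
  s <- 2
  big <- tract_bundle(lapply(b$streamlines, function(m) m * s), voxel_size_mm = s)
  pb <- compute_profile(big)
  expect_equal(pb$length_mm, s * p$length_mm, tolerance = 1e-9)
  expect_equal(pb$span_mm, s * p$span_mm, tolerance = 1e-9)
  expect_equal(pb$curl, p$curl, tolerance = 1e-9)
  expect_equal(pb$volume_mm3, s^3 * p$volume_mm3, tolerance = 1e-9)
  expect_equal(pb$surface_area_mm2, s^2 * p$surface_area_mm2, tolerance = 1e-9)
  expect_equal(pb$diameter_mm, s * p$diameter_mm, tolerance = 1e-9)
  expect_equal(pb$elongation, p$elongation, tolerance = 1e-9)
})

test_that("curl is at least 1 on arbitrary generated bundles", {
  set.seed(33)
  for (i in 1:20) {
    sls <- lapply(1:5, function(j) {
      steps <- matrix(rnorm(30), 10, 3)
      apply(steps, 2, cumsum)
    })
    b <- tract_bundle(sls)
    expect_gte(curl(bundle_length(b), bundle_span(b)), 1 - 1e-9)
  }
})

test_that("degenerate bundles are refused where descriptors are undefined", {
  loop_theta <- seq(0, 2 * pi, length.out = 100)
  loop <- tract_bundle(list(cbind(cos(loop_theta), sin(loop_theta), 0)))
  expect_error(compute_profile(loop), "span")
  expect_warning(bundle_length(tract_bundle(list(rbind(c(1, 1, 1), c(1, 1, 1))))),
                 "zero-length")
})
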