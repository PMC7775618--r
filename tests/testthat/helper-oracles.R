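# Brute-force oracles, kept independent of the package's implementations:
# plain double loops and flood fills over small instances.

# Hausdorff distance by exhaustive max-min over all point pairs.
brute_hausdorff <- function(a, b) {
  dmat <- matrix(0, nrow(a), nrow(b))
  for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b)))
      dmat[i, j] <- sqrt(sum((a[i, ] - b[j, ])^2))
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}

# Round half away from zero, scalar-wise (independent re-statement).
brute_round <- function(x) sign(x) * floor(abs(x) + 0.5)

# Voxel-wise streamline density as a named count table keyed by
# "x,y,z" strings; resamples with the package's rule stated inline.
brute_density <- function(bundle, scale = 2L) {
  step <- bundle$voxel_size_mm / scale
  counts <- new.env()
  for (s in bundle$streamlines) {
    pts <- s
    # subdivide segments so gaps < step
    out <- list(pts[1, ])
    for (j in seq_len(nrow(pts) - 1)) {
      d <- sqrt(sum((pts[j + 1, ] - pts[j, ])^2))
      k <- if (d > 0) floor(d / step) + 1 else 1
      for (q in seq_len(k))
        out[[length(out) + 1]] <- pts[j, ] + (q / k) * (pts[j + 1, ] - pts[j, ])
    }
    pm <- do.call(rbind, out)
    keys <- unique(apply(brute_round(pm * scale / bundle$voxel_size_mm), 1,
                         paste, collapse = ","))
    for (k in keys) {
      cur <- if (is.null(counts[[k]])) 0L else counts[[k]]
      counts[[k]] <- cur + 1L
    }
  }
  unlist(as.list(counts))
}

# Surface voxels by per-voxel neighbor scan over a coordinate set.
brute_surface <- function(coords, connectivity = 6L) {
  keys <- apply(coords, 1, paste, collapse = ",")
  off <- if (connectivity == 6L) {
    rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  } else {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  }
  surf <- logical(nrow(coords))
  for (i in seq_len(nrow(coords))) {
    for (j in seq_len(nrow(off))) {
      nb <- paste(coords[i, ] + off[j, ], collapse = ",")
      if (!(nb %in% keys)) { surf[i] <- TRUE; break }
    }
  }
  coords[surf, , drop = FALSE]
}

# Connected components by BFS flood fill; returns membership sizes sorted
# decreasingly.
brute_components <- function(coords, connectivity = 26L) {
  keys <- apply(coords, 1, paste, collapse = ",")
  idx_of <- stats::setNames(seq_along(keys), keys)
  off <- if (connectivity == 6L) {
    rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  } else {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  }
  seen <- logical(nrow(coords))
  comps <- list()
  for (start in seq_len(nrow(coords))) {
    if (seen[start]) next
    queue <- start; seen[start] <- TRUE; members <- integer(0)
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      members <- c(members, cur)
      for (j in seq_len(nrow(off))) {
        nb <- paste(coords[cur, ] + off[j, ], collapse = ",")
        k <- idx_of[nb]
        if (!is.na(k) && !seen[k]) { seen[k] <- TRUE; queue <- c(queue, k) }
      }
    }
    comps[[length(comps) + 1]] <- sort(members)
  }
  comps[order(-lengths(comps))]
}

# Random jagged polyline for property tests.
random_streamline <- function(npts = 10, spread = 20) {
  matrix(stats::runif(npts * 3, 0, spread), npts, 3)
}

rotation_z <- function(theta) {
  rbind(c(cos(theta), -sin(theta), 0),
        c(sin(theta),  cos(theta), 0),
        c(0, 0, 1))
}

# Cylinder whose streamlines sit on voxel-center columns with multiplicity
# >= 2, so its density map provably has no count-1 voxel: the fixture for
# "pruning removes exactly the planted strays".
dense_cylinder <- function(length_mm = 40, radius_cells = 4, mult = 3,
                           spacing = 0.4) {
  g <- as.matrix(expand.grid(y = -radius_cells:radius_cells,
                             z = -radius_cells:radius_cells))
  g <- g[g[, 1]^2 + g[, 2]^2 <= radius_cells^2, , drop = FALSE] * 0.5  # mm
  x <- seq(0, length_mm, by = spacing)
  sls <- list()
  for (i in seq_len(nrow(g)))
    for (m in seq_len(mult))
      sls[[length(sls) + 1]] <- cbind(x, g[i, 1], g[i, 2])
  tract_bundle(sls, voxel_size_mm = 1, label = "dense")
}

# Enumerated filled-disk voxel set in the z = 0 plane: all integer (x, y)
# whose mm position lies within the given radius, at scale-2 spacing.
disk_voxel_set <- function(radius_mm = 10, base_voxel_size_mm = 1, scale = 2L) {
  spacing <- base_voxel_size_mm / scale
  r_cells <- ceiling(radius_mm / spacing)
  g <- as.matrix(expand.grid(x = -r_cells:r_cells, y = -r_cells:r_cells))
  g <- g[(g[, 1]^2 + g[, 2]^2) * spacing^2 <= radius_mm^2, , drop = FALSE]
  voxel_set(cbind(g, 0L), scale = scale, base_voxel_size_mm = base_voxel_size_mm)
}
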