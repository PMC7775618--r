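test_that("bundle construction enforces its invariants", {
  expect_error(tract_bundle(list()), "at least one")
  expect_error(tract_bundle(list(matrix(0, 1, 3))), "at least 2 points")
  expect_error(tract_bundle(list(cbind(c(0, NA), 0, 0))), "finite")
  expect_error(tract_bundle(list(cbind(0:1, 0, 0)), voxel_size_mm = -1),
               "positive")
  b <- tract_bundle(list(cbind(0:4, 0, 0), cbind(0:2, 1, 1)), 1, "toy")
  expect_equal(n_streamlines(b), 2L)
})

test_that("TRK and TCK round trips preserve coordinates to float32", {
  set.seed(11)
  sls <- lapply(1:20, function(i) random_streamline(sample(3:30, 1), 80))
  b <- tract_bundle(sls, voxel_size_mm = 1, label = "rt")
  for (fmt in c("trk", "tck")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_bundle(b, path)
    b2 <- read_bundle(path)
    expect_equal(n_streamlines(b2), 20L)
    maxerr <- max(mapply(function(s1, s2) max(abs(s1 - s2)),
                         b$streamlines, b2$streamlines))
    expect_lt(maxerr, 1e-3)
    unlink(path)
  }
})

test_that("1000-streamline synthetic cylinder round-trips within 1e-3 mm", {
  b <- make_cylinder(60, 8, 1000, seed = 3)
  path <- tempfile(fileext = ".tck")
  write_bundle(b, path)
  b2 <- read_bundle(path)
  maxerr <- max(mapply(function(s1, s2) max(abs(s1 - s2)),
                       b$streamlines, b2$streamlines))
  expect_lt(maxerr, 1e-3)
  unlink(path)
})

test_that("TCK header announces the streamline count it carries", {
  b <- tract_bundle(replicate(3, cbind(seq(0, 4), 1, 2), simplify = FALSE))
  path <- tempfile(fileext = ".tck")
  write_bundle(b, path)
  hdr <- readLines(path, n = 3, warn = FALSE)
  expect_true(any(grepl("^count: 3$", hdr)))
  b2 <- read_bundle(path)
  expect_equal(n_streamlines(b2), 3L)
  expect_equal(vapply(b2$streamlines, nrow, integer(1)), rep(5L, 3))
  unlink(path)
})

test_that("TRK voxel-to-world affine is applied on read", {
  # hand-build a TRK with a scaled + translated affine and check two points
  # against a by-hand application of world = M (voxmm / zoom - 0.5)
  path <- tempfile(fileext = ".trk")
  zoom <- 2
  M <- diag(c(2, 2, 2, 1))
  M[1:3, 4] <- c(10, -5, 3)
  con <- file(path, "wb")
  writeBin(c(charToRaw("TRACK"), as.raw(0)), con)
  writeBin(integer(3), con, size = 2, endian = "little")
  writeBin(rep(zoom, 3), con, size = 4, endian = "little")
  writeBin(rep(0, 3), con, size = 4, endian = "little")
  writeBin(0L, con, size = 2, endian = "little"); writeBin(raw(200), con)
  writeBin(0L, con, size = 2, endian = "little"); writeBin(raw(200), con)
  writeBin(as.numeric(t(M)), con, size = 4, endian = "little")
  writeBin(raw(444), con)
  writeBin(c(charToRaw("RAS"), as.raw(0)), con); writeBin(raw(4), con)
  writeBin(rep(0, 6), con, size = 4, endian = "little")
  writeBin(raw(8), con)
  writeBin(1L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 4, endian = "little")
  writeBin(1000L, con, size = 4, endian = "little")
  voxmm <- rbind(c(1, 2, 3), c(4, 6, 8))
  writeBin(2L, con, size = 4, endian = "little")
  writeBin(as.numeric(t(voxmm)), con, size = 4, endian = "little")
  close(con)
  b <- read_bundle(path)
  expected <- t(apply(voxmm, 1, function(p) (M %*% c(p / zoom - 0.5, 1))[1:3]))
  expect_equal(b$streamlines[[1]], expected, tolerance = 1e-6)
  expect_equal(b$voxel_size_mm, 2)
  unlink(path)
})

test_that("files written here parse identically under nibabel", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  b <- tract_bundle(list(rbind(c(1.5, 2.25, 3), c(4, 5, 6), c(7, 8, 9.5)),
                         rbind(c(-1, -2, -3), c(0, 0.5, 1))),
                    voxel_size_mm = 1)
  for (fmt in c("trk", "tck")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_bundle(b, path)
    out <- system2("python", c("-c", shQuote(paste0(
      "import nibabel as nib; t = nib.streamlines.load('", path, "');",
      "print(len(t.streamlines));",
      "print(' '.join('%.6f' % v for s in t.streamlines for p in s for v in p))"
    ))), stdout = TRUE)
    expect_equal(as.integer(out[1]), 2L)
    got <- as.numeric(strsplit(out[2], " ")[[1]])
    ref <- unlist(lapply(b$streamlines, function(s) as.numeric(t(s))))
    expect_equal(got, ref, tolerance = 1e-4)
    unlink(path)
  }
})

test_that("anisotropic TRK voxel size is rejected unless overridden", {
  b <- tract_bundle(list(cbind(0:5, 1, 1)))
  path <- tempfile(fileext = ".trk")
  write_bundle(b, path)
  # patch the header's voxel_size field to be anisotropic
  con <- file(path, "r+b")
  seek(con, 12, rw = "write")
  writeBin(c(1, 1, 2.5), con, size = 4, endian = "little")
  close(con)
  expect_error(read_bundle(path), "anisotropic")
  expect_silent(b2 <- read_bundle(path, voxel_size_mm = 1))
  expect_equal(b2$voxel_size_mm, 1)
  unlink(path)
})

test_that("resampling bounds every gap, keeps endpoints, preserves length", {
  seg <- tract_bundle(list(rbind(c(0, 0, 0), c(10, 0, 0))))
  r <- resample_max_step(seg, 1)
  s <- r$streamlines[[1]]
  expect_gte(nrow(s), 11)
  gaps <- sqrt(rowSums(diff(s)^2))
  expect_true(all(gaps < 1))
  expect_equal(s[1, ], c(0, 0, 0))
  expect_equal(s[nrow(s), ], c(10, 0, 0))
  expect_equal(sum(gaps), 10)

  # semicircle: per-track polyline length preserved to 1e-9 relative
  theta <- seq(0, pi, length.out = 200)
  arc <- tract_bundle(list(cbind(50 * cos(theta), 50 * sin(theta), 0)))
  len0 <- bundle_length(arc)
  len1 <- bundle_length(resample_max_step(arc, 0.5))
  expect_lt(abs(len1 - len0) / len0, 1e-9)

  # already-compliant bundle comes back identical (idempotence)
  r2 <- resample_max_step(r, 1)
  expect_identical(r2$streamlines, r$streamlines)
})

test_that("coordinate table export is tidy and complete", {
  b <- tract_bundle(list(cbind(0:3, 0, 0), cbind(0:1, 5, 5)))
  tab <- as_coordinate_table(b)
  expect_equal(nrow(tab), 6L)
  expect_equal(tab$streamline, c(1, 1, 1, 1, 2, 2))
  expect_equal(tab$x[tab$streamline == 2], c(0, 1))
})
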