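#' Read a streamline file into a bundle
#'
#' Supports the TrackVis TRK and MRtrix TCK formats. Coordinates are
#' normalized to scanner (world) mm space: TRK files store coordinates in
#' "voxmm" units, which are mapped through the header's voxel-to-world
#' affine (corner-based convention, i.e. `world = M (voxmm / zoom - 0.5)`),
#' while TCK files already store world mm.
#'
#' The voxel size is taken from the TRK header; TCK headers carry no voxel
#' size, so `voxel_size_mm` must be supplied (default 1 mm, the isotropic
#' grid the descriptors were designed for). Anisotropic TRK voxel headers
#' are rejected unless `voxel_size_mm` is given explicitly as an override.
#'
#' @param path file path.
#' @param format `"trk"`, `"tck"`, or `NULL` to infer from the extension.
#' @param voxel_size_mm optional isotropic voxel size override in mm.
#' @param label optional bundle name (defaults to the file base name).
#' @return a [tract_bundle].
#' @seealso [write_bundle()]
#' @export
read_bundle <- function(path, format = NULL, voxel_size_mm = NULL, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- infer_format(path, format)
  if (is.null(label)) label <- sub("\\.[^.]+$", "", basename(path))
  switch(format,
         trk = read_trk(path, voxel_size_mm, label),
         tck = read_tck(path, voxel_size_mm, label),
         stop("unsupported format: ", format))
}

#' Write a bundle to a streamline file
#'
#' TRK files are written with an RAS voxel-to-world affine scaled by the
#' bundle's voxel size (corner-based voxmm convention); TCK files store the
#' world-mm coordinates directly. Storage is float32, so a round trip
#' preserves coordinates only to single precision.
#'
#' @param bundle a [tract_bundle].
#' @param path output file path.
#' @param format `"trk"`, `"tck"`, or `NULL` to infer from the extension.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path, format = NULL) {
  stopifnot(inherits(bundle, "tract_bundle"))
  format <- infer_format(path, format)
  switch(format,
         trk = write_trk(bundle, path),
         tck = write_tck(bundle, path),
         stop("unsupported format: ", format))
  invisible(path)
}

infer_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(tolower(format), c("trk", "tck")))
  ext <- tolower(sub(".*\\.", "", path))
  if (!ext %in% c("trk", "tck"))
    stop("cannot infer streamline format from extension '.", ext,
         "'; pass format = \"trk\" or \"tck\"")
  ext
}

# ---- TRK (TrackVis) -------------------------------------------------------
# 1000-byte binary header, version 2; body stores voxmm float32 coordinates.

read_trk <- function(path, voxel_size_mm, label) {
  con <- file(path, "rb")
  on.exit(close(con))
  id <- readBin(con, "raw", 6L)
  if (!identical(rawToChar(id[1:5]), "TRACK"))
    stop("not a TRK file (bad magic): ", path)
  dim3 <- readBin(con, "integer", 3L, size = 2L, endian = "little")
  zoom <- readBin(con, "double", 3L, size = 4L, endian = "little")
  readBin(con, "double", 3L, size = 4L, endian = "little")  # origin, unused
  n_scalars <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  readBin(con, "raw", 200L)
  n_props <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  readBin(con, "raw", 200L)
  M <- matrix(readBin(con, "double", 16L, size = 4L, endian = "little"),
              4L, 4L, byrow = TRUE)
  readBin(con, "raw", 444L + 4L + 4L + 24L + 2L + 6L)
  n_count <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  version <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hdr_size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (hdr_size != 1000L)
    stop("unsupported TRK header size ", hdr_size, " (expected 1000)")
  if (M[4L, 4L] == 0) {
    # pre-v2 files carry no affine; assume identity (voxmm == world/zoom grid)
    warning("TRK file has no voxel-to-world affine; assuming identity")
    M <- diag(4)
    M[cbind(1:3, 1:3)] <- zoom
  }
  if (any(zoom <= 0)) stop("TRK header has non-positive voxel size")
  if (is.null(voxel_size_mm)) {
    if (max(zoom) - min(zoom) > 1e-5)
      stop("anisotropic TRK voxel size (", paste(signif(zoom, 6), collapse = " x "),
           " mm); descriptors assume an isotropic grid. ",
           "Pass voxel_size_mm to force a value.")
    voxel_size_mm <- zoom[1L]
  }
  streamlines <- list()
  repeat {
    m <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(m) == 0L) break
    vals <- readBin(con, "double", m * (3L + n_scalars), size = 4L,
                    endian = "little")
    if (n_props > 0L) readBin(con, "double", n_props, size = 4L, endian = "little")
    pts <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    vox <- sweep(pts, 2L, zoom, "/") - 0.5      # voxmm -> voxel, corner-based
    world <- t(M %*% rbind(t(vox), 1))[, 1:3, drop = FALSE]
    streamlines[[length(streamlines) + 1L]] <- world
  }
  if (n_count > 0L && length(streamlines) != n_count)
    warning("TRK header announced ", n_count, " tracks but ",
            length(streamlines), " were read")
  tract_bundle(streamlines, voxel_size_mm = voxel_size_mm, label = label)
}

write_trk <- function(bundle, path) {
  vs <- bundle$voxel_size_mm
  M <- diag(4)
  M[cbind(1:3, 1:3)] <- vs
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("TRACK"), as.raw(0L)), con)
  writeBin(as.integer(c(0L, 0L, 0L)), con, size = 2L, endian = "little")
  writeBin(rep(vs, 3L), con, size = 4L, endian = "little")
  writeBin(rep(0, 3L), con, size = 4L, endian = "little")      # origin
  writeBin(0L, con, size = 2L, endian = "little")              # n_scalars
  writeBin(raw(200L), con)
  writeBin(0L, con, size = 2L, endian = "little")              # n_properties
  writeBin(raw(200L), con)
  writeBin(as.numeric(t(M)), con, size = 4L, endian = "little")
  writeBin(raw(444L), con)                                     # reserved
  writeBin(c(charToRaw("RAS"), as.raw(0L)), con)               # voxel_order
  writeBin(raw(4L), con)                                       # pad2
  writeBin(rep(0, 6L), con, size = 4L, endian = "little")      # orientation
  writeBin(raw(2L + 6L), con)                                  # pad1, inverts
  writeBin(length(bundle$streamlines), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 4L, endian = "little")              # version
  writeBin(1000L, con, size = 4L, endian = "little")           # hdr_size
  Minv <- solve(M)
  for (s in bundle$streamlines) {
    vox <- t(Minv %*% rbind(t(s), 1))[, 1:3, drop = FALSE]
    voxmm <- sweep(vox + 0.5, 2L, rep(vs, 3L), "*")
    writeBin(nrow(s), con, size = 4L, endian = "little")
    writeBin(as.numeric(t(voxmm)), con, size = 4L, endian = "little")
  }
}

# ---- TCK (MRtrix) ---------------------------------------------------------
# Text header terminated by END, then float32 world-mm triples; NaN triple
# separates streamlines, Inf triple ends the file.

read_tck <- function(path, voxel_size_mm, label) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readLines(con, n = 1L, warn = FALSE)
  if (!identical(first, "mrtrix tracks"))
    stop("not a TCK file (bad magic): ", path)
  offset <- NA_integer_
  datatype <- "Float32LE"
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("TCK header has no END line")
    if (identical(trimws(line), "END")) break
    kv <- regmatches(line, regexec("^([^:]+):\\s*(.*)$", line))[[1L]]
    if (length(kv) == 3L) {
      key <- trimws(kv[2L]); val <- trimws(kv[3L])
      if (key == "file") offset <- as.integer(sub("^\\.\\s*", "", val))
      if (key == "datatype") datatype <- val
    }
  }
  if (is.na(offset)) stop("TCK header lacks a 'file: . <offset>' entry")
  if (!datatype %in% c("Float32LE", "Float32BE"))
    stop("unsupported TCK datatype: ", datatype)
  endian <- if (datatype == "Float32LE") "little" else "big"
  seek(con, where = offset, origin = "start")
  n_bytes <- file.info(path)$size - offset
  vals <- readBin(con, "double", n_bytes %/% 4L, size = 4L, endian = endian)
  pts <- matrix(vals, ncol = 3L, byrow = TRUE)
  is_sep <- is.nan(pts[, 1L]) | is.infinite(pts[, 1L])
  grp <- cumsum(is_sep)
  keep <- !is_sep
  streamlines <- split.data.frame(pts[keep, , drop = FALSE], grp[keep])
  streamlines <- lapply(unname(streamlines), as.matrix)
  streamlines <- streamlines[vapply(streamlines, nrow, integer(1)) > 0L]
  if (is.null(voxel_size_mm)) voxel_size_mm <- 1
  tract_bundle(streamlines, voxel_size_mm = voxel_size_mm, label = label)
}

write_tck <- function(bundle, path) {
  n <- length(bundle$streamlines)
  hdr <- c("mrtrix tracks",
           paste0("count: ", n),
           "datatype: Float32LE",
           "tractshape_version: 0.1.0")
  # 'file: . <offset>' must state its own end position; iterate to fixpoint
  offset <- 0L
  repeat {
    file_line <- paste0("file: . ", offset)
    new_offset <- sum(nchar(c(hdr, file_line, "END"), type = "bytes") + 1L)
    if (new_offset == offset) break
    offset <- new_offset
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, paste0("file: . ", offset), "END"), con, sep = "\n")
  for (s in bundle$streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4L, endian = "little")
    writeBin(as.numeric(c(NaN, NaN, NaN)), con, size = 4L, endian = "little")
  }
  writeBin(as.numeric(c(Inf, Inf, Inf)), con, size = 4L, endian = "little")
}

# ---- resampling -----------------------------------------------------------

#' Resample streamlines to a maximum step length
#'
#' Subdivides every polyline segment so that the distance between any two
#' consecutive coordinates is strictly smaller than `max_step_mm`, a
#' prerequisite for voxelizing tracks without gaps. New points are placed by
#' linear interpolation on the existing segments, so endpoints and the
#' polyline geometry (hence per-streamline arc length) are preserved
#' exactly; an already-compliant streamline is returned unchanged.
#'
#' @param bundle a [tract_bundle].
#' @param max_step_mm positive scalar; defaults to the bundle's voxel size,
#'   matching the convention that consecutive points must be closer than one
#'   voxel.
#' @return a [tract_bundle] with the same geometry and denser sampling.
#' @export
resample_max_step <- function(bundle, max_step_mm = bundle$voxel_size_mm) {
  stopifnot(inherits(bundle, "tract_bundle"))
  if (!is.numeric(max_step_mm) || length(max_step_mm) != 1L || max_step_mm <= 0)
    stop("max_step_mm must be a positive scalar")
  out <- lapply(bundle$streamlines, resample_streamline, max_step_mm)
  tract_bundle(out, voxel_size_mm = bundle$voxel_size_mm, label = bundle$label)
}

resample_streamline <- function(s, step) {
  m <- nrow(s)
  from <- s[-m, , drop = FALSE]
  to   <- s[-1L, , drop = FALSE]
  d <- sqrt(rowSums((to - from)^2))
  if (all(d < step)) return(s)
  k <- ifelse(d > 0, floor(d / step) + 1, 1)   # pieces per segment; gap = d/k < step
  idx  <- rep.int(seq_len(m - 1L), k)
  frac <- (sequence(k) - 1) / rep.int(k, k)
  pts <- from[idx, , drop = FALSE] + frac * (to[idx, , drop = FALSE] - from[idx, , drop = FALSE])
  rbind(pts, s[m, , drop = FALSE])
}

#' Export bundle coordinates as a tidy table
#'
#' @param bundle a [tract_bundle].
#' @return a data.frame with columns `streamline`, `point`, `x`, `y`, `z`
#'   (mm), one row per coordinate, suitable for CSV export.
#' @export
as_coordinate_table <- function(bundle) {
  stopifnot(inherits(bundle, "tract_bundle"))
  npts <- vapply(bundle$streamlines, nrow, integer(1))
  pts <- all_points(bundle)
  data.frame(streamline = rep.int(seq_along(npts), npts),
             point = sequence(npts),
             x = pts[, 1L], y = pts[, 2L], z = pts[, 3L])
}
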