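#' Hausdorff distance between two streamlines
#'
#' The symmetric (undirected) Hausdorff distance between the discrete point
#' sets of two polylines: the larger of the two directed distances, where
#' each directed distance is the maximum over points of one set of the
#' distance to the nearest point of the other set. Sensitive to point
#' density, so candidates and references should share a common sampling
#' step (see [recognize()]).
#'
#' @param a,b numeric `m x 3` matrices or [tract_bundle] streamlines.
#' @return nonnegative scalar mm.
#' @export
hausdorff_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(ncol(a) == 3L, ncol(b) == 3L, nrow(a) >= 1L, nrow(b) >= 1L)
  d2 <- cross_dist2(a, b)
  sqrt(max(max(apply(d2, 1L, min)), max(apply(d2, 2L, min))))
}

# Squared Euclidean cross-distance matrix between two point sets.
cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# Directed min over b of distances for each point of a, used in recognize.
min_dist_to <- function(a, b) sqrt(apply(cross_dist2(a, b), 1L, min))

#' A named set of reference bundles
#'
#' @param bundles named list of [tract_bundle] objects (the reference /
#'   atlas trajectories, co-registered with the candidates).
#' @return object of class `reference_set`.
#' @export
reference_set <- function(bundles) {
  if (!is.list(bundles) || length(bundles) < 1L)
    stop("need at least one reference bundle")
  if (is.null(names(bundles)) || any(names(bundles) == ""))
    stop("reference bundles must be named")
  lapply(bundles, function(b) stopifnot(inherits(b, "tract_bundle")))
  structure(list(bundles = bundles[order(names(bundles))]),
            class = "reference_set")
}

#' Label candidate streamlines by shortest Hausdorff distance
#'
#' Each candidate streamline is assigned the label of the reference bundle
#' containing its nearest trajectory under the Hausdorff distance, and is
#' kept only if that shortest distance does not exceed `threshold_mm`
#' (default 16 mm). Candidates and references are first resampled to a
#' common maximum step (default 1 mm) so the discrete Hausdorff distance is
#' not biased by point density. Equidistant references resolve to the first
#' label in sorted-by-name order, making the result independent of the
#' reference ordering.
#'
#' @param candidates a [tract_bundle].
#' @param refs a [reference_set] (a named list is accepted and converted).
#' @param threshold_mm maximum allowed shortest distance (default 16).
#' @param resample_step_mm common resampling step (default 1); `NULL` skips
#'   resampling.
#' @return a data.frame of class `recognition_result` with one row per
#'   candidate: `streamline`, `label`, `distance_mm`, `kept`.
#' @export
recognize <- function(candidates, refs, threshold_mm = 16, resample_step_mm = 1) {
  stopifnot(inherits(candidates, "tract_bundle"))
  if (!inherits(refs, "reference_set")) refs <- reference_set(refs)
  if (threshold_mm <= 0) stop("threshold_mm must be positive")
  if (!is.null(resample_step_mm)) {
    candidates <- resample_max_step(candidates, resample_step_mm)
    refs$bundles <- lapply(refs$bundles, resample_max_step, resample_step_mm)
  }
  labels <- names(refs$bundles)
  n <- n_streamlines(candidates)
  best_label <- character(n)
  best_dist <- rep(Inf, n)
  for (i in seq_len(n)) {
    cand <- candidates$streamlines[[i]]
    for (lab in labels) {        # sorted-name order fixes the tie-break
      for (ref in refs$bundles[[lab]]$streamlines) {
        d <- hausdorff_distance(cand, ref)
        if (d < best_dist[i]) { best_dist[i] <- d; best_label[i] <- lab }
      }
    }
  }
  out <- data.frame(streamline = seq_len(n), label = best_label,
                    distance_mm = best_dist, kept = best_dist <= threshold_mm,
                    stringsAsFactors = FALSE)
  class(out) <- c("recognition_result", "data.frame")
  out
}

#' Keep the recognized streamlines of one label
#'
#' @param candidates the [tract_bundle] that was passed to [recognize()].
#' @param result the `recognition_result`.
#' @param label optional label filter; by default all kept streamlines.
#' @return a [tract_bundle] of the kept (and optionally label-matching)
#'   streamlines.
#' @export
filter_recognized <- function(candidates, result, label = NULL) {
  stopifnot(inherits(candidates, "tract_bundle"),
            inherits(result, "recognition_result"))
  keep <- result$kept
  if (!is.null(label)) keep <- keep & result$label == label
  if (!any(keep)) stop("no streamline survives the recognition filter")
  tract_bundle(candidates$streamlines[keep],
               voxel_size_mm = candidates$voxel_size_mm,
               label = label %||% candidates$label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
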