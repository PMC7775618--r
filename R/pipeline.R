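#' Run the full bundle-processing pipeline
#'
#' Ties the stages together in the canonical order — recognition against a
#' reference set (optional), topology-informed pruning, then shape
#' profiling — for a collection of input bundles, with per-bundle failure
#' isolation: a bundle that errors is reported in the returned `failures`
#' and does not stop the others. The fully resolved parameter set is
#' echoed to `config.json` in the output directory so every run is
#' reproducible from its outputs.
#'
#' @param inputs named list of [tract_bundle] objects, or a character
#'   vector of TRK/TCK file paths.
#' @param out_dir output directory (created if missing); `NULL` skips all
#'   file output.
#' @param refs optional [reference_set] (or named list of bundles); when
#'   given, each input bundle is filtered by [recognize()] first.
#' @param prune logical: run [tip_prune()] (default TRUE).
#' @param threshold_mm recognition distance threshold (default 16).
#' @param iterations pruning iterations (default 20).
#' @param low_density_threshold pruning density cutoff (default 1).
#' @param scale voxelization scale (default 2).
#' @param surface_connectivity,component_connectivity see
#'   [compute_profile()].
#' @param voxel_size_mm voxel size for TCK inputs (default 1).
#' @return a list with `profiles` (data.frame, one row per successful
#'   bundle) and `failures` (named character vector of error messages).
#' @export
run_pipeline <- function(inputs, out_dir = NULL, refs = NULL, prune = TRUE,
                         threshold_mm = 16, iterations = 20L,
                         low_density_threshold = 1L, scale = 2L,
                         surface_connectivity = 6L,
                         component_connectivity = 26L,
                         voxel_size_mm = 1) {
  if (is.character(inputs)) {
    paths <- inputs
    inputs <- stats::setNames(vector("list", length(paths)),
                              sub("\\.[^.]+$", "", basename(paths)))
    for (i in seq_along(paths)) {
      inputs[[i]] <- tryCatch(read_bundle(paths[i], voxel_size_mm = voxel_size_mm),
                              error = function(e) e)
    }
  }
  if (!is.null(refs) && !inherits(refs, "reference_set"))
    refs <- reference_set(refs)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  profiles <- list()
  failures <- character(0)
  for (nm in names(inputs)) {
    res <- tryCatch({
      b <- inputs[[nm]]
      if (inherits(b, "error")) stop(conditionMessage(b))
      if (is.null(b$label)) b$label <- nm
      if (!is.null(refs)) {
        rec <- recognize(b, refs, threshold_mm = threshold_mm)
        b <- filter_recognized(b, rec)
      }
      if (prune)
        b <- tip_prune(b, iterations = iterations,
                       low_density_threshold = low_density_threshold,
                       scale = scale)
      compute_profile(b, scale = scale,
                      surface_connectivity = surface_connectivity,
                      component_connectivity = component_connectivity)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[nm] <- conditionMessage(res)
    } else {
      profiles[[nm]] <- res
    }
  }
  profiles <- if (length(profiles)) do.call(rbind, profiles) else NULL
  if (!is.null(out_dir)) {
    if (!is.null(profiles))
      utils::write.csv(format_profile_csv(profiles),
                       file.path(out_dir, "profiles.csv"), row.names = FALSE)
    cfg <- list(threshold_mm = threshold_mm, iterations = iterations,
                low_density_threshold = low_density_threshold, scale = scale,
                surface_connectivity = surface_connectivity,
                component_connectivity = component_connectivity,
                voxel_size_mm = voxel_size_mm, pruned = prune,
                recognized = !is.null(refs),
                n_inputs = length(inputs), n_failed = length(failures),
                failures = as.list(failures))
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, pretty = TRUE),
                 file.path(out_dir, "config.json"))
    } else {
      utils::write.table(cbind(names(cfg)[1:10], unlist(cfg[1:10])),
                         file.path(out_dir, "config.txt"),
                         row.names = FALSE, col.names = FALSE, quote = FALSE)
    }
  }
  list(profiles = profiles, failures = failures)
}

# Presentation rounding for CSV export: 4 significant digits; internal
# values stay full precision.
format_profile_csv <- function(profiles) {
  num <- vapply(profiles, is.numeric, logical(1))
  profiles[num] <- lapply(profiles[num], signif, digits = 4L)
  profiles
}
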