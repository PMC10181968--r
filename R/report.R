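profile_metric_keys <- function() {
  c("volume_ml", "mld_hu", "ei_pct", "pei_pct", "ei_cc120_pct", "perc15_hu",
    "bi_pct", "ggoi_pct", "fibi_pct", "wp_pct", "awt_pi10_cm")
}

#' Write an analysis report as JSON
#'
#' Serializes region profiles and/or model fits into a schema-stable JSON
#' document: `{"software", "version", "seed", "regions": [...], "models":
#' [...]}`. Every profile carries all 11 metric keys (missing metrics are
#' `null`).
#'
#' @param profiles list of `qct_profile` objects (may be empty).
#' @param path output path.
#' @param models optional list of model summaries.
#' @param seed optional integer recorded for provenance.
#' @export
write_qct_report <- function(profiles, path, models = NULL, seed = NULL) {
  if (inherits(profiles, "qct_profile")) profiles <- list(profiles)
  regions <- lapply(profiles, function(p) {
    stopifnot(inherits(p, "qct_profile"))
    out <- list(region_id = p$region_id, voxel_count = p$voxel_count)
    for (k in profile_metric_keys()) out[[k]] <- p[[k]]
    out
  })
  doc <- list(
    software = "qctlung",
    version = as.character(utils::packageVersion("qctlung")),
    seed = seed,
    regions = regions,
    models = models
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a JSON report written by [write_qct_report()]
#' @param path report path.
#' @return the parsed report list.
#' @export
read_qct_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  jsonlite::read_json(path, simplifyVector = FALSE)
}
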