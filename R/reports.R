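.pkg_version <- function() as.character(utils::packageVersion("ibsa"))

.file_checksum <- function(path) {
  # lightweight content checksum (sum-based rolling hash) for provenance
  if (!file.exists(path) || dir.exists(path)) return(NA_character_)
  raw <- readBin(path, "raw", min(file.info(path)$size, 1e6))
  v <- as.integer(raw)
  sprintf("%08x", sum(v * (seq_along(v) %% 509 + 1)) %% 4294967291)
}

#' Serialize a surface measurement to a JSON report
#'
#' @param m a [SurfaceMeasurement-class].
#' @param path output JSON path.
#' @param input optional input path (a checksum is embedded).
#' @param config optional configuration list to echo.
#' @return Invisibly, the report list.
#' @export
writeMeasurementReport <- function(m, path, input = NULL, config = NULL) {
  rep <- list(
    tool = "ibsa", version = .pkg_version(),
    area_cm2 = m@area_cm2, area_m2 = m@area_m2,
    n_vertices = m@n_vertices, n_faces = m@n_faces,
    z_extent_mm = m@z_extent_mm,
    area_per_length_cm2_per_cm =
      if (is.na(m@area_per_length_cm2_per_cm)) NULL
      else m@area_per_length_cm2_per_cm,
    config_fingerprint = m@config_fingerprint,
    config = config,
    input_checksum = if (!is.null(input)) .file_checksum(input) else NULL)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(rep)
}

#' Serialize a simulation result to a JSON report
#'
#' @param sim a [SimulationResult-class].
#' @param path output JSON path.
#' @return Invisibly, the report list.
#' @export
writeSimulationReport <- function(sim, path) {
  rep <- list(
    tool = "ibsa", version = .pkg_version(),
    reclassification_rate = sim@reclassification_rate,
    shift_histogram = as.list(sim@shift_histogram),
    mc_standard_error = sim@mc_standard_error,
    config = sim@config)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(rep)
}

#' Serialize a Bland-Altman result to a JSON report
#'
#' @param ba a [BlandAltmanResult-class].
#' @param path output JSON path.
#' @param seed seed used for the bootstrap (echoed).
#' @return Invisibly, the report list.
#' @export
writeBlandAltmanReport <- function(ba, path, seed = NULL) {
  rep <- list(
    tool = "ibsa", version = .pkg_version(),
    mode = ba@mode, n = ba@n,
    bias_pct = ba@bias_pct, sd_pct = ba@sd_pct,
    loa_low_pct = ba@loa_low_pct, loa_high_pct = ba@loa_high_pct,
    ci_bias = ba@ci_bias, ci_sd = ba@ci_sd, seed = seed)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(rep)
}

#' Bland-Altman plot
#'
#' Scatter of per-pair differences against pair means with bias and limits of
#' agreement drawn as horizontal lines.
#'
#' @param values_a,values_b paired measurements.
#' @param ba the matching [BlandAltmanResult-class] (computed if missing).
#' @param path PNG output path.
#' @param ... passed to [blandAltman()] when `ba` is missing.
#' @export
plotBlandAltman <- function(values_a, values_b, ba = NULL, path, ...) {
  if (is.null(ba)) ba <- blandAltman(values_a, values_b, ...)
  d <- .ba_diffs(values_a, values_b, ba@mode)
  mid <- (values_a + values_b) / 2
  grDevices::png(path, width = 800, height = 600)
  on.exit(grDevices::dev.off())
  ylab <- if (ba@mode == "proportional") "difference (%)" else "difference"
  graphics::plot(mid, d, pch = 19, xlab = "pair mean", ylab = ylab,
                 main = sprintf("Bland-Altman (n = %d)", ba@n))
  graphics::abline(h = ba@bias_pct, col = "blue", lwd = 2)
  graphics::abline(h = c(ba@loa_low_pct, ba@loa_high_pct), col = "red",
                   lty = 2, lwd = 2)
  invisible(path)
}
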