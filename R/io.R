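#' Read a per-nucleus spot-count table from CSV
#'
#' Expected schema: \code{nucleus_id, channel, count[, diameter_um][, cells]}.
#' Counts must be non-negative integers and (nucleus, channel) pairs unique;
#' violations are reported with their row number.
#'
#' @param path CSV file path.
#' @return a \code{\link{SpotCountTable-class}}.
#' @export
readCountsCsv <- function(path) {
  if (!file.exists(path)) .fail("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("nucleus_id", "channel", "count")
  missing <- setdiff(need, names(df))
  if (length(missing))
    .fail("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  bad <- which(!is.finite(df$count) | df$count < 0 | df$count != floor(df$count))
  if (length(bad))
    .fail("invalid count at row ", bad[1L], " of ", path,
          " (must be a non-negative integer)")
  dup <- which(duplicated(df[, c("nucleus_id", "channel")]))
  if (length(dup))
    .fail("duplicate (nucleus_id, channel) at row ", dup[1L], " of ", path)
  SpotCountTable(nucleus_id = df$nucleus_id, channel = df$channel,
                 count = as.integer(df$count),
                 diameter_um = if ("diameter_um" %in% names(df))
                   df$diameter_um else NA_real_,
                 cells = if ("cells" %in% names(df)) df$cells else 1L)
}

#' Read aggregate point-process observations from CSV
#'
#' Expected schema: \code{field_id, channel, total_spots, total_area_um2}.
#'
#' @param path CSV file path.
#' @return named list of \code{\link{PointProcessObservations-class}}, one
#'   per channel.
#' @export
readObservationsCsv <- function(path) {
  if (!file.exists(path)) .fail("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("field_id", "channel", "total_spots", "total_area_um2")
  missing <- setdiff(need, names(df))
  if (length(missing))
    .fail("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  out <- lapply(split(df, df$channel), function(d)
    PointProcessObservations(field_id = d$field_id,
                             total_spots = as.integer(d$total_spots),
                             total_area_um2 = d$total_area_um2))
  out[unique(df$channel)]
}

#' Write a spot-count table back to CSV
#'
#' Round-trips losslessly through \code{\link{readCountsCsv}}.
#'
#' @param table a \code{\link{SpotCountTable-class}}.
#' @param path output CSV path.
#' @export
writeCountsCsv <- function(table, path) {
  utils::write.csv(table@counts, path, row.names = FALSE)
  invisible(path)
}

# estimates as a plain data.frame with the output schema
.estimatesFrame <- function(estimates) {
  do.call(rbind, lapply(estimates, function(e)
    data.frame(channel = e@channel, method = e@method,
               continuous = e@continuous, rounded = e@rounded,
               ci_low = e@ciLow, ci_high = e@ciHigh,
               stringsAsFactors = FALSE)))
}

#' Write copy-number estimates with provenance
#'
#' Writes a CSV with columns \code{channel, method, continuous, rounded,
#' ci_low, ci_high} and, alongside it, a JSON provenance file recording the
#' package version, the seed and the configuration, so a rerun with the
#' same inputs reproduces the files byte for byte.
#'
#' @param estimates list of \code{\link{CopyNumberEstimate-class}} objects.
#' @param path output CSV path; provenance goes to \code{<path>.prov.json}.
#' @param seed seed recorded in provenance (NULL allowed).
#' @param config named list recorded in provenance.
#' @return the estimates data.frame, invisibly.
#' @export
writeEstimates <- function(estimates, path, seed = NULL, config = list()) {
  df <- .estimatesFrame(estimates)
  utils::write.csv(df, path, row.names = FALSE)
  prov <- list(package = "sectionFISH",
               version = as.character(utils::packageVersion("sectionFISH")),
               seed = seed, config = config)
  jsonlite::write_json(prov, paste0(path, ".prov.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(df)
}
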