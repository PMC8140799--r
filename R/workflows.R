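#' End-to-end workflows: manual counts, automated counts, simulation
#'
#' These functions bind the package together into the three command-line
#' workflows. Each reads its inputs, runs the corresponding estimator(s),
#' writes results plus a provenance block, and returns the result table.
#'
#' \describe{
#'   \item{\code{cmdManual}}{per-nucleus manual counts (CSV) ->
#'     volume-adjusted Gamma-Poisson estimate per channel.}
#'   \item{\code{cmdAuto}}{aggregate (spots, area) observations (CSV), or a
#'     set of per-channel TIFF stacks processed through the image pipeline,
#'     -> point-process estimate per channel.}
#'   \item{\code{cmdSimulate}}{benchmark grid (JSON config) -> replicate
#'     estimate table.}
#' }
#'
#' @param countsPath CSV of per-nucleus counts, see
#'   \code{\link{readCountsCsv}}.
#' @param radiusUm,heightUm section geometry (micrometres).
#' @param priorShape,priorRate,chainLength,burnIn posterior settings.
#' @param seed integer seed recorded in provenance and used for sampling.
#' @param out optional output CSV path (written with provenance when set).
#' @return data.frame of estimates (one row per channel), invisibly when
#'   written to file.
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' write.csv(data.frame(nucleus_id = rep(1:20, 2),
#'                      channel = rep(c("myc", "terc"), each = 20),
#'                      count = rpois(40, 2)), tmp, row.names = FALSE)
#' cmdManual(tmp, radiusUm = 4.5, heightUm = 3, seed = 1)
#' @name workflows
NULL

#' @rdname workflows
#' @export
cmdManual <- function(countsPath, radiusUm, heightUm, priorShape = 0.001,
                      priorRate = 0.001, chainLength = 10000L,
                      burnIn = 1000L, seed = NULL, out = NULL) {
  table <- readCountsCsv(countsPath)
  geometry <- SectionGeometry(radiusUm = radiusUm, heightUm = heightUm)
  estimates <- lapply(channelNames(table), function(ch)
    estimateManual(table, geometry, channel = ch, priorShape = priorShape,
                   priorRate = priorRate, chainLength = chainLength,
                   burnIn = burnIn, seed = seed))
  .finishWorkflow(estimates, out, seed,
                  list(workflow = "manual", counts = countsPath,
                       radius_um = radiusUm, height_um = heightUm,
                       prior_shape = priorShape, prior_rate = priorRate,
                       chain_length = chainLength, burn_in = burnIn))
}

#' @rdname workflows
#' @param obsPath CSV of aggregate observations, see
#'   \code{\link{readObservationsCsv}}; mutually exclusive with
#'   \code{tiffPaths}.
#' @param tiffPaths named character vector of per-channel multi-page TIFF
#'   paths (must include a \code{dapi} entry); each file is read as a
#'   z-stack.
#' @param pixelSizeUm,zStepUm calibration for TIFF input.
#' @param thresholdMethods per-channel threshold methods, see
#'   \code{\link{processField}}.
#' @export
cmdAuto <- function(obsPath = NULL, tiffPaths = NULL, radiusUm, heightUm,
                    pixelSizeUm = 0.07, zStepUm = 0.3,
                    thresholdMethods = character(), seed = NULL, out = NULL) {
  geometry <- SectionGeometry(radiusUm = radiusUm, heightUm = heightUm)
  if (is.null(obsPath) == is.null(tiffPaths))
    .fail("supply exactly one of obsPath or tiffPaths")
  if (!is.null(obsPath)) {
    obsByChannel <- readObservationsCsv(obsPath)
    input <- list(workflow = "auto", observations = obsPath)
  } else {
    if (!"dapi" %in% names(tiffPaths))
      .fail("tiffPaths must include a 'dapi' channel")
    channels <- lapply(tiffPaths, function(p) {
      arr <- EBImage::imageData(EBImage::readImage(p))
      if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
      arr
    })
    stack <- ImageStack(channels, pixelSizeUm = pixelSizeUm, zStepUm = zStepUm)
    result <- processField(stack, thresholdMethods = thresholdMethods)
    obsByChannel <- extractObservation(result)
    input <- list(workflow = "auto", tiffs = as.list(tiffPaths),
                  pixel_size_um = pixelSizeUm, z_step_um = zStepUm)
  }
  estimates <- lapply(names(obsByChannel), function(ch) {
    e <- estimateAuto(obsByChannel[[ch]], geometry)
    e@channel <- ch
    e
  })
  .finishWorkflow(estimates, out, seed,
                  c(input, list(radius_um = radiusUm, height_um = heightUm)))
}

#' @rdname workflows
#' @param configPath JSON file describing the grid; recognised fields:
#'   \code{e_values}, \code{p_values}, \code{n_ctrl_values},
#'   \code{n_values}, \code{replicates}, \code{cells_per_section},
#'   \code{radius_um}, \code{height_um}. Missing fields use the benchmark
#'   defaults.
#' @export
cmdSimulate <- function(configPath = NULL, seed = 1L, out = NULL) {
  cfg <- if (is.null(configPath)) list()
         else jsonlite::read_json(configPath, simplifyVector = TRUE)
  pick <- function(name, default) if (!is.null(cfg[[name]])) cfg[[name]] else default
  base <- SimulationConfig(
    heightUm = pick("height_um", 3), radiusUm = pick("radius_um", 9),
    cellsPerSection = pick("cells_per_section", 50L))
  res <- runGrid(eValues = pick("e_values", c(-0.2, -0.1, -0.05, 0, 0.05, 0.1, 0.2)),
                 pValues = pick("p_values", c(0, 0.1, 0.3, 0.5, 0.8)),
                 nCtrlValues = pick("n_ctrl_values", 1:4),
                 nValues = pick("n_values", 1:10),
                 replicates = pick("replicates", 10L),
                 config = base, seed = seed)
  df <- benchmarkResults(res)
  if (!is.null(out)) {
    utils::write.csv(df, out, row.names = FALSE)
    prov <- list(package = "sectionFISH",
                 version = as.character(utils::packageVersion("sectionFISH")),
                 seed = seed, config = cfg)
    jsonlite::write_json(prov, paste0(out, ".prov.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    return(invisible(df))
  }
  df
}

.finishWorkflow <- function(estimates, out, seed, config) {
  if (!is.null(out)) {
    writeEstimates(estimates, out, seed = seed, config = config)
    return(invisible(.estimatesFrame(estimates)))
  }
  .estimatesFrame(estimates)
}
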