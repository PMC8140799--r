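#' BenchmarkResult: replicate-level estimates over a condition grid
#'
#' @slot results data.frame with columns \code{e}, \code{p}, \code{n_ctrl},
#'   \code{n}, \code{replicate}, \code{estimator}, \code{estimate},
#'   \code{truth}. For subclonal conditions \code{truth} is the
#'   ploidy-weighted average copy number.
#' @aliases BenchmarkResult-class
#' @exportClass BenchmarkResult
setClass("BenchmarkResult", representation(results = "data.frame"))

setMethod("show", "BenchmarkResult", function(object) {
  df <- object@results
  cat(sprintf("BenchmarkResult: %d estimates, %d condition(s), estimators: %s\n",
              nrow(df),
              nrow(unique(df[, c("e", "p", "n_ctrl", "n")])),
              paste(unique(df$estimator), collapse = ", ")))
})

#' @describeIn BenchmarkResult-class the replicate-level table.
#' @param object a \code{BenchmarkResult}.
#' @export
benchmarkResults <- function(object) object@results

#' Mean absolute error of copy-number estimates
#'
#' @param estimates continuous estimates.
#' @param truth true copy numbers (recycled to the estimate length).
#' @param na.rm drop NA estimates (undefined control baselines).
#' @return mean |estimate - truth| on the continuous scale.
#' @examples
#' mae(c(2, 2, 4), c(2, 3, 4))   # 1/3
#' @export
mae <- function(estimates, truth, na.rm = FALSE) {
  if (length(estimates) == 0L) .fail("no estimates supplied")
  truth <- rep_len(truth, length(estimates))
  mean(abs(estimates - truth), na.rm = na.rm)
}

#' Fraction of estimates that round to the true copy number
#'
#' @inheritParams mae
#' @return fraction in [0, 1].
#' @examples
#' accuracy(rep(2.4, 10), 2)   # 1: all round to 2
#' @export
accuracy <- function(estimates, truth, na.rm = FALSE) {
  if (length(estimates) == 0L) .fail("no estimates supplied")
  truth <- rep_len(truth, length(estimates))
  mean(roundHalfUp(estimates) == truth, na.rm = na.rm)
}

#' Run the simulated tissue-section benchmark grid
#'
#' Simulates replicate sections for every combination of counting-error
#' fraction, overlap probability, control copy number and true copy number,
#' and records each estimator's continuous estimate. The default grid is
#' the full benchmark design: e in {-0.2, -0.1, -0.05, 0, 0.05, 0.1, 0.2},
#' P in {0, 0.1, 0.3, 0.5, 0.8}, control copies 1..4, true copies 1..10,
#' 10 replicates of 50 nuclei. A single seed drives one RNG stream through
#' the whole grid, so results are exactly reproducible.
#'
#' @param eValues counting-error fractions.
#' @param pValues overlap probabilities.
#' @param nCtrlValues control-probe copy numbers.
#' @param nValues true copy numbers of the locus of interest.
#' @param replicates replicate sections per condition.
#' @param config base \code{\link{SimulationConfig-class}} supplying
#'   geometry and cells per section.
#' @param estimators estimator names, see \code{\link{sectionEstimates}}.
#' @param seed integer seed for the whole grid.
#' @param chainLength,burnIn,priorShape,priorRate posterior settings for the
#'   manual estimator.
#' @return a \code{\link{BenchmarkResult-class}}.
#' @examples
#' res <- runGrid(eValues = 0, pValues = 0, nCtrlValues = 2, nValues = 3,
#'                replicates = 3, seed = 1, chainLength = 1000)
#' summarizeBenchmark(res)
#' @export
runGrid <- function(eValues = c(-0.2, -0.1, -0.05, 0, 0.05, 0.1, 0.2),
                    pValues = c(0, 0.1, 0.3, 0.5, 0.8),
                    nCtrlValues = 1:4, nValues = 1:10, replicates = 10L,
                    config = SimulationConfig(),
                    estimators = c("frenchfish_manual", "control_adjusted",
                                   "naive"),
                    seed = 1L, chainLength = 10000L, burnIn = 1000L,
                    priorShape = 0.001, priorRate = 0.001) {
  grid <- expand.grid(e = eValues, p = pValues, n_ctrl = nCtrlValues,
                      n = nValues, KEEP.OUT.ATTRS = FALSE)
  set.seed(seed)
  rows <- vector("list", nrow(grid) * replicates)
  k <- 0L
  for (g in seq_len(nrow(grid))) {
    cond <- grid[g, ]
    cfg <- config
    cfg@errorFraction <- cond$e
    cfg@overlapProb <- cond$p
    cfg@trueCopies <- cond$n
    cfg@controlCopies <- cond$n_ctrl
    for (rep in seq_len(replicates)) {
      sec <- withCallingHandlers(
        simulateSection(cfg),
        warning = function(w) invokeRestart("muffleWarning"))
      est <- sectionEstimates(sec, estimators = estimators,
                              priorShape = priorShape, priorRate = priorRate,
                              chainLength = chainLength, burnIn = burnIn)
      k <- k + 1L
      rows[[k]] <- data.frame(e = cond$e, p = cond$p, n_ctrl = cond$n_ctrl,
                              n = cond$n, replicate = rep,
                              estimator = names(est), estimate = unname(est),
                              truth = cond$n, stringsAsFactors = FALSE)
    }
  }
  new("BenchmarkResult", results = do.call(rbind, rows))
}

#' Aggregate a benchmark into per-condition error and accuracy
#'
#' Computes the mean absolute error (continuous scale) and the rounded-count
#' accuracy per estimator and condition cell. The default grouping keeps the
#' full grid; grouping by \code{c("e", "p", "n_ctrl")} reproduces the
#' heatmap-cell granularity at which benchmark errors are conventionally
#' reported (aggregating over true copy number and replicates).
#'
#' @param object a \code{\link{BenchmarkResult-class}}.
#' @param by condition columns to group by, a subset of
#'   \code{c("e", "p", "n_ctrl", "n")}.
#' @return data.frame with one row per estimator and condition cell, with
#'   columns \code{mae} and \code{accuracy}.
#' @export
summarizeBenchmark <- function(object, by = c("e", "p", "n_ctrl", "n")) {
  df <- benchmarkResults(object)
  stopifnot(all(by %in% c("e", "p", "n_ctrl", "n")))
  key <- c("estimator", by)
  split_idx <- interaction(df[key], drop = TRUE)
  out <- do.call(rbind, lapply(split(df, split_idx), function(d) {
    cbind(d[1L, key, drop = FALSE],
          mae = mae(d$estimate, d$truth, na.rm = TRUE),
          accuracy = accuracy(d$estimate, d$truth, na.rm = TRUE))
  }))
  rownames(out) <- NULL
  out
}
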