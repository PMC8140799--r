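#' Mean observed spot count per cell
#'
#' Arithmetic mean of the observed counts in one channel, dividing by the
#' total number of cells (merged blobs count with their cell multiplicity).
#'
#' @param table a \code{\link{SpotCountTable-class}}.
#' @param channel probe channel; may be omitted for single-channel tables.
#' @return the mean observed count per cell.
#' @examples
#' meanObserved(SpotCountTable(1:3, "a", c(1, 2, 3)))
#' @export
meanObserved <- function(table, channel = NULL) {
  df <- .channelRows(table, channel)
  sum(df$count) / sum(df$cells)
}

#' Closed-form Gamma-Poisson posterior mean
#'
#' For Poisson counts with a conjugate Gamma(shape, rate) prior on the rate,
#' the posterior mean is (shape + sum(counts)) / (rate + C). The sufficient
#' statistic is generalised to real-valued (volume-adjusted) counts. This is
#' the analytic reference against which the sampling-based fit is checked.
#'
#' @param adjustedCounts non-negative (possibly real-valued) counts.
#' @param priorShape,priorRate Gamma prior hyperparameters.
#' @param nCells number of cells C; defaults to \code{length(adjustedCounts)}.
#' @return the posterior mean rate.
#' @examples
#' posteriorMeanClosedForm(rep(5, 20), 1, 1)  # (1 + 100) / (1 + 20)
#' @export
posteriorMeanClosedForm <- function(adjustedCounts, priorShape = 0.001,
                                    priorRate = 0.001,
                                    nCells = length(adjustedCounts)) {
  if (any(!is.finite(adjustedCounts)) || any(adjustedCounts < 0))
    .fail("adjustedCounts must be non-negative and finite")
  (priorShape + sum(adjustedCounts)) / (priorRate + nCells)
}

#' Fit the Gamma-Poisson model to volume-adjusted spot counts
#'
#' Models the adjusted per-cell counts as Poisson with rate lambda and a
#' conjugate Gamma(priorShape, priorRate) prior. Conjugacy makes the
#' posterior Gamma(priorShape + sum(counts), priorRate + C) in closed form,
#' so the chain is drawn directly from the posterior (independent samples;
#' any correct MCMC sampler converges to the same distribution). The
#' expected rate is the mean of the post-burn-in draws and equals the
#' expected copy number. The default prior (0.001, 0.001) is near-flat, so
#' the posterior mean is essentially the sample mean of the adjusted counts.
#'
#' @inheritParams posteriorMeanClosedForm
#' @param chainLength number of post-burn-in samples (default 10000).
#' @param burnIn number of initial samples to discard (default 1000).
#' @param seed optional integer seed for reproducible chains.
#' @return a \code{\link{PosteriorEstimate-class}}.
#' @examples
#' fit <- fitPoissonGamma(rep(4.909, 50), seed = 1)
#' expectedRate(fit)
#' @export
fitPoissonGamma <- function(adjustedCounts, priorShape = 0.001,
                            priorRate = 0.001, chainLength = 10000L,
                            burnIn = 1000L, seed = NULL,
                            nCells = length(adjustedCounts)) {
  if (length(adjustedCounts) == 0L) .fail("no counts supplied")
  if (any(!is.finite(adjustedCounts)) || any(adjustedCounts < 0))
    .fail("adjustedCounts must be non-negative and finite")
  chainLength <- as.integer(chainLength); burnIn <- as.integer(burnIn)
  if (chainLength < 1L) .fail("chainLength must be at least 1")
  if (burnIn < 0L) .fail("burnIn must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  shape <- priorShape + sum(adjustedCounts)
  rate <- priorRate + nCells
  draws <- stats::rgamma(burnIn + chainLength, shape = shape, rate = rate)
  chain <- draws[(burnIn + 1L):(burnIn + chainLength)]
  ci <- stats::quantile(chain, c(0.025, 0.975), names = FALSE)
  new("PosteriorEstimate", expectedRate = mean(chain),
      ciLow = min(ci[1L], mean(chain)), ciHigh = max(ci[2L], mean(chain)),
      chain = chain, chainLength = chainLength, burnIn = burnIn,
      priorShape = priorShape, priorRate = priorRate)
}

#' Copy number from manually counted nuclei
#'
#' The manual-counting estimator: observed per-nucleus spot counts are
#' volume-adjusted (scaled by V_sphere / V_avg) and the Gamma-Poisson
#' posterior expected rate of the adjusted counts is reported as the copy
#' number. No control probe is consulted.
#'
#' @param object a \code{\link{SpotCountTable-class}} or a numeric vector of
#'   observed per-nucleus counts.
#' @param geometry a \code{\link{SectionGeometry-class}}.
#' @param channel probe channel (tables only).
#' @param priorShape,priorRate Gamma prior hyperparameters (near-flat default).
#' @param chainLength,burnIn,seed posterior sampling settings, see
#'   \code{\link{fitPoissonGamma}}.
#' @param volumeModel,offsetMax volume-averaging model passed to
#'   \code{\link{volumeAdjust}}.
#' @param nCells number of cells (numeric method only).
#' @param ... passed through to the numeric method.
#' @return a \code{\link{CopyNumberEstimate-class}} with the posterior 95
#'   percent credible interval as its uncertainty.
#' @examples
#' g <- SectionGeometry(4.5, 3)
#' tbl <- SpotCountTable(1:50, "myc", rep(2L, 50))
#' estimateManual(tbl, g, seed = 1)   # about 4.91 copies
#' @export
setGeneric("estimateManual", function(object, geometry, ...)
  standardGeneric("estimateManual"))

#' @rdname estimateManual
setMethod("estimateManual", "SpotCountTable",
          function(object, geometry, channel = NULL, priorShape = 0.001,
                   priorRate = 0.001, chainLength = 10000L, burnIn = 1000L,
                   seed = NULL, volumeModel = c("closed_form", "uniform_offset"),
                   offsetMax = NULL) {
  df <- .channelRows(object, channel)
  est <- estimateManual(as.numeric(df$count), geometry,
                        priorShape = priorShape, priorRate = priorRate,
                        chainLength = chainLength, burnIn = burnIn, seed = seed,
                        volumeModel = match.arg(volumeModel),
                        offsetMax = offsetMax, nCells = sum(df$cells))
  est@channel <- df$channel[1L]
  est
})

#' @rdname estimateManual
setMethod("estimateManual", "numeric",
          function(object, geometry, priorShape = 0.001, priorRate = 0.001,
                   chainLength = 10000L, burnIn = 1000L, seed = NULL,
                   volumeModel = c("closed_form", "uniform_offset"),
                   offsetMax = NULL, nCells = length(object)) {
  adjusted <- volumeAdjust(object, geometry, volumeModel = match.arg(volumeModel),
                           offsetMax = offsetMax)
  fit <- fitPoissonGamma(adjusted, priorShape = priorShape,
                         priorRate = priorRate, chainLength = chainLength,
                         burnIn = burnIn, seed = seed, nCells = nCells)
  ci <- credibleInterval(fit)
  .CopyNumberEstimate(expectedRate(fit), "manual_poisson_gamma",
                      ciLow = ci[1L], ciHigh = ci[2L])
})

#' Homogeneous Poisson point-process intensity estimate
#'
#' Spots are modelled as events of a homogeneous Poisson point process over
#' segmented nuclear area. The maximum-likelihood intensity is the pooled
#' total spot count divided by the pooled area, in spots per square
#' micrometre.
#'
#' @param observations a \code{\link{PointProcessObservations-class}}.
#' @return the MLE intensity (spots / um^2).
#' @examples
#' fitPPP(PointProcessObservations("f1", 120, 600))  # 0.2
#' @export
fitPPP <- function(observations) {
  stopifnot(is(observations, "PointProcessObservations"))
  area <- totalArea(observations)
  if (area <= 0) .fail("total nuclear area is zero; intensity is undefined")
  totalSpots(observations) / area
}

#' Copy number from automated counting via the point process model
#'
#' Converts the fitted point-process intensity into copies per nucleus:
#' lambda * pi r^2 (spots per average nuclear cross-section) scaled by
#' V_sphere / V_avg to correct for partial sampling of nuclei by the
#' section. The uncertainty interval is the exact Poisson interval for the
#' pooled spot count, propagated through the same scaling.
#'
#' @param object a \code{\link{PointProcessObservations-class}}.
#' @param geometry a \code{\link{SectionGeometry-class}}.
#' @param volumeModel,offsetMax see \code{\link{volumeAdjust}}.
#' @param ... unused.
#' @return a \code{\link{CopyNumberEstimate-class}}.
#' @examples
#' g <- SectionGeometry(4.5, 3)
#' obs <- PointProcessObservations("f1", 60, 6000)
#' estimateAuto(obs, g)
#' @export
setGeneric("estimateAuto", function(object, geometry, ...)
  standardGeneric("estimateAuto"))

#' @rdname estimateAuto
setMethod("estimateAuto", "PointProcessObservations",
          function(object, geometry,
                   volumeModel = c("closed_form", "uniform_offset"),
                   offsetMax = NULL) {
  lambda <- fitPPP(object)
  r <- nucleusRadius(geometry)
  factor <- pi * r^2 * .volumeFactor(geometry, match.arg(volumeModel), offsetMax)
  n <- totalSpots(object); a <- totalArea(object)
  # exact Poisson interval on the pooled count, scaled like the point estimate
  lo <- if (n == 0) 0 else stats::qgamma(0.025, n) / a
  hi <- stats::qgamma(0.975, n + 1) / a
  .CopyNumberEstimate(lambda * factor, "auto_ppp",
                      ciLow = lo * factor, ciHigh = hi * factor)
})

#' Standard control-probe scaling
#'
#' The conventional baseline: the observed count for the locus of interest
#' is scaled by the ratio of the expected over the observed control-probe
#' copy number. Unbiased only when the control probe truly has the expected
#' copy number (usually 2).
#'
#' @param nObs observed (mean) count for the locus of interest.
#' @param ctrlObs observed (mean) count for the control probe; must be > 0.
#' @param ctrlExpected assumed control copy number (default 2, diploid).
#' @return the scaled estimate.
#' @examples
#' controlAdjust(3, 1, 2)   # 6
#' @export
controlAdjust <- function(nObs, ctrlObs, ctrlExpected = 2L) {
  if (!is.finite(ctrlObs) || ctrlObs <= 0)
    .fail("observed control count is zero; control baseline is undefined for this section")
  (ctrlExpected / ctrlObs) * nObs
}
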