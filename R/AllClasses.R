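#' @import methods
NULL

#' SectionGeometry: spherical nucleus cut by a planar tissue section
#'
#' Holds the nucleus radius r and the section thickness h (both in
#' micrometres). All volume-correction factors in the package derive from
#' these two quantities under the assumption that nuclei are spheres and the
#' tissue section is a slab of constant thickness.
#'
#' @slot radiusUm nucleus radius r in micrometres.
#' @slot heightUm section thickness h in micrometres.
#'
#' @section Validity:
#' Both slots must be single positive finite numbers. When h exceeds the
#' nucleus diameter 2r, the whole nucleus always fits inside the section and
#' the volume-fraction interpretation degenerates; the constructor warns.
#'
#' @examples
#' g <- SectionGeometry(radiusUm = 4.5, heightUm = 3)
#' sampledFraction(g)
#' @aliases SectionGeometry-class
#' @export SectionGeometry
#' @exportClass SectionGeometry
SectionGeometry <- setClass("SectionGeometry",
  representation(radiusUm = "numeric", heightUm = "numeric"))

setValidity("SectionGeometry", function(object) {
  r <- object@radiusUm; h <- object@heightUm
  if (length(r) != 1L || !is.finite(r) || r <= 0)
    return("radiusUm must be a single positive finite number")
  if (length(h) != 1L || !is.finite(h) || h <= 0)
    return("heightUm must be a single positive finite number")
  TRUE
})

#' @param radiusUm nucleus radius in micrometres.
#' @param heightUm section thickness in micrometres.
#' @rdname SectionGeometry-class
SectionGeometry <- function(radiusUm, heightUm) {
  obj <- new("SectionGeometry", radiusUm = radiusUm, heightUm = heightUm)
  if (heightUm > 2 * radiusUm)
    warning("section thickness exceeds the nucleus diameter (h > 2r); ",
            "nuclei are always fully contained and no volume correction applies")
  obj
}

#' @describeIn SectionGeometry-class nucleus radius accessor (micrometres).
#' @param object,x a \code{SectionGeometry}.
#' @export
nucleusRadius <- function(object) object@radiusUm

#' @describeIn SectionGeometry-class section thickness accessor (micrometres).
#' @export
sectionHeight <- function(object) object@heightUm

setMethod("show", "SectionGeometry", function(object) {
  cat(sprintf("SectionGeometry: nucleus radius %g um, section thickness %g um\n",
              object@radiusUm, object@heightUm))
  cat(sprintf("  average sampled volume fraction: %.4f\n",
              sampledFraction(object)))
})

#' SpotCountTable: per-nucleus FISH spot counts
#'
#' One row per counted object (normally a nucleus) and probe channel, holding
#' the observed integer spot count. An optional per-row nuclear diameter (in
#' micrometres) can be recorded, as produced by manual counting protocols.
#' The \code{cells} column gives the number of cell nuclei the counted object
#' represents: it is 1 for a cleanly separated nucleus and 2 when two
#' overlapping nuclei were counted as a single blob with their spots summed.
#' Estimators divide by the total number of cells, not the number of rows, so
#' that unresolved overlaps do not inflate the per-cell spot rate.
#'
#' @slot counts a \code{data.frame} with columns \code{nucleus_id},
#'   \code{channel}, \code{count}, and optionally \code{diameter_um} and
#'   \code{cells}.
#'
#' @examples
#' tbl <- SpotCountTable(nucleus_id = 1:3, channel = "myc", count = c(1, 2, 3))
#' meanObserved(tbl, "myc")
#' @aliases SpotCountTable-class
#' @export SpotCountTable
#' @exportClass SpotCountTable
SpotCountTable <- setClass("SpotCountTable",
  representation(counts = "data.frame"))

setValidity("SpotCountTable", function(object) {
  df <- object@counts
  need <- c("nucleus_id", "channel", "count", "cells")
  if (!all(need %in% names(df)))
    return(paste("missing columns:", paste(setdiff(need, names(df)), collapse = ", ")))
  if (nrow(df) < 1L) return("table must contain at least one nucleus")
  if (any(!is.finite(df$count)) || any(df$count < 0) ||
      any(df$count != floor(df$count)))
    return("counts must be non-negative integers")
  if (any(!is.finite(df$cells)) || any(df$cells < 1) ||
      any(df$cells != floor(df$cells)))
    return("cells multiplicities must be positive integers")
  if (anyDuplicated(df[, c("nucleus_id", "channel")]))
    return("duplicate (nucleus_id, channel) rows")
  TRUE
})

#' @param nucleus_id vector of nucleus identifiers.
#' @param channel character vector (recycled) of probe channel names.
#' @param count non-negative integer spot counts.
#' @param diameter_um optional per-nucleus diameters in micrometres.
#' @param cells number of cells per counted object (default 1).
#' @rdname SpotCountTable-class
SpotCountTable <- function(nucleus_id, channel, count, diameter_um = NA_real_,
                           cells = 1L) {
  df <- data.frame(nucleus_id = nucleus_id, channel = as.character(channel),
                   count = count, diameter_um = diameter_um,
                   cells = as.integer(cells), stringsAsFactors = FALSE)
  new("SpotCountTable", counts = df)
}

#' @describeIn SpotCountTable-class probe channels present in the table.
#' @export
channelNames <- function(object) unique(object@counts$channel)

#' @describeIn SpotCountTable-class observed counts for one channel.
#' @param object a \code{SpotCountTable}.
#' @param channel probe channel name; may be omitted when only one is present.
#' @export
spotCounts <- function(object, channel = NULL) {
  df <- .channelRows(object, channel)
  df$count
}

#' @describeIn SpotCountTable-class total number of cells in one channel
#'   (counting merged blobs with their multiplicity).
#' @export
nCells <- function(object, channel = NULL) {
  df <- .channelRows(object, channel)
  sum(df$cells)
}

.channelRows <- function(object, channel = NULL) {
  df <- object@counts
  if (is.null(channel)) {
    ch <- unique(df$channel)
    if (length(ch) > 1L)
      .fail("table has several channels (", paste(ch, collapse = ", "),
            "); specify one")
    channel <- ch
  }
  out <- df[df$channel == channel, , drop = FALSE]
  if (nrow(out) == 0L) .fail("no rows for channel '", channel, "'")
  out
}

setMethod("show", "SpotCountTable", function(object) {
  df <- object@counts
  cat(sprintf("SpotCountTable: %d rows, %d channel(s)\n", nrow(df),
              length(unique(df$channel))))
  for (ch in unique(df$channel)) {
    d <- df[df$channel == ch, ]
    cat(sprintf("  %s: %d cells, mean observed count %.3f\n",
                ch, sum(d$cells), sum(d$count) / sum(d$cells)))
  }
})

#' PointProcessObservations: aggregate spot counts over nuclear area
#'
#' The automated counting path does not segment single nuclei. Each field of
#' view contributes one observation: the total number of segmented spots
#' N(a) and the total segmented nuclear area a in square micrometres. Under a
#' homogeneous Poisson point process the intensity estimate depends only on
#' these totals.
#'
#' @slot fields a \code{data.frame} with columns \code{field_id},
#'   \code{total_spots}, \code{total_area_um2}.
#' @aliases PointProcessObservations-class
#' @examples
#' obs <- PointProcessObservations(field_id = c("f1", "f2"),
#'                                 total_spots = c(10, 30),
#'                                 total_area_um2 = c(100, 300))
#' fitPPP(obs)
#' @export PointProcessObservations
#' @exportClass PointProcessObservations
PointProcessObservations <- setClass("PointProcessObservations",
  representation(fields = "data.frame"))

setValidity("PointProcessObservations", function(object) {
  df <- object@fields
  need <- c("field_id", "total_spots", "total_area_um2")
  if (!all(need %in% names(df)))
    return(paste("missing columns:", paste(setdiff(need, names(df)), collapse = ", ")))
  if (any(!is.finite(df$total_spots)) || any(df$total_spots < 0) ||
      any(df$total_spots != floor(df$total_spots)))
    return("total_spots must be non-negative integers")
  if (any(!is.finite(df$total_area_um2)) || any(df$total_area_um2 < 0))
    return("total_area_um2 must be non-negative")
  if (any(df$total_spots > 0 & df$total_area_um2 <= 0))
    return("fields with spots must have positive nuclear area")
  TRUE
})

#' @param field_id field-of-view identifiers.
#' @param total_spots total segmented spot count per field.
#' @param total_area_um2 total segmented nuclear area per field (um^2).
#' @rdname PointProcessObservations-class
PointProcessObservations <- function(field_id, total_spots, total_area_um2) {
  new("PointProcessObservations",
      fields = data.frame(field_id = field_id, total_spots = total_spots,
                          total_area_um2 = total_area_um2,
                          stringsAsFactors = FALSE))
}

#' @describeIn PointProcessObservations-class pooled total spot count.
#' @param object a \code{PointProcessObservations}.
#' @export
totalSpots <- function(object) sum(object@fields$total_spots)

#' @describeIn PointProcessObservations-class pooled nuclear area (um^2).
#' @export
totalArea <- function(object) sum(object@fields$total_area_um2)

setMethod("show", "PointProcessObservations", function(object) {
  cat(sprintf("PointProcessObservations: %d field(s), %d spots over %.1f um^2\n",
              nrow(object@fields), totalSpots(object), totalArea(object)))
})

#' PosteriorEstimate: Gamma posterior over the Poisson spot rate
#'
#' Result of fitting the Gamma-Poisson model to volume-adjusted spot counts.
#' Because the Gamma prior is conjugate to the Poisson likelihood, the
#' posterior is Gamma with shape = priorShape + sum(counts) and rate =
#' priorRate + C; the chain holds post-burn-in samples from that posterior.
#'
#' @slot expectedRate posterior mean of the rate (copies per cell).
#' @slot ciLow,ciHigh central 95 percent credible interval of the chain.
#' @slot chain post-burn-in posterior samples.
#' @slot chainLength number of retained samples.
#' @slot burnIn number of discarded initial samples.
#' @slot priorShape,priorRate Gamma prior hyperparameters.
#' @aliases PosteriorEstimate-class
#' @exportClass PosteriorEstimate
setClass("PosteriorEstimate",
  representation(expectedRate = "numeric", ciLow = "numeric", ciHigh = "numeric",
                 chain = "numeric", chainLength = "integer", burnIn = "integer",
                 priorShape = "numeric", priorRate = "numeric"))

setValidity("PosteriorEstimate", function(object) {
  if (object@expectedRate < 0) return("expectedRate must be non-negative")
  if (object@chainLength < 1L) return("chainLength must be positive")
  if (object@burnIn < 0L) return("burnIn must be non-negative")
  if (object@ciLow > object@expectedRate || object@ciHigh < object@expectedRate)
    return("credible interval must contain the expected rate")
  TRUE
})

#' @describeIn PosteriorEstimate-class posterior mean rate.
#' @param object a \code{PosteriorEstimate}.
#' @export
expectedRate <- function(object) object@expectedRate

#' @describeIn PosteriorEstimate-class central 95 percent credible interval.
#' @export
credibleInterval <- function(object) c(object@ciLow, object@ciHigh)

setMethod("show", "PosteriorEstimate", function(object) {
  cat(sprintf("PosteriorEstimate: E[rate] = %.4f (95%% CI %.4f-%.4f)\n",
              object@expectedRate, object@ciLow, object@ciHigh))
  cat(sprintf("  chain: %d samples after burn-in of %d; Gamma(%g, %g) prior\n",
              object@chainLength, object@burnIn, object@priorShape,
              object@priorRate))
})

#' CopyNumberEstimate: continuous and rounded copy number with uncertainty
#'
#' @slot continuous real-valued copy-number estimate.
#' @slot rounded nearest non-negative integer (half rounds up).
#' @slot method one of \code{"manual_poisson_gamma"}, \code{"auto_ppp"},
#'   \code{"control_adjusted"}, \code{"naive"}.
#' @slot ciLow,ciHigh optional uncertainty interval (NA when unavailable).
#' @slot channel probe channel the estimate refers to (NA when unspecified).
#' @aliases CopyNumberEstimate-class
#' @exportClass CopyNumberEstimate
setClass("CopyNumberEstimate",
  representation(continuous = "numeric", rounded = "integer", method = "character",
                 ciLow = "numeric", ciHigh = "numeric", channel = "character"))

.cnMethods <- c("manual_poisson_gamma", "auto_ppp", "control_adjusted", "naive")

setValidity("CopyNumberEstimate", function(object) {
  if (!object@method %in% .cnMethods)
    return(paste("method must be one of:", paste(.cnMethods, collapse = ", ")))
  if (!is.finite(object@continuous)) return("continuous estimate must be finite")
  if (object@rounded != roundHalfUp(object@continuous))
    return("rounded must equal roundHalfUp(max(continuous, 0))")
  TRUE
})

.CopyNumberEstimate <- function(continuous, method, ciLow = NA_real_,
                                ciHigh = NA_real_, channel = NA_character_) {
  new("CopyNumberEstimate", continuous = continuous,
      rounded = roundHalfUp(continuous), method = method,
      ciLow = ciLow, ciHigh = ciHigh, channel = channel)
}

#' @describeIn CopyNumberEstimate-class continuous estimate accessor.
#' @param object a \code{CopyNumberEstimate}.
#' @export
copyNumber <- function(object) object@continuous

#' @describeIn CopyNumberEstimate-class rounded integer copy number.
#' @export
roundedCopyNumber <- function(object) object@rounded

#' @describeIn CopyNumberEstimate-class estimation method label.
#' @export
estimateMethod <- function(object) object@method

setMethod("show", "CopyNumberEstimate", function(object) {
  ch <- if (is.na(object@channel)) "" else sprintf(" [%s]", object@channel)
  ci <- if (is.na(object@ciLow)) "" else
    sprintf(" (95%% interval %.2f-%.2f)", object@ciLow, object@ciHigh)
  cat(sprintf("CopyNumberEstimate%s: %.3f -> %d copies%s, method = %s\n",
              ch, object@continuous, object@rounded, ci, object@method))
})
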