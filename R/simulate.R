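#' SimulationConfig: conditions for one simulated tissue section
#'
#' Holds the geometry and noise conditions under which simulated sections
#' are generated. Defaults mirror the benchmark design: 3 um sections,
#' 9 um nucleus radius, 50 cells per section, 10 replicates per condition.
#'
#' @slot heightUm section thickness h (um), default 3.
#' @slot radiusUm nucleus radius r (um), default 9. The offset sampler
#'   requires r > 2h.
#' @slot cellsPerSection number of nuclei C per section, default 50.
#' @slot trueCopies true copy number n of the locus of interest.
#' @slot controlCopies true copy number of the control probe.
#' @slot errorFraction e in [-1, 1]: a fraction |e| of nuclei have their
#'   count perturbed by +1 (e > 0) or -1, floored at zero (e < 0).
#' @slot overlapProb probability P that a nucleus merges with its successor.
#' @slot replicates replicate sections per condition, default 10.
#' @slot subclones optional data.frame with columns \code{ploidy} and
#'   \code{fraction} describing a subclonal mixture; fractions must sum to 1.
#'   When present, each nucleus draws its true copy number from the mixture.
#' @slot bFractionMax merged-nucleus centre distance is drawn uniformly from
#'   (0, bFractionMax] as a fraction of the nucleus diameter (default 0.3).
#' @aliases SimulationConfig-class
#' @examples
#' cfg <- SimulationConfig(trueCopies = 4, errorFraction = 0.1)
#' sec <- simulateSection(cfg, seed = 1)
#' @export SimulationConfig
#' @exportClass SimulationConfig
SimulationConfig <- setClass("SimulationConfig",
  representation(heightUm = "numeric", radiusUm = "numeric",
                 cellsPerSection = "integer", trueCopies = "numeric",
                 controlCopies = "numeric", errorFraction = "numeric",
                 overlapProb = "numeric", replicates = "integer",
                 subclones = "data.frame", bFractionMax = "numeric"),
  prototype(heightUm = 3, radiusUm = 9, cellsPerSection = 50L, trueCopies = 2,
            controlCopies = 2, errorFraction = 0, overlapProb = 0,
            replicates = 10L, subclones = data.frame(), bFractionMax = 0.3))

setValidity("SimulationConfig", function(object) {
  if (object@heightUm <= 0 || object@radiusUm <= 0)
    return("geometry must be positive")
  if (object@cellsPerSection < 1L) return("cellsPerSection must be >= 1")
  if (nrow(object@subclones) > 0L) {
    sc <- object@subclones
    if (!all(c("ploidy", "fraction") %in% names(sc)))
      return("subclones needs 'ploidy' and 'fraction' columns")
    if (abs(sum(sc$fraction) - 1) > 1e-8)
      return("subclone fractions must sum to 1")
    if (any(sc$ploidy < 0)) return("subclone ploidies must be non-negative")
  } else if (object@trueCopies < 1 || object@controlCopies < 1) {
    return("trueCopies and controlCopies must be >= 1")
  }
  if (abs(object@errorFraction) > 1) return("errorFraction must lie in [-1, 1]")
  if (object@overlapProb < 0 || object@overlapProb > 1)
    return("overlapProb must lie in [0, 1]")
  if (object@bFractionMax <= 0 || object@bFractionMax > 1)
    return("bFractionMax must lie in (0, 1]")
  TRUE
})

#' @param heightUm,radiusUm,cellsPerSection,trueCopies,controlCopies see slots.
#' @param errorFraction,overlapProb,replicates,subclones,bFractionMax see slots.
#' @rdname SimulationConfig-class
SimulationConfig <- function(heightUm = 3, radiusUm = 9, cellsPerSection = 50L,
                             trueCopies = 2, controlCopies = 2,
                             errorFraction = 0, overlapProb = 0,
                             replicates = 10L, subclones = data.frame(),
                             bFractionMax = 0.3) {
  if (is.list(subclones) && !is.data.frame(subclones))
    subclones <- do.call(rbind, lapply(subclones, as.data.frame))
  new("SimulationConfig", heightUm = heightUm, radiusUm = radiusUm,
      cellsPerSection = as.integer(cellsPerSection), trueCopies = trueCopies,
      controlCopies = controlCopies, errorFraction = errorFraction,
      overlapProb = overlapProb, replicates = as.integer(replicates),
      subclones = subclones, bFractionMax = bFractionMax)
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: r=%g um, h=%g um, C=%d, n=%g, ctrl=%g\n",
              object@radiusUm, object@heightUm, object@cellsPerSection,
              object@trueCopies, object@controlCopies))
  cat(sprintf("  error=%g, overlap=%g, replicates=%d%s\n", object@errorFraction,
              object@overlapProb, object@replicates,
              if (nrow(object@subclones)) sprintf(", %d subclones",
                                                  nrow(object@subclones)) else ""))
})

#' SimulatedSection: one simulated tissue section with ground truth
#'
#' @slot nuclei data.frame with one row per observed object: columns
#'   \code{offset_um}, \code{volume_fraction}, \code{true_copies},
#'   \code{true_control}, \code{observed}, \code{observed_control},
#'   \code{cells}, \code{merged}, \code{projected_area_um2}. Merged rows
#'   represent two cells (offset and volume fraction are those of the first
#'   partner; counts and true copies are summed).
#' @slot geometry the \code{\link{SectionGeometry-class}} used.
#' @slot config the generating \code{\link{SimulationConfig-class}}.
#' @aliases SimulatedSection-class
#' @exportClass SimulatedSection
setClass("SimulatedSection",
  representation(nuclei = "data.frame", geometry = "SectionGeometry",
                 config = "SimulationConfig"))

setValidity("SimulatedSection", function(object) {
  df <- object@nuclei
  if (any(df$observed < 0) || any(df$observed != floor(df$observed)))
    return("observed counts must be non-negative integers")
  if (any(df$observed_control < 0))
    return("observed control counts must be non-negative")
  TRUE
})

setMethod("show", "SimulatedSection", function(object) {
  df <- object@nuclei
  cat(sprintf("SimulatedSection: %d observed objects (%d cells), %d merged\n",
              nrow(df), sum(df$cells), sum(df$merged)))
  cat(sprintf("  mean observed count per cell: %.3f (locus), %.3f (control)\n",
              sum(df$observed) / sum(df$cells),
              sum(df$observed_control) / sum(df$cells)))
})

#' @describeIn SimulatedSection-class the per-object table.
#' @param object a \code{SimulatedSection}.
#' @export
sectionNuclei <- function(object) object@nuclei

#' Draw section offsets for simulated nuclei
#'
#' Offsets d_c (distance from the nucleus midline to the near face of the
#' section) are drawn i.i.d. from Uniform(0, r - 2h), the benchmark's stated
#' placement model; it requires r > 2h.
#'
#' @param config a \code{\link{SimulationConfig-class}}.
#' @param seed optional integer seed.
#' @return numeric vector of C offsets (um).
#' @export
sampleOffsets <- function(config, seed = NULL) {
  r <- config@radiusUm; h <- config@heightUm
  if (r <= 2 * h)
    .fail("offset range Uniform(0, r - 2h) requires r > 2h; got r = ", r,
          ", h = ", h)
  if (!is.null(seed)) set.seed(seed)
  stats::runif(config@cellsPerSection, 0, r - 2 * h)
}

#' Fraction of a nucleus contained in the section at a given offset
#'
#' segmentVolume(geometry, d) / sphereVolume(geometry); zero when the slab
#' misses the sphere.
#'
#' @param d offset(s) in micrometres.
#' @param geometry a \code{\link{SectionGeometry-class}}.
#' @return fractions in [0, 1].
#' @export
volumeFraction <- function(d, geometry) {
  segmentVolume(geometry, d) / sphereVolume(geometry)
}

#' Sample observed spot counts for given true copies and volume fractions
#'
#' Each nucleus contributes a Poisson draw with mean
#' \code{trueCopies * fraction}: the volume fraction acts as the probability
#' that any one of the true copies is captured by the section.
#'
#' @param trueCopies per-nucleus true copy numbers (recycled).
#' @param fraction per-nucleus volume fractions in [0, 1].
#' @param seed optional integer seed.
#' @return integer vector of observed counts.
#' @export
sampleObservedCounts <- function(trueCopies, fraction, seed = NULL) {
  if (any(trueCopies < 0)) .fail("trueCopies must be non-negative")
  if (any(fraction < 0 | fraction > 1)) .fail("fraction must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  stats::rpois(max(length(trueCopies), length(fraction)),
               trueCopies * fraction)
}

# area of the union of two equal circles of radius r at centre distance b
.twoCircleUnion <- function(r, b) {
  if (b >= 2 * r) return(2 * pi * r^2)
  lens <- 2 * r^2 * acos(b / (2 * r)) - (b / 2) * sqrt(4 * r^2 - b^2)
  2 * pi * r^2 - lens
}

#' Merge overlapping nuclei in a simulated section
#'
#' With probability \code{overlapProb}, a nucleus merges with its successor
#' in index order: the spot counts of the pair are summed into a single
#' observed object, the cell multiplicity becomes 2, and the projected area
#' becomes the union of two circles of radius r whose centre distance is
#' drawn as a fraction Uniform(0, bFractionMax] of the diameter. A merged
#' pair takes no further part in merging.
#'
#' @param nuclei the per-nucleus data.frame of a simulated section.
#' @param overlapProb merge probability P in [0, 1].
#' @param geometry a \code{\link{SectionGeometry-class}}.
#' @param bFractionMax centre-distance upper bound as a fraction of 2r.
#' @param seed optional integer seed.
#' @return the data.frame with merges applied.
#' @export
mergeOverlaps <- function(nuclei, overlapProb, geometry, bFractionMax = 0.3,
                          seed = NULL) {
  if (overlapProb < 0 || overlapProb > 1) .fail("overlapProb must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  if (overlapProb == 0 || nrow(nuclei) < 2L) return(nuclei)
  r <- nucleusRadius(geometry)
  keep <- rep(TRUE, nrow(nuclei))
  i <- 1L
  while (i < nrow(nuclei)) {
    if (stats::runif(1) < overlapProb) {
      j <- i + 1L
      b <- stats::runif(1, 0, bFractionMax) * 2 * r
      nuclei$observed[i] <- nuclei$observed[i] + nuclei$observed[j]
      nuclei$observed_control[i] <-
        nuclei$observed_control[i] + nuclei$observed_control[j]
      nuclei$true_copies[i] <- nuclei$true_copies[i] + nuclei$true_copies[j]
      nuclei$true_control[i] <- nuclei$true_control[i] + nuclei$true_control[j]
      nuclei$cells[i] <- nuclei$cells[i] + nuclei$cells[j]
      nuclei$merged[i] <- TRUE
      nuclei$projected_area_um2[i] <- .twoCircleUnion(r, b)
      keep[j] <- FALSE
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  nuclei[keep, , drop = FALSE]
}

#' Apply plus-or-minus-one counting error to a fraction of nuclei
#'
#' A fraction |e| of the observed objects (chosen without replacement;
#' |e| * C rounds half up) have their count incremented by one when e > 0 or
#' decremented by one, floored at zero, when e < 0.
#'
#' @param counts integer vector of observed counts.
#' @param errorFraction e in [-1, 1].
#' @param seed optional integer seed.
#' @return the perturbed counts.
#' @export
applyCountError <- function(counts, errorFraction, seed = NULL) {
  if (abs(errorFraction) > 1) .fail("errorFraction must lie in [-1, 1]")
  if (!is.null(seed)) set.seed(seed)
  if (errorFraction == 0 || length(counts) == 0L) return(counts)
  k <- min(length(counts), roundHalfUp(abs(errorFraction) * length(counts)))
  if (k == 0L) return(counts)
  idx <- sample.int(length(counts), k)
  delta <- sign(errorFraction)
  if (is.integer(counts)) delta <- as.integer(delta)
  counts[idx] <- pmax(counts[idx] + delta, if (is.integer(counts)) 0L else 0)
  counts
}

#' Simulate one tissue section
#'
#' Composes the generative steps: draw section offsets, compute per-nucleus
#' volume fractions, draw Poisson observed counts for the locus of interest
#' and the control probe, merge overlapping nuclei, then apply counting
#' error to the locus channel. With a subclone mixture, each nucleus first
#' draws its true copy number from the (ploidy, fraction) mixture.
#'
#' @param config a \code{\link{SimulationConfig-class}}.
#' @param seed optional integer seed; a fixed seed reproduces the section
#'   exactly.
#' @return a \code{\link{SimulatedSection-class}}.
#' @examples
#' sec <- simulateSection(SimulationConfig(trueCopies = 4), seed = 7)
#' head(sectionNuclei(sec))
#' @export
simulateSection <- function(config, seed = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  if (!is.null(seed)) set.seed(seed)
  geometry <- new("SectionGeometry", radiusUm = config@radiusUm,
                  heightUm = config@heightUm)
  C <- config@cellsPerSection
  if (nrow(config@subclones) > 0L) {
    sc <- config@subclones
    trueCopies <- sample(sc$ploidy, C, replace = TRUE, prob = sc$fraction)
  } else {
    trueCopies <- rep(config@trueCopies, C)
    if (config@trueCopies == config@controlCopies)
      warning("trueCopies equals controlCopies; the generative model is ",
              "stated for distinct locus and control copy numbers")
  }
  d <- sampleOffsets(config)
  vf <- volumeFraction(d, geometry)
  obs <- stats::rpois(C, trueCopies * vf)
  obsCtrl <- stats::rpois(C, config@controlCopies * vf)
  r <- config@radiusUm
  nuclei <- data.frame(
    offset_um = d, volume_fraction = vf, true_copies = trueCopies,
    true_control = rep(config@controlCopies, C), observed = obs,
    observed_control = obsCtrl, cells = rep(1L, C),
    merged = rep(FALSE, C), projected_area_um2 = pi * (r^2 - d^2))
  nuclei <- mergeOverlaps(nuclei, config@overlapProb, geometry,
                          bFractionMax = config@bFractionMax)
  nuclei$observed <- applyCountError(nuclei$observed, config@errorFraction)
  new("SimulatedSection", nuclei = nuclei, geometry = geometry, config = config)
}

#' Estimate copy number from a simulated section with each benchmark method
#'
#' Runs the requested estimators on one simulated section:
#' \code{frenchfish_manual} volume-adjusts the observed counts (using the
#' offset-model-consistent normalisation, since the simulator's section
#' placement is known exactly) and reports the Gamma-Poisson posterior mean;
#' \code{control_adjusted} scales the mean observed count by
#' expected-over-observed control (the control is assumed diploid);
#' \code{naive} reports the raw mean observed count per cell. All estimators
#' divide by the number of cells, counting merged blobs with multiplicity 2.
#'
#' @param section a \code{\link{SimulatedSection-class}}.
#' @param estimators character subset of
#'   \code{c("frenchfish_manual", "control_adjusted", "naive")}.
#' @param priorShape,priorRate,chainLength,burnIn posterior settings for the
#'   manual estimator.
#' @param ctrlExpected assumed control copy number for the baseline.
#' @return named numeric vector of continuous estimates (NA when a baseline
#'   is undefined, e.g. zero observed control counts).
#' @export
sectionEstimates <- function(section,
                             estimators = c("frenchfish_manual",
                                            "control_adjusted", "naive"),
                             priorShape = 0.001, priorRate = 0.001,
                             chainLength = 10000L, burnIn = 1000L,
                             ctrlExpected = 2) {
  df <- section@nuclei
  nCellsTotal <- sum(df$cells)
  out <- numeric(0)
  if ("frenchfish_manual" %in% estimators) {
    est <- estimateManual(as.numeric(df$observed), section@geometry,
                          priorShape = priorShape, priorRate = priorRate,
                          chainLength = chainLength, burnIn = burnIn,
                          volumeModel = "uniform_offset", nCells = nCellsTotal)
    out["frenchfish_manual"] <- copyNumber(est)
  }
  if ("control_adjusted" %in% estimators) {
    out["control_adjusted"] <- tryCatch(
      controlAdjust(sum(df$observed) / nCellsTotal,
                    sum(df$observed_control) / nCellsTotal, ctrlExpected),
      error = function(e) NA_real_)
  }
  if ("naive" %in% estimators)
    out["naive"] <- sum(df$observed) / nCellsTotal
  out
}
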