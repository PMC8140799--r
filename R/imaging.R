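#' ImageStack: multi-channel fluorescence z-stack
#'
#' A named list of channels (conventionally \code{"dapi"} plus one or more
#' spot channels), each a height x width x depth array of intensities, with
#' the physical pixel size and z step in micrometres.
#'
#' @slot channels named list of 3-D numeric arrays with identical dimensions.
#' @slot pixelSizeUm lateral pixel size (um), default 0.07.
#' @slot zStepUm z-step between planes (um), default 0.3.
#' @aliases ImageStack-class
#' @export ImageStack
#' @exportClass ImageStack
ImageStack <- setClass("ImageStack",
  representation(channels = "list", pixelSizeUm = "numeric",
                 zStepUm = "numeric"),
  prototype(pixelSizeUm = 0.07, zStepUm = 0.3))

setValidity("ImageStack", function(object) {
  if (length(object@channels) == 0L) return("at least one channel required")
  if (is.null(names(object@channels)) || any(names(object@channels) == ""))
    return("channels must be named")
  dims <- lapply(object@channels, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    return("each channel must be a 3-D array (height x width x depth)")
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    return("all channels must share dimensions")
  if (object@pixelSizeUm <= 0) return("pixelSizeUm must be positive")
  TRUE
})

#' @param channels named list of 3-D arrays (matrices are promoted to
#'   single-plane stacks).
#' @param pixelSizeUm,zStepUm physical calibration in micrometres.
#' @rdname ImageStack-class
ImageStack <- function(channels, pixelSizeUm = 0.07, zStepUm = 0.3) {
  channels <- lapply(channels, function(x) {
    if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
  })
  new("ImageStack", channels = channels, pixelSizeUm = pixelSizeUm,
      zStepUm = zStepUm)
}

#' @describeIn ImageStack-class channel accessor.
#' @param object an \code{ImageStack}.
#' @param name channel name.
#' @export
getChannel <- function(object, name) {
  if (!name %in% names(object@channels))
    .fail("no channel named '", name, "'")
  object@channels[[name]]
}

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@channels[[1L]])
  cat(sprintf("ImageStack: %d channel(s) [%s], %dx%d px, %d plane(s), %g um/px\n",
              length(object@channels),
              paste(names(object@channels), collapse = ", "),
              d[1L], d[2L], d[3L], object@pixelSizeUm))
})

#' SegmentationResult: nuclear mask and per-channel spot labels
#'
#' @slot fieldId field-of-view identifier.
#' @slot mask logical nuclear mask.
#' @slot nuclearAreaUm2 mask area in square micrometres.
#' @slot spotLabels named list of integer label matrices (one per channel).
#' @slot spotCounts named integer vector of spot counts per channel.
#' @slot pixelSizeUm lateral pixel size (um).
#' @slot plantedTruth for synthetic fields, the generator's ground truth.
#' @aliases SegmentationResult-class
#' @exportClass SegmentationResult
setClass("SegmentationResult",
  representation(fieldId = "character", mask = "matrix",
                 nuclearAreaUm2 = "numeric", spotLabels = "list",
                 spotCounts = "integer", pixelSizeUm = "numeric",
                 plantedTruth = "list"))

setValidity("SegmentationResult", function(object) {
  if (abs(object@nuclearAreaUm2 -
          sum(object@mask) * object@pixelSizeUm^2) > 1e-6)
    return("nuclearAreaUm2 must equal mask pixel count times pixel area")
  TRUE
})

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf("SegmentationResult [%s]: nuclear area %.1f um^2\n",
              object@fieldId, object@nuclearAreaUm2))
  for (ch in names(object@spotCounts))
    cat(sprintf("  %s: %d spot(s)\n", ch, object@spotCounts[[ch]]))
})

#' @describeIn SegmentationResult-class spot counts per channel.
#' @param object a \code{SegmentationResult}.
#' @export
segmentedSpotCounts <- function(object) object@spotCounts

#' @describeIn SegmentationResult-class the nuclear mask.
#' @export
nuclearMask <- function(object) object@mask

.asMatrix <- function(x) {
  x <- EBImage::imageData(x)
  dim(x) <- dim(x)[1:2]
  x
}

.gblurMat <- function(m, sigma) {
  # cap the kernel so it never exceeds the plane (small test images)
  radius <- min(2L * as.integer(ceiling(3 * sigma)) + 1L,
                (min(dim(m)) %/% 2L) * 2L - 1L)
  .asMatrix(EBImage::gblur(EBImage::Image(m), sigma = sigma, radius = radius))
}

#' Vollath F4 autofocus measure
#'
#' Correlation-based focus score: the sum of products of horizontally
#' adjacent pixels minus the sum of products of pixels two columns apart,
#' each over its valid domain. Sharp planes score higher than their blurred
#' copies, which drives best-focus plane selection in a z-stack.
#'
#' @param plane numeric matrix (at least 3 columns).
#' @return the focus score.
#' @examples
#' vollathF4(matrix(runif(100), 10, 10))
#' @export
vollathF4 <- function(plane) {
  if (!is.matrix(plane) || ncol(plane) < 3L)
    .fail("plane must be a matrix with at least 3 columns")
  W <- ncol(plane)
  sum(plane[, 1:(W - 1L)] * plane[, 2:W]) -
    sum(plane[, 1:(W - 2L)] * plane[, 3:W])
}

#' Select the in-focus window of a z-stack
#'
#' Scores every plane with \code{\link{vollathF4}}, finds the best-focused
#' plane, and keeps a window of 4 planes below to 5 planes above it,
#' clamped to the stack boundaries.
#'
#' @param stack 3-D array (height x width x depth).
#' @param below,above planes retained on each side of the best plane.
#' @return the sub-stack, with attributes \code{bestIndex} and
#'   \code{indices}.
#' @export
selectFocusWindow <- function(stack, below = 4L, above = 5L) {
  stopifnot(length(dim(stack)) == 3L)
  D <- dim(stack)[3L]
  scores <- vapply(seq_len(D), function(z) vollathF4(stack[, , z]), 0)
  best <- which.max(scores)
  idx <- max(1L, best - below):min(D, best + above)
  out <- stack[, , idx, drop = FALSE]
  attr(out, "bestIndex") <- best
  attr(out, "indices") <- idx
  out
}

#' Maximum intensity projection
#'
#' @param stack 3-D array (or a matrix, returned unchanged).
#' @return matrix of per-pixel maxima across planes.
#' @export
maxIntensityProjection <- function(stack) {
  if (is.matrix(stack)) return(stack)
  stopifnot(length(dim(stack)) == 3L)
  Reduce(pmax, lapply(seq_len(dim(stack)[3L]), function(z) stack[, , z]))
}

#' Contrast normalisation with saturation
#'
#' Linearly rescales a plane to [0, 1] after clipping the brightest
#' \code{saturation} fraction of pixels to the maximum, which lifts weak
#' spot signal relative to bright outliers. A constant plane is returned
#' unchanged, and if the clip level does not exceed the minimum (very
#' sparse images) a plain full-range rescale is used.
#'
#' @param plane numeric matrix.
#' @param saturation fraction of pixels allowed to saturate, in [0, 1).
#' @return rescaled matrix in [0, 1].
#' @export
normalizeContrast <- function(plane, saturation = 0.4) {
  if (saturation < 0 || saturation >= 1) .fail("saturation must lie in [0, 1)")
  lo <- min(plane); hi <- max(plane)
  if (hi <= lo) return(plane)
  q <- stats::quantile(plane, 1 - saturation, names = FALSE)
  if (q <= lo) q <- hi
  out <- pmin(plane, q)
  (out - lo) / (q - lo)
}

#' Segment nuclei in a DAPI plane
#'
#' Substitute nuclear segmenter: global Otsu threshold on the normalised
#' plane, hole filling, morphological opening, and removal of small
#' objects. It is not meant to separate touching nuclei (the point-process
#' model removes the need); it only has to delineate nuclear from
#' non-nuclear area.
#'
#' @param plane normalised DAPI matrix in [0, 1].
#' @param pixelSizeUm lateral pixel size (um).
#' @param minNucleusAreaUm2 objects smaller than this are discarded.
#' @param brushSize diameter (px) of the opening brush.
#' @return logical nuclear mask.
#' @export
segmentNuclei <- function(plane, pixelSizeUm = 0.07, minNucleusAreaUm2 = 3,
                          brushSize = 5L) {
  if (diff(range(plane)) == 0) {
    warning("constant DAPI plane; returning empty nuclear mask")
    return(matrix(FALSE, nrow(plane), ncol(plane)))
  }
  img <- EBImage::Image(normalizeContrast(plane, saturation = 0))
  thr <- EBImage::otsu(img, range = c(0, 1))
  mask <- EBImage::imageData(img) > thr
  mask <- .asMatrix(EBImage::fillHull(EBImage::Image(mask * 1)))> 0
  mask <- .asMatrix(EBImage::opening(EBImage::Image(mask * 1),
                                     EBImage::makeBrush(brushSize, "disc"))) > 0
  labels <- .asMatrix(EBImage::bwlabel(EBImage::Image(mask * 1)))
  if (max(labels) > 0) {
    areas <- tabulate(labels[labels > 0], nbins = max(labels))
    small <- which(areas * pixelSizeUm^2 < minNucleusAreaUm2)
    mask[labels %in% small] <- FALSE
  }
  if (!any(mask)) warning("empty nuclear mask")
  mask
}

#' Mask a spot channel with the nuclear segmentation
#'
#' Pixels outside the nuclear mask are zeroed, removing extranuclear
#' artifacts before spot detection.
#'
#' @param plane spot-channel matrix.
#' @param mask logical nuclear mask of the same dimensions.
#' @return masked matrix.
#' @export
maskSpotChannel <- function(plane, mask) {
  stopifnot(all(dim(plane) == dim(mask)))
  plane * mask
}

#' Keep only the top fraction of in-mask signal intensity
#'
#' Zeroes pixels below the (1 - keepFraction) intensity quantile of the
#' in-mask pixels, suppressing residual autofluorescence. With an empty
#' mask the output is all zero.
#'
#' @param plane (masked) spot-channel matrix.
#' @param mask logical mask defining the reference pixel population; when
#'   NULL the whole plane is used.
#' @param keepFraction fraction of signal retained (default 0.1).
#' @return filtered matrix.
#' @export
topFractionFilter <- function(plane, mask = NULL, keepFraction = 0.1) {
  if (keepFraction <= 0 || keepFraction > 1)
    .fail("keepFraction must lie in (0, 1]")
  ref <- if (is.null(mask)) plane else plane[mask]
  if (length(ref) == 0L) return(plane * 0)
  q <- stats::quantile(ref, 1 - keepFraction, names = FALSE)
  plane[plane < q] <- 0
  plane
}

#' Intermodes threshold of an intensity histogram
#'
#' Iteratively smooths the histogram with a 3-bin running mean until
#' exactly two local maxima remain (histogram ends may be maxima), then
#' returns the bin midway between the two modes. Returns NA if the
#' histogram never becomes bimodal within \code{maxIter} smoothing passes.
#'
#' @param counts numeric histogram counts.
#' @param maxIter maximum smoothing iterations.
#' @return threshold bin index (pixels in bins above it are foreground),
#'   or NA.
#' @export
intermodesThreshold <- function(counts, maxIter = 10000L) {
  h <- as.numeric(counts)
  B <- length(h)
  if (B < 3L) .fail("histogram needs at least 3 bins")
  peaks <- function(y) {
    lo <- c(-Inf, y[-B]); hi <- c(y[-1L], -Inf)
    which(y > lo & y >= hi & y > 0)
  }
  for (iter in seq_len(maxIter)) {
    pk <- peaks(h)
    if (length(pk) == 2L) return(as.integer(floor(mean(pk))))
    if (length(pk) < 2L) return(NA_integer_)
    h <- (c(h[1L], h[-B]) + h + c(h[-1L], h[B])) / 3
  }
  NA_integer_
}

#' Renyi-entropy threshold of an intensity histogram
#'
#' Maximises the sum of the Renyi entropies of order \code{alpha} of the
#' background and foreground intensity distributions over all candidate
#' split points. At \code{alpha = 1} the criterion reduces to the Shannon
#' (maximum-entropy) threshold.
#'
#' @param counts numeric histogram counts.
#' @param alpha entropy order (default 2).
#' @return threshold bin index (pixels in bins above it are foreground).
#' @export
renyiEntropyThreshold <- function(counts, alpha = 2) {
  p <- as.numeric(counts)
  if (sum(p) <= 0) .fail("empty histogram")
  p <- p / sum(p)
  B <- length(p)
  P1 <- cumsum(p)
  eps <- 1e-12
  Hsum <- rep(-Inf, B - 1L)
  for (t in seq_len(B - 1L)) {
    Pb <- P1[t]; Pf <- 1 - Pb
    if (Pb < eps || Pf < eps) next
    pb <- p[1:t] / Pb
    pf <- p[(t + 1L):B] / Pf
    if (abs(alpha - 1) < 1e-9) {
      Hb <- -sum(ifelse(pb > 0, pb * log(pb), 0))
      Hf <- -sum(ifelse(pf > 0, pf * log(pf), 0))
    } else {
      Hb <- log(sum(pb^alpha)) / (1 - alpha)
      Hf <- log(sum(pf^alpha)) / (1 - alpha)
    }
    Hsum[t] <- Hb + Hf
  }
  which.max(Hsum)
}

#' Automatic histogram thresholding of an image plane
#'
#' Bins the plane into \code{nBins} equal-width intensity bins and applies
#' either the Intermodes or the Renyi-entropy criterion. Intermodes suits
#' channels with a precipitation signal (an intermediate intensity mode);
#' Renyi entropy suits channels without. If Intermodes never reaches
#' bimodality the function falls back to Otsu's threshold with a warning.
#'
#' @param plane numeric matrix with at least two distinct values.
#' @param method \code{"renyi_entropy"} or \code{"intermodes"}.
#' @param nBins number of histogram bins (default 256).
#' @param alpha Renyi entropy order.
#' @param ignoreZero drop the lowest histogram bin from the criterion.
#'   Masked-and-filtered planes are dominated by exact-zero background
#'   pixels that would otherwise swamp either criterion; the pipeline sets
#'   this for its spot-segmentation stages.
#' @return logical foreground matrix with attributes \code{threshold}
#'   (intensity cutoff) and \code{bin} (threshold bin index).
#' @export
autoThreshold <- function(plane, method = c("renyi_entropy", "intermodes"),
                          nBins = 256L, alpha = 2, ignoreZero = FALSE) {
  method <- match.arg(method)
  lo <- min(plane); hi <- max(plane)
  if (hi <= lo) .fail("plane must contain at least two distinct values")
  binOf <- pmin(floor((plane - lo) / (hi - lo) * nBins) + 1L, nBins)
  counts <- tabulate(binOf, nbins = nBins)
  if (ignoreZero) counts[1L] <- 0
  idx <- if (method == "intermodes") intermodesThreshold(counts)
         else renyiEntropyThreshold(counts, alpha = alpha)
  if (is.na(idx)) {
    warning("histogram did not become bimodal; falling back to Otsu's threshold")
    norm <- (plane - lo) / (hi - lo)
    thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    out <- norm > thr
    attr(out, "threshold") <- lo + thr * (hi - lo)
    attr(out, "bin") <- NA_integer_
    return(out)
  }
  thr <- lo + idx / nBins * (hi - lo)  # upper edge of the threshold bin
  out <- binOf > idx
  attr(out, "threshold") <- thr
  attr(out, "bin") <- idx
  out
}

#' Two-stage blur-and-threshold spot segmentation
#'
#' Gaussian blur followed by automatic thresholding, applied twice: the
#' second pass blurs the binary result and re-thresholds it, which merges
#' fragmented spots and removes isolated small artifacts. All-constant
#' input returns an all-background binary.
#'
#' @param plane spot-channel matrix (masked and filtered).
#' @param method threshold method, see \code{\link{autoThreshold}}.
#' @param sigma1,sigma2 Gaussian standard deviations (px) of the two
#'   stages.
#' @param alpha Renyi entropy order.
#' @return logical spot binary.
#' @export
twoStageBlurThreshold <- function(plane,
                                  method = c("renyi_entropy", "intermodes"),
                                  sigma1 = 1, sigma2 = 2, alpha = 2,
                                  ignoreZero = TRUE) {
  method <- match.arg(method)
  if (diff(range(plane)) == 0)
    return(matrix(FALSE, nrow(plane), ncol(plane)))
  b1 <- autoThreshold(.gblurMat(plane, sigma1), method = method, alpha = alpha,
                      ignoreZero = ignoreZero)
  if (!any(b1) || all(b1)) return(unname(b1) & TRUE)
  b2 <- autoThreshold(.gblurMat(b1 * 1, sigma2), method = method, alpha = alpha,
                      ignoreZero = ignoreZero)
  matrix(as.vector(b2), nrow(plane), ncol(plane))
}

# 8-connected labelling: EBImage's bwlabel is 4-connected, so labels that
# touch only diagonally are merged with a union-find pass
.label8 <- function(binary) {
  labels <- .asMatrix(EBImage::bwlabel(EBImage::Image(binary * 1)))
  n <- max(labels)
  if (n < 2) return(labels)
  H <- nrow(labels); W <- ncol(labels)
  a <- labels[-H, -W]; b <- labels[-1, -1]   # down-right diagonal
  c1 <- labels[-1, -W]; d <- labels[-H, -1]  # up-right diagonal
  pairs <- rbind(cbind(a[a > 0 & b > 0 & a != b], b[a > 0 & b > 0 & a != b]),
                 cbind(c1[c1 > 0 & d > 0 & c1 != d], d[c1 > 0 & d > 0 & c1 != d]))
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (nrow(pairs)) for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(n), find, 0L)
  dense <- match(roots, sort(unique(roots)))
  out <- labels
  out[labels > 0] <- dense[labels[labels > 0]]
  out
}

#' Size-based spot filter
#'
#' Labels connected foreground components (8-connectivity) and keeps those
#' whose area falls inside the given bounds, relabelling the survivors
#' 1..k.
#'
#' @param binary logical spot binary.
#' @param minAreaUm2,maxAreaUm2 area bounds in square micrometres.
#' @param pixelSizeUm lateral pixel size (um).
#' @return integer label matrix with attribute \code{count}.
#' @export
sizeFilter <- function(binary, minAreaUm2, maxAreaUm2, pixelSizeUm = 0.07) {
  if (minAreaUm2 > maxAreaUm2) .fail("minAreaUm2 must not exceed maxAreaUm2")
  if (minAreaUm2 <= 0 || maxAreaUm2 <= 0) .fail("area bounds must be positive")
  labels <- .label8(binary)
  n <- max(labels)
  if (n == 0) {
    attr(labels, "count") <- 0L
    return(labels)
  }
  areas <- tabulate(labels[labels > 0], nbins = n) * pixelSizeUm^2
  keep <- which(areas >= minAreaUm2 & areas <= maxAreaUm2)
  remap <- integer(n)
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(labels), ncol(labels))
  pos <- labels > 0
  out[pos] <- remap[labels[pos]]
  attr(out, "count") <- length(keep)
  out
}

#' Bridge a segmentation result to the point-process model
#'
#' Collapses a \code{\link{SegmentationResult-class}} into the aggregate
#' (total spots, total nuclear area) observations the intensity estimator
#' consumes.
#'
#' @param result a \code{SegmentationResult}.
#' @param channels channels to extract (default: all spot channels).
#' @return a named list of single-field
#'   \code{\link{PointProcessObservations-class}}, one per channel.
#' @export
extractObservation <- function(result, channels = NULL) {
  if (is.null(channels)) channels <- names(result@spotCounts)
  area <- result@nuclearAreaUm2
  out <- lapply(channels, function(ch) {
    n <- result@spotCounts[[ch]]
    if (is.null(n)) .fail("no spot counts for channel '", ch, "'")
    if (area <= 0 && n > 0)
      .fail("segmentation inconsistency: spots found but nuclear area is zero")
    PointProcessObservations(field_id = result@fieldId, total_spots = n,
                             total_area_um2 = area)
  })
  names(out) <- channels
  out
}

#' Combine per-field observations into one pooled set
#'
#' @param ... \code{PointProcessObservations} objects (or one list of them).
#' @return a single \code{PointProcessObservations} with one row per field.
#' @export
bindObservations <- function(...) {
  objs <- list(...)
  if (length(objs) == 1L && is.list(objs[[1L]]) && !is(objs[[1L]], "PointProcessObservations"))
    objs <- objs[[1L]]
  new("PointProcessObservations",
      fields = do.call(rbind, lapply(objs, function(o) o@fields)))
}

#' Run the full image-processing chain on one field of view
#'
#' Focus selection on the DAPI stack (Vollath F4, window of 4 below / 5
#' above the best plane), maximum-intensity projection, nuclear
#' segmentation, then per spot channel: contrast normalisation with 40
#' percent saturation, nuclear masking, top-10-percent intensity filtering,
#' two-stage blur-and-threshold segmentation and a size filter. The chain
#' is deterministic given its input.
#'
#' @param stack an \code{\link{ImageStack-class}}.
#' @param fieldId identifier recorded in the result.
#' @param dapiChannel name of the nuclear-stain channel.
#' @param thresholdMethods named character vector mapping spot channels to
#'   \code{"renyi_entropy"} (no precipitation) or \code{"intermodes"}
#'   (precipitation present); unnamed channels default to Renyi entropy.
#' @param saturation contrast saturation fraction for spot channels.
#' @param keepFraction top-intensity fraction retained inside the mask.
#' @param sigma1,sigma2 blur widths (px) of the two threshold stages.
#' @param minSpotDiameterUm,maxSpotDiameterUm accepted spot diameters (um),
#'   converted to area bounds for the size filter.
#' @param minNucleusAreaUm2 passed to \code{\link{segmentNuclei}}.
#' @param truth optional planted truth to carry along (synthetic fields).
#' @return a \code{\link{SegmentationResult-class}}.
#' @export
processField <- function(stack, fieldId = "field1", dapiChannel = "dapi",
                         thresholdMethods = character(), saturation = 0.4,
                         keepFraction = 0.1, sigma1 = 1, sigma2 = 2,
                         minSpotDiameterUm = 0.2, maxSpotDiameterUm = 1.5,
                         minNucleusAreaUm2 = 3, truth = list()) {
  stopifnot(is(stack, "ImageStack"))
  px <- stack@pixelSizeUm
  dapi <- getChannel(stack, dapiChannel)
  window <- selectFocusWindow(dapi)
  idx <- attr(window, "indices")
  mask <- segmentNuclei(normalizeContrast(maxIntensityProjection(window), 0),
                        pixelSizeUm = px,
                        minNucleusAreaUm2 = minNucleusAreaUm2)
  spotChannels <- setdiff(names(stack@channels), dapiChannel)
  minArea <- pi * (minSpotDiameterUm / 2)^2
  maxArea <- pi * (maxSpotDiameterUm / 2)^2
  labels <- list(); counts <- integer()
  for (ch in spotChannels) {
    method <- if (ch %in% names(thresholdMethods)) thresholdMethods[[ch]]
              else "renyi_entropy"
    plane <- maxIntensityProjection(getChannel(stack, ch)[, , idx, drop = FALSE])
    plane <- normalizeContrast(plane, saturation = saturation)
    plane <- maskSpotChannel(plane, mask)
    plane <- topFractionFilter(plane, mask = mask, keepFraction = keepFraction)
    binary <- twoStageBlurThreshold(plane, method = method,
                                    sigma1 = sigma1, sigma2 = sigma2)
    binary <- binary & mask   # containment: spots live inside nuclei
    lab <- sizeFilter(binary, minArea, maxArea, pixelSizeUm = px)
    labels[[ch]] <- lab
    counts[[ch]] <- attr(lab, "count")
  }
  new("SegmentationResult", fieldId = fieldId, mask = mask,
      nuclearAreaUm2 = sum(mask) * px^2, spotLabels = labels,
      spotCounts = counts, pixelSizeUm = px, plantedTruth = truth)
}
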