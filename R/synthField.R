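#' Generate a synthetic FISH field of view with known ground truth
#'
#' Renders a multi-channel z-stack emulating the artifacts the image
#' pipeline is designed to handle: DAPI-stained nuclei as bright disks
#' (optionally partially overlapping), spot channels with small in-nucleus
#' Gaussian blobs whose per-nucleus count is Poisson(copies x sampled
#' volume fraction), diffuse extranuclear autofluorescence, bright
#' extranuclear artifact blobs, faint precipitation blobs inside nuclei,
#' and Gaussian background noise. The diffuse autofluorescence occupies
#' most of the frame, which is what makes the pipeline's saturating
#' contrast normalisation meaningful: weak spots are lifted to match the
#' bright extranuclear signal, and the nuclear mask then strips the
#' extranuclear component.
#' Out-of-focus planes are progressively blurred copies of the best-focus
#' plane. The planted truth (nuclear mask, spot counts, copy numbers) is
#' returned alongside the stack so the whole chain can be validated
#' end to end.
#'
#' Planted spots within one nucleus are kept at least \code{minSpotSepPx}
#' apart so that distinct spots remain resolvable by design on clean
#' fields.
#'
#' @param nNuclei number of nuclei to place.
#' @param radiusPx nucleus radius in pixels.
#' @param copiesPerChannel named integer vector: true copy number per spot
#'   channel.
#' @param overlapProb probability that a nucleus is placed overlapping its
#'   predecessor.
#' @param artifactDensity expected number of extranuclear bright artifacts
#'   (and, independently, of faint precipitation blobs) per field.
#' @param autofluorescence mean intensity of the diffuse extranuclear
#'   autofluorescence in spot channels (0 disables it).
#' @param noiseSd standard deviation of the additive Gaussian background.
#' @param dim image height and width in pixels.
#' @param depth number of z planes.
#' @param pixelSizeUm,zStepUm physical calibration.
#' @param sectionHeightUm section thickness used for the sampled-fraction
#'   thinning of spot counts; defaults to the nucleus radius in
#'   micrometres.
#' @param spotSigmaPx Gaussian radius of planted spots (px).
#' @param minSpotSepPx minimum distance between planted spots of one
#'   nucleus (px).
#' @param seed optional integer seed; fixed seed reproduces the stack
#'   exactly.
#' @return list with elements \code{stack} (an
#'   \code{\link{ImageStack-class}}) and \code{truth} (list: \code{mask},
#'   \code{counts} planted spots per channel, \code{copies},
#'   \code{centers}, \code{geometry} the matching
#'   \code{\link{SectionGeometry-class}}).
#' @examples
#' field <- synthField(nNuclei = 3, radiusPx = 15, dim = c(128, 128),
#'                     depth = 3, seed = 1)
#' field$truth$counts
#' @export
synthField <- function(nNuclei = 5, radiusPx = 26,
                       copiesPerChannel = c(probe = 2), overlapProb = 0,
                       artifactDensity = 0, autofluorescence = 0.12,
                       noiseSd = 0.005,
                       dim = c(256L, 256L), depth = 7L, pixelSizeUm = 0.1,
                       zStepUm = 0.3, sectionHeightUm = NULL,
                       spotSigmaPx = 1.2, minSpotSepPx = 12, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(copiesPerChannel)))
    names(copiesPerChannel) <- paste0("probe", seq_along(copiesPerChannel))
  H <- dim[1L]; W <- dim[2L]
  rUm <- radiusPx * pixelSizeUm
  if (is.null(sectionHeightUm)) sectionHeightUm <- rUm
  geometry <- SectionGeometry(radiusUm = rUm, heightUm = sectionHeightUm)
  frac <- sampledFraction(geometry)

  # place nuclei: rejection sampling, optionally overlapping the previous one
  margin <- radiusPx + 5
  centers <- matrix(NA_real_, nNuclei, 2L)
  for (i in seq_len(nNuclei)) {
    placed <- FALSE
    for (try in seq_len(500L)) {
      if (i > 1L && stats::runif(1) < overlapProb) {
        ang <- stats::runif(1, 0, 2 * pi)
        sep <- stats::runif(1, 1.0, 1.5) * radiusPx
        cand <- centers[i - 1L, ] + sep * c(cos(ang), sin(ang))
      } else {
        cand <- c(stats::runif(1, margin, H - margin),
                  stats::runif(1, margin, W - margin))
        if (i > 1L) {
          dmin <- min(sqrt(rowSums((centers[seq_len(i - 1L), , drop = FALSE] -
                                    matrix(cand, i - 1L, 2L, byrow = TRUE))^2)))
          if (dmin < 2.3 * radiusPx) next
        }
      }
      if (cand[1L] < margin || cand[1L] > H - margin ||
          cand[2L] < margin || cand[2L] > W - margin) next
      centers[i, ] <- cand
      placed <- TRUE
      break
    }
    if (!placed) .fail("could not place ", nNuclei, " nuclei in a ",
                       H, "x", W, " field; enlarge the field")
  }

  rowIdx <- matrix(seq_len(H), H, W)
  colIdx <- matrix(seq_len(W), H, W, byrow = TRUE)
  mask <- matrix(FALSE, H, W)
  for (i in seq_len(nNuclei))
    mask <- mask | ((rowIdx - centers[i, 1L])^2 +
                    (colIdx - centers[i, 2L])^2 <= radiusPx^2)

  addBlob <- function(img, center, sigma, amp) {
    r0 <- max(1L, floor(center[1L] - 4 * sigma))
    r1 <- min(H, ceiling(center[1L] + 4 * sigma))
    c0 <- max(1L, floor(center[2L] - 4 * sigma))
    c1 <- min(W, ceiling(center[2L] + 4 * sigma))
    rr <- r0:r1; cc <- c0:c1
    d2 <- outer((rr - center[1L])^2, (cc - center[2L])^2, "+")
    img[rr, cc] <- img[rr, cc] + amp * exp(-d2 / (2 * sigma^2))
    img
  }

  dapiBest <- .gblurMat(mask * 0.85, 1)
  # smooth extranuclear autofluorescence texture shared by the spot channels
  autofluoField <- if (autofluorescence > 0) {
    tex <- .gblurMat(matrix(stats::runif(H * W), H, W), 8)
    autofluorescence * (0.7 + 0.6 * tex) * !mask
  } else matrix(0, H, W)
  planted <- list()
  bestPlanes <- list(dapi = dapiBest)
  for (ch in names(copiesPerChannel)) {
    plane <- autofluoField
    total <- 0L
    spotCenters <- matrix(numeric(0), 0L, 2L)
    for (i in seq_len(nNuclei)) {
      k <- stats::rpois(1, copiesPerChannel[[ch]] * frac)
      pts <- matrix(numeric(0), 0L, 2L)
      for (s in seq_len(k)) {
        for (try in seq_len(200L)) {
          ang <- stats::runif(1, 0, 2 * pi)
          rad <- sqrt(stats::runif(1)) * 0.72 * radiusPx
          cand <- centers[i, ] + rad * c(cos(ang), sin(ang))
          ok <- nrow(pts) == 0L ||
            min(sqrt(rowSums((pts - matrix(cand, nrow(pts), 2L,
                                           byrow = TRUE))^2))) >= minSpotSepPx
          if (ok) { pts <- rbind(pts, cand); break }
        }
      }
      total <- total + nrow(pts)
      spotCenters <- rbind(spotCenters, pts)
      for (s in seq_len(nrow(pts)))
        plane <- addBlob(plane, pts[s, ], spotSigmaPx, 1)
    }
    # bright extranuclear artifacts and faint in-nucleus precipitation
    nArt <- stats::rpois(1, artifactDensity)
    for (a in seq_len(nArt)) {
      for (try in seq_len(200L)) {
        cand <- c(stats::runif(1, 5, H - 5), stats::runif(1, 5, W - 5))
        if (!mask[round(cand[1L]), round(cand[2L])]) {
          plane <- addBlob(plane, cand, 2.5, 1)
          break
        }
      }
    }
    nPrec <- stats::rpois(1, artifactDensity)
    for (a in seq_len(nPrec)) {
      i <- sample.int(nNuclei, 1L)
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- sqrt(stats::runif(1)) * 0.72 * radiusPx
      plane <- addBlob(plane, centers[i, ] + rad * c(cos(ang), sin(ang)),
                       1.5, 0.06)
    }
    bestPlanes[[ch]] <- pmin(plane, 1)
    planted[[ch]] <- list(count = total, centers = spotCenters)
  }

  best <- as.integer(ceiling(depth / 2))
  channels <- lapply(bestPlanes, function(p) {
    arr <- array(0, c(H, W, depth))
    for (z in seq_len(depth)) {
      pz <- if (z == best) p else .gblurMat(p, 1.2 * abs(z - best))
      if (noiseSd > 0) pz <- pz + matrix(stats::rnorm(H * W, 0, noiseSd), H, W)
      arr[, , z] <- pmin(pmax(pz, 0), 1)
    }
    arr
  })

  stack <- ImageStack(channels, pixelSizeUm = pixelSizeUm, zStepUm = zStepUm)
  truth <- list(mask = mask,
                counts = vapply(planted, function(x) x$count, 0L),
                spotCenters = lapply(planted, function(x) x$centers),
                copies = copiesPerChannel, centers = centers,
                geometry = geometry, bestPlane = best)
  list(stack = stack, truth = truth)
}
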