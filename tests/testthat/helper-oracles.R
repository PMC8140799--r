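# Independent oracles used to cross-check the package's closed forms and
# algorithms. These deliberately take a different computational route than
# the implementation (numeric quadrature, brute-force scans).

# slab-sphere intersection volume by numeric quadrature of the disc area
slabSphereOracle <- function(r, h, d) {
  lo <- min(d, r); hi <- min(d + h, r)
  if (lo >= hi) return(0)
  stats::integrate(function(z) pi * (r^2 - z^2), lo, hi,
                   rel.tol = 1e-12)$value
}

# expected segment volume under d ~ Uniform(0, L), by quadrature
uniformOffsetOracle <- function(r, h, L) {
  stats::integrate(Vectorize(function(d) slabSphereOracle(r, h, d)), 0, L,
                   rel.tol = 1e-10)$value / L
}

# homogeneous Poisson point-process log-likelihood maximiser (numeric)
pppMleOracle <- function(spots, areas) {
  ll <- function(lam) sum(stats::dpois(spots, lam * areas, log = TRUE))
  stats::optimize(ll, c(1e-9, max(sum(spots) / sum(areas) * 5, 1)),
                  maximum = TRUE, tol = 1e-10)$maximum
}

# Intermodes threshold, re-derived from its definition with an explicit
# convolution and a separate peak scan (ends may be peaks)
intermodesOracle <- function(counts, maxIter = 10000L) {
  y <- as.numeric(counts)
  n <- length(y)
  nPeaks <- function(v) {
    padded <- c(-Inf, v, -Inf)
    sum(vapply(seq_len(n), function(i)
      padded[i + 1] > padded[i] && padded[i + 1] >= padded[i + 2] &&
        padded[i + 1] > 0, NA))
  }
  iter <- 0L
  repeat {
    k <- nPeaks(y)
    if (k == 2L) break
    if (k < 2L || iter >= maxIter) return(NA_integer_)
    y2 <- numeric(n)
    for (i in seq_len(n)) {
      lo <- max(1L, i - 1L); hi <- min(n, i + 1L)
      # replicate ends: window always spans three samples
      w <- c(y[lo], y[i], y[hi])
      if (i == 1L) w <- c(y[1L], y[1L], y[2L])
      if (i == n) w <- c(y[n - 1L], y[n], y[n])
      y2[i] <- mean(w)
    }
    y <- y2
    iter <- iter + 1L
  }
  padded <- c(-Inf, y, -Inf)
  pk <- which(vapply(seq_len(n), function(i)
    padded[i + 1] > padded[i] && padded[i + 1] >= padded[i + 2] &&
      padded[i + 1] > 0, NA))
  as.integer(floor(mean(pk)))
}

# Renyi-entropy threshold by brute force: recompute both class entropies
# from scratch for every candidate split
renyiOracle <- function(counts, alpha = 2) {
  p <- counts / sum(counts)
  n <- length(p)
  ent <- function(q) {
    q <- q[q > 0]
    if (abs(alpha - 1) < 1e-9) -sum(q * log(q))
    else log(sum(q^alpha)) / (1 - alpha)
  }
  best <- -Inf; bestT <- NA_integer_
  for (t in 1:(n - 1)) {
    Pb <- sum(p[1:t])
    if (Pb < 1e-12 || Pb > 1 - 1e-12) next
    v <- ent(p[1:t] / Pb) + ent(p[(t + 1):n] / (1 - Pb))
    if (v > best) { best <- v; bestT <- t }
  }
  bestT
}

# a reproducible bimodal test histogram: two Gaussian-shaped modes
bimodalHistogram <- function(mu1, mu2, sd1 = 8, sd2 = 12, w = 0.7,
                             nBins = 256L) {
  x <- seq_len(nBins)
  round(1e4 * (w * exp(-(x - mu1)^2 / (2 * sd1^2)) +
               (1 - w) * exp(-(x - mu2)^2 / (2 * sd2^2))))
}
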