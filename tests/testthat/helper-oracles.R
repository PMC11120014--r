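# Shared helpers: naive reference oracles kept deliberately independent of
# the package implementation (plain double loops, no vectorized shortcuts).

# Haralick statistics by exhaustive double loop over all GLCM cells,
# 0-based indices; HaralickCorrelation in the ITK marginal-frequency
# convention (see the package docs).
naiveHaralick <- function(m) {
  G <- nrow(m)
  energy <- 0; entropy <- 0; inertia <- 0; idm <- 0; sij <- 0
  px <- numeric(G)
  for (i in 1:G) for (j in 1:G) px[i] <- px[i] + m[i, j]
  mu <- 0
  for (i in 1:G) mu <- mu + (i - 1) * px[i]
  sig2 <- 0; sumP2 <- 0
  for (i in 1:G) {
    sig2 <- sig2 + (i - 1 - mu)^2 * px[i]
    sumP2 <- sumP2 + px[i]^2
  }
  shade <- 0; prom <- 0
  for (i in 1:G) for (j in 1:G) {
    p <- m[i, j]
    energy <- energy + p^2
    if (p > 0) entropy <- entropy - p * log2(p)
    inertia <- inertia + ((i - 1) - (j - 1))^2 * p
    idm <- idm + p / (1 + ((i - 1) - (j - 1))^2)
    sij <- sij + (i - 1) * (j - 1) * p
    s <- (i - 1 - mu) + (j - 1 - mu)
    shade <- shade + s^3 * p
    prom <- prom + s^4 * p
  }
  mds <- 0
  for (i in 1:G) mds <- mds + (px[i] - 1 / G)^2
  mds <- mds / G
  c(ClusterProminence = prom, ClusterShade = shade,
    Correlation = if (sig2 > 1e-12) (sij - mu^2) / sig2 else 0,
    Energy = energy, Entropy = entropy,
    HaralickCorrelation = if (mds > 1e-12 / G) (sij - (1 / G)^2) / mds else 0,
    Inertia = inertia, InverseDifferenceMoment = idm)
}

# GLCM of a window by exhaustive pair enumeration (both orderings)
naiveGLCM <- function(q, offset, G) {
  d <- dim(q)
  m <- matrix(0, G, G)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    x2 <- x + offset[1]; y2 <- y + offset[2]; z2 <- z + offset[3]
    if (x2 >= 1 && x2 <= d[1] && y2 >= 1 && y2 <= d[2] &&
        z2 >= 1 && z2 <= d[3]) {
      a <- q[x, y, z] + 1L; b <- q[x2, y2, z2] + 1L
      m[a, b] <- m[a, b] + 1
      m[b, a] <- m[b, a] + 1
    }
  }
  if (sum(m) == 0) stop("no valid pairs")
  m / sum(m)
}

# replicate-padded window extraction around a (1-based) center
replWindow <- function(a, center, half) {
  d <- dim(a)
  ix <- pmin(pmax(center[1] + (-half):half, 1L), d[1])
  iy <- pmin(pmax(center[2] + (-half):half, 1L), d[2])
  iz <- pmin(pmax(center[3] + (-half):half, 1L), d[3])
  a[ix, iy, iz, drop = FALSE]
}

# per-voxel texture value by from-scratch recomputation at one voxel
naiveTextureAtVoxel <- function(q, voxel, G, window = 3L) {
  half <- window %/% 2L
  w <- replWindow(q, voxel, half)
  offs <- glcmOffsets(1L)
  acc <- numeric(8); nv <- 0L
  for (o in seq_len(nrow(offs))) {
    g <- tryCatch(naiveGLCM(w, offs[o, ], G), error = function(e) NULL)
    if (is.null(g)) next
    acc <- acc + naiveHaralick(g)
    nv <- nv + 1L
  }
  acc / nv
}

# tiny reduced architecture used across network tests
tinyConfig <- function(channels = 1L, fusion = "concat") {
  EnsembleConfig(inputChannels = channels, inputShape = c(8L, 8L, 8L),
                 cnnFilters = c(4L, 8L), cnnFeatureDim = 12L,
                 vitPatchEdge = 4L, vitDepth = 2L, vitDim = 8L,
                 vitHeads = 2L, fusion = fusion)
}

# balanced two-channel phantom inputs for training tests
cohortInputs <- function(nPerClass, seed, ...) {
  co <- makeCohort(nPerClass, seed = seed, ...)
  inp <- prepareEnsembleInputs(co$volumes)
  inp$masks <- co$masks
  inp
}

stackChannels <- function(ct, rad = NULL) {
  chans <- if (is.null(rad)) list(ct) else list(ct, rad)
  array(unlist(chans), c(dim(chans[[1]]), length(chans)))
}
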