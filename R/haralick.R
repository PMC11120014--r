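#' Quantize a scalar array into G equal-width gray levels
#'
#' Bins are equal-width over `range` (defaults to the array's own range)
#' with the boundary rule `bin = floor(G * (x - lo) / (hi - lo))` and
#' `x = hi` mapped to `G - 1`. Quantization is monotone; values outside the
#' range are clamped into the end bins. A constant array maps to all zeros.
#'
#' @param a numeric array.
#' @param G number of gray levels, >= 2.
#' @param range optional fixed (low, high) range.
#' @return integer array of the same shape with values in 0 .. G-1.
#' @examples
#' quantizeGrayLevels(c(0, 0.5, 1), G = 2)
#' @export
quantizeGrayLevels <- function(a, G, range = NULL) {
  G <- as.integer(G)
  if (G < 2L) stop("quantizeGrayLevels: G must be >= 2")
  if (any(!is.finite(a))) stop("quantizeGrayLevels: array contains NaN/Inf")
  if (is.null(range) || all(is.na(range))) range <- c(min(a), max(a))
  lo <- range[1]; hi <- range[2]
  d <- dim(a)
  if (hi <= lo) {
    q <- rep(0L, length(a))
  } else {
    q <- as.integer(floor(G * (as.numeric(a) - lo) / (hi - lo)))
    q[q < 0L] <- 0L
    q[q > G - 1L] <- G - 1L
  }
  if (!is.null(d)) dim(q) <- d
  q
}

#' Unique 3D co-occurrence offsets at a given distance
#'
#' The 13 unique direction vectors of the 26-neighbourhood (one per
#' antipodal pair, first nonzero component positive), scaled by `distance`.
#'
#' @param distance offset magnitude per axis component (default 1).
#' @return integer matrix, 13 x 3.
#' @export
glcmOffsets <- function(distance = 1L) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- apply(g, 1, function(d) {
    nz <- which(d != 0)
    length(nz) > 0 && d[nz[1]] > 0
  })
  m <- g[keep, , drop = FALSE]
  storage.mode(m) <- "integer"
  unname(m * as.integer(distance))
}

#' Gray-level co-occurrence matrix of one window
#'
#' Counts all voxel pairs (v, v + offset) with both ends inside the window,
#' accumulated symmetrically (both orderings) and normalized to sum 1.
#'
#' @param q integer array (a window), values in 0 .. G-1.
#' @param offset integer(3) displacement.
#' @param G number of gray levels.
#' @return G x G symmetric matrix summing to 1.
#' @export
glcmWindow <- function(q, offset, G) {
  d <- dim(q)
  stopifnot(length(d) == 3L, length(offset) == 3L)
  lo <- pmax(1L, 1L - offset)
  hi <- pmin(d, d - offset)
  if (any(hi < lo)) stop("glcmWindow: no valid pairs for this offset")
  src <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3]))
  dst <- sweep(src, 2, as.integer(offset), "+")
  a <- q[src]; b <- q[dst]
  cnt <- tabulate(a + G * b + 1L, nbins = G * G)
  m <- matrix(as.numeric(cnt), G, G)
  m <- m + t(m)
  m / sum(m)
}

#' The eight Haralick statistics of a GLCM
#'
#' With `p(i, j)` the normalized symmetric co-occurrence matrix over gray
#' levels `i, j = 0 .. G-1`, marginal `p_x`, marginal mean `mu` and variance
#' `sigma^2`:
#' \itemize{
#'   \item Energy = sum p^2
#'   \item Entropy = -sum p log2 p (0 log 0 = 0)
#'   \item Inertia = sum (i - j)^2 p
#'   \item InverseDifferenceMoment = sum p / (1 + (i - j)^2)
#'   \item Correlation = sum (i - mu)(j - mu) p / sigma^2
#'   \item ClusterShade = sum ((i - mu) + (j - mu))^3 p
#'   \item ClusterProminence = sum ((i - mu) + (j - mu))^4 p
#'   \item HaralickCorrelation = (sum i j p - mu_t^2) / sigma_t^2
#' }
#' HaralickCorrelation follows the ITK texture-feature convention, in which
#' `mu_t` and `sigma_t^2` are the mean and population variance of the
#' values of the marginal distribution `p_x` across its G bins (so
#' `mu_t = 1/G`). With index-based marginal moments the statistic would
#' collapse onto Correlation for every symmetric GLCM; the ITK convention
#' keeps the two maps distinct. Degenerate denominators (constant window
#' for Correlation, uniform marginal for HaralickCorrelation) return 0.
#'
#' @param m GLCM: square nonnegative matrix normalized to sum 1.
#' @return named numeric(8) in [HARALICK_FEATURES] order.
#' @export
haralickFeatures <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("haralickFeatures: GLCM must be square")
  if (any(m < 0)) stop("haralickFeatures: GLCM entries must be >= 0")
  if (abs(sum(m) - 1) > 1e-8) stop("haralickFeatures: GLCM is not normalized")
  G <- nrow(m)
  iv <- 0:(G - 1)
  D <- outer(iv, iv, "-")
  px <- rowSums(m)
  mu <- sum(iv * px)
  sig2 <- sum((iv - mu)^2 * px)
  sij <- sum(outer(iv, iv) * m)
  S <- outer(iv - mu, iv - mu, "+")
  pp <- m[m > 0]
  mds <- (sum(px^2) - 1 / G) / G
  c(ClusterProminence = sum(S^4 * m),
    ClusterShade = sum(S^3 * m),
    Correlation = if (sig2 > 1e-12) (sij - mu^2) / sig2 else 0,
    Energy = sum(m^2),
    Entropy = -sum(pp * log2(pp)),
    HaralickCorrelation = if (mds > 1e-12 / G) (sij - (1 / G)^2) / mds else 0,
    Inertia = sum(D^2 * m),
    InverseDifferenceMoment = sum(m / (1 + D^2)))
}

# replicate-padded extraction of the window centered at (x, y, z), 1-based
.extract_window <- function(a, center, half) {
  d <- dim(a)
  ix <- pmin(pmax(center[1] + (-half):half, 1L), d[1])
  iy <- pmin(pmax(center[2] + (-half):half, 1L), d[2])
  iz <- pmin(pmax(center[3] + (-half):half, 1L), d[3])
  a[ix, iy, iz, drop = FALSE]
}

#' Per-voxel Haralick texture maps
#'
#' For every voxel, the eight Haralick statistics are computed from the
#' GLCM of the centered `window^3` neighbourhood for each of the 13 unique
#' 3D offset directions at the configured distance, then averaged across
#' directions to yield one map per feature. Borders are handled by edge
#' replication, so maps are full-size. Gray levels are quantized once per
#' volume by default (`perWindowQuantize = TRUE` switches to the slow
#' per-window reference mode).
#'
#' @param v a [CTVolume] or 3D numeric array.
#' @param spec a [TextureSpec].
#' @return a [TextureMapSet].
#' @examples
#' v <- array(rnorm(6 * 6 * 6), c(6, 6, 6))
#' tm <- textureMaps(v, TextureSpec(grayLevels = 8))
#' range(textureMapList(tm)$Energy)
#' @export
textureMaps <- function(v, spec = TextureSpec()) {
  a <- if (is(v, "CTVolume")) v@voxels else v
  stopifnot(length(dim(a)) == 3L)
  validObject(spec)
  if (any(dim(a) < spec@window))
    stop("textureMaps: volume smaller than the texture window")
  offs <- glcmOffsets(spec@offsetDistance)
  G <- spec@grayLevels
  if (!spec@perWindowQuantize) {
    q <- quantizeGrayLevels(a, G, range = spec@quantizeRange)
    maps <- texture_maps_cpp(q, G, spec@window, offs)
  } else {
    d <- dim(a)
    half <- spec@window %/% 2L
    maps <- lapply(HARALICK_FEATURES, function(f) array(0, d))
    names(maps) <- HARALICK_FEATURES
    for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
      w <- .extract_window(a, c(x, y, z), half)
      qw <- quantizeGrayLevels(w, G)
      acc <- numeric(8); nval <- 0L
      for (o in seq_len(nrow(offs))) {
        g <- tryCatch(glcmWindow(qw, offs[o, ], G), error = function(e) NULL)
        if (is.null(g)) next
        acc <- acc + haralickFeatures(g)
        nval <- nval + 1L
      }
      for (f in seq_along(maps)) maps[[f]][x, y, z] <- acc[f] / nval
    }
  }
  TextureMapSet(maps = maps[HARALICK_FEATURES], spec = spec)
}
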