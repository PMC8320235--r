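#' @useDynLib epilink, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Assemble per-segment sampler arrays for the C++ kernel. The first
## segment's orientation bounds come from the epitope (phi1/theta1), all
## later segments kink relative to their predecessor.
.chainArgs <- function(chain, epitope) {
  segs <- chain@segments
  nseg <- length(segs)
  lenType <- integer(nseg)
  lenValues <- vector("list", nseg)
  phiLo <- phiHi <- thetaLo <- thetaHi <- numeric(nseg)
  for (i in seq_len(nseg)) {
    s <- segs[[i]]
    lenType[i] <- if (s@lenType == "set") 0L else 1L
    lenValues[[i]] <- s@lenValues
    if (i == 1L) {
      phiLo[i] <- epitope@phi1Bounds[1]; phiHi[i] <- epitope@phi1Bounds[2]
      thetaLo[i] <- epitope@theta1Bounds[1]; thetaHi[i] <- epitope@theta1Bounds[2]
    } else {
      phiLo[i] <- s@phiBounds[1]; phiHi[i] <- s@phiBounds[2]
      thetaLo[i] <- s@thetaBounds[1]; thetaHi[i] <- s@thetaBounds[2]
    }
  }
  list(nseg = nseg, lenType = lenType, lenValues = lenValues,
       phiLo = phiLo, phiHi = phiHi, thetaLo = thetaLo, thetaHi = thetaHi)
}

#' Propose and evaluate antibody conformations
#'
#' Draws `n` kinked-chain conformations (lengths and kink angles uniform
#' within their configured bounds) anchored at the epitope and evaluates
#' the steric predicate for each: all chain vertices must lie outside the
#' epitope radius and all point pairs on non-sequential segments must be
#' farther apart than `dMin`. Unlike [simulateBatch()], rejected proposals
#' are retained, which makes the proposal stream inspectable.
#'
#' @param chain A [ChainModel-class].
#' @param epitope An [EpitopeGeometry-class].
#' @param mt A [MicrotubuleGeometry-class] (radius recorded; the steric
#'   wall acts at the epitope radius).
#' @param n Number of proposals.
#' @param seed Optional integer seed (applied via [set.seed()]).
#' @param steric If `FALSE`, disable both wall and clash tests (all
#'   proposals accepted).
#' @param keepVertices Retain all chain vertices.
#' @return List with `endpoints` (n x 3), `accepted` (logical), `angles`,
#'   `lengths` and optionally `vertices`.
#' @export
proposeConformations <- function(chain, epitope, mt = MicrotubuleGeometry(),
                                 n, seed = NULL, steric = TRUE,
                                 keepVertices = FALSE) {
  stopifnot(is(chain, "ChainModel"), is(epitope, "EpitopeGeometry"),
            is(mt, "MicrotubuleGeometry"), n > 0)
  validObject(chain); validObject(epitope); validObject(mt)
  if (sqrt(epitope@y0^2 + epitope@z0^2) < mt@outerRadius - 1e-9)
    stop("epitope lies inside the microtubule")
  if (!is.null(seed)) set.seed(seed)
  a <- .chainArgs(chain, epitope)
  U <- matrix(stats::runif(n * 3L * a$nseg), nrow = n)
  chain_eval_cpp(U, a$lenValues, a$lenType, a$phiLo, a$phiHi,
                 a$thetaLo, a$thetaHi, epitope@y0, epitope@z0,
                 chain@dMin, chain@arcRes, steric, steric, keepVertices)
}

#' Sample a single conformation
#'
#' Draws one conformation and returns its vertices together with the
#' outcome of the steric test.
#'
#' @inheritParams proposeConformations
#' @return List with `accepted` (logical) and `vertices` (a
#'   (nseg+1) x 3 matrix starting at the epitope).
#' @export
sampleConformation <- function(chain, epitope, mt = MicrotubuleGeometry(),
                               seed = NULL, steric = TRUE) {
  p <- proposeConformations(chain, epitope, mt, n = 1L, seed = seed,
                            steric = steric, keepVertices = TRUE)
  v <- matrix(p$vertices[1L, ], ncol = 3L, byrow = TRUE)
  colnames(v) <- c("x", "y", "z")
  list(accepted = p$accepted[1L], vertices = v)
}

#' Simulate a batch of accepted antibody conformations
#'
#' Rejection-samples conformations until `nTarget` have been accepted.
#' Proposals are drawn in deterministic chunks from a single seeded RNG
#' stream, so a given (model, seed) pair always yields the same batch.
#'
#' @inheritParams proposeConformations
#' @param nTarget Number of accepted conformations required.
#' @param seed Integer seed; recorded in the result.
#' @param minAcceptance Abort if the running acceptance rate falls below
#'   this floor (guards against impossible configurations).
#' @param chunkSize Proposals per chunk (default `max(nTarget, 1e4)`).
#' @return A [ConformationBatch-class].
#' @export
simulateBatch <- function(chain, epitope, mt = MicrotubuleGeometry(),
                          nTarget, seed = 1L, steric = TRUE,
                          keepVertices = FALSE, minAcceptance = 1e-4,
                          chunkSize = NULL) {
  stopifnot(nTarget > 0)
  if (is.null(chunkSize)) chunkSize <- max(nTarget, 1e4)
  set.seed(seed)
  a <- .chainArgs(chain, epitope)
  if (sqrt(epitope@y0^2 + epitope@z0^2) < mt@outerRadius - 1e-9)
    stop("epitope lies inside the microtubule")
  eps <- matrix(numeric(0), 0, 3)
  verts <- NULL
  nAcc <- 0; nAtt <- 0
  repeat {
    U <- matrix(stats::runif(chunkSize * 3L * a$nseg), nrow = chunkSize)
    res <- chain_eval_cpp(U, a$lenValues, a$lenType, a$phiLo, a$phiHi,
                          a$thetaLo, a$thetaHi, epitope@y0, epitope@z0,
                          chain@dMin, chain@arcRes, steric, steric,
                          keepVertices)
    acc <- which(res$accepted)
    if (nAcc + length(acc) >= nTarget) {
      need <- nTarget - nAcc
      take <- acc[seq_len(need)]
      nAtt <- nAtt + take[need]        # attempts up to the last acceptance
      eps <- rbind(eps, res$endpoints[take, , drop = FALSE])
      if (keepVertices)
        verts <- rbind(verts, res$vertices[take, , drop = FALSE])
      nAcc <- nTarget
      break
    }
    nAcc <- nAcc + length(acc)
    nAtt <- nAtt + chunkSize
    eps <- rbind(eps, res$endpoints[acc, , drop = FALSE])
    if (keepVertices)
      verts <- rbind(verts, res$vertices[acc, , drop = FALSE])
    if (nAtt >= 10 * chunkSize && nAcc / nAtt < minAcceptance)
      stop(sprintf(paste0("acceptance rate %.2e below floor %.1e after %d ",
                          "attempts; check angle bounds and dMin"),
                   nAcc / nAtt, minAcceptance, nAtt))
    if (nAcc == 0 && nAtt >= 100 * chunkSize)
      stop("no conformation accepted; configuration admits none")
  }
  colnames(eps) <- c("x", "y", "z")
  new("ConformationBatch", endpoints = eps,
      vertices = if (keepVertices) verts else matrix(numeric(0), 0, 0),
      nAttempted = nAtt, nAccepted = nAcc, seed = as.numeric(seed))
}

## Peak and fwhm of a binned density; 3-bin moving-average smoothing,
## fwhm by linear interpolation of the half-maximum crossings.
.peakFwhm <- function(mids, dens, smooth = TRUE) {
  d <- dens
  if (smooth && length(d) >= 3)
    d <- stats::filter(dens, rep(1 / 3, 3), sides = 2) |> as.numeric()
  d[is.na(d)] <- dens[is.na(d)]
  ipk <- which.max(d)
  peak <- mids[ipk]
  half <- d[ipk] / 2
  left <- NA_real_; right <- NA_real_
  if (ipk > 1) {
    i <- max(which(d[seq_len(ipk - 1)] < half), -Inf)
    if (is.finite(i))
      left <- mids[i] + (half - d[i]) / (d[i + 1] - d[i]) * (mids[i + 1] - mids[i])
  }
  if (is.na(left)) left <- mids[1]
  if (ipk < length(d)) {
    js <- which(d[(ipk + 1):length(d)] < half)
    if (length(js)) {
      j <- ipk + js[1]
      right <- mids[j - 1] + (d[j - 1] - half) / (d[j - 1] - d[j]) * (mids[j] - mids[j - 1])
    }
  }
  if (is.na(right)) right <- mids[length(d)]
  c(peak = peak, fwhm = right - left)
}

#' Radial distribution of reporter positions
#'
#' Histograms the radial distance sqrt(y^2 + z^2) of batch endpoints from
#' the microtubule center and locates peak and fwhm on the smoothed
#' histogram.
#'
#' @param batch A [ConformationBatch-class], or a numeric vector of radii.
#' @param binWidth Bin width, nm.
#' @param smooth Apply 3-bin moving-average smoothing before locating the
#'   peak and half-maximum crossings.
#' @return A [RadialDistribution-class].
#' @export
radialDistribution <- function(batch, binWidth = 0.5, smooth = TRUE) {
  r <- if (is(batch, "ConformationBatch")) {
    if (nrow(batch@endpoints) == 0) stop("empty batch")
    sqrt(batch@endpoints[, 2]^2 + batch@endpoints[, 3]^2)
  } else as.numeric(batch)
  if (!length(r)) stop("empty batch")
  edges <- seq(floor(min(r) / binWidth) * binWidth,
               ceiling(max(r) / binWidth) * binWidth + binWidth,
               by = binWidth)
  h <- graphics::hist(r, breaks = edges, plot = FALSE)
  dens <- h$counts / sum(h$counts)
  pf <- .peakFwhm(h$mids, dens, smooth = smooth)
  new("RadialDistribution", binEdges = edges, density = dens,
      peak = unname(pf["peak"]), fwhm = unname(pf["fwhm"]))
}

#' 2D density map of reporter positions
#'
#' Bins batch endpoints in (y, z) on a square grid (default 1.25 nm) and
#' optionally refines the map by bilinear interpolation.
#'
#' @param batch A [ConformationBatch-class].
#' @param bin Bin width, nm.
#' @param interpolate Integer refinement factor (1 = raw histogram).
#' @return List with `y`, `z` (cell centers) and `values` (density, sums
#'   to 1 times no. of cells scale; mass normalized to 1).
#' @export
densityMap <- function(batch, bin = 1.25, interpolate = 1L) {
  stopifnot(is(batch, "ConformationBatch"))
  if (nrow(batch@endpoints) == 0) stop("empty batch")
  y <- batch@endpoints[, 2]; z <- batch@endpoints[, 3]
  ## square grid symmetric about the microtubule center
  E <- ceiling(max(abs(c(y, z))) / bin) * bin + bin
  ey <- seq(-E, E, by = bin)
  ez <- ey
  iy <- findInterval(y, ey, rightmost.closed = TRUE)
  iz <- findInterval(z, ez, rightmost.closed = TRUE)
  nb <- length(ey) - 1
  M <- matrix(tabulate((iz - 1) * nb + iy, nbins = nb * nb), nb, nb)
  M <- M / sum(M)
  ymid <- ey[-length(ey)] + bin / 2
  zmid <- ez[-length(ez)] + bin / 2
  if (interpolate > 1L) {
    fy <- seq(ymid[1], ymid[length(ymid)], length.out = interpolate * (length(ymid) - 1) + 1)
    fz <- seq(zmid[1], zmid[length(zmid)], length.out = interpolate * (length(zmid) - 1) + 1)
    M <- .bilinear(ymid, zmid, M, fy, fz)
    M <- M / sum(M)
    ymid <- fy; zmid <- fz
  }
  list(y = ymid, z = zmid, values = M)
}

## bilinear interpolation of matrix V (x by y) onto xo, yo grids
.bilinear <- function(x, y, V, xo, yo) {
  ix <- findInterval(xo, x, all.inside = TRUE)
  iy <- findInterval(yo, y, all.inside = TRUE)
  tx <- (xo - x[ix]) / (x[ix + 1] - x[ix])
  ty <- (yo - y[iy]) / (y[iy + 1] - y[iy])
  V00 <- V[ix, iy, drop = FALSE]; V10 <- V[ix + 1, iy, drop = FALSE]
  V01 <- V[ix, iy + 1, drop = FALSE]; V11 <- V[ix + 1, iy + 1, drop = FALSE]
  (1 - tx) %o% (1 - ty) * V00 + tx %o% (1 - ty) * V10 +
    (1 - tx) %o% ty * V01 + tx %o% ty * V11
}

#' Revolve a radial density and convolve with a blur kernel
#'
#' Distributes each radial bin's mass uniformly over its annulus on a 2D
#' grid (the "revolved" cross-section image) and convolves the image with
#' a normalized kernel, e.g. a [CompoundKernel-class] describing the
#' localization-precision and drift blur. Total mass is preserved.
#'
#' @param dist A [RadialDistribution-class].
#' @param kernel A [CompoundKernel-class], or `NULL` for no blur.
#' @param spacing Output grid spacing, nm (defaults to the kernel's).
#' @param extent Half-width of the output grid, nm.
#' @param oversample Sub-samples per cell edge when painting the annuli.
#' @return List with `y`, `z`, `values` (image mass per cell).
#' @export
revolveConvolve <- function(dist, kernel = NULL, spacing = NULL,
                            extent = NULL, oversample = 4L) {
  stopifnot(is(dist, "RadialDistribution"))
  if (is.null(spacing))
    spacing <- if (is.null(kernel)) 2 else kernel@spacing
  if (!is.null(kernel) && abs(kernel@spacing - spacing) > 1e-9)
    stop("kernel grid spacing does not match the image grid")
  if (is.null(extent)) {
    extent <- max(dist@binEdges)
    if (!is.null(kernel)) extent <- extent + max(abs(kernel@yGrid))
    extent <- ceiling(extent / spacing) * spacing
  }
  centers <- seq(-extent, extent, by = spacing)
  nc <- length(centers)
  ## radial mass profile per unit radius, interpolated between bin centers
  mids <- dist@binEdges[-length(dist@binEdges)] + diff(dist@binEdges) / 2
  bw <- diff(dist@binEdges)
  prof <- if (length(mids) >= 2)
    stats::approxfun(mids, dist@density / bw, yleft = 0, yright = 0)
  else
    function(r) ifelse(r >= dist@binEdges[1] & r < dist@binEdges[2],
                       dist@density / bw, 0)
  ## paint f(y,z) = p(rho)/(2 pi rho) with sub-cell sampling
  os <- max(1L, as.integer(oversample))
  sub <- (seq_len(os) - 0.5) / os - 0.5
  img <- matrix(0, nc, nc)
  for (dyi in seq_along(sub)) {
    for (dzi in seq_along(sub)) {
      yy <- centers + sub[dyi] * spacing
      zz <- centers + sub[dzi] * spacing
      rho <- sqrt(outer(yy^2, zz^2, "+"))
      val <- prof(rho) / (2 * pi * pmax(rho, spacing / (2 * os)))
      img <- img + val
    }
  }
  img <- img * spacing^2 / os^2
  img <- img / sum(img)      # exact unit mass on the grid
  if (!is.null(kernel)) img <- .conv2same(img, kernel@values)
  list(y = centers, z = centers, values = img)
}

## 2D 'same' convolution via FFT zero-padding; mass-preserving for a
## normalized kernel.
.conv2same <- function(A, K) {
  na <- dim(A); nk <- dim(K)
  n1 <- na[1] + nk[1] - 1; n2 <- na[2] + nk[2] - 1
  Ap <- matrix(0, n1, n2); Kp <- matrix(0, n1, n2)
  Ap[seq_len(na[1]), seq_len(na[2])] <- A
  Kp[seq_len(nk[1]), seq_len(nk[2])] <- K
  Cf <- stats::fft(stats::fft(Ap) * stats::fft(Kp), inverse = TRUE) / (n1 * n2)
  C <- Re(Cf)
  i0 <- (nk[1] - 1) %/% 2; j0 <- (nk[2] - 1) %/% 2
  C[i0 + seq_len(na[1]), j0 + seq_len(na[2])]
}

#' Normalized residual map between a simulated and an experimental image
#'
#' Rescales the simulated image by an affine least-squares match
#' (scale and offset) to the experimental image and returns the
#' difference normalized by the maximum of the rescaled image.
#'
#' @param sim,exp Numeric matrices on identical grids.
#' @return List with `residuals`, `scale` (a), `offset` (b); residuals
#'   are (exp - (a sim + b)) / max(a sim + b).
#' @export
residualMap <- function(sim, exp) {
  if (!all(dim(sim) == dim(exp))) stop("images must share a grid")
  s <- as.numeric(sim); e <- as.numeric(exp)
  if (stats::sd(s) == 0) stop("simulated image is constant; affine match is degenerate")
  ## normal equations for e ~ a s + b
  a <- stats::cov(s, e) / stats::var(s)
  b <- mean(e) - a * mean(s)
  fit <- a * sim + b
  m <- max(fit)
  if (m == 0) stop("rescaled image has zero maximum")
  list(residuals = (exp - fit) / m, scale = a, offset = b)
}
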