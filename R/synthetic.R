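#' Scene configuration for the synthetic localization generator
#'
#' Builds and validates the configuration of a synthetic SMLM scene:
#' straight (or gently curved) microtubule axes decorated with labels on
#' a Gaussian shell, each label blinking several times, each blink
#' localized with anisotropic precision drawn from a lognormal CRLB
#' model, plus residual drift jitter.
#'
#' @param mtAxes List of axes; each a list with `p0`, `p1` 3-vectors in
#'   nm (and optionally `curvatureRadius`, nm, for a circular arc).
#' @param shellR0 True shell radius, nm.
#' @param shellW0 True shell thickness fwhm, nm (radial Gaussian sigma =
#'   shellW0 / 2.35).
#' @param labelsPerMicron Mean number of labels per micron of axis.
#' @param blinksMean Mean blinks per label (geometric, minimum 1).
#' @param crlbMedianYZ,crlbMedianZ Median lateral / axial localization
#'   precision, nm.
#' @param crlbSpread Lognormal sdlog of the precision distributions.
#' @param driftSigma Residual drift jitter c(sigma_y, sigma_z), nm.
#' @return Validated configuration list of class `sceneConfig`.
#' @export
sceneConfig <- function(mtAxes = list(list(p0 = c(0, 0, 0),
                                           p1 = c(5000, 0, 0))),
                        shellR0 = 20, shellW0 = 10,
                        labelsPerMicron = 500, blinksMean = 6,
                        crlbMedianYZ = 6, crlbMedianZ = 12,
                        crlbSpread = 0.25, driftSigma = c(0, 0)) {
  stopifnot(shellR0 >= 0, shellW0 >= 0, labelsPerMicron > 0,
            blinksMean >= 1, crlbMedianYZ > 0, crlbMedianZ > 0,
            crlbSpread >= 0, all(driftSigma >= 0), length(mtAxes) >= 1)
  for (ax in mtAxes) {
    if (is.null(ax$p0) || is.null(ax$p1) || length(ax$p0) != 3 ||
        length(ax$p1) != 3)
      stop("each axis needs 3D endpoints p0 and p1")
    if (sum((ax$p1 - ax$p0)^2) <= 0) stop("axis endpoints coincide")
  }
  structure(list(mtAxes = mtAxes, shellR0 = shellR0, shellW0 = shellW0,
                 labelsPerMicron = labelsPerMicron, blinksMean = blinksMean,
                 crlbMedianYZ = crlbMedianYZ, crlbMedianZ = crlbMedianZ,
                 crlbSpread = crlbSpread, driftSigma = driftSigma),
            class = "sceneConfig")
}

#' Generate a synthetic localization scene with ground truth
#'
#' Places labels along each microtubule axis at Poisson axial spacing,
#' drawn uniformly per unit cross-section area from the configured
#' Gaussian-ring shell density exp(-(rho - r0)^2 / (2 sigma0^2)) (the
#' same form [fitRing()] fits); each label emits a geometric number of
#' blinks; each
#' blink is displaced by anisotropic Gaussian localization noise with
#' per-localization sigmas drawn from the lognormal CRLB model, plus
#' residual drift jitter. ROI lines subdivide each axis into ~250 nm
#' sections.
#'
#' @param config A [sceneConfig()].
#' @param seed Integer RNG seed.
#' @param roiLength Length of the ROI subdivision, nm (default 250).
#' @return List with `locs` (localization data.frame), `rois` (ROI
#'   data.frame), and `truth` (labels, per-localization parent index,
#'   true r0/w0, axes, seed).
#' @export
makeScene <- function(config, seed = 1L, roiLength = 250) {
  stopifnot(inherits(config, "sceneConfig"))
  set.seed(seed)
  sigma0 <- config$shellW0 / 2.35
  labList <- list(); locList <- list(); roiList <- list()
  parent <- integer(0)
  labelOffset <- 0L
  for (ai in seq_along(config$mtAxes)) {
    ax <- config$mtAxes[[ai]]
    p0 <- as.numeric(ax$p0); p1 <- as.numeric(ax$p1)
    v <- p1 - p0; L <- sqrt(sum(v^2)); u <- v / L
    e <- .perpBasis(u)
    nLab <- stats::rpois(1, config$labelsPerMicron * L / 1000)
    if (nLab == 0) next
    t <- stats::runif(nLab, 0, L)
    phi <- stats::runif(nLab, 0, 2 * pi)
    rad <- .sampleRingRadius(nLab, config$shellR0, sigma0)
    pos <- sweep(outer(t, u), 2, p0, "+") +
      outer(rad * cos(phi), e$e1) + outer(rad * sin(phi), e$e2)
    labList[[ai]] <- data.frame(axis = ai, x = pos[, 1], y = pos[, 2],
                                z = pos[, 3], t = t, r = rad)
    ## blinks
    pgeo <- 1 / config$blinksMean
    k <- stats::rgeom(nLab, pgeo) + 1L
    idx <- rep(seq_len(nLab), k)
    n <- length(idx)
    syz <- stats::rlnorm(n, log(config$crlbMedianYZ), config$crlbSpread)
    sz <- stats::rlnorm(n, log(config$crlbMedianZ), config$crlbSpread)
    noise <- cbind(stats::rnorm(n, 0, syz), stats::rnorm(n, 0, syz),
                   stats::rnorm(n, 0, sz))
    drift <- cbind(0, stats::rnorm(n, 0, config$driftSigma[1]),
                   stats::rnorm(n, 0, config$driftSigma[2]))
    ## drift jitter acts in the lab frame (y lateral, z optical); the
    ## synthetic axes are near the lab x-axis so this matches the
    ## cross-section frame to first order
    xyz <- pos[idx, , drop = FALSE] + noise + drift
    locList[[ai]] <- data.frame(
      frame = seq_len(n), x_nm = xyz[, 1], y_nm = xyz[, 2], z_nm = xyz[, 3],
      sigma_x_nm = syz, sigma_y_nm = syz, sigma_z_nm = sz)
    parent <- c(parent, labelOffset + idx)
    labelOffset <- labelOffset + nLab
    ## ROI subdivision
    nRoi <- max(1L, floor(L / roiLength))
    starts <- (seq_len(nRoi) - 1) * (L / nRoi)
    ends <- seq_len(nRoi) * (L / nRoi)
    roiList[[ai]] <- data.frame(
      roi_id = paste0("ax", ai, "_s", seq_len(nRoi)),
      x0 = p0[1] + starts * u[1], y0 = p0[2] + starts * u[2],
      z0 = p0[3] + starts * u[3],
      x1 = p0[1] + ends * u[1], y1 = p0[2] + ends * u[2],
      z1 = p0[3] + ends * u[3])
  }
  if (!length(locList)) stop("scene produced no localizations")
  locs <- do.call(rbind, locList)
  locs$frame <- seq_len(nrow(locs))
  rownames(locs) <- NULL
  list(locs = locs,
       rois = do.call(rbind, roiList),
       truth = list(labels = do.call(rbind, labList), parent = parent,
                    r0 = config$shellR0, w0 = config$shellW0,
                    axes = config$mtAxes, seed = seed))
}

## Radial distances of points drawn uniformly (per unit area) from the
## 2D Gaussian-ring density exp(-(rho - r0)^2 / (2 sigma0^2)): the radial
## mass density is rho-weighted, sampled by rejection from N(r0, sigma0).
## This matches the ring model fitted by fitRing().
.sampleRingRadius <- function(n, r0, sigma0) {
  if (sigma0 <= 0) return(rep(r0, n))
  out <- numeric(0)
  M <- r0 + 5 * sigma0
  while (length(out) < n) {
    m <- ceiling((n - length(out)) * 2.5) + 10L
    cand <- stats::rnorm(m, r0, sigma0)
    cand <- cand[cand > 0]
    keep <- stats::runif(length(cand)) < cand / M
    out <- c(out, cand[keep])
  }
  out[seq_len(n)]
}

#' Small chain fixtures with known endpoint distributions
#'
#' Returns tiny chain/epitope configurations whose endpoint
#' distributions have closed forms or cheap enumeration oracles:
#' \describe{
#'   \item{single-rod}{One 10 nm segment, free angles, no wall.}
#'   \item{fixed-angles}{Two segments with degenerate angle intervals; a
#'     deterministic endpoint.}
#'   \item{two-rod-free}{Two free segments (8 and 5 nm), no steric
#'     rules.}
#' }
#'
#' @param name Fixture name.
#' @return List with `chain`, `epitope`, `mt`.
#' @export
makeMcFixture <- function(name = c("single-rod", "fixed-angles",
                                   "two-rod-free")) {
  name <- match.arg(name)
  mt <- MicrotubuleGeometry(12.5)
  ep <- EpitopeGeometry(y0 = 0, z0 = 12.5,
                        phi1Bounds = c(-pi, pi), theta1Bounds = c(-pi, pi))
  chain <- switch(name,
    "single-rod" = ChainModel(list(
      SegmentSpec("rod", lengths = 10))),
    "fixed-angles" = {
      ep <- EpitopeGeometry(y0 = 0, z0 = 12.5,
                            phi1Bounds = c(pi / 6, pi / 6),
                            theta1Bounds = c(0, 0))
      ChainModel(list(
        SegmentSpec("a", lengths = 6, phiBounds = c(pi / 4, pi / 4),
                    thetaBounds = c(0, 0)),
        SegmentSpec("b", lengths = 4, phiBounds = c(-pi / 3, -pi / 3),
                    thetaBounds = c(pi / 5, pi / 5))))
    },
    "two-rod-free" = ChainModel(list(
      SegmentSpec("a", lengths = 8),
      SegmentSpec("b", lengths = 5))))
  list(chain = chain, epitope = ep, mt = mt)
}
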