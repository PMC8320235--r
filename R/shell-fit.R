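#' Select localizations near a microtubule ROI line
#'
#' Keeps localizations whose perpendicular distance to the finite ROI
#' segment is below `maxDistance`.
#'
#' @param locs Localization data.frame (see [readLocalizations()]).
#' @param roi List or one-row data.frame with `p0` and `p1` 3-vectors
#'   (nm), or columns `x0,y0,z0,x1,y1,z1`.
#' @param maxDistance Distance threshold, nm (default 60).
#' @return Subset of `locs` (possibly empty, with a warning).
#' @export
selectRoiLocalizations <- function(locs, roi, maxDistance = 60) {
  rr <- .roiEndpoints(roi)
  d <- .segmentDistance(as.matrix(locs[, c("x_nm", "y_nm", "z_nm")]),
                        rr$p0, rr$p1)
  out <- locs[d < maxDistance, , drop = FALSE]
  if (nrow(out) == 0) warning("no localizations within maxDistance of the ROI")
  out
}

.roiEndpoints <- function(roi) {
  if (is.list(roi) && !is.null(roi$p0))
    return(list(p0 = as.numeric(roi$p0), p1 = as.numeric(roi$p1)))
  list(p0 = as.numeric(roi[1, c("x0", "y0", "z0")]),
       p1 = as.numeric(roi[1, c("x1", "y1", "z1")]))
}

## distance of points (n x 3) to the finite segment p0--p1
.segmentDistance <- function(P, p0, p1) {
  v <- p1 - p0
  L2 <- sum(v^2)
  if (L2 <= 0) stop("ROI endpoints coincide")
  Q <- sweep(P, 2, p0)
  t <- pmin(pmax((Q %*% v) / L2, 0), 1)
  D <- Q - t %*% t(v)
  sqrt(rowSums(D^2))
}

#' Fit a cylinder axis to localizations
#'
#' Least-squares fit of a hollow cylinder: minimizes sum (d_i - R)^2 over
#' the axis (point + direction, 4 free parameters) and the radius R,
#' where d_i is the point-to-axis distance. Initialized from the ROI line
#' direction and the median point-to-line distance.
#'
#' @param locs Localization data.frame.
#' @param roi Initial axis guess (as in [selectRoiLocalizations()]).
#' @param minPoints Minimum number of localizations (default 20).
#' @return List with `center` (point on axis), `direction` (unit),
#'   `radius`, `residual` (RMS of d_i - R) and `converged`.
#' @export
fitCylinderAxis <- function(locs, roi, minPoints = 20) {
  P <- as.matrix(locs[, c("x_nm", "y_nm", "z_nm")])
  if (nrow(P) < minPoints)
    stop(sprintf("need at least %d localizations, got %d", minPoints, nrow(P)))
  rr <- .roiEndpoints(roi)
  d0 <- rr$p1 - rr$p0
  nd0 <- sqrt(sum(d0^2))
  if (nd0 <= 0) stop("degenerate ROI line")
  d0 <- d0 / nd0
  ## check the cloud is not collinear
  if (min(svd(sweep(P, 2, colMeans(P)))$d) < 1e-9 * max(1, max(abs(P))))
    stop("degenerate collinear localization cloud")
  e <- .perpBasis(d0)
  p0 <- colMeans(P)
  r0 <- stats::median(.axisDistance(P, p0, d0))

  resid <- function(par) {
    dir <- d0 + par[1] * e$e1 + par[2] * e$e2
    dir <- dir / sqrt(sum(dir^2))
    cen <- p0 + par[3] * e$e1 + par[4] * e$e2
    .axisDistance(P, cen, dir) - par[5]
  }
  fit <- minpack.lm::nls.lm(par = c(0, 0, 0, 0, r0), fn = resid,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!fit$info %in% 1:4)
    warning("cylinder fit did not converge: ", fit$message)
  par <- fit$par
  dir <- d0 + par[1] * e$e1 + par[2] * e$e2
  dir <- dir / sqrt(sum(dir^2))
  if (dir[1] < 0) dir <- -dir
  cen <- p0 + par[3] * e$e1 + par[4] * e$e2
  list(center = cen, direction = dir, radius = par[5],
       residual = sqrt(mean(resid(par)^2)), converged = fit$info %in% 1:4)
}

.perpBasis <- function(d) {
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  e1 <- .cross3(ref, d); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- .cross3(d, e1)
  list(e1 = e1, e2 = e2)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.axisDistance <- function(P, cen, dir) {
  Q <- sweep(P, 2, cen)
  t <- Q %*% dir
  sqrt(pmax(rowSums(Q^2) - t^2, 0))
}

#' Project localizations into the cylinder cross-section frame
#'
#' Expresses each localization in the plane perpendicular to the fitted
#' axis: y lateral (horizontal), z along the optical axis; the axial
#' coordinate is discarded. The lateral precision is set to the mean of
#' sigma_x and sigma_y.
#'
#' @param locs Localization data.frame.
#' @param axis Result of [fitCylinderAxis()] (or a list with `center` and
#'   `direction`).
#' @return data.frame with columns `y`, `z`, `sigma_yz`, `sigma_z`.
#' @export
projectToCrossSection <- function(locs, axis) {
  u <- axis$direction / sqrt(sum(axis$direction^2))
  zlab <- c(0, 0, 1)
  yhat <- .cross3(zlab, u)
  ny <- sqrt(sum(yhat^2))
  if (ny < 1e-8) { yhat <- c(0, 1, 0); ny <- 1 }   # axis along optical axis
  yhat <- yhat / ny
  zhat <- .cross3(u, yhat)
  Q <- sweep(as.matrix(locs[, c("x_nm", "y_nm", "z_nm")]), 2, axis$center)
  data.frame(y = as.numeric(Q %*% yhat),
             z = as.numeric(Q %*% zhat),
             sigma_yz = (locs$sigma_x_nm + locs$sigma_y_nm) / 2,
             sigma_z = locs$sigma_z_nm)
}

#' Bin cross-section localizations into a 2D histogram
#'
#' Pools one or more projected sections into counts on a square grid
#' centered at the axis, with half-open bins `[k b, (k+1) b)`.
#'
#' @param sections A projected section data.frame (from
#'   [projectToCrossSection()]) or a list of them.
#' @param bin Bin width, nm (default 2).
#' @param extent Half-width of the grid, nm (default 60).
#' @return List with `y`, `z` (cell centers), `counts` matrix, and
#'   `nSections`.
#' @export
binSection <- function(sections, bin = 2, extent = 60) {
  if (is.data.frame(sections)) sections <- list(sections)
  if (!length(sections)) stop("no sections given")
  edges <- seq(-ceiling(extent / bin) * bin, ceiling(extent / bin) * bin,
               by = bin)
  nb <- length(edges) - 1
  counts <- matrix(0, nb, nb)
  for (s in sections) {
    keep <- s$y >= edges[1] & s$y < edges[nb + 1] &
            s$z >= edges[1] & s$z < edges[nb + 1]
    iy <- floor((s$y[keep] - edges[1]) / bin) + 1
    iz <- floor((s$z[keep] - edges[1]) / bin) + 1
    counts <- counts + matrix(tabulate((iz - 1) * nb + iy, nbins = nb * nb),
                              nb, nb)
  }
  mids <- edges[-(nb + 1)] + bin / 2
  list(y = mids, z = mids, counts = counts, nSections = length(sections))
}

## cell-integrated 1D Gaussian masses on a uniform grid of centers
.discreteGaussian <- function(centers, sigma, spacing) {
  if (sigma <= 0) return(as.numeric(abs(centers) < spacing / 2))
  lo <- stats::pnorm(centers - spacing / 2, sd = sigma)
  hi <- stats::pnorm(centers + spacing / 2, sd = sigma)
  hi - lo
}

#' Build the compound anisotropic blur kernel
#'
#' Bins per-localization precisions (sigma_yz, sigma_z) into a 2D array
#' of CRLB bins, sums cell-integrated anisotropic 2D Gaussians with the
#' per-bin mean widths weighted by bin counts, convolves with the
#' residual-drift Gaussian, and renormalizes to unit mass.
#'
#' @param sections Projected section data.frame or list of them.
#' @param crlbBin CRLB bin width, nm (default 0.5).
#' @param drift Residual drift sigmas c(sigma_y, sigma_z), nm.
#' @param spacing Kernel grid spacing, nm (default 2, matching the
#'   cross-section histogram).
#' @param extent Optional kernel half-width, nm (default 4 sigma reach).
#' @return A [CompoundKernel-class].
#' @export
buildCompoundKernel <- function(sections, crlbBin = 0.5, drift = c(0, 0),
                                spacing = 2, extent = NULL) {
  if (is.data.frame(sections)) sections <- list(sections)
  sy <- unlist(lapply(sections, `[[`, "sigma_yz"))
  sz <- unlist(lapply(sections, `[[`, "sigma_z"))
  if (!length(sy)) stop("no localizations given")
  if (any(sy <= 0) || any(sz <= 0))
    stop("non-positive localization precisions")
  if (any(drift < 0)) stop("drift sigmas must be >= 0")
  iy <- floor(sy / crlbBin); iz <- floor(sz / crlbBin)
  key <- paste(iy, iz)
  agg <- data.frame(sy = sy, sz = sz)
  groups <- split(agg, key)
  wts <- vapply(groups, nrow, 1L)
  msy <- vapply(groups, function(g) mean(g$sy), 1)
  msz <- vapply(groups, function(g) mean(g$sz), 1)
  if (is.null(extent)) {
    reach <- 4 * (max(c(msy, msz)) + max(drift))
    extent <- max(spacing, ceiling(reach / spacing) * spacing)
  }
  centers <- seq(-extent, extent, by = spacing)
  K <- matrix(0, length(centers), length(centers))
  for (b in seq_along(wts)) {
    gy <- .discreteGaussian(centers, msy[b], spacing)
    gz <- .discreteGaussian(centers, msz[b], spacing)
    g2 <- outer(gy, gz)
    K <- K + wts[b] * g2 / sum(g2)
  }
  K <- K / sum(K)
  if (any(drift > 0)) {
    gd <- outer(.discreteGaussian(centers, drift[1], spacing),
                .discreteGaussian(centers, drift[2], spacing))
    K <- .conv2same(K, gd / sum(gd))
  }
  K <- pmax(K, 0)
  K <- K / sum(K)
  new("CompoundKernel", yGrid = centers, zGrid = centers, values = K,
      spacing = spacing)
}
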