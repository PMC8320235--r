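#' @import methods
NULL

#' Microtubule geometry
#'
#' Describes the microtubule as an impenetrable cylinder of fixed outer
#' radius whose axis coincides with the x-axis of the model frame.
#'
#' @slot outerRadius Outer radius of the microtubule in nm (default 12.5,
#'   the average outer radius of a 13-protofilament microtubule).
#' @export
setClass("MicrotubuleGeometry",
  representation(outerRadius = "numeric"),
  prototype(outerRadius = 12.5),
  validity = function(object) {
    if (length(object@outerRadius) != 1 || !is.finite(object@outerRadius) ||
        object@outerRadius <= 0)
      return("outerRadius must be a single positive number")
    TRUE
  })

#' @describeIn MicrotubuleGeometry Constructor.
#' @param outerRadius Outer radius in nm.
#' @export
MicrotubuleGeometry <- function(outerRadius = 12.5) {
  new("MicrotubuleGeometry", outerRadius = outerRadius)
}

#' Epitope geometry on the microtubule surface
#'
#' The epitope sits at (0, y0, z0) in the model frame (x along the
#' microtubule axis, z along the optical axis). The orientation of the
#' first chain segment relative to the outward radial direction is drawn
#' from uniform distributions over `phi1Bounds` (rotation about x) and
#' `theta1Bounds` (rotation about y); a degenerate interval fixes the
#' orientation (rigid Fab-epitope binding).
#'
#' @slot y0,z0 Epitope coordinates in nm.
#' @slot phi1Bounds,theta1Bounds Length-2 numeric, radians.
#' @export
setClass("EpitopeGeometry",
  representation(y0 = "numeric", z0 = "numeric",
                 phi1Bounds = "numeric", theta1Bounds = "numeric"),
  prototype(y0 = 0, z0 = 12.5, phi1Bounds = c(0, 2 * pi),
            theta1Bounds = c(0, 0)),
  validity = function(object) {
    msg <- character()
    if (!is.finite(object@y0) || !is.finite(object@z0))
      msg <- c(msg, "epitope coordinates must be finite")
    if (object@y0^2 + object@z0^2 <= 0)
      msg <- c(msg, "epitope cannot sit on the microtubule axis")
    for (b in list(object@phi1Bounds, object@theta1Bounds))
      if (length(b) != 2 || any(!is.finite(b)) || b[2] < b[1])
        msg <- c(msg, "angle bounds must be a valid interval")
    if (length(msg)) msg else TRUE
  })

#' @describeIn EpitopeGeometry Constructor; angles in radians.
#' @param y0,z0 Epitope coordinates in nm.
#' @param phi1Bounds,theta1Bounds Orientation bounds of the first segment,
#'   radians.
#' @export
EpitopeGeometry <- function(y0 = 0, z0 = 12.5, phi1Bounds = c(0, 2 * pi),
                            theta1Bounds = c(0, 0)) {
  new("EpitopeGeometry", y0 = y0, z0 = z0, phi1Bounds = phi1Bounds,
      theta1Bounds = theta1Bounds)
}

#' Rigid-segment specification
#'
#' One rigid segment of a kinked antibody chain. Its length is drawn
#' either from a finite set (`lengths`) or uniformly from a continuous
#' range (`range`); its orientation relative to the preceding segment is
#' set by a kink rotation phi about the local x-axis and theta about the
#' local y-axis, both drawn uniformly within bounds.
#'
#' @slot name Segment label.
#' @slot lenType "set" or "range".
#' @slot lenValues Candidate lengths (set) or c(lo, hi) (range), nm.
#' @slot phiBounds,thetaBounds Length-2 numeric, radians.
#' @export
setClass("SegmentSpec",
  representation(name = "character", lenType = "character",
                 lenValues = "numeric", phiBounds = "numeric",
                 thetaBounds = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@lenType %in% c("set", "range"))
      msg <- c(msg, "lenType must be 'set' or 'range'")
    if (any(object@lenValues <= 0) || !length(object@lenValues))
      msg <- c(msg, "all candidate lengths must be positive")
    if (object@lenType == "range" &&
        (length(object@lenValues) != 2 || diff(object@lenValues) < 0))
      msg <- c(msg, "length range must be c(lo, hi) with lo <= hi")
    for (b in list(object@phiBounds, object@thetaBounds))
      if (length(b) != 2 || any(!is.finite(b)) || b[2] < b[1])
        msg <- c(msg, "angle bounds must be a valid interval")
    if (length(msg)) msg else TRUE
  })

#' @describeIn SegmentSpec Constructor. Supply exactly one of `lengths`
#'   (finite set) or `range` (continuous). Angles in radians.
#' @param name Segment label.
#' @param lengths Finite set of candidate lengths, nm.
#' @param range Continuous length range c(lo, hi), nm.
#' @param phiBounds,thetaBounds Kink-angle bounds, radians.
#' @export
SegmentSpec <- function(name, lengths = NULL, range = NULL,
                        phiBounds = c(-pi, pi), thetaBounds = c(-pi, pi)) {
  if (is.null(lengths) == is.null(range))
    stop("supply exactly one of 'lengths' or 'range'")
  if (is.null(lengths))
    new("SegmentSpec", name = name, lenType = "range", lenValues = range,
        phiBounds = phiBounds, thetaBounds = thetaBounds)
  else
    new("SegmentSpec", name = name, lenType = "set", lenValues = lengths,
        phiBounds = phiBounds, thetaBounds = thetaBounds)
}

#' Kinked-chain antibody model
#'
#' Ordered rigid segments representing an antibody (3 segments:
#' CDR-Hinge, Hinge-Glu, Glu-Reporter) or a primary/secondary complex
#' (5 segments: 1 CDR-1 Hinge, 1 Hinge-2 epitope, 2 CDR-2 Hinge,
#' 2 Hinge-2 Glu, 2 Glu-Reporter). Uniform placement of the secondary
#' epitope along the primary Fc is encoded as a continuous length range
#' (0, Fc length) for the second segment. `dMin` is the minimum allowed
#' distance between points on non-sequential segments; points are sampled
#' every `arcRes` nm along each segment for the clash test.
#'
#' @slot segments List of [SegmentSpec-class] objects.
#' @slot dMin Minimum non-sequential segment distance, nm.
#' @slot arcRes Arc-length sampling resolution for the clash test, nm.
#' @export
setClass("ChainModel",
  representation(segments = "list", dMin = "numeric", arcRes = "numeric"),
  prototype(dMin = 0, arcRes = 0.5),
  validity = function(object) {
    msg <- character()
    if (!length(object@segments) ||
        !all(vapply(object@segments, is, TRUE, "SegmentSpec")))
      msg <- c(msg, "segments must be a non-empty list of SegmentSpec")
    if (object@dMin < 0) msg <- c(msg, "dMin must be >= 0")
    if (object@arcRes <= 0) msg <- c(msg, "arcRes must be > 0")
    if (length(msg)) msg else TRUE
  })

#' @describeIn ChainModel Constructor.
#' @param segments List of [SegmentSpec-class].
#' @param dMin Steric self-avoidance distance, nm.
#' @param arcRes Clash-test arc resolution, nm.
#' @export
ChainModel <- function(segments, dMin = 0, arcRes = 0.5) {
  new("ChainModel", segments = segments, dMin = dMin, arcRes = arcRes)
}

#' A batch of simulated antibody conformations
#'
#' @slot endpoints n x 3 matrix of reporter positions (x, y, z), nm.
#' @slot vertices Optional n x 3*(nseg+1) matrix of retained chain
#'   vertices (flattened), or a 0 x 0 matrix.
#' @slot nAttempted,nAccepted Proposal and acceptance counts.
#' @slot seed RNG seed used for the batch.
#' @export
setClass("ConformationBatch",
  representation(endpoints = "matrix", vertices = "matrix",
                 nAttempted = "numeric", nAccepted = "numeric",
                 seed = "numeric"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@endpoints) != 3)
      msg <- c(msg, "endpoints must have 3 columns")
    if (object@nAccepted > object@nAttempted)
      msg <- c(msg, "nAccepted cannot exceed nAttempted")
    if (nrow(object@endpoints) != object@nAccepted)
      msg <- c(msg, "endpoint count must equal nAccepted")
    if (length(msg)) msg else TRUE
  })

#' Binned radial density of reporter distance from the microtubule center
#'
#' @slot binEdges Bin edges, nm.
#' @slot density Normalized bin masses (sums to 1).
#' @slot peak Mode of the (smoothed) radial density, nm.
#' @slot fwhm Full width at half maximum, nm.
#' @export
setClass("RadialDistribution",
  representation(binEdges = "numeric", density = "numeric",
                 peak = "numeric", fwhm = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@density) != length(object@binEdges) - 1)
      msg <- c(msg, "density must have one value per bin")
    if (abs(sum(object@density) - 1) > 1e-8)
      msg <- c(msg, "density must sum to 1")
    if (length(msg)) msg else TRUE
  })

#' Compound anisotropic blur kernel
#'
#' Count-weighted sum of 2D Gaussians built from binned per-localization
#' precisions, convolved with a residual-drift Gaussian; normalized to
#' unit mass on its grid.
#'
#' @slot yGrid,zGrid Cell-center coordinates, nm.
#' @slot values Kernel weights (sum to 1).
#' @slot spacing Grid spacing, nm.
#' @export
setClass("CompoundKernel",
  representation(yGrid = "numeric", zGrid = "numeric", values = "matrix",
                 spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!all(dim(object@values) == c(length(object@yGrid),
                                     length(object@zGrid))))
      msg <- c(msg, "values must be length(yGrid) x length(zGrid)")
    if (any(object@values < 0)) msg <- c(msg, "kernel must be non-negative")
    if (abs(sum(object@values) - 1) > 1e-6)
      msg <- c(msg, "kernel must sum to 1")
    if (length(msg)) msg else TRUE
  })

#' Result of a convolved Gaussian-ring fit
#'
#' @slot r Shell radius, nm.
#' @slot sigma Radial Gaussian width, nm.
#' @slot w Shell thickness fwhm = 2.35 sigma, nm.
#' @slot ci95R,ci95W 95% confidence half-widths, nm.
#' @slot cov Parameter covariance of (r, sigma).
#' @slot nSections Number of pooled cross-sections.
#' @slot converged Logical.
#' @export
setClass("RingFit",
  representation(r = "numeric", sigma = "numeric", w = "numeric",
                 ci95R = "numeric", ci95W = "numeric", cov = "matrix",
                 nSections = "numeric", converged = "logical"),
  validity = function(object) {
    msg <- character()
    if (object@r < 0) msg <- c(msg, "r must be >= 0")
    if (abs(object@w - 2.35 * object@sigma) > 1e-6 * max(1, object@w))
      msg <- c(msg, "w must equal 2.35 * sigma")
    if (any(c(object@ci95R, object@ci95W) < 0))
      msg <- c(msg, "confidence intervals must be >= 0")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "MicrotubuleGeometry", function(object) {
  cat("MicrotubuleGeometry: outer radius", object@outerRadius, "nm\n")
})

setMethod("show", "EpitopeGeometry", function(object) {
  cat(sprintf("EpitopeGeometry at (0, %.2f, %.2f) nm (radius %.2f nm)\n",
              object@y0, object@z0, sqrt(object@y0^2 + object@z0^2)))
})

setMethod("show", "ChainModel", function(object) {
  cat(sprintf("ChainModel with %d segments (dMin = %.2f nm):\n",
              length(object@segments), object@dMin))
  for (i in seq_along(object@segments)) {
    s <- object@segments[[i]]
    lens <- if (s@lenType == "set")
      paste(s@lenValues, collapse = "/")
    else sprintf("U(%.2f, %.2f)", s@lenValues[1], s@lenValues[2])
    ang <- if (i == 1L) "orientation set by the epitope"
    else sprintf("phi in [%.0f, %.0f] deg, theta in [%.0f, %.0f] deg",
                 180 / pi * s@phiBounds[1], 180 / pi * s@phiBounds[2],
                 180 / pi * s@thetaBounds[1], 180 / pi * s@thetaBounds[2])
    cat(sprintf("  %-22s L = %s nm, %s\n", s@name, lens, ang))
  }
})

setMethod("show", "ConformationBatch", function(object) {
  cat(sprintf("ConformationBatch: %d accepted / %d attempted (%.1f%%), seed %s\n",
              object@nAccepted, object@nAttempted,
              100 * object@nAccepted / max(1, object@nAttempted),
              format(object@seed)))
})

setMethod("show", "RadialDistribution", function(object) {
  cat(sprintf("RadialDistribution: %d bins on [%.2f, %.2f] nm; peak %.2f nm, fwhm %.2f nm\n",
              length(object@density), min(object@binEdges),
              max(object@binEdges), object@peak, object@fwhm))
})

setMethod("show", "CompoundKernel", function(object) {
  cat(sprintf("CompoundKernel: %d x %d grid, %.2f nm spacing\n",
              length(object@yGrid), length(object@zGrid), object@spacing))
})

setMethod("show", "RingFit", function(object) {
  cat(sprintf("RingFit: r = %.2f +/- %.2f nm, w = %.2f +/- %.2f nm (sigma %.2f), %d sections%s\n",
              object@r, object@ci95R, object@w, object@ci95W, object@sigma,
              object@nSections,
              if (object@converged) "" else " [NOT CONVERGED]"))
})
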