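## Independent oracles used across tests. These deliberately re-derive
## the chain kinematics and density integrals with different code paths
## than the package internals.

deg <- pi / 180

## reference forward kinematics for a fixed-angle chain (matrix algebra,
## independent of the C++ implementation)
oracleForwardKinematics <- function(lengths, phis, thetas, y0 = 0, z0 = 12.5) {
  rotx <- function(p) matrix(c(1, 0, 0, 0, cos(p), sin(p),
                               0, -sin(p), cos(p)), 3, 3)
  roty <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0,
                               sin(t), 0, cos(t)), 3, 3)
  re <- sqrt(y0^2 + z0^2)
  M <- cbind(c(1, 0, 0), c(0, z0 / re, -y0 / re), c(0, y0 / re, z0 / re))
  v <- c(0, y0, z0)
  out <- matrix(v, 1, 3)
  for (i in seq_along(lengths)) {
    M <- M %*% rotx(phis[i]) %*% roty(thetas[i])
    v <- v + lengths[i] * M[, 3]
    out <- rbind(out, v)
  }
  out
}

## grid-enumeration oracle for the endpoint radius density of a 1- or
## 2-segment chain with free uniform angles (no steric rules); returns
## bin masses on the given edges. Vectorized rotation application, not
## the package's kinematics.
oracleRadialEnumeration <- function(lengths, edges, z0 = 12.5, nGrid = 32,
                                    phiRange = c(-pi, pi),
                                    thetaRange = c(-pi, pi)) {
  g <- function(rng) rng[1] + (seq_len(nGrid) - 0.5) / nGrid * diff(rng)
  applyRx <- function(phi, V) cbind(V[, 1],
                                    cos(phi) * V[, 2] - sin(phi) * V[, 3],
                                    sin(phi) * V[, 2] + cos(phi) * V[, 3])
  applyRy <- function(th, V) cbind(cos(th) * V[, 1] + sin(th) * V[, 3],
                                   V[, 2],
                                   -sin(th) * V[, 1] + cos(th) * V[, 3])
  if (length(lengths) == 1) {
    grid <- expand.grid(p1 = g(phiRange), t1 = g(thetaRange))
    V <- applyRx(grid$p1, applyRy(grid$t1, matrix(c(0, 0, 1), nrow(grid), 3,
                                                  byrow = TRUE)))
    end <- cbind(0, 0, z0)[rep(1, nrow(V)), ] + lengths[1] * V
  } else {
    grid <- expand.grid(p1 = g(phiRange), t1 = g(thetaRange),
                        p2 = g(phiRange), t2 = g(thetaRange))
    ez <- matrix(c(0, 0, 1), nrow(grid), 3, byrow = TRUE)
    d1 <- applyRx(grid$p1, applyRy(grid$t1, ez))
    d2 <- applyRx(grid$p1, applyRy(grid$t1,
            applyRx(grid$p2, applyRy(grid$t2, ez))))
    end <- cbind(0, 0, z0)[rep(1, nrow(grid)), ] +
      lengths[1] * d1 + lengths[2] * d2
  }
  r <- sqrt(end[, 2]^2 + end[, 3]^2)
  h <- hist(r, breaks = edges, plot = FALSE)
  h$counts / sum(h$counts)
}

## analytic radial mass density of a delta ring at r0 convolved with an
## isotropic Gaussian of width sk: the Rice density
## p(rho) = rho/sk^2 exp(-(rho^2+r0^2)/(2 sk^2)) I0(rho r0 / sk^2)
oracleRingGaussianProfile <- function(rho, r0, sk) {
  x <- rho * r0 / sk^2
  rho / sk^2 * exp(-(rho - r0)^2 / (2 * sk^2)) *
    besselI(x, 0, expon.scaled = TRUE)
}

## radii drawn uniformly per unit area from the 2D Gaussian-ring density
## (rho-weighted radial mass), by rejection; independent of the package's
## internal sampler
oracleRingRadii <- function(n, r0, sigma0) {
  out <- numeric(0)
  M <- r0 + 5 * sigma0
  while (length(out) < n) {
    cand <- rnorm(3 * n, r0, sigma0)
    cand <- cand[cand > 0]
    out <- c(out, cand[runif(length(cand)) < cand / M])
  }
  out[seq_len(n)]
}

## cross-section sample of a Gaussian-ring shell blurred with fixed
## anisotropic precision; used by ring-fit tests
ringSection <- function(n, r0, sigma0, sy, sz, seed = 1) {
  set.seed(seed)
  rad <- oracleRingRadii(n, r0, sigma0)
  az <- runif(n, 0, 2 * pi)
  data.frame(y = rad * cos(az) + rnorm(n, 0, sy),
             z = rad * sin(az) + rnorm(n, 0, sz),
             sigma_yz = sy, sigma_z = sz)
}

## small standard scene for pipeline tests
smallScene <- function(r0 = 20, w0 = 10, nSections = 40, seed = 1,
                       drift = c(0, 0), lpm = 500) {
  L <- nSections * 250 / 2
  cfg <- sceneConfig(
    mtAxes = list(list(p0 = c(0, 0, 0), p1 = c(L, 0, 0)),
                  list(p0 = c(0, 0, 3000), p1 = c(L, 0, 3000))),
    shellR0 = r0, shellW0 = w0, labelsPerMicron = lpm, blinksMean = 6,
    crlbMedianYZ = 6, crlbMedianZ = 12, driftSigma = drift)
  makeScene(cfg, seed = seed)
}
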