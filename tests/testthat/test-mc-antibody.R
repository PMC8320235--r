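test_that("degenerate angle samplers reproduce exact forward kinematics", {
  fx <- makeMcFixture("fixed-angles")
  s <- sampleConformation(fx$chain, fx$epitope, fx$mt, seed = 1)
  ## fixture angles: segment 1 takes the epitope orientation (phi = pi/6,
  ## theta = 0); segment 2 kinks by (phi = -pi/3, theta = pi/5)
  oracle <- oracleForwardKinematics(c(6, 4), c(pi / 6, -pi / 3),
                                    c(0, pi / 5))
  expect_equal(unname(s$vertices), unname(oracle), tolerance = 1e-10)
})

test_that("single free segment endpoints stay within the reach bound", {
  fx <- makeMcFixture("single-rod")
  p <- proposeConformations(fx$chain, fx$epitope, fx$mt, n = 5000,
                            seed = 2, steric = FALSE)
  d <- sqrt(p$endpoints[, 1]^2 + p$endpoints[, 2]^2 +
              (p$endpoints[, 3] - 12.5)^2)
  expect_true(all(d <= 10 + 1e-9))
  expect_true(all(d >= 10 - 1e-9))    # rigid rod: exactly L from the anchor
})

test_that("multi-segment endpoints obey the summed reach bound", {
  cfg <- readModelConfig(modelConfigPath("indirect"))
  b <- simulateBatch(cfg$chain, cfg$epitope, cfg$mt, nTarget = 20000,
                     seed = 3)
  maxReach <- sum(vapply(cfg$chain@segments,
                         function(s) max(s@lenValues), 1))
  d <- sqrt(rowSums(sweep(endpoints(b), 2, c(0, 0, 12.5))^2))
  expect_true(all(d <= maxReach + 1e-9))
})

test_that("every accepted conformation satisfies the steric wall exactly", {
  cfg <- readModelConfig(modelConfigPath("direct"))
  b <- simulateBatch(cfg$chain, cfg$epitope, cfg$mt, nTarget = 20000,
                     seed = 4, keepVertices = TRUE)
  v <- chainVertices(b)
  nseg <- length(cfg$chain@segments)
  re2 <- 12.5^2
  for (k in seq_len(nseg)) {   # vertices 1..nseg (vertex 0 is the epitope)
    y <- v[, 3 * k + 2]; z <- v[, 3 * k + 3]
    expect_true(all(y^2 + z^2 > re2))
  }
})

test_that("batches are reproducible under a fixed seed", {
  cfg <- readModelConfig(modelConfigPath("direct"))
  b1 <- simulateBatch(cfg$chain, cfg$epitope, cfg$mt, 1000, seed = 11)
  b2 <- simulateBatch(cfg$chain, cfg$epitope, cfg$mt, 1000, seed = 11)
  expect_identical(endpoints(b1), endpoints(b2))
  expect_identical(nAttempted(b1), nAttempted(b2))
  b3 <- simulateBatch(cfg$chain, cfg$epitope, cfg$mt, 1000, seed = 12)
  expect_false(identical(endpoints(b1), endpoints(b3)))
})

test_that("steric filtering selects a subset of the shared proposal stream", {
  cfg <- readModelConfig(modelConfigPath("indirect"))
  pOn <- proposeConformations(cfg$chain, cfg$epitope, cfg$mt, n = 20000,
                              seed = 5, steric = TRUE)
  pOff <- proposeConformations(cfg$chain, cfg$epitope, cfg$mt, n = 20000,
                               seed = 5, steric = FALSE)
  expect_identical(pOn$endpoints, pOff$endpoints)   # same proposals
  expect_true(all(pOff$accepted))
  expect_true(sum(pOn$accepted) < sum(pOff$accepted))
})

test_that("impossible configurations abort with a diagnostic", {
  ## epitope buried inside the microtubule wall radius: every first
  ## vertex of a short downward-pointing chain violates the wall
  ep <- EpitopeGeometry(0, 12.5, phi1Bounds = c(pi, pi),
                        theta1Bounds = c(0, 0))   # points inward
  ch <- ChainModel(list(SegmentSpec("a", lengths = 5)))
  expect_error(
    simulateBatch(ch, ep, MicrotubuleGeometry(12.5), nTarget = 100,
                  seed = 1, chunkSize = 1000),
    "acceptance|no conformation")
})

test_that("free two-segment chain matches the grid-enumeration oracle", {
  fx <- makeMcFixture("two-rod-free")
  p <- proposeConformations(fx$chain, fx$epitope, fx$mt, n = 2e5,
                            seed = 6, steric = FALSE)
  r <- sqrt(p$endpoints[, 2]^2 + p$endpoints[, 3]^2)
  edges <- seq(0, 26, by = 1)
  sampled <- hist(pmin(r, 25.5), breaks = edges, plot = FALSE)$counts / 2e5
  enum <- oracleRadialEnumeration(c(8, 5), edges, nGrid = 32)
  tv <- 0.5 * sum(abs(sampled - enum))
  expect_lt(tv, 0.02)
})

test_that("single-rod radial density matches dense quadrature", {
  fx <- makeMcFixture("single-rod")
  p <- proposeConformations(fx$chain, fx$epitope, fx$mt, n = 2e5,
                            seed = 7, steric = FALSE)
  r <- sqrt(p$endpoints[, 2]^2 + p$endpoints[, 3]^2)
  edges <- seq(2, 23, by = 0.5)
  sampled <- hist(r, breaks = edges, plot = FALSE)$counts / 2e5
  enum <- oracleRadialEnumeration(10, edges, nGrid = 400)
  expect_lt(0.5 * sum(abs(sampled - enum)), 0.02)
})

test_that("radial histogram recovers peak and width of a known Gaussian", {
  set.seed(8)
  r <- rnorm(1e5, 25, 3)
  rd <- radialDistribution(r, binWidth = 0.25)
  expect_equal(sum(radialDensity(rd)), 1, tolerance = 1e-12)
  expect_lt(abs(radialPeak(rd) - 25), 0.2)
  expect_lt(abs(radialFwhm(rd) - 2.3548 * 3), 0.3)
})

test_that("degenerate radial input occupies a single bin", {
  rd <- radialDistribution(rep(20, 100), binWidth = 0.5, smooth = FALSE)
  expect_equal(sum(radialDensity(rd) > 0), 1)
  expect_equal(radialPeak(rd), 20.25)   # mid of the occupied [20, 20.5) bin
  expect_error(radialDistribution(numeric(0)), "empty")
})

test_that("endpoint y-distribution is mirror symmetric for symmetric bounds", {
  cfg <- readModelConfig(modelConfigPath("direct"))
  b <- simulateBatch(cfg$chain, cfg$epitope, cfg$mt, nTarget = 1e5, seed = 9)
  y <- endpoints(b)[, 2]
  ks <- suppressWarnings(ks.test(y, -y))
  expect_gt(ks$p.value, 0.01)
})

test_that("density map conserves mass and annulus structure", {
  cfg <- readModelConfig(modelConfigPath("direct"))
  b <- simulateBatch(cfg$chain, cfg$epitope, cfg$mt, nTarget = 5e4, seed = 10)
  m <- densityMap(b, bin = 1.25)
  expect_equal(sum(m$values), 1, tolerance = 1e-12)
  mi <- densityMap(b, bin = 1.25, interpolate = 4L)
  expect_equal(sum(mi$values), 1, tolerance = 0.01)
  ## annulus re-integration: mass of map cells in [r1, r2) matches the
  ## radial histogram mass in the same annulus
  rho <- sqrt(outer(m$y^2, m$z^2, "+"))
  r <- sqrt(endpoints(b)[, 2]^2 + endpoints(b)[, 3]^2)
  for (ann in list(c(15, 20), c(20, 25))) {
    mapMass <- sum(m$values[rho >= ann[1] & rho < ann[2]])
    sampleMass <- mean(r >= ann[1] & r < ann[2])
    expect_lt(abs(mapMass - sampleMass), 0.02)
  }
  ## mirror symmetry of the map under y -> -y: the observed asymmetry
  ## statistic is compared with a permutation null built by randomly
  ## sign-flipping y (exactly symmetric by construction)
  asym <- function(ep) {
    bb <- new("ConformationBatch", endpoints = ep,
              vertices = matrix(numeric(0), 0, 0),
              nAttempted = nrow(ep), nAccepted = nrow(ep), seed = 0)
    v <- densityMap(bb, bin = 1.25)$values
    0.5 * sum(abs(v - v[rev(seq_len(nrow(v))), ]))
  }
  ep <- endpoints(b)
  tObs <- asym(ep)
  set.seed(99)
  tNull <- vapply(1:19, function(i) {
    s <- sample(c(-1, 1), nrow(ep), replace = TRUE)
    asym(cbind(ep[, 1], s * ep[, 2], ep[, 3]))
  }, 1)
  expect_lt(tObs, max(tNull) * 1.1)
})

test_that("revolving with a delta kernel preserves the radial profile", {
  set.seed(12)
  rd <- radialDistribution(rnorm(5e4, 20, 3), binWidth = 0.5)
  img <- revolveConvolve(rd, kernel = NULL, spacing = 1)
  expect_equal(sum(img$values), 1, tolerance = 1e-9)
  ## radial profile of the image matches the input density
  rho <- sqrt(outer(img$y^2, img$z^2, "+"))
  for (ann in list(c(14, 18), c(18, 22), c(22, 26))) {
    mids <- binEdges(rd)[-1] - 0.25
    want <- sum(radialDensity(rd)[mids >= ann[1] & mids < ann[2]])
    got <- sum(img$values[rho >= ann[1] & rho < ann[2]])
    expect_lt(abs(got - want), 0.02)
  }
})

test_that("delta ring blurred with an isotropic Gaussian matches the Rice form", {
  r0 <- 14.75; sk <- 3       # r0 on a radial bin center
  edges <- seq(0, 40, by = 0.5)
  dens <- as.numeric(abs(edges[-1] - 0.25 - r0) < 0.01)
  rd <- new("RadialDistribution", binEdges = edges, density = dens,
            peak = r0, fwhm = 0.5)
  centers <- seq(-30, 30, by = 1)
  g <- outer(exp(-centers^2 / (2 * sk^2)), exp(-centers^2 / (2 * sk^2)))
  kern <- new("CompoundKernel", yGrid = centers, zGrid = centers,
              values = g / sum(g), spacing = 1)
  img <- revolveConvolve(rd, kern)
  expect_equal(sum(img$values), 1, tolerance = 1e-6)
  ## per-cell comparison with the analytic Rice density evaluated at the
  ## cell centers (2D density = radial mass / (2 pi rho))
  rho <- sqrt(outer(img$y^2, img$z^2, "+"))
  ## 2D Rice density, regular at the origin:
  ## f = exp(-(rho-r0)^2/2 sk^2) I0scaled(rho r0/sk^2) / (2 pi sk^2)
  want <- exp(-(rho - r0)^2 / (2 * sk^2)) *
    besselI(rho * r0 / sk^2, 0, expon.scaled = TRUE)
  want <- want / sum(want)
  expect_lt(0.5 * sum(abs(img$values - want)), 0.02)
})

test_that("zero-radius ring revolves to the kernel itself", {
  edges <- c(0, 0.5)
  rd <- new("RadialDistribution", binEdges = edges, density = 1,
            peak = 0.25, fwhm = 0.5)
  centers <- seq(-20, 20, by = 2)
  g <- outer(exp(-centers^2 / 18), exp(-centers^2 / 50))
  kern <- new("CompoundKernel", yGrid = centers, zGrid = centers,
              values = g / sum(g), spacing = 2)
  img <- revolveConvolve(rd, kern, extent = 20)
  ## the near-delta ring blurred by the kernel reproduces the kernel
  expect_lt(0.5 * sum(abs(img$values - kernelValues(kern))), 0.03)
})

test_that("residual maps recover exact affine matches and noise levels", {
  set.seed(13)
  sim <- matrix(dnorm(seq(-3, 3, length.out = 31)), 31, 31) *
    rep(dnorm(seq(-3, 3, length.out = 31)), each = 31)
  resExact <- residualMap(sim, 3 * sim + 5)
  expect_equal(max(abs(resExact$residuals)), 0, tolerance = 1e-12)
  expect_equal(resExact$scale, 3, tolerance = 1e-10)
  expect_equal(resExact$offset, 5, tolerance = 1e-10)
  ## scale/offset equal the normal-equation solution
  noisy <- 2 * sim + 1 + matrix(rnorm(length(sim), 0, 0.001), nrow(sim))
  res <- residualMap(sim, noisy)
  X <- cbind(as.numeric(sim), 1)
  ab <- solve(t(X) %*% X, t(X) %*% as.numeric(noisy))
  expect_equal(res$scale, ab[1], tolerance = 1e-9)
  expect_equal(res$offset, ab[2], tolerance = 1e-9)
  ## known-noise residual RMS ~ sigma_n / peak
  sigN <- 0.002
  noisy2 <- sim + matrix(rnorm(length(sim), 0, sigN), nrow(sim))
  res2 <- residualMap(sim, noisy2)
  expect_equal(sqrt(mean(res2$residuals^2)), sigN / max(sim),
               tolerance = 0.15)
  expect_error(residualMap(matrix(1, 5, 5), matrix(1, 5, 5)), "constant")
  expect_error(residualMap(sim, sim[1:10, 1:10]), "grid")
})
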