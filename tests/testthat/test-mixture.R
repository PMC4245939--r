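# RDF computation, Kirkwood-Buff integration and the stability criterion.

test_that("RDF of fixed two-particle frame puts all weight in one bin", {
  coords <- matrix(c(1, 1, 1,
                     1.505, 1, 1), nrow = 2, byrow = TRUE)
  fr <- particleFrames(coords, species = c("N", "W"), box = 10,
                       periodic = TRUE)
  g <- computeRDF(fr, "N", "W", binWidth = 0.01, rMax = 2)
  hit <- which(g@g > 0)
  expect_length(hit, 1L)
  expect_true(abs(g@r[hit] - 0.505) < 0.005 + 1e-12)
})

test_that("RDF matches the naive all-pairs double-loop oracle", {
  fr <- simulateMixtureFrames("ideal", nN = 120, nW = 80, box = 4,
                              nFrames = 2, seed = 31)
  for (pair in list(c("N", "N"), c("N", "W"), c("W", "W"))) {
    g <- computeRDF(fr, pair[1], pair[2], binWidth = 0.05, rMax = 2)
    gref <- naiveRDF(fr, pair[1], pair[2], binWidth = 0.05, rMax = 2)
    expect_equal(g@g, gref, tolerance = 1e-12)
  }
})

test_that("RDF is symmetric in species order for distinct species", {
  fr <- simulateMixtureFrames("ideal", nN = 60, nW = 90, box = 4,
                              nFrames = 3, seed = 5)
  gNW <- computeRDF(fr, "N", "W", binWidth = 0.05)
  gWN <- computeRDF(fr, "W", "N", binWidth = 0.05)
  expect_equal(gNW@g, gWN@g, tolerance = 1e-12)
})

test_that("RDF input validation names the violated bound", {
  fr <- simulateMixtureFrames("ideal", nN = 10, nW = 10, box = 4,
                              nFrames = 1, seed = 1)
  expect_error(computeRDF(fr, "N", "W", rMax = 3), "half the smallest box")
  expect_error(computeRDF(fr, "X", "W"), "species 'X'")
})

test_that("KB integral of a flat curve is exactly zero and linear in g-1", {
  r <- seq(0.005, 1.995, by = 0.01)
  flat <- new("RDFCurve", pair = c("N", "N"), r = r, g = rep(1, length(r)),
              binWidth = 0.01, nFrames = 1L)
  expect_identical(kbG(kbIntegral(flat)), 0)

  set.seed(8)
  g1 <- 1 + cumsum(rnorm(length(r), sd = 0.01))
  curve1 <- new("RDFCurve", pair = c("N", "N"), r = r, g = pmax(g1, 0),
                binWidth = 0.01, nFrames = 1L)
  alpha <- 2.5
  curve2 <- new("RDFCurve", pair = c("N", "N"), r = r,
                g = pmax(1 + alpha * (pmax(g1, 0) - 1), 0),
                binWidth = 0.01, nFrames = 1L)
  # alpha chosen so g2 stays nonnegative on this draw
  expect_equal(kbG(kbIntegral(curve2)), alpha * kbG(kbIntegral(curve1)),
               tolerance = 1e-9)
})

test_that("KB running integral matches a 10x finer-grid quadrature oracle", {
  r <- seq(0.005, 1.995, by = 0.01)
  g <- 1 + 1.5 * exp(-(r - 0.45)^2 / 0.02) - 0.8 * exp(-(r - 0.2)^2 / 0.005)
  g <- pmax(g, 0)
  curve <- new("RDFCurve", pair = c("N", "N"), r = r, g = g,
               binWidth = 0.01, nFrames = 1L)
  kb <- kbIntegral(curve)
  last <- length(r)
  expect_equal(kb@running[last], fineGridRunningKB(r, g, r[last]),
               tolerance = 1e-3)
  mid <- 100L
  expect_equal(kb@running[mid], fineGridRunningKB(r, g, r[mid]),
               tolerance = 1e-3)
})

test_that("KB integral rejects an averaging window beyond the curve", {
  r <- seq(0.005, 0.995, by = 0.01)
  curve <- new("RDFCurve", pair = c("N", "N"), r = r, g = rep(1, length(r)),
               binWidth = 0.01, nFrames = 1L)
  expect_error(kbIntegral(curve, rLo = 1.5), "beyond the RDF curve")
  expect_error(kbIntegral(curve, rLo = 0.9, rHi = 0.5), "rLo < rHi")
})

test_that("stability derivative evaluates its defining identity", {
  s0 <- stabilityDerivative(GNN = 2, GNW = 1.5, GWW = 1, rhoN = 3, XN = 0.2)
  expect_equal(stabilityValue(s0), 1)  # G_NN + G_WW - 2 G_NW = 0
  expect_true(isStable(s0))

  s1 <- stabilityDerivative(GNN = 1, GNW = 0, GWW = 1, rhoN = 1, XN = 0.14)
  expect_equal(stabilityValue(s1), 1 / 1.28)
  expect_true(isStable(s1))

  # rho_N X_N (G_NN + G_WW - 2 G_NW) = -1.5 -> derivative -2, unstable
  s2 <- stabilityDerivative(GNN = -3, GNW = 0, GWW = 0, rhoN = 1, XN = 0.5)
  expect_equal(stabilityValue(s2), -2)
  expect_false(isStable(s2))
})

test_that("stability derivative tends to 1 at infinite dilution", {
  d <- vapply(c(1e-2, 1e-4, 1e-6), function(x) {
    stabilityValue(stabilityDerivative(GNN = 5, GNW = -2, GWW = 3,
                                       rhoN = 1, XN = x))
  }, numeric(1))
  expect_true(all(abs(d - 1) < c(0.15, 2e-3, 2e-5)))
})

test_that("stability derivative rejects invalid or singular input", {
  expect_error(stabilityDerivative(1, 0, 1, rhoN = -1, XN = 0.5), "rhoN")
  expect_error(stabilityDerivative(1, 0, 1, rhoN = 1, XN = 1), "XN")
  expect_error(stabilityDerivative(GNN = -1, GNW = 0, GWW = -1,
                                   rhoN = 1, XN = 0.5), "singular")
})

test_that("mixtureStability accepts KBResult inputs end to end", {
  fr <- simulateMixtureFrames("ideal", nN = 80, nW = 120, box = 4,
                              nFrames = 10, seed = 12)
  res <- mixtureStability(fr, binWidth = 0.02)
  expect_s4_class(res$stability, "StabilityResult")
  expect_equal(res$stability@XN, 0.4)
  expect_equal(res$stability@rhoN, 80 / 64)
  expect_equal(res$stability@GNN, kbG(res$kb$NN))
})
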