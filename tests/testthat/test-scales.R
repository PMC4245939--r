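# System bookkeeping, scale derivation algebra and reference conversions.

test_that("system spec fixes the water count from the target mole fraction", {
  sp <- buildSystemSpec("Asp", "URA")
  expect_equal(sp@nWater, 1050L)  # round(0.86 * 171 / 0.14)
  expect_equal(sp@nWater + sp@nBase + sp@nSolute, 1221L)
  expect_equal(sp@counterIon, "Na+")

  expect_equal(buildSystemSpec("A", "CYT", nBase = 1, xWater = 0.5)@nWater, 2L)
  expect_equal(buildSystemSpec("Lys", "GUA")@counterIon, "Cl-")
  expect_equal(buildSystemSpec("R", "ADE")@counterIon, "Cl-")
  expect_equal(buildSystemSpec("Glu", "ADE")@counterIon, "Na+")
  expect_equal(buildSystemSpec("His", "ADE")@counterIon, "none")

  expect_error(buildSystemSpec("Xyz", "URA"), "unknown residue")
  expect_error(buildSystemSpec("A", "DMP"), "unknown nucleobase")
})

test_that("system enumeration covers 38 solutes x 4 bases", {
  specs <- enumerateSystems()
  expect_length(specs, 152L)
  kinds <- vapply(specs, function(s) s@kind, "")
  solutes <- vapply(specs, function(s) s@solute, "")
  expect_equal(sum(kinds == "aa"), 80L)
  expect_equal(sum(kinds == "sca"), 72L)
  expect_false(any(solutes[kinds == "sca"] %in% c("G", "P")))
  expect_true(all(table(vapply(specs, function(s) s@base, "")) == 38L))
})

test_that("water-energy rescaling is proportional in the target count", {
  expect_equal(rescaleWaterEnergy(-1000, 1000, 1000), -1000)
  expect_equal(rescaleWaterEnergy(-1000, 1000, 1050), -1050)
  expect_equal(rescaleWaterEnergy(0, 17, 4242), 0)
  expect_error(rescaleWaterEnergy(-1, 0, 10), "counts")
})

test_that("deltaE derivation applies the water rescaling to the mean", {
  sp <- buildSystemSpec("L", "URA")  # 1050 waters target
  trConst <- energyTrace(rep(-50, 10), rep(-30, 10), solute = "L",
                         base = "URA", nWater = 1050L)
  expect_equal(deriveDeltaE(trConst, sp)$deltaE, -20)

  trEq <- energyTrace(rep(-42, 5), rep(-42, 5), solute = "L", base = "URA",
                      nWater = 1050L)
  expect_equal(deriveDeltaE(trEq, sp)$deltaE, 0)

  # different actual water count: mean e_xw scaled by 1050/1000
  trOff <- energyTrace(rep(-50, 4), rep(-30, 4), solute = "L", base = "URA",
                       nWater = 1000L)
  expect_equal(deriveDeltaE(trOff, sp)$deltaE, -50 + 30 * 1050 / 1000)

  trBad <- energyTrace(rep(-1, 3), rep(-1, 3), solute = "L", base = "CYT")
  expect_error(deriveDeltaE(trBad, sp), "does not match")
})

test_that("deltaE from a noisy synthetic trace lands within 3 standard errors", {
  tr <- simulateEnergyTrace(muXN = -80, muXW = -55, sigma = 4,
                            nFrames = 50000, solute = "L", base = "URA",
                            seed = 99)
  sp <- buildSystemSpec("L", "URA")
  se <- 4 * sqrt(2 / 50000)
  expect_lt(abs(deriveDeltaE(tr, sp)$deltaE - (-25)), 3 * se)
})

test_that("relative scales obey direct evaluation, antisymmetry and telescoping", {
  res <- LETTERS20(scaKind = TRUE)
  set.seed(3)
  a <- propensityScale(setNames(rnorm(18, -20, 10), res), base = "URA",
                       kind = "sca")
  b <- propensityScale(setNames(rnorm(18, 5, 10), res), base = "CYT",
                       kind = "sca")
  cc <- propensityScale(setNames(rnorm(18), res), base = "GUA", kind = "sca")

  ab <- relativeScale(a, b)
  expect_equal(unname(scaleValues(ab)["W"]),
               unname(scaleValues(a)["W"] - scaleValues(b)["W"]))
  expect_equal(scaleValues(ab), -scaleValues(relativeScale(b, a)))
  expect_equal(scaleValues(ab) + scaleValues(relativeScale(b, cc)),
               scaleValues(relativeScale(a, cc)))

  # a known single-residue value: -20 - (+5) = -25
  va <- scaleValues(a); va["W"] <- -20
  vb <- scaleValues(b); vb["W"] <- 5
  a2 <- propensityScale(va, base = "URA", kind = "sca")
  b2 <- propensityScale(vb, base = "CYT", kind = "sca")
  expect_equal(unname(scaleValues(relativeScale(a2, b2))["W"]), -25)
})

test_that("relative scales are invariant to a common constant shift", {
  res <- LETTERS20(scaKind = TRUE)
  set.seed(4)
  v <- setNames(rnorm(18), res)
  w <- setNames(rnorm(18), res)
  a <- propensityScale(v, base = "URA", kind = "sca")
  b <- propensityScale(w, base = "CYT", kind = "sca")
  aShift <- propensityScale(v + 7.3, base = "URA", kind = "sca")
  bShift <- propensityScale(w + 7.3, base = "CYT", kind = "sca")
  expect_equal(scaleValues(relativeScale(aShift, bShift)),
               scaleValues(relativeScale(a, b)))
})

test_that("relative scales refuse mismatched kinds or normalizations", {
  a <- fixtureScaleSCA()
  b <- fixtureScaleAA()
  expect_error(relativeScale(a, b), "kind")
  b2 <- propensityScale(scaleValues(a), base = "CYT", kind = "sca",
                        normalization = 0.9)
  expect_error(relativeScale(a, b2), "normalization")
})

test_that("association constants convert to standard-state free energies", {
  expect_equal(assocConstToDG(1, 300), 0)
  expect_equal(assocConstToDG(10, 300), -5.7437, tolerance = 1e-4)
  # halving K raises dG by RT ln 2
  expect_equal(assocConstToDG(5, 300) - assocConstToDG(10, 300),
               8.314462618e-3 * 300 * log(2))
  expect_error(assocConstToDG(-1), "positive")
  expect_error(assocConstToDG(1, -300), "positive")
})

test_that("solubility converts to saturated mole fraction", {
  expect_equal(solubilityToMoleFraction(0, 135.13), 0)
  x <- solubilityToMoleFraction(1.04, 135.13)
  expect_equal(x, (1.04 / 135.13) / (1.04 / 135.13 + 997 / 18.015))
  expect_error(solubilityToMoleFraction(-1, 135.13), "non-negative")
})

test_that("scale comparison agrees with a textbook-formula oracle", {
  set.seed(6)
  res <- LETTERS20(scaKind = TRUE)
  a <- setNames(rnorm(18), res)
  b <- setNames(rnorm(18), res)
  cmp <- compareScales(a, b)
  expect_equal(cmp$estimate, naiveCor(a, b), tolerance = 1e-12)
  expect_equal(cmp$n, 18L)

  expect_equal(compareScales(a, a)$estimate, 1)
  expect_equal(compareScales(a, a, method = "spearman")$estimate, 1)
  expect_equal(compareScales(a, -2 * a + 7)$estimate, -1)
})

test_that("Pearson scale comparison is affine-invariant, sign-flips under negation", {
  set.seed(7)
  a <- setNames(rnorm(18), LETTERS20(scaKind = TRUE))
  b <- setNames(rnorm(18), LETTERS20(scaKind = TRUE))
  r0 <- compareScales(a, b)$estimate
  expect_equal(compareScales(3 * a + 2, b)$estimate, r0, tolerance = 1e-12)
  expect_equal(compareScales(a, -b)$estimate, -r0, tolerance = 1e-12)
})

test_that("scale comparison supports subsetting and reports failures", {
  set.seed(9)
  a <- setNames(rnorm(20), LETTERS20())
  b <- setNames(rnorm(8), c("S", "T", "V", "L", "M", "K", "F", "W"))
  cmp <- compareScales(a, b)
  expect_equal(cmp$n, 8L)
  cmpEx <- compareScales(a, b, exclude = "K")
  expect_equal(cmpEx$n, 7L)
  expect_equal(cmpEx$estimate,
               naiveCor(a[setdiff(names(b), "K")], b[setdiff(names(b), "K")]),
               tolerance = 1e-12)
  cmpSub <- compareScales(a, b, subset = c("S", "T", "V"))
  expect_equal(cmpSub$n, 3L)
  expect_error(compareScales(a, b[1:2]), "at least 3")
  expect_error(compareScales(a, setNames(rep(1, 8), names(b))),
               "zero variance")
})
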