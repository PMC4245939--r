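# Cognate-pair validation, window profiles and profile matching.

test_that("translation validates, normalizes T->U and strips one trailing stop", {
  p <- translateAndValidate("AUGAAAUAA", "MK")
  expect_true(p@validated)
  expect_equal(p@mrna, "AUGAAA")
  expect_equal(p@protein, "MK")

  pT <- translateAndValidate("ATGAAA", "MK")
  expect_equal(pT@mrna, "AUGAAA")

  expect_error(translateAndValidate("AUGAAA", "MR"), "does not match")
  expect_error(translateAndValidate("AUGAAAU", "MK"), "divisible by 3")
  expect_error(translateAndValidate("AUGUAAAAA", "M*K"), "internal stop")
  expect_error(translateAndValidate("AUGANA", "MX"), "ambiguity")
})

test_that("Gly/Pro exclusion compacts residues together with their codons", {
  p <- translateAndValidate("AUGGGAAAACCGAAG", "MGKPK")
  ex <- excludeGlyPro(p)
  expect_equal(ex@protein, "MKK")
  expect_equal(ex@mrna, "AUGAAAAAG")
  expect_equal(nchar(p@mrna) - nchar(ex@mrna), 6L)

  noGP <- translateAndValidate("AUGAAA", "MK")
  expect_identical(excludeGlyPro(noGP), noGP)

  allGP <- translateAndValidate("GGACCAGGACCA", "GPGP")
  expect_equal(nchar(excludeGlyPro(allGP)@protein), 0L)
})

test_that("content profiles: homopolymer, complementarity and window counts", {
  allC <- strrep("UGC", 30)  # every codon contains C and U and G
  pyrs <- contentProfile(strrep("CCC", 30), bases = c("C", "U"))
  expect_true(all(profileValues(pyrs) == 1))
  expect_length(profileValues(pyrs), 30 - 21 + 1)

  set.seed(10)
  sc <- fixtureScaleAA()
  pair <- simulateCognateProteome(sc, nPairs = 1, coupling = 0.5,
                                  lengthRange = c(60, 60), seed = 2)[[1]]
  pyr <- contentProfile(pair, bases = c("C", "U"))
  pur <- contentProfile(pair, bases = c("A", "G"))
  expect_equal(profileValues(pyr) + profileValues(pur),
               rep(1, length(profileValues(pyr))))

  # single-base profiles partition every window
  tot <- Reduce(`+`, lapply(c("A", "C", "G", "U"), function(b) {
    profileValues(contentProfile(pair, bases = b))
  }))
  expect_equal(tot, rep(1, length(tot)))
})

test_that("a 22-codon mRNA yields exactly the two hand-enumerable windows", {
  set.seed(11)
  sc <- fixtureScaleAA()
  pair <- simulateCognateProteome(sc, nPairs = 1, coupling = 0,
                                  lengthRange = c(22, 22), seed = 3)[[1]]
  prof <- contentProfile(pair, bases = c("C", "U"))
  expect_length(profileValues(prof), 2L)
  expect_equal(profileCenters(prof), 11:12)
  expect_equal(profileValues(prof),
               naiveContent(pair@mrna, c("C", "U"), 21))
})

test_that("content profile rejects bad input", {
  expect_error(contentProfile(strrep("AAA", 10), bases = c("C", "U")),
               "too short")
  expect_error(contentProfile(strrep("AAA", 30), bases = "Z"), "subset")
  expect_error(contentProfile(strrep("AAA", 30), bases = c("C", "U"),
                              window = 20), "odd")
})

test_that("propensity profiles equal the brute-force sliding mean", {
  sc <- fixtureScaleAA()
  set.seed(12)
  protein <- paste(sample(LETTERS20(), 30, replace = TRUE), collapse = "")
  prof <- propensityProfile(protein, sc)
  vals <- scaleValues(sc)[strsplit(protein, "")[[1]]]
  expect_equal(profileValues(prof), naiveSlidingMean(unname(vals), 21),
               tolerance = 1e-12)
  expect_length(profileValues(prof), 30 - 20)

  homo <- strrep("W", 25)
  expect_equal(profileValues(propensityProfile(homo, sc)),
               rep(unname(scaleValues(sc)["W"]), 5))
})

test_that("propensity profile names the residue missing from the scale", {
  sc <- fixtureScaleSCA()
  expect_error(propensityProfile(strrep("WG", 15), sc), "G")
})

test_that("a constructed anti-correlated pair reaches R = -1 exactly", {
  m <- matchPair(antiCorrelatedPair(), antiCorrelatedScale())
  expect_equal(m@r, -1, tolerance = 1e-12)
  expect_equal(m@nPoints, 60L - 20L)
  mPos <- matchPair(posCorrelatedPair(), antiCorrelatedScale())
  expect_equal(mPos@r, 1, tolerance = 1e-12)
})

test_that("matching R is invariant under positive affine maps of the scale", {
  set.seed(13)
  sc <- fixtureScaleAA(rnorm(20))
  pair <- simulateCognateProteome(sc, nPairs = 1, coupling = 0.6,
                                  lengthRange = c(120, 120), seed = 5)[[1]]
  r0 <- matchPair(pair, sc)@r
  sc2 <- propensityScale(3.7 * scaleValues(sc) + 11, base = "URA",
                         kind = "aa")
  expect_equal(matchPair(pair, sc2)@r, r0, tolerance = 1e-12)
})

test_that("purine and pyrimidine content give exactly opposite R", {
  set.seed(14)
  sc <- fixtureScaleSCA()
  pairs <- simulateCognateProteome(sc, nPairs = 5, coupling = 0.4,
                                   seed = 6)
  for (pair in pairs) {
    rPyr <- matchPair(pair, sc, bases = c("C", "U"))@r
    rPur <- matchPair(pair, sc, bases = c("A", "G"))@r
    expect_equal(rPur, -rPyr, tolerance = 1e-12)
  }
})

test_that("per-pair R agrees with an independently coded correlation oracle", {
  set.seed(15)
  sc <- fixtureScaleAA(rnorm(20))
  pairs <- simulateCognateProteome(sc, nPairs = 3, coupling = 0.3,
                                   lengthRange = c(40, 80), seed = 7)
  for (pair in pairs) {
    x <- profileValues(contentProfile(pair, bases = c("C", "U")))
    y <- profileValues(propensityProfile(pair, sc))
    expect_equal(matchPair(pair, sc)@r, naiveCor(x, y), tolerance = 1e-12)
  }
})

test_that("proteome distribution medians, duplication invariance and skips", {
  sc <- antiCorrelatedScale()
  # three pairs with known R: -1, -1, +1 -> median -1
  pairs <- list(antiCorrelatedPair(), antiCorrelatedPair(),
                posCorrelatedPair())
  pairs[[2]]@id <- "anti2"
  pm <- proteomeDistribution(pairs, sc)
  expect_equal(medianR(pm), -1)
  expect_equal(pm@nPairs, 3L)

  # duplicating every pair leaves the median unchanged
  dup <- c(pairs, lapply(pairs, function(p) { p@id <- paste0(p@id, "b"); p }))
  expect_equal(medianR(proteomeDistribution(dup, sc)), medianR(pm))

  # too-short and zero-variance pairs are skipped with reasons
  short <- translateAndValidate(strrep("AUG", 10), strrep("M", 10),
                                id = "short")
  flat <- translateAndValidate(strrep("AAA", 30), strrep("K", 30),
                               id = "flat")  # zero-variance profiles
  pm2 <- proteomeDistribution(c(pairs, list(short, flat)), sc)
  expect_equal(pm2@nPairs, 3L)
  expect_equal(pm2@nSkipped, 2L)
  expect_equal(unname(pm2@skipReasons[c("short", "flat")]),
               c("too_short", "zero_variance"))

  expect_error(proteomeDistribution(list(short), sc), "no usable pairs")
})

test_that("sca-kind scales trigger the Gly/Pro exclusion in proteome runs", {
  sc <- fixtureScaleSCA()
  # 30 informative residues interleaved with prolines: usable only after
  # exclusion-aware handling; with exclusion the effective length is 30
  set.seed(16)
  res <- sample(LETTERS20(scaKind = TRUE), 30, replace = TRUE)
  inter <- paste(rbind(res, "P"), collapse = "")
  codons <- vapply(strsplit(inter, "")[[1]], function(r) {
    nucleoprop:::.codonsForResidue()[[r]][1]
  }, "")
  pair <- pairFromCodons(codons, id = "interleaved")
  m <- matchPair(pair, sc)
  expect_equal(m@nPoints, 30L - 20L)
  ex <- excludeGlyPro(pair)
  expect_equal(m@r, naiveCor(
    profileValues(contentProfile(ex, bases = c("C", "U"))),
    profileValues(propensityProfile(ex, sc))), tolerance = 1e-12)
})

test_that("median matching R is insensitive to the window size", {
  sc <- fixtureScaleSCA(seed = 77)
  prot <- simulateCognateProteome(sc, nPairs = 100, coupling = 0.7,
                                  seed = 1)
  meds <- vapply(c(11L, 21L, 31L, 41L), function(w) {
    medianR(proteomeDistribution(prot, sc, window = w))
  }, numeric(1))
  expect_lt(diff(range(meds)), 0.1)
})
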