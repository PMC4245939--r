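# Independent oracles: deliberately naive implementations (explicit loops,
# textbook formulas) used only to cross-check the package's vectorized code.

# All-pairs double-loop RDF histogram with the same definitional
# normalization (ideal-gas shell counts), written independently of
# computeRDF's vectorized path.
naiveRDF <- function(frames, a, b, binWidth, rMax) {
  box <- frames@box
  V <- prod(box)
  ia <- which(frames@species == a)
  ib <- which(frames@species == b)
  same <- identical(a, b)
  nBins <- floor(rMax / binWidth + 1e-9)
  counts <- numeric(nBins)
  for (fr in frames@coords) {
    for (i in ia) {
      for (j in ib) {
        if (same && j <= i) next
        d <- fr[i, ] - fr[j, ]
        if (frames@periodic) d <- d - box * round(d / box)
        r <- sqrt(sum(d * d))
        k <- floor(r / binWidth) + 1
        if (r > 0 && k <= nBins) counts[k] <- counts[k] + 1
      }
    }
  }
  nPairs <- if (same) length(ia) * (length(ia) - 1) / 2
            else length(ia) * length(ib)
  edges <- binWidth * (0:nBins)
  shellVol <- 4 / 3 * pi * diff(edges^3)
  counts / (length(frames@coords) * nPairs * shellVol / V)
}

# Running Kirkwood-Buff integral by trapezoid on a 10x finer grid through
# linear interpolation of the tabulated curve (g = 0 at r = 0).
fineGridRunningKB <- function(r, g, upTo, refine = 10L) {
  f <- approxfun(c(0, r), c(0, g))
  grid <- seq(0, upTo, length.out = refine * length(r) + 1L)
  y <- 4 * pi * grid^2 * (f(grid) - 1)
  sum(diff(grid) * (y[-1] + y[-length(y)]) / 2)
}

# Textbook-formula Pearson correlation (sum form).
naiveCor <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - sum(x) * sum(y) / n
  den <- sqrt((sum(x^2) - sum(x)^2 / n) * (sum(y^2) - sum(y)^2 / n))
  num / den
}

# Brute-force centred sliding mean, full windows only.
naiveSlidingMean <- function(v, window) {
  h <- (window - 1) %/% 2
  vapply((h + 1):(length(v) - h), function(i) mean(v[(i - h):(i + h)]),
         numeric(1))
}

# Brute-force window base-content fraction per codon centre.
naiveContent <- function(mrna, bases, window) {
  b <- strsplit(mrna, "")[[1]]
  nc <- length(b) / 3
  h <- (window - 1) %/% 2
  vapply((h + 1):(nc - h), function(i) {
    w <- b[(3 * (i - h - 1) + 1):(3 * (i + h))]
    mean(w %in% bases)
  }, numeric(1))
}

# Build a cognate pair from an explicit codon vector.
pairFromCodons <- function(codons, id = "fixture") {
  protein <- paste(vapply(codons, function(cd) {
    as.character(Biostrings::translate(Biostrings::RNAString(cd)))
  }, ""), collapse = "")
  translateAndValidate(paste(codons, collapse = ""), protein, id = id)
}

# Fixture scale covering all 20 residues (deterministic values).
fixtureScaleAA <- function(values = NULL) {
  if (is.null(values)) values <- seq(-10, 9, length.out = 20)
  propensityScale(setNames(values, LETTERS20()), base = "URA", kind = "aa")
}

fixtureScaleSCA <- function(seed = 401) {
  set.seed(seed)
  propensityScale(setNames(rnorm(18), LETTERS20(scaKind = TRUE)),
                  base = "URA", kind = "sca")
}

# Deterministic sidechain-analog scale whose informative residues all have
# pyrimidine-flexible synonym families (Leu/Ser/Arg/Ile/Val/Ala/Thr), so
# the generator's coupling dial acts at full strength.
strongCouplingScale <- function() {
  v <- setNames(rep(0, 18), LETTERS20(scaKind = TRUE))
  v[c("L", "S", "R", "I", "V", "A", "T")] <- c(-3, -2, -1, 1, 2, 3, 1.5)
  propensityScale(v, base = "URA", kind = "sca")
}

# Pair whose propensity profile is an exact negative affine transform of
# its pyrimidine-content profile: Phe (UUU, all-pyrimidine codon, scale -1)
# vs Lys (AAA, all-purine codon, scale +1) blocks.
antiCorrelatedPair <- function() {
  codons <- c(rep("UUU", 15), rep("AAA", 30), rep("UUU", 15))
  pairFromCodons(codons, id = "anti")
}

antiCorrelatedScale <- function() {
  v <- setNames(rep(0, 20), LETTERS20())
  v["F"] <- -1
  v["K"] <- 1
  v["Y"] <- 1
  v["E"] <- -1
  propensityScale(v, base = "URA", kind = "aa")
}

# Companion pair reaching R = +1 with the same scale: Tyr (UAU, 2
# pyrimidines, scale +1) vs Glu (GAA, 0 pyrimidines, scale -1).
posCorrelatedPair <- function() {
  codons <- c(rep("UAU", 15), rep("GAA", 30), rep("UAU", 15))
  pairFromCodons(codons, id = "pos")
}
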