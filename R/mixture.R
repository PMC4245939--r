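# Radial distribution functions, Kirkwood-Buff integrals and the
# microscopic-stability criterion for nucleobase/water mixtures.

#' Construct a ParticleFrames object
#'
#' @param coords list of `n x 3` coordinate matrices (nm), one per frame,
#'   or a single matrix for one frame.
#' @param species character vector of species labels (`"N"`, `"W"`, `"X"`),
#'   one per particle, constant across frames.
#' @param box numeric length-3 orthorhombic box edges (nm), or a scalar for
#'   a cubic box.
#' @param periodic logical; apply the minimum-image convention.
#' @return a [ParticleFrames-class] object.
#' @export
#' @examples
#' fr <- particleFrames(matrix(runif(30, 0, 4), ncol = 3),
#'                      species = rep(c("N", "W"), each = 5), box = 4)
particleFrames <- function(coords, species, box, periodic = TRUE) {
  if (is.matrix(coords)) coords <- list(coords)
  coords <- lapply(coords, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    dimnames(m) <- NULL
    m
  })
  if (length(box) == 1L) box <- rep(box, 3L)
  new("ParticleFrames", coords = coords, species = as.character(species),
      box = as.numeric(box), periodic = isTRUE(periodic))
}

# Pairwise distances between rows of A and rows of B, minimum image if
# periodic. For same = TRUE (A is B), returns each unordered pair once.
.pairDistances <- function(A, B, box, periodic, same) {
  dx <- outer(A[, 1], B[, 1], "-")
  dy <- outer(A[, 2], B[, 2], "-")
  dz <- outer(A[, 3], B[, 3], "-")
  if (periodic) {
    dx <- dx - box[1] * round(dx / box[1])
    dy <- dy - box[2] * round(dy / box[2])
    dz <- dz - box[3] * round(dz / box[3])
  }
  d2 <- dx * dx + dy * dy + dz * dz
  if (same) sqrt(d2[upper.tri(d2)]) else sqrt(as.vector(d2))
}

#' Radial distribution function between two labeled species
#'
#' Standard pair-distance histogram, averaged over frames and normalized by
#' the ideal-gas expectation `n_pairs * V_shell / V` so that an uncorrelated
#' (Poisson) system gives `g(r) = 1`. Uses the minimum-image convention for
#' periodic frames; self-pairs are excluded when `speciesA == speciesB`.
#'
#' @param frames a [ParticleFrames-class] object.
#' @param speciesA,speciesB species labels; order is irrelevant
#'   (`g_NW == g_WN` bin by bin).
#' @param binWidth histogram bin width in nm (default 0.01 nm, fine enough
#'   to resolve first-shell structure at 0.3-0.5 nm).
#' @param rMax upper distance cutoff (nm). Defaults to, and for periodic
#'   frames must not exceed, half the smallest box edge.
#' @return an [RDFCurve-class] with bin centres and g(r) values.
#' @export
#' @examples
#' fr <- simulateMixtureFrames("ideal", nN = 100, nW = 100, nFrames = 5,
#'                             seed = 1)
#' g <- computeRDF(fr, "N", "W")
computeRDF <- function(frames, speciesA, speciesB,
                       binWidth = 0.01, rMax = NULL) {
  stopifnot(is(frames, "ParticleFrames"))
  box <- frames@box
  halfMin <- min(box) / 2
  if (is.null(rMax)) rMax <- if (frames@periodic) halfMin else max(box) / 2
  if (frames@periodic && rMax > halfMin + 1e-12) {
    .stopf("rMax (%g nm) exceeds half the smallest box edge (%g nm)",
           rMax, halfMin)
  }
  if (binWidth <= 0 || rMax <= binWidth) {
    .stopf("need 0 < binWidth < rMax")
  }
  ia <- which(frames@species == speciesA)
  ib <- which(frames@species == speciesB)
  if (length(ia) == 0L) .stopf("no particles with species '%s'", speciesA)
  if (length(ib) == 0L) .stopf("no particles with species '%s'", speciesB)
  same <- identical(speciesA, speciesB)
  if (same && length(ia) < 2L) {
    .stopf("species '%s' needs at least 2 particles for a same-species RDF",
           speciesA)
  }

  nBins <- as.integer(floor(rMax / binWidth + 1e-9))
  edges <- binWidth * (0:nBins)
  counts <- numeric(nBins)
  for (fr in frames@coords) {
    d <- .pairDistances(fr[ia, , drop = FALSE], fr[ib, , drop = FALSE],
                        box, frames@periodic, same)
    d <- d[d > 0 & d < edges[nBins + 1L]]
    counts <- counts + tabulate(findInterval(d, edges), nbins = nBins)
  }

  V <- prod(box)
  nPairs <- if (same) length(ia) * (length(ia) - 1) / 2
            else length(ia) * length(ib)
  shellVol <- 4 / 3 * pi * diff(edges^3)
  expected <- length(frames@coords) * nPairs * shellVol / V
  new("RDFCurve", pair = c(speciesA, speciesB),
      r = edges[-1L] - binWidth / 2, g = counts / expected,
      binWidth = binWidth, nFrames = length(frames@coords))
}

#' Kirkwood-Buff integral of an RDF with plateau averaging
#'
#' Computes the running integral `G(r) = 4 pi Int_0^r r'^2 [g(r') - 1] dr'`
#' by trapezoidal quadrature on the RDF bin grid (with `g(0) = 0` below the
#' first bin centre) and reports the Kirkwood-Buff integral as the mean of
#' the running curve over the plateau window `[rLo, rHi]`. Averaging over a
#' window rather than reading off the endpoint damps the slow convergence
#' of the running integral.
#'
#' @param rdf an [RDFCurve-class].
#' @param rLo lower edge of the averaging window in nm (default 1.5 nm).
#' @param rHi upper edge in nm; defaults to the last bin centre.
#' @return a [KBResult-class]; extract the scalar integral with [kbG()].
#' @export
#' @examples
#' flat <- new("RDFCurve", pair = c("N", "N"), r = seq(0.005, 1.995, 0.01),
#'             g = rep(1, 200), binWidth = 0.01, nFrames = 1L)
#' kbG(kbIntegral(flat))  # exactly 0
kbIntegral <- function(rdf, rLo = 1.5, rHi = NULL) {
  stopifnot(is(rdf, "RDFCurve"))
  r <- rdf@r
  if (rLo > r[length(r)] + 1e-12) {
    .stopf("rLo (%g nm) lies beyond the RDF curve (last bin centre %g nm)",
           rLo, r[length(r)])
  }
  if (is.null(rHi)) rHi <- r[length(r)]
  if (rLo >= rHi) .stopf("need rLo < rHi")
  # Integrand on nodes (0, r_1, ..., r_k); g extrapolated to 0 at r = 0,
  # where the r^2 weight vanishes anyway.
  nodes <- c(0, r)
  f <- c(0, 4 * pi * r^2 * (rdf@g - 1))
  running <- cumsum(c(0, diff(nodes) * (head(f, -1) + f[-1]) / 2))[-1L]
  inw <- r >= rLo - 1e-12 & r <= rHi + 1e-12
  if (!any(inw)) .stopf("averaging window [%g, %g] contains no bins", rLo, rHi)
  new("KBResult", G = mean(running[inw]), running = running, r = r,
      window = c(rLo, rHi))
}

#' Microscopic stability derivative of a binary mixture
#'
#' Evaluates the derivative of the log-activity of the nucleobase with
#' respect to its log mole fraction,
#' `1 / (1 + rho_N X_N (G_NN + G_WW - 2 G_NW))`, from the three
#' Kirkwood-Buff integrals. A positive derivative means the mixture is
#' microscopically stable against demixing at the examined scale.
#'
#' @param GNN,GNW,GWW Kirkwood-Buff integrals (nm^3) of the
#'   nucleobase/nucleobase, nucleobase/water and water/water RDFs, either
#'   numerics or [KBResult-class] objects.
#' @param rhoN nucleobase number density (nm^-3), positive.
#' @param XN nucleobase mole fraction in (0, 1).
#' @return a [StabilityResult-class].
#' @export
#' @examples
#' stabilityDerivative(GNN = 1, GNW = 0, GWW = 1, rhoN = 1, XN = 0.14)
stabilityDerivative <- function(GNN, GNW, GWW, rhoN, XN) {
  g <- function(x) if (is(x, "KBResult")) x@G else as.numeric(x)
  GNN <- g(GNN); GNW <- g(GNW); GWW <- g(GWW)
  if (!(rhoN > 0)) .stopf("rhoN must be positive")
  if (!(XN > 0 && XN < 1)) .stopf("XN must lie strictly between 0 and 1")
  denom <- 1 + rhoN * XN * (GNN + GWW - 2 * GNW)
  if (abs(denom) < 1e-12) {
    .stopf("singular point: 1 + rho_N X_N (G_NN + G_WW - 2 G_NW) = 0")
  }
  d <- 1 / denom
  new("StabilityResult", rhoN = rhoN, XN = XN,
      GNN = GNN, GNW = GNW, GWW = GWW,
      derivative = d, isStable = d > 0)
}

#' Full stability analysis of a nucleobase/water ParticleFrames object
#'
#' Convenience pipeline: computes the N/N, N/W and W/W RDFs, their
#' Kirkwood-Buff integrals (plateau-averaged from `rLo`), the nucleobase
#' number density (particle count over box volume) and mole fraction, and
#' the stability derivative. Solute (`"X"`) particles are ignored for the
#' mixture bookkeeping.
#'
#' @inheritParams computeRDF
#' @inheritParams kbIntegral
#' @return a list with elements `rdf` (named list of [RDFCurve-class]),
#'   `kb` (named list of [KBResult-class]) and `stability`
#'   (a [StabilityResult-class]).
#' @export
mixtureStability <- function(frames, binWidth = 0.01, rMax = NULL,
                             rLo = 1.5, rHi = NULL) {
  stopifnot(is(frames, "ParticleFrames"))
  nN <- sum(frames@species == "N")
  nW <- sum(frames@species == "W")
  if (nN < 2L || nW < 2L) .stopf("need at least 2 N and 2 W particles")
  pairs <- list(NN = c("N", "N"), NW = c("N", "W"), WW = c("W", "W"))
  rdf <- lapply(pairs, function(p) {
    computeRDF(frames, p[1], p[2], binWidth = binWidth, rMax = rMax)
  })
  kb <- lapply(rdf, kbIntegral, rLo = rLo, rHi = rHi)
  stab <- stabilityDerivative(GNN = kb$NN, GNW = kb$NW, GWW = kb$WW,
                              rhoN = nN / prod(frames@box),
                              XN = nN / (nN + nW))
  list(rdf = rdf, kb = kb, stability = stab)
}
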