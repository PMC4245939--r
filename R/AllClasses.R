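# S4 classes for the pipeline's central objects.

#' ParticleFrames: labeled particle positions over simulation frames
#'
#' Holds centre-of-mass positions of labeled species (`"N"` nucleobase,
#' `"W"` water, `"X"` solute) for one or more frames in an orthorhombic,
#' optionally periodic box. Coordinates are in nanometres. The species
#' composition is constant across frames.
#'
#' @slot coords list of numeric matrices, one per frame, each `n x 3`.
#' @slot species character vector of length `n`, values in `N`, `W`, `X`.
#' @slot box numeric length-3 box edge lengths (nm).
#' @slot periodic logical; minimum-image convention applies when `TRUE`.
#' @exportClass ParticleFrames
setClass("ParticleFrames",
  representation(coords = "list", species = "character",
                 box = "numeric", periodic = "logical"))

setValidity("ParticleFrames", function(object) {
  if (length(object@box) != 3L || any(object@box <= 0)) {
    return("box must be three positive edge lengths (nm)")
  }
  if (length(object@coords) < 1L) return("at least one frame is required")
  n <- length(object@species)
  if (n < 1L) return("at least one particle is required")
  if (!all(object@species %in% c("N", "W", "X"))) {
    return("species labels must be drawn from {N, W, X}")
  }
  for (fr in object@coords) {
    if (!is.matrix(fr) || ncol(fr) != 3L || nrow(fr) != n) {
      return("each frame must be an n x 3 coordinate matrix matching species")
    }
    if (object@periodic &&
        any(fr < -1e-9 | sweep(fr, 2, object@box) > 1e-9)) {
      return("periodic frames must have all coordinates inside the box")
    }
  }
  TRUE
})

#' RDFCurve: radial distribution function for a species pair
#'
#' @slot pair character of length 2, the ordered species pair.
#' @slot r numeric bin centres (nm), strictly increasing, uniform.
#' @slot g numeric g(r) values, non-negative.
#' @slot binWidth numeric bin width (nm).
#' @slot nFrames integer number of frames averaged.
#' @exportClass RDFCurve
setClass("RDFCurve",
  representation(pair = "character", r = "numeric", g = "numeric",
                 binWidth = "numeric", nFrames = "integer"))

setValidity("RDFCurve", function(object) {
  if (length(object@pair) != 2L) return("pair must name two species")
  if (length(object@r) != length(object@g)) return("r and g lengths differ")
  if (length(object@r) < 2L) return("need at least two bins")
  dr <- diff(object@r)
  if (any(dr <= 0)) return("r must be strictly increasing")
  if (max(abs(dr - object@binWidth)) > 1e-8) return("bins must be uniform")
  if (any(object@g < -1e-12)) return("g(r) must be non-negative")
  TRUE
})

#' KBResult: Kirkwood-Buff integral with its running curve
#'
#' The running integral is `G(r) = 4 pi Int_0^r r'^2 [g(r') - 1] dr'`
#' evaluated on the RDF bin grid; the scalar `G` is the mean of the running
#' curve over the plateau-averaging window.
#'
#' @slot G numeric Kirkwood-Buff integral (nm^3).
#' @slot running numeric running integral at each bin centre (nm^3).
#' @slot r numeric bin centres (nm).
#' @slot window numeric length-2 averaging window `[r_lo, r_hi]` (nm).
#' @exportClass KBResult
setClass("KBResult",
  representation(G = "numeric", running = "numeric", r = "numeric",
                 window = "numeric"))

setValidity("KBResult", function(object) {
  if (length(object@running) != length(object@r)) {
    return("running and r lengths differ")
  }
  if (length(object@window) != 2L || object@window[1] >= object@window[2]) {
    return("window must be [r_lo, r_hi] with r_lo < r_hi")
  }
  inw <- object@r >= object@window[1] - 1e-12 &
         object@r <= object@window[2] + 1e-12
  if (!any(inw)) return("averaging window contains no bins")
  if (abs(object@G - mean(object@running[inw])) > 1e-8 * max(1, abs(object@G))) {
    return("G must equal the mean of the running integral over the window")
  }
  TRUE
})

#' StabilityResult: microscopic stability of a binary mixture
#'
#' Stores the derivative of ln(nucleobase activity) with respect to
#' ln(nucleobase mole fraction),
#' `1 / (1 + rho_N X_N (G_NN + G_WW - 2 G_NW))`, which must be positive for
#' the mixture to be microscopically stable against demixing.
#'
#' @slot rhoN nucleobase number density (nm^-3).
#' @slot XN nucleobase mole fraction.
#' @slot GNN,GNW,GWW Kirkwood-Buff integrals (nm^3).
#' @slot derivative the stability derivative (dimensionless).
#' @slot isStable logical, `derivative > 0`.
#' @exportClass StabilityResult
setClass("StabilityResult",
  representation(rhoN = "numeric", XN = "numeric",
                 GNN = "numeric", GNW = "numeric", GWW = "numeric",
                 derivative = "numeric", isStable = "logical"))

setValidity("StabilityResult", function(object) {
  expected <- 1 / (1 + object@rhoN * object@XN *
                     (object@GNN + object@GWW - 2 * object@GNW))
  if (abs(object@derivative - expected) > 1e-8 * max(1, abs(expected))) {
    return("derivative inconsistent with its defining formula")
  }
  if (!identical(object@isStable, unname(object@derivative > 0))) {
    return("isStable must equal derivative > 0")
  }
  TRUE
})

#' EnergyTrace: per-frame solute interaction energies
#'
#' Per-frame total potential energies (kJ/mol) between one solute and all
#' nucleobase molecules (`eXN`) and between the solute and all water
#' molecules (`eXW`), with the system composition recorded for water-count
#' rescaling.
#'
#' @slot solute residue identifier (one-letter, or `"X"` for generic).
#' @slot base nucleobase (`ADE`, `CYT`, `GUA`, `URA`).
#' @slot eXN,eXW equal-length numeric energy series (kJ/mol).
#' @slot nWater,nBase integer molecule counts in the simulated system.
#' @exportClass EnergyTrace
setClass("EnergyTrace",
  representation(solute = "character", base = "character",
                 eXN = "numeric", eXW = "numeric",
                 nWater = "integer", nBase = "integer"))

setValidity("EnergyTrace", function(object) {
  if (length(object@eXN) != length(object@eXW)) {
    return("eXN and eXW must have equal length")
  }
  if (length(object@eXN) < 1L) return("at least one frame is required")
  if (object@nWater < 1L || object@nBase < 1L) {
    return("nWater and nBase must be positive")
  }
  TRUE
})

#' SystemSpec: composition bookkeeping for one simulated system
#'
#' @slot solute one-letter residue identifier.
#' @slot kind `"aa"` (zwitterionic amino acid) or `"sca"` (sidechain analog).
#' @slot base nucleobase.
#' @slot nSolute,nBase,nWater molecule counts.
#' @slot counterIon `"none"`, `"Na+"` or `"Cl-"` (electroneutrality).
#' @slot xWater target water mole fraction.
#' @slot productionNs production run length (ns).
#' @exportClass SystemSpec
setClass("SystemSpec",
  representation(solute = "character", kind = "character", base = "character",
                 nSolute = "integer", nBase = "integer", nWater = "integer",
                 counterIon = "character", xWater = "numeric",
                 productionNs = "numeric"))

setValidity("SystemSpec", function(object) {
  if (!object@kind %in% c("aa", "sca")) return("kind must be 'aa' or 'sca'")
  if (object@kind == "sca" && object@solute %in% c("G", "P")) {
    return("no sidechain analog exists for Gly or Pro")
  }
  if (!object@counterIon %in% c("none", "Na+", "Cl-")) {
    return("counterIon must be 'none', 'Na+' or 'Cl-'")
  }
  tot <- object@nWater + object@nBase + object@nSolute
  if (abs(object@nWater / tot - object@xWater) > 0.5 / tot + 1e-9) {
    return("nWater inconsistent with xWater beyond rounding")
  }
  TRUE
})

#' PropensityScale: residue-to-energy interaction propensity scale
#'
#' Maps residues to `Delta E_NW` values (kJ/mol): the mean solute-nucleobase
#' potential energy minus the (rescaled) mean solute-water potential energy.
#' Lower values mean a more favourable interaction with the nucleobase.
#' Amino-acid (`"aa"`) scales cover all 20 residues; sidechain-analog
#' (`"sca"`) scales cover the 18 residues with analogs (no Gly/Pro).
#'
#' @slot base nucleobase the scale refers to (or a free label such as
#'   `"RANDOM"` for permutation-null scales).
#' @slot kind `"aa"` or `"sca"`.
#' @slot values named numeric, residue (one-letter) to value.
#' @slot normalization water mole fraction the values correspond to.
#' @exportClass PropensityScale
setClass("PropensityScale",
  representation(base = "character", kind = "character",
                 values = "numeric", normalization = "numeric"))

setValidity("PropensityScale", function(object) {
  if (!object@kind %in% c("aa", "sca")) return("kind must be 'aa' or 'sca'")
  res <- names(object@values)
  if (is.null(res) || anyDuplicated(res)) {
    return("values must be uniquely named by residue")
  }
  if (!all(res %in% .AA20)) {
    return(paste("unknown residue letters:",
                 paste(setdiff(res, .AA20), collapse = ", ")))
  }
  want <- if (object@kind == "sca") .SCA18 else .AA20
  if (!setequal(res, want)) {
    return(sprintf("%s scales must cover exactly {%s}",
                   object@kind, paste(want, collapse = ",")))
  }
  if (any(!is.finite(object@values))) return("values must be finite")
  TRUE
})

#' RelativeScale: preference for one nucleobase over another
#'
#' Per residue, `Delta E_N1N2 = Delta E_N1W - Delta E_N2W`: negative values
#' mean the residue prefers nucleobase `N1` to `N2`.
#'
#' @slot basePair ordered character pair `(N1, N2)`.
#' @slot kind `"aa"` or `"sca"`.
#' @slot values named numeric over the residue intersection of the inputs.
#' @exportClass RelativeScale
setClass("RelativeScale",
  representation(basePair = "character", kind = "character",
                 values = "numeric"))

setValidity("RelativeScale", function(object) {
  if (length(object@basePair) != 2L) return("basePair must name two bases")
  if (!object@kind %in% c("aa", "sca")) return("kind must be 'aa' or 'sca'")
  res <- names(object@values)
  if (is.null(res) || anyDuplicated(res) || !all(res %in% .AA20)) {
    return("values must be uniquely named by standard residues")
  }
  TRUE
})

#' CognatePair: an mRNA coding sequence and the protein it encodes
#'
#' The mRNA is held in the RNA alphabet (`A`,`C`,`G`,`U`; `T` is normalized
#' on input) with any single trailing stop codon stripped, so that
#' `nchar(mrna) == 3 * nchar(protein)` and the standard-code translation of
#' `mrna` equals `protein` exactly when `validated` is `TRUE`.
#'
#' @slot id record identifier.
#' @slot mrna coding sequence (RNA alphabet, stop stripped).
#' @slot protein amino-acid sequence (20 standard one-letter codes).
#' @slot validated logical translation-validity flag.
#' @exportClass CognatePair
setClass("CognatePair",
  representation(id = "character", mrna = "character",
                 protein = "character", validated = "logical"))

setValidity("CognatePair", function(object) {
  if (nchar(object@mrna) != 3L * nchar(object@protein)) {
    return("mRNA length must be exactly 3 x protein length (stop stripped)")
  }
  if (grepl("[^ACGU]", object@mrna)) {
    return("mRNA must be over the A/C/G/U alphabet")
  }
  if (nchar(object@protein) > 0L &&
      !all(strsplit(object@protein, "")[[1]] %in% .AA20)) {
    return("protein must be over the 20 standard residues")
  }
  TRUE
})

#' SequenceProfile: window-averaged property along a sequence
#'
#' One value per centre position with a complete window (no edge padding):
#' a sequence of effective length `L` yields `L - window + 1` values.
#' Content profiles are base fractions in `[0, 1]` over 3 x window bases;
#' propensity profiles are window means of a residue scale (kJ/mol).
#'
#' @slot property label, e.g. `"PYR content"` or `"propensity:URA/sca"`.
#' @slot centers integer centre indices (codon/residue coordinates, 1-based).
#' @slot values numeric window means.
#' @slot window odd integer window size in residues/codons.
#' @exportClass SequenceProfile
setClass("SequenceProfile",
  representation(property = "character", centers = "integer",
                 values = "numeric", window = "integer"))

setValidity("SequenceProfile", function(object) {
  if (length(object@centers) != length(object@values)) {
    return("centers and values lengths differ")
  }
  if (object@window < 3L || object@window %% 2L == 0L) {
    return("window must be an odd integer >= 3")
  }
  TRUE
})

#' MatchResult: per-pair profile-matching correlation
#'
#' @slot pairId pair identifier.
#' @slot r Pearson correlation between the aligned content and propensity
#'   profiles (`NA` when undefined, e.g. a zero-variance profile).
#' @slot nPoints number of aligned profile points used.
#' @exportClass MatchResult
setClass("MatchResult",
  representation(pairId = "character", r = "numeric", nPoints = "integer"))

setValidity("MatchResult", function(object) {
  if (!is.na(object@r) && (object@r < -1 - 1e-12 || object@r > 1 + 1e-12)) {
    return("r must lie in [-1, 1]")
  }
  TRUE
})

#' ProteomeMatch: distribution of profile-matching correlations
#'
#' @slot scaleLabel label of the propensity scale used.
#' @slot contentLabel label of the mRNA content property.
#' @slot rValues named numeric per-pair Pearson correlations.
#' @slot medianR sample median of `rValues`.
#' @slot nPairs number of usable pairs.
#' @slot nSkipped number of skipped pairs.
#' @slot skipReasons named character, reason per skipped pair.
#' @exportClass ProteomeMatch
setClass("ProteomeMatch",
  representation(scaleLabel = "character", contentLabel = "character",
                 rValues = "numeric", medianR = "numeric",
                 nPairs = "integer", nSkipped = "integer",
                 skipReasons = "character"))

setValidity("ProteomeMatch", function(object) {
  if (object@nPairs != length(object@rValues)) {
    return("nPairs must equal length(rValues)")
  }
  if (object@nSkipped != length(object@skipReasons)) {
    return("nSkipped must equal length(skipReasons)")
  }
  if (object@nPairs > 0L &&
      abs(object@medianR - median(object@rValues)) > 1e-12) {
    return("medianR must be the sample median of rValues")
  }
  TRUE
})

#' ScaleNull: random-scale permutation null for a proteome median
#'
#' The empirical p-value is the fraction of uniform-random residue scales
#' whose proteome median |R| is at least the observed median |R|; its
#' resolution is `1 / nRandom` and `p = 0` is reported as such (annotated
#' `< 1/nRandom` by `show`).
#'
#' @slot nRandom number of random scales drawn.
#' @slot seed RNG seed used.
#' @slot observedMedian observed proteome median R.
#' @slot nullMedians numeric vector of null medians (possibly empty if not
#'   retained).
#' @slot pValue empirical p-value in `[0, 1]`.
#' @exportClass ScaleNull
setClass("ScaleNull",
  representation(nRandom = "integer", seed = "integer",
                 observedMedian = "numeric", nullMedians = "numeric",
                 pValue = "numeric"))

setValidity("ScaleNull", function(object) {
  if (object@pValue < 0 || object@pValue > 1) return("pValue must be in [0,1]")
  k <- object@pValue * object@nRandom
  if (abs(k - round(k)) > 1e-9) {
    return("pValue must be a multiple of 1/nRandom")
  }
  TRUE
})
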