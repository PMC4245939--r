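# Accessor generics and show methods.

#' Accessors for pipeline objects
#'
#' Small accessor family so downstream code never touches slots directly:
#' `scaleValues()`/`scaleKind()`/`scaleBase()` for [PropensityScale-class]
#' and [RelativeScale-class]; `profileValues()`/`profileCenters()` for
#' [SequenceProfile-class]; `kbG()` for [KBResult-class];
#' `stabilityValue()`/`isStable()` for [StabilityResult-class];
#' `rValues()`/`medianR()` for [ProteomeMatch-class]; and `pValue()` /
#' `nullMedians()` for [ScaleNull-class].
#'
#' @param x an object of the documented class.
#' @return The slot contents (see the class documentation for units).
#' @name accessors
#' @aliases scaleValues scaleKind scaleBase profileValues profileCenters
#'   kbG stabilityValue isStable rValues medianR pValue nullMedians
#' @examples
#' sc <- propensityScale(setNames(seq_len(18), setdiff(LETTERS20(), c("G","P"))),
#'                       base = "URA", kind = "sca")
#' scaleValues(sc)["W"]
#' scaleKind(sc)
NULL

#' @export
setGeneric("scaleValues", function(x) standardGeneric("scaleValues"))
#' @export
setGeneric("scaleKind", function(x) standardGeneric("scaleKind"))
#' @export
setGeneric("scaleBase", function(x) standardGeneric("scaleBase"))
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))
#' @export
setGeneric("profileCenters", function(x) standardGeneric("profileCenters"))
#' @export
setGeneric("kbG", function(x) standardGeneric("kbG"))
#' @export
setGeneric("stabilityValue", function(x) standardGeneric("stabilityValue"))
#' @export
setGeneric("isStable", function(x) standardGeneric("isStable"))
#' @export
setGeneric("rValues", function(x) standardGeneric("rValues"))
#' @export
setGeneric("medianR", function(x) standardGeneric("medianR"))
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @export
setGeneric("nullMedians", function(x) standardGeneric("nullMedians"))

#' @rdname accessors
setMethod("scaleValues", "PropensityScale", function(x) x@values)
#' @rdname accessors
setMethod("scaleValues", "RelativeScale", function(x) x@values)
#' @rdname accessors
setMethod("scaleKind", "PropensityScale", function(x) x@kind)
#' @rdname accessors
setMethod("scaleKind", "RelativeScale", function(x) x@kind)
#' @rdname accessors
setMethod("scaleBase", "PropensityScale", function(x) x@base)
#' @rdname accessors
setMethod("scaleBase", "RelativeScale", function(x) x@basePair)
#' @rdname accessors
setMethod("profileValues", "SequenceProfile", function(x) x@values)
#' @rdname accessors
setMethod("profileCenters", "SequenceProfile", function(x) x@centers)
#' @rdname accessors
setMethod("kbG", "KBResult", function(x) x@G)
#' @rdname accessors
setMethod("stabilityValue", "StabilityResult", function(x) x@derivative)
#' @rdname accessors
setMethod("isStable", "StabilityResult", function(x) x@isStable)
#' @rdname accessors
setMethod("rValues", "ProteomeMatch", function(x) x@rValues)
#' @rdname accessors
setMethod("medianR", "ProteomeMatch", function(x) x@medianR)
#' @rdname accessors
setMethod("pValue", "ScaleNull", function(x) x@pValue)
#' @rdname accessors
setMethod("nullMedians", "ScaleNull", function(x) x@nullMedians)

#' One-letter codes of the 20 standard residues
#'
#' Convenience export of the canonical residue alphabet (alphabetical order),
#' mainly for building scales in examples and scripts.
#'
#' @param scaKind if `TRUE`, return the 18 residues that have sidechain
#'   analogs (Gly and Pro dropped).
#' @return character vector of one-letter residue codes.
#' @export
LETTERS20 <- function(scaKind = FALSE) if (scaKind) .SCA18 else .AA20

setMethod("show", "ParticleFrames", function(object) {
  cat(sprintf("ParticleFrames: %d frame(s), %d particles (%s), box %s nm%s\n",
              length(object@coords), length(object@species),
              paste(sprintf("%s=%d", names(table(object@species)),
                            as.integer(table(object@species))), collapse = " "),
              paste(signif(object@box, 4), collapse = " x "),
              if (object@periodic) ", periodic" else ""))
})

setMethod("show", "RDFCurve", function(object) {
  cat(sprintf("RDFCurve %s/%s: %d bins of %.4g nm up to %.4g nm (%d frames)\n",
              object@pair[1], object@pair[2], length(object@r),
              object@binWidth, max(object@r) + object@binWidth / 2,
              object@nFrames))
})

setMethod("show", "KBResult", function(object) {
  cat(sprintf("KBResult: G = %.5g nm^3 (mean of running integral over [%.3g, %.3g] nm)\n",
              object@G, object@window[1], object@window[2]))
})

setMethod("show", "StabilityResult", function(object) {
  cat(sprintf("StabilityResult: d(ln a_N)/d(ln X_N) = %.5g -> %s\n",
              object@derivative,
              if (object@isStable) "microscopically stable"
              else "NOT microscopically stable"))
  cat(sprintf("  rho_N = %.5g nm^-3, X_N = %.4g; G_NN = %.4g, G_NW = %.4g, G_WW = %.4g nm^3\n",
              object@rhoN, object@XN, object@GNN, object@GNW, object@GWW))
})

setMethod("show", "EnergyTrace", function(object) {
  cat(sprintf("EnergyTrace %s/%s: %d frames; mean E_XN = %.4g, mean E_XW = %.4g kJ/mol (nWater = %d, nBase = %d)\n",
              object@solute, object@base, length(object@eXN),
              mean(object@eXN), mean(object@eXW),
              object@nWater, object@nBase))
})

setMethod("show", "SystemSpec", function(object) {
  cat(sprintf("SystemSpec: %s (%s) in %s/water; %d base, %d water, counter ion %s; x_water = %.3g; %g ns\n",
              object@solute, object@kind, object@base, object@nBase,
              object@nWater, object@counterIon, object@xWater,
              object@productionNs))
})

setMethod("show", "PropensityScale", function(object) {
  cat(sprintf("PropensityScale (%s, %s): %d residues, normalization x_water = %.3g\n",
              object@base, object@kind, length(object@values),
              object@normalization))
  print(round(object@values, 3))
})

setMethod("show", "RelativeScale", function(object) {
  cat(sprintf("RelativeScale %s-%s (%s): %d residues\n",
              object@basePair[1], object@basePair[2], object@kind,
              length(object@values)))
  print(round(object@values, 3))
})

setMethod("show", "CognatePair", function(object) {
  cat(sprintf("CognatePair %s: %d residues / %d bases%s\n",
              object@id, nchar(object@protein), nchar(object@mrna),
              if (object@validated) " (validated)" else " (NOT validated)"))
})

setMethod("show", "SequenceProfile", function(object) {
  cat(sprintf("SequenceProfile '%s': %d centres, window %d\n",
              object@property, length(object@values), object@window))
})

setMethod("show", "MatchResult", function(object) {
  cat(sprintf("MatchResult %s: R = %s over %d points\n", object@pairId,
              if (is.na(object@r)) "NA (undefined)"
              else sprintf("%.4f", object@r),
              object@nPoints))
})

setMethod("show", "ProteomeMatch", function(object) {
  cat(sprintf("ProteomeMatch: %s vs %s\n", object@contentLabel,
              object@scaleLabel))
  cat(sprintf("  %d pairs, median R = %.4f; %d skipped\n",
              object@nPairs, object@medianR, object@nSkipped))
  if (object@nSkipped > 0L) {
    tab <- table(object@skipReasons)
    cat(sprintf("  skip reasons: %s\n",
                paste(sprintf("%s x%d", names(tab), as.integer(tab)),
                      collapse = ", ")))
  }
})

setMethod("show", "ScaleNull", function(object) {
  p <- if (object@pValue == 0) sprintf("< %.2g", 1 / object@nRandom)
       else sprintf("= %.4g", object@pValue)
  cat(sprintf("ScaleNull: observed median R = %.4f, p %s (%d random scales, seed %d)\n",
              object@observedMedian, p, object@nRandom, object@seed))
})
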