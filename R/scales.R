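# Interaction-propensity scales from interaction-energy traces, relative
# scales, reference-data conversions and scale comparison.

#' Construct an EnergyTrace
#'
#' @param eXN,eXW equal-length per-frame solute-nucleobase and solute-water
#'   potential energies (kJ/mol).
#' @param solute residue identifier (one- or three-letter; `"X"` allowed as
#'   a generic placeholder).
#' @param base nucleobase (`ADE`, `CYT`, `GUA`, `URA`).
#' @param nWater,nBase molecule counts of the simulated system the trace
#'   came from (needed for water-count rescaling).
#' @return an [EnergyTrace-class].
#' @export
energyTrace <- function(eXN, eXW, solute = "X", base = "URA",
                        nWater = 1050L, nBase = 170L) {
  solute <- if (toupper(solute) == "X") "X" else .normResidue(solute)
  new("EnergyTrace", solute = solute, base = .normBase(base),
      eXN = as.numeric(eXN), eXW = as.numeric(eXW),
      nWater = as.integer(nWater), nBase = as.integer(nBase))
}

#' Construct a PropensityScale
#'
#' @param values named numeric vector, one-letter residue to Delta E_NW
#'   (kJ/mol; lower = more favourable for the nucleobase).
#' @param base nucleobase label (or a free label such as `"RANDOM"`).
#' @param kind `"aa"` (all 20 residues) or `"sca"` (18, no Gly/Pro).
#' @param normalization water mole fraction the values correspond to.
#' @return a [PropensityScale-class].
#' @export
propensityScale <- function(values, base = "URA", kind = c("sca", "aa"),
                            normalization = 0.86) {
  kind <- match.arg(kind)
  values <- values[order(names(values))]
  new("PropensityScale", base = toupper(base), kind = kind,
      values = values, normalization = normalization)
}

#' Composition bookkeeping for one simulated system
#'
#' Given the solute, nucleobase and nucleobase count, fixes the water count
#' to hit the target water mole fraction,
#' `nWater = round(xWater * (nBase + 1) / (1 - xWater))`, and assigns a
#' counter ion for charged solutes (Na+ for Asp/Glu, Cl- for Lys/Arg;
#' His is treated as neutral by default).
#'
#' @param solute residue identifier (one- or three-letter).
#' @param base nucleobase.
#' @param nBase nucleobase molecule count (default 170).
#' @param xWater target water mole fraction (default 0.86).
#' @param kind `"aa"` or `"sca"`.
#' @param productionNs production run length in ns (default 100).
#' @return a [SystemSpec-class].
#' @export
#' @examples
#' buildSystemSpec("Asp", "URA")  # 1050 waters, Na+ counter ion
buildSystemSpec <- function(solute, base, nBase = 170L, xWater = 0.86,
                            kind = c("sca", "aa"), productionNs = 100) {
  kind <- match.arg(kind)
  solute <- .normResidue(solute)
  base <- .normBase(base)
  if (!(xWater > 0 && xWater < 1)) .stopf("xWater must lie in (0, 1)")
  if (nBase < 1L) .stopf("nBase must be >= 1")
  nWater <- as.integer(round(xWater * (nBase + 1L) / (1 - xWater)))
  counterIon <- if (solute %in% c("D", "E")) "Na+"
                else if (solute %in% c("K", "R")) "Cl-"
                else "none"
  new("SystemSpec", solute = solute, kind = kind, base = base,
      nSolute = 1L, nBase = as.integer(nBase), nWater = nWater,
      counterIon = counterIon, xWater = xWater,
      productionNs = productionNs)
}

#' Enumerate the full simulation campaign
#'
#' All 20 amino acids plus the 18 sidechain analogs (no Gly/Pro analog
#' exists), each against the four RNA nucleobases: 152 systems of 100 ns
#' production each, i.e. 15.2 microseconds in total.
#'
#' @inheritParams buildSystemSpec
#' @return list of [SystemSpec-class] objects (length 152 at defaults).
#' @export
enumerateSystems <- function(nBase = 170L, xWater = 0.86,
                             productionNs = 100) {
  specs <- list()
  for (base in .BASES) {
    for (aa in .AA20) {
      specs[[length(specs) + 1L]] <-
        buildSystemSpec(aa, base, nBase, xWater, kind = "aa",
                        productionNs = productionNs)
    }
    for (aa in .SCA18) {
      specs[[length(specs) + 1L]] <-
        buildSystemSpec(aa, base, nBase, xWater, kind = "sca",
                        productionNs = productionNs)
    }
  }
  specs
}

#' Rescale a mean solute-water energy to a target water count
#'
#' Systems built to the same target mole fraction can differ by a few water
#' molecules; assuming each water contributes to the solute-water potential
#' energy proportionally to its number, the mean energy is rescaled by
#' `nWaterTarget / nWaterActual` so all systems correspond to exactly the
#' same water mole fraction before scale building.
#'
#' @param meanEXW mean solute-water potential energy (kJ/mol).
#' @param nWaterActual,nWaterTarget actual and target water counts (>= 1).
#' @return rescaled mean energy (kJ/mol).
#' @export
rescaleWaterEnergy <- function(meanEXW, nWaterActual, nWaterTarget) {
  if (nWaterActual < 1 || nWaterTarget < 1) {
    .stopf("water counts must be >= 1")
  }
  meanEXW * nWaterTarget / nWaterActual
}

#' Interaction propensity of one solute for one nucleobase
#'
#' `Delta E_NW = mean(E_XN) - rescale(mean(E_XW))`: the difference between
#' the mean solute-nucleobase and (water-count rescaled) mean solute-water
#' potential energies. Lower values mean the solute prefers the nucleobase
#' over water. Values are meaningful in a relative sense only, at the
#' composition they were derived for.
#'
#' @param trace an [EnergyTrace-class] whose solute/base match `spec`.
#' @param spec a [SystemSpec-class] giving the target composition.
#' @return named list with `solute`, `base` and `deltaE` (kJ/mol).
#' @export
deriveDeltaE <- function(trace, spec) {
  stopifnot(is(trace, "EnergyTrace"), is(spec, "SystemSpec"))
  if (trace@solute != "X" && trace@solute != spec@solute) {
    .stopf("trace solute '%s' does not match spec solute '%s'",
           trace@solute, spec@solute)
  }
  if (trace@base != spec@base) {
    .stopf("trace base '%s' does not match spec base '%s'",
           trace@base, spec@base)
  }
  deltaE <- mean(trace@eXN) -
    rescaleWaterEnergy(mean(trace@eXW), trace@nWater, spec@nWater)
  list(solute = spec@solute, base = spec@base, deltaE = deltaE)
}

#' Assemble a PropensityScale from energy traces
#'
#' Applies [deriveDeltaE()] to one trace per residue and collects the
#' results into a scale.
#'
#' @param traces named list of [EnergyTrace-class] objects (names are
#'   one-letter residues; each trace's own solute must agree).
#' @param specs list of matching [SystemSpec-class] objects, or a single
#'   spec recycled for all residues (solute field ignored in that case).
#' @inheritParams propensityScale
#' @return a [PropensityScale-class].
#' @export
deriveScale <- function(traces, specs, base, kind = c("sca", "aa")) {
  kind <- match.arg(kind)
  if (is(specs, "SystemSpec")) {
    specs <- lapply(names(traces), function(res) {
      buildSystemSpec(res, specs@base, nBase = specs@nBase,
                      xWater = specs@xWater, kind = kind,
                      productionNs = specs@productionNs)
    })
    names(specs) <- names(traces)
  }
  vals <- vapply(names(traces), function(res) {
    deriveDeltaE(traces[[res]], specs[[res]])$deltaE
  }, numeric(1))
  propensityScale(vals, base = base, kind = kind,
                  normalization = specs[[1]]@xWater)
}

#' Relative preference scale between two nucleobases
#'
#' Per residue, `Delta E_N1N2 = Delta E_N1W - Delta E_N2W` over the residue
#' intersection of the two scales: the preference of each residue for
#' nucleobase N1 relative to N2 (negative = prefers N1). Swapping the
#' arguments flips every sign.
#'
#' @param scale1,scale2 [PropensityScale-class] objects of the same kind
#'   and normalization.
#' @return a [RelativeScale-class].
#' @export
relativeScale <- function(scale1, scale2) {
  stopifnot(is(scale1, "PropensityScale"), is(scale2, "PropensityScale"))
  if (scale1@kind != scale2@kind) {
    .stopf("cannot mix scale kinds ('%s' vs '%s')", scale1@kind, scale2@kind)
  }
  if (abs(scale1@normalization - scale2@normalization) > 1e-9) {
    .stopf("scales have different normalizations (%g vs %g)",
           scale1@normalization, scale2@normalization)
  }
  shared <- intersect(names(scale1@values), names(scale2@values))
  if (length(shared) == 0L) .stopf("scales share no residues")
  new("RelativeScale", basePair = c(scale1@base, scale2@base),
      kind = scale1@kind,
      values = scale1@values[shared] - scale2@values[shared])
}

#' Binding free energy from an association constant
#'
#' `Delta G = -R T ln(K / 1 M)` at the standard 1 M reference concentration,
#' with `R = 8.314462618e-3 kJ/(mol K)`.
#'
#' @param K association constant (1/M), positive.
#' @param temperature temperature in kelvin (default 298.15 K).
#' @return binding free energy (kJ/mol).
#' @export
#' @examples
#' assocConstToDG(10, 300)  # -5.7437 kJ/mol
assocConstToDG <- function(K, temperature = 298.15) {
  if (any(K <= 0)) .stopf("association constants must be positive")
  if (temperature <= 0) .stopf("temperature must be positive (kelvin)")
  -8.314462618e-3 * temperature * log(K)
}

#' Saturated mole fraction from aqueous solubility
#'
#' Converts a solubility in g/l to the solute mole fraction of the
#' saturated aqueous solution:
#' `X = (s / MW) / (s / MW + rho_w / MW_w)`.
#'
#' @param solubility solubility in g/l, non-negative.
#' @param mw solute molar mass (g/mol), positive.
#' @param waterDensity water density in g/l (default 997, 25 C).
#' @param waterMw water molar mass (default 18.015 g/mol).
#' @return mole fraction of the solute.
#' @export
#' @examples
#' solubilityToMoleFraction(1.04, 135.13)  # adenine, ~1e-4
#' solubilityToMoleFraction(8.00, 111.10)  # cytosine, ~1e-3
solubilityToMoleFraction <- function(solubility, mw,
                                     waterDensity = 997,
                                     waterMw = 18.015) {
  if (any(solubility < 0)) .stopf("solubility must be non-negative")
  if (mw <= 0 || waterDensity <= 0 || waterMw <= 0) {
    .stopf("molar masses and density must be positive")
  }
  nS <- solubility / mw
  nW <- waterDensity / waterMw
  nS / (nS + nW)
}

# Extract a named residue->value vector from a scale-like object.
.scaleVec <- function(x) {
  if (is(x, "PropensityScale") || is(x, "RelativeScale")) x@values
  else if (is.numeric(x) && !is.null(names(x))) x
  else stop("expected a PropensityScale/RelativeScale or a named numeric",
            call. = FALSE)
}

#' Correlate two residue scales
#'
#' Pearson or Spearman correlation over the residue intersection of the two
#' scales, with optional residue subsetting/exclusion (e.g. dropping an
#' outlier residue, or restricting to the residues an experimental
#' reference covers).
#'
#' @param a,b scales: [PropensityScale-class], [RelativeScale-class] or
#'   named numeric vectors (one-letter residue names).
#' @param method `"pearson"` or `"spearman"`.
#' @param subset optional residue set to restrict to.
#' @param exclude optional residues to drop.
#' @return list with `estimate` (the correlation), `n` (residues used) and
#'   `method`.
#' @export
#' @examples
#' a <- setNames(rnorm(18), LETTERS20(scaKind = TRUE))
#' compareScales(a, 2 * a + 1)$estimate  # exactly 1
compareScales <- function(a, b, method = c("pearson", "spearman"),
                          subset = NULL, exclude = NULL) {
  method <- match.arg(method)
  va <- .scaleVec(a)
  vb <- .scaleVec(b)
  shared <- intersect(names(va), names(vb))
  if (!is.null(subset)) shared <- intersect(shared, vapply(subset, .normResidue, ""))
  if (!is.null(exclude)) shared <- setdiff(shared, vapply(exclude, .normResidue, ""))
  if (length(shared) < 3L) {
    .stopf("need at least 3 shared residues after filtering (have %d)",
           length(shared))
  }
  x <- va[shared]
  y <- vb[shared]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    .stopf("correlation undefined: zero variance in one of the scales")
  }
  list(estimate = unname(cor(x, y, method = method)),
       n = length(shared), method = method)
}
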