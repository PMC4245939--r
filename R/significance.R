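# Random-scale permutation null for proteome medians.

#' Draw a uniform random residue scale
#'
#' One independent U(0,1) value per residue, using the current RNG state
#' (seed the stream with `set.seed()` or the `seed` argument of
#' [empiricalPValue()]). Because profile-matching Pearson correlations are
#' invariant under positive affine maps of the scale, the U(0,1) support is
#' as general as any other interval.
#'
#' @param kind `"aa"` (20 residues) or `"sca"` (18 residues).
#' @param residues optional explicit residue set overriding `kind`; must
#'   still cover the residue set that kind of scale requires.
#' @return a [PropensityScale-class] with base label `"RANDOM"`.
#' @export
randomScale <- function(kind = c("sca", "aa"), residues = NULL) {
  kind <- match.arg(kind)
  if (is.null(residues)) residues <- if (kind == "sca") .SCA18 else .AA20
  if (length(residues) == 0L) .stopf("residue set must be non-empty")
  propensityScale(setNames(runif(length(residues)), residues),
                  base = "RANDOM", kind = kind)
}

#' Empirical p-value of a proteome median against a random-scale null
#'
#' Recomputes the proteome median profile-matching Pearson R for `nRandom`
#' scales drawn uniformly at random (one U(0,1) value per residue) and
#' reports the two-sided empirical p-value: the fraction of random scales
#' whose median |R| is greater than or equal to the observed median |R|.
#' The estimator's resolution is `1/nRandom` and it admits `p = 0`, which
#' is reported as-is (read it as `p < 1/nRandom`).
#'
#' Internally the null medians are computed by an exact linear-algebra
#' shortcut (the propensity profile is linear in the scale vector), which
#' makes large `nRandom` practical; the result is identical to running
#' [proteomeDistribution()] once per random scale.
#'
#' @param pairs list of validated [CognatePair-class] objects.
#' @param scale the tested [PropensityScale-class]; its kind decides both
#'   the Gly/Pro exclusion and the residue set of the random scales.
#' @param bases base subset for the content profile (default pyrimidines).
#' @param nRandom number of random scales (default 10000; raise towards
#'   1e6 for publication-resolution p-values).
#' @param seed RNG seed for the null draws (restored afterwards).
#' @param window odd window size in residues/codons (default 21).
#' @param retainNull keep the vector of null medians in the result.
#' @return a [ScaleNull-class]; see [pValue()] and [nullMedians()].
#' @export
empiricalPValue <- function(pairs, scale, bases = c("C", "U"),
                            nRandom = 10000L, seed = 1L, window = 21L,
                            retainNull = TRUE) {
  stopifnot(is(scale, "PropensityScale"))
  nRandom <- as.integer(nRandom)
  if (nRandom < 1L) .stopf("nRandom must be >= 1")
  residues <- sort(names(scale@values))
  ctx <- .matchContext(pairs, residues, bases = bases, window = window,
                       excludeGP = (scale@kind == "sca"))
  if (length(ctx$entries) == 0L) .stopf("no usable pairs")

  obsR <- .contextCor(ctx, matrix(scale@values[residues], ncol = 1,
                                  dimnames = list(residues, NULL)))
  if (all(is.na(obsR))) .stopf("observed median undefined for every pair")
  observed <- median(obsR[, 1], na.rm = TRUE)

  nulls <- .withSeed(seed, {
    out <- numeric(nRandom)
    done <- 0L
    batch <- 2000L
    while (done < nRandom) {
      k <- min(batch, nRandom - done)
      S <- matrix(runif(length(residues) * k), nrow = length(residues),
                  dimnames = list(residues, NULL))
      R <- .contextCor(ctx, S)
      out[done + seq_len(k)] <- apply(R, 2L, median, na.rm = TRUE)
      done <- done + k
    }
    out
  })

  p <- sum(abs(nulls) >= abs(observed)) / nRandom
  new("ScaleNull", nRandom = nRandom, seed = as.integer(seed),
      observedMedian = observed,
      nullMedians = if (retainNull) nulls else numeric(0),
      pValue = p)
}
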