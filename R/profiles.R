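# Cognate-pair validation, window-averaged sequence profiles and
# proteome-wide profile matching.

#' Validate an mRNA/protein cognate pair
#'
#' Normalizes the coding sequence to the RNA alphabet (`T -> U`), checks
#' codon divisibility, translates under the standard genetic code, strips a
#' single trailing stop codon, rejects internal stops and ambiguity codes,
#' and requires the translation to equal the supplied protein exactly.
#'
#' @param mrna coding sequence (character, `A/C/G/T/U`, case-insensitive).
#' @param protein amino-acid sequence (20 standard one-letter codes).
#' @param id identifier for the pair.
#' @return a validated [CognatePair-class].
#' @export
#' @examples
#' translateAndValidate("AUGAAAUAA", "MK")
translateAndValidate <- function(mrna, protein, id = "pair") {
  m <- chartr("T", "U", toupper(gsub("[\\s]", "", mrna, perl = TRUE)))
  p <- toupper(gsub("[\\s]", "", protein, perl = TRUE))
  if (nchar(m) == 0L || nchar(p) == 0L) .stopf("%s: empty sequence", id)
  if (nchar(m) %% 3L != 0L) {
    .stopf("%s: mRNA length %d is not divisible by 3", id, nchar(m))
  }
  bad <- unique(strsplit(gsub("[ACGU]", "", m), "")[[1]])
  if (length(bad) > 0L) {
    .stopf("%s: ambiguity or invalid codes in mRNA: %s", id,
           paste(bad, collapse = ","))
  }
  aa <- as.character(Biostrings::translate(Biostrings::RNAString(m),
                                           no.init.codon = TRUE))
  n <- nchar(aa)
  if (substr(aa, n, n) == "*") {
    aa <- substr(aa, 1L, n - 1L)
    m <- substr(m, 1L, nchar(m) - 3L)
  }
  if (grepl("\\*", aa)) .stopf("%s: internal stop codon", id)
  if (!identical(aa, p)) {
    .stopf("%s: translation does not match the supplied protein", id)
  }
  new("CognatePair", id = as.character(id), mrna = m, protein = p,
      validated = TRUE)
}

#' Drop Gly/Pro residues and their codons from a cognate pair
#'
#' Sidechain-analog scales carry no values for Gly and Pro, so these
#' residues are ignored on the protein side together with their codons on
#' the mRNA side; downstream windows run over the compacted coordinates.
#'
#' @param pair a validated [CognatePair-class].
#' @return the compacted [CognatePair-class] (possibly of length 0 when the
#'   protein was all Gly/Pro; length handling is left to the caller).
#' @export
excludeGlyPro <- function(pair) {
  stopifnot(is(pair, "CognatePair"))
  if (!pair@validated) .stopf("%s: pair is not validated", pair@id)
  res <- strsplit(pair@protein, "")[[1]]
  keep <- !(res %in% c("G", "P"))
  if (all(keep)) return(pair)
  codons <- substring(pair@mrna, 3L * seq_along(res) - 2L, 3L * seq_along(res))
  new("CognatePair", id = pair@id,
      mrna = paste(codons[keep], collapse = ""),
      protein = paste(res[keep], collapse = ""),
      validated = TRUE)
}

#' Window-averaged nucleobase-content profile of an mRNA
#'
#' For each codon index with a complete window of `window` codons
#' (3 x `window` bases, default 63) centred on it, the value is the
#' fraction of those bases belonging to `bases`. Indexing by the central
#' codon makes the profile position-aligned with the protein profile of
#' the same window size. Only complete windows are reported: a sequence of
#' `L` codons yields `L - window + 1` values.
#'
#' @param x coding sequence (character, RNA alphabet, length divisible by
#'   3, stop stripped) or a [CognatePair-class].
#' @param bases base subset defining the content, e.g. `c("C", "U")` for
#'   pyrimidine (PYR) or `c("A", "G")` for purine (PUR) content.
#' @param window odd window size in codons (default 21).
#' @return a [SequenceProfile-class] with values in `[0, 1]`.
#' @export
#' @examples
#' pr <- contentProfile(strrep("UUC", 30), bases = c("C", "U"))
#' all(profileValues(pr) == 1)
contentProfile <- function(x, bases = c("C", "U"), window = 21L) {
  m <- if (is(x, "CognatePair")) x@mrna else
    chartr("T", "U", toupper(as.character(x)))
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) .stopf("window must be odd and >= 3")
  bases <- toupper(bases)
  if (!all(bases %in% c("A", "C", "G", "U")) || length(bases) == 0L) {
    .stopf("bases must be a non-empty subset of {A, C, G, U}")
  }
  L <- nchar(m)
  if (L %% 3L != 0L) .stopf("mRNA length %d is not divisible by 3", L)
  nc <- L %/% 3L
  if (nc < window) {
    .stopf("sequence too short: %d codons < window of %d", nc, window)
  }
  hit <- strsplit(m, "")[[1]] %in% bases
  cs <- c(0, cumsum(hit))
  h <- (window - 1L) %/% 2L
  centers <- (h + 1L):(nc - h)
  # bases of codons [i-h, i+h] span positions 3(i-h-1)+1 .. 3(i+h)
  vals <- (cs[3L * (centers + h) + 1L] - cs[3L * (centers - h - 1L) + 1L]) /
    (3L * window)
  lab <- if (setequal(bases, .PYR)) "PYR content"
         else if (setequal(bases, .PUR)) "PUR content"
         else paste0(paste(sort(bases), collapse = ""), " content")
  new("SequenceProfile", property = lab, centers = centers,
      values = as.numeric(vals), window = window)
}

#' Window-averaged propensity profile of a protein
#'
#' The value at each residue index with a complete window is the mean of
#' the scale values over the `window` residues centred there. Only complete
#' windows are reported (`L - window + 1` values for a protein of length
#' `L`). For sidechain-analog scales the sequence must already have Gly/Pro
#' removed (see [excludeGlyPro()]); a residue missing from the scale is an
#' error naming that residue.
#'
#' @param protein amino-acid sequence (character) or [CognatePair-class].
#' @param scale a [PropensityScale-class] (or [RelativeScale-class]).
#' @param window odd window size in residues (default 21).
#' @return a [SequenceProfile-class] (values in kJ/mol for energy scales).
#' @export
propensityProfile <- function(protein, scale, window = 21L) {
  p <- if (is(protein, "CognatePair")) protein@protein
       else toupper(as.character(protein))
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) .stopf("window must be odd and >= 3")
  vals <- .scaleVec(scale)
  res <- strsplit(p, "")[[1]]
  L <- length(res)
  if (L < window) {
    .stopf("sequence too short: %d residues < window of %d", L, window)
  }
  missing <- setdiff(unique(res), names(vals))
  if (length(missing) > 0L) {
    .stopf("residue(s) %s not covered by the scale",
           paste(missing, collapse = ","))
  }
  v <- unname(vals[res])
  prof <- as.numeric(stats::filter(v, rep(1 / window, window), sides = 2))
  h <- (window - 1L) %/% 2L
  centers <- (h + 1L):(L - h)
  lab <- if (is(scale, "PropensityScale")) {
    sprintf("propensity:%s/%s", scale@base, scale@kind)
  } else if (is(scale, "RelativeScale")) {
    sprintf("propensity:%s-%s/%s", scale@basePair[1], scale@basePair[2],
            scale@kind)
  } else "propensity"
  new("SequenceProfile", property = lab, centers = centers,
      values = prof[centers], window = window)
}

# Does a scale-like object require the Gly/Pro exclusion?
.isScaKind <- function(scale) {
  (is(scale, "PropensityScale") || is(scale, "RelativeScale")) &&
    scale@kind == "sca"
}

#' Profile-matching correlation for one cognate pair
#'
#' Pearson correlation between the codon-centre-aligned mRNA content
#' profile and the residue-centre protein propensity profile, reported with
#' its raw sign: under the energy convention (lower = more favourable) a
#' negative R means content and propensity rise together. For
#' sidechain-analog scales Gly/Pro and their codons are excluded first.
#'
#' @param pair a validated [CognatePair-class].
#' @param scale a [PropensityScale-class] or [RelativeScale-class].
#' @param bases base subset for the content profile (default pyrimidines).
#' @param window odd window size in residues/codons (default 21).
#' @param excludeGP apply the Gly/Pro exclusion; defaults to `TRUE` exactly
#'   when the scale is of kind `"sca"`.
#' @return a [MatchResult-class]; `r` is `NA` (with the pair to be counted
#'   as skipped by callers) when either profile has zero variance.
#' @export
matchPair <- function(pair, scale, bases = c("C", "U"), window = 21L,
                      excludeGP = .isScaKind(scale)) {
  stopifnot(is(pair, "CognatePair"))
  if (!pair@validated) .stopf("%s: pair is not validated", pair@id)
  if (excludeGP) pair <- excludeGlyPro(pair)
  if (nchar(pair@protein) < window) {
    .stopf("%s: too short after exclusions (%d residues < window %d)",
           pair@id, nchar(pair@protein), window)
  }
  cp <- contentProfile(pair, bases = bases, window = window)
  pp <- propensityProfile(pair, scale, window = window)
  x <- cp@values
  y <- pp@values
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) {
    .stopf("%s: fewer than 3 profile points", pair@id)
  }
  r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
       else unname(cor(x, y))
  new("MatchResult", pairId = pair@id, r = r, nPoints = length(x))
}

#' Proteome-wide distribution of profile-matching correlations
#'
#' Applies [matchPair()] to every pair (with the Gly/Pro exclusion exactly
#' when the scale is of sidechain-analog kind), collecting one Pearson R
#' per usable pair and the sample median. Pairs that are unvalidated,
#' shorter than one window after exclusions, or have a zero-variance
#' profile are skipped and counted with a reason rather than aborting the
#' run.
#'
#' @param pairs list of [CognatePair-class] objects.
#' @param scale a [PropensityScale-class] or [RelativeScale-class].
#' @inheritParams matchPair
#' @return a [ProteomeMatch-class]; see [rValues()] and [medianR()].
#' @export
proteomeDistribution <- function(pairs, scale, bases = c("C", "U"),
                                 window = 21L,
                                 excludeGP = .isScaKind(scale)) {
  if (length(pairs) == 0L) .stopf("no pairs supplied")
  rs <- numeric(0)
  skips <- character(0)
  for (pair in pairs) {
    if (!is(pair, "CognatePair") || !pair@validated) {
      skips[pair@id] <- "not_validated"
      next
    }
    eff <- if (excludeGP) excludeGlyPro(pair) else pair
    if (nchar(eff@protein) < window) {
      skips[pair@id] <- "too_short"
      next
    }
    m <- matchPair(pair, scale, bases = bases, window = window,
                   excludeGP = excludeGP)
    if (is.na(m@r)) {
      skips[pair@id] <- "zero_variance"
    } else {
      rs[pair@id] <- m@r
    }
  }
  if (length(rs) == 0L) .stopf("no usable pairs")
  contentLab <- if (setequal(toupper(bases), .PYR)) "PYR content"
                else if (setequal(toupper(bases), .PUR)) "PUR content"
                else paste0(paste(sort(toupper(bases)), collapse = ""),
                            " content")
  scaleLab <- if (is(scale, "PropensityScale")) {
    sprintf("%s/%s", scale@base, scale@kind)
  } else if (is(scale, "RelativeScale")) {
    sprintf("%s-%s/%s", scale@basePair[1], scale@basePair[2], scale@kind)
  } else "scale"
  new("ProteomeMatch", scaleLabel = scaleLab, contentLabel = contentLab,
      rValues = rs, medianR = median(rs), nPairs = length(rs),
      nSkipped = length(skips), skipReasons = skips)
}

# ---- fast linear-algebra path used by the permutation null ----------------
#
# The propensity profile is linear in the scale vector s: each profile value
# is (1/window) * (window residue-count row) %*% s. Pearson R against the
# fixed content profile is invariant to the 1/window factor, so per pair we
# precompute the centred content profile y and the count matrix C
# (centres x residues); for a matrix S of scales the per-scale correlations
# are colwise Pearson between y and C %*% S.

# Build the reusable context. Returns NULL-free list of per-pair entries:
# id, y (centred), ssY, C; pairs skipped for length/variance are recorded.
.matchContext <- function(pairs, residues, bases = c("C", "U"),
                          window = 21L, excludeGP = FALSE) {
  window <- as.integer(window)
  entries <- list()
  skips <- character(0)
  for (pair in pairs) {
    if (!is(pair, "CognatePair") || !pair@validated) {
      skips[pair@id] <- "not_validated"
      next
    }
    eff <- if (excludeGP) excludeGlyPro(pair) else pair
    L <- nchar(eff@protein)
    if (L < window) {
      skips[pair@id] <- "too_short"
      next
    }
    y <- contentProfile(eff, bases = bases, window = window)@values
    if (stats::sd(y) == 0) {
      skips[pair@id] <- "zero_variance"
      next
    }
    res <- strsplit(eff@protein, "")[[1]]
    ind <- matrix(0L, nrow = L, ncol = length(residues),
                  dimnames = list(NULL, residues))
    ind[cbind(seq_len(L), match(res, residues))] <- 1L
    cs <- rbind(0L, apply(ind, 2L, cumsum))
    h <- (window - 1L) %/% 2L
    centers <- (h + 1L):(L - h)
    C <- cs[centers + h + 1L, , drop = FALSE] -
         cs[centers - h, , drop = FALSE]
    yc <- y - mean(y)
    entries[[pair@id]] <- list(id = pair@id, yc = yc,
                               ssY = sum(yc^2), C = C)
  }
  list(entries = entries, skips = skips, residues = residues,
       window = window)
}

# Correlations for a matrix of scales: rows = pairs, cols = scales.
# Scales with a zero-variance propensity profile for a pair give NA there.
.contextCor <- function(ctx, S) {
  S <- as.matrix(S)
  if (!identical(rownames(S), ctx$residues)) {
    S <- S[ctx$residues, , drop = FALSE]
  }
  out <- matrix(NA_real_, nrow = length(ctx$entries), ncol = ncol(S),
                dimnames = list(names(ctx$entries), NULL))
  for (i in seq_along(ctx$entries)) {
    e <- ctx$entries[[i]]
    P <- e$C %*% S
    n <- nrow(P)
    num <- as.vector(crossprod(e$yc, P))
    ssP <- colSums(P^2) - colSums(P)^2 / n
    ok <- ssP > 0
    out[i, ok] <- num[ok] / sqrt(e$ssY * ssP[ok])
  }
  out
}
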