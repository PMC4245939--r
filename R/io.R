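# Readers and writers for the plain-text formats the pipeline touches:
# paired FASTA, scale TSV, frame CSV, curve CSV and GROMACS-style XVG.

#' Read and validate cognate mRNA/protein pairs from paired FASTA files
#'
#' Records are matched by exact ID (the first whitespace-delimited token of
#' the FASTA header). Each matched pair is passed through
#' [translateAndValidate()]; DNA-alphabet coding sequences (with `T`) are
#' accepted and normalized to RNA. Unmatched or invalid records are skipped
#' with a recorded reason (or raise an error when `skipInvalid = FALSE`);
#' duplicate IDs within a file are an error.
#'
#' @param mrnaPath path to the coding-sequence FASTA.
#' @param proteinPath path to the protein FASTA.
#' @param skipInvalid skip records that fail validation instead of erroring.
#' @return list of validated [CognatePair-class] objects, with a
#'   `"skipped"` attribute (named character vector of reasons).
#' @export
readFastaPairs <- function(mrnaPath, proteinPath, skipInvalid = TRUE) {
  mrna <- Biostrings::readBStringSet(mrnaPath)
  prot <- Biostrings::readBStringSet(proteinPath)
  idOf <- function(x) vapply(strsplit(names(x), "[ \t]"), `[`, "", 1L)
  names(mrna) <- idOf(mrna)
  names(prot) <- idOf(prot)
  if (anyDuplicated(names(mrna))) {
    .stopf("duplicate IDs in %s: %s", mrnaPath,
           paste(unique(names(mrna)[duplicated(names(mrna))]), collapse = ","))
  }
  if (anyDuplicated(names(prot))) {
    .stopf("duplicate IDs in %s: %s", proteinPath,
           paste(unique(names(prot)[duplicated(names(prot))]), collapse = ","))
  }
  shared <- intersect(names(mrna), names(prot))
  skipped <- setNames(rep("unmatched_id", length(setdiff(
    union(names(mrna), names(prot)), shared))),
    setdiff(union(names(mrna), names(prot)), shared))
  pairs <- list()
  for (id in shared) {
    res <- tryCatch(
      translateAndValidate(as.character(mrna[[id]]),
                           as.character(prot[[id]]), id = id),
      error = function(e) e)
    if (is(res, "error")) {
      if (!skipInvalid) stop(res)
      skipped[id] <- conditionMessage(res)
    } else {
      pairs[[id]] <- res
    }
  }
  if (length(pairs) == 0L) .stopf("zero valid matched pairs")
  attr(pairs, "skipped") <- skipped
  pairs
}

#' Write / read a residue scale as TSV
#'
#' Lossless round trip: a commented header line records base, kind and
#' normalization, followed by `residue` / `value_kj_mol` columns in
#' canonical (alphabetical) residue order at full precision.
#'
#' @param scale a [PropensityScale-class].
#' @param path file path.
#' @return `writeScale` returns `path` invisibly; `readScale` returns the
#'   [PropensityScale-class] (validity enforces the residue coverage, so a
#'   sidechain-analog scale containing Gly or Pro is rejected).
#' @export
writeScale <- function(scale, path) {
  stopifnot(is(scale, "PropensityScale"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# base=%s kind=%s normalization=%.17g",
                     scale@base, scale@kind, scale@normalization), con)
  writeLines("residue\tvalue_kj_mol", con)
  vals <- scale@values[order(names(scale@values))]
  writeLines(sprintf("%s\t%.17g", names(vals), vals), con)
  invisible(path)
}

#' @rdname writeScale
#' @export
readScale <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || !startsWith(lines[1], "#")) {
    .stopf("%s: missing scale header line ('# base=... kind=... normalization=...')",
           path)
  }
  m <- regmatches(lines[1],
                  regexec("base=(\\S+)\\s+kind=(\\S+)\\s+normalization=(\\S+)",
                          lines[1]))[[1]]
  if (length(m) != 4L) .stopf("%s: malformed scale header", path)
  body <- read.delim(text = lines[-1], header = TRUE,
                     colClasses = c("character", "numeric"))
  if (!identical(names(body), c("residue", "value_kj_mol"))) {
    .stopf("%s: expected columns 'residue' and 'value_kj_mol'", path)
  }
  if (anyDuplicated(body$residue)) {
    .stopf("%s: duplicate residues", path)
  }
  bad <- setdiff(body$residue, .AA20)
  if (length(bad) > 0L) {
    .stopf("%s: unknown residue letters: %s", path, paste(bad, collapse = ","))
  }
  propensityScale(setNames(body$value_kj_mol, body$residue),
                  base = m[2], kind = m[3],
                  normalization = as.numeric(m[4]))
}

#' Write / read particle frames as CSV
#'
#' Long-format CSV with columns `frame, species, x, y, z`; the box and
#' periodicity are carried in a commented first line so the round trip is
#' complete.
#'
#' @param frames a [ParticleFrames-class].
#' @param path file path.
#' @return `writeFrames` returns `path` invisibly; `readFrames` the
#'   [ParticleFrames-class].
#' @export
writeFrames <- function(frames, path) {
  stopifnot(is(frames, "ParticleFrames"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# box=%.17g,%.17g,%.17g periodic=%s",
                     frames@box[1], frames@box[2], frames@box[3],
                     frames@periodic), con)
  writeLines("frame,species,x,y,z", con)
  for (i in seq_along(frames@coords)) {
    m <- frames@coords[[i]]
    writeLines(sprintf("%d,%s,%.17g,%.17g,%.17g",
                       i, frames@species, m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' @rdname writeFrames
#' @export
readFrames <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L || !startsWith(lines[1], "#")) {
    .stopf("%s: missing '# box=... periodic=...' header", path)
  }
  m <- regmatches(lines[1],
                  regexec("box=([^ ]+)\\s+periodic=(\\S+)", lines[1]))[[1]]
  if (length(m) != 3L) .stopf("%s: malformed frames header", path)
  box <- as.numeric(strsplit(m[2], ",")[[1]])
  df <- read.csv(text = lines[-1])
  frames <- unname(lapply(split(df, df$frame), function(d) {
    as.matrix(d[, c("x", "y", "z")])
  }))
  sp <- split(df$species, df$frame)[[1]]
  particleFrames(frames, species = sp, box = box,
                 periodic = as.logical(m[3]))
}

#' Read a numeric curve or energy series from CSV or GROMACS-style XVG
#'
#' XVG comment/directive lines (starting with `#` or `@`) are ignored;
#' remaining lines must be whitespace-separated numbers. CSV files may
#' carry a header row. Non-numeric cells raise an error naming the line.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"` or `"xvg"`.
#' @return numeric matrix (one row per record), with column names when the
#'   CSV had a header.
#' @export
readCurve <- function(path, format = c("auto", "csv", "xvg")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.xvg$", path, ignore.case = TRUE)) "xvg" else "csv"
  }
  lines <- readLines(path)
  if (format == "xvg") {
    keep <- !grepl("^[#@]", trimws(lines)) & nzchar(trimws(lines))
    dat <- lines[keep]
    if (length(dat) == 0L) .stopf("%s: no data lines", path)
    rows <- strsplit(trimws(dat), "[ \t]+")
    ncol <- length(rows[[1]])
    out <- matrix(NA_real_, nrow = length(rows), ncol = ncol)
    for (i in seq_along(rows)) {
      v <- suppressWarnings(as.numeric(rows[[i]]))
      if (length(v) != ncol || anyNA(v)) {
        .stopf("%s: non-numeric or ragged data at line %d", path,
               which(keep)[i])
      }
      out[i, ] <- v
    }
    out
  } else {
    keep <- nzchar(trimws(lines)) & !grepl("^#", trimws(lines))
    if (!any(keep)) .stopf("%s: empty file", path)
    first <- strsplit(trimws(lines[keep][1]), ",")[[1]]
    header <- anyNA(suppressWarnings(as.numeric(first)))
    df <- tryCatch(
      read.csv(text = lines[keep], header = header,
               colClasses = "numeric"),
      error = function(e) .stopf("%s: %s", path, conditionMessage(e)))
    as.matrix(df)
  }
}

#' Read an RDF curve from a two-column file
#'
#' @param path CSV or XVG file with columns r (nm) and g(r).
#' @param pair ordered species pair label, e.g. `c("N", "N")`.
#' @param format see [readCurve()].
#' @return an [RDFCurve-class]; a non-monotone abscissa is an error.
#' @export
readRDFCurve <- function(path, pair = c("N", "N"),
                         format = c("auto", "csv", "xvg")) {
  m <- readCurve(path, format = match.arg(format))
  if (ncol(m) < 2L) .stopf("%s: need two columns (r, g)", path)
  r <- m[, 1]
  if (any(diff(r) <= 0)) .stopf("%s: r values must be strictly increasing",
                                path)
  new("RDFCurve", pair = pair, r = r, g = m[, 2],
      binWidth = mean(diff(r)), nFrames = 1L)
}

#' Read an energy trace from a three-column file
#'
#' @param path CSV or XVG file with columns frame, e_xn, e_xw (kJ/mol).
#' @inheritParams energyTrace
#' @param format see [readCurve()].
#' @return an [EnergyTrace-class].
#' @export
readEnergyTrace <- function(path, solute = "X", base = "URA",
                            nWater = 1050L, nBase = 170L,
                            format = c("auto", "csv", "xvg")) {
  m <- readCurve(path, format = match.arg(format))
  if (ncol(m) < 3L) .stopf("%s: need three columns (frame, e_xn, e_xw)",
                           path)
  energyTrace(m[, 2], m[, 3], solute = solute, base = base,
              nWater = nWater, nBase = nBase)
}

#' Write an energy trace as CSV
#'
#' @param trace an [EnergyTrace-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeEnergyTrace <- function(trace, path) {
  stopifnot(is(trace, "EnergyTrace"))
  df <- data.frame(frame = seq_along(trace@eXN), e_xn = trace@eXN,
                   e_xw = trace@eXW)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-pair profile-matching results as TSV
#'
#' @param match a [ProteomeMatch-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeMatchResults <- function(match, path) {
  stopifnot(is(match, "ProteomeMatch"))
  df <- data.frame(id = names(match@rValues), r = unname(match@rValues),
                   stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scale=%s content=%s median_r=%.17g n_pairs=%d n_skipped=%d",
                     match@scaleLabel, match@contentLabel, match@medianR,
                     match@nPairs, match@nSkipped), con)
  writeLines("id\tr", con)
  writeLines(sprintf("%s\t%.17g", df$id, df$r), con)
  invisible(path)
}

#' Write cognate pairs as paired FASTA files
#'
#' @param pairs list of [CognatePair-class] objects.
#' @param mrnaPath,proteinPath output FASTA paths (records share IDs).
#' @return invisible `NULL`.
#' @export
writeFastaPairs <- function(pairs, mrnaPath, proteinPath) {
  ids <- vapply(pairs, function(p) p@id, "")
  mrna <- Biostrings::BStringSet(setNames(
    vapply(pairs, function(p) p@mrna, ""), ids))
  prot <- Biostrings::BStringSet(setNames(
    vapply(pairs, function(p) p@protein, ""), ids))
  Biostrings::writeXStringSet(mrna, mrnaPath)
  Biostrings::writeXStringSet(prot, proteinPath)
  invisible(NULL)
}
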