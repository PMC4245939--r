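# Internal helpers: residue/codon tables and RNG scoping.

#' @importFrom methods is new validObject slot
#' @importFrom stats cor median rnorm runif filter setNames sd uniroot
#' @importFrom utils read.csv write.csv head
NULL

# Canonical residue sets (one-letter, alphabetical).
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
# Sidechain analogs exist for all residues except Gly and Pro.
.SCA18 <- setdiff(.AA20, c("G", "P"))

.BASES <- c("ADE", "CYT", "GUA", "URA")
.PYR <- c("C", "U")
.PUR <- c("A", "G")

.AA3TO1 <- c(ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
             GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
             MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
             SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y")

# Normalize a residue identifier (one- or three-letter) to one-letter.
.normResidue <- function(x) {
  x <- toupper(x)
  if (nchar(x) == 3L) {
    if (!x %in% names(.AA3TO1)) stop("unknown residue: ", x, call. = FALSE)
    return(unname(.AA3TO1[x]))
  }
  if (!x %in% .AA20) stop("unknown residue: ", x, call. = FALSE)
  x
}

.normBase <- function(x) {
  x <- toupper(x)
  if (!x %in% .BASES) {
    stop("unknown nucleobase: ", x, " (expected one of ",
         paste(.BASES, collapse = ", "), ")", call. = FALSE)
  }
  x
}

# Standard genetic code on the RNA alphabet, from Biostrings.
.codonTableRNA <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      names(gc) <- chartr("T", "U", names(gc))
      tab <<- gc
    }
    tab
  }
})

# Synonymous RNA codons per residue (stops excluded).
.codonsForResidue <- local({
  lst <- NULL
  function() {
    if (is.null(lst)) {
      gc <- .codonTableRNA()
      gc <- gc[gc != "*"]
      lst <<- split(names(gc), unname(gc))
    }
    lst
  }
})

# Pyrimidine (C/U) count of an RNA codon vector.
.pyrCount <- function(codons) {
  vapply(strsplit(codons, ""), function(b) sum(b %in% .PYR), integer(1))
}

# Evaluate expr with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so seeded generators do not perturb the global stream.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
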