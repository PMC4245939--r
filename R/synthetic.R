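# Deterministic synthetic-data generators. Each generator is a pure
# function of its seed and is designed so the expected output of the
# downstream stage is known by construction (flat RDF, known energy means,
# zero or strong composition-propensity coupling).

# Residue frequencies over the 20 residues: a baseline favouring residues
# whose synonymous codons differ in pyrimidine count (so the codon-choice
# coupling channel has room to act), extra-weighted where such flexible
# residues are also informative for the scale (high |z|), exponentially
# tilted within the residue set `covered` so the weighted covariance
# between the standardized scale z and the per-residue mean codon
# pyrimidine fraction is zero. Among multiple roots the mildest tilt
# (nearest t = 0) is taken, restricted to |t| <= 8 so the composition can
# never collapse onto a couple of residues; if no root lies in that range
# the covariance is minimized there instead (the residual bias is small).
# Residues outside `covered` (no scale value, excluded downstream) keep
# the baseline weight.
.deconfoundedFreqs <- function(z, covered) {
  cds <- .codonsForResidue()[.AA20]
  u <- vapply(cds, function(cd) mean(.pyrCount(cd)) / 3, numeric(1))
  vpd <- vapply(cds, function(cd) {
    pc <- .pyrCount(cd)
    mean((pc - mean(pc))^2)
  }, numeric(1))
  w0 <- exp(3 * vpd + 1.5 * sqrt(vpd) * abs(z))
  q <- setNames(w0 / sum(w0), .AA20)
  zs <- z[covered]
  us <- u[covered]
  w0s <- w0[covered]
  if (stats::sd(zs) == 0 || stats::sd(us) == 0) return(q)
  wcov <- function(t) {
    w <- w0s * exp(-t * (zs - mean(zs)) * (us - mean(us)))
    w <- w / sum(w)
    sum(w * (zs - sum(w * zs)) * (us - sum(w * us)))
  }
  grid <- seq(-8, 8, length.out = 641)
  v <- vapply(grid, wcov, numeric(1))
  crossings <- which(diff(sign(v)) != 0)
  t0 <- if (length(crossings) > 0L) {
    j <- crossings[which.min(pmin(abs(grid[crossings]),
                                  abs(grid[crossings + 1L])))]
    stats::uniroot(wcov, c(grid[j], grid[j + 1L]), tol = 1e-12)$root
  } else {
    grid[which.min(abs(v))]
  }
  q[covered] <- w0s * exp(-t0 * (zs - mean(zs)) * (us - mean(us)))
  q / sum(q)
}

#' Generate mixture configurations with known pair structure
#'
#' Three generative models for nucleobase (`N`) / water (`W`) particle
#' positions in a periodic orthorhombic box:
#' * `"ideal"` - every particle uniform in the box (Poisson field), so
#'   every RDF is flat at 1 and every Kirkwood-Buff integral converges to
#'   0 (and the stability derivative to 1) up to counting noise;
#' * `"hard_shell"` - sequential insertion rejecting any particle closer
#'   than `d` (minimum image) to an already placed one, so `g(r) = 0`
#'   below `d` by construction;
#' * `"clustered"` - nucleobases drawn from Gaussian blobs of width
#'   `sigma` around `nClusters` uniform centres (waters uniform), giving a
#'   first N/N peak well above 1.
#'
#' @param model one of `"ideal"`, `"hard_shell"`, `"clustered"`.
#' @param nN,nW nucleobase and water particle counts (>= 0).
#' @param box box edge lengths in nm (scalar for cubic; default 4 nm).
#' @param nFrames number of frames (default 10).
#' @param seed RNG seed; the same seed gives bit-identical output.
#' @param d hard-shell exclusion diameter in nm (default 0.3).
#' @param sigma cluster width in nm (default 0.2).
#' @param nClusters number of Gaussian clusters (default 3).
#' @param maxTries insertion attempts per particle for `"hard_shell"`
#'   before an infeasible-packing error (default 500).
#' @return a [ParticleFrames-class] object.
#' @export
#' @examples
#' fr <- simulateMixtureFrames("ideal", nN = 200, nW = 200, nFrames = 5,
#'                             seed = 7)
simulateMixtureFrames <- function(model = c("ideal", "hard_shell",
                                            "clustered"),
                                  nN, nW, box = 4, nFrames = 10L,
                                  seed = NULL, d = 0.3, sigma = 0.2,
                                  nClusters = 3L, maxTries = 500L) {
  model <- match.arg(model)
  if (nN < 0 || nW < 0 || nN + nW < 1) .stopf("need nN + nW >= 1, both >= 0")
  if (length(box) == 1L) box <- rep(box, 3L)
  if (any(box <= 0)) .stopf("box edges must be positive")
  n <- nN + nW
  species <- c(rep("N", nN), rep("W", nW))

  .uniform <- function(k) {
    cbind(runif(k, 0, box[1]), runif(k, 0, box[2]), runif(k, 0, box[3]))
  }
  .oneFrame <- switch(model,
    ideal = function() .uniform(n),
    hard_shell = function() {
      pts <- matrix(0, nrow = n, ncol = 3)
      for (i in seq_len(n)) {
        placed <- FALSE
        for (try in seq_len(maxTries)) {
          cand <- .uniform(1L)[1L, ]
          if (i == 1L) { placed <- TRUE }
          else {
            dx <- abs(sweep(pts[seq_len(i - 1L), , drop = FALSE], 2, cand))
            dx <- pmin(dx, sweep(-dx, 2, box, "+"))
            if (min(rowSums(dx^2)) >= d^2) placed <- TRUE
          }
          if (placed) { pts[i, ] <- cand; break }
        }
        if (!placed) {
          .stopf("infeasible packing: could not place particle %d of %d after %d tries (d = %g nm)",
                 i, n, maxTries, d)
        }
      }
      pts
    },
    clustered = function() {
      centers <- .uniform(nClusters)
      assign <- sample.int(nClusters, nN, replace = TRUE)
      ptsN <- centers[assign, , drop = FALSE] +
        matrix(rnorm(3L * nN, sd = sigma), ncol = 3)
      ptsN <- ptsN %% rep(box, each = nN)  # wrap into the box
      rbind(ptsN, .uniform(nW))
    })

  frames <- .withSeed(seed, lapply(seq_len(nFrames), function(i) .oneFrame()))
  particleFrames(frames, species = species, box = box, periodic = TRUE)
}

#' Generate an interaction-energy trace with known means
#'
#' Per-frame independent Gaussian draws around the supplied solute-
#' nucleobase and solute-water mean energies, with composition metadata
#' recorded for downstream rescaling. `sigma = 0` reproduces the means
#' exactly in every frame.
#'
#' @param muXN,muXW mean solute-nucleobase and solute-water potential
#'   energies (kJ/mol).
#' @param sigma per-frame standard deviation (kJ/mol, >= 0).
#' @param nFrames number of frames (>= 1).
#' @param nBase,nWater molecule counts recorded in the trace.
#' @param solute,base identifiers recorded in the trace.
#' @param seed RNG seed (same seed, identical trace).
#' @return an [EnergyTrace-class].
#' @export
simulateEnergyTrace <- function(muXN, muXW, sigma = 5, nFrames = 1000L,
                                nBase = 170L, nWater = 1050L,
                                solute = "X", base = "URA", seed = NULL) {
  if (nFrames < 1L) .stopf("nFrames must be >= 1")
  if (sigma < 0) .stopf("sigma must be >= 0")
  draws <- .withSeed(seed, {
    list(eXN = rnorm(nFrames, muXN, sigma), eXW = rnorm(nFrames, muXW, sigma))
  })
  energyTrace(draws$eXN, draws$eXW, solute = solute, base = base,
              nWater = nWater, nBase = nBase)
}

#' Generate a synthetic cognate proteome with tunable coupling
#'
#' Emits mRNA/protein cognate pairs whose composition-propensity coupling
#' is a single dial `coupling` in `[-1, 1]`. Residues are drawn i.i.d.
#' from a fixed baseline distribution (independent of the dial) and each
#' residue's synonymous codon is drawn with weights
#' `exp(-coupling * eta * tanh(z_r / 1.5) * pyrdev)`, where `z_r` is the
#' residue's standardized scale value and `pyrdev` the codon's pyrimidine
#' count relative to its synonym family: for `coupling > 0`,
#' favourable-scale (low-energy) residues are preferentially encoded by
#' pyrimidine-rich codons, so pyrimidine-rich mRNA neighbourhoods code for
#' favourable protein stretches and the expected profile-matching median R
#' is negative, with magnitude increasing monotonically in the dial.
#'
#' The baseline residue distribution favours residues whose synonym
#' families actually differ in pyrimidine count (Leu/Ser/Arg-like),
#' especially where those residues are also informative for the scale
#' (high |z|), and is tilted so the covariance between scale values and
#' per-residue mean
#' codon pyrimidine content is zero. The standard genetic code links the
#' two (Phe -> UUY, Lys -> AAR, ...); without the tilt that link alone
#' would hand every zero-coupling proteome a scale-dependent nonzero
#' matching R. With it, `coupling = 0` (uniform, scale-independent codon
#' choice) gives an expected median R of 0. `|coupling| = 1` switches the
#' codon choice from weighted sampling to a deterministic greedy argmax.
#' Because the coupling acts per position and both profiles are smoothed
#' with the same window, the resulting matching R is essentially
#' independent of the window size used downstream.
#' Every emitted pair translates exactly under the standard genetic code
#' (no stop codon is appended: the mRNA has exactly 3 x protein length
#' bases).
#'
#' @param scale a [PropensityScale-class] supplying the residue values the
#'   coupling refers to; residues absent from the scale (Gly/Pro for
#'   sidechain-analog scales) are generated with a neutral weight.
#' @param nPairs number of cognate pairs (default 200).
#' @param coupling the coupling dial in `[-1, 1]` (default 0).
#' @param lengthRange integer min/max protein length (default 100-300;
#'   minimum 21 so one full window always exists).
#' @param seed RNG seed; same seed, identical proteome.
#' @return list of validated [CognatePair-class] objects.
#' @export
#' @examples
#' sc <- propensityScale(setNames(rnorm(18), LETTERS20(scaKind = TRUE)))
#' prot <- simulateCognateProteome(sc, nPairs = 5, coupling = 0.8, seed = 1)
simulateCognateProteome <- function(scale, nPairs = 200L, coupling = 0,
                                    lengthRange = c(100L, 300L),
                                    seed = NULL) {
  stopifnot(is(scale, "PropensityScale"))
  if (abs(coupling) > 1) .stopf("coupling must lie in [-1, 1]")
  if (nPairs < 1L) .stopf("nPairs must be >= 1")
  lengthRange <- as.integer(lengthRange)
  if (length(lengthRange) != 2L || lengthRange[1] > lengthRange[2] ||
      lengthRange[1] < 21L) {
    .stopf("lengthRange must be [min, max] with 21 <= min <= max")
  }

  # Standardized scale over all 20 residues; residues without a value
  # (Gly/Pro for sca scales) get the neutral weight z = 0.
  z <- setNames(rep(0, length(.AA20)), .AA20)
  sv <- scale@values
  z[names(sv)] <- if (stats::sd(sv) > 0) (sv - mean(sv)) / stats::sd(sv)
                  else 0
  codons <- .codonsForResidue()[.AA20]
  pyrDev <- lapply(codons, function(cd) .pyrCount(cd) - mean(.pyrCount(cd)))

  # Deconfounded baseline residue frequencies (see .deconfoundedFreqs):
  # the tilt makes the c = 0 null centred on 0 by construction and keeps
  # the code confound out of the composition-noise channel at all c.
  q <- .deconfoundedFreqs(z, names(sv))

  eta <- 5  # codon-choice coupling strength
  greedy <- abs(coupling) == 1

  # Per-residue synonymous-codon distributions; fixed across positions.
  pcod <- lapply(.AA20, function(r) {
    w <- exp(-coupling * eta * tanh(z[r] / 1.5) * pyrDev[[r]])
    w / sum(w)
  })
  names(pcod) <- .AA20

  .withSeed(seed, {
    lapply(seq_len(nPairs), function(k) {
      L <- lengthRange[1] +
        sample.int(lengthRange[2] - lengthRange[1] + 1L, 1L) - 1L
      res <- sample(.AA20, L, replace = TRUE, prob = q)
      cod <- character(L)
      for (r in unique(res)) {
        at <- which(res == r)
        cds <- codons[[r]]
        cod[at] <- if (length(cds) == 1L) cds
          else if (greedy) cds[which.max(pcod[[r]])]
          else cds[sample.int(length(cds), length(at), replace = TRUE,
                              prob = pcod[[r]])]
      }
      translateAndValidate(paste(cod, collapse = ""),
                           paste(res, collapse = ""),
                           id = sprintf("SYN%04d", k))
    })
  })
}
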