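---
title: "Methods: Kirkwood-Buff stability, propensity scales and mRNA-protein profile matching"
author: "nucleoprop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Kirkwood-Buff stability, propensity scales and mRNA-protein profile matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleoprop)
```

# What the package computes

`nucleoprop` implements the post-simulation analysis chain used to study
amino acids (and their sidechain analogs) in crowded aqueous solutions of
RNA nucleobases, and to test whether mRNA coding sequences are
compositionally complementary to the proteins they encode:

1. **microscopic stability** of a nucleobase/water mixture from radial
   distribution functions (RDFs) and Kirkwood-Buff (KB) integrals;
2. **interaction propensity scales** — one energy value per residue per
   nucleobase — from per-frame interaction-energy traces, plus relative
   base-versus-base scales and comparison against experimental references;
3. **profile matching** — window-averaged pyrimidine/purine content of an
   mRNA against the window-averaged propensity of its cognate protein,
   scored by a Pearson correlation per cognate pair and a median over a
   proteome;
4. a **random-scale permutation null** giving an empirical p-value for a
   proteome median.

A synthetic-data module generates every input the chain consumes, so that
each stage can be validated against results that are known by construction.

# Mixture structure and stability

## Model

For a binary mixture of nucleobase (N) and water (W), the KB integral of a
species pair is

$$G_{SS}(r) = 4\pi \int_0^r r'^2\,[g_{SS}(r') - 1]\,dr',$$

and the derivative of the log-activity of the nucleobase with respect to
its log mole fraction is

$$\frac{\partial \ln a_N}{\partial \ln X_N}
  = \frac{1}{1 + \rho_N X_N (G_{NN} + G_{WW} - 2 G_{NW})},$$

which must be positive for the mixture to be microscopically stable
against demixing at the examined scale. Positions are centres of mass of
the molecules, supplied directly as labeled particle frames; computing
centres of mass from atomic trajectories is out of scope, which keeps the
module agnostic to any particular simulation engine.

## Numerical choices

* **RDF**: pair-distance histogram under the minimum-image convention,
  normalized per frame by the ideal-gas shell count
  $n_\text{pairs}\,V_\text{shell}/V$; self-pairs excluded for
  same-species RDFs; `rMax` must not exceed half the smallest box edge.
  The default bin width of 0.01 nm resolves first-shell structure at
  0.3–0.5 nm.
* **Quadrature**: trapezoid on the bin grid with $g(0) = 0$ below the
  first bin centre (the $r^2$ weight vanishes there anyway). A
  closed-form step curve ($g = 0$ below 0.3 nm) is reproduced to better
  than 0.1% at 0.01 nm bins.
* **Plateau averaging**: running KB integrals converge slowly, so the
  reported $G$ is the mean of the running curve from `rLo = 1.5` nm to
  the end of the curve (configurable). Only the start of the window is a
  fixed convention; the upper end defaults to the last bin at or below the
  half-box bound rather than inventing a stop point.
* **Density convention**: $\rho_N$ is the particle count over the box
  volume; $X_N = n_N / (n_N + n_W)$.

The ideal (Poisson) mixture generator provides the analytic reference:
flat RDFs, vanishing KB integrals and a stability derivative of 1. At the
problem size used in the tests (500 particles in a 4 nm box, 60 frames)
the derivative is reproduced within 0.1, consistent with the statistical
scatter of each KB integral at that sampling depth (about 0.05 nm^3).

# Propensity scales

The interaction propensity of a solute X for nucleobase N is

$$\Delta E_{NW_X} = \bar E_{X\text{-}N} - \bar E_{X\text{-}W},$$

the difference of the mean solute-nucleobase and solute-water potential
energies over the production run, in kJ/mol; lower values mean the solute
prefers the nucleobase environment over water. Because systems built to a
common target water mole fraction (0.86) can differ by a few water
molecules, the solute-water mean is first rescaled by
`nWaterTarget / nWaterActual`, which assumes each water molecule
contributes proportionally to its number — with that linearity, rescaling
the mean and rescaling per frame are equivalent, so the mean is rescaled.
Relative scales subtract two propensity scales residue-wise
($\Delta E_{N_1 N_2} = \Delta E_{N_1 W} - \Delta E_{N_2 W}$) and are
antisymmetric and telescoping by construction. Scale values are relative
quantities at the composition they were derived for; no absolute
calibration is attempted.

Composition bookkeeping fixes `nWater = round(xWater (nBase + 1) /
(1 - xWater))` — 1050 waters for 170 nucleobases at 0.86, about 1221
molecules per system — and assigns counter ions to charged solutes (Na+
for Asp/Glu, Cl- for Lys/Arg). Histidine is treated as neutral by
default, the common choice at pH 7; a charged variant can be described by
passing the counter ion explicitly when building custom specs. The full
campaign enumerates (20 amino acids + 18 sidechain analogs) x 4 bases =
152 systems of 100 ns each, 15.2 microseconds in total.

Two reference conversions are included: association constants to binding
free energies, $\Delta G = -RT \ln(K/1\,\mathrm{M})$ (the conversion
temperature defaults to 298.15 K and is configurable, since reference
tables rarely state it), and solubility to saturated mole fraction (water
density 997 g/l and molar mass 18.015 g/mol at 25 C by default). Scale
comparison (`compareScales`) is Pearson or Spearman over the residue
intersection with optional subsetting, so experimentally motivated
exclusions (for example dropping an outlier residue) are explicit
arguments rather than ad hoc edits.

# Profile matching

A cognate pair is an mRNA coding sequence and the protein it encodes
under the standard genetic code; validation normalizes `T` to `U`, strips
a single trailing stop codon, and rejects internal stops, ambiguity codes
and translation mismatches. For sidechain-analog scales, glycines and
prolines are ignored on the protein side together with their codons on
the mRNA side, and windows run over the compacted coordinates.

Profiles are window means with **complete windows only** (a sequence of
$L$ residues yields $L - 20$ values at the default window of 21): padding
would bias edge values, and "centred at a position" only makes sense for
a full window. The mRNA window is 21 codons = 63 bases centred on the
codon of the centre residue, which makes the two profiles equal-length
and index-aligned — the only alignment that pairs a 21-residue window
with a 63-base window one-to-one. Window sizes must be odd.

Each pair is scored by the Pearson correlation between the two profiles,
reported with its raw sign: propensity is an energy (lower = more
favourable), so a *negative* R means content and propensity rise
together. Purine and pyrimidine content sum to one at every window, so
the two give exactly opposite R. Pairs that are unvalidated, shorter than
one window after exclusions, or have a zero-variance profile (Pearson
undefined) are skipped with a recorded reason rather than aborting a
proteome run; the proteome summary is the vector of per-pair R values and
their sample median (mean-of-central-values for even counts).

# Permutation null

Significance of a proteome median is assessed against scales drawn
uniformly: one independent U(0,1) value per residue, the full median
recomputed per random scale, and

$$p = \frac{\#\{\text{random scales with } |\text{median}| \ge
  |\text{median}_\text{obs}|\}}{n_\text{random}}.$$

The estimator admits $p = 0$, which is reported as-is and displayed as
$p < 1/n_\text{random}$; no +1 correction is applied, keeping the
estimator exactly as defined. Because Pearson R is invariant under
positive affine maps of the scale, the U(0,1) support is as general as
any interval. The default `nRandom` is 10^4 (raise towards 10^6 for
publication-resolution p-values; the estimator is unchanged).

Since the propensity profile is linear in the scale vector — each profile
value is a window residue-count row times the scale — null medians are
computed by one matrix product per pair per batch of scales. This is an
exact algebraic shortcut, not an approximation, and the test suite
asserts its equality with the direct per-pair route.

A caution the null makes visible: random scales inherit the genetic
code's linkage between residue identity and codon pyrimidine content
(Phe is encoded UUY, Lys AAR, and so on), so null medians are *wide*
(standard deviation around 0.2–0.3 for typical synthetic proteomes).
Strong observed medians therefore yield small but nonzero p-values at
moderate `nRandom`; this mirrors the situation with real proteomes,
where medians near −0.7 carry p-values of order 10^-3 against 10^6
random scales rather than vanishing outright.

# The synthetic-data generators

The generators define the study conditions for every test; all are pure
functions of their seed, and seeded calls restore the caller's RNG state.

* **Mixture frames**: `ideal` (uniform Poisson field — flat RDF, zero KB
  integrals, stability derivative 1), `hard_shell` (sequential insertion
  with exclusion diameter `d`, bounded retries, explicit
  infeasible-packing error — $g(r) = 0$ below `d`), `clustered`
  (Gaussian blobs — first-peak $g > 1$). Defaults (4 nm box, on the
  order of a few hundred particles) echo the simulated mixtures the
  analysis is meant for.
* **Energy traces**: independent Gaussians around stated means;
  `sigma = 0` gives the means exactly. The default sigma of 5 kJ/mol is
  a realistic per-frame fluctuation scale for interaction-energy sums of
  this kind.
* **Cognate proteomes**: the coupling dial `c` in [-1, 1] links sequence
  composition to a supplied scale. Residues are drawn i.i.d. from a
  baseline distribution *independent of the dial*; each residue's
  synonymous codon is drawn with weight
  $\exp(-c\,\eta\,\tanh(z_r/1.5)\,\text{pyrdev})$, where $z_r$ is the
  residue's standardized scale value, pyrdev the codon's pyrimidine count
  relative to its synonym family, and $\eta = 5$. For $c > 0$,
  favourable residues are encoded by pyrimidine-rich codons, so the
  expected matching R is negative, with magnitude increasing
  monotonically (linear onset) in the dial; $|c| = 1$ replaces sampling
  with a deterministic greedy argmax. Protein lengths are uniform on
  100–300 by default (minimum 21, one full window); no stop codon is
  appended, so the mRNA has exactly 3L bases.

Two design points deserve emphasis, because the genetic code forced them:

* **Deconfounded baseline.** With residues drawn uniformly, shared
  window-composition noise hands *every* zero-coupling proteome a
  matching R close to the correlation between the scale and per-residue
  mean codon pyrimidine content — about +0.4 for a typical random scale,
  nothing like 0. The baseline residue distribution is therefore tilted
  (exponential tilt, solved numerically, mildest root, |t| bounded) so
  that covariance is exactly zero, which centres the zero-coupling null
  at 0 by construction. The baseline also favours residues whose synonym
  families actually differ in pyrimidine count (Leu/Ser/Arg-like),
  especially where those are informative for the scale, so the dial has
  room to act.
* **Codon-only coupling channel.** Coupling through *residue selection*
  (making favourable residues congregate in field-defined regions) was
  deliberately rejected: any such channel re-imports the code confound
  nonlinearly, with scale-dependent sign, and breaks the monotonicity of
  the dial. The synonymous-codon channel never touches residue identity,
  so it is confound-free, and being per-position it makes the resulting
  R essentially independent of the window size used downstream.

What the generators do *not* emulate: real codon-usage bias, organismal
composition differences, length/expression correlations, secondary
structure, or any force-field energetics. Passing the synthetic suites
therefore demonstrates that the machinery is correct and calibrated — not
that any particular real proteome shows complementarity; conclusions
about real data require the real sequences and the simulation-derived
scales.

# Problem sizes and determinism

The test and acceptance runs use: 500-particle/60-frame ideal mixtures
for the stability limit; 50,000-frame traces at sigma = 5 kJ/mol for
scale recovery (Pearson >= 0.99 against the generating values);
200-pair proteomes of length 100–300 for null calibration (zero-coupling
|median R| < 0.1, null p-value calibration over 200 repetitions at
`nRandom` = 200); and 10^4 random scales for reported p-values. These
sizes put each quantity's sampling noise well inside the tolerance it is
tested at. Every stochastic step takes an explicit seed, and identical
seeds give bit-identical output.

# Known limitations

* KB integrals carry no finite-size or closure corrections; the
  compressibility/pressure routes are not implemented.
* The stability analysis assumes an orthorhombic box and constant
  composition across frames.
* Propensity scales are composition-relative; comparing scales derived
  at different water mole fractions is refused rather than corrected.
* The permutation null draws one value per residue type (not per codon),
  the only reading consistent with how scales are structured.
* Whether stop-codon bases belonged in the final windows of the original
  analyses is unknowable from published descriptions; here the trailing
  stop is stripped before profiling, the standard coding-sequence
  convention.
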