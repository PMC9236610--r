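---
title: "Methods: predicting splice-site variant effects from probing-guided ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting splice-site variant effects from probing-guided ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psifold)
```

# The problem

Whether an alternative exon is spliced into a transcript is summarized by
its percent spliced in (PSI): 0 when every transcript skips the exon, 1
when every transcript includes it.  At a 5' splice site the donor 9-mer
(the last 3 exonic and first 6 intronic nucleotides) must base-pair with U1
snRNA, and the spliceosome must thread a progressively longer stretch of
single-stranded pre-mRNA through its assembly stages.  Pre-mRNA secondary
structure that sequesters this region therefore suppresses inclusion, while
splicing regulatory elements (SREs) — short enhancer and silencer motifs
bound by trans-acting proteins — tune it.  A single-nucleotide variant can
act through either channel: by reshaping the structural ensemble around the
junction or by creating/destroying motifs.

psifold quantifies both channels and combines them in a bounded-outcome
regression:

1. **Structure.** A nearest-neighbor folding engine, restrained by
   chemical-probing reactivities, samples N structures from the Boltzmann
   distribution of the junction region.  For every sampled structure the
   unfolding free energy of a spliceosome footprint
   $$\Delta G^{\ddagger} = \Delta G(\text{region forced single-stranded})
     - \Delta G(\text{folded}) \ge 0$$
   is the nonequilibrium cost of ripping the footprint open without letting
   the RNA refold.  The ensemble is summarized by the mean, SD, skewness
   and excess kurtosis of $\Delta G^{\ddagger}$, plus the value for the
   single MFE structure.
2. **Sequence.** Donor-site strength change ($\Delta SS$) from a 9-position
   log-odds matrix, and threshold-gated sliding-window $\Delta$strengths
   for ESE/ESS/ISE/ISS and RBP motif sets, aggregated into enhancer
   ($E$), silencer ($S$), and RBP exclusion/inclusion ($Ex$, $In$) terms.
3. **Regression.** PSI is modeled as Beta-distributed with mean linked by
   logit to the features.  Seven formulas are supported; the headline
   *interactive* model gates the structure block by
   (isSynonymous + isIntronic) and the SRE block by isNonSynonymous,
   encoding the observation that synonymous and intronic variants act
   predominantly through structure while non-synonymous variants act
   through the motifs they alter.

# The folding engine

The engine (Rcpp) implements loop-decomposition energy evaluation, a
McCaskill-style partition function with outside-algorithm base-pair
probabilities, MFE folding, and stochastic traceback sampling, all over one
self-contained nearest-neighbor parameter set:

* stacking: a 6 x 6 table over {AU, UA, CG, GC, GU, UG}; the default is
  generated from per-pair strengths $h(\mathrm{CG}) = 3.3$,
  $h(\mathrm{AU}) = 1.1$, $h(\mathrm{GU}) = 0.7$ kcal/mol as
  $-(h_1 + h_2)/2 - 0.4$, reproducing the qualitative ordering of measured
  stacks (strongest $-3.7$, weakest $-1.1$);
* hairpin loops: $5.0 + 1.08\,\ln(l/3)$ kcal/mol, minimum loop 3 nt;
* interior/bulge loops: $3.5 + 1.08\,\ln(s)$;
* multibranch loops: $3.4 + 0.4\,(\text{branches}+1) + 0.1\,u$;
* terminal AU/GU penalty 0.5 per helix-end pair; $RT = 0.0019872 \times
  310.15$ kcal/mol.

The table ships as data (`write_energy_model()` / `read_energy_model()`),
so measured parameter sets can be dropped in.  The engine does not claim
thermodynamic accuracy against measured parameter sets; the pipeline's
conclusions ride on ensemble *differences* between alleles, and every
recursion is verified exactly (relative tolerance $10^{-9}$) against
exhaustive enumeration on short sequences, with and without pseudo-energies.

**Search space.** Pseudoknot-free, hairpin loops $\ge 3$, no lonely-pair
prohibition, interior loops capped at 30 unpaired nucleotides inside the
dynamic programs (the standard cap; the energy *evaluator* scores any loop
size, which matters because forcing a footprint single-stranded can leave
arbitrarily large loops behind).

**Reactivity restraints.** DMS reactivities inform only A/C nucleotides.
A paired nucleotide with reactivity $r$ adds
$-RT \ln[P(r \mid \text{paired}) / P(r \mid \text{unpaired})]$; unpaired
and no-data ($-999$) positions add exactly 0, so an all-sentinel profile
reproduces the unrestrained computation bit for bit.  The dynamic programs
use a two-context form (helix-end and stacked likelihoods collapsed by
mixture with calibrated class weights); a three-context rescoring of fixed
structures is available (`rescore_with_contexts()`).  Context likelihoods
come either from kernel density fits against a reference structure
(`calibrate_context_distributions()`: reflection at 0, truncation at the
reactivity cap of 5, Silverman bandwidth, classes with under 20
observations merged into one paired class) or from truncated-gamma
parametric families (`context_distributions_gamma()`), whose likelihood
ratio is provably monotone in $r$ — the form used by the synthetic
generator and the default pipeline.

**Numerical choices.** Boltzmann weights are accumulated in double
precision without rescaling — adequate to ~300 nt with these parameter
magnitudes, and the partition function stops with an explicit overflow
error rather than returning nonsense.  MFE traceback examines alternatives
in a fixed order (unpaired exterior first, then pairs by position) and
takes the first alternative within $10^{-9}$ of the optimum, so degenerate
optima resolve deterministically (the tie-break is not an exact
fewest-pairs ranking).  Stochastic traceback consumes R's RNG stream, so
`sample_structures()` is bit-reproducible under its seed argument and
clamps floating-point remainders to the last available option.

# Reactivity processing

Raw reactivity is the background-subtracted mutation rate
$R_i = mutr_S - mutr_U$ (negative values retained), with SE propagated
from the binomial rate variances.  Normalization is per nucleotide type:
divide by the mean of the top 10% of values remaining after the most
reactive 2% are removed.  Rank counts are rounded half-up; the exclusion is
applied before decile selection; base types with fewer than 10 usable
values are emitted as no-data with a warning.  After normalization the
qualifying top-decile mean equals 1 exactly, which the tests assert, and
the operation is idempotent to $10^{-9}$.  For visualization, G/U profiles
are rescaled to a 0.1 maximum.  For folding, G/U are masked to $-999$,
values above 5 are capped, and negatives floored at 0.

# Spliceosome footprints

The built-in footprint table records the minimum pre-mRNA extents around
the junction enclosed at four assembly stages, as counted from cryo-EM
coordinates: Pre-B (2 exonic, 8 intronic), B (10, 17), Pre-B^act^ (9, 20),
B^act^ (12, 31) — 43 nt in total for B^act^, the stage whose unfolding
energetics the pipeline models by default.  `count_footprint_from_coordinates()`
recomputes such counts from any PDB file by counting resolved nucleotide
residues (any residue with at least one atom record) on the pre-mRNA chain
on either side of the declared junction residue; the shipped fixtures are
synthetic single-atom-per-residue files that exercise the counting, not
geometry.

Unfolding a region removes every pair with at least one endpoint inside it.
Region growth grows the removed-pair *set* monotonically; note the energy
itself is not monotone — removing an energetically unfavorable pair lowers
the cost — which is why the invariant is stated on sets.

# Motif scoring

PWMs are log2 odds against the uniform background 0.25, built either from
k-mer sets (position frequencies with a 0.5 pseudocount per base) or from
published position frequency matrices.  Each PWM carries a threshold: the
95th percentile (linear-interpolation quantile) of all $4^w$ k-mer scores,
recomputed exhaustively — a window counts as a motif instance only if the
better-scoring allele exceeds it, so both motif gain and motif loss are
captured (the threshold-passing allele is a genuinely open convention; we
gate on `max(WT, mutant)`).  Exonic PWMs scan windows fully inside the
exon, intronic PWMs fully inside the intron; junction-straddling and
end-truncated windows are skipped.  Per PWM, score differences of windows
overlapping the mutated positions are summed; per category, the mean of
non-zero per-PWM deltas (0 when none qualify) yields $\Delta$ESE etc., and
$E = \Delta ESE + \Delta ISE$, $S = \Delta ESS + \Delta ISS$.

The bundled default donor model is a first-order 9-position log-odds matrix
from canonical human donor consensus frequencies (GU at +1/+2 near
invariant); `read_splice_site_model()` accepts external score tables.  The
bundled SRE/RBP hexamer sets are synthetic stand-ins (named
`synthetic_*` under `extdata/`) because published screen sets are external
data; users supply their own via `read_hexamer_pwm()`.

# The PSI model

Beta regression in mean-precision form: $y_i \sim
\mathrm{Beta}(\mu_i\phi, (1-\mu_i)\phi)$, $\mathrm{logit}(\mu_i) =
x_i^\top\beta$.  The likelihood over $(\beta, \log\phi)$ is maximized by
BFGS with the analytic gradient, initialized from a logit-transformed
least-squares fit, relative tolerance $10^{-12}$, up to 500 iterations;
standard errors come from the inverse observed information.  When exact
0/1 responses occur the response is first shrunk by
$y' = (y(n-1) + 0.5)/n$; panels already inside the open interval are
fitted untransformed — applying the shrink unconditionally measurably
attenuates coefficients on boundary-free data, which our parameter-recovery
tests detect.  Constant (unidentifiable) columns — e.g. the gated
donor-strength term in a subsample with no donor-site non-synonymous
mutation — are dropped with a warning and reported NA, like `lm()` under
rank deficiency.

The interactive formula is implemented exactly as printed: gated products
only, no gate main effects.  Compensatory double mutations carry the flags
of their component substitutions (the formula has no compensatory term).
`bootstrap_r2()` subsamples 70% without replacement 10 times and reports
in-sample squared Pearson correlations overall and per category (a
held-out mode is provided, since "trained and tested" phrasing is genuinely
ambiguous for this design; neither mode is asserted against any published
R² value).

# Ensemble analysis

Structures digitize to element strings: stem 1, hairpin loop 2, other
loops (interior, bulge, multibranch, exterior segments between helices) 3,
and 5'/3' tails 0.  Interior loops map to "loop" because the five-letter
alphabet has no interior-loop symbol; exterior tails split f/t at the
midpoint on open chains, a choice that cannot affect downstream numbers
since both digitize to 0.  The concatenated per-variant matrices (e.g.
3 x 1000 x 234) are embedded in 2-D by principal components — a
deterministic library call equivalent to classical MDS under Euclidean
distance; the original analysis used a stochastic neighbor embedding, and
the occupancy/representative conclusions we compute are robust to this
choice while gaining exact reproducibility — then k-means with k = 5,
10 restarts, fixed seed.  Representative structures minimize Hamming
distance to the per-position plurality consensus (ties: lower digit, then
earliest member; the result is always an ensemble member).

Feature categorization clips non-zero values at their 5th/95th
percentiles, scales by the maximum absolute value, inverts silencer and
mean-$\Delta G^{\ddagger}$ columns so 1 always predicts inclusion, maps to
$[0,1]$ around 0.5, and calls support "both"/"SRE"/"structure"/"neither"
by strict direction agreement with PSI against 0.5 (exact 0.5 counts as no
support).  Hierarchical clustering (average linkage, Euclidean) runs first
on changed-flags (six clusters), then within clusters on the normalized
values.

# The synthetic generator

The generator replaces the study's raw data and defines the conditions all
statistical tests run under:

* `gen_junction_sequence()`: random sequence with one planted hairpin
  (default arm lengths and a 4-nt loop) straddling the declared junction;
  the study-sized fixture is 234 nt with the junction at 93.
* `simulate_reactivities()`: gamma draws with shape 2 and context means
  0.8 / 0.2 / 0.05 (unpaired / helix-end / stacked) — values chosen to
  reproduce the qualitative context ordering of probing data, since the
  calibrated histograms behind the real pipeline are not tabulated
  anywhere we can consume.  At these defaults reactivity separates paired
  from unpaired A/C nucleotides with AUC ~0.95.
* `simulate_profile_table()`: treated rate = background + scaled
  reactivity with binomial counting noise; the infinite-depth limit is
  exact, so `compute_raw_reactivity()` inverts it.
* `simulate_mutation_panel()`: categories drawn to the declared mix
  (non-synonymous and synonymous in the exon, intronic and compensatory in
  the intron), positions oversampled eightfold inside the donor 9-mer so
  the donor-strength feature varies (disease panels concentrate near the
  junction); features computed by the real pipeline; mean PSI =
  logit$^{-1}$ of the interactive linear predictor under the true
  coefficients; observed PSI ~ Beta$(\mu\phi, (1-\mu)\phi)$, with exact
  0/1 draws recorded at 0.02/0.98 (complete outcomes; Beta support is
  open).  Structure features enter as changes relative to the wild-type
  ensemble, making the generating model invariant to fixture length; the
  default true coefficients are calibrated to each feature's typical
  spread (ensemble-kurtosis shifts are an order of magnitude wider than
  mean shifts) so simulated PSI spans the unit interval without piling up
  on the boundaries.

What the generator does **not** emulate: replicate correlation between
cell lines, read-level sequencing artifacts, coupling between a mutation's
motif effects and its structural effects beyond what the planted fixture
induces, and the long-tailed empirical reactivity distributions of real
probing data.  Passing recovery tests therefore demonstrate correctness of
the estimation machinery under the stated model, not predictive accuracy
on biological data.

# Problem sizes and seeds

The shipped tests verify the engine against exhaustive enumeration on 200
random sequences of 6–14 nt, sampling consistency at $10^4$ draws,
$\Delta G^{\ddagger}$ invariants on 1000-member ensembles of the 234-nt
fixture, coefficient recovery on panels of n = 200 at $\phi = 50$ over 20
PSI realizations (asserting $\ge 95\%$ of z-scores within 3 SE and
$\ge 85\%$ CI coverage — the per-draw 3-SE event has probability 0.9973,
so demanding all 160 draws pass would fail a perfectly calibrated fitter
about a third of the time), and one full end-to-end recovery at study size
(234 nt, N = 200 samples per variant, 200 mutations).  Every stochastic
stage takes an explicit seed and is asserted byte-identical across
re-runs.

# Known limitations

* The energy model is a simplified parameter set: no dangles, coaxial
  stacking, or special hairpin/tetraloop terms; absolute free energies are
  not comparable to measured-parameter engines.
* Only the 5' (donor) side is modeled; 3' splice-site structure and
  sequence are out of scope.
* The two-context pseudo-energy collapse is a likelihood-ratio
  approximation; a full three-state recursion could re-weight ensembles
  differently.
* Kernel-density context likelihoods need not give monotone restraints;
  use the gamma family when monotonicity matters.
* In-sample bootstrap R² (the default) is an optimistic estimate of
  predictive performance; use `holdout = TRUE` for honest error.
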