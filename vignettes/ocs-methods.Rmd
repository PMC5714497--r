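---
title: "Managing introgressed breeds with segment-based optimum contribution selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Managing introgressed breeds with segment-based optimum contribution selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(nativesel)
```

## The problem

Local livestock breeds with a history of introgression from high-yielding
breeds face three coupled conflicts: raising genetic merit versus
controlling inbreeding, maintaining overall diversity versus preserving
what is genetically unique to the breed, and raising merit versus
recovering the original genetic background. Classical optimum
contribution selection (OCS) maximizes the expected merit of the next
generation, `c'EBV`, over the genetic contributions `c` of the selection
candidates subject to an upper bound on mean kinship — it addresses the
first conflict only. When the high-merit animals owe their merit to
introgressed material, kinship-constrained selection keeps importing that
material, diluting the native genome.

`nativesel` implements the genomic quantities and constraints needed to
manage all three conflicts from phased SNP data, and a forward-in-time
simulator to compare selection strategies over generations.

## Segment-based kinship, native alleles, migrant contribution

All quantities derive from *qualifying shared haplotype segments*:
maximal runs of marker-wise allele identity between two haplotypes that
contain at least 20 consecutive markers and span at least 2.5 Mb
(`segment_criteria()`). Long identical segments indicate recent identity
by descent rather than chance identity in state.

* **Kinship** `fSEG(i, j)` is the probability that two alleles drawn from
  a random genome position on random haplotypes of i and j lie on a
  qualifying shared segment: the average over the four haplotype
  pairings of the genome fraction covered by qualifying segments
  (`fseg_matrix()`). "Genome fraction" uses half-interval physical
  weights: each marker represents the interval reaching halfway to its
  neighbours, clipped at chromosome ends (`marker_weights()`; a
  marker-count weighting is available). For i = j the two same-haplotype
  pairings contribute 1 each, so the diagonal is at least 0.5.
* **Native classification**: a marker of a focal haplotype is *native*
  if, in every reference breed, the frequency of reference haplotypes
  sharing a qualifying segment covering that marker is strictly below
  0.01 (`native_mask()`). The frequency is evaluated per focal haplotype
  (sharing-based), and the threshold is strict, so in a reference panel
  of 100 haplotypes a single sharer (frequency 0.01) already makes the
  marker migrant.
* **Migrant contribution** `MC` of an individual is the genome-weighted
  fraction of its two haplotypes not classified native
  (`migrant_contribution()`).
* **Kinship at native alleles** `fSEG|N` conditions the kinship
  probability on both sampled alleles being native. It is kept as a
  numerator/denominator pair of matrices (`fseg_native_matrices()`):
  under contributions `c` the population value is
  `(c'Snat c) / (c'Dnat c)`, so the conditional expectation is formed
  after mixing, not per pair.

Population summaries under a contribution vector are `c'Fc`,
`(c'Snat c)/(c'Dnat c)` and `c'm` (`population_summaries()`), with the
uniform vector giving generation means. Note that `c'Fc` with uniform
`c` includes the self-kinship diagonal; the bound recursions below use
the same convention on both sides, so the convention cancels from the
tracking behaviour.

## The selection scenarios

Five strategies are compared (`scenario_config()`), all with 500 male
and 500 female candidates per generation at full scale, females fixed at
equal contributions, and optimization over males only:

* **REF** — no selection; every candidate leaves exactly two offspring.
  With zero family-size variance the effective size is twice the census
  size (`effective_size_equal_family()`).
* **TS** — truncation selection. From `1/Ne = 1/(4 Nsire) + 1/(4 Ndam)`
  with target `Ne = 100` and 500 dams, `n_sires_for_ne()` gives 26
  sires (the floor of 26.3); the top 26 by EBV get equal contributions.
* **OCS-I** — maximize `c'EBV` subject to `c'Fc <= ub`, with the bound
  updated each generation from the realized mean:
  `ub_{t+1} = mean_t + (1 - mean_t) * dF`, `dF = 1/(2 Ne) = 0.005`
  (`update_kinship_bound()`, `delta_f_from_ne()`).
* **OCS-II** — OCS-I plus the same recursion on `fSEG|N` and the
  requirement that mean MC not exceed its base-generation level.
* **OCS-III** — as OCS-II but the MC bound *decreases* 3% per
  generation. The decay is interpreted as relative (previous mean times
  0.97): a three-percentage-point absolute drop would cross zero within
  the horizon at the observed MC levels, whereas geometric decay matches
  a 0.62-to-0.45 trajectory over ten generations. An absolute mode is
  available (`update_mc_bound(mode = "absolute")`).

Bounds always chain on *realized* generation means, not on previous
bounds, so estimation drift does not accumulate. For OCS-II the MC
reference is the realized G0 mean of the replicate.

## The contribution optimizer

The selection problem is linear in `c` with convex quadratic
(`c'Fc <= ub`), linear (`c'm <= ub`) and fractional-quadratic
(`c'Sc / c'Dc <= ub`) constraints, plus `c >= 0` and the sex-sum
equality. No general QCQP solver is assumed; the package ships a primal
log-barrier interior-point method (`solve_ocs()`):

* Kinship matrices are first projected to positive semidefinite by
  flooring negative eigenvalues at zero (`nearest_psd()`) — estimated
  segment kinships need not be PSD, and flooring is the minimal
  perturbation that preserves the constraint's meaning. Achieved values
  are reported on the projected matrices.
* Each convex subproblem is solved by Newton centering with the
  equality constraint eliminated through a Cholesky/Schur step,
  path-following to a duality gap below 1e-9. A phase-I slack
  formulation finds a strictly feasible start or certifies
  infeasibility; infeasibility is reported loudly with per-constraint
  violations, never silently relaxed.
* The fractional constraint is handled by a fixed-denominator scheme:
  fix `delta = c'Dnat c` at the previous iterate, impose the convex
  constraint `c'Snat c <= ub * delta`, and re-solve. Two numerical
  points matter. First, every subproblem is cold-started from the
  uniform point, which makes the returned solution a deterministic,
  continuous function of `delta`; warm starts land on different points
  of the (often degenerate) optimal face and turn the iteration into a
  noisy map that cannot meet a tight convergence test. Second, once the
  ratio residual `g(delta) = c'Sc/c'Dc - ub` has been observed with
  both signs, the binding `delta*` is bracketed and refined by
  bisection. Convergence is declared when `|g| <= 1e-7` (binding case)
  or the denominator is stable to a relative 1e-6 (slack case), within
  25 subproblem solves; if `g` jumps across zero because the optimum
  snaps between two faces, the feasible-side solution is returned.
* Without optional bounds the problem is linear over the male simplex
  and the exact vertex solution (all male mass on the top-EBV male) is
  returned directly.

Contributions become offspring counts by largest-remainder rounding of
`c_i * 2 * n_offspring` over sires (ties broken by a seeded shuffle),
with every dam receiving exactly `n_offspring / n_dams` offspring
(`contributions_to_counts()`).

## The forward simulator

Offspring receive one gamete from each parent (`meiosis()`): per
chromosome, the crossover count is Poisson with mean equal to the
genetic length in Morgans (no interference), breakpoints are uniform on
the genetic map, and the starting haplotype is chosen at random. When no
genetic positions are supplied, 1 cM = 1 Mb. Mates are allocated
randomly subject to the requested family sizes; sexes are assigned
exactly half and half (`advance_generation()`). There is no mutation,
no sex-specific map and no overlapping generations. Reproducibility
comes from deterministic seeding per (replicate, generation); a single
seed reproduces a whole study.

Native masks are recomputed against the fixed reference panels each
generation (the panels represent genotyped reference animals that do
not change). An alternative estimator that propagates each marker's
origin from the parental haplotype it was inherited from is available
(`origin_mode = "propagate"`, using the meiosis source tracks), and is
useful for separating estimation effects from true ancestry changes.

## The synthetic study system

Real multi-breed chip data cannot be shipped, so the package generates a
study system with the statistical structure the method assumes
(`breed_model()`, `simulate_breed_panels()`, `make_study_population()`):

* Ancestral allele frequencies are Beta(0.8, 0.8) truncated to
  (0.05, 0.95); each breed's frequencies follow the Balding-Nichols
  model with drift 0.10.
* Each reference breed descends from a pool of 10 haplotypes; its panel
  haplotypes are block mosaics of that pool (exponential block lengths,
  mean 10 Mb). This gives within-breed segment kinships near 0.11 —
  introgression from a numerically strong commercial breed traces back
  to few, closely related ancestors, and this co-ancestry of migrant
  material is what couples kinship control to MC control.
* Focal founders are mosaics of a 40-haplotype native pool and the
  reference pools. Each founder draws its own migrant proportion from a
  Beta distribution with mean 0.62 and SD 0.15, and each block is
  migrant with that probability, the source breed drawn from mixture
  weights dominated by the Holstein group (0.448 Holstein-Friesian plus
  Red Holstein, 0.152 Norwegian Red, 0.021 Fleckvieh, normalized).
  Between-individual ancestry variation is essential: it creates the
  positive covariance between chromosome TBV components (so the TBV
  variance exceeds the genic variance at G0) and the positive MC-merit
  correlation.
* The trait has 300 QTL at desk scale (1500 at full scale); effect
  magnitudes are gamma(0.4), signs fair coins. The largest positive
  effects are then re-assigned to the sampled QTL whose mean
  reference-breed frequency most exceeds the focal frequency (rank
  pairing: k-th largest positive effect on the k-th ranked QTL;
  negative effects randomly among the rest), so migrant genome carries
  higher merit. Effects are rescaled so the focal founders' genic
  variance `sum 2 p (1-p) a^2` is exactly 0.075.
* EBVs are simulated at reliability 0.75:
  `EBV = mu + r2 (TBV - mu) + E`, `E ~ N(0, r2 (1 - r2) var(TBV))`,
  with `mu` the mean TBV of the generation (the generation mean is the
  natural reading of the EBV model's centering). The squared
  correlation between EBV and TBV is `r2` by construction.

What the generator does *not* emulate: linkage disequilibrium within
the ancestral pools (pool haplotypes are drawn marker-independently, so
segment sharing comes only from mosaic descent), genotyping error,
pedigree structure among reference animals beyond pool descent, and the
real chip's allele-frequency spectrum. Passing tests therefore show that
the estimators and the optimizer behave correctly on data with the
assumed segment structure, not that the numerical values of the original
cattle data are reproduced — reproducing those would require the
original reference genotypes.

## Study sizes and what the package's own study shows

The shipped study (`analysis/`, also the long-running acceptance test)
uses 3 chromosomes of 50 Mb / 500 markers each (0.1 Mb spacing, 50K-like
density), 60 focal founders, reference panels of 40/40/20/40 animals, a
base generation of 300 (150 dams; the sire formula then selects 30 of
150 males, a selection intensity comparable to the full-scale 26 of
500), 300 QTL, 10 generations and 3 replicates. These sizes keep the
whole five-scenario study near ten minutes on one core while leaving
every directional contrast intact: gain ordering TS ~ OCS-I > OCS-II >
OCS-III > REF; MC rising under TS/OCS-I, held under OCS-II, decaying
geometrically under OCS-III; fSEG|N rising fastest under TS; constrained
quantities tracking their bounds to within 0.002.

One scale effect deserves note: at full scale the no-selection scenario
shows slightly *decreasing* estimated fSEG, fSEG|N and MC, because
recombination splits old segments below the detection thresholds faster
than drift (at Ne = 2000) raises kinship. At a few hundred animals drift
(Ne = 600) can outweigh the splitting loss for fSEG, while estimated MC
still declines. The splitting mechanism itself is tested directly: the
gap between estimated MC and the true, origin-propagated migrant
fraction widens over unselected generations.

## Numerical conventions and degenerate inputs

* Segment length is measured first-to-last marker of the run; runs do
  not extend into flanking disagreement intervals. Thresholds are
  inclusive (>= 20 markers, >= 2.5 Mb); the native-frequency threshold
  is strict (< 0.01). No mismatches are tolerated within a run —
  simulated data are error-free, and error-tolerant ROH calling is out
  of scope.
* All-pair segment scans are bit-packed (64 markers per machine word)
  and run in C++; a panel of a few hundred haplotypes takes well under a
  second per kinship matrix.
* `fSEG|N` is undefined when no native genome remains
  (`c'Dnat c = 0`); this raises an error rather than returning a
  placeholder.
* Ties in truncation selection follow R's stable order; rounding ties
  in `contributions_to_counts()` are broken by a seeded shuffle.
* Single-marker chromosomes get zero length weight; maps must be
  strictly increasing in position within chromosomes.

## Limitations

The optimizer handles the constraint set used here (one quadratic per
kinship matrix, one linear MC bound, simplex constraints); it is not a
general-purpose conic solver. Mate allocation is random — no
mate-selection optimization. Selection acts on males only, as in
breeding programs where a substantial share of bull calves is genotyped;
female-side optimization is out of scope. The effective-size formulas
are the classical idealized ones and ignore the co-ancestry of the
selected group, which is precisely why realized inbreeding under TS
exceeds its nominal target — one of the study's points.
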