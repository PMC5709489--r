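---
title: "Multilocus DNA barcoding: models, simulator and pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilocus DNA barcoding: models, simulator and pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multibarcode)
```

## The problem

Distance-based species identification assumes a "barcoding gap": every
intraspecific distance smaller than every interspecific one. For a single
locus the two distributions are driven by a *single* realized genealogy,
so for recently diverged sister species — where expected divergence
(2τμ per site) is of the same order as within-species diversity (θ = 2Nμ)
— the distributions overlap even with perfect data. The overlap is mostly
coalescent sampling variance, and the remedy is averaging: the distance
computed on a concatenation of *k* independent loci has variance shrinking
roughly as 1/k, so the gap that exists in expectation eventually emerges.
This package quantifies that process and carries it through to a decision
procedure for unknown queries.

## Distances and identification criteria

`p_distance()` is the uncorrected proportion of mismatching sites among
*valid* sites, where a site is valid iff both sequences carry one of
`A/C/G/T` — pairwise deletion. Complete deletion (dropping a column for
all pairs whenever any sequence has a gap) was the design alternative;
pairwise deletion is standard p-distance practice and wastes no data when
missingness is scattered, so it is used throughout. `concat_distance()`
is exactly `p_distance()` on the physical concatenation: mismatch and
valid-site tallies are additive across loci, which the tests verify
against literal string concatenation.

The *all-species-barcodes* criterion declares a query correctly
identified only when **every** conspecific ranks closer than **every**
heterospecific. Exact distance ties between the farthest conspecific and
nearest heterospecific are resolved *against* the query (heterospecific
first). The tie-break is a design choice: it biases toward "incorrect",
never manufacturing successes from shared haplotypes, which matches the
criterion's conservative spirit; it is visible in `rank_neighbors()`
ordering and can be audited there. Success rates pool over
(individual × replicate): each of the 200 locus-resampling replicates
scores every individual as a query against all others (leave-one-out),
and the mean is taken over all those trials. Pooling, rather than
averaging per-replicate rates first, is a choice without consequence for
the mean but it defines the Monte-Carlo standard errors reported.

`optimize_threshold()` scans zero plus all midpoints of the sorted
observed distances and minimizes cumulative error
(#intra > T) + (#inter ≤ T), taking the smallest threshold on ties, and
`best_close_match()` applies the resulting threshold with verdicts
correct / incorrect / ambiguous / no id.

## The isolation-with-migration simulator

`simulate_genealogy()` implements the two-population structured
coalescent backward in time with the continuous-time exponential-rates
approximation of the Wright–Fisher coalescent: within population *i* each
pair coalesces at rate 1/Nᵢ per generation, each lineage in *i* migrates
at rate m_ij, and at the split time all lineages enter the ancestral
population. For N = 20,000 the discretization error of this
approximation is negligible relative to Monte-Carlo noise.

Two conventions deserve explicit statement:

* **Population sizes are gene copies** (haploid counts): the pairwise
  coalescence rate is 1/N, so E[TMRCA] for two lineages in one population
  is N generations. This matches the "number of genes" convention of
  widely used sequence simulators. The simulator's own acceptance anchor
  (success ≈ 0.111 at split 1,000 generations with 1,000 loci) reproduces
  under this reading (the package measures ≈ 0.07–0.11 across seeds), so
  the alternative diploid reading (rate 1/(2N)) is not used.
* **Migration rates are per lineage per generation, backward in time**,
  symmetric in units across directions; m = 0.0001 means each sampled
  lineage traces its ancestry to the other population at that rate.

Mutations follow Jukes–Cantor finite sites: branch counts are
Poisson(μ · L · branch length), each hit strikes a uniform site and
changes it to a uniform different base, and the root sequence is uniform
random. The model choice is deliberate: only a rate (2×10⁻⁸) is specified
for the study design, no transition bias, and JC keeps the saturation
behaviour honest (multiple hits are real, so deep-divergence p-distances
plateau). Loci recombine freely between, never within.

`success_vs_loci()` uses a pool-then-resample design: one simulated pool
(default 20,000 loci) per scenario, then 200 replicates draw the requested
number of loci *without replacement* within a replicate, independently
across replicates. Sampling without replacement mirrors how real panels
are subsampled from a fixed marker set. The default pool of 20,000
matches the scale of a large gene-capture marker set; scaled-down pools
remain usable for quick exploration, but power-curve estimates inherit
extra pool-level coalescent variance once the pool is within a small
multiple of the largest resampling level, so the package does not go
below 2,000.

### What the generator emulates — and what it does not

It emulates: coalescent genealogical variance across independent nuclear
loci, isolation with or without gene flow, finite-sites homoplasy, and
missing data (via masking helpers). It does **not** emulate: intralocus
recombination, rate heterogeneity among sites or loci, base-composition
bias, selection, population growth, alignment error, sequencing error, or
more than two descendant populations (the seven-species ladder fixture is
pure divergence, no migration). Passing tests therefore demonstrate the
statistical machinery under idealized neutral-coalescent conditions; on
real data, alignment quality and paralogy are additional failure modes
the package screens for only indirectly (`rank_loci_by_divergence()`
exposes outlier loci for inspection).

## The three-step pipeline

**Step 1 — screen.** `screen_candidates()` ranks species by minimum
individual distance to the query and keeps the four nearest: the nearest
single sequence need not be conspecific, so a small candidate set is
retained for model-based steps.

**Step 2 — species tree.** Gene trees are built by neighbor joining on
Jukes–Cantor-corrected distances rather than maximum likelihood. At this
scale (≤ 6 taxa, one representative per candidate species) the species-tree
step consumes only gene-tree *topologies*, for which NJ+JC is accurate,
deterministic and dependency-free; p ≥ 0.75 (beyond JC saturation) is
capped at the correction of 0.749 with a warning. The species tree is the
*exact* maximizer of quartet support: all 15 (5 taxa) or 105 (6 taxa)
unrooted topologies are enumerated and scored by the number of agreeing
induced gene-tree quartets — the same optimality criterion heuristic
quartet-amalgamation tools approximate at scale, solved exactly here.
Ties break on the lexicographically smallest newick string so reruns are
identical. The tree is rooted with the farthest screened species as
outgroup and the query's sister species is read off; with fewer than
three database species the tree step is skipped (flagged) and the nearest
species is taken as sister.

**Step 3 — delimitation.** The test compares two hypotheses for the query
group *versus* the sister species: **lump** (one panmictic group) and
**split** (two groups diverged at scaled time τ from an ancestor). The
likelihood is a composite pairwise-difference coalescent model, chosen as
a desk-scale, closed-form, quadrature-testable stand-in for SNP-based
delimitation likelihoods: for a pair with L valid sites, the coalescence
time is exponential, so the number of differences K is geometric with
mean θL; between-group pairs under the split add the fixed divergence —
K = Poisson(2τL) ⊕ Geometric(θ_anc·L), evaluated by exact convolution
over the finite Poisson support. Using all pairs at a locus
pseudo-replicates (pairs share one genealogy), which inflates apparent
evidence; this is documented, and `mode = "one_per_locus"` provides a
strict variant with one random pair per locus and class. The verdict
threshold (split favoured with 2lnBF ≥ 2, i.e. at least positive
evidence on the Kass–Raftery scale: <2 bare mention, 2–6 positive, 6–10
strong, ≥10 decisive) is insensitive to the pseudo-replication on the
package's fixtures because the deep-divergence signals are decisive by
orders of magnitude.

Priors are exponential with data-driven means: observed mean within-group
per-site diversity for the θs, half the net between-group divergence for
τ, floored at 10⁻⁵ so degenerate data (no variation) cannot produce a
zero-mean prior. They are user-overridable.

**Marginal likelihoods** come from path sampling: power posteriors at
β_k = (k/K)^{1/0.3}, which concentrates steps near the prior where the
integrand changes fastest; a random-walk Metropolis sampler on
log-parameters (proposal sd 0.4, Jacobian included) at each step; and
trapezoid integration of the mean log-likelihood over β.
`path_sampling_lnML()` defaults to the conventional large sizes (48
steps, 200,000 iterations, 50,000 pre-burn-in). `delimit()` and
`run_pipeline()` default to 12 steps × 2,500 iterations (250 pre-burn-in)
— the package's chosen sizes for its 1–4 parameter smooth, unimodal
composite likelihood, where the tests show agreement with 1-D quadrature
within 0.2 log units and seed-to-seed spread well below the decision
threshold. Acceptance rates outside [0.05, 0.9] warn rather than error.

## Numerical and degenerate-input choices

* Undefined distances (zero valid sites, or no shared locus) are errors,
  not silent zeros; `rank_neighbors()` drops such references with a
  warning instead of failing the whole query.
* Locus ranking excludes loci with fewer than two present individuals
  (warning) and breaks mean-divergence ties by locus id; panel selection
  breaks missingness ties by higher divergence, then locus id — all
  orderings are invariant to input order.
* `gap_summary()` pools distances across replicates at each level (the
  display convention for gap plots); the gap is signed, negative when the
  distributions overlap.
* Identification with no conspecific reference returns `no_id` and is
  excluded from success-rate denominators.
* Empty data passed to path sampling integrates a normalized prior:
  lnML ≈ 0, which the tests assert.

## Problem sizes used by the tests

The shipped test-and-acceptance runs use: pools of 20,000 loci and 200
replicates for the power anchors; 10,000 genealogies for simulator moment
checks; 200 random gene-tree sets for the quartet oracle; 60-locus,
five-individuals-per-species fixtures and 20 replicate seeds for the
pipeline end-to-end checks (conspecific assignment, new-species
discovery, and verdict stability under 20/30/50% query-locus deletion).
These sizes are the package's own choices balancing Monte-Carlo precision
against a test suite that runs in minutes on one CPU.

## Known limitations

* The delimitation likelihood ignores linkage between pairs at a locus
  (composite) and within-locus recombination; its 2lnBF magnitudes are
  not calibrated against SNP-based delimitation software, only its
  *decisions* are exercised on fixtures.
* The exact quartet species tree is limited to six taxa by enumeration;
  the pipeline's candidate screen guarantees this bound.
* The simulator supports exactly two demes with migration (plus a
  no-migration species ladder for fixtures); growth, bottlenecks and
  >2-deme gene flow are out of scope.
* NJ gene trees carry no branch-support notion; only topologies feed the
  species-tree step.
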