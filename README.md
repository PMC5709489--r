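# multibarcode

Species identification from a **single** barcode locus (typically COI)
fails exactly where it matters most: recently diverged sister species and
species connected by gene flow, whose intra- and interspecific distance
distributions overlap — there is no "barcoding gap". `multibarcode`
implements the alternative: barcode with **hundreds of independent nuclear
loci**, so that coalescent sampling noise averages out and the gap emerges.
It is aimed at molecular ecologists and systematists who want to quantify
how many loci a study group needs, and at method developers who need a
desk-scale, fully reproducible test bed for multilocus identification.

The package provides four connected toolsets:

1. **Distance analytics** — per-locus alignments over labelled individuals
   (`species|individual`), uncorrected p-distance with pairwise deletion,
   locus ranking by divergence, panel selection (keep the loci with least
   missing data, then the most divergent), and locus-resampled
   concatenation: `distance_profile()` / `gap_summary()` trace the
   intra/interspecific distributions and the gap
   `min(inter) − max(intra)` as a function of the number of loci.
2. **Identification criteria** — the strict *all-species-barcodes*
   criterion (a query is correct iff **every** conspecific ranks above
   every heterospecific), threshold optimization by cumulative-error
   minimization, and *best-close-match*; `success_rate()` estimates the
   identification success rate under locus resampling.
3. **A coalescent power lab** — a two-population isolation-with-migration
   structured-coalescent simulator (sizes in gene copies, so a pair in
   population *i* coalesces at rate 1/Nᵢ; per-lineage migration rates;
   Jukes–Cantor finite-sites mutation). `success_vs_loci()` reproduces the
   power curves of identification success against number of loci for any
   (split time, migration) scenario, and `single_vs_multi()` contrasts one
   long locus with many short ones of the same total length.
4. **A three-step barcoding pipeline** — `run_pipeline()` screens the
   database by p-distance (keep ≤ 4 candidate species), builds
   neighbor-joining gene trees and amalgamates them into an **exact**
   maximum-quartet-support species tree to find the query's sister
   species, then runs Bayes-factor species delimitation: a composite
   pairwise-difference coalescent likelihood (geometric within groups;
   Poisson(2τL) ⊕ geometric(θ_anc·L) between) compared between "lump" and
   "split" hypotheses by path-sampling marginal likelihoods,
   `2lnBF = 2(lnML₁ − lnML₂)`, interpreted on the Kass–Raftery scale
   (≥ 10 decisive). A supported split flags a putative new species.

Everything is seedable and runs from simulated data; `make_fixture()`
provides canned scenarios (deep split, shallow split with migration,
panmixia, and a seven-species ladder for pipeline tests).

## Worked example

```r
library(multibarcode)

# two species that split 700,000 generations ago, no migration
ds <- make_fixture("deep_split", n_loci = 200, seed = 42)
ds
#> <multilocus dataset> 200 loci, 10 individuals, 2 species
#>   completeness: 100% of (locus x individual) cells

prof <- distance_profile(ds, c("speciesA", "speciesB"),
                         levels = c(1, 10, 100), n_reps = 50, seed = 1)
gap_summary(prof)
#> # A tibble: 3 × 6
#>   level max_intra min_inter      gap    intra_var   inter_var
#> 1     1   0.01      0.00667 -0.00333 0.00000338   0.000102
#> 2    10   0.003     0.0223   0.0193  0.000000341  0.00000899
#> 3   100   0.00133   0.0268   0.0255  0.0000000323 0.000000302

success_rate(ds, n_loci = 10, n_reps = 100, seed = 2)
#> # A tibble: 1 × 4
#>   n_loci success_rate mc_se n_reps
#> 1     10            1     0    100
```

With a single locus the distributions overlap (`gap` negative); by 10 loci
the gap is positive and identification is already perfect at this depth of
divergence. The pooled variances of both distance classes shrink roughly
in proportion to the number of loci — the overlap at one locus is sampling
noise, not signal.

The full pipeline on a seven-species reference database:

```r
db <- make_fixture("sinipercid_like", n_loci = 80, seed = 7)
res <- run_pipeline(db, "species1|S1_1", seed = 8)
res
#> <barcoding pipeline result> query: species1|S1_1
#>   candidates: species1, species2, species3, species4
#>   species tree: (query,species1,(species2,(species3,species4)));
#>   sister: species1; 2lnBF = 5.523 (positive, favours lump)
#>   verdict: assigned to species1
glance(res)   # one-row tibble; tidy(res) gives the candidate table
```

The query's conspecifics are in the database, the species tree places it
sister to `species1`, and the Bayes factor favours lumping — the query is
assigned rather than flagged as new. Remove `species1` from the database
(`drop_individuals()`) and the same pipeline returns a decisive split: a
putative new species.

A thin command-line front end (`inst/cli/multibarcode.R`) exposes
`simulate`, `fixture`, `gap`, `identify`, `power` and `run` subcommands
driven by a YAML config; every artifact embeds its config and seed.

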