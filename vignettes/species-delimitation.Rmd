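---
title: "Delimiting cryptic fungal species from multilocus amplicon data"
author: "mycodelim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting cryptic fungal species from multilocus amplicon data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycodelim)
```

## The problem

Many macrofungal species are cryptic: reproductively isolated lineages that
look alike and cannot be separated by fruit-body morphology or by a single
barcode locus such as the ribosomal ITS region. A practical way forward is
to amplicon-sequence twenty or more short nuclear loci together with
mitochondrial markers for a population sample of dikaryotic fruit bodies,
and then ask two statistically explicit questions:

1. **Phylogeny-based**: on a tree built from the concatenated nuclear
   sequences, do branch lengths separate into a between-species and a
   within-species class (the Poisson tree processes model), and which
   clades does the Bayesian version of that model support as species?
2. **Population-genetics-based**: when nuclear SNP variation is partitioned
   hierarchically over mitochondrial haplotype, geographic region, sample
   and allele copy, how much variance sits between the mitochondrial
   haplotypes, and is that cytonuclear disequilibrium stronger than chance
   under permutation?

`mycodelim` implements this entire workflow — genotype calling from read
counts, consensus and concatenation, congruence testing, phylogenetic
placement of short queries, PTP/bPTP delimitation, and hierarchical AMOVA —
plus a synthetic-data generator so that every stage can be exercised and
validated without any external download.

## Genotype and haplotype calling

Each dikaryon carries two haploid nuclei, so a nuclear amplicon has one or
two true alleles. `callNuclearGenotypes()` keeps, per (sample, locus) cell,
the unique sequences whose read abundance is **at least 20%** of the cell
total (the comparison is inclusive: 20.0% passes, 19% does not). One
passing sequence is a homozygote, two a heterozygote. More than two passing
sequences is biologically impossible for a dikaryon; the caller keeps the
top two by count and flags the cell `anomalous` (a strict mode drops it
instead). Mitochondria are effectively haploid, so
`callMitoHaplotypes()` takes the single most abundant sequence per
mitochondrial locus; exact count ties are broken toward the
lexicographically smaller sequence, with a warning, so reruns are
reproducible. Samples sharing an identical concatenated mitochondrial
sequence receive one haplotype label (A, B, ... in sample-sorted discovery
order). Loci detected in **at most half** of the samples are removed by
`filterLociByPresence()` (the rule is strictly-greater-than-half to stay).

Cells where no sequence passes the threshold — possible only when more
than five equally rare sequences share the reads — are treated as missing
and flow into the 50% missing-data filters downstream.

## Consensus, concatenation and congruence

`iupacConsensus()` collapses the one or two alleles of a sample into a
single sequence with IUPAC ambiguity codes (A/G becomes R, and so on).
Column-wise gap handling is deliberately simple and documented: a gap
facing a base yields the base; a column is a gap only when every allele has
one. `concatenateLoci()` lays loci end-to-end over the sample universe,
padding samples that miss a locus with `N` — absence of data, not an
inferred deletion — and records a partition map (0-based half-open
internally, 1-based inclusive in every report, including the RAxML-style
partition text). `filterAmbiguousColumns()` is a declared stand-in for
heavier alignment-trimming tools: it removes columns whose gap fraction
exceeds a cutoff and returns the kept-column map. `countVariableSites()`
counts a site as variable only when two or more distinct unambiguous bases
occur; ambiguity codes and gaps are ignored for the distinctness test,
which is the conservative reading when consensus sequences contain
heterozygote codes.

Before concatenated phylogenetics it is good practice to check that the
per-locus distance structures agree. `cadmGlobal()` implements the
congruence-among-distance-matrices test: Kendall's W over the
rank-transformed unfolded upper triangles, with a permutation null that
shuffles the labels of every matrix except the first and the add-one
p-value convention p = (exceedances + 1)/(nPerm + 1), so p can never be
exactly zero and its minimum is 1/(nPerm + 1).

## Trees and placement

Maximum-likelihood tree search is out of scope: an externally inferred
tree can be supplied as newick, and `njTree()` (neighbor joining, with
negative branch estimates clamped to zero) is the built-in desk-scale
fallback. `patristicDistances()`, `pruneOutgroup()` and
`groupDistanceSummary()` provide the tree-derived statistics; group
distances are reported as min, max and mean per group pair, since a range
alone hides the central tendency.

`placeQuery()` is an evolutionary-placement-style scorer for short query
sequences (for instance ITS1-only database sequences aligned into the
concatenation's coordinates). The query is attached to every branch of the
reference tree by a pendant branch and scored under Jukes–Cantor with the
pruning algorithm; columns where the query has `-` or `N` contribute
likelihood 1, so a short query is judged on its informative columns only.
Per edge, the pendant length is optimised on a 20-point log-spaced grid
from 1e-6 to 1 followed by golden-section refinement, and the attachment
position along the branch is refined the same way. The likelihood weight
ratio is the softmax of per-edge log-likelihoods. Jukes–Cantor (equal base
frequencies, one exchangeability) was chosen because it keeps the scorer
self-contained and exactly checkable against an independent implementation;
the model tag is an explicit argument so richer models can be added without
changing the interface. A query with no informative overlap is returned as
explicitly unplaceable rather than assigned an arbitrary edge.

## The Poisson tree processes model

The PTP model classifies the branches of a rooted (non-ultrametric) tree
into a between-species class and a within-species class, each with its own
exponential branch-length rate; a delimitation is the set of "species
root" nodes, every tip having exactly one ancestor-or-self in the set. The
branch into a species root and everything above it is between-species;
branches inside a species are within-species. With class counts and length
sums \((n_s, L_s)\) and \((n_c, L_c)\), each class rate is profiled at its
maximum-likelihood estimate \(\hat\lambda = n/L\), giving

\[\log L = \sum_{\text{class}} \left( n \log \frac{n}{L} - n \right),\]

with empty classes contributing zero. Numerical choices: branch lengths are
floored at 1e-8 before rate estimation (the exponential density is
undefined at scale zero; the floor is an argument), and likelihood ties are
broken toward **fewer** species, which also resolves the fully degenerate
equal-branch-length tree to the single-species null.

`mlPtp()` is exact by enumeration up to 12 tips. For larger trees it runs
steepest-ascent hill climbing over single-node split/merge moves from
three starts (the lumped null, the fully split state, and a top-down greedy
dissection), followed by a short self-seeded stochastic exploration that
escapes shared local optima; the caller's RNG stream is saved and restored,
so the search is deterministic and side-effect free.

`bptp()` samples delimitations by Metropolis–Hastings under a uniform
prior. The proposal picks one internal node uniformly and flips its
status — split a species root into its children, or merge a node whose
children are all species roots — which is symmetric, so the Hastings ratio
is 1. Class rates stay profiled inside the likelihood, matching the model's
likelihood surface while keeping the state space to partitions only. The
posterior support of a candidate species is the fraction of retained
samples in which exactly that tip set forms one species. Defaults mirror
the full-scale analysis the package targets (1,000,000 generations,
thinning 1,000, 10% burn-in); the test suite uses 50,000/50/10%, which the
small-case exactness checks show is ample for trees of a few dozen tips.
Any outgroup must be pruned before delimitation, and the tree must be
rooted (midpoint rooting is the pipeline's fallback).

Two behaviours of this model are worth knowing. First, because the rates
are profiled rather than integrated, data with no speciation signal (all
branch lengths from one exponential) produce a *diffuse* posterior over
many partitions, not a posterior concentrated on the single-species null;
isolated long pendant branches can collect non-trivial support as singleton
species. We verified this against exact enumeration of the posterior on
small trees — the chain is faithful to the model; the diffuseness is the
model's. The practically reliable null signature is therefore the
*absence* of confidently supported multi-tip clades, which is what the
null tests assert. Second, on trees whose within-species branches are
heterogeneous mixtures (for instance many exactly-zero branches next to a
few longer ones, as neighbor joining produces from near-identical
sequences), part of the posterior mass leaks into sub-splits of a true
species, so clade supports settle in the 0.88–1.00 range rather than
pinning 1.00. Support recovery at or above 0.95 is asserted under the
model's own generating process (two clades with independent
exponential within-branch lengths and stem-to-within ratio of at least
100).

## Hierarchical AMOVA

`snpMatrixFromGenotypes()` turns called genotypes into the row-per-allele-
copy matrix AMOVA consumes: two rows per sample, one column per
polymorphic position, with the 50% missing-data cut-offs applied **loci
first, then samples** (the order is an argument and is logged;
`amovaCutoffSweep()` re-runs the analysis over a cut-off grid as a
sensitivity check). `pairwiseSquaredDistances()` counts differing
non-missing states per pair — the squared Euclidean distance over one-hot
SNP coding. By default, missing sites are simply ignored (no rescaling);
proportional rescaling is exposed as an option, with the comparable-site
count attached to the matrix either way.

`amova()` partitions the variance over four nested strata — between
haplotypes (a), between regions within haplotype (b), between samples
within region (c), within samples (d) — from within-group sums of squared
distances differenced down the hierarchy. The variance components solve
the expected-mean-square system; for the unbalanced designs real sampling
produces, the coefficient of component \(\sigma^2_L\) in
\(E[\mathrm{SS}]\) of a partition \(P\) is computed exactly from the group
size cross-tabulation, \(K_L(P)=\sum_c (n_c - \sum_g n_{cg}^2/n_c)\), so no
balanced-design approximation is involved. The Phi statistics are
\(\Phi_{CT} = \sigma^2_a/\sigma^2_{tot}\),
\(\Phi_{SC} = \sigma^2_b/(\sigma^2_b+\sigma^2_c+\sigma^2_d)\) and
\(\Phi_{SW} = \sigma^2_c/(\sigma^2_c+\sigma^2_d)\). Design decisions:
negative components are reported as-is with a warning (truncation would
break the SS/df accounting); a zero-df stratum (for example one allele
copy per sample) is collapsed out of the moment system with a message
rather than an error, because the two-level haploid reduction is a useful
special case — only a single top-level group is a hard error; when the
total variance is zero the Phi statistics are NA sentinels. Regions are
nested in haplotypes: one region observed under two haplotypes forms two
hierarchy groups, the standard nested convention.

`amovaPermutationTest()` runs the level-appropriate permutation schemes:
whole haplotype-by-region groups reassigned among haplotypes for
\(\Phi_{CT}\); samples permuted among regions within haplotype for
\(\Phi_{SC}\); allele copies permuted among samples within region for
\(\Phi_{SW}\); always with the add-one convention. A property to keep in
mind: the top-level scheme permutes *groups*, so with few regions the null
distribution is very discrete (and the observed assignment recurs among
permutations, e.g. via the global label swap), which makes the test
conservative and bounds the attainable p away from 1/(nPerm+1). The
calibration tests therefore use designs with 16+ region groups.

## The synthetic generator: what it emulates, and what it does not

`SimParams()` defaults encode the study design this workflow targets: two
species, 48 dikaryotic samples each, 29 regions with roughly a tenth
sympatric, 24 nuclear amplicons of 300 bp plus two mitochondrial loci,
between-species divergence 0.04 substitutions/site over within-species
diversity 0.005 (the between- and within-clade patristic ranges observed
in such data), heterozygosity 0.25, mean depth 100 reads with 10% error
reads and 5% locus dropout. Sequences evolve under Jukes–Cantor on a
star-plus-stem genealogy per locus: a shared ancestor, a stem of half the
divergence into each species' base sequence, and independent tip mutations
of half the within-species diversity per allele copy. Mitochondrial
sequences are invariant within species, so the haplotype label is in
perfect cytonuclear linkage with the species label — the hypothesis the
downstream analyses are supposed to confirm. Heterozygote reads split
Binomial(depth, 0.5) between alleles (balanced dikaryotic nuclei); error
reads are single random substitutions of a true allele, spread over at
most three spurious sequences so each stays below the 20% calling
threshold in expectation.

What this generator does **not** emulate: coalescent genealogy within
species (no shared within-species tree structure, no incomplete lineage
sorting), migration or isolation-by-distance (regions are labels, not
demes — the between-region component is essentially zero by construction),
indels and alignment error, chimeras, quality-score structure, or a
calibrated balance of heterozygous versus homozygous variance (the
within-sample variance share depends directly on the heterozygosity
parameter and is not fitted to any particular dataset). Passing tests on
these data therefore demonstrate the *statistical machinery* — threshold
arithmetic, variance accounting, likelihood surfaces, permutation
calibration — not robustness to the full messiness of real amplicon runs.

## Problem sizes used by the tests

The suite chooses desk-scale sizes so every oracle can be exhaustive:
PTP enumeration on trees of 4–9 tips (12 is the exactness bound), AMOVA
oracle toys of 6–12 samples, placement references of 5 taxa, bPTP chains
of 20,000–60,000 generations, type-I calibration over 200 replicates of a
12+12-sample design with 199 permutations each, and end-to-end runs of
10+10 samples at 12 loci. The acceptance script runs the full study-scale
configuration (96 samples, 26 loci, 1,000,000 MCMC generations, 9,999
permutations) in a few minutes.

## Known limitations

* Placement and the PTP family assume the supplied tree; uncertainty in
  the tree itself is not propagated.
* Only Jukes–Cantor is implemented for placement scoring; for strongly
  unequal base frequencies an external ML tree plus an external placement
  run can be imported instead.
* The bPTP proposal is the single-node flip kernel; it mixes well at desk
  scale (verified against exact enumeration) but no claim is made of
  chain-for-chain equivalence with other published samplers beyond the
  shared model likelihood.
* The AMOVA permutation test at the top level is conservative for designs
  with few regions, as discussed above.
* Phasing of heterozygous genotypes across loci is arbitrary (allele rows
  are stacked in call order); the AMOVA distance accounting is unaffected
  at the within-sample level it reports, but the rows are not haplotypes.
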