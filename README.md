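# mycodelim

Multilocus species delimitation for cryptic fungi.

Closely related fungal species often cannot be told apart morphologically,
and a single barcode locus (the ribosomal ITS) frequently lacks the
resolution to separate them. `mycodelim` is an R package for the
statistical side of that problem: given amplicon sequencing of ~20+ short
nuclear loci plus mitochondrial markers for a population sample of
dikaryotic fruit bodies, it delimits species with two complementary,
explicitly statistical frameworks and reports how strongly the data support
each boundary. It is aimed at mycologists and population geneticists who
have multilocus amplicon data (or want to prototype a sampling design
against simulated data) and need the full path from read counts to
delimitation statistics in one reproducible toolchain.

## What it computes

**Genotypes and haplotypes.** Per (sample, locus), unique sequences with a
read abundance of at least 20% of the cell total are called as the 1–2
alleles of the dikaryon; the most abundant mitochondrial sequence defines
the sample's haplotype (A, B, ...); loci detected in at most half of the
samples are removed.

**Poisson tree processes (PTP / bPTP).** On a rooted tree from the
concatenated nuclear consensus sequences, branches are classified into a
between-species and a within-species class, each exponential with rate
λ profiled at its MLE n/L:

    log L = Σ_class ( n · log(n/L) − n )

`mlPtp()` maximises this over all delimitations (exactly, up to 12 tips);
`bptp()` samples delimitations by MCMC under a uniform prior and reports
the posterior probability that each clade is exactly one species.

**Evolutionary placement.** `placeQuery()` attaches a short query sequence
(e.g. an ITS1-only database sequence) to every branch of the reference
tree under Jukes–Cantor, optimises the pendant branch, and reports per-edge
log-likelihoods and likelihood weight ratios, written as standard jplace.

**Hierarchical AMOVA.** Nuclear SNPs are partitioned over four nested
strata — between mitochondrial haplotypes, between regions within
haplotype, between samples within region, within samples — with
unbalanced-design variance components and

    Φ_CT = σ²_a / σ²_tot,  Φ_SC = σ²_b / (σ²_b+σ²_c+σ²_d),  Φ_SW = σ²_c / (σ²_c+σ²_d)

tested by level-appropriate permutation schemes (p = (hits+1)/(nPerm+1)).
A large, significant Φ_CT in (partial) sympatry is cytonuclear
disequilibrium — direct evidence of restricted gene flow between the
haplotype groups.

**Synthetic data.** `simulateTwoSpecies()` + `simulateReadTable()` generate
two diverged, partially sympatric species with perfect cytonuclear linkage,
within-sample heterozygosity and noisy read counts, so the whole workflow
is testable end-to-end without external data.

## Worked example

```r
library(mycodelim)

params <- SimParams(nSamplesPerSpecies = 12L, nRegions = 6L,
                    sympatryFraction = 0.34, nNuclearLoci = 12L,
                    locusLength = 200L, seed = 42L)
truth <- simulateTwoSpecies(params)
reads <- simulateReadTable(truth, params)
fix <- file.path(tempdir(), "demo")
writeFixture(truth, reads, fix)

cfg <- pipelineConfig(readsPath = file.path(fix, "reads.tsv"),
                      hierarchyPath = file.path(fix, "hierarchy.tsv"),
                      outDir = file.path(fix, "out"),
                      mitoLoci = c("mt01", "mt02"),
                      nPerm = 999,
                      mcmc = McmcConfig(100000L, 100L, 0.1, seed = 42L),
                      seed = 42L)
res <- runPipeline(cfg)

res$bptp
#> BptpResult: 900 retained samples, acceptance 0.035
#>   species with posterior support > 0.5:
#>     node 37  support 0.982  {S013,S014,S015,S016,S017,S018,S019,S020,S021,S022,S023,S024}
#>     node 36  support 0.637  {S001,S002,S003,S004,S005,S006,S007,S008,S009,S010,S011,S012}

res$amova
#> Hierarchical AMOVA
#>                            source df        SS       MS
#>                Between Haplotypes  1  960.0188 960.0188
#>  Between Regions Within Haplotype  6   53.3182   8.8864
#>     Between Samples Within Region 15  132.7500   8.8500
#>                    Within Samples 23   39.5000   1.7174
#>                             Total 45 1185.5870  26.3464
#>   % variance: sigma2_a=88.7  sigma2_b=0.0  sigma2_c=7.6  sigma2_d=3.7
#>   Phi: phiCT=0.887  phiSC=0.001  phiSW=0.675
#>   P ( 999 permutations): phiCT=0.034  phiSC=0.407  phiSW=0.001
```

Reading the output: the two clades recovered by bPTP are exactly the two
simulated species (samples S001–S012 versus S013–S024), and the AMOVA
attributes 88.7% of nuclear SNP variance to the between-haplotype stratum
with Φ_CT = 0.887 — strong cytonuclear disequilibrium, i.e. the two
mitochondrial haplotypes behave as reproductively isolated nuclear gene
pools. At this small demo scale the permutation null for Φ_CT is discrete
(only 8 region groups to reassign), hence the p of 0.034 rather than the
minimum attainable 0.001; the study-scale run in the acceptance script
reaches the minimum.

Every stage is also callable on its own (`callNuclearGenotypes()`,
`iupacConsensus()`, `concatenateLoci()`, `cadmGlobal()`, `njTree()`,
`placeQuery()`, `mlPtp()`, `bptp()`, `amova()`, ...), and a thin
command-line wrapper over the same functions is installed at
`inst/scripts/mycodelim.R` (subcommands `simulate`, `call`, `run-all`, ...).

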