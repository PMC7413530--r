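setOldClass("phylo")

#' Simulation parameters for the two-species synthetic generator
#'
#' Container for every tunable of the synthetic study design: two diverged,
#' partially sympatric dikaryotic species sampled across geographic regions,
#' genotyped at many short nuclear amplicons plus mitochondrial loci, with
#' within-sample heterozygosity and noisy per-amplicon read counts.
#'
#' @slot nSpecies number of species (the focal design uses 2).
#' @slot nSamplesPerSpecies dikaryotic samples simulated per species.
#' @slot nRegions number of geographic regions (collection sites).
#' @slot sympatryFraction fraction of regions that harbour both species.
#' @slot nNuclearLoci number of nuclear amplicon loci.
#' @slot locusLength length of each simulated amplicon, in bases.
#' @slot nMitoLoci number of mitochondrial loci.
#' @slot divergence expected substitutions/site separating the two species.
#' @slot thetaWithin expected pairwise diversity within a species.
#' @slot heterozygosityRate probability a sample draws two independent alleles
#'   at a nuclear locus.
#' @slot readDepthMean mean sequencing depth per (sample, locus).
#' @slot errorSeqRate expected fraction of reads diverted to spurious
#'   error sequences.
#' @slot missingLocusRate probability that a locus drops out for a sample.
#' @slot seed integer random seed.
#' @export
setClass("SimParams", slots = c(
  nSpecies = "integer", nSamplesPerSpecies = "integer", nRegions = "integer",
  sympatryFraction = "numeric", nNuclearLoci = "integer", locusLength = "integer",
  nMitoLoci = "integer", divergence = "numeric", thetaWithin = "numeric",
  heterozygosityRate = "numeric", readDepthMean = "numeric",
  errorSeqRate = "numeric", missingLocusRate = "numeric", seed = "integer"
))

setValidity("SimParams", function(object) {
  msgs <- character(0)
  chk <- function(expr, msg) if (!isTRUE(expr)) msgs <<- c(msgs, msg)
  chk(object@nSpecies >= 1L, "nSpecies must be >= 1")
  chk(object@nSamplesPerSpecies >= 1L, "nSamplesPerSpecies must be >= 1")
  chk(object@nRegions >= 1L, "nRegions must be >= 1")
  chk(object@nNuclearLoci >= 1L, "nNuclearLoci must be >= 1")
  chk(object@locusLength >= 1L, "locusLength must be >= 1")
  chk(object@nMitoLoci >= 1L, "nMitoLoci must be >= 1")
  chk(object@divergence >= 0, "divergence must be >= 0")
  chk(object@thetaWithin >= 0, "thetaWithin must be >= 0")
  for (f in c("sympatryFraction", "heterozygosityRate", "errorSeqRate",
              "missingLocusRate")) {
    v <- slot(object, f)
    chk(v >= 0 && v <= 1, paste0(f, " must lie in [0, 1]"))
  }
  chk(object@readDepthMean > 0, "readDepthMean must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Ground truth emitted by the simulator
#'
#' Per-sample species/region/haplotype labels and the true allele pair carried
#' at every locus (two copies per nuclear locus for a dikaryon, one per
#' mitochondrial locus). The mitochondrial haplotype label is a deterministic
#' function of the species label: the simulated species are in complete
#' cytonuclear linkage.
#'
#' @slot samples data.frame with columns `sample`, `species`, `region`,
#'   `haplotype`.
#' @slot alleles data.frame with columns `sample`, `locus`, `allele_index`,
#'   `sequence`.
#' @slot loci data.frame with columns `locus`, `type` ("nuclear"/"mito"),
#'   `length`.
#' @slot params the [SimParams] object that generated the truth.
#' @export
setClass("SimTruth", slots = c(
  samples = "data.frame", alleles = "data.frame", loci = "data.frame",
  params = "SimParams"
))

setValidity("SimTruth", function(object) {
  s <- object@samples; a <- object@alleles; l <- object@loci
  need <- function(df, cols, nm) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) sprintf("%s lacks columns: %s", nm, paste(miss, collapse = ", "))
    else NULL
  }
  msgs <- c(need(s, c("sample", "species", "region", "haplotype"), "samples"),
            need(a, c("sample", "locus", "allele_index", "sequence"), "alleles"),
            need(l, c("locus", "type", "length"), "loci"))
  if (length(msgs)) return(msgs)
  # cytonuclear linkage in truth: haplotype determined by species
  if (nrow(s) > 0 && anyDuplicated(unique(s[, c("species", "haplotype")])$species))
    return("haplotype label must be a deterministic function of species")
  TRUE
})

#' Per-sample, per-locus unique-sequence read counts
#'
#' The tabular input of the genotype caller: one row per unique sequence
#' observed in a (sample, locus) cell, with its read count.
#'
#' @slot records data.frame with columns `sample`, `locus`, `sequence_id`,
#'   `sequence`, `count`.
#' @export
setClass("ReadTable", slots = c(records = "data.frame"))

setValidity("ReadTable", function(object) {
  r <- object@records
  cols <- c("sample", "locus", "sequence_id", "sequence", "count")
  miss <- setdiff(cols, names(r))
  if (length(miss))
    return(sprintf("records lacks columns: %s", paste(miss, collapse = ", ")))
  if (nrow(r) == 0) return(TRUE)
  if (any(is.na(r$count)) || any(r$count < 0) || any(r$count != round(r$count)))
    return("counts must be non-negative integers")
  bad <- grepl("[^ACGTN-]", r$sequence)
  if (any(bad))
    return(sprintf("invalid characters in sequence for record(s): %s",
                   paste(head(paste(r$sample[bad], r$locus[bad], sep = "/"), 3),
                         collapse = ", ")))
  if (anyDuplicated(r[, c("sample", "locus", "sequence")]))
    return("(sample, locus, sequence) triples must be unique")
  TRUE
})

#' Called genotypes and mitochondrial haplotypes
#'
#' Holds 1-2 allele sequences per (sample, locus) cell with the read fraction
#' that supported each call, plus the per-sample mitochondrial haplotype label.
#'
#' @slot calls data.frame with columns `sample`, `locus`, `allele_index`,
#'   `sequence`, `fraction`, `zygosity`, `flag`.
#' @slot haplotypes data.frame with columns `sample`, `haplotype`, `sequence`.
#' @slot samples the full sample universe (used by presence filters).
#' @slot threshold the read-abundance calling threshold used.
#' @export
setClass("GenotypeSet", slots = c(
  calls = "data.frame", haplotypes = "data.frame",
  samples = "character", threshold = "numeric"
))

setValidity("GenotypeSet", function(object) {
  cl <- object@calls
  cols <- c("sample", "locus", "allele_index", "sequence", "fraction",
            "zygosity", "flag")
  miss <- setdiff(cols, names(cl))
  if (length(miss))
    return(sprintf("calls lacks columns: %s", paste(miss, collapse = ", ")))
  if (nrow(cl) > 0) {
    n <- table(paste(cl$sample, cl$locus, sep = "\r"))
    if (any(n > 2)) return("a (sample, locus) cell carries more than 2 alleles")
    if (any(!cl$zygosity %in% c("hom", "het")))
      return("zygosity must be 'hom' or 'het'")
  }
  TRUE
})

#' Concatenated multi-locus alignment with partition map
#'
#' An ordered set of per-locus aligned blocks over a shared sample universe,
#' with the column interval each locus occupies in the concatenation
#' (0-based, half-open internally; reports are 1-based inclusive). Samples
#' missing a locus are padded with the fill character.
#'
#' @slot loci ordered locus names.
#' @slot blocks named list of named character vectors (sample -> sequence).
#' @slot partition data.frame with columns `locus`, `start`, `end`
#'   (0-based half-open).
#' @slot samples sample universe of the concatenation.
#' @slot fill single fill character for missing loci (default "N").
#' @export
setClass("MultiLocusAlignment", slots = c(
  loci = "character", blocks = "list", partition = "data.frame",
  samples = "character", fill = "character"
))

setValidity("MultiLocusAlignment", function(object) {
  if (!identical(object@loci, names(object@blocks)))
    return("block names must equal the locus list")
  for (loc in object@loci) {
    b <- object@blocks[[loc]]
    if (length(b) && length(unique(nchar(b))) != 1L)
      return(sprintf("unequal sequence lengths within locus '%s'", loc))
  }
  p <- object@partition
  if (nrow(p) != length(object@loci)) return("partition must cover every locus")
  if (nrow(p) > 0) {
    if (p$start[1] != 0) return("partition must start at 0")
    if (any(p$end <= p$start)) return("empty partition interval")
    if (nrow(p) > 1 && any(p$start[-1] != p$end[-nrow(p)]))
      return("partition intervals must be contiguous")
  }
  TRUE
})

#' Placement of one query sequence on a reference tree
#'
#' Per-edge log-likelihoods of attaching the query to each branch of the
#' reference tree by a pendant branch, with likelihood weight ratios
#' (softmax over edges) and the optimised pendant length / attachment
#' position per edge.
#'
#' @slot query query label.
#' @slot tree the reference tree (ape `phylo`).
#' @slot edges data.frame with columns `edge`, `loglik`, `lwr`, `pendant`,
#'   `position`.
#' @slot bestEdge index (into the tree's edge matrix) of the top placement.
#' @slot placeable FALSE when the query carried no informative overlap.
#' @export
setClass("PlacementResult", slots = c(
  query = "character", tree = "phylo", edges = "data.frame",
  bestEdge = "integer", placeable = "logical"
))

setValidity("PlacementResult", function(object) {
  if (!object@placeable) return(TRUE)
  e <- object@edges
  if (abs(sum(e$lwr) - 1) > 1e-6) return("likelihood weight ratios must sum to 1")
  if (abs(max(e$loglik) - e$loglik[match(object@bestEdge, e$edge)]) > 1e-9)
    return("bestEdge must attain the maximum log-likelihood")
  TRUE
})

#' A species delimitation of a rooted tree
#'
#' Partition of the tips into species, represented by the set of species-root
#' nodes: each tip has exactly one ancestor-or-self in the set. Edges on or
#' above species roots belong to the between-species (speciation) branch
#' class, edges strictly inside a species to the within-species (coalescent)
#' class; each class carries its own exponential branch-length rate.
#'
#' @slot tree rooted ape `phylo`.
#' @slot speciesRoots node numbers of the species roots.
#' @slot assignment integer species id per tip (named by tip label).
#' @slot logLik Poisson tree processes log-likelihood of the partition.
#' @slot rates named numeric: `lambdaSp` and `lambdaCoal` (per-class MLE
#'   rates; NA for an empty class).
#' @export
setClass("Delimitation", slots = c(
  tree = "phylo", speciesRoots = "integer", assignment = "integer",
  logLik = "numeric", rates = "numeric"
))

#' MCMC settings for Bayesian PTP
#'
#' @slot generations total Markov chain generations.
#' @slot thinning keep one sample every `thinning` generations.
#' @slot burnin fraction of generations discarded from the start.
#' @slot seed integer random seed.
#' @export
setClass("McmcConfig", slots = c(
  generations = "integer", thinning = "integer", burnin = "numeric",
  seed = "integer"
))

setValidity("McmcConfig", function(object) {
  msgs <- character(0)
  if (object@generations < object@thinning || object@thinning < 1L)
    msgs <- c(msgs, "need generations >= thinning >= 1")
  if (object@burnin < 0 || object@burnin >= 1)
    msgs <- c(msgs, "burnin must lie in [0, 1)")
  if (length(msgs)) msgs else TRUE
})

#' Bayesian PTP result
#'
#' @slot tree the (rooted) input tree.
#' @slot nodeSupport posterior probability, per node, that the node's tip set
#'   forms exactly one species.
#' @slot supports data.frame of supported species (node, support, tips).
#' @slot partitionFreq data.frame of sampled delimitations (key, nSpecies,
#'   freq), most frequent first.
#' @slot trace data.frame (generation, logLik, nSpecies) of retained samples.
#' @slot acceptanceRate Metropolis-Hastings acceptance rate.
#' @slot config the [McmcConfig] used.
#' @export
setClass("BptpResult", slots = c(
  tree = "phylo", nodeSupport = "numeric", supports = "data.frame",
  partitionFreq = "data.frame", trace = "data.frame",
  acceptanceRate = "numeric", config = "McmcConfig"
))

#' Hierarchical AMOVA result
#'
#' Classic nested analysis-of-molecular-variance table (df, SS, MS per
#' stratum), method-of-moments variance components, percent of total
#' variance, Phi statistics and (optionally) permutation p-values.
#'
#' @slot table data.frame with columns `source`, `df`, `SS`, `MS`.
#' @slot components named numeric variance components (sigma2_a..sigma2_d for
#'   the strata retained in the design).
#' @slot percent components as percent of their (signed) total.
#' @slot phi named numeric: `phiCT`, `phiSC`, `phiSW` (NA when a stratum was
#'   collapsed or the total variance is zero).
#' @slot pvalues named numeric permutation p-values (NA until a permutation
#'   test is run).
#' @slot nPerm number of permutations behind `pvalues` (0 if none).
#' @export
setClass("AmovaResult", slots = c(
  table = "data.frame", components = "numeric", percent = "numeric",
  phi = "numeric", pvalues = "numeric", nPerm = "integer"
))

setValidity("AmovaResult", function(object) {
  t <- object@table
  if (!all(c("source", "df", "SS", "MS") %in% names(t)))
    return("table needs columns source, df, SS, MS")
  n <- nrow(t)
  if (n < 2) return("table needs at least one stratum plus the total row")
  tot <- t[n, ]
  if (abs(sum(t$df[-n]) - tot$df) > 0)
    return("stratum df must sum to the total df")
  ssTol <- 1e-9 * max(1, abs(tot$SS))
  if (abs(sum(t$SS[-n]) - tot$SS) > ssTol)
    return("stratum SS must sum to the total SS")
  ok <- t$df > 0
  if (any(abs(t$MS[ok] - t$SS[ok] / t$df[ok]) > 1e-9 * pmax(1, abs(t$MS[ok]))))
    return("MS must equal SS/df on every row")
  TRUE
})
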