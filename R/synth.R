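#' Construct simulation parameters
#'
#' Defaults mirror the study design the package targets: ~96 dikaryotic
#' samples (48 per species) from 29 localities, 24 nuclear amplicons of
#' ~300 bp plus 2 mitochondrial loci, two species separated by ~0.04
#' substitutions/site (the between-clade patristic range of the motivating
#' data) over a within-species diversity of ~0.005, partial sympatry in
#' roughly a tenth of the regions, and noisy amplicon read counts.
#'
#' @param nSpecies number of species (2 for the focal design).
#' @param nSamplesPerSpecies samples per species.
#' @param nRegions number of geographic regions.
#' @param sympatryFraction fraction of regions holding both species.
#' @param nNuclearLoci number of nuclear loci.
#' @param locusLength amplicon length (bases).
#' @param nMitoLoci number of mitochondrial loci.
#' @param divergence expected substitutions/site between species.
#' @param thetaWithin expected pairwise diversity within species.
#' @param heterozygosityRate probability of two independent allele draws.
#' @param readDepthMean mean reads per (sample, locus).
#' @param errorSeqRate expected fraction of error reads.
#' @param missingLocusRate per-(sample, locus) dropout probability.
#' @param seed integer random seed.
#' @return a validated [SimParams] object.
#' @export
#' @examples
#' p <- SimParams(nSamplesPerSpecies = 4L, nNuclearLoci = 3L, seed = 1L)
#' p
SimParams <- function(nSpecies = 2L, nSamplesPerSpecies = 48L, nRegions = 29L,
                      sympatryFraction = 0.1, nNuclearLoci = 24L,
                      locusLength = 300L, nMitoLoci = 2L, divergence = 0.04,
                      thetaWithin = 0.005, heterozygosityRate = 0.25,
                      readDepthMean = 100, errorSeqRate = 0.1,
                      missingLocusRate = 0.05, seed = 1L) {
  new("SimParams",
      nSpecies = .checkCount(nSpecies, "nSpecies"),
      nSamplesPerSpecies = .checkCount(nSamplesPerSpecies, "nSamplesPerSpecies"),
      nRegions = .checkCount(nRegions, "nRegions"),
      sympatryFraction = .checkFraction(sympatryFraction, "sympatryFraction"),
      nNuclearLoci = .checkCount(nNuclearLoci, "nNuclearLoci"),
      locusLength = .checkCount(locusLength, "locusLength"),
      nMitoLoci = .checkCount(nMitoLoci, "nMitoLoci"),
      divergence = { if (divergence < 0) .stopf("'divergence' must be >= 0"); divergence },
      thetaWithin = { if (thetaWithin < 0) .stopf("'thetaWithin' must be >= 0"); thetaWithin },
      heterozygosityRate = .checkFraction(heterozygosityRate, "heterozygosityRate"),
      readDepthMean = { if (readDepthMean <= 0) .stopf("'readDepthMean' must be > 0"); readDepthMean },
      errorSeqRate = .checkFraction(errorSeqRate, "errorSeqRate"),
      missingLocusRate = .checkFraction(missingLocusRate, "missingLocusRate"),
      seed = .checkCount(seed, "seed", min = 0))
}

#' Simulate ground truth for diverged species in partial sympatry
#'
#' Sequences are generated under a Jukes-Cantor star-plus-stem genealogy per
#' locus: a random ancestral sequence mutates along a stem of `divergence/2`
#' into each species' base sequence, and every allele copy adds independent
#' tip mutations of `thetaWithin/2`. Expected pairwise distance is therefore
#' about `thetaWithin` within a species and `divergence + thetaWithin`
#' between species. Each dikaryotic sample carries two allele copies per
#' nuclear locus (two independent draws with probability
#' `heterozygosityRate`, otherwise one draw duplicated) and a single
#' mitochondrial sequence identical within a species, so the mitochondrial
#' haplotype label (A, B, ...) is in perfect linkage with the species label.
#' Regions are assigned round-robin; `sympatryFraction` of the regions host
#' both species, the rest are private to one species.
#'
#' @param params a [SimParams] object.
#' @return a [SimTruth] object.
#' @export
#' @examples
#' truth <- simulateTwoSpecies(SimParams(nSamplesPerSpecies = 4L,
#'                                       nNuclearLoci = 2L, nRegions = 3L,
#'                                       locusLength = 60L, seed = 7L))
#' head(truthSamples(truth))
simulateTwoSpecies <- function(params) {
  stopifnot(is(params, "SimParams"))
  validObject(params)
  set.seed(params@seed)

  nSp <- params@nSpecies
  nPer <- params@nSamplesPerSpecies
  species <- rep(seq_len(nSp), each = nPer)
  samples <- sprintf("S%03d", seq_len(nSp * nPer))
  haplo <- LETTERS[species]

  # region layout: the first `nSym` regions are sympatric (host every
  # species); the remaining regions are divided among species round-robin.
  nSym <- floor(params@sympatryFraction * params@nRegions)
  regions <- sprintf("R%02d", seq_len(params@nRegions))
  private <- regions[setdiff(seq_len(params@nRegions), seq_len(nSym))]
  regionPool <- lapply(seq_len(nSp), function(sp) {
    own <- if (length(private))
      private[(seq_along(private) - 1L) %% nSp + 1L == sp] else character(0)
    pool <- c(regions[seq_len(nSym)], own)
    if (!length(pool)) pool <- regions
    pool
  })
  region <- character(length(samples))
  for (sp in seq_len(nSp)) {
    idx <- which(species == sp)
    pool <- regionPool[[sp]]
    region[idx] <- pool[(seq_along(idx) - 1L) %% length(pool) + 1L]
  }

  lociNuc <- if (params@nNuclearLoci)
    sprintf("nuc%02d", seq_len(params@nNuclearLoci)) else character(0)
  lociMt <- if (params@nMitoLoci)
    sprintf("mt%02d", seq_len(params@nMitoLoci)) else character(0)
  loci <- data.frame(
    locus = c(lociNuc, lociMt),
    type = c(rep("nuclear", length(lociNuc)), rep("mito", length(lociMt))),
    length = params@locusLength, stringsAsFactors = FALSE)

  half <- params@divergence / 2
  tip <- params@thetaWithin / 2
  out <- vector("list", nrow(loci))
  for (k in seq_len(nrow(loci))) {
    loc <- loci$locus[k]
    anc <- .randomSequence(params@locusLength)
    base <- vapply(seq_len(nSp), function(sp) .jcMutate(anc, half), character(1))
    if (loci$type[k] == "mito") {
      # one copy per sample; invariant within species so the haplotype label
      # is a clean deterministic function of the species.
      out[[k]] <- data.frame(sample = samples, locus = loc, allele_index = 1L,
                             sequence = base[species], stringsAsFactors = FALSE)
    } else {
      a1 <- vapply(species, function(sp) .jcMutate(base[sp], tip), character(1))
      het <- runif(length(samples)) < params@heterozygosityRate
      a2 <- a1
      if (any(het))
        a2[het] <- vapply(species[het], function(sp) .jcMutate(base[sp], tip),
                          character(1))
      out[[k]] <- data.frame(
        sample = rep(samples, 2L), locus = loc,
        allele_index = rep(1:2, each = length(samples)),
        sequence = c(a1, a2), stringsAsFactors = FALSE)
    }
  }
  alleles <- do.call(rbind, out)
  alleles <- alleles[order(alleles$sample, alleles$locus, alleles$allele_index), ]
  rownames(alleles) <- NULL

  new("SimTruth",
      samples = data.frame(sample = samples, species = species,
                           region = region, haplotype = haplo,
                           stringsAsFactors = FALSE),
      alleles = alleles, loci = loci, params = params)
}

#' Simulate a noisy amplicon read table from ground truth
#'
#' Per (sample, locus): the locus drops out with probability
#' `missingLocusRate`; otherwise total depth is Poisson(`readDepthMean`)
#' (minimum 1). `Binomial(depth, errorSeqRate)` reads are diverted to up to
#' three spurious sequences, each a single random substitution of a true
#' allele, so each error sequence stays below the 20% calling threshold in
#' expectation at the default error rate. Remaining reads split
#' `Binomial(n, 0.5)` between the two allele copies of a heterozygote
#' (balanced dikaryotic nuclei) or go entirely to the single allele of a
#' homozygote. Per-cell totals match the drawn depth exactly.
#'
#' @param truth a [SimTruth] object.
#' @param params the [SimParams] used to generate `truth` (depth, error and
#'   dropout rates are read from here).
#' @return a [ReadTable].
#' @export
simulateReadTable <- function(truth, params = truth@params) {
  stopifnot(is(truth, "SimTruth"), is(params, "SimParams"))
  validObject(params)
  set.seed(params@seed + 1L)

  al <- truth@alleles
  if (nrow(al) == 0L)
    return(new("ReadTable", records = data.frame(
      sample = character(0), locus = character(0), sequence_id = character(0),
      sequence = character(0), count = integer(0), stringsAsFactors = FALSE)))
  key <- paste(al$sample, al$locus, sep = "\r")
  cells <- split(al, key)
  recs <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    cell <- cells[[i]]
    if (runif(1) < params@missingLocusRate) next
    depth <- max(1L, rpois(1L, params@readDepthMean))
    nErr <- rbinom(1L, depth, params@errorSeqRate)
    uniq <- unique(cell$sequence)
    counts <- integer(length(uniq))
    good <- depth - nErr
    if (length(uniq) == 1L) {
      counts[1] <- good
    } else {
      a <- rbinom(1L, good, 0.5)
      counts <- c(a, good - a)
    }
    seqs <- uniq
    if (nErr > 0L) {
      nVar <- min(3L, max(1L, nErr))
      errSeqs <- vapply(seq_len(nVar), function(j)
        .jcMutate(sample(uniq, 1L), 1 / nchar(uniq[1])), character(1))
      split <- as.integer(rmultinom(1L, nErr, rep(1, nVar)))
      for (j in seq_len(nVar)) {
        if (split[j] == 0L) next
        hit <- match(errSeqs[j], seqs)
        if (is.na(hit)) { seqs <- c(seqs, errSeqs[j]); counts <- c(counts, split[j]) }
        else counts[hit] <- counts[hit] + split[j]
      }
    }
    keep <- counts > 0L
    seqs <- seqs[keep]; counts <- counts[keep]
    if (!length(seqs)) next
    recs[[i]] <- data.frame(
      sample = cell$sample[1], locus = cell$locus[1],
      sequence_id = sprintf("%s_%s_u%02d", cell$sample[1], cell$locus[1],
                            seq_along(seqs)),
      sequence = seqs, count = counts, stringsAsFactors = FALSE)
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  records <- if (length(recs)) do.call(rbind, recs) else data.frame(
    sample = character(0), locus = character(0), sequence_id = character(0),
    sequence = character(0), count = integer(0), stringsAsFactors = FALSE)
  records <- records[order(records$sample, records$locus, -records$count,
                           records$sequence), ]
  rownames(records) <- NULL
  new("ReadTable", records = records)
}

#' Write a synthetic fixture to disk
#'
#' Emits the plain-text file set every downstream module consumes: the
#' read-count TSV (`reads.tsv`: sample, locus, sequence_id, sequence, count),
#' one FASTA of true allele sequences per locus (`alleles_<locus>.fasta`),
#' the hierarchy TSV (`hierarchy.tsv`: sample, haplotype, region) and a truth
#' JSON (`truth.json`) with the full ground truth and parameters.
#'
#' @param truth a [SimTruth].
#' @param readTable a [ReadTable] (typically from [simulateReadTable]).
#' @param outDir output directory (created if absent).
#' @return invisibly, the named character vector of file paths written.
#' @export
writeFixture <- function(truth, readTable, outDir) {
  stopifnot(is(truth, "SimTruth"), is(readTable, "ReadTable"))
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
    .stopf("cannot create output directory '%s'", outDir)

  paths <- c(reads = file.path(outDir, "reads.tsv"),
             hierarchy = file.path(outDir, "hierarchy.tsv"),
             truth = file.path(outDir, "truth.json"))
  write.table(readTable@records, paths[["reads"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  hier <- truth@samples[, c("sample", "haplotype", "region")]
  write.table(hier, paths[["hierarchy"]], sep = "\t",
              quote = FALSE, row.names = FALSE)

  for (loc in truth@loci$locus) {
    a <- truth@alleles[truth@alleles$locus == loc, ]
    f <- file.path(outDir, sprintf("alleles_%s.fasta", loc))
    if (nrow(a)) {
      seqs <- Biostrings::DNAStringSet(a$sequence)
      names(seqs) <- sprintf("%s|%d", a$sample, a$allele_index)
      Biostrings::writeXStringSet(seqs, f)
    } else {
      writeLines(character(0), f)
    }
    paths[[paste0("fasta_", loc)]] <- f
  }

  truthList <- list(
    params = .paramsToList(truth@params),
    samples = truth@samples, loci = truth@loci, alleles = truth@alleles)
  jsonlite::write_json(truthList, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(paths)
}

.paramsToList <- function(p) {
  nm <- slotNames("SimParams")
  setNames(lapply(nm, function(s) slot(p, s)), nm)
}

#' Read a fixture back from disk
#'
#' Inverse of [writeFixture] for the read table and hierarchy; the truth JSON
#' round-trips through [readTruthJson].
#'
#' @param path path to the TSV file.
#' @return `readReadTableTsv` returns a [ReadTable]; `readHierarchyTsv` a
#'   data.frame with columns sample, haplotype, region.
#' @export
readReadTableTsv <- function(path) {
  if (!file.exists(path)) .stopf("no such file: '%s'", path)
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(sample = "character", locus = "character",
                                  sequence_id = "character",
                                  sequence = "character", count = "integer"))
  df$sequence <- toupper(df$sequence)
  new("ReadTable", records = df)
}

#' @rdname readReadTableTsv
#' @export
readHierarchyTsv <- function(path) {
  if (!file.exists(path)) .stopf("no such file: '%s'", path)
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("sample", "haplotype", "region")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .stopf("hierarchy file '%s' lacks columns: %s", path,
           paste(miss, collapse = ", "))
  df[, need]
}

#' @rdname readReadTableTsv
#' @export
readTruthJson <- function(path) {
  if (!file.exists(path)) .stopf("no such file: '%s'", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- x$params
  params <- SimParams(
    nSpecies = p$nSpecies, nSamplesPerSpecies = p$nSamplesPerSpecies,
    nRegions = p$nRegions, sympatryFraction = p$sympatryFraction,
    nNuclearLoci = p$nNuclearLoci, locusLength = p$locusLength,
    nMitoLoci = p$nMitoLoci, divergence = p$divergence,
    thetaWithin = p$thetaWithin, heterozygosityRate = p$heterozygosityRate,
    readDepthMean = p$readDepthMean, errorSeqRate = p$errorSeqRate,
    missingLocusRate = p$missingLocusRate, seed = p$seed)
  asDf <- function(d) as.data.frame(d, stringsAsFactors = FALSE)
  new("SimTruth", samples = asDf(x$samples), alleles = asDf(x$alleles),
      loci = asDf(x$loci), params = params)
}
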