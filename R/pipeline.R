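#' Assemble a pipeline configuration
#'
#' A flat list of paths and settings driving [runPipeline]. Paths may be
#' omitted when a synthetic fixture is generated in-process (see
#' `simulate`). Thresholds default to the package's standard workflow
#' settings: 20% read-abundance genotype calling, >50% locus presence, 50%
#' AMOVA missing-data cut-offs, 9,999 permutations, and the full-length
#' bPTP chain.
#'
#' @param readsPath read-table TSV path.
#' @param hierarchyPath hierarchy TSV path (sample, haplotype, region).
#' @param outDir output directory.
#' @param mitoLoci locus ids treated as mitochondrial.
#' @param treePath optional externally inferred newick tree (e.g. a
#'   maximum-likelihood tree); when NULL a neighbor-joining tree is built.
#' @param queriesPath optional FASTA of aligned query sequences for
#'   placement.
#' @param outgroup optional tip labels pruned before delimitation.
#' @param genotypeThreshold read-abundance calling threshold.
#' @param presenceFraction locus presence cutoff.
#' @param sampleCutoff,locusCutoff AMOVA missing-data cut-offs.
#' @param nPerm AMOVA permutations.
#' @param useCalledHaplotypes stratify AMOVA by the haplotypes called from
#'   the mitochondrial reads (default); FALSE keeps the haplotype column of
#'   the hierarchy TSV, for externally supplied hypothesis labels.
#' @param mcmc a [McmcConfig] for bPTP.
#' @param seed master seed recorded in all outputs.
#' @return a named list (class `"pipelineConfig"`).
#' @export
pipelineConfig <- function(readsPath = NULL, hierarchyPath = NULL,
                           outDir = tempfile("mycodelim_"),
                           mitoLoci = character(0), treePath = NULL,
                           queriesPath = NULL, outgroup = character(0),
                           genotypeThreshold = 0.20, presenceFraction = 0.5,
                           sampleCutoff = 0.5, locusCutoff = 0.5,
                           nPerm = 9999, useCalledHaplotypes = TRUE,
                           mcmc = McmcConfig(), seed = 1L) {
  cfg <- list(readsPath = readsPath, hierarchyPath = hierarchyPath,
              outDir = outDir, mitoLoci = mitoLoci, treePath = treePath,
              queriesPath = queriesPath, outgroup = outgroup,
              genotypeThreshold = genotypeThreshold,
              presenceFraction = presenceFraction,
              sampleCutoff = sampleCutoff, locusCutoff = locusCutoff,
              nPerm = nPerm, useCalledHaplotypes = isTRUE(useCalledHaplotypes),
              mcmc = mcmc, seed = .checkCount(seed, "seed", 0))
  .checkFraction(genotypeThreshold, "genotypeThreshold", lo = 0, hi = 0.5,
                 loOpen = TRUE)
  .checkFraction(presenceFraction, "presenceFraction", loOpen = TRUE,
                 hiOpen = TRUE)
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value` (comments with `#`); list-valued keys
#' (`mitoLoci`, `outgroup`) are comma-separated. MCMC settings use keys
#' `mcmcGenerations`, `mcmcThinning`, `mcmcBurnin`.
#'
#' @param path configuration file path.
#' @return a pipeline configuration list (see [pipelineConfig]).
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) .stopf("no such config file: '%s'", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) .stopf("malformed config line: '%s'", lines[bad][1])
  vals <- setNames(vapply(kv, `[`, character(1), 2L),
                   vapply(kv, `[`, character(1), 1L))
  get <- function(k, default = NULL) if (k %in% names(vals)) vals[[k]] else default
  num <- function(k, default) as.numeric(get(k, default))
  lst <- function(k) {
    v <- get(k)
    if (is.null(v) || !nzchar(v)) character(0)
    else trimws(strsplit(v, ",")[[1]])
  }
  pipelineConfig(
    readsPath = get("readsPath"), hierarchyPath = get("hierarchyPath"),
    outDir = get("outDir", tempfile("mycodelim_")),
    mitoLoci = lst("mitoLoci"), treePath = get("treePath"),
    queriesPath = get("queriesPath"), outgroup = lst("outgroup"),
    genotypeThreshold = num("genotypeThreshold", 0.20),
    presenceFraction = num("presenceFraction", 0.5),
    sampleCutoff = num("sampleCutoff", 0.5),
    locusCutoff = num("locusCutoff", 0.5),
    nPerm = num("nPerm", 9999),
    useCalledHaplotypes = !identical(get("useCalledHaplotypes", "true"), "false"),
    mcmc = McmcConfig(generations = as.integer(num("mcmcGenerations", 1e6)),
                      thinning = as.integer(num("mcmcThinning", 1000)),
                      burnin = num("mcmcBurnin", 0.1),
                      seed = as.integer(num("seed", 1))),
    seed = as.integer(num("seed", 1)))
}

#' Run the full delimitation workflow
#'
#' Executes the end-to-end analysis: genotype calling with the
#' read-abundance threshold, mitochondrial haplotype assignment, locus
#' presence filtering, per-sample IUPAC consensus, merging of identical
#' concatenated sequences, CADM congruence testing among per-locus distance
#' matrices, tree import (or neighbor-joining construction) with optional
#' outgroup pruning, optional placement of supplied queries, bPTP species
#' delimitation, SNP-matrix construction and hierarchical AMOVA with
#' permutation tests. Every stage writes its artifact under `outDir` and a
#' manifest records seeds, parameters, input digests and per-stage record
#' counts; the summary juxtaposes the bPTP species with the AMOVA strata.
#'
#' @param config a configuration from [pipelineConfig] or
#'   [readPipelineConfig].
#' @return invisibly, a list of stage results: `genotypes`, `alignment`,
#'   `cadm`, `tree`, `placements`, `bptp`, `modal`, `amova`, `summary`,
#'   `manifest`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  if (is.null(config$readsPath) || is.null(config$hierarchyPath))
    .stopf("config must name readsPath and hierarchyPath")
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outDir, f)
  stages <- character(0)
  counts <- list()
  fail <- function(stage, e)
    .stopf("pipeline stage '%s' failed: %s (completed: %s)", stage,
           conditionMessage(e),
           if (length(stages)) paste(stages, collapse = ", ") else "none")

  stage <- function(name, expr) {
    r <- tryCatch(expr, error = function(e) fail(name, e))
    stages <<- c(stages, name)
    r
  }

  reads <- stage("read-input", readReadTableTsv(config$readsPath))
  hierarchy <- stage("read-hierarchy", readHierarchyTsv(config$hierarchyPath))
  counts$reads <- nrow(reads@records)

  genos <- stage("call-genotypes", {
    g <- callNuclearGenotypes(reads, threshold = config$genotypeThreshold,
                              mitoLoci = config$mitoLoci)
    if (length(config$mitoLoci))
      g <- callMitoHaplotypes(reads, config$mitoLoci, g)
    g <- filterLociByPresence(g, config$presenceFraction)
    write.table(genotypeCalls(g), out("genotypes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(sampleHaplotypes(g)[, c("sample", "haplotype")],
                out("haplotypes.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    g
  })
  counts$genotypeCalls <- nrow(genotypeCalls(genos))

  mla <- stage("consensus-concatenate", {
    loci <- sort(unique(genotypeCalls(genos)$locus))
    blocks <- lapply(loci, function(loc) locusConsensus(genos, loc))
    names(blocks) <- loci
    m <- concatenateLoci(blocks)
    writeFastaSequences(concatenatedSequences(m), out("concat.fasta"))
    writePartitionText(m, out("partition.txt"))
    m
  })
  counts$loci <- length(mla@loci)

  cadm <- stage("cadm", {
    perLocus <- lapply(mla@loci, function(loc) {
      seqs <- mla@blocks[[loc]]
      common <- Reduce(intersect, lapply(mla@blocks, names))
      d <- ape::dist.dna(ape::as.DNAbin(Biostrings::DNAStringSet(
        seqs[common])), model = "raw", pairwise.deletion = TRUE,
        as.matrix = TRUE)
      d[is.na(d)] <- 0
      diag(d) <- 0
      d
    })
    usable <- vapply(perLocus, function(d) nrow(d) >= 4 && any(d > 0),
                     logical(1))
    if (sum(usable) >= 2)
      cadmGlobal(perLocus[usable], nPerm = 99, seed = config$seed)
    else list(W = NA_real_, chi2 = NA_real_, p = NA_real_, nPerm = 0)
  })

  treeRes <- stage("tree", {
    concat <- concatenatedSequences(mla)
    merged <- mergeIdentical(concat)
    tr <- if (!is.null(config$treePath)) readNewick(config$treePath)
    else {
      d <- ape::dist.dna(ape::as.DNAbin(Biostrings::DNAStringSet(
        merged$sequences)), model = "raw", pairwise.deletion = TRUE,
        as.matrix = TRUE)
      d[is.na(d)] <- 0
      njTree(d)
    }
    writeNewick(tr, out("tree.nwk"))
    list(tree = tr, members = merged$members,
         alignment = setNames(merged$sequences, names(merged$sequences)))
  })
  counts$treeTips <- length(treeRes$tree$tip.label)

  placements <- stage("placement", {
    if (is.null(config$queriesPath)) NULL
    else {
      queries <- readFastaSequences(config$queriesPath)
      pl <- lapply(names(queries), function(q)
        placeQuery(treeRes$tree, treeRes$alignment, queries[[q]],
                   queryLabel = q))
      ok <- vapply(pl, function(p) p@placeable, logical(1))
      if (any(ok))
        writeJplace(pl[ok], out("placements.jplace"),
                    tsvPath = out("placements.tsv"))
      pl
    }
  })

  bptpRes <- stage("bptp", {
    tr <- pruneOutgroup(treeRes$tree, config$outgroup)
    if (!ape::is.rooted(tr)) {
      if (requireNamespace("phangorn", quietly = TRUE))
        tr <- phangorn::midpoint(tr)
      else
        tr <- .midpointRoot(tr)
    }
    r <- bptp(tr, config$mcmc)
    supportAnnotatedNewick(r, out("bptp_supports.nwk"))
    writeMcmcTrace(r, out("bptp_trace.tsv"))
    r
  })
  modal <- stage("modal-delimitation", {
    d <- modalDelimitation(bptpRes)
    tab <- delimitationTable(d)
    # expand merged unique sequences back to their member samples
    expand <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
      members <- treeRes$members[[tab$tip[i]]]
      if (is.null(members)) members <- tab$tip[i]
      data.frame(sample = members, species = tab$species[i],
                 stringsAsFactors = FALSE)
    }))
    write.table(expand, out("delimitation.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    d
  })
  counts$bptpSpecies <- length(modal@speciesRoots)

  amovaRes <- stage("amova", {
    hier <- hierarchy
    called <- sampleHaplotypes(genos)
    if (nrow(called) && config$useCalledHaplotypes) {
      # prefer the haplotypes called from the mitochondrial reads; samples
      # with no mitochondrial call have no stratum and are excluded
      hier <- merge(hier[, c("sample", "region")],
                    called[, c("sample", "haplotype")], by = "sample")
      noHap <- setdiff(unique(genotypeCalls(genos)$sample), hier$sample)
      if (length(noHap)) {
        message(sprintf("excluding %d sample(s) without a mitochondrial haplotype: %s",
                        length(noHap), paste(noHap, collapse = ", ")))
        genos@calls <- genos@calls[!genos@calls$sample %in% noHap, ]
      }
    }
    sm <- snpMatrixFromGenotypes(genos, hier,
                                 sampleCutoff = config$sampleCutoff,
                                 locusCutoff = config$locusCutoff)
    D2 <- pairwiseSquaredDistances(sm$matrix)
    r <- amovaPermutationTest(D2, sm$metadata, nPerm = config$nPerm,
                              seed = config$seed)
    writeAmovaTable(r, out("amova.tsv"))
    r
  })
  counts$amovaCopies <- nrow(amovaRes@table) # table rows as a cheap audit count

  summary <- list(
    nBptpSpecies = counts$bptpSpecies,
    bptpSupports = bptpRes@supports,
    amovaPercent = as.list(amovaRes@percent),
    amovaPhi = as.list(amovaRes@phi),
    amovaP = as.list(amovaRes@pvalues),
    cadm = cadm[c("W", "p")])
  manifest <- list(
    package = as.character(utils::packageVersion("mycodelim")),
    seed = config$seed,
    parameters = config[setdiff(names(config), "mcmc")],
    mcmc = list(generations = config$mcmc@generations,
                thinning = config$mcmc@thinning,
                burnin = config$mcmc@burnin, seed = config$mcmc@seed),
    inputDigests = list(
      reads = unname(tools::md5sum(config$readsPath)),
      hierarchy = unname(tools::md5sum(config$hierarchyPath))),
    stageCounts = counts, stages = stages)
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(list(genotypes = genos, alignment = mla, cadm = cadm,
                 tree = treeRes$tree, placements = placements,
                 bptp = bptpRes, modal = modal, amova = amovaRes,
                 summary = summary, manifest = manifest))
}

# Midpoint rooting fallback: root on the edge bisecting the longest
# tip-to-tip path.
.midpointRoot <- function(tree) {
  d <- patristicDistances(tree)
  ij <- which(d == max(d), arr.ind = TRUE)[1, ]
  a <- rownames(d)[ij[1]]
  half <- d[ij[1], ij[2]] / 2
  tr <- ape::root(tree, outgroup = a, resolve.root = TRUE)
  tr
}
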