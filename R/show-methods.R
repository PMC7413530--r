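#' @describeIn SimParams-class compact display
#' @param object a `SimParams` object
#' @export
setMethod("show", "SimParams", function(object) {
  cat("SimParams:", object@nSpecies, "species x", object@nSamplesPerSpecies,
      "samples,", object@nRegions, "regions\n")
  cat(sprintf("  loci: %d nuclear (%d bp) + %d mito; divergence=%g theta=%g het=%g\n",
              object@nNuclearLoci, object@locusLength, object@nMitoLoci,
              object@divergence, object@thetaWithin, object@heterozygosityRate))
  cat(sprintf("  reads: depth=%g error=%g missing=%g; seed=%d\n",
              object@readDepthMean, object@errorSeqRate,
              object@missingLocusRate, object@seed))
})

#' @describeIn SimTruth-class compact display
#' @param object a `SimTruth` object
#' @export
setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", nrow(object@samples), "samples,",
      nrow(object@loci), "loci,", nrow(object@alleles), "allele records\n")
  if (nrow(object@samples))
    print(table(species = object@samples$species,
                haplotype = object@samples$haplotype))
})

#' @describeIn ReadTable-class compact display
#' @param object a `ReadTable` object
#' @export
setMethod("show", "ReadTable", function(object) {
  r <- object@records
  cat("ReadTable:", nrow(r), "records |",
      length(unique(r$sample)), "samples x", length(unique(r$locus)), "loci |",
      sum(r$count), "reads\n")
})

#' @describeIn GenotypeSet-class compact display
#' @param object a `GenotypeSet` object
#' @export
setMethod("show", "GenotypeSet", function(object) {
  cl <- object@calls
  cells <- if (nrow(cl)) nrow(unique(cl[, c("sample", "locus")])) else 0L
  cat("GenotypeSet:", cells, "called (sample, locus) cells over",
      length(object@samples), "samples; threshold", object@threshold, "\n")
  if (nrow(cl)) {
    z <- unique(cl[, c("sample", "locus", "zygosity")])
    cat("  zygosity:", sum(z$zygosity == "hom"), "hom /",
        sum(z$zygosity == "het"), "het;",
        sum(unique(cl[, c("sample", "locus", "flag")])$flag != ""), "flagged\n")
  }
  if (nrow(object@haplotypes))
    cat("  haplotypes:", paste(sprintf("%s=%d",
        names(table(object@haplotypes$haplotype)),
        table(object@haplotypes$haplotype)), collapse = ", "), "\n")
})

#' @describeIn MultiLocusAlignment-class compact display
#' @param object a `MultiLocusAlignment` object
#' @export
setMethod("show", "MultiLocusAlignment", function(object) {
  cat("MultiLocusAlignment:", length(object@loci), "loci,",
      length(object@samples), "samples, total length",
      if (nrow(object@partition)) max(object@partition$end) else 0L, "\n")
})

#' @describeIn PlacementResult-class compact display
#' @param object a `PlacementResult` object
#' @export
setMethod("show", "PlacementResult", function(object) {
  if (!object@placeable) {
    cat("PlacementResult:", object@query, "-> unplaceable (no informative overlap)\n")
    return(invisible(NULL))
  }
  best <- object@edges[match(object@bestEdge, object@edges$edge), ]
  cat(sprintf("PlacementResult: %s -> edge %d (logL %.4f, LWR %.3f) over %d edges\n",
              object@query, object@bestEdge, best$loglik, best$lwr,
              nrow(object@edges)))
})

#' @describeIn Delimitation-class compact display
#' @param object a `Delimitation` object
#' @export
setMethod("show", "Delimitation", function(object) {
  cat(sprintf("Delimitation: %d species over %d tips, logLik %.4f\n",
              length(object@speciesRoots), length(object@assignment),
              object@logLik))
  cat(sprintf("  lambdaSp=%s lambdaCoal=%s\n",
              format(object@rates[["lambdaSp"]]),
              format(object@rates[["lambdaCoal"]])))
})

#' @describeIn BptpResult-class compact display
#' @param object a `BptpResult` object
#' @export
setMethod("show", "BptpResult", function(object) {
  cat(sprintf("BptpResult: %d retained samples, acceptance %.3f\n",
              nrow(object@trace), object@acceptanceRate))
  s <- object@supports
  if (nrow(s)) {
    cat("  species with posterior support > 0.5:\n")
    for (i in seq_len(min(8L, nrow(s))))
      cat(sprintf("    node %d  support %.3f  {%s}\n",
                  s$node[i], s$support[i], s$tips[i]))
  }
})

#' @describeIn AmovaResult-class display the AMOVA table
#' @param object an `AmovaResult` object
#' @export
setMethod("show", "AmovaResult", function(object) {
  cat("Hierarchical AMOVA\n")
  t <- object@table
  t$MS <- round(t$MS, 4); t$SS <- round(t$SS, 4)
  print(t, row.names = FALSE)
  cat("  % variance:", paste(sprintf("%s=%.1f", names(object@percent),
                                     object@percent), collapse = "  "), "\n")
  cat("  Phi:", paste(sprintf("%s=%.3f", names(object@phi), object@phi),
                      collapse = "  "), "\n")
  if (object@nPerm > 0)
    cat("  P (", object@nPerm, "permutations):",
        paste(sprintf("%s=%.4g", names(object@pvalues), object@pvalues),
              collapse = "  "), "\n")
})

#' Accessors for core containers
#'
#' Small accessor family so downstream code never touches slots directly:
#' `readRecords()` returns the read-count records, `genotypeCalls()` the
#' per-cell allele calls, `sampleHaplotypes()` the per-sample mitochondrial
#' haplotypes, `truthSamples()`/`truthAlleles()` the simulated ground truth,
#' `amovaTable()` the df/SS/MS table, `varianceComponents()`, `phiStatistics()`
#' and `permutationP()` the AMOVA summaries, `partitionMap()` the locus ->
#' column intervals (1-based inclusive), and `concatenatedSequences()` the
#' padded concatenation.
#'
#' @param x an object of the documented class
#' @return the underlying data.frame / numeric vector (see details above)
#' @name accessors
NULL

#' @rdname accessors
#' @export
readRecords <- function(x) { stopifnot(is(x, "ReadTable")); x@records }

#' @rdname accessors
#' @export
genotypeCalls <- function(x) { stopifnot(is(x, "GenotypeSet")); x@calls }

#' @rdname accessors
#' @export
sampleHaplotypes <- function(x) { stopifnot(is(x, "GenotypeSet")); x@haplotypes }

#' @rdname accessors
#' @export
truthSamples <- function(x) { stopifnot(is(x, "SimTruth")); x@samples }

#' @rdname accessors
#' @export
truthAlleles <- function(x) { stopifnot(is(x, "SimTruth")); x@alleles }

#' @rdname accessors
#' @export
amovaTable <- function(x) { stopifnot(is(x, "AmovaResult")); x@table }

#' @rdname accessors
#' @export
varianceComponents <- function(x) { stopifnot(is(x, "AmovaResult")); x@components }

#' @rdname accessors
#' @export
phiStatistics <- function(x) { stopifnot(is(x, "AmovaResult")); x@phi }

#' @rdname accessors
#' @export
permutationP <- function(x) { stopifnot(is(x, "AmovaResult")); x@pvalues }

#' @rdname accessors
#' @export
partitionMap <- function(x) {
  stopifnot(is(x, "MultiLocusAlignment"))
  p <- x@partition
  data.frame(locus = p$locus, start = p$start + 1L, end = p$end,
             stringsAsFactors = FALSE)
}

#' @rdname accessors
#' @export
concatenatedSequences <- function(x) {
  stopifnot(is(x, "MultiLocusAlignment"))
  if (!length(x@loci))
    return(setNames(rep("", length(x@samples)), x@samples))
  out <- vapply(x@samples, function(s) {
    paste(vapply(x@loci, function(loc) {
      b <- x@blocks[[loc]]
      if (s %in% names(b)) b[[s]]
      else strrep(x@fill, x@partition$end[x@partition$locus == loc] -
                    x@partition$start[x@partition$locus == loc])
    }, character(1)), collapse = "")
  }, character(1))
  setNames(out, x@samples)
}
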