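#' Call nuclear genotypes by read-abundance threshold
#'
#' For every (sample, locus) cell with reads, unique sequences whose read
#' abundance is at least `threshold` of the cell total are presumed to
#' represent the genotype of the dikaryotic sample: one passing sequence is a
#' homozygote, two a heterozygote. A cell where more than two sequences pass
#' (biologically impossible for a dikaryon) keeps the top two by count and is
#' flagged `"anomalous"` — or dropped entirely with `strict = TRUE`. A cell
#' where nothing passes (only possible when more than `1/threshold` equally
#' rare sequences share the reads) is treated as missing. The comparison is
#' inclusive (`>=`), so a 20%-abundance sequence passes a 0.20 threshold and
#' a 19% one does not. Ties within the top two are broken by count, then by
#' lexicographically smaller sequence, for reproducibility.
#'
#' @param reads a [ReadTable].
#' @param threshold read-abundance calling threshold, in (0, 0.5].
#' @param strict drop anomalous cells instead of keeping the top two.
#' @param mitoLoci optional locus ids to exclude from nuclear calling (they
#'   are handled by [callMitoHaplotypes]).
#' @return a [GenotypeSet] (haplotype slot empty; fill it with
#'   [callMitoHaplotypes]).
#' @export
#' @examples
#' rt <- new("ReadTable", records = data.frame(
#'   sample = "s1", locus = "L1", sequence_id = c("u1", "u2", "u3"),
#'   sequence = c("AAAA", "AAAC", "AAGG"), count = c(60L, 30L, 10L)))
#' genotypeCalls(callNuclearGenotypes(rt))
callNuclearGenotypes <- function(reads, threshold = 0.20, strict = FALSE,
                                 mitoLoci = character(0)) {
  stopifnot(is(reads, "ReadTable"))
  validObject(reads)
  .checkFraction(threshold, "threshold", lo = 0, hi = 0.5, loOpen = TRUE)
  r <- reads@records
  r <- r[!r$locus %in% mitoLoci, , drop = FALSE]
  samples <- sort(unique(reads@records$sample))
  empty <- data.frame(sample = character(0), locus = character(0),
                      allele_index = integer(0), sequence = character(0),
                      fraction = numeric(0), zygosity = character(0),
                      flag = character(0), stringsAsFactors = FALSE)
  if (nrow(r) == 0L)
    return(new("GenotypeSet", calls = empty, haplotypes = .emptyHaplo(),
               samples = samples, threshold = threshold))

  key <- paste(r$sample, r$locus, sep = "\r")
  out <- lapply(split(r, key), function(cell) {
    total <- sum(cell$count)
    if (total == 0L) return(NULL)
    frac <- cell$count / total
    pass <- which(frac >= threshold)
    if (length(pass) == 0L) return(NULL)            # missing: nothing passes
    ord <- pass[order(-cell$count[pass], cell$sequence[pass])]
    flag <- ""
    if (length(ord) > 2L) {
      if (strict) return(NULL)
      flag <- "anomalous"
      ord <- ord[1:2]
    }
    data.frame(sample = cell$sample[1], locus = cell$locus[1],
               allele_index = seq_along(ord), sequence = cell$sequence[ord],
               fraction = frac[ord],
               zygosity = if (length(ord) == 2L) "het" else "hom",
               flag = flag, stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  calls <- if (length(out)) do.call(rbind, out) else empty
  calls <- calls[order(calls$sample, calls$locus, calls$allele_index), ]
  rownames(calls) <- NULL
  new("GenotypeSet", calls = calls, haplotypes = .emptyHaplo(),
      samples = samples, threshold = threshold)
}

.emptyHaplo <- function() data.frame(
  sample = character(0), haplotype = character(0), sequence = character(0),
  stringsAsFactors = FALSE)

#' Assign mitochondrial haplotypes from most-abundant sequences
#'
#' Per sample and mitochondrial locus, the single most abundant unique
#' sequence is presumed to represent the haplotype; exact count ties are
#' broken toward the lexicographically smaller sequence with a warning.
#' Samples sharing an identical concatenated mitochondrial sequence receive
#' the same haplotype label (A, B, ... in order of first appearance over
#' sample-sorted order). Samples with no mitochondrial reads are omitted
#' (and thereby excluded from haplotype-stratified analyses downstream).
#'
#' @param reads a [ReadTable].
#' @param mitoLoci character vector of mitochondrial locus ids.
#' @param genotypes optional [GenotypeSet] to attach the haplotypes to.
#' @return a [GenotypeSet]: `genotypes` with the haplotype slot filled (a
#'   fresh empty-call set if `genotypes` is missing).
#' @export
callMitoHaplotypes <- function(reads, mitoLoci, genotypes = NULL) {
  stopifnot(is(reads, "ReadTable"))
  validObject(reads)
  r <- reads@records
  if (!all(mitoLoci %in% r$locus))
    .stopf("mitochondrial loci absent from the read table: %s",
           paste(setdiff(mitoLoci, r$locus), collapse = ", "))
  r <- r[r$locus %in% mitoLoci, , drop = FALSE]
  samples <- sort(unique(r$sample))
  parts <- lapply(samples, function(s) {
    bits <- vapply(sort(mitoLoci), function(loc) {
      cell <- r[r$sample == s & r$locus == loc, , drop = FALSE]
      if (nrow(cell) == 0L || sum(cell$count) == 0L) return(NA_character_)
      top <- which(cell$count == max(cell$count))
      if (length(top) > 1L) {
        .warnf("haplotype tie for %s/%s broken lexicographically", s, loc)
        top <- top[order(cell$sequence[top])][1]
      }
      cell$sequence[top]
    }, character(1))
    if (anyNA(bits)) NA_character_ else paste(bits, collapse = "")
  })
  concat <- unlist(parts)
  keep <- !is.na(concat)
  uniq <- unique(concat[keep])             # discovery order over sorted samples
  labels <- setNames(LETTERS[seq_along(uniq)], uniq)
  if (length(uniq) > length(LETTERS))
    labels <- setNames(sprintf("H%02d", seq_along(uniq)), uniq)
  haplo <- data.frame(sample = samples[keep],
                      haplotype = unname(labels[concat[keep]]),
                      sequence = concat[keep], stringsAsFactors = FALSE)
  if (is.null(genotypes))
    genotypes <- new("GenotypeSet", calls = data.frame(
      sample = character(0), locus = character(0), allele_index = integer(0),
      sequence = character(0), fraction = numeric(0), zygosity = character(0),
      flag = character(0), stringsAsFactors = FALSE),
      haplotypes = haplo, samples = sort(unique(reads@records$sample)),
      threshold = NA_real_)
  else genotypes@haplotypes <- haplo
  genotypes
}

#' Remove loci detected in too few samples
#'
#' A locus is retained only when it is detected (has a genotype call) in
#' strictly more than `minFraction` of the sample universe; loci at exactly
#' the cutoff are removed. Removals are reported via `message()`.
#'
#' @param genotypes a [GenotypeSet].
#' @param minFraction presence cutoff (default 0.5: "more than half").
#' @return the filtered [GenotypeSet].
#' @export
filterLociByPresence <- function(genotypes, minFraction = 0.5) {
  stopifnot(is(genotypes, "GenotypeSet"))
  .checkFraction(minFraction, "minFraction")
  cl <- genotypes@calls
  if (nrow(cl) == 0L) .stopf("no genotype calls to filter")
  nTotal <- length(genotypes@samples)
  present <- tapply(cl$sample, cl$locus, function(s) length(unique(s)))
  drop <- names(present)[present <= minFraction * nTotal]
  if (length(drop)) {
    message(sprintf("removed %d locus/loci detected in <= %.0f%% of %d samples: %s",
                    length(drop), 100 * minFraction, nTotal,
                    paste(drop, collapse = ", ")))
    cl <- cl[!cl$locus %in% drop, , drop = FALSE]
    rownames(cl) <- NULL
    genotypes@calls <- cl
  }
  genotypes
}

#' IUPAC consensus of one or two aligned allele sequences
#'
#' Per column, the IUPAC code covering the set of observed unambiguous bases
#' (A/C -> M, A/G -> R, A/T -> W, C/G -> S, C/T -> Y, G/T -> K; identical
#' bases give the base; three- and four-base sets give V/H/D/B/N). A gap
#' ('-') or unknown ('N') facing a base yields the base; a column is '-' (or
#' 'N') only when every allele carries it.
#'
#' @param alleles character vector of 1 or 2 equal-length aligned sequences.
#' @return the consensus sequence (single string).
#' @export
#' @examples
#' iupacConsensus(c("ACGT", "ACGA"))  # "ACGW"
iupacConsensus <- function(alleles) {
  if (length(alleles) == 0L) .stopf("empty allele list")
  if (length(alleles) > 2L) .stopf("at most two alleles per dikaryotic sample")
  alleles <- toupper(alleles)
  .validateSequences(alleles, "allele")
  if (length(unique(nchar(alleles))) != 1L)
    .stopf("allele length mismatch: %s",
           paste(nchar(alleles), collapse = " vs "))
  if (length(alleles) == 1L) return(alleles)
  m <- .seqMatrix(alleles)
  out <- character(ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    bases <- sort(unique(col[col %in% c("A", "C", "G", "T")]))
    out[j] <- if (length(bases)) {
      .IUPAC_FROM_SET[[paste(bases, collapse = "")]]
    } else if (all(col == "-")) "-" else "N"
  }
  paste(out, collapse = "")
}

#' Per-sample consensus sequences for one locus
#'
#' Applies [iupacConsensus] to every sample's called alleles at `locus`.
#'
#' @param genotypes a [GenotypeSet].
#' @param locus locus id.
#' @return named character vector (sample -> consensus sequence).
#' @export
locusConsensus <- function(genotypes, locus) {
  stopifnot(is(genotypes, "GenotypeSet"))
  cl <- genotypes@calls[genotypes@calls$locus == locus, , drop = FALSE]
  if (nrow(cl) == 0L) .stopf("no calls at locus '%s'", locus)
  vapply(split(cl, cl$sample), function(d) iupacConsensus(d$sequence),
         character(1))
}
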