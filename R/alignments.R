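#' Merge identical sequences into unique records
#'
#' Sequences that are byte-identical collapse to a single record carrying all
#' member labels; the representative label is the sorted member labels joined
#' with "|", so output is deterministic regardless of input order.
#'
#' @param seqs named character vector of equal-length sequences.
#' @return list with `sequences` (named character vector of uniques) and
#'   `members` (named list: representative label -> member labels).
#' @export
#' @examples
#' mergeIdentical(c(s1 = "AAA", s2 = "AAA", s3 = "AAC"))
mergeIdentical <- function(seqs) {
  if (length(seqs) == 0L)
    return(list(sequences = setNames(character(0), character(0)),
                members = list()))
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    .stopf("sequences must be named")
  if (length(unique(nchar(seqs))) != 1L)
    .stopf("sequences have unequal lengths")
  groups <- split(names(seqs), unname(seqs))
  groups <- lapply(groups, sort)
  reps <- vapply(groups, paste, character(1), collapse = "|")
  ord <- order(reps)
  uniq <- setNames(names(groups)[ord], reps[ord])
  list(sequences = uniq, members = setNames(groups[ord], reps[ord]))
}

#' Remove alignment columns dominated by gaps
#'
#' A stand-in for heavier alignment-trimming tools: columns whose gap ('-')
#' fraction exceeds `maxGapFraction` are removed. The kept-column map
#' (original 1-based positions) is returned so trimmed coordinates stay
#' traceable.
#'
#' @param seqs named character vector of equal-length aligned sequences.
#' @param maxGapFraction columns with gap fraction strictly greater than this
#'   are dropped (1 keeps everything).
#' @return list with `sequences` (trimmed) and `kept` (integer vector of
#'   original 1-based column positions).
#' @export
filterAmbiguousColumns <- function(seqs, maxGapFraction = 0.5) {
  .checkFraction(maxGapFraction, "maxGapFraction")
  if (length(seqs) == 0L)
    return(list(sequences = seqs, kept = integer(0)))
  m <- .seqMatrix(seqs)
  gapFrac <- colMeans(m == "-")
  kept <- which(gapFrac <= maxGapFraction)
  trimmed <- .collapseRows(m[, kept, drop = FALSE])
  list(sequences = setNames(trimmed, names(seqs)), kept = kept)
}

#' Concatenate per-locus blocks into a multi-locus alignment
#'
#' Loci are laid end-to-end in the given order; samples missing a locus are
#' padded with `fill` ('N' by default: absence of data, not an inferred
#' deletion) across that locus' interval. The partition map records each
#' locus' column interval (0-based half-open internally; see
#' [partitionMap] and [writePartitionText] for 1-based reporting).
#'
#' @param blocks named list of named character vectors (locus -> sample ->
#'   aligned sequence).
#' @param samples sample universe; defaults to the union over all blocks.
#' @param fill single fill character for missing (sample, locus) cells.
#' @return a [MultiLocusAlignment].
#' @export
concatenateLoci <- function(blocks, samples = NULL, fill = "N") {
  if (is.null(names(blocks)) || any(names(blocks) == ""))
    .stopf("blocks must be a named list (locus names)")
  if (nchar(fill) != 1L) .stopf("'fill' must be a single character")
  for (loc in names(blocks)) {
    b <- blocks[[loc]]
    if (length(b)) {
      if (is.null(names(b)) || any(names(b) == ""))
        .stopf("sequences in locus '%s' must be named by sample", loc)
      if (anyDuplicated(names(b)))
        .stopf("duplicate sample within locus '%s': %s", loc,
               names(b)[duplicated(names(b))][1])
      if (length(unique(nchar(b))) != 1L)
        .stopf("unequal sequence lengths within locus '%s'", loc)
    }
  }
  if (is.null(samples))
    samples <- sort(unique(unlist(lapply(blocks, names), use.names = FALSE)))
  lens <- vapply(blocks, function(b) if (length(b)) nchar(b[[1]]) else 0L,
                 numeric(1))
  if (any(lens == 0L))
    .stopf("empty locus block(s): %s",
           paste(names(blocks)[lens == 0L], collapse = ", "))
  end <- as.integer(cumsum(lens))
  start <- c(0L, end[-length(end)])
  new("MultiLocusAlignment",
      loci = names(blocks), blocks = blocks,
      partition = data.frame(locus = names(blocks), start = start, end = end,
                             stringsAsFactors = FALSE),
      samples = samples, fill = fill)
}

#' Slice one locus back out of a concatenation
#'
#' @param mla a [MultiLocusAlignment].
#' @param locus locus id.
#' @return named character vector restricted to samples that carried the
#'   locus (padding removed).
#' @export
sliceLocus <- function(mla, locus) {
  stopifnot(is(mla, "MultiLocusAlignment"))
  i <- match(locus, mla@loci)
  if (is.na(i)) .stopf("unknown locus '%s'", locus)
  concat <- concatenatedSequences(mla)
  p <- mla@partition[i, ]
  out <- substr(concat, p$start + 1L, p$end)
  out[names(out) %in% names(mla@blocks[[locus]])]
}

#' Count total and variable alignment sites
#'
#' A site is variable iff at least two distinct unambiguous bases (A/C/G/T)
#' occur in its column; gaps, N and IUPAC ambiguity codes are ignored for the
#' distinctness test, so a column of `A` against `R` is not counted.
#'
#' @param seqs character vector of equal-length aligned sequences.
#' @return named integer vector: `total` sites and `variable` sites.
#' @export
#' @examples
#' countVariableSites(c("AAT", "AAA", "AAA"))  # total 3, variable 1
countVariableSites <- function(seqs) {
  if (length(seqs) == 0L) return(c(total = 0L, variable = 0L))
  m <- .seqMatrix(toupper(seqs))
  nDistinct <- apply(m, 2L, function(col) {
    length(unique(col[col %in% c("A", "C", "G", "T")]))
  })
  c(total = ncol(m), variable = sum(nDistinct >= 2L))
}

#' Write a RAxML-style partition map
#'
#' One line per locus in the form `DNA, locus = start-end` with 1-based
#' inclusive coordinates, for interoperability with external ML tools.
#'
#' @param mla a [MultiLocusAlignment].
#' @param path output file path.
#' @return invisibly, the lines written.
#' @export
writePartitionText <- function(mla, path) {
  stopifnot(is(mla, "MultiLocusAlignment"))
  p <- mla@partition
  lines <- sprintf("DNA, %s = %d-%d", p$locus, p$start + 1L, p$end)
  writeLines(lines, path)
  invisible(lines)
}

#' FASTA I/O for aligned sequence sets
#'
#' Thin wrappers over Biostrings keeping the package's named-character-vector
#' convention for aligned blocks.
#'
#' @param path FASTA file path.
#' @param seqs named character vector of sequences.
#' @return `readFastaSequences` returns a named character vector;
#'   `writeFastaSequences` invisibly returns `path`.
#' @export
readFastaSequences <- function(path) {
  if (!file.exists(path)) .stopf("no such file: '%s'", path)
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' @rdname readFastaSequences
#' @export
writeFastaSequences <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unname(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
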