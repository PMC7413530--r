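#' @import methods
#' @importFrom stats runif rbinom rpois rmultinom setNames ks.test optimize
#' @importFrom utils read.delim write.table head
NULL

# Allowed residue alphabet for read tables and alignments.
.DNA_CHARS <- c("A", "C", "G", "T", "-", "N")

# IUPAC ambiguity codes keyed by the sorted set of unambiguous bases they cover.
.IUPAC_FROM_SET <- c(
  "A" = "A", "C" = "C", "G" = "G", "T" = "T",
  "AC" = "M", "AG" = "R", "AT" = "W", "CG" = "S", "CT" = "Y", "GT" = "K",
  "ACG" = "V", "ACT" = "H", "AGT" = "D", "CGT" = "B", "ACGT" = "N"
)

# 4-bit base masks (A=1, C=2, G=4, T=8) for every residue code we accept.
.BASE_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L,
  N = 15L, `-` = 15L, `?` = 15L
)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.checkFraction <- function(x, name, lo = 0, hi = 1, loOpen = FALSE, hiOpen = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    .stopf("'%s' must be a single non-missing number", name)
  okLo <- if (loOpen) x > lo else x >= lo
  okHi <- if (hiOpen) x < hi else x <= hi
  if (!okLo || !okHi)
    .stopf("'%s' must lie in %s%g, %g%s (got %g)", name,
           if (loOpen) "(" else "[", lo, hi, if (hiOpen) ")" else "]", x)
  invisible(x)
}

.checkCount <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    .stopf("'%s' must be an integer >= %d (got %s)", name, min, format(x))
  as.integer(x)
}

# Split sequences into a character matrix (rows = sequences, cols = positions).
.seqMatrix <- function(seqs) {
  if (length(seqs) == 0L)
    return(matrix(character(0), nrow = 0, ncol = 0))
  n <- unique(nchar(seqs))
  if (length(n) != 1L)
    .stopf("sequences have unequal lengths (%s)", paste(sort(n), collapse = ", "))
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(seqs), ncol = n, byrow = TRUE)
  rownames(m) <- names(seqs)
  m
}

.collapseRows <- function(m) {
  if (nrow(m) == 0L) return(character(0))
  setNames(apply(m, 1L, paste, collapse = ""), rownames(m))
}

.validateSequences <- function(seqs, where = "sequence") {
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad))
    .stopf("invalid characters in %s: %s", where,
           paste(head(seqs[bad], 3L), collapse = ", "))
  invisible(seqs)
}

# Proportion of differing positions between two equal-length sequences,
# counting only positions where both carry an unambiguous base.
.hammingProp <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  if (!any(ok)) return(NA_real_)
  mean(x[ok] != y[ok])
}

# Jukes-Cantor mutation of a sequence: expected substitutions/site `d` are
# converted to the per-site probability of observing a different base.
.jcMutate <- function(seq, d) {
  if (d <= 0) return(seq)
  p <- 0.75 * (1 - exp(-4 * d / 3))
  bases <- strsplit(seq, "")[[1]]
  hit <- runif(length(bases)) < p
  if (any(hit)) {
    alt <- vapply(bases[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1))
    bases[hit] <- alt
  }
  paste(bases, collapse = "")
}

.randomSequence <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Symmetric zero-diagonal check used wherever a DistanceMatrix is consumed.
.checkDistanceMatrix <- function(d, name = "distance matrix") {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    .stopf("'%s' must be a square matrix", name)
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d)))
    .stopf("'%s' must carry identical row and column labels", name)
  if (any(d < 0)) .stopf("'%s' has negative entries", name)
  if (max(abs(d - t(d))) > 1e-8) .stopf("'%s' is not symmetric", name)
  if (any(abs(diag(d)) > 1e-12)) .stopf("'%s' has a non-zero diagonal", name)
  invisible(d)
}
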