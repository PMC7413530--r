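#' Newick tree I/O
#'
#' Thin wrappers over ape preserving topology, branch lengths and labels
#' through a round-trip. `readNewick` accepts a file path or a literal
#' newick string.
#'
#' @param x newick text (or a path to a newick file).
#' @param tree an ape `phylo` object.
#' @param path optional output path for `writeNewick`; when NULL the newick
#'   string is returned.
#' @param digits significant digits for branch lengths on output.
#' @return `readNewick`: a `phylo`; `writeNewick`: the newick string
#'   (invisibly when written to a file).
#' @export
readNewick <- function(x) {
  txt <- if (length(x) == 1L && !grepl("[(;]", x) && file.exists(x))
    paste(readLines(x), collapse = "") else x
  tr <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL)
  if (is.null(tr) || is.null(tr$tip.label)) {
    # locate the first structurally unbalanced position for the error message
    opens <- cumsum((strsplit(txt, "")[[1]] == "(") -
                      (strsplit(txt, "")[[1]] == ")"))
    pos <- which(opens < 0)[1]
    if (is.na(pos)) pos <- nchar(txt)
    .stopf("malformed newick near position %d: ...%s", pos,
           substr(txt, max(1, pos - 10), min(nchar(txt), pos + 5)))
  }
  tr
}

#' @rdname readNewick
#' @export
writeNewick <- function(tree, path = NULL, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (via ape), provided as desk-scale
#' plumbing where an externally inferred maximum-likelihood tree is not
#' supplied. Negative estimated branch lengths are clamped to zero with a
#' warning, since downstream branch-length models require non-negative
#' lengths.
#'
#' @param d a symmetric zero-diagonal distance matrix with labels.
#' @return an unrooted `phylo`.
#' @export
njTree <- function(d) {
  .checkDistanceMatrix(d)
  if (nrow(d) < 3L) .stopf("neighbor-joining needs at least 3 labels (got %d)",
                           nrow(d))
  tr <- ape::nj(as.dist(d))
  if (any(tr$edge.length < 0)) {
    .warnf("clamped %d negative branch length(s) to 0",
           sum(tr$edge.length < 0))
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Patristic distances between all tips
#'
#' Entry (i, j) is the sum of branch lengths along the unique tree path from
#' tip i to tip j.
#'
#' @param tree a `phylo` with branch lengths.
#' @return a symmetric labelled distance matrix.
#' @export
patristicDistances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) .stopf("tree has no branch lengths")
  d <- ape::cophenetic.phylo(tree)
  d <- d[tree$tip.label, tree$tip.label]
  d
}

#' Remove outgroup tips from a tree
#'
#' Drops the named tips and suppresses the resulting degree-2 nodes, summing
#' their branch lengths, so the ingroup tree is ready for branch-length-based
#' delimitation.
#'
#' @param tree a `phylo`.
#' @param labels tip labels to remove (may be empty: identity).
#' @return the pruned `phylo`.
#' @export
pruneOutgroup <- function(tree, labels) {
  stopifnot(inherits(tree, "phylo"))
  if (length(labels) == 0L) return(tree)
  unknown <- setdiff(labels, tree$tip.label)
  if (length(unknown))
    .stopf("unknown tip label(s): %s", paste(unknown, collapse = ", "))
  if (length(tree$tip.label) - length(labels) < 2L)
    .stopf("pruning would leave fewer than 2 tips")
  ape::drop.tip(tree, labels, collapse.singles = TRUE)
}

#' Group-wise patristic distance summary
#'
#' Minimum, maximum and mean patristic distance between (and within) groups
#' of tips — the usual way inter-clade distance ranges are reported.
#'
#' @param tree a `phylo` with branch lengths.
#' @param groups named character/factor vector: tip label -> group.
#' @return data.frame with columns group1, group2, min, max, mean.
#' @export
groupDistanceSummary <- function(tree, groups) {
  d <- patristicDistances(tree)
  tips <- intersect(rownames(d), names(groups))
  g <- as.character(groups[tips])
  lv <- sort(unique(g))
  out <- list()
  for (i in seq_along(lv)) for (j in i:length(lv)) {
    ri <- tips[g == lv[i]]; rj <- tips[g == lv[j]]
    v <- d[ri, rj, drop = FALSE]
    if (i == j) {
      if (length(ri) < 2) next
      v <- v[upper.tri(v)]
    }
    out[[length(out) + 1L]] <- data.frame(
      group1 = lv[i], group2 = lv[j], min = min(v), max = max(v),
      mean = mean(v), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Congruence among distance matrices (CADM)
#'
#' Kendall's coefficient of concordance W computed over the rank-transformed
#' unfolded upper triangles of two or more distance matrices over the same
#' labels, with Friedman's chi-square and a permutation p-value. Under the
#' null of incongruence, the labels of every matrix except the first are
#' permuted independently; the p-value follows the add-one convention
#' p = (exceedances + 1)/(nPerm + 1), so its minimum attainable value is
#' 1/(nPerm + 1). Ranks use midranks for ties with the standard tie
#' correction, so two identical matrices give exactly W = 1 and W is bounded
#' below by 1/k for k matrices.
#'
#' @param matrices list of >= 2 labelled distance matrices over identical
#'   label sets (any order; rows/columns are aligned by label).
#' @param nPerm number of permutations.
#' @param seed integer random seed.
#' @return list with `W`, `chi2`, `p`, `nPerm`.
#' @export
cadmGlobal <- function(matrices, nPerm = 999, seed = 1L) {
  if (!is.list(matrices) || length(matrices) < 2L)
    .stopf("need at least two distance matrices")
  labs <- rownames(matrices[[1]])
  for (i in seq_along(matrices)) {
    .checkDistanceMatrix(matrices[[i]], sprintf("matrix %d", i))
    if (!setequal(rownames(matrices[[i]]), labs))
      .stopf("matrix %d has a different label set", i)
    matrices[[i]] <- matrices[[i]][labs, labs]
  }
  nPerm <- .checkCount(nPerm, "nPerm")
  n <- length(labs)
  ut <- upper.tri(matrix(0, n, n))

  unfold <- function(mats) vapply(mats, function(m) m[ut], numeric(sum(ut)))
  Wobs <- .kendallW(unfold(matrices))
  k <- length(matrices)
  p_obj <- sum(ut)
  chi2 <- k * (p_obj - 1) * Wobs

  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(nPerm)) {
    perm <- matrices
    for (i in 2:k) {
      o <- sample.int(n)
      perm[[i]] <- perm[[i]][o, o]
    }
    if (.kendallW(unfold(perm)) >= Wobs) exceed <- exceed + 1L
  }
  list(W = Wobs, chi2 = chi2, p = (exceed + 1) / (nPerm + 1), nPerm = nPerm)
}

# Kendall's W with tie correction; columns of `x` are the k judges (matrices),
# rows the p objects (unfolded tip pairs).
.kendallW <- function(x) {
  p <- nrow(x); k <- ncol(x)
  ranks <- apply(x, 2L, rank)
  R <- rowSums(ranks)
  S <- sum((R - mean(R))^2)
  Tcorr <- sum(apply(ranks, 2L, function(r) {
    t <- table(r); sum(t^3 - t)
  }))
  denom <- k^2 * (p^3 - p) / 12 - k * Tcorr / 12
  if (denom <= 0) return(1)
  S / denom
}

#' Pairwise CADM tests
#'
#' Runs [cadmGlobal] for every pair of matrices, the usual follow-up when a
#' global test rejects.
#'
#' @inheritParams cadmGlobal
#' @param names optional matrix names.
#' @return data.frame with one row per pair: name1, name2, W, chi2, p.
#' @export
cadmPairwise <- function(matrices, nPerm = 999, seed = 1L, names = NULL) {
  k <- length(matrices)
  if (is.null(names)) names <- paste0("m", seq_len(k))
  out <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    r <- cadmGlobal(matrices[c(i, j)], nPerm = nPerm,
                    seed = seed + i * 131L + j)
    out[[length(out) + 1L]] <- data.frame(
      name1 = names[i], name2 = names[j], W = r$W, chi2 = r$chi2, p = r$p,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write a labelled distance matrix as square TSV
#'
#' @param d labelled distance matrix.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeDistanceMatrixTsv <- function(d, path) {
  .checkDistanceMatrix(d)
  df <- data.frame(label = rownames(d), d, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDistanceMatrixTsv
#' @export
readDistanceMatrixTsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  .checkDistanceMatrix(m)
  m
}
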