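# Jukes-Cantor transition probability matrix for branch length t
# (expected substitutions/site).
.jcP <- function(t) {
  e <- exp(-4 * t / 3)
  m <- matrix(0.25 - 0.25 * e, 4, 4)
  diag(m) <- 0.25 + 0.75 * e
  m
}

# Encode a sequence into a 4 x L partial-likelihood matrix via 4-bit base
# masks; '-', 'N' and '?' give all-ones columns, so missing data contributes
# likelihood 1. IUPAC ambiguity codes become the union of their bases.
.encodePartials <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  mask <- .BASE_MASK[chars]
  if (anyNA(mask))
    .stopf("unknown residue '%s' in sequence", chars[which(is.na(mask))[1]])
  rbind(A = as.numeric(bitwAnd(mask, 1L) > 0),
        C = as.numeric(bitwAnd(mask, 2L) > 0),
        G = as.numeric(bitwAnd(mask, 4L) > 0),
        T = as.numeric(bitwAnd(mask, 8L) > 0))
}

# Two-pass pruning engine for a fixed reference tree + alignment. For every
# edge it holds the conditional likelihood of the subtree below the edge
# ("down", at the child end) and of everything outside it ("up", at the
# parent end). JC is time-reversible with uniform base frequencies, so the
# orientation of P(t) is immaterial and any placement can be scored at the
# attachment point from these two vectors plus the query partials.
.placementEngine <- function(tree, align) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) .stopf("reference tree has no branch lengths")
  miss <- setdiff(tree$tip.label, names(align))
  if (length(miss))
    .stopf("reference tip(s) absent from the alignment: %s",
           paste(miss, collapse = ", "))
  L <- unique(nchar(align[tree$tip.label]))
  if (length(L) != 1L) .stopf("alignment sequences have unequal lengths")

  tr <- ape::reorder.phylo(tree, "postorder")
  nTip <- length(tr$tip.label)
  edge <- tr$edge
  nEdge <- nrow(edge)
  elen <- pmax(tr$edge.length, 1e-9)
  root <- setdiff(edge[, 1], edge[, 2])[1]
  Pmats <- lapply(elen, .jcP)

  down <- vector("list", nTip + tr$Nnode)
  for (i in seq_len(nTip)) down[[i]] <- .encodePartials(align[[tr$tip.label[i]]])
  for (e in seq_len(nEdge)) {
    par <- edge[e, 1]; chi <- edge[e, 2]
    contrib <- Pmats[[e]] %*% down[[chi]]
    down[[par]] <- if (is.null(down[[par]])) contrib else down[[par]] * contrib
  }

  upNode <- vector("list", nTip + tr$Nnode)
  upNode[[root]] <- matrix(1, 4, L)
  upEdge <- vector("list", nEdge)
  childEdges <- split(seq_len(nEdge), edge[, 1])
  for (e in rev(seq_len(nEdge))) {               # preorder over edges
    par <- edge[e, 1]; chi <- edge[e, 2]
    out <- upNode[[par]]
    for (se in setdiff(childEdges[[as.character(par)]], e))
      out <- out * (Pmats[[se]] %*% down[[edge[se, 2]]])
    upEdge[[e]] <- out
    if (chi > nTip) upNode[[chi]] <- Pmats[[e]] %*% out
  }

  refKey <- apply(vapply(seq_len(nTip), function(i)
    colSums(down[[i]] * c(1, 2, 4, 8)), numeric(L)), 1L, paste, collapse = ",")

  # edge rows are permuted by the postorder pass; translate caller-facing
  # indices (rows of the input tree's edge matrix) via the child node, which
  # identifies an edge uniquely
  orig2post <- match(tree$edge[, 2], edge[, 2])

  list(tree = tree, edge = edge, elen = elen, root = root, nTip = nTip, L = L,
       down = down, upEdge = upEdge, refKey = refKey, orig2post = orig2post,
       logLref = sum(log(colSums(down[[root]]) / 4)))
}

# Log-likelihood of the full tree with the query attached to `edgeIdx` at
# `position` (fraction of the edge length measured from the parent end) by a
# pendant branch of length `pendant`. `qp`, `w`, `cols` allow pre-compressed
# site patterns.
.attachLoglik <- function(eng, qp, edgeIdx, pendant, position, w = NULL,
                          cols = NULL) {
  edgeIdx <- eng$orig2post[edgeIdx]
  t <- eng$elen[edgeIdx]
  a <- position * t
  b <- t - a
  up <- eng$upEdge[[edgeIdx]]
  dn <- eng$down[[eng$edge[edgeIdx, 2]]]
  if (!is.null(cols)) { up <- up[, cols, drop = FALSE]; dn <- dn[, cols, drop = FALSE] }
  siteL <- colSums((.jcP(a) %*% up) * (.jcP(b) %*% dn) *
                     (.jcP(pendant) %*% qp)) / 4
  if (is.null(w)) sum(log(siteL)) else sum(log(siteL) * w)
}

#' Log-likelihood of one fixed query attachment
#'
#' Scores the tree obtained by attaching `query` to branch `edge` of the
#' reference tree at a fixed pendant length and attachment position, under
#' Jukes-Cantor with the pruning algorithm (columns where the query carries
#' '-'/'N' contribute likelihood 1). Exposed so placements can be verified
#' against independent implementations at matched attachment parameters.
#'
#' @param refTree reference `phylo` with branch lengths.
#' @param refAlign named character vector of aligned reference sequences.
#' @param query aligned query sequence (same column coordinates).
#' @param edge row index into `refTree$edge` of the attachment branch.
#' @param pendant pendant branch length.
#' @param position attachment point as a fraction of the branch length from
#'   the parent end (0.5 = midpoint).
#' @return the log-likelihood (a single number).
#' @export
attachmentLoglik <- function(refTree, refAlign, query, edge, pendant,
                             position = 0.5) {
  eng <- .placementEngine(refTree, refAlign)
  if (nchar(query) != eng$L)
    .stopf("query length %d != alignment length %d", nchar(query), eng$L)
  .checkFraction(position, "position")
  qp <- .encodePartials(query)
  .attachLoglik(eng, qp, edge, pendant, position)
}

#' Place a query sequence on a reference tree (EPA style)
#'
#' Attaches the query to every branch of the reference tree by a pendant
#' branch and reports per-edge log-likelihoods under Jukes-Cantor, computed
#' with the pruning algorithm; alignment columns absent from the query
#' ('-'/'N') are treated as missing data and contribute likelihood 1, so a
#' short query (e.g. one spacer region of a multi-locus concatenation) is
#' placed on its informative columns only. Per edge, the pendant length is
#' optimised on a coarse log-spaced grid (20 points, 1e-6 to 1) followed by
#' golden-section refinement, and the attachment position along the branch is
#' refined the same way. Likelihood weight ratios are the softmax of the
#' per-edge log-likelihoods. A query with no informative overlap at all is
#' returned as explicitly unplaceable rather than given an arbitrary edge.
#'
#' @param refTree reference `phylo` with branch lengths (tips must appear in
#'   `refAlign`).
#' @param refAlign named character vector of aligned reference sequences.
#' @param query aligned query sequence (same column coordinates).
#' @param queryLabel label carried into the result.
#' @param model substitution model tag; only `"JC"` is implemented.
#' @param optimizePosition also optimise the attachment point (default TRUE).
#' @return a [PlacementResult].
#' @export
placeQuery <- function(refTree, refAlign, query, queryLabel = "query",
                       model = "JC", optimizePosition = TRUE) {
  if (!identical(model, "JC"))
    .stopf("substitution model '%s' not implemented (only 'JC')", model)
  eng <- .placementEngine(refTree, refAlign)
  if (nchar(query) != eng$L)
    .stopf("query length %d != alignment length %d", nchar(query), eng$L)
  qpFull <- .encodePartials(query)

  informative <- colSums(qpFull) < 4
  if (!any(informative))
    return(new("PlacementResult", query = queryLabel, tree = eng$tree,
               edges = data.frame(edge = integer(0), loglik = numeric(0),
                                  lwr = numeric(0), pendant = numeric(0),
                                  position = numeric(0)),
               bestEdge = NA_integer_, placeable = FALSE))

  # compress to site patterns unique over (reference column, query residue)
  key <- paste(eng$refKey, colSums(qpFull * c(1, 2, 4, 8)), sep = "|")
  first <- !duplicated(key)
  w <- as.vector(table(factor(key, levels = key[first])))
  cols <- which(first)
  qp <- qpFull[, cols, drop = FALSE]

  grid <- exp(seq(log(1e-6), log(1), length.out = 20))
  nEdge <- nrow(eng$edge)
  res <- data.frame(edge = seq_len(nEdge), loglik = NA_real_,
                    lwr = NA_real_, pendant = NA_real_, position = NA_real_)
  for (e in seq_len(nEdge)) {
    f <- function(p, pos) .attachLoglik(eng, qp, e, p, pos, w, cols)
    pos <- 0.5
    ll <- vapply(grid, f, numeric(1), pos = pos)
    i <- which.max(ll)
    lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
    op <- optimize(f, c(lo, hi), pos = pos, maximum = TRUE, tol = 1e-6)
    pend <- op$maximum; best <- op$objective
    if (optimizePosition && eng$elen[e] > 1e-8) {
      og <- optimize(function(x) f(pend, x), c(0, 1), maximum = TRUE,
                     tol = 1e-6)
      if (og$objective > best) { pos <- og$maximum; best <- og$objective }
      op <- optimize(f, c(1e-9, 1), pos = pos, maximum = TRUE, tol = 1e-6)
      if (op$objective > best) { pend <- op$maximum; best <- op$objective }
    }
    res$loglik[e] <- best; res$pendant[e] <- pend; res$position[e] <- pos
  }
  rel <- exp(res$loglik - max(res$loglik))
  res$lwr <- rel / sum(rel)
  new("PlacementResult", query = queryLabel, tree = eng$tree, edges = res,
      bestEdge = res$edge[which.max(res$loglik)], placeable = TRUE)
}

# Newick string with jplace-style {edge_num} tags after each branch length.
# Edge numbers are the row indices of tree$edge.
.jplaceTreeString <- function(tree) {
  edge <- tree$edge
  nTip <- length(tree$tip.label)
  root <- setdiff(edge[, 1], edge[, 2])[1]
  edgeOf <- integer(max(edge))
  edgeOf[edge[, 2]] <- seq_len(nrow(edge))
  children <- split(edge[, 2], edge[, 1])
  fmt <- function(node) {
    lab <- if (node <= nTip) tree$tip.label[node] else ""
    inner <- if (node > nTip)
      paste0("(", paste(vapply(children[[as.character(node)]], fmt,
                               character(1)), collapse = ","), ")")
    else ""
    core <- paste0(inner, lab)
    if (node == root) return(core)
    e <- edgeOf[node]
    sprintf("%s:%.10g{%d}", core, tree$edge.length[e], e)
  }
  paste0(fmt(root), ";")
}

#' Write placements as a jplace file
#'
#' Emits the standard jplace JSON (version 3): the reference tree with
#' `{edge_num}` tags keyed to the edge indices used by [placeQuery], and one
#' placement record per query with `edge_num`, `likelihood`,
#' `like_weight_ratio`, `distal_length` and `pendant_length`. A TSV summary
#' of best placements is written alongside when `tsvPath` is given.
#'
#' @param placements list of [PlacementResult] objects over the same tree.
#' @param path output jplace path.
#' @param tsvPath optional TSV summary path.
#' @param topN edges reported per query (most likely first).
#' @return invisibly, `path`.
#' @export
writeJplace <- function(placements, path, tsvPath = NULL, topN = 7L) {
  if (is(placements, "PlacementResult")) placements <- list(placements)
  placements <- Filter(function(p) p@placeable, placements)
  if (!length(placements)) .stopf("no placeable queries to write")
  tree <- placements[[1]]@tree
  precs <- lapply(placements, function(pr) {
    e <- pr@edges[order(-pr@edges$loglik), ][seq_len(min(topN, nrow(pr@edges))), ]
    elen <- tree$edge.length[e$edge]
    list(p = lapply(seq_len(nrow(e)), function(i)
      list(e$edge[i], e$loglik[i], e$lwr[i],
           unname(e$position[i] * elen[i]), e$pendant[i])),
      n = list(pr@query))
  })
  obj <- list(
    version = 3L,
    tree = .jplaceTreeString(tree),
    placements = precs,
    fields = list("edge_num", "likelihood", "like_weight_ratio",
                  "distal_length", "pendant_length"),
    metadata = list(invocation = "mycodelim::placeQuery"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(tsvPath)) {
    tab <- do.call(rbind, lapply(placements, function(pr) {
      b <- pr@edges[match(pr@bestEdge, pr@edges$edge), ]
      data.frame(query = pr@query, best_edge = b$edge, loglik = b$loglik,
                 lwr = b$lwr, pendant = b$pendant, position = b$position,
                 stringsAsFactors = FALSE)
    }))
    write.table(tab, tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
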