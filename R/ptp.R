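# Shared tree bookkeeping for the Poisson tree processes model. Branch
# lengths are floored (default 1e-8) before rate estimation because the
# exponential density is undefined at scale zero.
.ptpPrep <- function(tree, lengthFloor = 1e-8) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) .stopf("tree has no branch lengths")
  if (!ape::is.rooted(tree))
    .stopf("tree is unrooted; root it first (e.g. midpoint or outgroup rooting)")
  nTip <- length(tree$tip.label)
  edge <- tree$edge
  elen <- pmax(tree$edge.length, lengthFloor)
  parent <- integer(nTip + tree$Nnode)
  edgeTo <- integer(nTip + tree$Nnode)          # edge index whose child is node
  parent[edge[, 2]] <- edge[, 1]
  edgeTo[edge[, 2]] <- seq_len(nrow(edge))
  root <- setdiff(edge[, 1], edge[, 2])[1]
  children <- split(edge[, 2], edge[, 1])
  list(tree = tree, nTip = nTip, edge = edge, elen = elen, root = root,
       parent = parent, edgeTo = edgeTo, children = children)
}

# Edge classification for a species-root set: the edge into node v is
# between-species ("speciation") iff v is a species root or an ancestor of
# one; edges strictly inside a species are within-species ("coalescent").
# Returns a logical vector over edges, TRUE = speciation.
.edgeClasses <- function(prep, roots) {
  anc <- logical(prep$nTip + prep$tree$Nnode)    # ancestor-of-root (strict)
  for (r in roots) {
    v <- prep$parent[r]
    while (v != 0L && !anc[v]) { anc[v] <- TRUE; v <- prep$parent[v] }
  }
  isRoot <- logical(length(anc)); isRoot[roots] <- TRUE
  isRoot[prep$edge[, 2]] | anc[prep$edge[, 2]]
}

# Validate that `roots` partitions the tips: every tip has exactly one
# ancestor-or-self in the set.
.checkRoots <- function(prep, roots) {
  count <- integer(prep$nTip)
  isRoot <- logical(prep$nTip + prep$tree$Nnode); isRoot[roots] <- TRUE
  for (tip in seq_len(prep$nTip)) {
    v <- tip
    while (v != 0L) { if (isRoot[v]) count[tip] <- count[tip] + 1L
      v <- prep$parent[v] }
  }
  if (any(count != 1L))
    .stopf("inconsistent delimitation: tip '%s' is covered by %d species roots",
           prep$tree$tip.label[which(count != 1L)[1]],
           count[which(count != 1L)[1]])
  invisible(TRUE)
}

# Class log-likelihood at the profiled exponential MLE rate lambda = n/L:
# n*log(n/L) - n. An empty class contributes 0.
.classLoglik <- function(n, L) if (n == 0L) 0 else n * log(n / L) - n

#' Poisson tree processes log-likelihood of a delimitation
#'
#' Branch lengths are modelled as exponential draws with one rate per branch
#' class — between-species (speciation) and within-species (coalescent) —
#' and each class rate is profiled out at its maximum-likelihood estimate
#' (class count / class length sum). The delimitation is given as the set of
#' species-root nodes; the branch into a species root, and every branch
#' above it, is in the speciation class, branches inside a species in the
#' coalescent class. With the whole tree a single species (root set =
#' `{root}`) all branches form one class: the one-rate null model.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param speciesRoots integer node numbers forming a consistent partition of
#'   the tips (every tip has exactly one ancestor-or-self in the set).
#' @param lengthFloor floor applied to branch lengths before rate estimation.
#' @return the log-likelihood (single number), with attributes `rates`
#'   (lambdaSp, lambdaCoal) and `classes` (speciation edge count, coalescent
#'   edge count).
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((a:1,b:1):4,c:4);")
#' ptpLoglik(tr, speciesRoots = length(tr$tip.label) + 1L)  # one species
ptpLoglik <- function(tree, speciesRoots, lengthFloor = 1e-8) {
  prep <- .ptpPrep(tree, lengthFloor)
  roots <- as.integer(speciesRoots)
  .checkRoots(prep, roots)
  sp <- .edgeClasses(prep, roots)
  nS <- sum(sp); nC <- sum(!sp)
  LS <- sum(prep$elen[sp]); LC <- sum(prep$elen[!sp])
  ll <- .classLoglik(nS, LS) + .classLoglik(nC, LC)
  attr(ll, "rates") <- c(lambdaSp = if (nS) nS / LS else NA_real_,
                         lambdaCoal = if (nC) nC / LC else NA_real_)
  attr(ll, "classes") <- c(speciation = nS, coalescent = nC)
  ll
}

# Enumerate every species-root set of the subtree rooted at `node`:
# either the node roots one species, or (if internal) every combination of
# partitions of its child subtrees.
.enumRootSets <- function(prep, node) {
  out <- list(node)
  if (node > prep$nTip) {
    kids <- prep$children[[as.character(node)]]
    combos <- list(integer(0))
    for (k in kids) {
      sub <- .enumRootSets(prep, k)
      combos <- unlist(lapply(combos, function(c0)
        lapply(sub, function(s) c(c0, s))), recursive = FALSE)
    }
    out <- c(out, combos)
  }
  out
}

.delimitationFromRoots <- function(prep, roots, ll) {
  assign <- integer(prep$nTip)
  names(assign) <- prep$tree$tip.label
  isRoot <- logical(prep$nTip + prep$tree$Nnode)
  isRoot[roots] <- TRUE
  id <- setNames(seq_along(roots), as.character(sort(roots)))
  for (tip in seq_len(prep$nTip)) {
    v <- tip
    while (!isRoot[v]) v <- prep$parent[v]
    assign[tip] <- id[[as.character(v)]]
  }
  new("Delimitation", tree = prep$tree, speciesRoots = sort(as.integer(roots)),
      assignment = assign, logLik = as.numeric(ll),
      rates = attr(ll, "rates"))
}

#' Maximum-likelihood PTP delimitation
#'
#' For trees of at most `exhaustiveMax` tips every consistent delimitation
#' is enumerated and the optimum is exact. Larger trees are searched by
#' recursive greedy splitting from the root followed by hill climbing over
#' single-node moves (split one species root into its children / merge a
#' node whose children are all species roots). Likelihood ties are broken
#' toward fewer species — the conservative, lumping choice, which also
#' resolves the degenerate equal-branch-length case to the single-species
#' null. A tree whose branches are all at the length floor returns the null
#' with a warning.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param exhaustiveMax tip count up to which enumeration is exact.
#' @param lengthFloor floor applied to branch lengths.
#' @return a [Delimitation].
#' @export
mlPtp <- function(tree, exhaustiveMax = 12L, lengthFloor = 1e-8) {
  prep <- .ptpPrep(tree, lengthFloor)
  if (prep$nTip < 2L) .stopf("need at least 2 tips")
  score <- function(roots) ptpLoglik(tree, roots, lengthFloor)
  if (all(prep$elen <= lengthFloor)) {
    .warnf("all branch lengths are at the floor; returning the single-species null")
    return(.delimitationFromRoots(prep, prep$root, score(prep$root)))
  }
  if (prep$nTip <= exhaustiveMax) {
    sets <- .enumRootSets(prep, prep$root)
    lls <- vapply(sets, function(s) as.numeric(score(s)), numeric(1))
    best <- max(lls)
    cand <- which(lls >= best - 1e-9)
    sizes <- lengths(sets[cand])
    pick <- cand[order(sizes, vapply(sets[cand], function(s)
      paste(sort(s), collapse = ","), character(1)))][1]
    return(.delimitationFromRoots(prep, sets[[pick]], score(sets[[pick]])))
  }
  # steepest-ascent hill climbing over single-node split/merge moves from
  # several starts: the lumped null, the fully split state, and one
  # recursive top-down greedy dissection
  climb <- function(roots) {
    repeat {
      bestLl <- as.numeric(score(roots)); bestRoots <- roots
      improved <- FALSE
      for (r in roots) {
        if (r <= prep$nTip) next
        cand <- c(setdiff(roots, r), prep$children[[as.character(r)]])
        ll <- as.numeric(score(cand))
        if (ll > bestLl + 1e-9) { bestLl <- ll; bestRoots <- cand; improved <- TRUE }
      }
      isRoot <- logical(prep$nTip + prep$tree$Nnode); isRoot[roots] <- TRUE
      for (u in (prep$nTip + 1L):(prep$nTip + prep$tree$Nnode)) {
        kids <- prep$children[[as.character(u)]]
        if (!all(isRoot[kids])) next
        cand <- c(setdiff(roots, kids), u)
        ll <- as.numeric(score(cand))
        if (ll > bestLl + 1e-9) { bestLl <- ll; bestRoots <- cand; improved <- TRUE }
      }
      if (!improved) return(roots)
      roots <- bestRoots
    }
  }
  greedyDissect <- function() {
    roots <- prep$root
    repeat {
      cur <- as.numeric(score(roots))
      gains <- lapply(roots[roots > prep$nTip], function(r)
        c(setdiff(roots, r), prep$children[[as.character(r)]]))
      if (!length(gains)) return(roots)
      lls <- vapply(gains, function(cand) as.numeric(score(cand)), numeric(1))
      if (max(lls) <= cur + 1e-9) return(roots)
      roots <- gains[[which.max(lls)]]
    }
  }
  # a short stochastic exploration (self-seeded; the caller's RNG stream is
  # restored) escapes local optima the deterministic climbs share
  explore <- function(roots, iters = 2000L) {
    hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (hasSeed) oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(if (hasSeed) assign(".Random.seed", oldSeed, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
              rm(".Random.seed", envir = globalenv()))
    set.seed(20201L)
    isRoot <- logical(prep$nTip + prep$tree$Nnode); isRoot[roots] <- TRUE
    cur <- as.numeric(score(roots))
    best <- roots; bestLl <- cur
    internals <- (prep$nTip + 1L):(prep$nTip + prep$tree$Nnode)
    for (i in seq_len(iters)) {
      u <- internals[sample.int(length(internals), 1L)]
      kids <- prep$children[[as.character(u)]]
      if (isRoot[u]) {
        cand <- c(which(isRoot & seq_along(isRoot) != u), kids)
      } else if (all(isRoot[kids])) {
        cand <- c(setdiff(which(isRoot), kids), u)
      } else next
      ll <- as.numeric(score(cand))
      if (ll >= cur || runif(1) < exp(2 * (ll - cur))) {
        isRoot[] <- FALSE; isRoot[cand] <- TRUE; cur <- ll
        if (ll > bestLl + 1e-9) { best <- cand; bestLl <- ll }
      }
    }
    best
  }
  starts <- list(prep$root, seq_len(prep$nTip), greedyDissect())
  sols <- lapply(starts, climb)
  lls <- vapply(sols, function(s) as.numeric(score(s)), numeric(1))
  sols <- c(sols, list(climb(explore(sols[[which.max(lls)]]))))
  lls <- vapply(sols, function(s) as.numeric(score(s)), numeric(1))
  cand <- which(lls >= max(lls) - 1e-9)
  pick <- cand[order(lengths(sols[cand]))][1]      # ties lump
  roots <- sols[[pick]]
  .delimitationFromRoots(prep, roots, score(roots))
}

#' Construct MCMC settings for Bayesian PTP
#'
#' Defaults mirror the study design the package targets: 1,000,000
#' generations, thinning every 1,000, 10% burn-in.
#'
#' @param generations total chain generations.
#' @param thinning sampling interval.
#' @param burnin fraction of generations discarded.
#' @param seed integer random seed.
#' @return a validated [McmcConfig].
#' @export
McmcConfig <- function(generations = 1000000L, thinning = 1000L,
                       burnin = 0.1, seed = 1L) {
  cfg <- new("McmcConfig",
             generations = .checkCount(generations, "generations"),
             thinning = .checkCount(thinning, "thinning"),
             burnin = .checkFraction(burnin, "burnin", hiOpen = TRUE),
             seed = .checkCount(seed, "seed", min = 0))
  validObject(cfg)
  cfg
}

#' Bayesian PTP delimitation by MCMC
#'
#' Metropolis-Hastings over consistent delimitations with a uniform prior.
#' The proposal flips the status of one internal node drawn uniformly: a
#' species root splits into its children; a node whose children are all
#' species roots merges them (any other node leaves the state unchanged, so
#' the kernel is symmetric and the Hastings ratio is 1). Class rates are
#' profiled out inside the likelihood as in [ptpLoglik]. After discarding
#' the burn-in, one sample is retained every `thinning` generations; the
#' posterior support of a candidate species is the fraction of retained
#' samples in which exactly that tip set forms one species (equivalently,
#' in which its crown node is a species root). Any outgroup must be pruned
#' before calling (see [pruneOutgroup]).
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param config a [McmcConfig].
#' @param lengthFloor floor applied to branch lengths.
#' @param supportThreshold report species above this posterior support.
#' @return a [BptpResult].
#' @export
bptp <- function(tree, config = McmcConfig(), lengthFloor = 1e-8,
                 supportThreshold = 0.5) {
  validObject(config)
  prep <- .ptpPrep(tree, lengthFloor)
  nTip <- prep$nTip
  nNode <- nTip + prep$tree$Nnode
  internals <- (nTip + 1L):nNode
  set.seed(config@seed)

  # state: species-root indicator + incremental class sums
  isRoot <- logical(nNode); isRoot[prep$root] <- TRUE
  spEdge <- .edgeClasses(prep, prep$root)
  nS <- sum(spEdge); LS <- sum(prep$elen[spEdge])
  nC <- sum(!spEdge); LC <- sum(prep$elen[!spEdge])
  curLl <- .classLoglik(nS, LS) + .classLoglik(nC, LC)
  nSpecies <- 1L

  gens <- config@generations
  burn <- floor(config@burnin * gens)
  keepGens <- seq.int(burn + config@thinning, gens, by = config@thinning)
  nKeep <- length(keepGens)
  if (nKeep == 0L) .stopf("no retained samples: increase generations or lower thinning")

  rootFreq <- numeric(nNode)
  traceLl <- numeric(nKeep); traceN <- integer(nKeep); traceGen <- integer(nKeep)
  partKeys <- character(nKeep)
  accepted <- 0L
  keepPtr <- 1L
  childList <- prep$children
  edgeToKids <- lapply(seq_len(nNode), function(u) {
    kids <- childList[[as.character(u)]]
    if (is.null(kids)) integer(0) else prep$edgeTo[kids]
  })
  kidNodes <- lapply(seq_len(nNode), function(u) {
    kids <- childList[[as.character(u)]]
    if (is.null(kids)) integer(0) else kids
  })

  pickPool <- internals
  for (g in seq_len(gens)) {
    u <- pickPool[sample.int(length(pickPool), 1L)]
    kids <- kidNodes[[u]]
    move <- if (isRoot[u]) "split" else if (all(isRoot[kids])) "merge" else ""
    if (nzchar(move)) {
      eIdx <- edgeToKids[[u]]
      dL <- sum(prep$elen[eIdx]); dn <- length(eIdx)
      if (move == "split") {
        nS2 <- nS + dn; LS2 <- LS + dL; nC2 <- nC - dn; LC2 <- LC - dL
      } else {
        nS2 <- nS - dn; LS2 <- LS - dL; nC2 <- nC + dn; LC2 <- LC + dL
      }
      newLl <- .classLoglik(nS2, LS2) + .classLoglik(nC2, LC2)
      if (newLl >= curLl || runif(1) < exp(newLl - curLl)) {
        accepted <- accepted + 1L
        nS <- nS2; LS <- LS2; nC <- nC2; LC <- LC2; curLl <- newLl
        if (move == "split") {
          isRoot[u] <- FALSE; isRoot[kids] <- TRUE
          nSpecies <- nSpecies + length(kids) - 1L
        } else {
          isRoot[u] <- TRUE; isRoot[kids] <- FALSE
          nSpecies <- nSpecies - length(kids) + 1L
        }
      }
    }
    if (keepPtr <= nKeep && g == keepGens[keepPtr]) {
      rootFreq <- rootFreq + isRoot
      traceLl[keepPtr] <- curLl; traceN[keepPtr] <- nSpecies
      traceGen[keepPtr] <- g
      partKeys[keepPtr] <- paste(which(isRoot), collapse = ",")
      keepPtr <- keepPtr + 1L
    }
  }

  nodeSupport <- rootFreq / nKeep
  names(nodeSupport) <- as.character(seq_len(nNode))
  tipsBelow <- .tipsBelow(prep)
  supNodes <- which(nodeSupport > supportThreshold)
  supports <- data.frame(
    node = supNodes, support = nodeSupport[supNodes],
    tips = vapply(supNodes, function(v)
      paste(sort(prep$tree$tip.label[tipsBelow[[v]]]), collapse = ","),
      character(1)),
    stringsAsFactors = FALSE)
  supports <- supports[order(-supports$support, supports$node), ]
  rownames(supports) <- NULL

  pf <- as.data.frame(table(partKeys), stringsAsFactors = FALSE)
  names(pf) <- c("key", "count")
  pf$freq <- pf$count / nKeep
  pf$nSpecies <- lengths(strsplit(pf$key, ","))
  pf <- pf[order(-pf$count), c("key", "nSpecies", "freq")]
  rownames(pf) <- NULL

  new("BptpResult", tree = prep$tree, nodeSupport = nodeSupport,
      supports = supports, partitionFreq = pf,
      trace = data.frame(generation = traceGen, logLik = traceLl,
                         nSpecies = traceN),
      acceptanceRate = accepted / gens, config = config)
}

# tip sets below every node (tips below a tip = itself); postorder ensures
# children are filled before their parent
.tipsBelow <- function(prep) {
  nNode <- prep$nTip + prep$tree$Nnode
  out <- vector("list", nNode)
  for (tip in seq_len(prep$nTip)) out[[tip]] <- tip
  for (v in unique(ape::reorder.phylo(prep$tree, "postorder")$edge[, 1])) {
    kids <- prep$children[[as.character(v)]]
    out[[v]] <- sort(unlist(out[kids]))
  }
  out
}

#' Modal delimitation and tip table from a bPTP run
#'
#' @param result a [BptpResult].
#' @return a [Delimitation] for the most frequently sampled partition.
#' @export
modalDelimitation <- function(result) {
  stopifnot(is(result, "BptpResult"))
  prep <- .ptpPrep(result@tree)
  roots <- as.integer(strsplit(result@partitionFreq$key[1], ",")[[1]])
  .delimitationFromRoots(prep, roots, ptpLoglik(result@tree, roots))
}

#' Export a delimitation as a tip table
#'
#' @param delim a [Delimitation].
#' @return data.frame with columns `tip`, `species`.
#' @export
delimitationTable <- function(delim) {
  stopifnot(is(delim, "Delimitation"))
  data.frame(tip = names(delim@assignment), species = unname(delim@assignment),
             stringsAsFactors = FALSE)
}

#' Annotate a tree with bPTP node supports
#'
#' Writes the tree in newick with per-node posterior supports as node labels,
#' the usual way delimitation supports are displayed.
#'
#' @param result a [BptpResult].
#' @param path optional output file.
#' @return the newick string (invisibly when written to file).
#' @export
supportAnnotatedNewick <- function(result, path = NULL) {
  stopifnot(is(result, "BptpResult"))
  tr <- result@tree
  nTip <- length(tr$tip.label)
  tr$node.label <- sprintf("%.3f", result@nodeSupport[(nTip + 1L):length(result@nodeSupport)])
  writeNewick(tr, path)
}

#' MCMC trace as TSV
#'
#' @param result a [BptpResult].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
writeMcmcTrace <- function(result, path) {
  stopifnot(is(result, "BptpResult"))
  write.table(result@trace, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
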