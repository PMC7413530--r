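# Shared fixtures and independent brute-force oracles. Every oracle here
# recomputes its quantity from first principles by a different route than the
# package implementation.

smallParams <- function(...) {
  defaults <- list(nSamplesPerSpecies = 6L, nRegions = 4L,
                   sympatryFraction = 0.5, nNuclearLoci = 4L,
                   locusLength = 120L, nMitoLoci = 2L, seed = 1L)
  args <- utils::modifyList(defaults, list(...))
  do.call(SimParams, args)
}

readTableFromCounts <- function(counts, sample = "s1", locus = "L1",
                                seqs = NULL) {
  # counts: named integer vector (names = short allele tags) or unnamed
  if (is.null(seqs)) {
    base <- "AAAAAAAAAA"
    seqs <- vapply(seq_along(counts), function(i) {
      s <- strsplit(base, "")[[1]]
      s[1] <- c("A", "C", "G", "T")[(i - 1L) %% 4L + 1L]
      s[2] <- c("A", "C", "G", "T")[((i - 1L) %/% 4L) %% 4L + 1L]
      paste(s, collapse = "")
    }, character(1))
  }
  new("ReadTable", records = data.frame(
    sample = sample, locus = locus,
    sequence_id = sprintf("u%02d", seq_along(counts)),
    sequence = seqs, count = as.integer(counts), stringsAsFactors = FALSE))
}

# --- tree oracles ----------------------------------------------------------

# patristic distance by explicit path enumeration through parent pointers
patristicOracle <- function(tree) {
  n <- length(tree$tip.label)
  parent <- integer(n + tree$Nnode); plen <- numeric(n + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    parent[tree$edge[e, 2]] <- tree$edge[e, 1]
    plen[tree$edge[e, 2]] <- tree$edge.length[e]
  }
  pathToRoot <- function(v) {
    nodes <- v
    while (parent[v] != 0L) { v <- parent[v]; nodes <- c(nodes, v) }
    nodes
  }
  D <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pi_ <- pathToRoot(i); pj <- pathToRoot(j)
    lca <- intersect(pi_, pj)[1]
    dist <- sum(plen[setdiff(pi_, pathToRoot(lca))]) +
      sum(plen[setdiff(pj, pathToRoot(lca))])
    D[i, j] <- D[j, i] <- dist
  }
  D
}

# --- PTP oracles -----------------------------------------------------------

# all consistent species-root sets by brute force over node subsets
ptpAllRootSetsOracle <- function(tree) {
  n <- length(tree$tip.label)
  nNode <- n + tree$Nnode
  parent <- integer(nNode)
  for (e in seq_len(nrow(tree$edge))) parent[tree$edge[e, 2]] <- tree$edge[e, 1]
  ancSelf <- function(v) { out <- v
    while (parent[v] != 0L) { v <- parent[v]; out <- c(out, v) }
    out }
  anc <- lapply(seq_len(nNode), ancSelf)
  keep <- list()
  for (mask in 1:(2^nNode - 1)) {
    set <- which(bitwAnd(mask, 2^(seq_len(nNode) - 1L)) > 0)
    cover <- vapply(seq_len(n), function(tip) sum(anc[[tip]] %in% set), 0L)
    if (all(cover == 1L)) keep[[length(keep) + 1L]] <- set
  }
  keep
}

# PTP log-likelihood by naive per-edge classification + dexp at the MLE rates
ptpLoglikOracle <- function(tree, roots, floor = 1e-8) {
  nNode <- length(tree$tip.label) + tree$Nnode
  parent <- integer(nNode)
  for (e in seq_len(nrow(tree$edge))) parent[tree$edge[e, 2]] <- tree$edge[e, 1]
  strictlyBelow <- function(v, s) {     # v strictly below s?
    v <- parent[v]
    while (v != 0L) { if (v == s) return(TRUE); v <- parent[v] }
    FALSE
  }
  lens <- pmax(tree$edge.length, floor)
  coal <- vapply(seq_len(nrow(tree$edge)), function(e)
    any(vapply(roots, function(s) strictlyBelow(tree$edge[e, 2], s),
               logical(1))), logical(1))
  ll <- 0
  for (cl in list(lens[!coal], lens[coal])) {
    if (length(cl) == 0) next
    rate <- length(cl) / sum(cl)
    ll <- ll + sum(stats::dexp(cl, rate, log = TRUE))
  }
  ll
}

# --- AMOVA oracles ---------------------------------------------------------

# naive pair-loop 4-level AMOVA: SS by double loops, expected-SS coefficients
# by per-pair indicator enumeration, components via solve()
amovaOracle <- function(D2, meta) {
  hap <- as.character(meta$haplotype)
  reg <- paste(hap, as.character(meta$region))
  sm <- as.character(meta$sample)
  N <- nrow(D2)
  ssW <- function(f) {
    tot <- 0
    for (g in unique(f)) {
      idx <- which(f == g); s <- 0
      for (i in idx) for (j in idx) s <- s + D2[i, j]
      tot <- tot + s / (2 * length(idx))
    }
    tot
  }
  ssTot <- sum(D2) / (2 * N)
  SS <- c(a = ssTot - ssW(hap), b = ssW(hap) - ssW(reg),
          c = ssW(reg) - ssW(sm), d = ssW(sm))
  df <- c(a = length(unique(hap)) - 1, b = length(unique(reg)) - length(unique(hap)),
          c = length(unique(sm)) - length(unique(reg)), d = N - length(unique(sm)))
  diffAt <- function(i, j, L) switch(L, a = hap[i] != hap[j],
                                     b = reg[i] != reg[j], c = sm[i] != sm[j],
                                     d = i != j)
  Kn <- function(f, L) {
    tot <- 0
    for (g in unique(f)) {
      idx <- which(f == g); s <- 0
      for (i in idx) for (j in idx) if (diffAt(i, j, L)) s <- s + 1
      tot <- tot + s / length(idx)
    }
    tot
  }
  parts <- list(tot = rep(1, N), hap = hap, reg = reg, samp = sm)
  lv <- c("a", "b", "c", "d")
  C <- matrix(0, 4, 4, dimnames = list(lv, lv))
  outer_ <- c(a = "tot", b = "hap", c = "reg", d = "samp")
  inner_ <- c(a = "hap", b = "reg", c = "samp", d = NA)
  for (st in lv) for (L in lv) {
    kO <- Kn(parts[[outer_[[st]]]], L)
    kI <- if (is.na(inner_[[st]])) 0 else Kn(parts[[inner_[[st]]]], L)
    C[st, L] <- kO - kI
  }
  keep <- df > 0
  sigma <- setNames(rep(NA_real_, 4), lv)
  sigma[keep] <- solve(C[keep, keep, drop = FALSE], SS[keep])
  list(SS = SS, df = df, sigma = sigma)
}

# classical one-way F_ST from variance components (balanced or not),
# Excoffier-style n_c, computed directly from definitions
onewayFstOracle <- function(D2, groups) {
  N <- nrow(D2); g <- as.character(groups)
  sizes <- table(g); G <- length(sizes)
  ssTot <- sum(D2) / (2 * N)
  ssW <- 0
  for (lev in names(sizes)) {
    idx <- which(g == lev)
    ssW <- ssW + sum(D2[idx, idx]) / (2 * length(idx))
  }
  ssA <- ssTot - ssW
  msA <- ssA / (G - 1); msW <- ssW / (N - G)
  nc <- (N - sum(sizes^2) / N) / (G - 1)
  sigW <- msW
  sigA <- (msA - msW) / nc
  c(fst = sigA / (sigA + sigW), sigA = sigA, sigW = sigW)
}

# --- synthetic SNP rows straight from simulated truth ----------------------

truthSnpMatrix <- function(truth) {
  al <- truthAlleles(truth)
  al <- al[grepl("^nuc", al$locus), ]
  samples <- sort(unique(al$sample))
  blocks <- lapply(split(al, al$locus), function(a) {
    m <- matrix(NA_character_, 2L * length(samples), nchar(a$sequence[1]))
    for (i in seq_along(samples)) {
      rows <- a[a$sample == samples[i], ]
      rows <- rows[order(rows$allele_index), ]
      m[2L * i - 1L, ] <- strsplit(rows$sequence[1], "")[[1]]
      m[2L * i, ] <- strsplit(rows$sequence[min(2L, nrow(rows))], "")[[1]]
    }
    m
  })
  m <- do.call(cbind, blocks)
  rownames(m) <- paste(rep(samples, each = 2L), 1:2, sep = "|")
  poly <- apply(m, 2L, function(col) length(unique(col)) >= 2L)
  m <- m[, poly, drop = FALSE]
  info <- truthSamples(truth)
  meta <- data.frame(sample = rep(samples, each = 2L),
                     region = rep(info$region[match(samples, info$sample)], each = 2L),
                     haplotype = rep(info$haplotype[match(samples, info$sample)],
                                     each = 2L), stringsAsFactors = FALSE)
  list(matrix = m, metadata = meta)
}

# two clades with iid exponential within-clade branch lengths joined by long
# stems: the generating process the branch-length delimiter assumes
twoCladeTree <- function(seed, n = 8, within = 0.001, stem = 0.5) {
  set.seed(seed)
  c1 <- ape::rtree(n, br = function(k) rexp(k, 1 / within))
  c2 <- ape::rtree(n, br = function(k) rexp(k, 1 / within))
  c1$tip.label <- paste0("t", 1:n)
  c2$tip.label <- paste0("u", 1:n)
  tr <- ape::bind.tree(ape::rtree(2, br = stem), c1, where = 1)
  ape::bind.tree(tr, c2, where = 1)
}

# run the full synthetic workflow up to a rooted tree + per-species tip sets
pipelineToTree <- function(params, mcmcSeed = params@seed) {
  truth <- simulateTwoSpecies(params)
  rt <- simulateReadTable(truth)
  g <- callNuclearGenotypes(rt, mitoLoci = c("mt01", "mt02"))
  g <- callMitoHaplotypes(rt, c("mt01", "mt02"), g)
  g <- suppressMessages(filterLociByPresence(g))
  loci <- sort(unique(genotypeCalls(g)$locus))
  blocks <- setNames(lapply(loci, function(l) locusConsensus(g, l)), loci)
  merged <- mergeIdentical(concatenatedSequences(concatenateLoci(blocks)))
  d <- ape::dist.dna(ape::as.DNAbin(Biostrings::DNAStringSet(merged$sequences)),
                     model = "raw", pairwise.deletion = TRUE, as.matrix = TRUE)
  d[is.na(d)] <- 0
  tr <- suppressWarnings(phangorn::midpoint(njTree(d)))
  sp <- truthSamples(truth)$species[match(sub("\\|.*", "", names(merged$sequences)),
                                          truthSamples(truth)$sample)]
  list(truth = truth, genotypes = g, tree = tr, merged = merged, species = sp)
}
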