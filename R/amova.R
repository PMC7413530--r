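#' Build an allele-copy SNP matrix from genotype calls
#'
#' Converts called genotypes into the row-per-allele-copy matrix hierarchical
#' AMOVA consumes: two rows per retained sample (a homozygote contributes two
#' identical rows, a heterozygote two rows differing at its heterozygous
#' sites), one column per polymorphic alignment position. Filtering follows
#' the usual missing-data cut-offs: loci called in fewer than
#' `1 - locusCutoff` of the samples are dropped first, then samples missing
#' more than `sampleCutoff` of the remaining loci are dropped, and finally
#' monomorphic columns are removed. The filtering order is reported via
#' `message()` so cut-off effects stay auditable.
#'
#' @param genotypes a [GenotypeSet] with nuclear calls.
#' @param hierarchy data.frame with columns `sample`, `haplotype`, `region`
#'   covering every retained sample.
#' @param sampleCutoff drop samples missing more than this fraction of loci.
#' @param locusCutoff drop loci missing in more than this fraction of samples.
#' @return list with `matrix` (character matrix, rownames `sample|copy`),
#'   `metadata` (data.frame sample, region, haplotype per row, aligned with
#'   the matrix rows), and `report` (dropped loci/samples).
#' @export
snpMatrixFromGenotypes <- function(genotypes, hierarchy, sampleCutoff = 0.5,
                                   locusCutoff = 0.5) {
  stopifnot(is(genotypes, "GenotypeSet"))
  .checkFraction(sampleCutoff, "sampleCutoff")
  .checkFraction(locusCutoff, "locusCutoff")
  cl <- genotypes@calls
  if (nrow(cl) == 0L) .stopf("no genotype calls")
  samples <- sort(unique(cl$sample))
  missingHier <- setdiff(samples, hierarchy$sample)
  if (length(missingHier))
    .stopf("sample(s) absent from the hierarchy table: %s",
           paste(missingHier, collapse = ", "))

  loci <- sort(unique(cl$locus))
  called <- unique(cl[, c("sample", "locus")])
  presence <- table(factor(called$locus, levels = loci))
  dropLoci <- names(presence)[presence < (1 - locusCutoff) * length(samples)]
  lociKept <- setdiff(loci, dropLoci)
  if (!length(lociKept)) .stopf("no locus survives the %g locus cut-off", locusCutoff)

  called2 <- called[called$locus %in% lociKept, ]
  persample <- table(factor(called2$sample, levels = samples))
  dropSamples <- names(persample)[persample < (1 - sampleCutoff) * length(lociKept)]
  samplesKept <- setdiff(samples, dropSamples)
  if (length(samplesKept) < 2L) .stopf("fewer than 2 samples survive filtering")
  if (length(dropLoci) || length(dropSamples))
    message(sprintf("SNP matrix filtering: dropped %d locus/loci, then %d sample(s)",
                    length(dropLoci), length(dropSamples)))

  cl <- cl[cl$locus %in% lociKept & cl$sample %in% samplesKept, ]

  # per locus: character matrix [2*nSample x positions], NA when missing
  blocks <- lapply(lociKept, function(loc) {
    sub <- cl[cl$locus == loc, ]
    len <- unique(nchar(sub$sequence))
    if (length(len) != 1L)
      .stopf("allele length mismatch within locus '%s'", loc)
    m <- matrix(NA_character_, nrow = 2L * length(samplesKept), ncol = len)
    for (i in seq_along(samplesKept)) {
      s <- samplesKept[i]
      a <- sub[sub$sample == s, ]
      if (nrow(a) == 0L) next
      a <- a[order(a$allele_index), ]
      a1 <- strsplit(a$sequence[1], "")[[1]]
      a2 <- strsplit(a$sequence[min(2L, nrow(a))], "")[[1]]
      m[2L * i - 1L, ] <- a1
      m[2L * i, ] <- a2
    }
    m
  })
  m <- do.call(cbind, blocks)
  rownames(m) <- paste(rep(samplesKept, each = 2L), rep(1:2, length(samplesKept)),
                       sep = "|")
  # keep polymorphic columns with unambiguous states only
  isBase <- function(x) x %in% c("A", "C", "G", "T")
  poly <- apply(m, 2L, function(col) {
    v <- unique(col[!is.na(col) & isBase(col)])
    length(v) >= 2L
  })
  m <- m[, poly, drop = FALSE]
  m[!is.na(m) & !isBase(m)] <- NA_character_   # gaps/ambiguity codes -> missing
  if (ncol(m) == 0L) .stopf("no polymorphic site survives filtering")

  hi <- hierarchy[match(samplesKept, hierarchy$sample), ]
  metadata <- data.frame(
    sample = rep(samplesKept, each = 2L),
    region = rep(hi$region, each = 2L),
    haplotype = rep(hi$haplotype, each = 2L), stringsAsFactors = FALSE)
  list(matrix = m, metadata = metadata,
       report = list(droppedLoci = dropLoci, droppedSamples = dropSamples,
                     lociKept = lociKept, nSites = ncol(m)))
}

#' Pairwise squared distances between allele-copy rows
#'
#' Entry (i, j) is the number of columns at which rows i and j carry
#' different non-missing states — the squared Euclidean distance over
#' one-hot-coded SNP states that underlies AMOVA. A missing state against
#' anything contributes 0 by default; the pair's comparable-site count is
#' attached as attribute `comparable` so callers can rescale
#' (`rescale = TRUE` multiplies each entry by nSites/comparable).
#'
#' @param m character (or integer) matrix with NA for missing.
#' @param rescale proportionally rescale for missing data (default FALSE:
#'   raw counts).
#' @return symmetric labelled matrix of squared distances.
#' @export
pairwiseSquaredDistances <- function(m, rescale = FALSE) {
  if (nrow(m) < 2L) .stopf("need at least 2 rows")
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  comp <- matrix(0L, n, n, dimnames = dimnames(D))
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    ok <- !is.na(x)
    okM <- outer(ok, ok, "&")
    comp <- comp + okM
    xi <- matrix(x, n, n)
    D <- D + (okM & xi != t(xi))
  }
  if (rescale) {
    f <- ifelse(comp > 0, ncol(m) / comp, 0)
    D <- D * f
    diag(D) <- 0
  }
  attr(D, "comparable") <- comp
  D
}

# Within-cluster sum of squared distances, SS_W(P) = sum_c (1/n_c)
# sum_{i<j in c} d2_ij, vectorised via rowsum over the full symmetric matrix.
.ssWithin <- function(D2, f) {
  cs <- rowsum(t(rowsum(D2, f)), f)       # cluster x cluster total sums
  n <- tabulate(f)
  sum(diag(cs) / (2 * n))
}

# Coefficient of a variance component in E[SS_W(P)]: for clusters c of
# partition P (integer codes 1..nP) and the finer grouping g (1..nG) whose
# units must DIFFER for the component to contribute,
# K = sum_c (n_c - sum_g n_cg^2 / n_c), via a tabulate-based crosstab.
.kCoef <- function(P, g, nP, nG) {
  cnt <- matrix(tabulate((P - 1L) * nG + g, nP * nG), nrow = nG)
  n <- colSums(cnt)
  sum(n - colSums(cnt^2) / n)
}

# Core 4-level AMOVA: squared-distance matrix + per-row haplotype/region/
# sample factors -> df, SS, method-of-moments variance components.
# Strata with zero df are collapsed out of the moment system. Regions are
# nested in haplotypes (a region observed in two haplotypes forms two
# hierarchy groups, the standard nested convention).
.amovaCore <- function(D2, hap, reg, samp) {
  N <- nrow(D2)
  hapF <- as.integer(factor(hap))
  regF <- as.integer(factor((hapF - 1L) * (max(as.integer(factor(reg))) + 1L) +
                              as.integer(factor(reg))))
  sampF <- as.integer(factor(samp))
  G <- max(hapF); R <- max(regF); S <- max(sampF)
  if (G < 2L)
    .stopf("degenerate design: the top level needs >= 2 haplotype groups (got %d)", G)

  ssTot <- sum(D2) / (2 * N)
  ssWhap <- .ssWithin(D2, hapF)
  ssWreg <- .ssWithin(D2, regF)
  ssWsamp <- .ssWithin(D2, sampF)
  SS <- c(a = ssTot - ssWhap, b = ssWhap - ssWreg, c = ssWreg - ssWsamp,
          d = ssWsamp)
  df <- c(a = G - 1L, b = R - G, c = S - R, d = N - S)

  # E[SS_stratum] = sum_L sigma2_L * (K_L(outer partition) - K_L(inner)),
  # where K_L uses the grouping whose units must differ for sigma2_L.
  one <- rep(1L, N)
  rowIdx <- seq_len(N)
  partitions <- list(tot = one, hap = hapF, reg = regF, samp = sampF)
  sizes <- c(tot = 1L, hap = G, reg = R, samp = S)
  groups <- list(a = hapF, b = regF, c = sampF, d = rowIdx)
  gsizes <- c(a = G, b = R, c = S, d = N)
  lv <- c("a", "b", "c", "d")
  Kmat <- matrix(0, 4, 4, dimnames = list(names(partitions), lv))
  for (P in names(partitions)) for (L in lv)
    Kmat[P, L] <- .kCoef(partitions[[P]], groups[[L]], sizes[[P]], gsizes[[L]])
  outer_ <- c(a = "tot", b = "hap", c = "reg", d = "samp")
  inner_ <- c(a = "hap", b = "reg", c = "samp", d = NA)
  C <- matrix(0, 4, 4, dimnames = list(lv, lv))
  for (st in lv)
    C[st, ] <- Kmat[outer_[[st]], ] -
      (if (is.na(inner_[[st]])) 0 else Kmat[inner_[[st]], ])

  keep <- df > 0L
  sigma <- setNames(rep(NA_real_, 4), lv)
  if (sum(keep) == 0L) .stopf("degenerate design: no stratum has positive df")
  sigma[keep] <- solve(C[keep, keep, drop = FALSE], SS[keep])
  list(df = df, SS = SS, sigma = sigma, keep = keep,
       G = G, R = R, S = S, N = N)
}

.phiFromSigma <- function(sigma, keep) {
  s <- ifelse(keep, sigma, 0)
  tot <- sum(s[keep])
  phi <- c(phiCT = NA_real_, phiSC = NA_real_, phiSW = NA_real_)
  if (!is.finite(tot) || abs(tot) < 1e-12) return(phi)  # undefined sentinel
  if (keep[["a"]]) phi[["phiCT"]] <- s[["a"]] / tot
  denSC <- s[["b"]] + s[["c"]] + s[["d"]]
  if (keep[["b"]] && abs(denSC) > 1e-12) phi[["phiSC"]] <- s[["b"]] / denSC
  denSW <- s[["c"]] + s[["d"]]
  if (keep[["c"]] && abs(denSW) > 1e-12) phi[["phiSW"]] <- s[["c"]] / denSW
  phi
}

#' Hierarchical four-level AMOVA
#'
#' Partitions the molecular variance of allele-copy squared distances across
#' the nested levels *between haplotypes* / *between regions within
#' haplotype* / *between samples within region* / *within samples*
#' (heterozygosity). Sums of squares come from within-group sums of squared
#' distances differenced down the hierarchy; variance components solve the
#' expected-mean-square linear system with unbalanced-design coefficients;
#' the Phi statistics are `phiCT` = sigma2_a/total, `phiSC` =
#' sigma2_b/(sigma2_b+sigma2_c+sigma2_d), `phiSW` =
#' sigma2_c/(sigma2_c+sigma2_d). Negative components are reported as-is
#' (with a warning), preserving the SS/df accounting; a stratum with zero
#' degrees of freedom (e.g. one allele copy per sample) is collapsed out of
#' the design with a message, and fewer than two haplotype groups is an
#' error. When every row is identical all components are zero and the Phi
#' statistics are returned as NA sentinels.
#'
#' @param D2 squared-distance matrix over allele copies (rows of the SNP
#'   matrix), e.g. from [pairwiseSquaredDistances].
#' @param metadata data.frame aligned with the rows of `D2`, with columns
#'   `sample`, `region`, `haplotype`.
#' @return an [AmovaResult] (p-values unset; see [amovaPermutationTest]).
#' @export
amova <- function(D2, metadata) {
  .checkDistanceMatrix(D2, "D2")
  need <- c("sample", "region", "haplotype")
  if (!all(need %in% names(metadata)))
    .stopf("metadata needs columns: %s", paste(need, collapse = ", "))
  if (nrow(metadata) != nrow(D2))
    .stopf("metadata rows (%d) != distance matrix rows (%d)",
           nrow(metadata), nrow(D2))
  core <- .amovaCore(D2, metadata$haplotype, metadata$region, metadata$sample)

  keep <- core$keep
  if (any(keep & core$sigma < 0))
    .warnf("negative variance component(s) retained: %s",
           paste(names(core$sigma)[keep & core$sigma < 0], collapse = ", "))
  if (any(!keep))
    message(sprintf("collapsed zero-df stratum/strata: %s",
                    paste(names(core$df)[!keep], collapse = ", ")))

  labels <- c(a = "Between Haplotypes", b = "Between Regions Within Haplotype",
              c = "Between Samples Within Region", d = "Within Samples")
  df <- core$df[keep]; SS <- core$SS[keep]
  tab <- data.frame(source = c(unname(labels[names(df)]), "Total"),
                    df = c(unname(df), sum(df)),
                    SS = c(unname(SS), sum(SS)), stringsAsFactors = FALSE)
  tab$MS <- ifelse(tab$df > 0, tab$SS / tab$df, NA_real_)

  sigma <- core$sigma[keep]
  names(sigma) <- paste0("sigma2_", names(sigma))
  tot <- sum(sigma)
  pct <- if (abs(tot) > 1e-12) 100 * sigma / tot else sigma * NA_real_
  phi <- .phiFromSigma(core$sigma, keep)

  new("AmovaResult", table = tab, components = sigma, percent = pct,
      phi = phi, pvalues = c(phiCT = NA_real_, phiSC = NA_real_,
                             phiSW = NA_real_), nPerm = 0L)
}

#' Permutation Monte Carlo tests for the AMOVA Phi statistics
#'
#' Level-appropriate permutation schemes, following standard nested-AMOVA
#' conventions: for `phiCT`, whole regions (haplotype-by-region groups) are
#' reassigned among haplotypes; for `phiSC`, samples are permuted among
#' regions within their haplotype; for `phiSW`, allele copies are permuted
#' among samples within their region. Each p-value is
#' (number of permuted Phi >= observed + 1)/(nPerm + 1), so the minimum
#' attainable p is 1/(nPerm + 1).
#'
#' @inheritParams amova
#' @param nPerm number of permutations (default 9999).
#' @param seed integer random seed.
#' @param levels which Phi statistics to test (default all three).
#' @return an [AmovaResult] with the `pvalues` slot filled (NA for untested
#'   levels).
#' @export
amovaPermutationTest <- function(D2, metadata, nPerm = 9999, seed = 1L,
                                 levels = c("phiCT", "phiSC", "phiSW")) {
  nPerm <- .checkCount(nPerm, "nPerm")
  res <- amova(D2, metadata)
  hap <- as.character(metadata$haplotype)
  reg <- as.character(metadata$region)
  samp <- as.character(metadata$sample)
  obs <- res@phi
  core0 <- .amovaCore(D2, hap, reg, samp)
  keep <- core0$keep

  phiOf <- function(h, r, s) {
    co <- tryCatch(.amovaCore(D2, h, r, s), error = function(e) NULL)
    if (is.null(co)) return(c(phiCT = NA_real_, phiSC = NA_real_,
                              phiSW = NA_real_))
    .phiFromSigma(co$sigma, co$keep)
  }

  set.seed(seed)
  counts <- c(phiCT = 0L, phiSC = 0L, phiSW = 0L)
  valid <- c(phiCT = !is.na(obs[["phiCT"]]) && "phiCT" %in% levels,
             phiSC = !is.na(obs[["phiSC"]]) && "phiSC" %in% levels,
             phiSW = !is.na(obs[["phiSW"]]) && "phiSW" %in% levels)

  # pre-group rows for the three schemes
  regKey <- paste(hap, reg, sep = "\r")
  regGroups <- split(seq_along(hap), regKey)
  grpHap <- vapply(regGroups, function(i) hap[i[1]], character(1))
  sampGroups <- split(seq_along(samp), samp)         # rows of each sample
  sampHap <- vapply(sampGroups, function(i) hap[i[1]], character(1))
  sampReg <- vapply(sampGroups, function(i) reg[i[1]], character(1))
  regOfSampGroups <- split(seq_along(sampGroups), paste(sampHap, sampReg, sep = "\r"))

  for (b in seq_len(nPerm)) {
    if (valid[["phiCT"]]) {
      h2 <- hap
      newHap <- sample(grpHap)
      for (k in seq_along(regGroups)) h2[regGroups[[k]]] <- newHap[k]
      p <- phiOf(h2, reg, samp)[["phiCT"]]
      if (!is.na(p) && p >= obs[["phiCT"]] - 1e-12)
        counts[["phiCT"]] <- counts[["phiCT"]] + 1L
    }
    if (valid[["phiSC"]]) {
      r2 <- reg
      for (h in unique(sampHap)) {
        idx <- which(sampHap == h)
        newReg <- sample(sampReg[idx])
        for (j in seq_along(idx))
          r2[sampGroups[[idx[j]]]] <- newReg[j]
      }
      p <- phiOf(hap, r2, samp)[["phiSC"]]
      if (!is.na(p) && p >= obs[["phiSC"]] - 1e-12)
        counts[["phiSC"]] <- counts[["phiSC"]] + 1L
    }
    if (valid[["phiSW"]]) {
      s2 <- samp
      for (rg in regOfSampGroups) {
        rows <- unlist(sampGroups[rg], use.names = FALSE)
        s2[rows] <- sample(samp[rows])
      }
      p <- phiOf(hap, reg, s2)[["phiSW"]]
      if (!is.na(p) && p >= obs[["phiSW"]] - 1e-12)
        counts[["phiSW"]] <- counts[["phiSW"]] + 1L
    }
  }
  pv <- ifelse(valid, (counts + 1) / (nPerm + 1), NA_real_)
  names(pv) <- names(counts)
  res@pvalues <- pv
  res@nPerm <- as.integer(nPerm)
  res
}

#' AMOVA table to TSV/JSON
#'
#' Writes the result in the familiar published-table shape (Variation
#' source, Df, Sum of squares, Mean squares, % of variance, Phi, P), plus a
#' JSON twin.
#'
#' @param result an [AmovaResult].
#' @param path output TSV path (`.json` twin written alongside).
#' @return invisibly, `path`.
#' @export
writeAmovaTable <- function(result, path) {
  stopifnot(is(result, "AmovaResult"))
  t <- result@table
  n <- nrow(t)
  phiCol <- rep(NA_real_, n); pCol <- rep(NA_real_, n)
  rowFor <- c(phiCT = "Between Haplotypes",
              phiSC = "Between Regions Within Haplotype",
              phiSW = "Between Samples Within Region")
  for (k in names(rowFor)) {
    i <- match(rowFor[[k]], t$source)
    if (!is.na(i)) {
      phiCol[i] <- result@phi[[k]]
      pCol[i] <- result@pvalues[[k]]
    }
  }
  pctCol <- rep(NA_real_, n)
  pctCol[match(t$source[-n], t$source)] <- unname(result@percent)
  pctCol[n] <- sum(result@percent)
  out <- data.frame(`Variation source` = t$source, Df = t$df,
                    `Sum of squares` = round(t$SS, 4),
                    `Mean squares` = round(t$MS, 4),
                    `% of variance` = round(pctCol, 1),
                    Phi = round(phiCol, 3), P = pCol, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(table = out, components = as.list(result@components),
         percent = as.list(result@percent), phi = as.list(result@phi),
         pvalues = as.list(result@pvalues), nPerm = result@nPerm),
    sub("\\.tsv$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Nested degrees of freedom of the sampling hierarchy
#'
#' The df column of the hierarchical AMOVA table, straight from the design:
#' (G - 1) between haplotypes, (R - G) between haplotype-by-region groups,
#' (N - R) between samples, (C - N) within samples for C = `copies` * N
#' allele copies, plus the total (C - 1).
#'
#' @param hierarchy data.frame with columns `sample`, `haplotype`, `region`
#'   (one row per sample).
#' @param copies allele copies per sample (2 for dikaryons).
#' @return named integer vector: betweenHaplotypes, betweenRegions,
#'   betweenSamples, withinSamples, total.
#' @export
amovaDegreesOfFreedom <- function(hierarchy, copies = 2L) {
  need <- c("sample", "haplotype", "region")
  if (!all(need %in% names(hierarchy)))
    .stopf("hierarchy needs columns: %s", paste(need, collapse = ", "))
  copies <- .checkCount(copies, "copies")
  G <- length(unique(hierarchy$haplotype))
  R <- nrow(unique(hierarchy[, c("haplotype", "region")]))
  N <- length(unique(hierarchy$sample))
  C <- copies * N
  c(betweenHaplotypes = G - 1L, betweenRegions = R - G,
    betweenSamples = N - R, withinSamples = C - N, total = C - 1L)
}

#' Mean squares from a published df/SS table
#'
#' The MS column of an AMOVA table is SS/df per stratum, and the total MS is
#' total SS / total df; this helper reproduces both from printed df and SS
#' values, preserving the names of `ss`.
#'
#' @param df integer vector of stratum degrees of freedom.
#' @param ss numeric vector of stratum sums of squares (same order).
#' @return numeric vector of mean squares with a trailing `total` element.
#' @export
amovaMeanSquares <- function(df, ss) {
  if (length(df) != length(ss)) .stopf("df and ss must have equal length")
  if (any(df <= 0)) .stopf("df must be positive")
  ms <- c(ss / df, total = sum(ss) / sum(df))
  if (!is.null(names(ss))) names(ms)[seq_along(ss)] <- names(ss)
  ms
}

#' Phi statistics from variance-component percentages
#'
#' Recovers the Phi column of a published AMOVA table from its
#' percent-of-variance column: with components (a, b, c, d) summing to
#' 100%, `phiCT` = a/100, `phiSC` = b/(b+c+d), `phiSW` = c/(c+d).
#'
#' @param percent numeric vector of the four percentages, top stratum first.
#' @return named numeric: phiCT, phiSC, phiSW.
#' @export
phiFromPercent <- function(percent) {
  if (length(percent) != 4L) .stopf("need exactly 4 percentages")
  a <- percent[1]; b <- percent[2]; c <- percent[3]; d <- percent[4]
  c(phiCT = a / sum(percent), phiSC = b / (b + c + d), phiSW = c / (c + d))
}

#' Cut-off sensitivity sweep for the SNP-matrix filters
#'
#' Re-runs the matrix construction and AMOVA over a grid of sample/locus
#' missing-data cut-offs, the usual robustness check that conclusions do not
#' hinge on one filtering choice.
#'
#' @inheritParams snpMatrixFromGenotypes
#' @param cutoffs numeric vector of cut-off levels applied to both filters.
#' @return data.frame: sampleCutoff, locusCutoff, nSamples, nSites, phiCT.
#' @export
amovaCutoffSweep <- function(genotypes, hierarchy, cutoffs = c(0.3, 0.5, 0.7)) {
  out <- list()
  for (sc in cutoffs) for (lc in cutoffs) {
    r <- tryCatch({
      sm <- snpMatrixFromGenotypes(genotypes, hierarchy, sc, lc)
      D2 <- pairwiseSquaredDistances(sm$matrix)
      a <- amova(D2, sm$metadata)
      data.frame(sampleCutoff = sc, locusCutoff = lc,
                 nSamples = nrow(sm$matrix) / 2L, nSites = ncol(sm$matrix),
                 phiCT = a@phi[["phiCT"]])
    }, error = function(e) NULL)
    if (!is.null(r)) out[[length(out) + 1L]] <- r
  }
  do.call(rbind, out)
}
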