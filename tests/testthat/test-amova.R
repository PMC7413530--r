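toyGenotypes <- function(records) {
  # records: data.frame(sample, locus, alleles = list of char vectors)
  rows <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    seqs <- records$alleles[[i]]
    data.frame(sample = records$sample[i], locus = records$locus[i],
               allele_index = seq_along(seqs), sequence = seqs,
               fraction = 1 / length(seqs),
               zygosity = if (length(seqs) == 2L) "het" else "hom",
               flag = "", stringsAsFactors = FALSE)
  }))
  new("GenotypeSet", calls = rows, haplotypes = mycodelim:::.emptyHaplo(),
      samples = sort(unique(records$sample)), threshold = 0.2)
}

simpleHier <- function(samples, hap, region) {
  data.frame(sample = samples, haplotype = hap, region = region,
             stringsAsFactors = FALSE)
}

test_that("SNP matrix rows encode zygosity correctly", {
  recs <- data.frame(sample = c("s1", "s2"), locus = "L1")
  recs$alleles <- list("ACGT", c("ACGT", "ACAT"))
  sm <- snpMatrixFromGenotypes(toyGenotypes(recs),
                               simpleHier(c("s1", "s2"), c("A", "B"), "r1"))
  m <- sm$matrix
  expect_identical(unname(m["s1|1", ]), unname(m["s1|2", ]))  # homozygote rows
  het <- which(m["s2|1", ] != m["s2|2", ])
  expect_equal(length(het), 1L)                    # het rows differ at one site
  # monomorphic columns dropped: only polymorphic positions remain
  expect_lte(ncol(m), 2L)
})

test_that("loci are filtered before samples, at the stated cut-offs", {
  # locus "rare" present in 4 of 10 samples (<50%): dropped first, so sample
  # s10 (which carries only "rare" and "core") survives via "core"
  samples <- sprintf("s%02d", 1:10)
  recs <- do.call(rbind, lapply(seq_along(samples), function(i) {
    loci <- c("core", if (i <= 4) "rare")
    data.frame(sample = samples[i], locus = loci)
  }))
  seqs <- c(core = "AT", rare = "GG")
  recs$alleles <- lapply(seq_len(nrow(recs)), function(i)
    if (recs$sample[i] == "s01" && recs$locus[i] == "core") "AA"
    else unname(seqs[recs$locus[i]]))
  sm <- suppressMessages(snpMatrixFromGenotypes(
    toyGenotypes(recs), simpleHier(samples, rep(c("A", "B"), 5), "r1")))
  expect_equal(sm$report$droppedLoci, "rare")
  expect_equal(length(sm$report$droppedSamples), 0L)
  expect_equal(nrow(sm$matrix), 20L)
  expect_error(snpMatrixFromGenotypes(
    toyGenotypes(recs), simpleHier(samples[-1], rep("A", 9), "r1")),
    "absent from the hierarchy")
})

test_that("pairwise squared distances count differing non-missing sites", {
  m <- rbind(a = c("A", "A", "G", "T"), b = c("A", "A", "G", "T"),
             c = c("A", "C", "T", "T"), d = c(NA, "C", "G", NA))
  D <- pairwiseSquaredDistances(m)
  expect_equal(D["a", "b"], 0)
  expect_equal(D["a", "c"], 2)
  expect_equal(D["a", "d"], 1)          # missing-vs-anything contributes 0
  expect_equal(attr(D, "comparable")["a", "d"], 2L)
  # optional proportional rescaling
  Dr <- pairwiseSquaredDistances(m, rescale = TRUE)
  expect_equal(Dr["a", "d"], 1 * 4 / 2)
})

test_that("pairwise distances match a naive double-loop oracle", {
  set.seed(30)
  m <- matrix(sample(c("A", "G", NA), 6 * 20, TRUE, prob = c(.45, .45, .1)),
              6, 20, dimnames = list(paste0("r", 1:6), NULL))
  D <- pairwiseSquaredDistances(m)
  for (i in 1:5) for (j in (i + 1):6) {
    naive <- sum(!is.na(m[i, ]) & !is.na(m[j, ]) & m[i, ] != m[j, ])
    expect_equal(unname(D[i, j]), naive)
  }
})

test_that("the nested df column follows the design", {
  # 2 haplotypes, 19 regions each (38 groups), 92 samples, 2 copies
  hier <- data.frame(
    sample = sprintf("s%02d", 1:92),
    haplotype = rep(c("A", "B"), each = 46),
    region = c(rep(sprintf("r%02d", 1:19), length.out = 46),
               rep(sprintf("q%02d", 1:19), length.out = 46)))
  df <- amovaDegreesOfFreedom(hier)
  expect_equal(unname(df), c(1L, 36L, 54L, 92L, 183L))
  expect_equal(sum(df[1:4]), df[["total"]])
})

test_that("identical rows give zero variance and NA Phi sentinels", {
  m <- matrix("A", 8, 5, dimnames = list(paste0("r", 1:8), NULL))
  D <- pairwiseSquaredDistances(m)
  meta <- data.frame(sample = rep(paste0("s", 1:4), each = 2),
                     region = rep(c("r1", "r2"), each = 4),
                     haplotype = rep(c("A", "B"), each = 4))
  res <- suppressMessages(amova(D, meta))
  expect_equal(sum(abs(amovaTable(res)$SS)), 0)
  expect_true(all(varianceComponents(res) == 0))
  expect_true(all(is.na(phiStatistics(res))))
})

test_that("SS and df always add up and total SS is permutation-invariant", {
  set.seed(32)
  m <- matrix(sample(c("A", "G"), 24 * 30, TRUE), 24, 30,
              dimnames = list(paste0("r", 1:24), NULL))
  D <- pairwiseSquaredDistances(m)
  meta <- data.frame(sample = rep(sprintf("s%02d", 1:12), each = 2),
                     region = rep(c("x", "x", "y", "z", "y", "z"), each = 4),
                     haplotype = rep(c("A", "B"), each = 12))
  res <- suppressWarnings(amova(D, meta))
  t <- amovaTable(res)
  n <- nrow(t)
  expect_equal(sum(t$df[-n]), t$df[n])
  expect_equal(sum(t$SS[-n]), t$SS[n], tolerance = 1e-9)
  expect_equal(t$MS, t$SS / t$df)
  expect_equal(sum(varianceComponents(res) / sum(varianceComponents(res))), 1)
  # permuting the metadata leaves the total SS unchanged
  set.seed(33)
  metaP <- meta[sample(nrow(meta)), ]
  resP <- suppressWarnings(amova(D[rownames(D), rownames(D)], metaP))
  expect_equal(amovaTable(resP)$SS[n], t$SS[n], tolerance = 1e-9)
})

test_that("the 4-level engine equals the naive pair-loop oracle", {
  set.seed(34)
  for (rep in 1:4) {
    nSamp <- sample(8:12, 1)
    m <- matrix(sample(c("A", "G", "T"), 2 * nSamp * 25, TRUE), 2 * nSamp, 25,
                dimnames = list(paste0("r", 1:(2 * nSamp)), NULL))
    meta <- data.frame(
      sample = rep(sprintf("s%02d", 1:nSamp), each = 2),
      region = rep(sample(c("r1", "r2", "r3"), nSamp, TRUE), each = 2),
      haplotype = rep(rep(c("A", "B"), length.out = nSamp), each = 2))
    D <- pairwiseSquaredDistances(m)
    res <- suppressWarnings(amova(D, meta))
    orc <- amovaOracle(D, meta)
    expect_equal(unname(varianceComponents(res)),
                 unname(orc$sigma[!is.na(orc$sigma)]), tolerance = 1e-9)
    expect_equal(unname(amovaTable(res)$SS[-nrow(amovaTable(res))]),
                 unname(orc$SS[orc$df > 0]), tolerance = 1e-9)
  }
})

test_that("the haploid two-level reduction reproduces classical F_ST", {
  set.seed(35)
  m <- matrix(sample(c("A", "G"), 12 * 20, TRUE), 12, 20,
              dimnames = list(paste0("r", 1:12), NULL))
  groups <- rep(c("A", "B"), each = 6)
  # one copy per sample and one region per group collapses strata b and d
  meta <- data.frame(sample = paste0("ind", 1:12), region = groups,
                     haplotype = groups)
  D <- pairwiseSquaredDistances(m)
  res <- suppressMessages(suppressWarnings(amova(D, meta)))
  orc <- onewayFstOracle(D, groups)
  expect_equal(unname(phiStatistics(res)[["phiCT"]]), unname(orc[["fst"]]),
               tolerance = 1e-9)
  expect_equal(unname(varianceComponents(res)),
               unname(orc[c("sigA", "sigW")]), tolerance = 1e-9)
})

test_that("a single haplotype group is a degenerate design", {
  m <- matrix(sample(c("A", "G"), 8 * 10, TRUE), 8, 10,
              dimnames = list(paste0("r", 1:8), NULL))
  meta <- data.frame(sample = rep(paste0("s", 1:4), each = 2),
                     region = "r1", haplotype = "A")
  expect_error(amova(pairwiseSquaredDistances(m), meta), "degenerate")
})

test_that("strong structure attains the minimum permutation p-value", {
  set.seed(36)
  truth <- simulateTwoSpecies(smallParams(
    nSamplesPerSpecies = 10L, nRegions = 16L, sympatryFraction = 0.25,
    divergence = 0.08, thetaWithin = 0.002,
    nNuclearLoci = 6L, seed = 37L))
  ts <- truthSnpMatrix(truth)
  D2 <- pairwiseSquaredDistances(ts$matrix)
  res <- amovaPermutationTest(D2, ts$metadata, nPerm = 99, seed = 2L)
  expect_equal(permutationP(res)[["phiCT"]], 1 / 100)
  expect_gt(phiStatistics(res)[["phiCT"]], 0.5)
})

test_that("estimated phiCT increases with simulated divergence", {
  phis <- vapply(c(0, 0.02, 0.08), function(d) {
    truth <- simulateTwoSpecies(smallParams(
      nSamplesPerSpecies = 10L, divergence = d, thetaWithin = 0.005,
      nNuclearLoci = 6L, seed = 53L))
    ts <- truthSnpMatrix(truth)
    s <- suppressWarnings(phiStatistics(amova(pairwiseSquaredDistances(ts$matrix),
                                              ts$metadata)))
    s[["phiCT"]]
  }, numeric(1))
  expect_true(all(diff(phis) > 0))
})

test_that("published-table helpers reproduce MS and Phi arithmetic", {
  ms <- amovaMeanSquares(df = c(2L, 9L), ss = c(20, 45))
  expect_equal(unname(ms), c(10, 5, 65 / 11))
  phi <- phiFromPercent(c(50, 25, 12.5, 12.5))
  expect_equal(unname(phi[["phiCT"]]), 0.5)
  expect_equal(unname(phi[["phiSW"]]), 0.5)
})

test_that("the AMOVA table exports in published shape", {
  set.seed(38)
  m <- matrix(sample(c("A", "G"), 16 * 12, TRUE), 16, 12,
              dimnames = list(paste0("r", 1:16), NULL))
  meta <- data.frame(sample = rep(paste0("s", 1:8), each = 2),
                     region = rep(c("r1", "r2", "r1", "r2"), each = 4),
                     haplotype = rep(c("A", "B"), each = 8))
  res <- suppressWarnings(amovaPermutationTest(pairwiseSquaredDistances(m),
                                               meta, nPerm = 19, seed = 1L))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeAmovaTable(res, f)
  tab <- read.delim(f, check.names = FALSE)
  expect_equal(names(tab), c("Variation source", "Df", "Sum of squares",
                             "Mean squares", "% of variance", "Phi", "P"))
  expect_equal(tab$Df[nrow(tab)], sum(tab$Df[-nrow(tab)]))
  expect_true(file.exists(sub("\\.tsv$", ".json", f)))
  # cut-off sensitivity sweep returns one row per grid point
  recs <- data.frame(sample = rep(paste0("s", 1:8), 2),
                     locus = rep(c("L1", "L2"), each = 8))
  recs$alleles <- as.list(sample(c("AG", "AT", "CG"), 16, TRUE))
  sweep <- suppressWarnings(amovaCutoffSweep(toyGenotypes(recs),
                            simpleHier(paste0("s", 1:8),
                                       rep(c("A", "B"), each = 4),
                                       rep(c("r1", "r2"), 4)),
                            cutoffs = c(0.5, 0.7)))
  expect_true(nrow(sweep) >= 1)
  expect_true(all(c("phiCT", "nSites") %in% names(sweep)))
})
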