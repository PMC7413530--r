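test_that("read-abundance threshold arithmetic is inclusive at the boundary", {
  calls <- genotypeCalls(callNuclearGenotypes(readTableFromCounts(c(60, 30, 10))))
  expect_equal(nrow(calls), 2L)                    # 10% sequence dropped
  expect_equal(calls$zygosity, c("het", "het"))
  expect_equal(sort(calls$fraction), c(0.3, 0.6))

  calls <- genotypeCalls(callNuclearGenotypes(readTableFromCounts(100)))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$zygosity, "hom")
  expect_equal(calls$fraction, 1)

  # 19% < 20% fails, 81% passes: homozygote for the majority sequence
  rt <- readTableFromCounts(c(19, 81))
  calls <- genotypeCalls(callNuclearGenotypes(rt))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$fraction, 0.81)
  # exactly 20% passes (inclusive comparison)
  calls <- genotypeCalls(callNuclearGenotypes(readTableFromCounts(c(20, 80))))
  expect_equal(nrow(calls), 2L)
})

test_that("more than two passing sequences is anomalous (or dropped in strict mode)", {
  rt <- readTableFromCounts(c(40, 30, 30))
  calls <- genotypeCalls(callNuclearGenotypes(rt))
  expect_equal(nrow(calls), 2L)
  expect_true(all(calls$flag == "anomalous"))
  expect_equal(calls$fraction[1], 0.4)             # top two kept by count
  strict <- genotypeCalls(callNuclearGenotypes(rt, strict = TRUE))
  expect_equal(nrow(strict), 0L)
})

test_that("invalid read tables are rejected with informative errors", {
  bad <- data.frame(sample = "s1", locus = "L1", sequence_id = "u1",
                    sequence = "ACGT", count = -1L)
  expect_error(new("ReadTable", records = bad), "non-negative")
  bad$count <- 5L; bad$sequence <- "ACXT"
  expect_error(new("ReadTable", records = bad), "invalid characters")
})

test_that("mitochondrial haplotypes follow the most-abundant rule", {
  rt <- new("ReadTable", records = data.frame(
    sample = rep(c("s1", "s2"), each = 2),
    locus = "mt1", sequence_id = paste0("u", 1:4),
    sequence = c("AAAA", "CCCC", "AAAA", "GGGG"),
    count = c(55L, 45L, 70L, 30L), stringsAsFactors = FALSE))
  g <- callMitoHaplotypes(rt, "mt1")
  h <- sampleHaplotypes(g)
  expect_equal(h$sequence, c("AAAA", "AAAA"))      # argmax per sample
  expect_equal(h$haplotype, c("A", "A"))           # shared label
})

test_that("haplotype count ties break lexicographically with a warning", {
  rt <- new("ReadTable", records = data.frame(
    sample = "s1", locus = "mt1", sequence_id = c("u1", "u2"),
    sequence = c("TTTT", "AAAA"), count = c(50L, 50L), stringsAsFactors = FALSE))
  expect_warning(g <- callMitoHaplotypes(rt, "mt1"), "lexicographically")
  expect_equal(sampleHaplotypes(g)$sequence, "AAAA")
})

test_that("haplotype labels are assigned in sample-sorted discovery order", {
  rt <- new("ReadTable", records = data.frame(
    sample = c("s3", "s1", "s2"), locus = "mt1",
    sequence_id = paste0("u", 1:3),
    sequence = c("GGGG", "TTTT", "GGGG"), count = 10L, stringsAsFactors = FALSE))
  h <- sampleHaplotypes(callMitoHaplotypes(rt, "mt1"))
  expect_equal(h$haplotype[h$sample == "s1"], "A")  # s1 first in sorted order
  expect_equal(h$haplotype[h$sample == "s2"], "B")
  expect_equal(h$haplotype[h$sample == "s3"], "B")
})

test_that("locus presence filter applies a strict majority rule", {
  mk <- function(nPresent, nTotal = 10L) {
    recs <- do.call(rbind, lapply(seq_len(nTotal), function(i) {
      loci <- c("keep", if (i <= nPresent) "maybe")
      data.frame(sample = sprintf("s%02d", i), locus = loci,
                 sequence_id = paste0("u", seq_along(loci)),
                 sequence = "ACGT", count = 100L, stringsAsFactors = FALSE)
    }))
    callNuclearGenotypes(new("ReadTable", records = recs))
  }
  # present in exactly 50% of samples: removed (not "more than 50%")
  expect_message(g5 <- filterLociByPresence(mk(5L)), "removed")
  expect_equal(unique(genotypeCalls(g5)$locus), "keep")
  # present in 60%: retained
  g6 <- filterLociByPresence(mk(6L))
  expect_setequal(unique(genotypeCalls(g6)$locus), c("keep", "maybe"))
  # all loci everywhere: identity
  gAll <- mk(10L)
  expect_identical(genotypeCalls(filterLociByPresence(gAll)),
                   genotypeCalls(gAll))
})

test_that("IUPAC consensus covers ambiguity, identity and gap rules", {
  expect_equal(iupacConsensus(c("ACGT", "ACGA")), "ACGW")
  expect_equal(iupacConsensus(c("ACGT", "ACGT")), "ACGT")
  expect_equal(iupacConsensus(c("AC-T", "ACGT")), "ACGT")  # gap vs base -> base
  expect_equal(iupacConsensus(c("A--T", "A--T")), "A--T")  # all-gap column kept
  expect_equal(iupacConsensus("TTNN"), "TTNN")             # single allele unchanged
  expect_equal(iupacConsensus(c("AG", "CT")), "MK")
  expect_error(iupacConsensus(c("AC", "ACG")), "mismatch")
  expect_error(iupacConsensus(character(0)), "empty")
})

test_that("consensus is idempotent for unambiguous sequences", {
  set.seed(1)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
    expect_identical(iupacConsensus(c(s, s)), s)
  }
})

test_that("every retained allele fraction meets the threshold on noisy data", {
  p <- smallParams(seed = 17L)
  rt <- simulateReadTable(simulateTwoSpecies(p), p)
  calls <- genotypeCalls(callNuclearGenotypes(rt, threshold = 0.2))
  expect_true(all(calls$fraction >= 0.2))
  calls3 <- genotypeCalls(callNuclearGenotypes(rt, threshold = 0.35))
  expect_true(all(calls3$fraction >= 0.35))
})

test_that("noise-free synthetic data is recovered exactly", {
  p <- smallParams(errorSeqRate = 0, missingLocusRate = 0, seed = 11L)
  truth <- simulateTwoSpecies(p)
  rt <- simulateReadTable(truth, p)
  calls <- genotypeCalls(callNuclearGenotypes(rt, mitoLoci = c("mt01", "mt02")))
  al <- truthAlleles(truth)
  al <- al[grepl("^nuc", al$locus), ]
  for (key in unique(paste(al$sample, al$locus))) {
    parts <- strsplit(key, " ")[[1]]
    tru <- sort(unique(al$sequence[al$sample == parts[1] & al$locus == parts[2]]))
    got <- sort(calls$sequence[calls$sample == parts[1] & calls$locus == parts[2]])
    expect_identical(got, tru)
  }
})
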