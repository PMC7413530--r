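knuckleToy <- function() {
  # 2 tips + stem: branch classes {1,1} within vs {4} between
  structure(list(edge = matrix(c(3L, 4L, 4L, 1L, 4L, 2L), 3, 2, byrow = TRUE),
                 tip.label = c("a", "b"), edge.length = c(4, 1, 1),
                 Nnode = 2L), class = "phylo")
}

test_that("the PTP log-likelihood matches hand arithmetic on a 3-branch toy", {
  ll <- ptpLoglik(knuckleToy(), speciesRoots = 4L)
  expect_equal(as.numeric(ll), 2 * (log(1) - 1) + (log(0.25) - 1))
  r <- attr(ll, "rates")
  expect_equal(unname(r[["lambdaCoal"]]), 1)       # 2 branches / length 2
  expect_equal(unname(r[["lambdaSp"]]), 0.25)      # 1 branch / length 4
})

test_that("equal branch lengths make every delimitation equally likely", {
  tr <- readNewick("((a:0.3,b:0.3):0.3,(c:0.3,d:0.3):0.3);")
  prep <- mycodelim:::.ptpPrep(tr)
  sets <- mycodelim:::.enumRootSets(prep, prep$root)
  lls <- vapply(sets, function(s) as.numeric(ptpLoglik(tr, s)), numeric(1))
  n <- nrow(tr$edge)
  expect_equal(lls, rep(n * (-log(0.3) - 1), length(lls)), tolerance = 1e-12)
  # tie broken toward the single-species null
  expect_equal(length(mlPtp(tr)@speciesRoots), 1L)
})

test_that("inconsistent delimitations are rejected naming the offender", {
  tr <- readNewick("((a:1,b:1):1,c:1);")
  expect_error(ptpLoglik(tr, speciesRoots = c(4L, 1L)), "tip 'a'")
  expect_error(ptpLoglik(tr, speciesRoots = c(1L, 2L)), "tip 'c'")
})

test_that("PTP log-likelihoods equal an exhaustive naive oracle on small trees", {
  set.seed(20)
  for (rep in 1:4) {
    tr <- ape::rtree(sample(4:6, 1))
    sets <- ptpAllRootSetsOracle(tr)
    prepSets <- mycodelim:::.enumRootSets(mycodelim:::.ptpPrep(tr),
                                          length(tr$tip.label) + 1L)
    # the two enumerations agree on the state space
    key <- function(s) paste(sort(s), collapse = ",")
    expect_setequal(vapply(sets, key, character(1)),
                    vapply(prepSets, key, character(1)))
    for (s in sets)
      expect_equal(as.numeric(ptpLoglik(tr, s)), ptpLoglikOracle(tr, s),
                   tolerance = 1e-9)
  }
})

test_that("maximum-likelihood search is exact on enumerable trees", {
  set.seed(21)
  for (rep in 1:4) {
    tr <- ape::rtree(sample(5:8, 1))
    best <- max(vapply(ptpAllRootSetsOracle(tr),
                       function(s) ptpLoglikOracle(tr, s), numeric(1)))
    expect_equal(mlPtp(tr)@logLik, best, tolerance = 1e-9)
  }
})

test_that("the null model never beats the ML delimitation", {
  set.seed(22)
  for (rep in 1:5) {
    tr <- ape::rtree(10)
    null <- as.numeric(ptpLoglik(tr, length(tr$tip.label) + 1L))
    expect_gte(mlPtp(tr)@logLik, null - 1e-12)
  }
})

test_that("greedy search attains the exhaustive optimum on most random trees", {
  set.seed(23)
  hits <- 0L
  n <- 30L
  for (rep in seq_len(n)) {
    tr <- ape::rtree(8, br = function(k) rexp(k, 5))
    exact <- mlPtp(tr)@logLik
    greedy <- mlPtp(tr, exhaustiveMax = 2L)@logLik
    expect_lte(greedy, exact + 1e-9)
    if (greedy >= exact - 1e-9) hits <- hits + 1L
  }
  expect_gte(hits / n, 0.95)
})

test_that("two well-separated clades are delimited as two species", {
  tr <- twoCladeTree(101, n = 6, within = 0.001, stem = 0.5)
  d <- mlPtp(tr)
  expect_equal(length(d@speciesRoots), 2L)
  byTip <- split(names(d@assignment), d@assignment)
  expect_setequal(vapply(byTip, function(x) paste(sort(x), collapse = ","),
                         character(1)),
                  c(paste(sort(paste0("t", 1:6)), collapse = ","),
                    paste(sort(paste0("u", 1:6)), collapse = ",")))
})

test_that("a degenerate all-floor tree returns the single-species null", {
  tr <- readNewick("((a:0,b:0):0,c:0);")
  expect_warning(d <- mlPtp(tr), "floor")
  expect_equal(length(d@speciesRoots), 1L)
})

test_that("the chain is deterministic under a fixed seed", {
  tr <- twoCladeTree(31, n = 4)
  cfg <- McmcConfig(5000L, 10L, 0.1, seed = 77L)
  a <- bptp(tr, cfg); b <- bptp(tr, cfg)
  expect_identical(a@trace, b@trace)
  expect_identical(a@nodeSupport, b@nodeSupport)
  expect_error(bptp(ape::unroot(tr), cfg), "unrooted")
  expect_error(McmcConfig(10L, 100L), "generations")
})

test_that("chain frequencies match the exact enumeration posterior", {
  # small-case exactness: posterior over all delimitations of a 3-tip tree
  tr <- readNewick("((a:0.02,b:0.03):0.6,c:0.5);")
  prep <- mycodelim:::.ptpPrep(tr)
  sets <- mycodelim:::.enumRootSets(prep, prep$root)
  lls <- vapply(sets, function(s) as.numeric(ptpLoglik(tr, s)), numeric(1))
  w <- exp(lls - max(lls)); w <- w / sum(w)
  keys <- vapply(sets, function(s) paste(sort(s), collapse = ","), character(1))
  res <- bptp(tr, McmcConfig(60000L, 10L, 0.2, seed = 5L))
  for (i in seq_along(keys)) {
    got <- res@partitionFreq$freq[match(keys[i], res@partitionFreq$key)]
    if (is.na(got)) got <- 0
    expect_equal(got, w[i], tolerance = 0.05)
  }
  # 2-tip tree: both delimitations have equal likelihood -> 50/50 visits
  tr2 <- readNewick("(a:0.1,b:0.4);")
  res2 <- bptp(tr2, McmcConfig(40005L, 7L, 0.2, seed = 6L))
  expect_equal(res2@partitionFreq$freq[1], 0.5, tolerance = 0.06)
})

test_that("posterior supports are probabilities and nest consistently", {
  tr <- twoCladeTree(41, n = 5, within = 0.01, stem = 0.3)
  res <- bptp(tr, McmcConfig(20000L, 20L, 0.1, seed = 9L))
  expect_true(all(res@nodeSupport >= 0 & res@nodeSupport <= 1))
  expect_true(res@acceptanceRate >= 0 && res@acceptanceRate <= 1)
  # for any tip, the supports of the mutually exclusive species containing it
  # (its ancestors-or-self) sum to at most 1
  prep <- mycodelim:::.ptpPrep(tr)
  for (tip in seq_along(tr$tip.label)) {
    v <- tip; anc <- v
    while (prep$parent[v] != 0L) { v <- prep$parent[v]; anc <- c(anc, v) }
    expect_lte(sum(res@nodeSupport[anc]), 1 + 1e-9)
  }
})

test_that("delimitation artifacts export cleanly", {
  tr <- twoCladeTree(51, n = 4)
  res <- bptp(tr, McmcConfig(10000L, 20L, 0.1, seed = 3L))
  nwk <- supportAnnotatedNewick(res)
  expect_true(grepl("^\\(", nwk))
  expect_equal(length(readNewick(nwk)$node.label), tr$Nnode)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeMcmcTrace(res, f)
  tab <- read.delim(f)
  expect_equal(names(tab), c("generation", "logLik", "nSpecies"))
  d <- modalDelimitation(res)
  expect_equal(nrow(delimitationTable(d)), length(tr$tip.label))
})
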