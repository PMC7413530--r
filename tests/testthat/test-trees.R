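test_that("newick round-trips preserve topology, lengths and labels", {
  for (txt in c("(A:0.1,B:0.2);",
                "((A:0.1,B:0.2):0.05,(C:0.3,(D:0.1,E:0.4):0.2):0.1);",
                "((A:0.1,B:0.2)inner:0.05,C:0.3);")) {
    tr <- readNewick(txt)
    back <- readNewick(writeNewick(tr))
    expect_identical(sort(back$tip.label), sort(tr$tip.label))
    expect_equal(patristicDistances(back)[tr$tip.label, tr$tip.label],
                 patristicDistances(tr), tolerance = 1e-9)
  }
  tr <- readNewick("((A:0.1,B:0.2)inner:0.05,C:0.3);")
  expect_true("inner" %in% tr$node.label)   # unlabeled/labeled internals kept
  expect_error(readNewick("((A:0.1,B:0.2:0.05;"), "malformed")
})

test_that("neighbor-joining recovers an additive 4-taxon tree exactly", {
  true <- readNewick("((A:0.2,B:0.3):0.15,C:0.4,D:0.55);")
  d <- patristicDistances(true)
  nj <- njTree(d)
  expect_equal(ape::dist.topo(ape::unroot(true), ape::unroot(nj)), 0,
               ignore_attr = TRUE)
  expect_equal(patristicDistances(nj)[rownames(d), colnames(d)], d,
               tolerance = 1e-9)
})

test_that("3-taxon neighbor-joining solves the three-point formulas", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  nj <- njTree(d)
  pd <- patristicDistances(nj)
  expect_equal(pd["A", "B"], 3)
  expect_equal(pd["A", "C"], 4)
  expect_equal(pd["B", "C"], 5)
  # closed form: a = (dAB + dAC - dBC)/2 etc.
  lens <- setNames(nj$edge.length[match(1:3, nj$edge[, 2])], nj$tip.label)
  expect_equal(unname(lens[c("A", "B", "C")]), c(1, 2, 3))
  expect_error(njTree(d[1:2, 1:2]), "at least 3")
})

test_that("neighbor-joining pairs the cherries of an ultrametric matrix", {
  true <- readNewick("((A:1,B:1):3,(C:1,D:1):3);")
  nj <- njTree(patristicDistances(true))
  expect_equal(ape::dist.topo(ape::unroot(true), ape::unroot(nj)), 0,
               ignore_attr = TRUE)
  # clamping property: output lengths are never negative
  set.seed(31)
  for (i in 1:5) {
    x <- matrix(runif(12), 6)
    d <- as.matrix(dist(x)); dimnames(d) <- list(letters[1:6], letters[1:6])
    expect_true(all(suppressWarnings(njTree(d))$edge.length >= 0))
  }
})

test_that("patristic distances match brute-force path enumeration", {
  expect_equal(patristicDistances(readNewick("(A:0.1,B:0.2);"))["A", "B"], 0.3)
  set.seed(5)
  for (i in 1:5) {
    tr <- ape::rtree(5)
    d <- patristicDistances(tr)
    expect_equal(unname(diag(d)), rep(0, 5))
    expect_equal(d, patristicOracle(tr), tolerance = 1e-12)
  }
})

test_that("patristic matrices satisfy the four-point condition", {
  set.seed(6)
  tr <- ape::rtree(8)
  d <- patristicDistances(tr)
  combs <- utils::combn(8, 4)
  for (k in seq_len(ncol(combs))) {
    q <- combs[, k]
    sums <- sort(c(d[q[1], q[2]] + d[q[3], q[4]],
                   d[q[1], q[3]] + d[q[2], q[4]],
                   d[q[1], q[4]] + d[q[2], q[3]]))
    expect_lt(sums[3] - sums[2], 1e-9)
  }
})

test_that("neighbor-joining from patristic distances reproduces the topology", {
  set.seed(7)
  for (i in 1:5) {
    tr <- ape::rtree(7)
    tr$edge.length <- tr$edge.length + 0.05       # all branches > 0
    nj <- njTree(patristicDistances(tr))
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(nj)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("outgroup pruning sums branch lengths through removed nodes", {
  tr <- readNewick("((A:0.1,B:0.2):0.3,C:0.4);")
  pruned <- pruneOutgroup(tr, "C")
  expect_setequal(pruned$tip.label, c("A", "B"))
  expect_equal(patristicDistances(pruned)["A", "B"], 0.3)
  expect_identical(pruneOutgroup(tr, character(0)), tr)
  expect_error(pruneOutgroup(tr, "Z"), "unknown")
  expect_error(pruneOutgroup(tr, c("A", "B")), "fewer than 2")
})

test_that("group distance summaries report min, max and mean per pair", {
  tr <- readNewick("((A:1,B:2):5,(C:1,D:3):5);")
  g <- c(A = "x", B = "x", C = "y", D = "y")
  s <- groupDistanceSummary(tr, g)
  xy <- s[s$group1 == "x" & s$group2 == "y", ]
  expect_equal(xy$min, 12)    # A-C: 1+5+5+1
  expect_equal(xy$max, 15)    # B-D: 2+5+5+3
  xx <- s[s$group1 == "x" & s$group2 == "x", ]
  expect_equal(xx$min, 3)
})

test_that("CADM is exact for identical matrices and bounded below by 1/k", {
  set.seed(8)
  x <- matrix(runif(16), 8)
  d <- as.matrix(dist(x)); dimnames(d) <- list(letters[1:8], letters[1:8])
  r <- cadmGlobal(list(d, d), nPerm = 99, seed = 1)
  expect_equal(r$W, 1)
  expect_lte(r$p, 5 / 100)       # concordance of identical matrices detected
  # W >= 1/k for k matrices
  mats <- lapply(1:4, function(i) {
    y <- matrix(runif(16), 8); m <- as.matrix(dist(y))
    dimnames(m) <- dimnames(d); m
  })
  r4 <- cadmGlobal(mats, nPerm = 49, seed = 2)
  expect_gte(r4$W, 1 / 4 - 1e-12)
  expect_lte(r4$W, 1)
  expect_error(cadmGlobal(list(d), nPerm = 9), "two")
  m2 <- mats[[1]]; rownames(m2)[1] <- colnames(m2)[1] <- "zz"
  expect_error(cadmGlobal(list(d, m2), nPerm = 9), "label")
})

test_that("CADM W agrees with the reference implementation in ape", {
  set.seed(9)
  mats <- lapply(1:3, function(i) {
    m <- as.matrix(dist(matrix(runif(14), 7)))
    dimnames(m) <- list(letters[1:7], letters[1:7]); m
  })
  mine <- cadmGlobal(mats, nPerm = 9, seed = 1)
  ref <- ape::CADM.global(do.call(rbind, mats), 3, 7, nperm = 9)
  expect_equal(mine$W, unname(ref$congruence_analysis[1, 1]), tolerance = 1e-10)
})

test_that("CADM p-values follow the add-one permutation convention", {
  set.seed(10)
  m <- as.matrix(dist(matrix(runif(12), 6)))
  dimnames(m) <- list(letters[1:6], letters[1:6])
  r <- cadmGlobal(list(m, m), nPerm = 19, seed = 3)
  expect_gte(r$p, 1 / 20)
  # pairwise wrapper returns one row per pair
  mats <- list(m, m, m)
  pw <- cadmPairwise(mats, nPerm = 9, seed = 1)
  expect_equal(nrow(pw), 3L)
  expect_true(all(pw$W == 1))
})

test_that("distance matrices round-trip through square TSV", {
  m <- as.matrix(dist(matrix(rnorm(10), 5)))
  dimnames(m) <- list(paste0("s", 1:5), paste0("s", 1:5))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeDistanceMatrixTsv(m, f)
  expect_equal(readDistanceMatrixTsv(f), m, tolerance = 1e-12)
})
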