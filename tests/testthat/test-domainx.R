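countFixture <- function() {
  m <- matrix(c(10, 90,
                30, 270,
                20, 180), nrow = 3, byrow = TRUE,
              dimnames = list(c("Lf", "A", "B"), c("d1", "d2")))
  domainCountMatrix(m)
}

test_that("count matrices read, validate and round-trip", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("genome\tdomain\tcount", "g1\td1\t5", "g1\td2\t7",
               "g2\td1\t3", "g3\td2\t1"), f)
  m <- readDomainCounts(f)
  expect_equal(dim(domainCounts(m)), c(3L, 2L))
  expect_equal(domainCounts(m)["g2", "d2"], 0)   # zero-filled
  expect_equal(unname(genomeTotals(m)), c(12, 3, 1))

  f2 <- tempfile(fileext = ".tsv")
  writeDomainCounts(m, f2)
  m2 <- readDomainCounts(f2)
  expect_equal(domainCounts(m2)[genomeNames(m), domainNames(m)],
               domainCounts(m))

  writeLines(c("genome\tdomain\tcount", "g1\td1\t5", "g1\td1\t2",
               "g2\td1\t1"), f)
  expect_error(readDomainCounts(f), "duplicate")
  writeLines(c("genome\tdomain\tcount", "g1\td1\t-2", "g2\td1\t1"), f)
  expect_error(readDomainCounts(f), "negative")
})

test_that("HMMER-style tables are filtered at the e-value threshold", {
  f1 <- tempfile(); f2 <- tempfile()
  writeLines(c("# comment line",
               "DomX PF00001.1 200 prot1 - 300 1e-06 10 1.5 - - -",
               "DomX PF00001.1 200 prot2 - 280 1e-04 9 1.1 - - -",
               "DomY PF00002.2 150 prot3 - 310 1e-30 50 2.2 - - -"), f1)
  writeLines("DomY PF00002.2 150 protz - 310 1e-10 40 2.0 - - -", f2)
  m <- readDomtbl(c(gA = f1, gB = f2), eValueMax = 1e-5)
  expect_equal(domainCounts(m)["gA", "PF00001.1"], 1)  # 1e-04 filtered out
  expect_equal(domainCounts(m)["gA", "PF00002.2"], 1)
  expect_equal(domainCounts(m)["gB", "PF00002.2"], 1)
})

test_that("expected counts follow frequency averaging over other genomes", {
  ## A: 10 of 100; B: 30 of 300 -> frequencies both 0.1; focal total 200
  lam <- expectedLambda(countFixture(), "Lf")
  expect_equal(unname(lam["d1"]), 0.1 * 100)

  set.seed(5)
  cnt <- matrix(rpois(5 * 20, 40), 5, 20,
                dimnames = list(paste0("g", 1:5), paste0("d", 1:20)))
  m <- domainCountMatrix(cnt)
  lam <- expectedLambda(m, "g3")
  for (d in sample(colnames(cnt), 6))
    expect_equal(unname(lam[d]), bruteLambda(cnt, "g3", d))

  allz <- domainCounts(countFixture()); allz["A", ] <- 0
  expect_error(expectedLambda(domainCountMatrix(allz), "Lf"), "zero total")
})

test_that("Poisson tails match closed forms, identities and conventions", {
  expect_equal(poissonTails(7, 2)$pUp, 0.00453, tolerance = 1e-3)
  for (lam in c(0.5, 2, 10)) {
    t0 <- poissonTails(0, lam)
    expect_equal(t0$pDown, exp(-lam))
    expect_equal(t0$pUp, 1)
  }
  set.seed(6)
  for (rep in 1:25) {
    x <- sample(0:60, 1); lam <- runif(1, 0, 50)
    tl <- poissonTails(x, lam)
    expect_equal(tl$pUp + tl$pDown - dpois(x, lam), 1)
  }
  ## the lambda = 0 point mass
  expect_equal(poissonTails(0, 0), list(pUp = 1, pDown = 1))
  expect_equal(poissonTails(3, 0), list(pUp = 0, pDown = 1))
  expect_error(poissonTails(-1, 2), "non-negative")
  expect_error(poissonTails(2, -1), "non-negative")
})

test_that("domain tests adjust, call directions and respect invariants", {
  m <- countFixture()
  res <- testDomains(m, "Lf")
  expect_equal(S4Vectors::metadata(res)$mTests, 2L)
  tails <- poissonTails(10, unname(expectedLambda(m, "Lf")["d1"]))
  expect_equal(res$pAdjUp[res$domain == "d1"],
               min(1, tails$pUp * 2 * 2))   # directions family: 2m

  ## observed equal to (rounded) expectation is always neutral
  cnt <- matrix(c(40, 400, 40, 400, 40, 400), 3, 2, byrow = TRUE,
                dimnames = list(c("Lf", "A", "B"), c("d1", "d2")))
  expect_true(all(testDomains(domainCountMatrix(cnt), "Lf")$call == "neutral"))

  ## frequency normalization: scaling one non-focal genome is a no-op
  sim <- simDomainMatrix(nDomains = 80, nExpanded = 2,
                         nContracted = 2, seed = 17)
  base <- testDomains(sim$matrix, "Lf")
  cnt2 <- domainCounts(sim$matrix)
  cnt2[3, ] <- cnt2[3, ] * 5
  scaled <- testDomains(domainCountMatrix(cnt2), "Lf")
  expect_equal(base$lambda, scaled$lambda)
  expect_identical(base$call, scaled$call)

  ## Bonferroni never makes more calls than unadjusted thresholding
  raw <- sum(base$pUp <= 0.05 & base$observed > base$lambda) +
         sum(base$pDown <= 0.05 & base$observed < base$lambda)
  expect_lte(sum(base$call != "neutral"), raw)

  ## a domain observed only in the focal genome is an automatic expansion
  d0 <- matrix(c(3, 100, 0, 100, 0, 100), 3, 2, byrow = TRUE,
               dimnames = list(c("Lf", "A", "B"), c("rare", "common")))
  r0 <- testDomains(domainCountMatrix(d0), "Lf")
  expect_identical(r0$call[r0$domain == "rare"], "expanded")
  expect_equal(r0$pUp[r0$domain == "rare"], 0)

  expect_error(testDomains(m, "Lf", alpha = 0), "alpha")
  expect_error(testDomains(m, "nope"), "unknown focal")
})

test_that("log2 ratios normalize, invert and scale as documented", {
  cnt <- matrix(rep(c(5, 50, 500), 3), 3, 3, byrow = TRUE,
                dimnames = list(paste0("g", 1:3), paste0("d", 1:3)))
  lrm <- log2RatioMatrix(domainCountMatrix(cnt))
  expect_true(all(abs(ratioMatrix(lrm)) < 1e-12))   # identical rows -> 0

  ## normalized frequencies sum to 1 per genome before rescaling
  expect_true(all(abs(rowSums(lrm@normalizedCounts) /
                      mean(genomeTotals(domainCountMatrix(cnt))) - 1) < 1e-12))

  ## one genome doubled on one domain approaches +1 as pc -> 0 and the
  ## reference mean is dominated by the unchanged genomes
  n <- 50
  cnt2 <- matrix(rep(c(100, 9900), each = n), n, 2,
                 dimnames = list(paste0("g", sprintf("%02d", 1:n)),
                                 c("dA", "dB")))
  cnt2[1, "dA"] <- 200
  lrm2 <- log2RatioMatrix(domainCountMatrix(cnt2), pseudocount = 1e-9)
  expect_equal(ratioMatrix(lrm2)[1, "dA"], 1, tolerance = 0.05)

  ## reconstruction invariant on random matrices
  set.seed(9)
  cnt3 <- matrix(rpois(6 * 10, 30) + 1, 6, 10,
                 dimnames = list(paste0("g", 1:6), paste0("d", 1:10)))
  lrm3 <- log2RatioMatrix(domainCountMatrix(cnt3), pseudocount = 0.5)
  rec <- log2(sweep(lrm3@normalizedCounts + 0.5, 2,
                    lrm3@referenceMeans + 0.5, "/"))
  expect_equal(ratioMatrix(lrm3), rec)
})

test_that("clustering merges identical rows first and matches brute force", {
  X <- rbind(a = c(4, 4, 0, 0), b = c(4, 4, 0, 0), c = c(-1, 0, 2, 1))
  cl <- clusterRatios(X)
  expect_identical(c(cl$merges$label1[1], cl$merges$label2[1]), c("a", "b"))
  expect_equal(cl$merges$height[1], 0)

  set.seed(10)
  for (rep in 1:10) {
    M <- matrix(rnorm(40), 5, 8,
                dimnames = list(paste0("g", 1:5), paste0("d", 1:8)))
    cl <- clusterRatios(M)
    oracle <- bruteCompleteLinkage(M)
    expect_identical(cl$merges$label1, oracle$label1)
    expect_identical(cl$merges$label2, oracle$label2)
    expect_equal(cl$merges$height, oracle$height)
  }
})

test_that("dendrograms serialize to Newick and re-parse to the same topology", {
  set.seed(12)
  M <- matrix(rnorm(48), 6, 8,
              dimnames = list(paste0("g", 1:6), paste0("d", 1:8)))
  cl <- clusterRatios(M)
  tr <- ape::read.tree(text = cl$newick)
  expect_setequal(tr$tip.label, rownames(M))
  ref <- ape::as.phylo(cl$hclust)
  expect_true(ape::all.equal.phylo(tr, ref, use.edge.length = FALSE))

  expect_error(clusterRatios(M[1, , drop = FALSE]), "at least two")
})
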