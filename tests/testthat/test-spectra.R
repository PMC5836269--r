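test_that("histogram parsing handles clean, malformed and unordered input", {
  f <- tempfile()
  writeLines(c("1 100", "2 50", "3 10"), f)
  h <- readHisto(f, k = 25)
  expect_s4_class(h, "KmerHistogram")
  expect_identical(multiplicities(h), 1:3)
  expect_identical(kmerCounts(h), c(100, 50, 10))
  expect_identical(kmerLength(h), 25L)

  writeLines(c("2 50", "1 100"), f)
  expect_identical(multiplicities(readHisto(f, k = 25)), 1:2)
  expect_error(readHisto(f, k = 25, resort = FALSE), "out of order")

  writeLines(c("1 100", "oops"), f)
  expect_error(readHisto(f, k = 25), "line 2")
  writeLines(character(0), f)
  expect_error(readHisto(f, k = 25), "empty")
})

test_that("a written histogram re-reads identically", {
  h <- KmerHistogram(31, c(1L, 5L, 44L, 45L, 46L), c(1e6, 3, 2e5, 3e5, 1e5))
  f <- tempfile()
  writeHisto(h, f)
  h2 <- readHisto(f, k = 31)
  expect_identical(multiplicities(h2), multiplicities(h))
  expect_equal(kmerCounts(h2), kmerCounts(h))
})

test_that("total volume matches closed forms and a brute-force sum", {
  h <- KmerHistogram(25, 1:2, c(100, 50))
  expect_equal(totalVolume(h), 200)
  expect_equal(totalVolume(h, 2, 2), 100)
  expect_equal(totalVolume(h, 5, 10), 0)
  expect_error(totalVolume(h, 3, 1), "lo")

  set.seed(11)
  for (rep in 1:20) {
    m <- sort(sample.int(500, 50))
    cnt <- sample.int(1e5, 50)
    h <- KmerHistogram(25, m, cnt)
    lo <- sample(m, 1)
    cand <- m[m >= lo]
    hi <- cand[sample.int(length(cand), 1)]
    expect_equal(totalVolume(h, lo, hi),
                 sum(m[m >= lo & m <= hi] * cnt[m >= lo & m <= hi]))
    ## additivity over a split point
    expect_equal(totalVolume(h, 1, hi) + totalVolume(h, hi + 1, Inf),
                 totalVolume(h))
  }
})

test_that("error threshold is the first local minimum after the error limb", {
  h <- KmerHistogram(25, 1:7, c(1000, 400, 100, 40, 60, 90, 60))
  expect_identical(detectErrorThreshold(h, smoothWindow = 1L), 4L)

  dec <- KmerHistogram(25, 1:5, c(100, 80, 60, 40, 20))
  expect_error(detectErrorThreshold(dec), "no valley")

  for (s in 1:5) {
    sim <- simDiploidSpectrum(3e5, 0.02, 45, errorRate = 0.01, k = 25,
                              seed = s)
    e <- detectErrorThreshold(sim$histogram)
    expect_gt(e, 1)
    expect_lt(e, 22.5)
  }
})

test_that("peak detection finds planted peaks and is scale invariant", {
  single <- KmerHistogram(25, 1:60, c(5000, 500, rep(5, 26),
                                      dpois(29:60, 30) * 1e6)[1:60])
  pk <- detectPeaks(single, e = 3)
  expect_true(30 %in% pk$depth)

  sim <- simDiploidSpectrum(1e6, 0.02, 45, errorRate = 0.01, k = 25,
                            seed = 42)
  e <- detectErrorThreshold(sim$histogram)
  pk <- detectPeaks(sim$histogram, e)
  dom <- pk[pk$height >= 0.05 * max(pk$height), ]
  expect_equal(nrow(dom), 2L)
  expect_lte(abs(dom$depth[1] - 22), 2)
  expect_lte(abs(dom$depth[2] - 45), 2)

  scaled <- KmerHistogram(25, multiplicities(sim$histogram),
                          kmerCounts(sim$histogram) * 7)
  expect_identical(detectPeaks(scaled, e)$depth, pk$depth)
})

test_that("ploidy classification follows the two-peak depth-ratio rule", {
  expect_identical(
    classifyPloidy(data.frame(depth = c(22, 45), height = c(5e5, 9e5))),
    "diploid-heterozygous")
  expect_identical(
    classifyPloidy(data.frame(depth = 30, height = 1e6)), "haploid-like")
  expect_identical(
    classifyPloidy(data.frame(depth = c(20, 70), height = c(5e5, 9e5))),
    "ambiguous")
  expect_identical(
    classifyPloidy(data.frame(depth = integer(0), height = numeric(0))),
    "ambiguous")
})

test_that("genome size follows the volume-minus-errors over peak-depth rule", {
  h <- KmerHistogram(25, c(1L, 2L, 30L), c(40000, 15000, 100000))
  expect_equal(totalVolume(h), 3070000)
  expect_equal(estimateGenomeSize(h, e = 3, cHom = 30), 100000)

  noiseless <- KmerHistogram(25, 40L, 250000)
  expect_identical(estimateGenomeSize(noiseless, e = 1, cHom = 40),
                   250000)

  ## scaling counts scales G; scaling the peak depth divides it
  h2 <- KmerHistogram(25, c(1L, 2L, 30L), c(40000, 15000, 100000) * 3)
  expect_equal(estimateGenomeSize(h2, 3, 30), 300000)
  expect_equal(estimateGenomeSize(h, 3, 60), 50000)
  expect_error(estimateGenomeSize(h, 3, 0), "cHom")
})

test_that("heterozygosity follows the het-volume model", {
  h <- KmerHistogram(17, 15L, 17000)
  r <- estimateHeterozygosity(h, e = 3, cHet = 15, cHom = 30, k = 17,
                              G = 1e5, window = c(10, 20),
                              truncationCorrection = FALSE)
  expect_equal(r, 0.005)   # 255000/15/(2*17)/1e5

  empty <- KmerHistogram(17, c(3L, 30L), c(10, 1000))
  expect_equal(estimateHeterozygosity(empty, 2, cHet = 15, cHom = 30,
                                      k = 17, G = 1e5, window = c(10, 20),
                                      truncationCorrection = FALSE), 0)
  expect_warning(
    estimateHeterozygosity(empty, 2, cHet = NA, cHom = 30, k = 17, G = 1e5),
    "no heterozygous peak")
})

test_that("profiles honour overrides, flag haploids and conserve volume", {
  sim <- simDiploidSpectrum(5e5, 0.02, 45, k = 25, seed = 9)
  p <- profileSpectrum(sim$histogram,
                       overrides = list(errorThreshold = 12,
                                        homPeakDepth = 45))
  expect_identical(p@errorThreshold, 12)
  expect_identical(p@homPeakDepth, 45)
  expect_setequal(p@overrides, c("errorThreshold", "homPeakDepth"))

  hap <- simDiploidSpectrum(5e5, 0, 45, k = 25, seed = 9)
  ph <- profileSpectrum(hap$histogram)
  expect_identical(ph@ploidyCall, "haploid-like")
  expect_identical(ph@heterozygosity, 0)
  expect_match(paste(ph@notes, collapse = " "), "no heterozygous peak")

  ## volume conservation: error + retained = total, exactly
  p2 <- profileSpectrum(sim$histogram)
  retained <- totalVolume(sim$histogram, p2@errorThreshold)
  expect_identical(p2@errorVolume + retained, p2@totalVolume)
  expect_true(p2@errorThreshold < p2@hetPeakDepth)
  expect_true(p2@hetPeakDepth < p2@homPeakDepth)

  expect_error(profileSpectrum(sim$histogram, overrides = list(bogus = 1)),
               "unknown override")
})
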