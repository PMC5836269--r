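## small fixture helpers: build a GeneModelSet from a compact exon table
gmFromTable <- function(tab) {
  geneModelSet(GenomicRanges::GRanges(
    tab$scaffold, IRanges::IRanges(tab$start, tab$end),
    strand = if (is.null(tab$strand)) "+" else tab$strand,
    model_id = tab$model_id))
}

ev <- function(id, qlen, span, evalue = 1e-40, subject = "sp|1") {
  data.frame(model_id = id, subject_id = subject, query_length = qlen,
             aligned_query_span = span, e_value = evalue)
}

test_that("gene-model sets validate exon structure", {
  bad <- GenomicRanges::GRanges("s", IRanges::IRanges(c(1, 50), c(100, 120)),
                                model_id = c("m1", "m1"))
  expect_error(geneModelSet(bad), "non-overlapping")
  ok <- gmFromTable(data.frame(scaffold = "s", start = c(1, 200),
                               end = c(100, 280), model_id = "m1"))
  expect_equal(modelTable(ok)$nExons, 2L)
  expect_equal(modelTable(ok)$cdsLength, 100 + 81)
})

test_that("best-hit selection is deterministic over e-value, span, subject", {
  e <- rbind(ev("m1", 100, 50, 1e-30, "spB"),
             ev("m1", 100, 90, 1e-40, "spC"),
             ev("m1", 100, 80, 1e-40, "spA"))
  best <- bestHits(e)
  expect_equal(nrow(best), 1L)
  expect_equal(best$aligned_query_span, 90)   # min e-value, then max span
  e2 <- rbind(ev("m1", 100, 90, 1e-40, "spB"),
              ev("m1", 100, 90, 1e-40, "spA"))
  expect_equal(bestHits(e2)$subject_id, "spA")
})

test_that("coverage filter keeps >= 90% aligned queries, boundary inclusive", {
  m <- gmFromTable(data.frame(scaffold = rep(c("s1", "s2", "s3"), each = 1),
                              start = c(1, 1, 1), end = c(300, 300, 300),
                              model_id = c("mA", "mB", "mC")))
  e <- rbind(ev("mA", 100, 90), ev("mB", 100, 89))
  res <- coverageFilter(m, e)
  expect_setequal(modelIds(res$models), "mA")
  expect_equal(res$rejected$reason[res$rejected$id == "mB"], "low-coverage")
  expect_equal(res$rejected$reason[res$rejected$id == "mC"], "no-hit")

  expect_error(coverageFilter(m, ev("ghost", 100, 95)), "unknown model")
})

test_that("exon filter applies the configurable exon-count threshold", {
  mk <- function(id, nEx) data.frame(
    scaffold = id, start = seq(1, by = 200, length.out = nEx),
    end = seq(100, by = 200, length.out = nEx), model_id = id)
  m <- gmFromTable(rbind(mk("mA", 4), mk("mB", 3), mk("mC", 1)))
  expect_setequal(modelIds(exonFilter(m)$models), "mA")
  expect_setequal(modelIds(exonFilter(m, minExons = 3)$models),
                  c("mA", "mB"))
  expect_false("mC" %in% modelIds(exonFilter(m, minExons = 3)$models))
})

test_that("redundancy filter removes nested and chained duplicates", {
  ## B (500 bp, one exon) nested in A (1000 bp)
  m <- gmFromTable(data.frame(scaffold = "s",
                              start = c(1, 101), end = c(1000, 600),
                              model_id = c("A", "B")))
  res <- redundancyFilter(m)
  expect_setequal(modelIds(res$models), "A")
  expect_equal(res$rejected$id, "B")

  ## disjoint models both survive
  d <- gmFromTable(data.frame(scaffold = "s", start = c(1, 5000),
                              end = c(1000, 6000), model_id = c("A", "B")))
  expect_setequal(modelIds(redundancyFilter(d)$models), c("A", "B"))

  ## chain A > B > C collapses to A
  ch <- gmFromTable(data.frame(scaffold = "s",
                               start = c(1, 101, 201),
                               end = c(1000, 800, 600),
                               model_id = c("A", "B", "C")))
  expect_setequal(modelIds(redundancyFilter(ch)$models), "A")
})

test_that("redundancy filter matches the per-base brute-force fixpoint", {
  set.seed(77)
  for (rep in 1:5) {
    n <- 40
    tab <- do.call(rbind, lapply(seq_len(n), function(i) {
      scaf <- paste0("s", sample.int(4, 1))
      nEx <- sample.int(3, 1)
      start <- sort(sample.int(3000, nEx))
      width <- sample(30:150, nEx, replace = TRUE)
      ## force non-overlap within the model by spacing
      start <- start + cumsum(rep(200, nEx))
      data.frame(scaffold = scaf, start = start, end = start + width - 1,
                 model_id = sprintf("m%02d", i))
    }))
    m <- gmFromTable(tab)
    got <- sort(modelIds(redundancyFilter(m)$models))
    expect_identical(got, bruteRedundancy(tab))
  }
})

test_that("repeat filter enforces any-overlap rejection with closed bounds", {
  ## BED [100,200) exon = GRanges 101..200; repeat BED [199,300) = 200..300
  m <- gmFromTable(data.frame(scaffold = "s", start = 101, end = 200,
                              model_id = "m1"))
  overlapping <- GenomicRanges::GRanges("s", IRanges::IRanges(200, 300))
  expect_equal(nrow(modelTable(repeatFilter(m, overlapping)$models)), 0L)
  expect_equal(repeatFilter(m, overlapping)$rejected$reason,
               "repeat-overlap")

  ## abutting half-open intervals ([100,200) vs [200,300)) do not overlap
  abutting <- GenomicRanges::GRanges("s", IRanges::IRanges(201, 300))
  expect_setequal(modelIds(repeatFilter(m, abutting)$models), "m1")

  ## models on scaffolds absent from the track are kept, with a message
  off <- GenomicRanges::GRanges("other", IRanges::IRanges(1, 1000))
  expect_message(res <- repeatFilter(m, off), "repeat-free")
  expect_setequal(modelIds(res$models), "m1")
})

test_that("repeat filter agrees with brute-force interval intersection", {
  set.seed(88)
  for (rep in 1:5) {
    tab <- do.call(rbind, lapply(1:30, function(i) {
      start <- sort(sample.int(5000, 2)) + c(0, 300)
      data.frame(scaffold = paste0("s", sample.int(3, 1)),
                 start = start, end = start + sample(50:200, 2, replace = TRUE),
                 model_id = sprintf("m%02d", i))
    }))
    reps <- data.frame(scaffold = paste0("s", sample.int(3, 15, replace = TRUE)),
                       start = sample.int(5500, 15))
    reps$end <- reps$start + sample(20:400, 15, replace = TRUE)
    m <- gmFromTable(tab)
    gr <- GenomicRanges::GRanges(reps$scaffold,
                                 IRanges::IRanges(reps$start, reps$end))
    kept <- suppressMessages(modelIds(repeatFilter(m, gr)$models))
    expectedHits <- unique(unlist(lapply(split(tab, tab$model_id), function(e) {
      r <- reps[reps$scaffold == e$scaffold[1], ]
      if (nrow(r) && length(intersect(.positions(e$start, e$end),
                                      .positions(r$start, r$end))))
        e$model_id[1]
    })))
    expect_setequal(kept, setdiff(unique(tab$model_id), expectedHits))
  }
})

test_that("the cascade recovers planted truth, is idempotent and order-stable", {
  for (s in 1:3) {
    sim <- simGeneModels(n = 300, seed = s)
    res <- suppressMessages(
      curateModels(sim$models, sim$evidence, sim$repeats))
    expect_setequal(survivingModels(res$report),
                    sim$truth$id[sim$truth$expectedFate == "kept"])
    rej <- merge(rejectedModels(res$report),
                 sim$truth[sim$truth$expectedFate == "rejected", ], by = "id")
    expect_equal(rej$reason, rej$expectedReason)
    expect_equal(rej$stage, rej$expectedStage)

    ## idempotence: rerunning on survivors removes nothing
    again <- suppressMessages(
      curateModels(res$models, sim$evidence, sim$repeats))
    expect_setequal(survivingModels(again$report),
                    survivingModels(res$report))
    expect_equal(sum(stageCounts(again$report)$nIn -
                     stageCounts(again$report)$nOut), 0)

    ## order invariance: shuffling exon rows changes nothing
    ex <- exonRanges(sim$models)
    shuf <- geneModelSet(ex[sample(length(ex))])
    res2 <- suppressMessages(
      curateModels(shuf, sim$evidence, sim$repeats))
    expect_setequal(survivingModels(res2$report),
                    survivingModels(res$report))
  }
})

test_that("degenerate cascade inputs behave: all-passing and empty sets", {
  sim <- simGeneModels(n = 40, mix = c(clean = 1), seed = 4)
  res <- suppressMessages(
    curateModels(sim$models, sim$evidence, sim$repeats))
  expect_setequal(survivingModels(res$report), modelIds(sim$models))
  expect_equal(nrow(rejectedModels(res$report)), 0L)

  emptySet <- geneModelSet(GenomicRanges::GRanges())
  resE <- suppressMessages(curateModels(
    emptySet, sim$evidence[0, ], GenomicRanges::GRanges()))
  expect_equal(length(survivingModels(resE$report)), 0L)
  expect_equal(stageCounts(resE$report)$nIn[1], 0L)
})
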