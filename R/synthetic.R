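#' Simulate a diploid k-mer spectrum with known truth
#'
#' Emulates the spectrum of a diploid genome sequenced at a given
#' coverage: heterozygous sites contribute 2k haplotype-specific k-mer
#' species each, piling up near half the homozygous depth; the remaining
#' k-mers are shared by both haplotypes and pile up at the homozygous
#' depth; sequencing errors add a descending limb of near-unique k-mers
#' at low multiplicity. Two modes are available: the default
#' \code{"direct"} mode samples k-mer multiplicities analytically from
#' this model; \code{"sequence"} mode builds both haplotype sequences,
#' enumerates their k-mers, and samples multiplicities per k-mer
#' species, which validates the analytic mode on small genomes.
#'
#' @param genomeLen haploid genome length in bases (>= 10 k).
#' @param hetRate per-base heterozygosity (0 <= rate < 0.05).
#' @param coverage homozygous sequencing depth (>= 5).
#' @param errorRate per-base sequencing error rate.
#' @param k k-mer length.
#' @param seed RNG seed (the function calls \code{set.seed}).
#' @param mode \code{"direct"} or \code{"sequence"}.
#' @return list with \code{histogram} (a \linkS4class{KmerHistogram}) and
#'   \code{truth} (list of all planted parameters plus the mode).
#' @export
simDiploidSpectrum <- function(genomeLen, hetRate, coverage,
                               errorRate = 0.01, k = 25L, seed = 1L,
                               mode = c("direct", "sequence")) {
  mode <- match.arg(mode)
  if (genomeLen < 10 * k) stop("genomeLen must be at least 10*k")
  if (hetRate < 0 || hetRate >= 0.05) stop("hetRate must lie in [0, 0.05)")
  if (coverage < 5) stop("coverage must be at least 5")
  set.seed(seed)
  if (mode == "direct") {
    nHetSites <- rbinom(1L, as.integer(genomeLen), hetRate)
    nHetKmers <- 2L * k * nHetSites              # haplotype-specific species
    nHomKmers <- max(0L, as.integer(genomeLen) - k * nHetSites)
    mult <- c(rpois(nHomKmers, coverage),        # shared by both haplotypes
              rpois(nHetKmers, coverage / 2))    # one haplotype only
  } else {
    genome <- sample(c("A", "C", "G", "T"), genomeLen, replace = TRUE)
    hetPos <- which(runif(genomeLen) < hetRate)
    nHetSites <- length(hetPos)
    hapB <- genome
    for (p in hetPos) hapB[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                                genome[p]), 1L)
    kmersOf <- function(chars) {
      s <- paste(chars, collapse = "")
      substring(s, seq_len(genomeLen - k + 1L), seq_len(genomeLen - k + 1L) +
                  k - 1L)
    }
    occ <- table(c(kmersOf(genome), kmersOf(hapB)))
    ## each genomic occurrence of a species is sequenced at half depth
    mult <- rpois(length(occ), as.numeric(occ) * coverage / 2)
  }
  ## error k-mers: near-unique species, multiplicity 1 + geometric
  ## (mean 1.3); each read error corrupts ~k overlapping k-mers
  errVolume <- genomeLen * coverage * errorRate * k
  nErr <- round(errVolume / 1.3)
  if (nErr > 0) mult <- c(mult, 1L + rgeom(nErr, prob = 1 / 1.3))
  mult <- mult[mult > 0]
  tab <- table(mult)
  hist <- KmerHistogram(k = k, multiplicity = as.integer(names(tab)),
                        count = as.numeric(tab))
  list(histogram = hist,
       truth = list(scenario = "diploid-spectrum", seed = seed, mode = mode,
                    genomeLen = genomeLen, hetRate = hetRate,
                    coverage = coverage, errorRate = errorRate, k = k,
                    nHetSites = nHetSites,
                    expectedHetDepth = coverage / 2,
                    expectedHomDepth = coverage))
}

#' Simulate a scaffold FASTA with known per-record truth
#'
#' Draws scaffold lengths (log-normal by default, or exact lengths if
#' supplied), generates random sequence, soft-masks the requested
#' fraction of each record (as a lowercase prefix), and optionally
#' writes a FASTA. The truth table holds the exact length and masked
#' count per record.
#'
#' @param n number of scaffolds.
#' @param lengths optional explicit lengths (overrides the length law).
#' @param meanLength,sdLog log-normal length-law parameters.
#' @param maskedFraction fraction of each scaffold to soft-mask.
#' @param seed RNG seed.
#' @param path optional output FASTA path.
#' @return list with \code{fasta} (a \code{BStringSet}), \code{truth}
#'   (data.frame id, length, masked_bases, gap_bases) and \code{path}.
#' @export
simScaffolds <- function(n, lengths = NULL, meanLength = 5000, sdLog = 1,
                         maskedFraction = 0, seed = 1L, path = NULL) {
  if (n < 1) stop("n must be at least 1")
  set.seed(seed)
  if (is.null(lengths))
    lengths <- pmax(100L, as.integer(round(rlnorm(n, log(meanLength), sdLog))))
  if (length(lengths) != n) stop("lengths must have n entries")
  ids <- sprintf("scaffold%05d", seq_len(n))
  seqs <- vapply(lengths, function(L) {
    s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    nm <- round(maskedFraction * L)
    if (nm > 0) s[seq_len(nm)] <- tolower(s[seq_len(nm)])
    paste(s, collapse = "")
  }, "")
  fasta <- Biostrings::BStringSet(setNames(seqs, ids))
  truth <- data.frame(id = ids, length = as.integer(lengths),
                      masked_bases = as.integer(round(maskedFraction *
                                                        lengths)),
                      gap_bases = 0L)
  if (!is.null(path)) {
    lines <- as.vector(rbind(paste0(">", ids), seqs))
    writeLinesAtomic(lines, path)
  }
  list(fasta = fasta, truth = truth, path = path)
}

## largest-remainder apportionment of n into round(n*p) with sum n
.apportion <- function(n, p) {
  raw <- n * p / sum(p)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1L
  }
  as.integer(base)
}

#' Simulate gene models with planted curation-filter violations
#'
#' Generates a gene-model set, alignment evidence and a repeat track in
#' which each model either passes every curation filter or carries
#' exactly one planted violation: protein coverage below threshold
#' (\code{lowCoverage}), no protein hit at all (\code{noHit}), too few
#' exons (\code{fewExons}), a redundant shorter twin of another model
#' (\code{redundant}, allocated in pairs whose longer member survives),
#' or an exon overlapping a repeat (\code{repeatOverlap}). Models are
#' placed on separate scaffolds (twins share theirs) so no accidental
#' interactions arise, and every planted violator passes all stages
#' before its own. The truth table records each model's expected fate.
#'
#' @param n number of models.
#' @param mix named non-negative weights over
#'   \code{clean, lowCoverage, noHit, fewExons, redundant, repeatOverlap}.
#' @param seed RNG seed.
#' @param dir optional output directory for \code{models.gff3},
#'   \code{evidence.tsv}, \code{repeats.bed}, \code{truth.json}.
#' @return list with \code{models} (\linkS4class{GeneModelSet}),
#'   \code{evidence}, \code{repeats} (\code{GRanges}), \code{truth}
#'   (data.frame id, type, expectedFate, expectedStage, expectedReason).
#' @export
simGeneModels <- function(n = 500L,
                          mix = c(clean = 0.5, lowCoverage = 0.1,
                                  noHit = 0.1, fewExons = 0.1,
                                  redundant = 0.1, repeatOverlap = 0.1),
                          seed = 1L, dir = NULL) {
  types <- c("clean", "lowCoverage", "noHit", "fewExons", "redundant",
             "repeatOverlap")
  if (!all(names(mix) %in% types)) stop("unknown violation type in mix")
  w <- setNames(numeric(length(types)), types)
  w[names(mix)] <- mix
  set.seed(seed)
  counts <- .apportion(n, w)
  names(counts) <- types
  ## redundant models come in pairs: odd leftover becomes clean
  if (counts["redundant"] %% 2L == 1L) {
    counts["redundant"] <- counts["redundant"] - 1L
    counts["clean"] <- counts["clean"] + 1L
  }
  assign <- sample(rep(types, counts))

  exScaffold <- character(0); exStart <- integer(0); exEnd <- integer(0)
  exStrand <- character(0); exModel <- character(0)
  evidence <- list()
  repScaffold <- character(0); repStart <- integer(0); repEnd <- integer(0)
  truth <- list()
  pendingTwin <- NULL   # scaffold/exons of the previous redundant host

  addExons <- function(scaf, starts, ends, strand, id) {
    exScaffold <<- c(exScaffold, rep(scaf, length(starts)))
    exStart <<- c(exStart, starts); exEnd <<- c(exEnd, ends)
    exStrand <<- c(exStrand, rep(strand, length(starts)))
    exModel <<- c(exModel, rep(id, length(starts)))
  }
  drawExons <- function(nEx) {
    widths <- sample(100:300, nEx, replace = TRUE)
    gaps <- sample(50:200, nEx, replace = TRUE)
    starts <- 1000L + cumsum(c(0L, (widths + gaps)[-nEx]))
    list(starts = as.integer(starts), ends = as.integer(starts + widths - 1L))
  }
  goodEvidence <- function(id) {
    qlen <- sample(100:500, 1L)
    span <- ceiling(qlen * runif(1, 0.92, 0.99))
    data.frame(model_id = id, subject_id = sprintf("sp|%05d", sample.int(
      99999L, 1L)), query_length = qlen, aligned_query_span = span,
      e_value = 10^runif(1, -80, -25))
  }

  for (i in seq_len(n)) {
    id <- sprintf("model%05d", i)
    type <- assign[i]
    scaf <- sprintf("scf%05d", i)
    strand <- sample(c("+", "-"), 1L)
    if (type == "redundant" && !is.null(pendingTwin)) {
      ## shorter twin: the host's exons trimmed 20 bp on each side,
      ## fully nested, so shared/shorter = 1
      host <- pendingTwin
      addExons(host$scaf, host$starts + 20L, host$ends - 20L, host$strand, id)
      evidence[[id]] <- goodEvidence(id)
      truth[[id]] <- data.frame(id = id, type = "redundant",
                                expectedFate = "rejected",
                                expectedStage = "redundancy",
                                expectedReason = "redundant")
      pendingTwin <- NULL
      next
    }
    nEx <- if (type == "fewExons") sample(1:3, 1L) else sample(4:8, 1L)
    ex <- drawExons(nEx)
    addExons(scaf, ex$starts, ex$ends, strand, id)
    if (type == "noHit") {
      truth[[id]] <- data.frame(id = id, type = type,
                                expectedFate = "rejected",
                                expectedStage = "coverage",
                                expectedReason = "no-hit")
    } else if (type == "lowCoverage") {
      qlen <- sample(100:500, 1L)
      evidence[[id]] <- data.frame(model_id = id,
        subject_id = sprintf("sp|%05d", sample.int(99999L, 1L)),
        query_length = qlen,
        aligned_query_span = floor(qlen * runif(1, 0.50, 0.85)),
        e_value = 10^runif(1, -80, -25))
      truth[[id]] <- data.frame(id = id, type = type,
                                expectedFate = "rejected",
                                expectedStage = "coverage",
                                expectedReason = "low-coverage")
    } else {
      evidence[[id]] <- goodEvidence(id)
      if (type == "fewExons") {
        truth[[id]] <- data.frame(id = id, type = type,
                                  expectedFate = "rejected",
                                  expectedStage = "exon-count",
                                  expectedReason = "few-exons")
      } else if (type == "repeatOverlap") {
        ## repeat overlapping the first exon by 30 bp
        repScaffold <- c(repScaffold, scaf)
        repStart <- c(repStart, ex$ends[1] - 29L)
        repEnd <- c(repEnd, ex$ends[1] + 100L)
        truth[[id]] <- data.frame(id = id, type = type,
                                  expectedFate = "rejected",
                                  expectedStage = "repeat",
                                  expectedReason = "repeat-overlap")
      } else {                           # clean, possibly a twin host
        truth[[id]] <- data.frame(id = id, type = type,
                                  expectedFate = "kept",
                                  expectedStage = NA_character_,
                                  expectedReason = NA_character_)
        if (type == "redundant")
          pendingTwin <- list(scaf = scaf, starts = ex$starts,
                              ends = ex$ends, strand = strand)
      }
    }
  }
  exons <- GenomicRanges::GRanges(exScaffold,
    IRanges::IRanges(exStart, exEnd), strand = exStrand,
    model_id = exModel)
  models <- geneModelSet(exons)
  evidence <- if (length(evidence)) do.call(rbind, unname(evidence)) else
    data.frame(model_id = character(0), subject_id = character(0),
               query_length = numeric(0), aligned_query_span = numeric(0),
               e_value = numeric(0))
  rownames(evidence) <- NULL
  repeats <- GenomicRanges::GRanges(repScaffold,
                                    IRanges::IRanges(repStart, repEnd))
  truth <- do.call(rbind, unname(truth))
  truth <- truth[order(truth$id), , drop = FALSE]
  rownames(truth) <- NULL
  out <- list(models = models, evidence = evidence, repeats = repeats,
              truth = truth,
              params = list(scenario = "gene-models", n = n, mix = as.list(w),
                            seed = seed))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeGeneModels(models, file.path(dir, "models.gff3"))
    writeEvidence(evidence, file.path(dir, "evidence.tsv"))
    writeRepeats(repeats, file.path(dir, "repeats.bed"))
    writeLinesAtomic(jsonlite::toJSON(c(out$params, list(truth = truth)),
                                      auto_unbox = TRUE, pretty = TRUE,
                                      digits = NA),
                     file.path(dir, "truth.json"))
  }
  out
}

#' Simulate a genome-by-domain count matrix with planted fold-changes
#'
#' Draws a shared baseline frequency profile over domains, multiplies
#' the focal genome's frequencies by the planted folds (fold > 1 plants
#' an expansion, fold < 1 a contraction), and samples each genome's
#' counts multinomially to its total. With no planted changes every
#' domain's expected call is neutral, which is the null configuration
#' used for family-wise error calibration.
#'
#' @param nGenomes number of genomes (first label is the default focal).
#' @param nDomains number of domains.
#' @param planted optional data.frame with columns \code{domain}
#'   (indices or names) and \code{fold}; \code{NULL} plants nothing.
#' @param nExpanded,nContracted,fold convenience alternative to
#'   \code{planted}: plant this many expansions (x fold) and
#'   contractions (/ fold) on randomly chosen domains whose baseline
#'   expected count lies in \code{lambdaRange}.
#' @param lambdaRange expected-count range for planted domains.
#' @param focal focal genome label.
#' @param totalCounts per-genome total domain count (scalar or vector).
#' @param minExpected floor on each domain's expected per-genome count;
#'   keeps the baseline away from the degenerate lambda = 0 regime.
#' @param seed RNG seed.
#' @return list with \code{matrix} (\linkS4class{DomainCountMatrix}) and
#'   \code{truth} (data.frame domain, fold, expectedCall).
#' @export
simDomainMatrix <- function(nGenomes = 10L, nDomains = 2000L, planted = NULL,
                            nExpanded = 0L, nContracted = 0L, fold = 4,
                            lambdaRange = c(20, 200), focal = NULL,
                            totalCounts = 40000L, minExpected = 5,
                            seed = 1L) {
  set.seed(seed)
  genomes <- if (nGenomes == 10L)
    c("Lf", "Mg", "Mp", "Bp", "Rp", "Py", "Cg", "Pf", "Lg", "Hd")
  else sprintf("g%02d", seq_len(nGenomes))
  if (is.null(focal)) focal <- genomes[1]
  domains <- sprintf("PF%05d", seq_len(nDomains))
  totals <- rep_len(totalCounts, nGenomes)

  nPlant <- nExpanded + nContracted
  if (is.null(planted) && nPlant > 0L) {
    ## reserve the planted domains a baseline frequency putting their
    ## expected count inside lambdaRange at the focal total; when
    ## expansions and contractions are planted in equal numbers the
    ## contraction baselines are paired at fold x the expansion
    ## baselines, which balances the planted mass exactly (the focal
    ## genome's unplanted composition is then unchanged, so "neutral"
    ## in the truth table means neutral in the sampling model too)
    if (nExpanded == nContracted && nExpanded > 0L) {
      lamExp <- runif(nExpanded, lambdaRange[1], lambdaRange[2] / fold)
      lam <- c(lamExp, fold * lamExp)
    } else {
      lam <- runif(nPlant, lambdaRange[1], lambdaRange[2])
    }
    baseFreqPlanted <- lam / totals[match(focal, genomes)]
    folds <- c(rep(fold, nExpanded), rep(1 / fold, nContracted))
    plantedIdx <- sample.int(nDomains, nPlant)
    planted <- data.frame(domain = domains[plantedIdx], fold = folds,
                          baseFreq = baseFreqPlanted)
  }
  base <- stats::rgamma(nDomains, shape = 2)
  base <- base / sum(base)
  ## floor the baseline so every domain expects >= minExpected counts per
  ## genome: a domain absent from every reference genome has lambda = 0,
  ## where the Poisson tail test is degenerate (any observation is an
  ## automatic expansion); that corner is exercised by its own unit
  ## tests, not by the recovery suite
  base <- pmax(base, minExpected / mean(totals))
  base <- base / sum(base)
  if (!is.null(planted) && nrow(planted)) {
    idx <- if (is.numeric(planted$domain)) as.integer(planted$domain)
           else match(planted$domain, domains)
    if (anyNA(idx) || anyDuplicated(idx)) stop("invalid planted domains")
    if (!is.null(planted$baseFreq)) base[idx] <- planted$baseFreq
    ## renormalize the unplanted mass so frequencies sum to 1
    rest <- setdiff(seq_len(nDomains), idx)
    base[rest] <- base[rest] / sum(base[rest]) * (1 - sum(base[idx]))
  }
  weights <- matrix(rep(base, each = nGenomes), nrow = nGenomes,
                    dimnames = list(genomes, domains))
  if (!is.null(planted) && nrow(planted))
    weights[focal, idx] <- weights[focal, idx] * planted$fold
  cnt <- t(vapply(seq_len(nGenomes), function(g)
    as.numeric(rmultinom(1L, totals[g], weights[g, ])), numeric(nDomains)))
  dimnames(cnt) <- list(genomes, domains)
  truth <- data.frame(domain = domains, fold = 1,
                      expectedCall = "neutral")
  if (!is.null(planted) && nrow(planted)) {
    truth$fold[idx] <- planted$fold
    truth$expectedCall[idx] <- ifelse(planted$fold > 1, "expanded",
                                      ifelse(planted$fold < 1, "contracted",
                                             "neutral"))
  }
  list(matrix = domainCountMatrix(cnt),
       truth = truth,
       params = list(scenario = "domain-matrix", seed = seed,
                     nGenomes = nGenomes, nDomains = nDomains,
                     focal = focal, totalCounts = totals))
}
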