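#' KmerHistogram: a k-mer multiplicity spectrum
#'
#' Tabulated output of a k-mer counter (e.g. Jellyfish \code{histo}):
#' for each multiplicity (x-fold coverage) the number of distinct k-mers
#' observed at that multiplicity.
#'
#' @slot k k-mer length used when counting.
#' @slot multiplicity strictly increasing integer vector of multiplicities.
#' @slot count number of distinct k-mers at each multiplicity (may exceed
#'   the integer range for large genomes, hence numeric).
#' @exportClass KmerHistogram
setClass("KmerHistogram",
  representation(k = "integer", multiplicity = "integer", count = "numeric"))

setValidity("KmerHistogram", function(object) {
  msg <- character()
  if (length(object@k) != 1L || is.na(object@k) || object@k < 1L)
    msg <- c(msg, "k must be a single positive integer")
  if (length(object@multiplicity) != length(object@count))
    msg <- c(msg, "multiplicity and count must have equal length")
  if (length(object@multiplicity) == 0L)
    msg <- c(msg, "histogram must have at least one entry")
  if (any(object@multiplicity < 1L))
    msg <- c(msg, "multiplicities must be positive")
  if (is.unsorted(object@multiplicity, strictly = TRUE))
    msg <- c(msg, "multiplicities must be strictly increasing")
  if (any(object@count < 0) || anyNA(object@count))
    msg <- c(msg, "counts must be non-negative")
  if (length(object@count) && all(object@count == 0))
    msg <- c(msg, "histogram must contain at least one positive count")
  if (length(msg)) msg else TRUE
})

#' Construct a KmerHistogram
#'
#' @param k k-mer length.
#' @param multiplicity integer vector of multiplicities (x-fold coverage).
#' @param count distinct k-mer counts, same length as \code{multiplicity}.
#' @param resort if \code{TRUE} (default) out-of-order rows are re-sorted;
#'   otherwise they raise an error.
#' @return A \linkS4class{KmerHistogram}.
#' @examples
#' KmerHistogram(25, 1:3, c(100, 50, 10))
#' @export
KmerHistogram <- function(k, multiplicity, count, resort = TRUE) {
  multiplicity <- as.integer(multiplicity)
  count <- as.numeric(count)
  if (anyDuplicated(multiplicity))
    stop("duplicated multiplicities in histogram")
  if (is.unsorted(multiplicity, strictly = TRUE)) {
    if (!resort) stop("multiplicities out of order and resort = FALSE")
    o <- order(multiplicity)
    multiplicity <- multiplicity[o]
    count <- count[o]
  }
  new("KmerHistogram", k = as.integer(k), multiplicity = multiplicity,
      count = count)
}

#' @describeIn KmerHistogram k-mer length accessor
#' @param x,object a \code{KmerHistogram}
#' @export
kmerLength <- function(x) x@k

#' @describeIn KmerHistogram multiplicity accessor
#' @export
multiplicities <- function(x) x@multiplicity

#' @describeIn KmerHistogram distinct-k-mer count accessor
#' @export
kmerCounts <- function(x) x@count

setMethod("show", "KmerHistogram", function(object) {
  cat(sprintf("KmerHistogram: k = %d, %d multiplicities (%d..%d), %s k-mers\n",
              object@k, length(object@multiplicity),
              min(object@multiplicity), max(object@multiplicity),
              format(sum(object@multiplicity * object@count),
                     big.mark = ",", scientific = FALSE)))
})

#' SpectrumProfile: inferences drawn from a k-mer spectrum
#'
#' Holds the error threshold, peak depths, k-mer volumes, genome size,
#' heterozygosity rate and ploidy call derived from a
#' \linkS4class{KmerHistogram} by \code{\link{profileSpectrum}}.
#' Fields a stage could not determine are \code{NA}, with an explanatory
#' note; user overrides are recorded in \code{overrides}.
#'
#' @slot k k-mer length.
#' @slot errorThreshold multiplicity below which k-mers are called erroneous.
#' @slot hetPeakDepth depth of the heterozygous peak (NA if absent).
#' @slot homPeakDepth depth of the homozygous peak.
#' @slot totalVolume total k-mer volume (sum of multiplicity x count).
#' @slot errorVolume volume at multiplicities strictly below the threshold.
#' @slot genomeSize estimated genome size in bases.
#' @slot heterozygosity estimated heterozygosity rate (fraction).
#' @slot ploidyCall one of "haploid-like", "diploid-heterozygous", "ambiguous".
#' @slot overrides names of fields fixed by the caller rather than detected.
#' @slot notes character vector of stage warnings.
#' @exportClass SpectrumProfile
setClass("SpectrumProfile",
  representation(k = "integer", errorThreshold = "numeric",
                 hetPeakDepth = "numeric", homPeakDepth = "numeric",
                 totalVolume = "numeric", errorVolume = "numeric",
                 genomeSize = "numeric", heterozygosity = "numeric",
                 ploidyCall = "character", overrides = "character",
                 notes = "character"))

setValidity("SpectrumProfile", function(object) {
  msg <- character()
  if (!object@ploidyCall %in%
      c("haploid-like", "diploid-heterozygous", "ambiguous", "unknown"))
    msg <- c(msg, "invalid ploidy call")
  e <- object@errorThreshold; ch <- object@hetPeakDepth
  cm <- object@homPeakDepth
  if (!is.na(e) && !is.na(ch) && !is.na(cm) && !(e < ch && ch < cm))
    msg <- c(msg, "need errorThreshold < hetPeakDepth < homPeakDepth")
  if (!is.na(object@errorVolume) && !is.na(object@totalVolume) &&
      object@errorVolume > object@totalVolume)
    msg <- c(msg, "errorVolume exceeds totalVolume")
  if (!is.na(object@heterozygosity) &&
      (object@heterozygosity < 0 || object@heterozygosity >= 1))
    msg <- c(msg, "heterozygosity must be in [0, 1)")
  if (!is.na(object@genomeSize) && object@genomeSize <= 0)
    msg <- c(msg, "genomeSize must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SpectrumProfile", function(object) {
  fmt <- function(x) ifelse(is.na(x), "NA",
                            format(x, big.mark = ",", scientific = FALSE))
  cat("SpectrumProfile (k =", object@k, ")\n")
  cat("  error threshold :", fmt(object@errorThreshold), "\n")
  cat("  het peak depth  :", fmt(object@hetPeakDepth), "\n")
  cat("  hom peak depth  :", fmt(object@homPeakDepth), "\n")
  cat("  total volume    :", fmt(object@totalVolume), "\n")
  cat("  error volume    :", fmt(object@errorVolume), "\n")
  cat("  genome size     :", fmt(roundHalfUp(object@genomeSize)), "bp\n")
  cat("  heterozygosity  :",
      ifelse(is.na(object@heterozygosity), "NA",
             sprintf("%.3f%%", 100 * object@heterozygosity)), "\n")
  cat("  ploidy call     :", object@ploidyCall, "\n")
  if (length(object@overrides))
    cat("  overridden      :", paste(object@overrides, collapse = ", "), "\n")
  for (n in object@notes) cat("  note:", n, "\n")
})

#' AssemblyStats: scaffold summary statistics for one assembly
#'
#' The usual comparison-table column for a genome assembly: scaffold
#' counts, size, extremes, size-class tallies, mean/median, N50, and
#' masked fraction. Values are stored unrounded; display rounding
#' happens in \code{\link{comparisonTable}} and \code{show}.
#'
#' @slot nScaffolds number of scaffolds.
#' @slot totalSize total assembly length in bases.
#' @slot longest,shortest extreme scaffold lengths.
#' @slot nOver1kb,pctOver1kb scaffolds longer than 1 kb and their percentage.
#' @slot nOver1Mb,pctOver1Mb scaffolds longer than 1 Mb and their percentage.
#' @slot meanSize,medianSize mean and median scaffold length (unrounded).
#' @slot n50 N50 scaffold length.
#' @slot maskedPercent percent of bases soft-masked (NA when unknown).
#' @slot pctOver50kb percent of assembly bases in scaffolds longer than 50 kb.
#' @exportClass AssemblyStats
setClass("AssemblyStats",
  representation(nScaffolds = "numeric", totalSize = "numeric",
                 longest = "numeric", shortest = "numeric",
                 nOver1kb = "numeric", pctOver1kb = "numeric",
                 nOver1Mb = "numeric", pctOver1Mb = "numeric",
                 meanSize = "numeric", medianSize = "numeric",
                 n50 = "numeric", maskedPercent = "numeric",
                 pctOver50kb = "numeric"))

setValidity("AssemblyStats", function(object) {
  msg <- character()
  if (object@shortest > object@medianSize || object@medianSize > object@longest)
    msg <- c(msg, "need shortest <= median <= longest")
  pct <- c(object@pctOver1kb, object@pctOver1Mb, object@pctOver50kb,
           object@maskedPercent)
  pct <- pct[!is.na(pct)]
  if (any(pct < 0 | pct > 100)) msg <- c(msg, "percentages must lie in [0,100]")
  if (abs(object@meanSize - object@totalSize / object@nScaffolds) > 1e-6)
    msg <- c(msg, "mean must equal totalSize/nScaffolds")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AssemblyStats", function(object) {
  tab <- comparisonTable(list(assembly = object))
  cat(tab, sep = "\n")
})

#' BuscoCounts: BUSCO category tallies
#'
#' Counts of benchmark universal single-copy orthologs by completeness
#' category. The two accounting identities (complete = single + duplicated;
#' complete + fragmented + missing = total searched) are enforced.
#'
#' @slot totalSearched,complete,completeSingle,completeDuplicated,fragmented,missing integer tallies.
#' @exportClass BuscoCounts
setClass("BuscoCounts",
  representation(totalSearched = "integer", complete = "integer",
                 completeSingle = "integer", completeDuplicated = "integer",
                 fragmented = "integer", missing = "integer"))

setValidity("BuscoCounts", function(object) {
  msg <- character()
  v <- c(object@totalSearched, object@complete, object@completeSingle,
         object@completeDuplicated, object@fragmented, object@missing)
  if (any(v < 0L)) msg <- c(msg, "counts must be non-negative")
  if (object@complete != object@completeSingle + object@completeDuplicated)
    msg <- c(msg, "violated identity: complete = single + duplicated")
  if (object@complete + object@fragmented + object@missing !=
      object@totalSearched)
    msg <- c(msg,
      "violated identity: complete + fragmented + missing = totalSearched")
  if (length(msg)) msg else TRUE
})

#' @describeIn BuscoCounts constructor
#' @param totalSearched,complete,completeSingle,completeDuplicated,fragmented,missing category counts
#' @export
buscoCounts <- function(totalSearched, complete, completeSingle,
                        completeDuplicated, fragmented, missing) {
  new("BuscoCounts", totalSearched = as.integer(totalSearched),
      complete = as.integer(complete),
      completeSingle = as.integer(completeSingle),
      completeDuplicated = as.integer(completeDuplicated),
      fragmented = as.integer(fragmented), missing = as.integer(missing))
}

setMethod("show", "BuscoCounts", function(object) {
  print(buscoPercentages(object))
})

#' GeneModelSet: exon structures of a set of gene models
#'
#' A set of transcript-derived gene models, each a sorted run of
#' non-overlapping exons on one scaffold and strand. Exons are held in a
#' \code{GRanges} with a \code{model_id} metadata column; per-model
#' summaries (exon count, CDS length) are precomputed.
#'
#' @slot exons \code{GRanges} of exons, sorted within model, with
#'   \code{model_id} metadata.
#' @slot models data.frame with one row per model: id, scaffold, strand,
#'   nExons, cdsLength.
#' @exportClass GeneModelSet
setClass("GeneModelSet",
  representation(exons = "GRanges", models = "data.frame"))

setValidity("GeneModelSet", function(object) {
  msg <- character()
  if (length(object@exons)) {
    ids <- S4Vectors::mcols(object@exons)$model_id
    if (is.null(ids)) return("exons must carry a model_id metadata column")
    byModel <- split(object@exons, ids)
    red <- sum(vapply(byModel,
                      function(g) length(GenomicRanges::reduce(g,
                        ignore.strand = TRUE)) != length(g), logical(1)))
    if (red > 0)
      msg <- c(msg, "exons within a model must be non-overlapping")
    nsc <- vapply(byModel, function(g)
      length(unique(as.character(GenomicRanges::seqnames(g)))), integer(1))
    if (any(nsc != 1L))
      msg <- c(msg, "all exons of a model must lie on one scaffold")
  }
  if (nrow(object@models) &&
      !setequal(object@models$id,
                unique(S4Vectors::mcols(object@exons)$model_id)))
    msg <- c(msg, "model table out of sync with exon ranges")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GeneModelSet", function(object) {
  cat(sprintf("GeneModelSet: %d models, %d exons on %d scaffolds\n",
              nrow(object@models), length(object@exons),
              length(unique(object@models$scaffold))))
})

#' @describeIn GeneModelSet model ids
#' @param x a \code{GeneModelSet}
#' @export
modelIds <- function(x) x@models$id

#' @describeIn GeneModelSet per-model summary table
#' @export
modelTable <- function(x) x@models

#' @describeIn GeneModelSet exon ranges accessor
#' @export
exonRanges <- function(x) x@exons

#' CurationReport: audit trail of the curation cascade
#'
#' @slot stages data.frame with stage name, models in, models out.
#' @slot survivors ids of models surviving every stage.
#' @slot rejected data.frame (id, stage, reason) for every removed model.
#' @exportClass CurationReport
setClass("CurationReport",
  representation(stages = "data.frame", survivors = "character",
                 rejected = "data.frame"))

setValidity("CurationReport", function(object) {
  msg <- character()
  if (nrow(object@stages)) {
    if (any(object@stages$nOut > object@stages$nIn))
      msg <- c(msg, "a stage cannot output more models than it received")
    nRej <- sum(object@stages$nIn - object@stages$nOut)
    if (nRej != nrow(object@rejected))
      msg <- c(msg, "rejection reasons must cover all removed models")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "CurationReport", function(object) {
  cat("CurationReport\n")
  print(object@stages, row.names = FALSE)
  cat(sprintf("  surviving models: %d\n", length(object@survivors)))
})

#' @describeIn CurationReport per-stage in/out counts
#' @param x a \code{CurationReport}
#' @export
stageCounts <- function(x) x@stages

#' @describeIn CurationReport surviving model ids
#' @export
survivingModels <- function(x) x@survivors

#' @describeIn CurationReport rejected models with stage and reason
#' @export
rejectedModels <- function(x) x@rejected

#' DomainCountMatrix: protein-domain counts across genomes
#'
#' Genome-by-domain matrix of non-negative domain occurrence counts
#' (e.g. Pfam assignments per genome), the input to the
#' expansion/contraction test. Row sums are the per-genome totals used
#' for frequency normalization.
#'
#' @slot counts numeric matrix, rows = genomes, columns = domains.
#' @exportClass DomainCountMatrix
setClass("DomainCountMatrix", representation(counts = "matrix"))

setValidity("DomainCountMatrix", function(object) {
  msg <- character()
  m <- object@counts
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "counts must have genome rownames and domain colnames")
  else {
    if (anyDuplicated(rownames(m))) msg <- c(msg, "duplicate genome labels")
    if (anyDuplicated(colnames(m))) msg <- c(msg, "duplicate domain labels")
  }
  if (nrow(m) < 2L) msg <- c(msg, "need at least two genomes")
  if (any(m < 0) || anyNA(m)) msg <- c(msg, "counts must be non-negative")
  if (any(m != floor(m))) msg <- c(msg, "counts must be integers")
  if (length(msg)) msg else TRUE
})

#' @describeIn DomainCountMatrix constructor from a counts matrix
#' @param counts genome-by-domain matrix with dimnames
#' @export
domainCountMatrix <- function(counts) {
  new("DomainCountMatrix", counts = as.matrix(counts))
}

#' @describeIn DomainCountMatrix counts accessor
#' @param x a \code{DomainCountMatrix}
#' @export
domainCounts <- function(x) x@counts

#' @describeIn DomainCountMatrix genome labels
#' @export
genomeNames <- function(x) rownames(x@counts)

#' @describeIn DomainCountMatrix domain labels
#' @export
domainNames <- function(x) colnames(x@counts)

#' @describeIn DomainCountMatrix per-genome total domain counts (row sums)
#' @export
genomeTotals <- function(x) rowSums(x@counts)

setMethod("show", "DomainCountMatrix", function(object) {
  cat(sprintf("DomainCountMatrix: %d genomes x %d domains, totals %s..%s\n",
              nrow(object@counts), ncol(object@counts),
              format(min(rowSums(object@counts)), big.mark = ","),
              format(max(rowSums(object@counts)), big.mark = ",")))
})

#' Log2RatioMatrix: normalized log2 count ratios for display/clustering
#'
#' Entry (g, d) is log2((n_gd + pc) / (mean_d + pc)) where n_gd is the
#' genome's domain count frequency-normalized to a common total, mean_d
#' the cross-genome mean of the normalized counts, and pc a pseudocount.
#'
#' @slot ratios genome-by-domain matrix of log2 ratios.
#' @slot pseudocount pseudocount used.
#' @slot referenceMeans per-domain cross-genome means of normalized counts.
#' @slot normalizedCounts the normalized counts the ratios were built from.
#' @exportClass Log2RatioMatrix
setClass("Log2RatioMatrix",
  representation(ratios = "matrix", pseudocount = "numeric",
                 referenceMeans = "numeric", normalizedCounts = "matrix"))

setValidity("Log2RatioMatrix", function(object) {
  msg <- character()
  if (any(!is.finite(object@ratios))) msg <- c(msg, "ratios must be finite")
  if (object@pseudocount < 0) msg <- c(msg, "pseudocount must be >= 0")
  rec <- log2((object@normalizedCounts + object@pseudocount) /
              rep(object@referenceMeans + object@pseudocount,
                  each = nrow(object@normalizedCounts)))
  if (max(abs(rec - object@ratios)) > 1e-8)
    msg <- c(msg, "ratios are not reconstructible from normalized counts")
  if (length(msg)) msg else TRUE
})

#' @describeIn Log2RatioMatrix log2-ratio matrix accessor
#' @param x a \code{Log2RatioMatrix}
#' @export
ratioMatrix <- function(x) x@ratios

setMethod("show", "Log2RatioMatrix", function(object) {
  cat(sprintf("Log2RatioMatrix: %d genomes x %d domains, pseudocount %g\n",
              nrow(object@ratios), ncol(object@ratios), object@pseudocount))
})
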