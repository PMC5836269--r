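#' Tally scaffold lengths, soft-masked bases and gaps from a FASTA
#'
#' One pass over a (possibly soft-masked) FASTA: per record, the length,
#' the number of lowercase (soft-masked) positions, and the number of
#' N/n gap positions. N and n are counted as gaps only, never as masked,
#' following the RepeatMasker soft-masking convention.
#'
#' @param path FASTA file (plain or gzip).
#' @return data.frame with columns \code{id}, \code{length},
#'   \code{masked_bases}, \code{gap_bases}; zero rows for an empty file.
#' @export
readFastaLengths <- function(path) {
  seqs <- tryCatch(Biostrings::readBStringSet(path), error = function(c) {
    ## an empty file is a legal degenerate input
    if (file.exists(path) && file.size(path) == 0)
      return(Biostrings::BStringSet())
    stop(c)
  })
  if (length(seqs) == 0L)
    return(data.frame(id = character(0), length = integer(0),
                      masked_bases = integer(0), gap_bases = integer(0)))
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  len <- Biostrings::width(seqs)
  if (any(len == 0L))
    stop("zero-length record(s) in ", path, ": ",
         paste(ids[len == 0L], collapse = ", "))
  ## lowercase n is a masked gap base; counted as gap only, not as masked
  lf <- Biostrings::letterFrequency(seqs, letters = c("acgt", "Nn"))
  data.frame(id = ids, length = len,
             masked_bases = as.integer(lf[, "a|c|g|t"]),
             gap_bases = as.integer(lf[, "N|n"]),
             row.names = NULL)
}

#' Nxx contiguity statistic
#'
#' The Nxx of a set of scaffold lengths is the length of the scaffold at
#' which, accumulating lengths from longest to shortest, the running sum
#' first reaches x percent of the total; N50 is the usual special case.
#'
#' @param lengths numeric vector of scaffold lengths.
#' @param x percentage threshold in (0, 100); default 50.
#' @return the Nxx length (always one of the observed lengths).
#' @examples
#' nxx(c(10, 8, 6, 4, 2))  # 8
#' @export
nxx <- function(lengths, x = 50) {
  if (length(lengths) == 0L) stop("empty length list")
  if (!is.numeric(x) || x <= 0 || x >= 100) stop("x must lie in (0, 100)")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= x / 100 * sum(s))[1]]
}

#' Split scaffolds into contigs at N-runs and return contig lengths
#'
#' Contigs are the gap-free pieces obtained by cutting each scaffold at
#' runs of at least \code{minGapRun} consecutive N/n characters.
#'
#' @param path FASTA file.
#' @param minGapRun minimum N-run length that defines a gap (default 10).
#' @return numeric vector of contig lengths.
#' @export
contigLengths <- function(path, minGapRun = 10L) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) return(numeric(0))
  pieces <- lapply(as.character(seqs), function(s) {
    parts <- strsplit(s, sprintf("[Nn]{%d,}", as.integer(minGapRun)))[[1]]
    nchar(parts[nchar(parts) > 0])
  })
  as.numeric(unlist(pieces, use.names = FALSE))
}

#' Summarize an assembly
#'
#' Computes the standard comparison-table statistics for one assembly:
#' scaffold count, total size, longest/shortest, counts and percentages
#' of scaffolds over 1 kb and 1 Mb (strictly greater), mean and median
#' scaffold size, N50, soft-masked percentage, and the percentage of
#' assembly bases in scaffolds over 50 kb. All values are stored
#' unrounded; display rounding is applied by \code{\link{comparisonTable}}.
#'
#' @param records data.frame from \code{\link{readFastaLengths}}, or a
#'   bare numeric vector of scaffold lengths (masked percentage is then
#'   \code{NA}).
#' @return An \linkS4class{AssemblyStats}.
#' @export
summarizeAssembly <- function(records) {
  if (is.numeric(records))
    records <- data.frame(length = records)
  len <- records$length
  if (is.null(len) || length(len) == 0L) stop("no scaffolds to summarize")
  len <- as.numeric(len)
  total <- sum(len)
  over1kb <- sum(len > 1e3)
  over1Mb <- sum(len > 1e6)
  maskedPct <- if (!is.null(records$masked_bases))
    100 * sum(as.numeric(records$masked_bases)) / total else NA_real_
  new("AssemblyStats",
      nScaffolds = as.numeric(length(len)), totalSize = total,
      longest = max(len), shortest = min(len),
      nOver1kb = as.numeric(over1kb),
      pctOver1kb = 100 * over1kb / length(len),
      nOver1Mb = as.numeric(over1Mb),
      pctOver1Mb = 100 * over1Mb / length(len),
      meanSize = total / length(len), medianSize = median(len),
      n50 = nxx(len, 50), maskedPercent = maskedPct,
      pctOver50kb = 100 * sum(len[len > 5e4]) / total)
}

#' BUSCO completeness percentages
#'
#' Converts BUSCO category counts into the usual percentage table:
#' percent = count / total groups searched x 100, rounded half-up to two
#' decimals (trailing zeros are trimmed when formatted).
#'
#' @param counts a \linkS4class{BuscoCounts}.
#' @return data.frame with columns \code{category}, \code{count},
#'   \code{percent}.
#' @examples
#' bc <- buscoCounts(978, 801, 769, 32, 72, 105)
#' buscoPercentages(bc)
#' @export
buscoPercentages <- function(counts) {
  stopifnot(is(counts, "BuscoCounts"))
  validObject(counts)
  n <- c(Complete = counts@complete,
         `Complete and single-copy` = counts@completeSingle,
         `Complete and duplicated` = counts@completeDuplicated,
         Fragmented = counts@fragmented,
         Missing = counts@missing)
  data.frame(category = names(n), count = as.integer(n),
             percent = roundHalfUp(100 * n / counts@totalSearched, 2L),
             row.names = NULL)
}

## canonical comparison-table rows; display rule per row
.comparisonRows <- function(st) {
  c("Number of scaffolds"        = format(st@nScaffolds),
    "Total size of scaffolds"    = format(st@totalSize, scientific = FALSE),
    "Longest scaffold"           = format(st@longest, scientific = FALSE),
    "Shortest scaffold"          = format(st@shortest, scientific = FALSE),
    "Number of scaffolds >1 K nt" = format(st@nOver1kb),
    "Percent scaffolds >1 K nt"  = sprintf("%.1f", roundHalfUp(st@pctOver1kb, 1L)),
    "Number of scaffolds >1 M nt" = format(st@nOver1Mb),
    "Percent scaffolds >1 M nt"  = sprintf("%.1f", roundHalfUp(st@pctOver1Mb, 1L)),
    "Mean scaffold size"         = format(roundHalfUp(st@meanSize), scientific = FALSE),
    "Median scaffold size"       = format(roundHalfUp(st@medianSize, 1L), scientific = FALSE),
    "N50 scaffold length"        = format(st@n50, scientific = FALSE),
    "Percent of genome in scaffolds >50 Kb" =
      sprintf("%.2f", roundHalfUp(st@pctOver50kb, 2L)),
    "Masked percent of genome"   =
      if (is.na(st@maskedPercent)) "NA" else
        sprintf("%.2f", roundHalfUp(st@maskedPercent, 2L)))
}

#' Side-by-side assembly comparison table
#'
#' Renders one or more \linkS4class{AssemblyStats} as TSV text with
#' assemblies as columns and statistics as rows, in the canonical row
#' order (counts and sizes, size-class rows, mean/median, N50, genome
#' fractions). Display rounding: integers half-up; size-class
#' percentages to one decimal; genome-fraction rows to two decimals.
#'
#' @param stats named list of \linkS4class{AssemblyStats}.
#' @return character vector of TSV lines (header + one line per row).
#' @export
comparisonTable <- function(stats) {
  if (length(stats) == 0L) stop("need at least one assembly")
  if (is(stats, "AssemblyStats")) stats <- list(assembly = stats)
  if (is.null(names(stats)) || any(!nzchar(names(stats))))
    names(stats) <- paste0("assembly", seq_along(stats))
  cols <- lapply(stats, .comparisonRows)
  rows <- names(cols[[1]])
  header <- paste(c("Statistic", names(stats)), collapse = "\t")
  body <- vapply(rows, function(r)
    paste(c(r, vapply(cols, `[[`, "", r)), collapse = "\t"), "")
  c(header, unname(body))
}
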