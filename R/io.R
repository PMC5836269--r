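## Format readers/writers shared by the analysis stages. Coordinate
## conventions are converted at these boundaries: GFF3 is 1-based closed
## (the GRanges convention, kept as-is), BED is 0-based half-open
## (shifted on import/export). Interval overlap downstream therefore
## behaves exactly as the half-open arithmetic would: abutting intervals
## do not overlap, a single shared base does.

#' Read gene models from GFF3
#'
#' Imports a GFF3 file and assembles a \linkS4class{GeneModelSet} from
#' its exon features. The model id is taken from the \code{Parent}
#' attribute (first value), falling back to \code{ID}.
#'
#' @param path GFF3 file.
#' @return A \linkS4class{GeneModelSet}.
#' @export
readGeneModels <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[tolower(as.character(gr$type)) == "exon"]
  parent <- gr$Parent
  ids <- if (!is.null(parent))
    vapply(as.list(parent), function(p)
      if (length(p)) p[[1]] else NA_character_, "")
  else rep(NA_character_, length(gr))
  if (anyNA(ids) && !is.null(gr$ID)) ids[is.na(ids)] <- gr$ID[is.na(ids)]
  if (anyNA(ids)) stop("exon(s) without Parent or ID attribute in ", path)
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                GenomicRanges::ranges(gr),
                                strand = GenomicRanges::strand(gr),
                                model_id = ids)
  geneModelSet(out)
}

#' Write gene models as GFF3
#'
#' @param models a \linkS4class{GeneModelSet}.
#' @param path output GFF3 file.
#' @return the path, invisibly.
#' @export
writeGeneModels <- function(models, path) {
  stopifnot(is(models, "GeneModelSet"))
  ex <- models@exons
  ids <- S4Vectors::mcols(ex)$model_id
  lines <- c("##gff-version 3",
             sprintf("%s\tmusselkit\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                     as.character(GenomicRanges::seqnames(ex)),
                     GenomicRanges::start(ex), GenomicRanges::end(ex),
                     as.character(GenomicRanges::strand(ex)), ids))
  writeLinesAtomic(lines, path)
}

#' Read a repeat track from BED
#'
#' BED intervals (0-based half-open) are converted to the 1-based closed
#' GRanges convention on import.
#'
#' @param path BED file.
#' @return \code{GRanges} of repeat intervals.
#' @export
readRepeats <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Write a repeat track as BED
#'
#' @param repeats \code{GRanges}.
#' @param path output BED file.
#' @return the path, invisibly.
#' @export
writeRepeats <- function(repeats, path) {
  stopifnot(is(repeats, "GRanges"))
  writeLinesAtomic(sprintf("%s\t%d\t%d",
                           as.character(GenomicRanges::seqnames(repeats)),
                           GenomicRanges::start(repeats) - 1L,
                           GenomicRanges::end(repeats)),
                   path)
}

#' Read alignment evidence from TSV
#'
#' Accepts either the package's long format (header columns
#' \code{model_id}, \code{subject_id}, \code{query_length},
#' \code{aligned_query_span}, \code{e_value}) or a tabular-BLAST-like
#' format with header columns \code{qseqid}, \code{sseqid}, \code{qlen},
#' \code{qstart}, \code{qend}, \code{evalue} (span = qend - qstart + 1).
#'
#' @param path TSV file with header.
#' @return evidence data.frame in the long format.
#' @export
readEvidence <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  long <- c("model_id", "subject_id", "query_length", "aligned_query_span",
            "e_value")
  if (all(long %in% names(df))) return(df[, long])
  blast <- c("qseqid", "sseqid", "qlen", "qstart", "qend", "evalue")
  if (all(blast %in% names(df)))
    return(data.frame(model_id = df$qseqid, subject_id = df$sseqid,
                      query_length = df$qlen,
                      aligned_query_span = df$qend - df$qstart + 1,
                      e_value = df$evalue))
  stop("unrecognized evidence format in ", path)
}

#' Write alignment evidence as TSV
#'
#' @param evidence evidence data.frame (long format).
#' @param path output TSV.
#' @return the path, invisibly.
#' @export
writeEvidence <- function(evidence, path) {
  lines <- c(paste(names(evidence), collapse = "\t"),
             do.call(sprintf, c(list(
               fmt = "%s\t%s\t%d\t%d\t%g"),
               list(evidence$model_id, evidence$subject_id,
                    as.integer(evidence$query_length),
                    as.integer(evidence$aligned_query_span),
                    evidence$e_value))))
  writeLinesAtomic(lines, path)
}

#' Write a spectrum profile as TSV and JSON
#'
#' Writes \code{<prefix>.profile.tsv} (field, value, unit) and
#' \code{<prefix>.profile.json} including a provenance block (package
#' version, timestamp, parameter echo).
#'
#' @param profile a \linkS4class{SpectrumProfile}.
#' @param prefix output path prefix.
#' @param config optional named list echoed into the provenance block.
#' @return paths of the two files, invisibly.
#' @export
writeProfile <- function(profile, prefix, config = list()) {
  stopifnot(is(profile, "SpectrumProfile"))
  num <- function(x) if (is.na(x)) "NA" else
    format(x, scientific = FALSE, trim = TRUE)
  tsv <- c("field\tvalue\tunit",
           sprintf("k\t%d\tbases", profile@k),
           sprintf("error_threshold\t%s\tmultiplicity",
                   num(profile@errorThreshold)),
           sprintf("het_peak_depth\t%s\tmultiplicity",
                   num(profile@hetPeakDepth)),
           sprintf("hom_peak_depth\t%s\tmultiplicity",
                   num(profile@homPeakDepth)),
           sprintf("total_volume\t%s\tkmers", num(profile@totalVolume)),
           sprintf("error_volume\t%s\tkmers", num(profile@errorVolume)),
           sprintf("genome_size\t%s\tbases", num(profile@genomeSize)),
           sprintf("heterozygosity\t%s\tfraction",
                   num(profile@heterozygosity)),
           sprintf("ploidy_call\t%s\tcall", profile@ploidyCall))
  writeLinesAtomic(tsv, paste0(prefix, ".profile.tsv"))
  obj <- list(profile = list(
                k = profile@k, error_threshold = profile@errorThreshold,
                het_peak_depth = profile@hetPeakDepth,
                hom_peak_depth = profile@homPeakDepth,
                total_volume = profile@totalVolume,
                error_volume = profile@errorVolume,
                genome_size = profile@genomeSize,
                heterozygosity = profile@heterozygosity,
                ploidy_call = profile@ploidyCall,
                overrides = profile@overrides, notes = profile@notes),
              provenance = runProvenance(config))
  writeLinesAtomic(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE,
                                    digits = NA, null = "null"),
                   paste0(prefix, ".profile.json"))
  invisible(paste0(prefix, c(".profile.tsv", ".profile.json")))
}

## provenance block embedded in JSON outputs: version, timestamp, full
## parameter echo
runProvenance <- function(config = list()) {
  list(tool = "musselkit",
       version = as.character(packageVersion("musselkit")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       parameters = config)
}
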