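#' Construct a GeneModelSet from exon ranges
#'
#' @param exons \code{GRanges} of exons carrying a \code{model_id}
#'   metadata column (1-based closed coordinates, the GRanges
#'   convention).
#' @return A \linkS4class{GeneModelSet}.
#' @export
geneModelSet <- function(exons) {
  stopifnot(is(exons, "GRanges"))
  if (length(exons)) {
    ids <- S4Vectors::mcols(exons)$model_id
    if (is.null(ids)) stop("exons must carry a model_id metadata column")
    exons <- exons[order(ids, GenomicRanges::start(exons))]
    ids <- S4Vectors::mcols(exons)$model_id
    first <- !duplicated(ids)
    models <- data.frame(
      id = ids[first],
      scaffold = as.character(GenomicRanges::seqnames(exons))[first],
      strand = as.character(GenomicRanges::strand(exons))[first],
      nExons = as.integer(table(ids)[ids[first]]),
      cdsLength = as.numeric(tapply(GenomicRanges::width(exons), ids,
                                    sum)[ids[first]]),
      row.names = NULL)
    models <- models[order(models$id), , drop = FALSE]
    rownames(models) <- NULL
  } else {
    models <- data.frame(id = character(0), scaffold = character(0),
                         strand = character(0), nExons = integer(0),
                         cdsLength = numeric(0))
  }
  new("GeneModelSet", exons = exons, models = models)
}

## subset a GeneModelSet to the given model ids (order-normalized)
keepModels <- function(set, ids) {
  sel <- S4Vectors::mcols(set@exons)$model_id %in% ids
  geneModelSet(set@exons[sel])
}

#' Reduce alignment evidence to the best hit per gene model
#'
#' Deterministic best-hit rule: smallest e-value, ties broken by larger
#' aligned query span, then by lexicographically smallest subject id.
#'
#' @param evidence data.frame with columns \code{model_id},
#'   \code{subject_id}, \code{query_length}, \code{aligned_query_span},
#'   \code{e_value}.
#' @return the same data.frame with one row per model.
#' @export
bestHits <- function(evidence) {
  req <- c("model_id", "subject_id", "query_length", "aligned_query_span",
           "e_value")
  if (!all(req %in% names(evidence)))
    stop("evidence must have columns: ", paste(req, collapse = ", "))
  if (any(evidence$aligned_query_span < 0) ||
      any(evidence$aligned_query_span > evidence$query_length))
    stop("aligned_query_span must lie in [0, query_length]")
  if (any(evidence$e_value < 0)) stop("e_value must be non-negative")
  o <- order(evidence$model_id, evidence$e_value,
             -evidence$aligned_query_span, evidence$subject_id)
  ev <- evidence[o, , drop = FALSE]
  ev <- ev[!duplicated(ev$model_id), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Coverage filter: require near-full-length protein support
#'
#' Keeps a gene model iff its best protein hit aligns at least
#' \code{minCov} of the query sequence (aligned span / query length,
#' boundary inclusive). Models with no evidence at all are rejected with
#' reason \code{"no-hit"}.
#'
#' @param models a \linkS4class{GeneModelSet}.
#' @param evidence alignment-evidence data.frame (any number of hits per
#'   model; reduced internally by \code{\link{bestHits}}).
#' @param minCov minimum aligned fraction (default 0.90).
#' @return list with \code{models} (surviving \linkS4class{GeneModelSet})
#'   and \code{rejected} (data.frame id, reason).
#' @export
coverageFilter <- function(models, evidence, minCov = 0.90) {
  stopifnot(is(models, "GeneModelSet"))
  ev <- bestHits(evidence)
  unknown <- setdiff(ev$model_id, modelIds(models))
  if (length(unknown))
    stop("evidence references unknown model id(s): ",
         paste(unknown, collapse = ", "))
  cov <- ev$aligned_query_span / ev$query_length
  covered <- ev$model_id[cov >= minCov]
  ids <- modelIds(models)
  keep <- ids %in% covered
  reason <- ifelse(ids %in% ev$model_id, "low-coverage", "no-hit")
  list(models = keepModels(models, ids[keep]),
       rejected = data.frame(id = ids[!keep], reason = reason[!keep]))
}

#' Exon-count filter
#'
#' Keeps models with at least \code{minExons} exons. The default of 4
#' encodes a strict reading of "more than 3 exons"; set
#' \code{minExons = 3} for the inclusive variant.
#'
#' @param models a \linkS4class{GeneModelSet}.
#' @param minExons minimum exon count to survive (default 4).
#' @return list with \code{models} and \code{rejected} as in
#'   \code{\link{coverageFilter}}.
#' @export
exonFilter <- function(models, minExons = 4L) {
  stopifnot(is(models, "GeneModelSet"))
  keep <- models@models$nExons >= minExons
  ids <- modelIds(models)
  list(models = keepModels(models, ids[keep]),
       rejected = data.frame(id = ids[!keep],
                             reason = rep("few-exons", sum(!keep))))
}

## exon-projected shared bases for every overlapping same-scaffold model
## pair; returns data.frame(id1, id2, shared)
.pairSharedBases <- function(set) {
  ex <- set@exons
  if (length(ex) < 2L)
    return(data.frame(id1 = character(0), id2 = character(0),
                      shared = numeric(0)))
  hits <- GenomicRanges::findOverlaps(ex, ex, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  ids <- S4Vectors::mcols(ex)$model_id
  sel <- ids[q] < ids[s]          # each unordered model pair once
  if (!any(sel))
    return(data.frame(id1 = character(0), id2 = character(0),
                      shared = numeric(0)))
  q <- q[sel]; s <- s[sel]
  ov <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(ex[q]), GenomicRanges::ranges(ex[s])))
  agg <- rowsum(ov, paste(ids[q], ids[s], sep = "\r"))
  key <- strsplit(rownames(agg), "\r", fixed = TRUE)
  data.frame(id1 = vapply(key, `[`, "", 1L),
             id2 = vapply(key, `[`, "", 2L),
             shared = as.numeric(agg[, 1L]))
}

#' Redundancy filter: collapse near-duplicate models
#'
#' For every same-scaffold model pair whose exon-projected shared bases
#' reach \code{minOverlap} of the denominator model's CDS length
#' (denominator: the shorter model by default), the shorter model is
#' removed and the longer retained; CDS-length ties are broken by
#' keeping the lexicographically smaller id. Removal proceeds in
#' simultaneous rounds over all currently surviving pairs until a fixed
#' point, which makes the result independent of input order.
#'
#' @param models a \linkS4class{GeneModelSet}.
#' @param minOverlap minimum overlap fraction (default 0.90).
#' @param denominator which CDS length normalizes the shared bases:
#'   \code{"shorter"} (default), \code{"longer"} or \code{"union"}
#'   (shared / bases covered by either model).
#' @return list with \code{models} and \code{rejected}.
#' @export
redundancyFilter <- function(models, minOverlap = 0.90,
                             denominator = c("shorter", "longer", "union")) {
  stopifnot(is(models, "GeneModelSet"))
  denominator <- match.arg(denominator)
  pairs <- .pairSharedBases(models)
  cds <- setNames(models@models$cdsLength, models@models$id)
  alive <- modelIds(models)
  rejected <- character(0)
  if (nrow(pairs)) {
    den <- switch(denominator,
      shorter = pmin(cds[pairs$id1], cds[pairs$id2]),
      longer  = pmax(cds[pairs$id1], cds[pairs$id2]),
      union   = cds[pairs$id1] + cds[pairs$id2] - pairs$shared)
    pairs <- pairs[pairs$shared / den >= minOverlap, , drop = FALSE]
    repeat {
      act <- pairs[pairs$id1 %in% alive & pairs$id2 %in% alive, ,
                   drop = FALSE]
      if (nrow(act) == 0L) break
      shorter1 <- cds[act$id1] < cds[act$id2] |
        (cds[act$id1] == cds[act$id2] & act$id1 > act$id2)
      losers <- unique(ifelse(shorter1, act$id1, act$id2))
      alive <- setdiff(alive, losers)
      rejected <- c(rejected, losers)
    }
  }
  list(models = keepModels(models, alive),
       rejected = data.frame(id = sort(rejected),
                             reason = rep("redundant", length(rejected))))
}

#' Repeat filter: discard models touching annotated repeats
#'
#' A model is removed if any of its exons overlaps any repeat interval
#' by at least one base ("free of repeat regions"). Models on scaffolds
#' absent from the repeat track are treated as repeat-free (a message is
#' emitted).
#'
#' @param models a \linkS4class{GeneModelSet}.
#' @param repeats \code{GRanges} of repeat intervals (strand ignored).
#' @return list with \code{models} and \code{rejected}.
#' @export
repeatFilter <- function(models, repeats) {
  stopifnot(is(models, "GeneModelSet"), is(repeats, "GRanges"))
  missingScaf <- setdiff(unique(models@models$scaffold),
                         as.character(unique(GenomicRanges::seqnames(repeats))))
  if (length(missingScaf))
    message("repeat track has no intervals on ", length(missingScaf),
            " scaffold(s); models there treated as repeat-free")
  ## disjoint seqlevel sets are expected (scaffolds without repeats)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(models@exons, repeats,
                                ignore.strand = TRUE))
  bad <- unique(S4Vectors::mcols(models@exons)$model_id[
    S4Vectors::queryHits(hits)])
  ids <- modelIds(models)
  keep <- !(ids %in% bad)
  list(models = keepModels(models, ids[keep]),
       rejected = data.frame(id = ids[!keep],
                             reason = rep("repeat-overlap", sum(!keep))))
}

#' Run the full gene-model curation cascade
#'
#' Applies, in order: the protein-coverage filter, the exon-count
#' filter, the redundancy filter, and the repeat filter, producing the
#' curated training set and a full audit report (per-stage in/out counts
#' and a rejection reason for every removed model). The cascade is
#' idempotent: re-running it on its own survivors changes nothing.
#'
#' @param models a \linkS4class{GeneModelSet}.
#' @param evidence alignment-evidence data.frame (see
#'   \code{\link{coverageFilter}}).
#' @param repeats \code{GRanges} repeat track.
#' @param minCov,minExons,minOverlap,denominator stage parameters, see
#'   the individual filters.
#' @return list with \code{models} (curated \linkS4class{GeneModelSet})
#'   and \code{report} (\linkS4class{CurationReport}).
#' @export
curateModels <- function(models, evidence, repeats, minCov = 0.90,
                         minExons = 4L, minOverlap = 0.90,
                         denominator = "shorter") {
  stopifnot(is(models, "GeneModelSet"))
  ## evidence for models outside the given set is dropped up front, so
  ## the cascade can be re-run on its own survivors with the original
  ## evidence table (idempotence); a direct coverageFilter() call keeps
  ## the strict unknown-id error
  extra <- !(evidence$model_id %in% modelIds(models))
  if (any(extra)) {
    message("dropping ", sum(extra),
            " evidence row(s) for models outside the input set")
    evidence <- evidence[!extra, , drop = FALSE]
  }
  stageNames <- c("coverage", "exon-count", "redundancy", "repeat")
  cur <- models
  stages <- data.frame(stage = stageNames, nIn = NA_integer_,
                       nOut = NA_integer_)
  rejected <- data.frame(id = character(0), stage = character(0),
                         reason = character(0))
  for (i in seq_along(stageNames)) {
    stages$nIn[i] <- nrow(cur@models)
    res <- switch(stageNames[i],
      "coverage"   = coverageFilter(cur, evidence, minCov),
      "exon-count" = exonFilter(cur, minExons),
      "redundancy" = redundancyFilter(cur, minOverlap, denominator),
      "repeat"     = repeatFilter(cur, repeats))
    cur <- res$models
    stages$nOut[i] <- nrow(cur@models)
    if (nrow(res$rejected))
      rejected <- rbind(rejected,
                        cbind(res$rejected[, "id", drop = FALSE],
                              stage = stageNames[i],
                              reason = res$rejected$reason))
  }
  rownames(rejected) <- NULL
  report <- new("CurationReport", stages = stages,
                survivors = modelIds(cur), rejected = rejected)
  list(models = cur, report = report)
}
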