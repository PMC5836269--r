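#' Read a genome-by-domain count matrix
#'
#' Long-format TSV with header columns \code{genome}, \code{domain},
#' \code{count}; missing (genome, domain) cells are zero-filled.
#'
#' @param path TSV file.
#' @return A \linkS4class{DomainCountMatrix}.
#' @seealso \code{\link{readDomtbl}} for per-genome HMMER tables,
#'   \code{\link{writeDomainCounts}}.
#' @export
readDomainCounts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("genome", "domain", "count")
  if (!all(req %in% names(df)))
    stop("expected columns genome, domain, count in ", path)
  if (any(df$count < 0)) stop("negative count in ", path)
  if (anyDuplicated(df[, c("genome", "domain")]))
    stop("duplicate (genome, domain) rows in ", path)
  genomes <- unique(df$genome)
  domains <- unique(df$domain)
  m <- matrix(0, nrow = length(genomes), ncol = length(domains),
              dimnames = list(genomes, domains))
  m[cbind(match(df$genome, genomes), match(df$domain, domains))] <- df$count
  domainCountMatrix(m)
}

#' Write a domain count matrix as long TSV
#'
#' @param m a \linkS4class{DomainCountMatrix}.
#' @param path output TSV.
#' @return the path, invisibly.
#' @export
writeDomainCounts <- function(m, path) {
  stopifnot(is(m, "DomainCountMatrix"))
  cnt <- domainCounts(m)
  long <- data.frame(genome = rep(rownames(cnt), times = ncol(cnt)),
                     domain = rep(colnames(cnt), each = nrow(cnt)),
                     count = as.vector(cnt))
  lines <- c("genome\tdomain\tcount",
             sprintf("%s\t%s\t%d", long$genome, long$domain,
                     as.integer(long$count)))
  writeLinesAtomic(lines, path)
}

#' Count domain hits from HMMER domtblout-like files
#'
#' Parses one whitespace-delimited, \code{#}-commented per-genome table
#' per file (HMMER \code{--domtblout} layout: target name, target
#' accession, ..., full-sequence E-value in column 7), keeps rows at or
#' below the e-value threshold, and tallies hits per domain. The domain
#' label is the target accession when present, else the target name.
#'
#' @param paths named character vector of files; names are the genome
#'   labels.
#' @param eValueMax e-value threshold (default 1e-05).
#' @param accessionColumn,eValueColumn 1-based column positions of the
#'   domain accession and the e-value.
#' @return A \linkS4class{DomainCountMatrix}.
#' @export
readDomtbl <- function(paths, eValueMax = 1e-5, accessionColumn = 2L,
                       eValueColumn = 7L) {
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    stop("paths must be named by genome label")
  tallies <- lapply(paths, function(p) {
    lines <- readLines(p)
    lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
    if (!length(lines)) return(table(character(0)))
    fields <- strsplit(trimws(lines), "\\s+")
    dom <- vapply(fields, function(f) {
      acc <- f[accessionColumn]
      if (is.na(acc) || acc == "-") f[1L] else acc
    }, "")
    ev <- as.numeric(vapply(fields, `[`, "", eValueColumn))
    if (anyNA(ev)) stop("non-numeric e-value in ", p)
    table(dom[ev <= eValueMax])
  })
  domains <- sort(unique(unlist(lapply(tallies, names))))
  m <- matrix(0, nrow = length(paths), ncol = length(domains),
              dimnames = list(names(paths), domains))
  for (g in names(paths)) m[g, names(tallies[[g]])] <- as.numeric(tallies[[g]])
  domainCountMatrix(m)
}

#' Expected domain counts in the focal genome
#'
#' The Poisson expectation for each domain in the focal genome: the
#' per-genome counts are normalized to frequencies by each genome's
#' total domain count (compensating genome size and annotation
#' discrepancies), the frequencies are averaged over the non-focal
#' genomes, and the average is rescaled by the focal genome's total.
#'
#' @param m a \linkS4class{DomainCountMatrix}.
#' @param focal focal genome label.
#' @return named numeric vector of expected counts, one per domain.
#' @export
expectedLambda <- function(m, focal) {
  stopifnot(is(m, "DomainCountMatrix"))
  cnt <- domainCounts(m)
  if (!focal %in% rownames(cnt)) stop("unknown focal genome: ", focal)
  totals <- rowSums(cnt)
  if (any(totals == 0))
    stop("genome(s) with zero total counts: ",
         paste(rownames(cnt)[totals == 0], collapse = ", "))
  freq <- cnt[rownames(cnt) != focal, , drop = FALSE] /
    totals[rownames(cnt) != focal]
  colMeans(freq) * totals[focal]
}

#' Poisson cumulative tail probabilities
#'
#' For an observed count x and expectation lambda:
#' \code{pDown = P(X <= x)} and \code{pUp = P(X >= x)} under
#' X ~ Poisson(lambda). At lambda = 0 the distribution is a point mass
#' at zero, so pDown = 1 and pUp = 1 iff x = 0, else 0. Vectorized.
#'
#' @param x non-negative integer count(s).
#' @param lambda non-negative expectation(s).
#' @return list with components \code{pUp} and \code{pDown}.
#' @examples
#' poissonTails(7, 2)$pUp  # ~0.00453
#' @export
poissonTails <- function(x, lambda) {
  if (any(x < 0) || any(x != floor(x))) stop("x must be a non-negative integer")
  if (any(lambda < 0)) stop("lambda must be non-negative")
  list(pUp = ppois(x - 1, lambda, lower.tail = FALSE),
       pDown = ppois(x, lambda))
}

#' Test domains for expansion or contraction in a focal genome
#'
#' For every domain observed anywhere, compares the focal genome's count
#' with its expectation from the other genomes
#' (\code{\link{expectedLambda}}) by one-sided Poisson cumulative tails,
#' applies Bonferroni correction over the tested domains, and calls a
#' domain expanded (adjusted upper tail at or below alpha, observed
#' above expectation), contracted (lower tail, observed below), or
#' neutral. Domains absent from every genome are skipped; no
#' pseudocount enters the test.
#'
#' @param m a \linkS4class{DomainCountMatrix}.
#' @param focal focal genome label.
#' @param alpha family-wise significance level (default 0.05).
#' @param familySize Bonferroni family: \code{"directions"} (default,
#'   twice the number of tested domains, counting the two one-sided
#'   tests per domain — the count under which Bonferroni guarantees
#'   family-wise error at most \code{alpha}) or \code{"domains"} (the
#'   number of tested domains only, which bounds the family-wise error
#'   at \code{2 alpha}).
#' @return A \code{\link[S4Vectors]{DataFrame}} with one row per tested
#'   domain: \code{domain}, \code{observed}, \code{lambda}, \code{pUp},
#'   \code{pDown}, \code{pAdjUp}, \code{pAdjDown}, \code{call}; metadata
#'   records focal, alpha and the family size.
#' @export
testDomains <- function(m, focal, alpha = 0.05,
                        familySize = c("directions", "domains")) {
  stopifnot(is(m, "DomainCountMatrix"))
  familySize <- match.arg(familySize)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  cnt <- domainCounts(m)
  lambda <- expectedLambda(m, focal)
  x <- cnt[focal, ]
  tested <- colSums(cnt) > 0          # skip domains absent everywhere
  x <- x[tested]; lambda <- lambda[tested]
  mTests <- sum(tested)
  fam <- if (familySize == "domains") mTests else 2L * mTests
  tails <- poissonTails(x, lambda)
  adjUp <- pmin(1, tails$pUp * fam)
  adjDown <- pmin(1, tails$pDown * fam)
  call <- rep("neutral", mTests)
  call[adjUp <= alpha & x > lambda] <- "expanded"
  call[adjDown <= alpha & x < lambda] <- "contracted"
  res <- S4Vectors::DataFrame(domain = names(x), observed = unname(x),
                              lambda = unname(lambda),
                              pUp = unname(tails$pUp),
                              pDown = unname(tails$pDown),
                              pAdjUp = unname(adjUp),
                              pAdjDown = unname(adjDown), call = call)
  S4Vectors::metadata(res) <- list(focal = focal, alpha = alpha,
                                   mTests = mTests, familySize = familySize)
  res
}

#' Log2-ratio matrix of normalized domain counts
#'
#' Counts are frequency-normalized per genome and rescaled to a common
#' total (the mean of the per-genome totals); each entry is the log2
#' ratio of the genome's normalized count (plus pseudocount) to the
#' cross-genome mean for that domain (plus pseudocount). This is the
#' display matrix behind expansion heatmaps; the pseudocount never
#' enters the Poisson test.
#'
#' @param m a \linkS4class{DomainCountMatrix}.
#' @param pseudocount added to numerator and denominator (default 0.5).
#' @return A \linkS4class{Log2RatioMatrix}.
#' @export
log2RatioMatrix <- function(m, pseudocount = 0.5) {
  stopifnot(is(m, "DomainCountMatrix"))
  cnt <- domainCounts(m)
  totals <- rowSums(cnt)
  if (any(totals == 0)) stop("genome(s) with zero total counts")
  norm <- cnt / totals * mean(totals)
  means <- colMeans(norm)
  ratios <- log2(sweep(norm + pseudocount, 2, means + pseudocount, "/"))
  new("Log2RatioMatrix", ratios = ratios, pseudocount = pseudocount,
      referenceMeans = means, normalizedCounts = norm)
}

## average-dot-product similarity matrix between the rows of X
.avgDotSimilarity <- function(X, similarity) {
  S <- X %*% t(X)
  if (similarity == "avgdot") S / ncol(X)
  else {                                 # cosine
    nrm <- sqrt(diag(S))
    nrm[nrm == 0] <- 1
    S / outer(nrm, nrm)
  }
}

#' Hierarchical clustering of a log2-ratio matrix
#'
#' Pairwise similarity between items (genomes or domains) is the
#' average dot product of their ratio vectors (elementwise product
#' averaged over the vector length; cosine similarity available as an
#' alternative). Similarities are converted to distances by subtracting
#' from the maximal off-diagonal similarity, so the most similar pair
#' sits at distance 0, and items are agglomerated with complete linkage.
#' Ties are broken by the lexicographic order of cluster labels (a
#' cluster is labelled by its smallest member), making the dendrogram
#' reproducible.
#'
#' @param lrm a \linkS4class{Log2RatioMatrix}, or a plain numeric matrix.
#' @param axis cluster \code{"genomes"} (rows, default) or
#'   \code{"domains"} (columns).
#' @param similarity \code{"avgdot"} (default) or \code{"cosine"}.
#' @return list with \code{merges} (data.frame: step, label1, label2,
#'   height), \code{hclust} (a \code{stats::hclust} object) and
#'   \code{newick} (Newick text with branch lengths from merge heights).
#' @export
clusterRatios <- function(lrm, axis = c("genomes", "domains"),
                          similarity = c("avgdot", "cosine")) {
  axis <- match.arg(axis)
  similarity <- match.arg(similarity)
  X <- if (is(lrm, "Log2RatioMatrix")) ratioMatrix(lrm) else as.matrix(lrm)
  if (axis == "domains") X <- t(X)
  n <- nrow(X)
  if (n < 2L) stop("need at least two items to cluster")
  labels <- rownames(X)
  if (is.null(labels)) labels <- paste0("item", seq_len(n))
  S <- .avgDotSimilarity(X, similarity)
  off <- S; diag(off) <- -Inf
  D <- max(off) - S
  diag(D) <- 0

  ## agglomeration state: active cluster label (smallest member),
  ## hclust-style node code, member distance matrix updated by complete
  ## linkage
  code <- -seq_len(n)                      # hclust convention
  clusterLabel <- labels
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  merges <- data.frame(step = integer(0), label1 = character(0),
                       label2 = character(0), height = numeric(0))
  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    best <- NULL; bestD <- Inf
    ## scan pairs in lexicographic label order; first strict improvement
    ## wins, so ties resolve to the smallest label pair
    ord <- idx[order(clusterLabel[idx])]
    for (a in seq_along(ord)[-length(ord)]) {
      for (b in (a + 1L):length(ord)) {
        i <- ord[a]; j <- ord[b]
        if (D[i, j] < bestD) { bestD <- D[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    la <- clusterLabel[i]; lb <- clusterLabel[j]
    merges <- rbind(merges, data.frame(
      step = step, label1 = min(la, lb), label2 = max(la, lb),
      height = bestD))
    merge[step, ] <- sort(c(code[i], code[j]))
    height[step] <- bestD
    ## complete linkage update into slot i; retire j
    newd <- pmax(D[i, ], D[j, ])
    D[i, ] <- newd; D[, i] <- newd; D[i, i] <- 0
    active[j] <- FALSE
    code[i] <- step
    clusterLabel[i] <- min(la, lb)
  }
  hc <- list(merge = merge, height = height,
             order = .hclustOrder(merge, n), labels = labels,
             method = "complete", call = match.call(),
             dist.method = similarity)
  class(hc) <- "hclust"
  phy <- ape::as.phylo(hc)
  list(merges = merges, hclust = hc,
       newick = ape::write.tree(phy))
}

## leaf order by traversal of the merge matrix
.hclustOrder <- function(merge, n) {
  leaves <- function(node) {
    if (node < 0) return(-node)
    c(leaves(merge[node, 1]), leaves(merge[node, 2]))
  }
  if (n == 1L) return(1L)
  leaves(n - 1L)
}
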