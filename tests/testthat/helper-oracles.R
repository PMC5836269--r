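## Independent brute-force oracles used to cross-check the package
## implementations. Deliberately written with naive loops and per-base /
## per-term arithmetic, sharing no code with the package.

## prefix-sum N50 by explicit accumulation
bruteNxx <- function(lengths, x = 50) {
  s <- sort(lengths, decreasing = TRUE)
  target <- x / 100 * sum(s)
  run <- 0
  for (L in s) {
    run <- run + L
    if (run >= target) return(L)
  }
}

## Poisson tails by term-by-term pmf summation (valid for lambda <= ~170)
brutePoissonTails <- function(x, lambda) {
  pmf <- function(i) exp(-lambda) * lambda^i / factorial(i)
  pDown <- 0
  for (i in 0:x) pDown <- pDown + pmf(i)
  list(pUp = 1 - pDown + pmf(x), pDown = pDown)
}

## expected focal count by explicit per-genome frequency averaging
bruteLambda <- function(cnt, focal, domain) {
  others <- setdiff(rownames(cnt), focal)
  acc <- 0
  for (g in others) acc <- acc + cnt[g, domain] / sum(cnt[g, ])
  (acc / length(others)) * sum(cnt[focal, ])
}

## exon positions of one model as an integer set (1-based closed ranges)
.positions <- function(starts, ends) {
  unlist(mapply(function(a, b) a:b, starts, ends, SIMPLIFY = FALSE))
}

## redundancy fixpoint on the declared semantics, via per-base set
## intersection: simultaneous rounds removing every over-threshold
## pair's shorter member (id tie-break) until stable
bruteRedundancy <- function(exonTable, minOverlap = 0.9) {
  ids <- unique(exonTable$model_id)
  pos <- lapply(ids, function(i) {
    e <- exonTable[exonTable$model_id == i, ]
    list(scaffold = e$scaffold[1], bases = .positions(e$start, e$end))
  })
  names(pos) <- ids
  cds <- vapply(pos, function(p) length(p$bases), numeric(1))
  alive <- ids
  repeat {
    losers <- character(0)
    for (a in seq_along(alive)) {
      for (b in seq_along(alive)) {
        if (a >= b) next
        i <- alive[a]; j <- alive[b]
        if (pos[[i]]$scaffold != pos[[j]]$scaffold) next
        shared <- length(intersect(pos[[i]]$bases, pos[[j]]$bases))
        if (shared / min(cds[i], cds[j]) >= minOverlap) {
          loser <- if (cds[i] < cds[j]) i
                   else if (cds[j] < cds[i]) j
                   else max(i, j)
          losers <- union(losers, loser)
        }
      }
    }
    if (!length(losers)) break
    alive <- setdiff(alive, losers)
  }
  sort(alive)
}

## which models overlap any repeat, by per-base intersection
bruteRepeatHits <- function(exonTable, repeatTable) {
  ids <- unique(exonTable$model_id)
  hit <- character(0)
  for (i in ids) {
    e <- exonTable[exonTable$model_id == i, ]
    bases <- .positions(e$start, e$end)
    r <- repeatTable[repeatTable$scaffold == e$scaffold[1], ]
    if (nrow(r) && length(intersect(bases, .positions(r$start, r$end))))
      hit <- c(hit, i)
  }
  hit
}

## O(n^3) complete-linkage agglomeration over the average-dot-product
## distance, tracking explicit member lists; ties broken by the sorted
## label pair, clusters labelled by their smallest member
bruteCompleteLinkage <- function(X) {
  n <- nrow(X)
  labels <- rownames(X)
  S <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    S[i, j] <- sum(X[i, ] * X[j, ]) / ncol(X)
  offmax <- max(S[row(S) != col(S)])
  D <- offmax - S
  members <- as.list(seq_len(n))
  clabel <- labels
  merges <- NULL
  while (length(members) > 1L) {
    best <- NULL; bestD <- Inf; bestPair <- NULL
    ord <- order(clabel)
    for (a in seq_along(ord)[-length(ord)]) {
      for (b in (a + 1L):length(ord)) {
        i <- ord[a]; j <- ord[b]
        d <- max(D[members[[i]], members[[j]]])
        if (d < bestD) { bestD <- d; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    merges <- rbind(merges, data.frame(
      label1 = min(clabel[i], clabel[j]),
      label2 = max(clabel[i], clabel[j]), height = bestD))
    members[[i]] <- c(members[[i]], members[[j]])
    clabel[i] <- min(clabel[i], clabel[j])
    members[[j]] <- NULL
    clabel <- clabel[-j]
  }
  merges
}

## small temporary FASTA writer for fixtures
writeTempFasta <- function(seqs) {
  path <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  path
}
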