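#' Read a Jellyfish-style k-mer histogram
#'
#' Parses whitespace-separated two-column text (multiplicity,
#' distinct-k-mer count), the \code{jellyfish histo} output format.
#' Multiplicities absent from the file are treated as zero-count; a final
#' catch-all bin, if present, is used at its nominal multiplicity unless
#' \code{dropLastBin = TRUE}.
#'
#' @param path path to the histogram file.
#' @param k k-mer length used when counting (not recorded in the file).
#' @param resort re-sort out-of-order rows (default) instead of erroring.
#' @param dropLastBin drop the final row (Jellyfish's catch-all bin).
#' @return A \linkS4class{KmerHistogram}.
#' @seealso \code{\link{writeHisto}}, \code{\link{profileSpectrum}}
#' @export
readHisto <- function(path, k, resort = TRUE, dropLastBin = FALSE) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) stop("empty histogram file: ", path)
  idx <- which(keep)
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  bad <- which(vapply(fields, length, integer(1)) != 2L)
  if (length(bad))
    stop(sprintf("malformed row at line %d of %s (expected 2 columns)",
                 idx[bad[1]], path))
  m <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 1L)))
  cnt <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  nonnum <- which(is.na(m) | is.na(cnt) | m != floor(m) | m < 1 | cnt < 0)
  if (length(nonnum))
    stop(sprintf("malformed row at line %d of %s (non-numeric or invalid)",
                 idx[nonnum[1]], path))
  if (dropLastBin && length(m) > 1L) {
    last <- which.max(m)
    m <- m[-last]; cnt <- cnt[-last]
  }
  KmerHistogram(k = k, multiplicity = m, count = cnt, resort = resort)
}

#' Write a k-mer histogram in Jellyfish histo format
#'
#' @param h a \linkS4class{KmerHistogram}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeHisto <- function(h, path) {
  stopifnot(is(h, "KmerHistogram"))
  writeLinesAtomic(sprintf("%d %s", h@multiplicity,
                           format(h@count, scientific = FALSE, trim = TRUE)),
                   path)
}

#' Total k-mer volume over a multiplicity range
#'
#' Sum of multiplicity x distinct-k-mer count over multiplicities in
#' \code{[lo, hi]}; with the defaults, the total k-mer volume of the
#' spectrum (i.e. the total number of k-mer observations in the reads).
#'
#' @param h a \linkS4class{KmerHistogram}.
#' @param lo,hi inclusive multiplicity bounds (\code{hi = Inf} for the tail).
#' @return numeric k-mer volume; 0 for an empty range.
#' @examples
#' h <- KmerHistogram(25, 1:2, c(100, 50))
#' totalVolume(h)  # 1*100 + 2*50 = 200
#' @export
totalVolume <- function(h, lo = 1, hi = Inf) {
  stopifnot(is(h, "KmerHistogram"))
  if (lo > hi) stop("lo must not exceed hi")
  sel <- h@multiplicity >= lo & h@multiplicity <= hi
  sum(as.numeric(h@multiplicity[sel]) * h@count[sel])
}

## dense (zero-filled) count vector over multiplicities 1..max, smoothed
denseSmoothed <- function(h, smoothWindow) {
  maxm <- max(h@multiplicity)
  dense <- numeric(maxm)
  dense[h@multiplicity] <- h@count
  movingAverage(dense, smoothWindow)
}

#' Detect the error threshold of a k-mer spectrum
#'
#' Sequencing errors produce a descending limb of low-multiplicity k-mers
#' to the left of the coverage peak(s). The threshold is the multiplicity
#' of the first local minimum of the (smoothed) count curve scanning
#' upward from multiplicity 1; k-mers strictly below it are treated as
#' erroneous.
#'
#' A dip only counts as the error/signal valley when the curve later
#' rises to at least twice the dip's height (the coverage peak); noise
#' wiggles in a monotone tail therefore do not qualify, and a spectrum
#' without an error limb (e.g. error-free simulated reads) signals
#' "no valley found".
#'
#' @param h a \linkS4class{KmerHistogram}.
#' @param smoothWindow odd width of the centered moving-average smoother
#'   (1 = no smoothing).
#' @return the threshold multiplicity.
#' @export
detectErrorThreshold <- function(h, smoothWindow = 3L) {
  stopifnot(is(h, "KmerHistogram"))
  s <- denseSmoothed(h, smoothWindow)
  n <- length(s)
  if (n >= 3L) {
    suffixMax <- rev(cummax(rev(s)))      # max of s[i..n]
    for (i in 2:(n - 1L)) {
      if (s[i] < s[i - 1L] && s[i] <= s[i + 1L] &&
          suffixMax[i + 1L] > 2 * s[i])
        return(i)
    }
  }
  stop("no valley found: spectrum has no local minimum after the error limb")
}

#' Detect coverage peaks of a k-mer spectrum
#'
#' Local maxima of the smoothed count curve at multiplicities above the
#' error threshold, in order of increasing depth. In a diploid spectrum
#' the first peak (near half the homozygous depth) collects
#' haplotype-specific k-mers from heterozygous sites and the second the
#' homozygous k-mers shared by both haplotypes.
#'
#' @param h a \linkS4class{KmerHistogram}.
#' @param e error threshold (from \code{\link{detectErrorThreshold}} or
#'   a user override).
#' @param smoothWindow odd smoothing window.
#' @return data.frame with columns \code{depth} (multiplicity) and
#'   \code{height} (smoothed count); zero rows when no maxima exist.
#' @export
detectPeaks <- function(h, e, smoothWindow = 3L) {
  stopifnot(is(h, "KmerHistogram"))
  s <- denseSmoothed(h, smoothWindow)
  n <- length(s)
  depth <- integer(0)
  i <- max(2L, as.integer(e) + 1L)
  while (i <= n) {
    isMax <- if (i < n) s[i] > s[i - 1L] && s[i] >= s[i + 1L]
             else s[i] > s[i - 1L]
    if (isMax && s[i] > 0) depth <- c(depth, i)
    i <- i + 1L
  }
  data.frame(depth = depth, height = s[depth])
}

#' Classify ploidy from detected spectrum peaks
#'
#' A double-peaked spectrum whose deeper peak sits at about twice the
#' depth of the shallower one is evidence of a diploid, heterozygous
#' genome; a single dominant peak is haploid-like; anything else is
#' ambiguous. Peaks below \code{dominanceFrac} of the tallest peak are
#' ignored as minor bumps.
#'
#' @param peaks data.frame from \code{\link{detectPeaks}}.
#' @param tau tolerance on the depth ratio: diploid requires
#'   ratio within \code{[2 - tau, 2 + tau]}.
#' @param dominanceFrac minimum height, as a fraction of the tallest
#'   peak, for a peak to count as dominant.
#' @return one of \code{"haploid-like"}, \code{"diploid-heterozygous"},
#'   \code{"ambiguous"}.
#' @export
classifyPloidy <- function(peaks, tau = 0.35, dominanceFrac = 0.05) {
  if (is.null(peaks) || nrow(peaks) == 0L) return("ambiguous")
  dom <- peaks[peaks$height >= dominanceFrac * max(peaks$height), ,
               drop = FALSE]
  if (nrow(dom) == 1L) return("haploid-like")
  if (nrow(dom) == 2L) {
    ratio <- max(dom$depth) / min(dom$depth)
    if (ratio >= 2 - tau && ratio <= 2 + tau) return("diploid-heterozygous")
  }
  "ambiguous"
}

#' Estimate genome size from a k-mer spectrum
#'
#' Genome size is the total k-mer volume, minus the volume of erroneous
#' k-mers (multiplicities strictly below the error threshold), divided by
#' the homozygous coverage-peak depth. The high-multiplicity repeat tail
#' is deliberately retained in the total.
#'
#' @param h a \linkS4class{KmerHistogram}.
#' @param e error threshold multiplicity.
#' @param cHom homozygous peak depth.
#' @return estimated genome size in bases.
#' @examples
#' # T = 3,070,000 with 70,000 in the error limb, peak depth 30:
#' h <- KmerHistogram(25, c(1, 2, 30), c(40000, 15000, 100000))
#' estimateGenomeSize(h, e = 3, cHom = 30)  # 100,000
#' @export
estimateGenomeSize <- function(h, e, cHom) {
  stopifnot(is(h, "KmerHistogram"))
  if (!is.numeric(cHom) || cHom <= 0) stop("cHom must be positive")
  if (e < 1) stop("error threshold must be >= 1")
  (totalVolume(h) - if (e > 1) totalVolume(h, 1, e - 1) else 0) / cHom
}

## valleys flanking the het peak: minimum of the smoothed curve strictly
## between a and b (multiplicities a+1 .. b-1); NA when the gap is empty
.valleyBetween <- function(s, a, b) {
  lo <- as.integer(a) + 1L; hi <- as.integer(b) - 1L
  if (lo > hi) return(NA_integer_)
  seg <- s[lo:hi]
  lo + which.min(seg) - 1L
}

#' Estimate heterozygosity from the heterozygous peak volume
#'
#' Each isolated heterozygous site contributes about 2k haplotype-specific
#' k-mers (k per haplotype) accumulating at the heterozygous peak depth.
#' The estimator integrates the spectrum over the heterozygous window
#' (valley-to-valley around the het peak), converts the volume to distinct
#' het k-mers by dividing by the het depth, to het sites by dividing by
#' 2k, and to a rate by dividing by the genome size.
#'
#' @param h a \linkS4class{KmerHistogram}.
#' @param e error threshold.
#' @param cHet,cHom heterozygous and homozygous peak depths; a missing
#'   (\code{NA}) het peak returns 0 with a warning.
#' @param k k-mer length (defaults to the histogram's).
#' @param G genome size in bases (from \code{\link{estimateGenomeSize}}).
#' @param smoothWindow odd smoothing window for valley location.
#' @param window optional explicit inclusive multiplicity window
#'   \code{c(lo, hi)} overriding valley detection.
#' @param truncationCorrection divide the window volume by the het-mass
#'   fraction the window captures under Poisson(\code{cHet}), removing
#'   the downward bias of narrow valley-to-valley windows at low
#'   coverage (default TRUE; skipped when the captured fraction is
#'   implausibly small).
#' @return estimated heterozygosity (fraction of sites).
#' @export
estimateHeterozygosity <- function(h, e, cHet, cHom, k = kmerLength(h), G,
                                   smoothWindow = 3L, window = NULL,
                                   truncationCorrection = TRUE) {
  stopifnot(is(h, "KmerHistogram"))
  if (is.null(cHet) || is.na(cHet)) {
    warning("no heterozygous peak: reporting heterozygosity 0")
    return(0)
  }
  if (cHet <= 0) stop("cHet must be positive")
  if (G <= 0) stop("G must be positive")
  if (is.null(window)) {
    s <- denseSmoothed(h, smoothWindow)
    v1 <- .valleyBetween(s, e, cHet)
    if (is.na(v1)) v1 <- as.integer(e)
    v2 <- .valleyBetween(s, cHet, cHom)
    if (is.na(v2)) v2 <- as.integer(ceiling((cHet + cHom) / 2))
    window <- c(v1, v2 - 1L)
  }
  aHet <- totalVolume(h, window[1], window[2])
  dHet <- aHet / cHet          # distinct haplotype-specific k-mers
  if (truncationCorrection) {
    ## fraction of the het component's volume the window captures under
    ## Poisson(cHet); uses m*dpois(m, l) = l*dpois(m-1, l)
    capt <- ppois(window[2] - 1, cHet) - ppois(window[1] - 2, cHet)
    if (capt > 0.1) dHet <- dHet / capt
  }
  (dHet / (2 * k)) / G         # het sites per base
}

#' Profile a k-mer spectrum
#'
#' Runs the full inference chain on a k-mer histogram: error-threshold
#' detection, peak detection, ploidy classification, genome-size and
#' heterozygosity estimation. Any of the landmark values can be forced
#' through \code{overrides} (e.g. \code{list(errorThreshold = 12,
#' homPeakDepth = 45)}); overridden fields are recorded in the profile.
#' Stages that fail leave their fields \code{NA} and add a note, so a
#' partial profile is still returned.
#'
#' In highly heterozygous genomes the haplotype-specific peak can dwarf
#' the homozygous peak to the point where the latter is only a shoulder,
#' not a local maximum. When a single dominant peak is found but the
#' k-mer volume beyond 1.5x its depth exceeds \code{shoulderFrac} of the
#' retained volume — far more than a single Poisson component's tail can
#' carry — the homozygous depth is rescued as the smoothed-curve argmax
#' inside the 1.6-2.4x window and enters the peak list before the
#' ploidy call.
#'
#' @param h a \linkS4class{KmerHistogram}.
#' @param overrides named list; recognised names \code{errorThreshold},
#'   \code{hetPeakDepth}, \code{homPeakDepth}.
#' @param smoothWindow odd smoothing window for valley/peak detection.
#' @param tau,dominanceFrac ploidy-call parameters, see
#'   \code{\link{classifyPloidy}}.
#' @param shoulderFrac minimum fraction of retained k-mer volume beyond
#'   1.5x the single detected peak that triggers the homozygous-shoulder
#'   rescue.
#' @return A \linkS4class{SpectrumProfile}.
#' @export
profileSpectrum <- function(h, overrides = list(), smoothWindow = 3L,
                            tau = 0.35, dominanceFrac = 0.05,
                            shoulderFrac = 0.05) {
  stopifnot(is(h, "KmerHistogram"))
  allowed <- c("errorThreshold", "hetPeakDepth", "homPeakDepth")
  if (length(overrides) && !all(names(overrides) %in% allowed))
    stop("unknown override(s): ",
         paste(setdiff(names(overrides), allowed), collapse = ", "))
  notes <- character()

  e <- overrides$errorThreshold
  if (is.null(e)) {
    e <- tryCatch(detectErrorThreshold(h, smoothWindow), error = function(c) {
      notes <<- c(notes, conditionMessage(c)); NA_real_
    })
  }

  peaks <- if (!is.na(e)) detectPeaks(h, e, smoothWindow)
           else data.frame(depth = integer(0), height = numeric(0))

  ## homozygous-shoulder rescue (see Details)
  if (nrow(peaks) && !is.na(e)) {
    dom <- peaks[peaks$height >= dominanceFrac * max(peaks$height), ,
                 drop = FALSE]
    if (nrow(dom) == 1L) {
      c1 <- dom$depth[1]
      retained <- totalVolume(h, e)
      beyond <- totalVolume(h, ceiling(1.5 * c1))
      if (retained > 0 && beyond / retained >= shoulderFrac) {
        ## the dominant peak is then the haplotype-specific one; the
        ## homozygous depth sits at twice its depth by diploid coverage
        ## arithmetic (the shoulder itself is tilted by the het tail, so
        ## its argmax would underestimate the depth)
        s <- denseSmoothed(h, smoothWindow)
        c2 <- 2L * as.integer(c1)
        if (c2 <= length(s) && s[c2] > 0) {
          peaks <- rbind(peaks, data.frame(depth = c2, height = s[c2]))
          peaks <- peaks[order(peaks$depth), , drop = FALSE]
          notes <- c(notes,
            "homozygous peak recovered from the shoulder beyond the dominant peak")
        }
      }
    }
  }
  ploidy <- classifyPloidy(peaks, tau, dominanceFrac)

  cHet <- overrides$hetPeakDepth
  cHom <- overrides$homPeakDepth
  if (is.null(cHet) || is.null(cHom)) {
    dom <- peaks[peaks$height >= dominanceFrac * max(c(peaks$height, 1)), ,
                 drop = FALSE]
    detHom <- detHet <- NA_real_
    if (nrow(dom) >= 2L && ploidy == "diploid-heterozygous") {
      top2 <- dom[order(-dom$height), ][1:2, ]
      detHet <- min(top2$depth); detHom <- max(top2$depth)
    } else if (nrow(dom) >= 1L) {
      detHom <- dom$depth[which.max(dom$height)]
    } else {
      notes <- c(notes, "no coverage peak found above the error threshold")
    }
    if (is.null(cHet)) cHet <- detHet
    if (is.null(cHom)) cHom <- detHom
  }

  totVol <- totalVolume(h)
  errVol <- if (!is.na(e) && e > 1) totalVolume(h, 1, e - 1) else
            if (!is.na(e)) 0 else NA_real_

  G <- NA_real_
  if (!is.na(e) && !is.na(cHom)) G <- estimateGenomeSize(h, e, cHom)

  r <- NA_real_
  if (!is.na(G)) {
    r <- withCallingHandlers(
      estimateHeterozygosity(h, e, cHet, cHom, k = h@k, G = G,
                             smoothWindow = smoothWindow),
      warning = function(w) {
        notes <<- c(notes, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }

  new("SpectrumProfile", k = h@k,
      errorThreshold = as.numeric(e),
      hetPeakDepth = as.numeric(if (is.null(cHet)) NA else cHet),
      homPeakDepth = as.numeric(if (is.null(cHom)) NA else cHom),
      totalVolume = totVol, errorVolume = errVol,
      genomeSize = G, heterozygosity = r, ploidyCall = ploidy,
      overrides = as.character(names(overrides)), notes = notes)
}

#' Plot a k-mer spectrum
#'
#' Log-scaled count curve with the error threshold and detected peaks of
#' an optional \linkS4class{SpectrumProfile} marked.
#'
#' @param h a \linkS4class{KmerHistogram}.
#' @param profile optional \linkS4class{SpectrumProfile} to annotate.
#' @param xmax right edge of the multiplicity axis.
#' @return invisibly, NULL.
#' @importFrom graphics abline legend lines
#' @export
plotSpectrum <- function(h, profile = NULL,
                         xmax = min(max(multiplicities(h)),
                                    3 * max(multiplicities(h)[
                                      which.max(kmerCounts(h))]))) {
  sel <- h@multiplicity <= xmax
  plot(h@multiplicity[sel], h@count[sel], type = "l",
       xlab = "k-mer multiplicity (x coverage)",
       ylab = "distinct k-mers",
       main = sprintf("%d-mer spectrum", h@k))
  if (!is.null(profile)) {
    if (!is.na(profile@errorThreshold))
      abline(v = profile@errorThreshold, lty = 2, col = "grey40")
    if (!is.na(profile@hetPeakDepth))
      abline(v = profile@hetPeakDepth, lty = 3, col = "steelblue")
    if (!is.na(profile@homPeakDepth))
      abline(v = profile@homPeakDepth, lty = 3, col = "firebrick")
    legend("topright", bty = "n", lty = c(2, 3, 3),
           col = c("grey40", "steelblue", "firebrick"),
           legend = c("error threshold", "het peak", "hom peak"))
  }
  invisible(NULL)
}
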