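## round half away from zero, the convention used for displayed integers and
## percentages (base round() is round-half-even)
roundHalfUp <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## centered moving average; `window` must be odd; edges average the available
## neighbours only, so a window of 1 is the identity
movingAverage <- function(x, window = 3L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("smoothing window must be a positive odd integer")
  if (window == 1L) return(as.numeric(x))
  half <- window %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, as.numeric(x)))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

## write `lines` to `path` atomically: temp file in the same directory, then
## rename, so a failed writer never leaves a partial output behind
writeLinesAtomic <- function(lines, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path))
    stop("could not move temporary file onto ", path)
  invisible(path)
}

isCount <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)
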