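# Shared fixtures: a small three-chromosome build (fast simulations) and
# independent oracles used across test files.

.helperEnv <- new.env()

toyBuild <- function() {
  if (!is.null(.helperEnv$toy)) return(.helperEnv$toy)
  armsPath <- file.path(tempdir(), "toy_arms.tsv")
  lociPath <- file.path(tempdir(), "toy_loci.tsv")
  writeLines(c("chrom\tlength\tcen_start\tcen_end",
               "chr1\t200000000\t100000000\t104000000",
               "chr2\t150000000\t60000000\t64000000",
               "chr3\t120000000\t50000000\t54000000"), armsPath)
  writeLines(c("name\tchrom\tstart\tend",
               "CCNE1\tchr3\t80000000\t80100000",
               "ERBB2\tchr2\t100000000\t100100000"), lociPath)
  .helperEnv$toy <- loadGenomeBuild(armsPath, lociPath)
  .helperEnv$toy
}

# toy-scale simulation config: 250 kb bins keep the toy genome near 1900
# bins, enough for the pipeline's validity floor but fast
toyConfig <- function(...) {
  simulationConfig(binSize = 2.5e5, ...)
}

# build a SegmentedProfile from a compact spec: data.frame with columns
# chrom, arm, startMb, endMb (1-based Mb boundaries), level
segProfile <- function(build, spec, sampleId = "toy") {
  df <- data.frame(chrom = spec$chrom, arm = spec$arm,
                   start = as.integer(spec$startMb * 1e6 + 1),
                   end = as.integer(spec$endMb * 1e6),
                   cnLevel = spec$level,
                   nBins = pmax(1L, as.integer((spec$endMb - spec$startMb) *
                                               1e6 / 5e4)))
  swgsHRD:::newSegmentedProfile(df, build, sampleId)
}

# exhaustive least-squares segmentation oracle for noise-free series:
# smallest number of breaks (<= maxBreaks) achieving an exact piecewise-
# constant fit, with the breakpoints found by enumeration
lsOracle <- function(x, maxBreaks = 3, tol = 1e-9) {
  n <- length(x)
  S <- cumsum(c(0, x)); S2 <- cumsum(c(0, x^2))
  rss <- function(a, b) {            # bins a..b fitted by their mean
    s <- S[b + 1] - S[a]
    (S2[b + 1] - S2[a]) - s^2 / (b - a + 1)
  }
  totalRss <- function(breaks) {
    bounds <- c(0, breaks, n)
    sum(vapply(seq_len(length(bounds) - 1),
               function(k) rss(bounds[k] + 1, bounds[k + 1]), numeric(1)))
  }
  if (totalRss(integer(0)) <= tol) return(integer(0))
  for (k in seq_len(maxBreaks)) {
    combos <- utils::combn(n - 1, k)
    r <- apply(combos, 2, totalRss)
    if (min(r) <= tol) return(sort(combos[, which.min(r)]))
  }
  stop("oracle: no exact fit with <= ", maxBreaks, " breaks")
}

# independent smallest-first small-segment dissolution on plain vectors:
# the small segment's territory is absorbed at the nearer neighbor's level,
# and equal-level adjacencies coalesce
bruteSmallFilter <- function(sizesMb, levels, nBins, floorMb) {
  coalesce <- function() {
    repeat {
      k <- which(abs(diff(levels)) <= 1e-9)
      if (!length(k)) break
      k <- k[1]
      sizesMb[k] <<- sizesMb[k] + sizesMb[k + 1]
      nBins[k] <<- nBins[k] + nBins[k + 1]
      sizesMb <<- sizesMb[-(k + 1)]; levels <<- levels[-(k + 1)]
      nBins <<- nBins[-(k + 1)]
    }
  }
  repeat {
    if (length(sizesMb) < 2) break
    cand <- which(sizesMb < floorMb)
    if (!length(cand)) break
    k <- cand[which.min(sizesMb[cand])]
    nb <- if (k == 1) 2L
          else if (k == length(sizesMb)) k - 1L
          else if (abs(levels[k - 1] - levels[k]) <=
                   abs(levels[k + 1] - levels[k])) k - 1L else k + 1L
    levels[k] <- levels[nb]
    a <- min(k, nb)
    sizesMb[a] <- sizesMb[k] + sizesMb[nb]
    nBins[a] <- nBins[k] + nBins[nb]
    b <- max(k, nb)
    sizesMb <- sizesMb[-b]; levels <- levels[-b]; nBins <- nBins[-b]
    coalesce()
  }
  list(sizesMb = sizesMb, levels = levels, nBins = nBins)
}

# noise-free piecewise-constant series with k breaks (adjacent levels
# differing by >= minStep); returns list(x, breaks)
randomPiecewise <- function(n, k, minSegLen = 5, minStep = 0.3) {
  stopifnot(n >= (k + 1) * minSegLen)
  repeat {
    breaks <- sort(sample(seq_len(n - 1), k))
    lens <- diff(c(0, breaks, n))
    if (all(lens >= minSegLen)) break
  }
  levels <- numeric(k + 1)
  levels[1] <- runif(1, 0.5, 2)
  if (k > 0) for (i in 2:(k + 1)) {
    step <- runif(1, minStep, 1) * sample(c(-1, 1), 1)
    levels[i] <- max(0.1, levels[i - 1] + step)
    if (abs(levels[i] - levels[i - 1]) < minStep)
      levels[i] <- levels[i - 1] + minStep
  }
  list(x = rep(levels, diff(c(0, breaks, n))), breaks = breaks)
}
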