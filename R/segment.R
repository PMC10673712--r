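#' @include AllClasses.R io.R
#' @useDynLib swgsHRD, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Segmentation parameters
#'
#' Defaults: 3 Mb small-segment floor (well below the 10 Mb LGA scale, so
#' filtering cannot delete a true LGA flank), level-merge deltas fitted per
#' quality category (good 0.10, fair 0.15, low 0.20 ratio units), FFPE
#' correlation merge threshold 0.5, 20 stochastic reruns for the LGA
#' confidence interval, and a per-split permutation significance of 0.01.
#'
#' @param minSegmentMb small-segment filter floor (Mb).
#' @param mergeDelta named numeric of per-quality level-merge thresholds.
#' @param ffpeCorrMergeThreshold FFPE-profile correlation above which a
#'   small segment is treated as artifact and merged.
#' @param nReruns reruns for [rerunConfidence()].
#' @param alpha CBS permutation significance per split.
#' @param nPerm permutations per ambiguous split.
#' @param seed base seed; rerun i uses \code{seed + i}.
#' @return a [SegmentationParams-class].
#' @export
segmentationParams <- function(minSegmentMb = 3,
                               mergeDelta = c(good = 0.10, fair = 0.15,
                                              low = 0.20),
                               ffpeCorrMergeThreshold = 0.5,
                               nReruns = 20L, alpha = 0.01, nPerm = 100L,
                               seed = 0L) {
  new("SegmentationParams", minSegmentMb = minSegmentMb,
      mergeDelta = mergeDelta,
      ffpeCorrMergeThreshold = ffpeCorrMergeThreshold,
      nReruns = as.integer(nReruns), alpha = alpha,
      nPerm = as.integer(nPerm), seed = as.integer(seed))
}

stopNonContributive <- function(msg) {
  stop(structure(class = c("nonContributiveError", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# run fn with a private RNG stream seeded by `seed`, restoring caller state
withSeed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Circular binary segmentation of a single series
#'
#' Recursive circular split search. Each candidate split uses the maximal
#' circular statistic (the least-squares-optimal arc) and is accepted when
#' its permutation p-value is below \code{alpha}. Two deterministic gates
#' bracket the permutation test so that permutations (the stochastic
#' component of the pipeline) only run for genuinely ambiguous splits:
#' statistics below the null-maximum expectation are rejected outright and
#' Bonferroni-significant statistics are accepted outright. On noise-free
#' input (robust residual sd of zero) any true level change is split
#' deterministically, which makes segmentation exact there.
#'
#' @param x numeric series (one chromosome arm of bin ratios).
#' @param alpha split significance.
#' @param nPerm permutations per ambiguous split.
#' @param sigma noise sd; estimated as \code{mad(diff(x))/sqrt(2)} when
#'   NULL.
#' @return sorted integer breakpoint positions: a value \code{k} means a
#'   copy-number break between \code{x[k]} and \code{x[k+1]}.
#' @export
cbsSegment <- function(x, alpha = 0.01, nPerm = 100L, sigma = NULL) {
  n <- length(x)
  if (n < 4) return(integer(0))
  if (is.null(sigma)) sigma <- stats::mad(diff(x)) / sqrt(2)
  tol <- 1e-7 * (1 + max(abs(x)))
  breaks <- integer(0)
  rec <- function(lo, hi) {
    m <- hi - lo + 1
    if (m < 4) return(invisible(NULL))
    seg <- x[lo:hi]
    sc <- .cbs_scan(seg)
    u <- sc$u
    sig <- if (sigma <= tol) {
      u > tol * sqrt(m)
    } else {
      t <- u / sigma
      N <- m * (m - 1) / 2
      if (t < sqrt(2 * log(N))) FALSE
      else if (2 * N * stats::pnorm(t, lower.tail = FALSE) < alpha) TRUE
      else .cbs_perm(seg, u, nPerm, alpha)$p < alpha
    }
    if (!sig) return(invisible(NULL))
    i <- sc$i; j <- sc$j
    if (i > 0) breaks <<- c(breaks, lo - 1L + i)
    if (j < m) breaks <<- c(breaks, lo - 1L + j)
    if (i > 0) rec(lo, lo - 1L + i)
    rec(lo + i, lo - 1L + j)
    if (j < m) rec(lo + j, hi)
    invisible(NULL)
  }
  rec(1L, n)
  breaks <- sort(unique(breaks))
  # refinement: the maximal circular arc can land one endpoint inside a
  # segment when more than two levels are present; reposition each break
  # to the least-squares optimum between its neighbors and drop breaks
  # that separate (numerically) identical levels
  for (pass in 1:10) {
    changed <- FALSE
    bounds <- c(0L, breaks, n)
    for (t in seq_along(breaks)) {
      lo <- bounds[t] + 1L; hi <- bounds[t + 2L]
      seg <- x[lo:hi]
      m <- length(seg)
      if (m < 2) next
      S <- cumsum(seg)
      k <- seq_len(m - 1)
      stat <- abs(S[k] - k / m * S[m]) * sqrt(m / (k * (m - k)))
      bstar <- lo - 1L + which.max(stat)
      if (bstar != breaks[t] && max(stat) > tol) {
        breaks[t] <- bstar
        changed <- TRUE
        bounds <- c(0L, breaks, n)
      }
    }
    bounds <- c(0L, breaks, n)
    mu <- vapply(seq_len(length(bounds) - 1L), function(s)
      mean(x[(bounds[s] + 1L):bounds[s + 1L]]), numeric(1))
    keep <- abs(diff(mu)) > tol
    if (any(!keep)) {
      breaks <- breaks[keep]
      changed <- TRUE
    }
    if (!changed) break
  }
  breaks
}

# extract the working valid-bin table of a profile
validBinTable <- function(p) {
  b <- p@bins
  keep <- mcols(b)$valid & !is.na(mcols(b)$arm)
  b <- b[keep]
  data.frame(chrom = as.character(seqnames(b)), start = start(b),
             end = end(b), arm = mcols(b)$arm, ratio = mcols(b)$ratio,
             stringsAsFactors = FALSE)
}

# expectedDev aligned to a valid-bin table (NA where no noise-profile bin)
alignExpectedDev <- function(bdf, np) {
  nb <- np@bins
  key <- paste(canonChrom(as.character(seqnames(nb))), start(nb))
  idx <- match(paste(bdf$chrom, bdf$start), key)
  mcols(nb)$expectedDev[idx]
}

# working segment table from per-arm breakpoints
segTableFromBreaks <- function(bdf, breaksByArm) {
  armKey <- paste(bdf$chrom, bdf$arm)
  idxByArm <- split(seq_len(nrow(bdf)),
                    factor(armKey, levels = unique(armKey)))
  out <- list()
  for (key in names(breaksByArm)) {
    ii <- idxByArm[[key]]
    br <- breaksByArm[[key]]
    bounds <- c(0L, br, length(ii))
    for (s in seq_len(length(bounds) - 1L)) {
      sel <- ii[(bounds[s] + 1L):bounds[s + 1L]]
      out[[length(out) + 1L]] <- data.frame(
        chrom = bdf$chrom[sel[1]], arm = bdf$arm[sel[1]],
        start = bdf$start[sel[1]], end = bdf$end[sel[length(sel)]],
        cnLevel = mean(bdf$ratio[sel]), nBins = length(sel),
        binFrom = sel[1], binTo = sel[length(sel)],
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  df[order(match(df$chrom, unique(bdf$chrom)), df$start), , drop = FALSE]
}

segTableFromProfile <- function(sp) {
  s <- sp@segments
  data.frame(chrom = as.character(seqnames(s)), arm = mcols(s)$arm,
             start = start(s), end = end(s), cnLevel = mcols(s)$cnLevel,
             nBins = mcols(s)$nBins, stringsAsFactors = FALSE)
}

# merge segment row k2 into k1 (adjacent, same arm) of a working table
mergeRows <- function(df, k1, k2) {
  a <- min(k1, k2); b <- max(k1, k2)
  w <- df$nBins[c(a, b)]
  df$cnLevel[a] <- sum(df$cnLevel[c(a, b)] * w) / sum(w)
  df$end[a] <- df$end[b]
  df$nBins[a] <- sum(w)
  if (!is.null(df$binTo)) df$binTo[a] <- df$binTo[b]
  df[-b, , drop = FALSE]
}

# absorb row k2 into k1 keeping k1's level (small-segment dissolution)
absorbRow <- function(df, k1, k2) {
  a <- min(k1, k2); b <- max(k1, k2)
  df$cnLevel[a] <- df$cnLevel[k1]
  df$end[a] <- df$end[b]
  df$nBins[a] <- sum(df$nBins[c(a, b)])
  if (!is.null(df$binTo)) df$binTo[a] <- df$binTo[b]
  df[-b, , drop = FALSE]
}

# coalesce adjacent same-arm segments whose levels are (numerically) equal
coalesceEqualLevels <- function(df, tol = 1e-9) {
  repeat {
    if (nrow(df) < 2) break
    same <- df$chrom[-1] == df$chrom[-nrow(df)] &
            df$arm[-1] == df$arm[-nrow(df)] &
            abs(df$cnLevel[-1] - df$cnLevel[-nrow(df)]) <= tol
    k <- which(same)
    if (!length(k)) break
    df <- mergeRows(df, k[1], k[1] + 1L)
  }
  df
}

smallFilterTable <- function(df, minSegmentMb) {
  repeat {
    sz <- (df$end - df$start + 1) / 1e6
    armKey <- paste(df$chrom, df$arm)
    multi <- armKey %in% names(which(table(armKey) > 1))
    cand <- which(sz < minSegmentMb & multi)
    if (!length(cand)) break
    k <- cand[which.min(sz[cand])]         # smallest first, ties leftmost
    left <- if (k > 1 && armKey[k - 1] == armKey[k]) k - 1L else NA
    right <- if (k < nrow(df) && armKey[k + 1] == armKey[k]) k + 1L else NA
    dl <- if (is.na(left)) Inf else abs(df$cnLevel[left] - df$cnLevel[k])
    dr <- if (is.na(right)) Inf else abs(df$cnLevel[right] - df$cnLevel[k])
    nb <- if (dl <= dr) left else right    # nearer level, ties to the left
    df <- absorbRow(df, nb, k)
    df <- coalesceEqualLevels(df)
  }
  df
}

mergeTable <- function(df, delta, corrThreshold = 0.5, ratio = NULL,
                       expDev = NULL, minCorrBins = 8L) {
  useFfpe <- !is.null(ratio) && !is.null(expDev) && !is.null(df$binFrom)
  repeat {
    if (nrow(df) < 2) break
    same <- df$chrom[-1] == df$chrom[-nrow(df)] &
            df$arm[-1] == df$arm[-nrow(df)]
    d <- abs(df$cnLevel[-1] - df$cnLevel[-nrow(df)])
    cand <- which(same & d < delta)
    if (length(cand)) {
      k <- cand[which.min(d[cand])]        # smallest difference first
      df <- mergeRows(df, k, k + 1L)
      next
    }
    if (!useFfpe) break
    # FFPE merges: a smaller segment is artifact when its bin-level
    # deviations track the expected FFPE deviation AND the level
    # difference to the neighbor disappears once the expected deviation
    # is subtracted (the correlation alone is shift-invariant and would
    # also fire on genuine copy-number offsets)
    bestK <- NA; bestCorr <- -Inf
    for (k in which(same)) {
      sm <- if (df$nBins[k] <= df$nBins[k + 1]) k else k + 1L
      lg <- if (sm == k) k + 1L else k
      if (df$nBins[sm] < minCorrBins) next
      sel <- df$binFrom[sm]:df$binTo[sm]
      selL <- df$binFrom[lg]:df$binTo[lg]
      ed <- expDev[sel]
      if (anyNA(ed) || anyNA(expDev[selL])) next
      smCorrected <- mean(ratio[sel] - ed)
      lgCorrected <- mean(ratio[selL] - expDev[selL])
      if (abs(smCorrected - lgCorrected) >= delta) next
      dev <- ratio[sel] - df$cnLevel[lg]
      if (stats::sd(dev) < 1e-12 || stats::sd(ed) < 1e-12) next
      cc <- stats::cor(dev, ed)
      if (is.finite(cc) && cc > bestCorr) { bestCorr <- cc; bestK <- k }
    }
    if (!is.na(bestK) && bestCorr >= corrThreshold) {
      df <- mergeRows(df, bestK, bestK + 1L)
      next
    }
    break
  }
  df
}

finishSegmentedProfile <- function(df, bdf, build, sampleId, seed) {
  res <- numeric(0)
  if (!is.null(df$binFrom)) {
    lev <- numeric(nrow(bdf))
    for (k in seq_len(nrow(df))) lev[df$binFrom[k]:df$binTo[k]] <- df$cnLevel[k]
    res <- bdf$ratio - lev
  }
  newSegmentedProfile(df, build, sampleId, residuals = res, runSeed = seed)
}

#' Segment a copy-number profile
#'
#' Noise reduction and breakpoint optimization: per-arm circular binary
#' segmentation, small-segment filtering, and quality-adaptive merging of
#' adjacent segments with small level differences or with bin-level
#' deviations that correlate with the FFPE noise profile. The run is fully
#' deterministic under \code{params@seed}.
#'
#' @param p a [BinnedProfile-class].
#' @param build the [GenomeBuild-class] the profile lives on.
#' @param params a [SegmentationParams-class].
#' @param np optional [NoiseProfile-class] enabling FFPE-correlation
#'   merges.
#' @param quality integrative quality category ("good"/"fair"/"low") or a
#'   [QualityAssessment-class]; selects the merge threshold.
#' @param merge set FALSE to stop after raw CBS (used for the coarse
#'   pre-segmentation in quality assessment).
#' @return a [SegmentedProfile-class].
#' @export
segmentProfile <- function(p, build, params = segmentationParams(),
                           np = NULL, quality = "good", merge = TRUE) {
  stopifnot(is(p, "BinnedProfile"))
  if (is(quality, "QualityAssessment")) quality <- quality@integrative
  bdf <- validBinTable(p)
  if (nrow(bdf) < 1000)
    stopNonContributive(sprintf(
      "only %d valid bins on arms; profile is non-contributive", nrow(bdf)))
  armKeys <- paste(bdf$chrom, bdf$arm)
  nArms <- length(unique(paste(as.character(seqnames(build@arms)),
                               mcols(build@arms)$arm)))
  covered <- sum(table(armKeys) >= 20)
  if (covered < nArms / 2)
    stopNonContributive("more than half of the arms lack usable bins")
  breaksByArm <- withSeed(params@seed, function() {
    lapply(split(bdf$ratio, factor(armKeys, levels = unique(armKeys))),
           cbsSegment, alpha = params@alpha, nPerm = params@nPerm)
  })
  df <- segTableFromBreaks(bdf, breaksByArm)
  if (merge) {
    df <- smallFilterTable(df, params@minSegmentMb)
    expDev <- if (!is.null(np)) alignExpectedDev(bdf, np) else NULL
    df <- mergeTable(df, params@mergeDelta[[quality]],
                     params@ffpeCorrMergeThreshold,
                     ratio = bdf$ratio, expDev = expDev)
  }
  finishSegmentedProfile(df, bdf, build, sampleId(p), params@seed)
}

#' Dissolve segments below the size floor
#'
#' Segments smaller than \code{minSegmentMb} are merged into the
#' nearer-level neighbor, smallest first, iterating to a fixpoint; arm
#' tiling is preserved.
#'
#' @param sp a [SegmentedProfile-class].
#' @param build the genome build.
#' @param minSegmentMb size floor in Mb.
#' @return a filtered [SegmentedProfile-class].
#' @export
filterSmallSegments <- function(sp, build, minSegmentMb = 3) {
  df <- smallFilterTable(segTableFromProfile(sp), minSegmentMb)
  newSegmentedProfile(df, build, sampleId(sp), runSeed = sp@runSeed)
}

#' Merge adjacent segments with small differences or FFPE-like deviations
#'
#' Adjacent same-arm segments are merged when their level difference is
#' below the quality-fitted threshold, smallest difference first; with a
#' noise profile and the source bins available, a smaller segment whose
#' bin-level deviations from the neighboring level correlate with the
#' expected FFPE deviation above the configured threshold is also merged.
#'
#' @param sp a [SegmentedProfile-class].
#' @param build the genome build.
#' @param params a [SegmentationParams-class].
#' @param quality quality category selecting the merge delta.
#' @return a merged [SegmentedProfile-class].
#' @export
mergeSegments <- function(sp, build, params = segmentationParams(),
                          quality = "good") {
  df <- mergeTable(segTableFromProfile(sp), params@mergeDelta[[quality]],
                   params@ffpeCorrMergeThreshold)
  newSegmentedProfile(df, build, sampleId(sp), runSeed = sp@runSeed)
}

#' LGA confidence interval from stochastic segmentation reruns
#'
#' Repeats the full segmentation/optimization with distinct sub-seeds
#' (\code{seed + i}) and counts LGA per run. The point estimate comes from
#' the base-seed run; the interval is reported both as min-max and as the
#' 2.5/97.5 percentiles over the runs.
#'
#' @param p a [BinnedProfile-class].
#' @param build the genome build.
#' @param params a [SegmentationParams-class]; \code{params@nReruns} runs.
#' @param np optional noise profile.
#' @param quality quality category.
#' @param lgaDelta CN-difference threshold used for the per-run LGA count.
#' @return a [LgaConfidence-class].
#' @export
rerunConfidence <- function(p, build, params = segmentationParams(),
                            np = NULL, quality = "good", lgaDelta = 0.10) {
  runs <- vapply(seq_len(params@nReruns) - 1L, function(i) {
    pi <- params
    pi@seed <- params@seed + i
    sp <- segmentProfile(p, build, pi, np = np, quality = quality)
    countLga(sp, delta = lgaDelta)
  }, integer(1))
  new("LgaConfidence", point = runs[1], low = min(runs), high = max(runs),
      q025 = as.numeric(stats::quantile(runs, 0.025)),
      q975 = as.numeric(stats::quantile(runs, 0.975)), runs = runs)
}
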