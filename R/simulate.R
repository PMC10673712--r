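#' @include AllClasses.R genome.R io.R segment.R
NULL

#' Simulation configuration
#'
#' Defaults emulate the data regime the pipeline targets: ~50 kb bins at
#' ~1X coverage from FFPE tumor samples of moderate cellularity (tumor
#' fraction 0.6), a diploid base, per-bin Gaussian ratio noise of sd 0.15,
#' and no FFPE wave unless requested. Planted copy-number steps are
#' multiplicative factors in \{0.5, 1.5, 2\} on the current copy number
#' (i.e. integer copy changes from the diploid base), so the observed step
#' heights span the soft/stringent thresholds across the purity range.
#'
#' @param seed integer seed fixing all randomness.
#' @param tumorFraction tumor cell fraction in [0,1].
#' @param basePloidy 2 (default) or 4.
#' @param nLga planted arm-internal breaks with both flanks >= 12 Mb.
#' @param nSmallEvents planted sub-10 Mb events (alternating gain/loss,
#'   3-9 Mb).
#' @param binNoiseSd per-bin ratio noise sd.
#' @param ffpeWaveAmplitude FFPE wave amplitude (ratio units).
#' @param waveSeed seed of the wave shape (shared artifact across profiles
#'   and panels with the same value).
#' @param plantCcne1Amp,plantErbb2Amp plant a cn-10 amplicon over the
#'   locus.
#' @param plantFocalAmpArms arms receiving a focal cn-10 amplification.
#' @param plantTdGains 1-10 Mb interstitial single-copy gains.
#' @param readDepthModel "gaussian" or "negative_binomial".
#' @param meanReadsPerBin mean coverage per bin for the count model
#'   (~1X over 50 kb corresponds to roughly 20 reads per bin at 150 bp
#'   read pairs; the ratio scale is what matters downstream).
#' @param nbDispersion negative-binomial size parameter.
#' @param binSize bin size in bp.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(seed = 1L, tumorFraction = 0.6,
                             basePloidy = 2, nLga = 0L, nSmallEvents = 0L,
                             binNoiseSd = 0.15, ffpeWaveAmplitude = 0,
                             waveSeed = 1234L, plantCcne1Amp = FALSE,
                             plantErbb2Amp = FALSE, plantFocalAmpArms = 0L,
                             plantTdGains = 0L,
                             readDepthModel = "gaussian",
                             meanReadsPerBin = 20, nbDispersion = 10,
                             binSize = 5e4) {
  new("SimulationConfig", seed = as.integer(seed),
      tumorFraction = tumorFraction, basePloidy = basePloidy,
      nLga = as.integer(nLga), nSmallEvents = as.integer(nSmallEvents),
      binNoiseSd = binNoiseSd, ffpeWaveAmplitude = ffpeWaveAmplitude,
      waveSeed = as.integer(waveSeed), plantCcne1Amp = plantCcne1Amp,
      plantErbb2Amp = plantErbb2Amp,
      plantFocalAmpArms = as.integer(plantFocalAmpArms),
      plantTdGains = as.integer(plantTdGains),
      readDepthModel = readDepthModel, meanReadsPerBin = meanReadsPerBin,
      nbDispersion = nbDispersion, binSize = binSize)
}

# snap a genomic offset (bp from arm start) to the bin grid
snapToGrid <- function(offset, binSize) round(offset / binSize) * binSize

# arm table of a build: chrom, arm, start, end (1-based closed)
armTable <- function(build) {
  a <- build@arms
  data.frame(chrom = as.character(seqnames(a)), arm = mcols(a)$arm,
             start = start(a), end = end(a), stringsAsFactors = FALSE)
}

# initial truth: one diploid-base segment per arm
initialTruth <- function(build, basePloidy) {
  at <- armTable(build)
  at$cn <- basePloidy
  at
}

# split the truth segment containing [start, end] on (chrom, arm) and set
# its copy number; boundaries must already be on the bin grid
insertTruthEvent <- function(truth, chrom, arm, start, end, cn) {
  k <- which(truth$chrom == chrom & truth$arm == arm &
             truth$start <= start & truth$end >= end)
  if (length(k) != 1) stop("event does not fall inside a single segment")
  host <- truth[k, ]
  rows <- list()
  if (start > host$start) {
    left <- host; left$end <- start - 1
    rows[[length(rows) + 1]] <- left
  }
  mid <- host; mid$start <- start; mid$end <- end; mid$cn <- cn
  rows[[length(rows) + 1]] <- mid
  if (end < host$end) {
    right <- host; right$start <- end + 1
    rows[[length(rows) + 1]] <- right
  }
  out <- rbind(truth[seq_len(k - 1L), ], do.call(rbind, rows),
               truth[-seq_len(k), ])
  rownames(out) <- NULL
  out
}

# minimal distance (bp) from a candidate interval to existing breakpoints
# of its arm (internal boundaries only)
armBreakDistance <- function(truth, chrom, arm, start, end) {
  seg <- truth[truth$chrom == chrom & truth$arm == arm, ]
  bnd <- setdiff(unique(c(seg$start, seg$end + 1L)),
                 c(min(seg$start), max(seg$end) + 1L))
  if (!length(bnd)) return(Inf)
  min(abs(bnd - start), abs(bnd - (end + 1L)))
}

# place an interstitial event of widthBp on a random arm, keeping
# marginBp clear of arm ends and existing breaks; NA on failure
placeEvent <- function(truth, widthBp, binSize, marginBp = 10.5e6,
                       maxTries = 200L) {
  arms <- unique(truth[c("chrom", "arm")])
  for (t in seq_len(maxTries)) {
    a <- arms[sample(nrow(arms), 1), ]
    seg <- truth[truth$chrom == a$chrom & truth$arm == a$arm, ]
    lo <- min(seg$start) + marginBp
    hi <- max(seg$end) - marginBp - widthBp
    if (hi <= lo) next
    s <- min(seg$start) +
      snapToGrid(stats::runif(1, lo, hi) - min(seg$start), binSize)
    e <- s + widthBp - 1L
    if (s < lo || e > max(seg$end) - marginBp) next
    if (armBreakDistance(truth, a$chrom, a$arm, s, e) < marginBp) next
    host <- seg[seg$start <= s & seg$end >= e, ]
    if (nrow(host) != 1) next
    return(list(chrom = a$chrom, arm = a$arm, start = s, end = e,
                hostCn = host$cn))
  }
  NULL
}

#' Plant a tandem-duplication phenotype into a truth table
#'
#' Adds \code{nGains} non-overlapping interstitial single-level gains with
#' sizes uniform in \code{sizeRangeMb}, scattered over arms, each kept
#' clear of existing breakpoints so planted LGA ground truth is preserved.
#' Operates on the simulator's truth table (a data.frame with columns
#' \code{chrom}, \code{arm}, \code{start}, \code{end}, \code{cn}).
#'
#' @param truth truth table under construction.
#' @param nGains number of gains.
#' @param binSize bin size the boundaries snap to.
#' @param sizeRangeMb size range in Mb (default 1-10).
#' @return the modified truth table.
#' @export
plantTdPhenotype <- function(truth, nGains, binSize = 5e4,
                             sizeRangeMb = c(1, 10)) {
  if (nGains == 0) return(truth)
  for (g in seq_len(nGains)) {
    wBp <- max(binSize,
               snapToGrid(stats::runif(1, sizeRangeMb[1], sizeRangeMb[2]) * 1e6,
                          binSize))
    wBp <- min(wBp, sizeRangeMb[2] * 1e6)
    ev <- placeEvent(truth, wBp, binSize)
    if (is.null(ev))
      stop("could not place a TD gain without overlap after bounded retries")
    truth <- insertTruthEvent(truth, ev$chrom, ev$arm, ev$start, ev$end,
                              ev$hostCn + 1)
  }
  truth
}

# plant nLga arm-internal breaks with both flanks >= minFlankMb; copy
# levels follow multiplicative steps in {0.5, 1.5, 2} on the current cn,
# rounded to integers and clamped to [1, 8]
plantLgaBreaks <- function(truth, nLga, binSize, minFlankMb = 12) {
  if (nLga == 0) return(truth)
  minFlank <- minFlankMb * 1e6
  arms <- unique(truth[c("chrom", "arm")])
  armLen <- vapply(seq_len(nrow(arms)), function(i) {
    seg <- truth[truth$chrom == arms$chrom[i] & truth$arm == arms$arm[i], ]
    max(seg$end) - min(seg$start) + 1
  }, numeric(1))
  capacity <- pmax(0, floor(armLen / minFlank) - 1)
  if (sum(capacity) < nLga)
    stop("build has too little arm territory for ", nLga, " planted LGA")
  alloc <- integer(nrow(arms))
  for (k in seq_len(nLga)) {
    open <- which(alloc < capacity)
    pick <- open[sample.int(length(open), 1,
                            prob = (capacity - alloc)[open])]
    alloc[pick] <- alloc[pick] + 1L
  }
  stepFactors <- c(0.5, 1.5, 2)
  for (i in which(alloc > 0)) {
    k <- alloc[i]
    seg <- truth[truth$chrom == arms$chrom[i] & truth$arm == arms$arm[i], ]
    a0 <- min(seg$start); a1 <- max(seg$end)
    L <- a1 - a0 + 1
    # k cut points with pairwise gaps >= minFlank (stick-breaking)
    slack <- L - (k + 1) * minFlank
    u <- sort(stats::runif(k, 0, slack))
    pos <- a0 + snapToGrid(u + minFlank * seq_len(k), binSize)
    cn <- truth$cn[truth$chrom == arms$chrom[i] &
                   truth$arm == arms$arm[i]][1]
    bounds <- c(a0, pos, a1 + 1)
    for (s in seq_len(k + 1)) {
      if (s > 1) {
        prev <- cn
        cn <- floor(prev * sample(stepFactors, 1) + 0.5)
        cn <- min(max(cn, 1), 8)
        if (cn == prev) cn <- if (prev >= 8) prev - 1 else prev + 1
      }
      if (s > 1)
        truth <- insertTruthEvent(truth, arms$chrom[i], arms$arm[i],
                                  bounds[s], bounds[s + 1] - 1, cn)
    }
  }
  truth
}

# amplicon halo keeps the planted event comfortably above the 3 Mb
# small-segment floor (CCNE1/ERBB2 amplicons of ~4 Mb are realistic)
plantAmplicon <- function(truth, build, locusName, binSize, cn = 10,
                          haloMb = 2) {
  loci <- build@loci
  lg <- loci[mcols(loci)$name == locusName]
  if (!length(lg)) stop("locus ", locusName, " absent from build")
  chrom <- as.character(seqnames(lg))[1]
  arm <- assignArms(lg, build)[1]
  seg <- truth[truth$chrom == chrom & truth$arm == arm, ]
  a0 <- min(seg$start)
  s <- a0 + snapToGrid(start(lg)[1] - haloMb * 1e6 - a0, binSize)
  e <- a0 + snapToGrid(end(lg)[1] + haloMb * 1e6 - a0, binSize) - 1L
  s <- max(s, a0)
  e <- min(e, max(seg$end))
  host <- seg[seg$start <= s & seg$end >= e, ]
  if (nrow(host) != 1)
    stop("amplicon window for ", locusName, " collides with planted breaks")
  insertTruthEvent(truth, chrom, arm, as.integer(s), as.integer(e), cn)
}

# FFPE wave: per-chromosome mixture of 3 low-frequency sinusoids
# (periods 5-30 Mb) plus sparse bin-level spikes; fully determined by
# waveSeed so tumors and panels can share the artifact
waveFor <- function(gridDf, amplitude, waveSeed) {
  if (amplitude == 0) return(numeric(nrow(gridDf)))
  withSeed(waveSeed, function() {
    chroms <- unique(gridDf$chrom)
    wave <- numeric(nrow(gridDf))
    for (ch in chroms) {
      ii <- which(gridDf$chrom == ch)
      x <- (gridDf$start[ii] + gridDf$end[ii]) / 2
      w <- numeric(length(ii))
      for (k in 1:3) {
        period <- stats::runif(1, 5e6, 30e6)
        phase <- stats::runif(1, 0, 2 * pi)
        w <- w + sin(2 * pi * x / period + phase)
      }
      wave[ii] <- amplitude * w / 3
    }
    spikes <- stats::rbinom(nrow(gridDf), 1, 0.005) *
      stats::rnorm(nrow(gridDf), 0, 3 * amplitude)
    wave + spikes
  })
}

truthToProfileGrid <- function(truth, gridDf) {
  cn <- numeric(nrow(gridDf))
  gridKey <- paste(gridDf$chrom, gridDf$arm)
  idxByArm <- split(seq_len(nrow(gridDf)),
                    factor(gridKey, levels = unique(gridKey)))
  for (key in names(idxByArm)) {
    ii <- idxByArm[[key]]
    seg <- truth[paste(truth$chrom, truth$arm) == key, , drop = FALSE]
    # truth boundaries are on the bin grid; locate each bin's segment
    j <- findInterval(gridDf$start[ii], seg$start)
    cn[ii] <- seg$cn[pmax(j, 1L)]
  }
  cn
}

truthSegments <- function(truth, build, cfg, sampleId) {
  lev <- cfg@tumorFraction * truth$cn / cfg@basePloidy +
    (1 - cfg@tumorFraction)
  newSegmentedProfile(
    data.frame(chrom = truth$chrom, arm = truth$arm, start = truth$start,
               end = truth$end, cnLevel = lev,
               nBins = pmax(1L, as.integer((truth$end - truth$start + 1) %/%
                                           cfg@binSize))),
    build, sampleId, runSeed = cfg@seed)
}

# ground-truth LGA count: brute force over adjacent same-arm true segments
trueLgaFromTruth <- function(truth) {
  n <- nrow(truth)
  if (n < 2) return(0L)
  same <- truth$chrom[-1] == truth$chrom[-n] & truth$arm[-1] == truth$arm[-n]
  szMb <- (truth$end - truth$start + 1) / 1e6
  rs <- floor(szMb + 0.5)
  sum(same & rs[-n] >= 10 & rs[-1] >= 10 & truth$cn[-1] != truth$cn[-n])
}

#' Simulate a tumor copy-number profile with known ground truth
#'
#' Builds a bin grid over the genome, plants copy-number events (LGA
#' breaks, small events, locus amplicons, focal amplifications, TD gains)
#' into a truth table, dilutes by tumor fraction
#' (\code{ratio = tf * cn / ploidy + (1 - tf)}), and adds the FFPE wave and
#' per-bin noise. Deterministic under \code{cfg@seed}.
#'
#' @param cfg a [SimulationConfig-class].
#' @param build a [GenomeBuild-class].
#' @return list with \code{profile} (a [BinnedProfile-class]) and
#'   \code{truth} (a [GroundTruth-class]).
#' @examples
#' build <- loadGenomeBuild("hg19")
#' sim <- simulateTumorProfile(simulationConfig(seed = 7, nLga = 10), build)
#' sim$truth@trueLgaCount
#' @export
simulateTumorProfile <- function(cfg, build) {
  stopifnot(is(cfg, "SimulationConfig"), is(build, "GenomeBuild"))
  withSeed(cfg@seed, function() {
    grid <- binGrid(build, cfg@binSize)
    gridDf <- data.frame(chrom = as.character(seqnames(grid)),
                         start = start(grid), end = end(grid),
                         arm = mcols(grid)$arm, stringsAsFactors = FALSE)
    truth <- initialTruth(build, cfg@basePloidy)
    truth <- plantLgaBreaks(truth, cfg@nLga, cfg@binSize)
    if (cfg@plantCcne1Amp)
      truth <- plantAmplicon(truth, build, "CCNE1", cfg@binSize)
    if (cfg@plantErbb2Amp)
      truth <- plantAmplicon(truth, build, "ERBB2", cfg@binSize)
    if (cfg@plantFocalAmpArms > 0) {
      for (a in seq_len(cfg@plantFocalAmpArms)) {
        wBp <- snapToGrid(stats::runif(1, 3.5e6, 8e6), cfg@binSize)
        ev <- placeEvent(truth, wBp, cfg@binSize)
        if (is.null(ev)) stop("could not place focal amplification")
        truth <- insertTruthEvent(truth, ev$chrom, ev$arm, ev$start,
                                  ev$end, 10)
      }
    }
    if (cfg@nSmallEvents > 0) {
      for (ev_i in seq_len(cfg@nSmallEvents)) {
        wBp <- snapToGrid(stats::runif(1, 3e6, 9e6), cfg@binSize)
        ev <- placeEvent(truth, wBp, cfg@binSize)
        if (is.null(ev)) stop("could not place small event")
        dcn <- if (ev_i %% 2 == 0) 1 else -1
        truth <- insertTruthEvent(truth, ev$chrom, ev$arm, ev$start, ev$end,
                                  max(1, ev$hostCn + dcn))
      }
    }
    truth <- plantTdPhenotype(truth, cfg@plantTdGains, cfg@binSize)
    cn <- truthToProfileGrid(truth, gridDf)
    clean <- cfg@tumorFraction * cn / cfg@basePloidy +
      (1 - cfg@tumorFraction)
    wave <- waveFor(gridDf, cfg@ffpeWaveAmplitude, cfg@waveSeed)
    n <- nrow(gridDf)
    ratio <- if (cfg@readDepthModel == "gaussian") {
      clean + wave + stats::rnorm(n, 0, cfg@binNoiseSd)
    } else {
      mu <- pmax(0.01, clean + wave) * cfg@meanReadsPerBin
      stats::rnbinom(n, mu = mu, size = cfg@nbDispersion) /
        cfg@meanReadsPerBin
    }
    sampleId <- sprintf("sim_seed%d", cfg@seed)
    gr <- grid
    mcols(gr)$ratio <- pmax(ratio, 0)
    mcols(gr)$valid <- TRUE
    mcols(gr)$arm <- gridDf$arm
    profile <- new("BinnedProfile", sampleId = sampleId, bins = gr,
                   binSize = cfg@binSize,
                   metadata = list(simulated = TRUE, seed = cfg@seed))
    flags <- list(ccne1Amp = cfg@plantCcne1Amp, erbb2Amp = cfg@plantErbb2Amp,
                  focalAmpArms = cfg@plantFocalAmpArms,
                  tdGains = cfg@plantTdGains, nLga = cfg@nLga,
                  tumorFraction = cfg@tumorFraction,
                  binNoiseSd = cfg@binNoiseSd)
    list(profile = profile,
         truth = new("GroundTruth",
                     trueSegments = truthSegments(truth, build, cfg,
                                                  sampleId),
                     trueLgaCount = trueLgaFromTruth(truth),
                     plantedFlags = flags))
  })
}

#' Simulate a panel of normal FFPE profiles
#'
#' \code{n} flat diploid profiles sharing the FFPE wave determined by
#' \code{cfg@waveSeed}, each with independent per-bin noise, so the wave is
#' recoverable by averaging across the panel.
#'
#' @param n panel size.
#' @param cfg a [SimulationConfig-class] (wave amplitude, noise, bin size).
#' @param build a [GenomeBuild-class].
#' @return list of [BinnedProfile-class].
#' @export
simulateNormalPanel <- function(n, cfg, build) {
  stopifnot(n >= 1)
  grid <- binGrid(build, cfg@binSize)
  gridDf <- data.frame(chrom = as.character(seqnames(grid)),
                       start = start(grid), end = end(grid),
                       arm = mcols(grid)$arm, stringsAsFactors = FALSE)
  wave <- waveFor(gridDf, cfg@ffpeWaveAmplitude, cfg@waveSeed)
  lapply(seq_len(n), function(i) {
    withSeed(cfg@seed + i, function() {
      gr <- grid
      mcols(gr)$ratio <- pmax(1 + wave +
                                stats::rnorm(nrow(gridDf), 0,
                                             cfg@binNoiseSd), 0)
      mcols(gr)$valid <- TRUE
      new("BinnedProfile", sampleId = sprintf("normal_%03d", i),
          bins = gr, binSize = cfg@binSize,
          metadata = list(simulated = TRUE, normal = TRUE))
    })
  })
}
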