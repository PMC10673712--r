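#' @include AllClasses.R segment.R
NULL

#' Cluster segment copy-number levels
#'
#' Greedy one-dimensional, genome-length-weighted clustering of segment
#' levels: levels are scanned in ascending order and joined to the current
#' cluster while they stay within \code{width} ratio units of its weighted
#' center. Returns the genome-length fraction of each cluster, descending,
#' named by the cluster center.
#'
#' @param sp a [SegmentedProfile-class].
#' @param width cluster width in ratio units.
#' @return named numeric vector of weights (descending).
#' @export
clusterCnLevels <- function(sp, width = 0.1) {
  s <- sp@segments
  if (!length(s)) stop("no segments to cluster")
  lev <- mcols(s)$cnLevel
  w <- as.numeric(width(s))
  ord <- order(lev)
  lev <- lev[ord]; w <- w[ord]
  centers <- numeric(0); weights <- numeric(0)
  curSum <- lev[1] * w[1]; curW <- w[1]
  for (k in seq_along(lev)[-1]) {
    if (abs(lev[k] - curSum / curW) <= width) {
      curSum <- curSum + lev[k] * w[k]; curW <- curW + w[k]
    } else {
      centers <- c(centers, curSum / curW); weights <- c(weights, curW)
      curSum <- lev[k] * w[k]; curW <- w[k]
    }
  }
  centers <- c(centers, curSum / curW); weights <- c(weights, curW)
  frac <- weights / sum(w)
  ord <- order(frac, decreasing = TRUE)
  stats::setNames(frac[ord], format(centers[ord], digits = 6))
}

#' Classify genome complexity from CN-level weights
#'
#' A genome is "simple" when its two most abundant CN levels account for
#' more than 70\% of the genome; "complex_plus" when four CN levels
#' contribute significantly and almost equally (operationalized as: the top
#' four weights each reach 0.15 and the first and fourth differ by at most
#' 0.15); "complex" otherwise.
#'
#' @param weights descending numeric weights from [clusterCnLevels()].
#' @return "simple", "complex" or "complex_plus".
#' @export
classifyGenomeComplexity <- function(weights) {
  if (!length(weights)) stop("empty weight vector")
  w <- sort(as.numeric(weights), decreasing = TRUE)
  if (sum(w[seq_len(min(2, length(w)))]) > 0.70) return("simple")
  if (length(w) >= 4 && all(w[1:4] >= 0.15) && (w[1] - w[4]) <= 0.15)
    return("complex_plus")
  "complex"
}

# table of all adjacent same-arm segment pairs (the breakpoints), with
# flank sizes/levels and the LGA call at a given CN-difference threshold
lgaBreakTable <- function(sp, delta = 0.10) {
  s <- sp@segments
  if (length(s) < 2)
    return(data.frame(chrom = character(0), arm = character(0),
                      left = integer(0), right = integer(0),
                      leftMb = integer(0), rightMb = integer(0),
                      leftLevel = numeric(0), rightLevel = numeric(0),
                      isLga = logical(0)))
  n <- length(s)
  same <- as.character(seqnames(s))[-1] == as.character(seqnames(s))[-n] &
          mcols(s)$arm[-1] == mcols(s)$arm[-n]
  left <- which(same)
  right <- left + 1L
  rs <- mcols(s)$roundedSizeMb
  lv <- mcols(s)$cnLevel
  data.frame(chrom = as.character(seqnames(s))[left],
             arm = mcols(s)$arm[left], left = left, right = right,
             leftMb = rs[left], rightMb = rs[right],
             leftLevel = lv[left], rightLevel = lv[right],
             isLga = rs[left] >= 10L & rs[right] >= 10L &
                     abs(lv[left] - lv[right]) >= delta,
             stringsAsFactors = FALSE)
}

#' Count large genomic alterations (LGA)
#'
#' An LGA is a copy-number break between two adjacent same-arm segments
#' whose sizes, rounded half-up to the integer megabase, are both at least
#' 10 Mb, and whose level difference reaches the CN-difference threshold.
#' Breaks across centromeres are never counted (segments are arm-confined).
#' The soft threshold (default 0.10 ratio units) is the permissive call
#' implied for complex genomes; the stringent one (default 0.20) the
#' restrictive call implied for simple genomes.
#'
#' @param sp a [SegmentedProfile-class].
#' @param delta CN-difference threshold in ratio units.
#' @return integer LGA count.
#' @export
countLga <- function(sp, delta = 0.10) {
  sum(lgaBreakTable(sp, delta)$isLga)
}

#' Detect the binary nonHRD-associated attributes
#'
#' CCNE1/ERBB2 amplification (a segment overlapping the locus with level at
#' or above \code{ampThreshold}), the focal amplification phenotype (more
#' than two chromosome arms carrying at least one amplified segment of at
#' most 10 Mb), and the CDK12-associated tandem-duplication phenotype (at
#' least \code{tdMinGains} interstitial gains of rounded size 1-10 Mb over
#' both flanking levels).
#'
#' @param sp a [SegmentedProfile-class].
#' @param build a [GenomeBuild-class] with CCNE1/ERBB2 loci.
#' @param ampThreshold ratio level calling an amplification (default 2.0,
#'   i.e. roughly twice the median ploidy).
#' @param tdMinGains minimal number of interstitial 1-10 Mb gains.
#' @param softDelta minimal gain over the flanking levels.
#' @return named logical vector: \code{ccne1Amp}, \code{erbb2Amp},
#'   \code{focalAmpPhenotype}, \code{cdk12TdPhenotype}.
#' @export
detectBinaryAttributes <- function(sp, build, ampThreshold = 2.0,
                                   tdMinGains = 8L, softDelta = 0.10) {
  s <- sp@segments
  loci <- build@loci
  if (!all(c("CCNE1", "ERBB2") %in% mcols(loci)$name))
    stop("build lacks CCNE1/ERBB2 locus definitions")
  lociAmp <- function(name) {
    lg <- loci[mcols(loci)$name == name]
    ov <- subsetByOverlaps(s, lg, ignore.strand = TRUE)
    length(ov) > 0 && any(mcols(ov)$cnLevel >= ampThreshold)
  }
  amp <- mcols(s)$cnLevel >= ampThreshold & mcols(s)$sizeMb <= 10
  armsWithAmp <- length(unique(paste(seqnames(s), mcols(s)$arm)[amp]))
  n <- length(s)
  nGains <- 0L
  if (n >= 3) {
    chr <- as.character(seqnames(s)); arm <- mcols(s)$arm
    lv <- mcols(s)$cnLevel; rs <- mcols(s)$roundedSizeMb
    mid <- 2:(n - 1)
    interstitial <- chr[mid] == chr[mid - 1] & chr[mid] == chr[mid + 1] &
                    arm[mid] == arm[mid - 1] & arm[mid] == arm[mid + 1]
    gain <- rs[mid] >= 1L & rs[mid] <= 10L &
            lv[mid] >= lv[mid - 1] + softDelta &
            lv[mid] >= lv[mid + 1] + softDelta
    nGains <- sum(interstitial & gain)
  }
  c(ccne1Amp = lociAmp("CCNE1"), erbb2Amp = lociAmp("ERBB2"),
    focalAmpPhenotype = armsWithAmp > 2,
    cdk12TdPhenotype = nGains >= tdMinGains)
}

#' Ancillary LGA indexes
#'
#' Five counts refining the LGA picture: extra-large LGA (both flanks at
#' least \code{extraLargeFlankMb}), telomeric LGA (the distal flank reaches
#' within \code{telomereWindowMb} of the arm's telomeric end), LGA between
#' the two most abundant CN levels, LGA involving one of the three most
#' abundant CN levels, and the number of chromosome arms carrying at least
#' one LGA.
#'
#' @param sp a [SegmentedProfile-class].
#' @param build a [GenomeBuild-class].
#' @param weights CN-level weights from [clusterCnLevels()] (computed when
#'   NULL).
#' @param delta CN-difference threshold of the underlying LGA call.
#' @param extraLargeFlankMb flank size (rounded Mb) defining extra-large.
#' @param telomereWindowMb distance to the arm end defining telomeric.
#' @param clusterWidth width used when clustering levels.
#' @return named integer vector of the five indexes.
#' @export
ancillaryLgaIndexes <- function(sp, build, weights = NULL, delta = 0.10,
                                extraLargeFlankMb = 30,
                                telomereWindowMb = 1, clusterWidth = 0.1) {
  if (is.null(weights)) weights <- clusterCnLevels(sp, clusterWidth)
  br <- lgaBreakTable(sp, delta)
  br <- br[br$isLga, , drop = FALSE]
  if (!nrow(br))
    return(c(extraLargeLga = 0L, telomericLga = 0L, lgaBetweenTop2 = 0L,
             lgaInvolvingTop3 = 0L, armsWithLga = 0L))
  s <- sp@segments
  centers <- as.numeric(names(weights))   # already ranked by weight
  nearestRank <- function(lv)
    vapply(lv, function(v) which.min(abs(centers - v)), integer(1))
  rkL <- nearestRank(br$leftLevel)
  rkR <- nearestRank(br$rightLevel)
  extraLarge <- sum(br$leftMb >= extraLargeFlankMb &
                    br$rightMb >= extraLargeFlankMb)
  # telomeric: distance of the distal flank's outer boundary to the arm end
  armKey <- paste(as.character(seqnames(build@arms)), mcols(build@arms)$arm)
  armStart <- stats::setNames(start(build@arms), armKey)
  armEnd <- stats::setNames(end(build@arms), armKey)
  win <- telomereWindowMb * 1e6
  telo <- vapply(seq_len(nrow(br)), function(k) {
    key <- paste(br$chrom[k], br$arm[k])
    if (br$arm[k] == "p")
      start(s)[br$left[k]] - armStart[[key]] <= win
    else
      armEnd[[key]] - end(s)[br$right[k]] <= win
  }, logical(1))
  c(extraLargeLga = as.integer(extraLarge),
    telomericLga = as.integer(sum(telo)),
    lgaBetweenTop2 = as.integer(sum(rkL <= 2 & rkR <= 2)),
    lgaInvolvingTop3 = as.integer(sum(rkL <= 3 | rkR <= 3)),
    armsWithLga = length(unique(paste(br$chrom, br$arm))))
}

#' Construct a GenomicFeatures object directly
#'
#' Mostly useful for tests and for exploring the decision rules; pipeline
#' code uses [computeGenomicFeatures()].
#'
#' @param complexity,cnLevelWeights,ccne1Amp,erbb2Amp,focalAmpPhenotype,cdk12TdPhenotype,lgaSoft,lgaStringent,extraLargeLga,telomericLga,lgaBetweenTop2,lgaInvolvingTop3,armsWithLga,nBreakpoints
#'   see [GenomicFeatures-class].
#' @return a [GenomicFeatures-class].
#' @export
genomicFeatures <- function(complexity = "simple",
                            cnLevelWeights = c("1" = 1),
                            ccne1Amp = FALSE, erbb2Amp = FALSE,
                            focalAmpPhenotype = FALSE,
                            cdk12TdPhenotype = FALSE,
                            lgaSoft = 0L, lgaStringent = 0L,
                            extraLargeLga = 0L, telomericLga = 0L,
                            lgaBetweenTop2 = 0L, lgaInvolvingTop3 = 0L,
                            armsWithLga = 0L, nBreakpoints = 0L) {
  new("GenomicFeatures", complexity = complexity,
      cnLevelWeights = cnLevelWeights, ccne1Amp = ccne1Amp,
      erbb2Amp = erbb2Amp, focalAmpPhenotype = focalAmpPhenotype,
      cdk12TdPhenotype = cdk12TdPhenotype, lgaSoft = as.integer(lgaSoft),
      lgaStringent = as.integer(lgaStringent),
      extraLargeLga = as.integer(extraLargeLga),
      telomericLga = as.integer(telomericLga),
      lgaBetweenTop2 = as.integer(lgaBetweenTop2),
      lgaInvolvingTop3 = as.integer(lgaInvolvingTop3),
      armsWithLga = as.integer(armsWithLga),
      nBreakpoints = as.integer(nBreakpoints))
}

#' Broad copy-number profile characterization
#'
#' Computes everything the classifier consumes from a segmented profile:
#' the complexity class, the four binary attributes, LGA counts under both
#' CN-difference thresholds, the five ancillary LGA indexes (on the soft
#' break list) and the total breakpoint count.
#'
#' @param sp a [SegmentedProfile-class].
#' @param build a [GenomeBuild-class].
#' @param config a [ClassifierConfig-class] supplying the thresholds.
#' @return a [GenomicFeatures-class].
#' @export
computeGenomicFeatures <- function(sp, build, config = classifierConfig()) {
  weights <- clusterCnLevels(sp)
  flags <- detectBinaryAttributes(sp, build,
                                  ampThreshold = config@ampThreshold,
                                  tdMinGains = config@tdMinGains,
                                  softDelta = config@softDelta)
  anc <- ancillaryLgaIndexes(sp, build, weights, delta = config@softDelta,
                             extraLargeFlankMb = config@extraLargeFlankMb,
                             telomereWindowMb = config@telomereWindowMb)
  genomicFeatures(
    complexity = classifyGenomeComplexity(weights),
    cnLevelWeights = weights,
    ccne1Amp = flags[["ccne1Amp"]], erbb2Amp = flags[["erbb2Amp"]],
    focalAmpPhenotype = flags[["focalAmpPhenotype"]],
    cdk12TdPhenotype = flags[["cdk12TdPhenotype"]],
    lgaSoft = countLga(sp, config@softDelta),
    lgaStringent = countLga(sp, config@stringentDelta),
    extraLargeLga = anc[["extraLargeLga"]],
    telomericLga = anc[["telomericLga"]],
    lgaBetweenTop2 = anc[["lgaBetweenTop2"]],
    lgaInvolvingTop3 = anc[["lgaInvolvingTop3"]],
    armsWithLga = anc[["armsWithLga"]],
    nBreakpoints = nrow(lgaBreakTable(sp, 0)))
}
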