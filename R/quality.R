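#' @include AllClasses.R segment.R features.R
NULL

#' Quality category thresholds
#'
#' The category structure (tumor content in four categories, intrinsic
#' sequencing noise in three, FFPE noise in four, integrated into
#' good/fair/low) is fixed; the numeric cut points are package defaults,
#' calibrated on the simulator so that tumor fractions of at least 0.4 /
#' 0.25 / 0.15 map to content categories 1-3 and anything lower to 4, and
#' are fully configurable here.
#'
#' @param tumorContent descending purity-proxy cut points for categories
#'   1-3 (below the last is category 4).
#' @param intrinsicNoise ascending derivative-MAD cut points for
#'   categories 1-2 (at or above the last is category 3).
#' @param ffpeNoise ascending FFPE-correlation cut points for categories
#'   1-3 (at or above the last is category 4).
#' @return named list of thresholds.
#' @export
qualityThresholds <- function(tumorContent = c(0.40, 0.25, 0.15),
                              intrinsicNoise = c(0.20, 0.35),
                              ffpeNoise = c(0.10, 0.25, 0.45)) {
  list(tumorContent = tumorContent, intrinsicNoise = intrinsicNoise,
       ffpeNoise = ffpeNoise)
}

cutCategory <- function(metric, ascendingCuts) {
  # ascending cuts c1 < c2 ...: cat k if metric < ck, else length+1
  as.integer(findInterval(metric, ascendingCuts) + 1L)
}

#' Estimate intrinsic sequencing noise
#'
#' The metric is the median absolute first difference of consecutive
#' valid-bin ratios within arms (a derivative MAD): for Gaussian bin noise
#' of sd \eqn{\sigma} it concentrates at
#' \eqn{\sqrt{2}\,\Phi^{-1}(0.75)\,\sigma \approx 0.954\sigma}, and it is
#' insensitive to the segment structure itself.
#'
#' @param p a [BinnedProfile-class].
#' @param cuts ascending category cut points.
#' @return list with \code{metric} and \code{category} (1-3, 1 cleanest).
#' @export
estimateIntrinsicNoise <- function(p,
                                   cuts = qualityThresholds()$intrinsicNoise) {
  bdf <- validBinTable(p)
  if (nrow(bdf) < 1000)
    stopNonContributive("too few valid bins to estimate noise")
  d <- unlist(lapply(split(bdf$ratio, paste(bdf$chrom, bdf$arm)), diff),
              use.names = FALSE)
  metric <- stats::median(abs(d))
  list(metric = metric, category = cutCategory(metric, cuts))
}

#' Estimate the tumor-content category
#'
#' The purity proxy inverts the dilution model on the segment-level
#' spacing: clustered CN levels of a tumor of purity \eqn{p} and ploidy 2
#' sit on a lattice with one-copy spacing \eqn{p/2}, so the recurrent
#' spacing between adjacent cluster centers maps back to
#' \eqn{p = 2\,\times} spacing (capped at 1). A flat genome carries no
#' spacing information and is assigned category 4 with a warning.
#'
#' @param sp a [SegmentedProfile-class] (a coarse segmentation suffices).
#' @param basePloidy assumed ploidy of the dilution model.
#' @param cuts descending purity cut points for categories 1-3.
#' @param clusterWidth level-clustering width.
#' @param minWeight minimal genome fraction for a cluster to enter the
#'   spacing estimate.
#' @return list with \code{purityProxy}, \code{category} (1-4, 1 highest
#'   content) and \code{warnings}.
#' @export
estimateTumorContentCategory <- function(sp, basePloidy = 2,
                                         cuts = qualityThresholds()$tumorContent,
                                         clusterWidth = 0.1,
                                         minWeight = 0.02) {
  w <- clusterCnLevels(sp, clusterWidth)
  centers <- sort(as.numeric(names(w))[w >= minWeight])
  if (length(centers) < 2)
    return(list(purityProxy = NA_real_, category = 4L,
                warnings = "flat or very low tumor content"))
  sp_ <- diff(centers)
  grid <- round(sp_ / 0.05) * 0.05
  tab <- table(grid)
  recurrent <- as.numeric(names(tab)[tab >= 2])
  h <- if (length(recurrent)) max(recurrent) else stats::median(sp_)
  proxy <- min(1, basePloidy * h)
  cat <- if (proxy >= cuts[1]) 1L else if (proxy >= cuts[2]) 2L
         else if (proxy >= cuts[3]) 3L else 4L
  list(purityProxy = proxy, category = cat, warnings = character(0))
}

#' Score FFPE noise by correlation with the panel noise profile
#'
#' Spearman correlation between the bin-level residuals of a coarse
#' pre-segmentation (avoiding circularity with the final segmentation) and
#' the expected per-bin FFPE deviation.
#'
#' @param p a [BinnedProfile-class].
#' @param np a [NoiseProfile-class] on the same grid.
#' @param sp optional coarse [SegmentedProfile-class]; computed with a
#'   plain CBS pass when NULL.
#' @param build genome build; required to compute or de-fragment the
#'   residual proxy.
#' @param cuts ascending correlation cut points.
#' @param minProxySegMb segments of the coarse pass below this size are
#'   dissolved before residuals are taken, so wave-scale artifacts remain
#'   in the residual track instead of being absorbed into pseudo-segments.
#' @return list with \code{correlation} and \code{category} (1-4, 1 least
#'   FFPE artifact).
#' @export
scoreFfpeNoise <- function(p, np, sp = NULL, build = NULL,
                           cuts = qualityThresholds()$ffpeNoise,
                           minProxySegMb = 15) {
  bdf <- validBinTable(p)
  ed <- alignExpectedDev(bdf, np)
  if (all(is.na(ed))) stop("noise profile grid does not match the profile")
  if (is.null(sp)) {
    if (is.null(build)) stop("need a build for the coarse pre-segmentation")
    sp <- segmentProfile(p, build, segmentationParams(nPerm = 20L),
                         merge = FALSE)
  }
  if (!is.null(build))
    sp <- filterSmallSegments(sp, build, minProxySegMb)
  res <- residualsOnBins(sp, bdf)
  ok <- !is.na(ed) & !is.na(res)
  corr <- suppressWarnings(stats::cor(res[ok], ed[ok], method = "spearman"))
  if (!is.finite(corr)) corr <- 0
  list(correlation = corr, category = cutCategory(corr, cuts))
}

# per-bin residuals of a segmentation, aligned to a valid-bin table
residualsOnBins <- function(sp, bdf) {
  s <- sp@segments
  lev <- rep(NA_real_, nrow(bdf))
  segChrom <- as.character(seqnames(s))
  for (k in seq_along(s)) {
    ii <- bdf$chrom == segChrom[k] & bdf$start >= start(s)[k] &
          bdf$end <= end(s)[k]
    lev[ii] <- mcols(s)$cnLevel[k]
  }
  bdf$ratio - lev
}

#' Integrate the three quality axes
#'
#' Deterministic lookup: "good" requires tumor content and FFPE categories
#' at most 2 and intrinsic noise at most 2; "low" is triggered by the
#' worst category on any single axis (content 4, noise 3, FFPE 4);
#' everything else is "fair". Worsening any single axis never improves the
#' class.
#'
#' @param tumorContentCat 1-4.
#' @param intrinsicNoiseCat 1-3.
#' @param ffpeNoiseCat 1-4.
#' @return "good", "fair" or "low".
#' @export
integrateQuality <- function(tumorContentCat, intrinsicNoiseCat,
                             ffpeNoiseCat) {
  if (!tumorContentCat %in% 1:4 || !intrinsicNoiseCat %in% 1:3 ||
      !ffpeNoiseCat %in% 1:4)
    stop("quality category out of range")
  if (tumorContentCat == 4 || intrinsicNoiseCat == 3 || ffpeNoiseCat == 4)
    return("low")
  if (tumorContentCat <= 2 && intrinsicNoiseCat <= 2 && ffpeNoiseCat <= 2)
    return("good")
  "fair"
}

#' Three-way sample quality attribution
#'
#' Classifies a profile by tumor content (four categories), intrinsic
#' sequencing noise (three categories) and FFPE noise (four categories),
#' then integrates the three axes into good/fair/low.
#'
#' @param p a [BinnedProfile-class].
#' @param build a [GenomeBuild-class].
#' @param np optional [NoiseProfile-class]; without it the FFPE axis is
#'   category 1 with a warning (no evidence of artifact, none assessable).
#' @param coarse optional pre-computed coarse segmentation.
#' @param thresholds from [qualityThresholds()].
#' @return a [QualityAssessment-class].
#' @export
assessQuality <- function(p, build, np = NULL, coarse = NULL,
                          thresholds = qualityThresholds()) {
  inoise <- estimateIntrinsicNoise(p, thresholds$intrinsicNoise)
  if (is.null(coarse))
    coarse <- segmentProfile(p, build, segmentationParams(nPerm = 20L),
                             merge = FALSE)
  tc <- estimateTumorContentCategory(coarse,
                                     cuts = thresholds$tumorContent)
  warnings <- tc$warnings
  if (is.null(np)) {
    ff <- list(correlation = NA_real_, category = 1L)
    warnings <- c(warnings,
                  "no FFPE noise profile supplied; FFPE axis not assessed")
  } else {
    ff <- scoreFfpeNoise(p, np, sp = coarse, build = build,
                         cuts = thresholds$ffpeNoise)
  }
  integ <- integrateQuality(tc$category, inoise$category, ff$category)
  new("QualityAssessment", tumorContentCat = tc$category,
      intrinsicNoiseCat = inoise$category, ffpeNoiseCat = ff$category,
      integrative = integ,
      metrics = list(purityProxy = tc$purityProxy,
                     intrinsicNoise = inoise$metric,
                     ffpeCorrelation = ff$correlation),
      warnings = warnings)
}
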