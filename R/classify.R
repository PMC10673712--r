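#' @include AllClasses.R features.R
NULL

#' Classifier configuration
#'
#' Decision constants of the stepwise HRD diagnostics. The score threshold
#' is 20 with a +/- 2 margin, so the clear-cut bounds are 18 and 22;
#' borderline cases are shifted to 19 (nonHRD evidence) or 21 (HRD
#' evidence). The penalty is 5 for exactly one binary attribute and 8 for
#' more than one; the bonus is 5 for a simple genome. The legacy v1
#' cutoffs (sensitive 15, specific 20) are carried for reference output
#' only. Ancillary-index floors drive the borderline evidence votes.
#'
#' @param threshold,margin,penaltyOne,penaltyMany,bonusSimple,borderlineDown,borderlineUp,v1Cutoffs,softDelta,stringentDelta,ampThreshold,tdMinGains,extraLargeFlankMb,telomereWindowMb,ancillaryFloors,lowQualityBreakpointCap
#'   see [ClassifierConfig-class].
#' @return a [ClassifierConfig-class].
#' @export
classifierConfig <- function(threshold = 20L, margin = 2L,
                             penaltyOne = 5L, penaltyMany = 8L,
                             bonusSimple = 5L, borderlineDown = 19L,
                             borderlineUp = 21L,
                             v1Cutoffs = c(sensitive = 15, specific = 20),
                             softDelta = 0.10, stringentDelta = 0.20,
                             ampThreshold = 2.0, tdMinGains = 8L,
                             extraLargeFlankMb = 30, telomereWindowMb = 1,
                             ancillaryFloors = c(extraLargeLga = 2,
                                                 telomericLga = 3,
                                                 lgaBetweenTop2 = 8,
                                                 lgaInvolvingTop3 = 12,
                                                 armsWithLga = 8),
                             lowQualityBreakpointCap = 40L) {
  new("ClassifierConfig", threshold = as.integer(threshold),
      margin = as.integer(margin), penaltyOne = as.integer(penaltyOne),
      penaltyMany = as.integer(penaltyMany),
      bonusSimple = as.integer(bonusSimple),
      borderlineDown = as.integer(borderlineDown),
      borderlineUp = as.integer(borderlineUp), v1Cutoffs = v1Cutoffs,
      softDelta = softDelta, stringentDelta = stringentDelta,
      ampThreshold = ampThreshold, tdMinGains = as.integer(tdMinGains),
      extraLargeFlankMb = extraLargeFlankMb,
      telomereWindowMb = telomereWindowMb,
      ancillaryFloors = ancillaryFloors,
      lowQualityBreakpointCap = as.integer(lowQualityBreakpointCap))
}

attributeFlags <- function(f) {
  c(f@ccne1Amp, f@erbb2Amp, f@focalAmpPhenotype, f@cdk12TdPhenotype)
}

#' Penalty from the binary attributes
#'
#' 0 when no attribute holds, \code{penaltyOne} (5) for exactly one,
#' \code{penaltyMany} (8) for more than one.
#'
#' @param f a [GenomicFeatures-class].
#' @param config a [ClassifierConfig-class].
#' @return integer penalty.
#' @export
computePenalty <- function(f, config = classifierConfig()) {
  k <- sum(attributeFlags(f))
  if (k == 0) 0L else if (k == 1) config@penaltyOne else config@penaltyMany
}

#' Bonus from the genome complexity
#'
#' \code{bonusSimple} (5) for a "simple" genome, 0 otherwise.
#'
#' @inheritParams computePenalty
#' @return integer bonus.
#' @export
computeBonus <- function(f, config = classifierConfig()) {
  if (f@complexity == "simple") config@bonusSimple else 0L
}

#' LGA-score
#'
#' \code{lgaRaw - penalty + bonus}, floored at 0.
#'
#' @param lgaRaw threshold-specific LGA count.
#' @param penalty,bonus from [computePenalty()] / [computeBonus()].
#' @return integer score.
#' @export
computeLgaScore <- function(lgaRaw, penalty, bonus) {
  max(0L, as.integer(lgaRaw) - as.integer(penalty) + as.integer(bonus))
}

newLgaScore <- function(lgaRaw, penalty, bonus, thresholdUsed) {
  new("LgaScore", lgaRaw = as.integer(lgaRaw), penalty = as.integer(penalty),
      bonus = as.integer(bonus),
      score = computeLgaScore(lgaRaw, penalty, bonus),
      thresholdUsed = thresholdUsed)
}

#' Resolve a borderline LGA-score
#'
#' Evidence votes over the configured items: nonHRD evidence is a positive
#' penalty, a "complex_plus" genome, and each ancillary index strictly
#' below its floor; HRD evidence is a zero penalty, a "simple" genome, and
#' each ancillary index strictly above its floor. The majority decides the
#' shift to \code{borderlineUp} (21) or \code{borderlineDown} (19); an
#' exact tie resolves conservatively to 19.
#'
#' @param score LGA-score within the clear-cut margins (18..22).
#' @param f a [GenomicFeatures-class].
#' @param penalty the penalty in force.
#' @param config a [ClassifierConfig-class].
#' @return list with \code{score} (19 or 21), \code{votesHrd},
#'   \code{votesNonHrd} and a text \code{evidence} trail.
#' @export
resolveBorderline <- function(score, f, penalty,
                              config = classifierConfig()) {
  lo <- config@threshold - config@margin
  hi <- config@threshold + config@margin
  if (score < lo || score > hi)
    stop("score ", score, " is not borderline (", lo, "..", hi, ")")
  idx <- c(extraLargeLga = f@extraLargeLga, telomericLga = f@telomericLga,
           lgaBetweenTop2 = f@lgaBetweenTop2,
           lgaInvolvingTop3 = f@lgaInvolvingTop3,
           armsWithLga = f@armsWithLga)
  floors <- config@ancillaryFloors[names(idx)]
  evid <- character(0)
  vHrd <- 0L; vNon <- 0L
  if (penalty == 0) { vHrd <- vHrd + 1L; evid <- c(evid, "penalty=0 (HRD)") }
  else { vNon <- vNon + 1L; evid <- c(evid, "penalty>0 (nonHRD)") }
  if (f@complexity == "simple") {
    vHrd <- vHrd + 1L; evid <- c(evid, "simple genome (HRD)")
  } else if (f@complexity == "complex_plus") {
    vNon <- vNon + 1L; evid <- c(evid, "complex+ genome (nonHRD)")
  }
  above <- sum(idx > floors, na.rm = TRUE)
  below <- sum(idx < floors, na.rm = TRUE)
  vHrd <- vHrd + above; vNon <- vNon + below
  evid <- c(evid, sprintf("ancillary indexes: %d above floor (HRD), %d below (nonHRD)",
                          above, below))
  shifted <- if (vHrd > vNon) config@borderlineUp else config@borderlineDown
  list(score = as.integer(shifted), votesHrd = vHrd, votesNonHrd = vNon,
       evidence = evid)
}

#' Step-wise HRD diagnostics
#'
#' Applies the quality-dependent decision rules to the per-threshold
#' LGA-scores. Good-quality samples use the conservative soft/stringent
#' pairing (clear-cut nonHRD requires even the permissive soft score below
#' 18; clear-cut HRD requires even the restrictive stringent score above
#' 22) and resolve borderline cases by evidence voting. Noisy samples are
#' fixed to the stringent threshold and low-tumor-content samples to the
#' soft one. Fair-quality samples receive only clear-cut diagnoses; the
#' borderline zone is non-determined. Low-quality samples receive only a
#' clear-cut nonHRD when the overall breakpoint count is small; everything
#' else is non-determined. A warning is attached (without overriding the
#' decision) when the rerun confidence interval spans a decision bound.
#'
#' @param f a [GenomicFeatures-class].
#' @param qa a [QualityAssessment-class].
#' @param ci optional [LgaConfidence-class].
#' @param config a [ClassifierConfig-class].
#' @return an [HrdCall-class].
#' @export
callHrd <- function(f, qa, ci = NULL, config = classifierConfig()) {
  stopifnot(is(f, "GenomicFeatures"), is(qa, "QualityAssessment"))
  penalty <- computePenalty(f, config)
  bonus <- computeBonus(f, config)
  scoreSoft <- newLgaScore(f@lgaSoft, penalty, bonus, "soft")
  scoreStr <- newLgaScore(f@lgaStringent, penalty, bonus, "stringent")
  lo <- config@threshold - config@margin
  hi <- config@threshold + config@margin
  audit <- c(sprintf("penalty=%d (%d attribute(s)), bonus=%d (%s genome)",
                     penalty, sum(attributeFlags(f)), bonus, f@complexity),
             sprintf("LGA-score soft=%d stringent=%d (raw %d/%d)",
                     scoreSoft@score, scoreStr@score, f@lgaSoft,
                     f@lgaStringent))
  warnings <- character(0)
  noisy <- qa@intrinsicNoiseCat >= 2L
  lowContent <- qa@tumorContentCat >= 3L
  sLo <- scoreSoft; sHi <- scoreStr
  if (lowContent) {
    sLo <- scoreSoft; sHi <- scoreSoft
    audit <- c(audit, "low tumor content: LGA threshold fixed to soft")
  } else if (noisy) {
    sLo <- scoreStr; sHi <- scoreStr
    audit <- c(audit, "noisy sample: LGA threshold fixed to stringent")
  }
  scores <- list(soft = scoreSoft, stringent = scoreStr,
                 v1Cutoffs = config@v1Cutoffs)
  finish <- function(stat, pw, sc, extraAudit = character(0)) {
    w <- c(warnings, if (!is.null(ci)) {
      spans <- (ci@low < lo && ci@high >= lo) ||
               (ci@low <= hi && ci@high > hi)
      if (spans) "rerun confidence interval spans a decision bound"
    })
    new("HrdCall", status = stat, pathway = pw,
        scoreFinal = as.numeric(sc), quality = qa, scores = scores,
        ci = ci, warnings = as.character(w),
        audit = c(audit, extraAudit))
  }
  qual <- qa@integrative
  if (qual == "low") {
    if (sLo@score < lo && f@nBreakpoints < config@lowQualityBreakpointCap)
      return(finish("nonHRD", "quality_restricted", sLo@score,
                    sprintf("low quality: clear-cut nonHRD (score %d < %d, %d breakpoints < %d)",
                            sLo@score, lo, f@nBreakpoints,
                            config@lowQualityBreakpointCap)))
    return(finish("ND", "quality_restricted", NA_real_,
                  "low quality: only clear-cut nonHRD with few breakpoints is diagnosable"))
  }
  if (sLo@score < lo)
    return(finish("nonHRD", "clear_cut", sLo@score,
                  sprintf("clear-cut nonHRD: %s score %d < %d",
                          sLo@thresholdUsed, sLo@score, lo)))
  if (sHi@score > hi)
    return(finish("HRD", "clear_cut", sHi@score,
                  sprintf("clear-cut HRD: %s score %d > %d",
                          sHi@thresholdUsed, sHi@score, hi)))
  if (qual == "fair")
    return(finish("ND", "quality_restricted", NA_real_,
                  "fair quality: borderline case left non-determined"))
  working <- if (f@complexity == "simple") sHi@score else sLo@score
  working <- min(max(working, lo), hi)
  res <- resolveBorderline(working, f, penalty, config)
  stat <- if (res$score > config@threshold) "HRD" else "nonHRD"
  finish(stat, "borderline_resolved", res$score,
         c(sprintf("borderline (working score %d): shifted to %d (votes HRD %d vs nonHRD %d)",
                   working, res$score, res$votesHrd, res$votesNonHrd),
           res$evidence))
}
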