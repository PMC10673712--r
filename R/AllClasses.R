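#' @import methods
#' @importFrom GenomicRanges GRanges granges findOverlaps mcols mcols<- seqnames start end width strand
#' @importFrom IRanges IRanges subsetByOverlaps overlapsAny
#' @importFrom S4Vectors queryHits subjectHits DataFrame metadata metadata<-
#' @importFrom GenomeInfoDb Seqinfo seqlevels seqlengths
NULL

#' Genome build: chromosomes, arm boundaries and named gene loci
#'
#' A \code{GenomeBuild} holds the genomic context in which profiles are
#' interpreted: the ordered chromosomes with their lengths, the p/q arm
#' intervals delimited by the centromere, and named gene windows (at least
#' CCNE1 and ERBB2) used for amplification attribute calls.
#'
#' @slot buildName label for the build (e.g. \code{"hg19"}).
#' @slot chromosomes \code{data.frame} with columns \code{chrom},
#'   \code{length}, \code{cen_start}, \code{cen_end} (0-based half-open).
#' @slot arms \code{GRanges} of arm intervals with metadata column
#'   \code{arm} ("p" or "q").
#' @slot loci \code{GRanges} of gene windows with metadata column
#'   \code{name}.
#'
#' @seealso [loadGenomeBuild()]
#' @export
setClass("GenomeBuild",
  slots = c(buildName = "character", chromosomes = "data.frame",
            arms = "GRanges", loci = "GRanges"))

setValidity("GenomeBuild", function(object) {
  ch <- object@chromosomes
  need <- c("chrom", "length", "cen_start", "cen_end")
  if (!all(need %in% names(ch)))
    return(sprintf("chromosomes table must have columns %s",
                   paste(need, collapse = ", ")))
  if (anyDuplicated(ch$chrom)) return("chromosome names must be unique")
  if (any(ch$cen_start < 0 | ch$cen_end > ch$length | ch$cen_start > ch$cen_end))
    return("centromere interval must lie within the chromosome")
  if (length(object@loci)) {
    lc <- as.character(seqnames(object@loci))
    idx <- match(lc, ch$chrom)
    if (anyNA(idx)) return("locus on unknown chromosome")
    if (any(end(object@loci) > ch$length[idx]))
      return("locus window extends beyond its chromosome")
  }
  TRUE
})

#' Bin-level normalized copy-number ratio profile
#'
#' Raw input to the pipeline: a fixed grid of ~50 kb bins, each carrying a
#' normalized copy-number ratio (1.0 = sample median ploidy) and a validity
#' flag. Bins are sorted, non-overlapping, and annotated with the chromosome
#' arm they fall in (\code{NA} for bins straddling or inside the centromere,
#' which are excluded from segmentation).
#'
#' @slot sampleId sample identifier.
#' @slot bins \code{GRanges} with metadata columns \code{ratio} (numeric),
#'   \code{valid} (logical) and \code{arm} (character, possibly \code{NA}).
#' @slot binSize nominal bin size in bp.
#' @slot metadata free-form provenance list.
#' @export
setClass("BinnedProfile",
  slots = c(sampleId = "character", bins = "GRanges",
            binSize = "numeric", metadata = "list"))

setValidity("BinnedProfile", function(object) {
  b <- object@bins
  mc <- names(mcols(b))
  if (!all(c("ratio", "valid", "arm") %in% mc))
    return("bins must carry ratio, valid and arm metadata columns")
  if (is.unsorted(order(as.integer(seqnames(b)), start(b))))
    return("bins must be sorted by (chrom, start)")
  r <- mcols(b)$ratio
  v <- mcols(b)$valid
  if (any(v & (is.na(r) | r < 0)))
    return("valid bins must have ratio >= 0")
  TRUE
})

#' Per-bin FFPE noise profile built from a panel of normals
#'
#' @slot bins \code{GRanges} on the working bin grid with metadata columns
#'   \code{expectedDev} (per-bin median artifactual deviation of the ratio
#'   from 1.0) and \code{dispersion} (MAD-scaled per-bin sd across the
#'   panel).
#' @slot panelSize number of normal profiles summarized.
#' @export
setClass("NoiseProfile",
  slots = c(bins = "GRanges", panelSize = "integer"))

setValidity("NoiseProfile", function(object) {
  if (!all(c("expectedDev", "dispersion") %in% names(mcols(object@bins))))
    return("bins must carry expectedDev and dispersion")
  if (object@panelSize < 1L) return("panelSize must be >= 1")
  TRUE
})

#' Piecewise-constant segmentation of a copy-number profile
#'
#' @slot sampleId sample identifier.
#' @slot segments \code{GRanges} with metadata columns \code{arm},
#'   \code{cnLevel} (mean ratio), \code{nBins}, \code{sizeMb} and
#'   \code{roundedSizeMb} (size rounded half-up to the integer megabase,
#'   the unit all LGA size rules operate on).
#' @slot residuals per-valid-bin (ratio - segment level) error track, in
#'   bin order over the bins covered by segments.
#' @slot runSeed seed of the segmentation run that produced this object.
#' @export
setClass("SegmentedProfile",
  slots = c(sampleId = "character", segments = "GRanges",
            residuals = "numeric", runSeed = "integer"))

setValidity("SegmentedProfile", function(object) {
  s <- object@segments
  need <- c("arm", "cnLevel", "nBins", "sizeMb", "roundedSizeMb")
  if (!all(need %in% names(mcols(s))))
    return(sprintf("segments must carry %s", paste(need, collapse = ", ")))
  if (length(s)) {
    if (any(mcols(s)$nBins < 1)) return("segments must have nBins >= 1")
    bad <- abs(mcols(s)$roundedSizeMb - floor(mcols(s)$sizeMb + 0.5)) > 0
    if (any(bad)) return("roundedSizeMb must equal sizeMb rounded half-up")
    key <- paste(seqnames(s), mcols(s)$arm)
    for (ii in split(seq_along(s), key)) {
      if (length(ii) > 1 &&
          any(start(s)[ii][-1] <= end(s)[ii][-length(ii)]))
        return("segments overlap within an arm")
    }
  }
  TRUE
})

#' Three-way sample quality assessment
#'
#' Ordinal categories for tumor content (1-4, 1 = highest), intrinsic
#' sequencing noise (1-3, 1 = cleanest) and FFPE artifact load (1-4,
#' 1 = least), integrated into a final good/fair/low class through a fixed,
#' documented lookup.
#'
#' @slot tumorContentCat integer 1-4.
#' @slot intrinsicNoiseCat integer 1-3.
#' @slot ffpeNoiseCat integer 1-4.
#' @slot integrative "good", "fair" or "low".
#' @slot metrics named list of the raw metric values behind the categories.
#' @slot warnings character vector of quality warnings.
#' @export
setClass("QualityAssessment",
  slots = c(tumorContentCat = "integer", intrinsicNoiseCat = "integer",
            ffpeNoiseCat = "integer", integrative = "character",
            metrics = "list", warnings = "character"))

setValidity("QualityAssessment", function(object) {
  if (!object@tumorContentCat %in% 1:4) return("tumorContentCat must be 1-4")
  if (!object@intrinsicNoiseCat %in% 1:3) return("intrinsicNoiseCat must be 1-3")
  if (!object@ffpeNoiseCat %in% 1:4) return("ffpeNoiseCat must be 1-4")
  if (!object@integrative %in% c("good", "fair", "low"))
    return("integrative must be good/fair/low")
  TRUE
})

#' Broad copy-number profile characterization
#'
#' Everything the LGA-score consumes: the genome complexity class, the four
#' binary penalty attributes, LGA counts under the soft and stringent
#' copy-number difference thresholds, and the ancillary LGA indexes used for
#' borderline resolution.
#'
#' @slot complexity "simple", "complex" or "complex_plus".
#' @slot cnLevelWeights genome-length fraction per clustered CN level,
#'   descending, named by cluster center.
#' @slot ccne1Amp,erbb2Amp,focalAmpPhenotype,cdk12TdPhenotype binary
#'   attributes associated with nonHRD biology.
#' @slot lgaSoft,lgaStringent LGA counts at the soft / stringent thresholds.
#' @slot extraLargeLga,telomericLga,lgaBetweenTop2,lgaInvolvingTop3,armsWithLga
#'   ancillary LGA indexes.
#' @slot nBreakpoints total number of same-arm breakpoints in the segmented
#'   profile (all size classes), used by the low-quality decision rule.
#' @export
setClass("GenomicFeatures",
  slots = c(complexity = "character", cnLevelWeights = "numeric",
            ccne1Amp = "logical", erbb2Amp = "logical",
            focalAmpPhenotype = "logical", cdk12TdPhenotype = "logical",
            lgaSoft = "integer", lgaStringent = "integer",
            extraLargeLga = "integer", telomericLga = "integer",
            lgaBetweenTop2 = "integer", lgaInvolvingTop3 = "integer",
            armsWithLga = "integer", nBreakpoints = "integer"))

setValidity("GenomicFeatures", function(object) {
  if (!object@complexity %in% c("simple", "complex", "complex_plus"))
    return("complexity must be simple/complex/complex_plus")
  if (object@lgaStringent > object@lgaSoft)
    return("stringent LGA count cannot exceed soft LGA count")
  cnt <- c(object@lgaSoft, object@lgaStringent, object@extraLargeLga,
           object@telomericLga, object@lgaBetweenTop2,
           object@lgaInvolvingTop3, object@armsWithLga, object@nBreakpoints)
  if (any(cnt < 0)) return("all counts must be >= 0")
  if (sum(object@cnLevelWeights) > 1 + 1e-8)
    return("cnLevelWeights must sum to <= 1")
  TRUE
})

#' LGA count confidence interval over stochastic segmentation reruns
#'
#' @slot point LGA count of the base-seed run.
#' @slot low,high min/max LGA count over the reruns.
#' @slot q025,q975 2.5/97.5 percentile of the rerun counts.
#' @slot runs per-run LGA counts.
#' @export
setClass("LgaConfidence",
  slots = c(point = "integer", low = "integer", high = "integer",
            q025 = "numeric", q975 = "numeric", runs = "integer"))

setValidity("LgaConfidence", function(object) {
  if (object@low > object@point || object@point > object@high)
    return("must satisfy low <= point <= high")
  TRUE
})

#' LGA-score: raw LGA count modified by penalty and bonus
#'
#' @slot lgaRaw threshold-specific LGA count.
#' @slot penalty 0, 5 or 8 depending on how many binary attributes hold.
#' @slot bonus 5 for a simple genome, 0 otherwise.
#' @slot score \code{max(0, lgaRaw - penalty + bonus)}.
#' @slot thresholdUsed "soft" or "stringent".
#' @export
setClass("LgaScore",
  slots = c(lgaRaw = "integer", penalty = "integer", bonus = "integer",
            score = "integer", thresholdUsed = "character"))

setValidity("LgaScore", function(object) {
  if (object@score != max(0L, object@lgaRaw - object@penalty + object@bonus))
    return("score must equal max(0, lgaRaw - penalty + bonus)")
  TRUE
})

#' Final HRD diagnosis with its audit trail
#'
#' @slot status "HRD", "nonHRD" or "ND" (non-determined).
#' @slot pathway which decision path fired: "clear_cut",
#'   "borderline_resolved", "quality_restricted" or "non_contributive".
#' @slot scoreFinal the LGA-score the decision was made on (NA for ND).
#' @slot quality the [QualityAssessment-class] of the sample.
#' @slot scores named list of [LgaScore-class] objects ("soft",
#'   "stringent") plus the v1 reference cutoffs.
#' @slot ci [LgaConfidence-class] or NULL.
#' @slot warnings warning messages (e.g. CI spanning a decision bound).
#' @slot audit ordered record of every decision rule that fired.
#' @export
setClass("HrdCall",
  slots = c(status = "character", pathway = "character",
            scoreFinal = "numeric", quality = "ANY", scores = "list",
            ci = "ANY", warnings = "character", audit = "character"))

setValidity("HrdCall", function(object) {
  if (!object@status %in% c("HRD", "nonHRD", "ND"))
    return("status must be HRD/nonHRD/ND")
  if (!object@pathway %in% c("clear_cut", "borderline_resolved",
                             "quality_restricted", "non_contributive"))
    return("unknown pathway")
  if (length(object@audit) == 0) return("audit trail must be non-empty")
  TRUE
})

#' 3x3 diagnostic contingency table
#'
#' Cross-tabulation of a reference test (rows) against an index test
#' (columns) over the categories Positive / Negative / NC
#' (non-contributive).
#'
#' @slot labels ordered category names.
#' @slot counts 3x3 matrix of non-negative integer counts.
#' @export
setClass("ContingencyTable",
  slots = c(labels = "character", counts = "matrix"))

setValidity("ContingencyTable", function(object) {
  k <- object@counts
  if (!is.numeric(k) || nrow(k) != 3 || ncol(k) != 3)
    return("counts must be a 3x3 numeric matrix")
  if (any(k < 0) || any(k != round(k)))
    return("counts must be non-negative integers")
  if (sum(k) <= 0) return("table total must be > 0")
  if (length(object@labels) != 3) return("need 3 category labels")
  TRUE
})

#' Simulation configuration
#'
#' Parameters of the synthetic tumor-profile generator. The defaults encode
#' the data regime the pipeline targets: ~50 kb bins at ~1X coverage,
#' FFPE-derived samples with moderate tumor content.
#'
#' @slot seed integer; fixes all randomness.
#' @slot tumorFraction tumor cell fraction in [0,1].
#' @slot basePloidy 2 or 4.
#' @slot nLga number of planted arm-internal CN breaks with both flanks
#'   >= 12 Mb.
#' @slot nSmallEvents number of planted sub-10 Mb events (mixed gain/loss).
#' @slot binNoiseSd sd of per-bin Gaussian ratio noise.
#' @slot ffpeWaveAmplitude amplitude of the smooth FFPE wave artifact
#'   (ratio units); 0 disables it.
#' @slot waveSeed seed of the wave shape; profiles and panels sharing the
#'   waveSeed share the artifact.
#' @slot plantCcne1Amp,plantErbb2Amp plant a high-level amplicon over the
#'   locus.
#' @slot plantFocalAmpArms number of arms receiving a focal (<10 Mb)
#'   amplification.
#' @slot plantTdGains number of 1-10 Mb interstitial single-copy gains
#'   (tandem-duplication phenotype).
#' @slot readDepthModel "gaussian" (noise on the ratio) or
#'   "negative_binomial" (counts at ~1X converted back to ratios).
#' @slot meanReadsPerBin mean reads per bin for the count model.
#' @slot nbDispersion negative-binomial size parameter.
#' @slot binSize bin size in bp.
#' @export
setClass("SimulationConfig",
  slots = c(seed = "integer", tumorFraction = "numeric",
            basePloidy = "numeric", nLga = "integer",
            nSmallEvents = "integer", binNoiseSd = "numeric",
            ffpeWaveAmplitude = "numeric", waveSeed = "integer",
            plantCcne1Amp = "logical", plantErbb2Amp = "logical",
            plantFocalAmpArms = "integer", plantTdGains = "integer",
            readDepthModel = "character", meanReadsPerBin = "numeric",
            nbDispersion = "numeric", binSize = "numeric"))

setValidity("SimulationConfig", function(object) {
  if (object@tumorFraction < 0 || object@tumorFraction > 1)
    return("tumorFraction must be in [0,1]")
  if (!object@basePloidy %in% c(2, 4)) return("basePloidy must be 2 or 4")
  if (any(c(object@nLga, object@nSmallEvents, object@plantFocalAmpArms,
            object@plantTdGains) < 0))
    return("event counts must be >= 0")
  if (!object@readDepthModel %in% c("gaussian", "negative_binomial"))
    return("readDepthModel must be gaussian or negative_binomial")
  TRUE
})

#' Ground truth of a simulated profile
#'
#' @slot trueSegments the planted [SegmentedProfile-class].
#' @slot trueLgaCount number of planted breaks whose two flanking true
#'   segments have rounded size >= 10 Mb and distinct CN levels.
#' @slot plantedFlags list of the planted phenotypes.
#' @export
setClass("GroundTruth",
  slots = c(trueSegments = "SegmentedProfile", trueLgaCount = "integer",
            plantedFlags = "list"))

#' Segmentation parameters
#'
#' @slot minSegmentMb small-segment filter floor in Mb (default 3, well
#'   below the 10 Mb LGA scale so filtering cannot delete true LGA flanks).
#' @slot mergeDelta named numeric: maximal level difference merged away,
#'   per quality category (good/fair/low).
#' @slot ffpeCorrMergeThreshold correlation with the FFPE noise profile
#'   above which a candidate segment is merged as artifact.
#' @slot nReruns number of stochastic reruns for the LGA confidence
#'   interval.
#' @slot alpha permutation significance for a CBS split.
#' @slot nPerm number of permutations per ambiguous split test.
#' @slot seed base seed; rerun i uses seed + i.
#' @export
setClass("SegmentationParams",
  slots = c(minSegmentMb = "numeric", mergeDelta = "numeric",
            ffpeCorrMergeThreshold = "numeric", nReruns = "integer",
            alpha = "numeric", nPerm = "integer", seed = "integer"))

setValidity("SegmentationParams", function(object) {
  if (object@nReruns < 1L) return("nReruns must be >= 1")
  if (any(object@mergeDelta <= 0)) return("mergeDelta must be > 0")
  if (!all(c("good", "fair", "low") %in% names(object@mergeDelta)))
    return("mergeDelta must be named good/fair/low")
  TRUE
})

#' Classifier configuration
#'
#' Decision constants of the stepwise diagnostics: threshold 20 with +/- 2
#' margins (clear-cut bounds 18 and 22), penalties 5/8 for one/several
#' binary attributes, bonus 5 for a simple genome, borderline shifts to
#' 19/21, and the legacy v1 cutoffs (sensitive 15 / specific 20) retained
#' for reference output only.
#'
#' @slot threshold decision threshold on the LGA-score.
#' @slot margin clear-cut margin around the threshold.
#' @slot penaltyOne,penaltyMany penalty for one / more than one attribute.
#' @slot bonusSimple bonus for a simple genome.
#' @slot borderlineDown,borderlineUp scores a borderline case is shifted to.
#' @slot v1Cutoffs named numeric c(sensitive=, specific=).
#' @slot softDelta,stringentDelta CN-difference thresholds (ratio units)
#'   for the soft / stringent LGA call.
#' @slot ampThreshold ratio level at or above which a segment is called
#'   amplified.
#' @slot tdMinGains minimal number of 1-10 Mb interstitial gains for the
#'   tandem-duplication phenotype.
#' @slot extraLargeFlankMb flank size defining an extra-large LGA.
#' @slot telomereWindowMb distance to the arm end defining a telomeric LGA.
#' @slot ancillaryFloors named numeric floors for the ancillary indexes in
#'   borderline evidence voting.
#' @slot lowQualityBreakpointCap maximal total breakpoint count for a
#'   low-quality clear-cut nonHRD call.
#' @export
setClass("ClassifierConfig",
  slots = c(threshold = "integer", margin = "integer",
            penaltyOne = "integer", penaltyMany = "integer",
            bonusSimple = "integer", borderlineDown = "integer",
            borderlineUp = "integer", v1Cutoffs = "numeric",
            softDelta = "numeric", stringentDelta = "numeric",
            ampThreshold = "numeric", tdMinGains = "integer",
            extraLargeFlankMb = "numeric", telomereWindowMb = "numeric",
            ancillaryFloors = "numeric", lowQualityBreakpointCap = "integer"))

setValidity("ClassifierConfig", function(object) {
  if (object@margin <= 0 || object@threshold <= 0)
    return("threshold and margin must be positive")
  if (!(object@threshold - object@margin < object@threshold &&
        object@threshold < object@threshold + object@margin))
    return("invalid margin")
  if (object@borderlineDown >= object@threshold ||
      object@borderlineUp <= object@threshold)
    return("borderline shifts must bracket the threshold")
  if (object@stringentDelta < object@softDelta)
    return("stringentDelta must be >= softDelta")
  TRUE
})
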