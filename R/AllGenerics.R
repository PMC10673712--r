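#' @include AllClasses.R
NULL

#' Accessors for swgsHRD objects
#'
#' Standard accessors for the package's S4 containers. Slots are never
#' accessed directly by user code.
#'
#' @param x an swgsHRD object.
#' @param object an swgsHRD object (for \code{residuals}).
#' @param ... unused.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("bins", function(x) standardGeneric("bins"))

#' @rdname accessors
#' @export
setGeneric("segments", function(x, ...) standardGeneric("segments"))

#' @rdname accessors
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname accessors
#' @export
setGeneric("status", function(x) standardGeneric("status"))

#' @rdname accessors
#' @export
setGeneric("pathway", function(x) standardGeneric("pathway"))

#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname accessors
#' @export
setMethod("sampleId", "BinnedProfile", function(x) x@sampleId)

#' @rdname accessors
#' @export
setMethod("sampleId", "SegmentedProfile", function(x) x@sampleId)

#' @rdname accessors
#' @export
setMethod("bins", "BinnedProfile", function(x) x@bins)

#' @rdname accessors
#' @export
setMethod("bins", "NoiseProfile", function(x) x@bins)

#' @rdname accessors
#' @export
setMethod("binSize", "BinnedProfile", function(x) x@binSize)

#' @rdname accessors
#' @export
setMethod("segments", "SegmentedProfile", function(x, ...) x@segments)

#' @rdname accessors
#' @export
setMethod("residuals", "SegmentedProfile", function(object, ...) object@residuals)

#' @rdname accessors
#' @export
setMethod("status", "HrdCall", function(x) x@status)

#' @rdname accessors
#' @export
setMethod("pathway", "HrdCall", function(x) x@pathway)

#' @rdname accessors
#' @export
setMethod("counts", "ContingencyTable", function(x) x@counts)

setMethod("show", "GenomeBuild", function(object) {
  cat(sprintf("GenomeBuild '%s': %d chromosomes, %d arms, %d loci\n",
              object@buildName, nrow(object@chromosomes),
              length(object@arms), length(object@loci)))
})

setMethod("show", "BinnedProfile", function(object) {
  b <- object@bins
  cat(sprintf("BinnedProfile '%s': %d bins (%d valid), bin size %g bp\n",
              object@sampleId, length(b), sum(mcols(b)$valid),
              object@binSize))
})

setMethod("show", "NoiseProfile", function(object) {
  cat(sprintf("NoiseProfile: %d bins, panel of %d normals\n",
              length(object@bins), object@panelSize))
})

setMethod("show", "SegmentedProfile", function(object) {
  s <- object@segments
  cat(sprintf("SegmentedProfile '%s': %d segments on %d arms (seed %d)\n",
              object@sampleId, length(s),
              length(unique(paste(seqnames(s), mcols(s)$arm))),
              object@runSeed))
})

setMethod("show", "QualityAssessment", function(object) {
  cat(sprintf(
    "QualityAssessment: tumor content %d/4, intrinsic noise %d/3, FFPE %d/4 -> %s\n",
    object@tumorContentCat, object@intrinsicNoiseCat, object@ffpeNoiseCat,
    object@integrative))
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
})

setMethod("show", "GenomicFeatures", function(object) {
  flags <- c(CCNE1 = object@ccne1Amp, ERBB2 = object@erbb2Amp,
             focalAmp = object@focalAmpPhenotype, TD = object@cdk12TdPhenotype)
  cat(sprintf("GenomicFeatures: %s genome, LGA soft/stringent %d/%d\n",
              object@complexity, object@lgaSoft, object@lgaStringent))
  cat("  attributes:", if (any(flags)) paste(names(flags)[flags], collapse = ", ")
      else "none", "\n")
})

setMethod("show", "LgaScore", function(object) {
  cat(sprintf("LgaScore (%s): %d LGA - %d penalty + %d bonus = %d\n",
              object@thresholdUsed, object@lgaRaw, object@penalty,
              object@bonus, object@score))
})

setMethod("show", "HrdCall", function(object) {
  cat(sprintf("HrdCall: %s (%s), final score %s\n", object@status,
              object@pathway,
              if (is.na(object@scoreFinal)) "NA" else object@scoreFinal))
})

setMethod("show", "ContingencyTable", function(object) {
  cat("ContingencyTable (rows = reference, cols = index):\n")
  m <- object@counts
  dimnames(m) <- list(object@labels, object@labels)
  print(m)
})

setMethod("show", "LgaConfidence", function(object) {
  cat(sprintf("LgaConfidence: point %d, range [%d, %d] over %d runs\n",
              object@point, object@low, object@high, length(object@runs)))
})
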