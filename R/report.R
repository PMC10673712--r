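#' @include AllClasses.R io.R segment.R quality.R features.R classify.R concordance.R simulate.R
NULL

resolveRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path")
  defaults <- list(input = NULL, dialect = "generic_tsv", sampleId = NULL,
                   build = "hg19", loci = NULL, noiseProfile = NULL,
                   seed = 0L, outDir = ".", nReruns = NULL,
                   segmentation = list(), classifier = list(),
                   quality = list())
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$input)) stop("config field 'input' is required")
  if (!file.exists(cfg$input)) stop("input does not exist: ", cfg$input)
  cfg
}

effectiveParams <- function(cfg) {
  sp <- do.call(segmentationParams,
                c(cfg$segmentation, list(seed = as.integer(cfg$seed))))
  if (!is.null(cfg$nReruns)) sp@nReruns <- as.integer(cfg$nReruns)
  cc <- do.call(classifierConfig, cfg$classifier)
  qt <- do.call(qualityThresholds, cfg$quality)
  list(segmentation = sp, classifier = cc, quality = qt)
}

scoreAsList <- function(s) {
  list(lga_raw = s@lgaRaw, penalty = s@penalty, bonus = s@bonus,
       score = s@score, threshold = s@thresholdUsed)
}

hrdReportList <- function(call, f = NULL, sampleId = "sample",
                          params = NULL) {
  qa <- call@quality
  rep <- list(
    sample = sampleId,
    status = call@status,
    pathway = call@pathway,
    score_final = if (is.na(call@scoreFinal)) NULL else call@scoreFinal,
    scores = if (length(call@scores))
      list(soft = scoreAsList(call@scores$soft),
           stringent = scoreAsList(call@scores$stringent),
           v1_cutoffs = as.list(call@scores$v1Cutoffs)) else NULL,
    quality = if (!is.null(qa)) list(
      tumor_content_cat = qa@tumorContentCat,
      intrinsic_noise_cat = qa@intrinsicNoiseCat,
      ffpe_noise_cat = qa@ffpeNoiseCat,
      integrative = qa@integrative,
      metrics = qa@metrics, warnings = qa@warnings) else NULL,
    ci = if (!is.null(call@ci)) list(
      point = call@ci@point, low = call@ci@low, high = call@ci@high,
      q025 = call@ci@q025, q975 = call@ci@q975,
      runs = call@ci@runs) else NULL,
    features = if (!is.null(f)) list(
      complexity = f@complexity,
      cn_level_weights = as.list(f@cnLevelWeights),
      ccne1_amp = f@ccne1Amp, erbb2_amp = f@erbb2Amp,
      focal_amp_phenotype = f@focalAmpPhenotype,
      cdk12_td_phenotype = f@cdk12TdPhenotype,
      lga_soft = f@lgaSoft, lga_stringent = f@lgaStringent,
      extra_large_lga = f@extraLargeLga, telomeric_lga = f@telomericLga,
      lga_between_top2 = f@lgaBetweenTop2,
      lga_involving_top3 = f@lgaInvolvingTop3,
      arms_with_lga = f@armsWithLga,
      n_breakpoints = f@nBreakpoints) else NULL,
    warnings = call@warnings,
    audit = call@audit)
  if (!is.null(params))
    rep$parameters <- list(
      segmentation = list(
        min_segment_mb = params$segmentation@minSegmentMb,
        merge_delta = as.list(params$segmentation@mergeDelta),
        ffpe_corr_merge_threshold =
          params$segmentation@ffpeCorrMergeThreshold,
        n_reruns = params$segmentation@nReruns,
        alpha = params$segmentation@alpha,
        n_perm = params$segmentation@nPerm,
        seed = params$segmentation@seed),
      classifier = list(
        threshold = params$classifier@threshold,
        margin = params$classifier@margin,
        penalty_one = params$classifier@penaltyOne,
        penalty_many = params$classifier@penaltyMany,
        bonus_simple = params$classifier@bonusSimple,
        soft_delta = params$classifier@softDelta,
        stringent_delta = params$classifier@stringentDelta,
        amp_threshold = params$classifier@ampThreshold,
        ancillary_floors = as.list(params$classifier@ancillaryFloors),
        low_quality_breakpoint_cap =
          params$classifier@lowQualityBreakpointCap),
      quality = params$quality)
  rep
}

writeTextReport <- function(rep, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("sample: %s", rep$sample)
  w("HRD status: %s (pathway: %s)", rep$status, rep$pathway)
  if (!is.null(rep$score_final)) w("final LGA-score: %s", rep$score_final)
  if (!is.null(rep$scores)) {
    w("LGA-score (soft):      %d LGA - %d penalty + %d bonus = %d",
      rep$scores$soft$lga_raw, rep$scores$soft$penalty,
      rep$scores$soft$bonus, rep$scores$soft$score)
    w("LGA-score (stringent): %d LGA - %d penalty + %d bonus = %d",
      rep$scores$stringent$lga_raw, rep$scores$stringent$penalty,
      rep$scores$stringent$bonus, rep$scores$stringent$score)
  }
  if (!is.null(rep$quality))
    w("quality: tumor content %d/4, intrinsic noise %d/3, FFPE %d/4 -> %s",
      rep$quality$tumor_content_cat, rep$quality$intrinsic_noise_cat,
      rep$quality$ffpe_noise_cat, rep$quality$integrative)
  if (!is.null(rep$ci))
    w("LGA over %d reruns: point %d, range [%d, %d]",
      length(rep$ci$runs), rep$ci$point, rep$ci$low, rep$ci$high)
  for (msg in rep$warnings) w("warning: %s", msg)
  w("audit trail:")
  for (a in rep$audit) w("  - %s", a)
}

#' Run the full HRD pipeline on one sample
#'
#' Executes preprocess, quality attribution, segmentation, feature
#' extraction and classification, and writes the comprehensive report:
#' \code{report.json}, a plain-text \code{report.txt}, the segments as
#' BED-like TSV, the per-rerun LGA table and a plot-ready bin track
#' (ratio, segment level, residual). A non-contributive input produces a
#' valid ND report rather than an error.
#'
#' @param config a list or YAML path with at least \code{input}; optional
#'   fields: \code{dialect}, \code{sampleId}, \code{build},
#'   \code{noiseProfile}, \code{seed}, \code{outDir}, \code{nReruns}, and
#'   parameter blocks \code{segmentation}, \code{classifier},
#'   \code{quality}.
#' @param reruns compute the rerun confidence interval (default TRUE; the
#'   pipeline runs \code{nReruns} extra segmentations).
#' @return an [HrdCall-class], invisibly; reports are written to
#'   \code{outDir}.
#' @export
runSample <- function(config, reruns = TRUE) {
  cfg <- resolveRunConfig(config)
  build <- loadGenomeBuild(cfg$build, lociPath = cfg$loci)
  params <- effectiveParams(cfg)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  p <- readBinnedProfile(cfg$input, build, dialect = cfg$dialect,
                         sampleId = cfg$sampleId)
  np <- if (!is.null(cfg$noiseProfile))
    readNoiseProfile(cfg$noiseProfile, build) else NULL
  outcome <- tryCatch({
    coarse <- segmentProfile(p, build, segmentationParams(
      nPerm = 20L, seed = params$segmentation@seed), merge = FALSE)
    qa <- assessQuality(p, build, np = np, coarse = coarse,
                        thresholds = params$quality)
    sp <- segmentProfile(p, build, params$segmentation, np = np,
                         quality = qa)
    f <- computeGenomicFeatures(sp, build, params$classifier)
    ci <- if (reruns)
      rerunConfidence(p, build, params$segmentation, np = np,
                      quality = qa@integrative,
                      lgaDelta = params$classifier@softDelta) else NULL
    call <- callHrd(f, qa, ci = ci, config = params$classifier)
    list(call = call, f = f, sp = sp, p = p)
  }, nonContributiveError = function(e) {
    qa <- new("QualityAssessment", tumorContentCat = 4L,
              intrinsicNoiseCat = 3L, ffpeNoiseCat = 4L,
              integrative = "low", metrics = list(),
              warnings = conditionMessage(e))
    call <- new("HrdCall", status = "ND", pathway = "non_contributive",
                scoreFinal = NA_real_, quality = qa, scores = list(),
                ci = NULL, warnings = conditionMessage(e),
                audit = paste("non-contributive input:",
                              conditionMessage(e)))
    list(call = call, f = NULL, sp = NULL, p = p)
  })
  rep <- hrdReportList(outcome$call, outcome$f, sampleId(p), params)
  jsonlite::write_json(rep, file.path(cfg$outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeTextReport(rep, file.path(cfg$outDir, "report.txt"))
  if (!is.null(outcome$sp)) {
    writeSegments(outcome$sp, file.path(cfg$outDir, "segments.bed"))
    ci <- outcome$call@ci
    if (!is.null(ci))
      utils::write.table(
        data.frame(run = seq_along(ci@runs) - 1L, lga = ci@runs),
        file.path(cfg$outDir, "lga_runs.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
    bdf <- validBinTable(outcome$p)
    res <- residualsOnBins(outcome$sp, bdf)
    utils::write.table(
      data.frame(chrom = bdf$chrom, start = bdf$start - 1L, end = bdf$end,
                 ratio = sprintf("%.4f", bdf$ratio),
                 segment_level = sprintf("%.4f", bdf$ratio - res),
                 residual = sprintf("%.4f", res)),
      file.path(cfg$outDir, "tracks.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  invisible(outcome$call)
}

#' Concordance metrics for one or more 3x3 tables
#'
#' @param tables named character vector / list of CSV paths, or
#'   [ContingencyTable-class] objects.
#' @param out optional JSON output path.
#' @return named list of [concordanceMetrics()] results.
#' @export
runConcordance <- function(tables, out = NULL) {
  if (is.character(tables)) {
    nm <- names(tables)
    tables <- as.list(tables)
    names(tables) <- if (is.null(nm))
      tools::file_path_sans_ext(basename(unlist(tables))) else nm
  }
  if (is.null(names(tables)))
    names(tables) <- paste0("table", seq_along(tables))
  res <- lapply(tables, function(t) {
    if (is.character(t)) t <- readContingencyTable(t)
    concordanceMetrics(t)
  })
  if (!is.null(out))
    jsonlite::write_json(res, out, auto_unbox = TRUE, digits = NA)
  res
}

#' Simulate a profile (and optionally a normal panel) to disk
#'
#' Writes the simulated profile in the generic TSV dialect together with a
#' ground-truth JSON (true segments, true LGA count, planted flags).
#' Byte-identical outputs under a fixed seed.
#'
#' @param cfg a [SimulationConfig-class] or a list of
#'   [simulationConfig()] arguments.
#' @param build a [GenomeBuild-class] or build name.
#' @param outDir output directory.
#' @return list with the written \code{profile} and \code{truth} paths.
#' @export
runSimulate <- function(cfg, build = "hg19", outDir = ".") {
  if (is.list(cfg)) cfg <- do.call(simulationConfig, cfg)
  stopifnot(is(cfg, "SimulationConfig"))
  if (is.character(build)) build <- loadGenomeBuild(build)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateTumorProfile(cfg, build)
  profilePath <- file.path(outDir, sprintf("%s.tsv", sampleId(sim$profile)))
  writeBinnedProfile(sim$profile, profilePath)
  ts <- sim$truth@trueSegments@segments
  truthPath <- file.path(outDir, sprintf("%s_truth.json",
                                         sampleId(sim$profile)))
  jsonlite::write_json(
    list(true_lga_count = sim$truth@trueLgaCount,
         planted = sim$truth@plantedFlags,
         true_segments = data.frame(
           chrom = as.character(seqnames(ts)), start = start(ts) - 1L,
           end = end(ts), arm = mcols(ts)$arm,
           cn_level = mcols(ts)$cnLevel)),
    truthPath, auto_unbox = TRUE, digits = NA)
  list(profile = profilePath, truth = truthPath)
}
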