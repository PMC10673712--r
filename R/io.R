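#' @include AllClasses.R genome.R
NULL

# All on-disk coordinates are 0-based half-open (BED convention); GRanges
# objects in memory are 1-based closed as usual. Conversion happens only at
# the I/O boundary.

#' Construct a bin-level profile from a bins table
#'
#' @param df data.frame with columns \code{chrom}, \code{start} (0-based),
#'   \code{end}, \code{ratio} and optionally \code{valid}.
#' @param build a [GenomeBuild-class] used to canonicalize chromosome names
#'   and assign arms.
#' @param sampleId sample identifier.
#' @param binSize nominal bin size; inferred from the modal start-to-start
#'   distance when NULL.
#' @param metadata provenance list.
#' @return a [BinnedProfile-class].
#' @export
binnedProfile <- function(df, build, sampleId = "sample", binSize = NULL,
                          metadata = list()) {
  need <- c("chrom", "start", "end", "ratio")
  if (!all(need %in% names(df)))
    stop("bins table must have columns ", paste(need, collapse = ", "))
  if (nrow(df) == 0) stop("empty bins table")
  chrom <- canonChrom(df$chrom)
  if (!all(unique(chrom) %in% build@chromosomes$chrom)) {
    unknown <- setdiff(unique(chrom), build@chromosomes$chrom)
    warning("dropping bins on chromosomes absent from the build: ",
            paste(unknown, collapse = ", "))
    keep <- chrom %in% build@chromosomes$chrom
    df <- df[keep, , drop = FALSE]
    chrom <- chrom[keep]
  }
  if (nrow(df) == 0) stop("no bins left on build chromosomes")
  valid <- if ("valid" %in% names(df)) as.logical(df$valid) else
    !is.na(df$ratio) & df$ratio >= 0
  valid[is.na(df$ratio) | df$ratio < 0] <- FALSE
  gr <- GRanges(chrom, IRanges(df$start + 1L, df$end),
                seqinfo = buildSeqinfo(build@chromosomes, build@buildName))
  ord <- order(as.integer(seqnames(gr)), start(gr))
  gr <- gr[ord]
  ratio <- df$ratio[ord]
  valid <- valid[ord]
  dup <- duplicated(paste(seqnames(gr), start(gr)))
  if (any(dup)) stop("duplicate bins at the same position")
  if (is.null(binSize)) {
    d <- unlist(lapply(split(start(gr), as.character(seqnames(gr))), diff))
    binSize <- if (length(d)) as.numeric(names(sort(table(d),
                                                    decreasing = TRUE))[1])
               else width(gr)[1]
  }
  mcols(gr)$ratio <- as.numeric(ratio)
  mcols(gr)$valid <- valid
  mcols(gr)$arm <- assignArms(gr, build)
  new("BinnedProfile", sampleId = as.character(sampleId), bins = gr,
      binSize = binSize, metadata = metadata)
}

#' Read a bin-level copy-number ratio profile
#'
#' Two dialects are supported. \code{"controlfreec_ratio"} is the
#' tab-separated ratio output of ControlFREEC (columns \code{Chromosome},
#' \code{Start}, \code{Ratio}, \code{MedianRatio}, \code{CopyNumber};
#' \code{Start} is the 1-based bin start, bin ends are implied by the grid,
#' and \code{Ratio == -1} marks invalid bins). \code{"generic_tsv"} has
#' columns \code{chrom}, \code{start}, \code{end}, \code{ratio}
#' (0-based half-open) plus optional \code{gc} and \code{reads} columns,
#' which are carried through in the profile metadata for GC correction.
#' Chromosome names are canonicalized to the build's convention; a warning
#' is emitted when the file mixes conventions.
#'
#' @param path input file.
#' @param build a [GenomeBuild-class].
#' @param dialect "generic_tsv" or "controlfreec_ratio".
#' @param sampleId sample identifier; defaults to the file base name.
#' @return a [BinnedProfile-class].
#' @export
readBinnedProfile <- function(path, build,
                              dialect = c("generic_tsv", "controlfreec_ratio"),
                              sampleId = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sampleId))
    sampleId <- sub("(_ratio)?\\.(txt|tsv)$", "", basename(path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (nrow(tab) == 0) stop("empty profile file: ", path)
  rawChrom <- if (dialect == "generic_tsv") tab$chrom else tab$Chromosome
  hasPrefix <- grepl("^chr", rawChrom)
  if (any(hasPrefix) && !all(hasPrefix))
    warning("mixed chromosome naming in ", basename(path),
            "; canonicalized to the build's convention")
  if (dialect == "controlfreec_ratio") {
    need <- c("Chromosome", "Start", "Ratio", "MedianRatio", "CopyNumber")
    if (!all(need %in% names(tab)))
      stop("not a ControlFREEC ratio file: missing ",
           paste(setdiff(need, names(tab)), collapse = ", "))
    starts <- as.numeric(tab$Start)
    d <- unlist(lapply(split(starts, tab$Chromosome),
                       function(s) diff(sort(s))))
    bs <- if (length(d)) as.numeric(names(sort(table(d),
                                               decreasing = TRUE))[1])
          else 5e4
    df <- data.frame(chrom = tab$Chromosome,
                     start = starts - 1,       # 1-based -> 0-based
                     end = starts - 1 + bs,
                     ratio = as.numeric(tab$Ratio),
                     valid = as.numeric(tab$Ratio) != -1,
                     stringsAsFactors = FALSE)
    md <- list(source = path, dialect = dialect,
               medianRatio = as.numeric(tab$MedianRatio),
               copyNumber = as.numeric(tab$CopyNumber))
    binnedProfile(df, build, sampleId, binSize = bs, metadata = md)
  } else {
    need <- c("chrom", "start", "end", "ratio")
    if (!all(need %in% names(tab)))
      stop("generic profile needs columns ", paste(need, collapse = ", "))
    md <- list(source = path, dialect = dialect)
    if ("gc" %in% names(tab)) md$gc <- as.numeric(tab$gc)
    if ("reads" %in% names(tab)) md$reads <- as.numeric(tab$reads)
    binnedProfile(tab[need], build, sampleId, metadata = md)
  }
}

#' Write a bin-level profile as generic TSV
#'
#' @param p a [BinnedProfile-class].
#' @param path output path (0-based half-open coordinates).
#' @export
writeBinnedProfile <- function(p, path) {
  stopifnot(is(p, "BinnedProfile"))
  b <- p@bins
  df <- data.frame(chrom = as.character(seqnames(b)), start = start(b) - 1L,
                   end = end(b), ratio = sprintf("%.6f", mcols(b)$ratio),
                   valid = as.integer(mcols(b)$valid))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# internal constructor from a segments data.frame
# (chrom, arm, start [1-based], end, cnLevel, nBins)
newSegmentedProfile <- function(df, build, sampleId, residuals = numeric(0),
                                runSeed = 0L) {
  gr <- GRanges(df$chrom, IRanges(df$start, df$end),
                seqinfo = buildSeqinfo(build@chromosomes, build@buildName))
  mcols(gr)$arm <- df$arm
  mcols(gr)$cnLevel <- df$cnLevel
  mcols(gr)$nBins <- as.integer(df$nBins)
  sz <- width(gr) / 1e6
  mcols(gr)$sizeMb <- sz
  mcols(gr)$roundedSizeMb <- as.integer(floor(sz + 0.5))
  ord <- order(as.integer(seqnames(gr)), start(gr))
  new("SegmentedProfile", sampleId = as.character(sampleId),
      segments = gr[ord], residuals = residuals,
      runSeed = as.integer(runSeed))
}

#' Write segments as BED-like TSV
#'
#' Columns: \code{chrom}, \code{start}, \code{end} (0-based half-open),
#' \code{cn_level}, \code{n_bins}, \code{arm}. Round-trips through
#' [readSegments()] exactly (coordinates, levels to 6 decimals).
#'
#' @param sp a [SegmentedProfile-class].
#' @param path output path.
#' @export
writeSegments <- function(sp, path) {
  stopifnot(is(sp, "SegmentedProfile"))
  s <- sp@segments
  df <- data.frame(chrom = as.character(seqnames(s)), start = start(s) - 1L,
                   end = end(s), cn_level = sprintf("%.6f", mcols(s)$cnLevel),
                   n_bins = mcols(s)$nBins, arm = mcols(s)$arm)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read segments written by [writeSegments()]
#'
#' @param path segments TSV.
#' @param build a [GenomeBuild-class].
#' @param sampleId sample identifier.
#' @return a [SegmentedProfile-class] (without residual track).
#' @export
readSegments <- function(path, build, sampleId = "sample") {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "cn_level", "n_bins", "arm")
  if (!all(need %in% names(tab)))
    stop("segments file needs columns ", paste(need, collapse = ", "))
  if (nrow(tab) == 0) {
    gr <- GRanges(seqinfo = buildSeqinfo(build@chromosomes, build@buildName))
    mcols(gr)$arm <- character(0); mcols(gr)$cnLevel <- numeric(0)
    mcols(gr)$nBins <- integer(0); mcols(gr)$sizeMb <- numeric(0)
    mcols(gr)$roundedSizeMb <- integer(0)
    return(new("SegmentedProfile", sampleId = sampleId, segments = gr,
               residuals = numeric(0), runSeed = 0L))
  }
  newSegmentedProfile(
    data.frame(chrom = canonChrom(tab$chrom), arm = tab$arm,
               start = tab$start + 1L, end = tab$end,
               cnLevel = as.numeric(tab$cn_level), nBins = tab$n_bins),
    build, sampleId)
}

#' Write / read an FFPE noise profile
#'
#' Serialized as a generic TSV (chrom, start, end, expected_dev,
#' dispersion) with a JSON sidecar (\code{<path>.json}) recording the panel
#' size, build and bin size.
#'
#' @param np a [NoiseProfile-class].
#' @param path output TSV path.
#' @param build a [GenomeBuild-class].
#' @name noiseProfileIO
#' @export
writeNoiseProfile <- function(np, path, build = NULL) {
  stopifnot(is(np, "NoiseProfile"))
  b <- np@bins
  df <- data.frame(chrom = as.character(seqnames(b)), start = start(b) - 1L,
                   end = end(b),
                   expected_dev = sprintf("%.6f", mcols(b)$expectedDev),
                   dispersion = sprintf("%.6f", mcols(b)$dispersion))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(panel_size = np@panelSize,
               build = if (is.null(build)) NA else build@buildName,
               n_bins = length(b))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname noiseProfileIO
#' @export
readNoiseProfile <- function(path, build) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "expected_dev", "dispersion")
  if (!all(need %in% names(tab)))
    stop("noise profile needs columns ", paste(need, collapse = ", "))
  gr <- GRanges(canonChrom(tab$chrom), IRanges(tab$start + 1L, tab$end),
                seqinfo = buildSeqinfo(build@chromosomes, build@buildName))
  mcols(gr)$expectedDev <- as.numeric(tab$expected_dev)
  mcols(gr)$dispersion <- as.numeric(tab$dispersion)
  panel <- 1L
  side <- paste0(path, ".json")
  if (file.exists(side))
    panel <- as.integer(jsonlite::read_json(side)$panel_size)
  new("NoiseProfile", bins = sort(gr), panelSize = panel)
}

#' Construct a 3x3 contingency table
#'
#' @param counts 3x3 matrix, rows = reference test, columns = index test.
#' @param labels category names, default Positive/Negative/NC.
#' @return a [ContingencyTable-class].
#' @export
contingencyTable <- function(counts,
                             labels = c("Positive", "Negative", "NC")) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "numeric"
  new("ContingencyTable", labels = labels, counts = counts)
}

#' Read a 3x3 contingency table from CSV
#'
#' Expected layout: a header row with the index-test categories and a
#' leading label column with the reference-test categories.
#'
#' @param path CSV path.
#' @return a [ContingencyTable-class].
#' @export
readContingencyTable <- function(path) {
  tab <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  if (nrow(tab) != 3 || ncol(tab) != 3)
    stop("expected a 3x3 table in ", path)
  contingencyTable(as.matrix(tab), labels = colnames(tab))
}
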