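#' @include AllClasses.R
NULL

# canonicalize chromosome names to the build's convention ("chr" prefix)
canonChrom <- function(x, prefix = TRUE) {
  x <- sub("^chr", "", as.character(x))
  x[x == "23"] <- "X"
  x[x == "24"] <- "Y"
  if (prefix) paste0("chr", x) else x
}

buildSeqinfo <- function(chromosomes, buildName = NA_character_) {
  Seqinfo(seqnames = chromosomes$chrom,
          seqlengths = as.integer(chromosomes$length),
          genome = buildName)
}

armRanges <- function(chromosomes, buildName) {
  si <- buildSeqinfo(chromosomes, buildName)
  p <- GRanges(chromosomes$chrom,
               IRanges(start = 1L, end = as.integer(chromosomes$cen_start)),
               arm = "p", seqinfo = si)
  q <- GRanges(chromosomes$chrom,
               IRanges(start = as.integer(chromosomes$cen_end) + 1L,
                       end = as.integer(chromosomes$length)),
               arm = "q", seqinfo = si)
  gr <- c(p, q)
  gr <- gr[width(gr) > 1L]
  sort(gr)
}

#' Load a genome build
#'
#' Returns the genomic context (chromosomes, p/q arm boundaries, gene loci)
#' used throughout the pipeline. The bundled \code{"hg19"} build covers the
#' 22 autosomes plus X (Y is excluded from scoring), with centromere
#' intervals derived from the UCSC cytoband track and locus windows for
#' CCNE1 and ERBB2. A custom build is loaded from a TSV with columns
#' \code{chrom}, \code{length}, \code{cen_start}, \code{cen_end}, plus an
#' optional companion loci TSV (\code{name}, \code{chrom}, \code{start},
#' \code{end}).
#'
#' @param name build name (\code{"hg19"}) or path to an arm-definition TSV.
#' @param lociPath optional path to a loci TSV; defaults to the bundled
#'   hg19 loci when \code{name == "hg19"}.
#' @return a [GenomeBuild-class].
#' @examples
#' build <- loadGenomeBuild("hg19")
#' build
#' @export
loadGenomeBuild <- function(name = "hg19", lociPath = NULL) {
  if (identical(name, "hg19")) {
    path <- system.file("extdata", "hg19_arms.tsv", package = "swgsHRD",
                        mustWork = TRUE)
    if (is.null(lociPath))
      lociPath <- system.file("extdata", "hg19_loci.tsv",
                              package = "swgsHRD", mustWork = TRUE)
    buildName <- "hg19"
  } else if (file.exists(name)) {
    path <- name
    buildName <- tools::file_path_sans_ext(basename(name))
  } else {
    stop("unknown genome build '", name,
         "' (not 'hg19' and not an existing file)")
  }
  ch <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "length", "cen_start", "cen_end")
  if (!all(need %in% names(ch)))
    stop("malformed build definition: need columns ",
         paste(need, collapse = ", "))
  ch$chrom <- canonChrom(ch$chrom)
  loci <- GRanges(seqinfo = buildSeqinfo(ch, buildName))
  mcols(loci)$name <- character(0)
  if (!is.null(lociPath) && nzchar(lociPath)) {
    lt <- utils::read.delim(lociPath, stringsAsFactors = FALSE)
    if (!all(c("name", "chrom", "start", "end") %in% names(lt)))
      stop("malformed loci file: need columns name, chrom, start, end")
    lt$chrom <- canonChrom(lt$chrom)
    if (!all(lt$chrom %in% ch$chrom))
      stop("locus on chromosome absent from the build")
    chLen <- ch$length[match(lt$chrom, ch$chrom)]
    if (any(lt$end > chLen | lt$start < 0))
      stop("locus window extends beyond its chromosome")
    loci <- GRanges(lt$chrom, IRanges(lt$start + 1L, lt$end),
                    name = lt$name, seqinfo = buildSeqinfo(ch, buildName))
  }
  new("GenomeBuild", buildName = buildName, chromosomes = ch,
      arms = armRanges(ch, buildName), loci = loci)
}

#' Tile a genome build into an arm-confined bin grid
#'
#' Each chromosome arm is tiled with consecutive bins of \code{binSize} bp;
#' the arm-terminal bin may be shorter. No bin straddles a centromere:
#' bins are confined to single arms by construction, so every base of every
#' arm is covered exactly once and the centromere gap carries no bins.
#'
#' @param build a [GenomeBuild-class].
#' @param binSize bin width in bp (default 50 kb).
#' @return \code{GRanges} with metadata column \code{arm}.
#' @export
binGrid <- function(build, binSize = 5e4) {
  stopifnot(is(build, "GenomeBuild"), binSize >= 1)
  key <- paste(build@buildName, nrow(build@chromosomes), binSize)
  cached <- .gridCache[[key]]
  if (!is.null(cached)) return(cached)
  arms <- build@arms
  nb <- ceiling(width(arms) / binSize)
  armIdx <- rep(seq_along(arms), nb)
  off <- unlist(lapply(nb, function(k) seq_len(k) - 1L)) * binSize
  s <- start(arms)[armIdx] + off
  e <- pmin(s + binSize - 1, end(arms)[armIdx])
  gr <- GRanges(seqnames(arms)[armIdx], IRanges(s, e),
                arm = mcols(arms)$arm[armIdx],
                seqinfo = GenomeInfoDb::seqinfo(arms))
  gr <- sort(gr)
  .gridCache[[key]] <- gr
  gr
}

.gridCache <- new.env(parent = emptyenv())

# assign an arm label to arbitrary bins: a bin gets an arm only when fully
# contained in it; centromere-straddling bins get NA and are dropped from
# segmentation downstream
assignArms <- function(gr, build) {
  arms <- build@arms
  hit <- findOverlaps(gr, arms, type = "within")
  arm <- rep(NA_character_, length(gr))
  arm[queryHits(hit)] <- mcols(arms)$arm[subjectHits(hit)]
  arm
}
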