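test_that("bundled hg19 build has 23 chromosomes with arm boundaries and loci", {
  build <- loadGenomeBuild("hg19")
  expect_s4_class(build, "GenomeBuild")
  expect_equal(nrow(build@chromosomes), 23)          # 22 autosomes + X
  expect_equal(sum(table(build@chromosomes$chrom) == 1), 23)
  # one centromere boundary per chromosome, two arms each
  expect_equal(length(build@arms), 46)
  expect_setequal(unique(S4Vectors::mcols(build@arms)$arm), c("p", "q"))
  expect_setequal(S4Vectors::mcols(build@loci)$name, c("CCNE1", "ERBB2"))
})

test_that("custom builds are read back and invalid loci rejected", {
  build <- toyBuild()
  expect_equal(nrow(build@chromosomes), 3)
  expect_equal(build@chromosomes$length[1], 2e8)
  badLoci <- file.path(tempdir(), "bad_loci.tsv")
  writeLines(c("name\tchrom\tstart\tend",
               "CCNE1\tchr1\t190000000\t210000000"), badLoci)
  armsPath <- file.path(tempdir(), "toy_arms.tsv")
  expect_error(loadGenomeBuild(armsPath, badLoci), "beyond its chromosome")
  expect_error(loadGenomeBuild("hg99"), "unknown genome build")
})

test_that("bin grid tiles every arm base exactly once and respects centromeres", {
  build <- toyBuild()
  grid <- binGrid(build, 1e6)
  expect_equal(sum(BiocGenerics::width(grid)),
               sum(BiocGenerics::width(build@arms)))
  expect_false(any(duplicated(paste(GenomicRanges::seqnames(grid),
                                    BiocGenerics::start(grid)))))
  # every bin fully inside one arm, none straddles a centromere
  expect_false(anyNA(swgsHRD:::assignArms(grid, build)))
  cen <- GenomicRanges::GRanges(
    build@chromosomes$chrom,
    IRanges::IRanges(build@chromosomes$cen_start + 1,
                     build@chromosomes$cen_end))
  expect_equal(sum(IRanges::overlapsAny(grid, cen)), 0)
})

test_that("generic TSV profiles read back with inferred bin size", {
  build <- toyBuild()
  path <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tratio",
               "chr1\t0\t50000\t1.00",
               "chr1\t50000\t100000\t1.10",
               "chr1\t100000\t150000\t0.90"), path)
  p <- readBinnedProfile(path, build, "generic_tsv")
  expect_equal(length(bins(p)), 3)
  expect_equal(binSize(p), 5e4)
  expect_equal(S4Vectors::mcols(bins(p))$ratio, c(1.0, 1.1, 0.9))
})

test_that("ControlFREEC dialect flags ratio -1 bins invalid", {
  build <- toyBuild()
  path <- tempfile(fileext = "_ratio.txt")
  writeLines(c("Chromosome\tStart\tRatio\tMedianRatio\tCopyNumber",
               "1\t1\t1.02\t1.0\t2",
               "1\t50001\t-1\t-1\t-1",
               "1\t100001\t0.98\t1.0\t2",
               "1\t150001\t1.51\t1.5\t3",
               "1\t200001\t1.49\t1.5\t3"), path)
  p <- readBinnedProfile(path, build, "controlfreec_ratio")
  expect_equal(length(bins(p)), 5)
  expect_equal(S4Vectors::mcols(bins(p))$valid,
               c(TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(binSize(p), 5e4)
  # 1-based ControlFREEC starts land on the same grid as 0-based generic
  expect_equal(BiocGenerics::start(bins(p))[1], 1)
})

test_that("mixed chromosome naming is canonicalized with a warning", {
  build <- toyBuild()
  path <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tratio",
               "chr1\t0\t50000\t1.0",
               "2\t0\t50000\t1.0"), path)
  expect_warning(p <- readBinnedProfile(path, build, "generic_tsv"),
                 "mixed chromosome naming")
  expect_setequal(as.character(GenomicRanges::seqnames(bins(p))),
                  c("chr1", "chr2"))
})

test_that("segments round-trip through the BED-like TSV exactly", {
  build <- toyBuild()
  sp <- segProfile(build, data.frame(
    chrom = c("chr1", "chr1", "chr2"), arm = c("p", "p", "q"),
    startMb = c(0, 50, 64), endMb = c(50, 100, 150),
    level = c(1.234567, 0.8, 1.5)))
  path <- tempfile(fileext = ".bed")
  writeSegments(sp, path)
  lines <- readLines(path)
  expect_length(lines, 4)                 # header + 3 rows
  back <- readSegments(path, build, sampleId(sp))
  expect_equal(BiocGenerics::start(segments(back)),
               BiocGenerics::start(segments(sp)))
  expect_equal(BiocGenerics::end(segments(back)),
               BiocGenerics::end(segments(sp)))
  expect_equal(S4Vectors::mcols(segments(back))$cnLevel,
               S4Vectors::mcols(segments(sp))$cnLevel, tolerance = 1e-6)
  expect_equal(S4Vectors::mcols(segments(back))$roundedSizeMb,
               S4Vectors::mcols(segments(sp))$roundedSizeMb)
})

test_that("an empty segmented profile writes a header-only file", {
  build <- toyBuild()
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr)$arm <- character(0)
  S4Vectors::mcols(gr)$cnLevel <- numeric(0)
  S4Vectors::mcols(gr)$nBins <- integer(0)
  S4Vectors::mcols(gr)$sizeMb <- numeric(0)
  S4Vectors::mcols(gr)$roundedSizeMb <- integer(0)
  sp <- new("SegmentedProfile", sampleId = "empty", segments = gr,
            residuals = numeric(0), runSeed = 0L)
  path <- tempfile(fileext = ".bed")
  writeSegments(sp, path)
  expect_length(readLines(path), 1)
  expect_equal(length(segments(readSegments(path, build))), 0)
})

test_that("bin profiles round-trip through the generic TSV", {
  build <- toyBuild()
  sim <- simulateTumorProfile(toyConfig(seed = 3, nLga = 2,
                                        binNoiseSd = 0.1), toyBuild())
  path <- tempfile(fileext = ".tsv")
  writeBinnedProfile(sim$profile, path)
  back <- readBinnedProfile(path, build, "generic_tsv")
  expect_equal(length(bins(back)), length(bins(sim$profile)))
  expect_equal(S4Vectors::mcols(bins(back))$ratio,
               S4Vectors::mcols(bins(sim$profile))$ratio,
               tolerance = 1e-6)
  expect_equal(BiocGenerics::start(bins(back)),
               BiocGenerics::start(bins(sim$profile)))
})
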