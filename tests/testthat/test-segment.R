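test_that("flat noise-free profiles segment into one segment per arm", {
  build <- toyBuild()
  sim <- simulateTumorProfile(toyConfig(seed = 1, binNoiseSd = 0), build)
  sp <- segmentProfile(sim$profile, build)
  expect_equal(length(segments(sp)), 6)   # 3 chromosomes x 2 arms
  expect_true(all(S4Vectors::mcols(segments(sp))$cnLevel == 1))
  expect_equal(sum(abs(residuals(sp))), 0)
})

test_that("noise-free breakpoints are exact and match the exhaustive oracle", {
  x <- c(rep(1, 25), rep(1.5, 18), rep(0.8, 17))
  expect_equal(cbsSegment(x), c(25L, 43L))
  expect_equal(cbsSegment(x), lsOracle(x))
  set.seed(99)
  for (i in 1:20) {
    k <- sample(0:3, 1)
    n <- sample(30:60, 1)
    pw <- randomPiecewise(n, k)
    expect_equal(cbsSegment(pw$x), pw$breaks)
    expect_equal(cbsSegment(pw$x), lsOracle(pw$x))
  }
})

test_that("small-segment filtering matches brute-force smallest-first removal", {
  build <- toyBuild()
  # a 1 Mb spike between equal levels dissolves into a single segment
  spike <- segProfile(build, data.frame(
    chrom = "chr1", arm = "p", startMb = c(0, 40, 41),
    endMb = c(40, 41, 100), level = c(1, 2, 1)))
  out <- filterSmallSegments(spike, build, 3)
  expect_equal(length(segments(out)), 1)
  # alternating chain of sub-floor spikes collapses to one segment
  chain <- segProfile(build, data.frame(
    chrom = "chr1", arm = "p",
    startMb = c(0, 30, 31, 32, 33, 34), endMb = c(30, 31, 32, 33, 34, 100),
    level = c(1, 1.6, 1, 1.7, 1, 1)))
  expect_equal(length(segments(filterSmallSegments(chain, build, 3))), 1)
  # nothing below the floor: identity
  ok <- segProfile(build, data.frame(
    chrom = "chr1", arm = "p", startMb = c(0, 50), endMb = c(50, 100),
    level = c(1, 1.5)))
  expect_equal(length(segments(filterSmallSegments(ok, build, 3))), 2)
  # randomized comparison against an independent implementation
  set.seed(7)
  for (i in 1:15) {
    nseg <- sample(3:8, 1)
    sizes <- round(runif(nseg, 0.5, 12), 2)
    levels <- round(runif(nseg, 0.8, 2.5), 3)
    bounds <- cumsum(c(0, sizes))
    spec <- data.frame(chrom = "chr1", arm = "p",
                       startMb = bounds[-length(bounds)], endMb = bounds[-1],
                       level = levels)
    sp <- segProfile(build, spec)
    got <- segments(filterSmallSegments(sp, build, 3))
    ref <- bruteSmallFilter(sizes, levels,
                            S4Vectors::mcols(segments(sp))$nBins, 3)
    expect_equal(S4Vectors::mcols(got)$cnLevel, ref$levels,
                 tolerance = 1e-9)
  }
})

test_that("level merging respects the delta and smallest-difference order", {
  build <- toyBuild()
  sp <- segProfile(build, data.frame(
    chrom = "chr1", arm = "p", startMb = c(0, 30, 60),
    endMb = c(30, 60, 100), level = c(1, 1, 1.5)))
  out <- mergeSegments(sp, build, segmentationParams())
  expect_equal(length(segments(out)), 2)  # the identical pair merged
  apart <- segProfile(build, data.frame(
    chrom = "chr1", arm = "p", startMb = c(0, 50), endMb = c(50, 100),
    level = c(1, 1.25)))
  expect_equal(length(segments(mergeSegments(apart, build,
                                             segmentationParams()))), 2)
  close <- segProfile(build, data.frame(
    chrom = "chr1", arm = "p", startMb = c(0, 50), endMb = c(50, 100),
    level = c(1, 1.05)))
  expect_equal(length(segments(mergeSegments(close, build,
                                             segmentationParams()))), 1)
})

test_that("wave pseudo-segments merge away against the noise profile, real breaks stay", {
  build <- toyBuild()
  cfg <- toyConfig(seed = 22, nLga = 4, tumorFraction = 0.9,
                   binNoiseSd = 0.05, ffpeWaveAmplitude = 0.12)
  np <- buildFfpeNoiseProfile(simulateNormalPanel(50, cfg, build))
  sim <- simulateTumorProfile(cfg, build)
  raw <- segmentProfile(sim$profile, build, merge = FALSE)
  denoised <- segmentProfile(sim$profile, build, np = np)
  noNp <- segmentProfile(sim$profile, build)
  expect_lte(length(segments(denoised)), length(segments(noNp)))
  expect_lt(length(segments(denoised)), length(segments(raw)))
  expect_lte(abs(countLga(denoised) - sim$truth@trueLgaCount), 1)
})

test_that("segmentation is deterministic per seed and residual RSS is zero noise-free", {
  build <- toyBuild()
  sim <- simulateTumorProfile(toyConfig(seed = 23, nLga = 6,
                                        binNoiseSd = 0.15), build)
  a <- segmentProfile(sim$profile, build, segmentationParams(seed = 5L))
  b <- segmentProfile(sim$profile, build, segmentationParams(seed = 5L))
  expect_identical(BiocGenerics::start(segments(a)),
                   BiocGenerics::start(segments(b)))
  expect_identical(S4Vectors::mcols(segments(a))$cnLevel,
                   S4Vectors::mcols(segments(b))$cnLevel)
  clean <- simulateTumorProfile(toyConfig(seed = 23, nLga = 6,
                                          binNoiseSd = 0), build)
  spClean <- segmentProfile(clean$profile, build)
  # merging on noise-free input cannot increase the residual sum of squares
  expect_equal(sum(residuals(spClean)^2), 0)
  expect_equal(countLga(spClean), clean$truth@trueLgaCount)
})

test_that("rerun confidence intervals bracket the point estimate", {
  build <- toyBuild()
  clean <- simulateTumorProfile(toyConfig(seed = 30, nLga = 5,
                                          binNoiseSd = 0), build)
  ciClean <- rerunConfidence(clean$profile, build,
                             segmentationParams(nReruns = 10L))
  expect_equal(ciClean@low, ciClean@high)     # width 0 without noise
  expect_equal(ciClean@point, clean$truth@trueLgaCount)
  noisy <- simulateTumorProfile(toyConfig(seed = 30, nLga = 5,
                                          tumorFraction = 0.35,
                                          binNoiseSd = 0.25), build)
  ci <- rerunConfidence(noisy$profile, build,
                        segmentationParams(nReruns = 10L))
  expect_lte(ci@low, ci@point)
  expect_gte(ci@high, ci@point)
  expect_length(ci@runs, 10)
})

test_that("profiles with too few usable bins are signalled non-contributive", {
  build <- toyBuild()
  sim <- simulateTumorProfile(toyConfig(seed = 2), build)
  small <- sim$profile
  small@bins <- bins(small)[1:500]
  expect_error(segmentProfile(small, build), class = "nonContributiveError")
})
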