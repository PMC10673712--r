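test_that("CN-level clustering weighs levels by genome length", {
  build <- toyBuild()
  one <- segProfile(build, data.frame(chrom = "chr1", arm = "p",
                                      startMb = 0, endMb = 100, level = 1))
  expect_equal(unname(clusterCnLevels(one)), 1)
  two <- segProfile(build, data.frame(
    chrom = c("chr1", "chr1"), arm = c("p", "p"),
    startMb = c(0, 60), endMb = c(60, 100), level = c(1, 1.5)))
  expect_equal(unname(clusterCnLevels(two)), c(0.6, 0.4))
  # simulated four-level genome recovers the planted levels
  sim <- simulateTumorProfile(toyConfig(seed = 41, nLga = 8,
                                        tumorFraction = 1,
                                        binNoiseSd = 0.05), toyBuild())
  sp <- segmentProfile(sim$profile, toyBuild())
  w <- clusterCnLevels(sp)
  trueLevels <- sort(unique(
    S4Vectors::mcols(segments(sim$truth@trueSegments))$cnLevel))
  centers <- sort(as.numeric(names(w)))[seq_along(trueLevels)]
  for (tl in trueLevels)
    expect_lt(min(abs(as.numeric(names(w)) - tl)), 0.05)
})

test_that("genome complexity rule and its boundaries", {
  expect_equal(classifyGenomeComplexity(c(0.5, 0.3, 0.2)), "simple")
  expect_equal(classifyGenomeComplexity(c(0.25, 0.25, 0.25, 0.25)),
               "complex_plus")
  expect_equal(classifyGenomeComplexity(c(0.4, 0.25, 0.2, 0.15)), "complex")
  # exactly 70% is not "more than 70%"
  expect_equal(classifyGenomeComplexity(c(0.4, 0.3, 0.15, 0.15)), "complex")
  expect_equal(classifyGenomeComplexity(c(0.40, 0.31, 0.29)), "simple")
  expect_equal(classifyGenomeComplexity(c(0.31, 0.25, 0.22, 0.22)),
               "complex_plus")
  expect_equal(classifyGenomeComplexity(c(0.32, 0.25, 0.22, 0.16)),
               "complex")  # w1 - w4 > 0.15
  expect_error(classifyGenomeComplexity(numeric(0)), "empty")
})

test_that("LGA size semantics: rounding decides the 10 Mb flank rule", {
  build <- toyBuild()
  mk <- function(flankMb)
    segProfile(build, data.frame(
      chrom = "chr1", arm = "p", startMb = c(0, flankMb),
      endMb = c(flankMb, flankMb + 50), level = c(1, 1.5)))
  expect_equal(countLga(mk(9.4)), 0)   # rounds to 9
  expect_equal(countLga(mk(9.6)), 1)   # rounds to 10
  expect_equal(countLga(mk(40)), 1)
  # a break across the centromere never counts
  cen <- segProfile(build, data.frame(
    chrom = c("chr1", "chr1"), arm = c("p", "q"),
    startMb = c(0, 104), endMb = c(100, 200), level = c(1, 1.6)))
  expect_equal(countLga(cen), 0)
  # threshold semantics on the level difference
  d <- segProfile(build, data.frame(
    chrom = "chr1", arm = "p", startMb = c(0, 50), endMb = c(50, 100),
    level = c(1, 1.15)))
  expect_equal(countLga(d, 0.10), 1)
  expect_equal(countLga(d, 0.20), 0)
})

test_that("stringent LGA count never exceeds the soft count on simulated draws", {
  build <- toyBuild()
  for (s in 1:10) {
    sim <- simulateTumorProfile(
      toyConfig(seed = 200 + s, nLga = sample(0:10, 1),
                tumorFraction = runif(1, 0.3, 1),
                binNoiseSd = runif(1, 0.05, 0.25)), build)
    sp <- segmentProfile(sim$profile, build)
    expect_lte(countLga(sp, 0.20), countLga(sp, 0.10))
  }
})

test_that("binary attributes: locus amplification and arm-count boundaries", {
  build <- toyBuild()
  flat <- segProfile(build, data.frame(
    chrom = rep(c("chr1", "chr2", "chr3"), each = 2),
    arm = rep(c("p", "q"), 3),
    startMb = c(0, 104, 0, 64, 0, 54),
    endMb = c(100, 200, 60, 150, 50, 120), level = 1))
  expect_false(any(detectBinaryAttributes(flat, build)))
  # planted CCNE1 amplicon recovered through the full pipeline
  sim <- simulateTumorProfile(toyConfig(seed = 42, tumorFraction = 0.8,
                                        binNoiseSd = 0.08,
                                        plantCcne1Amp = TRUE), build)
  sp <- segmentProfile(sim$profile, build)
  expect_true(detectBinaryAttributes(sp, build)[["ccne1Amp"]])
  # focal amplification needs more than two arms
  mkAmp <- function(arms) {
    pEnd <- c(chr1 = 100, chr2 = 60, chr3 = 50)
    qSpec <- data.frame(chrom = c("chr1", "chr2", "chr3"), arm = "q",
                        startMb = c(104, 64, 54), endMb = c(200, 150, 120),
                        level = 1)
    pSpec <- do.call(rbind, lapply(c("chr1", "chr2", "chr3"), function(ch) {
      if (ch %in% c("chr1", "chr2", "chr3")[seq_len(arms)])
        data.frame(chrom = ch, arm = "p", startMb = c(0, 20, 24),
                   endMb = c(20, 24, pEnd[[ch]]), level = c(1, 2.5, 1))
      else
        data.frame(chrom = ch, arm = "p", startMb = 0, endMb = pEnd[[ch]],
                   level = 1)
    }))
    segProfile(build, rbind(pSpec, qSpec))
  }
  expect_false(detectBinaryAttributes(mkAmp(2), build)[["focalAmpPhenotype"]])
  expect_true(detectBinaryAttributes(mkAmp(3), build)[["focalAmpPhenotype"]])
})

test_that("planted tandem-duplication phenotype is recovered end to end", {
  build <- toyBuild()
  sim <- simulateTumorProfile(toyConfig(seed = 43, tumorFraction = 0.9,
                                        binNoiseSd = 0.08,
                                        plantTdGains = 12L), build)
  sp <- segmentProfile(sim$profile, build)
  expect_true(detectBinaryAttributes(sp, build)[["cdk12TdPhenotype"]])
  none <- simulateTumorProfile(toyConfig(seed = 43, binNoiseSd = 0.08),
                               build)
  spN <- segmentProfile(none$profile, build)
  expect_false(detectBinaryAttributes(spN, build)[["cdk12TdPhenotype"]])
})

test_that("ancillary indexes match a hand-enumerated arm", {
  build <- toyBuild()
  # chr1 p (0-100 Mb): 0-35 @1 | 35-47 @1.5 | 47-60 @1 | 60-99.5 @1.5
  # breaks: 35 (flanks 35/12), 47 (12/13), 60 (13/40); the p-arm telomere
  # sits at position 0, so only the first break has a telomeric flank
  # (99.5 Mb is the centromeric end of the arm, not a telomere)
  sp <- segProfile(build, data.frame(
    chrom = "chr1", arm = "p",
    startMb = c(0, 35, 47, 60), endMb = c(35, 47, 60, 99.5),
    level = c(1, 1.5, 1, 1.5)))
  w <- clusterCnLevels(sp)
  idx <- ancillaryLgaIndexes(sp, build, w)
  expect_equal(countLga(sp), 3)
  expect_equal(idx[["extraLargeLga"]], 0L)    # no break with both flanks >= 30
  expect_equal(idx[["telomericLga"]], 1L)
  expect_equal(idx[["lgaBetweenTop2"]], 3L)   # only two levels exist
  expect_equal(idx[["lgaInvolvingTop3"]], 3L)
  expect_equal(idx[["armsWithLga"]], 1L)
  # q arm: the telomere is the chromosome end; extra-large when both
  # flanks reach 30 Mb
  big <- segProfile(build, data.frame(
    chrom = "chr1", arm = "q", startMb = c(104, 150), endMb = c(150, 200),
    level = c(1, 1.5)))
  bigIdx <- ancillaryLgaIndexes(big, build, clusterCnLevels(big))
  expect_equal(bigIdx[["extraLargeLga"]], 1L)
  expect_equal(bigIdx[["telomericLga"]], 1L)
})

test_that("ancillary indexes obey their ordering invariants on simulated draws", {
  build <- toyBuild()
  for (s in 1:6) {
    sim <- simulateTumorProfile(toyConfig(seed = 300 + s,
                                          nLga = sample(2:10, 1),
                                          tumorFraction = runif(1, 0.5, 1),
                                          binNoiseSd = 0.1), build)
    sp <- segmentProfile(sim$profile, build)
    lga <- countLga(sp)
    idx <- ancillaryLgaIndexes(sp, build)
    expect_lte(idx[["lgaBetweenTop2"]], idx[["lgaInvolvingTop3"]])
    expect_lte(idx[["lgaInvolvingTop3"]], lga)
    expect_lte(idx[["armsWithLga"]], max(lga, 1))
  }
})

test_that("LGA counting is invariant under segment order and chromosome relabeling", {
  build <- toyBuild()
  spec <- data.frame(
    chrom = c("chr1", "chr1", "chr2", "chr2"), arm = c("p", "p", "q", "q"),
    startMb = c(0, 40, 64, 110), endMb = c(40, 100, 110, 150),
    level = c(1, 1.4, 1, 1.8))
  base <- countLga(segProfile(build, spec))
  shuffled <- countLga(segProfile(build, spec[c(3, 1, 4, 2), ]))
  expect_equal(shuffled, base)
  relabeled <- spec
  relabeled$chrom <- c("chr3", "chr3", "chr1", "chr1")
  relabeled$arm <- c("q", "q", "p", "p")
  relabeled$startMb <- c(54, 80, 0, 46)
  relabeled$endMb <- c(80, 120, 46, 86)
  expect_equal(countLga(segProfile(build, relabeled)), base)
})
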