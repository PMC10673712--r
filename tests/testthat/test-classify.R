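mkQa <- function(integ = "good", tc = 1L, inoise = 1L, fnoise = 1L) {
  new("QualityAssessment", tumorContentCat = tc, intrinsicNoiseCat = inoise,
      ffpeNoiseCat = fnoise, integrative = integ, metrics = list(),
      warnings = character(0))
}

hrdFeatures <- function(lga, ...) {
  # strongly HRD-flavoured ancillary picture unless overridden
  genomicFeatures(complexity = "simple", lgaSoft = lga, lgaStringent = lga,
                  extraLargeLga = 5L, telomericLga = 6L,
                  lgaBetweenTop2 = 15L, lgaInvolvingTop3 = 20L,
                  armsWithLga = 15L, nBreakpoints = lga + 5L, ...)
}

test_that("penalty and bonus follow the attribute and complexity rules", {
  f0 <- genomicFeatures()
  expect_equal(computePenalty(f0), 0L)
  expect_equal(computePenalty(genomicFeatures(ccne1Amp = TRUE)), 5L)
  expect_equal(computePenalty(genomicFeatures(ccne1Amp = TRUE,
                                              focalAmpPhenotype = TRUE)), 8L)
  expect_equal(computePenalty(genomicFeatures(ccne1Amp = TRUE,
                                              erbb2Amp = TRUE,
                                              focalAmpPhenotype = TRUE,
                                              cdk12TdPhenotype = TRUE)), 8L)
  expect_equal(computeBonus(genomicFeatures(complexity = "simple")), 5L)
  expect_equal(computeBonus(genomicFeatures(complexity = "complex")), 0L)
  expect_equal(computeBonus(genomicFeatures(complexity = "complex_plus")), 0L)
})

test_that("the LGA-score is raw - penalty + bonus, floored at zero", {
  expect_equal(computeLgaScore(22, 0, 0), 22L)
  expect_equal(computeLgaScore(25, 8, 0), 17L)
  expect_equal(computeLgaScore(14, 0, 5), 19L)
  expect_equal(computeLgaScore(2, 8, 0), 0L)
})

test_that("borderline resolution votes per the quoted evidence items", {
  up <- resolveBorderline(20, hrdFeatures(20L), penalty = 0)
  expect_equal(up$score, 21L)
  down <- resolveBorderline(
    20, genomicFeatures(complexity = "complex_plus", lgaSoft = 20L,
                        lgaStringent = 20L, ccne1Amp = TRUE),
    penalty = 5)
  expect_equal(down$score, 19L)
  # exact tie resolves conservatively to 19: one HRD vote (penalty 0)
  # against one nonHRD vote (complex+), all indexes at their floors
  tie <- resolveBorderline(
    20, genomicFeatures(complexity = "complex_plus", lgaSoft = 20L,
                        lgaStringent = 20L, extraLargeLga = 2L,
                        telomericLga = 3L, lgaBetweenTop2 = 8L,
                        lgaInvolvingTop3 = 12L, armsWithLga = 8L),
    penalty = 0)
  expect_equal(tie$votesHrd, tie$votesNonHrd)
  expect_equal(tie$score, 19L)
  expect_error(resolveBorderline(25, hrdFeatures(25L), 0), "not borderline")
})

test_that("clear-cut calls fire far from the threshold", {
  call <- callHrd(hrdFeatures(30L), mkQa("good"))
  expect_equal(status(call), "HRD")
  expect_equal(pathway(call), "clear_cut")
  expect_gt(call@scoreFinal, 22)
  low <- callHrd(genomicFeatures(complexity = "complex", lgaSoft = 10L,
                                 lgaStringent = 8L), mkQa("good"))
  expect_equal(status(low), "nonHRD")
  expect_equal(pathway(low), "clear_cut")
  expect_lt(low@scoreFinal, 18)
})

test_that("quality restricts the decision rules", {
  # fair quality: borderline goes non-determined
  fair <- callHrd(hrdFeatures(15L), mkQa("fair"))  # score 20 borderline
  expect_equal(status(fair), "ND")
  expect_equal(pathway(fair), "quality_restricted")
  # fair quality still gets clear-cut calls
  expect_equal(status(callHrd(hrdFeatures(30L), mkQa("fair"))), "HRD")
  # low quality: only clear-cut nonHRD with few breakpoints
  lowF <- genomicFeatures(complexity = "complex", lgaSoft = 12L,
                          lgaStringent = 10L, nBreakpoints = 25L)
  lowCall <- callHrd(lowF, mkQa("low"))
  expect_equal(status(lowCall), "nonHRD")
  expect_equal(pathway(lowCall), "quality_restricted")
  manyBk <- genomicFeatures(complexity = "complex", lgaSoft = 12L,
                            lgaStringent = 10L, nBreakpoints = 80L)
  expect_equal(status(callHrd(manyBk, mkQa("low"))), "ND")
  expect_equal(status(callHrd(hrdFeatures(40L), mkQa("low"))), "ND")
})

test_that("noisy samples use the stringent threshold, low content the soft one", {
  # soft and stringent counts disagree strongly
  f <- genomicFeatures(complexity = "complex", lgaSoft = 30L,
                       lgaStringent = 10L, nBreakpoints = 35L)
  noisy <- callHrd(f, mkQa("good", inoise = 2L))
  expect_equal(status(noisy), "nonHRD")  # stringent score 10 < 18
  expect_match(noisy@audit, "fixed to stringent", all = FALSE)
  lowTc <- callHrd(f, mkQa("good", tc = 3L))
  # soft score 30 > 22: clear-cut HRD under the soft-only rule
  expect_equal(status(lowTc), "HRD")
  expect_match(lowTc@audit, "fixed to soft", all = FALSE)
})

test_that("every penalty/bonus/complexity/quality/score combination yields one status", {
  cfg <- classifierConfig()
  for (qual in c("good", "fair", "low")) {
    for (flags in 0:2) {
      for (cx in c("simple", "complex", "complex_plus")) {
        for (raw in c(0L, 10L, 17L, 19L, 21L, 23L, 40L)) {
          f <- genomicFeatures(
            complexity = cx, lgaSoft = raw, lgaStringent = raw,
            ccne1Amp = flags >= 1, erbb2Amp = flags >= 2,
            extraLargeLga = 5L, telomericLga = 5L, lgaBetweenTop2 = 10L,
            lgaInvolvingTop3 = 15L, armsWithLga = 10L,
            nBreakpoints = raw + 3L)
          call <- callHrd(f, mkQa(qual))
          expect_true(status(call) %in% c("HRD", "nonHRD", "ND"))
          expect_gt(length(call@audit), 0)
          if (status(call) == "HRD") expect_gt(call@scoreFinal, 20)
          if (status(call) == "nonHRD") expect_lt(call@scoreFinal, 20)
        }
      }
    }
  }
})

test_that("increasing the raw LGA count never flips HRD to nonHRD", {
  rankStatus <- c(nonHRD = 1, ND = 2, HRD = 3)
  for (flags in 0:2) {
    for (cx in c("simple", "complex", "complex_plus")) {
      for (qual in c("good", "fair", "low")) {
        prev <- NULL
        for (raw in 0:60) {
          f <- genomicFeatures(
            complexity = cx, lgaSoft = raw, lgaStringent = raw,
            ccne1Amp = flags >= 1, erbb2Amp = flags >= 2,
            extraLargeLga = 5L, telomericLga = 5L, lgaBetweenTop2 = 10L,
            lgaInvolvingTop3 = 15L, armsWithLga = 10L,
            nBreakpoints = 20L)
          st <- status(callHrd(f, mkQa(qual)))
          if (!is.null(prev) && prev == "HRD")
            expect_false(st == "nonHRD")
          prev <- st
        }
      }
    }
  }
})

test_that("a confidence interval spanning a bound attaches a warning, not an override", {
  ci <- new("LgaConfidence", point = 24L, low = 17L, high = 25L,
            q025 = 17, q975 = 25, runs = c(24L, 17L, 25L, 24L, 24L))
  call <- callHrd(hrdFeatures(24L), mkQa("good"), ci = ci)
  expect_equal(status(call), "HRD")
  expect_match(call@warnings, "spans a decision bound", all = FALSE)
  tight <- new("LgaConfidence", point = 30L, low = 29L, high = 31L,
               q025 = 29, q975 = 31, runs = c(30L, 29L, 31L))
  expect_length(callHrd(hrdFeatures(30L), mkQa("good"), ci = tight)@warnings,
                0)
})
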