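#' @include AllClasses.R io.R
NULL

# category index helpers: by convention labels are (Positive, Negative, NC)
posNegIdx <- function(t) {
  nc <- which(toupper(t@labels) %in% c("NC", "NON-CONTRIBUTIVE"))
  if (length(nc) != 1) stop("table must have exactly one NC category")
  list(pn = setdiff(seq_len(3), nc), nc = nc)
}

#' Overall agreement of two three-category diagnostic tests
#'
#' With \code{excludeNc} (the default) the non-contributive row and column
#' are dropped and agreement is the diagonal fraction of the remaining
#' 2x2; otherwise the full 3x3 diagonal fraction is returned.
#'
#' @param t a [ContingencyTable-class].
#' @param excludeNc drop the NC row/column first.
#' @return list with \code{fraction}, \code{numerator},
#'   \code{denominator}.
#' @export
overallAgreement <- function(t, excludeNc = TRUE) {
  k <- t@counts
  if (excludeNc) {
    ii <- posNegIdx(t)$pn
    k <- k[ii, ii, drop = FALSE]
  }
  den <- sum(k)
  if (den == 0) stop("zero denominator")
  list(fraction = sum(diag(k)) / den, numerator = sum(diag(k)),
       denominator = den)
}

#' Positive / negative agreement
#'
#' Agreement restricted to the rows where the reference test is positive
#' (resp. negative), excluding the NC column: the fraction of
#' reference-positive samples also called positive by the index test.
#'
#' @param t a [ContingencyTable-class].
#' @return list with \code{fraction}, \code{numerator},
#'   \code{denominator}.
#' @name categoryAgreement
#' @export
positiveAgreement <- function(t) {
  ii <- posNegIdx(t)
  pos <- ii$pn[1]
  den <- sum(t@counts[pos, ii$pn])
  if (den == 0) stop("zero denominator")
  list(fraction = t@counts[pos, pos] / den,
       numerator = t@counts[pos, pos], denominator = den)
}

#' @rdname categoryAgreement
#' @export
negativeAgreement <- function(t) {
  ii <- posNegIdx(t)
  neg <- ii$pn[2]
  den <- sum(t@counts[neg, ii$pn])
  if (den == 0) stop("zero denominator")
  list(fraction = t@counts[neg, neg] / den,
       numerator = t@counts[neg, neg], denominator = den)
}

#' Cohen's kappa for a diagnostic contingency table
#'
#' \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with the expected agreement from
#' the row/column marginals. With \code{includeNc} (the default) the
#' non-contributive outcome is treated as a genuine third category over the
#' full 3x3 table; otherwise the NC row/column are dropped and kappa is
#' computed on the 2x2. The three-category reading is the one that
#' reproduces the printed values; both are reported by [runConcordance()].
#'
#' @param t a [ContingencyTable-class].
#' @param includeNc treat NC as a third category.
#' @return kappa (numeric).
#' @export
cohensKappa <- function(t, includeNc = TRUE) {
  k <- t@counts
  if (!includeNc) {
    ii <- posNegIdx(t)$pn
    k <- k[ii, ii, drop = FALSE]
  }
  n <- sum(k)
  if (n == 0) stop("empty table")
  po <- sum(diag(k)) / n
  pe <- sum(rowSums(k) * colSums(k)) / n^2
  if (abs(1 - pe) < 1e-12)
    stop("degenerate marginals: expected agreement is 1, kappa undefined")
  (po - pe) / (1 - pe)
}

#' Failure (non-contributive) rate of either test
#'
#' @param t a [ContingencyTable-class].
#' @param which "index" (NC column) or "reference" (NC row).
#' @return list with \code{fraction}, \code{numerator},
#'   \code{denominator}.
#' @export
failureRate <- function(t, which = c("index", "reference")) {
  which <- match.arg(which)
  ii <- posNegIdx(t)
  num <- if (which == "index") sum(t@counts[, ii$nc])
         else sum(t@counts[ii$nc, ])
  list(fraction = num / sum(t@counts), numerator = num,
       denominator = sum(t@counts))
}

#' All concordance metrics of one table
#'
#' @param t a [ContingencyTable-class].
#' @return named list of agreement fractions, kappas (3-category and
#'   2-category) and failure rates; percentages are also given rounded
#'   half-up to the integer as displayed.
#' @export
concordanceMetrics <- function(t) {
  oa <- overallAgreement(t, excludeNc = TRUE)
  pa <- positiveAgreement(t)
  na_ <- negativeAgreement(t)
  fi <- failureRate(t, "index")
  fr <- failureRate(t, "reference")
  pct <- function(x) floor(100 * x + 0.5)
  list(overall = oa, positive = pa, negative = na_,
       kappa3 = cohensKappa(t, includeNc = TRUE),
       kappa2 = cohensKappa(t, includeNc = FALSE),
       indexFailure = fi, referenceFailure = fr,
       displayPercent = c(overall = pct(oa$fraction),
                          positive = pct(pa$fraction),
                          negative = pct(na_$fraction),
                          indexFailure = pct(fi$fraction),
                          referenceFailure = pct(fr$fraction)))
}
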