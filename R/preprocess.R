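#' @include AllClasses.R io.R
NULL

#' GC-content correction of raw bin read counts
#'
#' Normalizes per-bin read counts for GC bias: a robust LOESS curve
#' (span 0.3, local quadratic, symmetric family) is fitted to counts
#' against GC fraction (on an evenly spaced subsample for speed), each
#' bin's count is divided by the fitted value at its GC fraction, and the
#' resulting ratios are median-centered to 1.0 over valid bins. Bins with
#' GC outside [0.28, 0.68] or zero counts are flagged invalid. Correction
#' is idempotent on already-flat data and exact (to numerical precision)
#' when the bias is a smooth low-order curve.
#'
#' @param counts per-bin read counts.
#' @param gc per-bin GC fraction in [0,1].
#' @param gcRange GC window outside which bins are invalidated.
#' @param span LOESS span.
#' @return list with \code{ratio} (numeric, NA where invalid) and
#'   \code{valid} (logical).
#' @export
gcCorrect <- function(counts, gc, gcRange = c(0.28, 0.68), span = 0.3) {
  if (length(counts) != length(gc)) stop("counts and gc must be aligned")
  if (any(gc < 0 | gc > 1, na.rm = TRUE)) stop("gc must be in [0,1]")
  if (all(counts == 0, na.rm = TRUE)) stop("all-zero counts")
  valid <- !is.na(counts) & !is.na(gc) & counts > 0 &
           gc >= gcRange[1] & gc <= gcRange[2]
  if (sum(valid) < 100)
    stop("fewer than 100 valid bins for the GC fit")
  gx <- gc[valid]; cx <- counts[valid]
  expected <- rep(NA_real_, length(counts))
  if (diff(range(gx)) < 0.02) {
    # essentially constant GC: no bias estimable
    expected[valid] <- stats::median(cx)
  } else {
    ord <- order(gx)
    sel <- ord[unique(round(seq(1, length(ord),
                                length.out = min(2000, length(ord)))))]
    df <- data.frame(xs = gx[sel], ys = cx[sel])
    fit <- stats::loess(ys ~ xs, data = df, span = span, degree = 2,
                        family = "symmetric",
                        control = stats::loess.control(surface = "direct"))
    grid <- unique(c(seq(min(gx), max(gx), by = 0.001), max(gx)))
    if (length(grid) < 2) grid <- range(gx)
    predGrid <- stats::predict(fit, data.frame(xs = grid))
    expected[valid] <- pmax(stats::approx(grid, predGrid, xout = gx,
                                          rule = 2)$y, 1e-9)
  }
  ratio <- counts / expected
  ratio[!valid] <- NA_real_
  ratio <- ratio / stats::median(ratio[valid])
  list(ratio = ratio, valid = valid)
}

#' Build the FFPE noise profile from a panel of normals
#'
#' Summarizes a panel of normal FFPE profiles on a common bin grid into a
#' per-bin expected artifactual deviation (median of ratio - 1 across the
#' panel) and a MAD-scaled per-bin dispersion. At least 10 profiles are
#' required; below 50 the profile is computed but flagged low-confidence
#' with a warning (the reference regime is a panel of ~100).
#'
#' @param panel list of [BinnedProfile-class] on one grid.
#' @return a [NoiseProfile-class].
#' @export
buildFfpeNoiseProfile <- function(panel) {
  if (length(panel) < 2) stop("need at least 2 panel profiles")
  if (length(panel) < 10)
    warning("panel of ", length(panel),
            " normals is below the minimum of 10; noise profile unreliable")
  else if (length(panel) < 50)
    warning("panel of ", length(panel),
            " normals; expected deviations are low-confidence below 50")
  ref <- panel[[1]]@bins
  key <- paste(seqnames(ref), start(ref))
  mat <- vapply(panel, function(p) {
    b <- p@bins
    if (length(b) != length(ref) ||
        !identical(paste(seqnames(b), start(b)), key))
      stop("panel profiles are not on a common bin grid")
    r <- mcols(b)$ratio
    r[!mcols(b)$valid] <- NA
    r
  }, numeric(length(ref)))
  expectedDev <- apply(mat, 1, stats::median, na.rm = TRUE) - 1
  dispersion <- apply(mat, 1, stats::mad, na.rm = TRUE)
  expectedDev[!is.finite(expectedDev)] <- 0
  dispersion[!is.finite(dispersion)] <- 0
  out <- granges(ref)
  mcols(out)$expectedDev <- expectedDev
  mcols(out)$dispersion <- dispersion
  new("NoiseProfile", bins = out, panelSize = length(panel))
}

#' Invalidate bins intersecting a blacklist
#'
#' @param p a [BinnedProfile-class].
#' @param blacklist \code{GRanges} of intervals to exclude.
#' @return the profile with intersecting bins flagged invalid.
#' @export
filterBins <- function(p, blacklist) {
  stopifnot(is(p, "BinnedProfile"))
  if (!length(blacklist)) return(p)
  b <- p@bins
  hit <- overlapsAny(b, blacklist, ignore.strand = TRUE)
  removed <- sum(hit & mcols(b)$valid)
  if (removed) message(removed, " bin(s) invalidated by blacklist")
  mcols(b)$valid <- mcols(b)$valid & !hit
  p@bins <- b
  p
}
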