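#' Summarise a distance series as mean +/- SE
#'
#' Frames are treated as independent by default, i.e. SE = SD/sqrt(n)
#' with the sample SD (n - 1 denominator).  That reproduces the standard
#' reporting convention for MD distance traces (SEs of ~0.002 nm over
#' 5000 frames are only attainable this way) but understates uncertainty
#' when frames are autocorrelated; \code{essCorrection = TRUE} inflates
#' the SE by the integrated autocorrelation time instead.
#'
#' @param s a \linkS4class{DistanceSeries}.
#' @param burnInPs discard frames with time < t0 + burnInPs before
#'   summarising (default 0: all frames).
#' @param essCorrection replace n by the autocorrelation-based effective
#'   sample size in the SE.
#' @return A \linkS4class{SeriesSummary}.
#' @export
summarizeSeries <- function(s, burnInPs = 0, essCorrection = FALSE) {
  stopifnot(is(s, "DistanceSeries"))
  keep <- s@timesPs >= s@timesPs[1] + burnInPs
  v <- s@valuesNm[keep]
  n <- length(v)
  if (n < 2L) stop("need at least 2 frames to summarise", call. = FALSE)
  sdv <- stats::sd(v)
  se <- sdv / sqrt(n)
  if (essCorrection && sdv > 0) {
    tau <- .integratedAutocorrTime(v)
    se <- sdv * sqrt(tau / n)
  }
  new("SeriesSummary", meanNm = mean(v), seNm = se, sdNm = sdv,
      nFrames = as.integer(n), label = s@label)
}

# integrated autocorrelation time: 1 + 2 * sum of positive-lag ACF up to
# the first non-positive term (initial positive sequence estimator)
.integratedAutocorrTime <- function(v) {
  n <- length(v)
  ac <- stats::acf(v, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1]
  upTo <- which(ac <= 0)[1]
  if (!is.na(upTo)) ac <- ac[seq_len(upTo - 1L)]
  max(1, 1 + 2 * sum(ac))
}

#' Two-sample t test between distance series
#'
#' Compares the per-frame values of two series with an independent
#' two-sample t test: "student" is the pooled-variance form with
#' df = nA + nB - 2; "welch" uses the Satterthwaite approximation.  Two
#' identical constant series are the documented degenerate case: t = 0,
#' p = 1.
#'
#' @param a,b \linkS4class{DistanceSeries} objects (>= 2 frames each).
#' @param alpha significance level for the significance flag.
#' @param mode "student" (default, pooled variance) or "welch".
#' @return A \linkS4class{ComparisonResult}; direction is "A_lower" /
#'   "B_lower" for a significant difference, "none" otherwise.
#' @export
compareSeries <- function(a, b, alpha = 0.05,
                          mode = c("student", "welch")) {
  stopifnot(is(a, "DistanceSeries"), is(b, "DistanceSeries"))
  mode <- match.arg(mode)
  va <- a@valuesNm; vb <- b@valuesNm
  if (length(va) < 2L || length(vb) < 2L)
    stop("each series needs at least 2 frames", call. = FALSE)
  if (stats::sd(va) == 0 && stats::sd(vb) == 0) {
    # both constant: no within-group variance to test against
    if (mean(va) == mean(vb)) {
      tStat <- 0; p <- 1; df <- length(va) + length(vb) - 2
    } else {
      tStat <- sign(mean(va) - mean(vb)) * Inf; p <- 0
      df <- length(va) + length(vb) - 2
    }
  } else {
    tt <- stats::t.test(va, vb, var.equal = (mode == "student"))
    tStat <- unname(tt$statistic); df <- unname(tt$parameter)
    p <- tt$p.value
  }
  sig <- p < alpha
  dir <- if (!sig) "none" else if (mean(va) < mean(vb)) "A_lower" else
    "B_lower"
  new("ComparisonResult", tStat = tStat, df = df, pValue = p,
      alpha = alpha, significant = sig, direction = dir)
}

#' Detect a sustained detachment from the heme iron
#'
#' A detachment event is the first run of consecutive frames, lasting at
#' least \code{windowPs}, in which the distance stays strictly above
#' \code{thresholdNm}.  The default threshold of 0.6 nm separates
#' catalytically competent poses (means ~0.41-0.54 nm) from detached ones
#' (~0.63 nm and beyond); the 1 ns persistence window rules out transient
#' excursions.
#'
#' @param s a \linkS4class{DistanceSeries} spanning at least
#'   \code{windowPs}.
#' @param thresholdNm distance threshold, nm.
#' @param windowPs minimum persistence, ps.
#' @return A \linkS4class{DetachmentEvent}; \code{onsetPs(event)} is NA
#'   when no qualifying run exists.
#' @export
detectDetachment <- function(s, thresholdNm = 0.6, windowPs = 1000) {
  stopifnot(is(s, "DistanceSeries"))
  n <- length(s@valuesNm)
  dt <- if (n > 1L) s@timesPs[2] - s@timesPs[1] else NA_real_
  framesNeeded <- ceiling(windowPs / dt)
  if (!is.finite(framesNeeded) || framesNeeded > n)
    stop("persistence window longer than the series", call. = FALSE)
  above <- s@valuesNm > thresholdNm
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= framesNeeded)
  onset <- if (length(hit) == 0L) NA_real_ else s@timesPs[starts[hit[1]]]
  new("DetachmentEvent", onsetPs = onset, thresholdNm = thresholdNm,
      windowPs = windowPs)
}

#' Semi-quantitative substrate-likelihood call
#'
#' The probe envelope is the largest mean distance among well-behaved
#' probe substrates.  A complex whose mean sits within
#' \code{probeMarginNm} of the envelope behaves like a probe substrate;
#' within \code{minorMarginNm}, like a minor (non-optimal) substrate;
#' beyond that, a poor or non-substrate.  The margins are the package's
#' operationalisation of an explicitly semi-quantitative reading and are
#' configurable.
#'
#' @param summary a \linkS4class{SeriesSummary} for the complex.
#' @param probeMeansNm mean distances of the probe-substrate complexes,
#'   nm (non-empty).
#' @param probeMarginNm margin for "probe_like", nm.
#' @param minorMarginNm margin for "minor_substrate", nm.
#' @return A \linkS4class{SubstrateCall}.
#' @export
callSubstrate <- function(summary, probeMeansNm,
                          probeMarginNm = 0.05, minorMarginNm = 0.15) {
  stopifnot(is(summary, "SeriesSummary"))
  if (length(probeMeansNm) == 0L)
    stop("probe mean list must be non-empty", call. = FALSE)
  env <- max(probeMeansNm)
  m <- summary@meanNm
  lab <- if (m <= env + probeMarginNm) "probe_like"
  else if (m <= env + minorMarginNm) "minor_substrate"
  else "poor_or_non_substrate"
  new("SubstrateCall", label = lab, meanNm = m, probeEnvelopeNm = env)
}

#' Variant-vs-reference metabolic-effect call
#'
#' The variant's mean Fe--reactive-atom distance is compared against the
#' reference allele's.  A significantly lower mean (delta < 0) reads as
#' likely enhanced metabolic capacity; significantly higher as likely
#' reduced; a non-significant difference as unchanged.
#'
#' @param variant \linkS4class{DistanceSeries} for the variant complex.
#' @param reference \linkS4class{DistanceSeries} for the reference
#'   complex.
#' @param alpha significance level.
#' @param mode t-test mode, see \code{\link{compareSeries}}.
#' @return A \linkS4class{VariantEffectCall}.
#' @export
callVariantEffect <- function(variant, reference, alpha = 0.05,
                              mode = c("student", "welch")) {
  mode <- match.arg(mode)
  cmp <- compareSeries(variant, reference, alpha = alpha, mode = mode)
  delta <- summarizeSeries(variant)@meanNm -
    summarizeSeries(reference)@meanNm
  lab <- if (!cmp@significant) "unchanged"
  else if (delta < 0) "likely_enhanced" else "likely_reduced"
  new("VariantEffectCall", label = lab, deltaNm = delta, comparison = cmp)
}
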