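#' Accessors for CypDiscriminant objects
#'
#' Small typed getters so downstream code never touches slots directly.
#'
#' @param x an object of the relevant class.
#' @param value replacement value (for setters).
#' @return The slot content; see each method.
#' @name accessors
NULL

#' @rdname accessors
setMethod("timesPs", "DistanceSeries", function(x) x@timesPs)
#' @rdname accessors
setMethod("timesPs", "RMSDSeries", function(x) x@timesPs)
#' @rdname accessors
setMethod("valuesNm", "DistanceSeries", function(x) x@valuesNm)
#' @rdname accessors
setMethod("valuesNm", "RMSDSeries", function(x) x@valuesNm)
#' @rdname accessors
setMethod("seriesLabel", "DistanceSeries", function(x) x@label)
#' @rdname accessors
setMethod("seriesLabel", "RMSDSeries", function(x) x@selectionLabel)
#' @rdname accessors
setMethod("seriesLabel", "SeriesSummary", function(x) x@label)

#' @rdname accessors
setMethod("meanNm", "SeriesSummary", function(x) x@meanNm)
#' @rdname accessors
setMethod("meanNm", "SubstrateCall", function(x) x@meanNm)
#' @rdname accessors
setMethod("seNm", "SeriesSummary", function(x) x@seNm)
#' @rdname accessors
setMethod("sdNm", "SeriesSummary", function(x) x@sdNm)
#' @rdname accessors
setMethod("nFrames", "SeriesSummary", function(x) x@nFrames)
#' @rdname accessors
setMethod("nFrames", "HemeTrajectory", function(x) dim(x@coords)[3])

#' @rdname accessors
setMethod("pValue", "ComparisonResult", function(x) x@pValue)
#' @rdname accessors
setMethod("pValue", "VariantEffectCall", function(x) x@comparison@pValue)

#' @rdname accessors
setMethod("callLabel", "SubstrateCall", function(x) x@label)
#' @rdname accessors
setMethod("callLabel", "VariantEffectCall", function(x) x@label)
#' @rdname accessors
setMethod("callLabel", "StabilityCall", function(x) x@label)

#' @rdname accessors
setMethod("onsetPs", "DetachmentEvent", function(x) x@onsetPs)
#' @rdname accessors
setMethod("deltaNm", "VariantEffectCall", function(x) x@deltaNm)

#' @rdname accessors
setMethod("atomTable", "HemeStructure", function(x) x@atoms)
#' @rdname accessors
setMethod("atomTable", "HemeTrajectory", function(x) x@structure@atoms)

#' @rdname accessors
setMethod("refId", "ReferenceMSA", function(x) x@refId)
#' @rdname accessors
setMethod("refId<-", "ReferenceMSA", function(x, value) {
  x@refId <- value
  validObject(x)
  x
})

#' @rdname accessors
setMethod("conservedFraction", "ConservationReport",
          function(x) x@conservedFraction)

#' @rdname accessors
setMethod("mutationTable", "VariantDef", function(x) x@mutations)

setMethod("show", "HemeStructure", function(object) {
  a <- object@atoms
  cat("HemeStructure '", object@id, "': ", nrow(a), " atoms, ",
      length(unique(paste(a$chainId, a$resSeq))), " residues, chains ",
      paste(unique(a$chainId), collapse = ","), "\n", sep = "")
})

setMethod("show", "HemeTrajectory", function(object) {
  d <- dim(object@coords)
  cat("HemeTrajectory: ", d[3], " frames x ", d[1], " atoms, dt = ",
      object@dtPs, " ps (", (d[3] - 1) * object@dtPs / 1000,
      " ns span)\n", sep = "")
})

setMethod("show", "DistanceSeries", function(object) {
  cat("DistanceSeries '", object@label, "': ", length(object@valuesNm),
      " frames, mean ", round(mean(object@valuesNm), 3), " nm\n", sep = "")
})

setMethod("show", "RMSDSeries", function(object) {
  cat("RMSDSeries [", object@selectionLabel, "]: ",
      length(object@valuesNm), " frames, final ",
      round(utils::tail(object@valuesNm, 1), 3), " nm\n", sep = "")
})

setMethod("show", "VariantDef", function(object) {
  m <- object@mutations
  muts <- if (nrow(m) == 0L) "(none; reference allele)" else
    paste0(m$wt, m$pos, m$mut, collapse = ", ")
  cat("VariantDef ", object@allele, ": ", muts, "\n", sep = "")
})

setMethod("show", "SeriesSummary", function(object) {
  cat(sprintf("SeriesSummary '%s': %.3f +/- %.3f nm (SE), n = %d frames\n",
              object@label, object@meanNm, object@seNm, object@nFrames))
})

setMethod("show", "ComparisonResult", function(object) {
  cat(sprintf(
    "ComparisonResult: t = %.3f, df = %.1f, p = %.3g (%ssignificant at alpha = %g), direction %s\n",
    object@tStat, object@df, object@pValue,
    if (object@significant) "" else "not ", object@alpha, object@direction))
})

setMethod("show", "DetachmentEvent", function(object) {
  if (is.na(object@onsetPs))
    cat(sprintf("DetachmentEvent: none (> %.2f nm sustained %g ps)\n",
                object@thresholdNm, object@windowPs))
  else
    cat(sprintf("DetachmentEvent: onset %g ps (> %.2f nm sustained %g ps)\n",
                object@onsetPs, object@thresholdNm, object@windowPs))
})

setMethod("show", "SubstrateCall", function(object) {
  cat(sprintf("SubstrateCall: %s (mean %.3f nm vs probe envelope %.3f nm)\n",
              object@label, object@meanNm, object@probeEnvelopeNm))
})

setMethod("show", "VariantEffectCall", function(object) {
  cat(sprintf("VariantEffectCall: %s (delta %+0.3f nm, p = %.3g)\n",
              object@label, object@deltaNm, object@comparison@pValue))
})

setMethod("show", "StabilityCall", function(object) {
  cat(sprintf("StabilityCall: %s (ddG = %.2f kcal/mol)\n",
              object@label, object@ddGKcalMol))
})

setMethod("show", "ReferenceMSA", function(object) {
  cat("ReferenceMSA: ", length(object@aln), " records x ",
      Biostrings::width(object@aln)[1], " columns, reference '",
      object@refId, "'\n", sep = "")
})

setMethod("show", "ConservationReport", function(object) {
  cat(sprintf(
    "ConservationReport: column %d (ref %s%s): %.1f%% conserved over %d sequences\n",
    object@column, object@refResidue,
    if (is.na(object@refPosition)) "" else paste0(" @", object@refPosition),
    100 * object@conservedFraction, object@nSequences))
})

setMethod("show", "OUParams", function(object) {
  cat(sprintf("OUParams: mu %.3f nm, theta %.3g /ps, sigma %.4f nm/sqrt(ps)",
              object@muNm, object@thetaPerPs, object@sigmaNm))
  if (!is.na(object@switchTPs))
    cat(sprintf(", switch to %.3f nm at %g ps", object@switchMuNm,
                object@switchTPs))
  cat("\n")
})

setMethod("show", "ScenarioPreset", function(object) {
  cat("ScenarioPreset '", object@name, "'\n  ", sep = "")
  show(object@ou)
})
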