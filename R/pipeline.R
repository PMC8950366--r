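.CONFIG_DEFAULTS <- list(
  scenarios = NULL,            # NULL = all shipped presets
  trajectories = NULL,         # list of trajectory inputs (see runPipeline)
  nFrames = 5000L,
  dtPs = 10,
  seed = 1L,
  referenceAllele = "*1",
  effectCalls = TRUE,
  probeScenarios = c("dextromethorphan:*1", "bufuralol:*1"),
  alpha = 0.05,
  tMode = "student",
  burnInPs = 0,
  detachThresholdNm = 0.6,
  detachWindowPs = 1000,
  probeMarginNm = 0.05,
  minorMarginNm = 0.15,
  outDir = NULL,
  makePlots = FALSE)

#' Assemble a run configuration
#'
#' Merges the given fields over the documented defaults; unknown keys are
#' an error (fail-fast), so typos never silently fall back to defaults.
#'
#' @param ... configuration fields; see \code{\link{runPipeline}}.
#' @return A validated config list.
#' @export
runConfig <- function(...) {
  given <- list(...)
  unknown <- setdiff(names(given), names(.CONFIG_DEFAULTS))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(.CONFIG_DEFAULTS, given)
  if (!cfg$tMode %in% c("student", "welch"))
    stop("tMode must be 'student' or 'welch'", call. = FALSE)
  if (cfg$nFrames < 2L) stop("nFrames must be >= 2", call. = FALSE)
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose top-level keys mirror
#'   \code{\link{runConfig}} arguments.
#' @return A validated config list.
#' @export
readRunConfig <- function(path) {
  do.call(runConfig, yaml::read_yaml(path))
}

.scenarioSeries <- function(cfg) {
  presets <- scenarioPresets()
  wanted <- if (is.null(cfg$scenarios)) names(presets) else cfg$scenarios
  missing <- setdiff(wanted, names(presets))
  if (length(missing) > 0L)
    stop("unknown scenario(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- lapply(wanted, function(nm) {
    p <- presets[[nm]]
    # per-scenario seed derived from the global seed and the preset slot
    sd <- cfg$seed + match(nm, names(presets))
    series <- simulateDistanceSeries(p@ou, cfg$nFrames, cfg$dtPs,
                                     seed = sd, label = nm)
    list(series = series, ligand = p@ligand, allele = p@allele,
         seed = sd, rmsd = NULL)
  })
  stats::setNames(out, wanted)
}

.trajectorySeries <- function(cfg) {
  out <- lapply(cfg$trajectories, function(inp) {
    lig <- ligandSpec(inp$ligandResName, inp$reactiveAtomName,
                      if (is.null(inp$ligandLabel)) inp$ligandResName
                      else inp$ligandLabel)
    traj <- readModelTrajectory(inp$path, dtPs = cfg$dtPs)
    s <- traj@structure
    feIdx <- findHemeIron(s)
    rxIdx <- selectReactiveAtom(s, lig)
    label <- paste0(lig@label, ":", inp$allele)
    caIdx <- selectCalpha(s)
    rmsd <- list(
      protein = rmsdSeries(traj, caIdx, caIdx,
                           selectionLabel = "protein_calpha"),
      ligand = rmsdSeries(traj, selectResidueAtoms(s, lig@resName),
                          caIdx, selectionLabel = "ligand"))
    list(series = distanceSeries(traj, rxIdx, feIdx, label = label),
         ligand = lig@label, allele = inp$allele, seed = cfg$seed,
         rmsd = rmsd)
  })
  stats::setNames(out, vapply(out, function(x) x$series@label, ""))
}

#' Run the full distance-discriminant pipeline
#'
#' For every input complex -- either a shipped simulation scenario or a
#' multi-model PDB trajectory -- the pipeline computes the
#' Fe--reactive-atom distance series (plus protein/ligand RMSD series in
#' trajectory mode), the mean +/- SE summary, a detachment check and a
#' substrate-likelihood call against the probe envelope; then, for every
#' ligand whose reference-allele complex is present, a t-test comparison
#' and metabolic-effect call for each variant allele.
#'
#' Config fields: \code{scenarios} (preset names; NULL = all),
#' \code{trajectories} (list of \code{list(path, ligandResName,
#' reactiveAtomName, ligandLabel, allele)}), \code{nFrames},
#' \code{dtPs}, \code{seed}, \code{referenceAllele}, \code{effectCalls},
#' \code{probeScenarios}, \code{alpha}, \code{tMode}, \code{burnInPs},
#' \code{detachThresholdNm}, \code{detachWindowPs}, \code{probeMarginNm},
#' \code{minorMarginNm}, \code{outDir}, \code{makePlots}.
#'
#' @param config a config list from \code{\link{runConfig}} /
#'   \code{\link{readRunConfig}}.
#' @return A list with \code{complexes} (one row per complex),
#'   \code{effects} (one row per variant--reference pair), \code{series}
#'   (the underlying objects) and \code{config}.  When \code{outDir} is
#'   set, TSV and JSON reports (and optionally per-series plots) are
#'   written there.
#' @export
runPipeline <- function(config = runConfig()) {
  cfg <- do.call(runConfig, config)  # re-validate whatever was passed
  inputs <- if (!is.null(cfg$trajectories)) .trajectorySeries(cfg)
  else .scenarioSeries(cfg)
  if (length(inputs) == 0L) stop("no inputs configured", call. = FALSE)

  alleles <- vapply(inputs, function(x) x$allele, "")
  if (isTRUE(cfg$effectCalls) && !cfg$referenceAllele %in% alleles)
    stop("reference allele '", cfg$referenceAllele,
         "' is absent from the inputs but variant-effect calls are on",
         call. = FALSE)

  summaries <- lapply(inputs, function(x)
    summarizeSeries(x$series, burnInPs = cfg$burnInPs))

  probePresent <- intersect(cfg$probeScenarios, names(inputs))
  if (length(probePresent) == 0L)
    stop("none of the probe scenarios (",
         paste(cfg$probeScenarios, collapse = ", "),
         ") is among the inputs; substrate calls need a probe envelope",
         call. = FALSE)
  probeMeans <- vapply(summaries[probePresent], meanNm, numeric(1))

  span <- function(s) diff(range(timesPs(s)))
  complexes <- do.call(rbind, lapply(names(inputs), function(nm) {
    x <- inputs[[nm]]
    sm <- summaries[[nm]]
    det <- if (span(x$series) >= cfg$detachWindowPs)
      detectDetachment(x$series, cfg$detachThresholdNm,
                       cfg$detachWindowPs)@onsetPs
    else NA_real_
    sc <- callSubstrate(sm, probeMeans, cfg$probeMarginNm,
                        cfg$minorMarginNm)
    data.frame(label = nm, ligand = x$ligand, allele = x$allele,
               mean_nm = meanNm(sm), se_nm = seNm(sm), sd_nm = sdNm(sm),
               n_frames = nFrames(sm), substrate_call = callLabel(sc),
               detachment_onset_ps = det, seed = x$seed,
               stringsAsFactors = FALSE)
  }))

  effects <- NULL
  if (isTRUE(cfg$effectCalls)) for (lg in unique(complexes$ligand)) {
    members <- names(inputs)[complexes$ligand == lg]
    refNm <- members[complexes$allele[complexes$ligand == lg] ==
                       cfg$referenceAllele]
    if (length(refNm) != 1L) next
    for (nm in setdiff(members, refNm)) {
      eff <- callVariantEffect(inputs[[nm]]$series,
                               inputs[[refNm]]$series,
                               alpha = cfg$alpha, mode = cfg$tMode)
      cmp <- eff@comparison
      effects <- rbind(effects, data.frame(
        ligand = lg, allele = complexes$allele[complexes$label == nm],
        reference = cfg$referenceAllele, delta_nm = eff@deltaNm,
        t = cmp@tStat, df = cmp@df, p = cmp@pValue,
        significant = cmp@significant, effect_call = eff@label,
        stringsAsFactors = FALSE))
    }
  }

  result <- list(complexes = complexes, effects = effects,
                 series = inputs, config = cfg)
  if (!is.null(cfg$outDir)) .writeReports(result, cfg)
  result
}

.writeReports <- function(result, cfg) {
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(sprintf("# CypDiscriminant %s",
                   as.character(utils::packageVersion("CypDiscriminant"))),
           sprintf("# seed: %d  alpha: %g  tMode: %s  burnInPs: %g",
                   cfg$seed, cfg$alpha, cfg$tMode, cfg$burnInPs),
           sprintf("# detach: > %g nm for %g ps  margins: +%g/+%g nm",
                   cfg$detachThresholdNm, cfg$detachWindowPs,
                   cfg$probeMarginNm, cfg$minorMarginNm))
  writeTsv <- function(df, file) {
    con <- file.path(cfg$outDir, file)
    writeLines(hdr, con)
    suppressWarnings(utils::write.table(df, con, sep = "\t",
                                        quote = FALSE, row.names = FALSE,
                                        append = TRUE))
  }
  writeTsv(result$complexes, "complex_report.tsv")
  if (!is.null(result$effects))
    writeTsv(result$effects, "variant_effect_report.tsv")
  jsonlite::write_json(
    list(complexes = result$complexes, effects = result$effects,
         seed = cfg$seed),
    file.path(cfg$outDir, "report.json"), auto_unbox = TRUE, digits = NA)
  for (nm in names(result$series))
    exportSeriesTSV(result$series[[nm]]$series,
                    file.path(cfg$outDir,
                              paste0("series_", gsub("[*:]", "_", nm),
                                     ".tsv")))
  if (isTRUE(cfg$makePlots)) {
    pd <- file.path(cfg$outDir, "plots")
    dir.create(pd, showWarnings = FALSE)
    for (nm in names(result$series)) {
      g <- plotSeries(result$series[[nm]]$series,
                      thresholdNm = cfg$detachThresholdNm)
      ggplot2::ggsave(file.path(pd, paste0(gsub("[*:]", "_", nm),
                                           ".png")),
                      g, width = 7, height = 3.5, dpi = 120)
    }
  }
  invisible(NULL)
}

#' Run the conservation and motif workflow
#'
#' Reads (or accepts) an alignment, maps a reference position to its
#' column, reports the column's conservation, and scans the ungapped
#' reference with the strict and relaxed heme-binding-motif patterns.
#'
#' @param msa path to an alignment file or a \linkS4class{ReferenceMSA}.
#' @param refId reference record name (paths only; default first
#'   record).
#' @param refPosition reference residue position to analyse.
#' @param format "fasta" or "clustal" (paths only).
#' @param countGaps see \code{\link{columnConservation}}.
#' @param allowedPlusTwo residues admitted at the motif's +2 position in
#'   the relaxed scan.
#' @param outDir optional output directory for the TSV/JSON report.
#' @return A list with \code{conservation}
#'   (\linkS4class{ConservationReport}), \code{strictHits} and
#'   \code{relaxedHits} (motif hit tables on the ungapped reference).
#' @export
runConservation <- function(msa, refPosition, refId = NULL,
                            format = c("fasta", "clustal"),
                            countGaps = FALSE,
                            allowedPlusTwo = c("A", "S", "K"),
                            outDir = NULL) {
  if (is.character(msa))
    msa <- readMSA(msa, format = match.arg(format), refId = refId)
  stopifnot(is(msa, "ReferenceMSA"))
  report <- columnConservation(msa, refPosition = refPosition,
                               countGaps = countGaps)
  refUngapped <- gsub("-", "", as.character(msa@aln[[msa@refId]]),
                      fixed = TRUE)
  out <- list(conservation = report,
              strictHits = scanHemeMotif(refUngapped),
              relaxedHits = relaxedMotifScan(refUngapped, allowedPlusTwo))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    exportConservation(report, file.path(outDir, "conservation.tsv"),
                       file.path(outDir, "conservation.json"))
    utils::write.table(out$strictHits,
                       file.path(outDir, "motif_hits_strict.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(out$relaxedHits,
                       file.path(outDir, "motif_hits_relaxed.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
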