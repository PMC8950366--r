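#' @import methods
#' @importClassesFrom Biostrings AAStringSet
NULL

.AA1 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

.AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

# distances are stored in Angstrom (PDB native) and reported in nm
.ANG_PER_NM <- 10

#' HemeStructure: a single-model protein--ligand complex
#'
#' Holds the atom table of one structure (one model): serial number, atom
#' name, element, residue name, author residue number, chain, HETATM flag
#' and Cartesian coordinates in Angstrom.  Coordinates stay in Angstrom
#' internally; all user-facing distances are reported in nm.
#'
#' @slot atoms data.frame with columns serial, name, element, resName,
#'   resSeq, chainId, het (logical, HETATM record), x, y, z (Angstrom).
#' @slot id free-text structure label.
#' @exportClass HemeStructure
setClass("HemeStructure",
         representation(atoms = "data.frame", id = "character"))

setValidity("HemeStructure", function(object) {
  a <- object@atoms
  need <- c("serial", "name", "element", "resName", "resSeq",
            "chainId", "het", "x", "y", "z")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) < 1L) return("structure must contain at least one atom")
  if (anyDuplicated(a$serial)) return("atom serial numbers must be unique")
  if (any(!nzchar(a$element))) return("every atom needs an element symbol")
  if (!all(is.finite(c(a$x, a$y, a$z)))) return("coordinates must be finite")
  TRUE
})

#' LigandSpec: which ligand and which atom reacts
#'
#' Names the ligand residue and the reactive atom -- the ligand atom at
#' which the metabolic transformation (hydroxylation/demethylation) occurs.
#' PDB files carry no such annotation, so the atom name must be supplied
#' explicitly per ligand.
#'
#' @slot resName 3-letter residue code of the ligand.
#' @slot reactiveAtomName PDB atom name of the reactive atom.
#' @slot label free text, e.g. "OTA" or "dextromethorphan".
#' @exportClass LigandSpec
setClass("LigandSpec",
         representation(resName = "character",
                        reactiveAtomName = "character",
                        label = "character"))

setValidity("LigandSpec", function(object) {
  if (!nzchar(object@resName) || !nzchar(object@reactiveAtomName))
    return("resName and reactiveAtomName must be non-empty")
  TRUE
})

#' HemeTrajectory: ordered frames over a fixed atom set
#'
#' The unit of analysis: a topology (frame 0 structure) plus per-frame
#' coordinates and uniform time metadata.  The native on-disk dialect is
#' multi-model PDB.
#'
#' @slot structure a \linkS4class{HemeStructure} (topology, frame 1 coords).
#' @slot coords numeric array, n_atoms x 3 x n_frames, Angstrom.
#' @slot dtPs frame spacing, picoseconds.
#' @slot t0Ps time of the first frame, picoseconds.
#' @exportClass HemeTrajectory
setClass("HemeTrajectory",
         representation(structure = "HemeStructure", coords = "array",
                        dtPs = "numeric", t0Ps = "numeric"))

setValidity("HemeTrajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    return("coords must be an n_atoms x 3 x n_frames array")
  if (d[1] != nrow(object@structure@atoms))
    return("frame atom count must equal the structure's atom count")
  if (d[3] < 1L) return("need at least one frame")
  if (length(object@dtPs) != 1L || object@dtPs <= 0)
    return("dtPs must be a single positive number")
  TRUE
})

#' DistanceSeries: the Fe--reactive-atom discriminant signal
#'
#' Per-frame distances between the designated ligand atom and the heme
#' iron, in nm, on a strictly increasing time grid.
#'
#' @slot timesPs strictly increasing times, picoseconds.
#' @slot valuesNm non-negative distances, nm.
#' @slot label complex identifier (ligand x variant).
#' @slot metadata list of provenance (seed, flooring count, ...).
#' @exportClass DistanceSeries
setClass("DistanceSeries",
         representation(timesPs = "numeric", valuesNm = "numeric",
                        label = "character", metadata = "list"),
         prototype(metadata = list()))

setValidity("DistanceSeries", function(object) {
  if (length(object@timesPs) != length(object@valuesNm))
    return("times and values must have equal length")
  if (length(object@timesPs) > 1L && any(diff(object@timesPs) <= 0))
    return("times must be strictly increasing")
  if (anyNA(object@valuesNm) || any(object@valuesNm < 0))
    return("values must be non-negative and non-missing")
  TRUE
})

#' RMSDSeries: per-frame RMSD after optimal superposition
#'
#' @slot timesPs strictly increasing times, picoseconds.
#' @slot valuesNm RMSD values, nm.
#' @slot selectionLabel "protein_calpha" or "ligand".
#' @exportClass RMSDSeries
setClass("RMSDSeries",
         representation(timesPs = "numeric", valuesNm = "numeric",
                        selectionLabel = "character"))

setValidity("RMSDSeries", function(object) {
  if (length(object@timesPs) != length(object@valuesNm))
    return("times and values must have equal length")
  if (length(object@timesPs) > 1L && any(diff(object@timesPs) <= 0))
    return("times must be strictly increasing")
  if (anyNA(object@valuesNm) || any(object@valuesNm < 0))
    return("values must be non-negative and non-missing")
  if (!object@selectionLabel %in% c("protein_calpha", "ligand"))
    return("selectionLabel must be 'protein_calpha' or 'ligand'")
  TRUE
})

#' VariantDef: a star allele as a set of missense mutations
#'
#' Star-nomenclature haplotype (e.g. "*110") with its defining missense
#' substitutions in author residue numbering; "*1" is the reference allele
#' with an empty mutation set.
#'
#' @slot allele allele name, e.g. "*110".
#' @slot mutations data.frame with columns wt, pos, mut (one row per
#'   substitution; empty for the reference allele).
#' @exportClass VariantDef
setClass("VariantDef",
         representation(allele = "character", mutations = "data.frame"))

setValidity("VariantDef", function(object) {
  m <- object@mutations
  if (!all(c("wt", "pos", "mut") %in% names(m)))
    return("mutations needs columns wt, pos, mut")
  if (nrow(m) == 0L) return(TRUE)
  if (anyDuplicated(m$pos)) return("mutation positions must be unique")
  if (any(m$pos < 1L)) return("positions must be >= 1")
  if (any(m$wt == m$mut)) return("wt and mut residues must differ")
  if (!all(c(m$wt, m$mut) %in% .AA1))
    return("residues must be one-letter amino-acid codes")
  TRUE
})

#' StabilityCall: ddG-based stability classification
#'
#' @slot ddGKcalMol predicted unfolding free-energy change, kcal/mol.
#' @slot label "limited_effect" (ddG < 1) or "potentially_destabilising".
#' @exportClass StabilityCall
setClass("StabilityCall",
         representation(ddGKcalMol = "numeric", label = "character"))

#' SeriesSummary: mean +/- SE over frames
#'
#' @slot meanNm mean distance, nm.
#' @slot seNm standard error of the mean, nm.
#' @slot sdNm sample standard deviation (n - 1), nm.
#' @slot nFrames number of frames summarised.
#' @slot label complex identifier.
#' @exportClass SeriesSummary
setClass("SeriesSummary",
         representation(meanNm = "numeric", seNm = "numeric",
                        sdNm = "numeric", nFrames = "integer",
                        label = "character"))

setValidity("SeriesSummary", function(object) {
  if (object@nFrames < 2L) return("a summary needs at least 2 frames")
  if (!all(is.finite(c(object@meanNm, object@seNm, object@sdNm))))
    return("summary statistics must be finite")
  TRUE
})

#' ComparisonResult: two-sample t test between distance series
#'
#' @slot tStat t statistic.
#' @slot df degrees of freedom (pooled or Satterthwaite).
#' @slot pValue two-sided p value.
#' @slot alpha significance level used for the call.
#' @slot significant pValue < alpha.
#' @slot direction "A_lower", "B_lower" or "none" (not significant).
#' @exportClass ComparisonResult
setClass("ComparisonResult",
         representation(tStat = "numeric", df = "numeric",
                        pValue = "numeric", alpha = "numeric",
                        significant = "logical", direction = "character"))

setValidity("ComparisonResult", function(object) {
  if (object@pValue < 0 || object@pValue > 1) return("p must be in [0, 1]")
  if (object@significant != (object@pValue < object@alpha))
    return("significant must equal pValue < alpha")
  if (!object@direction %in% c("A_lower", "B_lower", "none"))
    return("direction must be A_lower, B_lower or none")
  if (!object@significant && object@direction != "none")
    return("direction must be 'none' when not significant")
  TRUE
})

#' DetachmentEvent: first sustained excursion above a distance threshold
#'
#' @slot onsetPs start time of the first qualifying run (NA if none).
#' @slot thresholdNm distance threshold, nm.
#' @slot windowPs minimum persistence, ps.
#' @exportClass DetachmentEvent
setClass("DetachmentEvent",
         representation(onsetPs = "numeric", thresholdNm = "numeric",
                        windowPs = "numeric"))

#' SubstrateCall: semi-quantitative substrate-likelihood label
#'
#' @slot label "probe_like", "minor_substrate" or "poor_or_non_substrate".
#' @slot meanNm the complex's mean distance, nm.
#' @slot probeEnvelopeNm max of the probe-substrate means, nm.
#' @exportClass SubstrateCall
setClass("SubstrateCall",
         representation(label = "character", meanNm = "numeric",
                        probeEnvelopeNm = "numeric"))

setValidity("SubstrateCall", function(object) {
  if (!object@label %in% c("probe_like", "minor_substrate",
                           "poor_or_non_substrate"))
    return("unknown substrate label")
  TRUE
})

#' VariantEffectCall: variant vs reference metabolic-capacity label
#'
#' A significantly shorter Fe--reactive-atom distance than the reference
#' allele reads as likely enhanced metabolism; significantly longer as
#' likely reduced; otherwise unchanged.
#'
#' @slot label "likely_enhanced", "likely_reduced" or "unchanged".
#' @slot deltaNm variant mean minus reference mean, nm.
#' @slot comparison the underlying \linkS4class{ComparisonResult}.
#' @exportClass VariantEffectCall
setClass("VariantEffectCall",
         representation(label = "character", deltaNm = "numeric",
                        comparison = "ComparisonResult"))

setValidity("VariantEffectCall", function(object) {
  ok <- switch(object@label,
    likely_enhanced = object@deltaNm < 0 && object@comparison@significant,
    likely_reduced  = object@deltaNm > 0 && object@comparison@significant,
    unchanged       = !object@comparison@significant,
    FALSE)
  if (!isTRUE(ok)) return("label inconsistent with delta/significance")
  TRUE
})

#' ReferenceMSA: an alignment with a designated reference record
#'
#' @slot aln \link[Biostrings]{AAStringSet} of equal-width aligned rows
#'   (gap "-", unknown "X").
#' @slot refId name of the reference record.
#' @exportClass ReferenceMSA
setClass("ReferenceMSA",
         representation(aln = "AAStringSet", refId = "character"))

setValidity("ReferenceMSA", function(object) {
  w <- Biostrings::width(object@aln)
  if (length(object@aln) < 2L) return("an MSA needs at least two records")
  if (length(unique(w)) != 1L) return("aligned rows must have equal length")
  if (!object@refId %in% names(object@aln))
    return(sprintf("reference id '%s' not found among records", object@refId))
  TRUE
})

#' ConservationReport: conservation of one alignment column
#'
#' @slot refPosition residue position in the ungapped reference (NA when
#'   the column was addressed directly).
#' @slot column 1-based alignment column.
#' @slot refResidue the reference residue at that column.
#' @slot conservedFraction fraction of counted sequences matching it.
#' @slot nSequences number of sequences counted (the denominator).
#' @slot substitutionCounts named integer vector of non-matching residues
#'   (includes "-" only when gaps are counted).
#' @slot countGaps whether gap-holding sequences entered the denominator.
#' @exportClass ConservationReport
setClass("ConservationReport",
         representation(refPosition = "numeric", column = "integer",
                        refResidue = "character",
                        conservedFraction = "numeric",
                        nSequences = "integer",
                        substitutionCounts = "integer",
                        countGaps = "logical"))

setValidity("ConservationReport", function(object) {
  nConserved <- round(object@conservedFraction * object@nSequences)
  if (nConserved + sum(object@substitutionCounts) != object@nSequences)
    return("conserved + substituted (+ gaps) must equal nSequences")
  TRUE
})

#' OUParams: Ornstein--Uhlenbeck parameters for a distance trace
#'
#' Mean-reverting Gaussian process used as the statistical stand-in for an
#' MD distance trace, with an optional one-time regime switch of the
#' stationary mean (detachment).
#'
#' @slot muNm stationary mean, nm.
#' @slot thetaPerPs mean-reversion rate, 1/ps.
#' @slot sigmaNm volatility, nm / sqrt(ps).
#' @slot x0Nm initial value, nm.
#' @slot switchTPs time of the regime switch, ps (NA for none).
#' @slot switchMuNm stationary mean after the switch, nm (NA for none).
#' @exportClass OUParams
setClass("OUParams",
         representation(muNm = "numeric", thetaPerPs = "numeric",
                        sigmaNm = "numeric", x0Nm = "numeric",
                        switchTPs = "numeric", switchMuNm = "numeric"),
         prototype(switchTPs = NA_real_, switchMuNm = NA_real_))

setValidity("OUParams", function(object) {
  if (object@thetaPerPs <= 0) return("theta must be > 0")
  if (object@sigmaNm < 0) return("sigma must be >= 0")
  if (object@muNm <= 0 || object@x0Nm <= 0) return("mu and x0 must be > 0")
  if (!is.na(object@switchTPs) && is.na(object@switchMuNm))
    return("a regime switch needs both switchTPs and switchMuNm")
  TRUE
})

#' ScenarioPreset: a named ligand x variant simulation scenario
#'
#' @slot name scenario label, "ligand:allele".
#' @slot ligand ligand label.
#' @slot allele star-allele label.
#' @slot ou \linkS4class{OUParams} calibrated to the complex.
#' @exportClass ScenarioPreset
setClass("ScenarioPreset",
         representation(name = "character", ligand = "character",
                        allele = "character", ou = "OUParams"))
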