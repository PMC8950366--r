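#' Construct a ReferenceMSA from aligned sequences
#'
#' @param seqs named character vector or
#'   \link[Biostrings]{AAStringSet} of equal-width aligned rows.
#' @param refId name of the reference record (default: first record).
#' @return A \linkS4class{ReferenceMSA}.
#' @export
referenceMSA <- function(seqs, refId = NULL) {
  if (is.character(seqs)) seqs <- Biostrings::AAStringSet(seqs)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("every record needs a name", call. = FALSE)
  if (is.null(refId)) refId <- names(seqs)[1]
  new("ReferenceMSA", aln = seqs, refId = refId)
}

#' Read a multiple-sequence alignment
#'
#' Reads aligned FASTA or Clustal via Biostrings.  The reference defaults
#' to the first record and can be reassigned with \code{refId<-}.
#'
#' @param path alignment file.
#' @param format "fasta" (aligned) or "clustal".
#' @param refId reference record name (default: first record).
#' @return A \linkS4class{ReferenceMSA}.
#' @export
readMSA <- function(path, format = c("fasta", "clustal"), refId = NULL) {
  format <- match.arg(format)
  if (format == "fasta") {
    seqs <- Biostrings::readAAStringSet(path)
    w <- Biostrings::width(seqs)
    if (length(unique(w)) != 1L) {
      bad <- which(w != w[1])[1]
      stop(sprintf(
        "ragged alignment: record '%s' has width %d, expected %d",
        names(seqs)[bad], w[bad], w[1]), call. = FALSE)
    }
  } else {
    aln <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    seqs <- as(aln, "AAStringSet")
  }
  if (length(seqs) < 2L)
    stop("an alignment needs at least 2 records", call. = FALSE)
  referenceMSA(seqs, refId)
}

.refRow <- function(msa) {
  as.character(msa@aln[[msa@refId]])
}

#' Map a reference residue position to an alignment column
#'
#' Returns the 1-based alignment column holding the
#' \code{refPosition}-th non-gap residue of the reference record.
#'
#' @param msa a \linkS4class{ReferenceMSA}.
#' @param refPosition 1-based position in the ungapped reference.
#' @return Integer column index.
#' @examples
#' m <- referenceMSA(c(ref = "A-CD", other = "AACD"))
#' mapPosition(m, 2)  # column 3
#' @export
mapPosition <- function(msa, refPosition) {
  stopifnot(is(msa, "ReferenceMSA"))
  chars <- strsplit(.refRow(msa), "")[[1]]
  nonGap <- cumsum(chars != "-")
  col <- which(chars != "-" & nonGap == refPosition)
  if (length(col) != 1L)
    stop(sprintf(
      "reference '%s' has only %d residues; position %d out of range",
      msa@refId, max(nonGap), refPosition), call. = FALSE)
  as.integer(col)
}

#' Conservation of one alignment column
#'
#' The conserved fraction is the share of sequences carrying the
#' reference residue at the column.  Gap-holding sequences are excluded
#' from both numerator and denominator by default (set
#' \code{countGaps = TRUE} to keep them in the denominator and count them
#' among the substitutions).
#'
#' @param msa a \linkS4class{ReferenceMSA}.
#' @param column 1-based alignment column.  Alternatively give
#'   \code{refPosition} to address the column through
#'   \code{\link{mapPosition}}.
#' @param countGaps keep gap rows in the denominator.
#' @param refPosition optional reference position (overrides
#'   \code{column}).
#' @return A \linkS4class{ConservationReport}.
#' @export
columnConservation <- function(msa, column = NULL, countGaps = FALSE,
                               refPosition = NULL) {
  stopifnot(is(msa, "ReferenceMSA"))
  if (!is.null(refPosition)) column <- mapPosition(msa, refPosition)
  if (is.null(column)) stop("give either column or refPosition",
                            call. = FALSE)
  width <- Biostrings::width(msa@aln)[1]
  if (column < 1L || column > width)
    stop(sprintf("column %d outside alignment width %d", column, width),
         call. = FALSE)
  colChars <- vapply(as.character(msa@aln),
                     function(s) substr(s, column, column), "")
  refRes <- substr(.refRow(msa), column, column)
  if (refRes == "-")
    stop("reference holds a gap at this column", call. = FALSE)
  isGap <- colChars == "-"
  counted <- if (countGaps) colChars else colChars[!isGap]
  if (length(counted) == 0L)
    stop("no ungapped observations at this column", call. = FALSE)
  conserved <- sum(counted == refRes)
  subs <- table(counted[counted != refRes])
  new("ConservationReport",
      refPosition = if (is.null(refPosition)) NA_real_ else
        as.numeric(refPosition),
      column = as.integer(column), refResidue = refRes,
      conservedFraction = conserved / length(counted),
      nSequences = length(counted),
      substitutionCounts = stats::setNames(as.integer(subs), names(subs)),
      countGaps = countGaps)
}

#' Conservation as an integer-rounded percentage
#'
#' @param report a \linkS4class{ConservationReport}.
#' @return Integer percentage (e.g. 95 for a fraction of 0.951).
#' @export
conservationPercent <- function(report) {
  stopifnot(is(report, "ConservationReport"))
  as.integer(round(100 * report@conservedFraction))
}

# the heme-binding motif around the Fe-coordinating Cys:
# G X [HR] X C [PLAV] G; position 7 ("+2", two downstream of the Cys)
# admits extra residues in the relaxed scan
.MOTIF_SETS <- list(c("G"), NULL, c("H", "R"), NULL, c("C"),
                    c("P", "L", "A", "V"), c("G"))

.motifScan <- function(seq, plusTwoSet) {
  chars <- strsplit(seq, "")[[1]]
  if (any(chars == "-"))
    stop("motif scan expects an ungapped sequence", call. = FALSE)
  n <- length(chars)
  sets <- .MOTIF_SETS
  sets[[7]] <- plusTwoSet
  hits <- data.frame(start = integer(), span = character(),
                     cysPos = integer(), plusTwoPos = integer(),
                     stringsAsFactors = FALSE)
  if (n < 7L) return(hits)
  for (s in seq_len(n - 6L)) {
    ok <- TRUE
    for (k in 1:7) {
      set <- sets[[k]]
      if (!is.null(set) && !(chars[s + k - 1L] %in% set)) {
        ok <- FALSE
        break
      }
    }
    if (ok)
      hits <- rbind(hits, data.frame(
        start = s, span = substr(seq, s, s + 6L),
        cysPos = s + 4L, plusTwoPos = s + 6L, stringsAsFactors = FALSE))
  }
  hits
}

#' Scan for the heme-binding motif
#'
#' Slides a 7-residue window over an ungapped sequence looking for
#' G-X-[HR]-X-C-[PLAV]-G, the conserved pattern around the
#' Fe-coordinating cysteine of heme proteins.  Each hit is annotated with
#' the Cys position and the "+2" position (two residues downstream of the
#' Cys, the motif's final G).  Overlapping hits are all reported.
#'
#' @param seq ungapped one-letter sequence.
#' @return data.frame with columns start, span, cysPos, plusTwoPos
#'   (1-based; empty for no match).
#' @examples
#' scanHemeMotif("GRHPCLG")
#' @export
scanHemeMotif <- function(seq) {
  .motifScan(seq, c("G"))
}

#' Heme-motif scan with a relaxed "+2" position
#'
#' Crystallographic surveys show the motif's final G (position +2 after
#' the Cys) tolerates substitutions (Ala, Ser, Lys among them); this scan
#' admits a caller-chosen residue set there in addition to G.
#'
#' @param seq ungapped one-letter sequence.
#' @param allowedPlusTwo residues admitted at the +2 position besides G;
#'   an empty set falls back to the strict scan.
#' @return data.frame as \code{\link{scanHemeMotif}}.
#' @export
relaxedMotifScan <- function(seq, allowedPlusTwo = c("A", "S", "K")) {
  .motifScan(seq, unique(c("G", allowedPlusTwo)))
}

#' Export a conservation report
#'
#' Writes the report as a single-row TSV plus a JSON mirror when
#' \code{jsonPath} is given.
#'
#' @param report a \linkS4class{ConservationReport}.
#' @param path TSV output path.
#' @param jsonPath optional JSON output path.
#' @return \code{path}, invisibly.
#' @export
exportConservation <- function(report, path, jsonPath = NULL) {
  row <- data.frame(
    ref_position = report@refPosition, column = report@column,
    ref_residue = report@refResidue,
    conserved_fraction = report@conservedFraction,
    conserved_percent = conservationPercent(report),
    n_sequences = report@nSequences,
    substitutions = paste(sprintf("%s:%d", names(report@substitutionCounts),
                                  report@substitutionCounts),
                          collapse = ","),
    count_gaps = report@countGaps)
  utils::write.table(row, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(as.list(row), jsonPath, auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}
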