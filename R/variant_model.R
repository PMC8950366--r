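#' Parse missense-mutation tokens
#'
#' Tokens follow the usual "G445R" shape: wild-type residue, author
#' position, substituted residue.
#'
#' @param tokens character vector like \code{c("G445R", "S486T")}.
#' @return data.frame with columns wt, pos, mut.
#' @export
parseMutations <- function(tokens) {
  tokens <- tokens[nzchar(trimws(tokens))]
  if (length(tokens) == 0L)
    return(data.frame(wt = character(), pos = integer(),
                      mut = character(), stringsAsFactors = FALSE))
  m <- regmatches(tokens, regexec("^([A-Z])([0-9]+)([A-Z])$", tokens))
  bad <- lengths(m) != 4L
  if (any(bad))
    stop("cannot parse mutation token(s): ",
         paste(tokens[bad], collapse = ", "), call. = FALSE)
  data.frame(wt = vapply(m, `[`, "", 2L),
             pos = as.integer(vapply(m, `[`, "", 3L)),
             mut = vapply(m, `[`, "", 4L),
             stringsAsFactors = FALSE)
}

#' Construct a variant definition
#'
#' @param allele star-nomenclature allele name, e.g. "*110".
#' @param mutations character vector of tokens like "G445R" (empty for
#'   the reference allele).
#' @return A \linkS4class{VariantDef}.
#' @export
variantDef <- function(allele, mutations = character()) {
  new("VariantDef", allele = allele, mutations = parseMutations(mutations))
}

#' Built-in CYP2D6 allele definitions
#'
#' The five alleles the package is calibrated around: the reference *1
#' (no mutations), *14A (P34S, G169R, R296C, S486T), *51 (R296C, E334A,
#' S486T), *110 (G445R) and *122 (V370I).  Positions are author numbering
#' of the mature CYP2D6 sequence.
#'
#' @return Named list of \linkS4class{VariantDef} objects.
#' @examples
#' mutationTable(builtinVariants()[["*110"]])
#' @export
builtinVariants <- function() {
  defs <- list(
    "*1"   = character(),
    "*14A" = c("P34S", "G169R", "R296C", "S486T"),
    "*51"  = c("R296C", "E334A", "S486T"),
    "*110" = "G445R",
    "*122" = "V370I")
  lapply(seq_along(defs), function(i)
    variantDef(names(defs)[i], defs[[i]])) |>
    stats::setNames(names(defs))
}

#' Read a variant table
#'
#' TSV with columns \code{allele} and \code{mutations}
#' (semicolon-separated tokens like "G445R;S486T"; empty for the
#' reference allele).
#'
#' @param path TSV path.
#' @return Named list of \linkS4class{VariantDef} objects.
#' @export
readVariantTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("allele", "mutations") %in% names(tab)))
    stop("variant table needs columns 'allele' and 'mutations'",
         call. = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    toks <- strsplit(tab$mutations[i], ";", fixed = TRUE)[[1]]
    variantDef(tab$allele[i], trimws(toks))
  })
  stats::setNames(out, tab$allele)
}

#' Read ddG annotations
#'
#' TSV with columns \code{allele} and \code{ddG_kcal_mol} (predicted
#' unfolding free-energy change; an external predictor's output).
#'
#' @param path TSV path.
#' @return data.frame with allele and ddG_kcal_mol.
#' @export
readDdgTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("allele", "ddG_kcal_mol") %in% names(tab)))
    stop("ddG table needs columns 'allele' and 'ddG_kcal_mol'",
         call. = FALSE)
  tab
}

#' Apply a variant's mutations to a sequence
#'
#' Every mutation's wild-type residue is checked against the sequence
#' before any substitution is made, guarding against numbering drift
#' between the sequence and the allele definition.
#'
#' @param seq one-letter sequence string.
#' @param offset author number of the first residue of \code{seq}.
#' @param v a \linkS4class{VariantDef}.
#' @return The mutated sequence string, differing from the input at
#'   exactly the mutated positions.
#' @examples
#' applyMutations("AG", 444, builtinVariants()[["*110"]])  # "AR"
#' @export
applyMutations <- function(seq, offset, v) {
  stopifnot(is(v, "VariantDef"))
  chars <- strsplit(seq, "")[[1]]
  m <- v@mutations
  for (i in seq_len(nrow(m))) {
    at <- m$pos[i] - offset + 1L
    if (at < 1L || at > length(chars))
      stop(sprintf("position %d outside sequence range [%d, %d]",
                   m$pos[i], offset, offset + length(chars) - 1L),
           call. = FALSE)
    if (chars[at] != m$wt[i])
      stop(sprintf(
        "wild-type mismatch at position %d: expected %s, found %s",
        m$pos[i], m$wt[i], chars[at]), call. = FALSE)
    chars[at] <- m$mut[i]
  }
  paste(chars, collapse = "")
}

#' Invert a variant definition
#'
#' Swaps wt and mut of every mutation, so applying a variant and then its
#' inverse restores the original sequence.
#'
#' @param v a \linkS4class{VariantDef}.
#' @return A \linkS4class{VariantDef} with reversed substitutions.
#' @export
invertVariant <- function(v) {
  m <- v@mutations
  new("VariantDef", allele = paste0(v@allele, ":inv"),
      mutations = data.frame(wt = m$mut, pos = m$pos, mut = m$wt,
                             stringsAsFactors = FALSE))
}

#' Classify mutation impact on protein stability
#'
#' Predicted unfolding free-energy changes below 1 kcal/mol are read as a
#' theoretically limited effect on protein stability; values at or above
#' the threshold as potentially destabilising (strict "<" at the
#' boundary).
#'
#' @param ddGKcalMol predicted unfolding ddG, kcal/mol.
#' @param thresholdKcalMol classification threshold (default 1.0).
#' @return A \linkS4class{StabilityCall}.
#' @examples
#' callLabel(classifyStability(0.9))  # "limited_effect"
#' @export
classifyStability <- function(ddGKcalMol, thresholdKcalMol = 1.0) {
  if (length(ddGKcalMol) != 1L || !is.finite(ddGKcalMol))
    stop("ddG must be a single finite number", call. = FALSE)
  lab <- if (ddGKcalMol < thresholdKcalMol) "limited_effect" else
    "potentially_destabilising"
  new("StabilityCall", ddGKcalMol = ddGKcalMol, label = lab)
}

#' Distance of mutation sites to the heme iron
#'
#' For each mutated position, the minimum over that residue's atoms of
#' the distance to the heme iron, reported in nm and annotated proximal
#' (inside the heme-pocket scale, default < 1.0 nm) or distal.  Mutations
#' far from the binding site are unlikely to reshape the binding
#' architecture directly.
#'
#' @param s a \linkS4class{HemeStructure}.
#' @param chain chain holding the mutated residues.
#' @param v a \linkS4class{VariantDef}.
#' @param feIndex atom index of the heme iron (see
#'   \code{\link{findHemeIron}}).
#' @param proximalCutoffNm proximal/distal cut-off, nm.
#' @return data.frame with columns pos, minDistNm, annotation.
#' @export
mutationSiteDistances <- function(s, chain, v, feIndex,
                                  proximalCutoffNm = 1.0) {
  stopifnot(is(s, "HemeStructure"), is(v, "VariantDef"))
  a <- s@atoms
  fe <- as.numeric(a[feIndex, c("x", "y", "z")])
  m <- v@mutations
  out <- data.frame(pos = integer(), minDistNm = numeric(),
                    annotation = character(), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(m))) {
    rows <- which(a$chainId == chain & a$resSeq == m$pos[i] & !a$het)
    if (length(rows) == 0L)
      stop(sprintf("residue %d not found in chain '%s'", m$pos[i], chain),
           call. = FALSE)
    d2 <- (a$x[rows] - fe[1])^2 + (a$y[rows] - fe[2])^2 +
      (a$z[rows] - fe[3])^2
    dNm <- sqrt(min(d2)) / .ANG_PER_NM
    out <- rbind(out, data.frame(
      pos = m$pos[i], minDistNm = dNm,
      annotation = if (dNm < proximalCutoffNm) "proximal" else "distal",
      stringsAsFactors = FALSE))
  }
  out
}
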