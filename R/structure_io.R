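#' Describe a ligand and its reactive atom
#'
#' @param resName 3-letter residue code used in the PDB file.
#' @param reactiveAtomName PDB atom name of the atom at which the metabolic
#'   reaction occurs (no standard annotation exists, so it must be given).
#' @param label human-readable ligand name; defaults to \code{resName}.
#' @return A \linkS4class{LigandSpec}.
#' @examples
#' ligandSpec("OTA", "C4", "ochratoxin A")
#' @export
ligandSpec <- function(resName, reactiveAtomName, label = resName) {
  new("LigandSpec", resName = resName,
      reactiveAtomName = reactiveAtomName, label = label)
}

# two-letter element symbols we trust when inferring from an atom name
.TWO_LETTER_ELEM <- c("FE", "ZN", "MG", "MN", "CU", "CO", "NI", "SE",
                      "BR", "CL")

.inferElement <- function(name, elesy) {
  out <- toupper(trimws(elesy))
  miss <- is.na(out) | !nzchar(out)
  if (any(miss)) {
    nm <- gsub("[0-9'\"]", "", toupper(trimws(name[miss])))
    out[miss] <- ifelse(nm %in% .TWO_LETTER_ELEM, nm, substr(nm, 1L, 1L))
  }
  out
}

# sanity-check fixed-width coordinate records before handing off to bio3d,
# so malformed files fail with a line number instead of a cryptic NA
.checkAtomLines <- function(lines) {
  rec <- grep("^(ATOM  |HETATM)", lines)
  if (length(rec) == 0L)
    stop("no ATOM/HETATM records found", call. = FALSE)
  for (i in rec) {
    ln <- lines[i]
    if (nchar(ln) < 54L)
      stop(sprintf("malformed PDB record at line %d: too short (%d chars)",
                   i, nchar(ln)), call. = FALSE)
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz))
      stop(sprintf("malformed PDB record at line %d: unreadable coordinates",
                   i), call. = FALSE)
  }
  invisible(rec)
}

.atomsFromBio3d <- function(pdb) {
  a <- pdb$atom
  data.frame(serial = as.integer(a$eleno),
             name = trimws(a$elety),
             element = .inferElement(a$elety, a$elesy),
             resName = trimws(a$resid),
             resSeq = as.integer(a$resno),
             chainId = ifelse(is.na(a$chain) | !nzchar(a$chain), " ", a$chain),
             het = a$type == "HETATM",
             x = a$x, y = a$y, z = a$z,
             stringsAsFactors = FALSE)
}

#' Read a single-model PDB structure
#'
#' Parses fixed-width ATOM/HETATM records (via bio3d) into a
#' \linkS4class{HemeStructure}.  Files holding more than one MODEL block
#' are refused: those are trajectories and belong to
#' \code{\link{readModelTrajectory}}.
#'
#' @param path path to a PDB file.
#' @param id structure label; defaults to the file name.
#' @return A \linkS4class{HemeStructure} with atoms in file order,
#'   coordinates in Angstrom, elements taken from columns 77--78 when
#'   present and inferred from the atom name otherwise.
#' @export
readPDB <- function(path, id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nModels <- sum(grepl("^MODEL", lines))
  if (nModels > 1L)
    stop(sprintf(
      "file has %d MODEL blocks; use readModelTrajectory() for trajectories",
      nModels), call. = FALSE)
  .checkAtomLines(lines)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  new("HemeStructure", atoms = .atomsFromBio3d(pdb), id = id)
}

#' Read a multi-model PDB trajectory
#'
#' Multi-model PDB is the package's native trajectory dialect: each MODEL
#' block is one frame over a constant atom set.  The topology is taken
#' from the first model.
#'
#' @param path path to a (multi-model) PDB file.
#' @param dtPs frame spacing in picoseconds.  The default of 10 ps makes a
#'   50 ns trajectory correspond to 5000 frames.
#' @param t0Ps time of the first frame, ps.
#' @param id trajectory label.
#' @return A \linkS4class{HemeTrajectory} with frames ordered by MODEL
#'   number.
#' @export
readModelTrajectory <- function(path, dtPs = 10, t0Ps = 0,
                                id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  .checkAtomLines(lines)
  starts <- grep("^MODEL", lines)
  if (length(starts) >= 2L) {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(starts))
      stop("unbalanced MODEL/ENDMDL blocks", call. = FALSE)
    counts <- mapply(function(s, e)
      sum(grepl("^(ATOM  |HETATM)", lines[s:e])), starts, ends)
    if (length(unique(counts)) != 1L) {
      bad <- which(counts != counts[1])[1]
      stop(sprintf(
        "model %d has %d atoms but model 1 has %d: atom count must be constant",
        bad, counts[bad], counts[1]), call. = FALSE)
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- .atomsFromBio3d(pdb)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  nAtoms <- nrow(atoms)
  nFrm <- nrow(xyz)
  coords <- array(NA_real_, dim = c(nAtoms, 3L, nFrm))
  for (f in seq_len(nFrm))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  structure0 <- atoms
  structure0[, c("x", "y", "z")] <- coords[, , 1L]
  new("HemeTrajectory",
      structure = new("HemeStructure", atoms = structure0, id = id),
      coords = coords, dtPs = dtPs, t0Ps = t0Ps)
}

.writeFrames <- function(atoms, xyzMat, path) {
  bio3d::write.pdb(pdb = NULL, file = path, xyz = xyzMat,
                   type = ifelse(atoms$het, "HETATM", "ATOM"),
                   resno = atoms$resSeq, resid = atoms$resName,
                   eleno = atoms$serial, elety = atoms$name,
                   chain = atoms$chainId, elesy = atoms$element)
  invisible(path)
}

#' Write a structure to a PDB file
#'
#' @param s a \linkS4class{HemeStructure}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writePDB <- function(s, path) {
  stopifnot(is(s, "HemeStructure"))
  a <- s@atoms
  .writeFrames(a, matrix(t(as.matrix(a[, c("x", "y", "z")])), nrow = 1L),
               path)
}

#' Write a trajectory as multi-model PDB
#'
#' @param traj a \linkS4class{HemeTrajectory}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeModelTrajectory <- function(traj, path) {
  stopifnot(is(traj, "HemeTrajectory"))
  nFrm <- dim(traj@coords)[3]
  xyz <- t(vapply(seq_len(nFrm),
                  function(f) as.numeric(t(traj@coords[, , f])),
                  numeric(dim(traj@coords)[1] * 3L)))
  .writeFrames(traj@structure@atoms, xyz, path)
}

#' Locate the heme iron
#'
#' The heme iron anchors every distance measurement: oxidation chemistry
#' happens at or near this atom, so the reactive-atom--Fe distance is the
#' catalytic-competence signal.
#'
#' @param s a \linkS4class{HemeStructure}.
#' @return Integer index (row in \code{atomTable(s)}) of the single FE
#'   atom inside a heme residue (HEM/HEC/HEA/HEB).
#' @export
findHemeIron <- function(s) {
  stopifnot(is(s, "HemeStructure"))
  a <- s@atoms
  idx <- which(a$element == "FE" &
               a$resName %in% c("HEM", "HEC", "HEA", "HEB"))
  if (length(idx) == 0L)
    stop("no heme iron found (FE atom within a HEM/HEC/HEA/HEB residue)",
         call. = FALSE)
  if (length(idx) > 1L)
    stop("multiple heme irons found (serials ",
         paste(a$serial[idx], collapse = ", "),
         "); disambiguate via configuration", call. = FALSE)
  idx
}

#' Locate the ligand's reactive atom
#'
#' @param s a \linkS4class{HemeStructure}.
#' @param lig a \linkS4class{LigandSpec}.
#' @return Integer index of the unique atom named
#'   \code{lig@reactiveAtomName} within the unique residue
#'   \code{lig@resName}.
#' @export
selectReactiveAtom <- function(s, lig) {
  stopifnot(is(s, "HemeStructure"), is(lig, "LigandSpec"))
  a <- s@atoms
  idx <- which(a$resName == lig@resName & a$name == lig@reactiveAtomName)
  if (length(idx) != 1L)
    stop(sprintf(
      "expected exactly one atom '%s' in residue '%s', found %d",
      lig@reactiveAtomName, lig@resName, length(idx)), call. = FALSE)
  idx
}

#' Extract a chain's one-letter sequence
#'
#' Only polymer (ATOM) residues enter the sequence; HETATM cofactors and
#' ligands are excluded.  Non-standard polymer residues map to "X".  Gaps
#' in author numbering do not insert placeholders; the first residue
#' number is returned as the offset so positions can be mapped back.
#'
#' @param s a \linkS4class{HemeStructure}.
#' @param chain single-character chain identifier.
#' @return A list with \code{sequence} (one-letter string) and
#'   \code{offset} (author number of the first residue).
#' @export
extractSequence <- function(s, chain) {
  stopifnot(is(s, "HemeStructure"))
  a <- s@atoms
  a <- a[a$chainId == chain & !a$het, , drop = FALSE]
  if (nrow(a) == 0L)
    stop("chain '", chain, "' not found (or holds no polymer atoms)",
         call. = FALSE)
  res <- a[!duplicated(a$resSeq), c("resSeq", "resName")]
  res <- res[order(res$resSeq), ]
  letters1 <- unname(.AA3TO1[res$resName])
  letters1[is.na(letters1)] <- "X"
  list(sequence = paste(letters1, collapse = ""),
       offset = res$resSeq[1])
}

#' Atom selections
#'
#' \code{selectCalpha} returns the indices of protein C-alpha atoms;
#' \code{selectResidueAtoms} the indices of all atoms of a named residue
#' type (e.g. the ligand).
#'
#' @param s a \linkS4class{HemeStructure}.
#' @param resName 3-letter residue code.
#' @return Integer atom indices.
#' @export
selectCalpha <- function(s) {
  a <- s@atoms
  which(!a$het & a$name == "CA" & a$resName %in% names(.AA3TO1))
}

#' @rdname selectCalpha
#' @export
selectResidueAtoms <- function(s, resName) {
  which(s@atoms$resName == resName)
}
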