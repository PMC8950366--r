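#' Optimal rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD of the
#' moving point set P onto the target Q, via SVD of the cross-covariance
#' with a determinant correction that excludes reflections (physical
#' rigid motion only).
#'
#' @param P n x 3 matrix of moving coordinates, Angstrom.
#' @param Q n x 3 matrix of target coordinates, Angstrom.
#' @return List with \code{rotation} (3 x 3, det +1), \code{translation}
#'   (length 3, Angstrom) such that \code{P \%*\% t(rotation) +
#'   translation} best matches Q, and \code{rmsdNm}, the minimised RMSD
#'   in nm.
#' @examples
#' P <- matrix(rnorm(12), 4, 3)
#' kabsch(P, P)$rmsdNm  # 0
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q)))
    stop("P and Q must have identical dimensions", call. = FALSE)
  if (ncol(P) != 3L) stop("coordinates must be n x 3", call. = FALSE)
  if (nrow(P) < 3L)
    stop("need at least 3 points for a rigid superposition", call. = FALSE)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(cq - R %*% cp)
  Pfit <- Pc %*% t(R)
  rmsdA <- sqrt(mean(rowSums((Pfit - Qc)^2)))
  list(rotation = R, translation = tr, rmsdNm = rmsdA / .ANG_PER_NM)
}

#' RMSD time series over a trajectory
#'
#' Each frame is rigidly superposed onto the reference frame using the
#' \code{superposeOn} atoms (Kabsch), then the RMSD is computed over the
#' \code{analyse} atoms.  The conventional modes are: protein stability,
#' analyse = superposeOn = C-alpha; ligand stability, superposeOn =
#' C-alpha with analyse = ligand atoms, i.e. ligand RMSD in the protein
#' frame, which is the mode that captures detachment.  RMSD is
#' mass-unweighted.
#'
#' @param traj a \linkS4class{HemeTrajectory}.
#' @param analyse integer atom indices to measure.
#' @param superposeOn integer atom indices to fit on.
#' @param reference reference frame index (default 1, i.e. frame 0 of the
#'   run; the input is assumed post-equilibration).
#' @param selectionLabel "protein_calpha" or "ligand".
#' @return An \linkS4class{RMSDSeries} in nm.
#' @export
rmsdSeries <- function(traj, analyse, superposeOn,
                       reference = 1L,
                       selectionLabel = c("protein_calpha", "ligand")) {
  stopifnot(is(traj, "HemeTrajectory"))
  selectionLabel <- match.arg(selectionLabel)
  if (length(analyse) == 0L || length(superposeOn) == 0L)
    stop("empty atom selection", call. = FALSE)
  nFrm <- dim(traj@coords)[3]
  if (reference < 1L || reference > nFrm)
    stop("reference frame out of range", call. = FALSE)
  refFit <- traj@coords[superposeOn, , reference, drop = FALSE][, , 1]
  refAna <- traj@coords[analyse, , reference, drop = FALSE][, , 1]
  vals <- vapply(seq_len(nFrm), function(f) {
    fit <- kabsch(traj@coords[superposeOn, , f, drop = FALSE][, , 1], refFit)
    moved <- traj@coords[analyse, , f, drop = FALSE][, , 1] %*%
      t(fit$rotation)
    moved <- sweep(moved, 2, fit$translation, `+`)
    sqrt(mean(rowSums((moved - refAna)^2))) / .ANG_PER_NM
  }, numeric(1))
  new("RMSDSeries",
      timesPs = traj@t0Ps + (seq_len(nFrm) - 1) * traj@dtPs,
      valuesNm = vals, selectionLabel = selectionLabel)
}

#' Fe--reactive-atom distance time series
#'
#' The discriminant signal: per-frame Euclidean distance between two
#' atoms (typically the heme iron and the ligand's reactive atom),
#' reported in nm.
#'
#' @param traj a \linkS4class{HemeTrajectory}.
#' @param i,j distinct atom indices (order irrelevant).
#' @param label series label, e.g. "OTA:*1".
#' @return A \linkS4class{DistanceSeries}.
#' @export
distanceSeries <- function(traj, i, j, label = "complex") {
  stopifnot(is(traj, "HemeTrajectory"))
  nAtoms <- dim(traj@coords)[1]
  if (i == j) stop("atom indices must be distinct", call. = FALSE)
  if (any(c(i, j) < 1L) || any(c(i, j) > nAtoms))
    stop("atom index out of range", call. = FALSE)
  dxyz <- traj@coords[i, , ] - traj@coords[j, , ]
  vals <- sqrt(colSums(dxyz^2)) / .ANG_PER_NM
  if (any(vals == 0))
    message(sum(vals == 0), " frame(s) with coincident atoms (distance 0)")
  nFrm <- dim(traj@coords)[3]
  new("DistanceSeries",
      timesPs = traj@t0Ps + (seq_len(nFrm) - 1) * traj@dtPs,
      valuesNm = vals, label = label)
}

#' Export a time series as TSV
#'
#' Columns time_ps, value_nm, label.
#'
#' @param series a \linkS4class{DistanceSeries} or
#'   \linkS4class{RMSDSeries}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
exportSeriesTSV <- function(series, path) {
  lab <- seriesLabel(series)
  utils::write.table(
    data.frame(time_ps = timesPs(series), value_nm = valuesNm(series),
               label = lab),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
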