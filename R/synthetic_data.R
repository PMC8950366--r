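#' Construct Ornstein--Uhlenbeck parameters
#'
#' @param muNm stationary mean, nm.
#' @param thetaPerPs mean-reversion rate, 1/ps.
#' @param sigmaNm volatility, nm/sqrt(ps).  The stationary SD is
#'   sigma/sqrt(2 theta).
#' @param x0Nm initial value (default: start at the stationary mean).
#' @param switchTPs optional regime-switch time, ps.
#' @param switchMuNm stationary mean after the switch, nm.
#' @return An \linkS4class{OUParams}.
#' @export
ouParams <- function(muNm, thetaPerPs, sigmaNm, x0Nm = muNm,
                     switchTPs = NA_real_, switchMuNm = NA_real_) {
  new("OUParams", muNm = muNm, thetaPerPs = thetaPerPs,
      sigmaNm = sigmaNm, x0Nm = x0Nm,
      switchTPs = as.numeric(switchTPs),
      switchMuNm = as.numeric(switchMuNm))
}

# hard-sphere contact floor for Fe--atom distances, nm
.CONTACT_FLOOR_NM <- 0.15

#' Simulate an OU distance trace
#'
#' Exact discretisation of the Ornstein--Uhlenbeck process,
#' \deqn{x_{t+dt} = \mu + (x_t - \mu) e^{-\theta dt} +
#'   \sigma \sqrt{(1 - e^{-2\theta dt}) / (2\theta)}\; z,}
#' the statistical stand-in for an MD distance trace: mean-reverting,
#' Gaussian, exponentially autocorrelated.  After the optional regime
#' switch, the stationary mean is replaced (detachment).  Values are
#' floored at the 0.15 nm hard-sphere contact distance; the number of
#' floored frames is recorded in the series metadata and reported via a
#' message when non-zero.
#'
#' @param p an \linkS4class{OUParams}.
#' @param nFrames number of frames (>= 2).
#' @param dtPs frame spacing, ps.
#' @param seed RNG seed.
#' @param label series label.
#' @return A \linkS4class{DistanceSeries}; frame 1 is at t = 0 with value
#'   x0.
#' @export
simulateDistanceSeries <- function(p, nFrames, dtPs = 10, seed = 1,
                                   label = "synthetic") {
  stopifnot(is(p, "OUParams"))
  validObject(p)
  if (nFrames < 2L) stop("need at least 2 frames", call. = FALSE)
  if (dtPs <= 0) stop("dtPs must be positive", call. = FALSE)
  times <- (seq_len(nFrames) - 1) * dtPs
  a <- exp(-p@thetaPerPs * dtPs)
  noiseSd <- p@sigmaNm * sqrt((1 - a^2) / (2 * p@thetaPerPs))
  mu <- rep(p@muNm, nFrames)
  if (!is.na(p@switchTPs)) mu[times >= p@switchTPs] <- p@switchMuNm
  set.seed(seed)
  z <- stats::rnorm(nFrames - 1L)
  # x_t = a x_{t-1} + [mu_t (1 - a) + noise]; recursive filter from x0
  drive <- mu[-1L] * (1 - a) + noiseSd * z
  x <- c(p@x0Nm,
         as.numeric(stats::filter(drive, a, method = "recursive",
                                  init = p@x0Nm)))
  floored <- sum(x < .CONTACT_FLOOR_NM)
  if (floored > 0) {
    message(floored, " frame(s) floored at the ",
            .CONTACT_FLOOR_NM, " nm contact distance")
    x <- pmax(x, .CONTACT_FLOOR_NM)
  }
  new("DistanceSeries", timesPs = times, valuesNm = x, label = label,
      metadata = list(seed = seed, flooredFrames = floored,
                      params = p))
}

#' Calibrated ligand x variant scenario presets
#'
#' One preset per reported CYP2D6 complex: dextromethorphan, bufuralol
#' and ochratoxin A (OTA) against the alleles *1, *14A, *51, plus
#' OTA-*110 and OTA-*122.  Stationary means equal the reported mean
#' Fe--reactive-atom distances of the nine numerically characterised
#' complexes; OTA-*122, for which only a marked early detachment is
#' described, carries a regime switch (default 5 ns into the run) to a
#' detached mean instead.  Volatilities are calibrated so that the naive
#' SE over 5000 frames matches the reported SEs, capped so the contact
#' floor is hit with probability < 1e-4 per frame; the mean-reversion
#' rate (0.2/ps, 5 ps decorrelation time) leaves mild autocorrelation at
#' the 10 ps frame spacing.  Shipped as a versioned TSV under
#' \code{extdata}.
#'
#' @return Named list of \linkS4class{ScenarioPreset} objects.
#' @examples
#' scenarioPresets()[["OTA:*110"]]
#' @export
scenarioPresets <- function() {
  path <- system.file("extdata", "scenario_presets.tsv",
                      package = "CypDiscriminant", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    new("ScenarioPreset", name = r$scenario, ligand = r$ligand,
        allele = r$allele,
        ou = ouParams(r$mu_nm, r$theta_per_ps, r$sigma_nm_sqrtps,
                      x0Nm = r$x0_nm, switchTPs = r$switch_t_ps,
                      switchMuNm = r$switch_mu_nm))
  })
  stats::setNames(out, tab$scenario)
}

#' Build a toy protein--heme--ligand complex
#'
#' A desk-scale stand-in for a docked CYP complex: one protein chain
#' (N/CA/C backbone on a self-avoiding random walk, random sequence), one
#' HEM residue holding a single FE atom, and one ligand residue
#' containing the named reactive atom placed 4.39 Angstrom from the iron.
#' Deterministic under the seed.
#'
#' @param nResidues number of protein residues (>= 10).
#' @param lig a \linkS4class{LigandSpec}.
#' @param seed RNG seed.
#' @return A \linkS4class{HemeStructure} on which
#'   \code{\link{findHemeIron}} and \code{\link{selectReactiveAtom}}
#'   succeed and \code{\link{extractSequence}} returns the generating
#'   sequence.
#' @export
buildToyComplex <- function(nResidues, lig, seed = 1) {
  stopifnot(is(lig, "LigandSpec"))
  if (nResidues < 10L) stop("need at least 10 residues", call. = FALSE)
  set.seed(seed)
  # self-avoiding CA walk, 3.8 A steps, 3.2 A exclusion
  ca <- matrix(NA_real_, nResidues, 3)
  ca[1, ] <- c(0, 0, 0)
  for (i in 2:nResidues) {
    for (try in 1:200) {
      u <- stats::rnorm(3)
      cand <- ca[i - 1, ] + 3.8 * u / sqrt(sum(u^2))
      d2 <- rowSums(sweep(ca[seq_len(i - 1), , drop = FALSE], 2,
                          cand)^2)
      if (all(d2 > 3.2^2)) break
      cand <- NULL
    }
    if (is.null(cand))
      stop("self-avoiding walk failed; try another seed", call. = FALSE)
    ca[i, ] <- cand
  }
  seqAA <- sample(.AA1, nResidues, replace = TRUE)
  res3 <- names(.AA3TO1)[match(seqAA, .AA3TO1)]
  atoms <- do.call(rbind, lapply(seq_len(nResidues), function(i) {
    data.frame(name = c("N", "CA", "C"), element = c("N", "C", "C"),
               resName = res3[i], resSeq = i, chainId = "A", het = FALSE,
               x = ca[i, 1] + c(-1.2, 0, 1.2),
               y = ca[i, 2] + c(0.4, 0, 0.4),
               z = ca[i, 3] + c(0, 0, 0), stringsAsFactors = FALSE)
  }))
  # heme iron well outside the protein envelope
  fe <- c(max(atoms$x) + 8, mean(atoms$y), mean(atoms$z))
  atoms <- rbind(atoms, data.frame(
    name = "FE", element = "FE", resName = "HEM",
    resSeq = nResidues + 10L, chainId = "A", het = TRUE,
    x = fe[1], y = fe[2], z = fe[3], stringsAsFactors = FALSE))
  # ligand: reactive atom 4.39 A from Fe plus two scaffold atoms
  u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
  rx <- fe + 4.39 * u
  atoms <- rbind(atoms, data.frame(
    name = c(lig@reactiveAtomName, "C98", "C99"),
    element = c("C", "C", "C"), resName = lig@resName,
    resSeq = nResidues + 11L, chainId = "A", het = TRUE,
    x = rx[1] + c(0, 1.5, 2.6), y = rx[2] + c(0, 0.4, -0.4),
    z = rx[3] + c(0, 0.2, 0.9), stringsAsFactors = FALSE))
  atoms <- cbind(serial = seq_len(nrow(atoms)), atoms)
  new("HemeStructure", atoms = atoms,
      id = sprintf("toy-%s-%d", lig@label, nResidues))
}

#' Embed a distance series into a toy trajectory
#'
#' Builds a trajectory in which, frame by frame, the ligand is rigidly
#' translated so that the reactive-atom--Fe distance equals the series
#' value exactly (before jitter), along the fixed direction of the
#' initial pose.  Independent Gaussian jitter of scale \code{jitterNm}
#' perturbs protein atoms only; the heme iron and the ligand are not
#' jittered, so the embedded distances are exact.
#'
#' @param s a \linkS4class{HemeStructure} with identifiable heme iron and
#'   reactive atom.
#' @param lig the \linkS4class{LigandSpec} naming the ligand residue.
#' @param series the \linkS4class{DistanceSeries} to embed.
#' @param jitterNm protein jitter scale, nm (0 for none).
#' @param seed RNG seed for the jitter.
#' @return A \linkS4class{HemeTrajectory} whose
#'   \code{\link{distanceSeries}} reproduces \code{series}.
#' @export
embedSeriesIntoTrajectory <- function(s, lig, series, jitterNm = 0,
                                      seed = 1) {
  stopifnot(is(s, "HemeStructure"), is(lig, "LigandSpec"),
            is(series, "DistanceSeries"))
  if (any(series@valuesNm < .CONTACT_FLOOR_NM))
    stop("series contains values below the ", .CONTACT_FLOOR_NM,
         " nm contact floor", call. = FALSE)
  feIdx <- findHemeIron(s)
  rxIdx <- selectReactiveAtom(s, lig)
  ligIdx <- selectResidueAtoms(s, lig@resName)
  a <- s@atoms
  xyz0 <- as.matrix(a[, c("x", "y", "z")])
  fe <- xyz0[feIdx, ]
  u <- xyz0[rxIdx, ] - fe
  nu <- sqrt(sum(u^2))
  u <- if (nu > 0) u / nu else c(1, 0, 0)
  protIdx <- which(!a$het)
  nFrm <- length(series@valuesNm)
  dts <- diff(series@timesPs)
  dtPs <- if (nFrm > 1L) dts[1] else 10
  set.seed(seed)
  coords <- array(NA_real_, dim = c(nrow(a), 3L, nFrm))
  for (f in seq_len(nFrm)) {
    frame <- xyz0
    target <- fe + u * series@valuesNm[f] * .ANG_PER_NM
    delta <- target - xyz0[rxIdx, ]
    frame[ligIdx, ] <- sweep(xyz0[ligIdx, , drop = FALSE], 2, delta, `+`)
    if (jitterNm > 0)
      frame[protIdx, ] <- frame[protIdx, ] +
        matrix(stats::rnorm(length(protIdx) * 3L,
                            sd = jitterNm * .ANG_PER_NM),
               ncol = 3L)
    coords[, , f] <- frame
  }
  structure0 <- a
  structure0[, c("x", "y", "z")] <- coords[, , 1L]
  new("HemeTrajectory",
      structure = new("HemeStructure", atoms = structure0, id = s@id),
      coords = coords, dtPs = dtPs, t0Ps = series@timesPs[1])
}

#' Simulate an MSA with controlled column conservation
#'
#' Record 1 is the reference.  Exactly \code{nSubstituted} of the other
#' records carry a residue from \code{substitutionAlphabet} at the target
#' column; the rest match the reference there.  All other columns of
#' non-reference records mutate i.i.d. at rate
#' \code{1 - backgroundIdentity}.  The alignment is gapless, so the
#' column conservation at the target position is exactly
#' \code{(nSequences - nSubstituted) / nSequences}.
#'
#' @param nSequences total records including the reference.
#' @param nSubstituted records substituted at the target column
#'   (<= nSequences - 1).
#' @param refSeq reference sequence (ungapped).
#' @param refPosition target position, 1-based.
#' @param substitutionAlphabet residues used for the planted
#'   substitutions (the reference residue is excluded automatically).
#' @param backgroundIdentity expected per-column identity elsewhere.
#' @param seed RNG seed.
#' @return A \linkS4class{ReferenceMSA} with reference record "REF".
#' @export
simulateMSA <- function(nSequences, nSubstituted, refSeq, refPosition,
                        substitutionAlphabet = c("A", "S", "Y", "F",
                                                 "D", "L"),
                        backgroundIdentity = 0.8, seed = 1) {
  refChars <- strsplit(refSeq, "")[[1]]
  L <- length(refChars)
  if (refPosition < 1L || refPosition > L)
    stop("refPosition outside the reference sequence", call. = FALSE)
  if (nSubstituted < 0L || nSubstituted > nSequences - 1L)
    stop("need 0 <= nSubstituted <= nSequences - 1", call. = FALSE)
  refRes <- refChars[refPosition]
  subAlphabet <- setdiff(substitutionAlphabet, refRes)
  if (nSubstituted > 0L && length(subAlphabet) == 0L)
    stop("substitution alphabet holds only the reference residue",
         call. = FALSE)
  set.seed(seed)
  nOther <- nSequences - 1L
  rows <- matrix(rep(refChars, nOther), nrow = nOther, byrow = TRUE)
  # background divergence everywhere except the target column
  mutMask <- matrix(stats::runif(nOther * L) > backgroundIdentity,
                    nOther, L)
  mutMask[, refPosition] <- FALSE
  nMut <- sum(mutMask)
  if (nMut > 0)
    rows[mutMask] <- vapply(rows[mutMask], function(ch)
      sample(setdiff(.AA1, ch), 1L), "")
  if (nSubstituted > 0L) {
    who <- sample.int(nOther, nSubstituted)
    rows[who, refPosition] <- sample(subAlphabet, nSubstituted,
                                     replace = TRUE)
  }
  seqs <- c(refSeq, apply(rows, 1L, paste, collapse = ""))
  names(seqs) <- c("REF", sprintf("SEQ%04d", seq_len(nOther)))
  referenceMSA(seqs, "REF")
}
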