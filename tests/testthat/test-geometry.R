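randRot <- function(seed) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(9), 3))) -> Q
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

test_that("kabsch recovers identity and pure translations exactly", {
  set.seed(1)
  P <- matrix(rnorm(15), 5, 3)
  fit <- kabsch(P, P)
  expect_equal(fit$rmsdNm, 0, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)

  Q <- sweep(P, 2, c(1, 2, 3), `+`)
  fit2 <- kabsch(P, Q)
  expect_equal(fit2$rmsdNm, 0, tolerance = 1e-12)
  expect_equal(fit2$translation, c(1, 2, 3), tolerance = 1e-9)

  expect_error(kabsch(P[1:2, ], P[1:2, ]), "at least 3")
  expect_error(kabsch(P, P[1:4, ]), "identical dimensions")
})

test_that("kabsch matches a brute-force minimiser over rotation space", {
  # asymmetric 4-point set vs a randomly rotated copy plus noise
  set.seed(42)
  P <- matrix(c(0, 0, 0, 3, 0, 0, 0, 2, 0, 1, 1, 4), 4, 3, byrow = TRUE)
  Q <- P %*% t(randRot(7)) + matrix(rnorm(12, sd = 0.1), 4, 3)

  eulerRmsd <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    R <- matrix(c(cy * cz, cy * sz, -sy,
                  sx * sy * cz - cx * sz, sx * sy * sz + cx * cz, sx * cy,
                  cx * sy * cz + sx * sz, cx * sy * sz - sx * cz, cx * cy),
                3, 3, byrow = TRUE)
    Pc <- scale(P, scale = FALSE) %*% t(R)
    Qc <- scale(Q, scale = FALSE)
    sqrt(mean(rowSums((Pc - Qc)^2)))
  }
  best <- Inf
  for (st in list(c(0, 0, 0), c(1, 1, 1), c(-1, 2, 0), c(2, -1, 1))) {
    o <- optim(st, eulerRmsd, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  expect_equal(kabsch(P, Q)$rmsdNm, best / 10, tolerance = 1e-3)
})

test_that("kabsch agrees with bio3d's superposition on random sets", {
  for (seed in 1:5) {
    set.seed(seed)
    P <- matrix(rnorm(30), 10, 3)
    Q <- P %*% t(randRot(seed + 50)) +
      matrix(rnorm(30, sd = 0.2), 10, 3)
    ours <- kabsch(P, Q)$rmsdNm * 10
    theirs <- bio3d::rmsd(as.numeric(t(Q)), as.numeric(t(P)),
                          fit = TRUE)
    expect_lt(abs(ours - theirs), 6e-4)  # bio3d rounds to 3 decimals
  }
})

test_that("superposed RMSD never exceeds the unsuperposed RMSD", {
  for (seed in 1:20) {
    set.seed(seed)
    P <- matrix(rnorm(24), 8, 3)
    Q <- matrix(rnorm(24), 8, 3)
    raw <- sqrt(mean(rowSums((P - Q)^2))) / 10
    expect_lte(kabsch(P, Q)$rmsdNm, raw + 1e-12)
  }
})

test_that("rmsdSeries is zero for identical and rigidly moved frames", {
  s <- toyComplex()
  ca <- selectCalpha(s)
  a <- atomTable(s)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  nFrm <- 5L
  coords <- array(rep(xyz, nFrm), dim = c(nrow(a), 3, nFrm))
  traj <- new("HemeTrajectory", structure = s, coords = coords,
              dtPs = 10, t0Ps = 0)
  expect_equal(valuesNm(rmsdSeries(traj, ca, ca)), rep(0, nFrm),
               tolerance = 1e-9)

  # rigid rotation + translation per frame: superposition removes it
  for (f in 2:nFrm)
    coords[, , f] <- xyz %*% t(randRot(f)) +
      matrix(rep(c(f, -f, 2 * f), each = nrow(a)), ncol = 3)
  trajR <- new("HemeTrajectory", structure = s, coords = coords,
               dtPs = 10, t0Ps = 0)
  expect_equal(valuesNm(rmsdSeries(trajR, ca, ca)), rep(0, nFrm),
               tolerance = 1e-9)
  expect_error(rmsdSeries(traj, integer(0), ca), "empty")
})

test_that("ligand RMSD in the protein frame equals constructed offsets", {
  s <- toyComplex()
  ca <- selectCalpha(s)
  ligIdx <- selectResidueAtoms(s, "OTA")
  a <- atomTable(s)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  offsets <- c(0, 0.5, 1.2, 2.0)  # Angstrom, along x
  coords <- array(NA_real_, dim = c(nrow(a), 3, length(offsets)))
  for (f in seq_along(offsets)) {
    frame <- xyz
    frame[ligIdx, 1] <- frame[ligIdx, 1] + offsets[f]
    coords[, , f] <- frame
  }
  traj <- new("HemeTrajectory", structure = s, coords = coords,
              dtPs = 10, t0Ps = 0)
  r <- rmsdSeries(traj, ligIdx, ca, selectionLabel = "ligand")
  expect_equal(valuesNm(r), offsets / 10, tolerance = 1e-3)
})

test_that("distanceSeries converts a fixed placement to nm", {
  atoms <- data.frame(serial = 1:2, name = c("FE", "C4"),
                      element = c("FE", "C"),
                      resName = c("HEM", "OTA"), resSeq = c(1L, 2L),
                      chainId = "A", het = TRUE,
                      x = c(0, 4.39), y = 0, z = 0)
  s <- new("HemeStructure", atoms = atoms, id = "pair")
  coords <- array(rep(as.matrix(atoms[, c("x", "y", "z")]), 3),
                  dim = c(2, 3, 3))
  traj <- new("HemeTrajectory", structure = s, coords = coords,
              dtPs = 10, t0Ps = 0)
  d <- distanceSeries(traj, 2L, 1L)
  expect_equal(valuesNm(d), rep(0.439, 3), tolerance = 1e-12)
  expect_equal(timesPs(d), c(0, 10, 20))
  expect_error(distanceSeries(traj, 1L, 1L), "distinct")

  coords[2, , 2] <- coords[1, , 2]  # coincident in one frame: allowed
  trajC <- new("HemeTrajectory", structure = s, coords = coords,
               dtPs = 10, t0Ps = 0)
  expect_message(dC <- distanceSeries(trajC, 2L, 1L), "coincident")
  expect_equal(valuesNm(dC)[2], 0)
})

test_that("distanceSeries is invariant under per-frame rigid transforms", {
  s <- toyComplex()
  lig <- toyLig()
  ser <- simulateDistanceSeries(ouParams(0.5, 0.2, 0.0447), 20, 10,
                                seed = 2)
  traj <- embedSeriesIntoTrajectory(s, lig, ser)
  i <- selectReactiveAtom(s, lig); j <- findHemeIron(s)
  base <- valuesNm(distanceSeries(traj, i, j))
  coords <- traj@coords
  for (f in seq_len(dim(coords)[3]))
    coords[, , f] <- coords[, , f] %*% t(randRot(f + 100)) +
      matrix(rep(c(3, -7, 11), each = dim(coords)[1]), ncol = 3)
  trajT <- new("HemeTrajectory", structure = traj@structure,
               coords = coords, dtPs = traj@dtPs, t0Ps = traj@t0Ps)
  expect_equal(valuesNm(distanceSeries(trajT, i, j)), base,
               tolerance = 1e-9)
})
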