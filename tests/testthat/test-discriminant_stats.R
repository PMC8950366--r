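distSeries <- function(values, dt = 10, label = "x") {
  new("DistanceSeries", timesPs = (seq_along(values) - 1) * dt,
      valuesNm = values, label = label)
}

test_that("summarizeSeries reproduces hand-computed statistics", {
  cst <- summarizeSeries(distSeries(rep(0.5, 100)))
  expect_equal(meanNm(cst), 0.5)
  expect_equal(seNm(cst), 0)

  two <- summarizeSeries(distSeries(c(0.4, 0.6)))
  expect_equal(meanNm(two), 0.5)
  expect_equal(sdNm(two), sqrt(0.02), tolerance = 1e-12)  # ~0.1414
  expect_equal(seNm(two), 0.1, tolerance = 1e-12)

  expect_error(summarizeSeries(distSeries(0.5)), "at least 2")
})

test_that("summarizeSeries recovers the OU stationary mean", {
  ser <- simulateDistanceSeries(ouParams(0.501, 0.2, 0.0447), 5000, 10,
                                seed = 31)
  sm <- summarizeSeries(ser)
  expect_lt(abs(meanNm(sm) - 0.501), 3 * batchSE(valuesNm(ser)))
  expect_equal(nFrames(sm), 5000L)
})

test_that("summaries are shift-equivariant and honour burn-in/ESS options", {
  ser <- simulateDistanceSeries(ouParams(0.5, 0.2, 0.0447), 500, 10,
                                seed = 4)
  sm <- summarizeSeries(ser)
  shifted <- distSeries(valuesNm(ser) + 0.25)
  sm2 <- summarizeSeries(shifted)
  expect_equal(meanNm(sm2), meanNm(sm) + 0.25, tolerance = 1e-12)
  expect_equal(sdNm(sm2), sdNm(sm), tolerance = 1e-12)
  expect_equal(seNm(sm2), seNm(sm), tolerance = 1e-12)

  smBurn <- summarizeSeries(ser, burnInPs = 1000)
  expect_equal(nFrames(smBurn), 400L)

  # positive autocorrelation means the effective sample size is smaller
  smEss <- summarizeSeries(ser, essCorrection = TRUE)
  expect_gt(seNm(smEss), seNm(sm))
})

test_that("compareSeries matches the pooled-variance formula and t.test", {
  set.seed(9)
  a <- distSeries(rnorm(10, 0.5, 0.05))
  b <- distSeries(rnorm(10, 0.55, 0.05))
  res <- compareSeries(a, b)
  # textbook pooled-variance computation, coded independently
  va <- valuesNm(a); vb <- valuesNm(b)
  sp2 <- ((9 * var(va)) + (9 * var(vb))) / 18
  tRef <- (mean(va) - mean(vb)) / sqrt(sp2 * (1 / 10 + 1 / 10))
  pRef <- 2 * pt(-abs(tRef), df = 18)
  expect_equal(res@tStat, tRef, tolerance = 1e-12)
  expect_equal(pValue(res), pRef, tolerance = 1e-12)
  expect_equal(res@df, 18)

  ident <- compareSeries(a, a)
  expect_equal(ident@tStat, 0)
  expect_equal(pValue(ident), 1)
  expect_false(ident@significant)
  expect_equal(ident@direction, "none")

  w <- compareSeries(a, distSeries(rnorm(25, 0.55, 0.12)), mode = "welch")
  expect_false(w@df == 33)  # Satterthwaite, not pooled
})

test_that("well-separated OU series give a significant A_lower call", {
  a <- simulateDistanceSeries(ouParams(0.439, 0.2, 0.0491), 2000, 10,
                              seed = 1, label = "probe")
  b <- simulateDistanceSeries(ouParams(0.518, 0.2, 0.0626), 2000, 10,
                              seed = 2, label = "variant")
  res <- compareSeries(a, b)
  expect_true(res@significant)
  expect_equal(res@direction, "A_lower")
  expect_lt(pValue(res), 0.001)

  # symmetry up to sign and direction swap
  rev <- compareSeries(b, a)
  expect_equal(rev@tStat, -res@tStat, tolerance = 1e-12)
  expect_equal(pValue(rev), pValue(res), tolerance = 1e-12)
  expect_equal(rev@direction, "B_lower")
})

test_that("degenerate constant series follow the documented contract", {
  res <- compareSeries(distSeries(rep(0.5, 5)), distSeries(rep(0.5, 5)))
  expect_equal(pValue(res), 1)
  res2 <- compareSeries(distSeries(rep(0.4, 5)), distSeries(rep(0.6, 5)))
  expect_true(res2@significant)
  expect_equal(res2@direction, "A_lower")
})

test_that("naive t-test type-I inflation stays within the documented bound", {
  # identical OU parameters; naive frame-wise t tests over-reject a bit
  # because frames are autocorrelated -- bounded at 0.10 (plus binomial
  # allowance for 200 replicates)
  p <- ouParams(0.501, 0.2, 0.044721)
  rejections <- 0L
  for (k in 1:200) {
    a <- simulateDistanceSeries(p, 1000, 10, seed = 2 * k)
    b <- simulateDistanceSeries(p, 1000, 10, seed = 2 * k + 1)
    if (compareSeries(a, b)@significant) rejections <- rejections + 1L
  }
  bound <- 0.10 + 1.96 * sqrt(0.10 * 0.90 / 200)
  expect_lte(rejections / 200, bound)
})

test_that("detachment detection finds the first sustained excursion", {
  calm <- distSeries(rep(0.45, 300))
  expect_true(is.na(onsetPs(detectDetachment(calm))))

  step <- distSeries(c(rep(0.45, 100), rep(0.80, 400)))
  ev <- detectDetachment(step)
  expect_equal(onsetPs(ev), 100 * 10)

  expect_error(detectDetachment(distSeries(rep(0.45, 50))),
               "window longer")

  # short excursions below the persistence window do not qualify
  blip <- distSeries(c(rep(0.45, 100), rep(0.8, 50), rep(0.45, 200)))
  expect_true(is.na(onsetPs(detectDetachment(blip))))

  # idempotence under truncation after the detected run
  v <- valuesNm(step)
  trunc <- distSeries(v[1:250])
  expect_equal(onsetPs(detectDetachment(trunc)), onsetPs(ev))
})

test_that("substrate calls follow the probe envelope and margins", {
  mk <- function(m) new("SeriesSummary", meanNm = m, seNm = 0.001,
                        sdNm = 0.07, nFrames = 5000L, label = "x")
  probes <- c(0.439, 0.407)
  expect_equal(callLabel(callSubstrate(mk(0.501), probes)),
               "minor_substrate")
  expect_equal(callLabel(callSubstrate(mk(1.157), probes)),
               "poor_or_non_substrate")
  expect_equal(callLabel(callSubstrate(mk(0.439), probes)), "probe_like")
  expect_error(callSubstrate(mk(0.5), numeric(0)), "non-empty")

  # monotone in the mean: labels never move back toward probe_like
  rank <- c(probe_like = 1, minor_substrate = 2, poor_or_non_substrate = 3)
  labs <- vapply(seq(0.3, 1.3, by = 0.01), function(m)
    rank[[callLabel(callSubstrate(mk(m), probes))]], numeric(1))
  expect_true(all(diff(labs) >= 0))
})

test_that("variant-effect calls read direction from the mean difference", {
  ref <- simulateDistanceSeries(ouParams(0.501, 0.2, 0.0447), 2000, 10,
                                seed = 5, label = "ref")
  lower <- simulateDistanceSeries(ouParams(0.448, 0.2, 0.0447), 2000, 10,
                                  seed = 6, label = "lower")
  higher <- simulateDistanceSeries(ouParams(0.628, 0.2, 0.0447), 2000, 10,
                                   seed = 7, label = "higher")
  expect_equal(callLabel(callVariantEffect(lower, ref)),
               "likely_enhanced")
  expect_equal(callLabel(callVariantEffect(higher, ref)),
               "likely_reduced")
  expect_equal(callLabel(callVariantEffect(ref, ref)), "unchanged")
})
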