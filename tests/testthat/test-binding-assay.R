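test_that("normalizeFluorescence converts to percent of the blank and is scale-invariant", {
  expect_equal(normalizeFluorescence(c(10, 5), 10), c(100, 50))
  expect_equal(normalizeFluorescence(c(8, 8, 8), 8), c(100, 100, 100))
  expect_equal(normalizeFluorescence(c(12, 6, 3), 12), c(100, 50, 25))

  set.seed(11)
  for (i in 1:20) {
    raw <- runif(6, 1, 50); ref <- runif(1, 10, 100); k <- runif(1, 0.1, 10)
    expect_equal(normalizeFluorescence(raw * k, ref * k),
                 normalizeFluorescence(raw, ref))
  }
  expect_error(normalizeFluorescence(c(1, 2), 0), "positive")
  expect_error(normalizeFluorescence(c(1, 2), -3), "positive")
})

test_that("fitSaturation recovers the generating constant from noiseless data", {
  for (k in c(11.66, 20.77, 15.32)) {
    s <- simulateSaturation(kProbe = k, bMax = 100, noiseSd = 0)
    nl <- fitSaturation(s, "nonlinear")
    sc <- fitSaturation(s, "scatchard")
    expect_lt(abs(kProbe(nl) - k) / k, 1e-6)
    expect_lt(abs(kProbe(sc) - k) / k, 1e-6)
    expect_lt(abs(kProbe(nl) - kProbe(sc)) / k, 0.01)
    expect_equal(nl@bMax, 100, tolerance = 1e-6)
  }
})

test_that("Scatchard linearisation has slope -1/K on noiseless one-site data", {
  s <- simulateSaturation(kProbe = 15.32, bMax = 80, noiseSd = 0)
  # independent route: linear regression of bound/free on bound
  b <- s@intensity
  slope <- unname(coef(lm(I(b / s@probeConc) ~ b))[2L])
  expect_equal(slope, -1 / 15.32, tolerance = 1e-9)
  expect_equal(kProbe(fitSaturation(s, "scatchard")), 15.32,
               tolerance = 1e-9)
})

test_that("degenerate saturation input raises a failed-fit error", {
  flat <- SaturationSeries("p", c(2, 5, 10, 20), rep(40, 4))
  expect_error(fitSaturation(flat), "does not vary")
  decreasing <- SaturationSeries("p", c(2, 5, 10, 20), c(40, 30, 20, 10))
  expect_error(fitSaturation(decreasing, "scatchard"))
})

test_that("both saturation methods tolerate 2% multiplicative noise", {
  errNl <- errSc <- numeric(40)
  for (i in seq_len(40)) {
    s <- simulateSaturation(kProbe = 11.66, noiseSd = 0.02, seed = 1000 + i)
    errNl[i] <- abs(kProbe(fitSaturation(s, "nonlinear")) - 11.66) / 11.66
    errSc[i] <- abs(kProbe(fitSaturation(s, "scatchard")) - 11.66) / 11.66
  }
  expect_lt(median(errNl), 0.05)
  expect_lt(median(errSc), 0.05)
})

test_that("fitCompetition recovers the analytic IC50 of the displacement model", {
  # L50 = Ki (1 + P/K) for the competitive one-site model
  cs <- simulateCompetition(ki = 5.719, kProbe = 11.66, probeConc = 2,
                            noiseSd = 0)
  expected <- 5.719 * (1 + 2 / 11.66)
  fit <- fitCompetition(cs)
  expect_identical(fitStatus(fit), "determined")
  expect_lt(abs(ic50(fit) - expected) / expected, 1e-4)

  # interpolation route lands close to the same crossing
  fiti <- fitCompetition(cs, method = "interpolation")
  expect_identical(fitStatus(fiti), "determined")
  expect_lt(abs(ic50(fiti) - expected) / expected, 0.05)
})

test_that("fitCompetition applies the undetermined rule and failure modes", {
  # true IC50 = 150 uM: above the 100 uM reporting threshold
  kiTrue <- 150 / (1 + 2 / 11.66)
  cs <- simulateCompetition(ki = kiTrue, kProbe = 11.66, probeConc = 2,
                            noiseSd = 0, concRange = c(2, 400), nPoints = 10)
  fit <- fitCompetition(cs)
  expect_identical(fitStatus(fit), "undetermined")
  expect_equal(ic50(fit), 150, tolerance = 1e-3)

  # the threshold is configurable
  expect_identical(fitStatus(fitCompetition(cs, undeterminedThreshold = 200)),
                   "determined")

  # flat curve at 100%: no displacement
  flat <- CompetitionSeries("p", "l", c(2, 5, 10, 20), rep(100, 4))
  expect_identical(fitStatus(fitCompetition(flat)), "failed")

  # rising curve: no displacement either
  rising <- CompetitionSeries("p", "l", c(2, 5, 10, 20), c(90, 95, 100, 110))
  expect_identical(fitStatus(fitCompetition(rising)), "failed")
})

test_that("interpolation ties at exactly 50% take the lower concentration", {
  cs <- CompetitionSeries("p", "l", c(1, 2, 4, 8), c(80, 50, 50, 20))
  fit <- fitCompetition(cs, method = "interpolation")
  expect_equal(ic50(fit), 2)
})

test_that("kiFromIC50 implements the competitive-displacement relation", {
  expect_equal(kiFromIC50(6.70, 2, 11.66), 5.7190, tolerance = 1e-4)
  expect_equal(kiFromIC50(326.26, 2, 11.66), 278.49, tolerance = 1e-4)
  # no probe: Ki equals IC50
  for (x in c(0.5, 7, 123)) expect_identical(kiFromIC50(x, 0, 11.66), x)
  expect_error(kiFromIC50(5, 2, 0), "positive")

  # Ki <= IC50 whenever probe is present, equality iff probe absent
  set.seed(21)
  for (i in 1:50) {
    ic <- runif(1, 0.1, 500); p <- runif(1, 0.01, 10); k <- runif(1, 0.5, 50)
    expect_lt(kiFromIC50(ic, p, k), ic)
    expect_identical(kiFromIC50(ic, 0, k), ic)
  }
})

test_that("round trip simulate -> fit -> convert recovers Ki on noiseless curves", {
  for (ki in c(1.5, 5.719, 20)) {
    cs <- simulateCompetition(ki = ki, kProbe = 11.66, probeConc = 2,
                              noiseSd = 0, nPoints = 8,
                              concRange = c(max(0.2, ki / 10), ki * 20))
    fit <- fitCompetition(cs)
    kiHat <- kiFromIC50(ic50(fit), 2, 11.66)
    expect_lt(abs(kiHat - ki) / ki, 1e-4)
  }
})

test_that("computeAffinity couples fit and probe constants correctly", {
  cs <- simulateCompetition(ki = 5.719, kProbe = 11.66, probeConc = 2,
                            noiseSd = 0, proteinId = "CSP1",
                            ligandId = "linoleic acid")
  af <- computeAffinity(cs, fitCompetition(cs), kProbe = 11.66)
  expect_identical(fitStatus(af), "determined")
  expect_lt(abs(kiValue(af) - 5.719) / 5.719, 1e-4)
  expect_lte(kiValue(af), ic50(af))
})

test_that("affinity tables render determined, undetermined and replicate entries", {
  mk <- function(prot, lig, ki, status = "determined")
    new("AffinityResult", proteinId = prot, ligandId = lig,
        ic50 = if (status == "determined") ki * (1 + 2 / 11.66) else NA_real_,
        ki = if (status == "determined") ki else NA_real_,
        kProbe = 11.66, probeConc = 2, status = status)

  tab <- buildAffinityTable(list(mk("CSP1", "linoleic acid", 5.78),
                                 mk("CSP2", "linoleic acid", NA, "undetermined")))
  expect_identical(tab$CSP1[tab$ligand == "linoleic acid"], "5.78")
  expect_identical(tab$CSP2[tab$ligand == "linoleic acid"], "u.d.")

  # empty input -> empty table
  expect_identical(nrow(buildAffinityTable(list())), 0L)

  # replicates: mean 5.8, sd 0.3
  reps <- list(mk("CSP1", "lig", 5.5), mk("CSP1", "lig", 5.8),
               mk("CSP1", "lig", 6.1))
  summ <- summarizeAffinities(reps)
  expect_equal(summ$kiMean, 5.8)
  expect_equal(summ$kiSd, 0.3)
  expect_identical(buildAffinityTable(reps)$CSP1, "5.80±0.30")

  # conflicting status for one pair is an error
  expect_error(summarizeAffinities(list(mk("CSP1", "lig", 5.5),
                                        mk("CSP1", "lig", NA, "undetermined"))),
               "conflicting")
})
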