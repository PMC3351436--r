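test_that("GNM trajectories are pure functions of their spec", {
  sp <- gnmSpec(nResidues = 20, firstResidue = 1, nFrames = 50, seed = 9)
  t1 <- gnmTrajectory(sp)
  t2 <- gnmTrajectory(sp)
  expect_identical(t1@coords, t2@coords)
  t3 <- gnmTrajectory(gnmSpec(nResidues = 20, firstResidue = 1, nFrames = 50,
                              seed = 10))
  expect_false(identical(t1@coords, t3@coords))
  # apo/holo pairs share the reference fold
  sp2 <- demoGNMSpecs(seed = 1, nFrames = 10)
  expect_identical(gnmReference(sp2$apo), gnmReference(sp2$holo))
})

test_that("stiffening all springs drives distance fluctuations to zero", {
  base <- gnmSpec(nResidues = 25, firstResidue = 1, nFrames = 300, seed = 4)
  stiff <- gnmSpec(nResidues = 25, firstResidue = 1, nFrames = 300, seed = 4,
                   perturbations = list(list(residues = 1:25,
                                             multiplier = 1e6)))
  dfB <- values(distanceFluctuation(gnmTrajectory(base), c(1, 25)))
  dfS <- values(distanceFluctuation(gnmTrajectory(stiff), c(1, 25)))
  expect_lt(max(dfS), max(dfB) / 1e4)
})

test_that("sampled displacement covariance converges to the target", {
  sp <- gnmSpec(nResidues = 40, firstResidue = 1, nFrames = 5000, seed = 13)
  C <- gnmCovariance(sp)
  tr <- gnmTrajectory(sp)
  ref <- gnmReference(sp)
  # average the three axes (they are iid draws from the same covariance)
  Cs <- matrix(0, 40, 40)
  for (ax in 1:3) {
    d <- t(tr@coords[, , ax]) - ref[, ax]
    d <- d - rowMeans(d)
    Cs <- Cs + tcrossprod(d) / ncol(d) / 3
  }
  relFrob <- sqrt(sum((Cs - C)^2)) / sqrt(sum(C^2))
  expect_lt(relFrob, 0.10)
})

test_that("a disconnected contact graph is rejected", {
  sp <- gnmSpec(nResidues = 15, firstResidue = 1, contactCutoff = 2,
                nFrames = 10, seed = 1)
  expect_error(gnmTrajectory(sp), "disconnected")
  expect_error(gnmCovariance(sp), "disconnected")
})

test_that("perturbation specs are validated", {
  expect_error(gnmSpec(nResidues = 10, firstResidue = 1,
                       perturbations = list(list(residues = 50:52,
                                                 multiplier = 2))),
               "outside")
  expect_error(gnmSpec(perturbations = list(list(residues = 30:31,
                                                 multiplier = -1))))
})

test_that("relaxation generation: exact at zero noise, reproducible, calibrated", {
  sp0 <- relaxSpec(1:30, s2 = 0.85, te = 30, rex = c(rep(0, 29), 4),
                   noise = c(R1 = 0, R2 = 0, NOE = 0), seed = 2)
  ds <- generateRelaxation(sp0)
  spin <- spinParameters(500)
  pred <- predictRates(sp0$truth$s2, 8, sp0$truth$te, sp0$truth$rex, 1, spin)
  expect_equal(residueData(ds)$R1, pred$R1, tolerance = 1e-12)
  expect_equal(residueData(ds)$R2, pred$R2, tolerance = 1e-12)
  expect_equal(residueData(ds)$NOE, pred$NOE, tolerance = 1e-12)
  # R1rho = R2 without the exchange term
  expect_equal(residueData(ds)$R1rho, pred$R2 - sp0$truth$rex,
               tolerance = 1e-12)

  spN <- relaxSpec(1:1000, s2 = 0.85, seed = 3)
  d1 <- residueData(generateRelaxation(spN))
  d2 <- residueData(generateRelaxation(spN))
  expect_identical(d1, d2)
  predN <- predictRates(0.85, 8, 0, 0, 1, spin)
  relDev <- (d1$R2 - predN$R2) / predN$R2
  expect_equal(sd(relDev), 0.02, tolerance = 0.1)
})

test_that("peak-table generation composes with the CSP and intensity analyses", {
  # empty implant set, zero noise: identical tables
  g0 <- generatePeakTables(peakSpec(residues = 1:30, seed = 6))
  expect_identical(residueData(g0$apo), residueData(g0$holo))
  # same spec twice: identical output
  g0b <- generatePeakTables(peakSpec(residues = 1:30, seed = 6))
  expect_identical(residueData(g0$apo), residueData(g0b$apo))

  # implanted ddH appears exactly in the csp records (zero noise)
  g <- generatePeakTables(peakSpec(
    residues = 120:150,
    shifted = data.frame(residue = 129, ddH = 0.1, ddN = 0),
    seed = 6))
  r <- csp(g$apo, g$holo)
  expect_equal(r$ddComb[r$residue == 129], 0.1, tolerance = 1e-12)
  expect_true(all(r$ddComb[r$residue != 129] == 0))

  # suppressed apo intensity recovering to baseline classifies as increased
  g2 <- generatePeakTables(demoPeakSpec(seed = 3))
  ic <- intensityChange(g2$apo, g2$holo)
  expect_true(all(ic$class[ic$residue %in% c(129, 144, 145)] == "increased"))
})
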