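# Reference values frozen from an independent implementation of the standard
# dipolar + CSA rate expressions (numpy, double precision), at 500 MHz with
# rNH = 1.02 A, csa = -172 ppm.
refJ_wN <- 3.659192658632e-10      # J(|wN|) at S2=0.85, tm=8 ns, te=50 ps
refRates <- c(R1 = 1.866100935682, R2 = 9.858206268162, NOE = 0.704295197362)
refRatesM1 <- c(R1 = 1.932267725876, R2 = 10.393964864357, NOE = 0.800535572924)

test_that("spectral density: rigid collapse, J(0), and the frozen oracle value", {
  expect_equal(spectralDensity(0, 8, 1), 0.4 * 8e-9, tolerance = 1e-12)
  w <- 2 * pi * 50e6
  expect_equal(spectralDensity(w, 8, 1),
               0.4 * 8e-9 / (1 + (w * 8e-9)^2), tolerance = 1e-12)
  sp <- spinParameters(500)
  expect_equal(spectralDensity(sp$wN, 8, 0.85, 50), refJ_wN,
               tolerance = 1e-12)
  # even in omega
  expect_identical(spectralDensity(-sp$wN, 8, 0.85, 50),
                   spectralDensity(sp$wN, 8, 0.85, 50))
})

test_that("predicted rates match the independent reference implementation", {
  sp <- spinParameters(500)
  r <- predictRates(0.85, 8, 50, 0, 1, sp)
  expect_equal(unlist(r), refRates, tolerance = 1e-9, ignore_attr = TRUE)
  r2 <- predictRates(0.9, 8, 0, 0, 1, sp)
  expect_equal(unlist(r2), refRatesM1, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("Rex is purely additive in R2 and model nesting holds at te = 0", {
  sp <- spinParameters(500)
  a <- predictRates(0.85, 8, 30, 0, 1, sp)
  b <- predictRates(0.85, 8, 30, 5, 1, sp)
  expect_equal(b$R2 - a$R2, 5)
  expect_equal(b$R1, a$R1)
  expect_equal(b$NOE, a$NOE)
  # M2 with te = 0 equals M1 with the same S2
  expect_equal(predictRates(0.8, 8, 0, 0, 1, sp),
               predictRates(0.8, 8, 1e-12, 0, 1, sp), tolerance = 1e-9)
})

test_that("NOE never exceeds the rigid-limit value at the same tm and field", {
  sp <- spinParameters(500)
  grid <- expand.grid(s2 = c(0.2, 0.5, 0.8, 0.95), te = c(0, 20, 100, 500),
                      tm = c(4, 8, 15))
  for (i in seq_len(nrow(grid))) {
    rigid <- predictRates(1, grid$tm[i], 0, 0, 1, sp)$NOE
    expect_lte(predictRates(grid$s2[i], grid$tm[i], grid$te[i], 0, 1, sp)$NOE,
               rigid + 1e-9)
  }
})

test_that("axially symmetric diffusion reduces to isotropic at D ratio 1", {
  sp <- spinParameters(500)
  iso <- predictRates(0.85, 8, 50, 2, 1, sp)
  ax <- predictRates(0.85, 8, 50, 2, 1, sp,
                     diffusion = list(ratio = 1, angle = 0.7))
  expect_lt(max(abs(unlist(iso) - unlist(ax))), 1e-9)
  # and genuinely differs once the tensor is anisotropic
  ax2 <- predictRates(0.85, 8, 50, 2, 1, sp,
                      diffusion = list(ratio = 1.5, angle = 0.7))
  expect_gt(max(abs(unlist(iso) - unlist(ax2))), 1e-3)
})

test_that("the fitting kernel agrees with predictRates", {
  sp <- spinParameters(600)
  for (p in list(c(0.9, 0, 0, 1), c(0.7, 80, 0, 1), c(0.85, 30, 4, 1),
                 c(0.6, 200, 0, 0.85))) {
    a <- unlist(predictRates(p[1], 9, p[2], p[3], p[4], sp))
    b <- allodyn:::.mfRates(p[1], 9, p[2], p[3], p[4], sp, NULL)
    expect_equal(unname(a), unname(b), tolerance = 1e-12)
  }
})

test_that("tm is recovered from rigid-ratio inversion and guards small inputs", {
  sp0 <- relaxSpec(1:50, s2 = 0.85, tm = 8, noise = c(R1 = 0, R2 = 0, NOE = 0))
  ds <- generateRelaxation(sp0)
  expect_equal(estimateTm(ds), 8, tolerance = 0.05 / 8)
  dsSmall <- RelaxationDataset(1:3, R1 = 1.9, R2 = 10, NOE = 0.8,
                               fieldMHz = 500)
  expect_error(estimateTm(dsSmall), "too few")
})

test_that("noise-free forward data from each model round-trips through the fit", {
  sp <- spinParameters(500)
  truths <- list(M1 = c(s2 = 0.90, te = 0, rex = 0),
                 M2 = c(s2 = 0.80, te = 50, rex = 0),
                 M3 = c(s2 = 0.85, te = 0, rex = 4),
                 M4 = c(s2 = 0.80, te = 80, rex = 3))
  admissible <- list(M1 = "M1", M2 = "M2", M3 = c("M3", "M4"),
                     M4 = c("M4"))
  for (m in names(truths)) {
    tr <- truths[[m]]
    r <- predictRates(tr["s2"], 8, tr["te"], tr["rex"], 1, sp)
    f <- fitResidue(r$R1, r$R2, r$NOE, 8, sp)
    expect_true(f$model %in% admissible[[m]], label = paste(m, "->", f$model))
    expect_lt(abs(f$s2 - tr["s2"]), 1e-3)
    if (tr["rex"] > 0) expect_lt(abs(f$rex - tr["rex"]), 0.1)
  }
})

test_that("best chi-square never worsens with model complexity (nesting)", {
  sp <- spinParameters(500)
  set.seed(42)
  for (i in 1:20) {
    s2 <- runif(1, 0.4, 0.95)
    te <- sample(c(0, 30, 200), 1)
    rex <- sample(c(0, 3), 1)
    r <- predictRates(s2, 8, te, rex, 1, sp)
    obs <- unlist(r) * (1 + 0.02 * rnorm(3))
    f <- fitResidue(obs[1], obs[2], obs[3], 8, sp)
    c2 <- vapply(f$allFits, `[[`, numeric(1), "chi2")
    expect_lte(c2[["M2"]], c2[["M1"]] + 1e-8)
    expect_lte(c2[["M4"]], c2[["M2"]] + 1e-8)
    expect_lte(c2[["M4"]], c2[["M3"]] + 1e-8)
  }
})

test_that("F-test selection picks a parsimonious adequate model", {
  sp <- spinParameters(500)
  r <- predictRates(0.9, 8, 0, 0, 1, sp)
  f <- fitResidue(r$R1, r$R2, r$NOE, 8, sp, criterion = "ftest")
  expect_equal(f$model, "M1")
  r3 <- predictRates(0.85, 8, 0, 6, 1, sp)
  f3 <- fitResidue(r3$R1, r3$R2, r3$NOE, 8, sp, criterion = "ftest")
  expect_lt(abs(f3$s2 - 0.85), 0.01)
  expect_gt(f3$rex, 5)
})

test_that("dataset fits separate flexible tail from core and are deterministic", {
  ds <- generateRelaxation(demoRelaxSpec(seed = 7))
  fit1 <- fitDataset(ds, c(30, 153))
  fit2 <- fitDataset(ds, c(30, 153))
  expect_identical(residueData(fit1), residueData(fit2))
  expect_identical(fit1@summary, fit2@summary)

  m <- merge(residueData(fit1), ds@truth, by = "residue")
  tail <- m[m$residue <= 39 & m$converged, ]
  core <- m[m$residue >= 40 & m$converged, ]
  expect_lt(abs(mean(tail$s2.x) - 0.30), 0.03)
  expect_lt(abs(mean(core$s2.x) - mean(core$s2.y)), 0.03)
  expect_error(fitDataset(ds, c(200, 250)), "no residues")
})

test_that("the flexibility threshold reproduces the printed summary arithmetic", {
  expect_equal(s2Threshold(0.79, 0.13, 2), 0.53)
  expect_equal(s2Threshold(0.8, 0.1, 0), 0.8)
  expect_equal(s2Threshold(0.8, 0, 5), 0.8)
})
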