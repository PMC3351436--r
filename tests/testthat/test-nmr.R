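test_that("csp: zero case, formula value, offset invariance, monotonicity", {
  apo <- simplePeakTable(1:5, dH = 8 + (1:5) / 10, dN = 115 + 1:5)
  expect_true(all(csp(apo, apo)$ddComb == 0))

  holo <- apo
  holo@data$dH[3] <- holo@data$dH[3] + 0.03
  holo@data$dN[3] <- holo@data$dN[3] + 0.5
  r <- csp(apo, holo, alpha = 0.154)
  expect_equal(r$ddComb[3], sqrt(0.03^2 + (0.154 * 0.5)^2), tolerance = 1e-12)
  expect_equal(r$ddComb[3], 0.0826, tolerance = 1e-3)
  # ddH alone passes through regardless of alpha
  holo2 <- apo; holo2@data$dH[1] <- holo2@data$dH[1] + 0.1
  expect_equal(csp(apo, holo2, alpha = 0.3)$ddComb[1], 0.1)

  # uniform referencing offset on both tables changes nothing
  off <- function(pt, h, n) {
    pt@data$dH <- pt@data$dH + h; pt@data$dN <- pt@data$dN + n; pt
  }
  expect_equal(csp(off(apo, 0.3, -2), off(holo, 0.3, -2))$ddComb, r$ddComb)

  # monotone in |ddH| and |ddN|
  holo3 <- holo; holo3@data$dN[3] <- holo3@data$dN[3] + 0.2
  expect_gt(csp(apo, holo3)$ddComb[3], r$ddComb[3])

  expect_error(csp(apo, simplePeakTable(10:12, 8, 115)), "in common")
  expect_warning(csp(apo, simplePeakTable(c(1:5, 9), 8, 115)), "unmatched")
})

test_that("csp significance flags spikes and implanted shifts, not flat noise", {
  rec <- data.frame(residue = 1:20, sidechain = FALSE, ddH = 0, ddN = 0,
                    ddComb = rep(0.02, 20), significant = FALSE)
  expect_false(any(cspSignificance(rec)$significant))

  rec$ddComb[7] <- 0.2
  out <- cspSignificance(rec, k = 3)
  expect_equal(which(out$significant), 7L)

  g <- generatePeakTables(peakSpec(
    residues = 1:60,
    shifted = data.frame(residue = c(10, 25, 40), ddH = c(0.1, 0.08, 0.12),
                         ddN = c(0.6, 0.5, 0.7)),
    shiftNoise = 0.002, seed = 5))
  out2 <- cspSignificance(csp(g$apo, g$holo), k = 3)
  expect_setequal(out2$residue[out2$significant], c(10, 25, 40))

  expect_equal(which(cspSignificance(rec, method = "fixed",
                                     cutoff = 0.1)$significant), 7L)
})

test_that("intensity changes are scale-invariant and class missing peaks apart", {
  apo <- simplePeakTable(1:6, 8, 115, intensity = c(1, 2, 0.5, 1.5, 1, 2))
  holo <- apo
  holo@data$intensity <- apo@data$intensity * 2   # proportional spectra
  r <- intensityChange(apo, holo)
  expect_equal(r$ratio, rep(1, 6))
  expect_true(all(r$class == "unchanged"))

  # suppressed apo peak recovering to baseline: increased
  apo2 <- apo; apo2@data$intensity[4] <- 0.2 * apo@data$intensity[4]
  r2 <- intensityChange(apo2, apo)
  expect_equal(r2$class[4], "increased")

  # a global rescale of either spectrum changes nothing
  holo3 <- apo; holo3@data$intensity <- holo3@data$intensity * 17
  expect_equal(intensityChange(apo2, holo3)$ratio, r2$ratio)

  apo3 <- apo; apo3@data$intensity[2] <- NA
  r3 <- intensityChange(apo3, apo)
  expect_equal(r3$class[2], "appeared")
  r4 <- intensityChange(apo, apo3)
  expect_equal(r4$class[2], "disappeared")

  zero <- apo; zero@data$intensity <- 0
  expect_error(intensityChange(zero, apo), "normalizer")
})

test_that("exchange flags respond to ratio outliers and shrink with k", {
  ds <- RelaxationDataset(1:20, R1 = 1.9, R2 = 10, NOE = 0.8, R1rho = 10,
                          fieldMHz = 500)
  expect_false(any(exchangeFlags(ds)$flagged))

  d <- residueData(ds)
  set.seed(2)
  r1rho <- 10 * (1 + 0.005 * rnorm(20))
  ds2 <- RelaxationDataset(1:20, d$R1, c(rep(10, 9), 20, rep(10, 10)),
                           d$NOE, r1rho, fieldMHz = 500)
  f <- exchangeFlags(ds2, k = 1)
  expect_equal(f$residue[f$flagged], 10L)
  expect_true(all(f$ratio > 0))
  # monotone non-increasing in k
  f2 <- exchangeFlags(ds2, k = 3)
  expect_true(all(f2$residue[f2$flagged] %in% f$residue[f$flagged]))
})

test_that("implanted Rex residues are flagged exactly in >= 90% of seeds", {
  hits <- vapply(1:20, function(s) {
    ds <- generateRelaxation(demoRelaxSpec(seed = 100 + s))
    truthRex <- ds@truth$residue[ds@truth$rex >= 2]
    f <- exchangeFlags(ds, k = 1)
    setequal(f$residue[f$flagged], truthRex)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("ePHOGSY classification applies the +/-50% change rule", {
  ids <- 1:40
  mk <- function(i) simplePeakTable(ids, 8, 115, intensity = i)
  base <- rep(c(2, 1.5, 1.2, 1, 0.8, 0.6, 0.5, 0.4, 0.3, 0.2), 4)
  roe <- rep(NA_real_, 40); roe[2] <- 1
  holoN <- base
  holoN[5] <- 1.6 * base[5]   # +60%: flagged (survives mean renormalization)
  holoN[6] <- 1.3 * base[6]   # +30%: not flagged
  out <- ephogsyClassify(mk(base), mk(roe), mk(holoN), mk(roe))
  expect_true(out$noeChange[5])
  expect_false(out$noeChange[6])
  expect_false(any(out$noeChange[-5]))
  # identical states: nothing flagged
  same <- ephogsyClassify(mk(base), mk(roe), mk(base), mk(roe))
  expect_false(any(same$noeChange | same$roeChange, na.rm = TRUE))
  # three classes exist and ROE-bearing residues never claim water proximity
  expect_setequal(unique(stats::na.omit(out$noeClass)),
                  c("high", "medium", "low"))
  expect_false(any(out$waterProximal[out$hasRoe]))
})
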