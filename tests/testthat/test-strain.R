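collinearTraj <- function(spacing = 5, nFrames = 3) {
  co <- array(0, c(nFrames, 3, 3))
  co[, 2, 1] <- spacing
  co[, 3, 1] <- 2 * spacing
  co[2, , 2] <- 1e-9   # break exact frame identity harmlessly
  Trajectory(co, 1:3)
}

test_that("neighbor maps follow the time-averaged geometry", {
  tr <- collinearTraj(spacing = 5)
  nm <- neighborMap(tr, cutoff = 6, range = c(1, 3))
  expect_equal(unname(rowSums(nm@adjacency)), c(1, 2, 1))
  expect_identical(nm@adjacency, t(nm@adjacency))
  # cutoff below the closest pair: everyone isolated
  nmIso <- neighborMap(tr, cutoff = 2, range = c(1, 3))
  expect_equal(isolatedResidues(nmIso), 1:3)
  # cutoff beyond the diameter: complete graph
  nmAll <- neighborMap(tr, cutoff = 100, range = c(1, 3))
  expect_equal(unname(rowSums(nmAll@adjacency)), c(2, 2, 2))
})

test_that("strain matches the hand-computed and static cases", {
  # two residues, d = {2, 4}: mean 3, per-frame strain (d - 3)^2 = 1 for both
  co <- array(0, c(2, 2, 3))
  co[1, 2, 1] <- 2; co[2, 2, 1] <- 4
  tr <- Trajectory(co, 1:2)
  nm <- neighborMap(tr, cutoff = 10, range = c(1, 2))
  ss <- strainSeries(tr, nm, window = 1)
  expect_equal(unname(values(ss)), matrix(1, 2, 2))

  # identical frames: zero strain everywhere
  coS <- array(rep(rnorm(9), each = 4), c(4, 3, 3))
  trS <- Trajectory(coS, 1:3)
  nmS <- neighborMap(trS, cutoff = 100, range = c(1, 3))
  expect_equal(max(values(strainSeries(trS, nmS, window = 2))), 0)
})

test_that("strain equals the brute-force oracle; window = n gives the time mean", {
  co <- randomCoords(20, 5, seed = 11)
  tr <- Trajectory(co, 1:5)
  nm <- neighborMap(tr, cutoff = 15, range = c(1, 5))
  expect_lt(length(isolatedResidues(nm)), 5)  # guard a vacuous comparison
  perFrame <- oracleStrainPerFrame(co, nm@adjacency)
  ss1 <- strainSeries(tr, nm, window = 1)
  relErr <- abs(values(ss1) - perFrame) / pmax(abs(perFrame), 1e-12)
  expect_lt(max(relErr, na.rm = TRUE), 1e-10)
  ssAll <- strainSeries(tr, nm, window = 20)
  expect_equal(ncol(values(ssAll)), 1)
  expect_equal(unname(values(ssAll)[, 1]), unname(rowMeans(values(ss1))))
  expect_error(strainSeries(tr, nm, window = 21), "exceeds")
})

test_that("strain is invariant under per-frame rigid motion", {
  co <- randomCoords(15, 5, seed = 4)
  tr <- Trajectory(co, 1:5)
  nm <- neighborMap(tr, cutoff = 15, range = c(1, 5))
  trR <- Trajectory(rigidScramble(co, seed = 8), 1:5)
  nmR <- neighborMap(trR, cutoff = 15, range = c(1, 5))
  expect_lt(max(abs(values(strainSeries(tr, nm, 1)) -
                    values(strainSeries(trR, nmR, 1))), na.rm = TRUE), 1e-9)
})

test_that("complete-graph window-1 strain averages to the mean pairwise DF", {
  co <- randomCoords(20, 5, seed = 21)
  tr <- Trajectory(co, 1:5)
  nm <- neighborMap(tr, cutoff = 1e6, range = c(1, 5))
  ss <- strainSeries(tr, nm, window = 1)
  df <- values(distanceFluctuation(tr, c(1, 5)))
  meanStrain <- mean(rowMeans(values(ss)))
  meanDF <- mean(df[upper.tri(df)])
  expect_lt(abs(meanStrain - meanDF), 1e-10)
})

test_that("profiles are row means and propagate isolation as missing", {
  co <- randomCoords(10, 4, seed = 2)
  co[, 4, ] <- co[, 4, ] + 100   # residue 4 far away: isolated
  tr <- Trajectory(co, 1:4)
  nm <- neighborMap(tr, cutoff = 30, range = c(1, 4))
  expect_equal(isolatedResidues(nm), 4L)
  ss <- strainSeries(tr, nm, window = 5)
  expect_true(all(is.na(values(ss)[4, ])))
  pr <- averageStrainProfile(ss)
  expect_true(is.na(values(pr)[["4"]]))
  expect_equal(unname(values(pr)[1:3]), unname(rowMeans(values(ss)[1:3, ])))
  # constant series gives a constant profile; zero series a zero profile
  zs <- new("StrainSeries", values = matrix(0, 3, 4, dimnames = list(1:3, 1:4)),
            window = 1L, normalized = TRUE)
  expect_equal(unname(values(averageStrainProfile(zs))), rep(0, 3))
})

test_that("strain hotspot calling: empty on equal profiles, recovery, monotone in k", {
  mkProfile <- function(v) new("StrainProfile",
                               values = setNames(v, seq_along(v)))
  set.seed(3)
  base <- 0.5 + abs(rnorm(40, sd = 0.01))
  apo <- mkProfile(base)
  expect_equal(nrow(strainHotspots(apo, apo)), 0)
  holo <- base
  holo[20:23] <- holo[20:23] + 1   # implanted soft region
  calls <- strainHotspots(apo, mkProfile(holo), k = 1, minLen = 3)
  expect_equal(nrow(calls), 1)
  expect_equal(c(calls$first, calls$last, calls$direction),
               c("20", "23", "enhanced"))
  expect_equal(nrow(strainHotspots(apo, mkProfile(holo), k = 1e6)), 0)
})
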