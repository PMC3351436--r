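test_that("multi-model PDB is read into frames x residues, deterministically", {
  p <- withr::local_tempfile(fileext = ".pdb")
  fr <- list(matrix(c(0, 0, 0, 3.8, 0, 0, 7.6, 0, 0), 3, byrow = TRUE),
             matrix(c(0, 0, 1, 3.8, 0, 1, 7.6, 0, 1), 3, byrow = TRUE))
  writePDBFixture(p, fr, ids = c(10, 11, 12))
  tr <- readTrajectory(p, format = "pdb")
  expect_equal(nFrames(tr), 2)
  expect_identical(residueIds(tr), c(10L, 11L, 12L))
  expect_equal(tr@coords[2, 3, 3], 1)
  tr2 <- readTrajectory(p, format = "pdb")
  expect_identical(tr@coords, tr2@coords)
})

test_that("residues lacking the selected atom are dropped with a warning", {
  p <- withr::local_tempfile(fileext = ".pdb")
  fr <- list(matrix(rnorm(6), 2), matrix(rnorm(6), 2))
  writePDBFixture(p, fr, ids = c(1, 2), extraAtomResidue = 3)
  expect_warning(tr <- readTrajectory(p, format = "pdb"), "dropped")
  expect_identical(residueIds(tr), c(1L, 2L))
})

test_that("coordinate tables are read, round-trip, and report bad rows", {
  p <- withr::local_tempfile()
  writeLines(c("# comment",
               "1 5 0 0 0", "1 6 1 0 0",
               "2 5 0 0 0", "2 6 3 0 0"), p)
  tr <- readTrajectory(p, format = "table")
  expect_identical(residueIds(tr), c(5L, 6L))
  expect_equal(tr@coords[2, 2, 1], 3)

  p2 <- withr::local_tempfile()
  writeTrajectoryTable(tr, p2)
  expect_identical(readTrajectory(p2, format = "table")@coords, tr@coords)

  pMiss <- withr::local_tempfile()
  writeLines(c("1 5 0 0 0", "1 6 1 0 0", "2 5 0 0 0"), pMiss)
  expect_error(readTrajectory(pMiss, format = "table"),
               "frame 2 is missing residue 6")

  pBad <- withr::local_tempfile()
  writeLines(c("1 5 0 0 0", "1 6 x 0 0", "2 5 0 0 0", "2 6 0 0 0"), pBad)
  expect_error(readTrajectory(pBad, format = "table"), "line 2")

  pOne <- withr::local_tempfile()
  writeLines("1 5 0 0 0", pOne)
  expect_error(readTrajectory(pOne, format = "table"), "at least 2 frames")
})

test_that("unsupported and underspecified trajectory formats error", {
  p <- withr::local_tempfile(fileext = ".xtc")
  writeLines("", p)
  expect_error(readTrajectory(p), "XTC")
  p2 <- withr::local_tempfile(fileext = ".dcd")
  writeLines("", p2)
  expect_error(readTrajectory(p2), "topology")
  expect_error(readTrajectory("/nonexistent/x.pdb"), "not found")
})

test_that("peak tables parse, keep missing values missing, and reject junk", {
  p <- withr::local_tempfile()
  writeLines(c("residue\tdH\tdN\tintensity",
               "10\t8.1\t120.5\t1.0",
               "11\t8.2\t118.2\t",
               "12\t7.9\t125.0\t0.5"), p)
  pt <- readPeakTable(p)
  expect_equal(nrow(residueData(pt)), 3)
  expect_true(is.na(residueData(pt)$intensity[2]))

  pDup <- withr::local_tempfile()
  writeLines(c("residue\tdH\tdN\tintensity",
               "129\t8.1\t120\t1", "129\t8.2\t121\t1"), pDup)
  expect_error(readPeakTable(pDup), "129")

  pBad <- withr::local_tempfile()
  writeLines(c("residue\tdH\tdN\tintensity",
               "10\t8.1\t120\t1", "11\tabc\t121\t1"), pBad)
  expect_error(readPeakTable(pBad), "row 2")
})

test_that("peak tables round-trip through write/read", {
  pt <- PeakTable(c(5, 6, 7), c(8.1, 8.2, NA), c(120, 121, 122),
                  c(1, NA, 0.5), c(FALSE, FALSE, TRUE))
  p <- withr::local_tempfile()
  writePeakTable(pt, p)
  expect_equal(residueData(readPeakTable(p)), residueData(pt))
})

test_that("relaxation tables carry the field and validate rates", {
  p <- withr::local_tempfile()
  writeLines(c("# field_MHz 500",
               "residue\tR1\tR2\tNOE",
               "10\t1.9\t10.4\t0.80",
               "11\t1.8\t9.9\t0.78"), p)
  ds <- readRelaxationTable(p)
  expect_equal(fieldMHz(ds), 500)
  expect_true(all(is.na(residueData(ds)$R1rho)))

  pNeg <- withr::local_tempfile()
  writeLines(c("# field_MHz 500", "residue\tR1\tR2\tNOE",
               "10\t1.9\t-2\t0.8", "11\t1.8\t9.9\t0.78"), pNeg)
  expect_error(readRelaxationTable(pNeg), "R2")

  pNoField <- withr::local_tempfile()
  writeLines(c("residue\tR1\tR2\tNOE", "10\t1.9\t10\t0.8"), pNoField)
  expect_error(readRelaxationTable(pNoField), "field_MHz")
})

test_that("relaxation tables round-trip through write/read", {
  ds <- RelaxationDataset(30:34, R1 = 1.9, R2 = 10.2, NOE = 0.8,
                          R1rho = c(10, NA, 10, 10, 10), eR1 = 0.04,
                          fieldMHz = 500)
  p <- withr::local_tempfile()
  writeRelaxationTable(ds, p)
  back <- readRelaxationTable(p)
  expect_equal(residueData(back), residueData(ds))
  expect_equal(fieldMHz(back), 500)
})

test_that("matrix and report writers round-trip exactly", {
  m <- matrix(rnorm(9), 3, dimnames = list(5:7, 5:7))
  p <- withr::local_tempfile()
  writeMatrixTSV(m, p)
  expect_equal(readMatrixTSV(p), m)

  r <- list(alpha = 0.154, flagged = c(129L, 144L), note = "x")
  pj <- withr::local_tempfile()
  writeReportJSON(r, pj)
  back <- readReportJSON(pj)
  expect_equal(back$alpha, 0.154)
  expect_equal(back$flagged, c(129L, 144L))
  expect_equal(back$schema_version, "1.0")
})
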