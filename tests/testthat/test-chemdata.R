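test_that("Hartree conversion is the CODATA linear map", {
  expect_identical(hartreeToEV(0), 0)
  expect_equal(hartreeToEV(1), 27.211386245988, tolerance = 1e-12)
  expect_equal(hartreeToEV(-0.5), -13.605693122994, tolerance = 1e-12)
  x <- c(-2.3, 0.17, 11)
  expect_equal(hartreeToEV(x), x * hartreeToEV(1))
})

test_that("minimal XYZ blocks parse; ids default to filestem_index", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "", "H 0 0 0"), f)
  ms <- readExtendedXYZ(f)
  expect_equal(nMol(ms), 1L)
  expect_equal(molElements(ms)[[1]], "H")
  expect_equal(molCoords(ms)[[1]], matrix(0, 1, 3))
  expect_equal(nrow(records(ms)), 0L)
  expect_match(molIds(ms), "_0$")
})

test_that("malformed XYZ input fails with the offending line number", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("5", "short block", "C 0 0 0", "C 1 0 0", "C 2 0 0", "C 3 0 0"), f)
  expect_error(readExtendedXYZ(f), "line 1.*5 atoms")
  writeLines(c("2", "", "C 0 0 0", "C 1 x 0"), f)
  expect_error(readExtendedXYZ(f), "non-numeric coordinate")
  writeLines(c("2", "", "C 0 0 0", "C"), f)
  expect_error(readExtendedXYZ(f), "malformed atom line")
})

test_that("comment-line properties map through the column config with units", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("5", "mol_a -0.3877 0.1171",
               "C 0 0 0", "H 0.63 0.63 0.63", "H -0.63 -0.63 0.63",
               "H -0.63 0.63 -0.63", "H 0.63 -0.63 -0.63"), f)
  ms <- readExtendedXYZ(f, propertyCols = c(homo = 2, lumo = 3),
                        level = "dft", unit = "hartree", idCol = 1)
  rec <- records(ms)
  expect_equal(molIds(ms), "mol_a")
  expect_equal(rec$homo, -10.550, tolerance = 1e-4)
  # gap filled from the orbitals, already in eV
  expect_equal(rec$gap, rec$lumo - rec$homo, tolerance = 1e-9)
})

test_that("property tables read from CSV and JSON lines with gap filling", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,homo,lumo", "m1,-9,-1"), f)
  rec <- readPropertyTable(f, level = "gw")
  expect_equal(rec$gap, 8.0)
  writeLines(c("id,gap", "m1,7.5"), f)
  rec <- readPropertyTable(f, level = "gw")
  expect_true(is.na(rec$homo) && is.na(rec$lumo))
  expect_equal(rec$gap, 7.5)
  j <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"id":"m1","homo":-9,"lumo":-1}',
               '{"id":"m2","gap":6.25}'), j)
  rec <- readPropertyTable(j, level = "gw")
  expect_equal(rec$gap, c(8.0, 6.25))
})

test_that("property-table format errors are reported", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("homo,lumo", "-9,-1"), f)
  expect_error(readPropertyTable(f, "gw"), "no 'id' column")
  writeLines(c("id,homo,lumo", "m1,-9,-1", "m1,-8,-2"), f)
  expect_error(readPropertyTable(f, "gw"), "duplicate id.*m1")
  writeLines(c("id,homo,gap", "m1,-9,"), f)
  expect_error(readPropertyTable(f, "gw"), "neither a gap nor both")
})

test_that("extended-XYZ write/read round trip preserves the dataset", {
  syn <- synthFixture("small")
  ms <- syn$molecules[1:12]
  f <- withr::local_tempfile(fileext = ".xyz")
  writeExtendedXYZ(ms, f, level = "target")
  back <- readExtendedXYZ(f, propertyCols = c(homo = 2, lumo = 3, gap = 4),
                          level = "target", idCol = 1)
  expect_identical(molIds(back), molIds(ms))
  expect_identical(molElements(back), molElements(ms))
  for (i in seq_len(nMol(ms)))
    expect_lt(max(abs(molCoords(back)[[i]] - molCoords(ms)[[i]])), 1e-8)
  expect_equal(unname(gaps(back, "target")), unname(gaps(ms, "target")),
               tolerance = 1e-9)
  expect_equal(unname(homos(back, "target")), unname(homos(ms, "target")),
               tolerance = 1e-9)
})

test_that("loaded records always satisfy the gap identity", {
  rec <- records(synthFixture("small")$molecules)
  expect_lt(max(abs(rec$gap - (rec$lumo - rec$homo))), 1e-6)
})

test_that("MoleculeSet validity rejects inconsistent construction", {
  expect_error(
    MoleculeSet(ids = c("a", "a"), elements = list("H", "H"),
                coords = list(matrix(0, 1, 3), matrix(0, 1, 3))),
    "duplicate molecule ids")
  expect_error(
    MoleculeSet(ids = "a", elements = list(c("H", "C")),
                coords = list(matrix(0, 1, 3))),
    "lengths disagree")
  expect_error(
    MoleculeSet(ids = "a", elements = list("H"),
                coords = list(matrix(0, 1, 3)), charges = list(6L)),
    "charges inconsistent")
  ms <- MoleculeSet(ids = "a", elements = list("H"),
                    coords = list(matrix(0, 1, 3)))
  expect_error(addRecords(ms, data.frame(id = "b", level = "x", gap = 1)),
               "unknown ids")
  expect_error(addRecords(ms, data.frame(id = "a", level = "x", homo = -9,
                                         lumo = -1, gap = 5)),
               "more than 1e-6")
})

test_that("subsetting keeps molecules and their records aligned", {
  syn <- synthFixture("small")
  sub <- syn$molecules[c("syn00003", "syn00010")]
  expect_equal(nMol(sub), 2L)
  expect_setequal(unique(records(sub)$id), c("syn00003", "syn00010"))
  expect_error(syn$molecules["nope"], "unknown molecule id")
})

test_that("SMILES lists read with optional ids", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO mol1", "c1ccccc1"), f)
  tab <- readSmilesFile(f)
  expect_equal(tab$smiles, c("CCO", "c1ccccc1"))
  expect_equal(tab$id[1], "mol1")
  expect_match(tab$id[2], "_1$")
})
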