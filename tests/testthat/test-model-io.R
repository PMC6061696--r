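test_that("atom-name dialects collapse to one internal spelling", {
  expect_equal(normalizeAtomName(c("O2'", "O2′", "O2*")),
               rep("O2'", 3))
  expect_equal(normalizeAtomName(c("O1P", "O2P")), c("OP1", "OP2"))
  e <- genSyntheticNSR(nModels = 1, seed = 1)
  expect_equal(resolveAtom(atomTable(e), "18:O4'"),
               resolveAtom(atomTable(e), "18:O4*"))
})

test_that("atom references resolve to exactly one atom or fail by name", {
  e <- genSyntheticNSR(nModels = 1, seed = 1)
  expect_length(resolveAtom(atomTable(e), "14:N3"), 1L)
  expect_error(resolveAtom(atomTable(e), "14:XX"), "14:XX")
  expect_error(atomRef("14"), "malformed")
  expect_error(atomRef("x:N3"), "non-integer")
})

test_that("multi-model PDB writing and reading round-trips", {
  e <- genSyntheticNSR(nModels = 3, seed = 4)
  f <- tempfile(fileext = ".pdb")
  writeEnsemble(e, f)
  e2 <- readEnsemble(f)
  expect_equal(nFrames(e2), 3L)
  expect_equal(nAtoms(e2), nAtoms(e))
  expect_identical(atomTable(e2)$atom, atomTable(e)$atom)
  expect_identical(atomTable(e2)$resno, atomTable(e)$resno)
  expect_lt(max(abs(coords(e2) - coords(e))), 5e-4 + 1e-12)
  expect_true(is.na(frameDt(e2)))
})

test_that("frame-series TSV round-trips including the time step", {
  e <- genConformerEnsemble(conformerSimSpec(nFrames = 4, seed = 2, dt = 25))
  f <- tempfile(fileext = ".tsv")
  writeEnsemble(e, f, format = "xyz-frames")
  e2 <- readEnsemble(f, format = "xyz-frames")
  expect_equal(nFrames(e2), 4L)
  expect_equal(frameDt(e2), 25)
  expect_lt(max(abs(coords(e2) - coords(e))), 5e-4 + 1e-12)
})

test_that("a single-model PDB gives a one-frame ensemble without dt", {
  e <- genSyntheticNSR(nModels = 1, seed = 1)
  f <- tempfile(fileext = ".pdb")
  writeEnsemble(e, f)
  e2 <- readEnsemble(f)
  expect_equal(nFrames(e2), 1L)
  expect_true(is.na(frameDt(e2)))
})

test_that("inconsistent atom counts across models name the offending model", {
  e <- genSyntheticNSR(nModels = 2, seed = 1)
  f <- tempfile(fileext = ".pdb")
  writeEnsemble(e, f)
  lines <- readLines(f)
  drop <- tail(grep("^ATOM|^HETATM", lines), 1L)  # in the last model
  writeLines(lines[-drop], f)
  expect_error(readEnsemble(f), "model 2")
})

test_that("unparsable frame-series coordinates are reported with a row", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("frame\tresno\tresname\tatom\telement\tx\ty\tz",
               "1\t1\tU\tN3\tN\t0.0\t0.0\t0.0",
               "1\t1\tU\tO2\tO\t0.0\tbad\t0.0"), f)
  expect_error(readEnsemble(f, format = "xyz-frames"), "row")
})

test_that("waters and ions are retained with normalized residue names", {
  e <- genSyntheticNSR(nModels = 1, seed = 1)
  f <- tempfile(fileext = ".pdb")
  writeEnsemble(e, f)
  a <- atomTable(readEnsemble(f))
  expect_true(any(a$resname == "HOH"))
  expect_true(any(a$resname == "K"))
  expect_equal(countRNAResidues(readEnsemble(f)), 27L)
})

test_that("NOE tables parse groups and reject malformed rows", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("group_a\tgroup_b\tupper_bound_A",
               "14:H3\t17:H8\t3.3",
               "14:H5'';14:H5'\t16:H8\t5.0"), f)
  rs <- readNOETable(f)
  expect_length(rs, 2L)
  expect_length(rs[[1]]@groupA, 1L)
  expect_equal(rs[[1]]@upper, 3.3)
  expect_length(rs[[2]]@groupA, 2L)

  writeLines(c("group_a\tgroup_b\tupper_bound_A",
               "14:H3\t17:H8\tabc"), f)
  expect_error(readNOETable(f), "row 1")
  writeLines(c("group_a\tgroup_b\tupper_bound_A",
               ";\t17:H8\t3.0"), f)
  expect_error(readNOETable(f), "row 1")
})

test_that("restraint groups must be nonempty and disjoint", {
  expect_error(noeRestraint("14:H3", "14:H3", 3), "disjoint")
  expect_error(noeRestraint("14:H3", "15:H3", -1), "positive")
})

test_that("shuffling file atom order within residues changes no distances", {
  e <- genSyntheticNSR(nModels = 2, seed = 8)
  f <- tempfile(fileext = ".tsv")
  writeEnsemble(e, f, format = "xyz-frames")
  lines <- readLines(f)
  hdr <- grep("\tresno\t|^frame", lines)[1]
  pre <- lines[seq_len(hdr)]
  body <- lines[-seq_len(hdr)]
  set.seed(1)
  ## shuffle rows within each frame block (atom table keys still match)
  frameOf <- sub("\t.*", "", body)
  shuffled <- unlist(lapply(split(body, frameOf), sample), use.names = FALSE)
  writeLines(c(pre, shuffled), f)
  e2 <- readEnsemble(f, format = "xyz-frames")
  d1 <- detectHBond(e, "14:N3", "14:H3", "17:OP2")
  d2 <- detectHBond(e2, "14:N3", "14:H3", "17:OP2")
  expect_equal(d2$distance, d1$distance, tolerance = 1e-3)
})

test_that("ensemble validity rejects broken inputs", {
  a <- data.frame(resno = 1L, resname = "U", atom = "N3", element = "N")
  expect_error(ensemble(a, array(NaN, c(1, 3, 1))), "finite")
  a2 <- rbind(a, a)
  expect_error(ensemble(a2, array(0, c(2, 3, 1))), "duplicate")
  expect_error(ensemble(a, array(0, c(1, 3, 1)), dt = -1), "dt")
})
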