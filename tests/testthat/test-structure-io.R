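test_that("structure round trip preserves hierarchy and coordinates", {
  g4 <- buildIdealG4(nTetrads = 3, twist = 30, rise = 3.4, ions = TRUE)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(g4, f)
  back <- readStructure(f)
  a1 <- atoms(g4)
  a2 <- atoms(back)
  expect_equal(nrow(a2), nrow(a1))
  expect_equal(a2$resno, a1$resno)
  expect_equal(a2$chain, a1$chain)
  expect_equal(a2$elety, a1$elety)
  expect_lt(max(abs(as.matrix(a1[, c("x", "y", "z")]) -
                    as.matrix(a2[, c("x", "y", "z")]))), 1e-3)
})

test_that("single ATOM record gives a 1-chain, 1-residue, 1-atom structure", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdbAtomLine(1, "C1'", " ", "DG", "A", 1, 1.5, 2.5, 3.5, 1, 10, "C"),
             f)
  s <- readStructure(f)
  expect_equal(nAtoms(s), 1L)
  expect_equal(chainIds(s), "A")
  expect_equal(atoms(s)$resno, 1L)
  expect_equal(unname(unlist(atoms(s)[1, c("x", "y", "z")])),
               c(1.5, 2.5, 3.5))
})

test_that("unreadable and empty files raise informative errors", {
  expect_error(readStructure(file.path(tempdir(), "does-not-exist.pdb")),
               "cannot read")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), f)
  expect_error(readStructure(f))
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdbAtomLine(1, "C1'", "A", "DG", "A", 1, 0, 0, 0, 0.40, 10, "C"),
    pdbAtomLine(2, "C1'", "B", "DG", "A", 1, 5, 0, 0, 0.60, 10, "C"),
    pdbAtomLine(3, "N9", " ", "DG", "A", 1, 1, 1, 1, 1.00, 10, "N")), f)
  s <- readStructure(f)
  a <- atoms(s)
  expect_equal(nrow(a), 2L)
  expect_equal(a$x[a$elety == "C1'"], 5) # occupancy 0.6 conformer kept
})

test_that("hydrogens are dropped by default and kept on request", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdbAtomLine(1, "C1'", " ", "DG", "A", 1, 0, 0, 0, 1, 0, "C"),
    pdbAtomLine(2, "H1'", " ", "DG", "A", 1, 1, 0, 0, 1, 0, "H")), f)
  expect_equal(nAtoms(readStructure(f)), 1L)
  expect_equal(nAtoms(readStructure(f, hydrogens = TRUE)), 2L)
})

test_that("oversized structures are refused by the writer", {
  n <- 100001L
  a <- data.frame(model = 1L, chain = "A", resno = rep(1L, n), resid = "DG",
                  elety = "C1'", elesy = "C", x = seq_len(n) * 0.001, y = 0,
                  z = 0, o = 1, b = 0, type = "ATOM",
                  stringsAsFactors = FALSE)
  s <- methods::new("AtomicStructure", atoms = a)
  expect_error(writeStructure(s, tempfile(fileext = ".pdb")), "99999")
})

test_that("bead model reader parses header volumes into radii", {
  centers <- matrix(rnorm(30, sd = 10), 10)
  for (case in list(list(phrase = "Dummy atom volume   :", v = 5.661, r = 1.106),
                    list(phrase = "Average volume per atom:", v = 11.056, r = 1.382))) {
    f <- withr::local_tempfile(fileext = ".pdb")
    m <- BeadModel(centers, radii = aerFromVolume(case$v),
                   dummyAtomVolume = case$v)
    writeBeadModel(m, f)
    # rewrite the remark with the alternative phrase
    lines <- readLines(f)
    lines[1] <- sprintf("REMARK 265  %s %.4f", case$phrase, case$v)
    writeLines(lines, f)
    back <- readBeadModel(f)
    expect_equal(nBeads(back), 10L)
    expect_equal(dummyAtomVolume(back), case$v)
    expect_equal(beadRadii(back), rep(case$r, 10), tolerance = 1e-3)
    # volume = (4/3) pi r^3 within 1e-6 relative
    expect_equal(4 / 3 * pi * beadRadii(back)[1]^3, case$v,
                 tolerance = 1e-6)
  }
})

test_that("bead files without a volume remark keep beads with unset radii", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeBeadModel(BeadModel(matrix(rnorm(15), 5)), f)
  m <- readBeadModel(f)
  expect_equal(nBeads(m), 5L)
  expect_true(all(is.na(beadRadii(m))))
  expect_true(is.na(dummyAtomVolume(m)))
})

test_that("malformed volume remarks warn and leave the volume absent", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeBeadModel(BeadModel(matrix(rnorm(9), 3)), f)
  writeLines(c("REMARK 265  Dummy atom volume : not-a-number",
               readLines(f)), f)
  expect_warning(m <- readBeadModel(f), "malformed")
  expect_true(is.na(dummyAtomVolume(m)))
})
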