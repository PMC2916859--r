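# Multi-model PDB round-tripping, atom selection and frame windows.

test_that("write/read round-trips coordinates and topology", {
  gen <- fixture_small()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(gen$ensemble, f)
  back <- read_multimodel_pdb(f)
  expect_equal(n_frames(back), n_frames(gen$ensemble))
  expect_lt(max(abs(back$xyz - gen$ensemble$xyz)), 1e-3 + 1e-9)
  for (col in c("atom_name", "residue_name", "residue_number", "chain_id"))
    expect_identical(back$topology[[col]], gen$ensemble$topology[[col]])
})

test_that("a file without MODEL records reads as one frame", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  NZ  LYS C 120       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  O6   DG A   2       3.000   0.000   0.000  1.00  0.00           O",
    "END"), f)
  e <- read_multimodel_pdb(f)
  expect_equal(n_frames(e), 1L)
  expect_equal(n_atoms(e), 2L)
})

test_that("atom-count mismatch between models is reported with its index", {
  f <- withr::local_tempfile(fileext = ".pdb")
  a1 <- "ATOM      1  NZ  LYS C 120       0.000   0.000   0.000  1.00  0.00           N"
  a2 <- "ATOM      2  O6   DG A   2       3.000   0.000   0.000  1.00  0.00           O"
  writeLines(c("MODEL        1", a1, a2, "ENDMDL",
               "MODEL        2", a1, "ENDMDL", "END"), f)
  expect_error(read_multimodel_pdb(f), "model 2")
})

test_that("prime spellings of atom names are interchangeable", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  C3*  DG A   2       3.000   0.000   0.000  1.00  0.00           C",
    "END"), f)
  e <- read_multimodel_pdb(f)
  expect_length(select_atoms(e, atom_name = "C3'"), 1)
  expect_length(select_atoms(e, atom_name = "C3*"), 1)
})

test_that("selection is conjunctive, order-stable and supports unions", {
  ens <- fixture_template()$ensemble
  nz <- select_atoms(ens, residue_number = 120, atom_name = "NZ",
                     chain_id = "C")
  expect_length(nz, 1)
  expect_identical(select_atoms(ens, chain_id = "Z"), integer(0))
  # union of singleton selections equals one multi-name selection
  multi <- select_atoms(ens, chain_id = "C", residue_number = 280,
                        atom_name = c("NE", "NH1", "NH2"))
  singles <- sort(unique(c(
    select_atoms(ens, chain_id = "C", residue_number = 280, atom_name = "NE"),
    select_atoms(ens, chain_id = "C", residue_number = 280, atom_name = "NH1"),
    select_atoms(ens, chain_id = "C", residue_number = 280,
                 atom_name = "NH2"))))
  expect_identical(multi, singles)
  expect_identical(multi, multi[order(multi)])  # topology order
})

test_that("frame windows resolve fractions and ranges with bounds checks", {
  expect_equal(resolve_window(30L, 2 / 3), 11:30)
  expect_equal(resolve_window(30L, 1 / 6), 26:30)
  expect_equal(resolve_window(30L, list(range = c(5, 9))), 5:9)
  expect_error(resolve_window(30L, list(range = c(6, 5))), "empty|range")
  expect_error(resolve_window(30L, 0), "fraction")
  expect_error(resolve_window(30L, list(range = c(0, 5))), "range")
})

test_that("ensemble constructor enforces congruence invariants", {
  top <- simple_topology(2)
  expect_error(ensemble(top, matrix(1:9, 1)), "match")
  expect_error(ensemble(top, matrix(c(1, NA, rep(0, 4)), 1)), "finite")
  top2 <- top; top2$serial <- c(1L, 1L)
  expect_error(ensemble(top2, matrix(0, 1, 6)), "unique")
})
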