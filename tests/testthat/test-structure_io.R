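test_that("multi-model files parse with correct shape and dialect rules", {
  lines <- c("MODEL        1", pdb_lines_one_model(), "ENDMDL",
             "MODEL        2", pdb_lines_one_model(), "ENDMDL",
             "MODEL        3", pdb_lines_one_model(), "ENDMDL", "END")
  p <- write_pdb_fixture(lines)
  e <- read_ensemble(p)
  expect_s3_class(e, "ensemble")
  expect_equal(length(e$models), 3L)
  expect_equal(n_residues(e), 3L)
  expect_equal(e$sequence, "AGA")

  # no MODEL records: one model
  p1 <- write_pdb_fixture(pdb_lines_one_model())
  e1 <- read_ensemble(p1)
  expect_equal(length(e1$models), 1L)

  # HETATM and non-A altlocs are skipped
  p2 <- write_pdb_fixture(c(
    pdb_lines_one_model(),
    "HETATM    8  O   HOH A   9      99.000  99.000  99.000  1.00  0.00"))
  expect_equal(n_residues(read_ensemble(p2)), 3L)
})

test_that("author numbering is discarded and residues renumbered 1..n", {
  p <- write_pdb_fixture(pdb_lines_one_model(resseq_offset = 56))
  e <- read_ensemble(p)
  expect_equal(n_residues(e), 3L)
  m <- e$models[[1]]
  expect_equal(tidy(m)$residue, 1:3)
})

test_that("interaction centers are side-chain centroids with CA fallback", {
  p <- write_pdb_fixture(pdb_lines_one_model())
  m <- read_ensemble(p)$models[[1]]
  # residue 1 has a CB side-chain atom; residue 2 (GLY) falls back to CA
  expect_equal(m$center[1, ], c(12.919, 6.898, -5.041))
  expect_equal(m$center[2, ], m$ca[2, ])
  expect_equal(m$ca[1, ], c(11.639, 6.071, -5.147))
})

test_that("malformed and inconsistent input is rejected with clear errors", {
  # inconsistent residue counts across models
  bad <- c("MODEL        1", pdb_lines_one_model(), "ENDMDL",
           "MODEL        2", pdb_lines_one_model()[1:4], "ENDMDL")
  expect_error(read_ensemble(write_pdb_fixture(bad)), "shape error")

  # corrupt coordinate field, error names the line
  lines <- pdb_lines_one_model()
  lines[2] <- sub("11.639", "xx.xxx", lines[2])
  expect_error(read_ensemble(write_pdb_fixture(lines)), "line 2")

  # multi-chain input is an error, not a merge
  two_chain <- c(pdb_lines_one_model(),
                 sub(" A ", " B ", "ATOM      8  CA  ALA B   9       1.000   2.000   3.000  1.00  0.00"))
  expect_error(read_ensemble(write_pdb_fixture(two_chain)), "chain")

  # residue without CA
  noca <- pdb_lines_one_model()[c(1, 3, 5, 6, 7)]
  expect_error(read_ensemble(write_pdb_fixture(noca)), "no CA atom")

  expect_error(read_ensemble(tempfile()), "no such file")
  expect_error(ensemble(list()), "at least one model")
})

test_that("write/read round-trips coordinates at PDB precision", {
  g <- generate_ensemble(synthetic_spec(n_core = 12, n_tail_n = 3,
                                        n_models = 2, seed = 5))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(g$ensemble, path)
  back <- read_ensemble(path)
  expect_equal(length(back$models), 2L)
  expect_equal(back$sequence, g$ensemble$sequence)
  for (k in 1:2) {
    expect_lt(max(abs(back$models[[k]]$ca - g$ensemble$models[[k]]$ca)), 1e-3)
    expect_lt(max(abs(back$models[[k]]$center - g$ensemble$models[[k]]$center)), 1e-3)
  }
  # single model still gets MODEL/ENDMDL bracketing
  single <- ensemble(list(g$ensemble$models[[1]]))
  p1 <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(single, p1)
  txt <- readLines(p1)
  expect_true(any(startsWith(txt, "MODEL")))
  expect_true(any(startsWith(txt, "ENDMDL")))
})

test_that("an independent PDB reader agrees with files we write", {
  skip_if_not_installed("bio3d")
  g <- generate_ensemble(synthetic_spec(n_core = 10, n_models = 1, seed = 9))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(g$ensemble, path)
  ref <- bio3d::read.pdb(path)
  ca <- ref$atom[ref$atom$elety == "CA", c("x", "y", "z")]
  expect_equal(unname(as.matrix(ca)), g$ensemble$models[[1]]$ca,
               tolerance = 1e-3)
})
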