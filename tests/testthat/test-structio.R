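# Structure I/O, standardization and sequence extraction.

test_that("minimal PDB parses with correct record counts and coordinates", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(minimal_pdb_lines(), f)
  s <- read_structure(f)
  expect_equal(length(unique(s$chain)), 1L)
  expect_equal(nrow(residue_table(s)), 1L)
  expect_equal(nrow(s), 5L)
  expect_setequal(s$atom, c("N", "CA", "C", "O", "CB"))
  expect_equal(s$x[s$atom == "CA"], 0)
})

test_that("the same content parses identically from PDB and mmCIF", {
  s0 <- fx_helix(10)
  fp <- withr::local_tempfile(fileext = ".pdb")
  fc <- withr::local_tempfile(fileext = ".cif")
  write_structure(s0, fp)
  write_structure(s0, fc)
  sp <- read_structure(fp)
  sc <- read_structure(fc)
  expect_equal(sp$atom, sc$atom)
  expect_equal(sp$resname, sc$resname)
  expect_equal(sp$resno, sc$resno)
  expect_lt(max(abs(coords(sp) - coords(sc))), 1e-3)
})

test_that("files with only hetero records raise an empty-structure error", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "HETATM    2  C1  LIG A   2       1.000   1.000   1.000  1.00  0.00           C",
    "END"), f)
  expect_error(read_structure(f), "no protein residues")
})

test_that("round-trip through both formats preserves geometry to 1e-3 A", {
  s <- fx_helix(20)
  for (fmt in c("pdb", "mmcif")) {
    f <- withr::local_tempfile(fileext = if (fmt == "pdb") ".pdb" else ".cif")
    write_structure(s, f, fmt)
    r <- read_structure(f)
    expect_equal(nrow(r), nrow(s))
    expect_equal(r$atom, s$atom)
    expect_equal(r$resno, s$resno)
    expect_lt(max(abs(coords(r) - coords(s))), 1e-3)
  }
})

test_that("coordinates beyond the fixed-width PDB capacity error out", {
  s <- fx_helix(5)
  s$x[1] <- 12345.678
  f <- withr::local_tempfile(fileext = ".pdb")
  expect_error(write_structure(new_structure(s), f, "pdb"), "mmCIF")
})

test_that("two-chain structures keep chain ids and TER separation", {
  a <- tibble::as_tibble(fx_helix(5))
  b <- a
  b$chain <- "B"
  b$x <- b$x + 50
  s <- new_structure(rbind(a, b))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, f, "pdb")
  lines <- readLines(f)
  expect_equal(sum(startsWith(lines, "TER")), 2L)
  r <- read_structure(f)
  expect_setequal(unique(r$chain), c("A", "B"))
  expect_equal(nrow(r), nrow(s))
})

test_that("sequences are extracted gapless, one letter per resolved residue", {
  s <- fx_helix(3)
  expect_equal(extract_sequence(s)$sequence, "ACD")
  # gap in author numbering must not introduce gap characters
  g <- tibble::as_tibble(fx_helix(3))
  g$resno[atom_res_idx(new_structure(g)) == 3] <- 5L
  sq <- extract_sequence(new_structure(g))
  expect_equal(nchar(sq$sequence), 3L)
  expect_false(grepl("-", sq$sequence))
})

test_that("selenomethionine maps to MET and reads despite HETATM records", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  N   MSE A   1       0.000   0.000   0.000  1.00  0.00           N",
    "HETATM    2  CA  MSE A   1       1.458   0.000   0.000  1.00  0.00           C",
    "HETATM    3  C   MSE A   1       2.009   1.420   0.000  1.00  0.00           C",
    "HETATM    4  SE  MSE A   1       2.000  -1.000   1.000  1.00  0.00          SE",
    "END"), f)
  s <- standardize_structure(read_structure(f))
  expect_equal(unique(s$resname), "MET")
  expect_true("SD" %in% s$atom)
  expect_equal(extract_sequence(s)$sequence, "M")
})

test_that("standardization resolves altlocs, strips hydrogens, and is idempotent", {
  base <- tibble::as_tibble(fx_helix(4))
  alt <- base[base$atom == "CA" & base$resno == 1, ]
  alt$altloc <- "B"; alt$occ <- 0.4; alt$x <- alt$x + 1
  base$altloc[base$atom == "CA" & base$resno == 1] <- "A"
  base$occ[base$atom == "CA" & base$resno == 1] <- 0.6
  h <- base[1, ]; h$atom <- "H"; h$element <- "H"
  s <- new_structure(rbind(base, alt, h))
  std <- standardize_structure(s)
  expect_false(any(std$element == "H"))
  ca1 <- std[std$atom == "CA" & std$resno == 1, ]
  expect_equal(nrow(ca1), 1L)
  expect_equal(ca1$x, base$x[base$atom == "CA" & base$resno == 1])
  expect_identical(tibble::as_tibble(standardize_structure(std)),
                   tibble::as_tibble(std))
  expect_lte(nrow(std), nrow(s))
})

test_that("unmappable residue types are dropped with a message", {
  base <- tibble::as_tibble(fx_helix(3))
  weird <- base[base$resno == 2, ]
  weird$resname <- "XYZ"
  s <- new_structure(rbind(base[base$resno != 2, ], weird))
  expect_message(std <- standardize_structure(s), "XYZ")
  expect_equal(nrow(residue_table(std)), 2L)
})

test_that("multi-model files keep the first model only", {
  one <- minimal_pdb_lines()
  f <- withr::local_tempfile(fileext = ".pdb")
  body <- one[1:5]
  shifted <- sub("   0.000", "   9.000", body, fixed = TRUE)
  writeLines(c("MODEL     1", body, "ENDMDL",
               "MODEL     2", shifted, "ENDMDL", "END"), f)
  s <- suppressWarnings(read_structure(f))
  expect_equal(nrow(s), 5L)
  expect_equal(s$x[s$atom == "CA"], 0)
})
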