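# Structure reading, heavy-atom selection, ligand partitioning and PDB
# round-trips.

write_fixture <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), f)
  f
}

test_that("a synthetic complex parses into protein chain plus ligand", {
  lines <- c(
    pdb_line("ATOM", 1, "N", "ALA", "A", 1, 0, 0, 0, element = "N"),
    pdb_line("ATOM", 2, "CA", "ALA", "A", 1, 1.46, 0, 0),
    pdb_line("ATOM", 3, "C", "ALA", "A", 1, 2.0, 1.3, 0),
    pdb_line("ATOM", 4, "N", "GLY", "A", 2, 3.3, 1.3, 0, element = "N"),
    pdb_line("ATOM", 5, "CA", "GLY", "A", 2, 4.2, 2.2, 0),
    pdb_line("ATOM", 6, "N", "SER", "A", 3, 5.5, 2.2, 0, element = "N"),
    pdb_line("ATOM", 7, "CA", "SER", "A", 3, 6.4, 3.1, 0),
    pdb_line("HETATM", 8, "C1", "LIG", "A", 90, 0, 5, 0),
    pdb_line("HETATM", 9, "C2", "LIG", "A", 90, 1.4, 5, 0),
    pdb_line("HETATM", 10, "O1", "LIG", "A", 90, 2.1, 6, 0, element = "O"),
    pdb_line("HETATM", 11, "N1", "LIG", "A", 90, 3.0, 5, 0, element = "N"),
    pdb_line("HETATM", 12, "C3", "LIG", "A", 90, 4.2, 5.5, 0)
  )
  s <- read_structure(write_fixture(lines))
  expect_equal(length(unique(s$chain[!s$is_ligand])), 1)
  lig <- ligands(s)
  expect_equal(nrow(lig), 5)
  expect_equal(unique(lig$ligand_id), "LIG")
})

test_that("waters are never ligands", {
  lines <- c(
    pdb_line("ATOM", 1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_line("HETATM", 2, "O", "HOH", "A", 101, 3, 3, 3, element = "O"),
    pdb_line("HETATM", 3, "O", "HOH", "A", 102, 5, 5, 5, element = "O")
  )
  s <- read_structure(write_fixture(lines))
  expect_equal(nrow(ligands(s)), 0)
})

test_that("a CA-only trace yields one heavy atom per residue and no ligand", {
  lines <- vapply(1:10, function(i) {
    pdb_line("ATOM", i, "CA", "GLY", "A", i, 3.8 * i, 0, 0)
  }, character(1))
  s <- read_structure(write_fixture(lines))
  expect_equal(nrow(heavy_atoms(s)), 10)
  expect_equal(nrow(ligands(s)), 0)
})

test_that("hydrogens are excluded from heavy atoms", {
  s <- new_structure(tibble::tibble(
    name = c("CA", "CB", "N", "O", "C", "OD1", "OD2", "H", "HA", "HB1", "HB2"),
    element = c("C", "C", "N", "O", "C", "O", "O", "H", "H", "H", "H"),
    x = seq(0, 20, length.out = 11), y = 0, z = 0,
    chain = "A", resname = "ASP", resno = 1
  ))
  expect_equal(nrow(heavy_atoms(s)), 7)
  expect_error(heavy_atoms(s, chain = "Z"), "unknown chain")
})

test_that("selenomethionine stays protein and carries the Se radius", {
  lines <- c(
    pdb_line("ATOM", 1, "CA", "MSE", "A", 1, 0, 0, 0),
    pdb_line("HETATM", 2, "SE", "MSE", "A", 1, 1.9, 0, 0, element = "SE")
  )
  s <- read_structure(write_fixture(lines))
  expect_equal(nrow(ligands(s)), 0)
  se <- s[s$element == "SE", ]
  expect_equal(nrow(se), 1)
  expect_equal(se$vdw, 1.90)
})

test_that("unknown elements raise instead of defaulting a radius", {
  expect_error(vdw_radius("XX"), "no van der Waals radius")
})

test_that("altloc handling keeps the highest-occupancy conformer", {
  lines <- c(
    pdb_line("ATOM", 1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.4, altloc = "A"),
    pdb_line("ATOM", 2, "CA", "ALA", "A", 1, 9, 9, 9, occ = 0.6, altloc = "B"),
    pdb_line("ATOM", 3, "CB", "ALA", "A", 1, 1.5, 0, 0)
  )
  s <- read_structure(write_fixture(lines))
  ca <- s[s$name == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 9)
  # tie in occupancy resolves toward altloc 'A'
  lines2 <- c(
    pdb_line("ATOM", 1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.5, altloc = "B"),
    pdb_line("ATOM", 2, "CA", "ALA", "A", 1, 9, 9, 9, occ = 0.5, altloc = "A")
  )
  s2 <- read_structure(write_fixture(lines2))
  expect_equal(s2$x[s2$name == "CA"], 9)
})

test_that("write/read round trip preserves heavy-atom content", {
  s <- make_toy_complex(4, 5, seed = 7)
  f <- tempfile(fileext = ".pdb")
  write_structure(s, f)
  s2 <- read_structure(f)
  expect_equal(nrow(s2), nrow(s))
  expect_equal(s2$name, s$name)
  expect_equal(s2$resname, s$resname)
  expect_equal(s2$x, s$x, tolerance = 1e-3)
  expect_equal(sort(round(s2$y, 3)), sort(round(s$y, 3)))
  expect_equal(nrow(ligands(s2)), nrow(ligands(s)))
  # two reads of the same file are identical (determinism)
  s3 <- read_structure(f)
  expect_identical(s2, s3)
})

test_that("insertion codes survive the round trip", {
  lines <- c(
    pdb_line("ATOM", 1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_line("ATOM", 2, "CA", "GLY", "A", 1, 3.8, 0, 0, insert = "A"),
    pdb_line("ATOM", 3, "CA", "SER", "A", 2, 7.6, 0, 0)
  )
  s <- read_structure(write_fixture(lines))
  expect_equal(s$insert, c("", "A", ""))
  f2 <- tempfile(fileext = ".pdb")
  write_structure(s, f2)
  expect_equal(read_structure(f2)$insert, c("", "A", ""))
})

test_that("SASA annotations are written as a separate chain X", {
  s <- make_toy_complex(3, 4, seed = 5)
  areas <- rep(NA_real_, nrow(s))
  hv <- which(s$is_heavy & !s$is_ligand)
  areas[hv] <- seq_along(hv)
  f <- tempfile(fileext = ".pdb")
  write_structure(s, f, sasa = areas)
  s2 <- read_structure(f)
  expect_true("X" %in% s2$chain)
  expect_equal(sum(s2$chain == "X"), length(hv))
  # the B-factor column of chain X carries the per-atom area
  expect_equal(sort(s2$b[s2$chain == "X"]), as.numeric(seq_along(hv)))
})

test_that("unreadable input raises a format error", {
  f <- tempfile(fileext = ".pdb")
  writeLines("this is not a structure", f)
  expect_error(read_structure(f))
  expect_error(read_structure("/nonexistent/file.pdb"), "no such file")
})
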