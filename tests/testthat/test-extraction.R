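# Cavity and surface-patch extraction, SASA, and the patch database.

test_that("ligand cavity matches a brute-force whole-residue shell", {
  s <- make_toy_complex(pocket_residues = 5, ligand_atoms = 5, seed = 2)
  cav <- extract_ligand_cavity(s, "LIG", min_atoms = 10)
  expect_s3_class(cav, "slam_substructure")
  # brute force: residues with any heavy atom within 7 A of any ligand atom
  lig <- ligands(s)
  prot <- s[!s$is_ligand & s$is_heavy, ]
  near <- vapply(seq_len(nrow(prot)), function(i) {
    any(sqrt((lig$x - prot$x[i])^2 + (lig$y - prot$y[i])^2 +
               (lig$z - prot$z[i])^2) <= 7)
  }, TRUE)
  bf_res <- sort(unique(prot$resno[near]))
  expect_equal(sort(unique(cav$resno)), bf_res)
  expect_equal(bf_res, 1:5) # construction guarantee
  # whole-residue closure: all or none of each residue
  counts <- table(prot$resno)
  expect_true(all(table(cav$resno) == counts[names(table(cav$resno))]))
  # the ligand itself is not part of the cavity
  expect_false(any(cav$is_ligand))
})

test_that("the cavity size filter is an inclusive >= bound", {
  s <- make_toy_complex(pocket_residues = 5, ligand_atoms = 5, seed = 2)
  n <- nrow(extract_ligand_cavity(s, "LIG", min_atoms = 1))
  expect_null(extract_ligand_cavity(s, "LIG", min_atoms = n + 1))
  expect_equal(nrow(extract_ligand_cavity(s, "LIG", min_atoms = n)), n)
  expect_null(extract_ligand_cavity(s, "LIG", radius = 0))
})

test_that("cavity radius is monotone: larger shells keep all residues", {
  s <- make_toy_complex(pocket_residues = 4, ligand_atoms = 5, seed = 9)
  r7 <- extract_ligand_cavity(s, "LIG", radius = 7, min_atoms = 1)
  r9 <- extract_ligand_cavity(s, "LIG", radius = 9, min_atoms = 1)
  expect_true(all(unique(r7$resno) %in% unique(r9$resno)))
})

test_that("SASA matches closed-form sphere results", {
  iso <- atoms_structure(matrix(c(0, 0, 0), 1))
  a <- compute_sasa(iso)
  expect_equal(a$area, 4 * pi * (1.70 + 1.4)^2, tolerance = 1e-6)
  # two far atoms: no occlusion
  far <- atoms_structure(rbind(c(0, 0, 0), c(50, 0, 0)))
  a2 <- compute_sasa(far)
  expect_equal(a2$area, rep(4 * pi * 3.1^2, 2), tolerance = 1e-6)
  # two overlapping carbons vs the analytic two-sphere formula
  d <- 2.0
  ov <- atoms_structure(rbind(c(0, 0, 0), c(d, 0, 0)))
  a3 <- compute_sasa(ov, n_points = 2000)
  expect_equal(a3$area, two_sphere_areas(3.1, 3.1, d), tolerance = 0.01)
  # a caged atom is buried
  dirs <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  dirs <- dirs[rowSums(abs(dirs)) > 0, ]
  cage <- atoms_structure(rbind(c(0, 0, 0), 2.2 * dirs / sqrt(rowSums(dirs^2))))
  a4 <- compute_sasa(cage)
  expect_lt(a4$area[1], 1)
})

test_that("SASA is invariant under rigid motion", {
  s <- make_toy_complex(3, 4, seed = 4)
  a1 <- compute_sasa(s, n_points = 480)
  s2 <- rigid_copy(s)
  a2 <- compute_sasa(s2, n_points = 480)
  expect_lt(max(abs(a2$area - a1$area)), 2.5) # point-sampling tolerance
})

test_that("surface exposure cut is strictly greater-than", {
  areas <- tibble::tibble(atom_id = 1:3, chain = "A", area = c(2.0, 120, 0))
  expect_equal(surface_atoms(areas, 2), 2L)
})

test_that("surface patches are whole-residue shells around the center", {
  s <- make_toy_complex(pocket_residues = 4, ligand_atoms = 4, seed = 3)
  prot <- s[!s$is_ligand & s$is_heavy, ]
  center <- prot$atom_id[1]
  p <- extract_surface_patch(s, center, radius = 7)
  ci <- match(center, s$atom_id)
  near <- vapply(seq_len(nrow(prot)), function(i) {
    sqrt((prot$x[i] - s$x[ci])^2 + (prot$y[i] - s$y[ci])^2 +
           (prot$z[i] - s$z[ci])^2) <= 7
  }, TRUE)
  expect_equal(sort(unique(p$resno)), sort(unique(prot$resno[near])))
  # radius covering everything selects all residues
  p_all <- extract_surface_patch(s, center, radius = 1000)
  expect_equal(sort(unique(p_all$resno)), sort(unique(prot$resno)))
  # determinism
  expect_identical(p, extract_surface_patch(s, center, radius = 7))
  expect_error(extract_surface_patch(s, 10000), "not in structure")
})

test_that("the patch database is deterministic and counts surface atoms", {
  structures <- list(make_toy_complex(2, 4, seed = 11),
                     make_toy_complex(2, 4, seed = 12))
  cfg <- slam_config(sasa_n_points = 240)
  d1 <- tempfile("patchdb1")
  man1 <- build_patch_database(structures, d1, cfg)
  # one patch per surface-exposed atom
  n_surf <- vapply(structures, function(s) {
    length(surface_atoms(compute_sasa(s, n_points = 240), 2))
  }, 1L)
  expect_equal(nrow(man1), sum(n_surf))
  expect_true(all(file.exists(file.path(d1, man1$file))))
  d2 <- tempfile("patchdb2")
  build_patch_database(structures, d2, cfg)
  expect_identical(readLines(file.path(d1, "manifest.tsv")),
                   readLines(file.path(d2, "manifest.tsv")))
})
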