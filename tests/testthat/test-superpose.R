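# Kabsch superposition, ligand transfer, pose displacement and FE-score.

test_that("identical point sets give the identity transform", {
  set.seed(21)
  A <- matrix(rnorm(15), 5)
  tf <- kabsch_superpose(A, A)
  expect_equal(tf$rotation, diag(3), tolerance = 1e-10)
  expect_equal(tf$translation, rep(0, 3), tolerance = 1e-10)
  expect_equal(tf$rmsd, 0, tolerance = 1e-10)
})

test_that("a known rotation + translation is inverted exactly", {
  set.seed(22)
  A <- matrix(rnorm(18), 6)
  R <- rot_about_z(pi / 6)
  B <- A %*% t(R) + matrix(rep(c(1, -2, 3), each = 6), 6)
  tf <- kabsch_superpose(B, A)
  expect_equal(tf$rmsd, 0, tolerance = 1e-9)
  expect_equal(apply_transform(B, tf), A, tolerance = 1e-9)
  expect_equal(det(tf$rotation), 1, tolerance = 1e-12)
  # mapping the other way composes to the identity
  tf2 <- kabsch_superpose(A, B)
  expect_equal(tf2$rotation %*% tf$rotation, diag(3), tolerance = 1e-9)
})

test_that("reflections are excluded", {
  set.seed(23)
  A <- matrix(rnorm(15), 5)
  B <- A
  B[, 1] <- -B[, 1] # mirrored set
  tf <- kabsch_superpose(B, A)
  expect_equal(det(tf$rotation), 1, tolerance = 1e-12)
  expect_gt(tf$rmsd, 0.1)
})

test_that("degenerate (collinear) inputs raise", {
  line <- cbind(1:4, 0, 0)
  expect_error(kabsch_superpose(line, line + 1), "degenerate")
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)))
})

test_that("the closed form is never beaten by a 5-degree rotation grid", {
  set.seed(24)
  for (case in 1:2) {
    n <- sample(4:6, 1)
    A <- matrix(rnorm(3 * n, sd = 2), n)
    B <- A %*% t(rot_about_z(runif(1, 0, pi))) +
      matrix(rnorm(3 * n, sd = 0.5), n)
    tf <- kabsch_superpose(B, A)
    expect_lte(tf$rmsd, grid_best_rmsd(B, A) + 1e-9)
  }
})

test_that("fit rmsd under isotropic noise matches the Monte-Carlo scale", {
  set.seed(25)
  n <- 20
  sg <- 0.5
  rms <- replicate(40, {
    A <- matrix(rnorm(3 * n), n)
    kabsch_superpose(A + matrix(rnorm(3 * n, 0, sg), n), A)$rmsd
  })
  # least-squares theory: E[rmsd] ~ sigma * sqrt(3 - 6/n)
  expect_equal(mean(rms), sg * sqrt(3 - 6 / n), tolerance = 0.2)
})

test_that("ligand transfer reproduces the crystallographic pose on self", {
  s <- make_toy_complex(5, 5, seed = 2)
  lig <- ligands(s)
  ann <- annotate_atoms(s)
  hv <- heavy_atoms(s)[!heavy_atoms(s)$is_ligand, ]
  pairs <- tibble::tibble(atom_id_a = hv$atom_id[1:10],
                          atom_id_b = hv$atom_id[1:10])
  pose <- transfer_ligand(s, lig, pairs, s)
  expect_equal(as.matrix(pose[, c("x", "y", "z")]),
               as.matrix(lig[, c("x", "y", "z")]), tolerance = 1e-6)
  # rigid-copy target: the transferred pose lands on the moved ligand
  s2 <- rigid_copy(s)
  pairs2 <- tibble::tibble(atom_id_a = hv$atom_id[1:10],
                           atom_id_b = hv$atom_id[1:10])
  pose2 <- transfer_ligand(s, lig, pairs2, s2)
  truth <- rigid_copy(lig)
  expect_equal(pose2$x, truth$x, tolerance = 1e-6)
  expect_equal(pose2$y, truth$y, tolerance = 1e-6)
})

test_that("pose shift implements RMSD and centroid displacement", {
  p <- matrix(rnorm(27), 9)
  expect_equal(pose_shift(p, p), 0)
  expect_equal(pose_shift(p, p + matrix(rep(c(2, 0, 0), each = 9), 9)), 2)
  q <- p
  q[1, ] <- q[1, ] + c(3, 0, 0) # one atom moved 3 A in a 9-atom ligand
  expect_equal(pose_shift(p, q), sqrt(9 / 9))
  expect_equal(pose_shift(p, q, mode = "centroid"), 3 / 9)
  expect_error(pose_shift(p, p[1:3, ]), "atom count")
})

test_that("FE-score and the TP rule follow the stated contract", {
  expect_equal(fe_score(-7, 0.9), -7)
  expect_equal(fe_score(0, 4), 0)
  expect_true(classify_tp(fe_score(-7, 0.9)))
  expect_false(classify_tp(fe_score(0, 1)))
  # boundary: exactly -1.5 is not a TP (strict <)
  expect_equal(fe_score(-3, 1.9), -1.5)
  expect_false(classify_tp(fe_score(-3, 1.9)))
  expect_error(fe_score(-3, -0.1))
  # monotone: deeper energies lower the score; larger shifts pull it to 0
  fe <- seq(-1, -10, by = -1)
  expect_true(all(diff(fe_score(fe, 1)) < 0))
  sh <- seq(0, 10, by = 0.5)
  expect_true(all(diff(fe_score(-5, sh)) > 0))
})

test_that("the stub engine rewards clash-free pockets and relieves clashes", {
  s <- make_toy_complex(5, 5, seed = 2)
  lig <- ligands(s)
  d <- optimize_pose(s, lig, engine = "stub")
  expect_lt(d$fe, 0)
  expect_true(is.finite(d$fe_score))
  expect_gte(d$shift, 0)
  # a pose shoved into the receptor is moved during optimization
  lig_clash <- lig
  lig_clash$x <- lig_clash$x + 3
  d2 <- optimize_pose(s, lig_clash, engine = "stub")
  expect_gt(d2$shift, 0)
})

test_that("the PDBQT writer emits rigid and ligand blocks", {
  s <- make_toy_complex(2, 4, seed = 3)
  lig <- ligands(s)
  f1 <- tempfile(fileext = ".pdbqt")
  slamr:::.write_pdbqt(heavy_atoms(s), f1, rigid_receptor = TRUE)
  lines1 <- readLines(f1)
  expect_true(all(startsWith(lines1, "ATOM")))
  f2 <- tempfile(fileext = ".pdbqt")
  slamr:::.write_pdbqt(lig, f2, rigid_receptor = FALSE)
  lines2 <- readLines(f2)
  expect_equal(lines2[1], "ROOT")
  expect_true("ENDROOT" %in% lines2)
  expect_true("TORSDOF 0" %in% lines2)
  # coordinates parse back from fixed columns
  al <- lines2[startsWith(lines2, "ATOM")]
  x <- as.numeric(substr(al, 31, 38))
  expect_equal(x, lig$x, tolerance = 1e-3)
})
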