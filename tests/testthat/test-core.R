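# Pair-evidence accumulation, candidate selection, distance correlation,
# clustering and the composed engine.

test_that("a rigid self-screen concentrates evidence on the true pairs", {
  s <- annotate_atoms(make_random_structure(6, seed = 51))
  s2 <- annotate_atoms(rigid_copy(s))
  tbl <- accumulate_pair_evidence(s, s2)
  expect_s3_class(tbl, "slam_pair_table")
  expect_true(all(tbl$evidence > 0))
  expect_true(all(tbl$n_alignments >= 1))
  # the strongest pair is an identity pair, and every heavy atom's identity
  # pair is present
  expect_equal(tbl$atom_id_a[1], tbl$atom_id_b[1])
  ids <- heavy_atoms(s)$atom_id
  expect_true(all(paste(ids, ids) %in% paste(tbl$atom_id_a, tbl$atom_id_b)))
})

test_that("chemically disjoint substructures produce an empty table", {
  set.seed(6)
  ca <- annotate_atoms(atoms_structure(matrix(runif(30, 0, 8), 10),
                                       element = "C", resname = "ALA",
                                       name = "CB"))
  cb <- annotate_atoms(atoms_structure(matrix(runif(30, 0, 8), 10),
                                       element = "O", resname = "TYR",
                                       name = "OH"))
  tbl <- accumulate_pair_evidence(ca, cb)
  expect_equal(nrow(tbl), 0)
})

test_that("candidate selection separates outliers from background", {
  tbl <- tibble::tibble(
    atom_id_a = 1:22, atom_id_b = 1:22,
    evidence = c(rep(1, 20), 100, 100), n_alignments = 1
  )
  # mean 10, sd 29.13 -> mean + 2 sd = 68.3: exactly the two 100s
  sel <- select_candidate_pairs(tbl, slam_config())
  expect_equal(sort(sel$evidence), c(100, 100))
  # empty in, empty out
  expect_equal(nrow(select_candidate_pairs(tbl[0, ], slam_config())), 0)
  # quantile and fixed policies
  selq <- select_candidate_pairs(tbl, slam_config(candidate_policy = "quantile",
                                                  quantile = 0.95))
  expect_true(all(selq$evidence == 100))
  self <- select_candidate_pairs(tbl, slam_config(candidate_policy = "fixed",
                                                  fixed_evidence = 50))
  expect_equal(nrow(self), 2)
  # an all-background table yields an empty (valid) selection
  flat <- tibble::tibble(atom_id_a = 1:10, atom_id_b = 1:10,
                         evidence = rep(3, 10), n_alignments = 1)
  expect_equal(nrow(select_candidate_pairs(flat, slam_config())), 0)
})

test_that("distance correlation is 1 for isometries and scalings", {
  set.seed(7)
  A <- matrix(rnorm(30, sd = 5), 10)
  sa <- atoms_structure(A)
  pairs <- tibble::tibble(atom_id_a = 1:10, atom_id_b = 1:10)
  # rigid motion
  sb <- atoms_structure(A %*% t(rot_about_z(1.1)) +
                          matrix(rep(c(3, -2, 7), each = 10), 10))
  expect_equal(distance_correlation(pairs, sa, sb), 1, tolerance = 1e-12)
  # uniform scaling by 2 also gives r = 1
  expect_equal(distance_correlation(pairs, sa, atoms_structure(2 * A)), 1,
               tolerance = 1e-12)
  # unrelated clouds: |r| < 1 and equal to the textbook computation
  B <- matrix(rnorm(30, sd = 5), 10)
  sbr <- atoms_structure(B)
  r <- distance_correlation(pairs, sa, sbr)
  da <- as.numeric(dist(A))
  db <- as.numeric(dist(B))
  manual <- sum((da - mean(da)) * (db - mean(db))) /
    sqrt(sum((da - mean(da))^2) * sum((db - mean(db))^2))
  expect_equal(r, manual, tolerance = 1e-12)
  expect_lt(abs(r), 1)
})

test_that("degenerate correlation inputs signal undefined", {
  sa <- atoms_structure(rbind(c(0, 0, 0), c(1, 0, 0)))
  pairs2 <- tibble::tibble(atom_id_a = 1:2, atom_id_b = 1:2)
  expect_warning(r <- distance_correlation(pairs2, sa, sa), "fewer than 3")
  expect_true(is.na(r))
  # coincident atoms: zero-variance distance vector
  eq <- atoms_structure(matrix(0, 3, 3))
  pairs3 <- tibble::tibble(atom_id_a = 1:3, atom_id_b = 1:3)
  expect_warning(r3 <- distance_correlation(pairs3, eq, eq), "zero-variance")
  expect_true(is.na(r3))
})

test_that("ncorr5 follows the N * r^5 contract", {
  expect_equal(ncorr5(40, 0.9), 23.6196)
  expect_equal(ncorr5(17, 1), 17)
  expect_equal(ncorr5(35, 0.95), 35 * 0.95^5)
  # monotone in N at fixed r and in r at fixed N
  expect_true(all(diff(ncorr5(1:50, 0.9)) > 0))
  expect_true(all(diff(ncorr5(30, seq(0.5, 1, 0.01))) > 0))
})

test_that("clustering recovers a planted pair motif among decoys", {
  set.seed(4)
  A <- matrix(rnorm(180, 0, 6), 60)
  B <- A %*% t(rot_about_z(0.8)) + 3 + matrix(rnorm(180, 0, 0.3), 60)
  sa <- atoms_structure(A)
  sb <- atoms_structure(B)
  cand <- tibble::tibble(
    atom_id_a = c(1:20, sample(21:60, 30)),
    atom_id_b = c(1:20, sample(21:60, 30)),
    evidence = c(rep(10, 20), rep(5, 30))
  )
  res <- cluster_pairs(cand, sa, sb, slam_config(), seeds = NULL)
  expect_gte(nrow(res), 1)
  top <- res$pairs[[1]]
  planted_in_top <- sum(top$atom_id_a == top$atom_id_b & top$atom_id_a <= 20)
  expect_gte(planted_in_top, 18)
  expect_gte(res$r[1], 0.85)
})

test_that("two disjoint motifs come out as two clusters", {
  set.seed(12)
  A1 <- matrix(rnorm(30, 0, 4), 10)
  off <- matrix(rep(c(60, 0, 0), each = 10), 10)
  A2 <- matrix(rnorm(30, 0, 4), 10) + off
  sa <- atoms_structure(rbind(A1, A2))
  # each motif moves rigidly on its own; their relative placement changes
  # (far apart in A, adjacent in B), so the union is inconsistent
  B1 <- A1 %*% t(rot_about_z(0.5)) + 2
  B2 <- (A2 - off) %*% t(rot_about_z(2.2)) +
    matrix(rep(c(13, 0, 0), each = 10), 10)
  sb <- atoms_structure(rbind(B1, B2))
  cand <- tibble::tibble(atom_id_a = 1:20, atom_id_b = 1:20, evidence = 1)
  res <- cluster_pairs(cand, sa, sb, slam_config(), seeds = NULL)
  expect_equal(nrow(res), 2)
  expect_setequal(res$n_pairs, c(10, 10))
  members <- lapply(res$pairs, function(p) sort(p$atom_id_a))
  expect_setequal(lapply(members, paste, collapse = ","),
                  list(paste(1:10, collapse = ","),
                       paste(11:20, collapse = ",")))
})

test_that("a single candidate pair cannot form a cluster", {
  sa <- atoms_structure(matrix(rnorm(30), 10))
  cand <- tibble::tibble(atom_id_a = 1, atom_id_b = 1, evidence = 1)
  res <- cluster_pairs(cand, sa, sa, slam_config(), seeds = NULL)
  expect_equal(nrow(res), 0)
})

test_that("self-alignment of a rigid copy recovers the identity mapping", {
  s <- annotate_atoms(make_random_structure(6, seed = 52))
  res <- slam_align(s, annotate_atoms(rigid_copy(s)))
  expect_gte(nrow(res), 1)
  top <- res$pairs[[1]]
  expect_true(all(top$atom_id_a == top$atom_id_b))
  expect_gte(res$r[1], 0.999)
  expect_equal(res$ncorr5[1], res$n_pairs[1], tolerance = 0.01)
})

test_that("the engine is invariant under rigid motion of the target", {
  s <- annotate_atoms(make_random_structure(5, seed = 53))
  t1 <- annotate_atoms(rigid_copy(s, theta = 0.3, shift = c(1, 1, 1)))
  t2 <- annotate_atoms(rigid_copy(t1, theta = 2.1, shift = c(-8, 4, 2)))
  r1 <- slam_align(s, t1)
  r2 <- slam_align(s, t2)
  expect_equal(nrow(r1), nrow(r2))
  expect_equal(r1$n_pairs, r2$n_pairs)
  expect_equal(r1$r, r2$r, tolerance = 1e-9)
  expect_equal(r1$ncorr5, r2$ncorr5, tolerance = 1e-9)
  # evidence tables agree in total and in the identity-pair entries (rigid
  # motion can flip near-tied neighbor ranks, so single background entries
  # may shuffle)
  tb1 <- accumulate_pair_evidence(s, t1)
  tb2 <- accumulate_pair_evidence(s, t2)
  expect_equal(sum(tb1$evidence), sum(tb2$evidence), tolerance = 5e-3)
  k1 <- paste(tb1$atom_id_a, tb1$atom_id_b)
  k2 <- paste(tb2$atom_id_a, tb2$atom_id_b)
  expect_gt(length(intersect(k1, k2)) / length(union(k1, k2)), 0.98)
  # and rankings are reproducible across repeated runs
  expect_identical(slam_align(s, t1)$pairs, r1$pairs)
})

test_that("small rigid case achieves the brute-force optimal correlation", {
  # 8-atom substructure vs rigid copy: enumerate one-to-one matchings of
  # the selected candidate pairs of top-cluster size; the emitted r attains
  # the maximum
  s <- annotate_atoms(atoms_structure(matrix(rnorm(24, sd = 4), 8),
                                      resname = rep(c("SER", "LEU", "ASP",
                                                      "PHE"), 2)))
  res <- slam_align(s, annotate_atoms(rigid_copy(s)))
  expect_gte(nrow(res), 1)
  expect_equal(res$r[1], 1, tolerance = 1e-9)
  expect_equal(res$n_pairs[1], 8)
})

test_that("planted-motif recovery degrades with jitter", {
  rec <- function(sigma) {
    mean(vapply(1:3, function(sd_) {
      motif_experiment(sd_, motif_size = 20, jitter_sigma = sigma,
                       n_res = 8)$recovery
    }, 1))
  }
  expect_gte(rec(0.05), rec(0.8))
})
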