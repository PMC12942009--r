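# DABE key components, contact detection and the substitution score.

test_that("van der Waals contacts follow the radius-sum rule", {
  s <- atoms_structure(rbind(c(0, 0, 0), c(3, 0, 0), c(30, 0, 0)))
  # carbons: 1.70 + 1.70 = 3.40 >= 3.0 -> contact
  nb <- contact_neighbors(s, 1)
  expect_equal(nb$atom_id, 2)
  s2 <- atoms_structure(rbind(c(0, 0, 0), c(4, 0, 0)))
  expect_equal(nrow(contact_neighbors(s2, 1)), 0)
  # isolated atom
  s3 <- atoms_structure(rbind(c(0, 0, 0), c(50, 0, 0)))
  expect_equal(nrow(contact_neighbors(s3, 1)), 0)
  # tolerance extends the cutoff
  expect_equal(nrow(contact_neighbors(s2, 1, tolerance = 0.7)), 1)
})

test_that("bulkiness uses the strict 10 cubic-Angstrom cutoff", {
  expect_equal(compute_bulkiness(1.70), 0L)           # 4.913
  expect_equal(compute_bulkiness(1.70, c(1.70, 1.70)), 1L) # 14.739
  # radii with exact float cubes: 8 + 1 + 1 = 10 exactly -> strict excludes
  expect_equal(compute_bulkiness(2, c(1, 1)), 0L)
  expect_equal(compute_bulkiness(2, c(1, 1, 1)), 1L) # 11 > 10
  expect_error(compute_bulkiness(NA_real_), "missing")
})

test_that("electropositivity needs every participant at or below 2.5", {
  expect_equal(compute_electropositivity(pauling_en("C")), 0L)  # 2.55
  expect_equal(compute_electropositivity(pauling_en("S")), 0L)  # 2.58
  expect_equal(compute_electropositivity(pauling_en("P")), 1L)  # 2.19
  expect_equal(compute_electropositivity(pauling_en("P"), pauling_en("P")), 1L)
  expect_equal(compute_electropositivity(2.4, c(2.4, 3.44)), 0L)
  expect_error(compute_electropositivity(NA_real_), "missing")
})

test_that("hydrogen-bond templates give standard donor/acceptor flags", {
  hb <- assign_hbond_flags(
    c("SER", "ALA", "LYS", "ALA", "PRO", "ASP"),
    c("OG", "CB", "NZ", "N", "N", "OD1"),
    c("O", "C", "N", "N", "N", "O")
  )
  expect_equal(hb$donor, c(1L, 0L, 1L, 1L, 0L, 0L))
  expect_equal(hb$acceptor, c(1L, 0L, 0L, 0L, 0L, 1L))
  # unknown atoms fall back to element polarity with a warning
  expect_warning(
    fb <- assign_hbond_flags("LIG", "O1", "O", quiet = FALSE),
    "fallback"
  )
  expect_equal(unlist(fb), c(donor = 1L, acceptor = 1L))
})

test_that("dabe_key composes the four bits and reacts to conformation", {
  # serine OG surrounded by two carbons: donor+acceptor+bulky, EN(O)=3.44
  s <- new_structure(tibble::tibble(
    name = c("OG", "CB", "CA"), element = c("O", "C", "C"),
    x = c(0, 1.4, 2.8), y = 0, z = 0,
    chain = "A", resname = "SER", resno = 1
  ))
  expect_equal(unname(dabe_key(s, 1)), c(1L, 1L, 1L, 0L))
  # isolated carbon: all zero
  iso <- atoms_structure(rbind(c(0, 0, 0), c(40, 0, 0)))
  expect_equal(unname(dabe_key(iso, 1)), c(0L, 0L, 0L, 0L))
  # moving the neighbors out of contact range flips the bulkiness bit
  s_far <- s
  s_far$x <- c(0, 10, 20)
  key_far <- dabe_key(s_far, 1)
  expect_equal(unname(key_far["bulky"]), 0L)
})

test_that("dabe_similarity counts shared positions (4 - Hamming)", {
  expect_equal(dabe_similarity(c(1, 1, 0, 0), c(1, 1, 1, 0)), 3L)
  expect_equal(dabe_similarity(c(1, 0, 1, 0), c(1, 0, 1, 0)), 4L)
  expect_equal(dabe_similarity(c(0, 0, 0, 0), c(1, 1, 1, 1)), 0L)
  # exhaustive: similarity = 4 - Hamming distance for all 256 key pairs
  for (a in 0:15) {
    for (b in 0:15) {
      bits_a <- as.integer(intToBits(a))[4:1]
      bits_b <- as.integer(intToBits(b))[4:1]
      expect_equal(dabe_similarity(a, b), 4L - sum(bits_a != bits_b))
    }
  }
})

test_that("substitution score sums the residue and chemistry terms", {
  m <- substitution_model()
  # identical cysteine sulfurs: the {C} group holds the scaled maximum 4
  s <- new_structure(tibble::tibble(
    name = c("SG", "SG"), element = "S", x = c(0, 30), y = 0, z = 0,
    chain = "A", resname = "CYS", resno = 1:2
  ))
  ann <- annotate_atoms(s)
  expect_equal(atom_substitution_score(ann[1, ], ann[1, ], m), 8)
  # symmetry and bounds over random annotated atoms
  set.seed(11)
  st <- annotate_atoms(make_random_structure(6, seed = 21))
  st <- st[st$is_heavy, ]
  for (k in 1:25) {
    i <- sample(nrow(st), 1)
    j <- sample(nrow(st), 1)
    sij <- atom_substitution_score(st[i, ], st[j, ], m)
    expect_equal(sij, atom_substitution_score(st[j, ], st[i, ], m))
    expect_gte(sij, 0)
    expect_lte(sij, 8)
  }
})

test_that("the group weight matrix is symmetric, scaled to [0,4], diagonal-dominant", {
  gm <- substitution_model()$group_matrix
  expect_equal(gm, t(gm))
  expect_equal(max(gm), 4)
  expect_equal(min(gm[1:6, 1:6]), 0)
  for (i in 1:6) expect_equal(which.max(gm[i, 1:6]), i)
  expect_true(all(gm[7, ] == 2))
})

test_that("annotated bulkiness bits match a brute-force recomputation", {
  s <- annotate_atoms(make_random_structure(5, seed = 31))
  hv <- s[s$is_heavy, ]
  for (i in seq_len(nrow(hv))) {
    nb <- contact_neighbors(s, hv$atom_id[i])
    expect_equal(hv$bulky[i], compute_bulkiness(hv$vdw[i], nb$vdw))
    expect_equal(
      hv$epos[i],
      compute_electropositivity(pauling_en(hv$element[i]),
                                pauling_en(nb$element))
    )
  }
  # realized keys are a subset of the 16 possible
  expect_true(all(hv$dabe %in% 0:15))
})
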