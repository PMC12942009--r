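# Independent oracles and small fixture builders shared across the suite.

# Brute-force optimum of the affine-gap global alignment over a position
# score matrix S: enumerate every monotone matching; each maximal run of g
# unmatched positions (in either sequence, counted separately) costs
# open + (g - 1) * ext. Exact for small k; independent of the DP code.
bf_align_score <- function(S, open, ext) {
  k1 <- nrow(S)
  k2 <- ncol(S)
  gp <- function(g) if (g == 0) 0 else open + (g - 1) * ext
  best <- gp(k1) + gp(k2) # the no-match alignment
  for (m in seq_len(min(k1, k2))) {
    rows_sets <- utils::combn(k1, m, simplify = FALSE)
    cols_sets <- utils::combn(k2, m, simplify = FALSE)
    for (rs in rows_sets) {
      for (cs in cols_sets) {
        sc <- sum(S[cbind(rs, cs)])
        ga <- c(diff(c(0, rs)) - 1, k1 - rs[m])
        gb <- c(diff(c(0, cs)) - 1, k2 - cs[m])
        sc <- sc + sum(vapply(ga, gp, 1)) + sum(vapply(gb, gp, 1))
        if (sc > best) best <- sc
      }
    }
  }
  best
}

# 5-degree rotation grid search oracle: smallest RMSD achievable mapping
# `from` onto `to` with any grid rotation plus the optimal translation.
grid_best_rmsd <- function(from, to, step_deg = 5) {
  Fc <- scale(from, scale = FALSE)
  Tc <- scale(to, scale = FALSE)
  M <- crossprod(Fc, Tc) # maximize tr(R M)
  const <- sum(Fc^2) + sum(Tc^2)
  n <- nrow(from)
  rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0,
                                0, 0, 1), 3)
  rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0,
                                sin(a), 0, cos(a)), 3)
  ang <- seq(0, 355, by = step_deg) * pi / 180
  angb <- seq(0, 175, by = step_deg) * pi / 180
  best <- Inf
  for (a in ang) {
    Ra <- rot_z(a)
    for (b in angb) {
      Rab <- Ra %*% rot_y(b)
      for (g in ang) {
        R <- Rab %*% rot_z(g)
        rm2 <- (const - 2 * sum(R * t(M))) / n
        if (rm2 < best) best <- rm2
      }
    }
  }
  sqrt(max(best, 0))
}

# analytic exposed area of each of two overlapping spheres (expanded radii
# r1, r2 at center distance d): full sphere minus the buried spherical cap
two_sphere_areas <- function(r1, r2, d) {
  if (d >= r1 + r2) {
    return(c(4 * pi * r1^2, 4 * pi * r2^2))
  }
  x1 <- (d^2 + r1^2 - r2^2) / (2 * d)
  h1 <- r1 - x1
  h2 <- r2 - (d - x1)
  c(4 * pi * r1^2 - 2 * pi * r1 * h1, 4 * pi * r2^2 - 2 * pi * r2 * h2)
}

# bare-atoms structure from coordinates, one single-atom residue each
atoms_structure <- function(xyz, element = "C", resname = "ALA",
                            name = NULL, record = "ATOM", chain = "A") {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  new_structure(tibble::tibble(
    record = record,
    name = if (is.null(name)) rep(element, n) else name,
    element = element,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    chain = chain, resname = resname, resno = seq_len(n)
  ))
}

# fixed-format PDB line for hand-written parse fixtures
pdb_line <- function(record, serial, name, resname, chain, resno, x, y, z,
                     occ = 1, b = 0, element = substr(name, 1, 1),
                     altloc = " ", insert = " ") {
  sprintf("%-6s%5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, altloc, resname, chain, resno, insert,
          x, y, z, occ, b, element)
}

# rigid transform helpers
rot_about_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0, 0, 0, 1), 3)
}

rigid_copy <- function(s, theta = 0.7, shift = c(5, -3, 2)) {
  R <- rot_about_z(theta)
  xyz <- as.matrix(s[, c("x", "y", "z")]) %*% t(R)
  s$x <- xyz[, 1] + shift[1]
  s$y <- xyz[, 2] + shift[2]
  s$z <- xyz[, 3] + shift[3]
  s
}

# planted-motif recovery experiment used by core and acceptance tests
motif_experiment <- function(seed, motif_size = 25, jitter_sigma = 0.3,
                             n_res = 10, decoy = FALSE,
                             config = slam_config()) {
  a <- make_random_structure(n_res, seed = 100 + seed)
  b <- make_random_structure(n_res, seed = 200 + seed)
  pl <- plant_shared_motif(a, b, motif_size = motif_size,
                           jitter_sigma = jitter_sigma, seed = seed)
  tgt <- if (decoy) {
    shuffle_chemistry(pl$structure_b, pl$pairs$atom_id_b, seed = seed)
  } else {
    pl$structure_b
  }
  ha <- heavy_atoms(pl$structure_a)
  sub_a <- as_substructure(
    ha[ha$atom_id %in% pl$pairs$atom_id_a, ],
    role = "surface_patch", anchor = pl$pairs$atom_id_a[1], source = "A"
  )
  res <- slam_align(sub_a, tgt, config)
  key <- paste(pl$pairs$atom_id_a, pl$pairs$atom_id_b)
  recovery <- if (nrow(res)) {
    top <- res$pairs[[1]]
    sum(key %in% paste(top$atom_id_a, top$atom_id_b)) / length(key)
  } else 0
  list(
    result = res, pairs = pl$pairs, recovery = recovery,
    top_ncorr5 = if (nrow(res)) res$ncorr5[1] else NA_real_
  )
}
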