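# Deterministic synthetic structure generators. These provide ground-truth
# fixtures for every other module: random protein-like chains, pairs of
# structures sharing a planted (jittered, rigidly moved) atom motif, and toy
# protein-ligand complexes with a known pocket-residue count. Geometry is
# idealized (fixed local bond lengths, no torsional realism): the engine
# only consumes interatomic distances and chemistry.

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed))
  force(code)
}

# side-chain atom names (beyond CB) per residue type; elements derived from
# the first letter of the atom name
.sidechain_atoms <- list(
  ALA = character(), GLY = character(), SER = "OG", CYS = "SG",
  THR = c("OG1", "CG2"), VAL = c("CG1", "CG2"), PRO = c("CG", "CD"),
  LEU = c("CG", "CD1", "CD2"), ILE = c("CG1", "CG2", "CD1"),
  ASP = c("CG", "OD1", "OD2"), ASN = c("CG", "OD1", "ND2"),
  GLU = c("CG", "CD", "OE1", "OE2"), GLN = c("CG", "CD", "OE1", "NE2"),
  MET = c("CG", "SD", "CE"), LYS = c("CG", "CD", "CE", "NZ"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  ARG = c("CG", "CD", "NE", "CZ", "NH1", "NH2"),
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2")
)

# residue template in a local frame: CA at the origin, backbone fixed,
# side-chain atoms on a gentle spiral from CB (deterministic per type)
.residue_template <- function(resname) {
  bb <- rbind(
    N = c(-1.458, 0.0, 0.0),
    CA = c(0.0, 0.0, 0.0),
    C = c(0.55, 1.42, 0.0),
    O = c(0.03, 2.51, 0.20)
  )
  side <- .sidechain_atoms[[resname]]
  names_all <- rownames(bb)
  xyz <- bb
  if (resname != "GLY") {
    cb <- c(0.55, -0.78, -1.21)
    xyz <- rbind(xyz, CB = cb)
    names_all <- c(names_all, "CB")
    if (length(side)) {
      # compact helical spiral out of CB: 0.75 A axial rise, 1.1 A radius
      u <- c(0.45, -0.55, -0.70)
      u <- u / sqrt(sum(u^2))
      v <- c(0.80, 0.55, 0.10)
      v <- v - sum(v * u) * u
      v <- v / sqrt(sum(v^2))
      w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
      for (i in seq_along(side)) {
        pos <- cb + 0.75 * i * u + 1.1 * (cos(2 * i) * v + sin(2 * i) * w)
        xyz <- rbind(xyz, pos)
        names_all <- c(names_all, side[i])
      }
    }
  }
  tibble::tibble(
    name = names_all,
    element = substr(names_all, 1, 1),
    dx = xyz[, 1], dy = xyz[, 2], dz = xyz[, 3]
  )
}

.random_rotation <- function() {
  # uniform random rotation from a normalized quaternion
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(
    a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
    2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
    2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2
  ), 3, 3, byrow = TRUE)
}

.default_palette <- c(
  "SER", "LEU", "ASP", "LYS", "PHE", "THR", "ASN", "VAL", "GLU",
  "HIS", "MET", "ILE", "ARG", "TYR", "GLN", "TRP", "ALA", "CYS"
)

#' Generate a random protein-like structure
#'
#' A self-avoiding persistent random walk of alpha-carbons (3.8 Angstrom
#' steps) carrying full heavy-atom residue templates (about 8 atoms per
#' residue) in random orientations. All atom pairs are kept at least 1.2
#' Angstrom apart (placement uses a stricter internal margin). Deterministic
#' under `seed`.
#'
#' @param n_residues chain length (>= 1).
#' @param seed RNG seed.
#' @param chain chain identifier.
#' @param structure_id label.
#' @param palette residue types sampled for the chain.
#' @return a `slam_structure`.
#' @export
make_random_structure <- function(n_residues, seed = 1, chain = "A",
                                  structure_id = paste0("synth", seed),
                                  palette = .default_palette) {
  stopifnot(n_residues >= 1)
  .with_seed(seed, {
    types <- sample(palette, n_residues, replace = TRUE)
    placed <- NULL
    ca <- c(0, 0, 0)
    dir <- c(1, 0, 0)
    rows <- vector("list", n_residues)
    for (i in seq_len(n_residues)) {
      tmpl <- .residue_template(types[i])
      ok <- FALSE
      for (attempt in 1:80) {
        if (i > 1) {
          step <- dir + 0.7 * stats::rnorm(3)
          step <- step / sqrt(sum(step^2))
          cand_ca <- ca + 3.8 * step
        } else {
          cand_ca <- ca
          step <- dir
        }
        R <- .random_rotation()
        xyz <- as.matrix(tmpl[, c("dx", "dy", "dz")]) %*% t(R)
        xyz <- sweep(xyz, 2, cand_ca, "+")
        if (is.null(placed)) {
          ok <- TRUE
        } else {
          dmin <- min(.min_cross_dist(xyz, placed))
          ok <- dmin >= 2.0
        }
        if (ok) {
          ca <- cand_ca
          dir <- step
          break
        }
      }
      if (!ok) stop("structure generation failed: no clash-free placement ",
                    "for residue ", i, " after bounded retries")
      placed <- rbind(placed, xyz)
      rows[[i]] <- tibble::tibble(
        name = tmpl$name, element = tmpl$element,
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
        chain = chain, resname = types[i], resno = i
      )
    }
    new_structure(dplyr::bind_rows(rows), structure_id = structure_id)
  })
}

.min_cross_dist <- function(a, b) {
  out <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    out[i] <- sqrt(min((b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2 +
                         (b[, 3] - a[i, 3])^2))
  }
  out
}

#' Plant a shared atom motif into a second structure
#'
#' Copies a spatially contiguous `motif_size`-atom piece of `host_a` (a seed
#' heavy atom and its nearest heavy atoms), applies a random rigid transform
#' plus per-coordinate Gaussian jitter of standard deviation `jitter_sigma`,
#' and appends it to `host_b` as additional residues (chemistry preserved).
#' The returned ground-truth pairing maps each motif atom in A to its copy
#' in the augmented B.
#'
#' @param host_a,host_b `slam_structure` objects.
#' @param motif_size number of atoms to copy (<= heavy atoms of `host_a`).
#' @param jitter_sigma per-coordinate Gaussian noise, Angstrom.
#' @param seed RNG seed.
#' @return list with `structure_a` (= `host_a`), `structure_b` (augmented),
#'   `pairs` (tibble `atom_id_a`, `atom_id_b` of the planted mapping).
#' @export
plant_shared_motif <- function(host_a, host_b, motif_size = 25,
                               jitter_sigma = 0.3, seed = 1) {
  ha <- heavy_atoms(host_a)
  if (motif_size > nrow(ha)) stop("motif_size exceeds heavy atoms of host_a")
  .with_seed(seed, {
    ctr <- colMeans(as.matrix(ha[, c("x", "y", "z")]))
    d <- sqrt((ha$x - ctr[1])^2 + (ha$y - ctr[2])^2 + (ha$z - ctr[3])^2)
    seed_atom <- which.min(d)
    dd <- sqrt((ha$x - ha$x[seed_atom])^2 + (ha$y - ha$y[seed_atom])^2 +
                 (ha$z - ha$z[seed_atom])^2)
    motif_idx <- order(dd, ha$atom_id)[seq_len(motif_size)]
    motif <- ha[motif_idx, ]

    bt <- tibble::as_tibble(host_b)
    b_xyz <- as.matrix(bt[, c("x", "y", "z")])
    b_ctr <- colMeans(b_xyz)
    b_rad <- max(sqrt(rowSums(sweep(b_xyz, 2, b_ctr)^2)))
    m_xyz0 <- as.matrix(motif[, c("x", "y", "z")])
    m_ctr <- colMeans(m_xyz0)
    m_rad <- max(sqrt(rowSums(sweep(m_xyz0, 2, m_ctr)^2)))

    placed <- NULL
    for (attempt in 1:100) {
      R <- .random_rotation()
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      gap <- stats::runif(1, 1.5, 4)
      dest <- b_ctr + (b_rad + m_rad + gap) * u
      xyz <- sweep(sweep(m_xyz0, 2, m_ctr) %*% t(R), 2, dest, "+")
      xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, jitter_sigma),
                          ncol = 3)
      if (min(.min_cross_dist(xyz, b_xyz)) >= 2.5) {
        placed <- xyz
        break
      }
    }
    if (is.null(placed)) {
      stop("motif placement failed: persistent clash with host_b")
    }

    new_rows <- motif
    new_rows$x <- placed[, 1]
    new_rows$y <- placed[, 2]
    new_rows$z <- placed[, 3]
    # renumber the copied residues after the host chain
    res_key <- paste(motif$chain, motif$resno, motif$insert)
    new_rows$resno <- max(bt$resno) + as.integer(factor(res_key,
                                                        levels = unique(res_key)))
    new_rows$chain <- bt$chain[1]
    aug <- dplyr::bind_rows(
      bt[, setdiff(names(bt), c("atom_id", "is_heavy", "is_ligand",
                                "ligand_id", "vdw"))],
      new_rows[, setdiff(names(new_rows), c("atom_id", "is_heavy",
                                            "is_ligand", "ligand_id", "vdw"))]
    )
    structure_b <- new_structure(aug,
      structure_id = paste0(attr(host_b, "structure_id"), "+motif"))
    pairs <- tibble::tibble(
      atom_id_a = motif$atom_id,
      atom_id_b = nrow(bt) + seq_len(motif_size)
    )
    list(structure_a = host_a, structure_b = structure_b, pairs = pairs)
  })
}

#' Shuffle the chemistry of selected atoms (decoy construction)
#'
#' Randomly permutes the chemical identity columns (atom name, element,
#' residue type, radius) among the given atoms while leaving coordinates
#' untouched. The resulting decoy preserves the planted geometry but
#' destroys the chemistry correspondence the aligner relies on.
#'
#' @param s a `slam_structure`.
#' @param atom_ids atoms whose chemistry is permuted among themselves.
#' @param seed RNG seed.
#' @return the modified structure.
#' @export
shuffle_chemistry <- function(s, atom_ids, seed = 1) {
  at <- tibble::as_tibble(s)
  idx <- match(atom_ids, at$atom_id)
  if (anyNA(idx)) stop("atom ids not present in structure")
  .with_seed(seed, {
    perm <- sample(idx)
    cols <- c("name", "element", "resname", "resno")
    at[idx, cols] <- at[perm, cols]
  })
  new_structure(
    at[, setdiff(names(at), c("atom_id", "is_heavy", "is_ligand",
                              "ligand_id", "vdw"))],
    structure_id = paste0(attr(s, "structure_id"), "-decoy")
  )
}

#' Generate a toy protein-ligand complex
#'
#' Places a small hetero ligand at the origin, `pocket_residues` residues
#' whose nearest atoms sit well inside the 7 Angstrom cavity shell, and a
#' ring of distant residues guaranteed outside it, so the cavity extraction
#' ground truth is known by construction.
#'
#' @param pocket_residues residues inside the shell.
#' @param ligand_atoms heavy-atom count of the ligand (>= 3).
#' @param distant_residues residues placed outside the shell.
#' @param seed RNG seed.
#' @return a `slam_structure` with one ligand (`ligand_id` "LIG").
#' @export
make_toy_complex <- function(pocket_residues = 5, ligand_atoms = 5,
                             distant_residues = 3, seed = 1) {
  stopifnot(ligand_atoms >= 3, pocket_residues >= 1)
  .with_seed(seed, {
    # compact ligand cluster around the origin
    lig_el <- rep(c("C", "O", "N"), length.out = ligand_atoms)
    lig_xyz <- matrix(0, ligand_atoms, 3)
    for (i in 2:ligand_atoms) {
      repeat {
        cand <- lig_xyz[i - 1, ] + 1.45 * {
          v <- stats::rnorm(3)
          v / sqrt(sum(v^2))
        }
        if (sqrt(sum(cand^2)) <= 2.5 &&
            min(.min_cross_dist(matrix(cand, 1), lig_xyz[seq_len(i - 1), ,
                                                         drop = FALSE])) >= 1.3) {
          lig_xyz[i, ] <- cand
          break
        }
      }
    }
    lig <- tibble::tibble(
      record = "HETATM",
      name = paste0(lig_el, seq_len(ligand_atoms)),
      element = lig_el,
      x = lig_xyz[, 1], y = lig_xyz[, 2], z = lig_xyz[, 3],
      chain = "A", resname = "LIG", resno = 900L
    )

    place_residue <- function(type, resno, dist_lo, dist_hi, placed) {
      tmpl <- .residue_template(type)
      for (attempt in 1:100) {
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        ca <- u * stats::runif(1, dist_lo, dist_hi)
        xyz <- as.matrix(tmpl[, c("dx", "dy", "dz")]) %*% t(.random_rotation())
        xyz <- sweep(xyz, 2, ca, "+")
        if (min(.min_cross_dist(xyz, placed)) >= 2.2) {
          return(tibble::tibble(
            record = "ATOM", name = tmpl$name, element = tmpl$element,
            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
            chain = "A", resname = type, resno = resno
          ))
        }
      }
      stop("toy complex generation failed: residue placement clash")
    }

    placed <- lig_xyz
    rows <- list(lig)
    types <- rep(c("SER", "LEU", "ASP", "PHE", "THR", "ASN", "VAL"),
                 length.out = pocket_residues + distant_residues)
    for (i in seq_len(pocket_residues)) {
      rr <- place_residue(types[i], i, 4.5, 6.0, placed)
      placed <- rbind(placed, as.matrix(rr[, c("x", "y", "z")]))
      rows[[length(rows) + 1]] <- rr
    }
    for (i in seq_len(distant_residues)) {
      rr <- place_residue(types[pocket_residues + i], pocket_residues + i,
                          18, 22, placed)
      placed <- rbind(placed, as.matrix(rr[, c("x", "y", "z")]))
      rows[[length(rows) + 1]] <- rr
    }
    new_structure(dplyr::bind_rows(rows),
                  structure_id = paste0("complex", seed))
  })
}
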