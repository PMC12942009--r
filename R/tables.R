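# Bundled physicochemical reference tables: van der Waals radii, Pauling
# electronegativities, hydrogen-bond donor/acceptor templates, and the
# reduced seven-group amino-acid alphabet. All values are explicit and
# auditable; radii follow Bondi-style conventions.

# Van der Waals radii (Angstrom), heavy elements encountered in PDB files.
.vdw_radii <- c(
  C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
  B = 1.92, H = 1.20, D = 1.20
)
# common ions / metals seen as HETATM
.vdw_metal <- c(
  MG = 1.73, ZN = 1.39, FE = 2.05, MN = 2.05, CU = 1.40, K = 2.75,
  CA = 2.31, NI = 1.63, CO = 2.00, MO = 2.10, W = 2.10, LI = 1.82
)
.vdw_metal <- c(.vdw_metal, c("NA" = 2.27))

# Pauling electronegativities.
.pauling_en <- c(
  H = 2.20, D = 2.20, C = 2.55, N = 3.04, O = 3.44, S = 2.58, P = 2.19,
  F = 3.98, CL = 3.16, BR = 2.96, I = 2.66, SE = 2.55, B = 2.04,
  MG = 1.31, ZN = 1.65, FE = 1.83, MN = 1.55, CU = 1.90, K = 0.82,
  CA = 1.00, NI = 1.91, CO = 1.88, MO = 2.16, W = 2.36, LI = 0.98
)
.pauling_en <- c(.pauling_en, c("NA" = 0.93))

#' Van der Waals radius lookup
#'
#' Returns the bundled van der Waals radius for each element symbol. Unknown
#' elements raise an error rather than defaulting silently, because the
#' bulkiness descriptor and contact definition both depend on the radius.
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element) {
  el <- toupper(trimws(element))
  tab <- c(.vdw_radii, .vdw_metal)
  r <- unname(tab[el])
  if (anyNA(r)) {
    bad <- unique(el[is.na(r)])
    stop("no van der Waals radius for element(s): ", paste(bad, collapse = ", "))
  }
  r
}

#' Pauling electronegativity lookup
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of Pauling electronegativities.
#' @export
pauling_en <- function(element) {
  el <- toupper(trimws(element))
  x <- unname(.pauling_en[el])
  if (anyNA(x)) {
    bad <- unique(el[is.na(x)])
    stop("no Pauling electronegativity for element(s): ", paste(bad, collapse = ", "))
  }
  x
}

# Standard amino acids (3-letter), plus the modified-residue whitelist that is
# treated as protein rather than ligand by default.
.standard_aa <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

.default_residue_whitelist <- c("MSE", "SEC", "PYL", "SEP", "TPO", "PTR", "CSO", "HYP")

.water_names <- c("HOH", "WAT", "DOD", "H2O")

#' Standard residue and water name sets
#' @return character vector of residue names.
#' @rdname residue_sets
#' @export
standard_residues <- function() .standard_aa

#' @rdname residue_sets
#' @export
default_residue_whitelist <- function() .default_residue_whitelist

# Hydrogen-bond donor/acceptor template per residue side-chain atom.
# Backbone handled generically: N donor (not for PRO), O/OXT acceptor.
# Encoded as "RES ATOM" -> c(donor, acceptor).
.hbond_sidechain <- list(
  "SER OG"  = c(1L, 1L), "THR OG1" = c(1L, 1L), "TYR OH"  = c(1L, 1L),
  "CYS SG"  = c(1L, 0L),
  "ASN OD1" = c(0L, 1L), "ASN ND2" = c(1L, 0L),
  "GLN OE1" = c(0L, 1L), "GLN NE2" = c(1L, 0L),
  "ASP OD1" = c(0L, 1L), "ASP OD2" = c(0L, 1L),
  "GLU OE1" = c(0L, 1L), "GLU OE2" = c(0L, 1L),
  "LYS NZ"  = c(1L, 0L),
  "ARG NE"  = c(1L, 0L), "ARG NH1" = c(1L, 0L), "ARG NH2" = c(1L, 0L),
  "HIS ND1" = c(1L, 1L), "HIS NE2" = c(1L, 1L),
  "TRP NE1" = c(1L, 0L),
  "MET SD"  = c(0L, 1L),
  # selenomethionine treated like methionine
  "MSE SE"  = c(0L, 1L)
)

#' Hydrogen-bond donor/acceptor flags for an atom
#'
#' Looks up a bundled per-residue template reproducing conventional
#' pharmacophore annotations for the 20 standard residues plus backbone
#' atoms. Atoms not covered by the template (ligand atoms, unusual names)
#' fall back to an element-based heuristic (N and O polar, S weak acceptor)
#' with a warning.
#'
#' @param residue_name 3-letter residue code (vectorised).
#' @param atom_name PDB atom name (vectorised).
#' @param element element symbol (vectorised), used by the fallback.
#' @param quiet suppress the fallback warning.
#' @return a tibble with columns `donor` and `acceptor` (integer 0/1).
#' @export
assign_hbond_flags <- function(residue_name, atom_name, element, quiet = FALSE) {
  n <- max(length(residue_name), length(atom_name), length(element))
  residue_name <- rep_len(toupper(trimws(residue_name)), n)
  atom_name <- rep_len(toupper(trimws(atom_name)), n)
  element <- rep_len(toupper(trimws(element)), n)

  donor <- integer(n)
  acceptor <- integer(n)
  is_protein <- residue_name %in% c(.standard_aa, .default_residue_whitelist)

  # backbone
  bbN <- is_protein & atom_name == "N"
  donor[bbN & residue_name != "PRO"] <- 1L
  bbO <- is_protein & atom_name %in% c("O", "OXT")
  acceptor[bbO] <- 1L

  key <- paste(residue_name, atom_name)
  hit <- match(key, names(.hbond_sidechain))
  idx <- which(!is.na(hit))
  if (length(idx)) {
    flags <- vapply(.hbond_sidechain[hit[idx]], identity, integer(2))
    donor[idx] <- flags[1L, ]
    acceptor[idx] <- flags[2L, ]
  }

  # element fallback for atoms outside the template that are not plain
  # protein carbons/covered backbone atoms
  covered <- is_protein | !is.na(hit)
  fb <- which(!covered)
  if (length(fb)) {
    if (!quiet) {
      rlang::warn(
        paste0(
          "hydrogen-bond template misses ", length(fb),
          " atom(s); using element-based fallback"
        ),
        .frequency = "once", .frequency_id = "slamr_hbond_fallback"
      )
    }
    donor[fb][element[fb] %in% c("N", "O")] <- 1L
    acceptor[fb][element[fb] %in% c("N", "O", "S")] <- 1L
  }
  tibble::tibble(donor = donor, acceptor = acceptor)
}

# Reduced seven-group amino-acid alphabet. Group 7 is the neutral class for
# non-amino-acid atoms (ligands, nucleic acids) and unknown residues.
.aa_groups <- list(
  `1` = c("ALA", "GLY", "PRO", "SER", "THR"),
  `2` = c("CYS"),
  `3` = c("ASP", "GLU", "ASN", "GLN"),
  `4` = c("PHE", "TRP", "TYR"),
  `5` = c("HIS", "LYS", "ARG"),
  `6` = c("ILE", "LEU", "MET", "VAL")
)

#' Amino-acid group of a residue under the reduced 7-letter alphabet
#'
#' Groups: 1 = \{A,G,P,S,T\}, 2 = \{C\}, 3 = \{D,E,N,Q\}, 4 = \{F,W,Y\},
#' 5 = \{H,K,R\}, 6 = \{I,L,M,V\}, 7 = everything else (neutral class for
#' hetero atoms). Selenomethionine maps with methionine; other whitelisted
#' modified residues map with their parent residue.
#'
#' @param residue_name character vector of 3-letter codes.
#' @return integer vector of groups 1-7.
#' @export
aa_group <- function(residue_name) {
  res <- toupper(trimws(residue_name))
  # modified residues fold onto their parents before grouping
  parent <- c(
    MSE = "MET", SEC = "CYS", PYL = "LYS", SEP = "SER", TPO = "THR",
    PTR = "TYR", CSO = "CYS", HYP = "PRO"
  )
  m <- match(res, names(parent))
  res[!is.na(m)] <- parent[m[!is.na(m)]]
  g <- rep.int(7L, length(res))
  for (k in seq_along(.aa_groups)) {
    g[res %in% .aa_groups[[k]]] <- as.integer(names(.aa_groups)[k])
  }
  g
}

# single-letter representatives used to average PAM250 within groups
.aa_three_to_one <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

#' Substitution model for atom-sequence alignment
#'
#' Builds the scoring model used by the linear neighborhood alignment. The
#' residue term is a 7x7 group weight matrix derived by averaging PAM250
#' entries over all residue pairs within each group pair, then affinely
#' rescaled so the minimum weight is 0 and the maximum is 4 -- the same range
#' as the DABE chemical-similarity score, so the two terms contribute
#' comparably. The neutral group 7 scores the matrix midpoint (2) against
#' every group. The total atom-to-atom score is
#' `group_weight + chem_weight * dabe_similarity`.
#'
#' @param gap_open gap opening penalty (applied to the first gapped position;
#'   negative). Default -4, the magnitude of the best possible match term.
#' @param gap_extend gap extension penalty per additional gapped position.
#' @param chem_weight multiplier on the DABE similarity term.
#' @return an object of class `slam_submodel`: list with `group_matrix`
#'   (7x7), `gap_open`, `gap_extend`, `chem_weight`.
#' @export
substitution_model <- function(gap_open = -4, gap_extend = -1, chem_weight = 1) {
  stopifnot(gap_open <= 0, gap_extend <= 0, chem_weight >= 0)
  pam <- get_pam250()
  m6 <- matrix(0, 6, 6)
  for (i in 1:6) {
    for (j in i:6) {
      gi <- .aa_three_to_one[.aa_groups[[as.character(i)]]]
      gj <- .aa_three_to_one[.aa_groups[[as.character(j)]]]
      m6[i, j] <- m6[j, i] <- mean(pam[gi, gj, drop = FALSE])
    }
  }
  lo <- min(m6)
  hi <- max(m6)
  m6 <- 4 * (m6 - lo) / (hi - lo)
  gm <- matrix(2, 7, 7) # neutral midpoint for group 7
  gm[1:6, 1:6] <- m6
  structure(
    list(
      group_matrix = gm,
      gap_open = gap_open,
      gap_extend = gap_extend,
      chem_weight = chem_weight
    ),
    class = "slam_submodel"
  )
}

get_pam250 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("PAM250", package = "Biostrings", envir = e)
      cache <<- e$PAM250
    }
    cache
  }
})

#' @export
print.slam_submodel <- function(x, ...) {
  cat("<slam_submodel> 7-group substitution model\n")
  cat("  gap_open:", x$gap_open, " gap_extend:", x$gap_extend,
      " chem_weight:", x$chem_weight, "\n")
  cat("  group weights scaled to [0, 4]; neutral group midpoint 2\n")
  invisible(x)
}
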