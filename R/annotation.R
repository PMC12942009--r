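# Atom annotation: van der Waals contact detection, the four-bit DABE key
# (hydrogen-bond Donor, Acceptor, Bulkiness, Electropositivity), the reduced
# amino-acid group, and the atom-to-atom substitution score that drives the
# linear alignments.

#' Van der Waals contact neighbors of an atom
#'
#' Heavy atoms j != a with `dist(a, j) <= w_a + w_j + tolerance`, where the
#' w are van der Waals radii. This is the neighbor set that the bulkiness and
#' electropositivity bits are computed over.
#'
#' @param s structure or substructure atom tibble.
#' @param atom_id id of the (heavy) central atom.
#' @param tolerance extra margin beyond the radius sum, Angstrom.
#' @return tibble of neighboring heavy-atom rows.
#' @export
contact_neighbors <- function(s, atom_id, tolerance = 0) {
  at <- tibble::as_tibble(s)
  i <- match(atom_id, at$atom_id)
  if (is.na(i)) stop("unknown atom_id: ", atom_id)
  if (!at$is_heavy[i]) stop("contact neighbors are defined for heavy atoms")
  hv <- at[at$is_heavy & at$atom_id != atom_id, , drop = FALSE]
  if (!nrow(hv)) return(hv)
  d <- sqrt((hv$x - at$x[i])^2 + (hv$y - at$y[i])^2 + (hv$z - at$z[i])^2)
  hv[d <= at$vdw[i] + hv$vdw + tolerance, , drop = FALSE]
}

#' Bulkiness bit of an atom
#'
#' An atom is bulky when its own van der Waals volume proxy plus those of its
#' contact neighbors exceed 10 cubic Angstrom:
#' `w_i^3 + sum_j w_j^3 > 10` (strict).
#'
#' @param vdw radius of the atom, Angstrom.
#' @param neighbor_vdw radii of its contact neighbors.
#' @return integer 0/1.
#' @export
compute_bulkiness <- function(vdw, neighbor_vdw = numeric()) {
  if (anyNA(c(vdw, neighbor_vdw))) stop("missing van der Waals radius")
  as.integer(vdw^3 + sum(neighbor_vdw^3) > 10)
}

#' Electropositivity bit of an atom
#'
#' 1 when the atom's own Pauling electronegativity and those of all its
#' contact neighbors are <= 2.5; an isolated atom is classified on its own
#' electronegativity alone.
#'
#' @param en electronegativity of the atom.
#' @param neighbor_en electronegativities of its contact neighbors.
#' @return integer 0/1.
#' @export
compute_electropositivity <- function(en, neighbor_en = numeric()) {
  if (anyNA(c(en, neighbor_en))) stop("missing electronegativity")
  as.integer(en <= 2.5 && all(neighbor_en <= 2.5))
}

#' Annotate every heavy atom of a structure
#'
#' Adds the DABE key bits (`donor`, `acceptor`, `bulky`, `epos`), the packed
#' `dabe` integer (0-15, bit order D,A,B,E from the high bit), and the
#' reduced-alphabet `aa_group` (1-7) to the atom table. Bulkiness and
#' electropositivity are conformation-dependent: they are computed over van
#' der Waals contact neighbors at the structure's current coordinates and
#' must be recomputed if coordinates change.
#'
#' @param s structure or substructure tibble (heavy atoms are annotated;
#'   hydrogens get NA bits).
#' @param tolerance contact tolerance beyond the radius sum, Angstrom.
#' @param quiet suppress the hydrogen-bond template fallback warning.
#' @return the input tibble with annotation columns appended.
#' @export
annotate_atoms <- function(s, tolerance = 0, quiet = TRUE) {
  at <- tibble::as_tibble(s)
  n <- nrow(at)
  donor <- acceptor <- bulky <- epos <- rep(NA_integer_, n)
  hv <- which(at$is_heavy)
  if (length(hv)) {
    hb <- assign_hbond_flags(at$resname[hv], at$name[hv], at$element[hv],
                             quiet = quiet)
    donor[hv] <- hb$donor
    acceptor[hv] <- hb$acceptor

    xyz <- as.matrix(at[hv, c("x", "y", "z")])
    w <- at$vdw[hv]
    en <- pauling_en(at$element[hv])
    d2 <- .pairwise_sq_dist(xyz)
    cutoff <- outer(w, w, "+") + tolerance
    contact <- d2 <= cutoff^2
    diag(contact) <- FALSE
    w3 <- w^3
    bulky[hv] <- as.integer(w3 + as.numeric(contact %*% w3) > 10)
    en_ok <- en <= 2.5
    # all contact neighbors electronegative-compatible (and self)
    bad_neighbor <- as.numeric(contact %*% (!en_ok)) > 0
    epos[hv] <- as.integer(en_ok & !bad_neighbor)
  }
  at$donor <- donor
  at$acceptor <- acceptor
  at$bulky <- bulky
  at$epos <- epos
  at$dabe <- donor * 8L + acceptor * 4L + bulky * 2L + epos
  at$aa_group <- ifelse(at$is_ligand, 7L, aa_group(at$resname))
  # restore substructure/structure class and attributes of the input
  attributes(at)[c("role", "anchor", "source", "structure_id")] <-
    attributes(s)[c("role", "anchor", "source", "structure_id")]
  class(at) <- class(s)
  at
}

.pairwise_sq_dist <- function(xyz) {
  q <- rowSums(xyz^2)
  d2 <- outer(q, q, "+") - 2 * tcrossprod(xyz)
  d2[d2 < 0] <- 0
  d2
}

#' DABE key of one atom in its structure context
#'
#' Convenience single-atom wrapper over [annotate_atoms()].
#'
#' @param s structure tibble.
#' @param atom_id atom identifier.
#' @param tolerance contact tolerance, Angstrom.
#' @return integer vector `c(donor, acceptor, bulky, epos)`.
#' @export
dabe_key <- function(s, atom_id, tolerance = 0) {
  at <- annotate_atoms(s, tolerance = tolerance)
  i <- match(atom_id, at$atom_id)
  if (is.na(i)) stop("unknown atom_id: ", atom_id)
  key <- c(at$donor[i], at$acceptor[i], at$bulky[i], at$epos[i])
  names(key) <- c("donor", "acceptor", "bulky", "epos")
  key
}

.as_dabe_int <- function(k) {
  if (length(k) == 4 && all(k %in% 0:1)) {
    sum(as.integer(k) * c(8L, 4L, 2L, 1L))
  } else if (length(k) == 1 && k %in% 0:15) {
    as.integer(k)
  } else {
    stop("a DABE key is four 0/1 bits or a packed integer 0-15")
  }
}

.popcount4 <- c(0L, 1L, 1L, 2L, 1L, 2L, 2L, 3L, 1L, 2L, 2L, 3L, 2L, 3L, 3L, 4L)

#' DABE chemical similarity between two keys
#'
#' The number of shared property positions: 4 minus the Hamming distance
#' between the two four-bit strings, hence an integer in 0..4.
#'
#' @param k1,k2 DABE keys: length-4 0/1 vectors (D,A,B,E order) or packed
#'   integers 0-15.
#' @return integer 0-4.
#' @export
dabe_similarity <- function(k1, k2) {
  a <- .as_dabe_int(k1)
  b <- .as_dabe_int(k2)
  4L - .popcount4[bitwXor(a, b) + 1L]
}

#' Atom-to-atom substitution score
#'
#' `group_weight(aa_group(a), aa_group(b)) + chem_weight * dabe_similarity`,
#' the symmetric score summed along matched positions of a linear
#' neighborhood alignment.
#'
#' @param a,b single annotated atom rows (from [annotate_atoms()]).
#' @param model a [substitution_model()].
#' @return numeric score.
#' @export
atom_substitution_score <- function(a, b, model = substitution_model()) {
  stopifnot(nrow(a) == 1, nrow(b) == 1)
  model$group_matrix[a$aa_group, b$aa_group] +
    model$chem_weight * dabe_similarity(a$dabe, b$dabe)
}

# full score matrix between the annotated heavy atoms of two substructures;
# rows index atoms of `a`, columns atoms of `b`
.score_matrix <- function(a, b, model) {
  ga <- a$aa_group
  gb <- b$aa_group
  aa_term <- model$group_matrix[ga, gb, drop = FALSE]
  xor <- bitwXor(rep(a$dabe, times = nrow(b)), rep(b$dabe, each = nrow(a)))
  chem <- matrix(4L - .popcount4[xor + 1L], nrow = nrow(a))
  aa_term + model$chem_weight * chem
}
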