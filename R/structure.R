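# Structure model: tidy atom tables read from / written to PDB (and mmCIF)
# files. A structure is a tibble with one row per atom; ligands are HETATM
# groups that are neither water nor (whitelisted) amino acids.

.structure_cols <- c(
  "atom_id", "record", "name", "element", "x", "y", "z", "chain",
  "resname", "resno", "insert", "occ", "b", "is_heavy", "is_ligand",
  "ligand_id", "vdw"
)

#' Construct a structure atom table
#'
#' Normalises an atom data frame into the canonical structure tibble used
#' throughout the package: stable `atom_id` in file order, heavy-atom flags,
#' ligand partitioning and van der Waals radii attached. Mostly used
#' internally and by the synthetic generators; users normally start from
#' [read_structure()].
#'
#' @param atoms data frame with at least `name`, `element`, `x`, `y`, `z`,
#'   `chain`, `resname`, `resno`; optional `record`, `insert`, `occ`, `b`.
#' @param structure_id label carried in the `structure_id` attribute.
#' @param residue_whitelist modified residues treated as protein, not ligand.
#' @return a tibble of class `slam_structure`.
#' @export
new_structure <- function(atoms, structure_id = "synthetic",
                          residue_whitelist = default_residue_whitelist()) {
  atoms <- tibble::as_tibble(atoms)
  n <- nrow(atoms)
  if (!n) stop("empty structure: no atoms")
  if (!"record" %in% names(atoms)) atoms$record <- "ATOM"
  if (!"insert" %in% names(atoms)) atoms$insert <- ""
  if (!"occ" %in% names(atoms)) atoms$occ <- 1
  if (!"b" %in% names(atoms)) atoms$b <- 0
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$element <- toupper(trimws(atoms$element))
  atoms$resname <- toupper(trimws(atoms$resname))
  atoms$atom_id <- seq_len(n)
  atoms$is_heavy <- !(atoms$element %in% c("H", "D"))

  protein_res <- c(standard_residues(), residue_whitelist)
  is_water <- atoms$resname %in% .water_names
  atoms$is_ligand <- atoms$record == "HETATM" & !is_water &
    !(atoms$resname %in% protein_res)
  atoms$ligand_id <- ifelse(atoms$is_ligand, atoms$resname, NA_character_)

  atoms$vdw <- NA_real_
  hv <- which(atoms$is_heavy)
  if (length(hv)) atoms$vdw[hv] <- vdw_radius(atoms$element[hv])

  atoms <- atoms[, .structure_cols]
  structure(
    atoms,
    structure_id = structure_id,
    class = c("slam_structure", class(tibble::tibble()))
  )
}

#' @export
print.slam_structure <- function(x, ...) {
  cat(
    "<slam_structure> ", attr(x, "structure_id"), ": ",
    sum(x$is_heavy), " heavy atoms, ",
    length(unique(x$chain[!x$is_ligand])), " chain(s), ",
    nrow(dplyr::distinct(x[x$is_ligand, ], .data$ligand_id, .data$chain, .data$resno)),
    " ligand(s)\n",
    sep = ""
  )
  NextMethod()
}

# derive an element symbol from a PDB atom name when the element column is
# absent; two-letter symbols are only trusted for HETATM records (where "CA"
# means calcium) -- in amino acids "CA" is an alpha carbon.
.guess_element <- function(name, record, resname) {
  nm <- gsub("[0-9']", "", toupper(trimws(name)))
  two <- substr(nm, 1, 2)
  one <- substr(nm, 1, 1)
  known2 <- c("CL", "BR", "SE", "FE", "ZN", "MG", "NA", "MN", "CU", "NI", "CO", "LI")
  aa <- resname %in% c(standard_residues(), .default_residue_whitelist)
  out <- one
  het2 <- record == "HETATM" & !aa & two %in% known2
  out[het2] <- two[het2]
  # MSE selenium is an ATOM-style record in some files
  out[resname == "MSE" & nm == "SE"] <- "SE"
  out
}

.apply_altloc <- function(at, policy = c("highest_occupancy", "first")) {
  policy <- match.arg(policy)
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (all(alt == "")) return(at)
  at$..alt <- alt
  key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety)
  keep <- rep(TRUE, nrow(at))
  for (k in unique(key[alt != ""])) {
    idx <- which(key == k)
    if (length(idx) < 2) next
    if (policy == "highest_occupancy") {
      occ <- at$o[idx]
      occ[is.na(occ)] <- 0
      best <- idx[occ == max(occ)]
      # ties resolved toward altloc 'A' (lexicographically smallest)
      best <- best[order(at$..alt[best])][1]
    } else {
      best <- idx[1]
    }
    keep[setdiff(idx, best)] <- FALSE
  }
  at <- at[keep, , drop = FALSE]
  at$..alt <- NULL
  at
}

#' Read a protein structure
#'
#' Reads a PDB (or mmCIF) file into a tidy atom table. Only the first model
#' of multi-model files is used; alternate locations are collapsed to a
#' single conformer (highest occupancy, ties resolved toward altloc 'A').
#' HETATM records are partitioned into ligands (non-water, non-amino-acid)
#' and whitelisted modified residues, which stay part of the protein.
#'
#' @param path path to a `.pdb`, `.ent`, or `.cif` file.
#' @param altloc_policy `"highest_occupancy"` (default) or `"first"`.
#' @param residue_whitelist modified residues treated as protein.
#' @param structure_id label; defaults to the file base name.
#' @return a tibble of class `slam_structure`.
#' @export
read_structure <- function(path, altloc_policy = "highest_occupancy",
                           residue_whitelist = default_residue_whitelist(),
                           structure_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)
  pdb <- tryCatch(
    if (is_cif) bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE, multi = FALSE,
                         rm.alt = FALSE),
    error = function(e) stop("unparseable structure file '", path, "': ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  if (is.null(at) || !nrow(at)) stop("empty structure: no atoms in ", path)
  at <- .apply_altloc(at, altloc_policy)

  el <- at$elesy
  if (is.null(el)) el <- rep(NA_character_, nrow(at))
  el <- toupper(trimws(el))
  miss <- is.na(el) | el == ""
  if (any(miss)) {
    el[miss] <- .guess_element(at$elety[miss], at$type[miss], at$resid[miss])
  }
  chain <- at$chain
  chain[is.na(chain) | chain == ""] <- "A"

  atoms <- tibble::tibble(
    record = at$type,
    name = trimws(at$elety),
    element = el,
    x = at$x, y = at$y, z = at$z,
    chain = chain,
    resname = trimws(at$resid),
    resno = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", at$insert),
    occ = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b)
  )
  if (is.null(structure_id)) {
    structure_id <- sub("\\.(pdb|ent|cif|mmcif)$", "", basename(path),
                        ignore.case = TRUE)
  }
  new_structure(atoms, structure_id = structure_id,
                residue_whitelist = residue_whitelist)
}

#' Heavy atoms of a structure
#'
#' @param s a `slam_structure` (or any structure atom tibble).
#' @param chain optional chain identifier; default all chains.
#' @param include_ligands keep ligand heavy atoms (default TRUE).
#' @return tibble of heavy-atom rows, in file order.
#' @export
heavy_atoms <- function(s, chain = NULL, include_ligands = TRUE) {
  out <- dplyr::filter(tibble::as_tibble(s), .data$is_heavy)
  if (!include_ligands) out <- dplyr::filter(out, !.data$is_ligand)
  if (!is.null(chain)) {
    if (!chain %in% s$chain) stop("unknown chain: ", chain)
    out <- dplyr::filter(out, .data$chain == !!chain)
  }
  out
}

#' Ligands of a structure
#'
#' Heavy atoms of every HETATM group that is neither water nor a (possibly
#' whitelisted) amino acid. A ligand instance is identified by
#' (`ligand_id`, `chain`, `resno`).
#'
#' @param s a `slam_structure`.
#' @return tibble of ligand heavy atoms; zero rows when no ligands.
#' @export
ligands <- function(s) {
  dplyr::filter(tibble::as_tibble(s), .data$is_ligand, .data$is_heavy)
}

#' Write a structure to a PDB file
#'
#' Round-trips the atom table through standard ATOM/HETATM records. When
#' `sasa` per-atom areas are supplied, they are appended as a separate
#' pseudo-chain 'X' whose B-factor column carries the area, so annotated
#' files remain valid PDB.
#'
#' @param s a `slam_structure` or substructure tibble.
#' @param path output file path.
#' @param sasa optional numeric vector of per-atom areas, parallel to
#'   `nrow(s)` (NA entries skipped), written as chain 'X'.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path, sasa = NULL) {
  at <- tibble::as_tibble(s)
  if (!nrow(at)) stop("refusing to write an empty structure")
  xyz <- as.numeric(t(as.matrix(at[, c("x", "y", "z")])))
  type <- at$record
  chain <- at$chain
  resno <- at$resno
  resid <- at$resname
  elety <- at$name
  insert <- at$insert
  o <- at$occ
  b <- at$b
  elesy <- at$element
  if (!is.null(sasa)) {
    stopifnot(length(sasa) == nrow(at))
    keep <- which(!is.na(sasa))
    xyz <- c(xyz, as.numeric(t(as.matrix(at[keep, c("x", "y", "z")]))))
    type <- c(type, rep("HETATM", length(keep)))
    chain <- c(chain, rep("X", length(keep)))
    resno <- c(resno, at$resno[keep])
    resid <- c(resid, at$resname[keep])
    elety <- c(elety, at$name[keep])
    insert <- c(insert, at$insert[keep])
    o <- c(o, at$occ[keep])
    b <- c(b, round(sasa[keep], 2))
    elesy <- c(elesy, at$element[keep])
  }
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  ok <- tryCatch({
    bio3d::write.pdb(
      file = path, xyz = xyz, type = type, resno = resno, resid = resid,
      eleno = seq_along(type), elety = elety, chain = chain,
      insert = ifelse(insert == "", NA, insert), o = o, b = b, elesy = elesy
    )
    TRUE
  }, error = function(e) {
    stop("cannot write structure to '", path, "': ", conditionMessage(e))
  })
  invisible(path)
}

#' Mark an atom table as a substructure
#'
#' Substructures (ligand cavities, surface patches) are the units the
#' aligner compares. Atoms are ordered deterministically by
#' (chain, residue number, insertion code, atom name).
#'
#' @param atoms atom tibble (rows of a structure).
#' @param role `"ligand_cavity"` or `"surface_patch"`.
#' @param anchor ligand instance label (cavities) or center atom id (patches).
#' @param source structure/chain provenance string.
#' @return tibble of class `slam_substructure`.
#' @export
as_substructure <- function(atoms, role = c("ligand_cavity", "surface_patch"),
                            anchor = NA, source = "") {
  role <- match.arg(role)
  atoms <- tibble::as_tibble(atoms)
  atoms <- atoms[order(atoms$chain, atoms$resno, atoms$insert, atoms$name), ]
  structure(
    atoms,
    role = role, anchor = anchor, source = source,
    class = c("slam_substructure", class(tibble::tibble()))
  )
}

#' @export
print.slam_substructure <- function(x, ...) {
  cat("<slam_substructure> role=", attr(x, "role"),
      " source=", attr(x, "source"),
      " anchor=", paste(attr(x, "anchor"), collapse = ","),
      " (", nrow(x), " atoms)\n", sep = "")
  NextMethod()
}
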