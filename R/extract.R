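# Substructure extraction: ligand-binding cavities (7 Angstrom whole-residue
# shells around a bound ligand, >= 40 atoms) and solvent-exposed surface
# patches (7 Angstrom shells around atoms with > 2 A^2 accessible area).

.protein_atoms <- function(s) {
  at <- tibble::as_tibble(s)
  dplyr::filter(at, .data$is_heavy, !.data$is_ligand,
                !(.data$resname %in% .water_names))
}

.residue_key <- function(at) paste(at$chain, at$resno, at$insert, sep = "|")

#' Extract the ligand-binding cavity around a bound ligand
#'
#' Selects every whole protein residue having at least one heavy atom within
#' `radius` of any heavy atom of the ligand. The ligand's own atoms are not
#' part of the cavity. Cavities below `min_atoms` heavy atoms are rejected
#' (returns NULL), matching the reference-database size filter.
#'
#' @param s a `slam_structure`.
#' @param ligand ligand selector: a `ligand_id` string (first matching
#'   instance), or a tibble of ligand atom rows.
#' @param chain restrict the cavity to one chain (default: all chains).
#' @param radius shell radius, Angstrom.
#' @param min_atoms minimum heavy-atom count for a valid cavity.
#' @return a `slam_substructure` with role `"ligand_cavity"`, or NULL.
#' @export
extract_ligand_cavity <- function(s, ligand, chain = NULL, radius = 7,
                                  min_atoms = 40) {
  lig <- if (is.character(ligand)) {
    all_lig <- ligands(s)
    pick <- all_lig[all_lig$ligand_id == ligand, , drop = FALSE]
    if (!nrow(pick)) stop("no ligand with id: ", ligand)
    first <- pick[1, ]
    pick[pick$chain == first$chain & pick$resno == first$resno, , drop = FALSE]
  } else {
    tibble::as_tibble(ligand)
  }
  lig <- lig[lig$is_heavy, , drop = FALSE]
  if (!nrow(lig)) stop("ligand has no heavy atoms")
  prot <- .protein_atoms(s)
  if (!is.null(chain)) prot <- prot[prot$chain == chain, , drop = FALSE]
  if (!nrow(prot) || radius <= 0) return(NULL)

  near <- .atoms_within(prot, as.matrix(lig[, c("x", "y", "z")]), radius)
  if (!any(near)) return(NULL)
  res_sel <- unique(.residue_key(prot[near, ]))
  cavity <- prot[.residue_key(prot) %in% res_sel, , drop = FALSE]
  if (nrow(cavity) < min_atoms) return(NULL)
  as_substructure(
    cavity,
    role = "ligand_cavity",
    anchor = paste0(lig$ligand_id[1], ":", lig$chain[1], ":", lig$resno[1]),
    source = paste0(attr(s, "structure_id"), ":",
                    paste(sort(unique(cavity$chain)), collapse = ""))
  )
}

# which rows of `at` lie within `radius` of any point in `pts` (n x 3)
.atoms_within <- function(at, pts, radius) {
  xyz <- as.matrix(at[, c("x", "y", "z")])
  r2 <- radius^2
  near <- rep(FALSE, nrow(xyz))
  for (i in seq_len(nrow(pts))) {
    di <- (xyz[, 1] - pts[i, 1])^2 + (xyz[, 2] - pts[i, 2])^2 +
      (xyz[, 3] - pts[i, 3])^2
    near <- near | di <= r2
  }
  near
}

# deterministic golden-spiral point set on the unit sphere
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over each heavy atom using a deterministic
#' golden-spiral point sampling. By default the area is computed per
#' isolated protein chain: only heavy protein atoms of the same chain
#' occlude each other, and ligands/waters are excluded from the occlusion
#' environment (configurable).
#'
#' @param s a `slam_structure`.
#' @param probe probe radius, Angstrom (water: 1.4).
#' @param n_points sample points per atom sphere.
#' @param per_chain occlude within each chain separately (default TRUE).
#' @param include_hetero include ligand/water heavy atoms as occluders and
#'   targets (default FALSE).
#' @return tibble `atom_id`, `chain`, `area` (square Angstrom).
#' @export
compute_sasa <- function(s, probe = 1.4, n_points = 960, per_chain = TRUE,
                         include_hetero = FALSE) {
  at <- if (include_hetero) {
    dplyr::filter(tibble::as_tibble(s), .data$is_heavy)
  } else {
    .protein_atoms(s)
  }
  if (!nrow(at)) {
    return(tibble::tibble(atom_id = integer(), chain = character(),
                          area = numeric()))
  }
  pts <- .sphere_points(n_points)
  chains <- if (per_chain) unique(at$chain) else "all"
  out <- vector("list", length(chains))
  for (ci in seq_along(chains)) {
    ca <- if (per_chain) at[at$chain == chains[ci], , drop = FALSE] else at
    xyz <- as.matrix(ca[, c("x", "y", "z")])
    rad <- ca$vdw + probe
    n <- nrow(ca)
    area <- numeric(n)
    for (i in seq_len(n)) {
      sp <- pts * rad[i]
      sp <- sweep(sp, 2, xyz[i, ], "+")
      acc <- rep(TRUE, n_points)
      dx <- xyz[, 1] - xyz[i, 1]
      dy <- xyz[, 2] - xyz[i, 2]
      dz <- xyz[, 3] - xyz[i, 3]
      d2 <- dx * dx + dy * dy + dz * dz
      nb <- which(d2 < (rad[i] + rad)^2 & d2 > 0)
      for (j in nb) {
        dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
          (sp[, 3] - xyz[j, 3])^2
        acc <- acc & dj2 > rad[j]^2
        if (!any(acc)) break
      }
      area[i] <- 4 * pi * rad[i]^2 * sum(acc) / n_points
    }
    out[[ci]] <- tibble::tibble(atom_id = ca$atom_id, chain = ca$chain,
                                area = area)
  }
  dplyr::bind_rows(out)
}

#' Surface-exposed atoms
#'
#' Atoms with strictly more than `threshold` square Angstrom of solvent
#' accessible area.
#'
#' @param areas tibble from [compute_sasa()].
#' @param threshold exposure cut, square Angstrom.
#' @return integer vector of atom ids.
#' @export
surface_atoms <- function(areas, threshold = 2) {
  areas$atom_id[areas$area > threshold]
}

#' Extract a surface patch around a surface-exposed atom
#'
#' Selects every whole protein residue having at least one heavy atom within
#' `radius` of the center atom, the surface-patch analogue of the
#' ligand-cavity shell.
#'
#' @param s a `slam_structure`.
#' @param center atom id of the (surface-exposed) center atom.
#' @param radius shell radius, Angstrom.
#' @return a `slam_substructure` with role `"surface_patch"`.
#' @export
extract_surface_patch <- function(s, center, radius = 7) {
  at <- tibble::as_tibble(s)
  i <- match(center, at$atom_id)
  if (is.na(i)) stop("center atom not in structure: ", center)
  prot <- .protein_atoms(s)
  near <- .atoms_within(prot, matrix(unlist(at[i, c("x", "y", "z")]), 1), radius)
  res_sel <- unique(.residue_key(prot[near, ]))
  patch <- prot[.residue_key(prot) %in% res_sel, , drop = FALSE]
  as_substructure(
    patch,
    role = "surface_patch", anchor = center,
    source = paste0(attr(s, "structure_id"), ":", at$chain[i])
  )
}

#' Build a database of surface patches
#'
#' One patch per surface-exposed atom of each structure, written as PDB
#' fragments with a TSV manifest (`structure_id`, `chain`, `role`, `anchor`,
#' `n_atoms`, `file`). Per-structure failures are reported and skipped, not
#' fatal to the batch; reruns over identical inputs reproduce the manifest
#' byte for byte.
#'
#' @param structures list of `slam_structure` objects.
#' @param out_dir output directory.
#' @param config a [slam_config()] (SASA probe/points, exposure cut, radius).
#' @param dedup drop patches whose residue set duplicates an earlier patch
#'   of the same structure (default FALSE: one patch per surface atom).
#' @return the manifest tibble, invisibly written to
#'   `file.path(out_dir, "manifest.tsv")`.
#' @export
build_patch_database <- function(structures, out_dir, config = slam_config(),
                                 dedup = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (s in structures) {
    sid <- attr(s, "structure_id")
    res <- tryCatch({
      areas <- compute_sasa(s, probe = config$sasa_probe,
                            n_points = config$sasa_n_points)
      surf <- surface_atoms(areas, threshold = config$sasa_min)
      if (!length(surf)) {
        message("structure ", sid, ": no surface-exposed atoms, skipped")
        NULL
      } else {
        seen <- character()
        srows <- list()
        for (a in surf) {
          p <- extract_surface_patch(s, a, radius = config$cavity_radius)
          key <- paste(sort(.residue_key(p)), collapse = ";")
          if (dedup && key %in% seen) next
          seen <- c(seen, key)
          fn <- sprintf("%s_patch_%06d.pdb", sid, a)
          write_structure(p, file.path(out_dir, fn))
          srows[[length(srows) + 1]] <- tibble::tibble(
            structure_id = sid, chain = p$chain[1], role = "surface_patch",
            anchor = as.character(a), n_atoms = nrow(p), file = fn
          )
        }
        dplyr::bind_rows(srows)
      }
    }, error = function(e) {
      message("structure ", sid, " failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1]] <- res
  }
  manifest <- dplyr::bind_rows(rows)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
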