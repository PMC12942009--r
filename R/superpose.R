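# Kabsch superposition, ligand pose transfer into the target frame, local
# pose optimization (external docking engine or a built-in steric stub), and
# the free-energy score used to classify docking quality.

#' Optimal rigid superposition (Kabsch)
#'
#' Closed-form least-squares rotation + translation mapping point set
#' `from` onto point set `to`; reflections are excluded, so the rotation is
#' proper (det = +1).
#'
#' @param from n x 3 matrix of moving points.
#' @param to n x 3 matrix of fixed points (same row order).
#' @return list of class `slam_transform`: `rotation` (3x3), `translation`
#'   (length 3), `rmsd` over the fitted points.
#' @export
kabsch_superpose <- function(from, to) {
  from <- as.matrix(from)
  to <- as.matrix(to)
  if (!all(dim(from) == dim(to)) || ncol(from) != 3 || nrow(from) < 3) {
    stop("need two equal point sets of at least 3 points in 3D")
  }
  cf <- colMeans(from)
  ct <- colMeans(to)
  P <- sweep(from, 2, cf)
  Q <- sweep(to, 2, ct)
  H <- crossprod(P, Q)
  sv <- svd(H)
  if (sv$d[2] < 1e-10) stop("degenerate geometry: points are collinear")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- ct - as.numeric(R %*% cf)
  fitted <- apply_transform(from, list(rotation = R, translation = tr))
  rmsd <- sqrt(mean(rowSums((fitted - to)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd),
            class = "slam_transform")
}

#' Apply a rigid transform to points
#'
#' @param points n x 3 matrix.
#' @param tf a `slam_transform` (or list with `rotation`, `translation`).
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(points, tf) {
  points <- as.matrix(points)
  sweep(points %*% t(tf$rotation), 2, tf$translation, "+")
}

#' @export
print.slam_transform <- function(x, ...) {
  cat("<slam_transform> rmsd =", format(x$rmsd, digits = 4), "A\n")
  invisible(x)
}

#' Transfer a ligand pose into the target frame
#'
#' Computes the Kabsch transform on the 3D alignment's matched atom pairs
#' (query-side atoms onto target-side atoms) and applies it to the probe
#' ligand's coordinates, establishing the ligand's initial pose with respect
#' to the target binding site.
#'
#' @param query query structure/substructure tibble (source of pair A atoms).
#' @param ligand_atoms tibble of probe ligand heavy atoms.
#' @param pairs matched-pair tibble (`atom_id_a` in query, `atom_id_b` in
#'   target), e.g. a `pairs[[1]]` entry of a `slam_result`.
#' @param target target structure tibble (source of pair B atoms).
#' @return the ligand tibble with transformed `x`, `y`, `z`; the transform
#'   is attached as attribute `transform`.
#' @export
transfer_ligand <- function(query, ligand_atoms, pairs, target) {
  A <- .pair_coords(pairs$atom_id_a, query)
  B <- .pair_coords(pairs$atom_id_b, target)
  tf <- kabsch_superpose(A, B)
  lig <- tibble::as_tibble(ligand_atoms)
  xyz <- apply_transform(as.matrix(lig[, c("x", "y", "z")]), tf)
  lig$x <- xyz[, 1]
  lig$y <- xyz[, 2]
  lig$z <- xyz[, 3]
  attr(lig, "transform") <- tf
  lig
}

#' Displacement between two poses
#'
#' The default is heavy-atom RMSD between the two poses, which also captures
#' rotation of elongated ligands; `"centroid"` gives the centroid-to-centroid
#' distance instead.
#'
#' @param p1,p2 pose coordinate matrices or atom tibbles (same atom order).
#' @param mode `"rmsd"` or `"centroid"`.
#' @return displacement in Angstrom.
#' @export
pose_shift <- function(p1, p2, mode = c("rmsd", "centroid")) {
  mode <- match.arg(mode)
  m1 <- .pose_xyz(p1)
  m2 <- .pose_xyz(p2)
  if (!all(dim(m1) == dim(m2))) stop("poses differ in atom count")
  if (mode == "rmsd") sqrt(mean(rowSums((m1 - m2)^2)))
  else sqrt(sum((colMeans(m1) - colMeans(m2))^2))
}

.pose_xyz <- function(p) {
  if (is.matrix(p)) p else as.matrix(tibble::as_tibble(p)[, c("x", "y", "z")])
}

#' Free-energy score and true-positive classification
#'
#' `FE-score = FE / (Shift + 0.1)`: the optimized binding free energy
#' divided by the regularized pose displacement. Large shifts indicate the
#' alignment-based transfer was suboptimal and suppress the score toward 0;
#' scores strictly below -1.5 classify the docking as a true positive.
#'
#' @param fe binding free energy after local optimization, kcal/mol.
#' @param shift pose displacement, Angstrom (>= 0).
#' @return numeric score (vectorised).
#' @export
fe_score <- function(fe, shift) {
  stopifnot(all(shift >= 0))
  fe / (shift + 0.1)
}

#' @rdname fe_score
#' @param score FE-score value(s).
#' @param threshold classification cutoff (strict `<`).
#' @export
classify_tp <- function(score, threshold = -1.5) {
  score < threshold
}

# ---- stub scoring engine ----------------------------------------------------

# soft steric energy of a ligand pose against rigid receptor heavy atoms:
# quadratic clash repulsion inside 0.75 * radius-sum, smooth Gaussian
# contact reward near the radius sum. Pseudo-kcal/mol; not a force field.
.stub_energy <- function(lig_xyz, lig_vdw, rec_xyz, rec_vdw) {
  e <- 0
  for (i in seq_len(nrow(lig_xyz))) {
    d <- sqrt((rec_xyz[, 1] - lig_xyz[i, 1])^2 +
              (rec_xyz[, 2] - lig_xyz[i, 2])^2 +
              (rec_xyz[, 3] - lig_xyz[i, 3])^2)
    rsum <- lig_vdw[i] + rec_vdw
    clash <- d < 0.75 * rsum
    if (any(clash)) e <- e + 10 * sum((0.75 * rsum[clash] - d[clash])^2)
    nearby <- d < 8
    if (any(nearby)) {
      d0 <- rsum[nearby] + 0.5
      e <- e - 0.25 * sum(exp(-(d[nearby] - d0)^2 / 2))
    }
  }
  e
}

.rigid_params_apply <- function(par, xyz) {
  # par = (tx, ty, tz, rx, ry, rz); small-angle-safe full rotation matrices
  cx <- cos(par[4]); sx <- sin(par[4])
  cy <- cos(par[5]); sy <- sin(par[5])
  cz <- cos(par[6]); sz <- sin(par[6])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  ctr <- colMeans(xyz)
  centered <- sweep(xyz, 2, ctr)
  sweep(centered %*% t(Rz %*% Ry %*% Rx), 2, ctr + par[1:3], "+")
}

#' Locally optimize a ligand pose in the target cavity
#'
#' Refines the transferred ligand pose with respect to the rigid target
#' receptor and reports the binding free energy of the optimized pose.
#' With `engine = "vina"` an external AutoDock Vina executable is run in
#' local-optimization mode on PDBQT inputs written by the package. The
#' default `engine = "stub"` is a built-in clash-penalized rigid local
#' search over the 6 rigid-body degrees of freedom; it lets the full
#' pipeline run end-to-end and is explicitly not publication-grade
#' energetics.
#'
#' @param target target structure tibble (receptor, kept rigid).
#' @param pose initial ligand pose (atom tibble with coordinates and `vdw`).
#' @param engine `"stub"` or `"vina"`.
#' @param vina_path path to the Vina executable (engine = "vina").
#' @param shift_mode displacement definition, see [pose_shift()].
#' @return list of class `slam_docking`: `fe` (kcal/mol), `shift` (A),
#'   `fe_score`, `is_tp`, `initial_pose`, `optimized_pose`, `engine`.
#' @export
optimize_pose <- function(target, pose, engine = c("stub", "vina"),
                          vina_path = Sys.which("vina"),
                          shift_mode = "rmsd") {
  engine <- match.arg(engine)
  pose <- tibble::as_tibble(pose)
  rec <- dplyr::filter(tibble::as_tibble(target), .data$is_heavy,
                       !.data$is_ligand)
  if (engine == "vina") {
    res <- .run_vina_local(rec, pose, vina_path)
  } else {
    lig_xyz <- .pose_xyz(pose)
    rec_xyz <- as.matrix(rec[, c("x", "y", "z")])
    obj <- function(par) {
      .stub_energy(.rigid_params_apply(par, lig_xyz), pose$vdw, rec_xyz,
                   rec$vdw)
    }
    opt <- stats::optim(rep(0, 6), obj, method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-6))
    new_xyz <- .rigid_params_apply(opt$par, lig_xyz)
    res <- list(fe = opt$value, xyz = new_xyz)
  }
  optimized <- pose
  optimized$x <- res$xyz[, 1]
  optimized$y <- res$xyz[, 2]
  optimized$z <- res$xyz[, 3]
  shift <- pose_shift(pose, optimized, mode = shift_mode)
  score <- fe_score(res$fe, shift)
  structure(
    list(
      fe = res$fe, shift = shift, fe_score = score,
      is_tp = classify_tp(score),
      initial_pose = pose, optimized_pose = optimized, engine = engine
    ),
    class = "slam_docking"
  )
}

#' @export
print.slam_docking <- function(x, ...) {
  cat("<slam_docking> engine=", x$engine,
      " FE=", format(x$fe, digits = 4),
      " shift=", format(x$shift, digits = 3),
      " FE-score=", format(x$fe_score, digits = 4),
      if (x$is_tp) " [TP]" else " [not TP]", "\n", sep = "")
  invisible(x)
}

# minimal PDBQT writer: rigid molecules, element-derived AutoDock types,
# zero partial charges (local-only optimization does not use a torsion tree)
.write_pdbqt <- function(atoms, path, rigid_receptor = TRUE) {
  at <- tibble::as_tibble(atoms)
  type_map <- c(C = "C", N = "NA", O = "OA", S = "SA", P = "P", H = "HD",
                F = "F", CL = "Cl", BR = "Br", I = "I", SE = "S")
  ad <- type_map[at$element]
  ad[is.na(ad)] <- at$element[is.na(ad)]
  con <- file(path, "w")
  on.exit(close(con))
  if (!rigid_receptor) writeLines("ROOT", con)
  for (i in seq_len(nrow(at))) {
    writeLines(sprintf(
      "ATOM  %5d %-4s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f    %6.3f %-2s",
      i, substr(at$name[i], 1, 4), substr(at$resname[i], 1, 3),
      substr(at$chain[i], 1, 1), at$resno[i] %% 10000,
      at$x[i], at$y[i], at$z[i], 1, 0, 0, ad[i]
    ), con)
  }
  if (!rigid_receptor) {
    writeLines("ENDROOT", con)
    writeLines("TORSDOF 0", con)
  }
  invisible(path)
}

.run_vina_local <- function(rec, pose, vina_path) {
  if (!nzchar(vina_path) || !file.exists(vina_path)) {
    stop("docking engine not found; install AutoDock Vina or use engine='stub'")
  }
  td <- tempfile("vina")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  rec_f <- file.path(td, "receptor.pdbqt")
  lig_f <- file.path(td, "ligand.pdbqt")
  out_f <- file.path(td, "out.pdbqt")
  .write_pdbqt(rec, rec_f, rigid_receptor = TRUE)
  .write_pdbqt(pose, lig_f, rigid_receptor = FALSE)
  ctr <- colMeans(.pose_xyz(pose))
  args <- c(
    "--receptor", rec_f, "--ligand", lig_f, "--local_only",
    "--center_x", ctr[1], "--center_y", ctr[2], "--center_z", ctr[3],
    "--size_x", 22, "--size_y", 22, "--size_z", 22, "--out", out_f
  )
  log <- tryCatch(
    system2(vina_path, args, stdout = TRUE, stderr = TRUE),
    error = function(e) stop("docking engine failed: ", conditionMessage(e))
  )
  st <- attr(log, "status")
  if (!is.null(st) && st != 0) {
    stop("docking engine exited with status ", st, ": ",
         paste(utils::tail(log, 5), collapse = " | "))
  }
  aff <- grep("^\\s*1\\s+", log, value = TRUE)
  fe <- suppressWarnings(as.numeric(strsplit(trimws(aff[1]), "\\s+")[[1]][2]))
  if (is.na(fe)) {
    res_line <- grep("Affinity", log, value = TRUE)
    fe <- suppressWarnings(as.numeric(sub(".*?(-?[0-9.]+).*", "\\1",
                                          res_line[1])))
  }
  if (is.na(fe)) stop("could not parse affinity from docking engine output")
  out_lines <- readLines(out_f)
  atom_lines <- grep("^(ATOM|HETATM)", out_lines, value = TRUE)
  xyz <- t(vapply(atom_lines, function(l) {
    c(as.numeric(substr(l, 31, 38)), as.numeric(substr(l, 39, 46)),
      as.numeric(substr(l, 47, 54)))
  }, numeric(3)))
  rownames(xyz) <- NULL
  list(fe = fe, xyz = xyz[seq_len(nrow(pose)), , drop = FALSE])
}
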