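# The engine: distance-sorted atom neighborhoods, all-against-all linear
# alignments, pair-evidence accumulation, candidate selection,
# correlation-constrained agglomerative clustering, and Ncorr5 scoring.

#' Distance-sorted atom neighborhoods of a substructure
#'
#' For every heavy atom (the center), the k nearest other heavy atoms of the
#' substructure are arranged in a linear sequence ordered by increasing
#' distance from the center. The center itself is not part of the sequence.
#' Equal distances are broken lexicographically by atom id, so neighborhoods
#' are bit-reproducible.
#'
#' @param sub substructure (or structure) atom tibble.
#' @param k neighborhood size; the canonical choice is 7 (an eight-atom
#'   neighborhood counting the center), values 7-11 are typical.
#' @return a tibble with columns `center`, `rank`, `atom_id`, `dist`, of
#'   class `slam_neighborhoods`; the k-column index matrix is attached as
#'   attribute `seq_matrix` (rows = centers, entries = positions in the
#'   heavy-atom table, attribute `heavy_ids` maps positions to atom ids).
#' @export
build_neighborhoods <- function(sub, k = 7) {
  at <- dplyr::filter(tibble::as_tibble(sub), .data$is_heavy)
  n <- nrow(at)
  if (n < k + 1) {
    stop("substructure too small: ", n, " heavy atoms, need at least k+1 = ",
         k + 1)
  }
  xyz <- as.matrix(at[, c("x", "y", "z")])
  d2 <- .pairwise_sq_dist(xyz)
  seq_m <- matrix(0L, nrow = n, ncol = k)
  dist_m <- matrix(0, nrow = n, ncol = k)
  ids <- at$atom_id
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(d2[i, others], ids[others])][seq_len(k)]
    seq_m[i, ] <- ord
    dist_m[i, ] <- sqrt(d2[i, ord])
  }
  out <- tibble::tibble(
    center = rep(ids, each = k),
    rank = rep(seq_len(k), times = n),
    atom_id = ids[as.integer(t(seq_m))],
    dist = as.numeric(t(dist_m))
  )
  structure(out,
    seq_matrix = seq_m, heavy_ids = ids,
    class = c("slam_neighborhoods", class(tibble::tibble()))
  )
}

#' Globally align two annotated atom sequences
#'
#' Optimal global (Needleman-Wunsch) alignment under the atom substitution
#' score with affine gap penalties; end gaps are penalized. The traceback is
#' deterministic (on ties a match is preferred to a gap in the second
#' sequence, which is preferred to a gap in the first).
#'
#' @param atoms_a,atoms_b annotated atom tibbles (see [annotate_atoms()]).
#' @param seq_a,seq_b atom-id vectors giving the two sequences.
#' @param model a [substitution_model()].
#' @return list with `score`, `pairs` (tibble of matched
#'   `atom_id_a`/`atom_id_b`), and `gaps` (count of gapped positions).
#' @export
align_sequences <- function(atoms_a, seq_a, atoms_b, seq_b,
                            model = substitution_model()) {
  ia <- match(seq_a, atoms_a$atom_id)
  ib <- match(seq_b, atoms_b$atom_id)
  if (anyNA(ia) || anyNA(ib)) stop("sequence atom ids not found in atom table")
  s <- .score_matrix(atoms_a[ia, ], atoms_b[ib, ], model)
  r <- .nw_align_cpp(s, model$gap_open, model$gap_extend)
  pairs <- tibble::tibble(
    atom_id_a = seq_a[r$pairs[, 1]],
    atom_id_b = seq_b[r$pairs[, 2]]
  )
  list(
    score = r$score,
    pairs = pairs,
    gaps = (length(seq_a) - nrow(pairs)) + (length(seq_b) - nrow(pairs))
  )
}

.self_scores <- function(atoms, seq_m, model) {
  per_atom <- diag(model$group_matrix)[atoms$aa_group] + model$chem_weight * 4
  apply(seq_m, 1L, function(ix) sum(per_atom[ix]))
}

#' Accumulate atom-pair evidence from all-against-all alignments
#'
#' Every neighborhood sequence of substructure A is aligned against every
#' neighborhood sequence of substructure B. Alignments that reach the
#' quality gate (a fraction `gate_frac` of the smaller sequence's
#' self-alignment score) contribute their full alignment score as evidence
#' to each matched atom pair; recurrently matched pairs therefore stand out
#' from background matches.
#'
#' @param sub_a,sub_b substructure atom tibbles (annotated automatically if
#'   the annotation columns are missing).
#' @param config a [slam_config()] (supplies k, gap penalties, gate).
#' @return a tibble of class `slam_pair_table`: `atom_id_a`, `atom_id_b`,
#'   `evidence`, `n_alignments`, sorted by decreasing evidence.
#' @export
accumulate_pair_evidence <- function(sub_a, sub_b, config = slam_config()) {
  sub_a <- .ensure_annotated(sub_a, config)
  sub_b <- .ensure_annotated(sub_b, config)
  model <- submodel_from_config(config)
  ha <- dplyr::filter(tibble::as_tibble(sub_a), .data$is_heavy)
  hb <- dplyr::filter(tibble::as_tibble(sub_b), .data$is_heavy)
  na <- build_neighborhoods(sub_a, k = config$k)
  nb <- build_neighborhoods(sub_b, k = config$k)
  sa <- attr(na, "seq_matrix")
  sb <- attr(nb, "seq_matrix")
  S <- .score_matrix(ha, hb, model)
  res <- .pair_evidence_cpp(
    sa, sb, S,
    .self_scores(ha, sa, model), .self_scores(hb, sb, model),
    config$gate_frac, model$gap_open, model$gap_extend
  )
  idx <- which(res$counts > 0, arr.ind = TRUE)
  out <- tibble::tibble(
    atom_id_a = ha$atom_id[idx[, 1]],
    atom_id_b = hb$atom_id[idx[, 2]],
    evidence = res$evidence[idx],
    n_alignments = res$counts[idx]
  )
  out <- out[order(-out$evidence, out$atom_id_a, out$atom_id_b), ]
  seeds <- tibble::tibble(
    alignment = res$seed_alignment,
    atom_id_a = ha$atom_id[res$seed_a],
    atom_id_b = hb$atom_id[res$seed_b]
  )
  structure(out, seeds = seeds,
            class = c("slam_pair_table", class(tibble::tibble())))
}

.ensure_annotated <- function(sub, config) {
  if (!"dabe" %in% names(sub)) annotate_atoms(sub, tolerance = config$tolerance)
  else sub
}

#' Select candidate atom pairs from the evidence table
#'
#' Separates the high-evidence outliers (recurrent pairs from superimposable
#' regions) from the background of incidental matches. Policies:
#' `"mean_sd"` keeps pairs with evidence above mean + c_sd * SD of the
#' evidence values; `"quantile"` keeps the top `1 - quantile` fraction;
#' `"fixed"` applies an absolute cutoff.
#'
#' @param tbl a `slam_pair_table` from [accumulate_pair_evidence()].
#' @param config a [slam_config()] (policy and its parameters).
#' @return the filtered pair table (possibly zero rows).
#' @export
select_candidate_pairs <- function(tbl, config = slam_config()) {
  if (!nrow(tbl)) return(tbl)
  thr <- switch(config$candidate_policy,
    mean_sd = {
      if (nrow(tbl) < 2) Inf
      else mean(tbl$evidence) + config$c_sd * stats::sd(tbl$evidence)
    },
    quantile = stats::quantile(tbl$evidence, config$quantile, names = FALSE),
    fixed = config$fixed_evidence
  )
  out <- tbl[tbl$evidence > thr, , drop = FALSE]
  attr(out, "seeds") <- attr(tbl, "seeds")
  out
}

#' Pearson correlation of interatomic distance vectors
#'
#' For matched pairs (a_i, b_i), computes the Pearson correlation between
#' the vector of distances d(a_i, a_j) within structure A and d(b_i, b_j)
#' within structure B over all i < j. Equal to 1 for any rigid motion and
#' for uniform scaling of one structure.
#'
#' @param pairs tibble with `atom_id_a`, `atom_id_b`.
#' @param atoms_a,atoms_b atom tibbles supplying coordinates.
#' @return the correlation, or NA (with a warning) when fewer than 3 pairs
#'   or a zero-variance distance vector make it undefined.
#' @export
distance_correlation <- function(pairs, atoms_a, atoms_b) {
  n <- nrow(pairs)
  if (n < 3) {
    warning("distance correlation undefined for fewer than 3 pairs")
    return(NA_real_)
  }
  pa <- .pair_coords(pairs$atom_id_a, atoms_a)
  pb <- .pair_coords(pairs$atom_id_b, atoms_b)
  da <- stats::dist(pa)
  db <- stats::dist(pb)
  if (stats::sd(da) == 0 || stats::sd(db) == 0) {
    warning("distance correlation undefined: zero-variance distance vector")
    return(NA_real_)
  }
  stats::cor(as.numeric(da), as.numeric(db))
}

.pair_coords <- function(atom_id, atoms) {
  i <- match(atom_id, atoms$atom_id)
  if (anyNA(i)) stop("atom ids not present in atom table")
  as.matrix(atoms[i, c("x", "y", "z")])
}

#' Ncorr5 score of a 3D alignment
#'
#' `N * r^5`: the number of matched atom pairs times the fifth power of the
#' interatomic-distance correlation. The fifth power sharpens the separation
#' between geometrically consistent and spurious alignments.
#'
#' @param n number of matched pairs.
#' @param r Pearson correlation of the interatomic distance vectors.
#' @return numeric score (vectorised).
#' @export
ncorr5 <- function(n, r) n * r^5

#' Cluster candidate pairs into correlation-consistent 3D alignments
#'
#' Agglomerative merging of matched-pair groups: the seed groups are the
#' candidate pairs of each gated neighborhood alignment (so every seed
#' carries the local geometry of one linear alignment); at each step the two
#' groups whose union has the highest interatomic distance correlation are
#' merged, provided the correlation exceeds `r_min` and the union stays
#' one-to-one in atoms on both sides. Groups may share identical pairs
#' (overlapping neighborhoods); their unions deduplicate. Terminal groups
#' with at least `min_pairs` distinct pairs are emitted as 3D alignments.
#' Without seed information every candidate pair starts as a singleton, and
#' two-pair unions are scored by the relative distance agreement
#' `1 - |dA - dB| / max(dA, dB)` in place of the (undefined) correlation.
#'
#' @param candidates pair tibble (`atom_id_a`, `atom_id_b`), e.g. from
#'   [select_candidate_pairs()].
#' @param atoms_a,atoms_b atom tibbles supplying coordinates.
#' @param config a [slam_config()] (`r_min`, `min_pairs`).
#' @param seeds optional tibble (`alignment`, `atom_id_a`, `atom_id_b`) of
#'   per-alignment matched pairs, as attached by
#'   [accumulate_pair_evidence()]; defaults to the candidates' own
#'   `seeds` attribute.
#' @return tibble of class `slam_result`: one row per emitted alignment with
#'   `n_pairs`, `r`, `ncorr5` and a `pairs` list-column, ranked by
#'   decreasing `ncorr5`.
#' @export
cluster_pairs <- function(candidates, atoms_a, atoms_b,
                          config = slam_config(),
                          seeds = attr(candidates, "seeds")) {
  m <- nrow(candidates)
  empty <- tibble::tibble(
    n_pairs = integer(), r = numeric(), ncorr5 = numeric(),
    pairs = list()
  )
  if (m < config$min_pairs) return(.as_slam_result(empty, config))
  if (!"evidence" %in% names(candidates)) candidates$evidence <- 0
  pa <- .pair_coords(candidates$atom_id_a, atoms_a)
  pb <- .pair_coords(candidates$atom_id_b, atoms_b)
  DA <- as.matrix(stats::dist(pa))
  DB <- as.matrix(stats::dist(pb))
  a_ids <- candidates$atom_id_a
  b_ids <- candidates$atom_id_b

  groups <- .seed_groups(candidates, seeds)
  if (length(groups) < 2) return(.as_slam_result(empty, config))
  m <- length(groups)
  merge_score <- function(u) {
    if (length(u) < 2) return(-Inf)
    if (length(u) == 2) {
      dA <- DA[u[1], u[2]]
      dB <- DB[u[1], u[2]]
      if (max(dA, dB) == 0) return(-Inf)
      return(1 - abs(dA - dB) / max(dA, dB) * config$pair_merge_rel_tol)
    }
    va <- DA[u, u][upper.tri(diag(length(u)))]
    vb <- DB[u, u][upper.tri(diag(length(u)))]
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) return(-Inf)
    stats::cor(va, vb)
  }
  # precedence for resolving atom conflicts: stronger evidence wins
  prec <- order(-candidates$evidence, seq_len(nrow(candidates)))
  prec_rank <- integer(nrow(candidates))
  prec_rank[prec] <- seq_along(prec)
  resolve_union <- function(u) {
    # enforce one-to-one: for an atom claimed by several pairs keep the
    # pair with the higher evidence (deterministic tie-break by row)
    u <- u[order(prec_rank[u])]
    keep <- !duplicated(a_ids[u]) & !duplicated(b_ids[u])
    sort(u[keep])
  }
  pair_score <- function(i, j) {
    u <- resolve_union(unique(c(groups[[i]], groups[[j]])))
    # no gain over the larger constituent: consolidate at top priority
    if (length(u) <= max(length(groups[[i]]), length(groups[[j]])) &&
        all(groups[[i]] %in% u) && all(groups[[j]] %in% u)) return(1)
    merge_score(u)
  }
  # cached union-score matrix among live groups; only the merged group's
  # row/column is recomputed after each merge
  S <- matrix(-Inf, m, m)
  for (i in seq_len(m - 1)) {
    for (j in seq.int(i + 1, m)) S[i, j] <- pair_score(i, j)
  }
  live <- rep(TRUE, m)
  repeat {
    if (sum(live) < 2) break
    best <- max(S)
    if (best <= config$r_min) break
    ij <- which(S == best, arr.ind = TRUE)[1, ]
    i <- ij[1]
    j <- ij[2]
    groups[[i]] <- resolve_union(unique(c(groups[[i]], groups[[j]])))
    live[j] <- FALSE
    S[j, ] <- -Inf
    S[, j] <- -Inf
    for (k in which(live)) {
      if (k == i) next
      v <- pair_score(min(i, k), max(i, k))
      S[min(i, k), max(i, k)] <- v
    }
  }

  keep <- Filter(function(g) length(g) >= config$min_pairs, groups[live])
  if (!length(keep)) return(.as_slam_result(empty, config))
  rows <- lapply(keep, function(g) {
    pr <- tibble::tibble(atom_id_a = a_ids[g], atom_id_b = b_ids[g])
    r <- distance_correlation(pr, atoms_a, atoms_b)
    tibble::tibble(
      n_pairs = length(g), r = r, ncorr5 = ncorr5(length(g), r),
      pairs = list(pr)
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- out[out$r >= config$r_min, , drop = FALSE]
  out <- out[order(-out$ncorr5,
                   vapply(out$pairs, function(p) min(p$atom_id_a), 1)), ]
  .as_slam_result(out, config)
}

# Hill-climb refinement of a clustered core over the full evidence table.
# Fast path: the best strictly improving addition of a non-conflicting
# table pair is applied immediately (growth dominates the climb). When no
# addition improves, repair moves are scanned: remove a member, swap a
# table pair for the single member it conflicts with, or apply a
# transposition (a pool pair conflicting two members, together with its
# complementary pair, replaces both -- escaping swapped-assignment optima).
# Every accepted move strictly increases N * r^5 under the r >= r_min
# constraint, so the deterministic climb terminates at a local maximum; a
# repair budget bounds the worst case. Internally runs on plain vectors
# with running Pearson sums (O(n) per candidate move).
.refine_cluster <- function(pairs, tbl, atoms_a, atoms_b, config,
                            max_iter = 200, repair_budget = 60) {
  cur_a <- as.integer(pairs$atom_id_a)
  cur_b <- as.integer(pairs$atom_id_b)
  dup <- duplicated(paste(cur_a, cur_b))
  cur_a <- cur_a[!dup]
  cur_b <- cur_b[!dup]
  # the pool is the evidence table (already evidence-sorted); cap it so
  # refinement cost stays bounded on very dense tables
  np_pool <- min(nrow(tbl), 2000L)
  pool_a <- as.integer(tbl$atom_id_a[seq_len(np_pool)])
  pool_b <- as.integer(tbl$atom_id_b[seq_len(np_pool)])
  pool_key <- pool_a * 10000000 + pool_b
  keep_u <- !duplicated(pool_key)
  pool_a <- pool_a[keep_u]
  pool_b <- pool_b[keep_u]
  pool_key <- pool_key[keep_u]
  pxa <- .pair_coords(pool_a, atoms_a)
  pxb <- .pair_coords(pool_b, atoms_b)

  r_cur <- NA_real_
  nc_cur <- -Inf
  repairs <- 0L
  for (iter in seq_len(max_iter)) {
    n <- length(cur_a)
    pa <- .pair_coords(cur_a, atoms_a)
    pb <- .pair_coords(cur_b, atoms_b)
    DA <- as.matrix(stats::dist(pa))
    DB <- as.matrix(stats::dist(pb))
    npairs <- n * (n - 1) / 2
    rs_x <- unname(rowSums(DA))
    rs_y <- unname(rowSums(DB))
    rs_x2 <- unname(rowSums(DA^2))
    rs_y2 <- unname(rowSums(DB^2))
    rs_xy <- unname(rowSums(DA * DB))
    tot <- c(sx = sum(rs_x) / 2, sy = sum(rs_y) / 2, sxx = sum(rs_x2) / 2,
             syy = sum(rs_y2) / 2, sxy = sum(rs_xy) / 2)
    r_of <- function(s, m) {
      num <- s[["sxy"]] - s[["sx"]] * s[["sy"]] / m
      den <- sqrt(max(s[["sxx"]] - s[["sx"]]^2 / m, 0) *
                    max(s[["syy"]] - s[["sy"]]^2 / m, 0))
      if (!is.finite(den) || den <= 0) NA_real_ else num / den
    }
    r_cur <- if (n >= 3) r_of(tot, npairs) else NA_real_
    # undersized or degenerate starts may still grow through add moves;
    # the margin keeps float noise between incremental and exact sums from
    # ever looking like an improvement
    nc_cur <- if (is.na(r_cur)) -Inf else ncorr5(n, r_cur)
    best_nc <- if (is.finite(nc_cur)) nc_cur + 1e-6 else nc_cur
    action <- NULL

    key_cur <- cur_a * 10000000 + cur_b
    live <- which(!(pool_key %in% key_cur))
    if (length(live)) {
      ia <- match(pool_a[live], cur_a)
      ib <- match(pool_b[live], cur_b)
      nconf <- (!is.na(ia)) + (!is.na(ib))

      # fast path: additions
      add <- live[nconf == 0]
      if (length(add)) {
        da <- .cross_dist(pxa[add, , drop = FALSE], pa)
        db <- .cross_dist(pxb[add, , drop = FALSE], pb)
        m_new <- npairs + n
        sx <- tot[["sx"]] + rowSums(da)
        sy <- tot[["sy"]] + rowSums(db)
        sxx <- tot[["sxx"]] + rowSums(da^2)
        syy <- tot[["syy"]] + rowSums(db^2)
        sxy <- tot[["sxy"]] + rowSums(da * db)
        num <- sxy - sx * sy / m_new
        den <- sqrt(pmax(sxx - sx^2 / m_new, 0) * pmax(syy - sy^2 / m_new, 0))
        r_new <- ifelse(den > 0, num / den, NA_real_)
        nc_new <- ncorr5(n + 1, r_new)
        ok <- !is.na(r_new) & r_new >= config$r_min & nc_new > best_nc
        if (any(ok)) {
          k <- add[which(ok)[which.max(nc_new[ok])]]
          cur_a <- c(cur_a, pool_a[k])
          cur_b <- c(cur_b, pool_b[k])
          next
        }
      }

      if (repairs < repair_budget) {
        # swap: pool pair conflicts with exactly one member j; base sums =
        # totals minus member j's row
        sw <- which(nconf == 1)
        if (length(sw)) {
          j_of <- ifelse(!is.na(ia[sw]), ia[sw], ib[sw])
          for (j in unique(j_of)) {
            rows <- live[sw[j_of == j]]
            keep <- setdiff(seq_len(n), j)
            base <- c(sx = tot[["sx"]] - rs_x[j], sy = tot[["sy"]] - rs_y[j],
                      sxx = tot[["sxx"]] - rs_x2[j],
                      syy = tot[["syy"]] - rs_y2[j],
                      sxy = tot[["sxy"]] - rs_xy[j])
            da <- .cross_dist(pxa[rows, , drop = FALSE],
                              pa[keep, , drop = FALSE])
            db <- .cross_dist(pxb[rows, , drop = FALSE],
                              pb[keep, , drop = FALSE])
            m_new <- npairs - (n - 1) + (n - 1)
            sx <- base[["sx"]] + rowSums(da)
            sy <- base[["sy"]] + rowSums(db)
            sxx <- base[["sxx"]] + rowSums(da^2)
            syy <- base[["syy"]] + rowSums(db^2)
            sxy <- base[["sxy"]] + rowSums(da * db)
            num <- sxy - sx * sy / m_new
            den <- sqrt(pmax(sxx - sx^2 / m_new, 0) *
                          pmax(syy - sy^2 / m_new, 0))
            r_new <- ifelse(den > 0, num / den, NA_real_)
            nc_new <- ncorr5(n, r_new)
            ok <- !is.na(r_new) & r_new >= config$r_min & nc_new > best_nc
            if (any(ok)) {
              k <- which(ok)[which.max(nc_new[ok])]
              best_nc <- nc_new[k]
              action <- list(type = "swap", i = j, k = rows[k])
            }
          }
        }

        # transposition: pool pair p conflicts members i1 (a side) and i2
        # (b side); together with complement q = (a of i2, b of i1) it
        # replaces both members, keeping N
        tw <- which(nconf == 2)
        if (length(tw)) {
          rows <- live[tw]
          comp_key <- cur_a[ib[tw]] * 10000000 + cur_b[ia[tw]]
          comp <- match(comp_key, pool_key)
          for (s in which(!is.na(comp))) {
            p <- rows[s]
            q <- comp[s]
            i1 <- ia[tw[s]]
            i2 <- ib[tw[s]]
            keep <- setdiff(seq_len(n), c(i1, i2))
            base <- c(
              sx = tot[["sx"]] - rs_x[i1] - rs_x[i2] + DA[i1, i2],
              sy = tot[["sy"]] - rs_y[i1] - rs_y[i2] + DB[i1, i2],
              sxx = tot[["sxx"]] - rs_x2[i1] - rs_x2[i2] + DA[i1, i2]^2,
              syy = tot[["syy"]] - rs_y2[i1] - rs_y2[i2] + DB[i1, i2]^2,
              sxy = tot[["sxy"]] - rs_xy[i1] - rs_xy[i2] +
                DA[i1, i2] * DB[i1, i2]
            )
            dpa <- .cross_dist(pxa[p, , drop = FALSE], pa[keep, , drop = FALSE])
            dpb <- .cross_dist(pxb[p, , drop = FALSE], pb[keep, , drop = FALSE])
            dqa <- .cross_dist(pxa[q, , drop = FALSE], pa[keep, , drop = FALSE])
            dqb <- .cross_dist(pxb[q, , drop = FALSE], pb[keep, , drop = FALSE])
            dpq_a <- sqrt(sum((pxa[p, ] - pxa[q, ])^2))
            dpq_b <- sqrt(sum((pxb[p, ] - pxb[q, ])^2))
            xs <- c(dpa, dqa, dpq_a)
            ys <- c(dpb, dqb, dpq_b)
            m_new <- npairs # unchanged: removed 2n-3, added 2n-3
            s2 <- c(sx = base[["sx"]] + sum(xs), sy = base[["sy"]] + sum(ys),
                    sxx = base[["sxx"]] + sum(xs^2),
                    syy = base[["syy"]] + sum(ys^2),
                    sxy = base[["sxy"]] + sum(xs * ys))
            r2 <- r_of(s2, m_new)
            nc2 <- if (is.na(r2)) NA_real_ else ncorr5(n, r2)
            if (!is.na(r2) && r2 >= config$r_min && !is.na(nc2) &&
                nc2 > best_nc) {
              best_nc <- nc2
              action <- list(type = "transpose", i = c(i1, i2), k = c(p, q))
            }
          }
        }
      }
    }

    # removal, also only on stall (base sums minus one member's row)
    if (is.null(action) && n > config$min_pairs && is.finite(nc_cur) &&
        repairs < repair_budget) {
      m1 <- npairs - (n - 1)
      sx <- tot[["sx"]] - rs_x
      sy <- tot[["sy"]] - rs_y
      sxx <- tot[["sxx"]] - rs_x2
      syy <- tot[["syy"]] - rs_y2
      sxy <- tot[["sxy"]] - rs_xy
      num <- sxy - sx * sy / m1
      den <- sqrt(pmax(sxx - sx^2 / m1, 0) * pmax(syy - sy^2 / m1, 0))
      r1 <- ifelse(den > 0, num / den, NA_real_)
      nc1 <- ncorr5(n - 1, r1)
      i <- which.max(ifelse(is.na(nc1), -Inf, nc1))
      if (is.finite(nc1[i]) && nc1[i] > best_nc) {
        action <- list(type = "remove", i = i)
      }
    }

    if (is.null(action)) break
    repairs <- repairs + 1L
    if (action$type == "remove") {
      cur_a <- cur_a[-action$i]
      cur_b <- cur_b[-action$i]
    } else if (action$type == "swap") {
      cur_a <- c(cur_a[-action$i], pool_a[action$k])
      cur_b <- c(cur_b[-action$i], pool_b[action$k])
    } else {
      cur_a <- c(cur_a[-action$i], pool_a[action$k])
      cur_b <- c(cur_b[-action$i], pool_b[action$k])
    }
  }
  list(pairs = tibble::tibble(atom_id_a = cur_a, atom_id_b = cur_b),
       r = r_cur, ncorr5 = nc_cur)
}

.cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# seed groups for clustering: candidate-pair sets of each gated alignment,
# mapped onto candidate row indices; falls back to singleton seeds when no
# seed information is available
.seed_groups <- function(candidates, seeds) {
  if (is.null(seeds) || !nrow(seeds)) {
    return(as.list(seq_len(nrow(candidates))))
  }
  key <- paste(candidates$atom_id_a, candidates$atom_id_b)
  row_of <- match(paste(seeds$atom_id_a, seeds$atom_id_b), key)
  ok <- !is.na(row_of)
  gl <- split(row_of[ok], seeds$alignment[ok])
  gl <- unique(lapply(gl, function(g) sort(unique(g))))
  gl <- gl[lengths(gl) >= 2]
  if (!length(gl)) return(as.list(seq_len(nrow(candidates))))
  gl
}

.as_slam_result <- function(x, config, query = NA_character_,
                            target = NA_character_) {
  structure(
    x,
    config = config, query = query, target = target,
    class = c("slam_result", class(tibble::tibble()))
  )
}

#' Local 3D alignment of two substructures
#'
#' The full engine: build distance-sorted neighborhoods, align them
#' all-against-all, accumulate pair evidence, select recurrent candidate
#' pairs, cluster them under the interatomic-distance correlation
#' constraint, and rank the resulting 3D alignments by Ncorr5. Deterministic
#' for a fixed configuration; only interatomic distances are used, so the
#' result is invariant under rigid motion of either substructure.
#'
#' @param sub_a query substructure (e.g. a ligand cavity).
#' @param sub_b target substructure (cavity or surface patch).
#' @param config a [slam_config()].
#' @return a ranked `slam_result` tibble (possibly zero rows): `n_pairs`,
#'   `r`, `ncorr5`, `pairs` list-column.
#' @export
slam_align <- function(sub_a, sub_b, config = slam_config()) {
  sub_a <- .ensure_annotated(sub_a, config)
  sub_b <- .ensure_annotated(sub_b, config)
  tbl <- accumulate_pair_evidence(sub_a, sub_b, config)
  cand <- select_candidate_pairs(tbl, config)
  res <- cluster_pairs(cand, sub_a, sub_b, config)
  if (!nrow(res) && config$candidate_policy == "mean_sd" && nrow(tbl)) {
    # no core at the strict outlier cut: relax the separation stepwise
    for (c_try in c(1, 0.5)) {
      if (c_try >= config$c_sd) next
      cfg2 <- config
      cfg2$c_sd <- c_try
      cand <- select_candidate_pairs(tbl, cfg2)
      res <- cluster_pairs(cand, sub_a, sub_b, cfg2)
      if (nrow(res)) break
    }
  }
  # refine by hill climb from every clustered core plus the
  # highest-evidence alignment seed groups (multi-start: cores built from a
  # contaminated candidate cut can sit in a poor basin); duplicates are
  # collapsed and results re-ranked by Ncorr5
  starts <- res$pairs
  seeds_tbl <- attr(tbl, "seeds")
  if (!is.null(seeds_tbl) && nrow(seeds_tbl)) {
    ev_map <- stats::setNames(tbl$evidence,
                              paste(tbl$atom_id_a, tbl$atom_id_b))
    gl <- split(seeds_tbl[, c("atom_id_a", "atom_id_b")],
                seeds_tbl$alignment)
    gl <- unique(lapply(gl, unique))
    sc <- vapply(gl, function(g) {
      sum(ev_map[paste(g$atom_id_a, g$atom_id_b)], na.rm = TRUE)
    }, 1)
    starts <- c(starts, gl[order(-sc)][seq_len(min(10, length(gl)))])
  }
  if (length(starts)) {
    # refine sequentially; a start already contained in a refined cluster
    # would converge to the same optimum and is skipped
    ext <- list()
    refined_keys <- list()
    for (st in starts) {
      stk <- paste(st$atom_id_a, st$atom_id_b)
      contained <- any(vapply(refined_keys,
                              function(k) all(stk %in% k), TRUE))
      if (length(refined_keys) && contained) next
      e <- .refine_cluster(st, tbl = tbl, atoms_a = sub_a, atoms_b = sub_b,
                           config = config)
      ext[[length(ext) + 1]] <- e
      refined_keys[[length(refined_keys) + 1]] <-
        paste(e$pairs$atom_id_a, e$pairs$atom_id_b)
    }
    ok <- vapply(ext, function(e) {
      is.finite(e$ncorr5) && nrow(e$pairs) >= config$min_pairs &&
        !is.na(e$r) && e$r >= config$r_min
    }, TRUE)
    ext <- ext[ok]
    keys <- vapply(ext, function(e) {
      p <- e$pairs[order(e$pairs$atom_id_a), ]
      paste(p$atom_id_a, p$atom_id_b, collapse = ";")
    }, character(1))
    ext <- ext[!duplicated(keys)]
    res <- dplyr::bind_rows(lapply(ext, function(e) {
      tibble::tibble(n_pairs = nrow(e$pairs), r = e$r, ncorr5 = e$ncorr5,
                     pairs = list(e$pairs))
    }))
    if (nrow(res)) {
      res <- res[order(-res$ncorr5,
                       vapply(res$pairs, function(p) min(p$atom_id_a), 1)), ]
    } else {
      res <- tibble::tibble(n_pairs = integer(), r = numeric(),
                            ncorr5 = numeric(), pairs = list())
    }
    res <- .as_slam_result(res, config)
  }
  attr(res, "query") <- attr(sub_a, "source") %||% attr(sub_a, "structure_id") %||% "A"
  attr(res, "target") <- attr(sub_b, "source") %||% attr(sub_b, "structure_id") %||% "B"
  res
}

#' @export
print.slam_result <- function(x, ...) {
  cat("<slam_result> ", attr(x, "query"), " vs ", attr(x, "target"),
      ": ", nrow(x), " alignment(s)\n", sep = "")
  NextMethod()
}
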