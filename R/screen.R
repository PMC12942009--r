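# Batch screening: one query substructure against many target structures,
# with per-target fault tolerance, optional docking of the probe ligand, and
# an audit trail (the resolved configuration is embedded in every output).

#' Screen a query cavity against target structures
#'
#' Runs the full engine for the query substructure against each target:
#' cavity/patch alignment, Ncorr5 ranking, and (optionally) Kabsch transfer
#' of the probe ligand plus local pose optimization and FE-score. Failures
#' on individual targets are recorded and do not abort the batch; target
#' order in equals row order out, so reruns are deterministic.
#'
#' @param query query substructure (e.g. from [extract_ligand_cavity()]),
#'   annotated automatically.
#' @param targets a named list of target substructures/structures, or a
#'   character vector of PDB file paths.
#' @param config a [slam_config()].
#' @param probe_ligand optional tibble of probe ligand heavy atoms; when
#'   given, the best alignment per target is docked and FE-scores reported.
#' @param query_structure structure the query cavity came from (needed for
#'   ligand transfer; defaults to `query`).
#' @return tibble of class `slam_screen`: one row per target with
#'   `target_id`, `status`, `n_pairs`, `r`, `ncorr5`, `pairs` list-column,
#'   and when docking ran: `fe`, `shift`, `fe_score`, `is_tp`.
#' @export
run_screen <- function(query, targets, config = slam_config(),
                       probe_ligand = NULL, query_structure = query) {
  if (is.character(targets)) {
    paths <- targets
    nm <- if (!is.null(names(targets))) names(targets) else
      sub("\\.(pdb|ent|cif)$", "", basename(paths), ignore.case = TRUE)
    targets <- lapply(paths, function(p) {
      tryCatch(read_structure(p), error = function(e) e)
    })
    names(targets) <- nm
  }
  if (is.null(names(targets))) {
    names(targets) <- paste0("target", seq_along(targets))
  }
  query <- .ensure_annotated(query, config)

  rows <- purrr::imap(targets, function(tgt, id) {
    base <- tibble::tibble(
      target_id = id, status = "ok", n_pairs = 0L,
      r = NA_real_, ncorr5 = NA_real_, pairs = list(tibble::tibble())
    )
    if (inherits(tgt, "error")) {
      base$status <- paste0("error: ", conditionMessage(tgt))
      return(base)
    }
    out <- tryCatch({
      res <- slam_align(query, tgt, config)
      if (nrow(res)) {
        base$n_pairs <- res$n_pairs[1]
        base$r <- res$r[1]
        base$ncorr5 <- res$ncorr5[1]
        base$pairs <- res$pairs[1]
      } else {
        base$status <- "no alignment"
      }
      if (!is.null(probe_ligand) && nrow(res)) {
        pose0 <- transfer_ligand(query_structure, probe_ligand,
                                 res$pairs[[1]], tgt)
        dock <- optimize_pose(tgt, pose0, engine = config$engine,
                              shift_mode = config$shift_mode)
        base$fe <- dock$fe
        base$shift <- dock$shift
        base$fe_score <- dock$fe_score
        base$is_tp <- dock$is_tp
      }
      base
    }, error = function(e) {
      base$status <- paste0("error: ", conditionMessage(e))
      base
    })
    out
  })
  res <- dplyr::bind_rows(rows)
  structure(res,
    config = config,
    query = attr(query, "source") %||% attr(query, "structure_id"),
    class = c("slam_screen", class(tibble::tibble()))
  )
}

#' Write screen results as TSV with embedded configuration
#'
#' The resolved configuration is written as `#cfg` comment lines ahead of
#' the header, so every result file carries its full provenance. Matched
#' pair lists are serialized as `idA:idB;...`.
#'
#' @param results a `slam_screen` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_screen_results <- function(results, path) {
  cfg <- attr(results, "config")
  flat <- tibble::as_tibble(results)
  flat$pairs <- vapply(flat$pairs, function(p) {
    if (!nrow(p)) "" else paste(p$atom_id_a, p$atom_id_b, sep = ":",
                                collapse = ";")
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#cfg %s=%s", names(cfg),
                     vapply(cfg, as.character, character(1))), con)
  writeLines(sprintf("#query %s", attr(results, "query")), con)
  utils::write.table(flat, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read screen results written by [write_screen_results()]
#'
#' @param path TSV path.
#' @return tibble with the `config` attribute restored (as strings).
#' @export
read_screen_results <- function(path) {
  lines <- readLines(path)
  cfg_lines <- grep("^#cfg ", lines, value = TRUE)
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.table(text = body, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  df <- tibble::as_tibble(df)
  kv <- sub("^#cfg ", "", cfg_lines)
  cfg <- stats::setNames(
    sub("^[^=]*=", "", kv),
    sub("=.*$", "", kv)
  )
  attr(df, "config") <- as.list(cfg)
  df
}
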