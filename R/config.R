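# Configuration surface: one flat list of tunables with schema validation,
# YAML round-trip, and the defaults used across the pipeline.

.config_schema <- list(
  k = "numeric", tolerance = "numeric",
  gap_open = "numeric", gap_extend = "numeric", chem_weight = "numeric",
  gate_frac = "numeric",
  candidate_policy = "character", c_sd = "numeric", quantile = "numeric",
  fixed_evidence = "numeric",
  r_min = "numeric", min_pairs = "numeric", pair_merge_rel_tol = "numeric",
  ncorr5_min = "numeric", ncorr5_stringent = "numeric",
  ncorr5_surface = "numeric",
  cavity_radius = "numeric", cavity_min_atoms = "numeric",
  sasa_probe = "numeric", sasa_n_points = "numeric", sasa_min = "numeric",
  fe_threshold = "numeric", shift_mode = "character",
  engine = "character", seed = "numeric"
)

#' Pipeline configuration
#'
#' All tunable parameters of the pipeline in one validated list. Defaults
#' follow the canonical setup: 7-atom neighborhoods, correlation threshold
#' 0.85 for cluster merging, 7 Angstrom residue shells with a 40-atom cavity
#' minimum, 2 square-Angstrom surface-exposure cut, significance thresholds
#' 25 (significant), 30 (stringent) and 35 (surface screens) on Ncorr5, and
#' a free-energy score cutoff of -1.5.
#'
#' @param ... named overrides of any default (unknown names raise an error).
#' @return a named list of class `slam_config`.
#' @export
slam_config <- function(...) {
  cfg <- list(
    k = 7L,
    tolerance = 0,
    gap_open = -4,
    gap_extend = -1,
    chem_weight = 1,
    gate_frac = 0.85,
    candidate_policy = "mean_sd",
    c_sd = 2,
    quantile = 0.99,
    fixed_evidence = 0,
    r_min = 0.85,
    min_pairs = 4L,
    pair_merge_rel_tol = 1,
    ncorr5_min = 25,
    ncorr5_stringent = 30,
    ncorr5_surface = 35,
    cavity_radius = 7,
    cavity_min_atoms = 40L,
    sasa_probe = 1.4,
    sasa_n_points = 960L,
    sasa_min = 2,
    fe_threshold = -1.5,
    shift_mode = "rmsd",
    engine = "stub",
    seed = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == "")) {
      stop("unknown config field(s): ", paste(bad, collapse = ", "))
    }
    cfg[names(dots)] <- dots
  }
  validate_config(cfg)
}

#' @rdname slam_config
#' @param cfg a config list to validate.
#' @export
validate_config <- function(cfg) {
  for (nm in names(.config_schema)) {
    if (is.null(cfg[[nm]])) stop("config field missing: ", nm)
    ok <- switch(.config_schema[[nm]],
      numeric = is.numeric(cfg[[nm]]),
      character = is.character(cfg[[nm]])
    )
    if (!ok || length(cfg[[nm]]) != 1) {
      stop("config field '", nm, "' must be a scalar ", .config_schema[[nm]])
    }
  }
  if (cfg$k < 2) stop("config field 'k': neighborhood size must be >= 2")
  if (cfg$gap_open > 0 || cfg$gap_extend > 0) {
    stop("gap penalties must be <= 0")
  }
  if (cfg$r_min <= 0 || cfg$r_min > 1) stop("r_min must be in (0, 1]")
  if (!cfg$candidate_policy %in% c("mean_sd", "quantile", "fixed")) {
    stop("candidate_policy must be mean_sd, quantile or fixed")
  }
  if (!cfg$shift_mode %in% c("rmsd", "centroid")) {
    stop("shift_mode must be rmsd or centroid")
  }
  if (!cfg$engine %in% c("stub", "vina")) stop("engine must be stub or vina")
  structure(cfg, class = "slam_config")
}

#' @rdname slam_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  validate_config(utils::modifyList(unclass(slam_config()),
                                    yaml::read_yaml(path)))
}

#' @rdname slam_config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(validate_config(cfg)), path)
  invisible(path)
}

#' @export
print.slam_config <- function(x, ...) {
  cat("<slam_config>\n")
  for (nm in names(x)) cat("  ", nm, ": ", x[[nm]], "\n", sep = "")
  invisible(x)
}

submodel_from_config <- function(cfg) {
  substitution_model(
    gap_open = cfg$gap_open, gap_extend = cfg$gap_extend,
    chem_weight = cfg$chem_weight
  )
}
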