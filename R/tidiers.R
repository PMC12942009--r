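# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a set of 3D alignments
#'
#' One row per matched atom pair, with the parent alignment's rank, `r` and
#' `ncorr5` carried along.
#'
#' @param x a `slam_result`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.slam_result <- function(x, ...) {
  if (!nrow(x)) {
    return(tibble::tibble(alignment = integer(), atom_id_a = integer(),
                          atom_id_b = integer(), n_pairs = integer(),
                          r = numeric(), ncorr5 = numeric()))
  }
  out <- tibble::as_tibble(x)
  out$alignment <- seq_len(nrow(out))
  out <- tidyr::unnest(out[, c("alignment", "n_pairs", "r", "ncorr5", "pairs")],
                       "pairs")
  out[, c("alignment", "atom_id_a", "atom_id_b", "n_pairs", "r", "ncorr5")]
}

#' @rdname tidy.slam_result
#' @export
glance.slam_result <- function(x, ...) {
  tibble::tibble(
    n_alignments = nrow(x),
    best_n_pairs = if (nrow(x)) x$n_pairs[1] else NA_integer_,
    best_r = if (nrow(x)) x$r[1] else NA_real_,
    best_ncorr5 = if (nrow(x)) x$ncorr5[1] else NA_real_,
    query = attr(x, "query"),
    target = attr(x, "target")
  )
}

#' @rdname tidy.gumbel_fit
#' @export
tidy.gumbel_fit <- function(x, ...) {
  tibble::tibble(
    term = c("mu", "beta"),
    estimate = c(x$mu, x$beta)
  )
}

#' Tidy/glance a Gumbel fit
#'
#' @param x a `gumbel_fit`.
#' @param ... unused.
#' @return a tibble.
#' @export
glance.gumbel_fit <- function(x, ...) {
  tibble::tibble(mu = x$mu, beta = x$beta, n = x$n, method = x$method)
}

#' @rdname tidy.slam_eval
#' @export
tidy.slam_eval <- function(x, ...) x$roc

#' Tidy/glance a screen evaluation
#'
#' `tidy()` returns the ROC points; `glance()` the one-row summary with AUC.
#'
#' @param x a `slam_eval`.
#' @param ... unused.
#' @return a tibble.
#' @export
glance.slam_eval <- function(x, ...) {
  dplyr::mutate(x$summary, auc = x$auc,
                score_threshold = x$score_threshold,
                fe_threshold = x$fe_threshold)
}

#' Plot matched-pair distance agreement of a 3D alignment
#'
#' Scatter of interatomic distances within the query vs within the target
#' over the matched pairs of the top (or chosen) alignment; points on the
#' diagonal indicate a geometrically consistent superimposition.
#'
#' @param object a `slam_result` with at least one alignment; the atom
#'   tables used to build it must be supplied.
#' @param atoms_a,atoms_b annotated atom tables of query and target.
#' @param rank which alignment to plot (default 1, the best).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.slam_result <- function(object, atoms_a, atoms_b, rank = 1, ...) {
  stopifnot(nrow(object) >= rank)
  pr <- object$pairs[[rank]]
  da <- as.numeric(stats::dist(.pair_coords(pr$atom_id_a, atoms_a)))
  db <- as.numeric(stats::dist(.pair_coords(pr$atom_id_b, atoms_b)))
  df <- tibble::tibble(query = da, target = db)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$query, y = .data$target)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = "interatomic distance in query (Å)",
      y = "interatomic distance in target (Å)",
      title = sprintf("alignment %d: N = %d, r = %.3f, Ncorr5 = %.2f",
                      rank, object$n_pairs[rank], object$r[rank],
                      object$ncorr5[rank])
    )
}

#' Plot the double-log score curve with Gumbel reference
#'
#' @param scores numeric score vector (e.g. best Ncorr5 per target).
#' @param threshold optional vertical line (e.g. a detected knee).
#' @return a ggplot object.
#' @export
plot_double_log <- function(scores, threshold = NULL) {
  curve <- double_log_curve(scores)
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$score, y = .data$y)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.5) +
    ggplot2::geom_smooth(
      data = curve[curve$score <= stats::quantile(curve$score, 0.9), ],
      method = "lm", formula = y ~ x, se = FALSE, colour = "steelblue",
      fullrange = TRUE, linewidth = 0.5
    ) +
    ggplot2::labs(x = "score", y = "log(-log F)",
                  title = "empirical score distribution vs Gumbel line")
  if (!is.null(threshold) && is.finite(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold, linetype = 2,
                                 colour = "firebrick")
  }
  p
}

#' ROC curve of a screen evaluation
#'
#' @param object a `slam_eval`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.slam_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false-positive rate", y = "true-positive rate",
      title = sprintf("ROC (AUC = %.3f)", object$auc)
    )
}
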