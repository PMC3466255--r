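# ggplot2 displays for the pipeline's result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Energy trace of a DMD trajectory
#'
#' @param object a `qmdmd_trajectory`.
#' @param ... unused.
#' @return a ggplot: potential and kinetic energy vs DMD time.
#' @export
autoplot.qmdmd_trajectory <- function(object, ...) {
  df <- tidyr::pivot_longer(object$frames,
                            c("potential_energy", "kinetic_energy"),
                            names_to = "component", values_to = "energy")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$energy,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (t.u.)", y = "energy (kcal/mol)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Convergence traces of a QM/DMD run
#'
#' Backbone RMSD, active-site all-atom RMSD and subset QM energy per
#' iteration, the standard convergence display for the iterative protocol.
#'
#' @param object a `qmdmd_run`.
#' @param ... unused.
#' @return a ggplot faceted by quantity.
#' @export
autoplot.qmdmd_run <- function(object, ...) {
  cv <- object$convergence
  keep <- c("backbone_rmsd", "site_rmsd", "qm_energy",
            if (!all(is.na(cv$gt_rmsd))) "gt_rmsd")
  df <- tidyr::pivot_longer(cv[, c("iteration", keep)], -"iteration",
                            names_to = "quantity", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL) +
    ggplot2::theme_minimal()
}

#' Ensemble reaction energetics
#'
#' @param object a `reaction_profile`.
#' @param ... unused.
#' @return a ggplot: per-member ZPE-corrected barrier and reaction energy.
#' @export
autoplot.reaction_profile <- function(object, ...) {
  df <- tidyr::pivot_longer(object$members[, c("member", "dE_ts", "dE_rxn")],
                            -"member", names_to = "quantity", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$member), y = .data$value,
                                   fill = .data$quantity)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "ensemble member", y = "energy vs reactant (kcal/mol)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
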