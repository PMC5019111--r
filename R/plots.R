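# ggplot2 views of the main result types.

#' Plot the per-position variant diversity profile
#'
#' @param profile Output of [site_diversity_profile()].
#' @return A ggplot.
#' @export
plot_site_diversity <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$rel_pos, y = .data$frac)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~kind, scales = "free_x") +
    ggplot2::labs(x = "position relative to intron boundary (no 0)",
                  y = "fraction of sites with a variant") +
    ggplot2::theme_minimal()
}

#' Plot the calibration sweep
#'
#' Chi-square statistic of HMM-vs-PWM class agreement across the neutral
#' threshold grid, with the best threshold marked.
#'
#' @param x A `splice_calibration`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot splice_calibration
#' @export
autoplot.splice_calibration <- function(x, ...) {
  ggplot2::ggplot(x$cells, ggplot2::aes(x = .data$tau,
                                        y = .data$chisq_stat)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = x$best_tau, linetype = 2) +
    ggplot2::labs(x = "neutral threshold tau",
                  y = "chi-square statistic",
                  title = sprintf("%s sites: best tau = %g", x$site_kind,
                                  x$best_tau)) +
    ggplot2::theme_minimal()
}

#' Plot DAF distributions by effect class
#'
#' @param daf_summary Output of [summarize_class_daf()].
#' @return A ggplot.
#' @export
plot_daf_by_class <- function(daf_summary) {
  ggplot2::ggplot(daf_summary$bins,
                  ggplot2::aes(x = .data$bin, y = .data$prop)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~effect_class) +
    ggplot2::labs(x = "derived allele frequency bin", y = "proportion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot the PSI response to accumulated score-delta alleles
#'
#' @param psi_tbl Tibble with `net_dosage` and a `psi` column (e.g. from
#'   [sim_psi_fixture()] after [compute_psi()]).
#' @return A ggplot.
#' @export
plot_psi_response <- function(psi_tbl) {
  ggplot2::ggplot(psi_tbl, ggplot2::aes(x = factor(.data$net_dosage),
                                        y = .data$psi)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "net dosage of positive-effect alleles",
                  y = "PSI") +
    ggplot2::theme_minimal()
}
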