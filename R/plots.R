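#' Plot a production-rate sweep
#'
#' Faceted view of the model predictions along the formate production
#' grid: adenine nucleotide pools, formate, fluxes and proliferation, one
#' line per scenario when several sweeps are bound together.
#'
#' @param sweep One or more row-bound [sweep_production()] results.
#' @param quantities Columns to facet over.
#' @return A ggplot object.
#' @export
#' @examples
#' grid <- seq(0, 0.6, length.out = 25)
#' sw <- dplyr::bind_rows(
#'   sweep_production(kinetic_params(), grid, "baseline_0.02mM"),
#'   sweep_production(kinetic_params(), grid, "formate_1mM")
#' )
#' plot_sweep(sw)
plot_sweep <- function(sweep, quantities = c("F", "ATP", "ADP", "AMP",
                                             "v_tr", "v_pur", "v_gly", "mu")) {
  long <- tidyr::pivot_longer(sweep, dplyr::all_of(quantities),
                              names_to = "quantity", values_to = "value")
  long$quantity <- factor(long$quantity, levels = quantities)
  ggplot2::ggplot(long, ggplot2::aes(.data$v_ser, .data$value,
                                     colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$quantity), scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(
      baseline_0.02mM = "black", formate_1mM = "#b2182b",
      cytosolic = "#2166ac"
    )) +
    ggplot2::labs(x = "serine-to-formate production rate (mM/h)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a formate titration
#'
#' Metabolite readouts of [gen_titration_metabolomics()] against the
#' supplemented formate concentration (log2 x-axis, matching the twofold
#' dilution design).
#'
#' @param sim A [gen_titration_metabolomics()] result.
#' @return A ggplot object.
#' @export
plot_titration <- function(sim) {
  long <- tidyr::pivot_longer(sim$table, -"feature",
                              names_to = "column", values_to = "value")
  info <- .split_omics_columns(unique(long$column))
  long <- dplyr::left_join(long, info, by = "column")
  long$F_ext <- as.numeric(sub("^F", "", long$condition))
  ggplot2::ggplot(long, ggplot2::aes(.data$F_ext, .data$value)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::facet_wrap(ggplot2::vars(.data$feature), scales = "free_y") +
    ggplot2::labs(x = "supplemented formate (mM)", y = "level (a.u.)") +
    ggplot2::theme_minimal()
}

#' Volcano-style plot of index associations
#'
#' Estimates versus permutation p-values from [oc_associations()].
#'
#' @param assoc An [oc_associations()] result.
#' @param alpha Significance level drawn as a reference line.
#' @return A ggplot object.
#' @export
plot_associations <- function(assoc, alpha = 0.05) {
  ggplot2::ggplot(assoc, ggplot2::aes(.data$estimate,
                                      -log10(.data$p_value))) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::labs(x = "statistic (log2 units per index step)",
                  y = "-log10 permutation p") +
    ggplot2::theme_minimal()
}
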