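# ggplot2 graphics for the result types.

#' Plot a ranked REG table as a diverging bar chart
#'
#' @param object A `reg_table`.
#' @param top_k Entries shown per side.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot reg_table
#' @export
autoplot.reg_table <- function(object, top_k = 5, ...) {
  sel <- rank_and_filter(object, top_k = top_k)
  sel$term <- factor(sel$term, levels = sel$term[order(sel$reg)])
  ggplot2::ggplot(sel, ggplot2::aes(x = .data$reg, y = .data$term,
                                    fill = .data$reg > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac",
                                          `FALSE` = "#b2182b")) +
    ggplot2::labs(x = "REG value (dimensionless)", y = NULL,
                  title = attr(object, "system") %||% NULL,
                  subtitle = sprintf("M = %s points, R² ≥ %s",
                                     attr(object, "m_points"),
                                     attr(object, "r2_threshold"))) +
    ggplot2::theme_minimal()
}

#' Plot the total-energy profile along the control coordinate
#'
#' @param object An `energy_profile`.
#' @param unit `"hartree"` or `"kJ/mol"` (relative to the last point).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot energy_profile
#' @export
autoplot.energy_profile <- function(object, unit = c("hartree", "kJ/mol"),
                                    ...) {
  unit <- match.arg(unit)
  tot <- total_energy(object)
  if (unit == "kJ/mol") {
    tot$e_tot <- hartree_to_kjmol(tot$e_tot - tot$e_tot[nrow(tot)])
  }
  ggplot2::ggplot(tot, ggplot2::aes(x = .data$s, y = .data$e_tot)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "control coordinate s",
                  y = paste0("E_tot (", unit, ")"),
                  title = attr(object, "system") %||% NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
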