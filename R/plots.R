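# ggplot2 views of the main result types.

#' Heat-map of SCRIT vectors
#'
#' One row per compound replicate, one column per vector component in
#' canonical order, diverging fill over the \[-1, 1\] response scale --
#' the compact fingerprint view of the differential screen.
#'
#' @param object a `scrit_tbl`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot scrit_tbl
#' @export
autoplot.scrit_tbl <- function(object, ...) {
  im <- scrit_index_map(object)
  long <- tidyr::pivot_longer(as_tibble(object), cols = all_of(im$component),
                              names_to = "component", values_to = "value")
  long$component <- factor(long$component, levels = im$component)
  long$item <- paste(long$compound, long$replicate, sep = ":")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$component, y = .data$item,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1),
                                  name = "response") +
    ggplot2::labs(x = "component (parameter | medium | dose)",
                  y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' MDS map of a classification
#'
#' Items in the first two MDS dimensions, colored by assigned group.
#'
#' @param object a `scrit_classification`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot scrit_classification
#' @export
autoplot.scrit_classification <- function(object, ...) {
  df <- left_join(object$mds, object$groups, by = "item")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mds1, y = .data$mds2,
                                   color = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "MDS 1", y = "MDS 2", color = "group") +
    ggplot2::theme_minimal()
}

#' Dose-response profiles of one or more compounds
#'
#' Signed KS (or rescaled viability) against dose on a log axis, one panel
#' per parameter, line type by growth medium.
#'
#' @param well_stats output of [well_statistics()] /
#'   [simulate_screen()].
#' @param compounds compounds to show (default: all test compounds).
#' @param parameters parameters to panel.
#' @return a ggplot.
#' @export
plot_dose_response <- function(well_stats,
                               compounds = NULL,
                               parameters = c("tmrm_peripheral_integral",
                                              "viability")) {
  ws <- well_stats[well_stats$role == "test" & !well_stats$excluded, ]
  if (!is.null(compounds)) ws <- ws[ws$compound %in% compounds, ]
  long <- bind_rows(lapply(parameters, function(p) {
    col <- if (p == "viability") "viability_rescaled" else paste0("ks_", p)
    tibble(compound = ws$compound, condition = ws$condition,
           dose = ws$dose, parameter = p, value = ws[[col]])
  }))
  long <- long %>%
    group_by(.data$compound, .data$condition, .data$dose, .data$parameter) %>%
    summarise(value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$dose, y = .data$value,
                                     color = .data$compound,
                                     linetype = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~parameter) +
    ggplot2::labs(x = "dose (uM)", y = "response (signed KS / rescaled viability)") +
    ggplot2::theme_minimal()
}
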