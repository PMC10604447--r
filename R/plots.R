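#' Plot month-level activity composition
#'
#' Stacked proportions of activity statuses per month, one panel per
#' molecule type.
#'
#' @param month_calls Output of [aggregate_by_month()].
#' @return A ggplot object.
#' @export
plot_activity_months <- function(month_calls) {
  check_columns(month_calls, c("votu_id", "month", "molecule", "status"),
                "month_calls")
  levels <- c("absent", "present-inactive", "detected", "active",
              "active-lytic")
  df <- month_calls |>
    mutate(status = factor(.data$status, levels = levels),
           month = factor(.data$month, levels = unique(.data$month)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$month, fill = .data$status)) +
    ggplot2::geom_bar(position = "fill") +
    ggplot2::facet_wrap(ggplot2::vars(.data$molecule)) +
    ggplot2::scale_fill_manual(values = c(
      "absent" = "grey30", "present-inactive" = "grey75",
      "detected" = "#74add1", "active" = "#f46d43",
      "active-lytic" = "#a50026"), drop = TRUE) +
    ggplot2::labs(x = NULL, y = "proportion of vOTUs", fill = "status") +
    ggplot2::theme_minimal()
}

#' Plot z-score activity profiles by host ecological strategy
#'
#' One line per vOTU across months, faceted by host strategy; the classic
#' view of seasonal activity cohorts.
#'
#' @param zscores Output of [zscore_profiles()].
#' @param months Optional month ordering.
#' @return A ggplot object.
#' @export
plot_zscore_profiles <- function(zscores, months = NULL) {
  check_columns(zscores, c("votu_id", "month", "z", "strategy"), "zscores")
  df <- zscores
  if (!is.null(months)) df$month <- factor(df$month, levels = months)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$month, y = .data$z,
                                   group = .data$votu_id)) +
    ggplot2::geom_line(alpha = 0.4, colour = "#00441b") +
    ggplot2::facet_wrap(ggplot2::vars(.data$strategy)) +
    ggplot2::labs(x = NULL, y = "z-score of mean RPKM") +
    ggplot2::theme_minimal()
}

#' Autoplot methods for soilvirome results
#' @param object Result object.
#' @param ... Passed to the underlying plot function.
#' @return A ggplot object.
#' @method autoplot virome_zscores
#' @export
autoplot.virome_zscores <- function(object, ...) {
  plot_zscore_profiles(object, ...)
}

#' @rdname autoplot.virome_zscores
#' @method autoplot virome_diffact
#' @export
autoplot.virome_diffact <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$eta_squared,
                                   y = -log10(pmax(.data$q_value, 1e-16)),
                                   colour = .data$seasonal)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = attr(object, "effect_min"),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "q_max")),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#d73027",
                                            `FALSE` = "grey55")) +
    ggplot2::labs(x = expression(eta^2), y = expression(-log[10](q)),
                  colour = "seasonal") +
    ggplot2::theme_minimal()
}
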