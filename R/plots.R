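# ggplot2 displays for the main result types.

#' Plot a carboxyform percentage profile
#'
#' Grouped bars of the percentage of each carboxyform (k carboxyl groups)
#' per sample, faceted by peptide family — the per-family carboxyform
#' distribution view used to compare supernatant and purified material.
#'
#' @param object A [carboxyform_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot carboxyform_profile
#' @export
autoplot.carboxyform_profile <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = factor(.data$k), y = .data$pct, fill = .data$sample)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~family) +
    ggplot2::labs(
      x = "carboxyl count k", y = "% of family intensity", fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a protein differential-abundance fit
#'
#' @param object A [protein_diff()] object.
#' @param ... Unused.
#' @return A ggplot object: log2 fold change vs -log10 adjusted p, with the
#'   significance threshold drawn.
#' @method autoplot protein_diff
#' @export
autoplot.protein_diff <- function(object, ...) {
  d <- tidy(object) %>% filter(is.finite(.data$log2fc))
  ggplot2::ggplot(
    d,
    ggplot2::aes(x = .data$log2fc, y = .data$neg_log10_p_adj,
                 colour = .data$significant)
  ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(object$alpha), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "red3")) +
    ggplot2::labs(
      x = bquote(log[2] ~ "fold change (" * .(object$groups[1]) ~ "vs" ~
                   .(object$groups[2]) * ")"),
      y = bquote(-log[10] ~ "adjusted" ~ italic(P))
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of a variant time-course matrix
#'
#' White-to-black tile display of per-variant abundance across samples,
#' the supernatant time-course view.
#'
#' @param series Long tibble with `variant` (or `family`), `sample` and a
#'   value column, as fed to [timecourse_matrix()].
#' @param value Value column name (default `"relative_abundance"`).
#' @param log10 Log10-transform for display (default `FALSE`)?
#' @return A ggplot object.
#' @export
plot_timecourse_heatmap <- function(series, value = "relative_abundance",
                                    log10 = FALSE) {
  key <- if ("variant" %in% names(series)) "variant" else "family"
  vals <- series[[value]]
  if (log10) vals <- log10(vals)
  d <- series %>% mutate(.value = vals)
  ggplot2::ggplot(
    d,
    ggplot2::aes(x = .data$sample, y = .data[[key]], fill = .data$.value)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "black",
                                 na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = value) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
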