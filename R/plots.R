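#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest plot of bootstrap marker effects
#'
#' Markers on the y-axis ordered by point estimate, log-odds on the x-axis
#' with the bootstrap confidence interval; bars that do not cross zero
#' (filled) are significantly predictive of one state over the other.
#'
#' @param object a `marker_effects` table.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.marker_effects <- function(object, ...) {
  df <- effects_table(object)
  df$marker <- factor(df$marker, levels = df$marker)
  ctr <- attr(object, "contrast")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$marker)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.25) +
    ggplot2::geom_point(ggplot2::aes(fill = .data$significant),
                        shape = 21, size = 2.5) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "black",
                                          `FALSE` = "white"),
                               guide = "none") +
    ggplot2::labs(
      x = sprintf("log-odds (%s ← 0 → %s)", ctr[1], ctr[2]),
      y = NULL,
      title = sprintf("Marker effects: %s vs %s", ctr[1], ctr[2])) +
    ggplot2::theme_minimal()
}

#' Scatter plot of LDA projections
#'
#' One point per donor-sample on the first two discriminant axes (or the
#' single axis against zero for two-group fits), coloured by group.
#'
#' @param object a `cyto_lda`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.cyto_lda <- function(object, ...) {
  pr <- object$projections
  if (!"LD2" %in% names(pr)) pr$LD2 <- 0
  ggplot2::ggplot(pr, ggplot2::aes(x = .data$LD1, y = .data$LD2,
                                   colour = .data$group)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(title = "Linear discriminant projections") +
    ggplot2::theme_minimal()
}

#' Per-group boxplots of gated frequencies
#'
#' @param freq a `frequency_tbl`.
#' @param design a `study_design` supplying group labels.
#' @return A ggplot, facetted by population.
#' @export
plot_frequencies <- function(freq, design) {
  df <- tibble::as_tibble(freq)
  df$group <- design$group[match(df$donor, design$donor)]
  df <- df[!df$empty_denominator & !is.na(df$group), ]
  df$group <- factor(df$group,
                     levels = c("control", "pregnant", "postpartum"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$percent)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::facet_wrap(~ .data$population) +
    ggplot2::labs(x = NULL,
                  y = sprintf("%% %s cells", df$combination[1])) +
    ggplot2::theme_minimal()
}
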