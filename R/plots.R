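#' @importFrom ggplot2 ggplot aes geom_col geom_step geom_point geom_tile
#'   facet_wrap labs scale_size_area theme_minimal autoplot
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Stacked program-composition bars per sample and timepoint
#'
#' @param comp A [program_composition()] tibble.
#' @return A ggplot.
#' @export
plot_composition <- function(comp) {
  ggplot(comp, aes(x = .data$timepoint, y = .data$pct,
                   fill = .data$program)) +
    geom_col() +
    facet_wrap(~ .data$patient, nrow = 1) +
    labs(x = NULL, y = "% of AML cells", fill = "program") +
    theme_minimal()
}

#' Kaplan-Meier curves for a survival fit
#'
#' @param object A `survival_fit` from [km_logrank()].
#' @param ... Unused.
#' @return A ggplot of right-continuous survival steps per group, annotated
#'   with the log-rank p-value.
#' @method autoplot survival_fit
#' @export
autoplot.survival_fit <- function(object, ...) {
  tb <- km_table(object)
  tb0 <- tb |>
    group_by(.data$group) |>
    summarise(time = 0, surv = 1, .groups = "drop")
  dat <- dplyr::bind_rows(tb0, tb |> select("group", "time", "surv"))
  ggplot(dat, aes(x = .data$time, y = .data$surv, colour = .data$group)) +
    geom_step() +
    labs(x = "time", y = "survival",
         subtitle = sprintf("log-rank p = %.3g", object$logrank_p)) +
    theme_minimal()
}

#' Bubble plot of scored receptor-ligand interactions
#'
#' Bubble area tracks the product of the two populations' expression
#' fractions; colour tracks the summed fold change, mirroring the usual
#' interaction-panel semantics.
#'
#' @param scored A [score_interactions()] tibble.
#' @param top_n Pairs to show (default 20, retained pairs first).
#' @return A ggplot.
#' @export
plot_interactions <- function(scored, top_n = 20) {
  df <- head(scored, top_n) |>
    mutate(pair = paste0(.data$aml_partner, " → ",
                         .data$tcell_partner))
  ggplot(df, aes(x = .data$orientation, y = .data$pair,
                 size = .data$frac_aml * .data$frac_tcell,
                 colour = .data$lfc_aml + .data$lfc_tcell)) +
    geom_point() +
    scale_size_area(max_size = 8) +
    labs(x = NULL, y = NULL, size = "fraction product",
         colour = "summed log2FC") +
    theme_minimal()
}

#' Heatmap of program abundance across bulk samples
#'
#' @param ab An abundance matrix (programs x samples).
#' @return A ggplot tile heatmap of z-scores.
#' @export
plot_abundance <- function(ab) {
  df <- as_tibble(ab, rownames = "program") |>
    tidyr::pivot_longer(-"program", names_to = "sample",
                        values_to = "abundance")
  ggplot(df, aes(x = .data$sample, y = .data$program,
                 fill = .data$abundance)) +
    geom_tile() +
    labs(x = NULL, y = NULL, fill = "abundance (z)") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
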