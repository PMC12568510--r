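#' Plot a validity report
#'
#' Point estimates with exact 95% interval bars for PPV and sensitivity, one
#' row per algorithm, facetted by analysis mode — the conventional display
#' for comparing identification algorithms whose PPV and sensitivity trade
#' off against each other.
#'
#' @param object An [hf_validity_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hf_validity_report
#' @export
autoplot.hf_validity_report <- function(object, ...) {
  d <- tibble::as_tibble(object) %>%
    dplyr::select(dplyr::all_of(c("algorithm_id", "mode")),
                  dplyr::starts_with("ppv"), dplyr::starts_with("sensitivity")) %>%
    tidyr::pivot_longer(-dplyr::all_of(c("algorithm_id", "mode")),
                        names_to = c("measure", "bound"),
                        names_pattern = "(ppv|sensitivity)(.*)") %>%
    dplyr::mutate(bound = ifelse(.data$bound == "", "point",
                                 sub("^_ci_", "", .data$bound))) %>%
    tidyr::pivot_wider(names_from = "bound", values_from = "value") %>%
    dplyr::mutate(algorithm_id = factor(.data$algorithm_id,
                                        levels = rev(unique(object$algorithm_id))))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$point, y = .data$algorithm_id,
                                  colour = .data$measure)) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$low, xmax = .data$high),
                            height = 0.3, na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$mode)) +
    ggplot2::scale_colour_manual(values = c(ppv = "black", sensitivity = "firebrick"),
                                 labels = c(ppv = "PPV", sensitivity = "Sensitivity")) +
    ggplot2::labs(x = "Percent (95% CI)", y = NULL, colour = NULL) +
    ggplot2::xlim(0, 100) +
    ggplot2::theme_minimal()
}

#' Plot a reviewer-agreement table
#'
#' Heat-map of the 4x4 cross-tabulation of the two reviewers' ordered case
#' categories, with cell counts printed; mass concentrates on the diagonal
#' when agreement is high.
#'
#' @param table A 4x4 agreement matrix (see [hf_agreement_table()]).
#' @return A ggplot object.
#' @export
plot_agreement <- function(table) {
  d <- tibble::as_tibble(as.table(table), .name_repair = "minimal")
  names(d) <- c("reviewer_a", "reviewer_b", "n")
  d$reviewer_a <- factor(d$reviewer_a, levels = rev(case_categories))
  d$reviewer_b <- factor(d$reviewer_b, levels = case_categories)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$reviewer_b, y = .data$reviewer_a,
                                  fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "Reviewer B", y = "Reviewer A", fill = "Cases") +
    ggplot2::theme_minimal()
}
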