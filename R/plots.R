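# ggplot2 counterparts of the usual presentation: per-domain correlation bar
# charts with significance marks and per-tissue correlation profiles.

#' Bar chart of the per-domain E-R correlations
#'
#' One bar per domain (intracellular, transmembrane, extracellular) showing
#' Spearman's rho against abundance; correlations with p < alpha are starred.
#'
#' @param correlations Output of [domain_correlations()].
#' @param alpha Significance threshold for the star annotation.
#' @return A ggplot object.
#' @export
plot_domain_correlations <- function(correlations, alpha = 0.05) {
  dat <- correlations |>
    mutate(
      domain = factor(.data$domain, levels = c("i", "t", "e"),
                      labels = c("intracellular", "transmembrane",
                                 "extracellular")),
      star = ifelse(!is.na(.data$p_two_tailed) & .data$p_two_tailed < alpha,
                    "*", "")
    )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$domain, y = .data$rho)) +
    ggplot2::geom_col(fill = "grey35", width = 0.6) +
    ggplot2::geom_text(
      ggplot2::aes(label = .data$star,
                   vjust = ifelse(.data$rho < 0, 1.5, -0.5)),
      size = 6
    ) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "Spearman's ρ (ω vs abundance)") +
    ggplot2::theme_minimal()
}

#' Per-tissue correlation profiles for the three domains
#'
#' @param per_tissue The `per_tissue` tibble from [tissue_sweep()].
#' @return A ggplot object.
#' @export
plot_tissue_sweep <- function(per_tissue) {
  long <- per_tissue |>
    tidyr::pivot_longer(c("rho_i", "rho_t", "rho_e"), names_to = "domain",
                        values_to = "rho") |>
    mutate(domain = factor(.data$domain,
                           levels = c("rho_i", "rho_t", "rho_e"),
                           labels = c("intracellular", "transmembrane",
                                      "extracellular")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tissue, y = .data$rho,
                                     group = .data$domain,
                                     colour = .data$domain)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "Spearman's ρ (ω vs abundance)",
                  colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
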