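#' Dot plot of differential-set loss over time groups
#'
#' One panel per modality; the ordinate walks through the time groups
#' compared against the reference, the abscissa gives the percentage of the
#' reference group's differential biomolecules lost.
#'
#' @param de_loss A tibble (`modality`, `group`, `loss_pct`), e.g. the
#'   `de_loss` element of [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_loss_curves <- function(de_loss) {
  ggplot2::ggplot(de_loss,
                  ggplot2::aes(x = .data$loss_pct, y = .data$group)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::facet_wrap(~modality) +
    ggplot2::labs(x = "biomolecule loss vs reference group [%]",
                  y = "ischemia time group") +
    ggplot2::xlim(0, 100) +
    ggplot2::theme_bw()
}

#' Forest-style plot of the confounder summary
#'
#' Mean signed coefficient estimates with SD whiskers per predictor level,
#' split by coefficient sign; the per-sign biomolecule counts label the
#' points.
#'
#' @param summary Output of [summarize_confounders()] (optionally with a
#'   `modality` column for faceting).
#' @return A ggplot object.
#' @export
plot_confounder_summary <- function(summary) {
  p <- ggplot2::ggplot(summary,
                       ggplot2::aes(x = .data$mean_estimate, y = .data$term,
                                    colour = .data$sign)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$mean_estimate - .data$sd_estimate,
                   xmax = .data$mean_estimate + .data$sd_estimate),
      height = 0.2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.8,
                       size = 3, show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(positive = "#b2182b",
                                            negative = "#2166ac")) +
    ggplot2::labs(x = "mean coefficient estimate (log2 units)",
                  y = NULL, colour = "sign") +
    ggplot2::theme_bw()
  if ("modality" %in% names(summary)) {
    p <- p + ggplot2::facet_wrap(~modality)
  }
  p
}

#' @rdname dpgp_fit
#' @param object A `dpgp_fit` object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.dpgp_fit <- function(object, ...) {
  ggplot2::ggplot(object$cluster_curves,
                  ggplot2::aes(x = .data$time, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         fill = "#92c5de", alpha = 0.5) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = "pseudo-time (ischemia group index)",
                  y = "normalized differential expression") +
    ggplot2::theme_bw()
}

#' @export
ggplot2::autoplot
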