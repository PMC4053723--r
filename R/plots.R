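#' Plot per-female skewing estimates by sample set
#'
#' Average subject-training AI per female, coloured by assigned group, with
#' the sample set's autosomal 99.5% threshold drawn as the group-1 cut.
#'
#' @param profiles [classify_females()] output.
#' @param thresholds [autosomal_thresholds()] output.
#' @return A ggplot object.
#' @export
plot_skew_profiles <- function(profiles, thresholds) {
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$sample_set,
                               y = .data$avg_subject_ai,
                               colour = .data$group)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, size = 2,
                         na.rm = TRUE) +
    ggplot2::geom_errorbar(
      data = thresholds,
      ggplot2::aes(x = .data$sample_set, ymin = .data$q995,
                   ymax = .data$q995),
      inherit.aes = FALSE, width = 0.5, linewidth = 0.7) +
    ggplot2::labs(x = "sample set",
                  y = "average subject-training AI",
                  colour = "group",
                  title = "Skewing of XCI per female",
                  subtitle = "bar: autosomal 99.5% AI threshold (group-1 cut)") +
    ggplot2::theme_minimal()
}

#' Plot the genic %Xi continuum
#'
#' Genes ranked by mean Xi expression (highest first), coloured by genic
#' status — the continuum-of-escape view of the X chromosome.
#'
#' @param genic [aggregate_genic()] output.
#' @return A ggplot object.
#' @export
plot_xi_continuum <- function(genic) {
  dat <- dplyr::arrange(genic, dplyr::desc(.data$mean_xi))
  dat$rank <- seq_len(nrow(dat))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$rank, y = .data$mean_xi,
                                    colour = .data$status)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = pmax(.data$mean_xi -
                                 .data$sd_xi / sqrt(.data$n_females), 0),
                   ymax = .data$mean_xi +
                     .data$sd_xi / sqrt(.data$n_females)),
      linewidth = 0.2, size = 0.2, na.rm = TRUE) +
    ggplot2::scale_colour_manual(values = c(subject = "#c0392b",
                                            variable_escape = "#8e44ad",
                                            escape = "#27ae60")) +
    ggplot2::labs(x = "gene rank (by mean %Xi)",
                  y = "Xi expression (fraction of Xa)",
                  colour = "genic status",
                  title = "Continuum of expression from the inactive X") +
    ggplot2::theme_minimal()
}

#' Plot the intensity-decay fit behind a Tau threshold
#'
#' Hex-binned homozygous-probe AI against total intensity with the fitted
#' one-phase decay curve and the Tau threshold.
#'
#' @param fit A `decay_fit` from [fit_intensity_decay()].
#' @param probes The uninformative probe rows the fit was run on.
#' @return A ggplot object.
#' @export
plot_intensity_decay <- function(fit, probes) {
  dat <- tibble::tibble(intensity = probes$intensity,
                        ai = homozygous_ai(probes$frac_cdna))
  grid <- tibble::tibble(
    intensity = seq(min(dat$intensity), max(dat$intensity),
                    length.out = 200))
  grid$ai <- fit$plateau + (fit$y0 - fit$plateau) *
    exp(-grid$intensity / fit$tau)
  ggplot2::ggplot(dat, ggplot2::aes(.data$intensity, .data$ai)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.4) +
    ggplot2::geom_line(data = grid, colour = "#2980b9",
                       linewidth = 0.9) +
    ggplot2::geom_vline(xintercept = fit$tau, linetype = "dashed") +
    ggplot2::labs(x = "total cDNA intensity",
                  y = "homozygous-probe AI",
                  title = sprintf("One-phase decay fit (%s): Tau = %.0f",
                                  fit$sample_set, fit$tau)) +
    ggplot2::theme_minimal()
}

#' Plot ChIP AI class means
#'
#' Mean histone ChIP |AI| with standard errors per expression class,
#' faceted by mark and region.
#'
#' @param summary A `chip_class_summary` from [chip_class_compare()].
#' @return A ggplot object.
#' @export
plot_chip_classes <- function(summary) {
  cm <- summary$class_means
  cm$expression_class <- factor(cm$expression_class,
                                levels = expression_class_levels())
  ggplot2::ggplot(cm, ggplot2::aes(x = .data$expression_class,
                                   y = .data$mean_ai)) +
    ggplot2::geom_col(fill = "#7f8c8d") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_ai - .data$se,
                   ymax = .data$mean_ai + .data$se), width = 0.3) +
    ggplot2::facet_grid(ggplot2::vars(.data$region),
                        ggplot2::vars(.data$mark)) +
    ggplot2::labs(x = NULL, y = "mean histone ChIP |AI|",
                  title = "Allelic chromatin imbalance by expression class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
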