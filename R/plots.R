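# ggplot2 displays for the main result types. Kept deliberately close to
# the field's standard figures: diversity histograms per family, relative
# position profiles, GS/IS regression scatter.

#' Plot a family's pairwise-diversity distribution
#'
#' Histogram of pairwise diversities with the kernel density overlay and
#' detected peaks; the modality call and (when available) the peak ages are
#' shown in the subtitle.
#'
#' @param object A `mite_diversity` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mite_diversity <- function(object, ...) {
  dat <- tibble(k = object$k_values)
  sub <- sprintf("%s; mean K = %.3f", object$modality, object$k_mean)
  if (length(object$peak_times_mya) > 0) {
    sub <- paste0(sub, sprintf(
      "; peaks ~ %s Mya", paste(sprintf("%.1f", object$peak_times_mya), collapse = ", ")
    ))
  }
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$k)) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(density)),
      bins = 40, fill = "grey70", colour = "grey30"
    ) +
    ggplot2::labs(
      title = sprintf("Pairwise nucleotide diversity: %s", object$family_name),
      subtitle = sub, x = "pairwise diversity K", y = "density"
    ) +
    ggplot2::theme_minimal()
  if (length(object$k_values) >= 2 && sd(object$k_values) > 0) {
    p <- p + ggplot2::geom_density(colour = "steelblue")
  }
  if (length(object$peaks) > 0) {
    p <- p + ggplot2::geom_vline(
      xintercept = object$peaks, linetype = "dashed", colour = "firebrick"
    )
  }
  p
}

#' Plot the GS/IS regression
#'
#' Scatter of intergenic vs genic copy counts per family with the fitted
#' line; IS-excess outlier families are highlighted.
#'
#' @param object A `mite_gsis` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mite_gsis <- function(object, ...) {
  dat <- object$data %>%
    mutate(outlier = .data$family %in% object$outlier_families)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$gs, y = .data$is)) +
    ggplot2::geom_abline(
      intercept = object$intercept, slope = object$slope, colour = "steelblue"
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$outlier)) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey30", `TRUE` = "firebrick"), guide = "none"
    ) +
    ggplot2::labs(
      title = "MITE copies in genic vs intergenic space",
      subtitle = sprintf("r² = %.2f, p = %.3g", object$r_squared, object$p_value),
      x = "copies in GS", y = "copies in IS"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a relative-position profile
#'
#' @param profile Profile tibble from [relative_position_profile()].
#' @param title Plot title.
#' @return A ggplot.
#' @export
plot_position_profile <- function(profile, title = "Small-RNA positions along MITEs") {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$rel_lo, y = .data$count)) +
    ggplot2::geom_col(width = 100 / nrow(profile), fill = "steelblue") +
    ggplot2::labs(title = title, x = "relative position (% of element)", y = "matches") +
    ggplot2::theme_minimal()
}

#' Plot a small-RNA length distribution
#'
#' @param lengths Tibble from [length_distribution()].
#' @return A ggplot.
#' @export
plot_length_distribution <- function(lengths) {
  ggplot2::ggplot(lengths, ggplot2::aes(x = factor(.data$srna_length), y = .data$proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "read length (nt)", y = "proportion of distinct reads") +
    ggplot2::theme_minimal()
}
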