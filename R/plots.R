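# ggplot2 displays for the main result types.

#' Plot a kinetic fit
#'
#' Measured fractions per replicate with the fitted rise-to-plateau curve.
#'
#' @param object A [fit_kapp()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kinetic_fit <- function(object, ...) {
  d <- object$data
  tmax <- max(d$time_min)
  curve <- tibble::tibble(
    time_min = seq(0, tmax, length.out = 200),
    fraction = object$plateau * (1 - exp(-object$k_app * seq(0, tmax, length.out = 200)))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_min, y = .data$fraction)) +
    ggplot2::geom_point(ggplot2::aes(shape = factor(.data$replicate)),
                        alpha = 0.8) +
    ggplot2::geom_line(data = curve, colour = "firebrick") +
    ggplot2::labs(
      x = "time (min)", y = "fraction deaminated", shape = "replicate",
      title = if (is.na(object$substrate_id)) NULL else object$substrate_id,
      subtitle = sprintf("k_app = %.3g ± %.2g min⁻¹",
                         object$k_app, object$k_sem)) +
    ggplot2::theme_minimal()
}

#' Plot a six-type mutation spectrum
#'
#' @param spectrum A [mutation_spectrum()] result, optionally with extra
#'   `group`/`replicate` columns from several runs bound together.
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectrum) {
  check_columns(spectrum, c("type", "frequency"), "`spectrum`")
  p <- ggplot2::ggplot(spectrum,
                       ggplot2::aes(x = factor(.data$type, levels = deam_types),
                                    y = .data$frequency))
  p <- if ("group" %in% names(spectrum)) {
    p + ggplot2::geom_col(ggplot2::aes(fill = .data$group),
                          position = "dodge")
  } else {
    p + ggplot2::geom_col(fill = "grey30")
  }
  p + ggplot2::labs(x = NULL, y = "mutations per site-observation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot trinucleotide-context mutation rates
#'
#' @param contexts A [context_spectrum()] result.
#' @return A ggplot object, one panel per substitution class.
#' @export
plot_context_spectrum <- function(contexts) {
  check_columns(contexts, c("type", "context", "rate"), "`contexts`")
  ggplot2::ggplot(contexts, ggplot2::aes(x = .data$context, y = .data$rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~type, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "collapsed trinucleotide context",
                  y = "mutations per site-observation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot per-culture mutation frequencies with group medians
#'
#' @param freqs A [mutation_frequency()] result.
#' @return A ggplot object.
#' @export
plot_frequencies <- function(freqs) {
  check_columns(freqs, c("group", "frequency"), "`freqs`")
  ggplot2::ggplot(freqs, ggplot2::aes(x = .data$group, y = .data$frequency)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::stat_summary(fun = median, geom = "crossbar", width = 0.4,
                          colour = "firebrick", linewidth = 0.4) +
    ggplot2::labs(x = NULL, y = "mutation frequency") +
    ggplot2::theme_minimal()
}
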