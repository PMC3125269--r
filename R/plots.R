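# ggplot2 views of the survey results.

#' Plot an SSR class distribution
#'
#' Bar chart of locus counts per canonical class, faceted by period group.
#'
#' @param object An `ssr_report` from [summarize_ssrs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ssr_report <- function(object, ...) {
  d <- object$by_class
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$class_label, -.data$n), y = .data$n
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$period_group), scales = "free") +
    ggplot2::labs(x = "canonical motif class", y = "loci",
                  title = "SSR class distribution") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the self-alignment hit census
#'
#' Histogram of per-read self-alignment hit counts coloured by census bin.
#'
#' @param census Census table from [self_hit_census()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_census <- function(census, ...) {
  ggplot2::ggplot(census, ggplot2::aes(x = .data$hit_count,
                                       fill = .data$census_class)) +
    ggplot2::geom_histogram(binwidth = 1, boundary = -0.5) +
    ggplot2::scale_fill_manual(values = c(LOW = "grey60",
                                          MODERATE = "orange",
                                          HIGH = "firebrick"),
                               drop = FALSE) +
    ggplot2::labs(x = "significant self-alignment hits (other reads)",
                  y = "reads", fill = "census bin",
                  title = "Residual-repeat census after masking") +
    ggplot2::theme_bw()
}

#' Plot paired-end synteny spans
#'
#' Span distribution of same-chromosome clone pairs with the microsynteny
#' window marked; discordant and single-end clones are summarised in the
#' subtitle.
#'
#' @param calls Synteny calls from [call_synteny()].
#' @param min_span,max_span Microsynteny window to mark, bp.
#' @return A ggplot object.
#' @export
plot_synteny_spans <- function(calls, min_span = 10000, max_span = 300000) {
  same <- calls[!is.na(calls$span_bp), , drop = FALSE]
  n_disc <- sum(calls$classification == "DISCORDANT")
  n_single <- sum(calls$classification == "SINGLE_END")
  ggplot2::ggplot(same, ggplot2::aes(x = .data$span_bp / 1000,
                                     fill = .data$classification)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::geom_vline(xintercept = c(min_span, max_span) / 1000,
                        linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(MACRO_ONLY = "grey60",
                                          MICRO = "darkgreen"),
                               drop = TRUE) +
    ggplot2::labs(x = "inner gap between paired-end hits (kb)", y = "clones",
                  title = "Paired-end spans on the reference genome",
                  subtitle = sprintf("%d discordant, %d single-end clones not shown",
                                     n_disc, n_single)) +
    ggplot2::theme_bw()
}
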