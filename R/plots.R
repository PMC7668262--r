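#' Plot a strand-resolved Alu siRNA length distribution
#'
#' Bars of counts per million by insert length, sense above and
#' antisense below the axis.
#'
#' @param object A `length_distribution` from [length_distribution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.length_distribution <- function(object, ...) {
  df <- as_tibble(unclass_keep(object))
  df$signed_cpm <- ifelse(df$strand == "+", df$cpm, -df$cpm)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length, y = .data$signed_cpm,
                                   fill = .data$strand)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(`+` = "#2166ac", `-` = "#b2182b"),
                               labels = c(`+` = "sense", `-` = "antisense")) +
    ggplot2::labs(x = "base length (nt)", y = "counts per million reads",
                  fill = "strand")
}

#' Plot a consensus positional 5'-start profile
#'
#' @param object A `consensus_profile` from [consensus_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.consensus_profile <- function(object, ...) {
  df <- as_tibble(unclass_keep(object))
  df$signed <- ifelse(df$strand == "+", df$count, -df$count)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$signed,
                                   colour = .data$strand)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$pos, yend = 0)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(`+` = "#2166ac", `-` = "#b2182b"),
                                 labels = c(`+` = "sense", `-` = "antisense")) +
    ggplot2::labs(x = "position on consensus (0-based)",
                  y = "5'-start read count", colour = "strand",
                  title = df$consensus_id[1])
}

#' Plot a per-length differential of normalized Alu siRNA counts
#'
#' Negative bars indicate a decrease in the normalized read number in
#' the treated library relative to control.
#'
#' @param object A `differential_profile` from [differential_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.differential_profile <- function(object, ...) {
  df <- as_tibble(unclass_keep(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length, y = .data$delta)) +
    ggplot2::geom_col(fill = "#4d4d4d") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "base length (nt)",
                  y = "normalized reads (treated - control)")
}

#' Plot strand-resolved coverage along a hairpin
#'
#' Sense coverage is drawn above the axis and antisense below; shaded
#' background marks the loop between the two arms.
#'
#' @param object A `strand_coverage` from [map_dicing_products()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.strand_coverage <- function(object, ...) {
  df <- as_tibble(unclass_keep(object))
  iv <- attr(object, "intervals")
  df$signed <- ifelse(df$strand == "+", df$coverage, -df$coverage)
  ggplot2::ggplot(df) +
    ggplot2::annotate("rect", xmin = iv$loop[1], xmax = iv$loop[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.15) +
    ggplot2::geom_area(ggplot2::aes(x = .data$pos, y = .data$signed,
                                    fill = .data$strand),
                       position = "identity") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(`+` = "#2166ac", `-` = "#b2182b"),
                               labels = c(`+` = "sense", `-` = "antisense")) +
    ggplot2::labs(x = "position on hairpin (0-based)", y = "coverage",
                  fill = "strand", title = attr(object, "hairpin"))
}
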