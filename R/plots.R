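# ggplot2 views of traces and selected networks.

#' @export
autoplot.tvn_trace <- function(object, type = c("positions", "k", "trace"), ...) {
  type <- match.arg(type)
  if (type == "positions") {
    df <- posterior_positions(object)
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$prob)) +
        ggplot2::geom_col(fill = "steelblue") +
        ggplot2::scale_x_continuous(breaks = df$position) +
        ggplot2::labs(x = "time point", y = "posterior changepoint probability",
                      title = sprintf("Changepoint posterior, target %s", object$target))
    )
  }
  if (type == "k") {
    df <- posterior_k(object)
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$k), y = .data$prob)) +
        ggplot2::geom_col(fill = "grey40") +
        ggplot2::labs(x = "number of changepoints", y = "posterior probability")
    )
  }
  ggplot2::ggplot(object$draws, ggplot2::aes(x = .data$iteration, y = .data$k)) +
    ggplot2::geom_step(colour = "grey30") +
    ggplot2::labs(x = "iteration", y = "k")
}

#' @export
autoplot.tvn_network <- function(object, ...) {
  edges <- object$edges
  if (!nrow(edges)) {
    return(
      ggplot2::ggplot() +
        ggplot2::annotate("text", x = 0, y = 0, label = "no supported edges") +
        ggplot2::theme_void()
    )
  }
  ggplot2::ggplot(edges, ggplot2::aes(y = .data$parent)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$phase_start, xend = .data$phase_end,
                   yend = .data$parent, colour = .data$sign),
      linewidth = 2
    ) +
    ggplot2::geom_vline(xintercept = object$changepoints$position,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c("+" = "firebrick", "-" = "navy")) +
    ggplot2::labs(x = "time point", y = "parent",
                  title = sprintf("Time-varying parents of %s", object$target))
}
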