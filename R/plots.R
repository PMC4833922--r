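# ggplot2 views of a run: per-amplicon depth and call proportions.

#' Plot per-amplicon calling depth
#'
#' Bar chart of the post-filter depth per tile, faceted by sample.
#'
#' @param run A `primercall_run`.
#' @return A ggplot object.
#' @export
plot_coverage <- function(run) {
  ggplot2::ggplot(run$coverage,
                  ggplot2::aes(x = .data$tile_id, y = .data$depth)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~sample) +
    ggplot2::labs(x = "amplicon tile", y = "read pairs used for calling") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Plot variant calls along the panel
#'
#' Concordant-pair proportion by position, coloured by filter status and
#' shaped by variant class, faceted by sample.
#'
#' @param run A `primercall_run`.
#' @return A ggplot object.
#' @export
plot_calls <- function(run) {
  d <- mutate(run$calls,
              status = ifelse(.data$filters == "", "PASS", .data$filters))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$proportion,
                                  colour = .data$status,
                                  shape = .data$vclass)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~sample, ncol = 1) +
    ggplot2::labs(x = "reference position", y = "concordant pair proportion",
                  colour = "filter", shape = "class") +
    ggplot2::theme_minimal()
}

#' Autoplot method for runs
#'
#' @param object A `primercall_run`.
#' @param type `"coverage"` or `"calls"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.primercall_run <- function(object, type = c("coverage", "calls"), ...) {
  type <- match.arg(type)
  switch(type, coverage = plot_coverage(object), calls = plot_calls(object))
}
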