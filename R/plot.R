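# Quick-look plots for the main result types.

#' Plot the repeat/spacer architecture of a CRISPR array
#'
#' @param array A \code{\link{crispr_array}}.
#' @return A ggplot object showing the ordered units along the genome.
#' @export
plot_array_architecture <- function(array) {
  units <- tidy.crispr_array(array)
  ggplot2::ggplot(units, ggplot2::aes(
    xmin = .data$start, xmax = .data$end, ymin = 0, ymax = 1, fill = .data$type
  )) +
    ggplot2::geom_rect(colour = "grey30", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = c("repeat" = "grey55", "spacer" = "#d95f8a")) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(
      x = sprintf("position on %s (bp)", array$contig_id), y = NULL,
      fill = NULL,
      title = sprintf("%d repeats / %d spacers", length(array$repeats),
                      length(array$spacers))
    ) +
    ggplot2::theme_minimal()
}

#' Plot an annotated vector map (linearized)
#'
#' @param object A \code{vector_design}.
#' @param ... Unused.
#' @return A ggplot object of the part layout on the linearized circle.
#' @method autoplot vector_design
#' @export
autoplot.vector_design <- function(object, ...) {
  f <- tidy.vector_design(object)
  f$ypos <- seq_len(nrow(f)) %% 2
  ggplot2::ggplot(f, ggplot2::aes(
    xmin = .data$start, xmax = .data$end,
    ymin = .data$ypos, ymax = .data$ypos + 0.8, fill = .data$part
  )) +
    ggplot2::geom_rect(colour = "grey30", linewidth = 0.2) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(
      x = "position (bp)", y = NULL,
      title = sprintf("%s (%s, %d bp circular)", object$name, object$kind,
                      nchar(object$full_seq))
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of a pairwise identity matrix
#'
#' @param mat A matrix from \code{\link{identity_matrix}}.
#' @return A ggplot tile plot.
#' @export
plot_identity_heatmap <- function(mat) {
  df <- expand.grid(a = rownames(mat), b = colnames(mat), stringsAsFactors = FALSE)
  df$identity <- mat[cbind(df$a, df$b)]
  ggplot2::ggplot(df, ggplot2::aes(.data$a, .data$b, fill = .data$identity)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$identity)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#b2182b",
                                 limits = c(0, 100)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "% identity") +
    ggplot2::theme_minimal()
}

#' One-row summary of a vector design
#' @param x A \code{vector_design}.
#' @param ... Unused.
#' @return A one-row tibble: name, kind, length, part and insertion counts.
#' @method glance vector_design
#' @export
glance.vector_design <- function(x, ...) {
  tibble::tibble(
    name = x$name, kind = x$kind, length = nchar(x$full_seq),
    n_features = nrow(x$features), n_insertions = nrow(x$insertions)
  )
}

#' One-row summary of an array diff
#' @param x An \code{array_diff}.
#' @param ... Unused.
#' @return A one-row tibble of the edit summary counts.
#' @method glance array_diff
#' @export
glance.array_diff <- function(x, ...) {
  tibble::as_tibble(x$counts)
}
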