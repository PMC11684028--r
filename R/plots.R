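# ggplot2 views of the result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_vline geom_col
#'   labs coord_flip theme_minimal
#' @export
ggplot2::autoplot

#' Plot a property density with its mode and mean
#'
#' @param object A `cki_density` from [density_summary()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cki_density <- function(object, ...) {
  curve <- attr(object, "density")
  if (is.null(curve)) {
    curve <- tibble(x = c(object$min, object$max), y = c(1, 1))
  }
  ggplot(curve, aes(x = .data$x, y = .data$y)) +
    geom_line() +
    geom_vline(xintercept = object$mode, linetype = "dashed") +
    geom_vline(xintercept = object$mean, linetype = "dotted") +
    labs(
      x = "value", y = "density",
      subtitle = sprintf(
        "mode %.3g (dashed), mean %.3g (dotted), n = %d",
        object$mode, object$mean, object$n
      )
    ) +
    theme_minimal()
}

#' Plot the most frequent adjacent fragments
#'
#' @param object A `cki_fragment_library`.
#' @param top Number of fragments shown (default 10).
#' @param ... Unused.
#' @return A ggplot bar chart of occurrence counts.
#' @export
autoplot.cki_fragment_library <- function(object, top = 10L, ...) {
  d <- head(as_tibble(object), top)
  d$fragment_smiles_clean <- factor(
    d$fragment_smiles_clean,
    levels = rev(d$fragment_smiles_clean)
  )
  ggplot(d, aes(x = .data$fragment_smiles_clean, y = .data$count)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "occurrences") +
    theme_minimal()
}

#' Plot cluster sizes of a fragment clustering
#'
#' @param object A `cki_hclust`.
#' @param ... Unused.
#' @return A ggplot bar chart of cluster sizes.
#' @export
autoplot.cki_hclust <- function(object, ...) {
  d <- count(object$labels, .data$cluster)
  ggplot(d, aes(x = factor(.data$cluster), y = .data$n)) +
    geom_col() +
    labs(x = "cluster", y = "fragments") +
    theme_minimal()
}
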