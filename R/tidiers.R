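# ---- broom-style tidiers and plots ------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a diversity index vector
#'
#' @param x a `pdindex_index`.
#' @param ... unused.
#' @return A tibble with `taxon`, numeric `value`, the exact `fraction`
#'   string, and the descending `rank` (ties share the smallest rank).
#' @export
#' @method tidy pdindex_index
tidy.pdindex_index <- function(x, ...) {
  v <- as.double(x$value)
  tibble::tibble(
    taxon = x$taxon,
    value = v,
    fraction = format(x$value),
    rank = rank(-v, ties.method = "min")
  )
}

#' @rdname tidy.pdindex_index
#' @return For `glance()`: a one-row tibble with the index name, number of
#'   taxa, and the exact and numeric total.
#' @export
#' @method glance pdindex_index
glance.pdindex_index <- function(x, ...) {
  tot <- rq_sum(x$value)
  tibble::tibble(
    index = attr(x, "index"),
    n_taxa = nrow(x),
    total = as.double(tot),
    total_fraction = format(tot)
  )
}

#' Rank taxa by an index
#'
#' Orders taxa by decreasing index value, breaking ties by taxon order and
#' flagging them.
#'
#' @param index a `pdindex_index`.
#' @return A tibble with `taxon`, `value`, `fraction`, `rank` and `tied`.
#' @export
rank_taxa <- function(index) {
  out <- tidy(index)
  out <- out[order(-out$value, out$taxon), ]
  out$tied <- duplicated(out$value) | duplicated(out$value, fromLast = TRUE)
  tibble::as_tibble(out)
}

#' Plot a diversity index vector
#'
#' A bar chart of the per-taxon index values, ordered by decreasing value.
#'
#' @param object a `pdindex_index`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
#' @method autoplot pdindex_index
autoplot.pdindex_index <- function(object, ...) {
  df <- tidy(object)
  df$taxon <- stats::reorder(df$taxon, -df$value)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$taxon, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = attr(object, "index"),
                  title = "Phylogenetic diversity index") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL

#' Tidy an index matrix
#'
#' @param x a `pdindex_gamma`.
#' @param ... unused.
#' @return A long tibble with `row` (cluster or split label), `taxon`,
#'   numeric `entry` and exact `fraction`.
#' @export
#' @method tidy pdindex_gamma
tidy.pdindex_gamma <- function(x, ...) {
  vals <- rqm_values(x$gamma)
  tibble::tibble(
    row = rep(x$rows, times = length(x$taxa)),
    taxon = rep(x$taxa, each = length(x$rows)),
    entry = as.double(vals),
    fraction = format(vals)
  )
}

#' Plot an index matrix
#'
#' A tile heatmap of the matrix entries, with rows in system order.
#'
#' @param object a `pdindex_gamma`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
#' @method autoplot pdindex_gamma
autoplot.pdindex_gamma <- function(object, ...) {
  df <- tidy(object)
  df$row <- factor(df$row, levels = rev(object$rows))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$taxon, y = .data$row,
                                   fill = .data$entry)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = .data$fraction), size = 3) +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "steelblue", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "entry") +
    ggplot2::theme_minimal()
}

#' Tidy a property report
#'
#' @param x a `pdindex_properties`.
#' @param ... unused.
#' @return A tibble with `property` and logical `satisfied`.
#' @export
#' @method tidy pdindex_properties
tidy.pdindex_properties <- function(x, ...) {
  nm <- c("complete", "nonnegative", "neutrality", "descendant_diversity")
  tibble::tibble(property = nm, satisfied = vapply(x[nm], isTRUE, TRUE))
}
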