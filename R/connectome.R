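#' Build a cardiac connectome graph
#'
#' A connectome is a directed weighted graph on the 12 lead symbols whose
#' edge weights are transition counts. Three constructions are supported:
#'
#' * `"sentence-transitions"` (default): edges are the non-zero cells of
#'   the sentence's symbol transition table ([sentence_transition_table()]),
#'   i.e. how often one symbol follows another in the Cardioish sentence.
#' * `"feature-pairs"`: one edge per selected feature, from its from-lead
#'   to its to-lead; the count is the multiplicity of that pair in the
#'   selection.
#' * `"class-aggregate"`: edges are the selected transition cells weighted
#'   by the summed raw per-beat transition counts over a class subset of a
#'   beat set, tying the graph back to the signal-level evidence.
#'
#' @param source A `cardioish_sentence` (modes 1 and 2; for
#'   `feature-pairs` a plain vector of selected feature indexes also
#'   works), or for `class-aggregate` a list with elements `beats` (a
#'   beat-set tibble), `sel_indexes`, and optional `classes` (labels to
#'   keep, default all).
#' @param mode One of `"sentence-transitions"`, `"feature-pairs"`,
#'   `"class-aggregate"`.
#' @return Object of class `cardioish_connectome`: list with `nodes` (the
#'   12 symbols), `edges` tibble (`from`, `to`, `count`), and `mode`.
#' @export
#' @examples
#' sent <- build_sentence(c(24, 1, 24))
#' build_connectome(sent)
#' build_connectome(sent, mode = "feature-pairs")
build_connectome <- function(source, mode = c("sentence-transitions",
                                              "feature-pairs",
                                              "class-aggregate")) {
  mode <- match.arg(mode)
  alpha <- cardioish_alphabet()
  tab <- switch(mode,
    "sentence-transitions" = {
      if (!inherits(source, "cardioish_sentence") && !is.character(source)) {
        abort("sentence-transitions mode needs a sentence or token vector.",
              class = "cardioish_config_error")
      }
      sentence_transition_table(source)
    },
    "feature-pairs" = {
      sel <- if (inherits(source, "cardioish_sentence")) {
        # reconstruct feature indexes from consecutive symbol-index pairs
        from <- source$sind[seq(1L, length(source$sind), by = 2L)]
        to <- source$sind[seq(2L, length(source$sind), by = 2L)]
        (from - 1L) * N_LEADS + to
      } else {
        as.integer(source)
      }
      tab <- matrix(0L, N_LEADS, N_LEADS,
                    dimnames = list(from = alpha, to = alpha))
      for (u in sel) {
        pr <- feature_symbol_pair(u)
        tab[pr[1], pr[2]] <- tab[pr[1], pr[2]] + 1L
      }
      tab
    },
    "class-aggregate" = {
      if (!is.list(source) || is.null(source$beats) || is.null(source$sel_indexes)) {
        abort("class-aggregate mode needs list(beats=, sel_indexes=, classes=).",
              class = "cardioish_config_error")
      }
      beats <- source$beats
      validate_beatset(beats)
      classes <- source$classes %||% unique(beats$label)
      keep <- beats$label %in% classes
      if (!any(keep)) {
        abort("No beats left after class filtering.", class = "cardioish_config_error")
      }
      total <- Reduce(`+`, purrr::map(beats$signal[keep], function(s) {
        count_transitions(transform_beat(s))
      }))
      mask <- matrix(FALSE, N_LEADS, N_LEADS)
      for (u in as.integer(source$sel_indexes)) {
        pr <- feature_symbol_pair(u)
        mask[pr[1], pr[2]] <- TRUE
      }
      total[!mask] <- 0L
      dimnames(total) <- list(from = alpha, to = alpha)
      total
    }
  )
  nz <- which(tab > 0, arr.ind = TRUE)
  edges <- tibble::tibble(
    from = alpha[nz[, 1]],
    to = alpha[nz[, 2]],
    count = as.integer(tab[nz])
  ) |>
    dplyr::arrange(match(.data$from, alpha), match(.data$to, alpha))
  structure(list(nodes = alpha, edges = edges, mode = mode),
            class = "cardioish_connectome")
}

#' @export
print.cardioish_connectome <- function(x, ...) {
  cat(sprintf("<cardioish_connectome> mode=%s, 12 nodes, %d edges, total count %d\n",
              x$mode, nrow(x$edges), sum(x$edges$count)))
  invisible(x)
}

#' @export
tidy.cardioish_connectome <- function(x, ...) {
  x$edges
}

#' Convert a connectome to an igraph object
#'
#' @param graph A `cardioish_connectome`.
#' @return An [igraph::graph] with all 12 symbol nodes and an integer
#'   `count` edge attribute.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "cardioish_connectome"))
  igraph::graph_from_data_frame(graph$edges, directed = TRUE,
                                vertices = data.frame(name = graph$nodes))
}

#' @export
autoplot.cardioish_connectome <- function(object, ...) {
  n <- length(object$nodes)
  theta <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  layout <- tibble::tibble(symbol = object$nodes,
                           x = cos(theta), y = sin(theta))
  e <- object$edges |>
    dplyr::left_join(layout, by = c(from = "symbol")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(layout, by = c(to = "symbol"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = dplyr::filter(e, .data$from != .data$to),
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x, yend = .data$y,
                   linewidth = .data$count),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      alpha = 0.6, colour = "grey40") +
    ggplot2::geom_point(data = layout, ggplot2::aes(x = .data$x, y = .data$y),
                        size = 9, colour = "firebrick") +
    ggplot2::geom_text(data = layout,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$symbol),
                       colour = "white", size = 2.6) +
    ggplot2::scale_linewidth(range = c(0.2, 1.6)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("Cardiac connectome (%s)", object$mode))
}
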