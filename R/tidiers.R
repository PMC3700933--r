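#' Tidy the event graph into an edge table
#'
#' @param x An [build_event_graph()] result.
#' @param ... Unused.
#' @return Tibble `from`, `to`, `weight` (minimum reciprocal overlap).
#' @export
tidy.event_graph <- function(x, ...) {
  if (igraph::ecount(x$graph) == 0) {
    return(tibble::tibble(from = character(), to = character(),
                          weight = numeric()))
  }
  el <- igraph::as_edgelist(x$graph)
  tibble::tibble(from = el[, 1], to = el[, 2],
                 weight = igraph::E(x$graph)$weight)
}

#' One-row summary of the event graph
#'
#' @param x An [build_event_graph()] result.
#' @param ... Unused.
#' @return Tibble `n_events`, `n_edges`, `density`, `n_components`,
#'   `min_overlap`.
#' @export
glance.event_graph <- function(x, ...) {
  tibble::tibble(
    n_events = igraph::vcount(x$graph),
    n_edges = igraph::ecount(x$graph),
    density = igraph::edge_density(x$graph),
    n_components = igraph::components(x$graph)$no,
    min_overlap = x$min_overlap)
}

#' Tidy recurrence-classified events
#'
#' @param x A [classify_recurrence()] result.
#' @param ... Unused.
#' @return The underlying tibble, unclassed.
#' @export
tidy.or_recurrence <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of recurrence classes
#'
#' @param x A [classify_recurrence()] result.
#' @param ... Unused.
#' @return Tibble with total event count and per-class counts.
#' @export
glance.or_recurrence <- function(x, ...) {
  tibble::tibble(
    n_events = nrow(x),
    n_hotspot = sum(x$class == "hotspot"),
    n_intermediate = sum(x$class == "intermediate"),
    n_rare = sum(x$class == "rare"),
    n_regions = dplyr::n_distinct(x$region_id))
}
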