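#' Build the pairwise-overlap event graph
#'
#' CNV events are nodes of an interval graph; an undirected edge joins two
#' events on the same chromosome whose minimum reciprocal overlap reaches
#' `min_overlap` (40% is the conventional merged-region threshold, 99% the
#' family threshold). Construction is a sorted sweep per chromosome, so
#' only intersecting pairs are examined.
#'
#' @param events Call tibble (`chrom`, `start`, `end`; `call_id` added if
#'   absent).
#' @param min_overlap Minimum reciprocal overlap in (0, 1\].
#' @return Object of class `event_graph`: list with `graph` (an
#'   \pkg{igraph} graph whose vertex names are event ids, edge weights the
#'   minimum reciprocal fraction), `events`, and `min_overlap`.
#' @export
build_event_graph <- function(events, min_overlap = 0.4) {
  if (min_overlap <= 0 || min_overlap > 1) {
    stop("`min_overlap` must be in (0, 1]", call. = FALSE)
  }
  assert_cols(events, c("chrom", "start", "end"), "events")
  events <- ensure_call_id(events)
  events <- dplyr::arrange(events, .data$chrom, .data$start, .data$end)
  edges <- list()
  for (ch in unique(events$chrom)) {
    ev <- events[events$chrom == ch, , drop = FALSE]
    n <- nrow(ev)
    if (n < 2) next
    for (i in seq_len(n - 1L)) {
      j <- i + 1L
      while (j <= n && ev$start[j] < ev$end[i]) {
        inter <- intersect_len(ev$start[i], ev$end[i], ev$start[j], ev$end[j])
        w <- min(inter / (ev$end[i] - ev$start[i]),
                 inter / (ev$end[j] - ev$start[j]))
        if (w >= min_overlap) {
          edges[[length(edges) + 1]] <-
            tibble::tibble(from = ev$call_id[i], to = ev$call_id[j],
                           weight = w)
        }
        j <- j + 1L
      }
    }
  }
  edge_df <- dplyr::bind_rows(edges)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(events), name = events$call_id)
  if (nrow(edge_df) > 0) {
    g <- igraph::add_edges(
      g, rbind(match(edge_df$from, events$call_id),
               match(edge_df$to, events$call_id)))
    igraph::E(g)$weight <- edge_df$weight
  }
  structure(list(graph = g, events = events, min_overlap = min_overlap),
            class = "event_graph")
}

#' @export
print.event_graph <- function(x, ...) {
  cat("<event_graph>", igraph::vcount(x$graph), "events,",
      igraph::ecount(x$graph), "edges at min reciprocal overlap",
      x$min_overlap, "\n")
  invisible(x)
}

#' Merged recurrent regions from maximal cliques
#'
#' Enumerates the maximal cliques of the event graph exactly and assigns
#' every event to one region: the largest maximal clique containing it,
#' ties broken by leftmost region span start, then by lexicographic member
#' ids, so output is deterministic. Each region's span is the union
#' interval of its members; by construction every member overlaps all
#' others at the graph's threshold.
#'
#' @param graph An [build_event_graph()] result.
#' @return Tibble: `region_id`, `chrom`, `start`, `end`, `n_events`,
#'   `event_ids` (list column), plus a `region_id` mapping joined onto the
#'   events, returned as attribute `"assignment"` (tibble `call_id`,
#'   `region_id`).
#' @export
merged_regions <- function(graph) {
  stopifnot(inherits(graph, "event_graph"))
  ev <- graph$events
  if (nrow(ev) == 0) {
    return(tibble::tibble(region_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          n_events = integer(), event_ids = list()))
  }
  cl <- igraph::max_cliques(graph$graph)
  members <- lapply(cl, function(v) sort(igraph::V(graph$graph)$name[v]))
  sizes <- lengths(members)
  span_start <- vapply(members, function(m) {
    min(ev$start[match(m, ev$call_id)])
  }, numeric(1))
  key <- vapply(members, paste, character(1), collapse = ",")
  ord <- order(-sizes, span_start, key)
  members <- members[ord]

  assigned <- setNames(rep(NA_integer_, nrow(ev)), ev$call_id)
  for (ci in seq_along(members)) {
    for (m in members[[ci]]) {
      if (is.na(assigned[[m]])) assigned[[m]] <- ci
    }
  }
  groups <- split(names(assigned), assigned)
  rows <- lapply(seq_along(groups), function(k) {
    ids <- sort(groups[[k]])
    sub <- ev[match(ids, ev$call_id), , drop = FALSE]
    tibble::tibble(chrom = sub$chrom[1], start = min(sub$start),
                   end = max(sub$end), n_events = length(ids),
                   event_ids = list(ids))
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$chrom, .data$start,
                        .data$end)
  out <- dplyr::mutate(out, region_id = sprintf("region_%03d",
                                                dplyr::row_number()),
                       .before = 1)
  assignment <- tidyr::unnest(out[, c("region_id", "event_ids")],
                              "event_ids")
  names(assignment)[2] <- "call_id"
  attr(out, "assignment") <- assignment
  out
}

#' Family groups of highly similar events
#'
#' [merged_regions()] at the family threshold (99% reciprocal overlap by
#' default): groups of events with near-identical breakpoints.
#'
#' @param events Call tibble.
#' @param min_overlap Family overlap threshold.
#' @return As [merged_regions()].
#' @export
cnv_families <- function(events, min_overlap = 0.99) {
  merged_regions(build_event_graph(events, min_overlap))
}

#' Classify events as hotspot, intermediate or rare
#'
#' Joins events to their merged region and classifies each region by the
#' number of distinct individuals contributing events: `rare` regions
#' contain events of exactly one individual (not seen in any other
#' individual of any population), `hotspot` regions gather at least
#' `hotspot_min_individuals` individuals (default 3), and everything else
#' is `intermediate`. The three classes partition the events.
#'
#' @param regions [merged_regions()] output.
#' @param events Event tibble with `call_id` and `sample`.
#' @param samples Tibble `sample`, `population`.
#' @param hotspot_min_individuals Individuals needed for a hotspot region.
#' @return Events with `region_id`, `n_individuals`, `n_populations`,
#'   `class` columns; class `or_recurrence`.
#' @export
classify_recurrence <- function(regions, events, samples,
                                hotspot_min_individuals = 3L) {
  assert_cols(events, c("call_id", "sample"), "events")
  assert_cols(samples, c("sample", "population"), "samples")
  assignment <- attr(regions, "assignment")
  if (is.null(assignment)) stop("`regions` must come from merged_regions()",
                                call. = FALSE)
  ev <- dplyr::left_join(events, assignment, by = "call_id")
  ev$population <- NULL  # authoritative assignment comes from `samples`
  ev <- dplyr::left_join(ev, samples, by = "sample")
  per_region <- dplyr::summarise(
    dplyr::group_by(ev, .data$region_id),
    n_individuals = dplyr::n_distinct(.data$sample),
    n_populations = dplyr::n_distinct(.data$population), .groups = "drop")
  per_region <- dplyr::mutate(
    per_region,
    class = dplyr::case_when(
      .data$n_individuals == 1 ~ "rare",
      .data$n_individuals >= hotspot_min_individuals ~ "hotspot",
      TRUE ~ "intermediate"))
  out <- dplyr::left_join(ev, per_region, by = "region_id")
  class(out) <- c("or_recurrence", class(out))
  out
}

#' Per-chromosome recurrence class counts
#'
#' @param classified [classify_recurrence()] output.
#' @return Tibble `chrom` x `class` event counts (wide, one column per
#'   class).
#' @export
recurrence_summary <- function(classified) {
  assert_cols(classified, c("chrom", "class"), "classified")
  counts <- dplyr::count(classified, .data$chrom, .data$class)
  tidyr::pivot_wider(counts, names_from = "class", values_from = "n",
                     values_fill = 0L)
}

#' Export the event graph as GEXF
#'
#' Writes a GEXF 1.2 document loadable by standard graph viewers, with the
#' recurrence class attached as a node attribute (usable for coloring).
#'
#' @param graph An [build_event_graph()] result.
#' @param classes Optional tibble `call_id`, `class` (from
#'   [classify_recurrence()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_gexf <- function(graph, classes = NULL, path) {
  stopifnot(inherits(graph, "event_graph"))
  doc <- xml2::xml_new_root(
    "gexf", xmlns = "http://www.gexf.net/1.2draft", version = "1.2")
  g <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected")
  attrs <- xml2::xml_add_child(g, "attributes", class = "node")
  xml2::xml_add_child(attrs, "attribute", id = "0", title = "class",
                      type = "string")
  nodes <- xml2::xml_add_child(g, "nodes")
  cls <- setNames(rep("unclassified", nrow(graph$events)),
                  graph$events$call_id)
  if (!is.null(classes)) {
    assert_cols(classes, c("call_id", "class"), "classes")
    cls[classes$call_id] <- classes$class
  }
  for (id in graph$events$call_id) {
    nd <- xml2::xml_add_child(nodes, "node", id = id, label = id)
    av <- xml2::xml_add_child(nd, "attvalues")
    xml2::xml_add_child(av, "attvalue", `for` = "0", value = cls[[id]])
  }
  edges <- xml2::xml_add_child(g, "edges")
  if (igraph::ecount(graph$graph) > 0) {
    el <- igraph::as_edgelist(graph$graph)
    w <- igraph::E(graph$graph)$weight %||% rep(1, nrow(el))
    for (i in seq_len(nrow(el))) {
      xml2::xml_add_child(edges, "edge", id = as.character(i - 1L),
                          source = el[i, 1], target = el[i, 2],
                          weight = format(w[i], digits = 6))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
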