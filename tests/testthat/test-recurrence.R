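mk_events <- function(starts, ends, chrom = "chr1",
                      samples = paste0("s", seq_along(starts))) {
  tibble::tibble(call_id = paste0("e", seq_along(starts)), sample = samples,
                 chrom = chrom, start = starts, end = ends, type = "dup")
}

graph_adj <- function(events, min_overlap) {
  # adjacency by direct pairwise arithmetic (oracle)
  n <- nrow(events)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || events$chrom[i] != events$chrom[j]) next
    fr <- brute_reciprocal(events$start[i], events$end[i],
                           events$start[j], events$end[j])
    adj[i, j] <- min(fr) >= min_overlap
  }
  adj
}

test_that("event graph edges follow the reciprocal-overlap rule", {
  # identical events: one edge at weight 1
  ev <- mk_events(c(100, 100), c(200, 200))
  g <- build_event_graph(ev, 0.4)
  expect_equal(igraph::ecount(g$graph), 1)
  expect_equal(igraph::E(g$graph)$weight, 1)

  # chain A-B-C with A,C disjoint: edges AB and BC only
  ev3 <- mk_events(c(100, 160, 220), c(200, 260, 320))
  g3 <- build_event_graph(ev3, 0.4)
  ed <- tidy(g3)
  expect_equal(nrow(ed), 2)
  expect_setequal(paste(ed$from, ed$to), c("e1 e2", "e2 e3"))

  # edges never join chromosomes
  ev_x <- mk_events(c(100, 100), c(200, 200), chrom = c("chr1", "chr2"))
  expect_equal(igraph::ecount(build_event_graph(ev_x, 0.4)$graph), 0)
})

test_that("sweep graph construction equals all-pairs brute force", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 200
    starts <- sample(1e5, n)
    ev <- mk_events(starts, starts + sample(500:20000, n, replace = TRUE),
                    chrom = sample(c("chr1", "chr2"), n, replace = TRUE))
    g <- build_event_graph(ev, 0.4)
    adj <- graph_adj(ev, 0.4)
    got <- sort(apply(igraph::as_edgelist(g$graph), 1,
                      function(r) paste(sort(r), collapse = "-")))
    idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
    want <- sort(apply(idx, 1, function(r) {
      paste(sort(ev$call_id[r]), collapse = "-")
    }))
    expect_equal(got, want)
  }
})

test_that("raising the overlap threshold never adds an edge", {
  set.seed(5)
  starts <- sample(1e5, 50)
  ev <- mk_events(starts, starts + sample(500:20000, 50, replace = TRUE))
  for (th in list(c(0.2, 0.4), c(0.4, 0.8), c(0.8, 0.99))) {
    lo <- tidy(build_event_graph(ev, th[1]))
    hi <- tidy(build_event_graph(ev, th[2]))
    expect_true(all(paste(hi$from, hi$to) %in% paste(lo$from, lo$to)))
  }
})

test_that("maximal cliques equal exhaustive enumeration on small instances", {
  set.seed(17)
  for (rep in 1:100) {
    n <- sample(4:12, 1)
    starts <- sample(5000, n)
    ev <- mk_events(starts, starts + sample(200:3000, n, replace = TRUE))
    g <- build_event_graph(ev, 0.4)
    cl <- igraph::max_cliques(g$graph)
    got <- lapply(cl, function(v) {
      sort(match(igraph::V(g$graph)$name[v], ev$call_id))
    })
    got <- got[order(vapply(got, paste, character(1), collapse = ","))]
    want <- brute_max_cliques(graph_adj(ev, 0.4))
    expect_equal(got, want)
  }
})

test_that("merged regions assign each event to its largest clique", {
  # single event: one singleton region
  ev1 <- mk_events(100, 200)
  r1 <- merged_regions(build_event_graph(ev1, 0.4))
  expect_equal(nrow(r1), 1)
  expect_equal(r1$n_events, 1L)

  # three mutually overlapping events: one region of size 3
  ev3 <- mk_events(c(100, 110, 120), c(300, 310, 320))
  r3 <- merged_regions(build_event_graph(ev3, 0.4))
  expect_equal(nrow(r3), 1)
  expect_equal(r3$n_events, 3L)
  expect_equal(r3$start, 100)
  expect_equal(r3$end, 320)

  # classes partition events: every event appears in exactly one region
  set.seed(33)
  starts <- sample(1e5, 40)
  ev <- mk_events(starts, starts + sample(500:20000, 40, replace = TRUE))
  rr <- merged_regions(build_event_graph(ev, 0.4))
  assigned <- unlist(rr$event_ids)
  expect_setequal(assigned, ev$call_id)
  expect_equal(anyDuplicated(assigned), 0L)
})

test_that("family grouping requires near-identical breakpoints", {
  # identical events form one family
  evi <- mk_events(c(1000, 1000), c(101000, 101000))
  fi <- cnv_families(evi)
  expect_equal(nrow(fi), 1)
  expect_equal(fi$n_events, 2L)
  # events offset by 2% of their length share no family edge at 99%
  evo <- mk_events(c(1000, 3000), c(101000, 103000))
  fo <- cnv_families(evo)
  expect_equal(nrow(fo), 2)
  # a planted hotspot of 10 near-identical events is one family
  starts <- 1000 + sample(0:5, 10, replace = TRUE)
  evh <- mk_events(starts, starts + 100000)
  fh <- cnv_families(evh)
  expect_equal(nrow(fh), 1)
  expect_equal(fh$n_events, 10L)
})

test_that("recurrence classes follow the individual-count rules", {
  samples <- tibble::tibble(sample = paste0("s", 1:8),
                            population = rep(c("P1", "P2"), each = 4))
  # region A: 5 individuals over 2 populations -> hotspot
  # region B: 2 individuals -> intermediate
  # region C: singleton -> rare
  ev <- dplyr::bind_rows(
    mk_events(rep(1000, 5), rep(101000, 5), samples = paste0("s", 1:5)),
    mk_events(rep(5e5, 2), rep(6e5, 2), samples = c("s6", "s7")),
    mk_events(9e5, 9.5e5, samples = "s8"))
  ev$call_id <- paste0("e", 1:8)
  reg <- merged_regions(build_event_graph(ev, 0.4))
  cls <- classify_recurrence(reg, ev, samples)
  expect_equal(unname(table(cls$class)[c("hotspot", "intermediate", "rare")]),
               c(5L, 2L, 1L),
               ignore_attr = TRUE)
  expect_equal(sum(cls$class == "hotspot") + sum(cls$class == "intermediate") +
                 sum(cls$class == "rare"), nrow(ev))
  expect_equal(cls$n_populations[cls$class == "hotspot"][1], 2L)
  smry <- recurrence_summary(cls)
  expect_equal(sum(unlist(smry[, -1])), nrow(ev))
  g <- glance(cls)
  expect_equal(g$n_events, 8L)
  expect_equal(g$n_regions, 3L)
})

test_that("rare classification is exact on planted private events", {
  cfg <- tiny_config(seed = 12)
  sim <- simulate_probe_panel(cfg)
  calls <- dplyr::mutate(sim$truth,
                         type = ifelse(.data$copy_state > 2, "dup", "del"),
                         call_id = paste0("t", dplyr::row_number()))
  reg <- merged_regions(build_event_graph(calls, 0.4))
  cls <- classify_recurrence(reg, calls, sim$samples)
  # planted loci are disjoint, so a region is rare iff its palette event
  # has exactly one carrier in the cohort
  truth_rare <- names(which(table(sim$truth$event_id) == 1))
  expect_true(all(c("rare_11q_homdel", "rare_14q_amp") %in% truth_rare))
  got_rare <- cls$event_id[cls$class == "rare"]
  # precision and recall of the rare class on the planted singletons
  expect_setequal(got_rare, truth_rare)
})

test_that("GEXF export round-trips through an XML parser", {
  ev <- mk_events(c(100, 160, 220), c(200, 260, 320))
  g <- build_event_graph(ev, 0.4)
  classes <- tibble::tibble(call_id = ev$call_id,
                            class = c("hotspot", "hotspot", "rare"))
  path <- tempfile(fileext = ".gexf")
  export_gexf(g, classes, path)
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  nodes <- xml2::xml_find_all(doc, ".//d1:node", ns)
  edges <- xml2::xml_find_all(doc, ".//d1:edge", ns)
  expect_equal(length(nodes), 3)
  expect_equal(length(edges), 2)
  attvals <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//d1:attvalue", ns), "value")
  expect_equal(sort(attvals), sort(classes$class))

  # empty graph: still a valid document
  g0 <- build_event_graph(mk_events(numeric(0), numeric(0)), 0.4)
  path0 <- tempfile(fileext = ".gexf")
  export_gexf(g0, NULL, path0)
  doc0 <- xml2::read_xml(path0)
  expect_equal(length(xml2::xml_find_all(doc0, ".//d1:node",
                                         xml2::xml_ns(doc0))), 0)
})
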