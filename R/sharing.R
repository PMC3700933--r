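#' Span of a breakpoint pair in integer kb
#'
#' Size is `end - start` in bp, divided by 1000 and rounded half-up to an
#' integer, the only rounding rule consistent with published breakpoint
#' tables (e.g. 22,317,500-22,588,019 is 270,519 bp, printed as 271 kb).
#'
#' @param start,end Breakpoints in bp (1-based, `end > start`), vectorized.
#' @return Integer kb.
#' @export
#' @examples
#' span_kb(22317500, 22588019)  # 271
span_kb <- function(start, end) {
  if (any(end <= start)) stop("`end` must be > `start`", call. = FALSE)
  as.integer(floor((end - start) / 1000 + 0.5))
}

#' Cross-population CNP sharing table
#'
#' Clusters events across populations into population-level CNPs: events
#' connected (directly or transitively) at `min_overlap` reciprocal
#' overlap and same type form one CNP. Each CNP records its union span,
#' the set of populations carrying it, and whether it is exclusive to a
#' single population. The result is invariant to the input order of
#' populations.
#'
#' @param calls Call tibble (`sample`, `chrom`, `start`, `end`, `type`).
#' @param samples Tibble `sample`, `population` (at least 2 populations).
#' @param min_overlap Reciprocal-overlap threshold for CNP identity.
#' @param ignore_type Cluster gains and losses together.
#' @return Tibble of class `or_sharing`: `cnp_id`, `chrom`, `start`, `end`,
#'   `size_kb`, `type`, `populations` (list column, sorted), `n_populations`,
#'   `n_events`, `exclusive`.
#' @export
sharing_table <- function(calls, samples, min_overlap = 0.5,
                          ignore_type = FALSE) {
  assert_cols(calls, c("sample", "chrom", "start", "end", "type"), "calls")
  assert_cols(samples, c("sample", "population"), "samples")
  if (dplyr::n_distinct(samples$population) < 2) {
    stop("sharing analysis needs at least 2 populations", call. = FALSE)
  }
  calls$population <- NULL  # authoritative assignment comes from `samples`
  calls <- ensure_call_id(dplyr::left_join(calls, samples, by = "sample"))
  key <- if (ignore_type) list(calls$chrom) else
    list(paste(calls$chrom, calls$type))
  parts <- split(calls, key[[1]])
  rows <- list()
  for (part in parts) {
    eg <- build_event_graph(part, min_overlap)
    comp <- igraph::components(eg$graph)
    for (ci in seq_len(comp$no)) {
      ids <- names(comp$membership)[comp$membership == ci]
      sub <- part[match(ids, part$call_id), , drop = FALSE]
      pops <- sort(unique(sub$population))
      rows[[length(rows) + 1]] <- tibble::tibble(
        chrom = sub$chrom[1], start = min(sub$start), end = max(sub$end),
        type = if (ignore_type) NA_character_ else sub$type[1],
        populations = list(pops), n_populations = length(pops),
        n_events = nrow(sub), exclusive = length(pops) == 1)
    }
  }
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$chrom, .data$start,
                        .data$end)
  out <- dplyr::mutate(out, size_kb = span_kb(.data$start, .data$end),
                       cnp_id = sprintf("cnp_%03d", dplyr::row_number()),
                       .before = 1)
  class(out) <- c("or_sharing", class(out))
  out
}

#' Summaries of the sharing table
#'
#' Venn-style tallies of a [sharing_table()]: per-population totals and
#' exclusive counts, CNP counts by number of carrying populations, and
#' pairwise shared counts.
#'
#' @param records An [sharing_table()] result.
#' @return List of tibbles: `per_population` (`population`, `n_total`,
#'   `n_exclusive`), `by_k` (`n_populations`, `n_cnps`), `pairwise`
#'   (`pop_a`, `pop_b`, `n_shared`).
#' @export
sharing_summary <- function(records) {
  assert_cols(records, c("populations", "exclusive"), "records")
  long <- tidyr::unnest(
    dplyr::select(records, "cnp_id", "populations", "exclusive"),
    "populations")
  per_pop <- dplyr::summarise(
    dplyr::group_by(long, population = .data$populations),
    n_total = dplyr::n(), n_exclusive = sum(.data$exclusive),
    .groups = "drop")
  by_k <- dplyr::count(records, .data$n_populations, name = "n_cnps")
  pops <- sort(unique(long$populations))
  pairs <- list()
  if (length(pops) >= 2) {
    cmb <- utils::combn(pops, 2)
    for (k in seq_len(ncol(cmb))) {
      a <- cmb[1, k]; b <- cmb[2, k]
      n_shared <- sum(vapply(records$populations,
                             function(p) all(c(a, b) %in% p), logical(1)))
      pairs[[k]] <- tibble::tibble(pop_a = a, pop_b = b, n_shared = n_shared)
    }
  }
  list(per_population = per_pop, by_k = by_k,
       pairwise = dplyr::bind_rows(pairs))
}

#' Presence/absence matrix of CNPs across populations
#'
#' Wide Y/blank matrix (one row per CNP, one column per population), the
#' supplementary-table style of reporting cross-population CNP sharing.
#'
#' @param records An [sharing_table()] result.
#' @return Tibble: `cnp_id`, `chrom`, `start`, `end`, `size_kb`, then one
#'   `"Y"`/`""` column per population.
#' @export
sharing_matrix <- function(records) {
  long <- tidyr::unnest(
    dplyr::select(records, "cnp_id", "chrom", "start", "end", "size_kb",
                  "populations"),
    "populations")
  long$present <- "Y"
  tidyr::pivot_wider(long, names_from = "populations",
                     values_from = "present", values_fill = "",
                     names_sort = TRUE)
}

#' Conserved breakpoints across CNPs
#'
#' Groups CNPs sharing a start (or end) coordinate within `tolerance` bp
#' on the same chromosome -- the "common start point, alternate end
#' points" pattern of recurrent breakpoint reuse. With the default
#' tolerance 0 only exact coordinate identity groups.
#'
#' @param records An [sharing_table()] result (or any tibble with `chrom`,
#'   `start`, `end` and an id column `cnp_id`).
#' @param tolerance Coordinate tolerance in bp.
#' @return Tibble: `side` (`start`/`end`), `chrom`, `coord`
#'   (representative, the group minimum), `n`, `cnp_ids` (list column).
#' @export
conserved_breakpoints <- function(records, tolerance = 0) {
  assert_cols(records, c("chrom", "start", "end"), "records")
  records <- ensure_call_id(records, "cnp_id")
  one_side <- function(side) {
    coord <- records[[side]]
    df <- tibble::tibble(chrom = records$chrom, coord = coord,
                         id = records$cnp_id)
    df <- df[order(df$chrom, df$coord), , drop = FALSE]
    out <- list()
    for (ch in unique(df$chrom)) {
      d <- df[df$chrom == ch, , drop = FALSE]
      grp <- cumsum(c(1, diff(d$coord) > tolerance))
      for (gi in unique(grp)) {
        sel <- grp == gi
        if (sum(sel) < 2) next
        out[[length(out) + 1]] <- tibble::tibble(
          side = side, chrom = ch, coord = min(d$coord[sel]),
          n = sum(sel), cnp_ids = list(sort(d$id[sel])))
      }
    }
    dplyr::bind_rows(out)
  }
  dplyr::bind_rows(one_side("start"), one_side("end"))
}
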