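#' Attach repertoire genes to CNV calls
#'
#' A gene is attached to a call when their intervals overlap by at least
#' 1 bp (any-overlap rule, the convention under which a CNV "contains" the
#' genes its span touches). Calls hitting no gene are kept with `NA` gene
#' columns so per-call gene counts are easy to compute.
#'
#' @param calls Call tibble (`chrom`, `start`, `end`; a `call_id` column is
#'   added if absent).
#' @param genes Gene tibble from [simulate_annotation()] or
#'   [read_annotation_bed()].
#' @return Long tibble: one row per (call, overlapping gene), calls without
#'   genes carried with `NA` `symbol`.
#' @export
intersect_genes <- function(calls, genes) {
  assert_cols(calls, c("chrom", "start", "end"), "calls")
  assert_cols(genes, c("symbol", "chrom", "start", "end", "status"), "genes")
  calls <- ensure_call_id(calls)
  gene_cols <- dplyr::select(genes, gene_chrom = "chrom",
                             gene_start = "start", gene_end = "end",
                             "symbol", "status",
                             dplyr::any_of(c("family", "subfamily", "cluster")))
  joined <- dplyr::inner_join(calls, gene_cols,
                              by = c(chrom = "gene_chrom"),
                              relationship = "many-to-many")
  joined <- dplyr::filter(
    joined,
    intersect_len(.data$start, .data$end,
                  .data$gene_start, .data$gene_end) > 0)
  missed <- calls[!calls$call_id %in% joined$call_id, , drop = FALSE]
  dplyr::arrange(dplyr::bind_rows(joined, missed),
                 .data$chrom, .data$start, .data$gene_start)
}

#' Population-level repertoire CNV statistics
#'
#' Per-population summaries in the style of repertoire survey figures:
#' percent of subjects carrying at least one gene-hitting CNV; percent of
#' the catalogue that is copy-number variable; duplication versus deletion
#' percentages among gene-hitting events (summing to 100); intact versus
#' pseudogene percentages among distinct hit genes (summing to 100); and
#' mean duplicated/deleted gene counts per individual.
#'
#' @param calls Call tibble (`sample`, `chrom`, `start`, `end`, `type`).
#' @param genes Gene catalogue tibble.
#' @param samples Tibble `sample`, `population` (each sample in exactly one
#'   population).
#' @return Tibble of class `or_repertoire_stats`, one row per population.
#' @export
repertoire_stats <- function(calls, genes, samples) {
  assert_cols(samples, c("sample", "population"), "samples")
  assert_cols(calls, c("sample", "chrom", "start", "end", "type"), "calls")
  if (anyDuplicated(samples$sample)) {
    stop("each sample must appear once in `samples`", call. = FALSE)
  }
  ann <- intersect_genes(calls, genes)
  hits <- dplyr::filter(ann, !is.na(.data$symbol))
  hits$population <- NULL  # authoritative assignment comes from `samples`
  hits <- dplyr::left_join(hits, samples, by = "sample")
  n_genes_total <- nrow(genes)

  pops <- unique(samples$population)
  rows <- lapply(pops, function(p) {
    samp_p <- samples$sample[samples$population == p]
    if (length(samp_p) == 0) {
      warning("population ", p, " has no samples; omitted", call. = FALSE)
      return(NULL)
    }
    h <- hits[hits$population %in% p, , drop = FALSE]
    carriers <- unique(h$sample)
    ev <- dplyr::distinct(h, .data$call_id, .keep_all = TRUE)
    n_dup <- sum(ev$type == "dup"); n_del <- sum(ev$type == "del")
    gene_tab <- dplyr::distinct(h, .data$symbol, .keep_all = TRUE)
    n_int <- sum(gene_tab$status == "intact")
    n_pse <- sum(gene_tab$status == "pseudogene")
    per_sample <- function(ty) {
      cnt <- dplyr::summarise(
        dplyr::group_by(h[h$type == ty, , drop = FALSE], .data$sample),
        n = dplyr::n_distinct(.data$symbol), .groups = "drop")
      sum(cnt$n) / length(samp_p)
    }
    tibble::tibble(
      population = p,
      n_samples = length(samp_p),
      pct_subjects_with_or_cnv = 100 * length(carriers) / length(samp_p),
      pct_repertoire_variable =
        100 * dplyr::n_distinct(h$symbol) / n_genes_total,
      pct_dup = if (n_dup + n_del > 0) 100 * n_dup / (n_dup + n_del) else NA_real_,
      pct_del = if (n_dup + n_del > 0) 100 * n_del / (n_dup + n_del) else NA_real_,
      pct_intact = if (n_int + n_pse > 0) 100 * n_int / (n_int + n_pse) else NA_real_,
      pct_pseudo = if (n_int + n_pse > 0) 100 * n_pse / (n_int + n_pse) else NA_real_,
      mean_gene_dups = per_sample("dup"),
      mean_gene_dels = per_sample("del"))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("or_repertoire_stats", class(out))
  out
}

#' Classify trio calls as inherited or de novo
#'
#' A child call is `inherited` when a call of the same type in either
#' parent matches it at `min_overlap` reciprocal overlap (the same 50%
#' rule used for call validation), `de_novo` otherwise, and `unknown` when
#' a parent is missing from the pedigree (`NA`); unknowns are excluded
#' from summary fractions.
#'
#' @param child_calls Calls of trio children (`sample`, `chrom`, `start`,
#'   `end`, `type`).
#' @param parent_calls Calls of the parents.
#' @param pedigree Tibble `child`, `father`, `mother`.
#' @param min_overlap Reciprocal-overlap threshold for a match.
#' @return `child_calls` with an `origin` column.
#' @export
classify_inheritance <- function(child_calls, parent_calls, pedigree,
                                 min_overlap = 0.5) {
  assert_cols(pedigree, c("child", "father", "mother"), "pedigree")
  assert_cols(child_calls, c("sample", "chrom", "start", "end", "type"),
              "child_calls")
  origin <- character(nrow(child_calls))
  for (i in seq_len(nrow(child_calls))) {
    ped <- pedigree[pedigree$child == child_calls$sample[i], , drop = FALSE]
    if (nrow(ped) == 0 || is.na(ped$father[1]) || is.na(ped$mother[1])) {
      origin[i] <- "unknown"
      next
    }
    pc <- parent_calls[parent_calls$sample %in% c(ped$father[1], ped$mother[1]) &
                         parent_calls$type == child_calls$type[i] &
                         parent_calls$chrom == child_calls$chrom[i], ,
                       drop = FALSE]
    if (nrow(pc) == 0) {
      origin[i] <- "de_novo"
      next
    }
    ov <- reciprocal_overlap(child_calls[i, c("chrom", "start", "end")],
                             pc[, c("chrom", "start", "end")], min_overlap)
    origin[i] <- if (any(ov$passes)) "inherited" else "de_novo"
  }
  dplyr::mutate(child_calls, origin = origin)
}

#' Summarize inherited versus de novo fractions
#'
#' Reports, for duplications and deletions separately, the inherited and
#' de novo call counts with two explicitly labelled normalizations: within
#' the call's own type (`pct_inherited_of_type`) and over all classified
#' calls (`pct_of_all_calls`). Reporting both avoids committing to either
#' convention used in published trio summaries.
#'
#' @param classified Output of [classify_inheritance()].
#' @return Tibble with one row per (type, origin).
#' @export
inheritance_summary <- function(classified) {
  assert_cols(classified, c("type", "origin"), "classified")
  known <- classified[classified$origin != "unknown", , drop = FALSE]
  if (nrow(known) == 0) {
    return(tibble::tibble(type = character(), origin = character(),
                          n = integer(), pct_inherited_of_type = numeric(),
                          pct_of_all_calls = numeric()))
  }
  tot <- nrow(known)
  out <- dplyr::summarise(
    dplyr::group_by(known, .data$type, .data$origin),
    n = dplyr::n(), .groups = "drop_last")
  out <- dplyr::mutate(out, pct_of_type = 100 * .data$n / sum(.data$n))
  dplyr::mutate(dplyr::ungroup(out), pct_of_all_calls = 100 * .data$n / tot)
}
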