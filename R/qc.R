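#' Retention criteria for collated CNV calls
#'
#' The standard retention rules for array CNP calls: LOD of at least
#' `min_lod` (default 10, the conventional ~5% FDR cutoff; calls without a
#' LOD, e.g. region genotyper calls, are not LOD-filtered), size strictly
#' greater than `min_size_bp` (default 1000) and strictly more than
#' `min_probes` probes (default 5), non-diploid state only, and region
#' genotyper calls retained only when the sample's state differs from the
#' population mode.
#'
#' @param min_lod Minimum LOD score (inclusive).
#' @param min_size_bp Size threshold in bp (exclusive: size must exceed it).
#' @param min_probes Probe-count threshold (exclusive).
#' @param keep_state_ne_2 Drop diploid-state calls.
#' @param cnp_mode_rule Keep `canary` calls only when state differs from
#'   the population mode.
#' @return Object of class `retention_criteria`.
#' @export
retention_criteria <- function(min_lod = 10, min_size_bp = 1000L,
                               min_probes = 5L, keep_state_ne_2 = TRUE,
                               cnp_mode_rule = TRUE) {
  if (min_lod < 0 || min_size_bp < 0 || min_probes < 0) {
    stop("retention thresholds must be nonnegative", call. = FALSE)
  }
  structure(list(min_lod = min_lod, min_size_bp = min_size_bp,
                 min_probes = min_probes, keep_state_ne_2 = keep_state_ne_2,
                 cnp_mode_rule = cnp_mode_rule),
            class = "retention_criteria")
}

known_algorithms <- c("hmm", "birdsuite", "canary", "threshold", "cnvfinder",
                      "gtc", "reference")

check_algorithm_tags <- function(tags) {
  parts <- unique(unlist(strsplit(tags, "+", fixed = TRUE)))
  bad <- setdiff(parts, known_algorithms)
  if (length(bad) > 0) {
    stop("unknown algorithm tag(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(tags)
}

#' Reciprocal overlap of two interval sets
#'
#' For paired intervals `a` and `b` (recycled row-wise), returns the
#' fraction of each interval covered by their intersection, with sizes
#' computed as `end - start`. The validation predicate used throughout the
#' pipeline is `min(frac_a, frac_b) >= threshold` (both intervals must pass
#' -- "reciprocal"). Intervals on different chromosomes overlap by 0.
#'
#' @param a,b Data frames with columns `chrom`, `start`, `end` (one may
#'   have a single row, which is recycled).
#' @param threshold Pass threshold for the `passes` column.
#' @return Tibble with `frac_a`, `frac_b`, `passes`.
#' @export
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 100, end = 200)
#' b <- tibble::tibble(chrom = "chr1", start = 150, end = 250)
#' reciprocal_overlap(a, b)  # 0.5 / 0.5, passes at 50%
reciprocal_overlap <- function(a, b, threshold = 0.5) {
  assert_cols(a, c("chrom", "start", "end"), "a")
  assert_cols(b, c("chrom", "start", "end"), "b")
  if (any(a$end <= a$start) || any(b$end <= b$start)) {
    stop("intervals must have end > start", call. = FALSE)
  }
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n); bi <- rep_len(seq_len(nrow(b)), n)
  inter <- ifelse(a$chrom[ai] == b$chrom[bi],
                  intersect_len(a$start[ai], a$end[ai],
                                b$start[bi], b$end[bi]), 0)
  frac_a <- inter / (a$end[ai] - a$start[ai])
  frac_b <- inter / (b$end[bi] - b$start[bi])
  tibble::tibble(frac_a = frac_a, frac_b = frac_b,
                 passes = pmin(frac_a, frac_b) >= threshold)
}

# union-find used for transitive call merging
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Collate calls from multiple algorithms under retention criteria
#'
#' Applies the retention rules of [retention_criteria()] to the union of
#' the supplied call sets, then merges duplicate records: calls from
#' different algorithms on the same sample with the same type and at least
#' 50% reciprocal overlap are collated into a single record spanning the
#' union interval, keeping the maximum LOD and probe count, with the
#' contributing algorithm tags joined by `"+"`. The operation is
#' idempotent.
#'
#' @param callsets A call tibble with an `algorithm` column, or a (possibly
#'   named) list of call tibbles; names supply missing `algorithm` tags.
#' @param criteria A [retention_criteria()].
#' @param merge_overlap Reciprocal-overlap threshold for the duplicate
#'   merge.
#' @return Retained, collated call tibble.
#' @export
collate_calls <- function(callsets, criteria = retention_criteria(),
                          merge_overlap = 0.5) {
  stopifnot(inherits(criteria, "retention_criteria"))
  if (is.data.frame(callsets)) {
    calls <- callsets
  } else {
    calls <- dplyr::bind_rows(lapply(seq_along(callsets), function(i) {
      cs <- callsets[[i]]
      if (!"algorithm" %in% names(cs) && !is.null(names(callsets))) {
        cs$algorithm <- names(callsets)[i]
      }
      cs
    }))
  }
  assert_cols(calls, c("sample", "chrom", "start", "end", "copy_state",
                       "n_probes", "type", "algorithm"), "calls")
  check_algorithm_tags(calls$algorithm)
  if (!"lod" %in% names(calls)) calls$lod <- NA_real_

  keep <- rep(TRUE, nrow(calls))
  keep <- keep & (is.na(calls$lod) | calls$lod >= criteria$min_lod)
  keep <- keep & (calls$end - calls$start) > criteria$min_size_bp
  keep <- keep & calls$n_probes > criteria$min_probes
  if (criteria$keep_state_ne_2) keep <- keep & calls$copy_state != 2L
  if (criteria$cnp_mode_rule && "mode_state" %in% names(calls)) {
    is_canary <- grepl("canary", calls$algorithm, fixed = TRUE)
    keep <- keep & (!is_canary | is.na(calls$mode_state) |
                      calls$copy_state != calls$mode_state)
  }
  calls <- calls[keep, , drop = FALSE]
  if (nrow(calls) == 0) return(calls)

  # transitive merge of cross-algorithm duplicates (same sample and type)
  calls <- dplyr::arrange(calls, .data$sample, .data$chrom, .data$start,
                          .data$end, .data$algorithm)
  parent <- seq_len(nrow(calls))
  groups <- split(seq_len(nrow(calls)),
                  paste(calls$sample, calls$type, calls$chrom))
  for (idx in groups) {
    if (length(idx) < 2) next
    for (ii in seq_along(idx)) {
      for (jj in seq_len(ii - 1L)) {
        i <- idx[ii]; j <- idx[jj]
        if (calls$start[i] >= calls$end[j] && calls$start[j] >= calls$end[i])
          next
        if (identical(calls$algorithm[i], calls$algorithm[j])) next
        ov <- reciprocal_overlap(calls[i, ], calls[j, ], merge_overlap)
        if (ov$passes) {
          ri <- uf_find(parent, i); rj <- uf_find(parent, j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  roots <- vapply(seq_len(nrow(calls)), function(i) uf_find(parent, i),
                  integer(1))
  merged <- dplyr::group_by(dplyr::mutate(calls, .root = roots), .data$.root)
  out <- dplyr::summarise(
    merged,
    sample = .data$sample[1], chrom = .data$chrom[1],
    start = min(.data$start), end = max(.data$end),
    copy_state = .data$copy_state[which.max(dplyr::coalesce(.data$lod, -Inf))],
    lod = if (all(is.na(.data$lod))) NA_real_ else max(.data$lod, na.rm = TRUE),
    n_probes = max(.data$n_probes),
    type = .data$type[1],
    algorithm = paste(sort(unique(unlist(
      strsplit(.data$algorithm, "+", fixed = TRUE)))), collapse = "+"),
    .groups = "drop")
  dplyr::arrange(dplyr::select(out, -".root"), .data$sample, .data$chrom,
                 .data$start)
}

#' Jaccard similarity of two call sets
#'
#' Matches calls one-to-one between the two sets (same sample where
#' available, same type unless `ignore_type`, at least `min_overlap`
#' reciprocal overlap), greedily by descending overlap, and returns
#' `|matched| / (|a| + |b| - |matched|)`. Losses and gains are handled
#' separately by the same-type rule. Two empty sets compare as 1 with a
#' warning.
#'
#' @param a,b Call tibbles (`chrom`, `start`, `end`, `type`, optional
#'   `sample`).
#' @param min_overlap Reciprocal-overlap threshold for a match.
#' @param ignore_type Match across types.
#' @return Jaccard statistic in \[0, 1\].
#' @export
jaccard_callsets <- function(a, b, min_overlap = 0.5, ignore_type = FALSE) {
  if (nrow(a) == 0 && nrow(b) == 0) {
    warning("both call sets empty; Jaccard defined as 1", call. = FALSE)
    return(1)
  }
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  pairs <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if ("sample" %in% names(a) && "sample" %in% names(b) &&
          a$sample[i] != b$sample[j]) next
      if (!ignore_type && a$type[i] != b$type[j]) next
      ov <- reciprocal_overlap(a[i, ], b[j, ], min_overlap)
      if (ov$passes) {
        pairs[[length(pairs) + 1]] <-
          c(i = i, j = j, w = min(ov$frac_a, ov$frac_b))
      }
    }
  }
  if (length(pairs) == 0) return(0)
  pm <- do.call(rbind, pairs)
  pm <- pm[order(-pm[, "w"], pm[, "i"], pm[, "j"]), , drop = FALSE]
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  n_match <- 0L
  for (r in seq_len(nrow(pm))) {
    i <- pm[r, "i"]; j <- pm[r, "j"]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE
      n_match <- n_match + 1L
    }
  }
  n_match / (nrow(a) + nrow(b) - n_match)
}

#' Sample-level quality control
#'
#' Flags samples whose genotyping call rate or contrast QC fall at or below
#' the pass thresholds (strictly greater than 0.97 and 0.4 respectively by
#' default, the conventional array QC gates), samples with missing metrics,
#' and samples on a configured exclusion list (e.g. population-structure
#' outliers identified externally).
#'
#' @param metrics Tibble with `sample`, `call_rate`, `contrast_qc`.
#' @param min_call_rate,min_contrast_qc Pass thresholds (exclusive).
#' @param exclusions Character vector of sample ids excluded regardless of
#'   metrics.
#' @return Tibble `sample`, `call_rate`, `contrast_qc`, `excluded`,
#'   `reason`.
#' @export
sample_qc <- function(metrics, min_call_rate = 0.97, min_contrast_qc = 0.4,
                      exclusions = character()) {
  assert_cols(metrics, c("sample", "call_rate", "contrast_qc"), "metrics")
  reason <- character(nrow(metrics))
  missing <- is.na(metrics$call_rate) | is.na(metrics$contrast_qc)
  low_cr <- !missing & metrics$call_rate <= min_call_rate
  low_cq <- !missing & metrics$contrast_qc <= min_contrast_qc
  listed <- metrics$sample %in% exclusions
  reason[low_cq] <- "contrast_qc"
  reason[low_cr] <- ifelse(reason[low_cr] == "", "call_rate",
                           paste(reason[low_cr], "call_rate", sep = ";"))
  reason[missing] <- "missing"
  reason[listed] <- "exclusion_list"
  tibble::tibble(sample = metrics$sample, call_rate = metrics$call_rate,
                 contrast_qc = metrics$contrast_qc,
                 excluded = missing | low_cr | low_cq | listed,
                 reason = dplyr::na_if(reason, ""))
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate, in (0, 1).
#' @param n_tests Number of tests, at least 1.
#' @return `alpha / n_tests`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 5e5)  # 1e-7
bonferroni_threshold <- function(alpha, n_tests) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  }
  if (n_tests < 1) stop("`n_tests` must be >= 1", call. = FALSE)
  alpha / n_tests
}
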