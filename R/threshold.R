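#' Robust multiple-threshold CNV caller
#'
#' A threshold caller in the style of array CNV detectors that assume the
#' bulk of probes is normally distributed around a log2 ratio of zero. The
#' central distribution's spread is estimated robustly (MAD about the
#' median, per sample and chromosome), so planted events do not inflate it.
#' A candidate run must contain at least one probe beyond the outer
#' threshold (`max(k_sd)` sds) and is extended over consecutive probes
#' beyond the inner threshold (`min(k_sd)` sds) of the same sign; runs of
#' at least `min_probes` probes are emitted, and same-type runs separated
#' by fewer than `gap_probes` probes are merged. Calls are typed by sign
#' (nominal state 3 for gains, 1 for losses) and LOD-scored against the
#' diploid state.
#'
#' @param track Probe tibble (`chrom`, `pos`, `log2ratio`, optional
#'   `sample`).
#' @param k_sd Numeric vector of threshold multiples; the smallest is the
#'   extension threshold, the largest the seed threshold.
#' @param min_probes Minimum probes per emitted run.
#' @param gap_probes Runs separated by fewer than this many probes merge.
#' @param params [hmm_params()] used only for LOD scoring of the result.
#' @return Call tibble as in [hmm_segment()], `algorithm = "threshold"`.
#' @export
threshold_caller <- function(track, k_sd = c(2, 4), min_probes = 5L,
                             gap_probes = 2L, params = hmm_params()) {
  if (nrow(track) == 0) stop("track is empty", call. = FALSE)
  check_sorted_track(track)
  grouping <- if ("sample" %in% names(track)) c("sample", "chrom") else "chrom"
  pieces <- dplyr::group_split(dplyr::group_by(
    track, dplyr::across(dplyr::all_of(grouping))))
  k_in <- min(k_sd); k_out <- max(k_sd)
  calls <- dplyr::bind_rows(lapply(pieces, function(df) {
    x <- df$log2ratio
    ctr <- median(x)
    s <- mad(x, center = ctr)
    if (s == 0) {
      warning("zero spread estimate; no calls emitted", call. = FALSE)
      return(NULL)
    }
    out <- list()
    for (sign_dir in c(1, -1)) {
      dev <- sign_dir * (x - ctr)
      ext <- dev > k_in * s
      seed <- dev > k_out * s
      r <- rle(ext)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      runs <- which(r$values)
      kept <- list()
      for (ri in runs) {
        i1 <- starts[ri]; i2 <- ends[ri]
        if (i2 - i1 + 1L < min_probes) next
        if (!any(seed[i1:i2])) next
        kept[[length(kept) + 1]] <- c(i1, i2)
      }
      if (length(kept) == 0) next
      # merge runs separated by < gap_probes probes
      merged <- list(kept[[1]])
      for (kk in kept[-1]) {
        last <- merged[[length(merged)]]
        if (kk[1] - last[2] - 1L < gap_probes) {
          merged[[length(merged)]] <- c(last[1], kk[2])
        } else {
          merged[[length(merged) + 1]] <- kk
        }
      }
      for (mm in merged) {
        out[[length(out) + 1]] <- tibble::tibble(
          chrom = df$chrom[1], start = df$pos[mm[1]], end = df$pos[mm[2]],
          copy_state = if (sign_dir > 0) 3L else 1L,
          n_probes = mm[2] - mm[1] + 1L,
          type = if (sign_dir > 0) "dup" else "del",
          sample = if ("sample" %in% names(df)) df$sample[1] else NA_character_)
      }
    }
    dplyr::bind_rows(out)
  }))
  if (nrow(calls) == 0) {
    return(empty_calls(has_sample = "sample" %in% names(track)))
  }
  if (!"sample" %in% names(track)) calls$sample <- NULL
  calls$lod <- lod_score(track, calls, params)
  calls$algorithm <- "threshold"
  sel <- intersect(c("sample", "chrom", "start", "end", "copy_state", "lod",
                     "n_probes", "type", "algorithm"), names(calls))
  calls[, sel]
}
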