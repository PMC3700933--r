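#' HMM parameters for copy-number segmentation
#'
#' A five-state (copy number 0-4) homogeneous hidden Markov model with
#' homoscedastic Gaussian emissions. The hidden state is the true integer
#' copy number; the observed state is the probe's normalized log2 ratio.
#' Self-transition probability defaults to 0.999 (expected run length about
#' 1000 probes before a switch), which favors multi-probe events over
#' single-probe noise; the remaining mass is spread uniformly over the
#' other four states.
#'
#' @param state_means Named numeric vector of emission means per copy state
#'   (default [or_state_means()]).
#' @param emission_sd Emission standard deviation (log2-ratio units).
#' @param stay_prob Self-transition probability, in (0, 1).
#' @return Object of class `hmm_params`.
#' @export
#' @examples
#' hmm_params(emission_sd = 0.1)
hmm_params <- function(state_means = or_state_means(), emission_sd = 0.2,
                       stay_prob = 0.999) {
  if (!identical(sort(names(state_means)), as.character(0:4))) {
    stop("`state_means` must be named \"0\"..\"4\"", call. = FALSE)
  }
  assert_positive(emission_sd, "emission_sd")
  if (stay_prob <= 0 || stay_prob >= 1) {
    stop("`stay_prob` must be in (0, 1)", call. = FALSE)
  }
  structure(list(state_means = state_means[as.character(0:4)],
                 emission_sd = emission_sd, stay_prob = stay_prob),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("<hmm_params> states 0..4\n")
  cat("  means:", paste(sprintf("%.3f", x$state_means), collapse = " "), "\n")
  cat("  emission sd:", x$emission_sd, " stay prob:", x$stay_prob, "\n")
  invisible(x)
}

check_sorted_track <- function(track) {
  assert_cols(track, c("chrom", "pos", "log2ratio"), "track")
  grouping <- intersect(c("sample", "chrom"), names(track))
  ok <- dplyr::summarise(
    dplyr::group_by(track, dplyr::across(dplyr::all_of(grouping))),
    sorted = !is.unsorted(.data$pos, strictly = FALSE), .groups = "drop")
  if (!all(ok$sorted)) {
    stop("track must be sorted by position within chromosome", call. = FALSE)
  }
  invisible(track)
}

# decode one sorted single-chromosome track; returns calls without sample col
decode_chrom <- function(chrom_df, params) {
  states <- viterbi_gaussian_cpp(
    chrom_df$log2ratio, unname(params$state_means), params$emission_sd,
    log(params$stay_prob), log((1 - params$stay_prob) / 4), 2L)
  r <- rle(states)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 2L
  if (!any(keep)) return(NULL)
  tibble::tibble(
    chrom = chrom_df$chrom[1],
    start = chrom_df$pos[starts[keep]],
    end = chrom_df$pos[ends[keep]],
    copy_state = as.integer(r$values[keep]),
    n_probes = r$lengths[keep],
    type = ifelse(r$values[keep] > 2, "dup", "del"))
}

#' Segment probe tracks into CNV calls by Viterbi decoding
#'
#' Decodes the most likely copy-state path per chromosome and emits one
#' call per maximal run of constant non-diploid state. Call boundaries are
#' the first and last probe positions of the run (marker-delimited
#' breakpoints). Ties in the decoder are broken toward the diploid state,
#' which makes calling conservative. Each call is scored with
#' [lod_score()].
#'
#' @param track Probe tibble with columns `chrom`, `pos`, `log2ratio` and
#'   optionally `sample` (multi-sample input is decoded per sample).
#' @param params An [hmm_params()].
#' @return Tibble of calls: `sample` (if present), `chrom`, `start`, `end`,
#'   `copy_state`, `lod`, `n_probes`, `type` (`dup`/`del`), `algorithm`
#'   (`"hmm"`).
#' @export
#' @examples
#' track <- tibble::tibble(chrom = "chr1", pos = seq(600, 60000, 600),
#'                         log2ratio = 0)
#' hmm_segment(track, hmm_params())  # all-diploid: no calls
hmm_segment <- function(track, params = hmm_params()) {
  stopifnot(inherits(params, "hmm_params"))
  if (nrow(track) == 0) return(empty_calls(has_sample = "sample" %in% names(track)))
  check_sorted_track(track)
  grouping <- if ("sample" %in% names(track)) c("sample", "chrom") else "chrom"
  pieces <- dplyr::group_split(dplyr::group_by(
    track, dplyr::across(dplyr::all_of(grouping))))
  calls <- dplyr::bind_rows(lapply(pieces, function(df) {
    out <- decode_chrom(df, params)
    if (is.null(out)) return(NULL)
    if ("sample" %in% names(df)) {
      out <- dplyr::mutate(out, sample = df$sample[1], .before = 1)
    }
    out
  }))
  if (nrow(calls) == 0) {
    return(empty_calls(has_sample = "sample" %in% names(track)))
  }
  calls$lod <- lod_score(track, calls, params)
  calls$algorithm <- "hmm"
  sel <- intersect(c("sample", "chrom", "start", "end", "copy_state", "lod",
                     "n_probes", "type", "algorithm"), names(calls))
  calls[, sel]
}

empty_calls <- function(has_sample = TRUE) {
  out <- tibble::tibble(chrom = character(), start = numeric(),
                        end = numeric(), copy_state = integer(),
                        lod = numeric(), n_probes = integer(),
                        type = character(), algorithm = character())
  if (has_sample) out <- dplyr::mutate(out, sample = character(), .before = 1)
  out
}

#' Log10-odds score of a called copy state against diploid
#'
#' For each call, sums over the probes inside the call span the log10 ratio
#' of the Gaussian emission likelihood under the called state versus under
#' copy state 2. Scores of independent segments are additive, and for fixed
#' per-probe evidence the score grows linearly with segment length. A
#' retention threshold of 10 is the conventional cutoff (approximate FDR of
#' about 5% in array CNP calling).
#'
#' @param track Probe tibble (`chrom`, `pos`, `log2ratio`, optional
#'   `sample`).
#' @param calls Call tibble (`chrom`, `start`, `end`, `copy_state`, optional
#'   `sample`); probes with `start <= pos <= end` are scored.
#' @param params An [hmm_params()].
#' @return Numeric vector of LOD scores, one per call row.
#' @export
#' @examples
#' track <- tibble::tibble(chrom = "chr1", pos = 600, log2ratio = -1)
#' call <- tibble::tibble(chrom = "chr1", start = 600, end = 600,
#'                        copy_state = 1L)
#' lod_score(track, call, hmm_params(emission_sd = 0.25))  # ~3.47
lod_score <- function(track, calls, params = hmm_params()) {
  assert_cols(calls, c("chrom", "start", "end", "copy_state"), "calls")
  m <- params$state_means
  sd <- params$emission_sd
  vapply(seq_len(nrow(calls)), function(i) {
    sel <- track$chrom == calls$chrom[i] & track$pos >= calls$start[i] &
      track$pos <= calls$end[i]
    if ("sample" %in% names(calls) && "sample" %in% names(track)) {
      sel <- sel & track$sample == calls$sample[i]
    }
    x <- track$log2ratio[sel]
    if (length(x) == 0) stop("call ", i, " covers no probes", call. = FALSE)
    mu_s <- m[[as.character(calls$copy_state[i])]]
    sum(dnorm(x, mu_s, sd, log = TRUE) - dnorm(x, m[["2"]], sd, log = TRUE)) /
      log(10)
  }, numeric(1))
}
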