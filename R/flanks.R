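#' Extract 1 kb breakpoint flanks from a genome
#'
#' For each call, the upstream flank covers the 1 kb immediately before the
#' start point (positions `start - flank_bp` to `start - 1`) and the
#' downstream flank the 1 kb immediately after the end point (positions
#' `end + 1` to `end + flank_bp`). Flanks running off a chromosome edge
#' are truncated and flagged.
#'
#' @param calls Call tibble (`chrom`, `start`, `end`; `call_id` added if
#'   absent).
#' @param genome Named character vector/list of chromosome sequences, or a
#'   FASTA path (read with [read_genome_fasta()]).
#' @param flank_bp Flank length (default 1000).
#' @return Tibble: `flank_id`, `call_id`, `side`, `chrom`, `start`, `end`
#'   (package-wide span convention: size is `end - start`), `truncated`,
#'   `sequence`.
#' @export
extract_flanks <- function(calls, genome, flank_bp = 1000L) {
  assert_cols(calls, c("chrom", "start", "end"), "calls")
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- read_genome_fasta(genome)
  }
  genome <- as.list(genome)
  calls <- ensure_call_id(calls)
  rows <- list()
  for (i in seq_len(nrow(calls))) {
    ch <- calls$chrom[i]
    if (!ch %in% names(genome)) {
      stop("chromosome ", ch, " not in genome", call. = FALSE)
    }
    clen <- nchar(genome[[ch]])
    for (side in c("upstream", "downstream")) {
      if (side == "upstream") {
        lo <- calls$start[i] - flank_bp; hi <- calls$start[i] - 1L
      } else {
        lo <- calls$end[i] + 1L; hi <- calls$end[i] + flank_bp
      }
      lo_c <- max(1L, lo); hi_c <- min(clen, hi)
      if (hi_c < lo_c) {
        stop("flank entirely outside chromosome for call ",
             calls$call_id[i], call. = FALSE)
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        flank_id = paste0(calls$call_id[i], "_", side),
        call_id = calls$call_id[i], side = side, chrom = ch,
        start = lo_c, end = hi_c + 1L,
        truncated = lo_c != lo || hi_c != hi,
        sequence = substr(genome[[ch]], lo_c, hi_c))
    }
  }
  dplyr::bind_rows(rows)
}

#' Optimal local alignment (Smith-Waterman, affine gaps)
#'
#' Exact optimal local alignment under affine gap scoring. Defaults:
#' match +1, mismatch -1, gap open -2 for the first gapped column and
#' gap extend -1 for each further column. Percent identity is
#' `100 * matches / alignment_columns`, with gap columns (and `N`s)
#' counting against identity.
#'
#' @param query,subject DNA strings over `ACGTN` (case-insensitive).
#' @param match,mismatch,gap_open,gap_ext Scoring parameters (penalties
#'   negative).
#' @return One-row tibble: `score`, `q_start`, `q_end`, `s_start`, `s_end`,
#'   `matches`, `columns`, `pct_identity`, `aligned_query`,
#'   `aligned_subject`.
#' @export
#' @examples
#' local_align("ACGTACGT", "TTACGTACGTTT")
local_align <- function(query, subject, match = 1, mismatch = -1,
                        gap_open = -2, gap_ext = -1) {
  query <- clean_dna(query, "query"); subject <- clean_dna(subject, "subject")
  res <- align_pair_cpp(query, subject, match, -abs(mismatch),
                        abs(gap_open), abs(gap_ext), TRUE)
  tibble::tibble(score = res$score, q_start = res$q_start, q_end = res$q_end,
                 s_start = res$s_start, s_end = res$s_end,
                 matches = res$matches, columns = res$columns,
                 pct_identity = res$pct_identity,
                 aligned_query = res$aligned_a,
                 aligned_subject = res$aligned_b)
}

#' Optimal global alignment (Needleman-Wunsch, affine gaps)
#'
#' Same scoring conventions as [local_align()], but end-to-end.
#'
#' @inheritParams local_align
#' @return One-row tibble as in [local_align()].
#' @export
global_align <- function(query, subject, match = 1, mismatch = -1,
                         gap_open = -2, gap_ext = -1) {
  query <- clean_dna(query, "query"); subject <- clean_dna(subject, "subject")
  res <- align_pair_cpp(query, subject, match, -abs(mismatch),
                        abs(gap_open), abs(gap_ext), FALSE)
  tibble::tibble(score = res$score, q_start = res$q_start, q_end = res$q_end,
                 s_start = res$s_start, s_end = res$s_end,
                 matches = res$matches, columns = res$columns,
                 pct_identity = res$pct_identity,
                 aligned_query = res$aligned_a,
                 aligned_subject = res$aligned_b)
}

#' Screen breakpoint flanks against a genome panel
#'
#' Locally aligns each flank against overlapping windows of every
#' chromosome of every genome in the panel and reports loci reaching
#' `min_identity` percent identity with at least `min_coverage` of the
#' flank length aligned (the coverage requirement suppresses spurious
#' short perfect matches in random sequence). Hits at the flank's own
#' origin locus are labelled `self`; other self-genome loci are
#' `paralogous_derived` and hits in other genomes `orthologous`. Per
#' flank, the closest non-self hit in identity is flagged as the nominated
#' recombining region.
#'
#' @param flanks Tibble from [extract_flanks()] or
#'   [simulate_flank_panel()]`$flanks` (`flank_id`, `chrom`, `start`,
#'   `end`, `sequence`).
#' @param panel Named list of genomes (each a named list/vector of
#'   chromosome sequences); the query's own genome must be named `self`.
#' @param min_identity Identity threshold in percent (default 95).
#' @param min_coverage Minimum aligned columns as a fraction of flank
#'   length.
#' @param self Name of the self genome in `panel`.
#' @return Tibble: `flank_id`, `subject_genome`, `chrom`, `start`, `end`,
#'   `score`, `pct_identity`, `columns`, `hit_class`, `nominated`.
#' @export
screen_panel <- function(flanks, panel, min_identity = 95,
                         min_coverage = 0.5, self = "self") {
  assert_cols(flanks, c("flank_id", "chrom", "start", "end", "sequence"),
              "flanks")
  rows <- list()
  for (fi in seq_len(nrow(flanks))) {
    fl <- flanks[fi, ]
    L <- nchar(fl$sequence)
    win <- 2L * L; step <- L
    for (gname in names(panel)) {
      chroms <- panel[[gname]]
      for (ch in names(chroms)) {
        seq_ch <- chroms[[ch]]
        clen <- nchar(seq_ch)
        starts <- unique(c(seq(1L, max(1L, clen - win + 1L), by = step),
                           max(1L, clen - win + 1L)))
        hits <- list()
        for (ws in starts) {
          wseq <- substr(seq_ch, ws, min(clen, ws + win - 1L))
          if (nchar(wseq) < min_coverage * L) next
          al <- local_align(fl$sequence, wseq)
          if (al$score <= 0) next
          if (al$pct_identity < min_identity) next
          if (al$columns < min_coverage * L) next
          hits[[length(hits) + 1]] <- dplyr::mutate(
            al, start = ws + al$s_start - 1L, end = ws + al$s_end - 1L + 1L)
        }
        if (length(hits) == 0) next
        h <- dplyr::arrange(dplyr::bind_rows(hits), .data$start)
        # merge window-duplicated hits at the same locus, keep the best
        h$locus <- cumsum(c(1, h$start[-1] >= cummax(h$end)[-nrow(h)]))
        h <- dplyr::slice_max(dplyr::group_by(h, .data$locus), .data$score,
                              n = 1, with_ties = FALSE)
        h <- dplyr::ungroup(h)
        is_self_locus <- gname == self & ch == fl$chrom &
          intersect_len(h$start, h$end, fl$start, fl$end) > 0
        rows[[length(rows) + 1]] <- tibble::tibble(
          flank_id = fl$flank_id, subject_genome = gname, chrom = ch,
          start = h$start, end = h$end, score = h$score,
          pct_identity = h$pct_identity, columns = h$columns,
          hit_class = dplyr::case_when(
            is_self_locus ~ "self",
            gname == self ~ "paralogous_derived",
            TRUE ~ "orthologous"))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(flank_id = character(), subject_genome = character(),
                          chrom = character(), start = integer(),
                          end = integer(), score = numeric(),
                          pct_identity = numeric(), columns = integer(),
                          hit_class = character(), nominated = logical()))
  }
  out <- dplyr::group_by(out, .data$flank_id)
  out <- dplyr::mutate(
    out,
    nominated = .data$hit_class != "self" &
      seq_len(dplyr::n()) == resolve_nominee(.data$hit_class,
                                             .data$pct_identity,
                                             .data$score))
  dplyr::arrange(dplyr::ungroup(out), .data$flank_id,
                 dplyr::desc(.data$pct_identity), .data$subject_genome,
                 .data$chrom, .data$start)
}

# index of the closest non-self hit (max identity, then score, then order)
resolve_nominee <- function(hit_class, pct_identity, score) {
  cand <- which(hit_class != "self")
  if (length(cand) == 0) return(0L)
  key <- order(-pct_identity[cand], -score[cand], cand)
  cand[key[1]]
}
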