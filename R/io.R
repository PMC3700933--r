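# On-disk contracts. Tab-separated files throughout; BED-like files are
# 0-based half-open on disk and converted to the package's 1-based span
# convention at this boundary. FASTA goes through Biostrings when
# available.

#' Write / read a per-sample probe track TSV
#'
#' Columns: `probe_id`, `chrom`, `pos`, `log2ratio`.
#'
#' @param track Probe tibble.
#' @param path File path.
#' @return `read_probe_track()` returns the tibble (with a `sample` column
#'   when `sample` is given).
#' @param sample Optional sample id attached on read.
#' @export
write_probe_track <- function(track, path) {
  assert_cols(track, c("probe_id", "chrom", "pos", "log2ratio"), "track")
  readr::write_tsv(track[, c("probe_id", "chrom", "pos", "log2ratio")], path)
  invisible(path)
}

#' @rdname write_probe_track
#' @export
read_probe_track <- function(path, sample = NULL) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    probe_id = readr::col_character(), chrom = readr::col_character(),
    pos = readr::col_integer(), log2ratio = readr::col_double()))
  if (!is.null(sample)) out <- dplyr::mutate(out, sample = sample, .before = 1)
  out
}

#' Write / read CNV calls as TSV
#'
#' Plain 1-based columns as used in memory (`sample`, `chrom`, `start`,
#' `end`, `copy_state`, `lod`, `n_probes`, `type`, `algorithm`).
#'
#' @param calls Call tibble.
#' @param path File path.
#' @export
write_calls_tsv <- function(calls, path) {
  readr::write_tsv(calls, path)
  invisible(path)
}

#' @rdname write_calls_tsv
#' @export
read_calls_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), start = readr::col_double(),
    end = readr::col_double(), .default = readr::col_guess()))
}

#' Write CNV calls as BED9 for genome browsers
#'
#' 0-based half-open coordinates; duplications colored red, deletions
#' blue via `itemRgb`.
#'
#' @param calls Call tibble.
#' @param path File path.
#' @export
write_calls_bed <- function(calls, path) {
  assert_cols(calls, c("chrom", "start", "end", "type"), "calls")
  calls <- ensure_call_id(calls)
  bed <- tibble::tibble(
    chrom = calls$chrom, start = calls$start - 1L, end = calls$end - 1L,
    name = calls$call_id,
    score = round(pmin(1000, pmax(0, (calls$lod %||% 0) * 10))),
    strand = ".", thickStart = calls$start - 1L, thickEnd = calls$end - 1L,
    itemRgb = ifelse(calls$type == "dup", "255,0,0", "0,0,255"))
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Write / read a truth table as BED-like TSV
#'
#' On disk: 0-based half-open `chrom`, `start`, `end` plus `sample`,
#' `copy_state`, `origin`, `event_id`.
#'
#' @param truth Truth tibble from the simulators.
#' @param path File path.
#' @export
write_truth_bed <- function(truth, path) {
  assert_cols(truth, c("sample", "chrom", "start", "end", "copy_state",
                       "origin"), "truth")
  out <- dplyr::mutate(truth, start = .data$start - 1L,
                       end = .data$end - 1L)
  readr::write_tsv(out[, c("chrom", "start", "end", "sample", "copy_state",
                           "origin",
                           intersect("event_id", names(out)))], path)
  invisible(path)
}

#' @rdname write_truth_bed
#' @export
read_truth_bed <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), start = readr::col_double(),
    end = readr::col_double(), .default = readr::col_guess()))
  dplyr::mutate(out, start = .data$start + 1L, end = .data$end + 1L)
}

#' Write / read the gene catalogue as BED-like TSV
#'
#' BED columns (`chrom`, 0-based `start`, `end`, `symbol`) plus `status`,
#' `family`, `subfamily`, `cluster`.
#'
#' @param genes Gene tibble.
#' @param path File path.
#' @export
write_annotation_bed <- function(genes, path) {
  assert_cols(genes, c("symbol", "chrom", "start", "end", "status"), "genes")
  out <- dplyr::mutate(genes, start = .data$start - 1L, end = .data$end - 1L)
  readr::write_tsv(out[, c("chrom", "start", "end", "symbol", "status",
                           intersect(c("family", "subfamily", "cluster"),
                                     names(out)))], path)
  invisible(path)
}

#' @rdname write_annotation_bed
#' @export
read_annotation_bed <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), start = readr::col_double(),
    end = readr::col_double(), .default = readr::col_guess()))
  dplyr::mutate(out, start = .data$start + 1L, end = .data$end + 1L)
}

#' Write / read a trio pedigree as 3-column TSV
#'
#' Columns `child`, `father`, `mother`.
#'
#' @param pedigree Pedigree tibble.
#' @param path File path.
#' @export
write_pedigree <- function(pedigree, path) {
  assert_cols(pedigree, c("child", "father", "mother"), "pedigree")
  readr::write_tsv(pedigree[, c("child", "father", "mother")], path)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default =
                                                  readr::col_character()))
}

#' Write / read a genome as FASTA
#'
#' A genome is a named list/vector of chromosome sequences.
#'
#' @param genome Named character vector or list of sequences.
#' @param path File path.
#' @export
write_genome_fasta <- function(genome, path) {
  genome <- unlist(as.list(genome))
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (nm in names(genome)) {
      writeLines(paste0(">", nm), con)
      writeLines(substring(genome[[nm]],
                           seq(1, nchar(genome[[nm]]), 70),
                           pmin(nchar(genome[[nm]]),
                                seq(70, nchar(genome[[nm]]) + 69, 70))), con)
    }
  }
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readDNAStringSet(path)
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(out))
    return(as.list(out))
  }
  lines <- readLines(path)
  idx <- grep("^>", lines)
  out <- list()
  for (k in seq_along(idx)) {
    from <- idx[k] + 1L
    to <- if (k < length(idx)) idx[k + 1L] - 1L else length(lines)
    nm <- sub("\\s.*$", "", sub("^>", "", lines[idx[k]]))
    out[[nm]] <- paste(lines[from:to], collapse = "")
  }
  out
}
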