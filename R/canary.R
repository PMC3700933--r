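#' Genotype a copy-number polymorphic region across samples
#'
#' Per-region CNP genotyping in the style of cross-sample intensity
#' summarization: each sample's summary statistic is the median log2 ratio
#' over the probes inside the region, which is then assigned to the nearest
#' canonical copy-state mean (1-D classification against
#' [or_state_means()]). The population mode state is recorded so that
#' downstream retention can keep only samples whose state departs from the
#' mode.
#'
#' @param probes Multi-sample probe tibble (`sample`, `chrom`, `pos`,
#'   `log2ratio`).
#' @param region One-row data frame or list with `chrom`, `start`, `end`.
#' @param state_means Canonical per-state means.
#' @return Tibble: `sample`, `summary`, `copy_state`, `mode_state`,
#'   `is_mode`.
#' @export
#' @examples
#' probes <- tidyr::crossing(sample = c("s1", "s2", "s3"),
#'                           pos = seq(600, 6000, 600))
#' probes <- dplyr::mutate(probes, chrom = "chr1",
#'                         log2ratio = ifelse(sample == "s1", -1, 0))
#' cnp_genotype(probes, list(chrom = "chr1", start = 600, end = 6000))
cnp_genotype <- function(probes, region, state_means = or_state_means()) {
  assert_cols(probes, c("sample", "chrom", "pos", "log2ratio"), "probes")
  if (length(unique(probes$sample)) < 2) {
    stop("CNP genotyping needs at least 2 samples", call. = FALSE)
  }
  sel <- probes$chrom == region$chrom & probes$pos >= region$start &
    probes$pos <= region$end
  reg <- probes[sel, , drop = FALSE]
  if (nrow(reg) == 0) stop("region contains no probes", call. = FALSE)
  out <- dplyr::summarise(dplyr::group_by(reg, .data$sample),
                          summary = median(.data$log2ratio), .groups = "drop")
  states <- as.integer(names(state_means))
  out$copy_state <- states[max.col(-abs(outer(out$summary, state_means, "-")),
                                   ties.method = "first")]
  mode_state <- as.integer(names(sort(-table(out$copy_state)))[1])
  dplyr::mutate(out, mode_state = mode_state,
                is_mode = .data$copy_state == mode_state)
}

#' Genotype several CNP regions and emit Canary-style calls
#'
#' Runs [cnp_genotype()] over a table of regions and returns non-mode
#' samples as calls (`algorithm = "canary"`), carrying the population mode
#' so retention rules can be applied later.
#'
#' @param probes Multi-sample probe tibble.
#' @param regions Tibble of regions (`chrom`, `start`, `end`, optional
#'   `region_id`).
#' @param state_means Canonical per-state means.
#' @return Call tibble with `sample`, `chrom`, `start`, `end`, `copy_state`,
#'   `mode_state`, `n_probes`, `type`, `algorithm`.
#' @export
cnp_genotype_regions <- function(probes, regions,
                                 state_means = or_state_means()) {
  assert_cols(regions, c("chrom", "start", "end"), "regions")
  dplyr::bind_rows(lapply(seq_len(nrow(regions)), function(i) {
    g <- cnp_genotype(probes, regions[i, ], state_means)
    n_probes <- sum(probes$chrom == regions$chrom[i] &
                      probes$pos >= regions$start[i] &
                      probes$pos <= regions$end[i] &
                      probes$sample == g$sample[1])
    dplyr::transmute(
      g, sample = .data$sample, chrom = regions$chrom[i],
      start = regions$start[i], end = regions$end[i],
      copy_state = .data$copy_state, mode_state = .data$mode_state,
      lod = NA_real_, n_probes = n_probes,
      type = dplyr::case_when(.data$copy_state > 2 ~ "dup",
                              .data$copy_state < 2 ~ "del",
                              TRUE ~ "neutral"),
      algorithm = "canary")
  }))
}
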