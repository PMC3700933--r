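#' Canonical log2-ratio means per copy-number state
#'
#' Expected log2 ratio of a probe under integer copy state 0--4 on an
#' autosomal diploid background: `log2(CN / 2)`, except state 0 where the
#' ratio is undefined and a floor constant is used instead (homozygous
#' deletions saturate array intensities rather than reaching -Inf).
#'
#' @param cn0_mean Floor value used for copy state 0 (default -2.5).
#' @return Named numeric vector over states `"0"`..`"4"`.
#' @export
#' @examples
#' or_state_means()
or_state_means <- function(cn0_mean = -2.5) {
  c(`0` = cn0_mean, `1` = log2(1 / 2), `2` = 0,
    `3` = log2(3 / 2), `4` = log2(4 / 2))
}

#' Simulation configuration for the synthetic cohort
#'
#' Bundles every knob of the synthetic-data generator: the simulated genome,
#' populations and trio counts, array probe spacing and noise, the palette of
#' planted copy-number events, the gene-catalogue layout and the breakpoint
#' flank panel. The same configuration (including `seed`) always produces
#' byte-identical outputs.
#'
#' @param seed Integer RNG seed.
#' @param populations Named integer vector: samples per population. Defaults
#'   to a six-population design (IND, CEU, CHB, JPT, YRI, TBT) of 10 each.
#' @param n_trios Trios simulated per population by [simulate_trios()].
#' @param chromosomes Named numeric vector of synthetic chromosome lengths
#'   (bp). Labels follow hg18-style naming so outputs stay joinable with
#'   cytoband-labelled reports.
#' @param probe_spacing_bp Inter-marker distance in bp (default 600,
#'   mimicking high-density SNP/CNV arrays with median spacing 500-600 bp).
#' @param noise_sd Gaussian sd of probe log2 ratios around the state mean.
#' @param event_palette Tibble of planted event templates; see
#'   [default_event_palette()]. Columns: `event_id`, `chrom`, `start`, `end`,
#'   `copy_state`, `freq` (list of named per-population carrier
#'   probabilities), `n_carriers` (NA, or an exact cohort-wide carrier count
#'   for private/rare events).
#' @param fraction_inherited Probability that a simulated child event is
#'   copied from a parent (identical breakpoints) rather than de novo.
#' @param trio_events_per_child Number of events planted per trio child.
#' @param annotation_params List: `n_genes`, `fraction_intact`,
#'   `gene_length_bp` (min/max), `n_families`, and optionally `clusters`
#'   (tibble cluster/chrom/start/end overriding [default_gene_clusters()]).
#' @param flank_params List: `flank_length_bp` (1000), `ortholog_identities`,
#'   `paralog_identities` (fractions in \[0.90, 1\]), `n_related_species`,
#'   `chrom_length_bp` for panel chromosomes.
#' @param cn0_mean Emission mean used for copy state 0.
#' @return An object of class `sim_config` (a named list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, populations = c(POP1 = 5, POP2 = 5))
#' names(cfg)
sim_config <- function(seed = 1L,
                       populations = c(IND = 10L, CEU = 10L, CHB = 10L,
                                       JPT = 10L, YRI = 10L, TBT = 10L),
                       n_trios = 5L,
                       chromosomes = c(chr1 = 2e6, chr7 = 1.5e6, chr11 = 2e6,
                                       chr14 = 1.5e6, chr15 = 1.6e6),
                       probe_spacing_bp = 600L,
                       noise_sd = 0.1,
                       event_palette = NULL,
                       fraction_inherited = 0.15,
                       trio_events_per_child = 3L,
                       annotation_params = list(),
                       flank_params = list(),
                       cn0_mean = -2.5) {
  if (is.null(names(populations)) || any(names(populations) == "")) {
    stop("`populations` must be a named vector", call. = FALSE)
  }
  if (any(populations < 0)) stop("negative population size", call. = FALSE)
  assert_positive(probe_spacing_bp, "probe_spacing_bp")
  assert_positive(noise_sd, "noise_sd")
  assert_scalar_prob(fraction_inherited, "fraction_inherited")
  if (is.null(names(chromosomes))) stop("`chromosomes` must be named", call. = FALSE)

  ann <- utils::modifyList(
    list(n_genes = 862L, fraction_intact = 0.4698,
         gene_length_bp = c(900L, 1100L), n_families = 18L, clusters = NULL),
    annotation_params)
  assert_scalar_prob(ann$fraction_intact, "fraction_intact")
  if (ann$n_genes < 1) stop("`n_genes` must be >= 1", call. = FALSE)

  flk <- utils::modifyList(
    list(flank_length_bp = 1000L,
         ortholog_identities = c(0.97, 0.98, 0.96, 0.96),
         paralog_identities = c(1.00, 0.99, 0.99, 0.98, 0.98, 0.97, 0.97, 0.97),
         n_related_species = 3L,
         chrom_length_bp = 40000L),
    flank_params)
  ids <- c(flk$ortholog_identities, flk$paralog_identities)
  if (any(ids > 1)) stop("planted identity > 1", call. = FALSE)
  if (any(ids < 0.90)) stop("planted identities must be >= 0.90", call. = FALSE)

  if (is.null(event_palette)) {
    event_palette <- default_event_palette(names(populations))
  }
  validate_palette(event_palette, names(populations), chromosomes)

  structure(
    list(seed = as.integer(seed), populations = populations,
         n_trios = as.integer(n_trios), chromosomes = chromosomes,
         probe_spacing_bp = as.integer(probe_spacing_bp), noise_sd = noise_sd,
         event_palette = event_palette,
         fraction_inherited = fraction_inherited,
         trio_events_per_child = as.integer(trio_events_per_child),
         annotation_params = ann, flank_params = flk, cn0_mean = cn0_mean),
    class = "sim_config")
}

#' Default palette of planted copy-number events
#'
#' A six-population design echoing the structure of array CNP surveys of the
#' OR subgenome: two cohort-wide recurrent (hotspot) events including a
#' 271 kb duplication analogue shared by every population, one 364 kb
#' deletion analogue absent from the first population, one exclusive event
#' per population, and two single-carrier (rare) events exercising copy
#' states 0 and 4.
#'
#' @param pops Character vector of population names.
#' @return Tibble usable as `event_palette` in [sim_config()].
#' @export
default_event_palette <- function(pops) {
  np <- length(pops)
  freq_all <- function(f) list(setNames(rep(f, np), pops))
  freq_one <- function(pop, f) {
    v <- setNames(rep(0, np), pops)
    v[pop] <- f
    list(v)
  }
  shared <- dplyr::bind_rows(
    tibble::tibble(event_id = "hs_15q_dup", chrom = "chr15", start = 600000,
                   end = 871000, copy_state = 3L, freq = freq_all(0.5),
                   n_carriers = NA_integer_),
    tibble::tibble(event_id = "hs_14q_dup", chrom = "chr14", start = 300000,
                   end = 618000, copy_state = 3L, freq = freq_all(0.4),
                   n_carriers = NA_integer_),
    tibble::tibble(event_id = "hs_15q_del", chrom = "chr15", start = 1100000,
                   end = 1464000, copy_state = 1L,
                   freq = if (np > 1) {
                     v <- setNames(rep(0.35, np), pops)
                     v[1] <- 0
                     list(v)
                   } else freq_all(0.35),
                   n_carriers = NA_integer_))
  excl_loci <- tibble::tibble(
    chrom = rep(c("chr11", "chr1", "chr7"), length.out = max(np, 1)),
    start = c(200000, 300000, 200000, 500000, 700000, 600000,
              900000, 1100000, 950000)[seq_len(max(np, 1))],
    end   = c(320000, 420000, 380000, 650000, 840000, 700000,
              1010000, 1250000, 1100000)[seq_len(max(np, 1))],
    copy_state = rep(c(3L, 1L), length.out = max(np, 1)))
  exclusive <- dplyr::bind_rows(lapply(seq_len(np), function(i) {
    tibble::tibble(event_id = paste0("excl_", pops[i]),
                   chrom = excl_loci$chrom[i], start = excl_loci$start[i],
                   end = excl_loci$end[i], copy_state = excl_loci$copy_state[i],
                   freq = freq_one(pops[i], 0.5), n_carriers = NA_integer_)
  }))
  rare <- dplyr::bind_rows(
    tibble::tibble(event_id = "rare_11q_homdel", chrom = "chr11",
                   start = 1500000, end = 1600000, copy_state = 0L,
                   freq = freq_all(1 / np), n_carriers = 1L),
    tibble::tibble(event_id = "rare_14q_amp", chrom = "chr14",
                   start = 900000, end = 1050000, copy_state = 4L,
                   freq = freq_all(1 / np), n_carriers = 1L))
  dplyr::bind_rows(shared, exclusive, rare)
}

validate_palette <- function(palette, pops, chromosomes) {
  assert_cols(palette, c("event_id", "chrom", "start", "end", "copy_state",
                         "freq"), "event_palette")
  if (!"n_carriers" %in% names(palette)) palette$n_carriers <- NA_integer_
  if (any(palette$end <= palette$start)) {
    stop("palette events must have end > start", call. = FALSE)
  }
  if (any(palette$copy_state == 2L)) {
    stop("planted events must not have copy state 2", call. = FALSE)
  }
  if (!all(palette$copy_state %in% 0:4)) {
    stop("copy states are capped at 0..4", call. = FALSE)
  }
  bad_chrom <- !palette$chrom %in% names(chromosomes)
  if (any(bad_chrom)) {
    stop("palette events on unknown chromosome(s): ",
         paste(unique(palette$chrom[bad_chrom]), collapse = ", "),
         call. = FALSE)
  }
  over <- palette$end > chromosomes[palette$chrom]
  if (any(over)) {
    stop("palette event(s) exceed chromosome length: ",
         paste(palette$event_id[over], collapse = ", "), call. = FALSE)
  }
  for (f in palette$freq) {
    if (any(f < 0) || any(f > 1)) {
      stop("carrier frequencies must be in [0, 1]", call. = FALSE)
    }
    if (!all(names(f) %in% pops)) {
      stop("palette frequency for unknown population", call. = FALSE)
    }
  }
  invisible(palette)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  seed:", x$seed, "\n")
  cat("  populations:",
      paste(names(x$populations), x$populations, sep = "=", collapse = ", "),
      "\n")
  cat("  chromosomes:", length(x$chromosomes),
      sprintf("(%.1f Mb total)", sum(x$chromosomes) / 1e6), "\n")
  cat("  probe spacing:", x$probe_spacing_bp, "bp; noise sd:", x$noise_sd, "\n")
  cat("  palette events:", nrow(x$event_palette), "\n")
  invisible(x)
}
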