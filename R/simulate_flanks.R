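random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# mutate exactly round((1 - identity) * L) positions (substitutions only)
mutate_to_identity <- function(seq, identity) {
  L <- nchar(seq)
  n_mut <- round((1 - identity) * L)
  if (n_mut == 0) return(seq)
  pos <- sample.int(L, n_mut)
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Simulate a genome panel with planted breakpoint-flank copies
#'
#' Builds a synthetic "self" genome plus related-species genomes, selects a
#' 1 kb flank locus on the self genome, and plants near-identical copies of
#' it: paralogous copies on other chromosomes of the self genome and
#' orthologous copies in the species genomes. Each copy is mutated to an
#' exact target identity (`round((1 - identity) * L)` substitutions) and
#' recorded in a truth table. The default plants 8 paralogous and 4
#' orthologous copies, the hit pattern reported for the most common CNV
#' start point in population OR surveys.
#'
#' @param config A [sim_config()]; uses `flank_params`.
#' @return List with `genomes` (named list of named chromosome sequence
#'   vectors; self genome is `"self"`), `flanks` (tibble: `flank_id`,
#'   `chrom`, `start`, `end`, `sequence`), and `truth` (tibble: `flank_id`,
#'   `subject_genome`, `chrom`, `start`, `end`, `true_identity` in percent,
#'   `class` = `orthologous`/`paralogous_derived`).
#' @export
#' @examples
#' panel <- simulate_flank_panel(sim_config(seed = 1))
#' panel$truth
simulate_flank_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fp <- config$flank_params
  set.seed(sub_seed(config$seed, 31L))
  L <- fp$flank_length_bp
  clen <- fp$chrom_length_bp
  if (clen < 3 * L) stop("panel chromosomes too short for flank planting",
                         call. = FALSE)

  species <- c("pan_troglodytes", "pongo_abelii", "rhesus_macaque",
               "gorilla_gorilla", "nomascus_leucogenys")
  species <- species[seq_len(min(fp$n_related_species, length(species)))]

  self_chroms <- c("chr2", "chr13", "chr14", "chr15")
  genomes <- list(self = setNames(
    lapply(self_chroms, function(ch) random_dna(clen)), self_chroms))
  for (sp in species) {
    chroms <- c("chrA", "chrB")
    genomes[[sp]] <- setNames(lapply(chroms, function(ch) random_dna(clen)),
                              chroms)
  }

  # flank source locus on self chr15
  f_start <- 2L * L
  f_end <- f_start + L            # end-exclusive span, size L
  flank_seq <- substr(genomes$self$chr15, f_start, f_end - 1L)
  flanks <- tibble::tibble(flank_id = "common_start_up", chrom = "chr15",
                           start = f_start, end = f_end, sequence = flank_seq)

  truth <- list()
  plant <- function(genome, chrom, identity, class, flank_id, slot) {
    host <- genomes[[genome]][[chrom]]
    # keep planted copies clear of each other and of the source locus
    at <- 1L + (slot - 1L) * 3L * L + L
    if (at + L - 1L > nchar(host)) {
      stop("panel chromosome too short for planted copy", call. = FALSE)
    }
    copy <- mutate_to_identity(flank_seq, identity)
    substr(host, at, at + L - 1L) <- copy
    genomes[[genome]][[chrom]] <<- host
    tibble::tibble(flank_id = flank_id, subject_genome = genome,
                   chrom = chrom, start = at, end = at + L,
                   true_identity = 100 * identity, class = class)
  }

  # paralogous copies: other chromosomes of the self genome
  par_hosts <- setdiff(self_chroms, "chr15")
  slots <- integer(0)
  for (i in seq_along(fp$paralog_identities)) {
    ch <- par_hosts[(i - 1L) %% length(par_hosts) + 1L]
    slot <- sum(slots == match(ch, par_hosts)) + 1L
    slots <- c(slots, match(ch, par_hosts))
    truth[[length(truth) + 1]] <- plant("self", ch, fp$paralog_identities[i],
                                        "paralogous_derived",
                                        "common_start_up", slot)
  }
  # orthologous copies: species genomes, round-robin
  sp_slots <- stats::setNames(integer(length(species)), species)
  for (i in seq_along(fp$ortholog_identities)) {
    sp <- species[(i - 1L) %% length(species) + 1L]
    ch <- if (sp_slots[[sp]] %% 2 == 0) "chrA" else "chrB"
    sp_slots[[sp]] <- sp_slots[[sp]] + 1L
    slot <- ceiling(sp_slots[[sp]] / 2)
    truth[[length(truth) + 1]] <- plant(sp, ch, fp$ortholog_identities[i],
                                        "orthologous", "common_start_up", slot)
  }

  list(genomes = genomes, flanks = flanks, truth = dplyr::bind_rows(truth))
}
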