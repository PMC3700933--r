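#' Default cytoband-style gene clusters for the synthetic annotation
#'
#' Cluster windows are placed so that the default event palette overlaps
#' them (planted CNVs hit genes, as in real OR cluster maps). Labels follow
#' hg18 cytoband grammar ("15q11.2") so reports stay joinable with
#' cluster-level tables.
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `cluster`, `chrom`, `start`, `end`.
#' @export
default_gene_clusters <- function(config) {
  cl <- tibble::tribble(
    ~cluster,   ~chrom,  ~start,   ~end,
    "1p36.33",  "chr1",  290000,   850000,
    "7q35",     "chr7",  190000,   710000,
    "11q11",    "chr11", 190000,   660000,
    "11q24.1",  "chr11", 1490000,  1610000,
    "14q11.2",  "chr14", 290000,   630000,
    "14q32.33", "chr14", 890000,   1060000,
    "15q11.2",  "chr15", 600000,   880000,
    "15q13.3",  "chr15", 1100000,  1470000)
  cl <- cl[cl$chrom %in% names(config$chromosomes) &
             cl$end <= config$chromosomes[cl$chrom], , drop = FALSE]
  if (nrow(cl) == 0) stop("no gene cluster fits the simulated chromosomes",
                          call. = FALSE)
  cl
}

#' Simulate an intact/pseudogene catalogue
#'
#' Places non-overlapping genes inside cytoband-labelled clusters and draws
#' intact/pseudogene status so the realized intact count is exactly
#' `round(n_genes * fraction_intact)` (the expected value of a Bernoulli
#' draw, fixed for reproducibility). Pseudogene symbols carry the
#' conventional trailing "P".
#'
#' @param config A [sim_config()]. Uses `annotation_params`
#'   (`n_genes`, `fraction_intact`, `gene_length_bp`, `n_families`,
#'   optional `clusters`).
#' @return Tibble with columns `symbol`, `chrom`, `start`, `end`, `status`
#'   (`intact`/`pseudogene`), `family`, `subfamily`, `cluster`.
#' @export
#' @examples
#' genes <- simulate_annotation(sim_config(seed = 1,
#'   annotation_params = list(n_genes = 100)))
#' table(genes$status)
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ann <- config$annotation_params
  set.seed(sub_seed(config$seed, 7L))

  clusters <- ann$clusters %||% default_gene_clusters(config)
  assert_cols(clusters, c("cluster", "chrom", "start", "end"), "clusters")
  if (any(clusters$end > config$chromosomes[clusters$chrom])) {
    stop("cluster layout exceeds chromosome length", call. = FALSE)
  }

  n <- ann$n_genes
  width <- clusters$end - clusters$start
  idx <- sort(sample.int(nrow(clusters), n, replace = TRUE,
                         prob = width / sum(width)))

  len_rng <- range(ann$gene_length_bp)
  rows <- vector("list", nrow(clusters))
  for (ci in seq_len(nrow(clusters))) {
    k <- sum(idx == ci)
    if (k == 0) next
    gaps <- sample(200:1500, k, replace = TRUE)
    lens <- sample(len_rng[1]:len_rng[2], k, replace = TRUE)
    starts <- clusters$start[ci] + cumsum(gaps) + cumsum(c(0, head(lens, -1)))
    ends <- starts + lens
    if (any(ends > clusters$end[ci])) {
      stop("impossible annotation layout: genes exceed cluster \"",
           clusters$cluster[ci], "\"", call. = FALSE)
    }
    rows[[ci]] <- tibble::tibble(chrom = clusters$chrom[ci], start = starts,
                                 end = ends, cluster = clusters$cluster[ci])
  }
  genes <- dplyr::bind_rows(rows)

  n_intact <- round(n * ann$fraction_intact)
  status <- rep("pseudogene", n)
  status[sample.int(n, n_intact)] <- "intact"

  fam_pool <- paste0("OR", seq_len(ann$n_families))
  family <- sample(fam_pool, n, replace = TRUE)
  subfamily <- paste0(family, sample(LETTERS[1:6], n, replace = TRUE))
  symbol <- paste0(subfamily, stats::ave(seq_len(n), subfamily, FUN = seq_along))
  symbol <- ifelse(status == "pseudogene", paste0(symbol, "P"), symbol)

  genes <- dplyr::mutate(genes, symbol = symbol, status = status,
                         family = family, subfamily = subfamily)
  dplyr::arrange(
    dplyr::select(genes, "symbol", "chrom", "start", "end", "status",
                  "family", "subfamily", "cluster"),
    .data$chrom, .data$start)
}

# shared probe grid over the simulated chromosomes
probe_grid <- function(config) {
  dplyr::bind_rows(lapply(names(config$chromosomes), function(ch) {
    pos <- seq(config$probe_spacing_bp, config$chromosomes[[ch]],
               by = config$probe_spacing_bp)
    tibble::tibble(probe_id = sprintf("%s_p%06d", ch, seq_along(pos)),
                   chrom = ch, pos = as.integer(pos))
  }))
}

cohort_samples <- function(config) {
  dplyr::bind_rows(lapply(names(config$populations), function(p) {
    n <- config$populations[[p]]
    if (n == 0) return(NULL)
    tibble::tibble(sample = sprintf("%s_s%02d", p, seq_len(n)), population = p)
  }))
}

# draw carriers for each palette event; exact count for n_carriers events
draw_carriers <- function(palette, samples) {
  out <- vector("list", nrow(palette))
  for (i in seq_len(nrow(palette))) {
    f <- palette$freq[[i]]
    p_samp <- f[samples$population]
    p_samp[is.na(p_samp)] <- 0
    nc <- palette$n_carriers[i]
    if (!is.na(nc)) {
      eligible <- which(p_samp > 0)
      if (length(eligible) == 0 || nc == 0) next
      nc <- min(nc, length(eligible))
      carriers <- eligible[sample.int(length(eligible), nc,
                                      prob = p_samp[eligible])]
    } else {
      carriers <- which(rbinom(nrow(samples), 1L, p_samp) == 1L)
    }
    if (length(carriers) == 0) next
    out[[i]] <- tibble::tibble(
      sample = samples$sample[carriers],
      population = samples$population[carriers],
      event_id = palette$event_id[i], chrom = palette$chrom[i],
      start = palette$start[i], end = palette$end[i],
      copy_state = palette$copy_state[i], origin = "founder")
  }
  dplyr::bind_rows(out)
}

# per-sample Gaussian emissions around the state means
emit_track <- function(grid, truth_sample, noise_sd, means) {
  mu <- rep(0, nrow(grid))
  if (nrow(truth_sample) > 0) {
    for (i in seq_len(nrow(truth_sample))) {
      hit <- grid$chrom == truth_sample$chrom[i] &
        grid$pos >= truth_sample$start[i] & grid$pos < truth_sample$end[i]
      mu[hit] <- means[[as.character(truth_sample$copy_state[i])]]
    }
  }
  dplyr::mutate(grid, log2ratio = rnorm(nrow(grid), mu, noise_sd))
}

#' Simulate per-sample probe intensity tracks with planted CNVs
#'
#' Every sample gets the same probe grid (fixed spacing across the synthetic
#' chromosomes); log2 ratios are Gaussian around the copy-state mean
#' (`log2(CN/2)`, floor constant for CN 0) with sd `noise_sd`. Carriers of
#' each palette event are drawn per population at the configured frequency
#' (or as an exact carrier count for rare events), and every planted segment
#' is recorded in the returned truth table.
#'
#' @param config A [sim_config()].
#' @return List with `probes` (tibble: `sample`, `probe_id`, `chrom`, `pos`,
#'   `log2ratio`), `truth` (tibble: `sample`, `population`, `event_id`,
#'   `chrom`, `start`, `end`, `copy_state`, `origin`), and `samples`
#'   (tibble: `sample`, `population`).
#' @export
#' @examples
#' sim <- simulate_probe_panel(sim_config(seed = 1,
#'   populations = c(POP1 = 2), chromosomes = c(chr15 = 1.6e6)))
#' head(sim$probes)
simulate_probe_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, 11L))
  grid <- probe_grid(config)
  samples <- cohort_samples(config)
  if (is.null(samples) || nrow(samples) == 0) {
    stop("no samples configured", call. = FALSE)
  }
  truth <- draw_carriers(config$event_palette, samples)
  means <- or_state_means(config$cn0_mean)
  probes <- dplyr::bind_rows(lapply(samples$sample, function(s) {
    ts <- if (nrow(truth) > 0) truth[truth$sample == s, , drop = FALSE]
          else truth
    dplyr::mutate(emit_track(grid, ts, config$noise_sd, means),
                  sample = s, .before = 1)
  }))
  list(probes = probes, truth = truth, samples = samples)
}

# one random de novo interval avoiding `avoid` (tibble chrom/start/end)
random_event <- function(config, avoid, size_range = c(5e4, 5e5)) {
  chroms <- config$chromosomes
  for (try in 1:100) {
    size <- round(exp(runif(1, log(size_range[1]), log(size_range[2]))))
    ch <- sample(names(chroms), 1, prob = chroms / sum(chroms))
    if (chroms[[ch]] <= size + 2) next
    start <- sample.int(chroms[[ch]] - size - 1L, 1)
    end <- start + size
    clash <- nrow(avoid) > 0 && any(
      avoid$chrom == ch & intersect_len(avoid$start, avoid$end, start, end) > 0)
    if (!clash) {
      return(tibble::tibble(chrom = ch, start = start, end = end,
                            copy_state = sample(c(0L, 1L, 3L, 4L), 1,
                                                prob = c(.05, .45, .45, .05))))
    }
  }
  NULL
}

#' Simulate parent-child trios with inherited and de novo CNVs
#'
#' Parents carry founder events drawn from the palette (at least one each).
#' Each child event is, with probability `fraction_inherited`, an exact copy
#' of a randomly chosen parental event (identical breakpoints, origin
#' `"inherited"`); otherwise it is a new interval overlapping no parental
#' event (origin `"de_novo"`).
#'
#' @param config A [sim_config()]; uses `n_trios` per population,
#'   `fraction_inherited` and `trio_events_per_child`.
#' @return List with `probes`, `truth`, `samples` as in
#'   [simulate_probe_panel()] plus `pedigree` (tibble: `child`, `father`,
#'   `mother`, `population`).
#' @export
simulate_trios <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_trios < 1) stop("`n_trios` must be >= 1", call. = FALSE)
  assert_scalar_prob(config$fraction_inherited, "fraction_inherited")
  set.seed(sub_seed(config$seed, 23L))

  grid <- probe_grid(config)
  means <- or_state_means(config$cn0_mean)
  palette <- config$event_palette

  truth <- list(); ped <- list(); samples <- list(); probes <- list()
  k <- 0
  for (pop in names(config$populations)) {
    for (t in seq_len(config$n_trios)) {
      ids <- sprintf("%s_trio%02d_%s", pop, t, c("child", "father", "mother"))
      parent_truth <- list()
      for (par in ids[2:3]) {
        w <- vapply(palette$freq, function(f) f[[pop]] %||% 0, numeric(1))
        carry <- which(rbinom(nrow(palette), 1L, w) == 1L)
        if (length(carry) == 0) {
          carry <- sample.int(nrow(palette), 1,
                              prob = if (sum(w) > 0) w else NULL)
        }
        parent_truth[[par]] <- tibble::tibble(
          sample = par, population = pop,
          event_id = palette$event_id[carry], chrom = palette$chrom[carry],
          start = palette$start[carry], end = palette$end[carry],
          copy_state = palette$copy_state[carry], origin = "founder")
      }
      par_tab <- dplyr::bind_rows(parent_truth)
      # distinct parental intervals usable as inheritance sources
      par_src <- dplyr::distinct(par_tab, .data$event_id, .data$chrom,
                                 .data$start, .data$end, .data$copy_state,
                                 .keep_all = TRUE)
      child <- list()
      placed <- par_tab[, c("chrom", "start", "end")]
      used_parental <- integer(0)
      for (e in seq_len(config$trio_events_per_child)) {
        avail <- setdiff(seq_len(nrow(par_src)), used_parental)
        if (runif(1) < config$fraction_inherited && length(avail) > 0) {
          pick <- if (length(avail) == 1) avail else sample(avail, 1)
          used_parental <- c(used_parental, pick)
          src <- par_src[pick, , drop = FALSE]
          child[[e]] <- dplyr::mutate(src, sample = ids[1],
                                      origin = "inherited",
                                      event_id = paste0(src$event_id, "_inh"))
        } else {
          ev <- random_event(config, placed)
          if (is.null(ev)) next
          placed <- dplyr::bind_rows(placed, ev[, c("chrom", "start", "end")])
          child[[e]] <- tibble::tibble(
            sample = ids[1], population = pop,
            event_id = sprintf("%s_trio%02d_dn%d", pop, t, e),
            chrom = ev$chrom, start = ev$start, end = ev$end,
            copy_state = ev$copy_state, origin = "de_novo")
        }
      }
      child_tab <- dplyr::bind_rows(child)
      trio_truth <- dplyr::bind_rows(child_tab, par_tab)
      k <- k + 1
      truth[[k]] <- trio_truth
      ped[[k]] <- tibble::tibble(child = ids[1], father = ids[2],
                                 mother = ids[3], population = pop)
      samples[[k]] <- tibble::tibble(sample = ids, population = pop)
      probes[[k]] <- dplyr::bind_rows(lapply(ids, function(s) {
        ts <- trio_truth[trio_truth$sample == s, , drop = FALSE]
        dplyr::mutate(emit_track(grid, ts, config$noise_sd, means),
                      sample = s, .before = 1)
      }))
    }
  }
  list(probes = dplyr::bind_rows(probes), truth = dplyr::bind_rows(truth),
       pedigree = dplyr::bind_rows(ped), samples = dplyr::bind_rows(samples))
}
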