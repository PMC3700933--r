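test_that("simulated annotation hits the configured catalogue composition", {
  cfg <- tiny_config(annotation_params = list(n_genes = 862L,
                                              fraction_intact = 0.4698))
  genes <- simulate_annotation(cfg)
  expect_equal(nrow(genes), 862)
  expect_equal(sum(genes$status == "intact"), 405)
  expect_equal(sum(genes$status == "pseudogene"), 457)
  # non-overlapping within chromosome
  by_chrom <- split(genes, genes$chrom)
  for (g in by_chrom) {
    g <- g[order(g$start), ]
    if (nrow(g) > 1) expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
  # cytoband grammar and pseudogene symbol convention
  expect_true(all(grepl("^[0-9XY]+[pq][0-9.]+$", genes$cluster)))
  expect_true(all(grepl("P$", genes$symbol[genes$status == "pseudogene"])))
  expect_false(any(grepl("P$", genes$symbol[genes$status == "intact"])))
})

test_that("annotation handles degenerate and impossible layouts", {
  cfg1 <- tiny_config(annotation_params = list(n_genes = 1L,
                                               fraction_intact = 1.0))
  g1 <- simulate_annotation(cfg1)
  expect_equal(nrow(g1), 1)
  expect_equal(g1$status, "intact")

  cfg_bad <- tiny_config(annotation_params = list(
    n_genes = 500L,
    clusters = tibble::tibble(cluster = "15q11.2", chrom = "chr15",
                              start = 600000, end = 640000)))
  expect_error(simulate_annotation(cfg_bad), "impossible")
})

test_that("simulators are deterministic under a fixed seed", {
  cfg <- tiny_config(seed = 7)
  expect_identical(simulate_annotation(cfg), simulate_annotation(cfg))
  expect_identical(simulate_probe_panel(cfg), simulate_probe_panel(cfg))
  expect_identical(simulate_trios(cfg), simulate_trios(cfg))
  expect_identical(simulate_flank_panel(cfg), simulate_flank_panel(cfg))
})

test_that("planted segments shift probe means as configured", {
  # zero-noise limit: probes inside a CN=1 segment sit exactly at log2(1/2)
  pal <- tibble::tibble(event_id = "e1", chrom = "chr15", start = 600000,
                        end = 871000, copy_state = 1L,
                        freq = list(c(POP1 = 1.0)), n_carriers = NA_integer_)
  cfg <- sim_config(seed = 3, populations = c(POP1 = 2L),
                    chromosomes = c(chr15 = 1.6e6), noise_sd = 1e-12,
                    event_palette = pal)
  sim <- simulate_probe_panel(cfg)
  for (s in sim$samples$sample) {
    tr <- sim$probes[sim$probes$sample == s, ]
    inside <- tr$pos >= 600000 & tr$pos < 871000
    expect_equal(tr$log2ratio[inside], rep(-1, sum(inside)), tolerance = 1e-9)
    expect_equal(tr$log2ratio[!inside], rep(0, sum(!inside)),
                 tolerance = 1e-9)
  }

  # CLT bound: segment mean of a CN=3 event within 3 sd / sqrt(n) over seeds
  pal3 <- dplyr::mutate(pal, copy_state = 3L)
  n_probes_seg <- floor((871000 - 600000) / 600)
  for (seed in 1:20) {
    cfg3 <- sim_config(seed = seed, populations = c(POP1 = 1L),
                       chromosomes = c(chr15 = 1.6e6), noise_sd = 0.05,
                       event_palette = pal3)
    sim3 <- simulate_probe_panel(cfg3)
    tr <- sim3$probes
    m <- mean(tr$log2ratio[tr$pos >= 600000 & tr$pos < 871000])
    expect_lt(abs(m - log2(3 / 2)), 3 * 0.05 / sqrt(n_probes_seg))
  }
})

test_that("frequency-1 shared events reach every sample of every population", {
  pal <- tibble::tibble(event_id = "shared", chrom = "chr15", start = 600000,
                        end = 871000, copy_state = 3L,
                        freq = list(c(POP1 = 1.0, POP2 = 1.0)),
                        n_carriers = NA_integer_)
  cfg <- sim_config(seed = 5, populations = c(POP1 = 3L, POP2 = 3L),
                    chromosomes = c(chr15 = 1.6e6), event_palette = pal)
  sim <- simulate_probe_panel(cfg)
  expect_setequal(sim$truth$sample, sim$samples$sample)
  expect_true(all(sim$truth$event_id == "shared"))
})

test_that("truth tables respect the planted-event invariants", {
  sim <- simulate_probe_panel(tiny_config(seed = 11))
  expect_true(all(sim$truth$copy_state != 2L))
  expect_true(all(sim$truth$end > sim$truth$start))
  # each (sample, event) pair is unique
  expect_false(any(duplicated(sim$truth[, c("sample", "event_id")])))
})

test_that("realized carrier frequencies are calibrated", {
  # binomial 99% bound on the pooled carrier count over 20 seeds
  f <- 0.4
  pal <- tibble::tibble(event_id = "cal", chrom = "chr15", start = 600000,
                        end = 871000, copy_state = 3L,
                        freq = list(c(POP1 = f)), n_carriers = NA_integer_)
  n_per_seed <- 12L
  carriers <- 0L
  for (seed in 1:20) {
    cfg <- sim_config(seed = seed, populations = c(POP1 = n_per_seed),
                      chromosomes = c(chr15 = 1.6e6), event_palette = pal)
    carriers <- carriers + nrow(simulate_probe_panel(cfg)$truth)
  }
  n_tot <- 20L * n_per_seed
  bounds <- qbinom(c(0.005, 0.995), n_tot, f)
  expect_gte(carriers, bounds[1])
  expect_lte(carriers, bounds[2])
})

test_that("trio simulation honors the inheritance fraction at its bounds", {
  cfg1 <- tiny_config(seed = 2, fraction_inherited = 1.0)
  tr1 <- simulate_trios(cfg1)
  kids1 <- tr1$truth[tr1$truth$sample %in% tr1$pedigree$child, ]
  expect_true(all(kids1$origin == "inherited"))
  for (i in seq_len(nrow(kids1))) {
    ped <- tr1$pedigree[tr1$pedigree$child == kids1$sample[i], ]
    par_ev <- tr1$truth[tr1$truth$sample %in% c(ped$father, ped$mother), ]
    expect_true(any(par_ev$chrom == kids1$chrom[i] &
                      par_ev$start == kids1$start[i] &
                      par_ev$end == kids1$end[i]))
  }

  cfg0 <- tiny_config(seed = 2, fraction_inherited = 0.0)
  tr0 <- simulate_trios(cfg0)
  kids0 <- tr0$truth[tr0$truth$sample %in% tr0$pedigree$child, ]
  expect_true(all(kids0$origin == "de_novo"))
  for (i in seq_len(nrow(kids0))) {
    ped <- tr0$pedigree[tr0$pedigree$child == kids0$sample[i], ]
    par_ev <- tr0$truth[tr0$truth$sample %in% c(ped$father, ped$mother), ]
    ov <- intersect_len(par_ev$start, par_ev$end, kids0$start[i],
                        kids0$end[i])
    expect_true(all(ov[par_ev$chrom == kids0$chrom[i]] == 0))
  }
})

test_that("trio inherited fraction stays inside binomial bounds", {
  frac <- 0.15
  n_inherited <- 0L; n_events <- 0L
  for (seed in 1:5) {
    cfg <- tiny_config(seed = seed, fraction_inherited = frac)
    tr <- simulate_trios(cfg)
    kids <- tr$truth[tr$truth$sample %in% tr$pedigree$child, ]
    n_inherited <- n_inherited + sum(kids$origin == "inherited")
    n_events <- n_events + nrow(kids)
  }
  bounds <- qbinom(c(0.005, 0.995), n_events, frac)
  expect_gte(n_inherited, bounds[1])
  expect_lte(n_inherited, bounds[2])
})

test_that("flank panel plants copies at exact identities", {
  cfg <- tiny_config(seed = 9)
  panel <- simulate_flank_panel(cfg)
  fl <- panel$flanks
  # source flank is an exact slice of the self genome
  expect_identical(
    fl$sequence,
    substr(panel$genomes$self[[fl$chrom]], fl$start, fl$end - 1))
  # 8 paralogous + 4 orthologous planted copies by default
  expect_equal(sum(panel$truth$class == "paralogous_derived"), 8)
  expect_equal(sum(panel$truth$class == "orthologous"), 4)
  # each planted copy differs from the source at exactly the configured
  # number of positions
  for (i in seq_len(nrow(panel$truth))) {
    tt <- panel$truth[i, ]
    copy <- substr(panel$genomes[[tt$subject_genome]][[tt$chrom]],
                   tt$start, tt$end - 1)
    mism <- sum(strsplit(copy, "")[[1]] != strsplit(fl$sequence, "")[[1]])
    expect_equal(mism, round((1 - tt$true_identity / 100) * 1000))
  }
  # identity-1 copy is an exact substring
  exact <- panel$truth[panel$truth$true_identity == 100, ]
  expect_gte(nrow(exact), 1)
  copy <- substr(panel$genomes[[exact$subject_genome[1]]][[exact$chrom[1]]],
                 exact$start[1], exact$end[1] - 1)
  expect_identical(copy, fl$sequence)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(noise_sd = 0), "positive")
  expect_error(sim_config(fraction_inherited = 1.5), "probability")
  expect_error(sim_config(flank_params = list(
    ortholog_identities = c(1.02))), "identity > 1")
  expect_error(sim_config(flank_params = list(
    paralog_identities = c(0.8))), ">= 0.90")
  pal <- tibble::tibble(event_id = "x", chrom = "chr15", start = 10,
                        end = 5e6, copy_state = 3L,
                        freq = list(c(IND = 0.5)), n_carriers = NA_integer_)
  expect_error(sim_config(event_palette = pal), "exceed chromosome")
  pal2 <- dplyr::mutate(pal, end = 20000, freq = list(c(IND = 1.4)))
  expect_error(sim_config(event_palette = pal2), "\\[0, 1\\]")
  pal3 <- dplyr::mutate(pal, end = 20000, copy_state = 2L)
  expect_error(sim_config(event_palette = pal3), "state 2")
})
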