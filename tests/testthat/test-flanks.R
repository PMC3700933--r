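test_that("flank extraction selects the 1 kb windows around breakpoints", {
  set.seed(1)
  genome <- list(chrX = random_dna_str(30000))
  call <- tibble::tibble(call_id = "c1", chrom = "chrX", start = 10000,
                         end = 20000)
  fl <- extract_flanks(call, genome)
  up <- fl[fl$side == "upstream", ]
  dn <- fl[fl$side == "downstream", ]
  # upstream covers [start - 1000, start): positions 9000..9999
  expect_equal(up$start, 9000)
  expect_equal(up$end - up$start, 1000)
  expect_identical(up$sequence, substr(genome$chrX, 9000, 9999))
  # downstream covers (end, end + 1000]: positions 20001..21000
  expect_identical(dn$sequence, substr(genome$chrX, 20001, 21000))
  expect_false(any(fl$truncated))

  # truncation at the chromosome start
  call2 <- tibble::tibble(call_id = "c2", chrom = "chrX", start = 500,
                          end = 29500)
  fl2 <- extract_flanks(call2, genome)
  up2 <- fl2[fl2$side == "upstream", ]
  expect_true(up2$truncated)
  expect_equal(nchar(up2$sequence), 499)
  dn2 <- fl2[fl2$side == "downstream", ]
  expect_true(dn2$truncated)
  expect_equal(nchar(dn2$sequence), 500)

  expect_error(extract_flanks(tibble::tibble(call_id = "x", chrom = "chrZ",
                                             start = 5000, end = 6000),
                              genome), "not in genome")
})

test_that("local alignment is exact against enumeration and identities", {
  # identical sequences: full-length perfect alignment
  set.seed(2)
  s <- random_dna_str(100)
  al <- local_align(s, s)
  expect_equal(al$score, 100)
  expect_equal(al$pct_identity, 100)

  # planted substitutions give the exact expected identity
  v <- strsplit(s, "")[[1]]
  pos <- sample(100, 3)
  for (p in pos) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
  al2 <- global_align(s, paste(v, collapse = ""))
  expect_equal(al2$pct_identity, 97)

  # brute-force enumeration oracle on short pairs
  set.seed(3)
  for (i in 1:12) {
    a <- random_dna_str(sample(3:6, 1))
    b <- random_dna_str(sample(3:6, 1))
    expect_equal(local_align(a, b)$score, brute_local_score(a, b))
    expect_equal(global_align(a, b)$score, brute_global_score(a, b))
  }
  expect_error(local_align("", "ACGT"), "empty")
  expect_error(local_align("ACGT", "ACXT"), "non-ACGTN")
})

test_that("local alignment agrees with an independent implementation", {
  skip_if_not_installed("Biostrings")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  set.seed(4)
  for (i in 1:10) {
    a <- random_dna_str(50); b <- random_dna_str(80)
    ref <- Biostrings::score(Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = mat, gapOpening = 1,
      gapExtension = 1))
    expect_equal(local_align(a, b)$score, ref)
  }
})

test_that("panel screening recovers planted copies and only those", {
  cfg <- tiny_config(seed = 13)
  panel <- simulate_flank_panel(cfg)
  hits <- screen_panel(panel$flanks, panel$genomes)
  nonself <- hits[hits$hit_class != "self", ]
  expect_equal(sum(nonself$hit_class == "paralogous_derived"), 8)
  expect_equal(sum(nonself$hit_class == "orthologous"), 4)
  # the source locus itself is labelled self
  expect_equal(sum(hits$hit_class == "self"), 1)
  # recall 1: every planted copy is found at its locus
  tr <- panel$truth
  for (i in seq_len(nrow(tr))) {
    expect_true(any(
      nonself$subject_genome == tr$subject_genome[i] &
        nonself$chrom == tr$chrom[i] &
        intersect_len(nonself$start, nonself$end, tr$start[i],
                      tr$end[i]) > 500))
  }
  # precision 1: every reported hit is a planted locus
  for (i in seq_len(nrow(nonself))) {
    expect_true(any(
      tr$subject_genome == nonself$subject_genome[i] &
        tr$chrom == nonself$chrom[i] &
        intersect_len(tr$start, tr$end, nonself$start[i],
                      nonself$end[i]) > 500))
  }
  # reported identities sit within a point of the planted identity
  for (i in seq_len(nrow(nonself))) {
    match_tr <- tr[tr$subject_genome == nonself$subject_genome[i] &
                     tr$chrom == nonself$chrom[i] &
                     intersect_len(tr$start, tr$end, nonself$start[i],
                                   nonself$end[i]) > 500, ]
    expect_lte(abs(nonself$pct_identity[i] - match_tr$true_identity[1]), 1)
  }
  # exactly one nominated recombining region, the closest non-self hit
  nom <- hits[hits$nominated, ]
  expect_equal(nrow(nom), 1)
  expect_equal(nom$pct_identity, max(nonself$pct_identity))
})

test_that("copies below the identity threshold are not reported", {
  set.seed(5)
  flank_seq <- random_dna_str(1000)
  host <- random_dna_str(6000)
  # plant a copy with 60 mutations (94% identity) at position 3001
  v <- strsplit(flank_seq, "")[[1]]
  pos <- sample(1000, 60)
  for (p in pos) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
  substr(host, 3001, 4000) <- paste(v, collapse = "")
  panel <- list(self = list(chr1 = paste0(random_dna_str(3000), flank_seq,
                                          random_dna_str(2000)),
                            chr2 = host))
  flanks <- tibble::tibble(flank_id = "f", chrom = "chr1", start = 3001,
                           end = 4001, sequence = flank_seq)
  hits95 <- screen_panel(flanks, panel, min_identity = 95)
  expect_equal(sum(hits95$hit_class != "self"), 0)
  hits90 <- screen_panel(flanks, panel, min_identity = 90)
  expect_equal(sum(hits90$hit_class == "paralogous_derived"), 1)
})

test_that("distance matrices reflect planted divergence", {
  set.seed(6)
  base <- random_dna_str(500)
  mut <- function(s, n) {
    v <- strsplit(s, "")[[1]]
    pos <- sample(length(v), n)
    for (p in pos) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
    paste(v, collapse = "")
  }
  seqs <- c(a = base, b = mut(base, 10), c = mut(base, 20), d = base)
  d <- seq_distance_matrix(seqs)
  expect_equal(d["a", "d"], 0)
  expect_equal(d["a", "b"], 2, tolerance = 0.2)
  expect_equal(d["a", "c"], 4, tolerance = 0.2)
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_error(seq_distance_matrix(c(x = "ACGT")), "at least 2")
})

test_that("UPGMA reproduces hand-computed merges and is ultrametric", {
  d <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- upgma(d)
  expect_equal(ape::write.tree(tree), "((A:1,B:1):3,C:4);")

  # ultrametricity on random matrices built from random points
  set.seed(7)
  for (rep in 1:5) {
    n <- 6
    seqs <- setNames(lapply(1:n, function(i) random_dna_str(200)),
                     paste0("t", 1:n))
    dm <- seq_distance_matrix(unlist(seqs))
    tr <- upgma(dm)
    depths <- ape::node.depth.edgelength(tr)[seq_len(n)]
    expect_lt(max(depths) - min(depths), 1e-9)
  }

  # equal distances: all leaf depths equal
  de <- matrix(5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(de) <- 0
  tre <- upgma(de)
  depths <- ape::node.depth.edgelength(tre)[1:4]
  expect_equal(max(depths) - min(depths), 0)

  # deterministic tie-break: smallest label pair merged first
  expect_identical(ape::write.tree(upgma(de)), ape::write.tree(upgma(de)))

  # agreement with average-linkage clustering heights
  set.seed(8)
  p <- matrix(runif(12), 6, 2)
  dm2 <- as.matrix(dist(p))
  dimnames(dm2) <- list(paste0("x", 1:6), paste0("x", 1:6))
  tr2 <- upgma(dm2)
  hc <- hclust(as.dist(dm2), method = "average")
  expect_equal(sort(ape::node.depth.edgelength(tr2))[1], 0,
               tolerance = 1e-9)
  expect_equal(max(ape::node.depth.edgelength(tr2)), max(hc$height) / 2,
               tolerance = 1e-9)

  dbad <- d; dbad[1, 2] <- 3
  expect_error(upgma(dbad), "symmetric")
})

test_that("neighbor joining recovers additive matrices exactly", {
  # 4-taxon additive matrix from a known tree:
  # ((A:1,B:2):3,(C:4,D:5));  internal edge 3
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 8
  d["A", "D"] <- d["D", "A"] <- 9
  d["B", "C"] <- d["C", "B"] <- 9
  d["B", "D"] <- d["D", "B"] <- 10
  d["C", "D"] <- d["D", "C"] <- 9
  tree <- neighbor_joining(d)
  # path distances on the tree reproduce the input exactly
  pd <- ape::cophenetic.phylo(tree)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(pd, d, tolerance = 1e-12)
  # AB vs CD split recovered
  expect_true(ape::is.monophyletic(ape::root(tree, "D"), c("A", "B")))

  # star matrix: internal branch near zero
  ds <- matrix(2, 4, 4, dimnames = dimnames(d)); diag(ds) <- 0
  ts <- neighbor_joining(ds)
  internal <- ts$edge.length[!ts$edge[, 2] %in% seq_len(4)]
  expect_true(all(abs(internal) < 1e-12))

  # ultrametric input: same topology as UPGMA
  du <- matrix(c(0, 2, 8, 8, 2, 0, 8, 8, 8, 8, 0, 4, 8, 8, 4, 0), 4, 4,
               dimnames = dimnames(d))
  tu <- upgma(du)
  tn <- neighbor_joining(du)
  expect_equal(ape::dist.topo(ape::unroot(tu), ape::unroot(tn))[1], 0)

  expect_error(neighbor_joining(d[1:2, 1:2]), "3 taxa")
})

test_that("Newick output round-trips to an isomorphic tree", {
  cfg <- tiny_config(seed = 14)
  panel <- simulate_flank_panel(cfg)
  tr <- panel$truth
  seqs <- setNames(
    vapply(seq_len(nrow(tr)), function(i) {
      substr(panel$genomes[[tr$subject_genome[i]]][[tr$chrom[i]]],
             tr$start[i], tr$end[i] - 1)
    }, character(1)),
    paste0(tr$subject_genome, "_", tr$chrom, "_", seq_len(nrow(tr))))
  res <- flank_trees(seqs[1:6])
  reparsed_u <- ape::read.tree(text = res$newick_upgma)
  expect_equal(ape::dist.topo(ape::unroot(res$upgma),
                              ape::unroot(reparsed_u))[1], 0)
  reparsed_n <- ape::read.tree(text = res$newick_nj)
  expect_equal(ape::dist.topo(ape::unroot(res$nj),
                              ape::unroot(reparsed_n))[1], 0)
})
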