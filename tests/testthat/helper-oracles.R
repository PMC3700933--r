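# Independent oracles used by the property tests. Each re-derives the
# expected result by exhaustive enumeration or direct arithmetic, never by
# calling the code path under test.

# exhaustive Viterbi: best state path over all K^n paths
brute_viterbi <- function(x, means, sd, stay_prob) {
  K <- length(means)
  n <- length(x)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K) - 1L), n)))
  lp <- rep(log(1 / K), nrow(paths))
  for (t in seq_len(n)) {
    lp <- lp + dnorm(x[t], means[paths[, t] + 1L], sd, log = TRUE)
    if (t > 1) {
      same <- paths[, t] == paths[, t - 1L]
      lp <- lp + ifelse(same, log(stay_prob), log((1 - stay_prob) / (K - 1)))
    }
  }
  unname(paths[which.max(lp), ])
}

# exhaustive maximal cliques of an undirected graph given as an adjacency
# matrix; returns a sorted list of sorted member-index vectors
brute_max_cliques <- function(adj) {
  n <- nrow(adj)
  cliques <- list()
  for (mask in seq_len(2^n) - 1L) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(members) == 0) next
    is_clique <- TRUE
    for (a in members) for (b in members) {
      if (a < b && !adj[a, b]) { is_clique <- FALSE; break }
    }
    if (!is_clique) next
    # maximal: no outside vertex adjacent to all members
    extendable <- any(vapply(setdiff(seq_len(n), members), function(v) {
      all(adj[v, members])
    }, logical(1)))
    if (!extendable) cliques[[length(cliques) + 1]] <- members
  }
  cliques <- lapply(cliques, sort)
  cliques[order(vapply(cliques, paste, character(1), collapse = ","))]
}

# exhaustive global alignment score with affine gaps (gap of length L costs
# open + (L-1)*ext); pure recursion, no DP table
brute_global_score <- function(a, b, match = 1, mismatch = -1,
                               open = 2, ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, state) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == bv[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, "m"))
    }
    if (i <= length(av)) {
      cost <- if (state == "ga") ext else open
      best <- max(best, -cost + rec(i + 1, j, "ga"))
    }
    if (j <= length(bv)) {
      cost <- if (state == "gb") ext else open
      best <- max(best, -cost + rec(i, j + 1, "gb"))
    }
    best
  }
  rec(1, 1, "m")
}

# exhaustive local alignment score: best global score over all substring
# pairs (empty alignment scores 0)
brute_local_score <- function(a, b, ...) {
  na <- nchar(a); nb <- nchar(b)
  best <- 0
  for (i1 in 1:na) for (i2 in i1:na) {
    sub_a <- substr(a, i1, i2)
    for (j1 in 1:nb) for (j2 in j1:nb) {
      best <- max(best, brute_global_score(sub_a, substr(b, j1, j2), ...))
    }
  }
  best
}

# direct interval arithmetic for reciprocal overlap
brute_reciprocal <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2))
  c(inter / (e1 - s1), inter / (e2 - s2))
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small fast config shared by tests (chromosomes must host the default
# palette's loci)
tiny_config <- function(seed = 1, populations = c(POP1 = 4L, POP2 = 4L),
                        ...) {
  sim_config(seed = seed,
             populations = populations,
             n_trios = 2L,
             chromosomes = c(chr1 = 1e6, chr11 = 1.7e6, chr14 = 1.5e6,
                             chr15 = 1.6e6),
             noise_sd = 0.05, ...)
}
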