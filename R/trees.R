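#' Pairwise alignment distance matrix
#'
#' Aligns every pair of sequences globally ([global_align()]) and converts
#' percent identity to a distance in percentage points:
#' `d = 100 - pct_identity`. Identical sequences are at distance 0; the
#' matrix is symmetric with a zero diagonal.
#'
#' @param sequences Named character vector of DNA sequences (>= 2).
#' @return Symmetric numeric matrix with sequence names as dimnames.
#' @export
#' @examples
#' seq_distance_matrix(c(a = "ACGTACGT", b = "ACGTACGA", c = "ACGTACGT"))
seq_distance_matrix <- function(sequences) {
  if (length(sequences) < 2) stop("need at least 2 sequences", call. = FALSE)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop("sequences must have unique names", call. = FALSE)
  }
  n <- length(sequences)
  d <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      al <- global_align(sequences[[i]], sequences[[j]])
      d[i, j] <- d[j, i] <- 100 - al$pct_identity
    }
  }
  d
}

check_dist_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop("distance matrix must be square", call. = FALSE)
  }
  if (max(abs(d - t(d))) > 1e-8) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(diag(d) != 0)) stop("diagonal must be zero", call. = FALSE)
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  d
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomerative clustering: at each step the pair of
#' clusters at minimal average distance is merged at height d/2, giving a
#' rooted ultrametric tree (all leaves equidistant from the root). Ties
#' are broken toward the lexicographically smallest label pair, so the
#' output is deterministic.
#'
#' @param d Symmetric distance matrix with zero diagonal (labels from
#'   dimnames).
#' @return An [ape::phylo] tree (rooted, ultrametric).
#' @export
#' @examples
#' d <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' ape::write.tree(upgma(d))  # ((A:1,B:1):3,C:4);
upgma <- function(d) {
  d <- check_dist_matrix(d)
  labels <- rownames(d)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 taxa", call. = FALSE)
  # active clusters: newick fragment, size, height, representative label
  frag <- labels
  size <- rep(1L, n)
  height <- rep(0, n)
  rep_lab <- labels
  dm <- d
  active <- seq_len(n)
  while (length(active) > 1) {
    best <- NULL
    for (ai in seq_along(active)) {
      for (aj in seq_len(ai - 1L)) {
        i <- active[ai]; j <- active[aj]
        dij <- dm[i, j]
        lab_pair <- sort(c(rep_lab[i], rep_lab[j]))
        if (is.null(best) || dij < best$d - 1e-12 ||
            (abs(dij - best$d) <= 1e-12 &&
             (lab_pair[1] < best$lab[1] ||
              (lab_pair[1] == best$lab[1] && lab_pair[2] < best$lab[2])))) {
          best <- list(i = i, j = j, d = dij, lab = lab_pair)
        }
      }
    }
    i <- best$i; j <- best$j
    h <- best$d / 2
    bi <- h - height[i]; bj <- h - height[j]
    # order children by representative label for a canonical output
    ord <- order(c(rep_lab[i], rep_lab[j]))
    kids <- c(sprintf("%s:%s", frag[i], format(bi, digits = 15)),
              sprintf("%s:%s", frag[j], format(bj, digits = 15)))[ord]
    new_frag <- paste0("(", kids[1], ",", kids[2], ")")
    # UPGMA update: size-weighted average distance to the new cluster
    for (k in active) {
      if (k == i || k == j) next
      dm[i, k] <- dm[k, i] <-
        (size[i] * dm[i, k] + size[j] * dm[j, k]) / (size[i] + size[j])
    }
    frag[i] <- new_frag
    size[i] <- size[i] + size[j]
    height[i] <- h
    rep_lab[i] <- min(rep_lab[i], rep_lab[j])
    active <- setdiff(active, j)
  }
  ape::read.tree(text = paste0(frag[active], ";"))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Q-criterion neighbor joining (via [ape::nj()]), returning an
#' unrooted tree that reconstructs additive distance matrices exactly.
#' Negative branch lengths (which NJ can produce on non-additive input)
#' are clamped to zero with a warning.
#'
#' @param d Symmetric distance matrix with zero diagonal, at least 3 taxa.
#' @return An [ape::phylo] tree (unrooted).
#' @export
neighbor_joining <- function(d) {
  d <- check_dist_matrix(d)
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa",
                        call. = FALSE)
  tree <- ape::nj(as.dist(d))
  if (any(tree$edge.length < 0)) {
    warning("negative branch lengths clamped to 0", call. = FALSE)
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Trees for breakpoint flank hits
#'
#' Convenience wrapper building the distance matrix over a set of labelled
#' sequences and returning both tree types, plus their Newick strings.
#'
#' @param sequences Named character vector (>= 3 for NJ; >= 2 for UPGMA).
#' @return List: `distances`, `upgma`, `nj` (NULL if < 3 taxa),
#'   `newick_upgma`, `newick_nj`.
#' @export
flank_trees <- function(sequences) {
  d <- seq_distance_matrix(sequences)
  up <- upgma(d)
  nj_tree <- if (nrow(d) >= 3) neighbor_joining(d) else NULL
  list(distances = d, upgma = up, nj = nj_tree,
       newick_upgma = ape::write.tree(up),
       newick_nj = if (!is.null(nj_tree)) ape::write.tree(nj_tree) else NULL)
}
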