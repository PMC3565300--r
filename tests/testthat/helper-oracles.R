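# Shared fixture builders and independent oracles used across tests.

# random alignment with given per-column variability
rand_aln <- function(n = 6, L = 50, pops = NULL, seed = 1) {
  set.seed(seed)
  mat <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE),
                nrow = n)
  ids <- paste0("s", seq_len(n))
  if (is.null(pops)) pops <- rep(c("P1", "P2"), length.out = n)
  labeled_alignment(apply(mat, 1, paste, collapse = ""), ids,
                    stats::setNames(pops, ids))
}

# random unrooted binary tree with positive branch lengths and its exact
# path-length (additive) distance matrix
random_additive <- function(ntaxa = 8) {
  tr <- ape::unroot(ape::rtree(ntaxa, br = function(k) stats::runif(k, 0.1, 1)))
  D <- ape::cophenetic.phylo(tr)
  ord <- sort(rownames(D))
  list(tree = tr, D = D[ord, ord])
}

# exhaustive small-parsimony oracle: minimum changes over all assignments
# of {A,C,G,T} to the internal nodes of a rooted tree (resolved tips only)
brute_fitch <- function(tree, tip_states) {
  n <- length(tree$tip.label)
  m <- tree$Nnode
  bases <- c("A", "C", "G", "T")
  tips <- tip_states[tree$tip.label]
  grid <- as.matrix(expand.grid(rep(list(bases), m),
                                stringsAsFactors = FALSE))
  # states per assignment (rows of grid) for node number n + k
  best <- Inf
  edge <- tree$edge
  st <- function(node, g) if (node <= n) rep(tips[node], nrow(g)) else
    g[, node - n]
  changes <- matrix(0L, nrow(grid), 1)
  tot <- rep(0L, nrow(grid))
  for (e in seq_len(nrow(edge))) {
    tot <- tot + (st(edge[e, 1], grid) != st(edge[e, 2], grid))
  }
  min(tot)
}

# random rooted binary tree for parsimony tests
rand_rooted <- function(ntaxa) {
  tr <- ape::rtree(ntaxa)
  tr$tip.label <- paste0("t", seq_len(ntaxa))
  tr
}

expect_phylo_equal_topology <- function(t1, t2) {
  testthat::expect_equal(phangorn::RF.dist(ape::unroot(t1),
                                           ape::unroot(t2)), 0)
}

# alignment of sequences related by limited divergence from a common
# ancestor (TN93-safe, unlike uniformly random sequences)
related_aln <- function(n = 6, L = 300, n_mut = 12, pops = NULL, seed = 1) {
  set.seed(seed)
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  seqs <- vapply(seq_len(n), function(i) {
    s <- anc
    mut <- sample(L, n_mut)
    s[mut] <- vapply(s[mut], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
    paste(s, collapse = "")
  }, character(1))
  ids <- paste0("s", seq_len(n))
  if (is.null(pops)) pops <- rep(c("P1", "P2"), length.out = n)
  labeled_alignment(seqs, ids, stats::setNames(pops, ids))
}
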