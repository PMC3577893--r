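# Independent oracles and small generators used across the suite.
# Each oracle is deliberately written without touching the package
# internals it checks.

# random symmetric dissimilarity matrix in [0, dmax]
random_distmat <- function(n, dmax = 0.2, ids = sprintf("e%02d", seq_len(n))) {
  m <- matrix(stats::runif(n * n, 0, dmax), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(ids, ids)
  as_distmat(m)
}

# random coded character matrix
random_char_matrix <- function(n_taxa, n_chars, states = 0:1,
                               type = "unordered",
                               partition = rep("p1", n_chars)) {
  st <- matrix(sample(states, n_taxa * n_chars, replace = TRUE),
               n_taxa, n_chars,
               dimnames = list(sprintf("t%02d", seq_len(n_taxa)), NULL))
  char_matrix(st, rep(type, length.out = n_chars), partition)
}

# connected components of the link graph d <= t (igraph oracle)
components_oracle <- function(d, t) {
  adj <- (unclass(d) <= t) * 1
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  stats::setNames(as.character(comp), rownames(d))
}

# two partitions describe the same grouping (up to label names)
same_partition <- function(p, q) {
  p <- p[sort(names(p))]
  q <- q[sort(names(q))]
  identical(names(p), names(q)) &&
    all(outer(p, p, "==") == outer(q, q, "=="))
}

# column-by-column p-distance oracle (pairwise deletion)
p_distance_oracle <- function(sa, sb) {
  a <- strsplit(sa, "")[[1]]
  b <- strsplit(sb, "")[[1]]
  keep <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  sum(a[keep] != b[keep]) / sum(keep)
}

# score-only affine-gap Smith-Waterman DP (Gotoh recurrences); an
# independent check of the local-alignment engine behind sw_similarity
sw_score_oracle <- function(a, b, match = 5, mismatch = -4, gap_open = 10,
                            gap_extend = 0.5) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e18
  H <- matrix(0, n + 1, m + 1)     # best alignment ending at (i, j)
  X <- matrix(NEG, n + 1, m + 1)   # ... ending with a gap in b
  Y <- matrix(NEG, n + 1, m + 1)   # ... ending with a gap in a
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (A[i] == B[j]) match else mismatch
      X[i + 1, j + 1] <- max(H[i, j + 1] - gap_open - gap_extend,
                             X[i, j + 1] - gap_extend)
      Y[i + 1, j + 1] <- max(H[i + 1, j] - gap_open - gap_extend,
                             Y[i + 1, j] - gap_extend)
      H[i + 1, j + 1] <- max(0, H[i, j] + s, X[i + 1, j + 1],
                             Y[i + 1, j + 1])
    }
  }
  max(H)
}

# exhaustive parsimony minimum over all topologies via phangorn
phangorn_min_score <- function(m) {
  taxa <- rownames(m$states)
  st <- m$states
  st[is.na(st)] <- "?"
  dat <- phangorn::phyDat(st, type = "USER",
                          levels = sort(unique(as.vector(m$states[!is.na(m$states)]))))
  trees <- phangorn::allTrees(length(taxa), tip.label = taxa)
  min(vapply(trees, function(tr)
    phangorn::parsimony(tr, dat, method = "fitch"), numeric(1)))
}

# tiny aligned msa builder
make_msa <- function(...) as_msa(c(...))

# inline GenBank flat-file text for parser tests
genbank_fixture_lines <- function() {
  c("LOCUS       TST00001                 500 bp    DNA     linear   PLN 15-MAR-2012",
    "DEFINITION  test record one.",
    "  ORGANISM  Synthsymbiont demo",
    "FEATURES             Location/Qualifiers",
    "     source          1..500",
    "                     /host=\"Macrotermes michaelseni\"",
    "                     /country=\"Kenya\"",
    "//",
    "LOCUS       TST00002                 500 bp    DNA     linear   PLN 02-JUL-2008",
    "  ORGANISM  Synthsymbiont demo",
    "FEATURES             Location/Qualifiers",
    "     source          1..500",
    "                     /host=\"Odontotermes sp.\"",
    "//",
    "LOCUS       TST00003                 500 bp    DNA     linear   PLN 01-JAN-2005",
    "  ORGANISM  Synthsymbiont demo",
    "FEATURES             Location/Qualifiers",
    "     source          1..500",
    "//")
}
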