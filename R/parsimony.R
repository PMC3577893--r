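# Maximum-parsimony machinery: generalized (Sankoff) scoring with per-
# character cost matrices, exact branch-and-bound tree search, DELTRAN
# branch lengths, partitioned Bremer support and MP bootstrapping.
# Exact search is limited to small taxon sets (default bound 12), the
# regime of culture-collection comparisons this package targets.

# ---- scoring engine ---------------------------------------------------

# Pre-digest a char_matrix: identical site patterns (same states, type and
# partition) are collapsed to one weighted column, characters are grouped
# by (type, state count) so a group shares one cost matrix, and per-taxon
# tip score matrices are built once.
build_parsimony_engine <- function(m) {
  stopifnot(inherits(m, "char_matrix"))
  pattern <- paste(m$type, m$partition,
                   apply(m$states, 2L, paste, collapse = ","))
  first <- which(!duplicated(pattern))
  weight <- as.numeric(table(factor(pattern, levels = pattern[first])))
  st <- m$states[, first, drop = FALSE]
  type <- m$type[first]
  partition <- m$partition[first]
  taxa <- rownames(st)
  nstates <- apply(st, 2L, function(col) max(2L, max(col, na.rm = TRUE) + 1L))
  nstates[!is.finite(nstates)] <- 2L   # all-missing character
  key <- paste(type, nstates)
  groups <- lapply(split(seq_len(ncol(st)), key), function(cols) {
    S <- nstates[cols[1L]]
    M <- if (type[cols[1L]] == "ordered")
      abs(outer(seq_len(S) - 1L, seq_len(S) - 1L, "-"))
    else 1 - diag(S)
    tips <- lapply(seq_along(taxa), function(i) {
      V <- matrix(Inf, S, length(cols))
      obs <- st[i, cols]
      V[, is.na(obs)] <- 0
      ok <- which(!is.na(obs))
      V[cbind(obs[ok] + 1L, ok)] <- 0
      V
    })
    names(tips) <- taxa
    list(S = S, cost = M, cols = cols, partition = partition[cols],
         tips = tips)
  })
  list(groups = groups, taxa = taxa, partitions = partition, weight = weight)
}

# min_t (cost[s, t] + V[t, c]) for all s, c
sankoff_combine <- function(V, M) {
  S <- nrow(M)
  out <- matrix(0, S, ncol(V))
  for (s in seq_len(S)) {
    X <- V + M[s, ]
    v <- X[1L, ]
    if (S > 1L) for (t in 2L:S) v <- pmin(v, X[t, ])
    out[s, ] <- v
  }
  out
}

row_mins <- function(V) {
  v <- V[1L, ]
  if (nrow(V) > 1L) for (t in 2L:nrow(V)) v <- pmin(v, V[t, ])
  v
}

# struct: list(postorder = node ids tips-before-parents, children = list,
# leaf_name = tip labels indexed by node id, n_nodes)
sankoff_root_vectors <- function(struct, engine) {
  lapply(engine$groups, function(g) {
    V <- vector("list", struct$n_nodes)
    for (nd in struct$postorder) {
      ch <- struct$children[[nd]]
      if (!length(ch)) {
        V[[nd]] <- g$tips[[struct$leaf_name[nd]]]
      } else {
        acc <- 0
        for (c in ch) acc <- acc + sankoff_combine(V[[c]], g$cost)
        V[[nd]] <- acc
      }
    }
    V
  })
}

sankoff_char_scores <- function(struct, engine) {
  Vs <- sankoff_root_vectors(struct, engine)
  root <- struct$postorder[length(struct$postorder)]
  scores <- numeric(length(engine$partitions))
  for (gi in seq_along(engine$groups)) {
    g <- engine$groups[[gi]]
    scores[g$cols] <- row_mins(Vs[[gi]][[root]])
  }
  scores
}

struct_from_phylo <- function(tree) {
  tree <- stats::reorder(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_nodes <- n_tip + tree$Nnode
  children <- rep(list(integer()), n_nodes)
  for (i in seq_len(nrow(tree$edge)))
    children[[tree$edge[i, 1L]]] <-
      c(children[[tree$edge[i, 1L]]], tree$edge[i, 2L])
  leaf_name <- c(tree$tip.label, rep(NA_character_, tree$Nnode))
  # node postorder: in a postorder-sorted edge matrix every node appears as
  # a child after all of its own descendants; append the root.
  postorder <- c(tree$edge[, 2L], n_tip + 1L)
  list(postorder = postorder, children = children, leaf_name = leaf_name,
       n_nodes = n_nodes)
}

# edges: integer matrix on node ids (leaves 1..n_total; internals > n_total);
# taxa_names: names for leaf ids. Rooted at the neighbour of leaf 1.
struct_from_edges <- function(edges, taxa_names) {
  n_nodes <- max(edges)
  adj <- rep(list(integer()), n_nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  root <- adj[[1L]][1L]   # internal neighbour of leaf 1; leaf 1 is a child
  children <- rep(list(integer()), n_nodes)
  stack <- list(c(root, 0L))
  order_seen <- integer(0)
  parent <- integer(n_nodes)
  # iterative DFS recording preorder, then reverse for postorder
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nd <- top[1L]; par <- top[2L]
    parent[nd] <- par
    order_seen <- c(order_seen, nd)
    kids <- setdiff(adj[[nd]], par)
    children[[nd]] <- kids
    for (k in kids) stack[[length(stack) + 1L]] <- c(k, nd)
  }
  leaf_name <- rep(NA_character_, n_nodes)
  leaf_name[seq_along(taxa_names)] <- taxa_names
  list(postorder = rev(order_seen), children = children,
       leaf_name = leaf_name, n_nodes = n_nodes)
}

#' Parsimony score of a tree under a coded character matrix
#'
#' Minimal number of state changes over the tree, summed over characters:
#' generalized (Sankoff) dynamic programming with unit costs for unordered
#' characters and linear `|i - j|` step costs for ordered ones.  Missing
#' states are free wildcards.  The score does not depend on the rooting.
#'
#' @param tree An `ape::phylo` whose tip labels equal the matrix taxa.
#' @param m A `"char_matrix"`.
#' @return Numeric vector of per-partition scores with a `"total"`
#'   attribute; `sum(result)` equals the total score.
#' @export
score_tree <- function(tree, m) {
  if (!setequal(tree$tip.label, rownames(m$states)))
    stop("tree tips and matrix taxa differ")
  engine <- build_parsimony_engine(m)
  sc <- sankoff_char_scores(struct_from_phylo(tree), engine) * engine$weight
  out <- tapply(sc, engine$partitions, sum)
  res <- stats::setNames(as.numeric(out), names(out))
  attr(res, "total") <- sum(sc)
  res
}

# ---- exact tree search ------------------------------------------------

insert_leaf <- function(edges, edge_row, leaf, newnode) {
  u <- edges[edge_row, 1L]; v <- edges[edge_row, 2L]
  rbind(edges[-edge_row, , drop = FALSE],
        matrix(c(u, newnode, newnode, v, newnode, leaf),
               ncol = 2L, byrow = TRUE))
}

edges_to_phylo <- function(edges, taxa) {
  struct <- struct_from_edges(edges, taxa)
  as_newick <- function(nd) {
    ch <- struct$children[[nd]]
    if (!length(ch)) return(struct$leaf_name[nd])
    paste0("(", paste(vapply(ch, as_newick, character(1)), collapse = ","), ")")
  }
  root <- struct$postorder[length(struct$postorder)]
  ape::read.tree(text = paste0(as_newick(root), ";"))
}

#' Exact maximum-parsimony tree search by branch and bound
#'
#' Stepwise-addition enumeration of unrooted binary topologies with
#' branch-and-bound pruning (a partial tree's score never decreases when
#' taxa are added).  Returns every topology attaining the global minimum
#' score, in deterministic enumeration order.
#'
#' @param m A `"char_matrix"` with at least 4 taxa.
#' @param max_taxa Enumeration bound; beyond it exact search is refused
#'   (the topology count grows as `(2n-5)!!`) and a heuristic search in a
#'   dedicated phylogenetics package is recommended instead.
#' @return List with `score` (total), `trees` (list of unrooted
#'   `ape::phylo`), and `n_evaluated` (number of complete topologies
#'   scored).
#' @export
bnb_search <- function(m, max_taxa = 12L) {
  taxa <- rownames(m$states)
  n <- length(taxa)
  if (n < 4L) stop("need at least 4 taxa for tree search")
  if (n > max_taxa)
    stop("exact search refused for ", n, " taxa (bound ", max_taxa,
         "); use a heuristic search from a phylogenetics package")
  engine <- build_parsimony_engine(m)
  score_edges <- function(edges)
    sum(sankoff_char_scores(struct_from_edges(edges, taxa), engine) *
        engine$weight)
  env <- new.env(parent = emptyenv())
  env$trees <- list()
  env$evaluated <- 0L
  base <- matrix(c(n + 1L, 1L, n + 1L, 2L, n + 1L, 3L), ncol = 2L,
                 byrow = TRUE)
  # greedy stepwise-addition tree: a cheap, achievable upper bound that
  # lets the branch-and-bound prune from the start
  greedy <- base
  for (k in seq(4L, n)) {
    cands <- lapply(seq_len(nrow(greedy)), function(i)
      insert_leaf(greedy, i, k, n + k - 2L))
    greedy <- cands[[which.min(vapply(cands, score_edges, numeric(1)))]]
  }
  env$best <- score_edges(greedy)
  recurse <- function(edges, k) {
    if (k > n) {
      sc <- score_edges(edges)
      env$evaluated <- env$evaluated + 1L
      if (sc < env$best) {
        env$best <- sc
        env$trees <- list(edges)
      } else if (sc == env$best) {
        env$trees[[length(env$trees) + 1L]] <- edges
      }
      return(invisible())
    }
    for (i in seq_len(nrow(edges))) {
      cand <- insert_leaf(edges, i, k, n + k - 2L)
      if (score_edges(cand) <= env$best) recurse(cand, k + 1L)
    }
  }
  recurse(base, 4L)
  list(score = env$best,
       trees = lapply(env$trees, edges_to_phylo, taxa = taxa),
       n_evaluated = env$evaluated)
}

# canonical split keys of the internal edges of an unrooted tree:
# leaves on the side NOT containing the first taxon, sorted, "|"-joined
tree_splits <- function(tree, taxa = sort(tree$tip.label)) {
  tree <- ape::unroot(tree)
  n_tip <- length(tree$tip.label)
  out <- character(0)
  for (i in seq_len(nrow(tree$edge))) {
    child <- tree$edge[i, 2L]
    if (child <= n_tip) next
    leaves <- tree$tip.label[intersect(unlist(phangorn_free_descendants(tree, child)),
                                       seq_len(n_tip))]
    if (taxa[1L] %in% leaves) leaves <- setdiff(tree$tip.label, leaves)
    if (length(leaves) < 2L || length(leaves) > n_tip - 2L) next
    out <- c(out, paste(sort(leaves), collapse = "|"))
  }
  unique(out)
}

# descendants of a node (including itself) without extra dependencies
phangorn_free_descendants <- function(tree, node) {
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  c(node, unlist(lapply(kids, phangorn_free_descendants, tree = tree)))
}

# ---- DELTRAN branch lengths ------------------------------------------

#' Per-branch, per-partition parsimony branch lengths (DELTRAN)
#'
#' Assigns ancestral states among the maximum-parsimony-optimal
#' possibilities with *delayed transformation*: at each node the parent's
#' state is retained whenever it is among the optimal states, pushing
#' changes toward the tips.  Remaining ties go to the smallest state.  The
#' branch length is the number of steps on that branch summed over each
#' partition's characters; lengths sum over branches to the tree's
#' parsimony score partition by partition.
#'
#' @param tree Rooted binary `ape::phylo` (root the tree first, e.g. with
#'   [midpoint_root()]).
#' @param m A `"char_matrix"` over the tree's tips.
#' @return data.frame with one row per edge (ape edge order): `parent`,
#'   `child`, `child_label` (tip label or ""), one `length_<partition>`
#'   column per partition and `length_total`.
#' @export
deltran_lengths <- function(tree, m) {
  if (!setequal(tree$tip.label, rownames(m$states)))
    stop("tree tips and matrix taxa differ")
  engine <- build_parsimony_engine(m)
  struct <- struct_from_phylo(tree)
  Vs <- sankoff_root_vectors(struct, engine)
  root <- struct$postorder[length(struct$postorder)]
  n_edges <- nrow(tree$edge)
  tags <- sort(unique(engine$partitions))
  len <- matrix(0, n_edges, length(tags), dimnames = list(NULL, tags))
  edge_of_child <- integer(struct$n_nodes)
  edge_idx <- stats::reorder(tree, "postorder")$edge
  for (i in seq_len(n_edges)) edge_of_child[edge_idx[i, 2L]] <- i
  for (gi in seq_along(engine$groups)) {
    g <- engine$groups[[gi]]
    V <- Vs[[gi]]
    nC <- length(g$cols)
    state <- matrix(NA_integer_, struct$n_nodes, nC)
    rv <- V[[root]]
    for (c in seq_len(nC)) state[root, c] <- which.min(rv[, c])
    for (nd in rev(struct$postorder)) {
      for (ch in struct$children[[nd]]) {
        Vc <- V[[ch]]
        for (c in seq_len(nC)) {
          s <- state[nd, c]
          costs <- g$cost[s, ] + Vc[, c]
          opt <- which(costs == min(costs))
          t <- if (s %in% opt) s else opt[1L]
          state[ch, c] <- t
          step <- g$cost[s, t] * engine$weight[g$cols[c]]
          if (step > 0)
            len[edge_of_child[ch], gi_tag(g, c)] <-
              len[edge_of_child[ch], gi_tag(g, c)] + step
        }
      }
    }
  }
  po_edge <- edge_idx
  out <- data.frame(parent = po_edge[, 1L], child = po_edge[, 2L],
                    child_label = ifelse(po_edge[, 2L] <= length(tree$tip.label),
                                         tree$tip.label[po_edge[, 2L]], ""))
  for (tg in tags) out[[paste0("length_", tg)]] <- len[, tg]
  out$length_total <- rowSums(len)
  out
}

gi_tag <- function(g, c) g$partition[c]

# ---- Bremer support ---------------------------------------------------

#' Total and partitioned Bremer (decay) support
#'
#' For every internal branch (bipartition) of a most-parsimonious tree, the
#' total Bremer support is the score of the best tree *not* containing that
#' bipartition minus the global minimum score.  The partitioned Bremer
#' support of a data partition is that partition's score on the best
#' incompatible tree minus its score on the given tree; it may be negative
#' (the partition conflicts with the branch) and the partition values sum
#' to the total on every branch by construction.  Implemented as a single
#' multi-target branch-and-bound enumeration; among equally good
#' incompatible trees the first in deterministic enumeration order is used.
#'
#' @param tree A most-parsimonious `ape::phylo` for `m` (see
#'   [bnb_search()]).
#' @param m A `"char_matrix"`.
#' @param max_taxa Enumeration bound as in [bnb_search()].
#' @return data.frame with one row per internal branch: `split` (canonical
#'   `|`-joined smaller side), one `bremer_<partition>` column per
#'   partition, and `bremer_total`.
#' @export
bremer <- function(tree, m, max_taxa = 12L) {
  taxa <- rownames(m$states)
  n <- length(taxa)
  if (n > max_taxa)
    stop("exact Bremer enumeration refused for ", n, " taxa (bound ",
         max_taxa, ")")
  engine <- build_parsimony_engine(m)
  tags <- sort(unique(engine$partitions))
  part_scores <- function(struct) {
    sc <- sankoff_char_scores(struct, engine) * engine$weight
    as.numeric(tapply(sc, engine$partitions, sum)[tags])
  }
  base_struct <- struct_from_phylo(tree)
  base_part <- part_scores(base_struct)
  base_total <- sum(base_part)
  targets <- tree_splits(tree, sort(taxa))
  if (!length(targets))
    return(data.frame(split = character(), bremer_total = numeric()))
  env <- new.env(parent = emptyenv())
  env$best <- stats::setNames(rep(Inf, length(targets)), targets)
  env$best_part <- rep(list(NULL), length(targets))
  names(env$best_part) <- targets
  score_edges <- function(edges)
    sum(sankoff_char_scores(struct_from_edges(edges, taxa), engine) *
        engine$weight)
  base <- matrix(c(n + 1L, 1L, n + 1L, 2L, n + 1L, 3L), ncol = 2L,
                 byrow = TRUE)
  recurse <- function(edges, k) {
    if (k > n) {
      ph <- edges_to_phylo(edges, taxa)
      splits <- tree_splits(ph, sort(taxa))
      miss <- setdiff(targets, splits)
      if (!length(miss)) return(invisible())
      sc <- part_scores(struct_from_phylo(ph))
      tot <- sum(sc)
      for (s in miss) {
        if (tot < env$best[[s]]) {
          env$best[[s]] <- tot
          env$best_part[[s]] <- sc
        }
      }
      return(invisible())
    }
    bound <- max(env$best)
    for (i in seq_len(nrow(edges))) {
      cand <- insert_leaf(edges, i, k, n + k - 2L)
      if (score_edges(cand) <= bound) recurse(cand, k + 1L)
    }
  }
  recurse(base, 4L)
  out <- data.frame(split = targets)
  pm <- do.call(rbind, lapply(targets, function(s)
    env$best_part[[s]] - base_part))
  colnames(pm) <- paste0("bremer_", tags)
  out <- cbind(out, as.data.frame(pm))
  out$bremer_total <- env$best - base_total
  rownames(out) <- NULL
  out
}

# ---- bootstrap --------------------------------------------------------

#' Maximum-parsimony bootstrap support
#'
#' Characters are resampled with replacement, an exact search is run per
#' replicate, and a clade of the reference tree is counted as recovered
#' when its bipartition occurs in *every* most-parsimonious tree of the
#' replicate (strict-consensus convention).  Reproducible for a fixed
#' seed.
#'
#' @param m A `"char_matrix"`.
#' @param reference Reference `ape::phylo` whose internal branches are
#'   scored; defaults to the first tree of [bnb_search()].
#' @param replicates Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param max_taxa Enumeration bound as in [bnb_search()].
#' @return data.frame with columns `split` and `bootstrap` (percentages).
#' @export
mp_bootstrap <- function(m, reference = NULL, replicates = 100L, seed = 1L,
                         max_taxa = 12L) {
  stopifnot(replicates >= 1L)
  if (is.null(reference)) reference <- bnb_search(m, max_taxa)$trees[[1L]]
  taxa <- sort(rownames(m$states))
  targets <- tree_splits(reference, taxa)
  hits <- stats::setNames(numeric(length(targets)), targets)
  set.seed(seed)
  for (r in seq_len(replicates)) {
    idx <- sample.int(ncol(m$states), replace = TRUE)
    mb <- char_matrix(m$states[, idx, drop = FALSE], m$type[idx],
                      m$partition[idx])
    res <- bnb_search(mb, max_taxa)
    splits_all <- lapply(res$trees, tree_splits, taxa = taxa)
    common <- Reduce(intersect, splits_all)
    hits[targets %in% common] <- hits[targets %in% common] + 1
  }
  data.frame(split = targets, bootstrap = 100 * hits / replicates,
             row.names = NULL)
}

# ---- midpoint rooting -------------------------------------------------

#' Midpoint rooting
#'
#' Roots a tree at the midpoint of the longest leaf-to-leaf path; among
#' equally long paths the lexicographically smallest (sorted) leaf-name
#' pair wins, making the rooting deterministic.  When all branch lengths
#' are zero the tree is rooted on its first edge with a warning.
#'
#' @param tree `ape::phylo` with non-negative branch lengths.
#' @return A rooted `ape::phylo`.
#' @export
midpoint_root <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (length(tree$tip.label) > 2L) tree <- ape::unroot(tree)
  n_tip <- length(tree$tip.label)
  D <- ape::dist.nodes(tree)
  DL <- D[seq_len(n_tip), seq_len(n_tip)]
  if (max(DL) == 0) {
    warning("all branch lengths zero; rooting on the first edge")
    return(ape::root(tree, outgroup = tree$tip.label[1L],
                     resolve.root = TRUE))
  }
  # deterministic longest pair: maximal distance, then smallest name pair
  pairs <- which(DL == max(DL), arr.ind = TRUE)
  pairs <- pairs[pairs[, 1L] < pairs[, 2L], , drop = FALSE]
  nm1 <- pmin(tree$tip.label[pairs[, 1L]], tree$tip.label[pairs[, 2L]])
  nm2 <- pmax(tree$tip.label[pairs[, 1L]], tree$tip.label[pairs[, 2L]])
  k <- order(nm1, nm2)[1L]
  u <- pairs[k, 1L]; v <- pairs[k, 2L]
  if (tree$tip.label[u] > tree$tip.label[v]) { tmp <- u; u <- v; v <- tmp }
  path <- ape::nodepath(tree, u, v)
  half <- DL[u, v] / 2
  cum <- 0
  for (i in seq_len(length(path) - 1L)) {
    a <- path[i]; b <- path[i + 1L]
    er <- which((tree$edge[, 1L] == a & tree$edge[, 2L] == b) |
                (tree$edge[, 1L] == b & tree$edge[, 2L] == a))
    el <- tree$edge.length[er]
    if (cum + el >= half) {
      # midpoint on edge (a, b) at distance (half - cum) from a;
      # reroot()'s position is measured from the parent end of the edge
      child <- tree$edge[er, 2L]
      rooted <- if (child == b)      # a is the parent
        phytools::reroot(tree, b, position = half - cum)
      else                           # b is the parent
        phytools::reroot(tree, a, position = cum + el - half)
      return(rooted)
    }
    cum <- cum + el
  }
  stop("midpoint not located; inconsistent branch lengths")
}
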