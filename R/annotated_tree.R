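# Annotated phylogeny: a rooted binary ape::phylo plus a per-branch table
# of per-partition DELTRAN lengths, per-partition Bremer supports,
# bootstrap percentages and within-species marks.  Branches are keyed by
# their child node; annotations survive Newick round trips via [&...]
# comment blocks.

#' Construct an annotated tree
#'
#' @param tree Rooted `ape::phylo`.
#' @param branch data.frame with columns `parent`, `child`, `child_label`
#'   and any of `length_<tag>`, `length_total`, `bremer_<tag>`,
#'   `bremer_total`, `bootstrap`, `within_species`.
#' @param partitions Character vector of partition tags.
#' @return An object of class `"annotated_tree"`.
#' @export
annotated_tree <- function(tree, branch, partitions) {
  stopifnot(inherits(tree, "phylo"), is.data.frame(branch))
  if (!all(c("parent", "child") %in% names(branch)))
    stop("branch table needs parent and child columns")
  if (nrow(branch) != nrow(tree$edge))
    stop("branch table must have one row per tree edge")
  lt <- paste0("length_", partitions)
  if (all(c(lt, "length_total") %in% names(branch))) {
    if (max(abs(rowSums(branch[, lt, drop = FALSE]) - branch$length_total)) > 1e-9)
      stop("per-partition branch lengths must sum to length_total")
  }
  bt <- paste0("bremer_", partitions)
  if (all(c(bt, "bremer_total") %in% names(branch))) {
    ok <- stats::complete.cases(branch[, c(bt, "bremer_total")])
    if (any(abs(rowSums(branch[ok, bt, drop = FALSE]) -
                branch$bremer_total[ok]) > 1e-9))
      stop("partitioned Bremer values must sum to bremer_total")
  }
  structure(list(tree = tree, branch = branch, partitions = partitions),
            class = "annotated_tree")
}

#' @export
print.annotated_tree <- function(x, ...) {
  cat("Annotated tree: ", length(x$tree$tip.label), " leaves, partitions: ",
      paste(x$partitions, collapse = ", "), "\n", sep = "")
  ann <- intersect(c("length_total", "bremer_total", "bootstrap",
                     "within_species"), names(x$branch))
  cat("Branch annotations:", paste(ann, collapse = ", "), "\n")
  if ("within_species" %in% names(x$branch))
    cat(sum(x$branch$within_species, na.rm = TRUE),
        "branch(es) marked as within-species\n")
  invisible(x)
}

#' Infer a fully annotated maximum-parsimony tree from a character matrix
#'
#' Convenience pipeline: exact MP search, midpoint rooting on total DELTRAN
#' branch lengths, DELTRAN per-partition lengths on the rooted tree,
#' partitioned Bremer supports, and (optionally) MP bootstrap percentages.
#'
#' @param m A `"char_matrix"`.
#' @param bootstrap_replicates Number of bootstrap replicates (0 to skip).
#' @param seed Seed for the bootstrap.
#' @param max_taxa Enumeration bound, see [bnb_search()].
#' @param with_bremer Compute partitioned Bremer supports?
#' @return An `"annotated_tree"`.
#' @export
annotate_tree <- function(m, bootstrap_replicates = 0L, seed = 1L,
                          max_taxa = 12L, with_bremer = TRUE) {
  res <- bnb_search(m, max_taxa)
  tr <- res$trees[[1L]]
  # provisional rooting only to obtain total change counts per edge
  prov <- ape::root(tr, outgroup = sort(tr$tip.label)[1L], resolve.root = TRUE)
  prov <- ape::collapse.singles(prov)
  lens <- deltran_lengths(prov, m)
  prov$edge.length <- lens$length_total[match_edges(prov, lens)]
  rooted <- midpoint_root(prov)
  branch <- deltran_lengths(rooted, m)
  rooted$edge.length <- branch$length_total[match_edges(rooted, branch)]
  taxa <- sort(rownames(m$states))
  if (with_bremer) {
    br <- bremer(tr, m, max_taxa)
    branch <- merge_split_column(rooted, branch, br, taxa)
  }
  if (bootstrap_replicates > 0L) {
    bs <- mp_bootstrap(m, reference = tr, replicates = bootstrap_replicates,
                       seed = seed, max_taxa = max_taxa)
    branch <- merge_split_column(rooted, branch, bs, taxa)
  }
  annotated_tree(rooted, branch, sort(unique(m$partition)))
}

# index of branch-table rows in the order of tree$edge rows
match_edges <- function(tree, branch) {
  key <- paste(tree$edge[, 1L], tree$edge[, 2L])
  match(key, paste(branch$parent, branch$child))
}

# attach split-keyed statistics (bremer / bootstrap tables) to the branch
# table of a rooted tree; branches whose bipartition is not an internal
# split of the unrooted tree get NA
merge_split_column <- function(tree, branch, tab, taxa) {
  n_tip <- length(tree$tip.label)
  split_of_child <- vapply(branch$child, function(ch) {
    if (ch <= n_tip) return(NA_character_)
    leaves <- tree$tip.label[intersect(
      unlist(phangorn_free_descendants(tree, ch)), seq_len(n_tip))]
    if (taxa[1L] %in% leaves) leaves <- setdiff(tree$tip.label, leaves)
    if (length(leaves) < 2L || length(leaves) > n_tip - 2L)
      return(NA_character_)
    paste(sort(leaves), collapse = "|")
  }, character(1))
  for (col in setdiff(names(tab), "split"))
    branch[[col]] <- tab[[col]][match(split_of_child, tab$split)]
  branch
}

# ---- annotated Newick -------------------------------------------------

#' Write a tree (optionally annotated) to Newick
#'
#' Plain `ape::phylo` objects are written as standard Newick (branch
#' lengths and node support labels preserved); `"annotated_tree"` objects
#' additionally carry their branch table as `[&key=value,...]` comment
#' blocks after each node, a bracket syntax analogous to annotated formats
#' used by Bayesian phylogenetics tools.
#'
#' @param x `ape::phylo` or `"annotated_tree"`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(x, path) {
  writeLines(newick_string(x), path)
  invisible(path)
}

newick_string <- function(x) {
  ann <- NULL
  if (inherits(x, "annotated_tree")) {
    tree <- x$tree
    keep <- setdiff(names(x$branch), c("parent", "child", "child_label"))
    ann <- x$branch[, keep, drop = FALSE]
    rownames(ann) <- x$branch$child
  } else tree <- x
  n_tip <- length(tree$tip.label)
  edge_of <- integer(n_tip + tree$Nnode)
  edge_of[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  fmt_num <- function(v) format(v, digits = 15, scientific = FALSE, trim = TRUE)
  node_str <- function(nd) {
    kids <- tree$edge[tree$edge[, 1L] == nd, 2L]
    lab <- if (nd <= n_tip) tree$tip.label[nd]
           else if (!is.null(tree$node.label) &&
                    !is.na(tree$node.label[nd - n_tip]) &&
                    nzchar(tree$node.label[nd - n_tip]))
             tree$node.label[nd - n_tip]
           else ""
    core <- if (length(kids))
      paste0("(", paste(vapply(kids, node_str, character(1)), collapse = ","),
             ")", lab)
    else lab
    cm <- ""
    if (!is.null(ann) && as.character(nd) %in% rownames(ann)) {
      row <- ann[as.character(nd), , drop = FALSE]
      keep <- !vapply(row, function(v) is.na(v), logical(1))
      if (any(keep)) {
        vals <- vapply(which(keep), function(j) {
          v <- row[[j]]
          if (is.logical(v)) as.character(as.integer(v)) else fmt_num(v)
        }, character(1))
        cm <- paste0("[&", paste(names(row)[keep], vals, sep = "=",
                                 collapse = ","), "]")
      }
    }
    br <- ""
    if (!is.null(tree$edge.length) && edge_of[nd] > 0L && nd != n_tip + 1L)
      br <- paste0(":", fmt_num(tree$edge.length[edge_of[nd]]))
    paste0(core, cm, br)
  }
  paste0(node_str(n_tip + 1L), ";")
}

#' Read a (possibly annotated) Newick tree
#'
#' Parses standard Newick; `[&key=value,...]` comment blocks, when
#' present, are collected into a branch table and an `"annotated_tree"` is
#' returned, otherwise a plain `ape::phylo`.
#'
#' @param path Newick file (first non-empty line is parsed).
#' @return `ape::phylo` or `"annotated_tree"`.
#' @export
read_newick <- function(path) {
  txt <- paste(trimws(readLines(path, warn = FALSE)), collapse = "")
  if (!nzchar(txt)) stop("empty Newick file: ", path)
  parse_newick(txt)
}

parse_newick <- function(txt) {
  if (!grepl(";\\s*$", txt)) stop("Newick parse error: missing ';'")
  chars <- strsplit(txt, "")[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (depth[length(chars)] != 0 || any(depth < 0))
    stop("Newick parse error: unbalanced parentheses")
  pos <- 1L
  peek <- function() if (pos <= length(chars)) chars[pos] else ""
  node_id <- 0L
  nodes <- list()   # each: list(children=ids, label, comment, length)
  parse_node <- function() {
    children <- integer(0)
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        children <- c(children, parse_node())
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        stop("Newick parse error near position ", pos)
      }
    }
    lab <- ""
    while (!(peek() %in% c("", ",", ")", ":", ";", "["))) {
      lab <- paste0(lab, peek()); pos <<- pos + 1L
    }
    comment <- NA_character_
    if (peek() == "[") {
      end <- pos
      while (chars[end] != "]") end <- end + 1L
      comment <- paste(chars[(pos + 1L):(end - 1L)], collapse = "")
      pos <<- end + 1L
    }
    len <- NA_real_
    if (peek() == ":") {
      pos <<- pos + 1L
      num <- ""
      while (grepl("[0-9eE.+-]", peek())) { num <- paste0(num, peek()); pos <<- pos + 1L }
      len <- as.numeric(num)
      if (peek() == "[") {
        end <- pos
        while (chars[end] != "]") end <- end + 1L
        comment <- paste(chars[(pos + 1L):(end - 1L)], collapse = "")
        pos <<- end + 1L
      }
    }
    node_id <<- node_id + 1L
    nodes[[node_id]] <<- list(children = children, label = lab,
                              comment = comment, length = len)
    node_id
  }
  root <- parse_node()
  if (peek() != ";") stop("Newick parse error: trailing characters")
  build_phylo_from_nodes(nodes, root)
}

build_phylo_from_nodes <- function(nodes, root) {
  is_leaf <- vapply(nodes, function(n) length(n$children) == 0L, logical(1))
  n_tip <- sum(is_leaf)
  tip_ids <- which(is_leaf)
  int_ids <- c(root, setdiff(which(!is_leaf), root))
  id_map <- integer(length(nodes))
  id_map[tip_ids] <- seq_len(n_tip)
  id_map[int_ids] <- n_tip + seq_along(int_ids)
  edges <- NULL
  for (i in which(!is_leaf))
    for (ch in nodes[[i]]$children)
      edges <- rbind(edges, c(id_map[i], id_map[ch]))
  tree <- list(edge = edges, Nnode = length(int_ids),
               tip.label = vapply(nodes[tip_ids], `[[`, "", "label"))
  lens <- vapply(nodes, `[[`, 0, "length")
  if (any(!is.na(lens))) {
    el <- rep(0, nrow(edges))
    for (i in seq_along(nodes))
      if (!is.na(lens[i])) el[which(edges[, 2L] == id_map[i])] <- lens[i]
    tree$edge.length <- el
  }
  int_labs <- vapply(nodes[int_ids], `[[`, "", "label")
  if (any(nzchar(int_labs))) tree$node.label <- int_labs
  class(tree) <- "phylo"
  tree <- stats::reorder(tree, "cladewise")
  comments <- vapply(nodes, `[[`, "", "comment")
  if (all(is.na(comments))) return(tree)
  rows <- lapply(seq_along(nodes), function(i) {
    if (is.na(comments[i])) return(NULL)
    cm <- sub("^&", "", comments[i])
    kv <- strsplit(strsplit(cm, ",")[[1]], "=")
    vals <- lapply(kv, function(p) {
      v <- suppressWarnings(as.numeric(p[2L]))
      if (is.na(v)) p[2L] else v
    })
    c(list(child = id_map[i]), stats::setNames(vals, vapply(kv, `[`, "", 1L)))
  })
  rows <- Filter(Negate(is.null), rows)
  cols <- unique(unlist(lapply(rows, names)))
  branch <- data.frame(parent = tree$edge[, 1L], child = tree$edge[, 2L],
                       child_label = ifelse(tree$edge[, 2L] <= n_tip,
                                            tree$tip.label[tree$edge[, 2L]], ""))
  for (cl in setdiff(cols, "child")) {
    v <- rep(NA_real_, nrow(branch))
    for (r in rows) if (cl %in% names(r))
      v[branch$child == r$child] <- r[[cl]]
    branch[[cl]] <- v
  }
  if ("within_species" %in% names(branch))
    branch$within_species <- branch$within_species > 0
  tags <- sub("^length_", "", grep("^length_(?!total)", names(branch),
                                   perl = TRUE, value = TRUE))
  annotated_tree(tree, branch, if (length(tags)) tags else character(0))
}
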