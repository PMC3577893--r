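# Species-boundary estimation: branches on which phenotype partitions
# (culture macromorphology, physiology) out-support or out-change the DNA
# marker are interpreted as within-species diversification, on the
# rationale that such phenotype characters drift faster than the marker
# within a species.  Contracting those branches (and, optionally,
# zero-length branches, which indicate clonality) partitions the leaves
# into species.

#' Configuration for the within-species branch-marking rule
#'
#' @param phenotype_partitions Partition tags treated as phenotype
#'   evidence.
#' @param seq_partition The DNA-marker partition tag compared against.
#' @param use_support Compare partitioned Bremer supports (internal
#'   branches)?
#' @param use_lengths Compare per-partition DELTRAN branch lengths (all
#'   branches)?
#' @param contract_zero_length Also contract branches of total length 0
#'   when deriving the species partition (zero-length terminals indicate
#'   clonal variants)?
#' @return A list of class `"boundary_config"`.
#' @export
boundary_config <- function(phenotype_partitions = c("macromorphology",
                                                     "physiology"),
                            seq_partition = "ITS",
                            use_support = TRUE, use_lengths = TRUE,
                            contract_zero_length = TRUE) {
  if (!use_support && !use_lengths)
    stop("at least one of use_support / use_lengths must be TRUE")
  structure(list(phenotype_partitions = phenotype_partitions,
                 seq_partition = seq_partition,
                 use_support = use_support, use_lengths = use_lengths,
                 contract_zero_length = contract_zero_length),
            class = "boundary_config")
}

#' Mark within-species branches on an annotated tree
#'
#' A branch is marked when some phenotype partition yields *strictly* more
#' Bremer support (if `use_support`) or *strictly* more DELTRAN changes
#' (if `use_lengths`) than the sequence partition on that branch.
#'
#' @param at An `"annotated_tree"` carrying the required per-partition
#'   annotations.
#' @param cfg A [boundary_config()].
#' @return The `"annotated_tree"` with a logical `within_species` column
#'   in its branch table.
#' @export
mark_within_species <- function(at, cfg = boundary_config()) {
  stopifnot(inherits(at, "annotated_tree"), inherits(cfg, "boundary_config"))
  br <- at$branch
  need <- character(0)
  if (cfg$use_lengths)
    need <- c(need, paste0("length_", c(cfg$seq_partition,
                                        cfg$phenotype_partitions)))
  if (cfg$use_support)
    need <- c(need, paste0("bremer_", c(cfg$seq_partition,
                                        cfg$phenotype_partitions)))
  miss <- setdiff(need, names(br))
  if (length(miss))
    stop("missing branch annotations: ", paste(miss, collapse = ", "))
  marked <- rep(FALSE, nrow(br))
  for (p in cfg$phenotype_partitions) {
    if (cfg$use_lengths)
      marked <- marked | (br[[paste0("length_", p)]] >
                          br[[paste0("length_", cfg$seq_partition)]])
    if (cfg$use_support) {
      b_p <- br[[paste0("bremer_", p)]]
      b_s <- br[[paste0("bremer_", cfg$seq_partition)]]
      cmp <- !is.na(b_p) & !is.na(b_s) & b_p > b_s
      marked <- marked | cmp
    }
  }
  at$branch$within_species <- marked
  at
}

#' Derive the species partition from a marked tree
#'
#' Every marked branch (and, if configured, every branch of total length
#' zero) is contracted; two leaves are conspecific exactly when they are
#' connected by a path consisting solely of contracted branches.
#'
#' @param at A marked `"annotated_tree"` (see [mark_within_species()]).
#' @param cfg A [boundary_config()] (only `contract_zero_length` is used).
#' @return Named character vector: leaf -> species label (`"S1"`, ... in
#'   order of each species' lexicographically smallest leaf).
#' @export
species_partition <- function(at, cfg = boundary_config()) {
  stopifnot(inherits(at, "annotated_tree"))
  br <- at$branch
  if (is.null(br$within_species))
    stop("tree has no within_species marks; run mark_within_species() first")
  contract <- br$within_species
  if (cfg$contract_zero_length) {
    if (is.null(br$length_total))
      stop("contract_zero_length requires length_total annotations")
    contract <- contract | br$length_total == 0
  }
  n_tip <- length(at$tree$tip.label)
  n_nodes <- n_tip + at$tree$Nnode
  parent <- seq_len(n_nodes)
  find <- function(i) { while (parent[i] != i) i <- parent[i] <<- parent[parent[i]]; i }
  for (k in which(contract)) {
    a <- find(br$parent[k]); b <- find(br$child[k])
    if (a != b) parent[b] <- a
  }
  comp <- vapply(seq_len(n_tip), find, integer(1))
  leaf <- at$tree$tip.label
  smallest <- vapply(split(leaf, comp), min, character(1))
  labs <- sort(smallest)
  stats::setNames(paste0("S", match(smallest[as.character(comp)], labs)), leaf)
}
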