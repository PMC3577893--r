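# Synthetic barcode datasets with controlled two-level divergence: species
# "centres" differ at disjoint, species-specific alignment positions
# (guaranteeing a minimum between-species p-distance), while members of a
# species mutate a bounded number of positions from a separate pool
# (guaranteeing a maximum within-species p-distance).  The construction
# makes the within/between distance gap certain rather than merely likely,
# which is what threshold-recovery tests require.  Host genera, partial
# species labels, deposition years and faster-within-species phenotype
# characters emulate the metadata structure of public barcode records.

#' Configuration for the synthetic-data generator
#'
#' @param n_species Number of species.
#' @param seqs_per_species Sequences per species (single number or
#'   per-species integer vector).
#' @param seq_length Alignment length in nt.
#' @param d_within_max Maximal within-species p-distance (fraction).
#' @param d_between_min Minimal between-species p-distance (fraction);
#'   must exceed `d_within_max`.
#' @param label_fraction Fraction of sequences carrying a species label in
#'   the emitted reference partition (database records are only partially
#'   annotated).
#' @param n_hosts Number of host genera available.
#' @param host_specificity Probability that a species keeps a single host
#'   genus; otherwise its members are split between a primary and a
#'   secondary genus.
#' @param year_range Integer vector `c(first, last)` of deposition years.
#' @param phenotype List `(n_chars, within_rate_multiplier)`: number of
#'   binary phenotype characters and the factor by which their
#'   within-species change rate exceeds the between-species base rate
#'   (`Inf` for characters changing within species only).
#' @param phenotype_base_rate Per-character probability of a state change
#'   on a species-level branch (the between-species rate).
#' @param seed Integer seed; every random draw flows through it.
#' @return A list of class `"synth_config"`.
#' @export
synth_config <- function(n_species = 6, seqs_per_species = 5,
                         seq_length = 600, d_within_max = 0.01,
                         d_between_min = 0.05, label_fraction = 1,
                         n_hosts = 4, host_specificity = 0.7,
                         year_range = c(1995, 2012),
                         phenotype = list(n_chars = 12,
                                          within_rate_multiplier = 8),
                         phenotype_base_rate = 0.04, seed = 1L) {
  stopifnot(n_species >= 1, all(seqs_per_species >= 1), seq_length > 0,
            d_within_max >= 0, d_between_min > d_within_max,
            label_fraction >= 0, label_fraction <= 1,
            n_hosts >= 1, host_specificity >= 0, host_specificity <= 1)
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a synthetic barcode dataset with known truth
#'
#' See [synth_config()] for the generating model.  The emitted alignment
#' is gap-free by construction (the analyses consume p-distances, for
#' which indels would only remove sites); the within/between distance gap
#' `(d_within_max, d_between_min)` is guaranteed, not merely expected.
#'
#' @param cfg A [synth_config()].
#' @return List with components `msa` (an `"msa"`), `meta` (metadata
#'   data.frame as from [parse_genbank_flatfiles()]), `phenotype` (a
#'   `"char_matrix"` of binary phenotype characters), `labels` (named
#'   vector: the partial reference partition), and `truth` (list:
#'   `species` full true partition, `host` true host-genus map, `config`).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  nsp <- cfg$n_species
  per <- rep(cfg$seqs_per_species, length.out = nsp)
  L <- cfg$seq_length
  m_between <- ceiling(L * cfg$d_between_min / 2)
  k_within <- floor(L * cfg$d_within_max / 2)
  need <- nsp * m_between + max(1L, k_within * 2L)
  if (need > L)
    stop("divergence targets infeasible at sequence length ", L,
         " (need >= ", need, " sites)")
  bases <- c("A", "C", "G", "T")
  root <- sample(bases, L, replace = TRUE)
  # disjoint site blocks: one per species (between-species signal), one
  # shared pool for within-species noise
  blocks <- split(seq_len(nsp * m_between),
                  rep(seq_len(nsp), each = m_between))
  within_pool <- (nsp * m_between + 1L):L
  mutate <- function(seq, sites) {
    for (s in sites) seq[s] <- sample(setdiff(bases, seq[s]), 1L)
    seq
  }
  centres <- lapply(seq_len(nsp), function(i) mutate(root, blocks[[i]]))
  ids <- unlist(lapply(seq_len(nsp), function(i)
    sprintf("SP%02d_%02d", i, seq_len(per[i]))))
  sp_of <- rep(seq_len(nsp), per)
  seqs <- character(length(ids))
  for (j in seq_along(ids)) {
    sites <- if (k_within > 0)
      sample(within_pool, sample.int(k_within + 1L, 1L) - 1L) else integer(0)
    seqs[j] <- paste(mutate(centres[[sp_of[j]]], sites), collapse = "")
  }
  names(seqs) <- ids
  msa <- as_msa(seqs)
  species <- stats::setNames(sprintf("species%02d", sp_of), ids)
  # hosts: primary genus per species; secondary genus for promiscuous ones
  genera <- sprintf("Hostgenus%02d", seq_len(cfg$n_hosts))
  primary <- sample(genera, nsp, replace = TRUE)
  specific <- stats::runif(nsp) < cfg$host_specificity
  host <- character(length(ids))
  for (j in seq_along(ids)) {
    i <- sp_of[j]
    host[j] <- if (specific[i] || stats::runif(1) < 0.5) primary[i]
               else genera[(match(primary[i], genera)) %% cfg$n_hosts + 1L]
  }
  host_species <- ifelse(seq_along(ids) %% 2L == 0L,
                         paste(host, "alpha"), NA_character_)
  meta <- data.frame(accession = ids, organism = "Synthsymbiont sp.",
                     host_genus = host, host_species = host_species,
                     country = NA_character_,
                     deposition_year = sample(
                       seq(cfg$year_range[1L], cfg$year_range[2L]),
                       length(ids), replace = TRUE))
  n_lab <- round(cfg$label_fraction * length(ids))
  labelled <- if (n_lab > 0) sort(sample(ids, n_lab)) else character(0)
  labels <- species[labelled]
  # binary phenotype characters on the same genealogy: species-level
  # changes at the base rate, member-level changes at a multiplied rate
  nch <- cfg$phenotype$n_chars
  mult <- cfg$phenotype$within_rate_multiplier
  p_within <- min(0.5, cfg$phenotype_base_rate *
                       (if (is.finite(mult)) mult else 10))
  p_between <- if (is.finite(mult)) cfg$phenotype_base_rate
               else 0   # infinite multiplier: within-species changes only
  root_ph <- stats::rbinom(nch, 1L, 0.5)
  centre_ph <- lapply(seq_len(nsp), function(i) {
    flip <- stats::runif(nch) < p_between
    ifelse(flip, 1L - root_ph, root_ph)
  })
  ph <- t(vapply(seq_along(ids), function(j) {
    base <- centre_ph[[sp_of[j]]]
    flip <- stats::runif(nch) < p_within
    as.integer(ifelse(flip, 1L - base, base))
  }, integer(nch)))
  rownames(ph) <- ids
  colnames(ph) <- sprintf("phen%03d", seq_len(nch))
  phenotype <- char_matrix(ph, rep("unordered", nch),
                           rep("macromorphology", nch))
  list(msa = msa, meta = meta, phenotype = phenotype, labels = labels,
       truth = list(species = species,
                    host = stats::setNames(host, ids), config = cfg))
}

#' Hand-checkable worked-example fixtures
#'
#' Emits the small instances used throughout the documentation and tests:
#' a 3-element chain distance matrix, tiny character matrices with known
#' parsimony behaviour, a 9-leaf annotated tree whose marked and
#' zero-length branches yield six species under the boundary rule
#' (a reconstruction of the study layout from its verbal description, not
#' measured data), and a 6-sequence/3-year coverage table.
#'
#' @return Named list of fixtures: `chain_distmat`, `four_taxon_matrix`,
#'   `conflict_matrix` (two partitions supporting different clades),
#'   `nine_host_tree` (an `"annotated_tree"`), `nine_host_species`
#'   (its expected six-species partition), `coverage_partition`,
#'   `coverage_meta`.
#' @export
simulate_worked_examples <- function() {
  chain <- matrix(c(0, 0.01, 0.05,
                    0.01, 0, 0.01,
                    0.05, 0.01, 0), 3, 3,
                  dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  four <- char_matrix(matrix(c(0L, 0L, 1L, 1L,
                               0L, 1L, 0L, 1L), 4, 2,
                             dimnames = list(c("t1", "t2", "t3", "t4"), NULL)),
                      c("unordered", "unordered"), c("ITS", "ITS"))
  # six taxa; partition "one" supports ((a,b),(c,d)...)-style clade AB,
  # partition "two" conflicts by linking a with c
  conf_states <- cbind(matrix(c(0L, 0L, 1L, 1L, 1L, 1L), 6, 4),  # one: supports {a,b}
                       matrix(c(0L, 1L, 0L, 1L, 1L, 1L), 6, 2))  # two: links {a,c}
  rownames(conf_states) <- letters[1:6]
  conflict <- char_matrix(conf_states, rep("unordered", 6),
                          c(rep("one", 4), rep("two", 2)))
  nine <- nine_host_example_tree()
  species <- c(A = "S1", A1 = "S1", F = "S1", B1 = "S2", B2 = "S3",
               D2 = "S3", C = "S4", D1 = "S5", E = "S6")
  cov_part <- stats::setNames(c("C1", "C1", "C1", "C2", "C2", "C3"),
                              sprintf("q%02d", 1:6))
  cov_meta <- data.frame(
    accession = sprintf("q%02d", 1:6),
    organism = "Synthsymbiont sp.",
    host_genus = c("G1", "G1", NA, "G2", NA, NA),
    host_species = c("G1 alpha", NA, NA, NA, NA, NA),
    country = NA_character_,
    deposition_year = c(2001, 2001, 2002, 2002, 2003, 2003))
  list(chain_distmat = as_distmat(chain), four_taxon_matrix = four,
       conflict_matrix = conflict, nine_host_tree = nine,
       nine_host_species = species[sort(names(species))],
       coverage_partition = cov_part, coverage_meta = cov_meta)
}

#' Synthetic coded culture-phenotype matrix
#'
#' A *synthetic stand-in* for coded culture-phenotype data of nine fungal
#' isolates: 10 macromorphological characters per cultivation medium on
#' three media (30 characters, binary or ordered multistate) and 8 binary
#' physiological characters.  The construction fixes the number of
#' parsimony-informative characters at 16 (macromorphology) and 4
#' (physiology); informative characters follow the six-species grouping
#' of [simulate_worked_examples()], the rest are constant, autapomorphic
#' or partially missing.  These are constructed values, not measurements.
#' The same matrix ships as a CSV at
#' `system.file("extdata", "synthetic_coded_phenotype.csv", package =
#' "otudelim")` in the layout read by [read_char_matrix()].
#'
#' @return A `"char_matrix"` with partitions `macromorphology` and
#'   `physiology`.
#' @export
synthetic_coded_phenotype <- function() {
  taxa <- c("A", "A1", "F", "B2", "D2", "B1", "D1", "C", "E")
  grp <- function(members, state = 1L, base = 0L) {
    v <- rep(base, 9L); v[match(members, taxa)] <- state; v
  }
  aaf <- c("A", "A1", "F"); bd <- c("B2", "D2")
  # 16 informative macromorphological characters: binary or ordered
  # contrasts between the species groups (each state in >= 2 taxa)
  informative_macro <- cbind(
    grp(aaf), grp(bd), grp(c(aaf, bd)), grp(c("B1", "D1", "C", "E")),
    grp(aaf, 2L) + grp(bd, 1L),              # ordered 0/1/2
    grp(c("C", "E")), grp(c("B1", "D1")), grp(c(aaf, "C", "E")),
    grp(aaf), grp(bd), grp(c("B1", "C")), grp(c("D1", "E")),
    grp(aaf, 2L), grp(c(aaf, bd), 1L) + grp(aaf, 1L),  # ordered
    grp(c("B2", "D2", "B1", "D1")), grp(c("A", "A1"))
  )
  # 14 uninformative: constants, autapomorphies, missing-heavy columns
  uninformative_macro <- cbind(
    rep(0L, 9L), rep(1L, 9L), rep(0L, 9L), rep(2L, 9L),
    grp("E"), grp("C"), grp("F"), grp("B1"), grp("D1"), grp("A"),
    grp("B2", 2L), grp("D2"), rep(0L, 9L), grp("E", 3L)
  )
  macro <- cbind(informative_macro, uninformative_macro)
  macro[1L, 21L] <- NA  # a few unscored cells, as real coded tables have
  macro[5L, 24L] <- NA
  # physiology: 4 informative + 4 uninformative binary characters
  physio <- cbind(
    grp(aaf), grp(c(aaf, bd)), grp(c("B1", "D1")), grp(c("C", "E", "F", "A", "A1")),
    rep(1L, 9L), rep(1L, 9L), grp("E"), grp("D2")
  )
  states <- cbind(macro, physio)
  rownames(states) <- taxa
  colnames(states) <- c(sprintf("mm_%s%02d", rep(c("pda", "mmn", "ma"), each = 10),
                                rep(1:10, 3)),
                        sprintf("phys%02d", 1:8))
  type <- c(ifelse(apply(macro, 2, max, na.rm = TRUE) > 1L, "ordered",
                   "unordered"),
            rep("unordered", 8))
  char_matrix(states, type,
              c(rep("macromorphology", 30), rep("physiology", 8)))
}

# Nine-culture annotated tree reconstructed from the study layout: leaves
# are host/mound indices; zero-length terminals A, A1, B2; within-species
# marks on the (A,A1) stem, the root-adjacent branch above the
# Odontotermes-symbiont clade, and the terminals F and D2.  Synthetic
# reconstruction: branch statistics are chosen to realise the described
# marking pattern, they are not measured values.
nine_host_example_tree <- function() {
  txt <- "((((A,A1)n1,F)n2,(C,E)n3)n4,((B2,D2)n5,(B1,D1)n6)n7)root;"
  tree <- ape::read.tree(text = txt)
  n_tip <- length(tree$tip.label)
  lab_of <- function(nd) if (nd <= n_tip) tree$tip.label[nd]
                         else tree$node.label[nd - n_tip]
  br <- data.frame(parent = tree$edge[, 1L], child = tree$edge[, 2L])
  br$child_label <- ifelse(br$child <= n_tip, tree$tip.label[br$child], "")
  key <- vapply(br$child, lab_of, character(1))
  ann <- list(
    #          ITS macro physio  bremer: ITS macro physio  boot
    A    = c(0, 0, 0, NA, NA, NA, NA),
    A1   = c(0, 0, 0, NA, NA, NA, NA),
    B2   = c(0, 0, 0, NA, NA, NA, NA),
    F    = c(1, 2, 2, NA, NA, NA, NA),
    D2   = c(0, 1, 0, NA, NA, NA, NA),
    B1   = c(3, 1, 0, NA, NA, NA, NA),
    D1   = c(4, 1, 1, NA, NA, NA, NA),
    C    = c(3, 1, 0, NA, NA, NA, NA),
    E    = c(4, 0, 1, NA, NA, NA, NA),
    n1   = c(1, 0, 0, 1, 2, 2, 64),   # (A,A1) stem: phenotype-supported
    n2   = c(2, 1, 0, 2, 1, 0, 71),
    n3   = c(3, 0, 0, 2, 0, 0, 58),
    n4   = c(2, 1, 0, 1, 2, 0, 66),   # root-adjacent branch: marked
    n5   = c(4, 1, 0, 3, 1, 0, 88),
    n6   = c(5, 0, 1, 4, -1, 1, 92),  # backbone: macromorphology conflicts
    n7   = c(6, 1, 0, 5, -1, 0, 85))
  m <- do.call(rbind, ann[key])
  br$length_ITS <- m[, 1L]
  br$length_macromorphology <- m[, 2L]
  br$length_physiology <- m[, 3L]
  br$length_total <- rowSums(m[, 1:3])
  br$bremer_ITS <- m[, 4L]
  br$bremer_macromorphology <- m[, 5L]
  br$bremer_physiology <- m[, 6L]
  br$bremer_total <- rowSums(m[, 4:6])
  br$bootstrap <- m[, 7L]
  tree$edge.length <- br$length_total
  tree$node.label <- NULL
  annotated_tree(tree, br,
                 c("ITS", "macromorphology", "physiology"))
}
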