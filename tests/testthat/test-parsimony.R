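test_that("parsimony-informative counting follows the two-states-twice rule", {
  st <- matrix(c(0L, 0L, 0L, 0L, 0L, 0L,     # constant
                 0L, 0L, 0L, 0L, 0L, 1L,     # autapomorphy
                 0L, 0L, 1L, 1L, NA, NA,     # informative despite missing
                 0L, 1L, 0L, 1L, 0L, 1L),    # informative
               nrow = 6,
               dimnames = list(paste0("t", 1:6), NULL))
  m <- char_matrix(st, rep("unordered", 4), c("p1", "p1", "p2", "p2"))
  expect_identical(parsimony_informative_count(m), 2L)
  expect_identical(parsimony_informative_count(m, "p1"), 0L)
  expect_identical(parsimony_informative_count(m, "p2"), 2L)
  four <- simulate_worked_examples()$four_taxon_matrix
  expect_identical(parsimony_informative_count(four), 2L)
})

test_that("tree scoring: identity, Fitch and linear ordered costs", {
  taxa <- paste0("t", 1:4)
  tr <- ape::read.tree(text = "((t1,t2),(t3,t4));")
  const <- char_matrix(matrix(1L, 4, 3, dimnames = list(taxa, NULL)),
                       rep("unordered", 3), rep("p", 3))
  expect_equal(sum(score_tree(tr, const)), 0)
  # A,A,C,C on ((1,2),(3,4)) needs exactly one change
  aacc <- char_matrix(matrix(c(0L, 0L, 1L, 1L), 4, 1,
                             dimnames = list(taxa, NULL)),
                      "unordered", "p")
  expect_equal(sum(score_tree(tr, aacc)), 1)
  # ordered 0 vs 2 costs two steps where unordered costs one
  st <- matrix(c(0L, 0L, 2L, 2L), 4, 1, dimnames = list(taxa, NULL))
  expect_equal(sum(score_tree(tr, char_matrix(st, "ordered", "p"))), 2)
  expect_equal(sum(score_tree(tr, char_matrix(st, "unordered", "p"))), 1)
  # missing data is a free wildcard
  stm <- matrix(c(0L, NA, 1L, 1L), 4, 1, dimnames = list(taxa, NULL))
  expect_equal(sum(score_tree(tr, char_matrix(stm, "unordered", "p"))), 1)
  expect_error(score_tree(ape::read.tree(text = "((a,b),(c,d));"), aacc),
               "differ")
})

test_that("score is never below the per-character state-count bound", {
  set.seed(141)
  for (i in 1:5) {
    m <- random_char_matrix(6, 8, states = 0:2)
    lower <- sum(apply(m$states, 2, function(col)
      max(0L, length(unique(col[!is.na(col)])) - 1L)))
    tr <- ape::rtree(6, tip.label = rownames(m$states))
    expect_gte(sum(score_tree(tr, m)), lower)
  }
})

test_that("branch and bound equals the 4-taxon exhaustive search", {
  four <- simulate_worked_examples()$four_taxon_matrix
  res <- bnb_search(four)
  # chars [0011] and [0101]: best pairings score 3; ((t1,t4),(t2,t3)) scores 4
  expect_equal(res$score, 3)
  expect_length(res$trees, 2L)
  scores <- vapply(res$trees, function(tr) sum(score_tree(tr, four)),
                   numeric(1))
  expect_equal(scores, rep(3, 2))
})

test_that("branch and bound matches the phangorn exhaustive oracle", {
  set.seed(151)
  for (i in 1:8) {
    n <- sample(5:6, 1)
    m <- random_char_matrix(n, 8)
    expect_equal(bnb_search(m)$score, phangorn_min_score(m))
  }
})

test_that("clean hierarchical signal recovers the generating topology", {
  taxa <- paste0("t", 1:6)
  # characters follow nested clades ((t1,t2),t3) and ((t4,t5),t6)
  st <- cbind(c(1L, 1L, 0L, 0L, 0L, 0L), c(1L, 1L, 0L, 0L, 0L, 0L),
              c(1L, 1L, 1L, 0L, 0L, 0L), c(1L, 1L, 1L, 0L, 0L, 0L),
              c(0L, 0L, 0L, 1L, 1L, 0L), c(0L, 0L, 0L, 1L, 1L, 0L))
  rownames(st) <- taxa
  m <- char_matrix(st, rep("unordered", 6), rep("p", 6))
  res <- bnb_search(m)
  expect_length(res$trees, 1L)
  truth <- ape::read.tree(text = "(((t1,t2),t3),((t4,t5),t6));")
  expect_equal(ape::dist.topo(ape::unroot(res$trees[[1]]),
                              ape::unroot(truth)), 0,
               ignore_attr = TRUE)
  expect_error(bnb_search(random_char_matrix(14, 4)), "refused")
})

test_that("DELTRAN lengths conserve the parsimony score per partition", {
  set.seed(161)
  for (i in 1:5) {
    m <- random_char_matrix(6, 10, states = 0:2,
                            type = rep(c("unordered", "ordered"), 5),
                            partition = rep(c("p1", "p2"), each = 5))
    tr <- bnb_search(m)$trees[[1]]
    rtr <- ape::root(tr, outgroup = "t01", resolve.root = TRUE)
    dl <- deltran_lengths(rtr, m)
    sc <- score_tree(tr, m)
    expect_equal(sum(dl$length_p1), unname(sc["p1"]))
    expect_equal(sum(dl$length_p2), unname(sc["p2"]))
    expect_equal(sum(dl$length_total), attr(sc, "total"))
  }
})

test_that("DELTRAN zero-length terminals for identical sisters; tip changes", {
  taxa <- c("a", "b", "c", "d")
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  rtr <- ape::root(tr, outgroup = "a", resolve.root = TRUE)
  rtr <- ape::collapse.singles(rtr)
  # a and b identical: their terminal branches carry no changes
  m <- char_matrix(matrix(c(0L, 0L, 1L, 1L,
                            0L, 0L, 1L, 0L), 4, 2,
                          dimnames = list(taxa, NULL)),
                   rep("unordered", 2), rep("p", 2))
  dl <- deltran_lengths(rtr, m)
  expect_equal(dl$length_total[dl$child_label == "a"], 0)
  expect_equal(dl$length_total[dl$child_label == "b"], 0)
  # single character differing in one tip only: that terminal gets the step
  m1 <- char_matrix(matrix(c(0L, 0L, 0L, 1L), 4, 1,
                           dimnames = list(taxa, NULL)),
                    "unordered", "p")
  dl1 <- deltran_lengths(rtr, m1)
  expect_equal(dl1$length_total[dl1$child_label == "d"], 1)
  expect_equal(sum(dl1$length_total), 1)
})

test_that("Bremer support: additivity, sign of conflict, zero support", {
  ex <- simulate_worked_examples()
  mp <- bnb_search(ex$conflict_matrix)
  br <- bremer(mp$trees[[1]], ex$conflict_matrix)
  expect_true(all(abs(rowSums(br[, c("bremer_one", "bremer_two")]) -
                      br$bremer_total) < 1e-9))
  # partition "one" supports the {a,b} clade, partition "two" conflicts
  ab <- br[br$split == "c|d|e|f", ]
  expect_gt(ab$bremer_one, 0)
  expect_lt(ab$bremer_two, 0)
  expect_gt(ab$bremer_total, 0)
  # unsupported clades decay at no cost
  expect_true(any(br$bremer_total == 0))
})

test_that("bootstrap is seed-reproducible; single replicate is 0 or 100", {
  m <- simulate_worked_examples()$conflict_matrix
  b1 <- mp_bootstrap(m, replicates = 10, seed = 5)
  b2 <- mp_bootstrap(m, replicates = 10, seed = 5)
  expect_identical(b1, b2)
  one <- mp_bootstrap(m, replicates = 1, seed = 6)
  expect_true(all(one$bootstrap %in% c(0, 100)))
})

test_that("perfectly congruent characters bootstrap to high support", {
  taxa <- paste0("t", 1:6)
  st <- do.call(cbind, rep(list(c(1L, 1L, 0L, 0L, 0L, 0L),
                                c(0L, 0L, 0L, 0L, 1L, 1L),
                                c(1L, 1L, 1L, 0L, 0L, 0L)), 6))
  rownames(st) <- taxa
  m <- char_matrix(st, rep("unordered", 18), rep("p", 18))
  bs <- mp_bootstrap(m, replicates = 50, seed = 7)
  expect_true(all(bs$bootstrap >= 90))
})

test_that("midpoint rooting: arithmetic, minimax property, degenerate input", {
  mr <- midpoint_root(ape::read.tree(text = "(A:3,B:1);"))
  expect_equal(sort(mr$edge.length), c(2, 2))
  set.seed(171)
  for (i in 1:5) {
    tr <- ape::rtree(7)
    mr <- midpoint_root(tr)
    D <- ape::dist.nodes(mr)
    root <- length(mr$tip.label) + 1L
    half <- max(ape::dist.nodes(tr)[1:7, 1:7]) / 2
    expect_equal(max(D[root, 1:7]), half, tolerance = 1e-9)
  }
  z <- ape::read.tree(text = "((A:0,B:0):0,C:0);")
  expect_warning(midpoint_root(z), "zero")
})
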