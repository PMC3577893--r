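test_that("Smith-Waterman similarity: self-identity and symmetry", {
  set.seed(11)
  s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  expect_equal(sw_similarity(c(x = s), c(x = s))$percent_similarity, 100)
  s2 <- paste(sample(c("A", "C", "G", "T"), 280, TRUE), collapse = "")
  expect_equal(sw_similarity(c(a = s), c(b = s2))$percent_similarity,
               sw_similarity(c(b = s2), c(a = s))$percent_similarity)
  expect_error(sw_similarity(c(x = "----"), c(y = s)), "empty")
})

test_that("two 500-nt sequences differing at two positions align at 99.6%", {
  set.seed(21)
  s <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  s2 <- s
  swap <- function(ch) c(A = "C", C = "G", G = "T", T = "A")[[ch]]
  substr(s2, 120, 120) <- swap(substr(s, 120, 120))
  substr(s2, 340, 340) <- swap(substr(s, 340, 340))
  expect_equal(sw_similarity(c(a = s), c(b = s2))$percent_similarity, 99.6)
})

test_that("alignment scores match an independent Gotoh DP", {
  set.seed(31)
  for (i in 1:5) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(60:90, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(60:90, 1), TRUE),
               collapse = "")
    expect_equal(sw_similarity(c(a = a), c(b = b))$score,
                 sw_score_oracle(a, b))
  }
})

test_that("p-distance matches a column-count oracle under pairwise deletion", {
  # 100 columns, 3 mismatches among shared sites, 10 columns gapped in one
  a <- paste(rep("A", 100), collapse = "")
  bv <- rep("A", 100)
  bv[c(5, 50, 95)] <- "C"
  bv[20:29] <- "-"
  b <- paste(bv, collapse = "")
  msa <- make_msa(x = a, y = b, z = a)
  d <- p_distance_matrix(msa)
  expect_equal(d["x", "y"], 3 / 90)
  expect_equal(d["x", "y"], p_distance_oracle(a, b))
  expect_equal(d["x", "z"], 0)
})

test_that("p-distance is symmetric, zero-diagonal and row-order invariant", {
  set.seed(41)
  seqs <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T", "-"), 80, TRUE,
                 prob = c(rep(0.22, 4), 0.12)), collapse = ""), "")
  names(seqs) <- paste0("s", 1:5)
  d <- p_distance_matrix(as_msa(seqs))
  expect_equal(unclass(d), t(unclass(d)), ignore_attr = TRUE)
  expect_true(all(diag(d) == 0))
  d2 <- p_distance_matrix(as_msa(rev(seqs)))
  expect_equal(d2[names(seqs), names(seqs)], d[names(seqs), names(seqs)],
               ignore_attr = TRUE)
})

test_that("columns gapped in both members do not affect the pair's distance", {
  a <- "ACGTACGT--"
  b <- "ACGTACGA--"
  c2 <- "ACGTACGAGG"
  d1 <- p_distance_matrix(make_msa(a = a, b = b, c = c2))
  d2 <- p_distance_matrix(make_msa(a = substr(a, 1, 8), b = substr(b, 1, 8),
                                   c = substr(c2, 1, 8)))
  expect_equal(d1["a", "b"], d2["a", "b"])
})

test_that("a pair with no shared sites is an error naming the pair", {
  msa <- make_msa(p = "AAAA----", q = "----TTTT", r = "AAAATTTT")
  expect_error(p_distance_matrix(msa), "p.*q|q.*p")
})

test_that("overlap filter keeps targets and applies the site threshold", {
  msa <- make_msa(
    T1 = paste(rep("A", 400), collapse = ""),
    T2 = paste(rep("C", 400), collapse = ""),
    near = paste(c(rep("A", 310), rep("-", 90)), collapse = ""),
    far = paste(c(rep("A", 250), rep("-", 150)), collapse = ""))
  out <- overlap_filter(msa, c("T1", "T2"), 300)
  expect_identical(names(out), c("T1", "T2", "near"))  # 250 shared sites dropped
  # threshold above alignment length: only targets remain
  out2 <- overlap_filter(msa, c("T1", "T2"), 401)
  expect_identical(names(out2), c("T1", "T2"))
  expect_error(overlap_filter(msa, "T1", 0), "positive")
  expect_error(overlap_filter(msa, "missing", 10), "absent")
})

test_that("retained set shrinks monotonically with the overlap threshold", {
  set.seed(51)
  seqs <- vapply(1:12, function(i) {
    len <- sample(100:400, 1)
    paste(c(rep("A", len), rep("-", 400 - len)), collapse = "")
  }, "")
  names(seqs) <- c("T1", paste0("g", 2:12))
  tab <- overlap_table(as_msa(seqs), "T1", seq(0, 450, by = 25))
  expect_true(all(diff(tab$retained) <= 0))
  # informative-only counting never retains more than plain counting
  tab2 <- overlap_table(as_msa(seqs), "T1", seq(0, 450, by = 25),
                        informative_only = TRUE)
  expect_true(all(tab2$retained <= tab$retained))
})

test_that("representative screening reports per-host similarity ranges", {
  set.seed(61)
  rep_seq <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  mutate1 <- function(s, at) {
    v <- strsplit(s, "")[[1]]
    v[at] <- setdiff(c("A", "C", "G", "T"), v[at])[1]
    paste(v, collapse = "")
  }
  groups <- list(
    H1 = c(m1 = rep_seq, m2 = rep_seq),
    H2 = c(m3 = mutate1(rep_seq, 10), m4 = mutate1(rep_seq, c(10, 200))))
  reps <- list(H1 = rep_seq, H2 = rep_seq)
  res <- screen_representatives(groups, reps,
                                categories = c(m1 = "culture", m2 = "nodule",
                                               m3 = "gut-clone", m4 = "gut-clone"))
  expect_equal(res$percent_similarity[res$host == "H1"], c(100, 100))
  s <- attr(res, "summary")
  expect_equal(s$by_host$min[s$by_host$group == "H1"], 100)
  expect_lt(s$by_host$min[s$by_host$group == "H2"], 100)
  expect_true(all(c("culture", "gut-clone", "nodule") %in% s$by_category$group))
  expect_error(screen_representatives(groups, reps["H1"]),
               "without representative.*H2")
  expect_warning(screen_representatives(list(H1 = character(0)),
                                        list(H1 = rep_seq)),
                 "no member")
})

test_that("distance-matrix TSV round trips", {
  d <- random_distmat(6)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_distmat(d, f)
  expect_equal(unclass(read_distmat(f)), unclass(d), tolerance = 1e-12,
               ignore_attr = TRUE)
})
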