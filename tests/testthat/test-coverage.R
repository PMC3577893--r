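test_that("the six-sequence three-year table matches manual tabulation", {
  ex <- simulate_worked_examples()
  cs <- coverage_series(ex$coverage_partition, ex$coverage_meta)
  expect_equal(cs$year, c(2001, 2002, 2003))
  expect_equal(cs$cumulative_clusters, c(1L, 2L, 3L))
  expect_equal(cs$mean_sequences_per_cluster, c(2, 2, 2))
  # 2001: C1 = {q01 (G1, G1 alpha), q02 (G1)}
  # 2002: + q03 (C1, no host), q04 (C2, G2)
  # 2003: + q05 (C2, no host), q06 (C3, no host)
  expect_equal(cs$mean_host_genera_per_cluster, c(1, 1, 2 / 3))
  expect_equal(cs$mean_host_species_per_cluster, c(1, 1 / 2, 1 / 3))
  expect_equal(cs$mean_clusters_per_host_genus, c(1, 1, 1))
  expect_equal(cs$mean_clusters_per_host_species, c(1, 1, 1))
})

test_that("clusters with unknown hosts pull the host mean below one", {
  p <- c(s1 = "C1", s2 = "C2")
  meta <- data.frame(accession = c("s1", "s2"),
                     host_genus = c("G1", NA), host_species = NA,
                     deposition_year = c(2000, 2000))
  cs <- coverage_series(p, meta)
  expect_equal(cs$mean_host_genera_per_cluster, 0.5)
})

test_that("all sequences in one year jump the series from zero to k", {
  p <- stats::setNames(c("C1", "C2", "C2"), paste0("s", 1:3))
  meta <- data.frame(accession = paste0("s", 1:3), host_genus = NA,
                     host_species = NA, deposition_year = 2005)
  cs <- coverage_series(p, meta, years = c(2004, 2005, 2006))
  expect_equal(cs$cumulative_clusters, c(0L, 2L, 2L))
})

test_that("cumulative clusters never decrease and sequences are conserved", {
  set.seed(191)
  d <- random_distmat(20)
  meta <- data.frame(accession = rownames(d),
                     host_genus = sample(c("G1", "G2", NA), 20, TRUE),
                     host_species = NA,
                     deposition_year = sample(2000:2010, 20, TRUE))
  p <- f_linkage_cluster(d, 0.08, 0.5)
  cs <- coverage_series(p, meta)
  expect_true(all(diff(cs$cumulative_clusters) >= 0))
  # conservation: sequences <= y = clusters x mean sequences per cluster
  nseq <- vapply(cs$year, function(y)
    sum(meta$deposition_year <= y), numeric(1))
  expect_equal(cs$cumulative_clusters * cs$mean_sequences_per_cluster, nseq)
})

test_that("metadata contract: missing rows error, missing years warn", {
  p <- c(s1 = "C1", s2 = "C1")
  expect_error(coverage_series(p, data.frame(accession = "s1",
                                             host_genus = NA,
                                             host_species = NA,
                                             deposition_year = 2000)),
               "missing for")
  meta <- data.frame(accession = c("s1", "s2"), host_genus = NA,
                     host_species = NA, deposition_year = c(2000, NA))
  expect_warning(cs <- coverage_series(p, meta), "without deposition year")
  expect_equal(cs$cumulative_clusters, 1L)
  expect_error(suppressWarnings(coverage_series(p, meta, years = numeric(0))),
               "empty")
})

test_that("final-year cluster counts fall as the threshold grows (F 0 and 1)", {
  set.seed(201)
  d <- random_distmat(15)
  meta <- data.frame(accession = rownames(d), host_genus = NA,
                     host_species = NA,
                     deposition_year = sample(2000:2005, 15, TRUE))
  for (F in c(0, 1)) {
    grid <- data.frame(F = F, t = c(0.02, 0.05, 0.1, 0.15))
    cov <- sensitivity_grid(d, meta, grid)
    final <- cov[cov$year == max(cov$year), ]
    expect_true(all(diff(final$cumulative_clusters[order(final$t)]) <= 0))
  }
})

test_that("duplicated parameter rows give identical series; recluster runs", {
  set.seed(211)
  d <- random_distmat(10)
  meta <- data.frame(accession = rownames(d), host_genus = "G1",
                     host_species = NA,
                     deposition_year = sample(2000:2003, 10, TRUE))
  cov <- sensitivity_grid(d, meta, data.frame(F = c(0.5, 0.5), t = c(0.1, 0.1)))
  half <- nrow(cov) / 2
  expect_equal(cov[seq_len(half), -(1:2)],
               cov[half + seq_len(half), -(1:2)], ignore_attr = TRUE)
  cov2 <- sensitivity_grid(d, meta, data.frame(F = 0.5, t = 0.1),
                           recluster_per_year = TRUE)
  expect_true(all(diff(cov2$cumulative_clusters) >= -1e9))  # runs and tabulates
  expect_equal(sort(unique(cov2$year)), sort(unique(meta$deposition_year)))
})

test_that("saturating designs flatten after the last new species year", {
  # all species present by 2002; later years only resample known clusters
  p <- stats::setNames(c("C1", "C2", "C1", "C2", "C1"), paste0("s", 1:5))
  meta <- data.frame(accession = paste0("s", 1:5), host_genus = NA,
                     host_species = NA,
                     deposition_year = c(2001, 2002, 2003, 2004, 2005))
  cs <- coverage_series(p, meta)
  expect_equal(cs$cumulative_clusters, c(1L, 2L, 2L, 2L, 2L))
})

test_that("the default sensitivity grid crosses shapes with 1-5% thresholds", {
  g <- default_sensitivity_params()
  expect_equal(nrow(g), 15L)
  expect_setequal(unique(g$F), c(0, 0.5, 1))
  expect_setequal(unique(g$t), (1:5) / 100)
  g2 <- default_sensitivity_params(data.frame(F = 0.5, t = 0.022))
  expect_equal(nrow(g2), 16L)
  expect_true(any(g2$optimal))
})
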