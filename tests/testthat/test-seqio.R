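test_that("FASTA reading preserves order, ids and normalizes case", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">seqB some description", "acgt", "ACGT",
               ">seqA", "TTT-?"), f)
  s <- read_fasta(f)
  expect_identical(names(s), c("seqB", "seqA"))
  expect_identical(unname(s[1]), "ACGTACGT")   # wrapped lines joined, upper-cased
  expect_identical(unname(s[2]), "TTT-?")
})

test_that("FASTA errors name the offending record", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">A", "ACGT", ">A", "ACGT"), f)
  expect_error(read_fasta(f), "duplicate.*A")
  writeLines(c(">ok", "ACGT", ">bad", "ACXZGT"), f)
  expect_error(read_fasta(f), "illegal.*bad")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty")
})

test_that("FASTA write/read round trip is the identity", {
  seqs <- c(r1 = "ACGT-?ACGT", r2 = "TTTTTTTTTT", r3 = "ACGTNRYSWK")
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, f, width = 4)
  back <- read_fasta(f)
  expect_identical(unclass(back)[seq_along(seqs)],
                   seqs, ignore_attr = TRUE)
  expect_identical(names(back), names(seqs))
})

test_that("GenBank flat files yield metadata without inventing hosts", {
  f <- withr::local_tempfile(fileext = ".gb")
  writeLines(genbank_fixture_lines(), f)
  meta <- parse_genbank_flatfiles(f)
  expect_identical(meta$accession, c("TST00001", "TST00002", "TST00003"))
  expect_identical(meta$host_genus, c("Macrotermes", "Odontotermes", NA))
  expect_identical(meta$host_species,
                   c("Macrotermes michaelseni", NA, NA))
  expect_identical(meta$country, c("Kenya", NA, NA))
  expect_identical(meta$deposition_year, c(2012, 2008, 2005))
  # host_species implies host_genus everywhere
  expect_true(all(is.na(meta$host_species) | !is.na(meta$host_genus)))
})

test_that("incomplete-year recode halves into the previous year", {
  f <- withr::local_tempfile(fileext = ".gb")
  writeLines(genbank_fixture_lines(), f)
  meta <- parse_genbank_flatfiles(f, incomplete_year = 2012)
  expect_identical(meta$deposition_year, c(2011.5, 2008, 2005))
})

test_that("LOCUS line without a date leaves the year missing with warning", {
  f <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       NODATE                 500 bp    DNA     linear   PLN",
               "  ORGANISM  Synthsymbiont demo",
               "//"), f)
  expect_warning(meta <- parse_genbank_flatfiles(f), "no date")
  expect_true(is.na(meta$deposition_year))
})

test_that("character-matrix CSV round trips with types and partitions", {
  m <- synthetic_coded_phenotype()
  f <- withr::local_tempfile(fileext = ".csv")
  write_char_matrix(m, f)
  back <- read_char_matrix(f)
  expect_identical(back$states, m$states)
  expect_identical(back$type, m$type)
  expect_identical(back$partition, m$partition)
})

test_that("character-matrix reader rejects malformed tables", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("taxon,c1,c2", "!type,unordered,unordered",
               "!partition,p,p", "t1,0,1", "t2,0,Z"), f)
  expect_error(read_char_matrix(f), "state symbols")
  writeLines(c("taxon,c1,c2", "t1,0,1", "t2,0,1"), f)
  expect_error(read_char_matrix(f), "!type")
})

test_that("an all-missing matrix is accepted with zero informative characters", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("taxon,c1,c2", "!type,unordered,unordered",
               "!partition,p,p", "t1,?,?", "t2,?,?", "t3,?,?"), f)
  m <- read_char_matrix(f)
  expect_identical(parsimony_informative_count(m), 0L)
})

test_that("partition TSV round trips", {
  p <- c(a1 = "C1", a2 = "C1", b1 = "C2")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_partition(p, f)
  expect_identical(read_partition(f), p)
})

test_that("plain Newick round-trips byte-identically; labels survive", {
  f <- withr::local_tempfile()
  writeLines("((A,B),C);", f)
  g <- withr::local_tempfile()
  write_newick(read_newick(f), g)
  expect_identical(readLines(g), "((A,B),C);")
  writeLines("((A:1,B:2)95:0.5,C:3);", f)
  write_newick(read_newick(f), g)
  expect_identical(readLines(g), "((A:1,B:2)95:0.5,C:3);")
})

test_that("annotated Newick round-trips a 9-leaf annotated tree", {
  at <- mark_within_species(simulate_worked_examples()$nine_host_tree)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(at, f)
  back <- read_newick(f)
  expect_s3_class(back, "annotated_tree")
  expect_true(ape::all.equal.phylo(back$tree, at$tree,
                                   use.edge.length = FALSE))
  # node numbering may legitimately differ after re-reading; key each
  # branch by the leaf set of the clade below it
  clade_key <- function(x) {
    n_tip <- length(x$tree$tip.label)
    below <- function(nd) {
      kids <- x$tree$edge[x$tree$edge[, 1] == nd, 2]
      if (!length(kids)) return(x$tree$tip.label[nd])
      sort(unlist(lapply(kids, below)))
    }
    keys <- vapply(x$branch$child, function(ch)
      paste(below(ch), collapse = "|"), character(1))
    out <- x$branch[order(keys), c("length_ITS", "length_macromorphology",
                                   "length_physiology", "length_total",
                                   "bremer_total", "within_species")]
    rownames(out) <- sort(keys)
    out
  }
  expect_equal(clade_key(back), clade_key(at), ignore_attr = TRUE)
})

test_that("unbalanced Newick is a parse error", {
  f <- withr::local_tempfile()
  writeLines("((A,B,C);", f)
  expect_error(read_newick(f), "unbalanced")
})
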