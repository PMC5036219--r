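# Alignment container, I/O, filtering, redundancy reduction and
# per-column profiling.

test_that("aligned sequence sets enforce rectangularity and identifiers", {
  a <- aligned_seqs(c("a", "b"), c("ACD-E", "ACDFE"))
  expect_equal(a$n_columns, 5L)
  expect_error(aligned_seqs(c("a", "b"), c("ACDEF", "ACDE")),
               "row 2 \\('b'\\)")
  expect_error(aligned_seqs(c("a", "a"), c("ACD", "ACD")), "duplicated")
  # '.' gaps normalised, residues upper-cased
  expect_equal(aligned_seqs("x", "ac.e")$seqs, "AC-E")
})

test_that("FASTA read/write round-trips a synthetic 212x420 alignment", {
  g <- make_msa(n_seq = 212, substitution_rate = 0.15, seed = 41)
  tmp <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(g$alignment, tmp)
  expect_identical(read_alignment(tmp), g$alignment)
})

test_that("Stockholm alignments are read", {
  tmp <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", "s1 ACD-E", "s2 ACDFE", "//"), tmp)
  a <- read_alignment(tmp, "stockholm")
  expect_equal(a$ids, c("s1", "s2"))
  expect_equal(a$n_columns, 5L)
})

test_that("ragged or empty FASTA input is rejected", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">r1", "ACDEF", ">r2", "ACDE"), tmp)
  expect_error(read_alignment(tmp), "r2")
  tmp2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), tmp2)
  expect_error(read_alignment(tmp2))
})

test_that("incomplete-sequence filtering keeps covered rows in order", {
  a <- aligned_seqs(c("full", "half"), c("ACDEFGHIKL", "ACDEF-----"))
  f <- filter_incomplete(a, 0.9)
  expect_equal(f$ids, "full")
  # gap-free alignment unchanged at any threshold
  b <- aligned_seqs(c("x", "y"), c("ACDE", "MNPQ"))
  expect_identical(filter_incomplete(b, 0.99), b)
  expect_error(filter_incomplete(a, 2), "min_coverage")
  expect_error(filter_incomplete(
    aligned_seqs("only", "A---------"), 0.9), "no sequences")
})

test_that("filtering 7 planted fragments from 219 sequences leaves 212", {
  g <- make_msa(n_seq = 219, substitution_rate = 0.1,
                incomplete_fraction = 7 / 219, seed = 5)
  # direct-scan oracle: count rows whose non-gap fraction passes 0.9
  m <- strsplit(g$alignment$seqs, "")
  cov <- vapply(m, function(r) mean(r != "-"), numeric(1))
  expect_equal(sum(cov >= 0.9), 212L)
  f <- filter_incomplete(g$alignment, 0.9)
  expect_equal(length(f$ids), 212L)
  expect_false(any(g$truth$fragment_ids %in% f$ids))
})

test_that("filter_incomplete is monotone in the coverage threshold", {
  g <- make_msa(n_seq = 40, substitution_rate = 0.1,
                incomplete_fraction = 0.2, incomplete_coverage = 0.7,
                seed = 8)
  sizes <- vapply(c(0.3, 0.5, 0.7, 0.9),
                  function(th) length(filter_incomplete(g$alignment,
                                                        th)$ids),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("redundancy reduction collapses planted clusters to one member", {
  g <- make_msa(n_seq = 40, substitution_rate = 0.2,
                n_redundant_clusters = 4, cluster_size = 3, seed = 13)
  r <- reduce_redundancy(g$alignment, 0.9)
  # brute-force all-pairs identity oracle on the full input
  n <- length(g$alignment$ids)
  idm <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
    identity_oracle(g$alignment$seqs[i], g$alignment$seqs[j])))
  # oracle greedy selection in input order
  kept <- integer(0)
  for (i in seq_len(n))
    if (!any(idm[i, kept] >= 0.9)) kept <- c(kept, i)
  expect_equal(r$ids, g$alignment$ids[kept])
  # exactly one representative per planted cluster survives
  surviving_cluster <- g$truth$cluster_ids[match(r$ids, g$alignment$ids)]
  expect_equal(unname(table(surviving_cluster[!is.na(surviving_cluster)])),
               rep(1L, 4L), ignore_attr = TRUE)
})

test_that("redundancy reduction is idempotent and keeps distinct rows", {
  two <- aligned_seqs(c("a", "b"), c("ACDE", "ACDE"))
  expect_equal(length(reduce_redundancy(two, 0.9)$ids), 1L)
  distinct <- aligned_seqs(c("a", "b", "c"),
                           c("ACDEFGHIKL", "MNPQRSTVWY", "AMCNDPEQFR"))
  expect_identical(reduce_redundancy(distinct, 0.9), distinct)
  g <- make_msa(n_seq = 30, substitution_rate = 0.2,
                n_redundant_clusters = 2, seed = 21)
  once <- reduce_redundancy(g$alignment, 0.9)
  expect_identical(reduce_redundancy(once, 0.9), once)
})

test_that("column profiles equal a naive per-cell tally", {
  a <- aligned_seqs(c("r1", "r2", "r3", "r4"),
                    c("A", "A", "G", "-"))
  p <- column_profiles(a)
  expect_equal(unname(p["A", 1]), 2L)
  expect_equal(unname(p["G", 1]), 1L)
  expect_equal(unname(p["-", 1]), 1L)
  # random 50x30 set against an explicit double-loop tally
  set.seed(99)
  rows <- replicate(50, paste(sample(c("A", "C", "D", "G", "-"), 30,
                                     replace = TRUE), collapse = ""))
  b <- aligned_seqs(sprintf("s%02d", 1:50), rows)
  p <- column_profiles(b)
  mat <- do.call(rbind, strsplit(rows, ""))
  for (j in c(1, 7, 30)) {
    for (sym in c("A", "C", "D", "G", "-")) {
      expect_equal(unname(p[sym, j]), sum(mat[, j] == sym))
    }
  }
  expect_true(all(colSums(p) == 50L))
})
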