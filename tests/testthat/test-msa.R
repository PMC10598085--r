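test_that("progressive MSA handles identical sequences and pairs exactly", {
  set.seed(51)
  s <- random_protein(60)
  same <- records_tbl(c("a", "b", "c"), rep(s, 3))
  aln <- progressive_msa(same)
  expect_false(any(grepl("-", aln$rows, fixed = TRUE)))
  # two sequences: equals the optimal global pairwise alignment
  t <- substitute_k(s, 10, 1)
  pair <- progressive_msa(records_tbl(c("x", "y"), c(s, t)))
  nw <- align_global(s, t)
  expect_equal(pair$rows[[1]], nw$aligned_query)
  expect_equal(pair$rows[[2]], nw$aligned_target)
  expect_error(progressive_msa(records_tbl("x", s)), "at least 2")
  # round-trip: removing gaps reproduces inputs
  rec <- records_tbl(c("p", "q", "r"),
                     c(s, t, paste0(substr(s, 1, 30), substr(s, 36, 60))))
  out <- msa_sequences(progressive_msa(rec))
  expect_equal(out$sequence, rec$sequence)
})

test_that("a planted indel produces one gap block in exactly that row", {
  set.seed(52)
  base <- random_protein(90)
  seqs <- vapply(1:6, function(i) substitute_k(base, 4, i), character(1))
  seqs[4] <- paste0(substr(seqs[4], 1, 40), substr(seqs[4], 46, 90))
  aln <- progressive_msa(records_tbl(paste0("h", 1:6), seqs))
  m <- do.call(rbind, strsplit(aln$rows, ""))
  gap_cols <- which(colSums(m == "-") > 0)
  expect_length(gap_cols, 5)
  expect_true(all(diff(gap_cols) == 1))   # contiguous block
  expect_true(all(m[4, gap_cols] == "-"))
  expect_true(all(m[-4, gap_cols] != "-"))
})

test_that("conservation ranks use the 12-rank scale with * and + symbols", {
  aln <- new_msa(paste0("s", 1:4),
                 c("KIDAK", "KLDAR", "KLDG-", "KIDAK"))
  cr <- conservation_ranks(aln)
  # column 1: all K, gap-free -> rank 11, '*'
  expect_equal(cr$rank[1], 11L)
  expect_equal(cr$symbol[1], "*")
  # column 2 {I,L,L,I}: identical property profiles -> rank 10, '+'
  expect_equal(cr$rank[2], 10L)
  expect_equal(cr$symbol[2], "+")
  # column 5 has a gap: capped at 9, never * or +
  expect_lte(cr$rank[5], 9L)
  expect_false(cr$symbol[5] %in% c("*", "+"))
  # shared-property monotonicity: {I,L,V} >= {I,L,D}
  r_ilv <- conservation_ranks(new_msa(paste0("s", 1:3), c("I", "L", "V")))
  r_ild <- conservation_ranks(new_msa(paste0("s", 1:3), c("I", "L", "D")))
  expect_gte(r_ilv$rank[1], r_ild$rank[1])
})

test_that("trimming removes gapped columns per the fraction threshold", {
  clean <- new_msa(c("a", "b"), c("ACDE", "ACDE"))
  expect_equal(trim_alignment(clean)$rows, clean$rows)
  gapped <- new_msa(paste0("s", 1:2), c("ACDEFGHIK", "ACDE----K"))
  tr <- trim_alignment(gapped)
  expect_equal(nchar(tr$rows[[1]]), 5)
  expect_false(any(grepl("-", tr$rows, fixed = TRUE)))
  expect_equal(attr(tr, "columns"), c(1:4, 9L))
  # fraction threshold: 2 gaps in 6 rows = 0.33 <= 0.5 -> retained
  six <- new_msa(paste0("s", 1:6), c("AC", "AC", "AC", "AC", "-C", "-C"))
  expect_equal(nchar(trim_alignment(six, 0.5)$rows[[1]]), 2)
  expect_error(trim_alignment(new_msa(c("a", "b"), c("A-", "-A")), 0),
               "all columns")
})

test_that("alignment FASTA and Stockholm round-trip", {
  aln <- new_msa(c("seq1", "seq2"), c("AC-DE", "ACWDE"))
  f <- withr::local_tempfile(fileext = ".afa")
  write_alignment_fasta(aln, f)
  expect_equal(read_alignment_fasta(f)$rows, aln$rows)
  s <- withr::local_tempfile(fileext = ".sto")
  write_stockholm(aln, s)
  back <- read_stockholm(s)
  expect_equal(back$ids, aln$ids)
  expect_equal(back$rows, aln$rows)
})
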