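test_that("Karlin-Altschul E-values follow the closed form", {
  sc <- scoring_scheme()  # lambda 0.267, K 0.041
  e <- evalue_ka(40, 100, 100, sc)
  expect_equal(e$evalue, 0.041 * 1e4 * exp(-0.267 * 40), tolerance = 1e-12)
  expect_equal(e$evalue, 9.4e-3, tolerance = 0.01)
  # strictly decreasing in S; linear in n
  es <- evalue_ka(c(40, 41, 42), 100, 100, sc)$evalue
  expect_true(all(diff(es) < 0))
  expect_equal(evalue_ka(40, 100, 200, sc)$evalue, 2 * e$evalue)
  expect_error(evalue_ka(40, 0, 100, sc), "m and n")
})

test_that("search_local finds self-matches and applies both thresholds", {
  set.seed(31)
  q <- records_tbl("Q", random_protein(200))
  shared60 <- substr(q$sequence, 71, 130)
  # boundary targets are exactly the shared block, so the alignment
  # cannot extend and query coverage is exactly 60/200 resp. 58/200
  db <- records_tbl(
    c("SELF", "BLK60", "BLK58", "RAND"),
    c(q$sequence, shared60, substr(shared60, 1, 58), random_protein(200)))
  hits <- search_local(q, db)
  expect_true("SELF" %in% hits$target_id)
  self <- hits[hits$target_id == "SELF", ]
  expect_equal(self$identity_pct, 100)
  expect_equal(self$coverage, 1)
  expect_lt(self$evalue, 1e-10)
  # 60/200 = 0.30 retained at the boundary; 58/200 = 0.29 dropped
  expect_true("BLK60" %in% hits$target_id)
  expect_equal(hits$coverage[hits$target_id == "BLK60"], 0.30)
  expect_false("BLK58" %in% hits$target_id)
  expect_false("RAND" %in% hits$target_id)
  # sorted by ascending E-value; coordinates within bounds
  expect_false(is.unsorted(hits$evalue))
  expect_true(all(hits$q_start >= 1 & hits$q_end <= 200))
  expect_error(search_local(records_tbl("Q", "AC"), db), "shorter")
})

test_that("best local score equals the exhaustive Smith-Waterman oracle", {
  set.seed(17)
  sc <- scoring_scheme()
  for (i in 1:25) {
    q <- random_protein(sample(40:300, 1))
    t <- random_protein(sample(40:300, 1))
    expect_equal(align_local(q, t, sc)$score, biostrings_local_score(q, t))
  }
})

test_that("dual-query search merges target sets without duplication", {
  set.seed(32)
  fam <- vapply(rep(300, 5), random_protein, character(1))
  db <- records_tbl(paste0("T", 1:5), fam)
  qf <- records_tbl("QF", fam[1])
  qd <- records_tbl("QD", substr(fam[1], 100, 250))
  both <- dual_query_search(qf, qd, db)
  expect_equal(both$target_id[both$target_id == "T1"], "T1")
  expect_equal(sum(both$target_id == "T1"), 1)
  expect_equal(both$query_class[both$target_id == "T1"], "full+domain")
  # disjoint target sets union: 3 + 2 = 5
  dbx <- records_tbl(paste0("U", 1:5), c(
    substitute_k(fam[2], 30, 1), substitute_k(fam[2], 30, 2),
    substitute_k(fam[2], 30, 3),
    paste0(random_protein(150), substr(fam[3], 1, 150)),
    paste0(random_protein(150), substr(fam[3], 21, 171))))
  u <- dual_query_search(records_tbl("A", fam[2]),
                         records_tbl("B", substr(fam[3], 1, 150)), dbx)
  expect_equal(sort(u$target_id), paste0("U", 1:5))
  # invariant to query order
  qf2 <- records_tbl(c("A", "C"), c(fam[2], fam[4]))
  qf2r <- qf2[2:1, ]
  expect_equal(dual_query_search(qf2, NULL, dbx)$target_id,
               dual_query_search(qf2r, NULL, dbx)$target_id)
  expect_error(dual_query_search(qf, qd, db[0, ]), "empty")
})

test_that("planted families are recovered with zero decoy hits", {
  # spec-level property: divergence <= 40% of sites, 0 decoys among hits
  set.seed(77)
  anc <- random_protein(350)
  db <- dplyr::bind_rows(
    records_tbl(sprintf("FAM%02d", 1:12),
                vapply(1:12, function(i) substitute_k(anc, 140, i),
                       character(1)),
                species = rep(paste0("SP", 1:4), 3)),
    records_tbl(sprintf("DEC%02d", 1:10),
                vapply(rep(350, 10), random_protein, character(1)),
                species = rep(paste0("SP", 1:5), 2)))
  hits <- dual_query_search(records_tbl("Q", anc), NULL, db)
  found <- hits$target_id
  expect_gte(mean(sprintf("FAM%02d", 1:12) %in% found), 0.95)
  expect_equal(sum(startsWith(found, "DEC")), 0)
})

test_that("inventory counts genes, collapses isoforms and summarises", {
  rec <- dplyr::bind_rows(
    records_tbl(paste0("A", 1:6), vapply(rep(200, 6), random_protein,
                                         character(1)), species = "SpA"),
    records_tbl("B1", random_protein(300), species = "SpB"),
    records_tbl("Z1", random_protein(200), species = "SpC"))
  rec$gene_id <- c(paste0("gA", 1:6), "gB", "gZ")
  # B1 gene emitted as four isoform records
  iso <- records_tbl(paste0("B1_i", 1:3),
                     vapply(c(150, 220, 180), random_protein, character(1)),
                     species = "SpB")
  iso$gene_id <- "gB"
  iso$is_isoform <- TRUE
  rec <- dplyr::bind_rows(rec, iso)
  hits <- tibble::tibble(target_id = setdiff(rec$id, "Z1"))
  inv <- build_inventory(hits, rec)
  expect_equal(inv$n_genes[inv$species == "SpA"], 6L)
  expect_equal(inv$n_family_records[inv$species == "SpB"], 4L)
  expect_equal(inv$n_genes[inv$species == "SpB"], 1L)
  # longest member represents the gene
  expect_equal(inv$representative_ids[inv$species == "SpB"][[1]], "B1")
  # species without hits listed with zero
  expect_equal(inv$n_genes[inv$species == "SpC"], 0L)
  # population SD over species with >= 1 member: {6, 1}
  expect_equal(attr(inv, "mean_genes"), 3.5)
  expect_equal(attr(inv, "sd_genes"), 2.5)
  expect_error(build_inventory(tibble::tibble(target_id = "NOPE"), rec),
               "unknown")
  empty <- build_inventory(tibble::tibble(target_id = character()), rec)
  expect_true(all(empty$n_genes == 0))
  expect_true(is.na(attr(empty, "mean_genes")))
})
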