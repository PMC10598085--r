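# deterministic seed alignment around a template for profile tests
seed_aln_for <- function(template, n = 5, divergence = 0.1, seed = 71) {
  set.seed(seed)
  rows <- vapply(seq_len(n), function(i) substitute_k(
    template, round(nchar(template) * divergence), seed * 100 + i),
    character(1))
  new_msa(paste0("seed", seq_len(n)), rows)
}

test_that("profiles score their seeds high and background low", {
  set.seed(72)
  template <- random_protein(80)
  same <- new_msa(c("a", "b", "c"), rep(template, 3))
  prof <- build_profile(same, "SAME", calibrate = FALSE)
  # each column's top-scoring residue is the seed residue
  top <- colnames(prof$scores)[apply(prof$scores, 1, which.max)]
  expect_equal(paste(top, collapse = ""), template)
  # consensus scores at least as high as any single seed row
  aln <- seed_aln_for(template)
  prof2 <- build_profile(aln, "T", calibrate = FALSE)
  cons <- paste(colnames(prof2$scores)[apply(prof2$scores, 1, which.max)],
                collapse = "")
  score_of <- function(s) {
    idx <- match(strsplit(s, "")[[1]], colnames(prof2$scores))
    sum(prof2$scores[cbind(seq_len(nrow(prof2$scores)), idx)])
  }
  row_scores <- vapply(msa_sequences(aln)$sequence, score_of, numeric(1))
  expect_true(all(score_of(cons) >= row_scores))
  # background-random sequences score <= 0 on average (per-position sum)
  set.seed(73)
  nulls <- vapply(1:300, function(i) score_of(random_protein(80)), numeric(1))
  expect_lte(mean(nulls), 0)
  expect_error(build_profile(new_msa("x", template), "X"), ">= 2 rows")
})

test_that("profile scans find planted domains and reject shuffles", {
  set.seed(74)
  tpl <- domain_templates()
  profs <- default_profiles()
  planted_start <- 101
  prot <- records_tbl("P1", paste0(random_protein(100), tpl[["CLP1_P"]],
                                   random_protein(60)))
  hits <- scan_profiles(prot, profs["CLP1_P"])
  expect_equal(nrow(hits), 1)
  span <- CLP1P_span <- c(planted_start, planted_start + 169)
  overlap <- min(hits$end, span[2]) - max(hits$start, span[1]) + 1
  expect_gte(overlap / 170, 0.9)
  # shuffled version of the same protein: no hit at 1e-3
  shuf <- records_tbl("P2", paste(sample(strsplit(prot$sequence, "")[[1]]),
                                  collapse = ""))
  expect_equal(nrow(scan_profiles(shuf, profs["CLP1_P"])), 0)
  # three planted domains give three ordered, non-overlapping hits
  prot3 <- records_tbl("P3", paste0(
    "MSTV", tpl[["CLP1_EN"]], random_protein(12), tpl[["CLP1_P"]],
    random_protein(12), tpl[["CLP1_EC"]], "KR"))
  h3 <- scan_profiles(prot3, profs[c("CLP1_EN", "CLP1_P", "CLP1_EC")])
  expect_equal(h3$domain_name, c("CLP1_EN", "CLP1_P", "CLP1_EC"))
  expect_true(all(h3$start[-1] > h3$end[-3]))
  # profile longer than protein: silently no hit
  expect_equal(nrow(scan_profiles(records_tbl("P4", "ACDEFGHIKL"),
                                  profs["CLP1_P"])), 0)
})

test_that("unannotated segments are the complement above min_len", {
  prot <- records_tbl("P", random_protein(400, seed = 75))
  none <- unannotated_segments(prot, empty_hits_tbl(), min_len = 50)
  expect_equal(c(none$start, none$end), c(1L, 400L))
  hit <- tibble::tibble(protein_id = "P", domain_name = "D",
                        start = 101L, end = 200L, score = 1,
                        evalue = 0, origin = "profile")
  seg <- unannotated_segments(prot, hit, min_len = 50)
  expect_equal(seg$start, c(1L, 201L))
  expect_equal(seg$end, c(100L, 400L))
  # a 30-aa tail is not reported at min_len 50
  tail_hit <- dplyr::mutate(hit, start = 31L, end = 370L)
  expect_equal(nrow(unannotated_segments(prot, tail_hit, min_len = 50)), 0)
})

test_that("novel domains emerge from conserved unannotated blocks", {
  set.seed(76)
  block <- random_protein(150)
  block2 <- random_protein(120)
  mk_seg <- function(id, core, jitter_seed) {
    tibble::tibble(protein_id = id, start = 31L,
                   end = 30L + nchar(core),
                   sequence = substitute_k(core, 15, jitter_seed))
  }
  segs <- purrr::map_dfr(1:8, function(i) mk_seg(paste0("A", i), block, i))
  recs <- records_tbl(paste0("A", 1:8), rep("X", 8),
                      species = paste0("SP", rep(1:4, 2)))
  recs$sequence <- segs$sequence  # placeholder, only species is used
  nd <- discover_novel_domains(segs, recs)
  expect_equal(dplyr::n_distinct(nd$domain_name), 1)
  expect_equal(nrow(nd), 8)
  expect_equal(unique(nd$n_members), 8L)
  expect_equal(unique(nd$mean_length), mean(nd$end - nd$start + 1))
  expect_lt(abs(unique(nd$mean_length) - 150), 10)
  # two disjoint planted blocks in different species sets: two domains
  segs2 <- dplyr::bind_rows(
    segs,
    purrr::map_dfr(1:4, function(i) mk_seg(paste0("B", i), block2, 50 + i)))
  recs2 <- dplyr::bind_rows(
    recs, records_tbl(paste0("B", 1:4), rep("X", 4),
                      species = paste0("SQ", 1:4)))
  nd2 <- discover_novel_domains(segs2, recs2)
  expect_equal(dplyr::n_distinct(nd2$domain_name), 2)
  cross <- table(nd2$domain_name, substr(nd2$protein_id, 1, 1))
  expect_true(all(rowSums(cross > 0) == 1))  # no cross-edges
  # membership invariant to segment input order
  nd_rev <- discover_novel_domains(segs2[nrow(segs2):1, ], recs2)
  key <- function(x) {
    split(x$protein_id, x$domain_name) |>
      lapply(sort) |> unname() |> (\(l) l[order(vapply(l, `[`, "", 1))])()
  }
  expect_equal(key(nd_rev), key(nd2))
  # components smaller than min_species vanish
  nd3 <- discover_novel_domains(segs2, recs2, min_species = 5)
  expect_equal(nrow(nd3), 0)
})

test_that("architecture assembly is ordered, non-overlapping, profile-first", {
  prot <- records_tbl("P", random_protein(300, seed = 77))
  ph <- tibble::tibble(protein_id = "P",
                       domain_name = c("CLP1_EN", "CLP1_P"),
                       start = c(10L, 120L), end = c(100L, 260L),
                       score = c(50, 90), evalue = c(1e-8, 1e-12),
                       origin = "profile")
  nh <- tibble::tibble(protein_id = "P", domain_name = "NDOM1",
                       start = 250L, end = 299L, score = NA_real_,
                       evalue = NA_real_, origin = "novel")
  out <- assemble_architecture(prot, ph, nh)
  # the novel hit overlaps the stronger profile hit and is dropped
  expect_equal(out$architecture, "CLP1_EN|CLP1_P")
  nh2 <- dplyr::mutate(nh, start = 265L)
  out2 <- assemble_architecture(prot, ph, nh2)
  expect_equal(out2$architecture, "CLP1_EN|CLP1_P|NDOM1")
  expect_true(all(diff(out2$hits$start) > 0))
  empty <- assemble_architecture(prot, empty_hits_tbl(), empty_hits_tbl())
  expect_equal(empty$architecture, "")
})

test_that("domtblout import maps the HMMER columns", {
  f <- withr::local_tempfile(fileext = ".domtblout")
  writeLines(c(
    "# comment",
    paste("prot1 - 400 CLP1_P - 170 1e-20 50.1 0.1 1 1 1e-22 1e-21 48.0 0.1",
          "5 160 30 190 28 195 0.9 desc")), f)
  hits <- read_domtblout(f)
  expect_equal(hits$protein_id, "prot1")
  expect_equal(hits$domain_name, "CLP1_P")
  expect_equal(c(hits$start, hits$end), c(30L, 190L))
  expect_equal(hits$origin, "profile")
})
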