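test_that("every record has exactly one truth row and counts add up", {
  sim <- small_sim(seed = 7)
  expect_setequal(sim$records$id, sim$truth$id)
  expect_equal(anyDuplicated(sim$records$id), 0L)
  expect_equal(sum(sim$truth$is_decoy),
               sim$config$n_decoys * sim$config$n_species)
  # default world: no losses/duplications -> one gene per lineage/species
  genes <- sim$truth[!sim$truth$is_decoy & is.na(sim$truth$isoform_parent), ]
  expect_equal(nrow(genes),
               sim$config$n_species * length(sim$config$lineages))
  expect_equal(sort(unique(genes$lineage)), c("nol9", "t1", "t2", "t3"))
})

test_that("zero divergence makes same-lineage sequences identical", {
  sim <- simulate_dataset(simulation_config(
    n_species = 4, divergence = 0, indel_prob = 0, isoform_prob = 0,
    n_decoys = 0, seed = 8))
  genes <- sim$truth[is.na(sim$truth$isoform_parent), ]
  for (lin in unique(genes$lineage)) {
    seqs <- sim$records$sequence[sim$records$id %in%
                                   genes$id[genes$lineage == lin]]
    expect_equal(dplyr::n_distinct(seqs), 1)
  }
})

test_that("a fixed seed reproduces the dataset byte-identically", {
  s1 <- small_sim(seed = 9)
  s2 <- small_sim(seed = 9)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth, s2$truth)
  expect_identical(ape::write.tree(s1$species_tree),
                   ape::write.tree(s2$species_tree))
  s3 <- small_sim(seed = 10)
  expect_false(identical(s1$records$sequence, s3$records$sequence))
})

test_that("motif sites are protected unless ablated", {
  sim <- simulate_dataset(simulation_config(
    n_species = 3, indel_prob = 0, isoform_prob = 0, n_decoys = 0,
    seed = 11))
  tpl <- domain_templates()
  walker_a <- substr(tpl[["CLP1_P"]], 21, 28)
  clasp <- substr(tpl[["CLP1_P"]], 111, 118)
  genes <- sim$truth[is.na(sim$truth$isoform_parent), ]
  t2_seqs <- sim$records$sequence[sim$records$id %in%
                                    genes$id[genes$lineage == "t2"]]
  expect_true(all(grepl(walker_a, t2_seqs, fixed = TRUE)))
  expect_true(all(grepl(clasp, t2_seqs, fixed = TRUE)))
  # t1 is Clasp-ablated by default: instance destroyed, truth inactive
  t1_seqs <- sim$records$sequence[sim$records$id %in%
                                    genes$id[genes$lineage == "t1"]]
  expect_false(any(grepl(clasp, t1_seqs, fixed = TRUE)))
  expect_true(all(grepl(walker_a, t1_seqs, fixed = TRUE)))
  expect_false(any(genes$active[genes$lineage == "t1"]))
  expect_true(all(genes$active[genes$lineage == "t2"]))
  # t3 carries the truncated (< 130 aa) kinase domain: inactive
  expect_true(all(genes$clp1p_length[genes$lineage == "t3"] < 130))
  expect_false(any(genes$active[genes$lineage == "t3"]))
})

test_that("ablate_motif marks lineages inactive in truth", {
  cfg <- simulation_config(n_species = 3, n_decoys = 0, isoform_prob = 0,
                           seed = 12)
  cfg2 <- ablate_motif(cfg, "t2", "Lid")
  sim <- simulate_dataset(cfg2)
  genes <- sim$truth[is.na(sim$truth$isoform_parent), ]
  expect_false(any(genes$active[genes$lineage == "t2"]))
  expect_error(ablate_motif(cfg, "t2", "WalkerC"), "unknown motif")
  expect_error(ablate_motif(cfg, "zz", "Lid"), "unknown lineage")
})

test_that("substitutions along the tree follow the branch-binomial model", {
  cfg <- simulation_config(n_species = 6, divergence = 0.2, indel_prob = 0,
                           isoform_prob = 0, n_decoys = 0, seed = 13)
  sim <- simulate_dataset(cfg)
  tree <- sim$species_tree
  D <- ape::cophenetic.phylo(tree)
  genes <- sim$truth[sim$truth$lineage == "t2", ]
  # compare the planted kinase-domain spans: domains evolve by pure
  # substitution (linkers are resampled wholesale and tell us nothing)
  span_of <- function(id) {
    d <- sim$truth_domains[sim$truth_domains$id == id &
                             sim$truth_domains$domain == "CLP1_P", ]
    rec <- sim$records$sequence[sim$records$id == id]
    strsplit(substr(rec, d$start, d$end), "")[[1]]
  }
  pair <- which(D == min(D[D > 0]), arr.ind = TRUE)[1, ]
  id1 <- genes$id[genes$species == rownames(D)[pair[1]]]
  id2 <- genes$id[genes$species == rownames(D)[pair[2]]]
  s1 <- span_of(id1)
  s2 <- span_of(id2)
  p_path <- cfg$divergence * min(D[D > 0])
  n <- length(s1)
  p_obs <- mean(s1 != s2)
  # expected difference ~ p_path (protected motif sites and coincident
  # double hits push it slightly below); 3 binomial SDs + small slack
  expect_lt(abs(p_obs - p_path),
            3 * sqrt(p_path * (1 - p_path) / n) + 0.03)
})

test_that("written datasets round-trip through the path-based loader", {
  sim <- small_sim(seed = 14)
  dir <- withr::local_tempdir()
  write_dataset(sim, dir)
  expect_true(file.exists(file.path(dir, "SP01.fasta")))
  expect_true(file.exists(file.path(dir, "truth.tsv")))
  rec <- read_fasta(file.path(dir, "SP02.fasta"),
                    metadata = file.path(dir, "metadata.tsv"))
  orig <- sim$records[sim$records$species == "SP02", ]
  expect_setequal(rec$id, orig$id)
  expect_equal(rec$sequence[match(orig$id, rec$id)], orig$sequence)
  expect_equal(rec$species[1], "SP02")
})
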