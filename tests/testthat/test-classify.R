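# A hand-built rooted tree with two groups and three cross-species
# lineages inside the first group.
two_group_tree <- function() {
  txt <- paste0(
    "(((A_sp1:1,A_sp2:1,A_sp3:1):2,(B_sp1:1,B_sp2:1,B_sp3:1):2,",
    "(C_sp1:1,C_sp2:1,C_sp3:1):2):3,",
    "(N_sp1:1,N_sp2:1,N_sp3:1):3);")
  ape::read.tree(text = txt)
}

test_that("anchored group splitting labels every leaf", {
  tree <- two_group_tree()
  anchors <- c(A_sp1 = "Clp1", N_sp2 = "Nol9/Grc3")
  g <- split_groups(tree, anchors)
  expect_equal(sort(unique(g$group)), c("Clp1", "Nol9/Grc3"))
  expect_true(all(g$group[startsWith(g$protein_id, "N_")] == "Nol9/Grc3"))
  expect_true(all(g$group[!startsWith(g$protein_id, "N_")] == "Clp1"))
  # both groups' anchors majority in one subtree -> failure
  bad <- c(A_sp1 = "Clp1", B_sp1 = "Nol9/Grc3")
  expect_error(split_groups(tree, bad), "classification failure")
})

test_that("group splitting scales to anchor-sparse synthetic trees", {
  set.seed(91)
  n_per <- 30
  tree <- ape::read.tree(text = paste0(
    "((", paste(sprintf("L%02d:1", 1:n_per), collapse = ","), "):4,",
    "(", paste(sprintf("R%02d:1", 1:n_per), collapse = ","), "):4);"))
  ids <- tree$tip.label
  truthg <- ifelse(startsWith(ids, "L"), "Clp1", "Nol9/Grc3")
  pick <- sample(length(ids), 6)  # ~10% anchor density
  # make sure both groups are represented among the anchors
  pick <- c(pick, which(ids == "L01"), which(ids == "R01"))
  anchors <- stats::setNames(truthg[pick], ids[pick])
  g <- split_groups(tree, anchors)
  expect_equal(stats::setNames(g$group, g$protein_id)[ids],
               stats::setNames(truthg, ids))
})

test_that("type assignment finds cross-species clades with shared domains", {
  tree <- two_group_tree()
  members <- grep("^[ABC]_", tree$tip.label, value = TRUE)
  arch <- stats::setNames(
    paste0("EN|P|", rep(c("C1", "C2", "C3"), each = 3)), members)
  species <- stats::setNames(sub("^._", "", tree$tip.label),
                             tree$tip.label)
  ty <- assign_types(members, tree, arch, species)
  # three types, one per lineage, every species once in each
  expect_equal(dplyr::n_distinct(ty$type_label), 3)
  by_type <- split(ty$protein_id, ty$type_label)
  expect_true(all(lengths(by_type) == 3))
  expect_true(all(vapply(by_type, function(ids)
    dplyr::n_distinct(arch[ids]) == 1, logical(1))))
  expect_false(any(ty$duplicate_flag))
  expect_error(assign_types(c(members, "GHOST"), tree, arch, species),
               "absent")
})

test_that("a single same-species duplicate is tolerated and flagged", {
  txt <- paste0("(((A_sp1:1,A_sp2:1,A_sp3:1,A_sp3b:1):2,",
                "(B_sp1:1,B_sp2:1,B_sp3:1):2):3,(N_sp1:1,N_sp2:1):3);")
  tree <- ape::read.tree(text = txt)
  members <- grep("^[AB]_", tree$tip.label, value = TRUE)
  arch <- stats::setNames(
    ifelse(startsWith(members, "A_"), "EN|P|C1", "EN|P|C2"), members)
  species <- stats::setNames(sub("b$", "", sub("^._", "", tree$tip.label)),
                             tree$tip.label)
  ty <- assign_types(members, tree, arch, species)
  dup_rows <- ty[ty$protein_id %in% c("A_sp3", "A_sp3b"), ]
  expect_equal(dplyr::n_distinct(dup_rows$type_label), 1)
  expect_false(any(is.na(dup_rows$type_label)))
  expect_true(all(dup_rows$duplicate_flag))
})

test_that("co-occurring unclustered members get letter suffixes", {
  # three same-species members with different architectures: no clade
  txt <- "((X_sp1:1,(Y_sp1:1,Q_sp2:1):1):1,Z_sp1:2);"
  tree <- ape::read.tree(text = txt)
  members <- c("X_sp1", "Y_sp1", "Z_sp1")
  arch <- stats::setNames(c("EN|P", "EN|P|C9", "P"), members)
  species <- stats::setNames(c("sp1", "sp1", "sp2", "sp1"),
                             c("X_sp1", "Y_sp1", "Q_sp2", "Z_sp1"))
  ty <- assign_types(members, tree, arch, species)
  expect_true(all(is.na(ty$type_label)))
  expect_equal(ty$letter_suffix[match(c("X_sp1", "Y_sp1", "Z_sp1"),
                                      ty$protein_id)], c("a", "b", "c"))
})

test_that("identity matrix prints identities, N/D and the dash diagonal", {
  set.seed(92)
  a <- random_protein(220)
  b <- substitute_k(a, 60, 1)
  unrelated <- random_protein(240)
  rec <- records_tbl(c("P1", "P2", "P3"), c(a, b, unrelated))
  m <- identity_matrix(rec)
  expect_equal(m$P1[m$protein_id == "P1"], "\u2013")
  expect_match(m$P2[m$protein_id == "P1"], "^\\d+ \\(\\d+\\)$")
  expect_equal(m$P3[m$protein_id == "P1"], "N/D")
  expect_equal(m$P1[m$protein_id == "P3"], "N/D")
  # numeric cells: similarity >= identity, both in [0, 100]
  cell <- m$P2[m$protein_id == "P1"]
  nums <- as.numeric(strsplit(gsub("[()]", "", cell), " ")[[1]])
  expect_true(all(nums >= 0 & nums <= 100))
  expect_gte(nums[2], nums[1])
  # a sequence against its own copy off-diagonal: 100 (100)
  twin <- records_tbl(c("T1", "T2"), c(a, a))
  mt <- identity_matrix(twin)
  expect_equal(mt$T2[mt$protein_id == "T1"], "100 (100)")
})

test_that("family calls combine groups, types, motifs and activity", {
  sim <- small_sim(seed = 6)
  gene_rec <- sim$records[!sim$records$is_isoform &
                            !sim$truth$is_decoy[match(sim$records$id,
                                                      sim$truth$id)], ]
  groups <- tibble::tibble(protein_id = gene_rec$id,
                           group = sim$truth$group[match(gene_rec$id,
                                                         sim$truth$id)])
  types <- tibble::tibble(protein_id = gene_rec$id,
                          type_label = NA_character_,
                          letter_suffix = NA_character_,
                          duplicate_flag = FALSE)
  arch <- stats::setNames(rep("X", nrow(gene_rec)), gene_rec$id)
  spans <- stats::setNames(vector("list", nrow(gene_rec)), gene_rec$id)
  tpl <- domain_templates()
  for (id in gene_rec$id) {
    spans[[id]] <- list(sequence = tpl[["CLP1_P"]], length = 170L)
  }
  calls <- family_calls(gene_rec, groups, types, arch, spans)
  expect_equal(nrow(calls), nrow(gene_rec))
  expect_true(all(calls$predicted_activity == "active"))
  expect_true(all(calls$n_motifs_matched == 4))
  # every member gets exactly one group
  expect_true(all(!is.na(calls$group)))
})
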