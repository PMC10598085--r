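test_that("NJ solves the three-point closed form", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  phy <- nj_tree(D)
  lens <- stats::setNames(phy$edge.length, phy$tip.label[phy$edge[, 2]])
  expect_equal(unname(lens[c("A", "B", "C")]), c(1, 1, 3))
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2)), "3 taxa")
  Dns <- D; Dns[1, 2] <- 5
  expect_error(nj_tree(Dns), "symmetric")
})

test_that("NJ reconstructs additive trees exactly", {
  set.seed(61)
  for (i in 1:10) {
    n <- sample(6:10, 1)
    true <- ape::rtree(n)
    true$edge.length <- true$edge.length + 0.1
    D <- ape::cophenetic.phylo(true)
    est <- nj_tree(D)
    expect_equal(ape::dist.topo(ape::unroot(true), est), 0,
                 ignore_attr = TRUE)
    expect_equal(max(abs(ape::cophenetic.phylo(est)[rownames(D), colnames(D)]
                         - D)), 0, tolerance = 1e-9)
  }
})

test_that("equidistant taxa give a star-like tree with equal tips", {
  D <- matrix(2, 4, 4) - diag(2, 4)
  dimnames(D) <- list(letters[1:4], letters[1:4])
  phy <- nj_tree(D)
  tip_edges <- phy$edge.length[phy$edge[, 2] <= 4]
  expect_true(all(abs(tip_edges - 1) < 1e-9))
  internal <- phy$edge.length[phy$edge[, 2] > 4]
  expect_true(all(abs(internal) < 1e-9))
})

test_that("midpoint rooting equalizes the two deepest leaf depths", {
  # two leaves with branches 1 and 3: root 2 from each
  two <- ape::read.tree(text = "(A:1,B:3);")
  r2 <- midpoint_root(two)
  d <- ape::node.depth.edgelength(r2)[1:2]
  expect_equal(unname(d), c(2, 2))
  # caterpillar: deepest pair equidistant, path lengths preserved
  cat_tree <- ape::read.tree(text = "(((A:5,B:1):1,C:1):1,(D:1,E:2):1);")
  rooted <- midpoint_root(cat_tree)
  dd <- ape::node.depth.edgelength(rooted)
  tips <- seq_along(rooted$tip.label)
  depths <- sort(dd[tips], decreasing = TRUE)
  expect_equal(depths[1], depths[2], tolerance = 1e-9)
  before <- ape::cophenetic.phylo(cat_tree)
  after <- ape::cophenetic.phylo(rooted)
  expect_equal(after[rownames(before), colnames(before)], before,
               tolerance = 1e-9)
  # midpoint exactly on an internal node: zero-length root edge tie-break
  sym <- ape::read.tree(text = "((A:2,B:2):1,(C:2,D:2):1);")
  rs <- midpoint_root(ape::unroot(sym))
  ds <- ape::node.depth.edgelength(rs)
  expect_equal(max(ds[1:4]), 3, tolerance = 1e-9)
  expect_equal(sort(ds[1:4])[3], sort(ds[1:4])[4], tolerance = 1e-9)
  expect_error(midpoint_root(ape::read.tree(text = "(A:0,B:0);")),
               "zero length")
})

test_that("midpoint rooting agrees with the phangorn reference", {
  skip_if_not_installed("phangorn")
  set.seed(62)
  for (i in 1:20) {
    phy <- ape::unroot(ape::rtree(sample(4:12, 1)))
    ours <- midpoint_root(phy)
    ref <- phangorn::midpoint(phy)
    do <- ape::node.depth.edgelength(ours)[seq_along(ours$tip.label)]
    dr <- ape::node.depth.edgelength(ref)[seq_along(ref$tip.label)]
    expect_equal(sort(stats::setNames(do, ours$tip.label)),
                 sort(stats::setNames(dr, ref$tip.label)),
                 tolerance = 1e-8)
  }
})

test_that("bootstrap supports are reproducible and bounded", {
  set.seed(63)
  a <- random_protein(60)
  b <- substitute_k(a, 3, 1)
  cd <- substitute_k(a, 30, 2)
  d <- substitute_k(cd, 3, 3)
  aln <- progressive_msa(records_tbl(c("A", "B", "C", "D"), c(a, b, cd, d)))
  t1 <- bootstrap_support(aln, n_reps = 50, seed = 7)
  t2 <- bootstrap_support(aln, n_reps = 50, seed = 7)
  expect_identical(t1$node.label, t2$node.label)
  sup <- suppressWarnings(as.numeric(t1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  # every column supports AB|CD: the split gets 100
  expect_true(100 %in% sup)
  # binary unrooted 4-taxon tree has exactly n - 3 = 1 internal edge
  expect_equal(length(sup), 1)
  expect_error(bootstrap_support(aln, n_reps = 0), "n_reps")
})

test_that("newick round-trips topology, lengths and support", {
  set.seed(64)
  phy <- ape::rtree(8)
  phy$node.label <- as.character(seq_len(phy$Nnode) * 10)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(phy, f)
  back <- read_tree_newick(f)
  expect_equal(ape::dist.topo(ape::unroot(phy), ape::unroot(back)), 0,
               ignore_attr = TRUE)
  expect_equal(back$edge.length, phy$edge.length, tolerance = 1e-6)
  expect_identical(back$node.label, phy$node.label)
})
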