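#' Pairwise distances from a (trimmed) alignment
#'
#' Per-pair fraction of differing residues over columns where both rows
#' hold residues, optionally Kimura-corrected for multiple substitutions:
#' `d = -ln(1 - p - 0.2 p^2)` (capped at p = 0.85 to stay finite).
#'
#' @param aln A `clp1_msa` (typically gap-trimmed).
#' @param correction `"kimura"` (default) or `"raw"`.
#' @return A symmetric distance matrix with sequence ids as dimnames.
#' @export
alignment_distances <- function(aln, correction = c("kimura", "raw")) {
  correction <- match.arg(correction)
  m <- msa_matrix(aln)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      p <- if (any(ok)) mean(m[i, ok] != m[j, ok]) else 0
      d <- if (correction == "kimura") {
        pc <- min(p, 0.85)
        -log(1 - pc - 0.2 * pc^2)
      } else {
        p
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree
#'
#' Standard NJ (via ape) on a symmetric distance matrix; negative branch
#' lengths are clamped to zero with the deficit moved to the sibling edge,
#' so desk-scale trees stay interpretable.
#'
#' @param D Symmetric numeric matrix (zero diagonal, n >= 3) with taxon
#'   ids as dimnames.
#' @return An unrooted `phylo`.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3) stop("need at least 3 taxa")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric")
  }
  phy <- ape::nj(stats::as.dist(D))
  neg <- which(phy$edge.length < 0)
  for (e in neg) {
    deficit <- phy$edge.length[e]
    phy$edge.length[e] <- 0
    sib <- which(phy$edge[, 1] == phy$edge[e, 1] & seq_along(phy$edge[, 1]) != e)
    if (length(sib) > 0) {
      s <- sib[1]
      phy$edge.length[s] <- max(0, phy$edge.length[s] + deficit)
    }
  }
  phy
}

# Canonical key for the bipartition separated by the edge above each
# internal node: the side not containing the alphabetically first leaf.
bipartition_keys <- function(phy) {
  tips <- phy$tip.label
  first <- sort(tips)[1]
  pp <- ape::prop.part(phy)
  keys <- vapply(seq_along(pp), function(k) {
    side <- tips[pp[[k]]]
    if (first %in% side) side <- setdiff(tips, side)
    paste(sort(side), collapse = "|")
  }, character(1))
  names(keys) <- length(tips) + seq_along(pp)
  keys
}

#' Bootstrap support by column resampling
#'
#' Nonparametric bootstrap: alignment columns are resampled with
#' replacement `n_reps` times; each replicate yields distances and an NJ
#' tree, and the support of every internal bipartition of the base tree is
#' the percentage of replicate trees containing it.  This is a standard
#' column-resampling bootstrap, not an ultrafast approximation.
#'
#' @param aln A `clp1_msa`.
#' @param n_reps Number of replicates (default 1000).
#' @param seed Integer seed (reproducibility contract).
#' @param correction Distance correction, see [alignment_distances()].
#' @return The base NJ tree with `node.label` holding supports in [0, 100]
#'   (empty for the basal node).
#' @export
bootstrap_support <- function(aln, n_reps = 1000, seed = 1,
                              correction = "kimura") {
  if (n_reps < 1) stop("n_reps must be >= 1")
  base <- nj_tree(alignment_distances(aln, correction))
  base_keys <- bipartition_keys(base)
  counts <- stats::setNames(numeric(length(base_keys)), base_keys)
  m <- msa_matrix(aln)
  withr::with_seed(seed, {
    for (r in seq_len(n_reps)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      rep_aln <- msa_from_matrix(m[, cols, drop = FALSE])
      rep_tree <- try(nj_tree(alignment_distances(rep_aln, correction)),
                      silent = TRUE)
      if (inherits(rep_tree, "try-error")) next
      rk <- bipartition_keys(rep_tree)
      hit <- base_keys %in% rk
      counts[hit] <- counts[hit] + 1
    }
  })
  support <- round(100 * counts / n_reps, 1)
  labs <- as.character(support)
  ntip <- length(base$tip.label)
  trivial <- !nzchar(base_keys) |
    vapply(strsplit(base_keys, "|", fixed = TRUE), length, integer(1)) >= ntip - 1
  labs[trivial] <- ""
  base$node.label <- labs
  base
}

#' Midpoint rooting
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path.  If
#' the midpoint falls exactly on an internal node, the root is attached
#' there through a zero-length edge (documented tie-break).  Ties between
#' equally long leaf pairs are broken by the lexicographically smallest
#' pair of leaf labels.  Existing bipartition supports are carried over by
#' re-matching bipartitions after rerooting.
#'
#' @param phy An unrooted `phylo` with >= 2 leaves and finite branch
#'   lengths.
#' @return A rooted `phylo`; the two deepest root-to-leaf distances are
#'   equal to within 1e-9.
#' @export
midpoint_root <- function(phy) {
  ntip <- length(phy$tip.label)
  if (ntip < 2) stop("need at least 2 leaves")
  if (any(!is.finite(phy$edge.length))) stop("branch lengths must be finite")
  dn <- ape::dist.nodes(phy)
  dl <- dn[seq_len(ntip), seq_len(ntip), drop = FALSE]
  if (max(dl) <= 0) stop("longest leaf-to-leaf path has zero length")
  # lexicographic tie-break on leaf labels
  best <- which(dl == max(dl), arr.ind = TRUE)
  pair_lab <- t(apply(best, 1, function(r) sort(phy$tip.label[r])))
  o <- order(pair_lab[, 1], pair_lab[, 2])[1]
  u <- best[o, 1]; v <- best[o, 2]
  half <- dl[u, v] / 2

  path <- ape::nodepath(phy, u, v)
  # edge lengths along the path
  elen <- function(a, b) {
    e <- which((phy$edge[, 1] == a & phy$edge[, 2] == b) |
                 (phy$edge[, 1] == b & phy$edge[, 2] == a))
    phy$edge.length[e[1]]
  }
  cum <- 0
  root_on_node <- NA_integer_
  seg_a <- seg_b <- NA_integer_
  pos_from_a <- NA_real_
  for (k in seq_len(length(path) - 1)) {
    a <- path[k]; b <- path[k + 1]
    L <- elen(a, b)
    if (abs(cum - half) < 1e-12) { root_on_node <- a; break }
    if (cum + L >= half - 1e-12) {
      seg_a <- a; seg_b <- b; pos_from_a <- half - cum
      if (abs(pos_from_a - L) < 1e-12) root_on_node <- b
      if (abs(pos_from_a) < 1e-12) root_on_node <- a
      break
    }
    cum <- cum + L
  }

  # adjacency with lengths over original node ids, plus the new root
  nnode_tot <- ntip + phy$Nnode
  edges <- cbind(phy$edge, phy$edge.length)
  new_root <- nnode_tot + 1L
  if (is.na(root_on_node)) {
    e <- which((phy$edge[, 1] == seg_a & phy$edge[, 2] == seg_b) |
                 (phy$edge[, 1] == seg_b & phy$edge[, 2] == seg_a))[1]
    L <- edges[e, 3]
    edges <- edges[-e, , drop = FALSE]
    edges <- rbind(edges,
                   c(new_root, seg_a, pos_from_a),
                   c(new_root, seg_b, L - pos_from_a))
    root_id <- new_root
  } else {
    root_id <- root_on_node
    if (root_id <= ntip) {
      # midpoint on a leaf can only happen for pathological zero branches
      edges <- rbind(edges, c(new_root, root_id, 0))
      root_id <- new_root
    }
  }

  rooted <- orient_edges(edges, root_id, ntip, phy$tip.label)
  if (!is.null(phy$node.label)) {
    rooted <- transfer_supports(phy, rooted)
  }
  rooted
}

# Build a rooted phylo from an undirected weighted edge list and a root id.
orient_edges <- function(edges, root_id, ntip, tip_labels) {
  nodes <- sort(unique(c(edges[, 1], edges[, 2])))
  adj <- lapply(stats::setNames(vector("list", length(nodes)),
                                as.character(nodes)), identity)
  for (r in seq_len(nrow(edges))) {
    a <- as.character(edges[r, 1]); b <- as.character(edges[r, 2])
    adj[[a]] <- rbind(adj[[a]], c(edges[r, 2], edges[r, 3]))
    adj[[b]] <- rbind(adj[[b]], c(edges[r, 1], edges[r, 3]))
  }
  # iterative DFS from root
  parent <- list()
  order_visited <- numeric(0)
  stack <- root_id
  seen <- character(0)
  while (length(stack) > 0) {
    x <- stack[length(stack)]
    stack <- stack[-length(stack)]
    xs <- as.character(x)
    if (xs %in% seen) next
    seen <- c(seen, xs)
    order_visited <- c(order_visited, x)
    nb <- adj[[xs]]
    if (is.null(nb)) next
    for (r in seq_len(nrow(nb))) {
      if (!(as.character(nb[r, 1]) %in% seen)) {
        parent[[as.character(nb[r, 1])]] <- c(x, nb[r, 2])
        stack <- c(stack, nb[r, 1])
      }
    }
  }
  internals_old <- order_visited[order_visited > ntip | order_visited == root_id]
  internals_old <- order_visited[!(order_visited <= ntip)]
  # renumber: leaves keep 1..ntip, internals in visit order from ntip+1
  remap <- stats::setNames(seq_len(ntip), as.character(seq_len(ntip)))
  remap[as.character(internals_old)] <- ntip + seq_along(internals_old)
  kids <- setdiff(order_visited, root_id)
  edge <- t(vapply(kids, function(ch) {
    p <- parent[[as.character(ch)]]
    c(remap[[as.character(p[1])]], remap[[as.character(ch)]])
  }, numeric(2)))
  lens <- vapply(kids, function(ch) parent[[as.character(ch)]][2], numeric(1))
  phy <- list(edge = matrix(as.integer(edge), ncol = 2),
              edge.length = unname(lens),
              tip.label = tip_labels,
              Nnode = length(internals_old))
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  ape::reorder.phylo(phy, "cladewise")
}

# Carry bipartition supports from the unrooted source onto a rerooted tree.
transfer_supports <- function(src, dst) {
  src_keys <- bipartition_keys(src)
  src_lab <- src$node.label
  names(src_lab) <- src_keys
  dst_keys <- bipartition_keys(dst)
  labs <- unname(src_lab[dst_keys])
  labs[is.na(labs)] <- ""
  dst$node.label <- labs
  dst
}

# Rooted star topology (all leaves attached to the root with zero-length
# edges); the degenerate stand-in when every pairwise distance is zero.
star_tree <- function(labels) {
  n <- length(labels)
  phy <- list(edge = cbind(rep(n + 1L, n), seq_len(n)),
              edge.length = rep(0, n), tip.label = labels, Nnode = 1L)
  class(phy) <- "phylo"
  phy
}

#' Newick import/export
#'
#' Thin wrappers over ape's newick reader/writer: branch lengths and
#' internal-node support labels round-trip.  The import path lets
#' externally inferred (e.g. maximum-likelihood) trees drive the
#' classification stages.
#'
#' @param phy A `phylo`.
#' @param path File path.
#' @return The tree (reader) or `path` invisibly (writer).
#' @name newick_io
NULL

#' @rdname newick_io
#' @export
write_tree_newick <- function(phy, path) {
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' @rdname newick_io
#' @export
read_tree_newick <- function(path) {
  ape::read.tree(path)
}
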