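#' Split family members into Clp1 and Nol9/Grc3 groups from a rooted tree
#'
#' The two subtrees under the root of the (midpoint-rooted) kinase-domain
#' tree are labelled by the majority group of the anchor leaves they
#' contain; every leaf inherits its subtree's label.  Leaves in a subtree
#' without anchors are labelled `"unknown"`.  If one subtree holds the
#' majority of both groups' anchors the tree is not bipartitionable and a
#' classification-failure error is raised.
#'
#' @param tree A rooted `phylo` over kinase-domain sequences.
#' @param anchors Named character vector: leaf id -> group
#'   (`"Clp1"` or `"Nol9/Grc3"`); at least one anchor per group.
#' @return Tibble with `protein_id`, `group`.
#' @export
split_groups <- function(tree, anchors) {
  groups <- sort(unique(unname(anchors)))
  if (length(groups) < 2) stop("need at least one anchor per group")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  leafsets <- lapply(kids, function(k) {
    if (k <= ntip) tree$tip.label[k] else
      ape::extract.clade(tree, k)$tip.label
  })
  labels <- vapply(leafsets, function(ls) {
    a <- anchors[intersect(names(anchors), ls)]
    if (length(a) == 0) return(NA_character_)
    tab <- sort(table(a), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) {
      stop("classification failure: anchor groups tied within one ",
           "root subtree; the tree does not bipartition the family")
    }
    names(tab)[1]
  }, character(1))
  for (g in groups) {
    if (!g %in% labels) {
      stop("classification failure: anchors of both groups fall in one ",
           "root subtree; the tree does not bipartition the family")
    }
  }
  purrr::map_dfr(seq_along(kids), function(i) {
    tibble::tibble(protein_id = leafsets[[i]],
                   group = dplyr::coalesce(labels[[i]], "unknown"))
  })
}

#' Assign cross-species types and per-species letter suffixes
#'
#' Within one group, maximal clades that (i) span at least two species,
#' (ii) hold at most one member per species (a single duplicated species
#' is tolerated and flagged), and (iii) share a domain-architecture
#' signature not shared by another such clade, are numbered t1..tn by
#' decreasing clade size (ties by alphabetically first member id).
#' Members left over that co-occur with another leftover member of the
#' same species receive letter suffixes a, b, c in input order; singletons
#' get no decoration.
#'
#' @param member_ids Character vector of this group's protein ids, in
#'   input order (drives letter suffixes).
#' @param tree A rooted `phylo` covering (at least) these members.
#' @param architectures Named character vector: protein id -> architecture
#'   string.
#' @param species Named character vector: protein id -> species.
#' @return Tibble with `protein_id`, `type_label`, `letter_suffix`,
#'   `duplicate_flag`.
#' @export
assign_types <- function(member_ids, tree, architectures, species) {
  missing <- setdiff(member_ids, tree$tip.label)
  if (length(missing) > 0) {
    stop("member(s) absent from tree: ", paste(missing, collapse = ", "))
  }
  ntip <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  cand <- list()
  for (k in seq_along(pp)) {
    ls <- tree$tip.label[pp[[k]]]
    if (!all(ls %in% member_ids)) next
    sp <- species[ls]
    counts <- table(sp)
    if (length(counts) < 2) next                      # (i) >= 2 species
    if (any(counts > 2) || sum(counts - 1) > 1) next  # (ii) <= 1 extra
    archs <- unique(architectures[ls])
    if (length(archs) != 1) next                      # (iii) shared signature
    cand[[length(cand) + 1]] <- list(leaves = ls, signature = archs)
  }
  # maximal candidates only
  if (length(cand) > 1) {
    keep <- vapply(seq_along(cand), function(i) {
      !any(vapply(seq_along(cand), function(j) {
        i != j && all(cand[[i]]$leaves %in% cand[[j]]$leaves) &&
          length(cand[[j]]$leaves) > length(cand[[i]]$leaves)
      }, logical(1)))
    }, logical(1))
    cand <- cand[keep]
  }
  # signature must be unique among the maximal clades
  if (length(cand) > 1) {
    sigs <- vapply(cand, `[[`, character(1), "signature")
    cand <- cand[!(sigs %in% sigs[duplicated(sigs)])]
  }
  out <- tibble::tibble(protein_id = member_ids,
                        type_label = NA_character_,
                        letter_suffix = NA_character_,
                        duplicate_flag = FALSE)
  if (length(cand) > 0) {
    sizes <- vapply(cand, function(c) length(c$leaves), integer(1))
    firsts <- vapply(cand, function(c) min(c$leaves), character(1))
    ord <- order(-sizes, firsts)
    for (t in seq_along(ord)) {
      ls <- cand[[ord[t]]]$leaves
      idx <- match(ls, out$protein_id)
      out$type_label[idx] <- paste0("t", t)
      dup_sp <- names(which(table(species[ls]) > 1))
      if (length(dup_sp) > 0) {
        out$duplicate_flag[idx][species[ls] %in% dup_sp] <- TRUE
      }
    }
  }
  # letter suffixes for co-occurring undecorated members
  rest <- out$protein_id[is.na(out$type_label)]
  if (length(rest) > 0) {
    by_sp <- split(rest, species[rest])
    for (ids in by_sp) {
      if (length(ids) >= 2) {
        ids <- ids[order(match(ids, member_ids))]
        out$letter_suffix[match(ids, out$protein_id)] <-
          letters[seq_along(ids)]
      }
    }
  }
  out
}

#' Round-robin identity (similarity) matrix
#'
#' Query-vs-target local-alignment identities in publication style: cell
#' (q, t) holds `"identity (similarity)"` integers from the best local hit
#' of query q against target t, `"N/D"` when no hit passes the search
#' thresholds, and an en dash on the diagonal.  Because alignments are
#' query-dependent the matrix may be asymmetric.
#'
#' @param members Record tibble (>= 2 rows).
#' @param params A [search_params()]; by default the E-value statistics use
#'   the single-target search space (`db_size_policy = "pair"`).
#' @return Tibble: first column `protein_id`, one character column per
#'   member.
#' @export
identity_matrix <- function(members,
                            params = search_params(db_size_policy = "pair")) {
  validate_records(members)
  if (nrow(members) < 2) stop("need at least 2 members")
  ids <- members$id
  cells <- matrix("\u2013", nrow(members), nrow(members),
                  dimnames = list(ids, ids))
  for (q in seq_len(nrow(members))) {
    for (t in seq_len(nrow(members))) {
      if (q == t) next
      hit <- search_local(members[q, ], members[t, ], params)
      cells[q, t] <- if (nrow(hit) == 0) {
        "N/D"
      } else {
        sprintf("%d (%d)", as.integer(hit$identity_pct[1]),
                as.integer(hit$positive_pct[1]))
      }
    }
  }
  dplyr::bind_cols(tibble::tibble(protein_id = ids),
                   tibble::as_tibble(cells))
}

#' Assemble per-protein family calls
#'
#' Joins group labels, type/letter decorations, architectures, kinase-span
#' motif reports and activity predictions into one Table-1-style tibble.
#'
#' @param records Record tibble of the classified members.
#' @param groups Tibble from [split_groups()].
#' @param types Tibble from [assign_types()] (may cover only a subset).
#' @param architectures Named character vector id -> architecture string.
#' @param clp1p_spans Named list id -> list(sequence, length) for the
#'   located kinase span (`NULL` entries allowed).
#' @param models Motif models for [scan_motifs()].
#' @return Tibble `family_calls`: `protein_id`, `species`, `protein_name`,
#'   `length`, `group`, `type_label`, `letter_suffix`, `duplicate_flag`,
#'   `architecture`, `clp1p_length`, `n_motifs_matched`, `motifs` (list),
#'   `predicted_activity`.
#' @export
family_calls <- function(records, groups, types, architectures,
                         clp1p_spans, models = motif_models()) {
  calls <- records |>
    dplyr::transmute(protein_id = .data$id, species = .data$species,
                     length = nchar(.data$sequence)) |>
    dplyr::left_join(groups, by = "protein_id") |>
    dplyr::left_join(types, by = "protein_id") |>
    dplyr::mutate(
      group = dplyr::coalesce(.data$group, "unknown"),
      architecture = unname(architectures[.data$protein_id]))
  reports <- purrr::map(calls$protein_id, function(id) {
    span <- clp1p_spans[[id]]
    scan_motifs(if (is.null(span)) NA_character_ else span$sequence, models)
  })
  calls$clp1p_length <- purrr::map_int(calls$protein_id, function(id) {
    span <- clp1p_spans[[id]]
    if (is.null(span)) NA_integer_ else as.integer(span$length)
  })
  calls$n_motifs_matched <- purrr::map_int(reports, ~ sum(.x$matched))
  calls$motifs <- reports
  calls$predicted_activity <- purrr::map2_chr(
    reports, calls$clp1p_length, predict_activity)
  decoration <- dplyr::coalesce(calls$type_label, calls$letter_suffix)
  calls$protein_name <- paste0(
    calls$species, "-", sub("/", "", calls$group, fixed = TRUE),
    ifelse(is.na(decoration), "", paste0("-", decoration)))
  dplyr::select(calls, "protein_id", "species", "protein_name", "length",
                "group", "type_label", "letter_suffix", "duplicate_flag",
                "architecture", "clp1p_length", "n_motifs_matched",
                "motifs", "predicted_activity")
}
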