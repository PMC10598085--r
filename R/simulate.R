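# Synthetic proteome simulator with planted family structure and ground
# truth: lineage ancestors are assembled from a shipped library of
# synthetic domain templates, evolved down a species tree with motif sites
# protected, then decorated with isoforms and composition-shuffled decoys.

# Motif instance coordinates inside the CLP1_P / NOL9_P templates
# (1-based inclusive, template coordinates).
CLP1P_MOTIF_SITES <- list(
  WalkerA = c(21L, 28L),
  WalkerB = c(75L, 80L),
  Clasp   = c(111L, 118L),
  Lid     = c(146L, 153L)
)

#' Synthetic domain-template library
#'
#' The synthetic (not Pfam-derived) domain templates shipped with the
#' package: kinase domains `CLP1_P`/`NOL9_P` with embedded Walker A,
#' Walker B, Clasp and Lid motif instances, flanking domains `CLP1_EN`,
#' `CLP1_EC`, `NOL9_EN`, `NOL9_EC`, and the lineage-specific C-terminal
#' replacement domains `CLP1_EUC1`--`CLP1_EUC3` and `CLP1_ALC`.
#'
#' @return Named character vector of template sequences.
#' @export
domain_templates <- function() {
  path <- system.file("extdata", "domain_templates.fasta",
                      package = "clp1family", mustWork = TRUE)
  rec <- read_fasta(path)
  stats::setNames(rec$sequence, rec$id)
}

default_lineages <- function() {
  list(
    t1 = list(name = "t1", group = "Clp1",
              domains = c("CLP1_EN", "CLP1_P", "CLP1_EUC1"),
              kinase_domain = "CLP1_P", kinase_trunc = NA_integer_,
              ablated_motifs = "Clasp"),
    t2 = list(name = "t2", group = "Clp1",
              domains = c("CLP1_EN", "CLP1_P", "CLP1_EUC2"),
              kinase_domain = "CLP1_P", kinase_trunc = NA_integer_,
              ablated_motifs = character()),
    t3 = list(name = "t3", group = "Clp1",
              domains = c("CLP1_EN", "CLP1_P", "CLP1_EUC3"),
              kinase_domain = "CLP1_P", kinase_trunc = 100L,
              ablated_motifs = character()),
    nol9 = list(name = "nol9", group = "Nol9/Grc3",
                domains = c("NOL9_EN", "NOL9_P", "NOL9_EC"),
                kinase_domain = "NOL9_P", kinase_trunc = NA_integer_,
                ablated_motifs = character())
  )
}

lineage_active <- function(lineage, min_length = 130) {
  k <- if (is.na(lineage$kinase_trunc)) 170L else lineage$kinase_trunc
  motifs_present <- vapply(names(CLP1P_MOTIF_SITES), function(m) {
    CLP1P_MOTIF_SITES[[m]][2] <= k && !(m %in% lineage$ablated_motifs)
  }, logical(1))
  all(motifs_present) && k >= min_length
}

#' Simulation configuration
#'
#' The defaults are the stated world emulated throughout the package:
#' 8 species carrying three Clp1-group paralog lineages with distinct
#' C-terminal replacement domains (t1 Clasp-ablated, t2 fully intact, t3
#' with a 100-aa truncated kinase domain) plus one Nol9/Grc3-like lineage;
#' root-to-leaf divergence 0.125 so within-lineage pairwise divergence
#' stays around 25%; no duplications or losses unless configured; 10%
#' isoform probability; five composition-shuffled decoys per species.
#'
#' @param n_species Number of species (>= 2).
#' @param species_tree Optional `phylo` (or newick path); default a random
#'   coalescent tree scaled to height 1.
#' @param lineages List of lineage definitions (see `default_lineages`
#'   inside this file); each has `name`, `group`, `domains`,
#'   `kinase_domain`, `kinase_trunc`, `ablated_motifs`.
#' @param lineage_divergence Substitution fraction separating each lineage
#'   ancestor from the shared templates.
#' @param divergence Expected root-to-leaf substitution fraction per site.
#' @param duplication_prob,loss_prob Per lineage per species event
#'   probabilities.
#' @param indel_prob Per-branch probability of one linker indel.
#' @param indel_mean_len Mean indel length (aa).
#' @param n_decoys Decoy proteins per species.
#' @param isoform_prob Per-gene probability of emitting a truncated
#'   splicing-isoform record.
#' @param isoform_trunc Range (fractions) of the C-terminal truncation.
#' @param seed Integer seed; the whole dataset is a pure function of the
#'   config including this seed.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_species = 8, species_tree = NULL,
                              lineages = default_lineages(),
                              lineage_divergence = 0.15,
                              divergence = 0.125,
                              duplication_prob = 0, loss_prob = 0,
                              indel_prob = 0.3, indel_mean_len = 3,
                              n_decoys = 5, isoform_prob = 0.1,
                              isoform_trunc = c(0.1, 0.4), seed = 1L) {
  rates <- c(lineage_divergence, divergence, duplication_prob, loss_prob,
             indel_prob, isoform_prob)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (n_species < 2) stop("n_species must be >= 2")
  if (length(lineages) < 1) stop("at least one lineage required")
  structure(list(
    n_species = as.integer(n_species), species_tree = species_tree,
    lineages = lineages, lineage_divergence = lineage_divergence,
    divergence = divergence, duplication_prob = duplication_prob,
    loss_prob = loss_prob, indel_prob = indel_prob,
    indel_mean_len = indel_mean_len, n_decoys = as.integer(n_decoys),
    isoform_prob = isoform_prob, isoform_trunc = isoform_trunc,
    seed = as.integer(seed)), class = "sim_config")
}

#' Ablate a PNK motif in one lineage
#'
#' Marks the motif's sites for randomization in that lineage's ancestor;
#' ground truth then records the lineage as PNK-inactive.
#'
#' @param config A [simulation_config()].
#' @param lineage Lineage name present in the config.
#' @param motif One of `WalkerA`, `WalkerB`, `Clasp`, `Lid`.
#' @return The modified config.
#' @export
ablate_motif <- function(config, lineage, motif) {
  if (!motif %in% names(CLP1P_MOTIF_SITES)) stop("unknown motif: ", motif)
  if (!lineage %in% names(config$lineages)) stop("unknown lineage: ", lineage)
  config$lineages[[lineage]]$ablated_motifs <-
    union(config$lineages[[lineage]]$ablated_motifs, motif)
  config
}

# internal sequence state: residues, region label and protection per site
new_state <- function(res, region, prot) {
  list(res = res, region = region, prot = prot)
}

random_residues <- function(n) {
  sample(AA20, n, replace = TRUE, prob = AA_BACKGROUND[AA20])
}

build_lineage_ancestor <- function(lineage, templates, lineage_divergence,
                                   linker_len = 12L, tail_len = 5L) {
  res <- random_residues(tail_len)
  region <- rep("tail", tail_len)
  prot <- rep(FALSE, tail_len)
  for (d in lineage$domains) {
    seqd <- split_residues(templates[[d]])
    protd <- rep(FALSE, length(seqd))
    if (d == lineage$kinase_domain) {
      if (!is.na(lineage$kinase_trunc)) {
        seqd <- seqd[seq_len(lineage$kinase_trunc)]
        protd <- protd[seq_len(lineage$kinase_trunc)]
      }
      for (m in names(CLP1P_MOTIF_SITES)) {
        span <- CLP1P_MOTIF_SITES[[m]]
        if (span[2] > length(seqd)) next
        sites <- span[1]:span[2]
        if (m %in% lineage$ablated_motifs) {
          seqd[sites] <- vapply(seqd[sites], function(a) {
            sample(setdiff(AA20, a), 1)
          }, character(1))
        } else {
          protd[sites] <- TRUE
        }
      }
    }
    res <- c(res, seqd, random_residues(linker_len))
    region <- c(region, rep(d, length(seqd)), rep("linker", linker_len))
    prot <- c(prot, protd, rep(FALSE, linker_len))
  }
  # trailing linker becomes the C-terminal tail
  region[region == "linker" & seq_along(region) > length(region) - linker_len] <- "tail"
  st <- new_state(res, region, prot)
  mutate_state(st, lineage_divergence)
}

mutate_state <- function(st, p) {
  idx <- which(!st$prot)
  hit <- idx[stats::runif(length(idx)) < p]
  if (length(hit) > 0) {
    st$res[hit] <- vapply(st$res[hit], function(a) {
      sample(setdiff(AA20, a), 1)
    }, character(1))
  }
  st
}

# Linkers and tails are fast-evolving and effectively unalignable between
# species: on every branch with nonzero divergence each linker/tail run is
# resampled with a new Poisson length.  This keeps the planted domain
# boundaries the only conserved signal outside domains.
resample_linkers <- function(st, p_resample) {
  if (p_resample <= 0) return(st)
  free <- st$region %in% c("linker", "tail")
  if (!any(free)) return(st)
  runs <- rle(free)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  for (k in rev(which(runs$values))) {
    if (stats::runif(1) >= p_resample) next
    idx <- starts[k]:ends[k]
    new_len <- max(2L, stats::rpois(1, length(idx)))
    lab <- st$region[idx[1]]
    st$res <- append(st$res[-idx], random_residues(new_len),
                     after = idx[1] - 1L)
    st$region <- append(st$region[-idx], rep(lab, new_len),
                        after = idx[1] - 1L)
    st$prot <- append(st$prot[-idx], rep(FALSE, new_len),
                      after = idx[1] - 1L)
  }
  st
}

apply_indel <- function(st, mean_len) {
  free <- which(st$region %in% c("linker", "tail"))
  if (length(free) < 2) return(st)
  len <- max(1L, stats::rpois(1, mean_len))
  at <- sample(free, 1)
  if (stats::runif(1) < 0.5) {  # insertion after `at`
    ins <- random_residues(len)
    st$res <- append(st$res, ins, after = at)
    st$region <- append(st$region, rep(st$region[at], len), after = at)
    st$prot <- append(st$prot, rep(FALSE, len), after = at)
  } else {                      # deletion within the same free run
    run <- free[free >= at & free < at + len]
    run <- run[seq_len(min(length(run), len))]
    if (length(run) > 0 && length(run) < length(st$res)) {
      st$res <- st$res[-run]
      st$region <- st$region[-run]
      st$prot <- st$prot[-run]
    }
  }
  st
}

state_domains <- function(st) {
  keep <- !(st$region %in% c("linker", "tail"))
  if (!any(keep)) {
    return(tibble::tibble(domain = character(), start = integer(),
                          end = integer()))
  }
  pos <- seq_along(st$region)
  tibble::tibble(domain = st$region[keep], position = pos[keep]) |>
    dplyr::group_by(.data$domain) |>
    dplyr::summarise(start = min(.data$position), end = max(.data$position),
                     .groups = "drop") |>
    dplyr::arrange(.data$start)
}

#' Simulate a multi-species proteome dataset with planted ground truth
#'
#' Lineage ancestors assembled from the domain templates are evolved down
#' a species tree (site substitutions with motif sites protected unless
#' ablated, indels confined to linkers/tails), then duplications, losses,
#' splicing-isoform records and composition-shuffled decoys are applied.
#' Fully reproducible: the same config (including seed) yields a
#' byte-identical dataset.
#'
#' @param config A [simulation_config()].
#' @return A `clp1_sim` list: `records` (tibble of all emitted proteins),
#'   `truth` (one row per record), `truth_domains` (planted domain
#'   coordinates), `queries_full`/`queries_domain` (lineage-ancestor
#'   seeds), `anchors` (named id -> group vector), `species_tree`,
#'   `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  templates <- domain_templates()
  withr::with_seed(config$seed, {
    tree <- config$species_tree
    if (is.character(tree)) tree <- ape::read.tree(tree)
    if (is.null(tree)) tree <- ape::rcoal(config$n_species)
    tree$tip.label <- sprintf("SP%02d", seq_len(config$n_species))
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length / depth

    species <- tree$tip.label
    taxa <- stats::setNames(
      rep(c("TaxonA", "TaxonB"), length.out = length(species)), species)

    records <- list()
    truth <- list()
    truth_domains <- list()
    queries_full <- list()
    queries_domain <- list()
    counter <- 0L

    for (lin in config$lineages) {
      anc <- build_lineage_ancestor(lin, templates, config$lineage_divergence)
      queries_full[[lin$name]] <- paste(anc$res, collapse = "")
      kin <- state_domains(anc)
      kin <- kin[kin$domain == lin$kinase_domain, ]
      queries_domain[[lin$name]] <-
        substr(queries_full[[lin$name]], kin$start[1], kin$end[1])

      # evolve along the tree (preorder over edges)
      states <- list()
      states[[as.character(length(species) + 1L)]] <- anc
      eord <- ape::reorder.phylo(tree, "cladewise")
      for (e in seq_len(nrow(eord$edge))) {
        parent <- as.character(eord$edge[e, 1])
        child <- eord$edge[e, 2]
        p_branch <- config$divergence * eord$edge.length[e]
        st <- mutate_state(states[[parent]], p_branch)
        st <- resample_linkers(st, as.numeric(p_branch > 0))
        if (stats::runif(1) < config$indel_prob) {
          st <- apply_indel(st, config$indel_mean_len)
        }
        states[[as.character(child)]] <- st
      }

      for (si in seq_along(species)) {
        sp <- species[si]
        if (stats::runif(1) < config$loss_prob) next
        n_copies <- 1L + (stats::runif(1) < config$duplication_prob)
        for (copy in seq_len(n_copies)) {
          st <- states[[as.character(si)]]
          if (copy > 1) st <- mutate_state(st, 0.02)
          counter <- counter + 1L
          gid <- sprintf("SYN%04d", counter)
          emitted <- emit_protein(st, gid, sp, taxa[[sp]], lin, config)
          records <- c(records, emitted$records)
          truth <- c(truth, emitted$truth)
          truth_domains <- c(truth_domains, emitted$domains)
        }
      }
    }

    # decoys: composition-preserving shuffles of the concatenated templates
    pool <- split_residues(paste(unlist(templates), collapse = ""))
    for (sp in species) {
      for (k in seq_len(config$n_decoys)) {
        counter <- counter + 1L
        gid <- sprintf("SYN%04d", counter)
        len <- sample(200:600, 1)
        seqs <- paste(sample(pool, len), collapse = "")
        records[[gid]] <- tibble::tibble(
          id = gid, species = sp, taxon = taxa[[sp]], sequence = seqs,
          description = "hypothetical protein", is_isoform = FALSE,
          gene_id = gid)
        truth[[gid]] <- tibble::tibble(
          id = gid, species = sp, taxon = taxa[[sp]], gene_id = gid,
          lineage = NA_character_, group = NA_character_,
          architecture = "", clp1p_length = NA_integer_,
          active = NA, isoform_parent = NA_character_, is_decoy = TRUE)
      }
    }

    records <- dplyr::bind_rows(records)
    truth <- dplyr::bind_rows(truth)
    truth_domains <- dplyr::bind_rows(truth_domains)
    anchors <- truth |>
      dplyr::filter(!.data$is_decoy, is.na(.data$isoform_parent)) |>
      dplyr::group_by(.data$lineage) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
    anchor_vec <- stats::setNames(anchors$group, anchors$id)

    structure(list(
      records = records, truth = truth, truth_domains = truth_domains,
      queries_full = tibble::tibble(
        id = paste0("Q_", names(queries_full)),
        sequence = unlist(unname(queries_full))),
      queries_domain = tibble::tibble(
        id = paste0("Q_", names(queries_domain), "_P"),
        sequence = unlist(unname(queries_domain))),
      anchors = anchor_vec, species_tree = tree, config = config),
      class = "clp1_sim")
  })
}

# One gene (plus a possible isoform record) from an evolved state.
emit_protein <- function(st, gid, sp, taxon, lin, config) {
  doms <- state_domains(st)
  kin <- doms[doms$domain == lin$kinase_domain, ]
  motif_ok <- motif_truth(lin)
  active <- lineage_active(lin)
  seqs <- paste(st$res, collapse = "")
  rec <- tibble::tibble(
    id = gid, species = sp, taxon = taxon, sequence = seqs,
    description = sprintf("%s family protein lineage %s", lin$group, lin$name),
    is_isoform = FALSE, gene_id = gid)
  tr <- tibble::tibble(
    id = gid, species = sp, taxon = taxon, gene_id = gid,
    lineage = lin$name, group = lin$group,
    architecture = paste(doms$domain, collapse = "|"),
    clp1p_length = if (nrow(kin)) as.integer(kin$end[1] - kin$start[1] + 1)
                   else NA_integer_,
    active = active, isoform_parent = NA_character_, is_decoy = FALSE)
  dom_rows <- dplyr::mutate(doms, id = gid, .before = 1)
  recs <- list(rec)
  trs <- list(tr)
  names(recs) <- names(trs) <- gid

  if (stats::runif(1) < config$isoform_prob) {
    frac <- stats::runif(1, config$isoform_trunc[1], config$isoform_trunc[2])
    cut <- max(50L, as.integer(length(st$res) * (1 - frac)))
    iso_id <- paste0(gid, "_i1")
    iso_doms <- doms |>
      dplyr::filter(.data$start <= cut) |>
      dplyr::mutate(end = pmin(.data$end, cut))
    iso_kin <- iso_doms[iso_doms$domain == lin$kinase_domain, ]
    iso_kin_len <- if (nrow(iso_kin)) {
      as.integer(iso_kin$end[1] - iso_kin$start[1] + 1)
    } else {
      NA_integer_
    }
    motifs_kept <- if (nrow(iso_kin)) {
      vapply(names(CLP1P_MOTIF_SITES), function(m) {
        motif_ok[[m]] &&
          (iso_kin$start[1] + CLP1P_MOTIF_SITES[[m]][2] - 1) <= cut
      }, logical(1))
    } else {
      stats::setNames(rep(FALSE, 4), names(CLP1P_MOTIF_SITES))
    }
    iso_active <- !is.na(iso_kin_len) && all(motifs_kept) &&
      iso_kin_len >= 130
    recs[[iso_id]] <- tibble::tibble(
      id = iso_id, species = sp, taxon = taxon,
      sequence = substr(seqs, 1, cut),
      description = sprintf("%s family protein lineage %s isoform X1",
                            lin$group, lin$name),
      is_isoform = TRUE, gene_id = gid)
    trs[[iso_id]] <- tibble::tibble(
      id = iso_id, species = sp, taxon = taxon, gene_id = gid,
      lineage = lin$name, group = lin$group,
      architecture = paste(iso_doms$domain, collapse = "|"),
      clp1p_length = iso_kin_len, active = iso_active,
      isoform_parent = gid, is_decoy = FALSE)
    dom_rows <- dplyr::bind_rows(
      dom_rows, dplyr::mutate(iso_doms, id = iso_id, .before = 1))
  }
  list(records = recs, truth = trs, domains = list(dom_rows))
}

motif_truth <- function(lin) {
  k <- if (is.na(lin$kinase_trunc)) 170L else lin$kinase_trunc
  vapply(names(CLP1P_MOTIF_SITES), function(m) {
    CLP1P_MOTIF_SITES[[m]][2] <= k && !(m %in% lin$ablated_motifs)
  }, logical(1))
}

#' @export
print.clp1_sim <- function(x, ...) {
  cat("<clp1_sim> ", nrow(x$records), " records (",
      sum(!x$truth$is_decoy), " family, ", sum(x$truth$is_decoy),
      " decoys) across ", x$config$n_species, " species\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Per-species FASTA files, a metadata/ground-truth TSV, the species tree
#' (newick) and the query seeds, matching the pipeline's input contract.
#'
#' @param sim A `clp1_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in unique(sim$records$species)) {
    write_fasta(sim$records[sim$records$species == sp, ],
                file.path(dir, paste0(sp, ".fasta")))
  }
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  readr::write_tsv(
    dplyr::select(sim$records, "id", "species", "taxon", "gene_id"),
    file.path(dir, "metadata.tsv"))
  write_tree_newick(sim$species_tree, file.path(dir, "species_tree.nwk"))
  write_fasta(sim$queries_full, file.path(dir, "queries_full.fasta"))
  write_fasta(sim$queries_domain, file.path(dir, "queries_domain.fasta"))
  readr::write_tsv(
    tibble::tibble(id = names(sim$anchors), group = unname(sim$anchors)),
    file.path(dir, "anchors.tsv"))
  invisible(dir)
}
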