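# End-to-end orchestration: identification -> inventory -> clustering ->
# alignment/trees -> domain annotation -> classification -> reporting.

#' Default domain profiles from the template library
#'
#' Builds calibrated scoring profiles for the known domains (the kinase
#' domains and the conserved N-/C-terminal flanking domains).  The
#' lineage-specific C-terminal replacement domains are deliberately not
#' modelled: discovering them de novo is the point of the novel-domain
#' stage.  Seed alignments are diverged copies of each template
#' (deterministic for a fixed seed).
#'
#' @param n_seed Sequences per seed alignment.
#' @param divergence Substitution fraction of the seed copies.
#' @param seed Integer seed.
#' @return Named list of `domain_profile` objects.
#' @export
default_profiles <- function(n_seed = 6, divergence = 0.15, seed = 7L) {
  known <- c("CLP1_EN", "CLP1_P", "CLP1_EC", "NOL9_P", "NOL9_EN", "NOL9_EC")
  templates <- domain_templates()
  out <- lapply(known, function(nm) {
    aln <- template_seed_alignment(nm, templates[[nm]], n_seed, divergence,
                                   seed)
    build_profile(aln, nm, seed = seed)
  })
  stats::setNames(out, known)
}

template_seed_alignment <- function(name, template, n_seed, divergence,
                                    seed) {
  rows <- withr::with_seed(seed + utf8ToInt(substr(name, nchar(name), nchar(name))), {
    vapply(seq_len(n_seed), function(i) {
      res <- split_residues(template)
      hit <- which(stats::runif(length(res)) < divergence)
      res[hit] <- vapply(res[hit], function(a) sample(setdiff(AA20, a), 1), "")
      paste(res, collapse = "")
    }, character(1))
  })
  new_msa(paste0(name, "_seed", seq_len(n_seed)), rows)
}

# Domain names treated as the kinase (Clp1_P) domain when locating spans.
KINASE_DOMAINS <- c("CLP1_P", "NOL9_P")

#' Pipeline configuration
#'
#' Collects all stage parameters.  Inputs can be in-memory tibbles (from
#' [simulate_dataset()]) or paths (per-species FASTA directory plus
#' metadata, query FASTAs, anchor TSV).  Paths are validated here, before
#' any compute.
#'
#' @param records Record tibble, or a directory of per-species FASTA files
#'   with a `metadata.tsv`.
#' @param queries_full,queries_domain Record tibbles or FASTA paths.
#' @param anchors Named character vector (id -> group) or a two-column TSV.
#' @param search A [search_params()].
#' @param cluster_threshold Greedy-clustering identity threshold.
#' @param trim_gap_fraction Column gap-fraction tolerance before trees.
#' @param bootstrap_reps Bootstrap replicates for the kinase-domain tree
#'   (0 disables).
#' @param profiles Named list of `domain_profile`s (default
#'   [default_profiles()], built lazily at run time).
#' @param profile_evalue_max Domain-scan E-value threshold.
#' @param novel_min_len Minimum unannotated-segment length.
#' @param novel_min_members,novel_min_species Novel-domain acceptance.
#' @param motifs Motif models ([motif_models()]).
#' @param seed Integer seed for all stochastic steps.
#' @param out_dir Optional output directory for persisted artifacts and
#'   the JSON run manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(records, queries_full, queries_domain, anchors,
                            search = search_params(),
                            cluster_threshold = 0.70,
                            trim_gap_fraction = 0,
                            bootstrap_reps = 100,
                            profiles = NULL,
                            profile_evalue_max = 1e-3,
                            novel_min_len = 50,
                            novel_min_members = 3, novel_min_species = 3,
                            motifs = motif_models(),
                            seed = 1L, out_dir = NULL) {
  for (p in list(records, queries_full, queries_domain)) {
    if (is.character(p) && !file.exists(p)) stop("path not found: ", p)
  }
  if (is.character(anchors) && length(anchors) == 1 && !file.exists(anchors)) {
    stop("anchor file not found: ", anchors)
  }
  stopifnot(cluster_threshold > 0, cluster_threshold <= 1,
            trim_gap_fraction >= 0, trim_gap_fraction < 1,
            bootstrap_reps >= 0, profile_evalue_max > 0)
  structure(list(records = records, queries_full = queries_full,
                 queries_domain = queries_domain, anchors = anchors,
                 search = search, cluster_threshold = cluster_threshold,
                 trim_gap_fraction = trim_gap_fraction,
                 bootstrap_reps = bootstrap_reps, profiles = profiles,
                 profile_evalue_max = profile_evalue_max,
                 novel_min_len = novel_min_len,
                 novel_min_members = novel_min_members,
                 novel_min_species = novel_min_species,
                 motifs = motifs, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

load_pipeline_inputs <- function(config) {
  rec <- config$records
  if (is.character(rec)) {
    meta <- file.path(rec, "metadata.tsv")
    fastas <- list.files(rec, pattern = "\\.fasta$", full.names = TRUE)
    fastas <- fastas[!grepl("queries", basename(fastas))]
    rec <- purrr::map_dfr(sort(fastas), read_fasta,
                          metadata = if (file.exists(meta)) meta else NULL)
  }
  qf <- config$queries_full
  if (is.character(qf)) qf <- read_fasta(qf)
  qd <- config$queries_domain
  if (is.character(qd)) qd <- read_fasta(qd)
  anchors <- config$anchors
  if (is.character(anchors) && is.null(names(anchors))) {
    tab <- readr::read_tsv(anchors[1], show_col_types = FALSE)
    anchors <- stats::setNames(tab$group, tab$id)
  }
  list(records = rec, queries_full = qf, queries_domain = qd,
       anchors = anchors)
}

#' Run the full classification pipeline
#'
#' Stages, in the order of the underlying analysis: dual-query homolog
#' search; per-species inventory with isoform collapsing; greedy
#' clustering of the gene representatives; profile domain scan plus novel
#' domain discovery and architecture assembly; kinase-domain tree
#' (progressive MSA, gap trimming, NJ, optional bootstrap, midpoint
#' rooting) and anchor-based group split; per-group full-length trees and
#' type / letter-suffix assignment; motif scanning and activity
#' prediction; report tables.  With `out_dir` set, every intermediate
#' artifact is persisted as plain TSV/FASTA/newick plus a JSON manifest,
#' and re-running the same config reproduces identical outputs.
#'
#' @param config A [pipeline_config()] (or a `clp1_sim`, as a shortcut
#'   that uses its records, queries and anchors with default parameters).
#' @param ... Passed to [pipeline_config()] when `config` is a `clp1_sim`.
#' @return A `clp1_pipeline` object; see [tidy.clp1_pipeline()] /
#'   [glance.clp1_pipeline()].
#' @export
run_pipeline <- function(config, ...) {
  if (inherits(config, "clp1_sim")) {
    config <- pipeline_config(records = config$records,
                              queries_full = config$queries_full,
                              queries_domain = config$queries_domain,
                              anchors = config$anchors, ...)
  }
  stopifnot(inherits(config, "pipeline_config"))
  inputs <- load_pipeline_inputs(config)
  records <- validate_records(inputs$records)

  withr::with_seed(config$seed, {
    ## identification
    hits <- dual_query_search(inputs$queries_full, inputs$queries_domain,
                              records, config$search)
    inventory <- build_inventory(hits, records)
    members <- records[records$id %in%
                         unlist(inventory$representative_ids), , drop = FALSE]

    ## clustering (reported artifact; trees use all members)
    clusters <- if (nrow(members) >= 2) {
      greedy_cluster(members, config$cluster_threshold, config$search$scheme)
    } else {
      NULL
    }

    ## domain annotation
    profiles <- config$profiles
    if (is.null(profiles)) profiles <- default_profiles()
    profile_hits <- purrr::map_dfr(seq_len(nrow(members)), function(i) {
      scan_profiles(members[i, ], profiles, config$profile_evalue_max,
                    db_size = nrow(members))
    })
    segments <- purrr::map_dfr(seq_len(nrow(members)), function(i) {
      unannotated_segments(members[i, ],
                           profile_hits[profile_hits$protein_id ==
                                          members$id[[i]], , drop = FALSE],
                           config$novel_min_len)
    })
    novel <- discover_novel_domains(segments, members, config$search,
                                    config$novel_min_members,
                                    config$novel_min_species)
    arch <- purrr::map(seq_len(nrow(members)), function(i) {
      assemble_architecture(members[i, ], profile_hits,
                            dplyr::select(novel, -"n_members", -"n_species",
                                          -"mean_length", -"sd_length"))
    })
    architectures <- stats::setNames(
      vapply(arch, `[[`, character(1), "architecture"), members$id)
    domain_hits <- purrr::map_dfr(arch, "hits")

    ## kinase spans
    clp1p_spans <- stats::setNames(
      purrr::map(members$id, function(id) {
        h <- domain_hits[domain_hits$protein_id == id &
                           domain_hits$domain_name %in% KINASE_DOMAINS, ,
                         drop = FALSE]
        if (nrow(h) == 0) return(NULL)
        h <- h[which.max(h$score), ]
        list(sequence = substr(members$sequence[[match(id, members$id)]],
                               h$start, h$end),
             length = h$end - h$start + 1, start = h$start, end = h$end)
      }), members$id)

    ## kinase-domain tree and group split
    span_rec <- tibble::tibble(
      id = members$id,
      sequence = vapply(members$id, function(i) {
        s <- clp1p_spans[[i]]
        if (is.null(s)) NA_character_ else s$sequence
      }, character(1))) |>
      dplyr::filter(!is.na(.data$sequence))
    p_tree <- NULL
    groups <- tibble::tibble(protein_id = character(), group = character())
    if (nrow(span_rec) >= 3) {
      p_aln <- progressive_msa(span_rec, config$search$scheme)
      p_trim <- trim_alignment(p_aln, config$trim_gap_fraction)
      p_tree <- if (config$bootstrap_reps > 0) {
        bootstrap_support(p_trim, config$bootstrap_reps, config$seed)
      } else {
        nj_tree(alignment_distances(p_trim))
      }
      p_tree <- midpoint_root(p_tree)
      anchors <- inputs$anchors[names(inputs$anchors) %in% p_tree$tip.label]
      groups <- split_groups(p_tree, anchors)
    }
    groups_full <- tibble::tibble(protein_id = members$id) |>
      dplyr::left_join(groups, by = "protein_id") |>
      dplyr::mutate(group = dplyr::coalesce(.data$group, "unknown"))

    ## per-group trees and type assignment
    species_map <- stats::setNames(members$species, members$id)
    types <- purrr::map_dfr(
      setdiff(unique(groups_full$group), "unknown"), function(g) {
        ids <- groups_full$protein_id[groups_full$group == g]
        ids <- ids[order(match(ids, members$id))]
        if (length(ids) < 3) {
          return(tibble::tibble(protein_id = ids,
                                type_label = NA_character_,
                                letter_suffix = NA_character_,
                                duplicate_flag = FALSE))
        }
        g_rec <- members[match(ids, members$id), ]
        g_aln <- progressive_msa(g_rec, config$search$scheme)
        g_trim <- trim_alignment(g_aln, max(config$trim_gap_fraction, 0.5))
        D <- alignment_distances(g_trim)
        # identical members give an all-zero matrix: fall back to a star
        g_tree <- if (max(D) > 0) {
          midpoint_root(nj_tree(D))
        } else {
          star_tree(ids)
        }
        assign_types(ids, g_tree, architectures, species_map)
      })

    ## calls, matrix, report
    calls <- family_calls(members, groups_full, types, architectures,
                          clp1p_spans, config$motifs)
    id_matrix <- if (nrow(members) >= 2 && nrow(members) <= 60) {
      identity_matrix(members)
    } else {
      NULL
    }
    report <- report_tables(calls, inventory, id_matrix, records)

    result <- structure(
      list(records = records, hits = hits, inventory = inventory,
           members = members, clusters = clusters,
           profile_hits = profile_hits, novel = novel,
           domain_hits = domain_hits, architectures = architectures,
           clp1p_spans = clp1p_spans, p_tree = p_tree,
           groups = groups_full, types = types, calls = calls,
           id_matrix = id_matrix, report = report, config = config),
      class = "clp1_pipeline")
    if (!is.null(config$out_dir)) persist_pipeline(result, config$out_dir)
    result
  })
}

#' @export
print.clp1_pipeline <- function(x, ...) {
  cat("<clp1_pipeline> ", nrow(x$hits), " family records across ",
      sum(x$inventory$n_genes > 0), " species; ",
      nrow(x$members), " genes; ",
      dplyr::n_distinct(x$novel$domain_name), " novel domains\n", sep = "")
  cat(" ", x$report$summary_line, "\n")
  invisible(x)
}

persist_pipeline <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) readr::write_tsv(df, file.path(out_dir, name))
  write_hits_tsv(result$hits, file.path(out_dir, "hits.tsv"))
  w(dplyr::select(result$inventory, -"member_ids", -"representative_ids"),
    "inventory.tsv")
  if (!is.null(result$clusters)) w(result$clusters, "clusters.tsv")
  write_domain_tsv(result$domain_hits, file.path(out_dir, "domains.tsv"))
  w(result$report$table1, "table1_calls.tsv")
  if (!is.null(result$id_matrix)) w(result$id_matrix, "table2_matrix.tsv")
  w(result$report$histogram, "gene_count_histogram.tsv")
  if (!is.null(result$p_tree)) {
    write_tree_newick(result$p_tree, file.path(out_dir, "clp1p_tree.nwk"))
  }
  files <- sort(list.files(out_dir, full.names = TRUE))
  manifest <- list(
    package = "clp1family",
    version = as.character(utils::packageVersion("clp1family")),
    seed = result$config$seed,
    parameters = list(
      evalue_max = result$config$search$evalue_max,
      coverage_min = result$config$search$coverage_min,
      cluster_threshold = result$config$cluster_threshold,
      trim_gap_fraction = result$config$trim_gap_fraction,
      bootstrap_reps = result$config$bootstrap_reps,
      profile_evalue_max = result$config$profile_evalue_max,
      novel_min_members = result$config$novel_min_members,
      novel_min_species = result$config$novel_min_species),
    n_records = nrow(result$records),
    n_family = nrow(result$hits),
    output_md5 = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Publication-style report tables
#'
#' Builds the per-protein classification table (species, decorated protein
#' name, accession, length, group, type, isoform count), passes through
#' the identity/similarity matrix, and summarises gene counts per species
#' as a per-taxon histogram plus a `mean +/- SD` line (population SD).
#'
#' @param calls Output of [family_calls()].
#' @param inventory Output of [build_inventory()].
#' @param id_matrix Output of [identity_matrix()] (or `NULL`).
#' @param records Full record tibble (for isoform counts); optional.
#' @return List with `table1`, `table2`, `histogram`, `summary_line`.
#' @export
report_tables <- function(calls, inventory, id_matrix = NULL,
                          records = NULL) {
  if (nrow(calls) == 0) warning("no family calls: emitting empty tables")
  n_iso <- if (!is.null(records) && "gene_id" %in% names(records)) {
    iso <- records |>
      dplyr::filter(.data$is_isoform) |>
      dplyr::count(.data$gene_id)
    stats::setNames(iso$n, iso$gene_id)
  } else {
    integer()
  }
  table1 <- calls |>
    dplyr::transmute(
      taxon = NA_character_, species = .data$species,
      protein_name = .data$protein_name, accession = .data$protein_id,
      aa_length = .data$length, group = .data$group,
      type = dplyr::coalesce(.data$type_label, .data$letter_suffix),
      n_isoforms = dplyr::coalesce(
        unname(n_iso[.data$protein_id]), 0L),
      predicted_activity = .data$predicted_activity)
  if (!is.null(records) && "taxon" %in% names(records)) {
    table1$taxon <- records$taxon[match(table1$accession, records$id)]
  }
  taxon_map <- if (!is.null(records) && "taxon" %in% names(records)) {
    stats::setNames(records$taxon, records$species)
  } else {
    NULL
  }
  histogram <- inventory |>
    tibble::as_tibble() |>
    dplyr::mutate(taxon = if (is.null(taxon_map)) "all" else
      unname(taxon_map[.data$species])) |>
    dplyr::count(.data$taxon, .data$n_genes, name = "n_species")
  m <- attr(inventory, "mean_genes")
  s <- attr(inventory, "sd_genes")
  summary_line <- if (is.null(m) || is.na(m)) {
    "no family members detected"
  } else {
    sprintf("%.1f \u00b1 %.1f proteins per species on average", m, s)
  }
  list(table1 = table1, table2 = id_matrix, histogram = histogram,
       summary_line = summary_line)
}
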