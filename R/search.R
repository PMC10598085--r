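#' Homolog-search parameters
#'
#' Thresholds and statistics for the seeded family search: hits must reach
#' `evalue_max` (default 1e-4) and cover at least `coverage_min` (default
#' 30%) of the query.  `db_size_policy` controls the Karlin--Altschul search
#' space: `"db"` uses m = query length, n = total residues in the database
#' (BLAST-like); `"pair"` uses the single target length.
#'
#' @param evalue_max Maximum E-value.
#' @param coverage_min Minimum aligned fraction of the query (per best HSP).
#' @param scheme A [scoring_scheme()].
#' @param seed_word_length Minimum query length (word size analogue).
#' @param db_size_policy `"db"` or `"pair"`.
#' @return A `search_params` object.
#' @export
search_params <- function(evalue_max = 1e-4, coverage_min = 0.30,
                          scheme = scoring_scheme(), seed_word_length = 3L,
                          db_size_policy = c("db", "pair")) {
  stopifnot(evalue_max > 0, coverage_min > 0, coverage_min <= 1)
  structure(list(evalue_max = evalue_max, coverage_min = coverage_min,
                 scheme = scheme, seed_word_length = as.integer(seed_word_length),
                 db_size_policy = match.arg(db_size_policy)),
            class = "search_params")
}

#' Karlin--Altschul E-value and bit score
#'
#' `E = K * m * n * exp(-lambda * S)`; bit score
#' `S' = (lambda * S - ln K) / ln 2`.
#'
#' @param raw_score Integer raw alignment score.
#' @param m Query length (residues).
#' @param n Search-space residue count.
#' @param scheme A [scoring_scheme()] carrying `lambda` and `K`.
#' @return Tibble with `evalue` and `bit_score`.
#' @export
evalue_ka <- function(raw_score, m, n, scheme = scoring_scheme()) {
  if (any(m < 1) || any(n < 1)) stop("m and n must be >= 1")
  tibble::tibble(
    evalue = scheme$K * m * n * exp(-scheme$lambda * raw_score),
    bit_score = (scheme$lambda * raw_score - log(scheme$K)) / log(2)
  )
}

#' Local-alignment search of one query against a protein database
#'
#' For each database sequence the single best-scoring gapped local alignment
#' (exact affine Smith--Waterman, one HSP per target) is computed; hits
#' failing the E-value or query-coverage thresholds are dropped.  Coverage
#' is measured on the query: `(q_end - q_start + 1) / query length`.
#'
#' @param query One-row record tibble (or list with `id`, `sequence`).
#' @param db Record tibble (the database).
#' @param params A [search_params()].
#' @return Tibble of hits sorted by ascending E-value (ties by `target_id`):
#'   `query_id`, `target_id`, `raw_score`, `bit_score`, `evalue`,
#'   `identity_pct`, `positive_pct`, `coverage`, `q_start`, `q_end`,
#'   `t_start`, `t_end`, `align_len`.
#' @export
search_local <- function(query, db, params = search_params()) {
  validate_records(db)
  qseq <- query$sequence[[1]]
  qid <- query$id[[1]]
  if (nchar(qseq) < params$seed_word_length) {
    stop("query '", qid, "' shorter than seed word length")
  }
  if (nrow(db) == 0) stop("empty database")
  m <- nchar(qseq)
  n_total <- sum(nchar(db$sequence))
  hits <- purrr::map_dfr(seq_len(nrow(db)), function(i) {
    aln <- align_pair(qseq, db$sequence[[i]], params$scheme, local = TRUE)
    if (aln$score <= 0) return(NULL)
    n <- if (params$db_size_policy == "db") n_total else nchar(db$sequence[[i]])
    ka <- evalue_ka(aln$score, m, n, params$scheme)
    pcts <- percent_identity_similarity(
      list(aligned_query = aln$aligned_query,
           aligned_target = aln$aligned_target),
      params$scheme)
    tibble::tibble(
      query_id = qid, target_id = db$id[[i]],
      raw_score = aln$score, bit_score = ka$bit_score, evalue = ka$evalue,
      identity_pct = unname(pcts["identity"]),
      positive_pct = unname(pcts["similarity"]),
      coverage = (aln$q_end - aln$q_start + 1) / m,
      q_start = aln$q_start, q_end = aln$q_end,
      t_start = aln$t_start, t_end = aln$t_end,
      align_len = nchar(aln$aligned_query)
    )
  })
  if (nrow(hits) == 0) return(empty_hits())
  hits <- dplyr::filter(hits, .data$evalue <= params$evalue_max,
                        .data$coverage >= params$coverage_min)
  dplyr::arrange(hits, .data$evalue, .data$target_id)
}

empty_hits <- function() {
  tibble::tibble(query_id = character(), target_id = character(),
                 raw_score = numeric(), bit_score = numeric(),
                 evalue = numeric(), identity_pct = numeric(),
                 positive_pct = numeric(), coverage = numeric(),
                 q_start = integer(), q_end = integer(),
                 t_start = integer(), t_end = integer(),
                 align_len = integer())
}

#' Dual-query family search with duplicate-free merging
#'
#' Runs [search_local()] for every full-length query and every
#' kinase-domain query, then merges the per-query hit sets by target: each
#' target appears once, annotated with its best (lowest E-value, ties by
#' query id) supporting hit and which query class(es) found it.
#'
#' @param full_queries,domain_queries Record tibbles (either may be empty,
#'   not both).
#' @param db Record tibble to search.
#' @param params A [search_params()].
#' @return Tibble: one row per detected target, columns of [search_local()]
#'   plus `query_class` (`"full"`, `"domain"` or `"full+domain"`), sorted by
#'   ascending E-value then target id.
#' @export
dual_query_search <- function(full_queries, domain_queries, db,
                              params = search_params()) {
  if (nrow(db) == 0) stop("empty database")
  n_full <- if (is.null(full_queries)) 0 else nrow(full_queries)
  n_dom <- if (is.null(domain_queries)) 0 else nrow(domain_queries)
  if (n_full + n_dom == 0) stop("at least one query list must be non-empty")
  run_class <- function(queries, label) {
    if (is.null(queries) || nrow(queries) == 0) return(NULL)
    purrr::map_dfr(seq_len(nrow(queries)), function(i) {
      dplyr::mutate(search_local(queries[i, ], db, params),
                    query_class = label)
    })
  }
  hits <- dplyr::bind_rows(run_class(full_queries, "full"),
                           run_class(domain_queries, "domain"))
  if (nrow(hits) == 0) {
    return(dplyr::mutate(empty_hits(), query_class = character()))
  }
  classes <- hits |>
    dplyr::group_by(.data$target_id) |>
    dplyr::summarise(
      query_class = paste(intersect(c("full", "domain"),
                                    unique(.data$query_class)),
                          collapse = "+"),
      .groups = "drop")
  best <- hits |>
    dplyr::group_by(.data$target_id) |>
    dplyr::arrange(.data$evalue, .data$query_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select(-"query_class")
  dplyr::left_join(best, classes, by = "target_id") |>
    dplyr::arrange(.data$evalue, .data$target_id)
}

#' Per-species family inventory
#'
#' Counts family records and isoform-collapsed genes per species.  Records
#' sharing a `gene_id` (or an isoform flag tying them to a parent) collapse
#' to one gene represented by the longest member.  Species present in
#' `records` but without hits are listed with zero counts.  The summary
#' attribute reports mean and population SD of genes per species over
#' species with at least one member.
#'
#' @param hits Hit tibble ([dual_query_search()] output) whose `target_id`s
#'   resolve to `records`.
#' @param records Record tibble with `species` (and ideally `gene_id`).
#' @return Tibble with `species`, `n_family_records`, `n_genes`,
#'   `member_ids` (list), `representative_ids` (list); attributes
#'   `mean_genes`, `sd_genes` (also via [summary()]).
#' @export
build_inventory <- function(hits, records) {
  validate_records(records)
  unknown <- setdiff(hits$target_id, records$id)
  if (length(unknown) > 0) {
    stop("hit(s) reference unknown record id(s): ",
         paste(unknown, collapse = ", "))
  }
  rec <- tibble::as_tibble(records)
  if (!"gene_id" %in% names(rec)) rec$gene_id <- rec$id
  rec$gene_id <- dplyr::coalesce(rec$gene_id, rec$id)
  members <- rec[rec$id %in% hits$target_id, , drop = FALSE]
  species_all <- sort(unique(rec$species))
  per_species <- members |>
    dplyr::mutate(len = nchar(.data$sequence)) |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      n_family_records = dplyr::n(),
      n_genes = dplyr::n_distinct(.data$gene_id),
      member_ids = list(sort(.data$id)),
      representative_ids = list({
        d <- dplyr::arrange(dplyr::pick(dplyr::everything()),
                            dplyr::desc(.data$len), .data$id)
        d$id[!duplicated(d$gene_id)]
      }),
      .groups = "drop")
  inv <- tibble::tibble(species = species_all) |>
    dplyr::left_join(per_species, by = "species") |>
    dplyr::mutate(
      n_family_records = dplyr::coalesce(.data$n_family_records, 0L),
      n_genes = dplyr::coalesce(.data$n_genes, 0L),
      member_ids = purrr::map(.data$member_ids, ~ .x %||% character()),
      representative_ids = purrr::map(.data$representative_ids,
                                      ~ .x %||% character()))
  nz <- inv$n_genes[inv$n_genes > 0]
  attr(inv, "mean_genes") <- if (length(nz)) mean(nz) else NA_real_
  attr(inv, "sd_genes") <- if (length(nz)) sqrt(mean((nz - mean(nz))^2)) else NA_real_
  class(inv) <- c("clp1_inventory", class(inv))
  inv
}

#' @export
summary.clp1_inventory <- function(object, ...) {
  m <- attr(object, "mean_genes")
  s <- attr(object, "sd_genes")
  line <- if (is.na(m)) {
    "no family members detected"
  } else {
    sprintf("%.1f \u00b1 %.1f genes per species (n = %d species with >= 1 member)",
            m, s, sum(object$n_genes > 0))
  }
  cat(line, "\n")
  invisible(c(mean = m, sd = s))
}

#' Write hits as a 12-column BLAST outfmt-6 style TSV
#'
#' Columns: qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend,
#' sstart, send, evalue, bitscore.  `mismatch`/`gapopen` are derived from
#' the stored alignment summary (mismatches = aligned residue pairs that are
#' not identical).
#'
#' @param hits Hit tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  out <- tibble::tibble(
    qseqid = hits$query_id, sseqid = hits$target_id,
    pident = hits$identity_pct, length = hits$align_len,
    mismatch = pmax(0L, as.integer(round(
      hits$align_len * (100 - hits$identity_pct) / 100))),
    gapopen = 0L,
    qstart = hits$q_start, qend = hits$q_end,
    sstart = hits$t_start, send = hits$t_end,
    evalue = signif(hits$evalue, 3), bitscore = round(hits$bit_score, 1))
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}
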