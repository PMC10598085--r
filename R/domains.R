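#' Build a position-specific scoring profile from a seed alignment
#'
#' Per-column log-odds of residue frequencies (background-proportional
#' pseudocounts) against the background distribution, in natural-log units.
#' Columns with more than 50% gaps are excluded from the model.  The null
#' score distribution used for E-values is calibrated once per profile:
#' scores of the profile against `null_n` background-random sequences of
#' length `null_len` are fitted to a Gumbel by the method of moments and
#' cached on the profile (fixed internal seed, so profiles are
#' deterministic).
#'
#' @param seed_aln A `clp1_msa` with >= 2 rows (the seed alignment).
#' @param name Domain name.
#' @param pseudocount Total pseudocount mass per column, distributed
#'   proportionally to the background frequencies (so unobserved residues
#'   always score below zero).
#' @param gap_open,gap_extend Gap penalties used when the profile is
#'   aligned to sequences.
#' @param calibrate Fit the Gumbel null now (default TRUE).
#' @param null_n,null_len Null calibration sample size and sequence length.
#' @param seed Internal seed for the calibration draws.
#' @return A `domain_profile` object.
#' @export
build_profile <- function(seed_aln, name, pseudocount = 1,
                          gap_open = 10, gap_extend = 1,
                          calibrate = TRUE, null_n = 100, null_len = 400,
                          seed = 7L) {
  if (length(seed_aln$ids) < 2) stop("seed alignment needs >= 2 rows")
  m <- msa_matrix(seed_aln)
  gap_frac <- colMeans(m == "-")
  keep <- which(gap_frac <= 0.5)
  if (length(keep) < 10) stop("profile would have fewer than 10 columns")
  m <- m[, keep, drop = FALSE]
  counts <- apply(m, 2, function(col) {
    tabulate(match(col[col != "-"], AA20), nbins = 20)
  })
  freqs <- t(counts + pseudocount * AA_BACKGROUND[AA20])
  freqs <- freqs / rowSums(freqs)
  scores <- log(sweep(freqs, 2, AA_BACKGROUND[AA20], "/"))
  colnames(scores) <- AA20
  prof <- structure(
    list(name = name, length = nrow(scores), scores = scores,
         gap_open = gap_open, gap_extend = gap_extend,
         source = "seed_alignment", null = NULL),
    class = "domain_profile")
  if (calibrate) {
    prof$null <- calibrate_profile_null(prof, null_n, null_len, seed)
  }
  prof
}

#' @export
print.domain_profile <- function(x, ...) {
  cat("<domain_profile> ", x$name, ": ", x$length, " columns",
      if (!is.null(x$null)) " (null calibrated)", "\n", sep = "")
  invisible(x)
}

# Gumbel (EVD) fit by method of moments on null local-alignment scores.
calibrate_profile_null <- function(profile, null_n, null_len, seed) {
  scores <- withr::with_seed(seed, {
    vapply(seq_len(null_n), function(i) {
      s <- paste(sample(AA20, null_len, replace = TRUE,
                        prob = AA_BACKGROUND[AA20]), collapse = "")
      profile_raw_score(profile, s)
    }, numeric(1))
  })
  beta <- stats::sd(scores) * sqrt(6) / pi
  mu <- mean(scores) - 0.5772156649 * beta
  list(mu = mu, beta = beta, ref_len = null_len, n = null_n)
}

# Score matrix of profile columns vs sequence positions.
profile_score_matrix <- function(profile, sequence) {
  idx <- match(split_residues(sequence), AA20)
  S <- profile$scores[, ifelse(is.na(idx), 1L, idx), drop = FALSE]
  if (anyNA(idx)) S[, is.na(idx)] <- 0  # X scores neutrally
  S
}

profile_raw_score <- function(profile, sequence) {
  local_score_cpp(profile_score_matrix(profile, sequence),
                  profile$gap_open, profile$gap_extend)
}

# Best local placement of a profile on a sequence, with Gumbel E-value.
profile_best_hit <- function(profile, sequence) {
  S <- profile_score_matrix(profile, sequence)
  res <- align_score_matrix_cpp(S, profile$gap_open, profile$gap_extend, TRUE)
  if (res$score <= 0) return(NULL)
  ev <- NA_real_
  if (!is.null(profile$null)) {
    z <- (res$score - profile$null$mu) / profile$null$beta
    p <- 1 - exp(-exp(-z))
    # linear length scaling relative to the calibration length
    ev <- p * nchar(sequence) / profile$null$ref_len
  }
  list(score = res$score, evalue = ev,
       start = res$j_start, end = res$j_end,
       p_start = res$i_start, p_end = res$i_end)
}

#' Scan a protein with domain profiles
#'
#' Each profile is locally aligned to the protein; placements with Gumbel
#' E-value above `evalue_max` (default 1e-3) are dropped, and overlapping
#' accepted placements are resolved best-score-first.  A profile longer
#' than the protein simply yields no hit.
#'
#' @param protein One-row record tibble (or list with `id`, `sequence`).
#' @param profiles List of `domain_profile` objects.
#' @param evalue_max E-value threshold (default 1e-3).
#' @param db_size Number of sequences in the scanned database; the
#'   E-value is the expected number of false placements in the whole
#'   search (HMMER semantics), i.e. the per-scan tail probability scaled
#'   by `db_size`.
#' @return Tibble of domain hits: `protein_id`, `domain_name`, `start`,
#'   `end`, `score`, `evalue`, `origin` (= `"profile"`), sorted by `start`.
#' @export
scan_profiles <- function(protein, profiles, evalue_max = 1e-3,
                          db_size = 1) {
  seqs <- protein$sequence[[1]]
  if (!nzchar(seqs)) stop("empty protein sequence")
  hits <- purrr::map_dfr(profiles, function(p) {
    h <- profile_best_hit(p, seqs)
    if (is.null(h) || is.na(h$evalue)) return(NULL)
    h$evalue <- h$evalue * db_size
    if (h$evalue > evalue_max) return(NULL)
    tibble::tibble(protein_id = protein$id[[1]], domain_name = p$name,
                   start = h$start, end = h$end,
                   score = h$score, evalue = h$evalue, origin = "profile")
  })
  if (nrow(hits) == 0) return(empty_domain_hits())
  resolve_overlaps(hits)
}

empty_domain_hits <- function() {
  tibble::tibble(protein_id = character(), domain_name = character(),
                 start = integer(), end = integer(), score = numeric(),
                 evalue = numeric(), origin = character())
}

# Keep hits best-score-first, dropping any that overlap an accepted hit.
# `priority` optionally ranks origins before score (profile-first assembly).
resolve_overlaps <- function(hits, priority = NULL) {
  if (nrow(hits) <= 1) return(dplyr::arrange(hits, .data$start))
  ord <- if (is.null(priority)) {
    order(-hits$score, hits$domain_name)
  } else {
    order(match(hits$origin, priority), -hits$score, hits$domain_name)
  }
  hits <- hits[ord, , drop = FALSE]
  kept <- hits[0, , drop = FALSE]
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    if (nrow(kept) == 0 ||
        all(h$end < kept$start | h$start > kept$end)) {
      kept <- dplyr::bind_rows(kept, h)
    }
  }
  dplyr::arrange(kept, .data$start)
}

#' Unannotated segments of a protein
#'
#' Maximal intervals not covered by any domain hit, of length at least
#' `min_len` (1-based inclusive coordinates).
#'
#' @param protein One-row record tibble (or list with `id`, `sequence`).
#' @param hits Non-overlapping domain-hit tibble for this protein.
#' @param min_len Minimum reported segment length (default 50).
#' @return Tibble with `protein_id`, `start`, `end`, `sequence`.
#' @export
unannotated_segments <- function(protein, hits, min_len = 50) {
  len <- nchar(protein$sequence[[1]])
  covered <- rep(FALSE, len)
  if (nrow(hits) > 0) {
    for (i in seq_len(nrow(hits))) {
      covered[hits$start[i]:hits$end[i]] <- TRUE
    }
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  free <- !r$values & r$lengths >= min_len
  if (!any(free)) {
    return(tibble::tibble(protein_id = character(), start = integer(),
                          end = integer(), sequence = character()))
  }
  tibble::tibble(
    protein_id = protein$id[[1]],
    start = starts[free], end = ends[free],
    sequence = substring(protein$sequence[[1]], starts[free], ends[free]))
}

#' Discover novel conserved domains from unannotated segments
#'
#' All-versus-all local alignment of the segments; pairs passing both the
#' E-value and query-coverage thresholds become edges, and single-linkage
#' connected components with at least `min_members` members from at least
#' `min_species` species are reported as novel domains (named NDOM1,
#' NDOM2, ... by decreasing member count, ties by first member id).
#' Member boundaries are refined to the aligned core: the median start and
#' end of the member's pairwise aligned spans across its in-component
#' alignments, i.e. the region that at least half of the supporting
#' alignments cover.  Fast-evolving flanks outside the conserved block are
#' thereby excluded from the reported domain.
#'
#' @param segments Tibble from [unannotated_segments()] (rows across many
#'   proteins), with `protein_id`, `start`, `end`, `sequence`.
#' @param records Record tibble supplying `species` per protein id.
#' @param params A [search_params()]; defaults (1e-4, 0.30) match the
#'   family-search thresholds.
#' @param min_members,min_species Component acceptance thresholds
#'   (defaults 3 and 3).
#' @return Tibble with one row per member segment: `domain_name`,
#'   `protein_id`, `start`, `end`, `score`, `evalue`, `origin`
#'   (= `"novel"`), plus per-domain summary columns `n_members`,
#'   `n_species`, `mean_length`, `sd_length`.
#' @export
discover_novel_domains <- function(segments, records,
                                   params = search_params(),
                                   min_members = 3, min_species = 3) {
  if (nrow(segments) < 2) return(empty_novel_domains())
  segments <- dplyr::mutate(segments,
                            seg_id = paste0(.data$protein_id, ":",
                                            .data$start, "-", .data$end))
  n <- nrow(segments)
  m_len <- nchar(segments$sequence)
  edges <- list()
  spans <- lapply(seq_len(n), function(i) list(starts = integer(),
                                               ends = integer()))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      aln <- align_pair(segments$sequence[[i]], segments$sequence[[j]],
                        params$scheme, local = TRUE)
      if (aln$score <= 0) next
      ka <- evalue_ka(aln$score, m_len[i], m_len[j], params$scheme)
      cov <- (aln$q_end - aln$q_start + 1) / m_len[i]
      if (ka$evalue <= params$evalue_max && cov >= params$coverage_min) {
        edges[[length(edges) + 1]] <- c(i, j)
        spans[[i]]$starts <- c(spans[[i]]$starts, aln$q_start)
        spans[[i]]$ends <- c(spans[[i]]$ends, aln$q_end)
        spans[[j]]$starts <- c(spans[[j]]$starts, aln$t_start)
        spans[[j]]$ends <- c(spans[[j]]$ends, aln$t_end)
      }
    }
  }
  comp <- union_find(n, edges)
  species <- records$species[match(segments$protein_id, records$id)]
  out <- list()
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    if (length(idx) < min_members) next
    if (dplyr::n_distinct(species[idx]) < min_species) next
    refined <- refine_component(segments[idx, , drop = FALSE], spans[idx])
    refined$n_species <- dplyr::n_distinct(species[idx])
    out[[length(out) + 1]] <- refined
  }
  if (length(out) == 0) return(empty_novel_domains())
  # order by decreasing size, ties by first member id
  sizes <- vapply(out, nrow, integer(1))
  firsts <- vapply(out, function(d) min(d$protein_id), character(1))
  ord <- order(-sizes, firsts)
  res <- purrr::map_dfr(seq_along(ord), function(k) {
    d <- out[[ord[k]]]
    d$domain_name <- paste0("NDOM", k)
    d
  })
  dplyr::select(res, "domain_name", dplyr::everything())
}

empty_novel_domains <- function() {
  tibble::tibble(domain_name = character(), protein_id = character(),
                 start = integer(), end = integer(), score = numeric(),
                 evalue = numeric(), origin = character(),
                 n_members = integer(), n_species = integer(),
                 mean_length = numeric(), sd_length = numeric())
}

union_find <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (e in edges) {
    a <- find(e[1]); b <- find(e[2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  vapply(seq_len(n), find, integer(1))
}

# Trim each member to its aligned core: the median start/end of the
# pairwise aligned spans supporting its component membership.
refine_component <- function(seg, spans) {
  res <- purrr::map_dfr(seq_len(nrow(seg)), function(i) {
    sp <- spans[[i]]
    if (length(sp$starts) == 0) {
      first_off <- 1L
      last_off <- nchar(seg$sequence[[i]])
    } else {
      first_off <- as.integer(round(stats::median(sp$starts)))
      last_off <- as.integer(round(stats::median(sp$ends)))
    }
    tibble::tibble(protein_id = seg$protein_id[[i]],
                   start = seg$start[[i]] + first_off - 1L,
                   end = seg$start[[i]] + last_off - 1L,
                   score = NA_real_, evalue = NA_real_, origin = "novel")
  })
  lens <- res$end - res$start + 1
  res$n_members <- nrow(res)
  res$mean_length <- mean(lens)
  res$sd_length <- stats::sd(lens)
  res
}

#' Assemble a protein's domain architecture
#'
#' Union of profile and novel hits with overlaps resolved profile-first,
#' then best-score (equal-score ties deterministically by domain name,
#' with a warning).  The canonical string form joins ordered domain names
#' with `|`.
#'
#' @param protein One-row record tibble.
#' @param profile_hits,novel_hits Domain-hit tibbles for this protein.
#' @return A list with `protein_id`, `architecture` (string, `""` when no
#'   hits) and `hits` (ordered non-overlapping tibble).
#' @export
assemble_architecture <- function(protein, profile_hits, novel_hits = NULL) {
  hits <- dplyr::bind_rows(profile_hits, novel_hits)
  if (nrow(hits) > 0) {
    hits <- hits[hits$protein_id == protein$id[[1]], , drop = FALSE]
  }
  if (nrow(hits) == 0) {
    return(list(protein_id = protein$id[[1]], architecture = "",
                hits = empty_domain_hits()))
  }
  dup <- hits |>
    dplyr::group_by(.data$origin, .data$score) |>
    dplyr::filter(dplyr::n() > 1) |>
    dplyr::ungroup()
  if (nrow(dup) > 0 && anyDuplicated(dup$score)) {
    overlapping <- any(outer(dup$start, dup$end, `<=`) &
                         outer(dup$end, dup$start, `>=`) &
                         !diag(nrow(dup)))
    if (overlapping) {
      warning("equal-score overlapping hits resolved by domain name")
    }
  }
  assembled <- resolve_overlaps(hits, priority = c("profile", "novel"))
  list(protein_id = protein$id[[1]],
       architecture = paste(assembled$domain_name, collapse = "|"),
       hits = assembled)
}

#' Write / import domain hits
#'
#' TSV export of domain hits, and an importer for HMMER `--domtblout`
#' tables so externally computed profile hits can drive the pipeline.
#'
#' @param hits Domain-hit tibble.
#' @param path File path.
#' @return `path` invisibly (writer) or a domain-hit tibble (importer).
#' @name domain_io
NULL

#' @rdname domain_io
#' @export
write_domain_tsv <- function(hits, path) {
  readr::write_tsv(
    dplyr::select(hits, "protein_id", domain = "domain_name",
                  "start", "end", "score", "evalue", "origin"),
    path)
  invisible(path)
}

#' @rdname domain_io
#' @export
read_domtblout <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_domain_hits())
  parts <- strsplit(trimws(lines), "\\s+")
  tibble::tibble(
    protein_id = vapply(parts, `[[`, character(1), 1),
    domain_name = vapply(parts, `[[`, character(1), 4),
    start = as.integer(vapply(parts, `[[`, character(1), 18)),
    end = as.integer(vapply(parts, `[[`, character(1), 19)),
    score = as.numeric(vapply(parts, `[[`, character(1), 14)),
    evalue = as.numeric(vapply(parts, `[[`, character(1), 13)),
    origin = "profile")
}
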