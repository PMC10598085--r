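#' Multiple-alignment container
#'
#' A light S3 class: parallel vectors of ids and equal-length gapped rows.
#'
#' @param ids Character vector of sequence ids.
#' @param rows Character vector of gapped rows (equal lengths).
#' @return A `clp1_msa` object.
#' @export
new_msa <- function(ids, rows) {
  ids <- unname(ids)
  rows <- unname(rows)
  stopifnot(length(ids) == length(rows), length(ids) >= 1)
  if (length(unique(nchar(rows))) != 1) stop("alignment rows differ in length")
  structure(list(ids = ids, rows = rows), class = "clp1_msa")
}

#' @export
print.clp1_msa <- function(x, ...) {
  cat("<clp1_msa> ", length(x$ids), " sequences x ",
      nchar(x$rows[[1]]), " columns\n", sep = "")
  invisible(x)
}

msa_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
  rownames(m) <- aln$ids
  m
}

msa_from_matrix <- function(m, ids = rownames(m)) {
  new_msa(ids, apply(m, 1, paste, collapse = ""))
}

#' Ungapped sequences of an alignment
#'
#' @param aln A `clp1_msa`.
#' @return Record tibble with `id` and `sequence` (gaps removed).
#' @export
msa_sequences <- function(aln) {
  tibble::tibble(id = aln$ids, sequence = gsub("-", "", aln$rows, fixed = TRUE))
}

# Column frequency profile over the allowed alphabet (gaps contribute 0,
# so poorly occupied columns score low against everything).
profile_freq <- function(mat, alphabet) {
  n <- nrow(mat)
  t(apply(mat, 2, function(col) {
    tabulate(match(col, alphabet), nbins = length(alphabet)) / n
  }))
}

#' Progressive multiple sequence alignment
#'
#' Desk-scale progressive aligner: a k-mer-distance guide tree (UPGMA on
#' shared 3-mer fractions) followed by profile--profile global alignment
#' under the scheme's substitution scores and affine gap penalties.
#' Deterministic for a fixed input order; for two sequences it reduces to
#' the optimal global pairwise alignment.  Externally computed alignments
#' can be imported with [read_alignment_fasta()] instead.
#'
#' @param records Record tibble (>= 2 rows).
#' @param scheme A [scoring_scheme()].
#' @param k k-mer size for guide-tree distances.
#' @return A `clp1_msa` with rows in the input record order.
#' @export
progressive_msa <- function(records, scheme = scoring_scheme(), k = 3L) {
  validate_records(records)
  n <- nrow(records)
  if (n < 2) stop("progressive_msa needs at least 2 records")
  alphabet <- intersect(rownames(scheme$matrix), AA_ALLOWED)
  B <- scheme$matrix[alphabet, alphabet]

  kmers <- lapply(records$sequence, function(s) {
    if (nchar(s) < k) return(character(0))
    unique(substring(s, 1:(nchar(s) - k + 1), k:nchar(s)))
  })
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      denom <- max(1L, min(length(kmers[[i]]), length(kmers[[j]])))
      d <- 1 - length(intersect(kmers[[i]], kmers[[j]])) / denom
      D[i, j] <- D[j, i] <- d
    }
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")

  # progressive merge following the hclust merge table
  groups <- lapply(seq_len(n), function(i) {
    m <- matrix(split_residues(records$sequence[[i]]), nrow = 1)
    rownames(m) <- records$id[[i]]
    m
  })
  merged <- vector("list", nrow(hc$merge))
  get_grp <- function(x) if (x < 0) groups[[-x]] else merged[[x]]
  for (step in seq_len(nrow(hc$merge))) {
    g1 <- get_grp(hc$merge[step, 1])
    g2 <- get_grp(hc$merge[step, 2])
    merged[[step]] <- merge_profiles(g1, g2, B, alphabet, scheme)
  }
  final <- if (nrow(hc$merge) > 0) merged[[nrow(hc$merge)]] else groups[[1]]
  final <- final[match(records$id, rownames(final)), , drop = FALSE]
  msa_from_matrix(final)
}

merge_profiles <- function(g1, g2, B, alphabet, scheme) {
  F1 <- profile_freq(g1, alphabet)
  F2 <- profile_freq(g2, alphabet)
  S <- F1 %*% B %*% t(F2)
  res <- align_score_matrix_cpp(S, scheme$gap_open, scheme$gap_extend, FALSE)
  ncol_out <- length(res$path_i)
  out <- matrix("-", nrow(g1) + nrow(g2), ncol_out)
  rownames(out) <- c(rownames(g1), rownames(g2))
  sel1 <- res$path_i > 0
  sel2 <- res$path_j > 0
  out[seq_len(nrow(g1)), sel1] <- g1[, res$path_i[sel1], drop = FALSE]
  out[nrow(g1) + seq_len(nrow(g2)), sel2] <- g2[, res$path_j[sel2], drop = FALSE]
  out
}

#' Column conservation ranks (0--11) with symbols
#'
#' Rank 11 (`*`): gap-free column of identical residues.  Rank 10 (`+`):
#' gap-free column whose residues all carry an identical physicochemical
#' property profile ("partially conserved").  Otherwise the rank is the
#' number of properties shared by all residues present (0--9); any gap in
#' the column caps the rank at 9, so gapped columns are never `*` or `+`.
#'
#' @param aln A `clp1_msa`.
#' @return Tibble with `column`, `rank`, `symbol` (digit, `+`, or `*`).
#' @export
conservation_ranks <- function(aln) {
  m <- msa_matrix(aln)
  prop <- aa_property_matrix()
  prop <- rbind(prop, X = rep(FALSE, ncol(prop)))
  purrr::map_dfr(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    has_gap <- any(col == "-")
    res <- col[col != "-"]
    if (length(res) == 0) {
      return(tibble::tibble(column = j, rank = 0L, symbol = "0"))
    }
    if (!has_gap && length(unique(res)) == 1) {
      return(tibble::tibble(column = j, rank = 11L, symbol = "*"))
    }
    pm <- prop[res, , drop = FALSE]
    same_profile <- all(apply(pm, 2, function(v) length(unique(v)) == 1))
    if (!has_gap && same_profile) {
      return(tibble::tibble(column = j, rank = 10L, symbol = "+"))
    }
    shared <- sum(apply(pm, 2, all))
    r <- min(shared, 9L)
    tibble::tibble(column = j, rank = as.integer(r), symbol = as.character(r))
  })
}

#' Remove gapped columns from an alignment
#'
#' Columns whose gap fraction exceeds `gap_fraction_max` are removed.  The
#' default 0 deletes every column containing any gap (the strict "remove
#' all gaps" trimming used ahead of tree building); other thresholds give
#' the fractional behaviour of common trimming tools.  A provenance map of
#' retained source columns is kept in `attr(, "columns")`.
#'
#' @param aln A `clp1_msa`.
#' @param gap_fraction_max Maximum tolerated gap fraction per column.
#' @return Trimmed `clp1_msa`.
#' @export
trim_alignment <- function(aln, gap_fraction_max = 0) {
  m <- msa_matrix(aln)
  gf <- colMeans(m == "-")
  keep <- which(gf <= gap_fraction_max)
  if (length(keep) == 0) {
    stop("trimming removed all columns; raise gap_fraction_max")
  }
  out <- msa_from_matrix(m[, keep, drop = FALSE])
  attr(out, "columns") <- keep
  out
}

#' Read / write alignments
#'
#' FASTA and Stockholm flavours for gapped alignments.
#'
#' @param aln A `clp1_msa`.
#' @param path File path.
#' @return The alignment (readers) or `path` invisibly (writers).
#' @name alignment_io
NULL

#' @rdname alignment_io
#' @export
write_alignment_fasta <- function(aln, path) {
  writeLines(as.vector(rbind(paste0(">", aln$ids), aln$rows)), path)
  invisible(path)
}

#' @rdname alignment_io
#' @export
read_alignment_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  is_header <- startsWith(lines, ">")
  if (!is_header[1]) stop("malformed alignment FASTA: ", path)
  grp <- cumsum(is_header)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[is_header]))
  rows <- vapply(split(lines[!is_header], grp[!is_header]),
                 paste, character(1), collapse = "")
  new_msa(ids, toupper(unname(rows)))
}

#' @rdname alignment_io
#' @export
write_stockholm <- function(aln, path) {
  pad <- formatC(aln$ids, width = max(nchar(aln$ids)), flag = "-")
  writeLines(c("# STOCKHOLM 1.0", paste(pad, aln$rows), "//"), path)
  invisible(path)
}

#' @rdname alignment_io
#' @export
read_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^#", lines) & !grepl("^//", lines) &
                  nzchar(trimws(lines))]
  parts <- strsplit(trimws(body), "\\s+")
  ids <- vapply(parts, `[[`, character(1), 1)
  rows <- vapply(parts, `[[`, character(1), 2)
  seqs <- vapply(split(rows, factor(ids, levels = unique(ids))),
                 paste, character(1), collapse = "")
  new_msa(unique(ids), toupper(gsub("\\.", "-", unname(seqs))))
}
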