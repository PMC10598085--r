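#' Read protein records from a FASTA file
#'
#' Returns one row per FASTA entry, in file order.  The record id is the
#' first whitespace-delimited token of the header; the rest is kept as the
#' description.  A record is flagged as a splicing isoform when its
#' description contains `isoform_marker` (case-insensitive), mirroring
#' RefSeq annotation wording.  Optional per-id metadata (species, taxon,
#' gene id) can be joined from a data frame or TSV file with an `id` column.
#'
#' @param path FASTA file path.
#' @param metadata Optional data frame or TSV path with columns `id` and any
#'   of `species`, `taxon`, `gene_id`.
#' @param isoform_marker Substring marking splicing isoforms (default
#'   `"isoform"`).
#' @return A tibble with columns `id`, `species`, `taxon`, `sequence`,
#'   `description`, `is_isoform` (and `gene_id` when supplied).
#' @export
read_fasta <- function(path, metadata = NULL, isoform_marker = "isoform") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  first_content <- which(keep)[1]
  if (is.na(first_content) || !startsWith(lines[first_content], ">")) {
    stop("malformed FASTA in ", path, ": line ",
         if (is.na(first_content)) 1 else first_content,
         " expected a '>' header")
  }
  is_header <- startsWith(lines, ">")
  grp <- cumsum(is_header)
  headers <- sub("^>", "", lines[is_header])
  ids <- sub("\\s.*$", "", headers)
  desc <- trimws(sub("^\\S*\\s*", "", headers))
  seqs <- vapply(split(lines[!is_header & keep], grp[!is_header & keep]),
                 function(x) gsub("\\s", "", paste(x, collapse = "")),
                 character(1))
  sequences <- character(length(ids))
  names(sequences) <- as.character(seq_along(ids))
  sequences[names(seqs)] <- toupper(seqs)
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  bad <- !grepl(paste0("^[", paste(AA_ALLOWED, collapse = ""), "]+$"), sequences)
  if (any(bad)) {
    stop("illegal residue letters (or empty sequence) in record(s): ",
         paste(ids[bad], collapse = ", "))
  }
  records <- tibble::tibble(
    id = ids,
    species = NA_character_,
    taxon = NA_character_,
    sequence = unname(sequences),
    description = desc,
    is_isoform = grepl(isoform_marker, desc, ignore.case = TRUE)
  )
  if (!is.null(metadata)) {
    if (is.character(metadata)) {
      metadata <- readr::read_tsv(metadata, show_col_types = FALSE)
    }
    metadata <- tibble::as_tibble(metadata)
    stopifnot("metadata needs an 'id' column" = "id" %in% names(metadata))
    for (col in intersect(c("species", "taxon", "gene_id"), names(metadata))) {
      m <- metadata[[col]][match(records$id, metadata$id)]
      if (col %in% names(records)) {
        records[[col]] <- dplyr::coalesce(as.character(m), records[[col]])
      } else {
        records[[col]] <- as.character(m)
      }
    }
  }
  records
}

#' Write protein records to FASTA
#'
#' Inverse of [read_fasta()]: headers are `>id description` (description
#' omitted when empty), sequences wrapped at `width` columns.
#'
#' @param records Tibble with `id`, `sequence` and optionally `description`.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  desc <- if ("description" %in% names(records)) records$description else ""
  desc <- ifelse(is.na(desc) | !nzchar(desc), "", paste0(" ", desc))
  out <- purrr::map2(paste0(">", records$id, desc), records$sequence,
                     function(h, s) {
                       c(h, substring(s, seq(1, nchar(s), width),
                                      pmin(seq(width, nchar(s) + width - 1, width),
                                           nchar(s))))
                     })
  writeLines(unlist(out), path)
  invisible(path)
}

validate_records <- function(records) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  if (anyDuplicated(records$id)) stop("record ids must be unique")
  if (any(!nzchar(records$sequence))) stop("empty sequences not allowed")
  invisible(records)
}

#' Percent identity and similarity of a pairwise alignment
#'
#' Identity is the percentage of alignment columns with identical residues;
#' similarity additionally counts columns whose residue pair has a positive
#' substitution score ("chemically similar").  The denominator is the full
#' alignment length including gap columns (BLAST-style reporting).
#'
#' @param aln One-row data frame (or list) with `aligned_query` and
#'   `aligned_target`, as returned by [align_local()]/[align_global()].
#' @param scheme A [scoring_scheme()].
#' @param digits Rounding for the returned percentages; `digits = 0` gives
#'   the integers used in publication-style tables.
#' @return Named numeric vector `c(identity = , similarity = )`.
#' @export
percent_identity_similarity <- function(aln, scheme = scoring_scheme(),
                                        digits = 0) {
  q <- split_residues(aln$aligned_query[[1]])
  t <- split_residues(aln$aligned_target[[1]])
  if (length(q) != length(t)) stop("alignment rows differ in length")
  if (length(q) == 0) stop("zero-length alignment")
  if (any(q == "-" & t == "-")) stop("column with gap in both rows")
  len <- length(q)
  resid <- q != "-" & t != "-"
  scores <- rep(-Inf, len)
  scores[resid] <- scheme$matrix[cbind(q[resid], t[resid])]
  ident <- sum(resid & q == t)
  simil <- sum(resid & (q == t | scores > 0))
  c(identity = round(100 * ident / len, digits),
    similarity = round(100 * simil / len, digits))
}

#' Average molecular mass of a protein sequence
#'
#' Sum of standard average residue (monomer-minus-water) masses plus one
#' water (18.015 Da), in kDa.  Sequences containing `X` or other
#' non-canonical letters are rejected: their mass is undefined.
#'
#' @param sequence Residue string over the 20 canonical letters.
#' @param digits Rounding (default 1 decimal, publication style).
#' @return Mass in kDa.
#' @export
average_mass <- function(sequence, digits = 1) {
  if (is.na(sequence) || !nzchar(sequence)) stop("empty sequence: mass undefined")
  res <- split_residues(sequence)
  if (!all(res %in% AA20)) {
    stop("mass undefined for non-canonical residues: ",
         paste(unique(setdiff(res, AA20)), collapse = ", "))
  }
  round((sum(AA_AVG_MASS[res]) + MASS_WATER) / 1000, digits)
}
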