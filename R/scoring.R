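#' Substitution scoring scheme
#'
#' Bundles a protein substitution matrix with affine gap penalties and the
#' Karlin--Altschul parameters (`lambda`, `K`) used to convert raw local
#' alignment scores into bit scores and E-values.  The default is BLOSUM62
#' with gap open 11 / extend 1 and the standard gapped-BLOSUM62 constants
#' lambda = 0.267 nats per score unit, K = 0.041; no composition-based or
#' effective-length adjustment is applied.
#'
#' @param matrix A symmetric integer substitution matrix with residue
#'   one-letter codes as dimnames, or the string `"BLOSUM62"` (the copy
#'   shipped with Biostrings).
#' @param gap_open,gap_extend Positive gap penalties; a gap of length k
#'   costs `gap_open + k * gap_extend`.
#' @param lambda,K Karlin--Altschul parameters (positive reals).
#' @return An object of class `scoring_scheme`.
#' @examples
#' sc <- scoring_scheme()
#' sc$matrix["D", "E"]
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11L,
                           gap_extend = 1L, lambda = 0.267, K = 0.041) {
  if (is.character(matrix) && length(matrix) == 1) {
    mat <- get_builtin_matrix(matrix)
  } else {
    mat <- as.matrix(matrix)
  }
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("substitution matrix must have residue dimnames")
  }
  core <- mat[AA20, AA20]
  if (!isTRUE(all.equal(core, t(core)))) {
    stop("substitution matrix must be symmetric on the 20 canonical residues")
  }
  if (!(gap_open >= gap_extend && gap_extend >= 1)) {
    stop("require gap_open >= gap_extend >= 1")
  }
  if (!(lambda > 0 && K > 0)) stop("lambda and K must be positive")
  structure(
    list(matrix = mat, gap_open = as.numeric(gap_open),
         gap_extend = as.numeric(gap_extend), lambda = lambda, K = K),
    class = "scoring_scheme"
  )
}

get_builtin_matrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  as.matrix(get(name, envir = e))
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the plain-text matrix layout used by NCBI BLAST (comment lines
#' starting with `#`, a header row of residue letters, then one labelled row
#' per residue).
#'
#' @param path Path to the matrix file.
#' @return An integer matrix with residue dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  labels <- vapply(rows, `[[`, character(1), 1)
  vals <- t(vapply(rows, function(r) as.integer(r[-1]), integer(length(header))))
  dimnames(vals) <- list(labels, header)
  vals
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("<scoring_scheme> ", nrow(x$matrix), "x", ncol(x$matrix),
      " matrix, gap ", x$gap_open, "/", x$gap_extend,
      ", lambda=", x$lambda, ", K=", x$K, "\n", sep = "")
  invisible(x)
}

# Convert a residue string to indices into `alphabet` (stop on unknowns).
seq_index <- function(sequence, alphabet) {
  idx <- match(split_residues(sequence), alphabet)
  if (anyNA(idx)) stop("sequence contains letters outside the matrix alphabet")
  idx
}

# Pairwise cell-score matrix for two residue strings under a scheme.
pair_score_matrix <- function(q, t, scheme) {
  ab <- rownames(scheme$matrix)
  qi <- seq_index(q, ab)
  ti <- seq_index(t, ab)
  scheme$matrix[qi, ti, drop = FALSE]
}

# Shared low-level aligner: returns score, coordinates and gapped strings.
align_pair <- function(q, t, scheme, local = TRUE) {
  S <- pair_score_matrix(q, t, scheme)
  res <- align_score_matrix_cpp(S, scheme$gap_open, scheme$gap_extend, local)
  qr <- split_residues(q)
  tr <- split_residues(t)
  aligned_q <- ifelse(res$path_i > 0, qr[pmax(res$path_i, 1)], "-")
  aligned_t <- ifelse(res$path_j > 0, tr[pmax(res$path_j, 1)], "-")
  list(score = res$score,
       q_start = res$i_start, q_end = res$i_end,
       t_start = res$j_start, t_end = res$j_end,
       aligned_query = paste(aligned_q, collapse = ""),
       aligned_target = paste(aligned_t, collapse = ""))
}

#' Optimal gapped local alignment of two protein sequences
#'
#' Exact affine-gap Smith--Waterman over the scheme's substitution matrix.
#'
#' @param query,target Residue strings.
#' @param scheme A [scoring_scheme()].
#' @return A one-row tibble with score, 1-based inclusive coordinates and the
#'   two gapped alignment rows.
#' @export
align_local <- function(query, target, scheme = scoring_scheme()) {
  res <- align_pair(query, target, scheme, local = TRUE)
  tibble::tibble(score = res$score,
                 q_start = res$q_start, q_end = res$q_end,
                 t_start = res$t_start, t_end = res$t_end,
                 aligned_query = res$aligned_query,
                 aligned_target = res$aligned_target)
}

#' Optimal gapped global alignment of two protein sequences
#'
#' Affine-gap Needleman--Wunsch with penalized end gaps.
#'
#' @inheritParams align_local
#' @return A one-row tibble as in [align_local()].
#' @export
align_global <- function(query, target, scheme = scoring_scheme()) {
  res <- align_pair(query, target, scheme, local = FALSE)
  tibble::tibble(score = res$score,
                 q_start = res$q_start, q_end = res$q_end,
                 t_start = res$t_start, t_end = res$t_end,
                 aligned_query = res$aligned_query,
                 aligned_target = res$aligned_target)
}
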