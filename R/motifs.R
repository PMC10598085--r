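#' Default PNK motif models
#'
#' The four sequence motifs of the Clp1 kinase (Clp1_P / P-loop) domain
#' required for polynucleotide-kinase activity, expected in the order
#' Walker A < Walker B < Clasp < Lid along the domain.  Each pattern is a
#' string of position classes: a literal residue, `x` for any residue, or
#' a bracketed class like `[AG]`.  Walker A is the canonical P-loop
#' `[AG]-x(4)-G-K-[ST]`; Walker B is four hydrophobics followed by two
#' acidics.  The Clasp and Lid consensus strings are synthetic stand-ins
#' (the published consensus lives in supplementary material not bundled
#' here) and should be overridden with `motif_models()` when a curated
#' consensus is available.
#'
#' @param walker_a,walker_b,clasp,lid Pattern strings.
#' @param max_mismatches Integer vector (recycled) of tolerated pattern
#'   mismatches per motif.
#' @return Tibble with `name`, `pattern`, `max_mismatches`, `order`.
#' @export
motif_models <- function(walker_a = "[AG]xxxxGK[ST]",
                         walker_b = "[ILVFMA][ILVFMA][ILVFMA][ILVFMA][DE][DE]",
                         clasp = "RWx[ST][ILV]G[DE][FY]",
                         lid = "[RK]xx[DE][WY]x[RK][RK]",
                         max_mismatches = c(0L, 0L, 1L, 1L)) {
  tibble::tibble(
    name = c("WalkerA", "WalkerB", "Clasp", "Lid"),
    pattern = c(walker_a, walker_b, clasp, lid),
    max_mismatches = rep_len(as.integer(max_mismatches), 4),
    order = 1:4)
}

# Parse a pattern string into a list of allowed-residue sets.
parse_pattern <- function(pattern) {
  out <- list()
  i <- 1
  chars <- split_residues(pattern)
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      close <- i + which(chars[(i + 1):length(chars)] == "]")[1]
      out[[length(out) + 1]] <- chars[(i + 1):(close - 1)]
      i <- close + 1
    } else if (ch == "x") {
      out[[length(out) + 1]] <- AA_ALLOWED
      i <- i + 1
    } else {
      out[[length(out) + 1]] <- ch
      i <- i + 1
    }
  }
  out
}

# Mismatch count of a pattern placed at each feasible offset; returns the
# best placement at or after `from` (fewest mismatches, then leftmost).
best_placement <- function(residues, pattern, from = 1L) {
  k <- length(pattern)
  n <- length(residues)
  if (n - from + 1 < k) return(NULL)
  offsets <- from:(n - k + 1)
  mm <- vapply(offsets, function(o) {
    sum(!vapply(seq_len(k), function(p) {
      residues[o + p - 1] %in% pattern[[p]]
    }, logical(1)))
  }, numeric(1))
  best <- which.min(mm)
  list(start = offsets[best], end = offsets[best] + k - 1L,
       mismatches = mm[best])
}

#' Scan a kinase-domain span for the four PNK motifs
#'
#' Each motif is matched at its best placement (fewest pattern
#' mismatches, leftmost tie-break) at or after the end of the previous
#' motif, enforcing the expected Walker A < Walker B < Clasp < Lid order.
#' A motif matches when its pattern is satisfied with at most its
#' `max_mismatches`.  An empty span leaves all motifs unmatched.
#'
#' @param clp1p_seq Residue string of the located Clp1_P span (may be
#'   `""`/`NA` when the domain was not found).
#' @param models Motif models, see [motif_models()].
#' @return Tibble with one row per motif: `name`, `matched`, `start`,
#'   `end`, `mismatches`, `matched_seq` (span coordinates, 1-based).
#' @export
scan_motifs <- function(clp1p_seq, models = motif_models()) {
  models <- dplyr::arrange(models, .data$order)
  empty <- tibble::tibble(name = models$name, matched = FALSE,
                          start = NA_integer_, end = NA_integer_,
                          mismatches = NA_integer_,
                          matched_seq = NA_character_)
  if (is.na(clp1p_seq) || !nzchar(clp1p_seq)) return(empty)
  residues <- split_residues(clp1p_seq)
  from <- 1L
  out <- empty
  for (i in seq_len(nrow(models))) {
    pat <- parse_pattern(models$pattern[[i]])
    hit <- best_placement(residues, pat, from)
    if (is.null(hit)) next
    matched <- hit$mismatches <= models$max_mismatches[[i]]
    out$matched[i] <- matched
    out$start[i] <- hit$start
    out$end[i] <- hit$end
    out$mismatches[i] <- as.integer(hit$mismatches)
    out$matched_seq[i] <- paste(residues[hit$start:hit$end], collapse = "")
    if (matched) from <- hit$end + 1L
  }
  out
}

#' Predict PNK activity from the motif report and kinase-domain length
#'
#' A protein is called `active` only when all four motifs matched and the
#' located Clp1_P span is at least 130 aa (kinase domains much shorter
#' than the family mean lack the Clasp/Lid region and with it PNK
#' activity); `inactive` when any motif failed or the span is shorter;
#' `unknown` when the Clp1_P domain was not located at all.
#'
#' @param motif_report Output of [scan_motifs()].
#' @param clp1p_length Length (aa) of the located Clp1_P span, or `NA`.
#' @param min_length Activity length threshold (default 130 aa).
#' @return One of `"active"`, `"inactive"`, `"unknown"`.
#' @export
predict_activity <- function(motif_report, clp1p_length, min_length = 130) {
  if (is.na(clp1p_length)) return("unknown")
  if (all(motif_report$matched) && clp1p_length >= min_length) {
    return("active")
  }
  "inactive"
}
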