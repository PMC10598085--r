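#' Greedy identity clustering (CD-HIT style)
#'
#' Records are sorted by decreasing length (ties by id) and assigned
#' greedily: each record joins the first existing cluster whose
#' representative has global-alignment identity at or above `threshold`,
#' otherwise it founds a new cluster.  Identity is identical positions
#' divided by the shorter sequence length, the cited tool's semantics.
#' Because founders are processed longest-first, every representative is
#' the longest member of its cluster.
#'
#' @param records Record tibble.
#' @param threshold Identity fraction in (0, 1]; default 0.70.
#' @param scheme A [scoring_scheme()] for the global alignments.
#' @return Tibble with one row per record: `cluster` (integer, founding
#'   order), `representative_id`, `member_id`, `identity_to_rep`.
#' @export
greedy_cluster <- function(records, threshold = 0.70,
                           scheme = scoring_scheme()) {
  validate_records(records)
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0, 1]")
  ord <- order(-nchar(records$sequence), records$id)
  rec <- records[ord, , drop = FALSE]
  rep_idx <- integer(0)
  assign <- integer(nrow(rec))
  ident <- numeric(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    placed <- FALSE
    for (k in seq_along(rep_idx)) {
      pid <- pair_identity_short(rec$sequence[[i]],
                                 rec$sequence[[rep_idx[k]]], scheme)
      if (pid >= threshold) {
        assign[i] <- k
        ident[i] <- pid
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rep_idx <- c(rep_idx, i)
      assign[i] <- length(rep_idx)
      ident[i] <- 1
    }
  }
  tibble::tibble(
    cluster = assign,
    representative_id = rec$id[rep_idx[assign]],
    member_id = rec$id,
    identity_to_rep = ident
  ) |>
    dplyr::arrange(.data$cluster, .data$member_id)
}

# Global-alignment identity: identical positions / shorter sequence length.
pair_identity_short <- function(a, b, scheme = scoring_scheme()) {
  aln <- align_pair(a, b, scheme, local = FALSE)
  qa <- split_residues(aln$aligned_query)
  ta <- split_residues(aln$aligned_target)
  sum(qa == ta & qa != "-") / min(nchar(a), nchar(b))
}

#' Representative set from clusters, with required anchors re-added
#'
#' Selects each cluster's representative and appends any anchor records not
#' already selected, mirroring the construction of a reduced representative
#' sequence set that must still contain the named reference members.
#'
#' @param clusters Output of [greedy_cluster()].
#' @param records Record tibble the clusters were built from.
#' @param anchor_ids Character vector of ids that must be present.
#' @return Record tibble of representatives (file order: cluster order,
#'   then appended anchors).
#' @export
cluster_representatives <- function(clusters, records, anchor_ids = character()) {
  reps <- unique(clusters$representative_id)
  missing <- setdiff(anchor_ids, records$id)
  if (length(missing)) {
    stop("anchor id(s) not in records: ", paste(missing, collapse = ", "))
  }
  ids <- c(reps, setdiff(anchor_ids, reps))
  records[match(ids, records$id), , drop = FALSE]
}
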