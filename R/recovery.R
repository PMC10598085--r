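#' Recovery metrics of a pipeline run against planted ground truth
#'
#' Confusion/accuracy summary per pipeline stage, computed from a
#' simulation's truth table and the corresponding [run_pipeline()] result:
#'
#' * `detection_sensitivity`: detected family records / true family
#'   records (decoys never enter the denominator);
#' * `decoy_false_positives`: decoy records among the hits (count);
#' * `clustering_purity`: member-weighted majority-lineage fraction over
#'   clusters;
#' * `group_accuracy`, `type_accuracy`: fraction of gene representatives
#'   whose group / type assignment matches truth.  Predicted type labels
#'   are matched one-to-one to planted lineages by maximal overlap first
#'   (labels such as `t1` are arbitrary clade numberings);
#' * `architecture_match_rate`: exact architecture-string matches after
#'   mapping each discovered novel domain to the planted domain it
#'   overlaps most;
#' * `activity_accuracy`: predicted activity vs planted truth.
#'
#' @param truth Truth tibble from [simulate_dataset()] (or the whole
#'   `clp1_sim`, which also carries the planted domain coordinates).
#' @param result A `clp1_pipeline` from [run_pipeline()].
#' @param truth_domains Planted domain-coordinate tibble (taken from the
#'   `clp1_sim` automatically when `truth` is one).
#' @return Tibble with `metric`, `value`, `n` (denominator).
#' @export
expected_recovery_report <- function(truth, result, truth_domains = NULL) {
  if (inherits(truth, "clp1_sim")) {
    truth_domains <- truth$truth_domains
    truth <- truth$truth
  }
  unknown <- setdiff(result$hits$target_id, truth$id)
  if (length(unknown) > 0) {
    stop("pipeline ids absent from truth: ", paste(unknown, collapse = ", "))
  }
  family_ids <- truth$id[!truth$is_decoy]
  decoy_ids <- truth$id[truth$is_decoy]
  detected <- result$hits$target_id
  sens <- length(intersect(detected, family_ids)) / length(family_ids)
  fp <- length(intersect(detected, decoy_ids))

  gene_truth <- truth[!truth$is_decoy & is.na(truth$isoform_parent), ,
                      drop = FALSE]
  calls <- result$calls[result$calls$protein_id %in% gene_truth$id, ,
                        drop = FALSE]
  tr <- gene_truth[match(calls$protein_id, gene_truth$id), , drop = FALSE]

  purity <- NA_real_
  if (!is.null(result$clusters)) {
    lin <- truth$lineage[match(result$clusters$member_id, truth$id)]
    purity <- result$clusters |>
      dplyr::mutate(lineage = lin) |>
      dplyr::group_by(.data$cluster) |>
      dplyr::summarise(n = dplyr::n(),
                       maj = max(table(.data$lineage)), .groups = "drop") |>
      dplyr::summarise(p = sum(.data$maj) / sum(.data$n)) |>
      dplyr::pull(.data$p)
  }

  group_acc <- mean(calls$group == tr$group)

  # one-to-one map: predicted type label -> planted lineage, by overlap
  type_acc <- NA_real_
  typed_truth <- !is.na(tr$lineage) & tr$lineage %in%
    names(which(table(gene_truth$lineage[!is.na(gene_truth$lineage)]) >= 2))
  if (any(!is.na(calls$type_label))) {
    # type labels are only unique within a group; key on both
    pred_key <- paste(calls$group, calls$type_label)
    pred_key[is.na(calls$type_label)] <- NA
    ov <- table(pred_key[!is.na(pred_key)], tr$lineage[!is.na(pred_key)])
    map <- character(0)
    remaining <- ov
    while (length(remaining) > 0 && max(remaining) > 0) {
      best <- which(remaining == max(remaining), arr.ind = TRUE)[1, ]
      map[rownames(remaining)[best[1]]] <- colnames(remaining)[best[2]]
      remaining <- remaining[-best[1], -best[2], drop = FALSE]
    }
    predicted_lineage <- unname(map[pred_key])
    type_acc <- mean(!is.na(predicted_lineage[typed_truth]) &
                       predicted_lineage[typed_truth] ==
                         tr$lineage[typed_truth])
  } else if (!any(typed_truth)) {
    type_acc <- 1
  } else {
    type_acc <- 0
  }

  # architecture: rename discovered novel domains by majority overlap with
  # the planted domains, then compare strings exactly
  arch_map <- novel_domain_map(result, truth_domains)
  pred_arch <- vapply(calls$protein_id, function(id) {
    a <- result$architectures[[id]]
    for (nm in names(arch_map)) {
      a <- gsub(nm, arch_map[[nm]], a, fixed = TRUE)
    }
    a
  }, character(1))
  arch_acc <- mean(pred_arch == tr$architecture)

  truth_act <- ifelse(tr$active, "active", "inactive")
  act_acc <- mean(calls$predicted_activity == truth_act)

  tibble::tibble(
    metric = c("detection_sensitivity", "decoy_false_positives",
               "clustering_purity", "group_accuracy", "type_accuracy",
               "architecture_match_rate", "activity_accuracy"),
    value = c(sens, fp, purity, group_acc, type_acc, arch_acc, act_acc),
    n = c(length(family_ids), length(decoy_ids),
          if (is.null(result$clusters)) NA_integer_ else
            nrow(result$clusters),
          nrow(calls), sum(typed_truth), nrow(calls), nrow(calls)))
}

# Map NDOMk -> planted domain name by majority coordinate overlap.
novel_domain_map <- function(result, truth_domains = NULL) {
  novel <- result$novel
  if (is.null(novel) || nrow(novel) == 0) return(character(0))
  sim_domains <- truth_domains
  if (is.null(sim_domains)) return(character(0))
  out <- character(0)
  for (nm in unique(novel$domain_name)) {
    seg <- novel[novel$domain_name == nm, ]
    votes <- character(0)
    for (i in seq_len(nrow(seg))) {
      td <- sim_domains[sim_domains$id == seg$protein_id[[i]], , drop = FALSE]
      if (nrow(td) == 0) next
      ov <- pmin(td$end, seg$end[[i]]) - pmax(td$start, seg$start[[i]]) + 1
      if (max(ov) > 0) votes <- c(votes, td$domain[which.max(ov)])
    }
    if (length(votes) > 0) {
      out[nm] <- names(sort(table(votes), decreasing = TRUE))[1]
    }
  }
  out
}
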