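#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pipeline result
#'
#' One row per classified gene representative: the family-call table
#' (species, decorated name, group, type, architecture, kinase-domain
#' length, motif count, predicted activity).
#'
#' @param x A `clp1_pipeline`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.clp1_pipeline <- function(x, ...) {
  dplyr::select(x$calls, -"motifs")
}

#' One-row summary of a pipeline run
#'
#' @param x A `clp1_pipeline`.
#' @param ... Unused.
#' @return A one-row tibble: record/hit/gene counts, species with members,
#'   mean and population SD of genes per species, novel-domain count, and
#'   counts of predicted-active/inactive proteins.
#' @export
glance.clp1_pipeline <- function(x, ...) {
  tibble::tibble(
    n_records = nrow(x$records),
    n_family_records = nrow(x$hits),
    n_genes = nrow(x$members),
    n_species_with_member = sum(x$inventory$n_genes > 0),
    mean_genes_per_species = attr(x$inventory, "mean_genes"),
    sd_genes_per_species = attr(x$inventory, "sd_genes"),
    n_novel_domains = dplyr::n_distinct(x$novel$domain_name),
    n_predicted_active = sum(x$calls$predicted_activity == "active"),
    n_predicted_inactive = sum(x$calls$predicted_activity == "inactive"))
}

#' Plot a per-species inventory
#'
#' Histogram of family-gene counts per species, faceted by taxon when
#' taxon assignments are available (the Fig-1a style distribution).
#'
#' @param object A `clp1_inventory` (from [build_inventory()]).
#' @param records Optional record tibble supplying species -> taxon.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.clp1_inventory <- function(object, records = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(records) && "taxon" %in% names(records)) {
    df$taxon <- records$taxon[match(df$species, records$species)]
  } else {
    df$taxon <- "all"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_genes)) +
    ggplot2::geom_bar() +
    ggplot2::facet_wrap(~taxon) +
    ggplot2::labs(x = "Clp1 family genes per species",
                  y = "number of species") +
    ggplot2::theme_minimal()
}

#' Plot domain architectures of classified proteins
#'
#' Segment plot of the assembled domain hits along each protein (the
#' Fig-2/3 style architecture panel), ordered by group and type.
#'
#' @param object A `clp1_pipeline`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.clp1_pipeline <- function(object, ...) {
  ord <- dplyr::arrange(object$calls, .data$group, .data$type_label,
                        .data$protein_name)
  hits <- object$domain_hits |>
    dplyr::mutate(protein = factor(.data$protein_id, levels = ord$protein_id))
  lens <- tibble::tibble(
    protein = factor(object$members$id, levels = ord$protein_id),
    len = nchar(object$members$sequence))
  ggplot2::ggplot(hits) +
    ggplot2::geom_segment(
      data = lens,
      ggplot2::aes(x = 1, xend = .data$len, y = .data$protein,
                   yend = .data$protein),
      linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end, y = .data$protein,
                   yend = .data$protein, colour = .data$domain_name),
      linewidth = 3) +
    ggplot2::labs(x = "position (aa)", y = NULL, colour = "domain") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
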