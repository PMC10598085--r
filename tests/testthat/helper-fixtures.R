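# Shared fixtures: everything is built in code at test time.

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AA_LETTERS, n, replace = TRUE), collapse = "")
}

# substitute exactly k positions (each to a different residue)
substitute_k <- function(sequence, k, seed = 1) {
  set.seed(seed)
  res <- strsplit(sequence, "")[[1]]
  pos <- sample(length(res), k)
  res[pos] <- vapply(res[pos], function(a) sample(setdiff(AA_LETTERS, a), 1),
                     character(1))
  paste(res, collapse = "")
}

records_tbl <- function(ids, seqs, species = NA_character_) {
  tibble::tibble(id = ids, species = species, taxon = NA_character_,
                 sequence = seqs, description = "", is_isoform = FALSE)
}

write_tmp_fasta <- function(lines) {
  f <- withr::local_tempfile(fileext = ".fasta",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# Independent local-alignment score oracle (Biostrings, C code unrelated
# to the package's aligner).
biostrings_local_score <- function(q, t) {
  Biostrings::pairwiseAlignment(q, t, type = "local",
                                substitutionMatrix = "BLOSUM62",
                                gapOpening = 11, gapExtension = 1,
                                scoreOnly = TRUE)
}

biostrings_global_score <- function(q, t) {
  Biostrings::pairwiseAlignment(q, t, type = "global",
                                substitutionMatrix = "BLOSUM62",
                                gapOpening = 11, gapExtension = 1,
                                scoreOnly = TRUE)
}

empty_hits_tbl <- function() {
  tibble::tibble(protein_id = character(), domain_name = character(),
                 start = integer(), end = integer(), score = numeric(),
                 evalue = numeric(), origin = character())
}

# small simulated world used by pipeline-level tests (4 species, light)
small_sim <- function(seed = 5, ...) {
  simulate_dataset(simulation_config(n_species = 4, n_decoys = 2,
                                     seed = seed, ...))
}
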