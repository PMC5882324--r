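# small references used across tests
ref_small <- function(seed = 1, ...) {
  simulate_reference_pair(n_homolog_pairs = 25, n_unique_per_species = 5,
                          median_length = 400, min_length = 300,
                          seed = seed, ...)
}

# hand-built dual reference from explicit transcript tables; homology empty
manual_ref <- function(seq_a, seq_b = character(0)) {
  ta <- tibble::tibble(species = "A",
                       gene_id = sprintf("GA%04d", seq_along(seq_a)),
                       transcript_id = sprintf("TA%04d", seq_along(seq_a)),
                       length = nchar(seq_a), sequence = unname(seq_a))
  tb <- tibble::tibble(species = "B",
                       gene_id = sprintf("GB%04d", seq_along(seq_b)),
                       transcript_id = sprintf("TB%04d", seq_along(seq_b)),
                       length = nchar(seq_b), sequence = unname(seq_b))
  structure(
    list(transcripts = dplyr::bind_rows(ta, tb),
         homology = tibble::tibble(gene_a = character(0),
                                   gene_b = character(0),
                                   transcript_a = character(0),
                                   transcript_b = character(0),
                                   divergence = numeric(0),
                                   block_start = integer(0),
                                   block_length = integer(0)),
         unique_a = ta$gene_id, unique_b = tb$gene_id,
         params = list(divergence = NA_real_)),
    class = "dual_reference")
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
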